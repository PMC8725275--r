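#' Genus-level taxon count table with per-sample read accounting
#'
#' A `taxon_table` bundles the two tables every stage of the pipeline consumes:
#' a wide tibble of non-negative integer counts (one row per sample, one column
#' per genus, first column `sample_id`) and a read-accounting tibble with the
#' per-sample `total_reads`, `filtered_reads`, `mapped_reads` and `empty_reads`
#' coming out of the sequencing QC.
#'
#' Invariants enforced at construction: unique sample and taxon identifiers,
#' all counts non-negative and finite, `filtered_reads <= total_reads`,
#' `mapped_reads <= total_reads` and `empty_reads <= total_reads`. Mapped reads
#' are counted against the raw stream, so `mapped_reads` may legitimately
#' exceed `filtered_reads`.
#'
#' @param counts Data frame with a `sample_id` column followed by one numeric
#'   column per genus.
#' @param read_stats Data frame with columns `sample_id`, `total_reads`,
#'   `filtered_reads`, `mapped_reads`, `empty_reads`; one row per sample of
#'   `counts`.
#' @return An object of class `taxon_table`: a list with tibbles `counts` and
#'   `read_stats`.
#' @examples
#' counts <- tibble::tibble(
#'   sample_id = c("s1", "s2"),
#'   Lactobacillus = c(900L, 50L),
#'   Gardnerella = c(100L, 950L)
#' )
#' stats <- tibble::tibble(
#'   sample_id = c("s1", "s2"), total_reads = c(3000L, 3200L),
#'   filtered_reads = c(1000L, 1000L), mapped_reads = c(1250L, 1300L),
#'   empty_reads = c(60L, 80L)
#' )
#' taxon_table(counts, stats)
#' @export
taxon_table <- function(counts, read_stats) {
  counts <- as_tibble(counts)
  read_stats <- as_tibble(read_stats)
  if (names(counts)[1] != "sample_id") {
    abort("`counts` must have `sample_id` as its first column.")
  }
  need <- c("sample_id", "total_reads", "filtered_reads", "mapped_reads",
            "empty_reads")
  missing_cols <- setdiff(need, names(read_stats))
  if (length(missing_cols) > 0) {
    abort(paste0("`read_stats` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- structure(
    list(counts = counts, read_stats = read_stats[need]),
    class = "taxon_table"
  )
  validate_taxon_table(out)
}

validate_taxon_table <- function(x) {
  counts <- x$counts
  stats <- x$read_stats
  sample_ids <- counts$sample_id
  taxa <- setdiff(names(counts), "sample_id")
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample_id: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(taxa)) {
    abort(paste0("Duplicate taxon column: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  if (length(taxa) == 0) abort("`counts` has no taxon columns.")
  mat <- as.matrix(counts[taxa])
  if (!is.numeric(mat)) abort("Taxon counts must be numeric.")
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Negative or non-finite count at sample '%s', taxon '%s'.",
      sample_ids[bad[1, 1]], taxa[bad[1, 2]]
    ))
  }
  if (!setequal(stats$sample_id, sample_ids) ||
      length(stats$sample_id) != length(sample_ids)) {
    abort("`read_stats` must cover exactly the samples of `counts`.")
  }
  for (col in c("total_reads", "filtered_reads", "mapped_reads",
                "empty_reads")) {
    v <- stats[[col]]
    if (any(!is.finite(v) | v < 0)) {
      abort(sprintf("`read_stats$%s` must be non-negative and finite.", col))
    }
  }
  over <- stats$filtered_reads > stats$total_reads |
    stats$mapped_reads > stats$total_reads |
    stats$empty_reads > stats$total_reads
  if (any(over)) {
    abort(sprintf(
      "Read accounting exceeds total_reads for sample '%s'.",
      stats$sample_id[which(over)[1]]
    ))
  }
  x
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf(
    "<taxon_table> %d samples x %d taxa\n",
    nrow(x$counts), length(taxon_names(x))
  ))
  print(head(x$counts, 5))
  invisible(x)
}

#' Accessors for a taxon_table
#'
#' `taxon_names()` and `sample_names()` return the ordered identifiers;
#' `count_matrix()` returns the counts as a numeric matrix with samples as
#' rows (rownames = sample ids).
#'
#' @param x A [taxon_table()].
#' @return Character vector or numeric matrix.
#' @export
taxon_names <- function(x) setdiff(names(x$counts), "sample_id")

#' @rdname taxon_names
#' @export
sample_names <- function(x) x$counts$sample_id

#' @rdname taxon_names
#' @export
count_matrix <- function(x) {
  m <- as.matrix(x$counts[taxon_names(x)])
  rownames(m) <- x$counts$sample_id
  m
}

#' Read and write taxon tables
#'
#' The on-disk representation is two UTF-8 tab-separated files: the count
#' table (first column `sample_id`, remaining columns genera) and a read-stats
#' sidecar keyed by `sample_id`. A BIOM file can be imported instead of the
#' count TSV when the biomformat package is available; read stats always come
#' from the TSV sidecar.
#'
#' @param path Path of the count table (TSV, or BIOM for
#'   `format = "biom"`).
#' @param read_stats_path Path of the read-stats sidecar TSV. Defaults to
#'   `<path>.read_stats.tsv` next to the count table.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return `read_taxon_table()` returns a validated [taxon_table()];
#'   `write_taxon_table()` returns `path` invisibly.
#' @export
read_taxon_table <- function(path, read_stats_path = NULL,
                             format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(read_stats_path)) {
    read_stats_path <- paste0(path, ".read_stats.tsv")
  }
  if (!file.exists(read_stats_path)) {
    abort(sprintf("Read-stats sidecar not found: %s", read_stats_path))
  }
  counts <- switch(format,
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    biom = read_biom_counts(path)
  )
  stats <- readr::read_tsv(read_stats_path, show_col_types = FALSE,
                           progress = FALSE)
  taxon_table(counts, stats)
}

read_biom_counts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("BIOM import requires the biomformat package.")
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # taxa x samples in BIOM
  tibble(sample_id = colnames(m)) |>
    dplyr::bind_cols(as_tibble(t(m)))
}

#' @rdname read_taxon_table
#' @param x A [taxon_table()] to write.
#' @export
write_taxon_table <- function(x, path, read_stats_path = NULL) {
  if (is.null(read_stats_path)) {
    read_stats_path <- paste0(path, ".read_stats.tsv")
  }
  readr::write_tsv(x$counts, path, progress = FALSE)
  readr::write_tsv(x$read_stats, read_stats_path, progress = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `sample_type` (EF or EB),
#' `outcome` (LB, NP, BP, CM or UNKNOWN), `is_blank` (logical) and `run_id`.
#' Blanks must carry outcome UNKNOWN; when `table` is supplied every sample of
#' the table must have exactly one metadata row.
#'
#' @param path TSV file path.
#' @param table Optional [taxon_table()] to validate against.
#' @return A tibble of validated metadata.
#' @export
read_sample_meta <- function(path, table = NULL) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_meta(meta, table)
}

#' @rdname read_sample_meta
#' @param meta Metadata data frame to validate.
#' @export
validate_sample_meta <- function(meta, table = NULL) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "sample_type", "outcome", "is_blank", "run_id")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Metadata sample_id values must be unique.")
  }
  bad_type <- setdiff(unique(meta$sample_type), c("EF", "EB"))
  if (length(bad_type) > 0) {
    abort(paste0("Unknown sample_type: ", paste(bad_type, collapse = ", ")))
  }
  bad_out <- setdiff(unique(meta$outcome), c("LB", "NP", "BP", "CM", "UNKNOWN"))
  if (length(bad_out) > 0) {
    abort(paste0("Unknown outcome: ", paste(bad_out, collapse = ", ")))
  }
  meta$is_blank <- as.logical(meta$is_blank)
  if (any(meta$is_blank & meta$outcome != "UNKNOWN")) {
    abort("Blank samples must have outcome UNKNOWN.")
  }
  if (!is.null(table)) {
    ids <- sample_names(table)
    if (!all(ids %in% meta$sample_id)) {
      abort("Every sample in the table needs a metadata row.")
    }
  }
  meta
}

#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(as_tibble(meta), path, progress = FALSE)
  invisible(path)
}

# Restrict a taxon_table to given samples and/or taxa, preserving order.
subset_table <- function(x, samples = NULL, taxa = NULL) {
  counts <- x$counts
  stats <- x$read_stats
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, counts$sample_id)
    if (length(missing_s) > 0) {
      abort(paste0("Unknown sample(s): ", paste(missing_s, collapse = ", ")))
    }
    counts <- counts[match(samples, counts$sample_id), ]
    stats <- stats[match(samples, stats$sample_id), ]
  }
  if (!is.null(taxa)) {
    missing_t <- setdiff(taxa, names(counts))
    if (length(missing_t) > 0) {
      abort(paste0("Unknown taxon(s): ", paste(missing_t, collapse = ", ")))
    }
    counts <- counts[c("sample_id", taxa)]
  }
  structure(list(counts = counts, read_stats = stats), class = "taxon_table")
}
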