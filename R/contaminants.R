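#' Score taxa for blank-prevalence contamination
#'
#' Implements prevalence-based contaminant identification against blank
#' controls: a taxon is "present" in a sample when its relative abundance
#' strictly exceeds `presence_threshold` (default 0, i.e. any non-zero
#' count), and the score is the one-sided Fisher exact p-value for enrichment
#' of presence in blanks versus biological samples (a chi-square variant is
#' available via `method`). A taxon is called contaminant when its score is
#' below `alpha` and its blank prevalence exceeds its prevalence in
#' biological samples.
#'
#' @param table A [taxon_table()] containing blanks and biological samples.
#' @param meta Sample metadata with `is_blank`.
#' @param presence_threshold Relative-abundance presence cutoff (strict).
#' @param alpha Significance level for the contaminant call.
#' @param method `"fisher"` (exact, default) or `"chisq"`.
#' @return Tibble with one row per taxon: `taxon_id`, `prevalence_in_blanks`,
#'   `prevalence_in_samples`, `score`, `is_contaminant`. With no blanks a
#'   zero-row tibble is returned with a warning (the stage is skipped).
#' @export
score_contaminants <- function(table, meta, presence_threshold = 0,
                               alpha = 0.05,
                               method = c("fisher", "chisq")) {
  method <- match.arg(method)
  meta <- as_tibble(meta)
  m <- count_matrix(table)
  rel <- m / pmax(rowSums(m), 1)
  blanks <- meta$sample_id[meta$is_blank]
  bio <- meta$sample_id[!meta$is_blank]
  blanks <- intersect(blanks, rownames(rel))
  bio <- intersect(bio, rownames(rel))
  if (length(blanks) == 0) {
    warn("No blank samples: contaminant identification skipped.")
    return(tibble(taxon_id = character(), prevalence_in_blanks = numeric(),
                  prevalence_in_samples = numeric(), score = numeric(),
                  is_contaminant = logical()))
  }
  if (length(blanks) < 2 || length(bio) < 2) {
    abort("Need at least 2 blanks and 2 biological samples.")
  }
  present <- rel > presence_threshold
  n_b <- length(blanks)
  n_s <- length(bio)
  purrr::map_dfr(colnames(m), function(taxon) {
    k_b <- sum(present[blanks, taxon])
    k_s <- sum(present[bio, taxon])
    tab <- matrix(c(k_b, n_b - k_b, k_s, n_s - k_s), nrow = 2, byrow = TRUE)
    p <- if (method == "fisher") {
      fisher.test(tab, alternative = "greater")$p.value
    } else {
      suppressWarnings(chisq.test(tab)$p.value)
    }
    prev_b <- k_b / n_b
    prev_s <- k_s / n_s
    tibble(
      taxon_id = taxon, prevalence_in_blanks = prev_b,
      prevalence_in_samples = prev_s, score = p,
      is_contaminant = p < alpha && prev_b > prev_s
    )
  })
}

#' Dual abundance-prevalence taxon filter
#'
#' Retains a taxon if it reaches at least 1% relative abundance in at least
#' 5% of samples, or at least 0.1% relative abundance in at least 15% of
#' samples (all thresholds inclusive). Sample fractions should be computed
#' over detectable biological samples only; pass those ids via `samples`.
#'
#' @param table A [taxon_table()].
#' @param samples Optional sample ids defining the denominator (default all).
#' @param abund1,prev1 First criterion: abundance / sample-fraction cutoffs.
#' @param abund2,prev2 Second criterion.
#' @return Tibble `taxon_id`, `frac_ge_abund1`, `frac_ge_abund2`, `retained`.
#' @export
abundance_filter <- function(table, samples = NULL,
                             abund1 = 0.01, prev1 = 0.05,
                             abund2 = 0.001, prev2 = 0.15) {
  m <- count_matrix(table)
  if (!is.null(samples)) m <- m[intersect(samples, rownames(m)), ,
                                drop = FALSE]
  if (nrow(m) == 0) abort("No samples available for the abundance filter.")
  totals <- rowSums(m)
  if (any(totals == 0)) {
    warn("Samples with zero total counts are excluded from the filter.")
    m <- m[totals > 0, , drop = FALSE]
  }
  rel <- m / rowSums(m)
  f1 <- colMeans(rel >= abund1)
  f2 <- colMeans(rel >= abund2)
  tibble(
    taxon_id = colnames(m),
    frac_ge_abund1 = unname(f1),
    frac_ge_abund2 = unname(f2),
    retained = unname(f1 >= prev1 | f2 >= prev2)
  )
}

#' Remove kitome-listed genera from a taxon list
#'
#' Case-insensitive set difference preserving the input order. The exclusion
#' list also serves for genera not colonising humans; supply any plain list
#' of genus names.
#'
#' @param taxa Character vector of genus names.
#' @param exclusions Genus names to remove (default shipped kitome list).
#' @return Filtered character vector; warns when nothing survives.
#' @export
apply_kitome_exclusion <- function(taxa,
                                   exclusions = default_kitome_exclusions()) {
  keep <- !(tolower(taxa) %in% tolower(exclusions))
  out <- taxa[keep]
  if (length(out) == 0 && length(taxa) > 0) {
    warn("Kitome exclusion removed every taxon; the panel is empty.")
  }
  out
}

#' Run the full taxon filter chain
#'
#' Applies, in order: blank-prevalence contaminant removal
#' ([score_contaminants()]), the dual abundance-prevalence filter
#' ([abundance_filter()]) over detectable biological samples, and kitome
#' exclusion ([apply_kitome_exclusion()]). Each removal is attributed to the
#' first stage that drops the taxon, so the three removal lists are disjoint
#' and `panel_out` is the input minus their union.
#'
#' @param table A [taxon_table()].
#' @param meta Sample metadata.
#' @param detectable_ids Sample ids of detectable biological samples used as
#'   the abundance-filter denominator (default: all non-blank samples).
#' @param exclusions Kitome exclusion list.
#' @param presence_threshold,alpha,method Passed to [score_contaminants()].
#' @return A list of class `filter_report` with elements `taxa_in`,
#'   `removed_contaminant`, `removed_low_abundance`, `removed_kitome`,
#'   `panel_out`, plus the per-stage tables `contaminant_calls` and
#'   `abundance_table`.
#' @export
filter_taxa <- function(table, meta, detectable_ids = NULL,
                        exclusions = default_kitome_exclusions(),
                        presence_threshold = 0, alpha = 0.05,
                        method = c("fisher", "chisq")) {
  meta <- as_tibble(meta)
  taxa_in <- taxon_names(table)
  if (is.null(detectable_ids)) {
    detectable_ids <- meta$sample_id[!meta$is_blank]
  }
  calls <- score_contaminants(table, meta, presence_threshold, alpha,
                              match.arg(method))
  removed_contaminant <- if (nrow(calls)) {
    calls$taxon_id[calls$is_contaminant]
  } else {
    character()
  }
  left1 <- setdiff(taxa_in, removed_contaminant)

  ab <- abundance_filter(subset_table(table, taxa = left1),
                         samples = detectable_ids)
  removed_low <- ab$taxon_id[!ab$retained]
  left2 <- setdiff(left1, removed_low)

  left3 <- apply_kitome_exclusion(left2, exclusions)
  removed_kitome <- setdiff(left2, left3)

  structure(
    list(
      taxa_in = taxa_in,
      removed_contaminant = removed_contaminant,
      removed_low_abundance = removed_low,
      removed_kitome = removed_kitome,
      panel_out = left3,
      contaminant_calls = calls,
      abundance_table = ab
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d taxa in -> %d retained (contaminant %d, low-abundance %d, kitome %d)\n",
    length(x$taxa_in), length(x$panel_out), length(x$removed_contaminant),
    length(x$removed_low_abundance), length(x$removed_kitome)
  ))
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` from [filter_taxa()].
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    report[c("taxa_in", "removed_contaminant", "removed_low_abundance",
             "removed_kitome", "panel_out")],
    path, pretty = TRUE
  )
  invisible(path)
}

#' Assemble per-sample-type panels and their overlap
#'
#' Combines filtered panels (e.g. from [filter_taxa()] of each sample type)
#' into a [panel_config()], reporting shared and type-specific genera. Errors
#' if the anchor genus is missing from any panel, since the downstream
#' Lactobacillus-difference statistic would be undefined.
#'
#' @param panels Named list of character vectors (e.g.
#'   `list(EF = ..., EB = ...)`).
#' @param lactobacillus Anchor genus name.
#' @param ... Passed to [panel_config()].
#' @return A [panel_config()] with an extra `overlap` element: tibble
#'   `genus`, `in_types` (comma-separated types containing it).
#' @export
build_panels <- function(panels, lactobacillus = "Lactobacillus", ...) {
  cfg <- panel_config(panels, lactobacillus = lactobacillus, ...)
  all_genera <- unique(unlist(panels))
  cfg$overlap <- tibble(
    genus = all_genera,
    in_types = unname(vapply(all_genera, function(g) {
      paste(names(panels)[vapply(panels, function(p) g %in% p, logical(1))],
            collapse = ",")
    }, character(1)))
  )
  cfg
}

#' Shared and type-specific panel sizes
#'
#' @param cfg A [panel_config()].
#' @return Tibble with one row per sample type plus a `shared` row, columns
#'   `set` and `n_taxa`.
#' @export
panel_sizes <- function(cfg) {
  sizes <- tibble(
    set = names(cfg$panel_taxa),
    n_taxa = unname(vapply(cfg$panel_taxa, length, integer(1)))
  )
  shared <- Reduce(intersect, cfg$panel_taxa)
  dplyr::bind_rows(sizes, tibble(set = "shared", n_taxa = length(shared)))
}
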