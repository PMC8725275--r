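#' Per-sample sequencing quality metrics
#'
#' Computes the three quality parameters used to separate detectable-biomass
#' samples from blank-like, low-biomass ones:
#' * `empty_read_pct` = 100 * empty_reads / total_reads,
#' * `dispersion_index` = variance / mean of the sample's per-taxon counts
#'   (variance with the n-1 denominator; 0 for an all-zero profile),
#' * `fm_ratio` = filtered_reads / mapped_reads (set `invert = TRUE` to use
#'   mapped / filtered if your pipeline reports the inverse).
#'
#' Samples with zero mapped reads get `fm_ratio = NA` with a warning and are
#' treated as not detectable downstream.
#'
#' @param table A [taxon_table()].
#' @param invert Use mapped/filtered instead of filtered/mapped.
#' @return Tibble with columns `sample_id`, `empty_read_pct`,
#'   `dispersion_index`, `fm_ratio`.
#' @export
compute_quality <- function(table, invert = FALSE) {
  stats <- table$read_stats
  m <- count_matrix(table)
  disp <- apply(m, 1, function(row) {
    mu <- mean(row)
    if (mu == 0) 0 else var(row) / mu
  })
  num <- if (invert) stats$mapped_reads else stats$filtered_reads
  den <- if (invert) stats$filtered_reads else stats$mapped_reads
  fm <- ifelse(den == 0, NA_real_, num / den)
  if (anyNA(fm)) {
    warn(sprintf(
      "%d sample(s) have zero mapped reads; fm_ratio is NA and they will be classified not-detectable.",
      sum(is.na(fm))
    ))
  }
  tibble(
    sample_id = stats$sample_id,
    empty_read_pct = 100 * stats$empty_reads / stats$total_reads,
    dispersion_index = unname(disp),
    fm_ratio = fm
  )
}

#' Classify samples as detectable or not-detectable biomass
#'
#' A sample is detectable when its filtered/mapped read ratio strictly
#' exceeds the sample-type threshold (default 0.65 for endometrial fluid,
#' 0.7 for endometrial biopsy); samples exactly at the threshold are not
#' detectable. Only detectable biological samples proceed to downstream
#' analysis stages.
#'
#' @param quality Output of [compute_quality()].
#' @param meta Sample metadata (needs `sample_id`, `sample_type`).
#' @param thresholds Named thresholds per sample type.
#' @return `quality` with `sample_type` and logical `detectable` appended.
#' @export
classify_detectable <- function(quality, meta,
                                thresholds = c(EF = 0.65, EB = 0.7)) {
  meta <- as_tibble(meta)
  out <- left_join(as_tibble(quality),
                   meta[c("sample_id", "sample_type")], by = "sample_id")
  unknown <- setdiff(unique(out$sample_type), names(thresholds))
  if (length(unknown) > 0 || anyNA(out$sample_type)) {
    abort(paste0("No detectability threshold for sample type: ",
                 paste(c(unknown, if (anyNA(out$sample_type)) "<missing>"),
                       collapse = ", ")))
  }
  thr <- unname(thresholds[out$sample_type])
  out$detectable <- !is.na(out$fm_ratio) & out$fm_ratio > thr
  out
}

#' Principal-component ordination of quality metrics
#'
#' PCA of the z-standardised quality features (`empty_read_pct`,
#' `dispersion_index`, `fm_ratio`), used to check that low-biomass samples
#' cluster with blank controls. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so orientations are
#' reproducible.
#'
#' @param quality Output of [compute_quality()] (or
#'   [classify_detectable()]); needs at least 3 samples. Samples with an `NA`
#'   feature are dropped with a warning.
#' @return Tibble `sample_id`, `PC1`, `PC2`, ... with attributes
#'   `explained_variance` (per component) and `loadings`.
#' @export
qc_ordination <- function(quality) {
  quality <- as_tibble(quality)
  feats <- c("empty_read_pct", "dispersion_index", "fm_ratio")
  x <- quality[c("sample_id", feats)]
  drop <- !stats::complete.cases(x[feats])
  if (any(drop)) {
    warn(sprintf("Dropping %d sample(s) with missing quality features.",
                 sum(drop)))
    x <- x[!drop, ]
  }
  if (nrow(x) < 3) abort("Ordination needs at least 3 complete samples.")
  m <- as.matrix(x[feats])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant quality feature(s): ",
                 paste(feats[sds == 0], collapse = ", ")))
  }
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(p$x, 2, flip, `*`)
  rot <- sweep(p$rotation, 2, flip, `*`)
  out <- dplyr::bind_cols(tibble(sample_id = x$sample_id),
                          as_tibble(scores))
  attr(out, "explained_variance") <- p$sdev^2 / sum(p$sdev^2)
  attr(out, "loadings") <- rot
  out
}

#' Plot the QC ordination coloured by biomass class
#'
#' @param scores Output of [qc_ordination()].
#' @param meta Sample metadata; blanks and (if present) the simulated
#'   `biomass_class` are used for colouring, falling back to outcome.
#' @return A ggplot object.
#' @export
plot_qc_ordination <- function(scores, meta) {
  meta <- as_tibble(meta)
  colour_var <- if ("biomass_class" %in% names(meta)) "biomass_class" else
    "outcome"
  df <- left_join(as_tibble(scores), meta, by = "sample_id")
  ev <- attr(scores, "explained_variance")
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data[[colour_var]],
                                   shape = .data$is_blank)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * ev[2]),
      colour = colour_var, shape = "blank"
    ) +
    ggplot2::theme_minimal()
}
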