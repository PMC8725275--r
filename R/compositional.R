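#' Centred log-ratio transform of a composition
#'
#' `clr(x) = log(x / geometric_mean(x))`; the result sums to zero and is
#' invariant to rescaling of `x`. A pseudocount (default 1, added to counts
#' before closure) handles zeros; with `pseudocount = 0` all parts must be
#' strictly positive.
#'
#' @param x Numeric vector of counts or proportions.
#' @param pseudocount Non-negative value added to every part.
#' @return Numeric vector of clr values (same length, sums to 0).
#' @examples
#' clr(c(1, 4, 16), pseudocount = 0) # -1.386, 0, 1.386
#' @export
clr <- function(x, pseudocount = 1) {
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  x <- x + pseudocount
  if (any(x <= 0)) {
    abort("clr undefined: non-positive parts remain (use a pseudocount > 0).")
  }
  lx <- log(x)
  lx - mean(lx)
}

#' clr-transform a taxon table over a panel
#'
#' Restricts the count table to the panel genera of its sample type (taxa not
#' observed in a sample simply carry count 0) and applies [clr()] per sample.
#'
#' @param table A [taxon_table()].
#' @param panel Character vector of panel genera, or a [panel_config()]
#'   together with `sample_type`.
#' @param sample_type Needed when `panel` is a [panel_config()].
#' @param samples Optional sample ids to keep (e.g. detectable biological
#'   samples).
#' @param pseudocount Added to panel counts before closure (default 1).
#' @return A `clr_matrix`: tibble `sample_id` + one column per panel genus,
#'   with attributes `pseudocount`, `zscored = FALSE` and `panel`.
#' @export
clr_transform <- function(table, panel, sample_type = NULL, samples = NULL,
                          pseudocount = 1) {
  if (inherits(panel, "panel_config")) {
    if (is.null(sample_type)) {
      abort("Supply `sample_type` when `panel` is a panel_config.")
    }
    panel <- panel$panel_taxa[[sample_type]]
  }
  tt <- subset_table(table, samples = samples)
  m <- count_matrix(tt)
  missing_t <- setdiff(panel, colnames(m))
  if (length(missing_t) > 0) {
    # genera absent from the table enter as structural zeros
    zeros <- matrix(0, nrow(m), length(missing_t),
                    dimnames = list(rownames(m), missing_t))
    m <- cbind(m, zeros)
  }
  m <- m[, panel, drop = FALSE]
  vals <- t(apply(m, 1, clr, pseudocount = pseudocount))
  out <- dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(vals))
  new_clr_matrix(out, pseudocount = pseudocount, zscored = FALSE,
                 panel = panel)
}

new_clr_matrix <- function(tbl, pseudocount, zscored, panel) {
  structure(tbl, pseudocount = pseudocount, zscored = zscored, panel = panel,
            scale = "clr", class = c("clr_matrix", class(tibble())))
}

#' Analysis matrix for reference-range distance testing
#'
#' Builds the per-taxon value matrix the reference-range stage operates on.
#' On the default `"clr"` scale, detected counts are clr-transformed with the
#' pseudocount, and undetected entries (count 0) are assigned the value 0 on
#' the analysis scale — the convention for taxa not detected in a sample —
#' which places them at the compositional centre instead of an unbounded
#' negative log-ratio. On the `"relative"` scale undetected taxa are 0 by
#' construction.
#'
#' @inheritParams clr_transform
#' @param scale `"clr"` (default) or `"relative"`.
#' @return A tibble `sample_id` + panel columns with attributes `panel` and
#'   `scale`.
#' @export
refrange_matrix <- function(table, panel, sample_type = NULL, samples = NULL,
                            pseudocount = 1, scale = c("clr", "relative")) {
  scale <- match.arg(scale)
  if (scale == "relative") {
    return(relative_abundance(table, panel, sample_type, samples))
  }
  x <- clr_transform(table, panel, sample_type, samples,
                     pseudocount = pseudocount)
  panel_taxa <- attr(x, "panel")
  tt <- subset_table(table, samples = samples)
  m <- count_matrix(tt)
  tbl <- as_tibble(x)
  for (taxon in panel_taxa) {
    if (taxon %in% colnames(m)) {
      tbl[[taxon]][m[tbl$sample_id, taxon] == 0] <- 0
    } else {
      tbl[[taxon]] <- 0
    }
  }
  structure(tbl, panel = panel_taxa, scale = "clr",
            class = class(tibble()))
}

#' Panel-restricted relative abundances
#'
#' Closes the counts over the panel genera to proportions summing to 1 per
#' sample; undetected genera enter as 0. This is the bounded scale used by
#' default for reference-range distance testing: distances below the lower
#' bound cannot exceed the bound itself, so excess-abundance signals are not
#' masked by the unbounded negative tail that undetected taxa produce under
#' clr.
#'
#' @inheritParams clr_transform
#' @return A tibble `sample_id` + one column per panel genus with attributes
#'   `panel` and `scale = "relative"`.
#' @export
relative_abundance <- function(table, panel, sample_type = NULL,
                               samples = NULL) {
  if (inherits(panel, "panel_config")) {
    if (is.null(sample_type)) {
      abort("Supply `sample_type` when `panel` is a panel_config.")
    }
    panel <- panel$panel_taxa[[sample_type]]
  }
  tt <- subset_table(table, samples = samples)
  m <- count_matrix(tt)
  missing_t <- setdiff(panel, colnames(m))
  if (length(missing_t) > 0) {
    zeros <- matrix(0, nrow(m), length(missing_t),
                    dimnames = list(rownames(m), missing_t))
    m <- cbind(m, zeros)
  }
  m <- m[, panel, drop = FALSE]
  rel <- m / pmax(rowSums(m), 1)
  out <- dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(rel))
  structure(out, panel = panel, scale = "relative",
            class = class(tibble()))
}

clr_values <- function(x) {
  as.matrix(as_tibble(x)[attr(x, "panel")])
}

#' Z-score a clr matrix per taxon
#'
#' Standardises each taxon column to mean 0 and unit standard deviation
#' (sample sd, n-1 denominator) within a normalisation stratum, mitigating
#' between-run or between-sample-type scale differences before computing the
#' Lactobacillus-difference statistic. With `stratify_by = NULL` (default)
#' the whole matrix is one stratum; pass metadata and a column name (e.g.
#' `"run_id"`) to standardise within strata.
#'
#' @param x A `clr_matrix` from [clr_transform()].
#' @param meta Metadata tibble (needed only when stratifying).
#' @param stratify_by Metadata column defining strata, or `NULL`.
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return A z-scored `clr_matrix` (`zscored = TRUE`). Constant columns map
#'   to 0 with a warning.
#' @export
zscore_clr <- function(x, meta = NULL, stratify_by = NULL,
                       sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  panel <- attr(x, "panel")
  tbl <- as_tibble(x)
  strata <- if (is.null(stratify_by)) {
    rep("all", nrow(tbl))
  } else {
    meta <- as_tibble(meta)
    meta[[stratify_by]][match(tbl$sample_id, meta$sample_id)]
  }
  warned <- FALSE
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 2) {
      abort(sprintf("Stratum '%s' has a single sample; cannot z-score.", s))
    }
    for (taxon in panel) {
      v <- tbl[[taxon]][idx]
      s_v <- sd(v)
      if (sd_type == "population") {
        s_v <- sqrt(mean((v - mean(v))^2))
      }
      if (is.na(s_v) || s_v == 0) {
        tbl[[taxon]][idx] <- 0
        warned <- TRUE
      } else {
        tbl[[taxon]][idx] <- (v - mean(v)) / s_v
      }
    }
  }
  if (warned) warn("Constant taxon column(s) mapped to 0 during z-scoring.")
  new_clr_matrix(tbl, pseudocount = attr(x, "pseudocount"), zscored = TRUE,
                 panel = panel)
}

#' Lactobacillus-minus-other-taxa statistic
#'
#' For each sample, `d = z(Lactobacillus) - aggregate of z(other panel
#' genera)`, computed on z-scored clr values. The default aggregate is the
#' mean, which keeps `d` comparable across panels of different sizes; the sum
#' is available via `aggregate = "sum"`.
#'
#' @param z A z-scored `clr_matrix` ([zscore_clr()]).
#' @param meta Optional metadata; if given, `outcome` is joined in.
#' @param lactobacillus Anchor genus column name.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Tibble `sample_id`, `d` (and `outcome` when `meta` is supplied).
#' @export
lacto_diff <- function(z, meta = NULL, lactobacillus = "Lactobacillus",
                       aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!isTRUE(attr(z, "zscored"))) {
    abort("`z` must be a z-scored clr_matrix (see zscore_clr()).")
  }
  panel <- attr(z, "panel")
  if (!lactobacillus %in% panel) {
    abort(sprintf("Anchor genus '%s' not in the panel.", lactobacillus))
  }
  others <- setdiff(panel, lactobacillus)
  if (length(others) == 0) {
    abort("Panel of size 1: the difference statistic is undefined.")
  }
  m <- clr_values(z)
  agg <- if (aggregate == "mean") {
    rowMeans(m[, others, drop = FALSE])
  } else {
    rowSums(m[, others, drop = FALSE])
  }
  out <- tibble(sample_id = as_tibble(z)$sample_id,
                d = unname(m[, lactobacillus] - agg))
  if (!is.null(meta)) {
    out <- left_join(out, as_tibble(meta)[c("sample_id", "outcome")],
                     by = "sample_id")
  }
  out
}

#' Boxplot of the Lactobacillus-difference statistic by outcome
#'
#' @param diffs Output of [lacto_diff()] including `outcome`.
#' @return A ggplot object.
#' @export
plot_lacto_diff <- function(diffs) {
  diffs <- as_tibble(diffs)
  if (!"outcome" %in% names(diffs)) {
    abort("`diffs` needs an `outcome` column (pass meta to lacto_diff()).")
  }
  ggplot2::ggplot(diffs, ggplot2::aes(.data$outcome, .data$d,
                                      fill = .data$outcome)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "z(Lactobacillus) - mean z(other taxa)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
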