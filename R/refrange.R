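#' Fit a live-birth-anchored reference range for one taxon
#'
#' Uses the Student's t distribution on the reference-group (live birth)
#' values. Two interval modes:
#' * `mean_ci` (default): 95% confidence interval for the mean,
#'   `mean +/- t * sd / sqrt(n)`;
#' * `prediction`: 95% prediction interval for a single new sample,
#'   `mean +/- t * sd * sqrt(1 + 1/n)` (always wider; most individual
#'   samples fall inside it).
#'
#' @param values Numeric reference values (n >= 2).
#' @param level Coverage level (default 0.95).
#' @param mode `"mean_ci"` or `"prediction"`.
#' @return One-row tibble: `n`, `mean`, `sd`, `df`, `lower`, `upper`,
#'   `mode`, `level`.
#' @examples
#' fit_reference_range(c(1, 2, 3)) # [-0.484, 4.484]
#' @export
fit_reference_range <- function(values, level = 0.95,
                                mode = c("mean_ci", "prediction")) {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("Reference range needs at least 2 reference values.")
  m <- mean(values)
  s <- sd(values)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  half <- if (mode == "mean_ci") tq * s / sqrt(n) else tq * s * sqrt(1 + 1 / n)
  tibble(n = n, mean = m, sd = s, df = n - 1,
         lower = m - half, upper = m + half, mode = mode, level = level)
}

#' Per-taxon reference ranges from the reference outcome group
#'
#' Fits [fit_reference_range()] per panel taxon over the samples of the
#' reference outcome (live birth by default).
#'
#' @param x A `clr_matrix` (clr values; the analysis scale of the ranges
#'   follows the input).
#' @param meta Metadata with `outcome`.
#' @param ref_outcome Reference group label (default `"LB"`).
#' @param level,mode Passed to [fit_reference_range()].
#' @return Tibble with one row per taxon (`taxon` + range columns).
#' @export
reference_ranges <- function(x, meta, ref_outcome = "LB", level = 0.95,
                             mode = c("mean_ci", "prediction")) {
  mode <- match.arg(mode)
  meta <- as_tibble(meta)
  tbl <- as_tibble(x)
  ref_ids <- meta$sample_id[meta$outcome == ref_outcome]
  keep <- tbl$sample_id %in% ref_ids
  if (sum(keep) < 2) {
    abort(sprintf("Fewer than 2 '%s' samples; cannot fit reference ranges.",
                  ref_outcome))
  }
  purrr::map_dfr(attr(x, "panel"), function(taxon) {
    dplyr::bind_cols(tibble(taxon = taxon),
                     fit_reference_range(tbl[[taxon]][keep], level, mode))
  })
}

#' Out-of-range distances to a reference interval
#'
#' For each value strictly above the upper bound the distance
#' `value - upper`; strictly below the lower bound, `lower - value`; values
#' inside the range (bounds included) contribute nothing.
#'
#' @param values Numeric vector.
#' @param range One-row tibble with `lower` and `upper` (e.g. from
#'   [fit_reference_range()]).
#' @return Tibble `value`, `side` (`above`/`below`/`in`), `distance`
#'   (0 for in-range values).
#' @export
out_of_range_distances <- function(values, range) {
  side <- ifelse(values > range$upper, "above",
                 ifelse(values < range$lower, "below", "in"))
  distance <- ifelse(side == "above", values - range$upper,
                     ifelse(side == "below", range$lower - values, 0))
  tibble(value = values, side = side, distance = distance)
}

#' Compare upper- versus lower-distance distributions
#'
#' Two-sided Mann-Whitney U test between the distances of samples above the
#' upper bound and those below the lower bound. The exact distribution is
#' used for combined n <= 20 without ties; a tie-corrected normal
#' approximation otherwise. Groups smaller than `min_n` yield
#' `direction = "none"` with a recorded reason rather than an error, since
#' small failed-outcome groups are an expected, reportable state.
#'
#' @param upper_distances,lower_distances Positive distance vectors.
#' @param alpha Significance level.
#' @param min_n Minimum per-group size to test (default 3).
#' @return One-row tibble: `n_upper`, `n_lower`, `U`, `pval`, `direction`
#'   (`above`/`below`/`none`), `significant`, `reason`.
#' @export
test_direction <- function(upper_distances, lower_distances, alpha = 0.05,
                           min_n = 3) {
  n_u <- length(upper_distances)
  n_l <- length(lower_distances)
  base <- tibble(n_upper = n_u, n_lower = n_l, U = NA_real_,
                 pval = NA_real_, direction = "none", significant = FALSE,
                 reason = NA_character_)
  if (n_u < min_n || n_l < min_n) {
    base$reason <- sprintf("insufficient data (need >= %d per group)", min_n)
    return(base)
  }
  combined <- c(upper_distances, lower_distances)
  has_ties <- anyDuplicated(combined) > 0
  exact <- (n_u + n_l) <= 20 && !has_ties
  wt <- suppressWarnings(
    wilcox.test(upper_distances, lower_distances, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  u <- unname(wt$statistic)
  base$U <- u
  base$pval <- wt$p.value
  if (wt$p.value < alpha) {
    base$significant <- TRUE
    base$direction <- if (u > n_u * n_l / 2) "above" else "below"
  }
  base
}

#' Distance tests for every taxon and failed outcome
#'
#' Full reference-range comparison: per taxon, samples of each non-reference
#' outcome are scored against the live-birth range, their out-of-range
#' distances split into above/below groups, and the two distributions
#' compared with [test_direction()]. No multiple-testing correction is
#' applied by default (per-taxon results are reported as-is); set
#' `p_adjust = "BH"` to adjust within each outcome.
#'
#' @param x A `clr_matrix`.
#' @param meta Metadata with `outcome`.
#' @param ranges Output of [reference_ranges()].
#' @param outcomes Outcome labels to test (default `c("NP", "BP", "CM")`).
#' @param alpha,min_n Passed to [test_direction()].
#' @param p_adjust `"none"` or `"BH"`.
#' @return Tibble with one row per (taxon, outcome).
#' @export
distance_tests <- function(x, meta, ranges,
                           outcomes = c("NP", "BP", "CM"), alpha = 0.05,
                           min_n = 3, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  meta <- as_tibble(meta)
  tbl <- as_tibble(x)
  res <- purrr::map_dfr(outcomes, function(oc) {
    ids <- meta$sample_id[meta$outcome == oc]
    keep <- tbl$sample_id %in% ids
    purrr::map_dfr(ranges$taxon, function(taxon) {
      rng <- ranges[ranges$taxon == taxon, ]
      dd <- out_of_range_distances(tbl[[taxon]][keep], rng)
      tr <- test_direction(dd$distance[dd$side == "above"],
                           dd$distance[dd$side == "below"],
                           alpha = alpha, min_n = min_n)
      dplyr::bind_cols(tibble(taxon = taxon, outcome = oc), tr)
    })
  })
  if (p_adjust == "BH") {
    res <- res |>
      group_by(.data$outcome) |>
      mutate(pval = p.adjust(.data$pval, method = "BH"),
             significant = !is.na(.data$pval) & .data$pval < alpha,
             direction = ifelse(.data$significant, .data$direction, "none")) |>
      ungroup()
  }
  res
}

#' Chronic-endometritis pathogen screen
#'
#' Applies the reference-range distance machinery to the fixed panel of ten
#' CE-associated genera (*Enterococcus*, *Escherichia*, *Klebsiella*,
#' *Streptococcus*, *Staphylococcus*, *Gardnerella*, *Mycoplasma*,
#' *Ureaplasma*, *Chlamydia*, *Neisseria*). Genera absent from the detected
#' panel are reported with status `not_assessable`.
#'
#' @param x A `clr_matrix`.
#' @param meta Metadata.
#' @param ranges Output of [reference_ranges()].
#' @param panel A [panel_config()] carrying `ce_pathogens`.
#' @param ... Passed to [distance_tests()].
#' @return Tibble like [distance_tests()] plus a `status` column
#'   (`tested` / `not_assessable`).
#' @export
ce_pathogen_screen <- function(x, meta, ranges, panel = default_panel_config(),
                               ...) {
  ce <- panel$ce_pathogens
  assessable <- intersect(ce, ranges$taxon)
  missing_g <- setdiff(ce, assessable)
  res <- if (length(assessable) > 0) {
    distance_tests(x, meta, ranges[ranges$taxon %in% assessable, ], ...) |>
      mutate(status = "tested")
  } else {
    tibble()
  }
  if (length(missing_g) > 0) {
    res <- dplyr::bind_rows(
      res,
      tidyr::crossing(taxon = missing_g,
                      outcome = c("NP", "BP", "CM")) |>
        mutate(status = "not_assessable")
    )
  }
  res
}

#' Write distance-test results
#'
#' @param results Tibble from [distance_tests()] or [ce_pathogen_screen()].
#' @param tsv_path,json_path Output paths (`NULL` to skip).
#' @export
write_distance_tests <- function(results, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(results, tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(results, json_path, pretty = TRUE, na = "null")
  }
  invisible(c(tsv_path, json_path))
}
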