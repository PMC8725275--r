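#' Tabulate outcomes with half-up percentages
#'
#' Counts and percentages over the analysed denominator for an outcome-like
#' label column. Percentages are rounded half-up to one decimal, the
#' convention used for printed cohort tables.
#'
#' @param data Data frame of analysed patients (one row per patient/sample).
#' @param var Column holding the label to tabulate (default `outcome`).
#' @return Tibble with columns `<var>`, `n`, `pct`; `n` sums to `nrow(data)`.
#' @examples
#' cohort <- tibble::tibble(
#'   outcome = rep(c("LB", "NP", "BP", "CM"), c(141, 144, 27, 28))
#' )
#' outcome_tabulation(cohort) # LB 41.2%, NP 42.1%
#' @export
outcome_tabulation <- function(data, var = "outcome") {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("Cannot tabulate an empty cohort.")
  if (!var %in% names(data)) {
    abort(sprintf("Column '%s' not found.", var))
  }
  if (anyNA(data[[var]])) abort("All analysed patients need a known label.")
  data |>
    dplyr::count(.data[[var]], name = "n") |>
    mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    arrange(dplyr::desc(.data$n))
}

#' Inflate a target sample size for expected attrition
#'
#' Given planned receptive and non-receptive group sizes and an expected loss
#' rate, returns the recruitment target
#' `round((n_receptive + n_nonreceptive) * (1 + attrition_rate))` with half-up
#' rounding. For example, 234 + 100 patients inflated by 30% gives 434.
#'
#' @param n_receptive,n_nonreceptive Non-negative planned group sizes.
#' @param attrition_rate Expected proportion lost, in `[0, 1)`.
#' @return Integer recruitment target.
#' @examples
#' inflate_for_attrition(234, 100, 0.30) # 434
#' @export
inflate_for_attrition <- function(n_receptive, n_nonreceptive,
                                  attrition_rate) {
  if (n_receptive < 0 || n_nonreceptive < 0) {
    abort("Group sizes must be non-negative.")
  }
  if (!is.numeric(attrition_rate) || attrition_rate < 0 ||
      attrition_rate >= 1) {
    abort("`attrition_rate` must lie in [0, 1).")
  }
  as.integer(round_half_up((n_receptive + n_nonreceptive) *
                             (1 + attrition_rate)))
}

#' Per-group sample size for comparing two proportions
#'
#' Normal-approximation sample size with pooled variance under the null
#' (Fleiss, without continuity correction), ceiling-rounded:
#' \deqn{n = \frac{\left(z_{1-\alpha}\sqrt{2\bar p \bar q} +
#'   z_{power}\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1 - p_2)^2}}
#' with \eqn{\bar p = (p_1 + p_2)/2}; for a two-sided test
#' \eqn{z_{1-\alpha/2}} replaces \eqn{z_{1-\alpha}}.
#'
#' @param p1,p2 Proportions in the two groups, both in (0, 1) and distinct.
#' @param alpha Type-I error level.
#' @param power Target power.
#' @param sided `"one"` or `"two"`.
#' @return Integer per-group sample size.
#' @examples
#' sample_size_two_proportions(0.5, 0.7, 0.05, 0.8, "one") # 74
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8,
                                        sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot_scalar_prob(p1, "p1")
  stopifnot_scalar_prob(p2, "p2")
  stopifnot_scalar_prob(alpha, "alpha")
  stopifnot_scalar_prob(power, "power")
  if (p1 == p2) abort("`p1` and `p2` must differ; n is undefined at p1 == p2.")
  za <- if (sided == "one") qnorm(1 - alpha) else qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  pbar <- (p1 + p2) / 2
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}
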