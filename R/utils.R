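# Shared internal helpers.

# Half-up rounding (round() in R rounds half to even; printed cohort
# percentages use commercial half-up rounding).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Dirichlet draws via normalised gammas; rows are draws.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    abort(sprintf(
      "`%s` must lie in the %s interval (0, 1).", name,
      if (open) "open" else "closed"
    ))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
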