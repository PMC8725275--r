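# Independent oracles used to verify the package's statistics.
# These deliberately avoid the code paths they check.

# One-sided (enrichment in group 1) Fisher exact p for the 2x2 table
# [k1, n1-k1; k2, n2-k2], by direct hypergeometric enumeration with choose().
enum_fisher_greater <- function(k1, n1, k2, n2) {
  k_tot <- k1 + k2
  n_tot <- n1 + n2
  lo <- max(0, k_tot - n2)
  hi <- min(n1, k_tot)
  probs <- vapply(lo:hi, function(k) {
    choose(n1, k) * choose(n2, k_tot - k) / choose(n_tot, k_tot)
  }, numeric(1))
  sum(probs[(lo:hi) >= k1])
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) group assignments (ties not supported).
enum_mw_two_sided <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  u_obs <- sum(outer(x, y, ">"))
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) {
    sum(outer(vals[i], vals[-i], ">"))
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Deterministic grid quadrature of the two-parameter normal posterior with
# priors mu ~ N(mu0, tau0) and sigma ~ Uniform(sig_lo, sig_hi).
grid_posterior <- function(y, mu0, tau0 = 10, sig_lo = 0, sig_hi = 10,
                           n_grid = 400) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y^2)
  mu_grid <- seq(mu0 - 5, mu0 + 5, length.out = n_grid)
  sig_grid <- seq(sig_lo + (sig_hi - sig_lo) / (2 * n_grid), sig_hi,
                  length.out = n_grid)
  ll <- outer(mu_grid, sig_grid, function(mu, sig) {
    -n * log(sig) - (syy - 2 * mu * sy + n * mu^2) / (2 * sig^2)
  })
  lp <- ll + matrix(dnorm(mu_grid, mu0, tau0, log = TRUE),
                    n_grid, n_grid)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(
    mu_mean = sum(rowSums(w) * mu_grid),
    mu_sd = sqrt(sum(rowSums(w) * mu_grid^2) -
                   sum(rowSums(w) * mu_grid)^2),
    sigma_mean = sum(colSums(w) * sig_grid),
    sigma_sd = sqrt(sum(colSums(w) * sig_grid^2) -
                      sum(colSums(w) * sig_grid)^2)
  )
}
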