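#' Specification of the per-outcome Bayesian normal model
#'
#' The Lactobacillus-difference statistic `d` is modelled per reproductive
#' outcome as `Y_ij ~ Normal(mu_outcome, sigma_outcome)` with priors
#' `mu ~ Normal(x_bar, 10)` — centred on the mean of `d` over the whole
#' dataset, with prior standard deviation 10 (vague on the z-difference
#' scale) — and `sigma ~ Uniform(0, 10)`.
#'
#' @param prior_mu_center Prior centre for `mu`; `NULL` (default) uses the
#'   global dataset mean of `d` at fit time. Set `per_outcome_center = TRUE`
#'   to centre each outcome's prior on its own group mean instead.
#' @param prior_mu_sd Prior sd of `mu` (default 10).
#' @param prior_sigma_low,prior_sigma_high Bounds of the uniform prior on
#'   `sigma` (default 0 and 10).
#' @param per_outcome_center Logical; see above.
#' @return List of class `bayes_model_spec`.
#' @export
bayes_model_spec <- function(prior_mu_center = NULL, prior_mu_sd = 10,
                             prior_sigma_low = 0, prior_sigma_high = 10,
                             per_outcome_center = FALSE) {
  if (prior_sigma_high <= prior_sigma_low || prior_sigma_low < 0) {
    abort("Require prior_sigma_high > prior_sigma_low >= 0.")
  }
  if (prior_mu_sd <= 0) abort("`prior_mu_sd` must be positive.")
  structure(
    list(prior_mu_center = prior_mu_center, prior_mu_sd = prior_mu_sd,
         prior_sigma_low = prior_sigma_low,
         prior_sigma_high = prior_sigma_high,
         per_outcome_center = per_outcome_center),
    class = "bayes_model_spec"
  )
}

# One MCMC chain: Gibbs update for mu (conjugate normal given sigma),
# random-walk Metropolis for sigma on its bounded support.
run_chain <- function(y, mu0, tau0, sig_lo, sig_hi, n_warmup, n_draws) {
  n <- length(y)
  ybar <- mean(y)
  mu <- ybar + rnorm(1, 0, max(sd(y), 0.1) / sqrt(n))
  sigma <- min(max(sd(y), 0.05), sig_hi * 0.95)
  if (is.na(sigma)) sigma <- (sig_lo + sig_hi) / 2
  step <- max(sigma / sqrt(2 * n), 1e-3) * 2.4
  total <- n_warmup + n_draws
  mu_out <- numeric(n_draws)
  sig_out <- numeric(n_draws)
  acc <- 0
  for (it in seq_len(total)) {
    prec <- 1 / tau0^2 + n / sigma^2
    mu <- rnorm(1, (mu0 / tau0^2 + n * ybar / sigma^2) / prec,
                sqrt(1 / prec))
    ss <- sum((y - mu)^2)
    prop <- sigma + rnorm(1, 0, step)
    if (prop > sig_lo && prop < sig_hi) {
      log_r <- (-n * log(prop) - ss / (2 * prop^2)) -
        (-n * log(sigma) - ss / (2 * sigma^2))
      if (log(runif(1)) < log_r) {
        sigma <- prop
        acc <- acc + 1
      }
    }
    # crude step adaptation during warm-up only
    if (it <= n_warmup && it %% 100 == 0) {
      rate <- acc / it
      if (rate < 0.2) step <- step * 0.7
      if (rate > 0.6) step <- step * 1.4
    }
    if (it > n_warmup) {
      mu_out[it - n_warmup] <- mu
      sig_out[it - n_warmup] <- sigma
    }
  }
  list(mu = mu_out, sigma = sig_out)
}

# Split-chain potential scale reduction factor.
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[1:h], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Fit the Bayesian normal model per outcome
#'
#' Independent fits per outcome of the two-parameter normal model of
#' [bayes_model_spec()], via MCMC (conjugate Gibbs update for `mu`,
#' random-walk Metropolis for `sigma` on its bounded support). Convergence
#' is monitored with the split-chain R-hat; fits with R-hat above 1.1 are
#' flagged. Posterior predictive draws (one new `Y` per retained posterior
#' draw) are generated alongside.
#'
#' @param diffs Tibble with columns `d` and `outcome` (from [lacto_diff()]).
#' @param spec A [bayes_model_spec()].
#' @param n_draws Retained draws per chain (default 2000).
#' @param n_warmup Warm-up iterations per chain (default 1000).
#' @param n_chains Number of chains (default 4).
#' @param seed Integer seed.
#' @param hpd_level HPD interval mass (default 0.95).
#' @return An `outcome_posterior`: named list (one element per outcome) of
#'   lists with `mu_draws`, `sigma_draws`, `ppd_draws`, `hpd_mu`,
#'   `hpd_predictive`, `rhat_mu`, `rhat_sigma`, `n_obs`, `accepted`.
#' @export
fit_outcome_model <- function(diffs, spec = bayes_model_spec(),
                              n_draws = 2000, n_warmup = 1000, n_chains = 4,
                              seed = 1, hpd_level = 0.95) {
  diffs <- as_tibble(diffs)
  if (!all(c("d", "outcome") %in% names(diffs))) {
    abort("`diffs` needs columns `d` and `outcome`.")
  }
  set.seed(seed)
  global_center <- spec$prior_mu_center %||% mean(diffs$d)
  fits <- list()
  for (oc in unique(diffs$outcome)) {
    y <- diffs$d[diffs$outcome == oc]
    y <- y[is.finite(y)]
    if (length(y) < 2) {
      warn(sprintf("Outcome %s has fewer than 2 observations; skipped.", oc))
      next
    }
    if (sd(y) > spec$prior_sigma_high) {
      warn(sprintf(
        "Outcome %s: data spread (%.2f) exceeds the sigma prior upper bound (%g); the prior truncation is binding.",
        oc, sd(y), spec$prior_sigma_high
      ))
    }
    mu0 <- if (spec$per_outcome_center) mean(y) else global_center
    chains <- lapply(seq_len(n_chains), function(i) {
      run_chain(y, mu0, spec$prior_mu_sd, spec$prior_sigma_low,
                spec$prior_sigma_high, n_warmup, n_draws)
    })
    mu_draws <- unlist(lapply(chains, `[[`, "mu"))
    sigma_draws <- unlist(lapply(chains, `[[`, "sigma"))
    ppd <- rnorm(length(mu_draws), mu_draws, sigma_draws)
    rhat_mu <- split_rhat(lapply(chains, `[[`, "mu"))
    rhat_sigma <- split_rhat(lapply(chains, `[[`, "sigma"))
    fits[[oc]] <- list(
      outcome = oc, n_obs = length(y),
      mu_draws = mu_draws, sigma_draws = sigma_draws, ppd_draws = ppd,
      hpd_mu = hpd_interval(mu_draws, hpd_level),
      hpd_predictive = hpd_interval(ppd, hpd_level),
      rhat_mu = rhat_mu, rhat_sigma = rhat_sigma,
      accepted = rhat_mu <= 1.1 && rhat_sigma <= 1.1,
      hpd_level = hpd_level, prior_mu_center = mu0
    )
    if (!fits[[oc]]$accepted) {
      warn(sprintf("Outcome %s: R-hat above 1.1; inspect the fit.", oc))
    }
  }
  structure(fits, class = "outcome_posterior")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(level * n)` of the
#' sorted draws.
#'
#' @param draws Numeric vector of at least 100 draws.
#' @param level Interval mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) abort("HPD interval needs at least 100 draws.")
  s <- sort(draws)
  m <- ceiling(level * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

#' Posterior predictive draws from a fitted outcome
#'
#' Resamples `(mu, sigma)` pairs from the posterior and draws one `Y` from
#' `Normal(mu, sigma)` for each.
#'
#' @param fit One element of an `outcome_posterior` (or the whole object, in
#'   which case a named list of draw vectors is returned).
#' @param n_pred Number of predictive draws.
#' @param seed Optional seed.
#' @return Numeric vector (or named list) of predictive draws.
#' @export
posterior_predictive <- function(fit, n_pred = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "outcome_posterior")) {
    return(lapply(fit, posterior_predictive, n_pred = n_pred))
  }
  idx <- sample.int(length(fit$mu_draws), n_pred, replace = TRUE)
  rnorm(n_pred, fit$mu_draws[idx], fit$sigma_draws[idx])
}

#' @export
print.outcome_posterior <- function(x, ...) {
  cat("<outcome_posterior>\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy outcome_posterior
#' @export
tidy.outcome_posterior <- function(x, ...) {
  purrr::map_dfr(x, function(f) {
    tibble(
      outcome = f$outcome, n_obs = f$n_obs,
      mu_mean = mean(f$mu_draws), mu_sd = sd(f$mu_draws),
      sigma_mean = mean(f$sigma_draws),
      hpd_mu_lower = f$hpd_mu[["lower"]],
      hpd_mu_upper = f$hpd_mu[["upper"]],
      hpd_pred_lower = f$hpd_predictive[["lower"]],
      hpd_pred_upper = f$hpd_predictive[["upper"]],
      rhat_mu = f$rhat_mu, rhat_sigma = f$rhat_sigma,
      accepted = f$accepted
    )
  })
}

#' @method glance outcome_posterior
#' @export
glance.outcome_posterior <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_outcomes = nrow(td),
    n_obs = sum(td$n_obs),
    all_converged = all(td$accepted),
    max_rhat = max(td$rhat_mu, td$rhat_sigma)
  )
}

#' Density plot of posterior predictive draws by outcome
#'
#' @param fit An `outcome_posterior`.
#' @return A ggplot object.
#' @export
plot_posterior_predictive <- function(fit) {
  df <- purrr::map_dfr(fit, function(f) {
    tibble(outcome = f$outcome, y = f$ppd_draws)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$y, colour = .data$outcome,
                                   fill = .data$outcome)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::labs(x = "predicted z(Lactobacillus) - mean z(other taxa)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Export posterior summaries
#'
#' @param fit An `outcome_posterior`.
#' @param json_path,draws_tsv_path Output paths (`NULL` to skip); the TSV
#'   holds the raw draws for plotting.
#' @export
write_posterior <- function(fit, json_path = NULL, draws_tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(tidy(fit), json_path, pretty = TRUE, digits = NA)
  }
  if (!is.null(draws_tsv_path)) {
    draws <- purrr::map_dfr(fit, function(f) {
      tibble(outcome = f$outcome, mu = f$mu_draws, sigma = f$sigma_draws,
             ppd = f$ppd_draws)
    })
    readr::write_tsv(draws, draws_tsv_path, progress = FALSE)
  }
  invisible(c(json_path, draws_tsv_path))
}
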