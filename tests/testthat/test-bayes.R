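test_that("HPD intervals are the shortest draw-covering intervals", {
  grid <- seq(0, 1, length.out = 1000)
  h <- hpd_interval(grid, 0.95)
  expect_gte(h[["upper"]] - h[["lower"]], 0.94)
  expect_lte(h[["upper"]] - h[["lower"]], 0.96)

  hc <- hpd_interval(rep(2.5, 500))
  expect_equal(unname(hc), c(2.5, 2.5))

  expect_error(hpd_interval(rnorm(50)), "at least 100")

  # unimodal symmetric draws: HPD ~ central quantile interval
  set.seed(4)
  draws <- rnorm(20000)
  h2 <- hpd_interval(draws)
  q <- quantile(draws, c(0.025, 0.975))
  expect_lt(abs(h2[["lower"]] - q[[1]]), 0.06)
  expect_lt(abs(h2[["upper"]] - q[[2]]), 0.06)
})

test_that("degenerate data concentrate the posterior on the sample value", {
  diffs <- tibble::tibble(d = rep(2.0, 50), outcome = "LB")
  # sigma's posterior piles up at its lower boundary for zero-variance data,
  # so the convergence flag is expected here
  expect_warning(
    fit <- fit_outcome_model(diffs, n_draws = 1000, n_warmup = 500,
                             n_chains = 2, seed = 1),
    "R-hat"
  )
  expect_lt(abs(mean(fit$LB$mu_draws) - 2.0), 0.05)
})

test_that("the sampler recovers known normal parameters", {
  set.seed(9)
  diffs <- tibble::tibble(d = rnorm(200, 0.7, 0.5), outcome = "NP")
  fit <- fit_outcome_model(diffs, n_draws = 1500, n_warmup = 500,
                           n_chains = 2, seed = 2)
  f <- fit$NP
  expect_lt(abs(mean(f$mu_draws) - 0.7), 0.1)
  expect_true(f$hpd_mu[["lower"]] < 0.7 && 0.7 < f$hpd_mu[["upper"]])
  expect_lte(f$rhat_mu, 1.1)
  expect_lte(f$rhat_sigma, 1.1)
  expect_true(f$accepted)
})

test_that("MCMC agrees with a deterministic grid quadrature of the posterior", {
  set.seed(14)
  cases <- list(
    rnorm(60, 1.2, 0.8),
    rnorm(25, -0.4, 1.5),
    rnorm(150, 0, 0.4)
  )
  for (y in cases) {
    diffs <- tibble::tibble(d = y, outcome = "X")
    spec <- bayes_model_spec(prior_mu_center = mean(y))
    fit <- fit_outcome_model(diffs, spec, n_draws = 2000, n_warmup = 1000,
                             n_chains = 2, seed = 3)
    oracle <- grid_posterior(y, mu0 = mean(y))
    expect_lt(abs(mean(fit$X$mu_draws) - oracle$mu_mean), 0.02)
    expect_lt(abs(sd(fit$X$mu_draws) - oracle$mu_sd), 0.02)
    expect_lt(abs(mean(fit$X$sigma_draws) - oracle$sigma_mean), 0.02)
  }
})

test_that("posterior predictive draws have the right moments and spread", {
  diffs <- tibble::tibble(d = rnorm(300, 0, 1), outcome = "LB")
  fit <- fit_outcome_model(diffs, n_draws = 2500, n_warmup = 500,
                           n_chains = 2, seed = 5)
  ppd <- posterior_predictive(fit$LB, n_pred = 10000, seed = 6)
  expect_lt(abs(mean(ppd) - mean(diffs$d)), 0.05)
  expect_lt(abs(sd(ppd) - 1), 0.06)
  # law of total variance: predictive spread exceeds posterior-mu spread
  expect_gte(sd(fit$LB$ppd_draws), sd(fit$LB$mu_draws))
  # determinism
  expect_identical(posterior_predictive(fit$LB, 100, seed = 7),
                   posterior_predictive(fit$LB, 100, seed = 7))
})

test_that("fits are reproducible and tidy into one row per outcome", {
  diffs <- tibble::tibble(
    d = c(rnorm(40, 1), rnorm(40, -0.5)),
    outcome = rep(c("LB", "NP"), each = 40)
  )
  f1 <- fit_outcome_model(diffs, n_draws = 500, n_warmup = 300,
                          n_chains = 2, seed = 11)
  f2 <- fit_outcome_model(diffs, n_draws = 500, n_warmup = 300,
                          n_chains = 2, seed = 11)
  expect_identical(f1$LB$mu_draws, f2$LB$mu_draws)

  td <- tidy(f1)
  expect_equal(nrow(td), 2)
  expect_true(all(c("mu_mean", "hpd_pred_lower", "rhat_mu") %in% names(td)))
  expect_equal(glance(f1)$n_outcomes, 2)

  expect_warning(
    fit_outcome_model(tibble::tibble(d = 1, outcome = "CM"), n_draws = 200,
                      n_warmup = 100, n_chains = 2),
    "fewer than 2"
  )
})

test_that("model specification guards its prior parameters", {
  expect_error(bayes_model_spec(prior_sigma_high = 0), "prior_sigma_high")
  expect_error(bayes_model_spec(prior_mu_sd = -1), "prior_mu_sd")
  spec <- bayes_model_spec(per_outcome_center = TRUE)
  expect_true(spec$per_outcome_center)
})
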