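#' Run the full analysis pipeline on a cohort
#'
#' Chains every stage in the order a real study would run them:
#' quality metrics and detectability classification, taxon filtering
#' (blank-prevalence contaminants, abundance-prevalence filter over
#' detectable biological samples, kitome exclusion), clr transformation and
#' z-scoring, per-outcome co-occurrence networks, live-birth reference
#' ranges with distance tests and the CE pathogen screen, and the Bayesian
#' outcome model of the Lactobacillus-difference statistic. When `cohort` is
#' `NULL` a synthetic cohort is simulated from `config`.
#'
#' @param cohort List with `table` ([taxon_table()]) and `meta`, e.g. from
#'   [simulate_cohort()]; `NULL` to simulate.
#' @param config A [sim_config()] used when simulating.
#' @param thresholds Detectability thresholds per sample type.
#' @param alpha Significance level shared by the network and distance-test
#'   stages.
#' @param refrange_mode Reference-interval mode (see
#'   [fit_reference_range()]).
#' @param refrange_scale Analysis scale for the reference-range stage:
#'   `"clr"` (default; undetected taxa enter as 0 on the analysis scale,
#'   see [refrange_matrix()]) or `"relative"`.
#' @param n_draws,n_chains MCMC budget for the Bayesian stage.
#' @param seed Seed for the stochastic stages (community detection, MCMC).
#' @return A list of class `endometrial_pipeline` with elements `cohort`,
#'   `quality`, `detectable_ids`, `filter`, `clr`, `zscore`, `diffs`,
#'   `networks`, `network_summary`, `ranges`, `distance_tests`, `ce_screen`,
#'   `posterior`.
#' @export
run_pipeline <- function(cohort = NULL, config = sim_config(),
                         thresholds = c(EF = 0.65, EB = 0.7), alpha = 0.05,
                         refrange_mode = c("mean_ci", "prediction"),
                         refrange_scale = c("clr", "relative"),
                         n_draws = 2000, n_chains = 4, seed = 1) {
  refrange_mode <- match.arg(refrange_mode)
  refrange_scale <- match.arg(refrange_scale)
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  table <- cohort$table
  meta <- validate_sample_meta(cohort$meta, table)
  sample_type <- unique(meta$sample_type)
  if (length(sample_type) != 1) {
    abort("run_pipeline() analyses one sample type at a time.")
  }

  quality <- compute_quality(table) |>
    classify_detectable(meta, thresholds)
  detectable_ids <- quality$sample_id[
    quality$detectable &
      !meta$is_blank[match(quality$sample_id, meta$sample_id)]
  ]
  message(sprintf("QC: %d of %d biological samples detectable.",
                  length(detectable_ids), sum(!meta$is_blank)))

  filt <- filter_taxa(table, meta, detectable_ids = detectable_ids)
  message(sprintf("Filter: %d -> %d taxa.", length(filt$taxa_in),
                  length(filt$panel_out)))

  clr_m <- clr_transform(table, filt$panel_out, samples = detectable_ids)
  z_m <- zscore_clr(clr_m)
  diffs <- lacto_diff(z_m, meta)

  nets <- outcome_networks(clr_m, meta, sample_type = sample_type,
                           alpha = alpha, seed = seed)
  net_summary <- summarize_networks(nets)

  ref_m <- refrange_matrix(table, filt$panel_out, samples = detectable_ids,
                           scale = refrange_scale)
  ranges <- reference_ranges(ref_m, meta, mode = refrange_mode)
  dtests <- distance_tests(ref_m, meta, ranges, alpha = alpha)
  ce <- ce_pathogen_screen(ref_m, meta, ranges, alpha = alpha)

  posterior <- fit_outcome_model(diffs, n_draws = n_draws,
                                 n_chains = n_chains, seed = seed)

  structure(
    list(
      cohort = cohort, quality = quality, detectable_ids = detectable_ids,
      filter = filt, clr = clr_m, zscore = z_m, diffs = diffs,
      networks = nets, network_summary = net_summary, ranges = ranges,
      distance_tests = dtests, ce_screen = ce, posterior = posterior
    ),
    class = "endometrial_pipeline"
  )
}

#' @export
print.endometrial_pipeline <- function(x, ...) {
  cat("<endometrial_pipeline>\n")
  cat(sprintf("  samples: %d (%d detectable biological)\n",
              nrow(x$cohort$table$counts), length(x$detectable_ids)))
  cat(sprintf("  panel: %d taxa after filtering\n",
              length(x$filter$panel_out)))
  cat(sprintf("  networks: %s\n",
              paste(x$network_summary$stratum, collapse = ", ")))
  cat("  posterior means of mu by outcome:\n")
  td <- tidy(x$posterior)
  for (i in seq_len(nrow(td))) {
    cat(sprintf("    %s: %.2f (HPD %.2f..%.2f)\n", td$outcome[i],
                td$mu_mean[i], td$hpd_pred_lower[i], td$hpd_pred_upper[i]))
  }
  invisible(x)
}
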