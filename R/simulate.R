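#' Configuration of the synthetic endometrial cohort generator
#'
#' The generator emulates the statistical structure of low-biomass endometrial
#' 16S genus profiles: outcome-stratified compositions with graded
#' *Lactobacillus* dominance, blank controls dominated by reagent contaminant
#' genera, a low-biomass subset of biological samples whose profiles are
#' contaminant-shifted mixtures and whose filtered/mapped read ratio falls at
#' or below the detectability threshold, and per-sample read-accounting
#' metrics on the scale reported for endometrial fluid sequencing runs.
#'
#' Biological compositions are drawn per sample around the outcome-specific
#' expected composition (anchor genus at `lacto_base[outcome]`, the
#' remainder spread over the other panel genera with per-outcome pathogen
#' boosts in the carrier subset), then counts are multinomial at the
#' sample's filtered read depth. Two composition models are available:
#' * `"logistic_normal"` (default): the anchor (Lactobacillus) share is
#'   drawn logit-normally with a bias-corrected centre so its expectation
#'   equals `lacto_base[outcome]` (`lacto_logit_sd` controls dominance
#'   spread); the remaining mass is split over the other genera by softmax
#'   of Gaussian log-weights (`log_noise_sd`). clr marginals are then
#'   approximately normal and symmetric — the distributional structure the
#'   t-based reference ranges and Pearson correlation tests downstream
#'   assume.
#' * `"dirichlet"`: classical Dirichlet-multinomial with precision
#'   `dirichlet_concentration`; rare taxa then have strongly left-skewed
#'   log-scale marginals.
#' A per-sample lognormal factor shared by the commensal genera
#' (`commensal_block_sd`) plants positive co-occurrence within the commensal
#' block of the live-birth stratum, the structure the network stage is
#' expected to recover.
#'
#' @param n_per_outcome Named vector of biological sample counts per outcome.
#' @param sample_type `"EF"` or `"EB"`.
#' @param panel A [panel_config()]; the panel of `sample_type` is simulated.
#' @param lacto_base Expected *Lactobacillus* share per outcome. Defaults
#'   LB 0.75, NP 0.55, CM 0.40, BP 0.35, chosen so the group means of the
#'   Lactobacillus-difference statistic are ordered LB > NP > CM > BP.
#' @param composition_model `"logistic_normal"` (default) or `"dirichlet"`.
#' @param log_noise_sd Per-taxon log-abundance noise sd of the
#'   logistic-normal model (default 0.6).
#' @param lacto_logit_sd Log-odds sd of the anchor share in the
#'   logistic-normal model (default 1.0).
#' @param dirichlet_concentration Dirichlet precision of the `"dirichlet"`
#'   model; larger means less between-sample spread. Default 50.
#' @param pathogen_boost Named list (outcome -> named numeric) multiplying the
#'   base weight of specific pathogen genera in that outcome's carrier
#'   subset (see `carrier_fraction`). The default plants a Gardnerella
#'   excess in NP carriers (about 14% expected share, a typical dysbiotic
#'   level) and milder pathogen shifts in BP/CM.
#' @param commensal_taxa,commensal_block_sd Genera sharing a per-sample
#'   lognormal abundance factor, and the log-sd of that factor per outcome.
#' @param pathogen_taxa,pathogen_anticorr Dysbiosis-associated genera whose
#'   log-weights load negatively on the sample's Lactobacillus-dominance
#'   deviation with slope `pathogen_anticorr` (default 0.4): samples with
#'   depleted Lactobacillus carry more of these genera, reproducing the
#'   negative Lactobacillus-pathogen co-occurrence seen in endometrial
#'   networks.
#' @param depth_log_mean,depth_log_sd Lognormal parameters of filtered read
#'   depth; defaults put typical biological depths in the tens of thousands
#'   (roughly 28k-140k filtered reads).
#' @param contaminant_taxa Named vector of contaminant genus proportions used
#'   for blanks and for the contaminant component of low-biomass samples.
#' @param detectability_fraction Proportion of biological samples simulated as
#'   low-biomass (default 0.35).
#' @param detection_limit Relative-abundance detection limit: a non-anchor
#'   genus drawn below this share in a sample is recorded as not detected
#'   (count 0), emulating the sparsity of real low-biomass genus tables
#'   (default 0.002).
#' @param carrier_fraction Fraction of an outcome's samples that carry the
#'   planted pathogen excess (default 0.5); the boost of `pathogen_boost`
#'   applies only to carriers, mirroring the subset-dysbiosis pattern of
#'   real cohorts.
#' @param low_biomass_lambda Range of the contaminant mixing weight for
#'   low-biomass samples; drawn uniformly (default 0.6-0.95).
#' @param n_runs,n_blanks_per_run Sequencing-run structure; each run carries
#'   its own blanks (default 3 per run, within the usual 2-4).
#' @param thresholds Detectability thresholds used when constructing read
#'   stats (`EF` 0.65, `EB` 0.7).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_per_outcome = c(LB = 100, NP = 100, BP = 100,
                                         CM = 100),
                       sample_type = c("EF", "EB"),
                       panel = default_panel_config(),
                       lacto_base = c(LB = 0.75, NP = 0.55, CM = 0.40,
                                      BP = 0.35),
                       composition_model = c("logistic_normal", "dirichlet"),
                       log_noise_sd = 0.6,
                       lacto_logit_sd = 1.0,
                       dirichlet_concentration = 50,
                       pathogen_boost = list(
                         NP = c(Gardnerella = 6),
                         CM = c(Staphylococcus = 4, Haemophilus = 3),
                         BP = c(Streptococcus = 3, Atopobium = 3)
                       ),
                       commensal_taxa = c("Streptomyces", "Clostridium",
                                          "Corynebacterium", "Microbacterium",
                                          "Propionibacterium"),
                       commensal_block_sd = c(LB = 0.8, NP = 0.5, BP = 0,
                                              CM = 0),
                       pathogen_taxa = c("Gardnerella", "Atopobium",
                                         "Bifidobacterium", "Streptococcus",
                                         "Staphylococcus", "Chryseobacterium",
                                         "Haemophilus"),
                       pathogen_anticorr = 0.4,
                       depth_log_mean = log(85000),
                       depth_log_sd = 0.25,
                       contaminant_taxa = default_contaminant_profile(),
                       detectability_fraction = 0.35,
                       detection_limit = 0.002,
                       carrier_fraction = 0.5,
                       low_biomass_lambda = c(0.6, 0.95),
                       n_runs = 2,
                       n_blanks_per_run = 3,
                       thresholds = c(EF = 0.65, EB = 0.7),
                       seed = 1L) {
  sample_type <- match.arg(sample_type)
  composition_model <- match.arg(composition_model)
  if (length(n_per_outcome) == 0 || is.null(names(n_per_outcome))) {
    abort("`n_per_outcome` must be a non-empty named vector.")
  }
  if (any(lacto_base <= 0 | lacto_base >= 1)) {
    abort("`lacto_base` values must lie in (0, 1).")
  }
  missing_base <- setdiff(names(n_per_outcome), names(lacto_base))
  if (length(missing_base) > 0) {
    abort(paste0("No `lacto_base` for outcome(s): ",
                 paste(missing_base, collapse = ", ")))
  }
  stopifnot_scalar_prob(detectability_fraction, "detectability_fraction",
                        open = FALSE)
  if (dirichlet_concentration <= 0) {
    abort("`dirichlet_concentration` must be positive.")
  }
  structure(
    list(
      n_per_outcome = n_per_outcome, sample_type = sample_type,
      panel = panel, lacto_base = lacto_base,
      composition_model = composition_model, log_noise_sd = log_noise_sd,
      lacto_logit_sd = lacto_logit_sd,
      dirichlet_concentration = dirichlet_concentration,
      pathogen_boost = pathogen_boost,
      commensal_taxa = commensal_taxa,
      commensal_block_sd = commensal_block_sd,
      pathogen_taxa = pathogen_taxa, pathogen_anticorr = pathogen_anticorr,
      depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
      contaminant_taxa = contaminant_taxa,
      detectability_fraction = detectability_fraction,
      detection_limit = detection_limit,
      carrier_fraction = carrier_fraction,
      low_biomass_lambda = low_biomass_lambda,
      n_runs = n_runs, n_blanks_per_run = n_blanks_per_run,
      thresholds = thresholds, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default contaminant (kitome-like) profile for blanks
#'
#' Proportions of classic reagent genera used to populate blank controls and
#' the contaminant component of low-biomass samples. Blank contaminant loads
#' are a calibration choice of the generator, not measured values.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_contaminant_profile <- function() {
  p <- c(Ralstonia = 0.30, Sphingomonas = 0.20, Pseudomonas = 0.15,
         Burkholderia = 0.10, Bradyrhizobium = 0.08, Methylobacterium = 0.07,
         Delftia = 0.05, Acinetobacter = 0.05)
  p / sum(p)
}

# Outcome-specific expected composition over the panel.
outcome_base_composition <- function(config, outcome) {
  panel <- config$panel$panel_taxa[[config$sample_type]]
  anchor <- config$panel$lactobacillus
  others <- setdiff(panel, anchor)
  w <- setNames(rep(1, length(others)), others)
  boost <- config$pathogen_boost[[outcome]]
  if (!is.null(boost)) {
    hit <- intersect(names(boost), names(w))
    w[hit] <- w[hit] * boost[hit]
  }
  lacto <- config$lacto_base[[outcome]]
  base <- c(setNames(lacto, anchor), w / sum(w) * (1 - lacto))
  base[panel] # panel order, sums to 1
}

# Same, but without the pathogen boost (non-carrier samples).
outcome_base_composition_plain <- function(config, outcome) {
  cfg <- config
  cfg$pathogen_boost <- list()
  outcome_base_composition(cfg, outcome)
}

# Centre of the logit-normal anchor share such that E[plogis(N(c, tau))]
# equals the target mean share (corrects the logit-scale Jensen bias).
logit_center_for_mean <- function(target, tau) {
  z <- seq(-6, 6, length.out = 401)
  wdens <- stats::dnorm(z)
  wdens <- wdens / sum(wdens)
  f <- function(c) sum(stats::plogis(c + tau * z) * wdens) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Simulate read-accounting quality metrics
#'
#' Draws per-sample read statistics (`total_reads`, `filtered_reads`,
#' `mapped_reads`, `empty_reads`) for a given biomass class. By construction,
#' detectable samples receive a filtered/mapped ratio strictly above the
#' sample-type detectability threshold (0.65 EF, 0.7 EB), while low-biomass
#' samples and blanks fall at or below it with depleted depth and elevated
#' empty-read percentages.
#'
#' @param biomass_class `"detectable"`, `"low"` or `"blank"`.
#' @param sample_type `"EF"` or `"EB"`.
#' @param n Number of samples to draw.
#' @param config A [sim_config()] supplying depth and threshold parameters.
#' @param seed Optional seed for reproducibility.
#' @return Tibble with the four read-stat columns (no `sample_id`).
#' @export
simulate_quality_metrics <- function(biomass_class = c("detectable", "low",
                                                       "blank"),
                                     sample_type = c("EF", "EB"), n = 1,
                                     config = NULL, seed = NULL) {
  biomass_class <- match.arg(biomass_class)
  sample_type <- match.arg(sample_type)
  if (is.null(config)) config <- sim_config(sample_type = sample_type)
  if (!is.null(seed)) set.seed(seed)
  thr <- config$thresholds[[sample_type]]
  depth_scale <- switch(biomass_class, detectable = 1, low = 0.15,
                        blank = 0.02)
  filtered <- pmax(200L, as.integer(round(
    rlnorm(n, config$depth_log_mean + log(depth_scale), config$depth_log_sd)
  )))
  fm_ratio <- switch(biomass_class,
    detectable = thr + runif(n, 0.05, 0.30),
    low = thr - runif(n, 0.02, 0.25),
    blank = thr - runif(n, 0.05, 0.30)
  )
  mapped <- as.integer(round(filtered / fm_ratio))
  total <- as.integer(round(pmax(filtered, mapped) * runif(n, 2.0, 2.6)))
  empty_pct <- switch(biomass_class,
    detectable = runif(n, 1, 8),
    low = runif(n, 15, 40),
    blank = runif(n, 25, 60)
  )
  tibble(
    total_reads = total,
    filtered_reads = filtered,
    mapped_reads = mapped,
    empty_reads = as.integer(round(total * empty_pct / 100))
  )
}

#' Simulate an outcome-stratified low-biomass cohort
#'
#' Generates a [taxon_table()] and matching sample metadata under the
#' generative model described in [sim_config()]. The metadata carries an
#' extra `biomass_class` column (`detectable`, `low` or `blank`) recording
#' the simulation ground truth, which downstream QC is expected to recover
#' from the read statistics alone.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with elements `table` ([taxon_table()]) and `meta`
#'   (tibble of sample metadata).
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_per_outcome = c(LB = 10, NP = 10), seed = 7
#' ))
#' cohort$table
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config.")
  set.seed(seed %||% config$seed)
  panel <- config$panel$panel_taxa[[config$sample_type]]
  contam <- config$contaminant_taxa
  all_taxa <- union(panel, names(contam))
  contam_full <- setNames(numeric(length(all_taxa)), all_taxa)
  contam_full[names(contam)] <- contam / sum(contam)

  rows <- list()
  meta_rows <- list()
  run_ids <- paste0("run", seq_len(config$n_runs))
  idx <- 0L

  for (outcome in names(config$n_per_outcome)) {
    n <- config$n_per_outcome[[outcome]]
    if (n == 0) next
    base <- outcome_base_composition(config, outcome)
    base_plain <- outcome_base_composition_plain(config, outcome)
    anchor_center <- logit_center_for_mean(config$lacto_base[[outcome]],
                                           config$lacto_logit_sd)
    block_sd <- config$commensal_block_sd[[outcome]] %||% 0
    if (is.na(block_sd)) block_sd <- 0
    commensals <- intersect(config$commensal_taxa, panel)
    low_flags <- runif(n) < config$detectability_fraction
    for (i in seq_len(n)) {
      idx <- idx + 1L
      cls <- if (low_flags[i]) "low" else "detectable"
      carrier <- runif(1) < config$carrier_fraction
      w <- if (carrier) base else base_plain
      if (block_sd > 0 && length(commensals) > 0) {
        w[commensals] <- w[commensals] * exp(rnorm(1, -block_sd^2 / 2,
                                                   block_sd))
      }
      if (config$composition_model == "logistic_normal") {
        anchor <- config$panel$lactobacillus
        others <- setdiff(panel, anchor)
        u <- rnorm(1, anchor_center, config$lacto_logit_sd)
        s_anchor <- stats::plogis(u)
        logw <- log(w[others]) + rnorm(length(others), 0,
                                       config$log_noise_sd)
        pathogens <- intersect(config$pathogen_taxa, others)
        if (length(pathogens) > 0 && config$pathogen_anticorr != 0) {
          logw[pathogens] <- logw[pathogens] -
            config$pathogen_anticorr * (u - anchor_center)
        }
        p_oth <- exp(logw - max(logw))
        p_oth <- p_oth / sum(p_oth) * (1 - s_anchor)
        p_bio <- setNames(numeric(length(panel)), panel)
        p_bio[anchor] <- s_anchor
        p_bio[others] <- p_oth
        p_bio <- p_bio[panel]
      } else {
        alpha <- config$dirichlet_concentration * w / sum(w)
        p_bio <- drop(rdirichlet_mat(1, alpha))
      }
      names(p_bio) <- panel
      if (config$detection_limit > 0) {
        anchor <- config$panel$lactobacillus
        undetected <- setdiff(panel[p_bio < config$detection_limit], anchor)
        p_bio[undetected] <- 0
        p_bio <- p_bio / sum(p_bio)
      }
      p_full <- setNames(numeric(length(all_taxa)), all_taxa)
      p_full[panel] <- p_bio
      mix <- if (cls == "low") {
        runif(1, config$low_biomass_lambda[1], config$low_biomass_lambda[2])
      } else {
        runif(1, 0, 0.05) # trace reagent bleed into real samples
      }
      p <- (1 - mix) * p_full + mix * contam_full
      stats <- simulate_quality_metrics(cls, config$sample_type, 1, config)
      counts <- drop(rmultinom(1, stats$filtered_reads, p))
      sid <- sprintf("%s_%s_%03d", config$sample_type, outcome, i)
      rows[[idx]] <- c(list(sample_id = sid), as.list(counts),
                       as.list(stats))
      meta_rows[[idx]] <- tibble(
        sample_id = sid, sample_type = config$sample_type, outcome = outcome,
        is_blank = FALSE, run_id = run_ids[(idx %% config$n_runs) + 1L],
        biomass_class = cls
      )
    }
  }
  if (idx == 0L) abort("`n_per_outcome` produced no samples.")

  for (run in run_ids) {
    for (b in seq_len(config$n_blanks_per_run)) {
      idx <- idx + 1L
      p_blank <- setNames(numeric(length(all_taxa)), all_taxa)
      p_blank[names(contam)] <- drop(rdirichlet_mat(1, 30 * contam))
      stats <- simulate_quality_metrics("blank", config$sample_type, 1, config)
      counts <- drop(rmultinom(1, stats$filtered_reads, p_blank))
      sid <- sprintf("%s_BLANK_%s_%d", config$sample_type, run, b)
      rows[[idx]] <- c(list(sample_id = sid), as.list(counts),
                       as.list(stats))
      meta_rows[[idx]] <- tibble(
        sample_id = sid, sample_type = config$sample_type,
        outcome = "UNKNOWN", is_blank = TRUE, run_id = run,
        biomass_class = "blank"
      )
    }
  }

  big <- dplyr::bind_rows(lapply(rows, as_tibble))
  counts <- big[c("sample_id", all_taxa)]
  counts[all_taxa] <- lapply(counts[all_taxa], as.integer)
  stats <- big[c("sample_id", "total_reads", "filtered_reads",
                 "mapped_reads", "empty_reads")]
  list(
    table = taxon_table(counts, stats),
    meta = dplyr::bind_rows(meta_rows)
  )
}
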