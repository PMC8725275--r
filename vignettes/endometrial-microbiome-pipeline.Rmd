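---
title: "Methods: low-biomass endometrial microbiome profiling and outcome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-biomass endometrial microbiome profiling and outcome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endomicro)
```

# The analytical problem

The endometrium is a low-biomass niche: 16S rRNA amplicon profiles from
endometrial fluid (EF) and endometrial biopsy (EB) samples sit close to the
noise floor of reagent ("kitome") contamination, and a substantial fraction
of samples contain so little bacterial DNA that their profiles are
indistinguishable from blank extraction controls. Any claim that the
endometrial microbiome relates to assisted-reproduction outcomes — live
birth (LB), no pregnancy (NP), biochemical pregnancy (BP), clinical
miscarriage (CM) — therefore hinges on an analysis pipeline that first
separates genuine microbial signal from contamination, and only then models
composition against outcome.

This package implements that pipeline end to end:

1. **Detectability QC.** Per-sample read-accounting metrics — empty-read
   percentage, index of dispersion of the taxon counts, and the ratio of
   filtered to mapped reads — classify samples as *detectable* or
   *not-detectable* biomass. The operational rule is the ratio threshold:
   a sample is detectable iff its filtered/mapped ratio strictly exceeds
   0.65 (EF) or 0.70 (EB). A PCA of the standardised metrics verifies that
   not-detectable samples cluster with blanks.
2. **Contaminant and taxon filtering.** Genera enriched in blanks
   (one-sided Fisher exact test on presence/absence, `alpha = 0.05`) are
   removed; remaining genera must reach ≥1% relative abundance in ≥5% of
   detectable samples *or* ≥0.1% in ≥15% (both boundaries inclusive);
   finally a configurable kitome exclusion list removes recurrent reagent
   genera. The shipped exclusion list is a stand-in assembled from commonly
   reported reagent contaminants and is expected to be replaced when a
   specific literature consensus is required.
3. **Compositional transform.** Panel counts (+1 pseudocount) are mapped
   through the centred log-ratio (clr) transform, z-scored per taxon, and
   summarised per sample by the Lactobacillus-difference statistic
   `d = z(Lactobacillus) − mean z(other panel taxa)`.
4. **Co-occurrence networks.** Per outcome stratum, all taxon pairs are
   tested with Pearson correlation on clr values; edges with `p < 0.05`
   get weight `w = |corr| − p`, and Louvain communities are detected on
   `max(w, 1e-6)`.
5. **Reference-range distance tests.** Per taxon, a Student-t 95% interval
   fitted on LB samples defines the physiological range; for each failed
   outcome, distances of samples above the upper bound are compared with
   distances below the lower bound by a two-sided Mann-Whitney U test
   (exact for combined n ≤ 20 without ties). A fixed ten-genus chronic
   endometritis (CE) panel is screened with the same machinery.
6. **Bayesian outcome model.** Per outcome,
   `Y_ij ~ Normal(mu, sigma)` with priors `mu ~ Normal(x̄, 10)` (x̄ = the
   dataset mean of `d`) and `sigma ~ Uniform(0, 10)`, fitted by MCMC;
   95% highest-posterior-density (HPD) intervals are reported for `mu` and
   for the posterior predictive.

# The synthetic cohort generator

Real endometrial sequencing data cannot ship with a package, so every stage
is exercised against `simulate_cohort()`, whose job is to reproduce the
*statistical structure the downstream stages assume*, under conditions the
analyst controls.

**What it emulates.**

* Outcome-stratified Lactobacillus dominance: the anchor share is drawn
  logit-normally with expectation 0.75 (LB), 0.55 (NP), 0.40 (CM),
  0.35 (BP) — values chosen so the group means of `d` are ordered
  LB > NP > CM > BP, the direction the outcome model is expected to
  recover. The logit centre is numerically bias-corrected so the group
  mean equals the configured share exactly.
* Near-normal clr marginals: the non-anchor mass is split by softmax of
  Gaussian log-weights (sd 0.6). This matters: the t-based reference
  interval and the upper-vs-lower distance comparison are only calibrated
  when taxon values are roughly symmetric on the analysis scale. A
  classical Dirichlet-multinomial variant (`composition_model =
  "dirichlet"`) is retained; with realistic concentrations it gives rare
  taxa strongly left-skewed log-marginals, and the distance test then
  reflects that skewness rather than group differences.
* Subset dysbiosis: pathogen excesses are planted in a *carrier subset*
  (default half of an outcome's samples), e.g. a 6-fold Gardnerella weight
  boost in NP carriers (≈14% expected share, a typical dysbiotic level).
  Whole-group shifts were deliberately avoided: they push *every* sample
  beyond the LB interval, emptying the lower-distance group so the
  Mann-Whitney comparison cannot run at all.
* Structured co-occurrence: a shared lognormal factor on a commensal block
  (sd 0.8 in LB, 0.5 in NP, 0 in BP/CM) makes the LB network denser with
  higher mean degree; dysbiosis-associated genera load negatively
  (slope 0.4) on the sample's Lactobacillus-dominance deviation, planting
  the negative Lactobacillus–pathogen edges.
* Detection sparsity: a genus drawn below 0.2% relative abundance is
  recorded as not detected (count 0). In the reference-range stage,
  undetected taxa enter as value 0 *on the analysis scale* — at the
  compositional centre under clr — rather than as an unbounded negative
  log-ratio. Higher limits (0.5–1%) were examined and rejected: they
  truncate the lower tail so strongly that the distance comparison becomes
  anticonservative under the null.
* Read accounting: filtered depths are lognormal (median ≈ 85k, typical
  range ≈ 28k–140k); detectable samples get filtered/mapped ratios
  strictly above the sample-type threshold, low-biomass samples and blanks
  at or below it, with depleted depth and elevated empty-read fractions.
  Low-biomass profiles are mixtures `(1−λ)·biological + λ·contaminant`,
  `λ ~ U(0.6, 0.95)`, so they cluster with blanks in the QC ordination.
* Blanks: 3 per run (within the usual 2–4), drawn from a fixed reagent
  genus profile at low depth. Blank contaminant loads are calibration
  choices, not measured values.

**What it does not emulate.** Read-level error, chimeras, taxonomic
misassignment, cross-sample index bleed, patient covariates, and
between-run batch effects beyond what z-scoring absorbs. Passing tests on
this generator show the pipeline's statistical machinery behaves as
specified under its assumptions — not that those assumptions hold in any
particular clinical data set.

# Numerical and design choices

* **Filtered/mapped ratio** is implemented as `filtered_reads /
  mapped_reads` (an `invert` flag covers pipelines that report the
  inverse). Mapped reads are counted against the raw stream, so mapped may
  exceed filtered; both are bounded by total reads.
* **Dispersion index** is the sample variance (n−1 denominator) over the
  mean of a sample's taxon counts; a two-count profile `[0, 8]` gives 8.
* **Detectability** is decided by the ratio alone; the other two metrics
  enter the QC ordination. The classification rule is strict at the
  boundary.
* **Contaminant score**: the one-sided Fisher exact test is computed
  natively on the presence 2×2 table (a chi-square variant is selectable);
  a taxon must also be more prevalent in blanks than in biological samples
  to be called. The test suite verifies the score against a full
  hypergeometric enumeration for all margins up to 12.
* **Filter order** is contaminants → abundance-prevalence → kitome, each
  removal attributed to the first stage that drops the taxon; the chain is
  idempotent.
* **Zero replacement** for the clr is an integer pseudocount of 1 on panel
  counts — the simplest reproducible choice.
* **Aggregation of "other taxa"** in `d` uses the *mean* of z-scores, so
  `d` is comparable across panels of different sizes (15 EF vs 19 EB); the
  sum is available via an argument.
* **z-scores** use the sample (n−1) standard deviation, computed within a
  sample-type stratum by default; run-wise stratification is available.
* **Network edges** use uncorrected `p < 0.05` (a Benjamini–Hochberg
  option exists but is off by default, matching the practice of reporting
  any significant Pearson coefficient). The weight `w = |corr| − p` can be
  slightly negative when `p > |corr|`; Louvain requires non-negative
  weights, so community detection uses `max(w, 1e-6)` while exports keep
  the raw value.
* **Reference intervals** default to the 95% confidence interval for the
  mean (`mean ± t·sd/√n`), the literal reading of a "95% confidence
  interval" on the reference group; a prediction-interval mode
  (`mean ± t·sd·√(1+1/n)`) is first-class, since a mean-CI leaves most
  individual samples "outside the range" — which is precisely what the
  distance-distribution comparison consumes. Distances use the
  strictly-outside convention (boundary values contribute nothing), and
  groups smaller than 3 are reported as `insufficient` rather than tested.
* **Reference-range scale** defaults to clr with the undetected-as-0 rule.
  The relative-abundance scale is available but makes the upper-vs-lower
  comparison structurally asymmetric (lower distances are bounded by the
  lower bound itself), which inflates "above" calls under the null — we
  measured per-test null rates up to ~0.6 on that scale versus ~0.056 on
  the clr default.
* **The null behaviour of the distance test** deserves a caveat: comparing
  upper with lower distances is exactly calibrated only for symmetric
  value distributions. With three assessable CE genera and three failed
  outcomes, nine level-0.05 tests run per cohort, so even a perfectly
  calibrated screen produces at least one spurious call in roughly a third
  of cohorts; results should be read per taxon, not as a family.
* **MCMC**: `mu` has a conjugate normal full conditional and is Gibbs
  updated; `sigma` takes random-walk Metropolis steps on its bounded
  support, with step-size adaptation during warm-up only. Defaults are 4
  chains × 2000 retained draws after 1000 warm-up iterations, split-chain
  R-hat ≤ 1.1 for acceptance. Correctness is enforced in the tests by
  agreement (within 0.02) with a deterministic grid quadrature of the same
  posterior, not by sampler identity. For zero-variance data the sigma
  posterior piles up at its lower boundary and the R-hat flag fires by
  design.
* **HPD** intervals are the shortest contiguous interval containing
  `⌈0.95·n⌉` sorted draws; both the interval for `mu` and for the
  posterior predictive are reported, the predictive first (its width is
  the one comparable to per-patient spread).
* **Prior centre** x̄ is the global dataset mean of `d`; a per-outcome
  centring option exists.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on synthetic data at
sizes chosen to make every stage's behaviour measurable while staying
quick on a single CPU: the end-to-end cohort uses 100 biological samples
per outcome (plus blanks); calibration checks use 1000 reference-interval
replicates, 400 null correlation pairs at n = 200, 20 posterior-recovery
replicates at n = 150, and exhaustive enumerations for the exact tests
(Fisher margins ≤ 12, Mann-Whitney combined n ≤ 10). With those sizes the
full suite completes in about a minute.

# Known limitations

* The planted NP Gardnerella excess is detected in most but not all
  simulated cohorts (measured ≈ 7/8 seeds at the default effect size);
  the flag is an honest per-cohort test result, not a certainty.
* The kitome exclusion list is a stand-in; reproducing any specific
  published panel requires the corresponding list.
* The pipeline analyses one sample type per run; EF/EB integration happens
  at the panel level (`build_panels()`), not by joint modelling.
* No hierarchical pooling across outcomes in the Bayesian stage; groups
  are fitted independently, as small-group HPD widths will reflect.
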