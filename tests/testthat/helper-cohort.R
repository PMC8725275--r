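# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small default-structure cohort used by several unit tests.
test_cohort <- function(seed = 7, n = 30) {
  key <- paste0("cohort_", seed, "_", n)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(
      n_per_outcome = c(LB = n, NP = n, BP = ceiling(n / 2),
                        CM = ceiling(n / 2)),
      seed = seed
    )
    .fixture_env[[key]] <- suppressWarnings(simulate_cohort(cfg))
  }
  .fixture_env[[key]]
}

# QC + filter + clr stages of the small cohort, cached.
test_stages <- function(seed = 7, n = 30) {
  key <- paste0("stages_", seed, "_", n)
  if (is.null(.fixture_env[[key]])) {
    co <- test_cohort(seed, n)
    quality <- suppressWarnings(
      classify_detectable(compute_quality(co$table), co$meta)
    )
    blank <- co$meta$is_blank[match(quality$sample_id, co$meta$sample_id)]
    det <- quality$sample_id[quality$detectable & !blank]
    filt <- suppressWarnings(filter_taxa(co$table, co$meta,
                                         detectable_ids = det))
    clr_m <- clr_transform(co$table, filt$panel_out, samples = det)
    .fixture_env[[key]] <- list(cohort = co, quality = quality,
                                detectable = det, filter = filt,
                                clr = clr_m)
  }
  .fixture_env[[key]]
}

# Full default-scale pipeline (shared by the end-to-end checks).
test_pipeline_full <- function() {
  if (is.null(.fixture_env$pipeline_full)) {
    .fixture_env$pipeline_full <- suppressWarnings(suppressMessages(
      run_pipeline(config = sim_config(seed = 1), seed = 1)
    ))
  }
  .fixture_env$pipeline_full
}

# Tiny hand-built taxon table.
tiny_table <- function() {
  taxon_table(
    counts = tibble::tibble(
      sample_id = c("s1", "s2", "s3"),
      Lactobacillus = c(900L, 50L, 400L),
      Gardnerella = c(100L, 950L, 600L)
    ),
    read_stats = tibble::tibble(
      sample_id = c("s1", "s2", "s3"),
      total_reads = c(3000L, 3200L, 2900L),
      filtered_reads = c(1000L, 1000L, 1000L),
      mapped_reads = c(1250L, 1300L, 1100L),
      empty_reads = c(60L, 80L, 120L)
    )
  )
}

tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    sample_type = "EF",
    outcome = c("LB", "NP", "LB"),
    is_blank = FALSE,
    run_id = "run1"
  )
}
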