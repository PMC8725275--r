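# Build a table with fixed blank/biological presence patterns.
presence_table <- function(k_blank, n_blank, k_bio, n_bio, taxon = "Tx") {
  n <- n_blank + n_bio
  ids <- sprintf("s%02d", seq_len(n))
  present <- c(rep(c(1L, 0L), c(k_blank, n_blank - k_blank)),
               rep(c(1L, 0L), c(k_bio, n_bio - k_bio)))
  counts <- tibble::tibble(sample_id = ids,
                           !!taxon := present * 50L,
                           Filler = 100L)
  stats <- tibble::tibble(sample_id = ids, total_reads = 1000L,
                          filtered_reads = 200L, mapped_reads = 250L,
                          empty_reads = 5L)
  meta <- tibble::tibble(
    sample_id = ids, sample_type = "EF",
    outcome = rep(c("UNKNOWN", "LB"), c(n_blank, n_bio)),
    is_blank = rep(c(TRUE, FALSE), c(n_blank, n_bio)), run_id = "r1"
  )
  list(table = taxon_table(counts, stats), meta = meta)
}

test_that("blank-enriched taxa are called contaminants", {
  x <- presence_table(4, 4, 0, 40)
  calls <- score_contaminants(x$table, x$meta)
  tx <- calls[calls$taxon_id == "Tx", ]
  expect_true(tx$is_contaminant)
  expect_equal(tx$prevalence_in_blanks, 1)
  expect_equal(tx$prevalence_in_samples, 0)

  # absent from blanks: cannot be blank-enriched
  x2 <- presence_table(0, 4, 10, 40)
  expect_false(
    score_contaminants(x2$table, x2$meta)$is_contaminant[1]
  )

  # equal prevalence everywhere: p = 1
  x3 <- presence_table(4, 4, 40, 40)
  calls3 <- score_contaminants(x3$table, x3$meta)
  expect_equal(calls3$score[calls3$taxon_id == "Tx"], 1)
  expect_false(calls3$is_contaminant[calls3$taxon_id == "Tx"])
})

test_that("the Fisher score equals hypergeometric enumeration (small margins)", {
  for (n1 in c(2, 4, 6)) {
    for (n2 in c(2, 5, 8)) {
      for (k1 in 0:n1) {
        for (k2 in c(0, 1, n2)) {
          x <- presence_table(k1, n1, k2, n2)
          got <- score_contaminants(x$table, x$meta)
          got <- got$score[got$taxon_id == "Tx"]
          expect_equal(got, enum_fisher_greater(k1, n1, k2, n2),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("missing blanks skip the stage with a warning", {
  x <- presence_table(0, 2, 5, 10)
  meta <- dplyr::mutate(x$meta, is_blank = FALSE, outcome = "LB")
  expect_warning(calls <- score_contaminants(x$table, meta), "No blank")
  expect_equal(nrow(calls), 0)
})

test_that("abundance filter applies the dual criterion at its stated boundaries", {
  # 20 samples; taxon A at 2% in exactly 1 sample (5%) -> retained via crit 1
  # taxon B at 0.2% in 3 samples (15%) -> retained via crit 2
  # taxon C at 0.05% everywhere -> removed
  n <- 20
  depth <- 100000L
  a <- c(2000L, rep(0L, n - 1))
  b <- c(rep(200L, 3), rep(0L, n - 3))
  cc <- rep(50L, n)
  filler <- depth - a - b - cc
  counts <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           A = a, B = b, C = cc, Filler = filler)
  stats <- tibble::tibble(sample_id = counts$sample_id, total_reads = depth,
                          filtered_reads = depth, mapped_reads = depth,
                          empty_reads = 0L)
  res <- abundance_filter(taxon_table(counts, stats))
  expect_true(res$retained[res$taxon_id == "A"])
  expect_true(res$retained[res$taxon_id == "B"])
  expect_false(res$retained[res$taxon_id == "C"])
})

test_that("a planted ubiquitous-rare taxon is always removed, a dominant never", {
  st <- test_stages()
  co <- st$cohort
  counts <- co$table$counts
  m <- count_matrix(co$table)
  # rare: ~0.01% everywhere; dominant taxon is the anchor
  counts$PlantedRare <- pmax(1L, as.integer(round(rowSums(m) * 1e-4)))
  tt <- taxon_table(counts, co$table$read_stats)
  res <- abundance_filter(tt, samples = st$detectable)
  expect_false(res$retained[res$taxon_id == "PlantedRare"])
  expect_true(res$retained[res$taxon_id == "Lactobacillus"])
})

test_that("kitome exclusion is case-insensitive and order-preserving", {
  taxa <- c("Lactobacillus", "RALSTONIA", "Gardnerella", "sphingomonas")
  out <- apply_kitome_exclusion(taxa, c("Ralstonia", "Sphingomonas"))
  expect_equal(out, c("Lactobacillus", "Gardnerella"))
  expect_equal(apply_kitome_exclusion(c("A", "B"), c("C")), c("A", "B"))
  expect_warning(apply_kitome_exclusion(c("Ralstonia"), c("ralstonia")),
                 "empty")
})

test_that("the filter chain is idempotent and its removals partition the input", {
  st <- test_stages()
  rep1 <- st$filter
  expect_setequal(
    rep1$panel_out,
    setdiff(rep1$taxa_in, c(rep1$removed_contaminant,
                            rep1$removed_low_abundance, rep1$removed_kitome))
  )
  # disjoint removal lists
  all_removed <- c(rep1$removed_contaminant, rep1$removed_low_abundance,
                   rep1$removed_kitome)
  expect_equal(anyDuplicated(all_removed), 0L)

  # applying the chain to the already-filtered table keeps the panel
  co <- st$cohort
  sub <- endomicro:::subset_table(co$table, taxa = rep1$panel_out)
  rep2 <- suppressWarnings(
    filter_taxa(sub, co$meta, detectable_ids = st$detectable)
  )
  expect_setequal(rep2$panel_out, rep1$panel_out)
})

test_that("filter reports serialise to JSON", {
  st <- test_stages()
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(st$filter, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(parsed$panel_out, st$filter$panel_out)
})
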