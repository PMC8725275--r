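test_that("reference ranges follow the t-distribution arithmetic", {
  r0 <- fit_reference_range(c(5, 5, 5, 5))
  expect_equal(c(r0$lower, r0$upper), c(5, 5))

  r <- fit_reference_range(c(1, 2, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 1)
  expect_equal(r$df, 2)
  expect_equal(r$lower, -0.4841377, tolerance = 1e-6)
  expect_equal(r$upper, 4.4841377, tolerance = 1e-6)

  rp <- fit_reference_range(c(1, 2, 3), mode = "prediction")
  expect_lt(rp$lower, r$lower)
  expect_gt(rp$upper, r$upper)

  expect_error(fit_reference_range(2), "at least 2")
})

test_that("out-of-range distances use the strictly-outside convention", {
  rng <- fit_reference_range(c(1, 2, 3))
  d <- out_of_range_distances(c(6.0, 2.0, rng$lower, -2.0), rng)
  expect_equal(d$side, c("above", "in", "in", "below"))
  expect_equal(d$distance[1], 6.0 - rng$upper, tolerance = 1e-6)
  expect_equal(d$distance[1], 1.5158623, tolerance = 1e-6)
  expect_equal(d$distance[2], 0)
  expect_equal(d$distance[3], 0) # boundary value contributes nothing
  expect_equal(d$distance[4], rng$lower - (-2.0), tolerance = 1e-6)
})

test_that("the direction test reproduces the exact Mann-Whitney distribution", {
  res <- test_direction(c(3, 4, 5), c(1, 2), min_n = 2)
  expect_equal(res$U, 6)
  expect_equal(res$pval, 0.2)
  expect_equal(res$direction, "none") # 0.2 > alpha
  expect_false(res$significant)

  # identical groups: p = 1, no direction
  res_id <- test_direction(c(1, 2, 3), c(1, 2, 3))
  expect_gt(res_id$pval, 0.99)
  expect_equal(res_id$direction, "none")

  # exact p matches full enumeration for every split with combined n <= 10
  set.seed(21)
  for (n1 in 2:5) {
    for (n2 in 2:min(5, 10 - n1)) {
      for (rep in 1:3) {
        vals <- sample(seq(0.1, 99.9, by = 0.1), n1 + n2)
        x <- vals[seq_len(n1)]
        y <- vals[-seq_len(n1)]
        res <- test_direction(x, y, min_n = 2)
        expect_equal(res$pval, enum_mw_two_sided(x, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("directions follow the dominating side at significance", {
  up <- test_direction(c(5, 6, 7, 8, 9), c(0.1, 0.2, 0.3, 0.4), min_n = 3)
  expect_true(up$significant)
  expect_equal(up$direction, "above")
  down <- test_direction(c(0.1, 0.2, 0.3, 0.4), c(5, 6, 7, 8, 9), min_n = 3)
  expect_equal(down$direction, "below")
})

test_that("small distance groups are reported, not tested", {
  res <- test_direction(c(1, 2), c(3, 4, 5))
  expect_equal(res$direction, "none")
  expect_false(res$significant)
  expect_match(res$reason, "insufficient")
  expect_true(is.na(res$pval))
})

test_that("p-values are invariant under translating all values", {
  st <- test_stages()
  meta <- st$cohort$meta
  rm1 <- refrange_matrix(st$cohort$table, st$filter$panel_out,
                         samples = st$detectable)
  ranges1 <- reference_ranges(rm1, meta)
  t1 <- distance_tests(rm1, meta, ranges1)

  shift <- 4.2
  tbl2 <- tibble::as_tibble(rm1)
  tbl2[attr(rm1, "panel")] <- tbl2[attr(rm1, "panel")] + shift
  rm2 <- structure(tbl2, panel = attr(rm1, "panel"), scale = "clr",
                   class = class(tibble::tibble()))
  ranges2 <- reference_ranges(rm2, meta)
  t2 <- distance_tests(rm2, meta, ranges2)
  expect_equal(t1$pval, t2$pval, tolerance = 1e-9)
  expect_equal(t1$direction, t2$direction)
})

test_that("the CE screen reports absent genera as not assessable", {
  st <- test_stages()
  meta <- st$cohort$meta
  rm1 <- refrange_matrix(st$cohort$table, st$filter$panel_out,
                         samples = st$detectable)
  ranges <- reference_ranges(rm1, meta)
  ce <- ce_pathogen_screen(rm1, meta, ranges)
  # EF panel carries only Streptococcus, Staphylococcus, Gardnerella
  na_rows <- ce[ce$status == "not_assessable", ]
  expect_true(all(c("Mycoplasma", "Chlamydia", "Neisseria") %in%
                    na_rows$taxon))
  tested <- unique(ce$taxon[ce$status == "tested"])
  expect_true(all(tested %in% st$filter$panel_out))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tests(ce, tsv_path = path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), nrow(ce))
})
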