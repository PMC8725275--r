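test_that("clr matches hand-computed log-ratios", {
  expect_equal(clr(c(1, 1, 1, 1), pseudocount = 0), rep(0, 4))
  expect_equal(clr(c(1, 4, 16), pseudocount = 0),
               c(-log(4), 0, log(4)), tolerance = 1e-12)
  expect_error(clr(c(0, 1), pseudocount = 0), "non-positive")
})

test_that("clr closes to zero and is scale invariant on random rows", {
  set.seed(11)
  for (i in 1:1000) {
    x <- rgamma(sample(3:20, 1), shape = 0.5) + 1e-6
    v <- clr(x, pseudocount = 0)
    expect_lt(abs(sum(v)), 1e-8)
    k <- runif(1, 0.01, 100)
    expect_lt(max(abs(clr(k * x, pseudocount = 0) - v)), 1e-10)
  }
})

test_that("clr_transform fills structural zeros for panel taxa absent from the table", {
  tt <- tiny_table()
  x <- clr_transform(tt, c("Lactobacillus", "Gardnerella", "Atopobium"))
  expect_equal(attr(x, "panel")[3], "Atopobium")
  vals <- as.matrix(tibble::as_tibble(x)[attr(x, "panel")])
  expect_true(all(abs(rowSums(vals)) < 1e-8))
  # Atopobium only carries pseudocount
  expect_true(all(vals[, "Atopobium"] < vals[, "Lactobacillus"]))
})

test_that("z-scoring standardises per taxon under the sample-sd convention", {
  tt <- tiny_table()
  x <- clr_transform(tt, c("Lactobacillus", "Gardnerella"))
  tbl <- tibble::as_tibble(x)
  tbl <- tbl[1:2, ]
  x2 <- endomicro:::new_clr_matrix(tbl, 1, FALSE,
                                   c("Lactobacillus", "Gardnerella"))
  z <- zscore_clr(x2)
  # two samples: sample-sd z-scores are +/- 1/sqrt(2)
  expect_equal(sort(tibble::as_tibble(z)$Lactobacillus),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  zp <- zscore_clr(x2, sd_type = "population")
  expect_equal(sort(tibble::as_tibble(zp)$Lactobacillus), c(-1, 1),
               tolerance = 1e-12)

  # z of z = z
  st <- test_stages()
  z1 <- zscore_clr(st$clr)
  z2 <- zscore_clr(z1)
  expect_equal(tibble::as_tibble(z2), tibble::as_tibble(z1),
               tolerance = 1e-6)

  # constant columns map to zero with a warning
  tbl3 <- tibble::as_tibble(st$clr)
  tbl3$Gardnerella <- 1.5
  x3 <- endomicro:::new_clr_matrix(tbl3, 1, FALSE, attr(st$clr, "panel"))
  expect_warning(z3 <- zscore_clr(x3), "Constant")
  expect_true(all(tibble::as_tibble(z3)$Gardnerella == 0))

  expect_error(zscore_clr(endomicro:::new_clr_matrix(tbl[1, ], 1, FALSE,
                                                     attr(x2, "panel"))),
               "single sample")
})

test_that("the Lactobacillus-difference statistic is the anchor minus the mean of others", {
  panel <- c("Lactobacillus", "A", "B", "C")
  tbl <- tibble::tibble(sample_id = c("s1", "s2"),
                        Lactobacillus = c(1.2, 0),
                        A = c(0.3, 0), B = c(-0.5, 0), C = c(0.2, 0))
  z <- endomicro:::new_clr_matrix(tbl, 1, TRUE, panel)
  d <- lacto_diff(z)
  expect_equal(d$d, c(1.2, 0))

  # location invariance: adding a constant within a sample leaves d unchanged
  tbl_shift <- tbl
  tbl_shift[2:5] <- tbl_shift[2:5] + 3.7
  z_shift <- endomicro:::new_clr_matrix(tbl_shift, 1, TRUE, panel)
  expect_equal(lacto_diff(z_shift)$d, d$d)

  # sum aggregation option
  expect_equal(lacto_diff(z, aggregate = "sum")$d[1], 1.2 - 0.0)

  # guard rails
  expect_error(lacto_diff(endomicro:::new_clr_matrix(tbl, 1, FALSE, panel)),
               "z-scored")
  z1 <- endomicro:::new_clr_matrix(tbl[c("sample_id", "Lactobacillus")],
                                   1, TRUE, "Lactobacillus")
  expect_error(lacto_diff(z1), "size 1")
})

test_that("refrange matrices assign undetected taxa the value 0", {
  tt <- tiny_table()
  tt$counts$Gardnerella[1] <- 0L
  rm_clr <- refrange_matrix(tt, c("Lactobacillus", "Gardnerella"))
  expect_equal(tibble::as_tibble(rm_clr)$Gardnerella[1], 0)
  # detected entries keep their clr values
  x <- clr_transform(tt, c("Lactobacillus", "Gardnerella"))
  expect_equal(tibble::as_tibble(rm_clr)$Gardnerella[2],
               tibble::as_tibble(x)$Gardnerella[2])
  rm_rel <- refrange_matrix(tt, c("Lactobacillus", "Gardnerella"),
                            scale = "relative")
  rel <- tibble::as_tibble(rm_rel)
  expect_equal(rel$Lactobacillus + rel$Gardnerella, rep(1, 3))
  expect_equal(rel$Gardnerella[1], 0)
})
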