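# Wrap a plain numeric matrix as a clr-like input for build_network().
as_clr_input <- function(m) {
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(m)))),
    tibble::as_tibble(m)
  )
  endomicro:::new_clr_matrix(tbl, 1, FALSE, colnames(m))
}

test_that("edge weights equal |corr| - pval with the correlation's sign", {
  set.seed(2)
  n <- 40
  x <- rnorm(n)
  m <- cbind(a = x, b = 2 * x, c = -x + rnorm(n, sd = 0.3),
             d = rnorm(n))
  net <- build_network(as_clr_input(m))
  # perfectly collinear pair: corr 1, p ~ 0, weight ~ 1
  ab <- net$edges[net$edges$taxon_a == "a" & net$edges$taxon_b == "b", ]
  expect_equal(ab$corr, 1, tolerance = 1e-12)
  expect_equal(ab$weight, 1, tolerance = 1e-10)
  expect_equal(ab$sign, "positive")
  # anti-correlated pair is negative
  ac <- net$edges[net$edges$taxon_a == "a" & net$edges$taxon_b == "c", ]
  expect_equal(ac$sign, "negative")
  expect_lt(ac$corr, -0.8)
  # every edge: weight recomputed, significant, bounded
  expect_equal(net$edges$weight, abs(net$edges$corr) - net$edges$pval)
  expect_true(all(net$edges$pval < net$alpha))
  expect_true(all(net$edges$weight >= -1 & net$edges$weight <= 1))
})

test_that("edge inclusion behaves like a level-alpha test for independent taxa", {
  present <- 0
  for (seed in 1:50) {
    set.seed(seed)
    m <- cbind(a = rnorm(200), b = rnorm(200))
    net <- build_network(as_clr_input(m))
    present <- present + nrow(net$edges)
  }
  expect_lte(present, 5) # ~alpha of 50 null pairs
})

test_that("small strata and constant taxa are handled explicitly", {
  m <- cbind(a = rnorm(3), b = rnorm(3))
  expect_error(build_network(as_clr_input(m)), "at least 4 samples")
  set.seed(1)
  m2 <- cbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  expect_warning(net <- build_network(as_clr_input(m2)), "Constant")
  expect_true("b" %in% net$nodes$taxon) # kept as an isolated node
  expect_false(any(net$edges$taxon_a == "b" | net$edges$taxon_b == "b"))
})

test_that("Louvain recovers planted partitions and is deterministic", {
  # two disjoint 4-cliques via two independent latent factors
  set.seed(5)
  n <- 120
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  m <- cbind(
    a1 = f1 + rnorm(n, sd = 0.4), a2 = f1 + rnorm(n, sd = 0.4),
    a3 = f1 + rnorm(n, sd = 0.4), a4 = f1 + rnorm(n, sd = 0.4),
    b1 = f2 + rnorm(n, sd = 0.4), b2 = f2 + rnorm(n, sd = 0.4),
    b3 = f2 + rnorm(n, sd = 0.4), b4 = f2 + rnorm(n, sd = 0.4)
  )
  net <- detect_communities(build_network(as_clr_input(m)), seed = 0)
  comm <- setNames(net$nodes$community, net$nodes$taxon)
  expect_length(unique(comm), 2)
  expect_length(unique(comm[c("a1", "a2", "a3", "a4")]), 1)
  expect_length(unique(comm[c("b1", "b2", "b3", "b4")]), 1)

  # determinism up to labels
  net2 <- detect_communities(build_network(as_clr_input(m)), seed = 0)
  expect_equal(net$nodes$community, net2$nodes$community)

  # uniform triangle collapses to one community
  set.seed(6)
  f <- rnorm(80)
  tri <- cbind(x = f + rnorm(80, sd = 0.2), y = f + rnorm(80, sd = 0.2),
               z = f + rnorm(80, sd = 0.2))
  net3 <- detect_communities(build_network(as_clr_input(tri)))
  expect_equal(length(unique(net3$nodes$community)), 1)

  # partition modularity is at least the singleton partition's
  g <- endomicro:::conetwork_igraph(net)
  mod_singleton <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                                      weights = igraph::E(g)$weight)
  expect_gte(attr(net, "modularity"), mod_singleton)
})

test_that("network summaries report density, degree and isolation", {
  # complete graph on 5 nodes
  set.seed(9)
  f <- rnorm(100)
  m <- sapply(1:5, function(i) f + rnorm(100, sd = 0.1))
  colnames(m) <- paste0("t", 1:5)
  net <- detect_communities(build_network(as_clr_input(m)))
  s <- summarize_networks(list(full = net))
  expect_equal(s$density, 1)
  expect_equal(s$mean_degree, 4)
  expect_equal(s$n_isolated, 0)

  # edgeless graph
  set.seed(10)
  m0 <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  net0 <- build_network(as_clr_input(m0), alpha = 1e-9)
  s0 <- summarize_networks(list(none = net0))
  expect_equal(s0$density, 0)
  expect_equal(s0$n_isolated, 3)
})

test_that("networks survive the taxon-pair order and export round-trips", {
  set.seed(3)
  f <- rnorm(60)
  m <- cbind(a = f + rnorm(60, sd = 0.5), b = f + rnorm(60, sd = 0.5),
             c = rnorm(60))
  net <- build_network(as_clr_input(m))
  net_rev <- build_network(as_clr_input(m[, rev(colnames(m))]))
  key <- function(n) {
    e <- n$edges
    sort(paste(pmin(e$taxon_a, e$taxon_b), pmax(e$taxon_a, e$taxon_b)))
  }
  expect_equal(key(net), key(net_rev))

  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_conetwork(net, gml, tsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  edges_back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(edges_back), nrow(net$edges))
  expect_true("stratum" %in% names(edges_back))

  # broom-style accessors
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  expect_equal(glance(net)$n_nodes, 3)
})
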