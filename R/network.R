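#' Build a taxon co-occurrence network for one stratum
#'
#' Tests every pair of panel genera with a Pearson correlation on clr values
#' within the stratum, keeps edges with `p < alpha` (uncorrected by default;
#' the published criterion is a significant Pearson coefficient with no
#' correction stated), and assigns each edge the weight
#' `w = |corr| - pval`, combining effect size and significance. Edge sign
#' records the direction of the correlation. Constant taxa cannot be tested
#' and are excluded with a warning (they remain isolated nodes).
#'
#' @param x A `clr_matrix` (clr or z-scored values) restricted to the
#'   stratum's samples; needs at least 4 samples.
#' @param stratum Label stored on the network (e.g. `"EF:LB"`).
#' @param alpha Edge-inclusion significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment across all tested pairs.
#' @return A `conetwork`: list with tibbles `nodes` (`taxon`,
#'   `mean_abundance`, `community` — `NA` until [detect_communities()]) and
#'   `edges` (`taxon_a`, `taxon_b`, `corr`, `pval`, `weight`, `sign`), plus
#'   `stratum`, `alpha`, `n_samples`.
#' @export
build_network <- function(x, stratum = "ALL", alpha = 0.05,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  m <- clr_values(x)
  if (nrow(m) < 4) {
    abort("Need at least 4 samples to build a correlation network.")
  }
  if (ncol(m) < 2) abort("Need at least 2 panel taxa.")
  sds <- apply(m, 2, sd)
  constant <- colnames(m)[sds == 0]
  if (length(constant) > 0) {
    warn(paste0("Constant taxa excluded from correlation testing: ",
                paste(constant, collapse = ", ")))
  }
  testable <- setdiff(colnames(m), constant)
  pairs <- if (length(testable) >= 2) utils::combn(testable, 2) else
    matrix(character(), nrow = 2, ncol = 0)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    ct <- suppressWarnings(cor.test(m[, a], m[, b], method = "pearson"))
    tibble(taxon_a = a, taxon_b = b,
           corr = unname(ct$estimate), pval = ct$p.value)
  })
  if (nrow(res) > 0 && p_adjust == "BH") {
    res$pval <- p.adjust(res$pval, method = "BH")
  }
  edges <- res |>
    filter(.data$pval < alpha) |>
    mutate(
      weight = abs(.data$corr) - .data$pval,
      sign = ifelse(.data$corr < 0, "negative", "positive")
    )
  nodes <- tibble(
    taxon = colnames(m),
    mean_abundance = unname(colMeans(m)),
    community = NA_integer_
  )
  structure(
    list(nodes = nodes, edges = edges, stratum = stratum, alpha = alpha,
         n_samples = nrow(m)),
    class = "conetwork"
  )
}

#' @export
print.conetwork <- function(x, ...) {
  cat(sprintf("<conetwork> stratum %s: %d nodes, %d edges (n = %d samples)\n",
              x$stratum, nrow(x$nodes), nrow(x$edges), x$n_samples))
  invisible(x)
}

conetwork_igraph <- function(net, weight_floor = 1e-6) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("taxon_a", "taxon_b", "weight", "corr", "pval", "sign")],
    directed = FALSE,
    vertices = net$nodes[c("taxon", "mean_abundance")]
  )
  if (igraph::ecount(g) > 0) {
    # Louvain needs non-negative weights; w = |corr| - pval can dip below 0
    igraph::E(g)$weight <- pmax(igraph::E(g)$weight, weight_floor)
  }
  g
}

#' Louvain community detection on a co-occurrence network
#'
#' Runs the Louvain algorithm on the network using `max(w, 1e-6)` as edge
#' weights (the raw `w = |corr| - pval` can be slightly negative when the
#' p-value exceeds the absolute correlation, but Louvain requires
#' non-negative weights; exports keep the raw `w`). Isolated nodes form
#' singleton communities. Deterministic given `seed`.
#'
#' @param net A `conetwork` from [build_network()].
#' @param seed Integer seed (default 0).
#' @param resolution Louvain resolution parameter (default 1).
#' @return `net` with `nodes$community` filled and attribute `modularity`.
#' @export
detect_communities <- function(net, seed = 0, resolution = 1) {
  if (nrow(net$nodes) == 0) return(net)
  g <- conetwork_igraph(net)
  set.seed(seed)
  if (igraph::ecount(g) == 0) {
    membership <- seq_len(igraph::vcount(g))
    mod <- 0
  } else {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    membership <- igraph::membership(cl)
    mod <- igraph::modularity(cl)
  }
  net$nodes$community <-
    as.integer(membership[match(net$nodes$taxon, igraph::V(g)$name)])
  attr(net, "modularity") <- mod
  net
}

#' Summarise networks across strata
#'
#' Density, mean degree, community count and isolated-node count per
#' network; used to compare the live-birth stratum (expected denser, with a
#' higher degree distribution) against failed-outcome strata.
#'
#' @param nets A named list of `conetwork` objects (names are used as
#'   stratum labels when a network lacks one), or a single `conetwork`.
#' @return Tibble with columns `stratum`, `n_nodes`, `n_edges`, `density`,
#'   `mean_degree`, `n_communities`, `n_isolated`.
#' @export
summarize_networks <- function(nets) {
  if (inherits(nets, "conetwork")) nets <- list(nets)
  purrr::imap_dfr(nets, function(net, nm) {
    n <- nrow(net$nodes)
    e <- nrow(net$edges)
    degree <- table(c(net$edges$taxon_a, net$edges$taxon_b))
    deg <- setNames(numeric(n), net$nodes$taxon)
    deg[names(degree)] <- as.numeric(degree)
    n_comm <- if (all(is.na(net$nodes$community))) NA_integer_ else
      length(unique(net$nodes$community))
    tibble(
      stratum = net$stratum %||% as.character(nm),
      n_nodes = n, n_edges = e,
      density = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
      mean_degree = mean(deg),
      n_communities = n_comm,
      n_isolated = sum(deg == 0)
    )
  })
}

#' Build per-outcome networks from a clr matrix
#'
#' Splits samples by outcome (plus an `ALL` stratum) and builds one network
#' per stratum with at least `min_n` samples; communities are detected on
#' each.
#'
#' @param x A `clr_matrix`.
#' @param meta Metadata with `outcome`.
#' @param sample_type Label prefixed to stratum names.
#' @param alpha,seed Passed to [build_network()] / [detect_communities()].
#' @param min_n Minimum samples per stratum (default 4).
#' @return Named list of `conetwork` objects.
#' @export
outcome_networks <- function(x, meta, sample_type = "EF", alpha = 0.05,
                             seed = 0, min_n = 4) {
  meta <- as_tibble(meta)
  tbl <- as_tibble(x)
  outcomes <- meta$outcome[match(tbl$sample_id, meta$sample_id)]
  strata <- c(list(ALL = tbl$sample_id),
              split(tbl$sample_id, outcomes))
  nets <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    if (length(ids) < min_n) {
      warn(sprintf("Stratum %s has %d samples (< %d); skipped.",
                   nm, length(ids), min_n))
      next
    }
    sub <- new_clr_matrix(as_tibble(x)[tbl$sample_id %in% ids, ],
                          pseudocount = attr(x, "pseudocount"),
                          zscored = attr(x, "zscored"),
                          panel = attr(x, "panel"))
    nets[[nm]] <- build_network(sub, stratum = paste(sample_type, nm,
                                                     sep = ":"),
                                alpha = alpha) |>
      detect_communities(seed = seed)
  }
  nets
}

#' Export a network as GraphML and a flat edge list
#'
#' @param net A `conetwork`.
#' @param graphml_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_conetwork <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(conetwork_igraph(net), graphml_path,
                        format = "graphml")
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(
      mutate(net$edges, stratum = net$stratum),
      edges_path, progress = FALSE
    )
  }
  invisible(c(graphml_path, edges_path))
}

#' @method tidy conetwork
#' @export
tidy.conetwork <- function(x, ...) {
  mutate(x$edges, stratum = x$stratum)
}

#' @method glance conetwork
#' @export
glance.conetwork <- function(x, ...) {
  summarize_networks(list(x))
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout (seeded for reproducibility); node colour is
#' the Louvain community, node size the mean clr abundance, edge colour the
#' correlation sign (red negative, grey positive).
#'
#' @param net A `conetwork`, ideally after [detect_communities()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_conetwork <- function(net, seed = 0) {
  g <- conetwork_igraph(net)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- mutate(net$nodes, x = xy[, 1], y = xy[, 2])
  edges <- net$edges |>
    left_join(nodes[c("taxon", "x", "y")], by = c(taxon_a = "taxon")) |>
    rename(xa = "x", ya = "y") |>
    left_join(nodes[c("taxon", "x", "y")], by = c(taxon_b = "taxon")) |>
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$sign,
                   linewidth = .data$weight), alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$mean_abundance,
                   fill = factor(.data$community)),
      shape = 21
    ) +
    ggplot2::geom_text(
      data = nodes, ggplot2::aes(.data$x, .data$y, label = .data$taxon),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(negative = "firebrick",
                                            positive = "grey50")) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::labs(title = net$stratum, fill = "community") +
    ggplot2::theme_void()
}
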