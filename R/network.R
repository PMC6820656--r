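#' Extract the condition-specific miRNA-mRNA subnetwork
#'
#' Keeps the edges of a reference regulatory network whose miRNA endpoint is
#' differentially expressed AND whose mRNA endpoint is differentially
#' expressed; nodes left without an edge drop out.  This is the
#' resistance-associated subnetwork on which all downstream vulnerability
#' statistics are computed.
#'
#' @param reference Reference edge tibble (`mirna`, `mrna`).
#' @param de_mirnas,de_mrnas Character vectors of differentially expressed
#'   feature IDs (non-empty).
#' @return An edge tibble, possibly with zero rows (with a warning).
#' @export
extract_subnetwork <- function(reference, de_mirnas, de_mrnas) {
  reference <- validate_network(reference, arg = "reference")
  if (length(de_mirnas) == 0 || length(de_mrnas) == 0) {
    stop_parameter("`de_mirnas` and `de_mrnas` must be non-empty.")
  }
  sub <- dplyr::filter(reference,
                       .data$mirna %in% de_mirnas,
                       .data$mrna %in% de_mrnas)
  if (nrow(sub) == 0) {
    warn("extracted subnetwork is empty: no reference edge joins the DE lists.")
  }
  sub
}

#' Node-level topology of a bipartite regulatory network
#'
#' Treats the graph as undirected and computes, per node: degree,
#' betweenness centrality normalized by `(N-1)(N-2)/2`, and closeness with
#' Wasserman-Faust component scaling (closeness is computed within each
#' connected component and multiplied by the component's share
#' `(n_c - 1)/(N - 1)`, so values are comparable across a disconnected
#' graph and lie in `[0, 1]`).  Hubs are the top `hub_fraction` of nodes by
#' degree and bottlenecks the top fraction by betweenness: rank descending,
#' take the `ceiling(hub_fraction * N)`-th value as cutoff, and include every
#' node tied with it.
#'
#' @param edges Edge tibble (`mirna`, `mrna`), non-empty.
#' @param hub_fraction Top fraction for hub/bottleneck flags (default 0.10).
#' @param rank_within `"all"` ranks hubs/bottlenecks over all nodes
#'   (default); `"mirna"` restricts the ranking to miRNA nodes.
#' @return A tibble with columns `node`, `type` (mirna/mrna), `degree`,
#'   `betweenness`, `closeness`, `is_hub`, `is_bottleneck`.
#' @export
network_topology <- function(edges, hub_fraction = 0.10,
                             rank_within = c("all", "mirna")) {
  edges <- validate_network(edges)
  if (nrow(edges) == 0) stop_degenerate("network is empty.")
  check_scalar_prob(hub_fraction, "hub_fraction")
  rank_within <- match.arg(rank_within)

  mirnas <- unique(edges$mirna)
  mrnas <- unique(edges$mrna)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(g)$name
  n <- length(nodes)

  deg <- igraph::degree(g)
  btw <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    setNames(rep(0, n), nodes)
  }

  # closeness with Wasserman-Faust component scaling
  comp <- igraph::components(g)
  clo <- setNames(rep(0, n), nodes)
  for (ci in seq_len(comp$no)) {
    members <- nodes[comp$membership == ci]
    nc <- length(members)
    if (nc < 2) next
    dm <- igraph::distances(g, v = members, to = members)
    clo[members] <- (nc - 1) / rowSums(dm) * (nc - 1) / (n - 1)
  }

  top_flag <- function(values, pool) {
    k <- ceiling(hub_fraction * length(pool))
    cutoff <- sort(values[pool], decreasing = TRUE)[k]
    flags <- setNames(rep(FALSE, n), nodes)
    flags[pool] <- values[pool] >= cutoff
    flags
  }
  pool <- if (rank_within == "mirna") mirnas else nodes

  tibble::tibble(
    node = nodes,
    type = ifelse(nodes %in% mirnas, "mirna", "mrna"),
    degree = as.integer(deg[nodes]),
    betweenness = unname(btw[nodes]),
    closeness = unname(clo[nodes]),
    is_hub = unname(top_flag(deg, pool)[nodes]),
    is_bottleneck = unname(top_flag(btw, pool)[nodes])
  )
}

#' Log-log least-squares fit of the degree distribution
#'
#' For every distinct degree `k` with frequency `f(k) > 0`, fits ordinary
#' least squares to `(log10 k, log10 f(k))` — the raw-frequency convention of
#' classic network-analyzer tools.  A high `r_squared` indicates a
#' scale-free-like (power-law) degree distribution.
#'
#' @param edges Edge tibble (`mirna`, `mrna`); needs >= 3 distinct degree
#'   values.
#' @return An object of class `mirvuln_powerlaw`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, and the fitted `points` tibble.
#' @export
fit_degree_powerlaw <- function(edges) {
  edges <- validate_network(edges)
  if (nrow(edges) == 0) stop_degenerate("network is empty.")
  deg <- c(table(c(edges$mirna, edges$mrna)))
  tab <- table(deg)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 3) {
    stop_degenerate("degenerate degree distribution: fewer than 3 distinct degrees.")
  }
  pts <- tibble::tibble(degree = k, frequency = f,
                        log_k = log10(k), log_f = log10(f))
  fit <- lm(log_f ~ log_k, data = pts)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    # R^2 of simple OLS = squared Pearson correlation of the log-log points
    r_squared = stats::cor(pts$log_k, pts$log_f)^2,
    n_points = length(k),
    points = pts
  ), class = "mirvuln_powerlaw")
}

#' @export
tidy.mirvuln_powerlaw <- function(x, ...) x$points

#' @export
glance.mirvuln_powerlaw <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
print.mirvuln_powerlaw <- function(x, ...) {
  cat(sprintf(
    "Degree-distribution power-law fit: slope = %.3f, R^2 = %.3f (%d degree values)\n",
    x$slope, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Log-log degree-distribution plot with the fitted line
#'
#' @param object A `mirvuln_powerlaw` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirvuln_powerlaw <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$log_k, y = .data$log_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "log10 degree", y = "log10 frequency",
      title = sprintf("Degree distribution (R^2 = %.3f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
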