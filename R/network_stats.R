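#' Global network efficiency
#'
#' Mean over ordered node pairs of the reciprocal shortest-path length,
#' `(1/(n(n-1))) * sum_{i != j} 1/d_ij`, with `1/Inf = 0` for disconnected
#' pairs. Ranges from 0 (edgeless) to 1 (complete graph).
#'
#' @param network an [encounter_network()].
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(network) {
  n <- network_n(network)
  if (n < 2) {
    stop("global efficiency needs at least 2 nodes", call. = FALSE)
  }
  d <- igraph::distances(as_igraph(network))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Community structure and modularity via walktrap
#'
#' Detects communities with the walktrap random-walk agglomeration (default
#' walk length 4, the algorithm's canonical choice) and reports the Newman
#' modularity Q of the resulting partition. Every node, including isolated
#' ones, is assigned to exactly one community.
#'
#' @param network an [encounter_network()] with at least one node.
#' @param steps walktrap random-walk length.
#' @return A list with `membership` (named integer vector node -> community)
#'   and `Q` (modularity; `NA` for an edgeless network).
#' @export
modularity_walktrap <- function(network, steps = 4) {
  if (network_n(network) == 0) {
    stop("network must be non-empty", call. = FALSE)
  }
  g <- as_igraph(network)
  if (network_e(network) == 0) {
    return(list(membership = stats::setNames(seq_len(network_n(network)),
                                             network$nodes),
                Q = NA_real_))
  }
  cl <- igraph::cluster_walktrap(g, steps = steps)
  memb <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(memb), names(memb)),
       Q = igraph::modularity(g, memb))
}

#' Degree range of a network
#'
#' The number of distinct degree values `k` for which at least one node has
#' degree `k`. Networks whose degrees span many scales (scale-free-like, and
#' biological encounter networks) have a high degree range; regular graphs
#' have degree range 1.
#'
#' @param network an [encounter_network()].
#' @return Integer count of occupied degree values.
#' @export
degree_range <- function(network) {
  length(unique(network_degrees(network)))
}

#' Summary statistics of an encounter network
#'
#' Collects the structural statistics used to interrogate bingo performance:
#' size, mean degree, global efficiency, walktrap modularity, connected
#' components and degree range/histogram.
#'
#' @param network an [encounter_network()].
#' @return A list of class `stats_record` with fields `n`, `e`,
#'   `mean_degree`, `global_efficiency`, `modularity_Q`, `membership`,
#'   `component_count`, `component_sizes`, `degree_range`,
#'   `degree_histogram`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  n <- network_n(network)
  e <- network_e(network)
  deg <- network_degrees(network)
  comp <- if (n > 0) igraph::components(as_igraph(network)) else
    list(no = 0L, csize = integer())
  mod <- if (n > 0) modularity_walktrap(network) else
    list(membership = integer(), Q = NA_real_)
  structure(
    list(n = n, e = e,
         mean_degree = if (n > 0) 2 * e / n else NA_real_,
         global_efficiency = if (n >= 2) global_efficiency(network)
                             else NA_real_,
         modularity_Q = mod$Q,
         membership = mod$membership,
         component_count = comp$no,
         component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
         degree_range = if (n > 0) degree_range(network) else 0L,
         degree_histogram = if (n > 0) table(deg) else table(integer())),
    class = "stats_record"
  )
}

#' @export
print.stats_record <- function(x, ...) {
  cat(sprintf(
    "<stats_record: n %d, e %d, <k> %.3g, eff %.3g, Q %.3g, %d comp, degree range %d>\n",
    x$n, x$e, x$mean_degree, x$global_efficiency, x$modularity_Q,
    x$component_count, x$degree_range))
  invisible(x)
}
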