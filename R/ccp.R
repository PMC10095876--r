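#' Coupon-collector predictions of bingo performance
#'
#' A mitochondrion exchanging with `m` partners, each contributing one of the
#' `L` genetic elements uniformly at random, is a coupon collector drawing
#' `m` coupons from `L` types. These closed forms predict, from node degrees
#' alone, how many nodes of an encounter network can assemble the full
#' product set — without simulating the exchange game.
#'
#' @name ccp
NULL

#' Expected number of distinct elements after m uniform draws
#'
#' `L * (1 - (1 - 1/L)^m)`, by linearity over elements.
#'
#' @param L number of element types (>= 1).
#' @param m number of draws (>= 0). Vectorised over `m`.
#' @return Expected count of distinct elements seen.
#' @export
expected_distinct <- function(L, m) {
  stopifnot(L >= 1, all(m >= 0))
  L * (1 - (1 - 1 / L)^m)
}

#' Probability of holding all L elements after m uniform draws
#'
#' Inclusion-exclusion over the `L - owned` still-needed elements, with every
#' draw uniform on all `L` types: `sum_j (-1)^j C(L-owned, j) (1 - j/L)^m`.
#' `owned = 1` conditions on the collector already holding one element (its
#' own genetic complement), so draws of that element are "wasted".
#'
#' @param L number of element types (>= 1).
#' @param m number of draws (>= 0). Vectorised over `m`.
#' @param owned 0 or 1 elements held before drawing.
#' @return Probability in `[0, 1]`.
#' @export
prob_complete <- function(L, m, owned = 0) {
  stopifnot(L >= 1, all(m >= 0), owned %in% c(0, 1))
  need <- L - owned
  j <- 0:need
  signs <- (-1)^j * choose(need, j)
  vapply(m, function(mi) {
    p <- sum(signs * (1 - j / L)^mi)
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Expected number of draws to complete the collection
#'
#' The classical coupon-collector waiting time `L * H_L` (or `L * H_{L-1}`
#' when one element is already owned), with `H_0 = 0`.
#'
#' @param L number of element types (>= 1).
#' @param owned 0 or 1 elements held at the start.
#' @return Expected number of uniform draws.
#' @export
expected_draws_to_complete <- function(L, owned = 0) {
  stopifnot(L >= 1, owned %in% c(0, 1))
  k <- L - owned
  if (k == 0) return(0)
  L * sum(1 / seq_len(k))
}

#' Node-wise coupon-collector prediction of the bingo count
#'
#' Sums, over nodes, the probability that a node with degree `m_i` completes
#' the collection: each of its `m_i` encounter partners is modelled as an
#' independent uniform draw from the `L` elements.
#'
#' @param network an [encounter_network()].
#' @param L number of genetic elements.
#' @param owned 1 (default) if each node's own element counts towards its
#'   collection, else 0.
#' @return Expected number of nodes scoring bingo (in `[0, n]`).
#' @export
predict_bingo_nodewise <- function(network, L, owned = 1) {
  deg <- network_degrees(network)
  sum(prob_complete(L, deg, owned = owned))
}

#' Degree-threshold coupon-collector prediction of the bingo count
#'
#' A coarser scalar predictor: the number of nodes whose degree reaches the
#' `L`-dependent threshold `T(L)`, the expected number of draws needed to
#' complete the collection (rounded up), or the median such number under
#' `rule = "median"`.
#'
#' @param network an [encounter_network()].
#' @param L number of genetic elements.
#' @param owned 1 (default) or 0 elements already held.
#' @param rule `"ceiling"` (default: `T = ceiling(L * H_{L-owned})`) or
#'   `"median"` (`T` = smallest m with completion probability >= 1/2).
#' @return Integer count of nodes with degree >= `T(L)`.
#' @export
predict_bingo_threshold <- function(network, L, owned = 1,
                                    rule = c("ceiling", "median")) {
  rule <- match.arg(rule)
  thr <- if (rule == "ceiling") {
    ceiling(expected_draws_to_complete(L, owned = owned))
  } else {
    m <- 0
    while (prob_complete(L, m, owned = owned) < 0.5) m <- m + 1
    m
  }
  deg <- network_degrees(network)
  sum(deg >= thr)
}
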