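#' Synthetic null-model network generators
#'
#' Seven families of synthetic networks, each constructed to match a reference
#' encounter network's node count `n` (and, where the construction permits,
#' its edge count `e`): Erdos-Renyi (`ER`), three scale-free variants
#' (`SF-i`, `SF-ii`, `SF-iii`), Watts-Strogatz (`WS`), four cliquey variants
#' (`clique-a` ... `clique-d`), geometric random graphs (`GRG`) and star
#' graphs (`star`). All generators return simple graphs (no self-loops or
#' multi-edges) with exactly `n` nodes, carry no timestamps, and are
#' reproducible under a fixed seed.
#'
#' @name generators
NULL

new_generated_network <- function(edge_mat, n, family, params) {
  nodes <- sprintf("v%d", seq_len(n))
  edges <- NULL
  if (nrow(edge_mat) > 0) {
    a <- pmin(edge_mat[, 1], edge_mat[, 2])
    b <- pmax(edge_mat[, 1], edge_mat[, 2])
    edges <- data.frame(from = nodes[a], to = nodes[b],
                        t_first = NA_real_, count = 1L,
                        stringsAsFactors = FALSE)
  }
  encounter_network(nodes, edges,
                    metadata = c(list(family = family), params))
}

check_ne <- function(n, e) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  max_e <- n * (n - 1) / 2
  if (!is.numeric(e) || length(e) != 1 || e < 0 || e != round(e) ||
      e > max_e) {
    stop(sprintf("`e` must be an integer in [0, %d] for n = %d nodes",
                 max_e, n), call. = FALSE)
  }
  invisible(NULL)
}

pair_key <- function(a, b) {
  pmin(a, b) + pmax(a, b) * 2^26
}

# Shared padding routine: add uniformly random missing edges (as an integer
# matrix of endpoint pairs) until `e` total. Used by SF-iii, clique-c/d, star.
pad_random_edges <- function(edge_mat, n, e) {
  have <- nrow(edge_mat)
  if (have > e) {
    stop(sprintf("construction already has %d edges, more than target e = %d",
                 have, e), call. = FALSE)
  }
  if (have == e) return(edge_mat)
  existing <- new.env(parent = emptyenv())
  for (k in as.character(pair_key(edge_mat[, 1], edge_mat[, 2]))) {
    existing[[k]] <- TRUE
  }
  while (have < e) {
    ab <- sample.int(n, 2)
    k <- as.character(pair_key(ab[1], ab[2]))
    if (is.null(existing[[k]])) {
      existing[[k]] <- TRUE
      edge_mat <- rbind(edge_mat, ab)
      have <- have + 1
    }
  }
  edge_mat
}

#' @describeIn generators Erdos-Renyi: `e` edges placed between uniformly
#'   chosen distinct pairs, repeats rejected.
#' @param n node count.
#' @param e edge count.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return An [encounter_network()].
#' @export
generate_er <- function(n, e, seed = NULL) {
  check_ne(n, e)
  with_seed(seed, {
    # uniform rejection sampling of distinct pairs is distributionally a
    # uniform e-subset of all pairs; sample the subset directly
    idx <- sample.int(n * (n - 1) / 2, e)
    # unrank: pair j among upper-triangle pairs ordered column-major
    b <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    a <- idx - (b - 1) * (b - 2) / 2
    new_generated_network(cbind(as.integer(a), as.integer(b)), n,
                          "ER", list(n = n, e = e, seed = seed))
  })
}

#' @describeIn generators Scale-free, three variants. (i) `e` repetitions of
#'   endpoint sampling with probability proportional to degree + 1 (the +1
#'   lets an empty graph bootstrap); (ii) a path seed graph enforcing
#'   connectivity, then as (i); (iii) sequential node arrival with
#'   preferential attachment to one existing node, then padding as (i).
#' @param variant `"i"`, `"ii"` or `"iii"`.
#' @export
generate_sf <- function(n, e, variant = c("i", "ii", "iii"), seed = NULL) {
  check_ne(n, e)
  variant <- match.arg(variant)
  if (variant %in% c("ii", "iii") && e < n - 1) {
    stop(sprintf("SF variant %s needs e >= n - 1 (seed structure has %d edges)",
                 variant, n - 1), call. = FALSE)
  }
  with_seed(seed, {
    deg <- integer(n)
    edge_mat <- matrix(integer(), 0, 2)
    existing <- new.env(parent = emptyenv())
    add_edge <- function(a, b) {
      edge_mat <<- rbind(edge_mat, c(a, b))
      existing[[as.character(pair_key(a, b))]] <- TRUE
      deg[c(a, b)] <<- deg[c(a, b)] + 1L
    }
    if (variant == "ii") {
      for (i in seq_len(n - 1)) add_edge(i, i + 1L)
    }
    if (variant == "iii") {
      for (i in 2:n) {
        prev <- seq_len(i - 1)
        w <- deg[prev]
        if (sum(w) == 0) w <- rep(1, length(prev))
        a <- if (length(prev) == 1) prev else sample(prev, 1, prob = w)
        add_edge(a, i)
      }
    }
    guard <- 0
    while (nrow(edge_mat) < e) {
      ab <- sample.int(n, 2, prob = deg + 1)
      if (is.null(existing[[as.character(pair_key(ab[1], ab[2]))]])) {
        add_edge(ab[1], ab[2])
        guard <- 0
      } else if ((guard <- guard + 1) > 1e6) {
        stop("degree-proportional sampling failed to place new edges",
             call. = FALSE)
      }
    }
    new_generated_network(edge_mat, n, paste0("SF-", variant),
                          list(n = n, e = e, variant = variant, seed = seed))
  })
}

#' @describeIn generators Watts-Strogatz: ring lattice whose per-node forward
#'   neighbour counts round the half mean degree `e/n` to adjacent integers
#'   (mean-preserving, and summing exactly to `e`), followed by rewiring each
#'   forward edge with probability `rewire_prob` to a uniform non-duplicate
#'   target.
#' @param rewire_prob probability that a lattice edge is rewired.
#' @export
generate_ws <- function(n, e, rewire_prob = 0.1, seed = NULL) {
  check_ne(n, e)
  assert_scalar_number(rewire_prob, "rewire_prob", lower = 0, upper = 1)
  if (e > n * floor((n - 1) / 2)) {
    stop("ring lattice cannot host this many edges without wrap-around ",
         "collisions; reduce e", call. = FALSE)
  }
  with_seed(seed, {
    base_f <- e %/% n
    n_up <- e - n * base_f
    f <- rep(base_f, n)
    if (n_up > 0) f[sample.int(n, n_up)] <- base_f + 1L
    existing <- new.env(parent = emptyenv())
    edge_mat <- matrix(integer(), 0, 2)
    for (i in seq_len(n)) {
      if (f[i] == 0) next
      for (d in seq_len(f[i])) {
        j <- ((i + d - 1L) %% n) + 1L
        edge_mat <- rbind(edge_mat, c(i, j))
        existing[[as.character(pair_key(i, j))]] <- TRUE
      }
    }
    # rewire forward edges
    for (r in seq_len(nrow(edge_mat))) {
      if (stats::runif(1) < rewire_prob) {
        i <- edge_mat[r, 1]
        repeat {
          j <- sample.int(n, 1)
          if (j != i &&
              is.null(existing[[as.character(pair_key(i, j))]])) break
        }
        rm(list = as.character(pair_key(i, edge_mat[r, 2])), envir = existing)
        existing[[as.character(pair_key(i, j))]] <- TRUE
        edge_mat[r, 2] <- j
      }
    }
    new_generated_network(edge_mat, n, "WS",
                          list(n = n, e = e, rewire_prob = rewire_prob,
                               seed = seed))
  })
}

#' @describeIn generators Cliquey networks: the `n` nodes are partitioned into
#'   `floor(n/c)` cliques of size `c` (any remainder nodes form one smaller
#'   clique). Variant `a` stops there; `b` joins consecutive cliques with
#'   single bridging edges; `c` and `d` pad variants `a`/`b` with random edges
#'   up to `e` total (an error if the clique edges alone already exceed `e`).
#' @param clique_size clique size `c` (>= 2, <= n).
#' @export
generate_cliquey <- function(n, e = NULL, clique_size,
                             variant = c("a", "b", "c", "d"), seed = NULL) {
  variant <- match.arg(variant)
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(clique_size) || clique_size < 2 ||
      clique_size != round(clique_size) || clique_size > n) {
    stop("`clique_size` must be an integer in [2, n]", call. = FALSE)
  }
  padded <- variant %in% c("c", "d")
  if (padded && is.null(e)) {
    stop("padded variants need a target edge count `e`", call. = FALSE)
  }
  with_seed(seed, {
    sizes <- rep(clique_size, n %/% clique_size)
    if (n %% clique_size > 0) sizes <- c(sizes, n %% clique_size)
    stop_at <- cumsum(sizes)
    start_at <- c(1, utils::head(stop_at, -1) + 1)
    edge_mat <- matrix(integer(), 0, 2)
    members <- vector("list", length(sizes))
    for (k in seq_along(sizes)) {
      mem <- seq.int(start_at[k], stop_at[k])
      members[[k]] <- mem
      if (length(mem) >= 2) {
        pairs <- utils::combn(mem, 2)
        edge_mat <- rbind(edge_mat, t(pairs))
      }
    }
    if (variant %in% c("b", "d") && length(members) >= 2) {
      for (k in seq_len(length(members) - 1)) {
        a <- if (length(members[[k]]) == 1) members[[k]] else
          sample(members[[k]], 1)
        b <- if (length(members[[k + 1]]) == 1) members[[k + 1]] else
          sample(members[[k + 1]], 1)
        edge_mat <- rbind(edge_mat, c(a, b))
      }
    }
    if (padded) {
      check_ne(n, e)
      if (nrow(edge_mat) > e) {
        stop(sprintf(
          "clique structure has %d edges, exceeding target e = %d",
          nrow(edge_mat), e), call. = FALSE)
      }
      edge_mat <- pad_random_edges(edge_mat, n, e)
    }
    new_generated_network(edge_mat, n, paste0("clique-", variant),
                          list(n = n, e = nrow(edge_mat),
                               clique_size = clique_size,
                               variant = variant, seed = seed))
  })
}

#' @describeIn generators Geometric random graph: `n` uniform points in the
#'   unit square; edges added between the currently unlinked pair at minimal
#'   Euclidean distance until `e` edges exist. Point coordinates are stored in
#'   the result's metadata.
#' @export
generate_grg <- function(n, e, seed = NULL) {
  check_ne(n, e)
  with_seed(seed, {
    x <- stats::runif(n)
    y <- stats::runif(n)
    d <- as.matrix(stats::dist(cbind(x, y)))
    ut <- which(upper.tri(d), arr.ind = TRUE)
    dd <- d[upper.tri(d)]
    sel <- order(dd)[seq_len(e)]
    edge_mat <- cbind(ut[sel, 1], ut[sel, 2])
    new_generated_network(edge_mat, n, "GRG",
                          list(n = n, e = e, seed = seed,
                               points = cbind(x = x, y = y)))
  })
}

#' @describeIn generators Star graph: one hub connected to all other nodes,
#'   padded with random edges up to `e` (requires `e >= n - 1`).
#' @export
generate_star <- function(n, e, seed = NULL) {
  check_ne(n, e)
  if (e < n - 1) {
    stop("star graph needs e >= n - 1", call. = FALSE)
  }
  with_seed(seed, {
    edge_mat <- cbind(1L, seq.int(2L, n))
    edge_mat <- pad_random_edges(edge_mat, n, e)
    new_generated_network(edge_mat, n, "star",
                          list(n = n, e = e, seed = seed))
  })
}

#' Generate a network by family label
#'
#' Dispatcher over the generator families, using the labels of
#' [generators]: `"ER"`, `"SF-i"`, `"SF-ii"`, `"SF-iii"`, `"WS"`,
#' `"clique-a"` ... `"clique-d"`, `"GRG"`, `"star"`.
#'
#' @param family family label.
#' @param n,e node and edge counts.
#' @param clique_size clique size for the clique families.
#' @param rewire_prob rewiring probability for `WS`.
#' @param seed integer seed.
#' @return An [encounter_network()].
#' @export
generate_network <- function(family, n, e, clique_size = 3,
                             rewire_prob = 0.1, seed = NULL) {
  switch(
    family,
    "ER" = generate_er(n, e, seed = seed),
    "SF-i" = generate_sf(n, e, "i", seed = seed),
    "SF-ii" = generate_sf(n, e, "ii", seed = seed),
    "SF-iii" = generate_sf(n, e, "iii", seed = seed),
    "WS" = generate_ws(n, e, rewire_prob = rewire_prob, seed = seed),
    "clique-a" = generate_cliquey(n, clique_size = clique_size,
                                  variant = "a", seed = seed),
    "clique-b" = generate_cliquey(n, clique_size = clique_size,
                                  variant = "b", seed = seed),
    "clique-c" = generate_cliquey(n, e, clique_size = clique_size,
                                  variant = "c", seed = seed),
    "clique-d" = generate_cliquey(n, e, clique_size = clique_size,
                                  variant = "d", seed = seed),
    "GRG" = generate_grg(n, e, seed = seed),
    "star" = generate_star(n, e, seed = seed),
    stop("unknown network family: ", family, call. = FALSE)
  )
}
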