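# Fixtures and independent oracles shared across the test files.
# Everything is generated in code; no binary data.

# trajectory set from a compact description: per-track x positions (y = 0),
# frames 0..(len-1), regular frame interval
make_tracks <- function(xs, frame_interval = 1.0) {
  pts <- do.call(rbind, lapply(names(xs), function(id) {
    x <- xs[[id]]
    data.frame(track_id = id, frame = seq_along(x) - 1L,
               t_s = (seq_along(x) - 1L) * frame_interval,
               x_um = x, y_um = 0, stringsAsFactors = FALSE)
  }))
  trajectory_set(pts, frame_interval = frame_interval)
}

# general fixture: data frame of (track_id, frame, x, y)
make_tracks_xy <- function(df, frame_interval = 1.0) {
  df$t_s <- df$frame * frame_interval
  df$x_um <- df$x
  df$y_um <- df$y
  trajectory_set(df[c("track_id", "frame", "t_s", "x_um", "y_um")],
                 frame_interval = frame_interval)
}

# brute-force encounter-network oracle: exhaustive per-frame pairwise check
oracle_edges <- function(trajectories, threshold) {
  pts <- trajectories$points
  found <- list()
  for (fr in sort(unique(pts$frame))) {
    sub <- pts[pts$frame == fr, ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        d <- sqrt((sub$x_um[i] - sub$x_um[j])^2 +
                  (sub$y_um[i] - sub$y_um[j])^2)
        if (d <= threshold) {
          key <- paste(sort(c(sub$track_id[i], sub$track_id[j])),
                       collapse = "|")
          if (is.null(found[[key]])) found[[key]] <- sub$t_s[i]
        }
      }
    }
  }
  found
}

edge_keys <- function(network) {
  if (network_e(network) == 0) return(character())
  sort(paste(network$edges$from, network$edges$to, sep = "|"))
}

# hand-built encounter network from an edge matrix (character endpoints)
net_from_pairs <- function(nodes, pairs, t_first = NA_real_) {
  edges <- NULL
  if (length(pairs) > 0) {
    edges <- data.frame(from = vapply(pairs, `[`, character(1), 1),
                        to = vapply(pairs, `[`, character(1), 2),
                        t_first = t_first, count = 1L,
                        stringsAsFactors = FALSE)
  }
  encounter_network(nodes, edges)
}

# exhaustive coupon-collector oracle: enumerate all L^m equally likely draw
# sequences
enum_prob_complete <- function(L, m, owned = 0) {
  needed <- if (owned == 1) setdiff(seq_len(L), 1L) else seq_len(L)
  if (length(needed) == 0) return(1)
  if (m == 0) return(0)
  draws <- as.matrix(expand.grid(rep(list(seq_len(L)), m)))
  mean(apply(draws, 1, function(s) all(needed %in% s)))
}

enum_expected_distinct <- function(L, m) {
  if (m == 0) return(0)
  draws <- as.matrix(expand.grid(rep(list(seq_len(L)), m)))
  mean(apply(draws, 1, function(s) length(unique(s))))
}

# Floyd-Warshall all-pairs shortest paths oracle on an encounter network
oracle_distances <- function(network) {
  n <- network_n(network)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  idx <- stats::setNames(seq_len(n), network$nodes)
  ed <- network$edges
  for (r in seq_len(nrow(ed))) {
    i <- idx[[ed$from[r]]]
    j <- idx[[ed$to[r]]]
    d[i, j] <- 1
    d[j, i] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  dimnames(d) <- list(network$nodes, network$nodes)
  d
}

# simple graph sanity: no loops, no duplicate pairs
expect_simple_graph <- function(network, n = NULL, e = NULL) {
  ed <- network$edges
  expect_false(any(ed$from == ed$to))
  expect_equal(anyDuplicated(paste(ed$from, ed$to)), 0)
  if (!is.null(n)) expect_equal(network_n(network), n)
  if (!is.null(e)) expect_equal(network_e(network), e)
}
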