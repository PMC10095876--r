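#' Encounter networks
#'
#' An `encounter_network` records which organelles came within a threshold
#' distance of one another during an observation window. Nodes are organelle
#' (track) identifiers; each undirected edge carries the time of first contact
#' and the number of frames on which the pair was in contact. Networks from
#' synthetic generators carry no timestamps (`t_first` is `NA`); the bingo
#' game then assigns them a seeded random temporal order.
#'
#' @param nodes character vector of node identifiers (may include isolated
#'   nodes).
#' @param edges data frame with columns `from`, `to`, `t_first`, `count`. Pairs
#'   must be unique and free of self-loops; `from`/`to` order is canonicalised.
#' @param window_length observation window in seconds (`NA` if unknown).
#' @param metadata optional named list describing provenance (generator family,
#'   parameters, seed, ...).
#'
#' @return An object of class `encounter_network`.
#' @export
encounter_network <- function(nodes, edges = NULL, window_length = NA_real_,
                              metadata = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node ids", call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        t_first = numeric(), count = integer(),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(edges))
    if (!all(c("from", "to") %in% names(edges))) {
      stop("`edges` needs columns from, to", call. = FALSE)
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!"t_first" %in% names(edges)) edges$t_first <- NA_real_
    if (!"count" %in% names(edges)) edges$count <- 1L
    edges <- edges[c("from", "to", "t_first", "count")]
    if (any(edges$from == edges$to)) {
      stop("self-loops are not allowed", call. = FALSE)
    }
    unknown <- setdiff(c(edges$from, edges$to), nodes)
    if (length(unknown) > 0) {
      stop("edge endpoints not in node set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    flip <- edges$from > edges$to
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      stop("duplicate edges", call. = FALSE)
    }
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, window_length = window_length,
         metadata = metadata),
    class = "encounter_network"
  )
}

#' @export
print.encounter_network <- function(x, ...) {
  fam <- x$metadata$family %||% "encounter"
  cat(sprintf("<encounter_network [%s]: n = %d, e = %d>\n",
              fam, network_n(x), network_e(x)))
  invisible(x)
}

#' Node and edge counts of an encounter network
#' @param network an [encounter_network()].
#' @return integer count.
#' @export
network_n <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  length(network$nodes)
}

#' @rdname network_n
#' @export
network_e <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  nrow(network$edges)
}

#' Node degrees of an encounter network
#' @param network an [encounter_network()].
#' @return named integer vector, one entry per node (zero for singletons).
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0) {
    tab <- table(c(network$edges$from, network$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Convert an encounter network to an igraph graph
#'
#' Edge attributes `t_first` and `count` are preserved. Used internally for
#' the path-based summary statistics.
#'
#' @param network an [encounter_network()].
#' @return an `igraph` object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Build an encounter network from trajectories
#'
#' Two tracks are linked by an edge if their positions are ever within
#' `threshold` micrometres of each other in the same frame; distances are
#' plain 2D Euclidean and are never interpolated between frames. The first
#' such frame sets the edge's `t_first`; each further frame in contact
#' increments `count`. Tracks that never approach anyone remain as
#' degree-zero nodes.
#'
#' @param trajectories a [trajectory_set()].
#' @param threshold colocalisation distance in micrometres (> 0).
#' @return An [encounter_network()] with one node per track.
#' @export
build_encounter_network <- function(trajectories, threshold) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  assert_scalar_number(threshold, "threshold",
                       lower = .Machine$double.eps)
  pts <- trajectories$points
  nodes <- unique(pts$track_id)
  if (nrow(pts) == 0) {
    return(encounter_network(character(),
                             window_length = trajectories$window_length))
  }
  first_time <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  by_frame <- split(pts, pts$frame)
  frames <- as.numeric(names(by_frame))
  for (k in order(frames)) {
    fr <- by_frame[[k]]
    m <- nrow(fr)
    if (m < 2) next
    d <- as.matrix(stats::dist(cbind(fr$x_um, fr$y_um)))
    hit <- which(d <= threshold & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) == 0) next
    a <- fr$track_id[hit[, 1]]
    b <- fr$track_id[hit[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    keys <- paste(a, b, sep = "\r")
    tt <- fr$t_s[1]
    for (i in seq_along(keys)) {
      key <- keys[i]
      if (is.null(first_time[[key]])) {
        first_time[[key]] <- tt
        counts[[key]] <- 1L
      } else {
        counts[[key]] <- counts[[key]] + 1L
      }
    }
  }
  keys <- ls(first_time)
  if (length(keys) == 0) {
    return(encounter_network(nodes,
                             window_length = trajectories$window_length))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    t_first = vapply(keys, function(k) first_time[[k]], numeric(1)),
    count = vapply(keys, function(k) counts[[k]], integer(1)),
    stringsAsFactors = FALSE
  )
  encounter_network(nodes, edges,
                    window_length = trajectories$window_length)
}

#' Truncate trajectories to their first frames
#'
#' Keeps only the first `max_frames` observations of every track, emulating a
#' shorter observation window so that the effect of finite tracking time on
#' the encounter network can be studied.
#'
#' @param trajectories a [trajectory_set()].
#' @param max_frames keep at most this many observations per track (>= 1).
#' @return A [trajectory_set()].
#' @export
truncate_trajectories <- function(trajectories, max_frames) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (!is.numeric(max_frames) || length(max_frames) != 1L ||
      is.na(max_frames) || max_frames < 1) {
    stop("`max_frames` must be a single integer >= 1", call. = FALSE)
  }
  pts <- trajectories$points
  keep <- unlist(lapply(split(seq_len(nrow(pts)), pts$track_id),
                        function(idx) idx[seq_len(min(length(idx), max_frames))]),
                 use.names = FALSE)
  trajectory_set(pts[sort(keep), , drop = FALSE],
                 frame_interval = trajectories$frame_interval,
                 pixel_scale = trajectories$pixel_scale,
                 window_length = trajectories$window_length)
}

#' Remove degree-zero nodes from a network
#'
#' Singletons occur in biological encounter networks simply because the
#' observation window is finite; this removes them while leaving the edge set
#' untouched.
#'
#' @param network an [encounter_network()].
#' @return An [encounter_network()] without isolated nodes.
#' @export
prune_singletons <- function(network) {
  stopifnot(inherits(network, "encounter_network"))
  deg <- network_degrees(network)
  keep <- names(deg)[deg > 0]
  encounter_network(keep, network$edges,
                    window_length = network$window_length,
                    metadata = network$metadata)
}

#' Read and write encounter networks as edge lists
#'
#' Plain-text weighted edge list with one line per edge:
#' `node_a<TAB>node_b<TAB>t_first<TAB>count`. Isolated nodes are preserved
#' through comment header lines `# node: <id>`.
#'
#' @param network an [encounter_network()].
#' @param path file path.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns an [encounter_network()].
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "encounter_network"))
  con <- file(path, "w")
  on.exit(close(con))
  deg <- network_degrees(network)
  for (nd in names(deg)[deg == 0]) {
    writeLines(sprintf("# node: %s", nd), con)
  }
  ed <- network$edges
  if (nrow(ed) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%d", ed$from, ed$to,
                       format(ed$t_first, digits = 17), ed$count), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  node_lines <- grep("^# node: ", lines, value = TRUE)
  singletons <- sub("^# node: ", "", node_lines)
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(data_lines) == 0) {
    return(encounter_network(singletons))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 4)
  if (length(bad) > 0) {
    stop("malformed edge list line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    t_first = as.numeric(vapply(parts, `[`, character(1), 3)),
    count = as.integer(vapply(parts, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  nodes <- c(unique(c(edges$from, edges$to)), singletons)
  encounter_network(nodes, edges)
}

#' Write an encounter network as GraphML
#'
#' Delegates to igraph's GraphML writer; the `t_first` and `count` edge
#' attributes travel with the file.
#'
#' @param network an [encounter_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Temporal order of edges
#'
#' Returns the edge indices of `network` sorted by first-contact time, with
#' ties (and fully timestamp-free networks) broken by a seeded shuffle so the
#' ordering is always total. This is the ordering along which the bingo game
#' enables a growing proportion `q` of encounters.
#'
#' @param network an [encounter_network()].
#' @param seed integer seed for the tie-break shuffle (`NULL` uses the current
#'   RNG stream).
#' @return Integer vector: a permutation of `seq_len(network_e(network))`.
#' @export
edge_temporal_order <- function(network, seed = NULL) {
  stopifnot(inherits(network, "encounter_network"))
  e <- network_e(network)
  if (e == 0) return(integer())
  t_first <- network$edges$t_first
  with_seed(seed, {
    jitter <- sample.int(e)
    if (all(is.na(t_first))) {
      jitter
    } else {
      order(t_first, jitter)
    }
  })
}
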