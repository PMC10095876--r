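#' Bingo game configuration
#'
#' The "bingo" game models exchange of genetic material on an encounter
#' network. Each node (mitochondrion) carries a DNA complement — a subset of
#' the `L` distinct genetic elements that together constitute the full
#' mtDNA-encoded product set — and a level in `[0, 1]` for each of the `L`
#' gene products. Expression is fast compared to decay, so a product whose
#' gene is present sits at level 1; products without a local gene decay
#' exponentially at rate `nu`. Encounters, visited in temporal order, may
#' permit exchange: DNA complements are combined (`union` mode) or traded
#' (`swap` mode), products backed by a gene jump to level 1, and levels of
#' products without a gene in either partner are averaged. A node scores a
#' *bingo* when all `L` products sit above the threshold `tau`.
#'
#' @param L number of distinct genetic elements (>= 1).
#' @param tau product-level threshold in (0, 1) used by the bingo score.
#' @param nu product decay rate; per second when the network carries real
#'   first-contact times, per unit edge step for timestamp-free networks.
#'   The default corresponds to a 1-hour half-life in seconds.
#' @param ic initial condition: `"empty"` (each node has only the product of
#'   its own genetic element) or `"full"` (every product at level 1).
#' @param scoring `"ever"` (a node counts once it has ever held a full
#'   product set) or `"final"` (it must hold one at the end of the window).
#'   Default: `"ever"` for empty ICs, `"final"` for full ICs.
#' @param q_grid proportions of encounters that permit exchange, each in
#'   `[0, 1]`; taken as a prefix of the temporal edge order.
#' @param reps number of independent repetitions.
#' @param exchange_mode `"union"` (DNA complements merge; information is
#'   duplicated) or `"swap"` (complements are traded; molecules are
#'   conserved).
#' @param assignment `"uniform"` (each node's genetic element i.i.d. uniform
#'   on `1..L`) or `"round_robin"` (elements dealt cyclically in node order,
#'   guaranteeing all L elements exist in the population).
#' @param seed integer seed.
#' @return An object of class `bingo_config`.
#' @export
bingo_config <- function(L,
                         tau = 0.5,
                         nu = log(2) / 3600,
                         ic = c("empty", "full"),
                         scoring = NULL,
                         q_grid = seq(0, 1, by = 0.1),
                         reps = 10,
                         exchange_mode = c("union", "swap"),
                         assignment = c("uniform", "round_robin"),
                         seed = NULL) {
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L)) {
    stop("`L` must be a single integer >= 1", call. = FALSE)
  }
  assert_scalar_number(tau, "tau", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(nu, "nu", lower = 0)
  ic <- match.arg(ic)
  exchange_mode <- match.arg(exchange_mode)
  assignment <- match.arg(assignment)
  if (is.null(scoring)) {
    scoring <- if (ic == "empty") "ever" else "final"
  }
  scoring <- match.arg(scoring, c("ever", "final"))
  if (any(q_grid < 0 | q_grid > 1)) {
    stop("`q_grid` values must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(q_grid)) {
    stop("`q_grid` must be sorted increasing", call. = FALSE)
  }
  if (!is.numeric(reps) || reps < 1) {
    stop("`reps` must be >= 1", call. = FALSE)
  }
  structure(
    list(L = as.integer(L), tau = tau, nu = nu, ic = ic, scoring = scoring,
         q_grid = q_grid, reps = as.integer(reps),
         exchange_mode = exchange_mode, assignment = assignment, seed = seed),
    class = "bingo_config"
  )
}

#' Initialise a bingo state on a network
#'
#' Each node is assigned exactly one genetic element (uniformly at random, or
#' round-robin in node order). Under the empty initial condition a node's
#' product levels are 1 for its own element and 0 elsewhere; under the full
#' initial condition every level is 1.
#'
#' @param network an [encounter_network()].
#' @param config a [bingo_config()].
#' @return An object of class `bingo_state`: a list with `dna` (list of
#'   integer vectors per node), `levels` (n x L matrix), `bingo_ever`
#'   (logical per node) and `time` (current game time).
#' @export
init_bingo_state <- function(network, config) {
  stopifnot(inherits(network, "encounter_network"),
            inherits(config, "bingo_config"))
  n <- network_n(network)
  L <- config$L
  own <- if (config$assignment == "round_robin") {
    ((seq_len(n) - 1L) %% L) + 1L
  } else {
    sample.int(L, n, replace = TRUE)
  }
  levels <- matrix(if (config$ic == "full") 1 else 0, n, L)
  levels[cbind(seq_len(n), own)] <- 1
  state <- structure(
    list(dna = as.list(own), levels = levels,
         bingo_ever = logical(n), time = 0,
         nodes = network$nodes),
    class = "bingo_state"
  )
  state$bingo_ever <- bingo_score(state, config$tau) >= 1
  state
}

#' Bingo score of each node
#'
#' The proportion of the `L` gene products a node holds at a level strictly
#' above the threshold `tau`; a score of 1 is a *bingo*.
#'
#' @param state a `bingo_state`.
#' @param tau threshold in (0, 1).
#' @return Numeric vector of per-node scores in `[0, 1]`.
#' @export
bingo_score <- function(state, tau) {
  stopifnot(inherits(state, "bingo_state"))
  rowMeans(state$levels > tau)
}

#' Apply product decay to a bingo state
#'
#' Products without a local gene decay as `level * exp(-nu * dt)`; products
#' whose gene is present remain at level 1 (expression is fast relative to
#' decay).
#'
#' @param state a `bingo_state`.
#' @param dt elapsed time (>= 0), in the network's time unit.
#' @param nu decay rate per time unit.
#' @return The updated `bingo_state` (with `time` advanced by `dt`).
#' @export
apply_decay <- function(state, dt, nu) {
  stopifnot(inherits(state, "bingo_state"))
  assert_scalar_number(dt, "dt", lower = 0)
  state$levels <- state$levels * exp(-nu * dt)
  for (i in seq_along(state$dna)) {
    state$levels[i, state$dna[[i]]] <- 1
  }
  state$time <- state$time + dt
  state
}

# decay restricted to two nodes; used by the lazily-clocked game loop
decay_nodes <- function(state, idx, dts, nu) {
  for (k in seq_along(idx)) {
    i <- idx[k]
    state$levels[i, ] <- state$levels[i, ] * exp(-nu * dts[k])
    state$levels[i, state$dna[[i]]] <- 1
  }
  state
}

#' Exchange between two nodes
#'
#' In `union` mode both DNA complements become their union; in `swap` mode
#' they are traded. In both modes each partner's product levels are then
#' updated by one rule: products backed by a gene in that partner's new
#' complement go to level 1, all other products take the arithmetic mean of
#' the two partners' prior levels.
#'
#' @param state a `bingo_state`.
#' @param a,b distinct node indices.
#' @param mode `"union"` or `"swap"`.
#' @return The updated `bingo_state`.
#' @export
exchange <- function(state, a, b, mode = c("union", "swap")) {
  stopifnot(inherits(state, "bingo_state"))
  mode <- match.arg(mode)
  if (a == b) {
    stop("exchange requires two distinct nodes", call. = FALSE)
  }
  if (mode == "union") {
    merged <- union(state$dna[[a]], state$dna[[b]])
    new_a <- merged
    new_b <- merged
  } else {
    new_a <- state$dna[[b]]
    new_b <- state$dna[[a]]
  }
  m <- (state$levels[a, ] + state$levels[b, ]) / 2
  la <- m
  la[new_a] <- 1
  lb <- m
  lb[new_b] <- 1
  state$dna[[a]] <- new_a
  state$dna[[b]] <- new_b
  state$levels[a, ] <- la
  state$levels[b, ] <- lb
  state
}

# Resolve edge times for the game clock. Networks with real first-contact
# times keep them (clock = "real" or "auto"); timestamp-free networks (or
# clock = "rank") place edges at unit spacing 1..e in temporal order, and nu
# is then interpreted per unit step.
game_clock <- function(network, ord, clock) {
  e <- length(ord)
  t_first <- network$edges$t_first[ord]
  use_real <- switch(clock,
                     real = TRUE,
                     rank = FALSE,
                     auto = !any(is.na(t_first)))
  if (use_real) {
    if (any(is.na(t_first))) {
      stop("network has no usable timestamps for clock = \"real\"",
           call. = FALSE)
    }
    t_end <- network$window_length
    if (is.na(t_end) || t_end < max(t_first)) t_end <- max(t_first)
    list(times = t_first, t_end = t_end)
  } else {
    list(times = seq_len(e), t_end = e)
  }
}

#' Play the bingo game on a network
#'
#' For each repetition and each exchange proportion `q` in the config's
#' `q_grid`, the game initialises node complements, walks the network's edges
#' in temporal order, and performs an exchange at the first `ceiling(q * e)`
#' edges. Decay acts continuously in (game) time regardless of which edges
#' permit exchange, and a final decay interval runs to the end of the
#' observation window. The proportion `p` of nodes scoring a bingo is
#' recorded per `(q, rep)`: nodes that have ever held a full product set
#' (`scoring = "ever"`) or that hold one at the window end
#' (`scoring = "final"`).
#'
#' Per repetition, one element assignment and one temporal tie-break order
#' are drawn and reused across the whole `q_grid`, so p(q) curves are
#' comparable across `q` under matched seeds.
#'
#' @param network an [encounter_network()].
#' @param config a [bingo_config()].
#' @param clock `"auto"` (real seconds when the network has timestamps, unit
#'   edge steps otherwise), `"real"`, or `"rank"` (force unit steps; makes
#'   games on differently-clocked networks commensurable).
#' @return An object of class `bingo_result`: list with `p_of_q` (data frame
#'   `q`, `rep`, `p`), `summary` (mean/sd of `p` per `q`), `final_score`
#'   (mean `p` at the largest `q`), `per_node` (bingo counts per node at the
#'   largest `q`, across reps), `empty` flag, and the `config`.
#' @export
play_game <- function(network, config, clock = c("auto", "real", "rank")) {
  stopifnot(inherits(network, "encounter_network"),
            inherits(config, "bingo_config"))
  clock <- match.arg(clock)
  n <- network_n(network)
  e <- network_e(network)
  if (n == 0) {
    return(structure(
      list(p_of_q = data.frame(q = numeric(), rep = integer(),
                               p = numeric()),
           summary = data.frame(q = numeric(), p_mean = numeric(),
                                p_sd = numeric()),
           final_score = NA_real_, per_node = integer(), empty = TRUE,
           config = config),
      class = "bingo_result"))
  }
  from_idx <- match(network$edges$from, network$nodes)
  to_idx <- match(network$edges$to, network$nodes)
  q_grid <- config$q_grid
  reps <- config$reps
  per_node <- integer(n)
  rows_q <- numeric(0)
  rows_rep <- integer(0)
  rows_p <- numeric(0)

  with_seed(config$seed, {
    for (r in seq_len(reps)) {
      ord <- edge_temporal_order(network)
      clk <- game_clock(network, ord, clock)
      state0 <- init_bingo_state(network, config)
      ef <- from_idx[ord]
      et <- to_idx[ord]
      for (q in q_grid) {
        m <- ceiling(q * e)
        # hot loop: operate on plain local objects (in-place updates) rather
        # than the exported state API, which would copy the level matrix at
        # every edge event
        lv <- state0$levels
        dna <- state0$dna
        ever <- state0$bingo_ever
        nu <- config$nu
        tau <- config$tau
        union_mode <- config$exchange_mode == "union"
        last_touch <- numeric(n)  # per-node time of last level update
        if (m > 0) {
          for (k in seq_len(m)) {
            a <- ef[k]
            b <- et[k]
            tk <- clk$times[k]
            la <- lv[a, ] * exp(-nu * (tk - last_touch[a]))
            lb <- lv[b, ] * exp(-nu * (tk - last_touch[b]))
            la[dna[[a]]] <- 1
            lb[dna[[b]]] <- 1
            last_touch[a] <- tk
            last_touch[b] <- tk
            if (union_mode) {
              new_a <- union(dna[[a]], dna[[b]])
              new_b <- new_a
            } else {
              new_a <- dna[[b]]
              new_b <- dna[[a]]
            }
            mm <- (la + lb) / 2
            la <- mm
            la[new_a] <- 1
            lb <- mm
            lb[new_b] <- 1
            dna[[a]] <- new_a
            dna[[b]] <- new_b
            lv[a, ] <- la
            lv[b, ] <- lb
            if (!ever[a] && all(la > tau)) ever[a] <- TRUE
            if (!ever[b] && all(lb > tau)) ever[b] <- TRUE
          }
        }
        # final decay to the window end for every node
        decayed <- lv * exp(-nu * (clk$t_end - last_touch))
        for (i in seq_len(n)) decayed[i, dna[[i]]] <- 1
        bingo <- if (config$scoring == "ever") {
          ever
        } else {
          rowSums(decayed > tau) == config$L
        }
        p <- mean(bingo)
        rows_q <- c(rows_q, q)
        rows_rep <- c(rows_rep, r)
        rows_p <- c(rows_p, p)
        if (q == max(q_grid)) {
          per_node <- per_node + as.integer(bingo)
        }
      }
    }
  })

  p_of_q <- data.frame(q = rows_q, rep = rows_rep, p = rows_p)
  agg_mean <- tapply(p_of_q$p, p_of_q$q, mean)
  agg_sd <- tapply(p_of_q$p, p_of_q$q, stats::sd)
  summary <- data.frame(q = as.numeric(names(agg_mean)),
                        p_mean = as.numeric(agg_mean),
                        p_sd = as.numeric(agg_sd))
  structure(
    list(p_of_q = p_of_q, summary = summary,
         final_score = summary$p_mean[which.max(summary$q)],
         per_node = stats::setNames(per_node, network$nodes),
         empty = FALSE, config = config),
    class = "bingo_result"
  )
}

#' @export
print.bingo_result <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<bingo_result: empty network, p undefined>\n")
    return(invisible(x))
  }
  cat(sprintf("<bingo_result: L = %d, %d reps, final score p = %.3f>\n",
              x$config$L, x$config$reps, x$final_score))
  invisible(x)
}

#' Final bingo scores for a labelled set of networks
#'
#' Runs the game at `q = 1` (all encounters permit exchange) for each network
#' and each value of `L`, and normalises every score by the reference
#' network's score at the same `L` (the reference scores 1 by construction;
#' normalised values are `NA` when the reference score is 0).
#'
#' @param networks named list of [encounter_network()] objects.
#' @param config a [bingo_config()]; its `L` is ignored in favour of
#'   `L_values`, and its `q_grid` is forced to `1`.
#' @param L_values integer vector of `L` values to evaluate.
#' @param reference name of the reference network in `networks`.
#' @param clock passed to [play_game()]; defaults to `"rank"` so that
#'   differently-clocked networks share one decay clock.
#' @return Data frame with columns `label`, `family`, `n`, `e`, `L`,
#'   `score_mean`, `score_sd`, `normalized`.
#' @export
final_score_table <- function(networks, config, L_values = config$L,
                              reference = names(networks)[1],
                              clock = "rank") {
  stopifnot(is.list(networks), length(networks) > 0)
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("`networks` must be a fully named list", call. = FALSE)
  }
  if (!reference %in% names(networks)) {
    stop("reference label not found among networks: ", reference,
         call. = FALSE)
  }
  rows <- list()
  for (L in L_values) {
    for (lab in names(networks)) {
      net <- networks[[lab]]
      cfg <- bingo_config(
        L = L, tau = config$tau, nu = config$nu, ic = config$ic,
        scoring = config$scoring, q_grid = 1, reps = config$reps,
        exchange_mode = config$exchange_mode,
        assignment = config$assignment,
        seed = derive_seed(config$seed, L * 1000 + match(lab, names(networks))))
      res <- play_game(net, cfg, clock = clock)
      reps_p <- res$p_of_q$p
      rows[[length(rows) + 1]] <- data.frame(
        label = lab,
        family = net$metadata$family %||% "unknown",
        n = network_n(net), e = network_e(net), L = L,
        score_mean = mean(reps_p), score_sd = stats::sd(reps_p),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ref_scores <- tab[tab$label == reference, c("L", "score_mean")]
  tab$normalized <- tab$score_mean /
    ref_scores$score_mean[match(tab$L, ref_scores$L)]
  tab$normalized[!is.finite(tab$normalized)] <- NA_real_
  rownames(tab) <- NULL
  tab
}
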