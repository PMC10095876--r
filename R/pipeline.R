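#' Build an ensemble of synthetic networks matched to a reference
#'
#' Instantiates the requested generator families, each with the reference
#' network's node count and — where the family supports exact matching — its
#' edge count. Unpadded clique families keep their structurally determined
#' edge counts (recorded as `matched_e = FALSE`); families that are
#' infeasible at the reference's `(n, e)` (for example padded cliques whose
#' clique edges alone exceed `e`) are skipped with a reason rather than
#' aborting the ensemble.
#'
#' @param reference an [encounter_network()].
#' @param families character vector of family labels understood by
#'   [generate_network()].
#' @param clique_sizes named numeric vector: clique size per clique family
#'   label (a label may also be of the form `"clique-a:5"` to set the size
#'   inline).
#' @param rewire_prob rewiring probability for the WS family.
#' @param seed master seed; per-family seeds are derived deterministically.
#' @return A list with `networks` (named list of networks that were built)
#'   and `info` (data frame: label, family, n, e, matched_e, skipped,
#'   reason).
#' @export
matched_ensemble <- function(reference,
                             families = c("ER", "SF-i", "WS", "GRG", "star",
                                          "clique-d:3"),
                             clique_sizes = NULL,
                             rewire_prob = 0.1,
                             seed = NULL) {
  stopifnot(inherits(reference, "encounter_network"))
  n <- network_n(reference)
  e <- network_e(reference)
  networks <- list()
  info <- list()
  for (i in seq_along(families)) {
    label <- families[i]
    fam <- label
    csize <- 3
    if (grepl(":", label, fixed = TRUE)) {
      parts <- strsplit(label, ":", fixed = TRUE)[[1]]
      fam <- parts[1]
      csize <- as.numeric(parts[2])
    } else if (!is.null(clique_sizes) && label %in% names(clique_sizes)) {
      csize <- clique_sizes[[label]]
    }
    net <- tryCatch(
      generate_network(fam, n, e, clique_size = csize,
                       rewire_prob = rewire_prob,
                       seed = derive_seed(seed, i)),
      error = function(err) err
    )
    if (inherits(net, "error")) {
      info[[i]] <- data.frame(label = label, family = fam, n = NA_integer_,
                              e = NA_integer_, matched_e = FALSE,
                              skipped = TRUE,
                              reason = conditionMessage(net),
                              stringsAsFactors = FALSE)
    } else {
      networks[[label]] <- net
      info[[i]] <- data.frame(label = label, family = fam,
                              n = network_n(net), e = network_e(net),
                              matched_e = network_e(net) == e,
                              skipped = FALSE, reason = "",
                              stringsAsFactors = FALSE)
    }
  }
  list(networks = networks, info = do.call(rbind, info))
}

# decay rate giving a half-life of half the reference game length, the
# retention regime of the comparison experiments (products decay on the same
# timescale as the encounter dynamics themselves)
default_comparison_nu <- function(reference_e) {
  log(2) / (reference_e / 2)
}

#' Matched-ensemble bingo comparison
#'
#' The headline experiment: the final bingo score (p at q = 1) of a reference
#' encounter network against a panel of synthetic null-model networks built
#' at the reference's node and edge counts, across a grid of `L`. Scores are
#' normalised by the reference's score at each `L`, and structural summary
#' statistics are attached per network.
#'
#' Default study conditions: full initial conditions with final scoring, the
#' `swap` exchange mode (DNA molecules are traded, not duplicated), a shared
#' rank-based decay clock (one unit of time per network-wide encounter), and
#' a decay half-life of half the reference game length — the regime where
#' gene products decay on the timescale of the encounter dynamics, as in the
#' worked hour-scale decay/encounter scenario that motivates the model. All
#' are overridable.
#'
#' @param reference an [encounter_network()] (from trajectories, edge list or
#'   the physical simulator).
#' @param extra_networks optional named list of additional networks to score
#'   as-is (e.g. alternative simulator parameterisations such as a
#'   pure-diffusion run).
#' @param families generator family labels, as in [matched_ensemble()].
#' @param L_values integer vector of `L` values; the default spans the
#'   regimes where small and large network structures trade places.
#' @param reps repetitions per network and `L`.
#' @param ic,scoring,exchange_mode,tau,nu bingo game conditions (see
#'   [bingo_config()]); `nu = NULL` uses the half-game half-life default.
#' @param rewire_prob WS rewiring probability.
#' @param reference_label label used for the reference network.
#' @param seed master seed.
#' @return A list with `scores` (the [final_score_table()] data frame),
#'   `stats` (one row of summary statistics per network), `ensemble_info`
#'   (matching/skip report) and `conditions` (the game conditions used).
#' @export
run_comparison <- function(reference,
                           extra_networks = list(),
                           families = c("ER", "SF-i", "WS", "GRG", "star",
                                        "clique-d:3"),
                           L_values = c(2, 3, 5, 10, 15, 20),
                           reps = 10,
                           ic = "full",
                           scoring = "final",
                           exchange_mode = "swap",
                           tau = 0.5,
                           nu = NULL,
                           rewire_prob = 0.1,
                           reference_label = "reference",
                           seed = NULL) {
  stopifnot(inherits(reference, "encounter_network"))
  ens <- matched_ensemble(reference, families = families,
                          rewire_prob = rewire_prob,
                          seed = derive_seed(seed, 1))
  networks <- c(stats::setNames(list(reference), reference_label),
                extra_networks, ens$networks)
  if (is.null(nu)) {
    nu <- default_comparison_nu(network_e(reference))
  }
  cfg <- bingo_config(L = L_values[1], tau = tau, nu = nu, ic = ic,
                      scoring = scoring, q_grid = 1, reps = reps,
                      exchange_mode = exchange_mode,
                      seed = derive_seed(seed, 2))
  scores <- final_score_table(networks, cfg, L_values = L_values,
                              reference = reference_label, clock = "rank")
  stats_rows <- lapply(names(networks), function(lab) {
    s <- summarize_network(networks[[lab]])
    data.frame(label = lab, n = s$n, e = s$e, mean_degree = s$mean_degree,
               global_efficiency = s$global_efficiency,
               modularity_Q = s$modularity_Q,
               component_count = s$component_count,
               degree_range = s$degree_range,
               singletons = sum(network_degrees(networks[[lab]]) == 0),
               stringsAsFactors = FALSE)
  })
  list(scores = scores,
       stats = do.call(rbind, stats_rows),
       ensemble_info = ens$info,
       conditions = list(ic = ic, scoring = scoring,
                         exchange_mode = exchange_mode, tau = tau, nu = nu,
                         reps = reps, L_values = L_values, clock = "rank",
                         seed = seed))
}

#' Prediction-versus-observation study
#'
#' For each network and each `L`, compares the coupon-collector predictions
#' (node-wise and degree-threshold, see [ccp]) with the observed mean number
#' of nodes scoring bingo in the simulated game, and reports the Spearman
#' rank correlation between prediction and observation across all
#' (network, L) points for each predictor.
#'
#' @param networks named list of [encounter_network()] objects.
#' @param L_values integer vector of `L` values.
#' @param reps game repetitions per network and `L` (default 20).
#' @param owned 1 if a node's own element counts towards its collection.
#' @param ic,scoring,exchange_mode,tau,nu game conditions. The default
#'   (`swap`, no decay, empty start, ever scoring) is the regime the
#'   coupon-collector mapping describes: molecules are conserved, so every
#'   encounter delivers exactly one partner element — one coupon draw.
#'   Under `union` the game vastly outruns the prediction (partners hand
#'   over whole accumulated sets) and only a loose positive rank relation
#'   remains.
#' @param seed master seed.
#' @return A list with `table` (columns label, L, n, e, predicted_nodewise,
#'   predicted_threshold, observed_mean, observed_sd) and the Spearman
#'   correlations `rho_nodewise`, `rho_threshold`.
#' @export
run_prediction_study <- function(networks,
                                 L_values = c(2, 3, 5),
                                 reps = 20,
                                 owned = 1,
                                 ic = "empty",
                                 scoring = "ever",
                                 exchange_mode = "swap",
                                 tau = 0.5,
                                 nu = 0,
                                 seed = NULL) {
  stopifnot(is.list(networks), length(networks) > 0,
            !is.null(names(networks)))
  rows <- list()
  idx <- 0
  for (L in L_values) {
    for (lab in names(networks)) {
      idx <- idx + 1
      net <- networks[[lab]]
      n <- network_n(net)
      cfg <- bingo_config(L = L, tau = tau, nu = nu, ic = ic,
                          scoring = scoring, q_grid = 1, reps = reps,
                          exchange_mode = exchange_mode,
                          seed = derive_seed(seed, idx))
      res <- play_game(net, cfg, clock = "rank")
      counts <- res$p_of_q$p * n
      rows[[idx]] <- data.frame(
        label = lab, L = L, n = n, e = network_e(net),
        predicted_nodewise = predict_bingo_nodewise(net, L, owned = owned),
        predicted_threshold = predict_bingo_threshold(net, L, owned = owned),
        observed_mean = mean(counts), observed_sd = stats::sd(counts),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rho <- function(pred) {
    suppressWarnings(stats::cor(pred, tab$observed_mean,
                                method = "spearman"))
  }
  list(table = tab,
       rho_nodewise = rho(tab$predicted_nodewise),
       rho_threshold = rho(tab$predicted_threshold))
}

#' Pruning / truncation robustness experiment
#'
#' Re-runs the matched-ensemble comparison after transforming the reference:
#' either removing its degree-zero nodes (`mode = "prune"`) or truncating the
#' underlying trajectories to their first `max_frames` observations and
#' rebuilding the network (`mode = "truncate"`). New synthetic ensembles are
#' matched to the transformed network's node and edge counts.
#'
#' @param reference an [encounter_network()] (prune mode), or `NULL` when
#'   truncating (the network is rebuilt from `trajectories`).
#' @param mode `"prune"` or `"truncate"`.
#' @param trajectories a [trajectory_set()] (required for truncate mode).
#' @param max_frames truncation length in frames (truncate mode).
#' @param threshold encounter distance in micrometres used to rebuild the
#'   network from trajectories (truncate mode).
#' @param ... further arguments passed to [run_comparison()].
#' @return A list with `before` and `after` comparison results, and
#'   `transform` describing what changed (n, e, removed nodes).
#' @export
run_robustness <- function(reference = NULL,
                           mode = c("prune", "truncate"),
                           trajectories = NULL,
                           max_frames = NULL,
                           threshold = NULL,
                           ...) {
  mode <- match.arg(mode)
  if (mode == "truncate") {
    if (is.null(trajectories) || is.null(threshold)) {
      stop("truncate mode needs `trajectories` and `threshold`",
           call. = FALSE)
    }
    if (is.null(max_frames)) {
      stop("truncate mode needs `max_frames`", call. = FALSE)
    }
    before_net <- reference %||%
      build_encounter_network(trajectories, threshold)
    after_net <- build_encounter_network(
      truncate_trajectories(trajectories, max_frames), threshold)
  } else {
    if (is.null(reference)) {
      stop("prune mode needs a `reference` network", call. = FALSE)
    }
    before_net <- reference
    after_net <- prune_singletons(reference)
  }
  list(
    before = run_comparison(before_net, ...),
    after = run_comparison(after_net, ...),
    transform = list(
      mode = mode,
      n_before = network_n(before_net), e_before = network_e(before_net),
      n_after = network_n(after_net), e_after = network_e(after_net),
      removed_nodes = setdiff(before_net$nodes, after_net$nodes))
  )
}
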