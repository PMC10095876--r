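#' Physical simulation configuration
#'
#' Parameters of the agent-based model of mitochondrial motion in a 2D
#' rectangular cell domain with reflecting walls. Agents diffuse (diffusion
#' constant `D`), stochastically attach to an implicit cytoskeleton (per-step
#' probability `p_attach`) whereupon they move ballistically at speed `v`
#' along an axis-aligned direction until detaching (`p_detach`), and may
#' stochastically switch between an active state and an inactive state
#' (rates `k_act`, `k_inact` per second) modelling entry to and exit from the
#' region of observation. Inactive agents are frozen and invisible to
#' encounters. Two simultaneously active agents within `r_enc` micrometres
#' add an edge to the growing encounter network.
#'
#' @param domain_width,domain_height domain size in micrometres.
#' @param dt timestep in seconds.
#' @param D diffusion constant, um^2/s.
#' @param v ballistic speed while attached, um/s.
#' @param p_attach,p_detach per-timestep attachment/detachment probabilities.
#' @param k_act,k_inact activation/inactivation rates per second (both 0
#'   disables the entry/exit process and keeps every agent active).
#' @param r_enc encounter radius in micrometres.
#' @param n_agents number of agents.
#' @param target_edges stop once the encounter network has this many edges.
#' @param max_steps hard step limit (an incomplete-network error is raised if
#'   it is reached first).
#' @param seed integer seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(domain_width = 40,
                       domain_height = 10,
                       dt = 0.1,
                       D = 0.1,
                       v = 1.0,
                       p_attach = 0.05,
                       p_detach = 0.2,
                       k_act = 0,
                       k_inact = 0,
                       r_enc = 1.6,
                       n_agents = 100,
                       target_edges = 150,
                       max_steps = 50000,
                       seed = NULL) {
  assert_scalar_number(domain_width, "domain_width", lower = 1e-9)
  assert_scalar_number(domain_height, "domain_height", lower = 1e-9)
  assert_scalar_number(dt, "dt", lower = 1e-12)
  assert_scalar_number(D, "D", lower = 0)
  assert_scalar_number(v, "v", lower = 0)
  assert_scalar_number(p_attach, "p_attach", lower = 0, upper = 1)
  assert_scalar_number(p_detach, "p_detach", lower = 0, upper = 1)
  assert_scalar_number(k_act, "k_act", lower = 0)
  assert_scalar_number(k_inact, "k_inact", lower = 0)
  assert_scalar_number(r_enc, "r_enc", lower = 1e-12)
  assert_scalar_number(n_agents, "n_agents", lower = 1)
  assert_scalar_number(target_edges, "target_edges", lower = 0)
  assert_scalar_number(max_steps, "max_steps", lower = 1)
  structure(
    list(domain_width = domain_width, domain_height = domain_height,
         dt = dt, D = D, v = v,
         p_attach = p_attach, p_detach = p_detach,
         k_act = k_act, k_inact = k_inact,
         r_enc = r_enc, n_agents = as.integer(n_agents),
         target_edges = as.integer(target_edges),
         max_steps = as.integer(max_steps), seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: %g x %g um, dt %g s, D %g um^2/s, v %g um/s,\n  p_att %g, p_det %g, k_act %g/s, k_inact %g/s, r_enc %g um,\n  %d agents, target e %d>\n",
    x$domain_width, x$domain_height, x$dt, x$D, x$v, x$p_attach, x$p_detach,
    x$k_act, x$k_inact, x$r_enc, x$n_agents, x$target_edges))
  invisible(x)
}

# Reflect positions into [0, width], flipping velocity components of bounced
# agents (odd number of reflections reverses the direction of travel).
reflect_axis <- function(pos, vel, width) {
  period <- 2 * width
  w <- pos %% period
  w <- ifelse(w < 0, w + period, w)
  flip <- w > width
  pos_out <- ifelse(flip, period - w, w)
  # an agent ends up direction-reversed when its unfolded position sits in an
  # odd mirror copy of the domain
  mirror_odd <- (floor(pos / width) %% 2) != 0
  vel_out <- ifelse(mirror_odd, -vel, vel)
  list(pos = pos_out, vel = vel_out)
}

#' Initial agent state for a simulation
#'
#' Positions are uniform over the domain; all agents start detached. When the
#' entry/exit process is enabled, initial activity is drawn from its
#' stationary distribution `k_act / (k_act + k_inact)`, otherwise every agent
#' is active.
#'
#' @param config a [sim_config()].
#' @return A list with numeric vectors `x`, `y`, `vx`, `vy` and logical
#'   vectors `attached`, `active`.
#' @export
init_agents <- function(config) {
  n <- config$n_agents
  active <- if (config$k_act + config$k_inact > 0) {
    stats::runif(n) < config$k_act / (config$k_act + config$k_inact)
  } else {
    rep(TRUE, n)
  }
  list(x = stats::runif(n, 0, config$domain_width),
       y = stats::runif(n, 0, config$domain_height),
       vx = numeric(n), vy = numeric(n),
       attached = rep(FALSE, n),
       active = active)
}

#' Advance the physical simulation by one timestep
#'
#' Update order, fixed for reproducibility: displacement (diffusive or
#' ballistic) -> wall reflection -> attachment/detachment resampling ->
#' activation/inactivation. Inactive agents do not move or change attachment.
#' Detached active agents receive independent per-axis Normal(0,
#' sqrt(2 D dt)) displacements; attached active agents move by their velocity
#' vector times `dt`. On attachment, a new velocity is drawn uniformly from
#' the four axis-aligned directions with magnitude `v`. Activity switches
#' occur with probabilities `1 - exp(-k dt)`.
#'
#' @param agents agent state as returned by [init_agents()].
#' @param config a [sim_config()].
#' @return Updated agent state.
#' @export
sim_step <- function(agents, config) {
  n <- config$n_agents
  moving <- agents$active
  diff_move <- moving & !agents$attached
  ball_move <- moving & agents$attached

  dx <- numeric(n)
  dy <- numeric(n)
  nd <- sum(diff_move)
  if (nd > 0) {
    sd_step <- sqrt(2 * config$D * config$dt)
    dx[diff_move] <- stats::rnorm(nd, 0, sd_step)
    dy[diff_move] <- stats::rnorm(nd, 0, sd_step)
  }
  dx[ball_move] <- agents$vx[ball_move] * config$dt
  dy[ball_move] <- agents$vy[ball_move] * config$dt

  rx <- reflect_axis(agents$x + dx, agents$vx, config$domain_width)
  ry <- reflect_axis(agents$y + dy, agents$vy, config$domain_height)
  agents$x[moving] <- rx$pos[moving]
  agents$y[moving] <- ry$pos[moving]
  agents$vx[moving] <- rx$vel[moving]
  agents$vy[moving] <- ry$vel[moving]

  # attachment/detachment (active agents only)
  u <- stats::runif(n)
  attach_now <- moving & !agents$attached & u < config$p_attach
  detach_now <- moving & agents$attached & u < config$p_detach
  if (any(attach_now)) {
    k <- sum(attach_now)
    dir <- sample.int(4, k, replace = TRUE)
    agents$vx[attach_now] <- c(config$v, -config$v, 0, 0)[dir]
    agents$vy[attach_now] <- c(0, 0, config$v, -config$v)[dir]
    agents$attached[attach_now] <- TRUE
  }
  if (any(detach_now)) {
    agents$attached[detach_now] <- FALSE
    agents$vx[detach_now] <- 0
    agents$vy[detach_now] <- 0
  }

  if (config$k_act + config$k_inact > 0) {
    p_on <- 1 - exp(-config$k_act * config$dt)
    p_off <- 1 - exp(-config$k_inact * config$dt)
    u2 <- stats::runif(n)
    turn_on <- !agents$active & u2 < p_on
    turn_off <- agents$active & u2 < p_off
    agents$active[turn_on] <- TRUE
    agents$active[turn_off] <- FALSE
  }
  agents
}

detect_encounters <- function(agents, config) {
  act <- which(agents$active)
  if (length(act) < 2) {
    return(matrix(integer(), 0, 2))
  }
  d <- as.matrix(stats::dist(cbind(agents$x[act], agents$y[act])))
  hit <- which(d <= config$r_enc & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(matrix(integer(), 0, 2))
  }
  cbind(act[hit[, 1]], act[hit[, 2]])
}

#' Run the physical simulation until the target edge count
#'
#' Advances the simulation until the encounter network holds `target_edges`
#' edges (or errors with class `mitobingo_incomplete_network`, carrying the
#' partial results in its `data` field, if `max_steps` is exhausted first).
#' Encounters are recorded between pairs of simultaneously active agents
#' within `r_enc`, including at the initial configuration (step 0).
#'
#' @param config a [sim_config()].
#' @param record_trajectories keep per-step positions? Disable for long
#'   sweeps where only the network is needed.
#' @return A list with elements `network` (an [encounter_network()] with
#'   first-contact timestamps), `trajectories` (a [trajectory_set()], or
#'   `NULL` when recording is off) and `steps` (number of steps taken).
#'   Trajectory rows of inactive agents are dropped, mimicking observation of
#'   only the organelles present in the region.
#' @export
run_until_edges <- function(config, record_trajectories = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    agents <- init_agents(config)
    n <- config$n_agents
    edge_env <- new.env(parent = emptyenv())
    edge_from <- integer(0)
    edge_to <- integer(0)
    edge_t <- numeric(0)
    edge_count <- new.env(parent = emptyenv())
    traj <- if (record_trajectories) vector("list", config$max_steps + 1)
            else NULL

    note_frame <- function(step) {
      if (record_trajectories && any(agents$active)) {
        act <- agents$active
        traj[[step + 1]] <<- cbind(which(act), step,
                                   agents$x[act], agents$y[act])
      }
    }
    absorb <- function(pairs, t_now) {
      if (nrow(pairs) == 0) return(invisible(NULL))
      keys <- paste(pairs[, 1], pairs[, 2], sep = "-")
      for (i in seq_along(keys)) {
        key <- keys[i]
        if (is.null(edge_env[[key]])) {
          edge_env[[key]] <- TRUE
          edge_from <<- c(edge_from, pairs[i, 1])
          edge_to <<- c(edge_to, pairs[i, 2])
          edge_t <<- c(edge_t, t_now)
          edge_count[[key]] <- 1L
        } else {
          edge_count[[key]] <- edge_count[[key]] + 1L
        }
      }
    }

    note_frame(0L)
    absorb(detect_encounters(agents, config), 0)
    step <- 0L
    while (length(edge_from) < config$target_edges &&
           step < config$max_steps) {
      step <- step + 1L
      agents <- sim_step(agents, config)
      note_frame(step)
      absorb(detect_encounters(agents, config), step * config$dt)
    }

    trajectories <- NULL
    if (record_trajectories) {
      tr <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
      if (is.null(tr)) {
        tr <- matrix(numeric(), 0, 4)
      }
      pts <- data.frame(
        track_id = sprintf("a%03d", tr[, 1]),
        frame = as.integer(tr[, 2]),
        t_s = tr[, 2] * config$dt,
        x_um = tr[, 3],
        y_um = tr[, 4],
        stringsAsFactors = FALSE
      )
      trajectories <- trajectory_set(
        pts, frame_interval = config$dt,
        window_length = step * config$dt)
    }
    ids <- sprintf("a%03d", seq_len(n))
    keys <- paste(edge_from, edge_to, sep = "-")
    edges <- if (length(edge_from) > 0) {
      data.frame(
        from = ids[edge_from], to = ids[edge_to], t_first = edge_t,
        count = vapply(keys, function(k) edge_count[[k]], integer(1)),
        stringsAsFactors = FALSE)
    } else NULL
    network <- encounter_network(
      ids, edges, window_length = step * config$dt,
      metadata = list(family = "simulated", config = unclass(config),
                      steps = step))
    result <- list(network = network, trajectories = trajectories,
                   steps = step)
    if (length(edge_from) < config$target_edges) {
      stop(errorCondition(
        sprintf(
          "simulation reached max_steps = %d with only %d of %d edges",
          config$max_steps, length(edge_from), config$target_edges),
        class = c("mitobingo_incomplete_network", "error"),
        data = result))
    }
    result
  })
}

#' Run a sweep of simulation configurations
#'
#' Runs [run_until_edges()] independently for each configuration; per-run
#' failures (e.g. incomplete networks) are captured rather than aborting the
#' sweep.
#'
#' @param configs a (optionally named) list of [sim_config()] objects.
#' @param record_trajectories passed through to [run_until_edges()].
#' @return A named list, one element per config: either the run result or the
#'   captured error condition (check with `inherits(x, "error")`; partial
#'   results are in its `data` field).
#' @export
sweep_simulations <- function(configs, record_trajectories = FALSE) {
  if (length(configs) == 0) {
    stop("`configs` must be a non-empty list", call. = FALSE)
  }
  if (is.null(names(configs))) {
    names(configs) <- sprintf("run%02d", seq_along(configs))
  }
  lapply(configs, function(cf) {
    tryCatch(run_until_edges(cf, record_trajectories = record_trajectories),
             error = function(e) e)
  })
}
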