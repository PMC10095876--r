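test_that("config validation rejects bad parameters", {
  expect_error(sim_config(D = -1), "D")
  expect_error(sim_config(p_attach = 1.5), "p_attach")
  expect_error(sim_config(r_enc = 0), "r_enc")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("motionless parameters freeze every agent", {
  cfg <- sim_config(D = 0, v = 0, p_attach = 0, n_agents = 10,
                    target_edges = 0, max_steps = 10, seed = 1)
  withr::with_seed(1, {
    ag <- init_agents(cfg)
    x0 <- ag$x
    y0 <- ag$y
    for (i in 1:20) ag <- sim_step(ag, cfg)
    expect_equal(ag$x, x0)
    expect_equal(ag$y, y0)
  })
})

test_that("ballistic reflection folds position and reverses direction", {
  # attached agent at x = 1 moving +2 um/s for 1 s in a width-2 domain ends
  # at x = 1 moving in -x
  cfg <- sim_config(domain_width = 2, domain_height = 2, dt = 1, D = 0,
                    v = 2, p_attach = 0, p_detach = 0, n_agents = 1,
                    target_edges = 0, max_steps = 10)
  ag <- list(x = 1, y = 1, vx = 2, vy = 0, attached = TRUE, active = TRUE)
  ag2 <- withr::with_seed(1, sim_step(ag, cfg))
  expect_equal(ag2$x, 1)
  expect_equal(ag2$vx, -2)
  expect_equal(ag2$y, 1)
})

test_that("agents never leave the domain over many steps", {
  cfg <- sim_config(domain_width = 12, domain_height = 3, dt = 0.1,
                    D = 0.5, v = 2, p_attach = 0.2, p_detach = 0.1,
                    n_agents = 25, target_edges = 0, max_steps = 10)
  withr::with_seed(5, {
    ag <- init_agents(cfg)
    for (i in seq_len(4000)) {  # 25 agents x 4000 steps = 1e5 agent-steps
      ag <- sim_step(ag, cfg)
      if (any(ag$x < 0 | ag$x > 12 | ag$y < 0 | ag$y > 3)) {
        fail(sprintf("agent escaped at step %d", i))
      }
    }
    succeed()
  })
})

test_that("pure diffusion reproduces the 2D mean-squared-displacement law", {
  D <- 0.25
  dt <- 0.2
  steps <- 40
  n <- 800
  cfg <- sim_config(domain_width = 1e4, domain_height = 1e4, dt = dt, D = D,
                    v = 0, p_attach = 0, n_agents = n, target_edges = 0,
                    max_steps = steps)
  withr::with_seed(11, {
    ag <- init_agents(cfg)
    # recentre away from walls so reflection never interferes
    ag$x <- rep(5e3, n)
    ag$y <- rep(5e3, n)
    x0 <- ag$x
    y0 <- ag$y
    msd <- numeric(steps)
    for (s in seq_len(steps)) {
      ag <- sim_step(ag, cfg)
      msd[s] <- mean((ag$x - x0)^2 + (ag$y - y0)^2)
    }
    t <- dt * seq_len(steps)
    slope <- stats::coef(stats::lm(msd ~ 0 + t))[[1]]
    expect_equal(slope, 4 * D, tolerance = 0.1)
  })
})

test_that("attachment occupancy converges to its two-state stationary value", {
  p_att <- 0.08
  p_det <- 0.24
  n <- 600
  cfg <- sim_config(D = 0.01, v = 0.5, p_attach = p_att, p_detach = p_det,
                    n_agents = n, target_edges = 0, max_steps = 10,
                    domain_width = 100, domain_height = 100)
  withr::with_seed(21, {
    ag <- init_agents(cfg)
    for (i in seq_len(400)) ag <- sim_step(ag, cfg)  # burn-in >> 1/(p+q)
    frac <- mean(ag$attached)
  })
  pi_att <- p_att / (p_att + p_det)
  se <- sqrt(pi_att * (1 - pi_att) / n)
  expect_lt(abs(frac - pi_att), 3 * se)
})

test_that("the entry/exit process sustains the 10% active regime", {
  k_act <- 0.01
  k_inact <- 0.09
  n <- 800
  cfg <- sim_config(D = 0.01, v = 0, p_attach = 0, k_act = k_act,
                    k_inact = k_inact, dt = 0.5, n_agents = n,
                    target_edges = 0, max_steps = 10,
                    domain_width = 100, domain_height = 100)
  withr::with_seed(31, {
    ag <- init_agents(cfg)
    # start everyone inactive so the test covers relaxation, not the
    # stationary initialisation
    ag$active <- rep(FALSE, n)
    for (i in seq_len(2000)) ag <- sim_step(ag, cfg)
    frac <- mean(ag$active)
  })
  pi_act <- k_act / (k_act + k_inact)
  expect_equal(pi_act, 0.1)
  se <- sqrt(pi_act * (1 - pi_act) / n)
  expect_lt(abs(frac - pi_act), 3 * se)
})

test_that("run_until_edges stops at the target and is deterministic", {
  cfg <- sim_config(n_agents = 25, target_edges = 20, seed = 42,
                    max_steps = 20000)
  r1 <- run_until_edges(cfg, record_trajectories = FALSE)
  expect_gte(network_e(r1$network), 20)
  expect_equal(network_n(r1$network), 25)
  r2 <- run_until_edges(cfg, record_trajectories = FALSE)
  expect_identical(r1$network$edges, r2$network$edges)
})

test_that("two agents born in contact finish at step zero", {
  cfg <- sim_config(n_agents = 2, target_edges = 1, r_enc = 100,
                    domain_width = 10, domain_height = 10, seed = 3,
                    max_steps = 10)
  r <- run_until_edges(cfg)
  expect_equal(r$steps, 0)
  expect_equal(network_e(r$network), 1)
  expect_equal(r$network$edges$t_first, 0)
})

test_that("an unreachable edge target raises an incomplete-network error", {
  # all agents permanently inactive: no encounters can ever occur
  cfg <- sim_config(n_agents = 10, target_edges = 5, k_act = 0,
                    k_inact = 10, seed = 4, max_steps = 50)
  expect_error(run_until_edges(cfg), class = "mitobingo_incomplete_network")
  cond <- tryCatch(run_until_edges(cfg), condition = function(c) c)
  expect_s3_class(cond$data$network, "encounter_network")
  expect_lt(network_e(cond$data$network), 5)
})

test_that("exported trajectories reproduce the simulator's network exactly", {
  for (seed in c(7, 8)) {
    cfg <- sim_config(n_agents = 30, target_edges = 40, seed = seed,
                      k_act = 0.05, k_inact = 0.05, max_steps = 20000)
    r <- run_until_edges(cfg, record_trajectories = TRUE)
    rebuilt <- build_encounter_network(r$trajectories, cfg$r_enc)
    expect_setequal(edge_keys(rebuilt), edge_keys(r$network))
    ord1 <- order(paste(r$network$edges$from, r$network$edges$to))
    ord2 <- order(paste(rebuilt$edges$from, rebuilt$edges$to))
    expect_equal(r$network$edges$t_first[ord1],
                 rebuilt$edges$t_first[ord2])
    expect_equal(r$network$edges$count[ord1], rebuilt$edges$count[ord2])
  }
})

test_that("sweeps run every configuration and capture failures", {
  cfgs <- list(
    ok = sim_config(n_agents = 10, target_edges = 3, seed = 1,
                    max_steps = 5000),
    doomed = sim_config(n_agents = 5, target_edges = 10, k_inact = 10,
                        seed = 2, max_steps = 20)
  )
  res <- sweep_simulations(cfgs)
  expect_named(res, c("ok", "doomed"))
  expect_s3_class(res$ok$network, "encounter_network")
  expect_s3_class(res$doomed, "mitobingo_incomplete_network")
  expect_error(sweep_simulations(list()), "non-empty")
})
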