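test_that("local growth rate reproduces hand-computed values", {
  cfg <- sim_config()
  net <- make_network(rho = matrix(0.2, 1, 1), beta = matrix(0, 1, 1),
                      alpha = matrix(0.1, 1, 1), r0 = 0.1)
  # facilitative mediator at its saturation concentration adds rho/2
  expect_equal(local_growth_rate(1, cfg$k_sat, net, cfg), 0.1 + 0.2 / 2)
  # no mediators, negligible crowding: rate is the basal rate
  expect_equal(local_growth_rate(1, 0, net, cfg), 0.1, tolerance = 1e-8)
  # crowding at capacity kills all growth regardless of mediators
  expect_equal(local_growth_rate(cfg$k_Y, cfg$k_sat, net, cfg), 0)
  # inhibition is linear in concentration
  inh <- make_network(rho = matrix(-0.2, 1, 1), beta = matrix(0, 1, 1),
                      alpha = matrix(0.1, 1, 1), r0 = 0.1)
  expect_equal(local_growth_rate(1, 2 * cfg$k_sat, inh, cfg),
               0.1 - 0.2 * 2, tolerance = 1e-8)
  expect_error(local_growth_rate(-1, 0, net, cfg), "nonnegative")
})

test_that("a lone species grows exponentially at its basal rate", {
  net <- lone_species_network(r0 = 0.2)
  cfg <- sim_config(k_Y = Inf)
  wm <- simulate_well_mixed(well_mixed_state(100, 0), net, cfg, t_target = 10)
  expect_equal(wm$final$S, 100 * exp(0.2 * 10), tolerance = 1e-3)
  # same in space from a uniform field
  st <- spatial_state(matrix(100, 1, cfg$n_z), matrix(0, 1, cfg$n_z))
  sp <- advance(st, net, cfg, t_target = 10)
  expect_equal(as.numeric(sp$final$S), rep(100 * exp(2), cfg$n_z),
               tolerance = 1e-3)
})

test_that("growth/uptake step updates mediators by net production", {
  cfg <- tiny_cfg()
  net <- make_network(rho = matrix(0, 2, 1), beta = matrix(c(0.1, 0), 1, 2),
                      alpha = matrix(0, 1, 2), r0 = c(0.1, 0.1))
  S <- matrix(0, 2, cfg$n_z)
  S[1, 1:5] <- 1e4       # producer occupies the left end
  S[2, 6:10] <- 1e4      # non-producer elsewhere
  st <- spatial_state(S, matrix(0, 1, cfg$n_z))
  out <- step_growth(st, net, cfg)
  expect_equal(out$C[1, 1:5], rep(0.1 * 1e4 * cfg$dtau, 5))
  expect_true(all(out$C[1, 6:cfg$n_z] == 0))
  expect_equal(out$t, cfg$dtau)

  # no production, no consumption: mediators untouched
  quiet <- make_network(rho = matrix(0.1, 2, 1), beta = matrix(0, 1, 2),
                        alpha = matrix(0, 1, 2), r0 = c(0.1, 0.1))
  st2 <- spatial_state(S, matrix(7, 1, cfg$n_z))
  expect_equal(step_growth(st2, quiet, cfg)$C, st2$C)

  # consumption is clamped: concentrations never go negative
  eater <- make_network(rho = matrix(0.1, 2, 1), beta = matrix(0, 1, 2),
                        alpha = matrix(5, 1, 2), r0 = c(0.1, 0.1))
  st3 <- spatial_state(S, matrix(1e-6, 1, cfg$n_z))
  expect_true(all(step_growth(st3, eater, cfg)$C >= 0))
})

test_that("compiled growth kernel agrees with the R reference step", {
  cfg <- tiny_cfg(D_med = 1e-5, D_cell = 1e-12)  # no diffusion event in dtau
  for (s in 1:5) {
    net <- generate_network(seed = 800 + s)
    set.seed(s)
    st <- spatial_state(matrix(runif(10 * cfg$n_z, 0, 1e4), 10, cfg$n_z),
                        matrix(runif(5 * cfg$n_z, 0, 2e4), 5, cfg$n_z))
    ref <- step_growth(st, net, cfg)
    out <- advance(st, net, cfg, t_target = cfg$dtau)$final
    expect_equal(out$S, ref$S, tolerance = 1e-12)
    expect_equal(out$C, ref$C, tolerance = 1e-12)
  }
})

test_that("explicit diffusion conserves mass and leaves uniform fields fixed", {
  cfg <- sim_config()
  set.seed(1)
  u <- matrix(runif(3 * cfg$n_z, 0, 10), 3, cfg$n_z)
  out <- step_diffusion(u, D = cfg$D_med, dt = cfg$dt, dz = cfg$dz,
                        n_steps = 1e4)
  expect_lt(max(abs(rowSums(out) - rowSums(u)) / rowSums(u)), 1e-10)
  expect_true(all(out >= 0))

  flat <- rep(4.2, cfg$n_z)
  expect_equal(step_diffusion(flat, cfg$D_med, cfg$dt, cfg$dz, 10), flat,
               tolerance = 0)
})

test_that("cosine eigenmode decays at the analytic rate", {
  cfg <- sim_config()
  zc <- (seq_len(cfg$n_z) - 0.5) * cfg$dz
  u0 <- 1 + 0.5 * cos(pi * zc / cfg$Z)
  t_end <- 0.1 * cfg$Z^2 / cfg$D_med
  n_steps <- round(t_end / cfg$dt)
  u <- step_diffusion(u0, cfg$D_med, cfg$dt, cfg$dz, n_steps)
  amp <- max(u) - mean(u)
  expect_equal(amp, 0.5 * exp(-cfg$D_med * (pi / cfg$Z)^2 * t_end),
               tolerance = 0.01)
})

test_that("unstable diffusion steps are refused", {
  expect_error(step_diffusion(rep(1, 10), D = 1, dt = 1, dz = 0.1),
               "unstable")
  expect_error(sim_config(dt_factor = 0.6), "stability")
})

test_that("slow dispersal leaves spatial support untouched within a round", {
  cfg <- sim_config()          # dc = 0.1 dz^2 / D_cell = 500 hr
  expect_gt(cfg$dc, 400)
  net <- generate_network(seed = 21)
  st <- initial_condition(net, cfg)
  out <- advance(st, net, cfg, t_target = 10)$final
  expect_identical(out$S == 0, st$S == 0)
})

test_that("uniform spatial fields reproduce the well-mixed trajectory", {
  cfg <- sim_config()
  for (s in 1:10) {
    net <- generate_network(fac_ratio = runif(1), seed = 900 + s)
    S0 <- rep(cfg$TID / 10, 10)
    sp <- advance(spatial_state(matrix(S0, 10, cfg$n_z),
                                matrix(0, 5, cfg$n_z)),
                  net, cfg, t_target = 20, record_every = 5)
    wm <- simulate_well_mixed(well_mixed_state(S0, rep(0, 5)),
                              net, cfg, t_target = 20, record_every = 5)
    for (k in seq_along(sp$states)) {
      expect_equal(rowMeans(sp$states[[k]]$S), wm$states[[k]]$S,
                   tolerance = 1e-3)
    }
    expect_equal(rowMeans(sp$final$S), wm$final$S, tolerance = 1e-3)
  }
})

test_that("well-mixed stepping converges to the continuous ODE solution", {
  skip_if_not_installed("deSolve")
  cfg <- sim_config()
  for (s in 1:3) {
    # gentle consumption so concentrations stay positive and the printed
    # ODE (no clamping) is the correct continuum limit
    net <- generate_network(alpha0 = 0.01, fac_ratio = 0.6, seed = 950 + s)
    S0 <- rep(cfg$TID / 10, 10)
    rhs <- function(t, y, p) {
      S <- y[1:10]; C <- y[11:15]
      crowd <- 1 - sum(S) / cfg$k_Y
      g <- net$r0 +
        as.vector(pmax(net$rho, 0) %*% (C / (C + cfg$k_sat))) +
        as.vector(pmin(net$rho, 0) %*% (C / cfg$k_sat))
      list(c(crowd * g * S, as.vector((net$beta - net$alpha) %*% S)))
    }
    ode <- deSolve::lsoda(c(rep(cfg$TID / 10, 10), rep(0, 5)), c(0, 10),
                          rhs, NULL, rtol = 1e-10, atol = 1e-8)
    ref <- ode[2, 2:11]
    wm <- simulate_well_mixed(well_mixed_state(S0, rep(0, 5)), net, cfg, 10)
    expect_equal(unname(wm$final$S), unname(ref), tolerance = 0.02)
    # quartering dtau brings the discrete scheme closer to the ODE
    cfg4 <- update_config(cfg, dtau = 0.0025)
    wm4 <- simulate_well_mixed(well_mixed_state(S0, rep(0, 5)), net, cfg4, 10)
    err1 <- max(abs(wm$final$S / ref - 1))
    err4 <- max(abs(wm4$final$S / ref - 1))
    expect_lt(err4, err1)
  }
})

test_that("trajectory summaries round-trip through CSV", {
  cfg <- tiny_cfg()
  net <- generate_network(seed = 61)
  tr <- advance(initial_condition(net, cfg), net, cfg, t_target = 2,
                record_every = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(tr$times))
  expect_equal(back$t_hours, tr$times)
  expect_equal(as.numeric(back[nrow(back), -1]),
               unname(species_abundance(tr$states[[length(tr$states)]])))
  expect_error(write_trajectory_csv(advance(initial_condition(net, cfg),
                                            net, cfg, 1), path),
               "record_every")
})

test_that("growth response has the right sign structure", {
  cfg <- sim_config()
  # all-inhibitory: rate equals the linear bound and decreases with each
  # inhibitor concentration
  inh <- make_network(rho = matrix(c(-0.1, -0.2), 1, 2),
                      beta = matrix(0, 2, 1), alpha = matrix(0.1, 2, 1),
                      r0 = 0.15)
  r_at <- function(C) local_growth_rate(1, C, inh, cfg)
  expect_equal(r_at(c(100, 50)),
               (1 - 1 / cfg$k_Y) *
                 (0.15 - 0.1 * 100 / cfg$k_sat - 0.2 * 50 / cfg$k_sat))
  expect_lt(r_at(c(200, 50)), r_at(c(100, 50)))
  expect_lt(r_at(c(100, 80)), r_at(c(100, 50)))

  # unidirectional facilitation: the recipient beats its basal rate once
  # the producer has released mediator
  fac <- make_network(rho = rbind(c(0.2), c(0)),
                      beta = matrix(c(0, 0.1), 1, 2),
                      alpha = matrix(0, 1, 2), r0 = c(0.1, 0.15))
  wm <- simulate_well_mixed(well_mixed_state(c(100, 100), 0), fac,
                            sim_config(k_Y = Inf), t_target = 20)
  expect_gt(wm$final$S[1], 100 * exp(0.1 * 20))
  expect_equal(wm$final$S[2], 100 * exp(0.15 * 20), tolerance = 1e-3)
})

test_that("densities and concentrations stay nonnegative under the defaults", {
  cfg <- tiny_cfg()
  for (s in 1:5) {
    net <- generate_network(fac_ratio = 0.3, seed = 970 + s)
    st <- initial_condition(net, cfg)
    out <- advance(st, net, cfg, t_target = 30)$final
    expect_true(all(out$S >= 0))
    expect_true(all(out$C >= 0))
  }
})

test_that("halving the grid spacing barely changes the outcome", {
  net <- generate_network(fac_ratio = 0.9, seed = 31)
  cfg1 <- sim_config(n_gen = 25)
  cfg2 <- sim_config(n_gen = 25, dz = 0.0025)
  r1 <- run_enrichment(net, cfg1, mode = "spatial")
  r2 <- run_enrichment(net, cfg2, mode = "spatial")
  a1 <- species_abundance(r1$final_state)
  a2 <- species_abundance(r2$final_state)
  keep <- a1 > 1  # compare species that are not numerically extinct
  expect_lt(max(abs(a2[keep] / a1[keep] - 1)), 0.02)
  expect_identical(r1$richness, r2$richness)
})
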