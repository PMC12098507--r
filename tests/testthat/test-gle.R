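test_that("simulation is bit-reproducible under a fixed seed", {
  p <- double_well(U_L = 2, L_L = 1)
  k <- memory_kernel(1, 0.1)
  cfg <- sim_config(mass = 0.01, n_steps = 2e5, seed = 101,
                    sampling_stride = 10)
  a <- simulate_gle(p, k, cfg)
  b <- simulate_gle(p, k, cfg)
  expect_identical(a$position, b$position)
  cfg2 <- sim_config(mass = 0.01, n_steps = 2e5, seed = 102,
                     sampling_stride = 10)
  c <- simulate_gle(p, k, cfg2)
  expect_false(identical(a$position, c$position))
  # initial-state draws replay bit-identically too
  s1 <- draw_initial_state(p, k, cfg, n = 5)
  s2 <- draw_initial_state(p, k, cfg, n = 5)
  expect_identical(s1, s2)
})

test_that("initial velocities follow the Maxwell distribution", {
  p <- double_well(U_L = 2, L_L = 1)
  k <- memory_kernel(1, 0.1)
  cfg <- sim_config(mass = 0.02, beta = 1, n_steps = 100, seed = 12)
  st <- draw_initial_state(p, k, cfg, n = 1e5)
  v_var <- 1 / (cfg$beta * cfg$mass)
  expect_lt(abs(mean(st$velocity)), 4 * sqrt(v_var / 1e5))
  se_var <- v_var * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(st$velocity) - v_var), 3 * se_var)
  expect_equal(st$position[1], -1)  # left minimum by default
  # auxiliary variables start in their stationary law
  z_var <- 1 / (cfg$beta * 0.1)    # gamma / (beta tau)
  expect_lt(abs(var(st$z_1) - z_var), 3 * z_var * sqrt(2 / 1e5))
})

test_that("harmonic-well equipartition holds for position and velocity", {
  h <- harmonic_well(10)
  k <- memory_kernel(1, 0.1)
  cfg <- sim_config(mass = 0.01, n_steps = 2e7, seed = 3,
                    sampling_stride = 40, record_velocity = TRUE,
                    initial_position = 0, dt = 1e-4)
  tr <- simulate_gle(h, k, cfg)
  # block standard errors: samples are serially correlated
  x2 <- tr$position^2
  expect_lt(abs(mean(x2) - 0.1), 3 * block_se(x2))
  v2 <- tr$velocity^2
  expect_lt(abs(mean(v2) - 100), 3 * block_se(v2))
})

test_that("free GLE diffusion recovers the Einstein relation within 5%", {
  k <- memory_kernel(1, 0.1)
  cfg <- sim_config(mass = 0.01, n_steps = 4e8, seed = 5,
                    sampling_stride = 100, dt = 2e-4,
                    initial_position = 0, burn_in = 0)
  tr <- simulate_gle(NULL, k, cfg)
  x <- tr$position
  ds <- attr(tr, "dt_sample")
  l1 <- round(2 / ds); l2 <- round(10 / ds)
  msd1 <- mean((x[-(1:l1)] - head(x, -l1))^2)
  msd2 <- mean((x[-(1:l2)] - head(x, -l2))^2)
  D <- (msd2 - msd1) / (2 * (l2 - l1) * ds)
  expect_equal(D, 1, tolerance = 0.05)  # D = 1/(beta gamma)
})

test_that("a symmetric double well is occupied evenly", {
  p <- double_well(U_L = 3, L_L = 1)
  k <- memory_kernel(1, 0.1)
  cfg <- sim_config(mass = 0.01, n_steps = 2e7, seed = 11,
                    sampling_stride = 50, dt = 2e-4)
  tr <- simulate_gle(p, k, cfg)
  left <- as.numeric(tr$position < 0)
  expect_lt(abs(mean(left) - 0.5), 3 * block_se(left))
})

test_that("realized random-force autocorrelation obeys fluctuation-dissipation", {
  # single exponential: 5% relative at lags {0, tau, 2tau}
  k <- memory_kernel(1, 0.5)
  dt <- 0.01
  f <- simulate_noise(k, n = 2e7, dt = dt, seed = 8)$force
  for (lag_t in c(0, 0.5, 1)) {
    l <- round(lag_t / dt)
    emp <- if (l == 0) mean(f^2) else mean(f[-(1:l)] * head(f, -l))
    expect_equal(emp, kernel_value(k, lag_t), tolerance = 0.05)
  }
  # two components: absolute error scales with Gamma(0), so compare within
  # estimator error (4 block standard errors) across lags
  k2 <- memory_kernel(gamma = c(1, 2), tau = c(0.1, 1))
  dt <- 0.005
  f <- simulate_noise(k2, n = 2e7, dt = dt, seed = 9)$force
  for (lag_t in c(0, 0.1, 0.5, 1, 2)) {
    l <- round(lag_t / dt)
    prod <- if (l == 0) f^2 else f[-(1:l)] * head(f, -l)
    expect_lt(abs(mean(prod) - kernel_value(k2, lag_t)),
              4 * block_se(prod, n_blocks = 50))
  }
})

test_that("GLE with vanishing memory matches an independent Langevin reference integrator", {
  p <- double_well(U_L = 2.5, L_L = 1)
  pairs <- cbind(c(-1, 1), c(1, -1))
  # run lengths sized so the SEM (~1.5%) dominates the residual ~1% memory
  # speed-up that tau/tau_D = 1e-3 still carries
  kg <- memory_kernel(1, 0.001)
  cfg_g <- sim_config(mass = 0.01, n_steps = 5e7, seed = 31,
                      sampling_stride = 1e8, dt = 2e-5)
  tg <- simulate_gle(p, kg, cfg_g, passages = pairs)
  cfg_l <- sim_config(mass = 0.01, n_steps = 2e7, seed = 77,
                      sampling_stride = 1e8, dt = 5e-5)
  tl <- simulate_langevin(p, gamma = 1, cfg_l, passages = pairs)
  for (i in 1:2) {
    eg <- mfpt_estimate(passage_groups(tg)[[i]])
    el <- mfpt_estimate(passage_groups(tl)[[i]])
    expect_lt(abs(eg$mean - el$mean), 2 * sqrt(eg$sem^2 + el$sem^2))
  }
})

test_that("without noise and friction the integrator conserves energy to O(dt^2)", {
  p <- double_well(U_L = 3, L_L = 1)
  k <- memory_kernel(1e-300, 1)  # negligible friction
  drift <- sapply(c(2e-4, 1e-4), function(dt) {
    cfg <- sim_config(mass = 0.01, n_steps = 2e5, seed = 1, dt = dt,
                      burn_in = 0, sampling_stride = 1,
                      record_velocity = TRUE, noise = FALSE,
                      initial_position = -0.6)
    tr <- simulate_gle(p, k, cfg)
    E <- 0.5 * 0.01 * tr$velocity^2 + potential_energy(p, tr$position)
    max(abs(E - E[1]))
  })
  expect_lt(drift[1] / potential_energy(p, -0.6), 1e-3)
  # quartering dt -> roughly quartered energy error (second-order scheme)
  expect_gt(drift[1] / drift[2], 2.5)
  expect_lt(drift[1] / drift[2], 6)
})

test_that("non-equilibrium engine reduces to equilibrium statistics at tau_R = tau_V", {
  h <- harmonic_well(10)
  nk <- neq_kernel(1, tau_V = 0.1, tau_R = 0.1)
  cfg <- sim_config(mass = 0.01, n_steps = 1e7, seed = 13,
                    sampling_stride = 40, initial_position = 0, dt = 1e-4)
  tr <- simulate_gle(h, nk, cfg)
  x2 <- tr$position^2
  expect_lt(abs(mean(x2) - 0.1), 3 * block_se(x2))
  # and the non-equilibrium noise channel has the stated autocorrelation
  ns <- simulate_noise(nk, n = 1e6, dt = 0.002, seed = 4)
  f <- ns$force
  expect_equal(mean(f^2), 10, tolerance = 0.05)
  l <- round(0.1 / 0.002)
  expect_equal(mean(f[-(1:l)] * head(f, -l)), 10 * exp(-1), tolerance = 0.05)
})

test_that("tau_R != tau_V produces a non-Boltzmann stationary state", {
  # tau_R = 2 tau_V acts as an effective inverse temperature 4 beta: the
  # within-well position spread collapses to ~1/4 of its Boltzmann value
  # (well-hopping freezes at the cold effective temperature, so the
  # discriminating statistic is the in-well distribution, not occupancy)
  p <- double_well(U_L = 3, U_R = 4, L_L = 1, L_R = 1)
  nk <- neq_kernel(1, tau_V = 0.1, tau_R = 0.2)
  cfg <- sim_config(mass = 0.1, n_steps = 2e7, seed = 17,
                    sampling_stride = 100, dt = 5e-4,
                    initial_position = "right-minimum")
  tr <- simulate_gle(p, nk, cfg)
  right <- tr$position[tr$position > 0]
  dev2 <- (right - 1)^2
  K_R <- curvature_at_minimum(p, "right")
  v_neq <- 1 / (4 * K_R)   # harmonic approximation at beta_NEQ = 4
  v_eq <- 1 / K_R
  expect_lt(mean(dev2) + 4 * block_se(dev2), v_eq / 2)
  expect_equal(mean(dev2), v_neq, tolerance = 0.15)
})

test_that("stability contract and invalid configurations are rejected with diagnostics", {
  p <- double_well(U_L = 3, L_L = 1)
  k <- memory_kernel(1, 0.1)
  cfg_bad <- sim_config(mass = 0.01, n_steps = 1e4, dt = 0.05)
  expect_error(simulate_gle(p, k, cfg_bad), class = "memfpt_error_stability")
  expect_error(sim_config(mass = 0, n_steps = 1e4),
               class = "memfpt_error_domain")
  cfg_small <- sim_config(mass = 0.01, n_steps = 10, burn_in = 100)
  expect_error(simulate_gle(p, k, cfg_small), class = "memfpt_error_domain")
})
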