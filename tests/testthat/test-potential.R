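test_that("potential energy matches the piecewise-quartic form at landmark points", {
  p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 1)
  expect_equal(potential_energy(p, 0), 3)       # barrier top = U_L, both branches
  expect_equal(potential_energy(p, -1), 0)      # left minimum pinned to zero
  p2 <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  expect_equal(potential_energy(p2, 0.5), -2)   # right minimum at U_L - U_R
  expect_error(potential_energy(p, Inf), class = "memfpt_error_domain")
  expect_error(potential_energy(p, NA_real_), class = "memfpt_error_domain")
})

test_that("force is the negative gradient and vanishes at stationary points", {
  p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  expect_equal(potential_force(p, 0), 0)
  expect_equal(potential_force(p, -1), 0)
  expect_equal(potential_force(p, 0.5), 0)
  for (x in c(-1.4, -0.5, -0.1, 0.2, 0.45, 0.8)) {
    expect_equal(potential_force(p, x),
                 -fd_derivative(function(y) potential_energy(p, y), x),
                 tolerance = 1e-7)
  }
  expect_error(potential_force(p, NaN), class = "memfpt_error_domain")
})

test_that("curvatures follow 8U/L^2 at minima and -4U/L^2 one-sided at the top", {
  p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  expect_equal(curvature_at_minimum(p, "left"), 24)
  expect_equal(curvature_at_minimum(p, "right"), 160)
  expect_equal(barrier_curvature(p, "left"), -12)
  expect_equal(barrier_curvature(p, "right"), -80)
  # second derivative is discontinuous at the top for asymmetric wells,
  # equal for symmetric ones
  expect_false(barrier_curvature(p, "left") == barrier_curvature(p, "right"))
  ps <- double_well(U_L = 2.5, L_L = 0.7)
  expect_equal(barrier_curvature(ps, "left"), barrier_curvature(ps, "right"))
})

test_that("curvatures agree with finite-difference oracles on random parameters", {
  set.seed(99)
  for (i in 1:8) {
    p <- double_well(U_L = runif(1, 0.5, 6), U_R = runif(1, 0.5, 6),
                     L_L = runif(1, 0.3, 2), L_R = runif(1, 0.3, 2))
    Uf <- function(x) potential_energy(p, x)
    expect_equal(curvature_at_minimum(p, "left"),
                 fd_second_derivative(Uf, -p$L_L), tolerance = 1e-5)
    expect_equal(curvature_at_minimum(p, "right"),
                 fd_second_derivative(Uf, p$L_R), tolerance = 1e-5)
    # one-sided second derivatives at the barrier top
    h <- 1e-4
    left2 <- (Uf(-2 * h) - 2 * Uf(-h) + Uf(0)) / h^2
    right2 <- (Uf(0 + 1e-12) - 2 * Uf(h) + Uf(2 * h)) / h^2
    expect_equal(barrier_curvature(p, "left"), left2, tolerance = 1e-3)
    expect_equal(barrier_curvature(p, "right"), right2, tolerance = 1e-3)
  }
})

test_that("potential and first derivative are continuous at the barrier top; symmetric wells are even", {
  set.seed(7)
  for (i in 1:10) {
    p <- double_well(U_L = runif(1, 0.5, 6), U_R = runif(1, 0.5, 6),
                     L_L = runif(1, 0.3, 2), L_R = runif(1, 0.3, 2))
    eps <- 1e-9
    expect_equal(potential_energy(p, -eps), potential_energy(p, eps),
                 tolerance = 1e-6)
    expect_equal(potential_force(p, -eps), potential_force(p, eps),
                 tolerance = 1e-6)
  }
  ps <- double_well(U_L = 4, L_L = 1.2)
  x <- seq(0.01, 2, length.out = 50)
  expect_equal(potential_energy(ps, x), potential_energy(ps, -x))
})

test_that("fit recovers exact double-well parameters from a clean profile", {
  p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  x <- seq(-1.4, 0.8, length.out = 200)
  prof <- tibble::tibble(position = x, energy = potential_energy(p, x))
  fit <- fit_double_well(prof)
  expect_true(fit$converged)
  est <- fit$potential
  expect_equal(est$U_L, 3, tolerance = 1e-6)
  expect_equal(est$U_R, 5, tolerance = 1e-6)
  expect_equal(est$L_L, 1, tolerance = 1e-6)
  expect_equal(est$L_R, 0.5, tolerance = 1e-6)
  expect_equal(fit$x_shift, 0, tolerance = 1e-6)
  expect_equal(fit$energy_shift, 0, tolerance = 1e-6)
  # translated frame is recovered and reported
  prof2 <- tibble::tibble(position = x + 0.3,
                          energy = potential_energy(p, x) + 1.25)
  fit2 <- fit_double_well(prof2)
  expect_equal(fit2$x_shift, 0.3, tolerance = 1e-6)
  expect_equal(fit2$energy_shift, 1.25, tolerance = 1e-6)
  expect_equal(fit2$potential$U_L, 3, tolerance = 1e-6)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_setequal(td$term, c("U_L", "U_R", "L_L", "L_R", "x0", "e0"))
  expect_true(glance(fit)$rss < 1e-10)
})

test_that("fit stays within 5% median parameter error under 0.05 kBT noise", {
  p <- double_well(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  x <- seq(-1.4, 0.8, length.out = 200)
  clean <- potential_energy(p, x)
  truth <- c(U_L = 3, U_R = 5, L_L = 1, L_R = 0.5)
  errs <- sapply(1:50, function(s) {
    set.seed(s)
    prof <- tibble::tibble(position = x, energy = clean + rnorm(200, 0, 0.05))
    fit <- fit_double_well(prof)
    est <- unlist(fit$potential[c("U_L", "U_R", "L_L", "L_R")])
    abs(est - truth) / truth
  })
  expect_lt(median(errs), 0.05)
})

test_that("profiles without double-well topology are rejected with a shape error", {
  x <- seq(-1, 1, length.out = 50)
  expect_error(fit_double_well(tibble::tibble(position = x, energy = x^2)),
               class = "memfpt_error_shape")
  expect_error(fit_double_well(tibble::tibble(position = x, energy = x)),
               class = "memfpt_error_shape")
  # malformed profiles are rejected before shape analysis
  expect_error(as_free_energy_profile(tibble::tibble(position = c(1, 1, 2, 3, 4),
                                                     energy = 1:5)),
               class = "memfpt_error_domain")
  expect_error(as_free_energy_profile(tibble::tibble(position = 1:3,
                                                     energy = 1:3)),
               class = "memfpt_error_domain")
})

test_that("profile text round-trip preserves data", {
  f <- withr::local_tempfile(fileext = ".dat")
  p <- double_well(2, 3, 0.8, 1.1)
  x <- seq(-1.2, 1.6, length.out = 60)
  prof <- tibble::tibble(position = x, energy = potential_energy(p, x))
  write_profile(prof, f, comment = "synthetic test profile")
  back <- read_profile(f)
  expect_equal(back$position, prof$position, tolerance = 1e-12)
  expect_equal(back$energy, prof$energy, tolerance = 1e-12)
})

test_that("potential JSON round-trip preserves parameters exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  p <- double_well(1.7, 3.2, 0.15, 0.08)
  write_potential_json(p, f)
  q <- read_potential_json(f)
  expect_equal(q, p)
})
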