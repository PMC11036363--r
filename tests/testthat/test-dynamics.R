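test_that("zero force and zero friction give uniform drift", {
  x <- matrix(0, 2, 3)
  v <- matrix(c(0.01, 0, 0, 0, -0.02, 0), 2, 3)
  gf <- function(xx) matrix(0, 2, 3)
  s <- langevin_step(x, v, gf, masses = c(12, 12), dt = 1, friction = 0,
                     temperature = 300)
  expect_equal(s$coords, x + v * 1)
  expect_equal(s$velocities, v)
})

test_that("identical seeds give bit-identical trajectories", {
  gf <- function(xx) 2 * 30 * xx
  run <- function() {
    set.seed(99)
    x <- matrix(0.2, 1, 3); v <- matrix(0, 1, 3); g <- gf(x)
    for (i in 1:200) {
      s <- langevin_step(x, v, gf, 12, dt = 1, friction = 10,
                         temperature = 300, gradient = g)
      x <- s$coords; v <- s$velocities; g <- s$gradient
    }
    list(x, v)
  }
  expect_identical(run(), run())
})

test_that("thermostatted harmonic oscillator satisfies equipartition", {
  set.seed(20)
  k <- 50; m <- 12
  gf <- function(x) 2 * k * x
  x <- matrix(0, 1, 3); v <- matrix(0, 1, 3); g <- gf(x)
  n <- 20000
  ke <- numeric(n)
  for (i in seq_len(n)) {
    s <- langevin_step(x, v, gf, m, dt = 1, friction = 10, temperature = 300,
                       gradient = g)
    x <- s$coords; v <- s$velocities; g <- s$gradient
    ke[i] <- 0.5 * m * sum(v^2) / 4.184e-4
  }
  ke <- ke[-(1:2000)] / 3          # per degree of freedom
  nb <- 30
  bm <- colMeans(matrix(ke[1:(nb * floor(length(ke) / nb))],
                        ncol = nb))
  se <- stats::sd(bm) / sqrt(nb)
  expect_lt(abs(mean(ke) - boltzmann_kcal() * 300 / 2), 3 * se)
})

test_that("NVE dynamics conserves energy on a toy crystal", {
  set.seed(21)
  ring <- make_rigid_ring()
  p <- ring$params
  cl <- unit_cell(7.5, 8, 7, 90, 95, 90)
  st <- crystal_state(ring$topology,
                      sweep(ring$coords, 2, frac_to_cart(cl, c(.3, .4, .5)), "+"),
                      cl, "P1", lambda = 1)
  m <- ring$topology$mass
  x <- st$coords
  v <- matrix(rnorm(18), 6, 3) * sqrt(boltzmann_kcal() * 100 * 4.184e-4 / m)
  gf <- function(xx) { s2 <- st; s2$coords <- xx; total_potential(s2, p)$gradient }
  etot <- function(xx, vv) {
    s2 <- st; s2$coords <- xx
    total_potential(s2, p)$total + 0.5 * sum(m * rowSums(vv^2)) / 4.184e-4
  }
  e0 <- etot(x, v); g <- gf(x)
  ## the symplectic integrator's energy error is a bounded oscillation of the
  ## shadow Hamiltonian; over a 10 ps window the per-ps drift resolves it
  for (i in 1:10000) {
    s <- langevin_step(x, v, gf, m, dt = 1, friction = 0, temperature = 100,
                       gradient = g)
    x <- s$coords; v <- s$velocities; g <- s$gradient
  }
  drift <- abs(etot(x, v) - e0) / 10 / 18   # per ps per DoF
  expect_lt(drift, 1e-4)
})

test_that("lambda propagates as a bounded random walk under sin^2 theta", {
  ## dlambda/dtheta vanishes at the endpoints: no reflection needed
  dynp <- dynamics_params(lambda_mass = 1e4)
  s <- lambda_step(0, 0, dU_dlambda = 50, params = dynp, temperature = 1e-12)
  expect_equal(s$lambda, 0, tolerance = 1e-12)   # zero chain-rule force at 0
  set.seed(22)
  th <- 0.2; vth <- 0
  occ <- numeric(1e5)
  for (i in seq_len(1e5)) {
    st <- lambda_step(th, vth, 0, dynp, 298.15)
    th <- st$theta; vth <- st$vtheta; occ[i] <- st$lambda
  }
  expect_true(all(occ >= 0 & occ <= 1))
  expect_gt(mean(occ < 0.1), 0)     # both endpoint deciles visited
  expect_gt(mean(occ > 0.9), 0)
  ## strong restraint toward lambda = 1 localizes there
  set.seed(23)
  th <- asin(sqrt(0.5)); vth <- 0
  for (i in 1:20000) {
    st <- lambda_step(th, vth, dU_dlambda = -200, params = dynp,
                      temperature = 298.15)
    th <- st$theta; vth <- st$vtheta
  }
  expect_gt(sin(th)^2, 0.9)
})

test_that("lattice proposals bound the volume move and respect constraints", {
  set.seed(24)
  bp <- barostat_params(v_max = 1, a_max = 0.5)
  cl <- unit_cell(8, 9, 10, 90, 90, 90)
  dv <- numeric(0)
  for (i in 1:2000) {
    prop <- propose_lattice_move(cl, "orthorhombic", bp)
    expect_true(lattice_constraints_ok(prop, "orthorhombic", tol = 0))
    if (attr(prop, "kind") == "length")
      dv <- c(dv, cell_volume(prop) - cell_volume(cl))
  }
  expect_true(all(abs(dv) <= bp$v_max + 1e-9))
  expect_lt(abs(mean(dv)), 3 * stats::sd(dv) / sqrt(length(dv)))
  ## angle moves preserve the volume exactly while changing the angle
  set.seed(25)
  clm <- unit_cell(8, 9, 10, 90, 100, 90)
  n_angle <- 0L
  for (i in 1:500) {
    prop <- propose_lattice_move(clm, "monoclinic", bp)
    expect_identical(prop$alpha, 90)
    expect_identical(prop$gamma, 90)
    if (attr(prop, "kind") == "angle") {
      n_angle <- n_angle + 1L
      expect_equal(cell_volume(prop), cell_volume(clm), tolerance = 1e-10)
      expect_lte(abs(prop$beta - 100), bp$a_max)
    }
  }
  expect_gt(n_angle, 50)
  ## tandem scaling keeps tied lengths exactly equal
  set.seed(26)
  clc <- unit_cell(7, 7, 7, 90, 90, 90)
  for (i in 1:200) {
    prop <- propose_lattice_move(clc, "cubic", bp)
    expect_identical(prop$a, prop$b)
    expect_identical(prop$b, prop$c)
  }
})

test_that("barostat trial energy matches the closed form", {
  cond <- thermo_conditions(298.15, 1)
  kT <- boltzmann_kcal() * 298.15
  expect_identical(barostat_delta_e(0, 500, 500, 1, cond), 0)
  expect_equal(barostat_delta_e(0, 500, 1000, 1, cond),
               1 * 500 * 1.4584e-5 - kT * log(2), tolerance = 1e-12)
  expect_equal(barostat_delta_e(2.5, 400, 380, 3, cond),
               2.5 + 1 * (-20) * 1.4584e-5 - 3 * kT * log(380 / 400),
               tolerance = 1e-12)
  expect_error(barostat_delta_e(0, -1, 10, 1, cond), "positive")
})

test_that("Metropolis acceptance has the correct rate", {
  cond <- thermo_conditions(298.15, 1)
  set.seed(27)
  expect_true(all(replicate(50, barostat_accept(-5, cond))))
  expect_true(all(replicate(50, barostat_accept(0, cond))))  # e^0 = 1
  kT <- boltzmann_kcal() * 298.15
  n <- 1e5
  acc <- mean(replicate(n, barostat_accept(kT, cond)))
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc - p), 3 * se)
})

test_that("out-of-band density proposals are rejected without an energy call", {
  lj <- make_lj_monatomic()
  st <- crystal_state(lj$topology, lj$coords, unit_cell(4, 4, 4, 90, 90, 90),
                      "P1", lambda = 0)
  ## the 64 A^3 cell sits at 0.63 g/cm^3; +-1 A^3 moves cannot re-enter the
  ## [0.75, 1.6] band, so every proposal must be rejected before any energy call
  bp <- barostat_params(rho_min = 0.75, rho_max = 1.6, v_max = 1)
  cond <- thermo_conditions()
  boom <- function(s) stop("energy must not be evaluated")
  set.seed(28)
  for (i in 1:100) {
    tr <- xtalpath:::barostat_trial(st, bp, cond, energy_fn = boom,
                                    current_energy = 0)
    expect_true(tr$skipped)
    expect_false(tr$accepted)
  }
})

test_that("snapshot criterion enforces coupling and energy window", {
  expect_true(snapshot_criterion(0.85, minimized_energy = 3, best_energy = 0))
  expect_false(snapshot_criterion(0.70, minimized_energy = 0, best_energy = 0))
  expect_false(snapshot_criterion(0.95, minimized_energy = 12, best_energy = 0))
  expect_true(snapshot_criterion(0.95, minimized_energy = -5, best_energy = 0))
  expect_true(snapshot_criterion(0.9, minimized_energy = 4, best_energy = Inf))
})

test_that("a zero-step walker returns the initial state and empty records", {
  lj <- make_lj_monatomic()
  st <- crystal_state(lj$topology, lj$coords, unit_cell(4, 4, 4, 90, 90, 90),
                      "P1", lambda = 0.5)
  res <- run_walker(st, aparams = lj$params,
                    dynp = dynamics_params(n_steps = 0L, seed = 1))
  expect_identical(res$status, 0L)
  expect_identical(nrow(res$trajectory), 0L)
  expect_length(res$snapshots, 0)
  expect_equal(res$state$coords, st$coords)
})

test_that("walkers are reproducible under a fixed seed", {
  lj <- make_lj_monatomic()
  st <- crystal_state(lj$topology, lj$coords,
                      unit_cell(4.2, 4.2, 4.2, 90, 90, 90), "P1", lambda = 0.3)
  run1 <- run_walker(st, aparams = lj$params,
                     dynp = dynamics_params(n_steps = 300L, seed = 7,
                                            lambda_mass = 5e3),
                     minimize_snapshots = FALSE)
  run2 <- run_walker(st, aparams = lj$params,
                     dynp = dynamics_params(n_steps = 300L, seed = 7,
                                            lambda_mass = 5e3),
                     minimize_snapshots = FALSE)
  expect_identical(run1$trajectory, run2$trajectory)
  expect_identical(run1$state$coords, run2$state$coords)
})

test_that("ideal-gas NPT sampling matches the analytic volume distribution", {
  ## stationary law p(V) ~ V^n e^{-beta p V}; mean = (n+1) kT / p
  lj <- make_lj_monatomic()
  cond <- thermo_conditions(298.15, 150)
  bp <- barostat_params(rho_min = 1e-6, rho_max = 1e6, v_max = 120, a_max = 2)
  st <- crystal_state(lj$topology, lj$coords, unit_cell(8, 8, 8, 90, 90, 90),
                      "P1", lambda = 0)
  set.seed(29)
  warm <- run_barostat_only(st, bp, cond, 2e4)
  res <- run_barostat_only(warm$state, bp, cond, 1e5)
  kT <- boltzmann_kcal() * 298.15
  expected <- 2 * kT / (150 * 1.4584e-5)
  v <- res$volumes
  nb <- 40
  bm <- colMeans(matrix(v, ncol = nb))
  se <- stats::sd(bm) / sqrt(nb)
  expect_lt(abs(mean(v) - expected), 3 * se)
})
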