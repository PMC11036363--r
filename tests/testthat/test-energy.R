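test_that("bonded terms evaluate to closed forms", {
  ring <- make_rigid_ring()
  ## construction geometry: every bond at b0, every angle at theta0
  be <- bonded_energy(ring$topology, ring$coords)
  expect_equal(be$energy, 0, tolerance = 1e-20)
  expect_equal(max(abs(be$gradient)), 0, tolerance = 1e-9)
  ## single stretched bond: k (b - b0)^2
  top <- molecule_topology(element = c("C", "C"), mass = c(12, 12),
                           eps = c(0.1, 0.1), r0 = c(3.4, 3.4),
                           charge = c(0, 0),
                           bonds = data.frame(i = 1, j = 2, k = 300, b0 = 1.5))
  be2 <- bonded_energy(top, rbind(c(0, 0, 0), c(1.6, 0, 0)))
  expect_equal(be2$energy, 300 * 0.01, tolerance = 1e-12)
})

test_that("bonded gradient (incl. angles and torsions) matches finite differences", {
  set.seed(8)
  top <- molecule_topology(
    element = rep("C", 4), mass = rep(12, 4), eps = rep(0.1, 4),
    r0 = rep(3.4, 4), charge = rep(0, 4),
    bonds = data.frame(i = 1:3, j = 2:4, k = 300, b0 = 1.5),
    angles = data.frame(i = 1:2, j = 2:3, k = 3:4, ktheta = 60, theta0 = 110),
    torsions = data.frame(i = 1, j = 2, k = 3, l = 4, amp = 1.5, per = 3,
                          phase = 30))
  co <- matrix(rnorm(12), 4, 3) + cbind(0:3 * 1.4, 0, 0)
  be <- bonded_energy(top, co)
  h <- 1e-6
  for (i in 1:4) for (k in 1:3) {
    cp <- co; cp[i, k] <- cp[i, k] + h
    cm <- co; cm[i, k] <- cm[i, k] - h
    fd <- (bonded_energy(top, cp)$energy - bonded_energy(top, cm)$energy) / (2 * h)
    expect_lt(abs(fd - be$gradient[i, k]), 1e-6)
  }
})

test_that("softcore buffered 14-7 honours its endpoints", {
  p <- alchemical_params()
  expect_equal(softcore_vdw_pair(3.8, 0.5, 3.8, 1, p), -0.5, tolerance = 1e-12)
  expect_equal(softcore_vdw_pair(2.0, 0.5, 3.8, 0, p), 0)
  expect_equal(softcore_vdw_pair(9.0, 0.5, 3.8, 0, p), 0)
  u0 <- softcore_vdw_pair(0, 0.5, 3.8, 0.5, p)
  expect_true(is.finite(u0))
  ## taper: identically zero at and beyond the cutoff
  expect_equal(softcore_vdw_pair(p$cutoff, 0.5, 3.8, 1, p), 0)
  expect_equal(softcore_vdw_pair(p$cutoff + 1, 0.5, 3.8, 1, p), 0)
  ## plain buffered 14-7 inside the switching window at lambda = 1
  r <- 4.5
  rho <- r / 3.8
  plain <- 0.5 * (1.07 / (rho + 0.07))^7 * (1.12 / (rho^7 + 0.12) - 2)
  expect_equal(softcore_vdw_pair(r, 0.5, 3.8, 1, p), plain, tolerance = 1e-12)
})

test_that("energy derivatives match finite differences on a symmetric crystal", {
  set.seed(9)
  st <- ring_crystal("P21/c", lambda = 0.63)
  p <- make_rigid_ring()$params
  er <- total_potential(st, p)
  expect_identical(dim(er$gradient), c(6L, 3L))
  expect_true(all(is.finite(unlist(er[c("total", "gradient", "dU_dl",
                                        "d2U_dl2", "d2U_dldx")]))))
  expect_lt(max(abs(fd_gradient(st, p) - er$gradient)), 1e-6)
  h <- 1e-6
  sp <- st; sp$lambda <- st$lambda + h
  sm <- st; sm$lambda <- st$lambda - h
  ep <- total_potential(sp, p); em <- total_potential(sm, p)
  expect_lt(abs((ep$total - em$total) / (2 * h) - er$dU_dl), 1e-6)
  expect_lt(abs((ep$dU_dl - em$dU_dl) / (2 * h) - er$d2U_dl2), 1e-6)
  expect_lt(max(abs((ep$gradient - em$gradient) / (2 * h) - er$d2U_dldx)), 1e-6)
})

test_that("lambda = 0 fully uncouples the symmetry mates", {
  set.seed(10)
  st <- ring_crystal("Pbca", lambda = 0)
  p <- make_rigid_ring()$params
  inter <- intermolecular_energy(st, p)
  expect_identical(inter$energy, 0)
  er <- total_potential(st, p)
  expect_identical(er$dU_dl, 0)
  ## with exponent n >= 2 the derivative also vanishes smoothly near 0
  st$lambda <- 1e-9
  expect_lt(abs(total_potential(st, p)$dU_dl), 1e-6)
})

test_that("single LJ atom energy equals the brute-force image sum", {
  lj <- make_lj_monatomic()
  p <- lj$params
  cl <- unit_cell(4.1, 4.1, 4.1, 90, 90, 90)
  st <- crystal_state(lj$topology, lj$coords, cl, "P1", lambda = 1)
  ## direct lattice sum over all images within the cutoff
  n <- ceiling(p$cutoff / 4.1) + 1
  sh <- as.matrix(expand.grid(-n:n, -n:n, -n:n))
  sh <- sh[rowSums(abs(sh)) > 0, ]
  r <- sqrt(rowSums((sh %*% t(cl$m))^2))
  r <- r[r < p$cutoff]
  oracle <- 0.5 * sum(softcore_vdw_pair(r, lj$topology$eps, lj$topology$r0,
                                        1, p))
  expect_equal(total_potential(st, p)$total, oracle, tolerance = 1e-10)
})

test_that("per-molecule energy is identical for ASU, P1 and replicated forms", {
  set.seed(11)
  p <- make_rigid_ring()$params
  for (s in space_group_names()) {
    st <- ring_crystal(s, lambda = 0.8)
    e1 <- energy_per_molecule(st, p)
    p1 <- suppressWarnings(expand_to_p1(st))
    e2 <- energy_per_molecule(p1, p)
    e3 <- energy_per_molecule(replicate_cell(p1, 2, 2, 1), p)
    expect_lt(abs(e2 - e1), 1e-6)
    expect_lt(abs(e3 - e1), 1e-6)
  }
})

test_that("P1 energy is invariant under rigid translation of the contents", {
  set.seed(12)
  lj <- make_lj_monatomic()
  cl <- unit_cell(4.5, 4.2, 4.8, 85, 95, 90)
  st <- crystal_state(lj$topology, matrix(c(0.3, -0.2, 1.1), 1), cl, "P1")
  e0 <- total_potential(st, lj$params)$total
  for (k in 1:5) {
    st2 <- st
    st2$coords <- st$coords + matrix(rnorm(3), 1)
    expect_equal(total_potential(st2, lj$params)$total, e0, tolerance = 1e-9)
  }
})

test_that("U(lambda) is smooth and rises monotonically for a clashing state", {
  lj <- make_lj_monatomic()
  p <- lj$params
  ## tight cell: repulsive contacts dominate
  cl <- unit_cell(2.2, 2.2, 2.2, 90, 90, 90)
  ls <- seq(0, 1, by = 0.02)
  ev <- lapply(ls, function(l) {
    st <- crystal_state(lj$topology, matrix(0, 1, 3), cl, "P1", lambda = l)
    e <- total_potential(st, p)
    c(u = e$total, f = e$dU_dl)
  })
  u <- vapply(ev, `[[`, numeric(1), "u")
  f <- vapply(ev, `[[`, numeric(1), "f")
  ## the softcore's buffered distance briefly visits the attractive basin at
  ## small lambda, so the rise carries a detour of a few hundredths of a
  ## kcal/mol -- negligible against the clash scale; beyond it the energy
  ## grows strictly
  expect_lt(max(cummax(u) - u), 0.05)
  expect_lt(max(cummax(u) - u) / max(u), 1e-3)
  coupled <- ls >= 0.4
  expect_true(all(diff(u[coupled]) > 0))
  ## continuity/differentiability: secants agree with the analytic dU/dlambda
  dl <- diff(ls)
  secant <- diff(u) / dl
  trap <- (f[-1] + f[-length(f)]) / 2
  expect_lt(max(abs(secant - trap) / (abs(trap) + 1)), 0.02)
})

test_that("intramolecular nonbonded pairs stay fully coupled at any lambda", {
  ## 5-atom chain: the 1-5 pair is beyond three bonds, so it interacts
  top <- molecule_topology(
    element = rep("C", 5), mass = rep(12, 5), eps = rep(0.2, 5),
    r0 = rep(3.0, 5), charge = rep(0, 5),
    bonds = data.frame(i = 1:4, j = 2:5, k = 300, b0 = 1.5))
  co <- cbind(c(0, 1.5, 3.0, 4.5, 6.0), 0, 0)
  cl <- unit_cell(60, 60, 60, 90, 90, 90)  # no intermolecular images in range
  e_at <- function(l) total_potential(
    crystal_state(top, co, cl, "P1", lambda = l),
    alchemical_params(cutoff = 12, use_elec = FALSE))$total
  e1 <- e_at(1); e0 <- e_at(0)
  expect_equal(e1, e0, tolerance = 1e-12)
  expect_equal(e1, softcore_vdw_pair(6.0, 0.2, 3.0, 1, alchemical_params()),
               tolerance = 1e-10)
})
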