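test_that("hill deposition and evaluation follow the truncated Gaussian", {
  p <- ost_params()
  g <- ost_grid(p)
  ## deposit exactly at a bin center
  lc <- (floor(0.5 / p$dl) + 0.5) * p$dl
  fc <- g$fmin + (floor((10 - g$fmin) / p$df) + 0.5) * p$df
  deposit_hill(g, lc, fc, 0.05)
  expect_equal(bias_energy_and_gradient(g, lc, fc)$energy, 0.05)
  expect_equal(bias_energy_and_gradient(g, lc + p$w1, fc)$energy,
               0.05 * exp(-0.5), tolerance = 1e-12)
  expect_equal(bias_energy_and_gradient(g, lc, fc + p$w2)$energy,
               0.05 * exp(-0.5), tolerance = 1e-12)
  ## truncated after five bins
  expect_identical(bias_energy_and_gradient(g, lc + 6 * p$dl, fc)$energy, 0)
  expect_error(deposit_hill(g, 0.5, NaN, 0.05), "non-finite")
  expect_error(deposit_hill(g, 1.5, 0, 0.05), "lambda")
})

test_that("empty grid evaluates to zero and bias stays nonnegative", {
  g <- ost_grid()
  b <- bias_energy_and_gradient(g, 0.3, 5)
  expect_identical(unlist(b), c(energy = 0, ddl = 0, ddf = 0))
  set.seed(13)
  for (i in 1:30) deposit_hill(g, runif(1), runif(1, -80, 80),
                               runif(1, 0.01, 0.05))
  for (i in 1:50)
    expect_gte(bias_energy_and_gradient(g, runif(1), runif(1, -90, 90))$energy, 0)
})

test_that("analytic bias partials match finite differences", {
  set.seed(14)
  p <- ost_params()
  g <- ost_grid(p)
  for (i in 1:10) deposit_hill(g, runif(1), runif(1, -50, 50),
                               runif(1, 0.01, 0.05))
  h <- 1e-7
  for (pt in list(c(0.471, 7.3), c(0.12, -22), c(0.9, 0.5))) {
    b <- bias_energy_and_gradient(g, pt[1], pt[2])
    fd_l <- (bias_energy_and_gradient(g, pt[1] + h, pt[2])$energy -
               bias_energy_and_gradient(g, pt[1] - h, pt[2])$energy) / (2 * h)
    fd_f <- (bias_energy_and_gradient(g, pt[1], pt[2] + h)$energy -
               bias_energy_and_gradient(g, pt[1], pt[2] - h)$energy) / (2 * h)
    expect_lt(abs(fd_l - b$ddl), 1e-8)
    expect_lt(abs(fd_f - b$ddf), 1e-8)
  }
})

test_that("single-hill bias is symmetric at its center", {
  p <- ost_params()
  g <- ost_grid(p)
  lc <- (floor(0.4 / p$dl) + 0.5) * p$dl
  fc <- g$fmin + (floor((0 - g$fmin) / p$df) + 0.5) * p$df
  deposit_hill(g, lc, fc, 0.05)
  b <- bias_energy_and_gradient(g, lc, fc)
  expect_equal(b$ddl, 0)
  expect_equal(b$ddf, 0)
})

test_that("coverage statistic equals brute-force min-of-max", {
  set.seed(15)
  p <- ost_params(dl = 0.2, df = 2)   # 5 lambda bins
  for (rep in 1:5) {
    g <- ost_grid(p, f_init = 7)      # 7 F bins
    expect_identical(g$nl, 5L)
    for (i in 1:40) deposit_hill(g, runif(1), runif(1, -6.9, 6.9),
                                 runif(1, 0.01, 0.05))
    expect_equal(coverage_statistic(g), min(apply(g$H, 1, max)))
  }
  ## an untouched lambda column pins the coverage at zero
  g2 <- ost_grid(p, f_init = 7)
  deposit_hill(g2, 0.1, 0, 0.05)
  expect_identical(coverage_statistic(g2), 0)
  ## all bins equal c -> c
  g3 <- ost_grid(p, f_init = 7)
  g3$H[] <- 0.3
  expect_identical(coverage_statistic(g3), 0.3)
})

test_that("transition tempering holds then decays exponentially", {
  p <- ost_params()
  kT <- boltzmann_kcal() * 298.15
  expect_identical(tempering_height(p, 0), 0.05)
  expect_identical(tempering_height(p, p$v_th), 0.05)
  expect_equal(tempering_height(p, p$v_th + p$dT * kT), 0.05 * exp(-1),
               tolerance = 1e-12)
  expect_lt(tempering_height(p, 100), 1e-10)
  v <- seq(0, 10, by = 0.25)
  h <- vapply(v, tempering_height, numeric(1), params = p)
  expect_true(all(diff(h) <= 0))
})

test_that("thermodynamic-integration profile integrates a constant exactly", {
  p <- ost_params()
  g <- ost_grid(p)
  beta <- 1 / (boltzmann_kcal() * 298.15)
  ## no samples anywhere -> profile and bias identically zero
  expect_true(all(ost_lambda_profile(g, beta) == 0))
  expect_true(all(one_d_bias(g, beta) == 0))
  for (l in seq(0.0025, 0.9975, by = 0.005)) record_visit(g, l, 4.0)
  prof <- ost_lambda_profile(g, beta)
  lc <- (seq_len(g$nl) - 0.5) * p$dl
  expect_equal(as.numeric(prof), 4.0 * lc, tolerance = 1e-12)
  ## the applied 1D bias is the negative of the profile
  expect_equal(as.numeric(one_d_bias(g, beta)), -4.0 * lc, tolerance = 1e-12)
})

test_that("unvisited lambda bins inherit their nearest neighbours and are flagged", {
  p <- ost_params(dl = 0.1)
  g <- ost_grid(p)
  record_visit(g, 0.05, 2)   # bin 1
  record_visit(g, 0.95, 6)   # bin 10
  prof <- ost_lambda_profile(g, 1)
  filled <- attr(prof, "filled")
  expect_identical(sum(filled), 8L)
  fbar <- attr(prof, "fbar")
  expect_identical(fbar[2], fbar[1])
  expect_identical(fbar[9], fbar[10])
})

test_that("total bias composes the 1D and 2D parts exactly", {
  set.seed(16)
  p <- ost_params()
  g <- ost_grid(p)
  beta <- 1 / (boltzmann_kcal() * 298.15)
  expect_identical(total_bias(g, 0.4, 3, beta), 0)
  for (i in 1:20) {
    deposit_hill(g, runif(1), runif(1, -40, 40), runif(1, 0.01, 0.05))
    record_visit(g, runif(1), runif(1, -40, 40))
  }
  for (pt in list(c(0.25, -3), c(0.77, 12))) {
    expected <- xtalpath:::one_d_bias_at(g, beta, pt[1])$energy +
      bias_energy_and_gradient(g, pt[1], pt[2])$energy
    expect_equal(total_bias(g, pt[1], pt[2], beta), expected)
  }
})

test_that("expanding the F range preserves deposited bias bit-exactly", {
  set.seed(17)
  p <- ost_params()
  g <- ost_grid(p, f_init = 20)
  for (i in 1:15) deposit_hill(g, runif(1), runif(1, -18, 18),
                               runif(1, 0.01, 0.05))
  pts <- replicate(10, c(runif(1), runif(1, -19, 19)), simplify = FALSE)
  before <- vapply(pts, function(x)
    bias_energy_and_gradient(g, x[1], x[2])$energy, numeric(1))
  deposit_hill(g, 0.5, 250, 0.05)  # forces repeated doubling
  after <- vapply(pts, function(x)
    bias_energy_and_gradient(g, x[1], x[2])$energy, numeric(1))
  expect_identical(before, after)
})

test_that("checkpoints round-trip bit-exactly and merge additively", {
  set.seed(18)
  p <- ost_params()
  g <- ost_grid(p)
  for (i in 1:12) {
    deposit_hill(g, runif(1), runif(1, -60, 60), runif(1, 0.01, 0.05))
    record_visit(g, runif(1), runif(1, -60, 60))
  }
  f1 <- withr::local_tempfile()
  write_ost_checkpoint(g, f1)
  g2 <- read_ost_checkpoint(f1)
  expect_identical(g2$H, g$H)
  expect_identical(g2$counts, g$counts)
  expect_identical(g2$fsum, g$fsum)
  ## merge two walkers
  gb <- ost_grid(p)
  deposit_hill(gb, 0.2, -30, 0.04)
  record_visit(gb, 0.2, -30)
  f2 <- withr::local_tempfile()
  write_ost_checkpoint(gb, f2)
  gm <- merge_ost_checkpoints(c(f1, f2))
  expect_equal(sum(gm$H), sum(g$H) + sum(gb$H), tolerance = 1e-14)
  expect_equal(sum(gm$counts), sum(g$counts) + sum(gb$counts))
  expect_error(read_ost_checkpoint(f1 <- withr::local_tempfile(lines = "oops")),
               "checkpoint")
})
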