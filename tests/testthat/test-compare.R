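test_that("rmsd_n is a premetric: zero on identity, lattice-shift invariant, symmetric", {
  lj <- make_lj_monatomic()
  cl <- unit_cell(3.686, 3.686, 3.686, 60, 60, 60)
  A <- crystal_state(lj$topology, lj$coords, cl, "P1")
  expect_lt(rmsd_n(A, A, 20), 1e-6)
  B <- A
  B$coords <- B$coords + matrix(frac_to_cart(cl, c(1, -2, 1)), 1)
  expect_lt(rmsd_n(A, B, 20), 1e-6)
  ## distinct packings separate, symmetrically
  a_sc <- cell_volume(cl)^(1 / 3)
  C <- crystal_state(lj$topology, lj$coords,
                     unit_cell(a_sc, a_sc, a_sc, 90, 90, 90), "P1")
  d1 <- rmsd_n(A, C, 12); d2 <- rmsd_n(C, A, 12)
  expect_gt(d1, 0.5)
  expect_lt(abs(d1 - d2), 1e-6)
  ## multi-atom identity through a symmetry-bearing group
  set.seed(31)
  st <- ring_crystal("P21/c", lambda = 1)
  expect_lt(rmsd_n(st, st, 12), 1e-6)
})

test_that("greedy shell matching agrees with the exhaustive oracle at small N", {
  set.seed(32)
  ring <- make_rigid_ring()
  cl <- unit_cell(9, 10, 11, 90, 90, 90)
  base <- sweep(ring$coords, 2, frac_to_cart(cl, c(0.25, 0.3, 0.4)), "+")
  A <- crystal_state(ring$topology, base, cl, "P1")
  ## B: one shell molecule displaced by 0.3 A
  shellA <- packing_shell(A, n_mol = 3, max_centers = 1, n_env = 3)[[1]]
  B <- A
  B$coords <- base + matrix(rnorm(18, sd = 0.05), 6, 3)
  shellB <- packing_shell(B, n_mol = 3, max_centers = 1, n_env = 3)[[1]]
  greedy <- xtalpath:::superpose_shells(shellA, shellB)
  oracle <- brute_shell_rmsd(shellA, shellB)
  expect_lt(abs(greedy - oracle), 1e-6)
  expect_gt(greedy, 0)
  ## too few molecules available is a named error
  expect_error(packing_shell(A, n_mol = 1e5), "molecules")
})

test_that("Kabsch recovers exact superposition of rotated copies", {
  set.seed(33)
  x <- matrix(rnorm(30), 10, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  y <- x %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  k <- kabsch(x, y)
  expect_lt(k$rmsd, 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
})

test_that("density/energy filtering applies the printed rule exactly", {
  tab <- data.frame(energy = c(0, 1, 11, 9, 2, 3),
                    density = c(1.30, 1.20, 1.40, 1.26, 1.00, 1.50))
  out <- filter_snapshots(tab)
  expect_identical(as.integer(rownames(out)), c(1L, 4L, 6L))
  expect_identical(nrow(out), 3L)
  ## all pass when cuts are permissive
  expect_identical(nrow(filter_snapshots(tab, rho_cut = 0, e_window = Inf)), 6L)
  ## empty input stays empty
  expect_identical(nrow(filter_snapshots(tab[0, ])), 0L)
  expect_length(filter_snapshots(list()), 0)
  ## list-of-records input
  recs <- lapply(seq_len(6), function(i)
    list(energy = tab$energy[i], density = tab$density[i]))
  expect_length(filter_snapshots(recs), 3)
})

test_that("iterative clustering finds the brute-force minimum on a chain", {
  d <- abs(outer(1:6, 1:6, "-")) * 0.4
  cl <- iterative_cluster(d, cutoff = 0.5, restarts = 1000, seed = 1)
  expect_identical(cl$n_clusters, brute_min_clusters(d, 0.5))
  ## partition invariants
  expect_true(all(cl$assignment >= 1))
  expect_identical(length(cl$assignment), 6L)
  for (k in seq_len(cl$n_clusters)) {
    members <- which(cl$assignment == k)
    expect_true(all(d[cl$seeds[k], members] <= 0.5))
  }
})

test_that("degenerate clustering cases behave", {
  all_close <- matrix(0.1, 4, 4); diag(all_close) <- 0
  expect_identical(iterative_cluster(all_close, 0.5, 50, seed = 2)$n_clusters, 1L)
  all_far <- matrix(9, 4, 4); diag(all_far) <- 0
  expect_identical(iterative_cluster(all_far, 0.5, 50, seed = 2)$n_clusters, 4L)
})

test_that("best-of-k cluster count is nonincreasing in k", {
  set.seed(34)
  n <- 12
  pts <- matrix(runif(n * 2, 0, 3), n, 2)
  d <- as.matrix(dist(pts))
  counts <- vapply(c(1, 5, 25, 125), function(k) {
    set.seed(99)
    iterative_cluster(d, cutoff = 0.8, restarts = k)$n_clusters
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("match assessment applies the similarity thresholds", {
  expect_identical(as.character(match_assessment(rmsd = 0.9)), "match")
  expect_identical(as.character(match_assessment(rmsd = 1.2)), "promotable")
  expect_identical(as.character(match_assessment(rmsd = 2.0)), "miss")
  expect_identical(as.character(match_assessment(rmsd = 1.0)), "match")
  lj <- make_lj_monatomic()
  cl <- unit_cell(3.686, 3.686, 3.686, 60, 60, 60)
  A <- crystal_state(lj$topology, lj$coords, cl, "P1")
  m <- match_assessment(A, A, n_mol = 12)
  expect_identical(as.character(m), "match")
  expect_lt(attr(m, "rmsd"), 1e-6)
})

test_that("reduction report tabulates per-group survivors by stage", {
  stages <- list(
    snapshots = c(rep("P-1", 6), rep("P21/c", 4)),
    filtered = c(rep("P-1", 3), rep("P21/c", 2)),
    clustered = c("P-1", "P21/c"))
  rep_ <- reduction_report(stages)
  expect_identical(rep_$snapshots[rep_$space_group == "P-1"], 6L)
  expect_identical(rep_$filtered[rep_$space_group == "P21/c"], 2L)
  expect_identical(rep_$clustered[rep_$space_group == "total"], 2L)
  ## single no-op stage leaves counts unchanged
  one <- reduction_report(list(all = rep("P1", 5)))
  expect_identical(one$all[one$space_group == "P1"], 5L)
  ## empty input gives a zero-row table
  expect_identical(nrow(reduction_report(list(s = character(0)))), 0L)
})

test_that("similarity matrices are symmetric with zero diagonal and round-trip", {
  lj <- make_lj_monatomic()
  mk <- function(a, alpha) crystal_state(
    lj$topology, lj$coords, unit_cell(a, a, a, alpha, alpha, alpha), "P1")
  states <- list(mk(3.686, 60), mk(3.686, 60), mk(3.3, 90))
  m <- similarity_matrix(states, n_mol = 12)
  expect_equal(m, t(m), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diag(m) < 1e-6))
  expect_lt(m[1, 2], 1e-6)
  expect_gt(m[1, 3], 0.3)
  f <- withr::local_tempfile()
  write_similarity_tsv(m, f)
  m2 <- read_similarity_tsv(f)
  expect_equal(unclass(m)[, ], m2[, ], tolerance = 1e-10, ignore_attr = TRUE)
})
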