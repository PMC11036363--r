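test_that("expansion to P1 yields one molecule per symmetry operator", {
  set.seed(4)
  ring <- make_rigid_ring()
  ## P1 input is returned unchanged
  cl <- unit_cell(8, 8, 8, 90, 90, 90)
  st <- crystal_state(ring$topology, place_molecule(ring$coords, cl), cl, "P1")
  expect_identical(expand_to_p1(st)$n_molecules, 1L)
  for (s in c("P-1", "P21/c", "C2/c", "R-3")) {
    stx <- ring_crystal(s)
    p1 <- suppressWarnings(expand_to_p1(stx))
    expect_identical(p1$n_molecules, stx$sg$n_ops)
    expect_identical(p1$sg$symbol, "P1")
  }
})

test_that("replication multiplies molecules and scales edges", {
  set.seed(5)
  st <- ring_crystal("P-1")
  p1 <- suppressWarnings(expand_to_p1(st))
  expect_identical(replicate_cell(p1, 1, 1, 1)$n_molecules, p1$n_molecules)
  big <- replicate_cell(p1, 3, 3, 3)
  expect_identical(big$n_molecules, 54L)       # 2 molecules x 27 cells
  expect_equal(big$cell$a, 3 * p1$cell$a)
  st2 <- ring_crystal("P21/c")
  p2 <- suppressWarnings(expand_to_p1(st2))
  expect_identical(replicate_cell(p2, 3, 3, 2)$n_molecules, 72L)
  expect_error(replicate_cell(p2, 0, 1, 1), "positive")
  expect_error(replicate_cell(st2, 2, 2, 2), "P1")
})

test_that("density is identical across representations", {
  set.seed(6)
  for (s in c("P-1", "Pbca")) {
    st <- ring_crystal(s)
    p1 <- suppressWarnings(expand_to_p1(st))
    big <- replicate_cell(p1, 2, 3, 1)
    expect_identical(crystal_density(st), crystal_density(p1))
    ## replication scales mass and volume by the same integer factor
    expect_equal(crystal_density(big), crystal_density(st), tolerance = 1e-14)
  }
})

test_that("degree-of-freedom accounting is 3 per atom over the contents", {
  top43 <- molecule_43()
  cl <- unit_cell(15, 15, 15, 90, 90, 101)
  asu <- crystal_state(top43, matrix(seq_len(129) / 10, 43, 3), cl, "P-1")
  expect_identical(count_dof(asu), 129L)
  p1 <- suppressWarnings(expand_to_p1(asu))
  expect_identical(count_dof(p1), 258L)
  expect_identical(count_dof(replicate_cell(p1, 3, 3, 3)), 6966L)
  one <- crystal_state(make_lj_monatomic()$topology, matrix(0, 1, 3),
                       cl, "P1")
  expect_identical(count_dof(one), 3L)
})

test_that("overlapping symmetry images warn instead of failing", {
  ring <- make_rigid_ring()
  cl <- unit_cell(6, 6, 6, 90, 90, 90)
  ## molecule on the inversion center: images overlap exactly
  st <- crystal_state(ring$topology, ring$coords, cl, "P-1")
  expect_warning(expand_to_p1(st), "overlapping")
})

test_that("coordinate rescaling preserves molecular geometry and COM fractions", {
  set.seed(7)
  st <- ring_crystal("P21")
  new_cell <- unit_cell(st$cell$a * 1.07, st$cell$b * 0.96, st$cell$c * 1.01,
                        90, st$cell$beta + 1.5, 90)
  ## identity when the cell is unchanged
  expect_equal(rescale_coordinates(st, st$cell), st$coords, tolerance = 1e-14)
  co2 <- rescale_coordinates(st, new_cell)
  d_old <- dist(st$coords)
  d_new <- dist(co2)
  expect_lt(max(abs(d_old - d_new)), 1e-12)
  w <- st$topology$mass / sum(st$topology$mass)
  com_frac_old <- cart_to_frac(st$cell, colSums(st$coords * w))
  com_frac_new <- cart_to_frac(new_cell, colSums(co2 * w))
  expect_lt(max(abs(com_frac_old - com_frac_new)), 1e-12)
})

test_that("crystal state validates lambda and coordinate shape", {
  lj <- make_lj_monatomic()
  cl <- unit_cell(5, 5, 5, 90, 90, 90)
  expect_error(crystal_state(lj$topology, matrix(0, 1, 3), cl, "P1",
                             lambda = 1.2), "lambda")
  expect_error(crystal_state(lj$topology, matrix(0, 2, 3), cl, "P1"),
               "coords")
})
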