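## Deterministic toy systems and analytic potentials. These are first-class,
## tested generators: every stage of the search pipeline can be exercised on
## them without any external input.

#' Lennard-Jones-like monatomic toy system
#'
#' A single atom with buffered 14-7 parameters and no bonded terms; the
#' simplest Z' = 1 "molecule". Its close-packed global minimum is reachable by
#' a brute-force lattice grid scan ([lattice_grid_minimum()]), which anchors
#' the end-to-end search test. The bundled `params` use a 7 Angstrom cutoff so
#' that desk-scale lattice sums stay small.
#'
#' @param eps well depth (kcal/mol, default 0.4).
#' @param r0 minimum-energy pair distance (Angstrom, default 3.8).
#' @param mass atomic mass (amu, default 24.305).
#' @param element element symbol used in output files (default "Mg").
#' @param seed integer stored with the fixture (regeneration is deterministic).
#' @return object of class `toy_system`: `topology`, `coords` (1 x 3, origin),
#'   `params` (an [alchemical_params()]), `seed`.
#' @export
make_lj_monatomic <- function(eps = 0.4, r0 = 3.8, mass = 24.305,
                              element = "Mg", seed = 1L) {
  top <- molecule_topology(element = element, mass = mass, eps = eps, r0 = r0,
                           charge = 0)
  structure(list(topology = top, coords = matrix(0, 1, 3),
                 params = alchemical_params(cutoff = 7, use_elec = FALSE),
                 seed = as.integer(seed)),
            class = "toy_system")
}

#' Rigid planar ring toy system
#'
#' A regular planar n-ring with alternating point charges: harmonic bonds
#' along the ring edges and harmonic angles at the interior angle, both at
#' their minima in the construction geometry; no torsions. Exercises
#' electrostatics and multi-atom rigid-body moves.
#'
#' @param n_atoms ring size (even, >= 4; default 6).
#' @param charge magnitude of the alternating charges (e, default 0.2).
#' @param bond_length ring edge length (Angstrom, default 1.4).
#' @param seed integer stored with the fixture.
#' @return a `toy_system` (see [make_lj_monatomic()]).
#' @export
make_rigid_ring <- function(n_atoms = 6L, charge = 0.2, bond_length = 1.4,
                            seed = 1L) {
  if (n_atoms < 4L || n_atoms %% 2L != 0L)
    stop("make_rigid_ring: n_atoms must be even and >= 4")
  n <- as.integer(n_atoms)
  R <- bond_length / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(R * cos(ang), R * sin(ang), 0)
  coords <- sweep(coords, 2, colMeans(coords))  # COM at origin
  q <- rep(c(charge, -charge), length.out = n)
  top <- molecule_topology(
    element = rep("C", n), mass = rep(12.011, n),
    eps = rep(0.1, n), r0 = rep(3.4, n), charge = q,
    bonds = data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1L),
                       k = 350, b0 = bond_length),
    angles = data.frame(i = c(n, seq_len(n - 1L)), j = seq_len(n),
                        k = c(seq_len(n)[-1], 1L),
                        ktheta = 60, theta0 = 180 * (n - 2) / n))
  structure(list(topology = top, coords = coords,
                 params = alchemical_params(cutoff = 7),
                 seed = as.integer(seed)),
            class = "toy_system")
}

#' Analytic one-dimensional lambda potential with closed-form free energy
#'
#' `U(lambda) = dG * s(lambda) + barrier * 16 lambda^2 (1-lambda)^2` with the
#' smoothstep `s = 3 lambda^2 - 2 lambda^3`, so `U(0) = 0`, `U(1) = dG`,
#' dU/dlambda vanishes at both endpoints, and a bump of amplitude `barrier`
#' separates the states. With no other degrees of freedom the free-energy
#' difference is exactly `dG`; the fixture plugs into [run_ost_lambda()] in
#' place of a crystal energy.
#'
#' @param dg_target free-energy difference U(1) - U(0) (kcal/mol; default -3).
#' @param barrier bump amplitude (kcal/mol; default 5).
#' @param seed integer stored with the fixture.
#' @return object of class `toy_system` with functions `u(lambda)`,
#'   `dudl(lambda)` and the scalar `delta_g`.
#' @export
make_analytic_lambda_well <- function(dg_target = -3, barrier = 5, seed = 1L) {
  u <- function(l) dg_target * (3 * l^2 - 2 * l^3) + barrier * 16 * l^2 * (1 - l)^2
  dudl <- function(l) dg_target * 6 * l * (1 - l) +
    barrier * 32 * l * (1 - l) * (1 - 2 * l)
  structure(list(u = u, dudl = dudl, delta_g = dg_target,
                 barrier = barrier, seed = as.integer(seed)),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  if (!is.null(x$topology)) {
    cat("toy system: "); print(x$topology)
  } else {
    cat(sprintf("toy lambda well: delta G = %.3f kcal/mol, barrier = %.3f\n",
                x$delta_g, x$barrier))
  }
  invisible(x)
}

#' Brute-force lattice-grid global minimum for a monatomic P1 crystal
#'
#' Scans rhombohedral-family cells (`a = b = c`, `alpha = beta = gamma`) over
#' a fixed, documented grid and returns the lowest per-molecule energy. The
#' family contains the close-packed fcc lattice (alpha = 60 degrees), the
#' global minimum for a monatomic pairwise potential representable with one
#' molecule per cell; the scan is bit-reproducible under a fixed grid.
#'
#' @param toy a monatomic `toy_system` from [make_lj_monatomic()].
#' @param a_grid vector of cell lengths (Angstrom); default
#'   `seq(0.92, 1.08, by = 0.0025) * r0`.
#' @param alpha_grid vector of cell angles (degrees); default `seq(50, 120, 1)`.
#' @param params an [alchemical_params()]; defaults to the fixture's.
#' @return list `energy` (kcal/mol per molecule), `cell` (the argmin
#'   [unit_cell()]), `a`, `alpha`.
#' @export
lattice_grid_minimum <- function(toy, a_grid = NULL, alpha_grid = NULL,
                                 params = NULL) {
  stopifnot(inherits(toy, "toy_system"), toy$topology$n_atoms == 1L)
  r0 <- toy$topology$r0[1]
  a_grid <- a_grid %||% (seq(0.92, 1.08, by = 0.0025) * r0)
  alpha_grid <- alpha_grid %||% seq(50, 120, by = 1)
  params <- params %||% toy$params
  best <- list(energy = Inf, a = NA_real_, alpha = NA_real_)
  for (alpha in alpha_grid) {
    for (a in a_grid) {
      cl <- tryCatch(unit_cell(a, a, a, alpha, alpha, alpha),
                     error = function(e) NULL)
      if (is.null(cl)) next
      st <- crystal_state(toy$topology, toy$coords, cl, "P1", lambda = 1)
      e <- total_potential(st, params)$total
      if (e < best$energy) best <- list(energy = e, a = a, alpha = alpha)
    }
  }
  best$cell <- unit_cell(best$a, best$a, best$a, best$alpha, best$alpha,
                         best$alpha)
  best
}
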