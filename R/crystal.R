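#' Crystal state
#'
#' The central simulation state: one molecule (Z' = 1) of asymmetric-unit
#' content in Cartesian coordinates, a unit cell, a space group and the
#' alchemical coupling value lambda. A multi-molecule P1 state (as produced by
#' [expand_to_p1()] or [replicate_cell()]) carries `n_molecules > 1` and a
#' `molecule` index per atom.
#'
#' @param topology a [molecule_topology()] (the content of one molecule).
#' @param coords n x 3 Cartesian coordinates in Angstrom. For states with
#'   `n_molecules > 1` the rows are molecule-major.
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] or symbol accepted by [space_group()].
#' @param lambda coupling value in `[0, 1]`.
#' @param n_molecules number of molecules in the (possibly expanded) cell
#'   contents; 1 for a Z' = 1 asymmetric unit.
#' @return object of class `crystal_state`.
#' @export
crystal_state <- function(topology, coords, cell, sg, lambda = 1,
                          n_molecules = 1L) {
  if (is.character(sg)) sg <- space_group(sg)
  stopifnot(inherits(topology, "molecule_topology"),
            inherits(cell, "unit_cell"), inherits(sg, "space_group"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != topology$n_atoms * n_molecules)
    stop("crystal_state: coords must be (n_atoms * n_molecules) x 3")
  stopifnot_scalar(lambda)
  if (lambda < 0 || lambda > 1) stop("crystal_state: lambda must be in [0, 1]")
  structure(list(topology = topology, coords = unname(coords), cell = cell,
                 sg = sg, lambda = lambda, n_molecules = as.integer(n_molecules)),
            class = "crystal_state")
}

#' @export
print.crystal_state <- function(x, ...) {
  cat(sprintf("crystal: %s, %d molecule(s) x %d atoms, lambda=%.3f, density=%.4f g/cm^3\n",
              x$sg$symbol, x$n_molecules, x$topology$n_atoms, x$lambda,
              crystal_density(x)))
  print(x$cell)
  invisible(x)
}

#' Crystal density
#'
#' `(molecular mass x number of molecules in the full cell) / cell volume`,
#' in g/cm^3. For a symmetry-bearing state the cell contains
#' `n_molecules * n_ops` molecules.
#'
#' @param state a [crystal_state()].
#' @return density in g/cm^3.
#' @export
crystal_density <- function(state) {
  n_cell <- state$n_molecules * state$sg$n_ops
  molecule_mass(state$topology) * n_cell /
    cell_volume(state$cell) * AMU_A3_TO_GCC
}

#' Asymmetric-unit volume
#'
#' Cell volume divided by the space-group multiplicity; the volume variable of
#' the Monte Carlo barostat.
#'
#' @param state a [crystal_state()].
#' @return volume in Angstrom^3.
#' @export
asu_volume <- function(state) cell_volume(state$cell) / state$sg$n_ops

#' Count coordinate degrees of freedom
#'
#' Three per atom over the full (possibly expanded/replicated) contents.
#'
#' @param state a [crystal_state()].
#' @return integer.
#' @export
count_dof <- function(state) {
  3L * state$topology$n_atoms * state$n_molecules
}

#' Molecule index of each atom row
#' @param state a [crystal_state()].
#' @return integer vector of length `n_atoms * n_molecules`.
#' @export
molecule_index <- function(state) {
  rep(seq_len(state$n_molecules), each = state$topology$n_atoms)
}

#' Expand an asymmetric unit to a P1 cell
#'
#' Applies every symmetry operator of the space group to the asymmetric-unit
#' contents, producing a P1 crystal with `n_ops` times as many molecules in the
#' same cell. Images whose atoms approach another image closer than 0.5
#' Angstrom trigger a warning (search states may clash), not an error.
#'
#' @param state a [crystal_state()].
#' @return a P1 [crystal_state()].
#' @export
expand_to_p1 <- function(state) {
  if (state$sg$symbol == "P1" && state$sg$n_ops == 1L) return(state)
  frac <- cart_to_frac(state$cell, state$coords)
  blocks <- lapply(state$sg$ops, function(op)
    frac_to_cart(state$cell, apply_symop(op, frac)))
  coords <- do.call(rbind, blocks)
  out <- crystal_state(state$topology, coords, state$cell, space_group("P1"),
                       lambda = state$lambda,
                       n_molecules = state$n_molecules * state$sg$n_ops)
  d <- min_intermolecular_distance(out)
  if (is.finite(d) && d < 0.5)
    warning(sprintf("expand_to_p1: overlapping symmetry images (min distance %.3f A)", d))
  out
}

## Minimum intermolecular atom-atom distance inside the cell (no images);
## used only for the clash warning.
min_intermolecular_distance <- function(state) {
  if (state$n_molecules < 2L) return(Inf)
  mol <- molecule_index(state)
  dmin <- Inf
  for (i in seq_len(state$n_molecules - 1L)) for (j in (i + 1L):state$n_molecules) {
    a <- state$coords[mol == i, , drop = FALSE]
    b <- state$coords[mol == j, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    dmin <- min(dmin, sqrt(max(0, min(d2))))
  }
  dmin
}

#' Replicate a P1 cell
#'
#' Builds an `na x nb x nc` supercell of a P1 state: the cell edges are scaled
#' by the factors and the molecule count is multiplied by `na*nb*nc`.
#'
#' @param p1_state a P1 [crystal_state()].
#' @param na,nb,nc positive integer replication factors.
#' @return a P1 [crystal_state()] for the supercell.
#' @export
replicate_cell <- function(p1_state, na, nb, nc) {
  if (p1_state$sg$n_ops != 1L)
    stop("replicate_cell: input must be a P1 state (expand_to_p1 first)")
  f <- c(na, nb, nc)
  if (any(f < 1) || any(f != round(f)))
    stop("replicate_cell: replication factors must be positive integers")
  f <- as.integer(f)
  if (all(f == 1L)) return(p1_state)
  cl <- p1_state$cell
  shifts <- as.matrix(expand.grid(ia = 0:(f[1] - 1L), ib = 0:(f[2] - 1L),
                                  ic = 0:(f[3] - 1L)))
  ## order molecule-major: every translate of the whole cell contents
  coords <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    t_cart <- frac_to_cart(cl, as.numeric(shifts[k, ]))
    sweep(p1_state$coords, 2, t_cart, "+")
  }))
  big <- unit_cell(cl$a * f[1], cl$b * f[2], cl$c * f[3],
                   cl$alpha, cl$beta, cl$gamma)
  crystal_state(p1_state$topology, coords, big, space_group("P1"),
                lambda = p1_state$lambda,
                n_molecules = p1_state$n_molecules * prod(f))
}

#' Rescale coordinates after a lattice change
#'
#' Rigidly translates each molecule so that the fractional coordinates of its
#' center of mass are identical under the new cell; intramolecular geometry is
#' untouched.
#'
#' @param state a [crystal_state()].
#' @param new_cell a [unit_cell()].
#' @return the coordinate matrix for the new cell.
#' @export
rescale_coordinates <- function(state, new_cell) {
  mol <- molecule_index(state)
  mass <- rep(state$topology$mass, state$n_molecules)
  out <- state$coords
  for (m in seq_len(state$n_molecules)) {
    sel <- mol == m
    w <- mass[sel] / sum(mass[sel])
    com <- colSums(state$coords[sel, , drop = FALSE] * w)
    com_frac <- cart_to_frac(state$cell, com)
    new_com <- frac_to_cart(new_cell, com_frac)
    out[sel, ] <- sweep(state$coords[sel, , drop = FALSE], 2, new_com - com, "+")
  }
  out
}
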