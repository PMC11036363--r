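#' Triclinic unit cell
#'
#' Constructs a unit cell from the six lattice parameters and caches the
#' fractional-to-Cartesian matrix and its inverse. The Cartesian frame is the
#' crystallographic standard: `a` along x, `b` in the xy plane.
#'
#' @param a,b,c cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return an object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`,
#'   the 3x3 matrix `m` (columns are the cell vectors; maps fractional to
#'   Cartesian) and its inverse `mi`.
#' @examples
#' cell <- unit_cell(10, 10, 10, 90, 90, 90)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- unname(c(a, b, c, alpha, beta, gamma))
  if (!is.numeric(p) || length(p) != 6L || any(!is.finite(p)))
    stop("unit_cell: six finite numeric parameters required")
  a <- p[1]; b <- p[2]; c <- p[3]
  alpha <- p[4]; beta <- p[5]; gamma <- p[6]
  if (any(p[1:3] <= 0)) stop("unit_cell: lengths must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180))
    stop("unit_cell: angles must lie in (0, 180) degrees")
  ca <- cos(deg2rad(alpha)); cb <- cos(deg2rad(beta)); cg <- cos(deg2rad(gamma))
  sg <- sin(deg2rad(gamma))
  ## volume factor; must be positive for a non-degenerate cell (the threshold
  ## also rejects numerically flat cells, e.g. alpha = beta = gamma = 120)
  vf2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vf2 <= 1e-10) stop("unit_cell: degenerate angle combination (volume <= 0)")
  vf <- sqrt(vf2)
  m <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, c * vf / sg
  ), nrow = 3L, ncol = 3L)
  ## m is upper triangular: invert by back substitution (hot path)
  mi <- matrix(0, 3, 3)
  mi[1, 1] <- 1 / m[1, 1]
  mi[2, 2] <- 1 / m[2, 2]
  mi[3, 3] <- 1 / m[3, 3]
  mi[1, 2] <- -m[1, 2] * mi[1, 1] * mi[2, 2]
  mi[2, 3] <- -m[2, 3] * mi[2, 2] * mi[3, 3]
  mi[1, 3] <- (m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2]) * mi[1, 1] * mi[2, 2] * mi[3, 3]
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, m = m, mi = mi, v = a * b * c * vf),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' Unit-cell volume
#'
#' Closed-form triclinic volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma+2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell a [unit_cell()].
#' @return volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  cell$v
}

#' Fractional to Cartesian coordinates (and inverse)
#'
#' @param cell a [unit_cell()].
#' @param x numeric 3-vector or n x 3 matrix of coordinates.
#' @return coordinates of the same shape in the other basis.
#' @export
frac_to_cart <- function(cell, x) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(x)) t(cell$m %*% t(x)) else as.numeric(cell$m %*% x)
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, x) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(x)) t(cell$mi %*% t(x)) else as.numeric(cell$mi %*% x)
}

#' Perpendicular widths of a cell
#'
#' Distance between opposite faces along each axis; the quantity that governs
#' the minimum image convention.
#'
#' @param cell a [unit_cell()].
#' @return numeric 3-vector of widths in Angstrom.
#' @keywords internal
cell_perp_widths <- function(cell) {
  ## width_k = V / area of the face spanned by the other two vectors
  ##         = 1 / |row k of the inverse matrix|
  1 / sqrt(rowSums(cell$mi^2))
}

#' Minimum-image replication factors
#'
#' Smallest integers `(na, nb, nc)` such that the replicated cell has
#' perpendicular width of at least twice the interaction cutoff along each
#' axis, so that the minimum image convention is valid.
#'
#' @param cell a [unit_cell()].
#' @param cutoff interaction cutoff in Angstrom (> 0).
#' @return integer 3-vector.
#' @export
min_image_factors <- function(cell, cutoff) {
  stopifnot_scalar(cutoff)
  if (cutoff <= 0) stop("min_image_factors: cutoff must be positive")
  w <- cell_perp_widths(cell)
  as.integer(ceiling(2 * cutoff / w))
}

## ---- lattice systems -------------------------------------------------------

LATTICE_SYSTEMS <- c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
                     "rhombohedral", "hexagonal", "cubic")

## Free lattice degrees of freedom per system. Each entry is a list of "moves";
## a move is either a group of length parameters scaled in tandem or a group of
## angle parameters changed in tandem. The constrained parameters are implied:
##  monoclinic: alpha = gamma = 90 (unique axis b); orthorhombic: all 90;
##  tetragonal: a = b, all 90; rhombohedral: a = b = c, alpha = beta = gamma;
##  hexagonal: a = b, alpha = beta = 90, gamma = 120; cubic: a = b = c, all 90.
.dof_cache <- new.env(parent = emptyenv())

lattice_free_dof <- function(system) {
  cached <- .dof_cache[[system]]
  if (!is.null(cached)) return(cached)
  .dof_cache[[system]] <- lattice_free_dof_build(system)
}

lattice_free_dof_build <- function(system) {
  switch(system,
    triclinic = list(
      list(kind = "length", par = "a"), list(kind = "length", par = "b"),
      list(kind = "length", par = "c"), list(kind = "angle", par = "alpha"),
      list(kind = "angle", par = "beta"), list(kind = "angle", par = "gamma")),
    monoclinic = list(
      list(kind = "length", par = "a"), list(kind = "length", par = "b"),
      list(kind = "length", par = "c"), list(kind = "angle", par = "beta")),
    orthorhombic = list(
      list(kind = "length", par = "a"), list(kind = "length", par = "b"),
      list(kind = "length", par = "c")),
    tetragonal = list(
      list(kind = "length", par = c("a", "b")), list(kind = "length", par = "c")),
    rhombohedral = list(
      list(kind = "length", par = c("a", "b", "c")),
      list(kind = "angle", par = c("alpha", "beta", "gamma"))),
    hexagonal = list(
      list(kind = "length", par = c("a", "b")), list(kind = "length", par = "c")),
    cubic = list(
      list(kind = "length", par = c("a", "b", "c"))),
    stop(sprintf("unknown lattice system '%s'", system))
  )
}

#' Independently sampled lattice parameters of a lattice system
#'
#' The count implied by the lattice-system constraint sets: triclinic 6,
#' monoclinic 4 (alpha = gamma = 90 fixed), orthorhombic 3 (all angles fixed),
#' tetragonal 2, rhombohedral 2, hexagonal 2, cubic 1.
#'
#' @param system one of `"triclinic"`, `"monoclinic"`, `"orthorhombic"`,
#'   `"tetragonal"`, `"rhombohedral"`, `"hexagonal"`, `"cubic"`.
#' @return integer count of free lattice parameters.
#' @export
count_lattice_dof <- function(system) {
  length(lattice_free_dof(match.arg(system, LATTICE_SYSTEMS)))
}

#' Check a unit cell against its lattice-system constraints
#'
#' @param cell a [unit_cell()].
#' @param system lattice system name.
#' @param tol tolerance; the barostat and minimizer maintain constraints
#'   exactly, so the default is 0.
#' @return logical.
#' @export
lattice_constraints_ok <- function(cell, system, tol = 0) {
  eq <- function(x, y) abs(x - y) <= tol
  switch(match.arg(system, LATTICE_SYSTEMS),
    triclinic = TRUE,
    monoclinic = eq(cell$alpha, 90) && eq(cell$gamma, 90),
    orthorhombic = eq(cell$alpha, 90) && eq(cell$beta, 90) && eq(cell$gamma, 90),
    tetragonal = eq(cell$a, cell$b) && eq(cell$alpha, 90) &&
      eq(cell$beta, 90) && eq(cell$gamma, 90),
    rhombohedral = eq(cell$a, cell$b) && eq(cell$b, cell$c) &&
      eq(cell$alpha, cell$beta) && eq(cell$beta, cell$gamma),
    hexagonal = eq(cell$a, cell$b) && eq(cell$alpha, 90) &&
      eq(cell$beta, 90) && eq(cell$gamma, 120),
    cubic = eq(cell$a, cell$b) && eq(cell$b, cell$c) && eq(cell$alpha, 90) &&
      eq(cell$beta, 90) && eq(cell$gamma, 90)
  )
}

## Canonicalize a parameter list into a cell respecting a lattice system.
## Used by the barostat and the minimizer so constraints hold by construction.
cell_from_free_params <- function(system, values) {
  dof <- lattice_free_dof(system)
  stopifnot(length(values) == length(dof))
  p <- c(a = NA_real_, b = NA_real_, c = NA_real_,
         alpha = 90, beta = 90, gamma = 90)
  if (system == "hexagonal") p["gamma"] <- 120
  for (i in seq_along(dof)) p[dof[[i]]$par] <- values[i]
  if (system == "rhombohedral" && is.na(p["alpha"])) p[c("alpha","beta","gamma")] <- 90
  if (any(is.na(p[1:3]))) stop("cell_from_free_params: missing length")
  unit_cell(p["a"], p["b"], p["c"], p["alpha"], p["beta"], p["gamma"])
}

free_params_from_cell <- function(system, cell) {
  dof <- lattice_free_dof(system)
  vapply(dof, function(d) cell[[d$par[1]]], numeric(1))
}
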