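#' Alchemical surrogate force-field parameters
#'
#' Controls the pairwise potential: buffered 14-7 van der Waals with an
#' alchemical softcore, damped shifted-force (Wolf-style) point-charge
#' electrostatics, a quintic taper to zero at the cutoff, and the
#' lambda-coupling exponent.
#'
#' The softcore enters through the reduced distance,
#' `rho_soft^7 = alpha*(1-lambda)^2 + (r/r0)^7`, inside the buffered 14-7
#' expression, and the whole intermolecular pair energy is scaled by
#' `lambda^n`. With `n >= 2` the derivative dU/dlambda vanishes at lambda = 0.
#'
#' @param alpha softcore strength (dimensionless, > 0; default 0.7).
#' @param n lambda exponent (integer >= 2; default 5).
#' @param cutoff interaction cutoff in Angstrom (default 12).
#' @param taper_width width of the quintic switching window before the cutoff
#'   (Angstrom, default 1).
#' @param kappa damping parameter of the shifted-force electrostatics
#'   (1/Angstrom; default 0.2; 0 gives undamped shifted-force Coulomb).
#' @param use_elec logical; evaluate point-charge electrostatics (default TRUE).
#' @return object of class `alchemical_params`.
#' @export
alchemical_params <- function(alpha = 0.7, n = 5L, cutoff = 12,
                              taper_width = 1, kappa = 0.2, use_elec = TRUE) {
  if (alpha <= 0) stop("alchemical_params: alpha must be positive")
  if (n < 2 || n != round(n)) stop("alchemical_params: n must be an integer >= 2")
  if (cutoff <= 0 || taper_width <= 0 || taper_width >= cutoff)
    stop("alchemical_params: need 0 < taper_width < cutoff")
  structure(list(alpha = alpha, n = as.integer(n), cutoff = cutoff,
                 taper_width = taper_width, kappa = kappa,
                 use_elec = isTRUE(use_elec)),
            class = "alchemical_params")
}

## ---- switching window ------------------------------------------------------

## Quintic taper: 1 for r <= cutoff - w, 0 for r >= cutoff, C2-smooth between.
taper_fn <- function(r, cutoff, w) {
  z <- (r - (cutoff - w)) / w
  z <- pmin(pmax(z, 0), 1)
  s <- 1 - (10 * z^3 - 15 * z^4 + 6 * z^5)
  ds <- ifelse(z > 0 & z < 1, -(30 * z^2 - 60 * z^3 + 30 * z^4) / w, 0)
  list(s = s, ds = ds)
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

## ---- buffered 14-7 van der Waals with softcore ------------------------------
##
## Core (before lambda^n and taper), as a function of y = rho_soft^7:
##   g(y) = 1.07^7 * (y^(1/7) + 0.07)^(-7) * (1.12/(y + 0.12) - 2)
## g(1) = -1, so u(r = r0, lambda = 1) = -eps.
vdw_g <- function(y) {
  t <- y^(1 / 7)
  P <- (t + 0.07)^(-7)
  Q <- 1.12 / (y + 0.12) - 2
  Pp <- -(t + 0.07)^(-8) * t^(-6)                       # dP/dy
  Qp <- -1.12 / (y + 0.12)^2
  Ppp <- (1 / 7) * t^(-6) *
    (8 * (t + 0.07)^(-9) * t^(-6) + 6 * (t + 0.07)^(-8) * t^(-7))
  Qpp <- 2.24 / (y + 0.12)^3
  c7 <- 1.07^7
  list(g = c7 * P * Q,
       g1 = c7 * (Pp * Q + P * Qp),
       g2 = c7 * (Ppp * Q + 2 * Pp * Qp + P * Qpp))
}

## Vectorized pair kernel. Returns energy and the derivatives needed by the
## OST machinery: du/dr, du/dlambda, d2u/(dlambda dr), d2u/dlambda2.
pair_vdw <- function(r, eps, r0, lambda, par) {
  n <- par$n; al <- par$alpha
  s <- (r / r0)^7
  A <- al * (1 - lambda)^2
  y <- A + s
  gg <- vdw_g(y)
  y_r <- 7 * r^6 / r0^7
  y_l <- -2 * al * (1 - lambda)
  y_ll <- 2 * al
  ln <- lambda^n
  ln1 <- if (n >= 1) lambda^(n - 1) else 0
  ln2 <- if (n >= 2) lambda^(n - 2) else 0
  FF <- ln * gg$g
  F_r <- ln * gg$g1 * y_r
  F_l <- n * ln1 * gg$g + ln * gg$g1 * y_l
  F_rl <- n * ln1 * gg$g1 * y_r + ln * gg$g2 * y_l * y_r
  F_ll <- n * (n - 1) * ln2 * gg$g +
    2 * n * ln1 * gg$g1 * y_l + ln * (gg$g2 * y_l^2 + gg$g1 * y_ll)
  tp <- taper_fn(r, par$cutoff, par$taper_width)
  list(u = eps * FF * tp$s,
       du_dr = eps * (F_r * tp$s + FF * tp$ds),
       du_dl = eps * F_l * tp$s,
       d2u_dldr = eps * (F_rl * tp$s + F_l * tp$ds),
       d2u_dl2 = eps * F_ll * tp$s)
}

#' Softcore buffered 14-7 pair energy
#'
#' Single-pair convenience wrapper around the vectorized kernel; tapered to
#' zero at the cutoff, finite at r = 0 for lambda < 1, and equal to the plain
#' buffered 14-7 value at lambda = 1.
#'
#' @param r interatomic distance (Angstrom, >= 0).
#' @param eps pair well depth (kcal/mol).
#' @param r0 pair minimum-energy distance (Angstrom).
#' @param lambda coupling in `[0, 1]`.
#' @param params an [alchemical_params()].
#' @return energy in kcal/mol.
#' @export
softcore_vdw_pair <- function(r, eps, r0, lambda, params = alchemical_params()) {
  out <- pair_vdw(r, eps, r0, lambda, params)
  ifelse(r >= params$cutoff, 0, out$u)
}

## ---- damped shifted-force electrostatics with softcore ----------------------
##
## phi(t) = erfc(kappa t)/t, shifted so both the potential and its derivative
## vanish at the cutoff. Softcore enters through t = sqrt(r^2 + alpha(1-l)^2),
## i.e. a buffered distance with a 1 Angstrom^2 scale on the softcore term.
pair_elec <- function(r, qq, lambda, par) {
  k <- par$kappa; Rc <- par$cutoff; al <- par$alpha; n <- par$n
  two_k_pi <- 2 * k / sqrt(pi)
  c0 <- erfc_(k * Rc) / Rc
  c1 <- erfc_(k * Rc) / Rc^2 + two_k_pi * exp(-k^2 * Rc^2) / Rc
  A <- al * (1 - lambda)^2
  y <- r^2 + A
  t <- sqrt(y)
  e2 <- exp(-k^2 * t^2)
  phi <- erfc_(k * t) / t
  phi1 <- -erfc_(k * t) / t^2 - two_k_pi * e2 / t
  phi2 <- 2 * erfc_(k * t) / t^3 + two_k_pi * e2 * (2 * k^2 + 2 / t^2)
  h <- phi - c0 + c1 * (t - Rc)
  h1 <- phi1 + c1
  h2 <- phi2
  H <- h
  H1 <- h1 / (2 * t)                 # dH/dy
  H2 <- h2 / (4 * y) - h1 / (4 * t^3)
  y_r <- 2 * r
  y_l <- -2 * al * (1 - lambda)
  y_ll <- 2 * al
  ln <- lambda^n
  ln1 <- lambda^(n - 1)
  ln2 <- if (n >= 2) lambda^(n - 2) else 0
  FF <- ln * H
  F_r <- ln * H1 * y_r
  F_l <- n * ln1 * H + ln * H1 * y_l
  F_rl <- n * ln1 * H1 * y_r + ln * H2 * y_l * y_r
  F_ll <- n * (n - 1) * ln2 * H + 2 * n * ln1 * H1 * y_l +
    ln * (H2 * y_l^2 + H1 * y_ll)
  tp <- taper_fn(r, Rc, par$taper_width)
  q <- COULOMB * qq
  list(u = q * FF * tp$s,
       du_dr = q * (F_r * tp$s + FF * tp$ds),
       du_dl = q * F_l * tp$s,
       d2u_dldr = q * (F_rl * tp$s + F_l * tp$ds),
       d2u_dl2 = q * F_ll * tp$s)
}

## combined nonbonded pair kernel
pair_nonbonded <- function(r, eps, r0, qq, lambda, par) {
  v <- pair_vdw(r, eps, r0, lambda, par)
  if (par$use_elec && any(qq != 0)) {
    e <- pair_elec(r, qq, lambda, par)
    list(u = v$u + e$u, du_dr = v$du_dr + e$du_dr,
         du_dl = v$du_dl + e$du_dl, d2u_dldr = v$d2u_dldr + e$d2u_dldr,
         d2u_dl2 = v$d2u_dl2 + e$d2u_dl2,
         u_vdw = v$u, u_elec = e$u)
  } else {
    c(v, list(u_vdw = v$u, u_elec = 0 * v$u))
  }
}

## ---- bonded terms -----------------------------------------------------------

#' Bonded (intramolecular) energy and gradient
#'
#' Harmonic bonds `k (b - b0)^2`, harmonic angles `k (theta - theta0)^2`
#' (theta0 in degrees, k per rad^2) and cosine torsions
#' `amp (1 + cos(per*phi - phase))`. Lambda-independent.
#'
#' @param topology a [molecule_topology()].
#' @param coords n x 3 Cartesian coordinates of one molecule (Angstrom).
#' @return list with `energy` (kcal/mol) and `gradient` (n x 3, kcal/mol/A).
#' @export
bonded_energy <- function(topology, coords) {
  coords <- as.matrix(coords)
  n <- topology$n_atoms
  stopifnot(nrow(coords) == n)
  e <- 0
  g <- matrix(0, n, 3)
  b <- topology$bonds
  for (r in seq_len(nrow(b))) {
    d <- coords[b$i[r], ] - coords[b$j[r], ]
    bl <- sqrt(sum(d^2))
    e <- e + b$k[r] * (bl - b$b0[r])^2
    dd <- 2 * b$k[r] * (bl - b$b0[r]) * d / bl
    g[b$i[r], ] <- g[b$i[r], ] + dd
    g[b$j[r], ] <- g[b$j[r], ] - dd
  }
  a <- topology$angles
  for (r in seq_len(nrow(a))) {
    u <- coords[a$i[r], ] - coords[a$j[r], ]
    v <- coords[a$k[r], ] - coords[a$j[r], ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    uh <- u / nu; vh <- v / nv
    ct <- max(-1, min(1, sum(uh * vh)))
    st <- sqrt(max(1e-12, 1 - ct^2))
    th <- acos(ct)
    th0 <- deg2rad(a$theta0[r])
    e <- e + a$ktheta[r] * (th - th0)^2
    dU <- 2 * a$ktheta[r] * (th - th0)
    gi <- (ct * uh - vh) / (nu * st)
    gk <- (ct * vh - uh) / (nv * st)
    g[a$i[r], ] <- g[a$i[r], ] + dU * gi
    g[a$k[r], ] <- g[a$k[r], ] + dU * gk
    g[a$j[r], ] <- g[a$j[r], ] - dU * (gi + gk)
  }
  tt <- topology$torsions
  for (r in seq_len(nrow(tt))) {
    p1 <- coords[tt$i[r], ]; p2 <- coords[tt$j[r], ]
    p3 <- coords[tt$k[r], ]; p4 <- coords[tt$l[r], ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    phi <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2))
    ph0 <- deg2rad(tt$phase[r]); per <- tt$per[r]
    e <- e + tt$amp[r] * (1 + cos(per * phi - ph0))
    dU <- -tt$amp[r] * per * sin(per * phi - ph0)
    g1 <- -nb2 / sum(n1^2) * n1
    g4 <- nb2 / sum(n2^2) * n2
    f12 <- sum(b1 * b2) / nb2^2
    f32 <- sum(b3 * b2) / nb2^2
    g2 <- -g1 - f12 * g1 + f32 * g4
    g3 <- -g4 + f12 * g1 - f32 * g4
    g[tt$i[r], ] <- g[tt$i[r], ] + dU * g1
    g[tt$j[r], ] <- g[tt$j[r], ] + dU * g2
    g[tt$k[r], ] <- g[tt$k[r], ] + dU * g3
    g[tt$l[r], ] <- g[tt$l[r], ] + dU * g4
  }
  list(energy = e, gradient = g)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- intermolecular lattice sum ---------------------------------------------

## Integer translation box large enough that every image within the cutoff of
## any ASU atom is generated (automatic internal replication for small cells).
## The box is recentered per symmetry operator: with unwrapped fractional
## coordinates, the base image R f + tau can lie several cells away from the
## home molecule.
translation_box <- function(state, cutoff) {
  w <- cell_perp_widths(state$cell)
  co <- state$coords
  diam <- if (nrow(co) > 1) {
    rg <- apply(co, 2, range)
    sqrt(sum((rg[2, ] - rg[1, ])^2))
  } else 0
  n <- as.integer(ceiling((cutoff + diam) / w)) + 1L
  if (prod(2 * n + 1) > 2e6)
    stop(sprintf(paste0("translation_box: cell too thin for the cutoff ",
                        "(%d x %d x %d images required)"),
                 2 * n[1] + 1, 2 * n[2] + 1, 2 * n[3] + 1))
  shifts <- as.matrix(expand.grid(-n[1]:n[1], -n[2]:n[2], -n[3]:n[3]))
  colnames(shifts) <- NULL
  shifts
}

is_identity_op <- function(op) {
  all(op$rot == diag(3)) && all(abs(op$trans %% 1) < 1e-12 |
                                abs(op$trans %% 1 - 1) < 1e-12)
}

#' Intermolecular (symmetry-mate) energy of a crystal state
#'
#' Sums all pair interactions between asymmetric-unit atoms and atoms of
#' symmetry mates / periodic images within the cutoff, with the alchemical
#' lambda scaling. Pairs between distinct molecules inside the cell count
#' once; pairs with external images carry weight 1/2 (shared between cells),
#' so the result is the intermolecular energy per asymmetric unit. Gradients
#' include the symmetry chain-rule terms for images generated from ASU atoms.
#'
#' @param state a [crystal_state()].
#' @param params an [alchemical_params()].
#' @return list: `energy`, `vdw`, `elec`, `gradient` (n x 3), `dU_dl`,
#'   `d2U_dl2`, `d2U_dldx` (n x 3).
#' @export
intermolecular_energy <- function(state, params = alchemical_params()) {
  top <- state$topology
  co <- state$coords
  N <- nrow(co)
  lam <- state$lambda
  mol <- molecule_index(state)
  nat <- top$n_atoms
  eps_a <- rep(top$eps, state$n_molecules)
  r0_a <- rep(top$r0, state$n_molecules)
  q_a <- rep(top$charge, state$n_molecules)

  zero <- list(energy = 0, vdw = 0, elec = 0,
               gradient = matrix(0, N, 3), dU_dl = 0, d2U_dl2 = 0,
               d2U_dldx = matrix(0, N, 3))
  if (lam == 0) return(zero)

  acc <- zero
  frac <- cart_to_frac(state$cell, co)
  shifts0 <- translation_box(state, params$cutoff)
  K <- nrow(shifts0)

  for (oi in seq_along(state$sg$ops)) {
    op <- state$sg$ops[[oi]]
    ident <- is_identity_op(op)
    Cs <- state$cell$m %*% op$rot %*% state$cell$mi   # Cartesian rotation
    bfrac <- apply_symop(op, frac)
    ## recenter the translation box on the image's fractional offset
    d0 <- round(colMeans(frac) - colMeans(bfrac))
    shifts <- sweep(shifts0, 2, d0, "+")
    t_cart <- shifts %*% t(state$cell$m)     # K x 3 Cartesian translations
    zero_shift <- which(rowSums(abs(shifts)) == 0)
    if (!length(zero_shift)) zero_shift <- -1L
    base <- frac_to_cart(state$cell, bfrac)  # N x 3
    ## images: block per translation, rows atom-major inside a block
    imgs <- base[rep(seq_len(N), times = K), , drop = FALSE] +
      t_cart[rep(seq_len(K), each = N), , drop = FALSE]
    j_atom <- rep(seq_len(N), times = K)
    blk <- rep(seq_len(K), each = N)
    for (i in seq_len(N)) {
      dxyz <- matrix(co[i, ], nrow(imgs), 3, byrow = TRUE) - imgs
      r2 <- rowSums(dxyz^2)
      sel <- r2 < params$cutoff^2
      if (ident) {
        ## exclude the self cell (handled as direct intra/inter below)
        sel <- sel & blk != zero_shift
      }
      ## guard exact overlaps (r = 0): zero separation carries no direction;
      ## energy is finite under the softcore, force taken as zero
      if (!any(sel)) next
      r <- sqrt(r2[sel])
      ja <- j_atom[sel]
      ai <- ((i - 1L) %% nat) + 1L
      aj <- ((ja - 1L) %% nat) + 1L
      pe <- pair_nonbonded(
        r = pmax(r, 1e-12),
        eps = sqrt(top$eps[ai] * top$eps[aj]),
        r0 = 0.5 * (top$r0[ai] + top$r0[aj]),
        qq = top$charge[ai] * top$charge[aj],
        lambda = lam, par = params)
      w <- 0.5
      acc$energy <- acc$energy + w * sum(pe$u)
      acc$vdw <- acc$vdw + w * sum(pe$u_vdw)
      acc$elec <- acc$elec + w * sum(pe$u_elec)
      acc$dU_dl <- acc$dU_dl + w * sum(pe$du_dl)
      acc$d2U_dl2 <- acc$d2U_dl2 + w * sum(pe$d2u_dl2)
      rsafe <- pmax(r, 1e-12)
      uv <- dxyz[sel, , drop = FALSE] / rsafe    # unit vectors (xi - y)/r
      uv[r < 1e-12, ] <- 0
      gi <- w * colSums(pe$du_dr * uv)
      acc$gradient[i, ] <- acc$gradient[i, ] + gi
      di <- w * colSums(pe$d2u_dldr * uv)
      acc$d2U_dldx[i, ] <- acc$d2U_dldx[i, ] + di
      ## chain rule onto the generating ASU atoms of the images
      gj <- rowsum(-w * pe$du_dr * uv, group = ja)
      dj <- rowsum(-w * pe$d2u_dldr * uv, group = ja)
      rows <- as.integer(rownames(gj))
      acc$gradient[rows, ] <- acc$gradient[rows, ] + gj %*% Cs
      acc$d2U_dldx[rows, ] <- acc$d2U_dldx[rows, ] + dj %*% Cs
    }
  }

  ## direct pairs inside the home cell between distinct molecules (weight 1)
  if (state$n_molecules > 1L) {
    for (i in seq_len(N - 1L)) {
      js <- which(mol[(i + 1L):N] != mol[i]) + i
      if (!length(js)) next
      dxyz <- matrix(co[i, ], length(js), 3, byrow = TRUE) -
        co[js, , drop = FALSE]
      r2 <- rowSums(dxyz^2)
      sel <- r2 < params$cutoff^2
      if (!any(sel)) next
      r <- sqrt(r2[sel]); js <- js[sel]
      ai <- ((i - 1L) %% nat) + 1L
      aj <- ((js - 1L) %% nat) + 1L
      pe <- pair_nonbonded(pmax(r, 1e-12),
                           sqrt(top$eps[ai] * top$eps[aj]),
                           0.5 * (top$r0[ai] + top$r0[aj]),
                           top$charge[ai] * top$charge[aj], lam, params)
      acc$energy <- acc$energy + sum(pe$u)
      acc$vdw <- acc$vdw + sum(pe$u_vdw)
      acc$elec <- acc$elec + sum(pe$u_elec)
      acc$dU_dl <- acc$dU_dl + sum(pe$du_dl)
      acc$d2U_dl2 <- acc$d2U_dl2 + sum(pe$d2u_dl2)
      uv <- dxyz[sel, , drop = FALSE] / pmax(r, 1e-12)
      uv[r < 1e-12, ] <- 0
      acc$gradient[i, ] <- acc$gradient[i, ] + colSums(pe$du_dr * uv)
      acc$d2U_dldx[i, ] <- acc$d2U_dldx[i, ] + colSums(pe$d2u_dldr * uv)
      gj <- rowsum(-pe$du_dr * uv, group = js)
      dj <- rowsum(-pe$d2u_dldr * uv, group = js)
      rows <- as.integer(rownames(gj))
      acc$gradient[rows, ] <- acc$gradient[rows, ] + gj
      acc$d2U_dldx[rows, ] <- acc$d2U_dldx[rows, ] + dj
    }
  }
  if (!is.finite(acc$energy))
    stop("intermolecular_energy: non-finite energy (overlapping geometry?)")
  acc
}

## Intramolecular nonbonded pairs (beyond 1-4): fully coupled at any lambda.
intra_nonbonded_energy <- function(state, params) {
  top <- state$topology
  pairs <- intra_nb_pairs(top)
  N <- nrow(state$coords)
  out <- list(energy = 0, vdw = 0, elec = 0, gradient = matrix(0, N, 3))
  if (!nrow(pairs)) return(out)
  for (m in seq_len(state$n_molecules)) {
    off <- (m - 1L) * top$n_atoms
    i <- pairs[, 1] + off; j <- pairs[, 2] + off
    dxyz <- state$coords[i, , drop = FALSE] - state$coords[j, , drop = FALSE]
    r <- sqrt(rowSums(dxyz^2))
    sel <- r < params$cutoff
    if (!any(sel)) next
    i <- i[sel]; j <- j[sel]; r <- r[sel]
    ai <- pairs[sel, 1]; aj <- pairs[sel, 2]
    pe <- pair_nonbonded(r, sqrt(top$eps[ai] * top$eps[aj]),
                         0.5 * (top$r0[ai] + top$r0[aj]),
                         top$charge[ai] * top$charge[aj],
                         lambda = 1, par = params)
    out$energy <- out$energy + sum(pe$u)
    out$vdw <- out$vdw + sum(pe$u_vdw)
    out$elec <- out$elec + sum(pe$u_elec)
    uv <- dxyz[sel, , drop = FALSE] / r
    gi <- pe$du_dr * uv
    gacc <- rowsum(rbind(gi, -gi), group = c(i, j))
    rows <- as.integer(rownames(gacc))
    out$gradient[rows, ] <- out$gradient[rows, ] + gacc
  }
  out
}

#' Total potential energy of a crystal state
#'
#' Bonded + intramolecular nonbonded (fully coupled) + lambda-scaled
#' intermolecular terms, with the analytic Cartesian gradient, dU/dlambda,
#' d2U/dlambda2 and the mixed derivative d2U/(dlambda dx) needed to assemble
#' the orthogonal-space bias force.
#'
#' @param state a [crystal_state()].
#' @param params an [alchemical_params()].
#' @return object of class `energy_result`: `total`, `bonded`, `vdw`, `elec`,
#'   `gradient`, `dU_dl`, `d2U_dl2`, `d2U_dldx`.
#' @export
total_potential <- function(state, params = alchemical_params()) {
  top <- state$topology
  N <- nrow(state$coords)
  eb <- 0
  gb <- matrix(0, N, 3)
  for (m in seq_len(state$n_molecules)) {
    idx <- ((m - 1L) * top$n_atoms + 1L):(m * top$n_atoms)
    bi <- bonded_energy(top, state$coords[idx, , drop = FALSE])
    eb <- eb + bi$energy
    gb[idx, ] <- gb[idx, ] + bi$gradient
  }
  intra <- intra_nonbonded_energy(state, params)
  inter <- intermolecular_energy(state, params)
  total <- eb + intra$energy + inter$energy
  if (!is.finite(total)) {
    stop(sprintf(paste0("total_potential: non-finite energy ",
                        "(bonded=%g intra=%g inter=%g, lambda=%.4f)"),
                 eb, intra$energy, inter$energy, state$lambda))
  }
  structure(list(
    total = total,
    bonded = eb,
    vdw = intra$vdw + inter$vdw,
    elec = intra$elec + inter$elec,
    gradient = gb + intra$gradient + inter$gradient,
    dU_dl = inter$dU_dl,
    d2U_dl2 = inter$d2U_dl2,
    d2U_dldx = inter$d2U_dldx
  ), class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("energy: total=%.6f (bonded=%.6f vdw=%.6f elec=%.6f), dU/dl=%.6f\n",
              x$total, x$bonded, x$vdw, x$elec, x$dU_dl))
  invisible(x)
}

#' Per-molecule potential energy
#'
#' Total potential divided by the number of molecules in the state's contents;
#' identical (to numerical precision) for an ASU-symmetric state, its P1
#' expansion and any replication of it.
#'
#' @param state a [crystal_state()].
#' @param params an [alchemical_params()].
#' @return energy in kcal/mol per molecule.
#' @export
energy_per_molecule <- function(state, params = alchemical_params()) {
  total_potential(state, params)$total / state$n_molecules
}
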