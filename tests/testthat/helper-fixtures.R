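## Shared helpers: small fixture builders and independent oracles.

## random cell compatible with a lattice system (lengths around `scale`)
rand_cell_for <- function(system, scale) {
  dof <- xtalpath:::lattice_free_dof(system)
  repeat {
    vals <- vapply(dof, function(d) {
      if (d$kind == "length") stats::runif(1, 0.9, 1.3) * scale
      else stats::runif(1, 80, 100)
    }, numeric(1))
    cl <- tryCatch(xtalpath:::cell_from_free_params(system, vals),
                   error = function(e) NULL)
    if (!is.null(cl)) return(cl)
  }
}

## random rigid placement of a molecule inside a cell
place_molecule <- function(coords0, cell) {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords0 %*% t(R), 2, frac_to_cart(cell, stats::runif(3)), "+")
}

## a ring crystal in an arbitrary shipped space group
ring_crystal <- function(symbol, lambda = 0.8, scale_per_mol = 7) {
  ring <- make_rigid_ring()
  sg <- space_group(symbol)
  cl <- rand_cell_for(sg$system, scale_per_mol * sg$n_ops^(1 / 3))
  crystal_state(ring$topology, place_molecule(ring$coords, cl), cl, sg,
                lambda = lambda)
}

## brute-force minimal cluster count over every seed ordering (small n)
brute_min_clusters <- function(d, cutoff) {
  n <- nrow(d)
  best <- n
  rec <- function(unc, k) {
    if (!length(unc)) { best <<- min(best, k); return(invisible()) }
    if (k + 1 >= best) return(invisible())
    for (s in unc) rec(setdiff(unc, unc[d[s, unc] <= cutoff]), k + 1L)
  }
  rec(seq_len(n), 0L)
  best
}

## exhaustive shell superposition: all permutations of non-central molecules,
## Kabsch over matched heavy atoms (oracle for the greedy matcher; shells
## must carry exactly n_mol molecules, i.e. built with n_env = n_mol)
brute_shell_rmsd <- function(sa, sb) {
  n <- length(sa$coords)
  stopifnot(n == sa$n_mol, length(sb$coords) == n)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ca <- colMeans(sa$coords[[1]]); cb <- colMeans(sb$coords[[1]])
  A <- lapply(sa$coords, function(m) sweep(m, 2, ca))
  B <- lapply(sb$coords, function(m) sweep(m, 2, cb))
  best <- Inf
  for (p in perms(seq_len(n)[-1])) {
    xb <- do.call(rbind, B[c(1L, p)])
    best <- min(best, kabsch(xb, do.call(rbind, A))$rmsd)
  }
  best
}

## finite-difference gradient of total_potential w.r.t. coordinates
fd_gradient <- function(state, params, h = 1e-6) {
  g <- matrix(0, nrow(state$coords), 3)
  for (i in seq_len(nrow(state$coords))) for (k in 1:3) {
    sp <- state; sp$coords[i, k] <- sp$coords[i, k] + h
    sm <- state; sm$coords[i, k] <- sm$coords[i, k] - h
    g[i, k] <- (total_potential(sp, params)$total -
                  total_potential(sm, params)$total) / (2 * h)
  }
  g
}

## generic 43-atom molecule (sizes only; used for degree-of-freedom accounting)
molecule_43 <- function() {
  n <- 43L
  molecule_topology(element = rep(c("C", "H"), length.out = n),
                    mass = rep(c(12.011, 1.008), length.out = n),
                    eps = rep(0.1, n), r0 = rep(3.5, n), charge = rep(0, n))
}
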