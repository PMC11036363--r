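## Crystal packing similarity (rmsd_N), filtering, clustering and match
## assessment.
##
## The shell comparison is a documented simplification of packing-alignment
## algorithms: build the N-molecule shells of lowest radius of gyration,
## match molecules greedily by center-of-mass distance after superposing the
## central molecules, then optimally superpose all matched heavy atoms
## (Kabsch). It is validated by its contract properties and by small-N
## exhaustive oracles, not by equivalence to any reference program.

#' Kabsch optimal superposition
#'
#' Rotation (proper, det = +1) minimizing the rmsd of `x` onto `y` after both
#' are centered by their means.
#'
#' @param x,y n x 3 coordinate matrices in correspondence.
#' @return list `rotation` (applies to centered x), `rmsd`.
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  xr <- xc %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((xr - yc)^2))))
}

## heavy-atom selector
heavy_idx <- function(topology) which(topology$element != "H")

#' Packing shell of N whole molecules
#'
#' Expands the crystal periodically around a central molecule and keeps the
#' `n_mol` nearest whole molecules by center-of-mass distance (central
#' molecule included). Candidate centers are the symmetry-distinct molecules
#' of the home cell; shells are ranked by the radius of gyration of their
#' heavy atoms and the `max_centers` lowest-Rg shells are returned.
#'
#' @param state a [crystal_state()].
#' @param n_mol shell size N (default 20).
#' @param max_centers how many low-Rg candidate shells to return (default 5).
#' @param n_env number of environment molecules carried with each shell
#'   (default `n_mol + 14`); the extra molecules make the comparison robust to
#'   ties in the Nth coordination distance.
#' @return list of shells; each shell has `coords` (list of per-molecule heavy
#'   atom matrices, central first; `n_env` entries), `coms`, `n_mol`, `rg`
#'   (radius of gyration of the N-molecule shell).
#' @export
packing_shell <- function(state, n_mol = 20L, max_centers = 5L,
                          n_env = n_mol + 14L) {
  p1 <- suppressWarnings(expand_to_p1(state))
  top <- p1$topology
  hv <- heavy_idx(top)
  if (!length(hv)) stop("packing_shell: no heavy atoms in topology")
  nm_cell <- p1$n_molecules
  ## replicate far enough to guarantee n_env neighbours in every direction,
  ## with a hard cap so absurd requests fail before allocating a huge crystal
  need <- ceiling((n_env / nm_cell)^(1 / 3))
  m <- min(max(1L, need), 4L)
  avail <- (2L * m + 1L)^3 * nm_cell
  if (avail < n_mol)
    stop(sprintf("packing_shell: only %d molecules obtainable, need %d",
                 avail, n_mol))
  n_env <- min(n_env, avail)
  big <- replicate_cell(p1, 2L * m + 1L, 2L * m + 1L, 2L * m + 1L)
  mol <- molecule_index(big)
  mass <- top$mass
  nmol_big <- big$n_molecules
  nat <- top$n_atoms
  w <- mass / sum(mass)
  comx <- rowsum(big$coords * w[(seq_len(nmol_big * nat) - 1L) %% nat + 1L],
                 group = mol)
  coms <- as.matrix(comx)
  ## home-cell molecules sit in the central replicate block; replicate_cell
  ## enumerates shifts with the first axis fastest, so block (m, m, m) is at
  nrep <- 2L * m + 1L
  center_block <- m + m * nrep + m * nrep^2   # 0-based
  home <- center_block * nm_cell + seq_len(nm_cell)
  shells <- lapply(home, function(cidx) {
    d2 <- rowSums(sweep(coms, 2, coms[cidx, ])^2)
    ord <- order(d2)[seq_len(n_env)]
    ord <- c(cidx, setdiff(ord, cidx))[seq_len(n_env)]
    sh_coords <- lapply(ord, function(k) {
      sel <- (k - 1L) * nat + seq_len(nat)
      big$coords[sel[hv], , drop = FALSE]
    })
    all_xyz <- do.call(rbind, sh_coords[seq_len(n_mol)])
    cen <- colMeans(all_xyz)
    rg <- sqrt(mean(rowSums(sweep(all_xyz, 2, cen)^2)))
    list(coords = sh_coords, coms = coms[ord, , drop = FALSE],
         n_mol = as.integer(n_mol), rg = rg)
  })
  shells <- shells[order(vapply(shells, `[[`, numeric(1), "rg"))]
  shells[seq_len(min(max_centers, length(shells)))]
}

## Superpose shell sa (its N-molecule shell) onto the environment of sb:
## greedy COM assignment of each of sa's N molecules to the nearest unused
## molecule anywhere in sb's environment, then Kabsch over the matched heavy
## atoms. The enlarged target side makes the result insensitive to ties in
## the Nth coordination distance.
superpose_shells <- function(sa, sb, n_iter = 4L) {
  na <- sa$n_mol
  nb <- length(sb$coords)
  ## center on the central molecules' heavy-atom centroids
  ca <- colMeans(sa$coords[[1]])
  cb <- colMeans(sb$coords[[1]])
  A <- lapply(sa$coords[seq_len(na)], function(m) sweep(m, 2, ca))
  B <- lapply(sb$coords, function(m) sweep(m, 2, cb))
  comsA <- sweep(sa$coms[seq_len(na), , drop = FALSE], 2, ca)
  comsB <- sweep(sb$coms, 2, cb)
  ## initial rotation from the central molecules
  R <- kabsch(B[[1]], A[[1]])$rotation
  best <- Inf
  for (it in seq_len(n_iter)) {
    comsBr <- comsB %*% t(R)
    free_b <- setdiff(seq_len(nb), 1L)
    perm <- integer(na); perm[1] <- 1L
    for (ia in setdiff(seq_len(na), 1L)) {
      d2 <- rowSums(sweep(comsBr[free_b, , drop = FALSE], 2, comsA[ia, ])^2)
      j <- free_b[which.min(d2)]
      perm[ia] <- j
      free_b <- setdiff(free_b, j)
    }
    xa <- do.call(rbind, A)
    xb <- do.call(rbind, B[perm])
    kb <- kabsch(xb, xa)
    R <- kb$rotation
    if (kb$rmsd >= best - 1e-12) { best <- min(best, kb$rmsd); break }
    best <- kb$rmsd
  }
  best
}

#' Crystal packing rmsd over N-molecule shells
#'
#' Root-mean-square deviation of heavy atoms after optimal superposition of
#' N-molecule packing shells from two crystals; the minimum over the tried
#' central-molecule choices and over both comparison directions (so the
#' measure is symmetric).
#'
#' @param a,b [crystal_state()] objects sharing a molecule topology.
#' @param n_mol shell size N (default 20; rmsd_20).
#' @param max_centers candidate central molecules per crystal (default 5).
#' @return rmsd in Angstrom.
#' @export
rmsd_n <- function(a, b, n_mol = 20L, max_centers = 5L) {
  if (a$topology$n_atoms != b$topology$n_atoms ||
      !identical(a$topology$element, b$topology$element))
    stop("rmsd_n: crystals must share a molecule topology")
  sha <- packing_shell(a, n_mol, max_centers)
  shb <- packing_shell(b, n_mol, max_centers)
  best <- Inf
  for (sa in sha) for (sb in shb)
    best <- min(best, superpose_shells(sa, sb), superpose_shells(sb, sa))
  best
}

#' Pairwise similarity matrix of snapshots
#'
#' @param states list of [crystal_state()].
#' @param n_mol shell size for [rmsd_n()].
#' @param labels optional character labels.
#' @param ... passed to [rmsd_n()].
#' @return symmetric matrix of class `similarity_matrix` with zero diagonal.
#' @export
similarity_matrix <- function(states, n_mol = 20L, labels = NULL, ...) {
  n <- length(states)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- rmsd_n(states[[i]], states[[j]], n_mol, ...)
  }
  labels <- labels %||% sprintf("s%03d", seq_len(n))
  dimnames(m) <- list(labels, labels)
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Filter snapshots by density and relative energy
#'
#' Keeps snapshots with density strictly above `rho_cut` and minimized energy
#' within `e_window` of the most stable snapshot in the input.
#'
#' @param snapshots a data.frame with columns `energy` (kcal/mol) and
#'   `density` (g/cm^3), or a list of records carrying those fields.
#' @param rho_cut density cutoff in g/cm^3 (default 1.25).
#' @param e_window energy window in kcal/mol (default 10).
#' @return the surviving subset, same type as the input.
#' @export
filter_snapshots <- function(snapshots, rho_cut = 1.25, e_window = 10) {
  if (is.data.frame(snapshots)) {
    if (!nrow(snapshots)) return(snapshots)
    keep <- snapshots$density > rho_cut &
      (snapshots$energy - min(snapshots$energy)) <= e_window
    snapshots[keep, , drop = FALSE]
  } else {
    if (!length(snapshots)) return(snapshots)
    e <- vapply(snapshots, `[[`, numeric(1), "energy")
    d <- vapply(snapshots, `[[`, numeric(1), "density")
    snapshots[d > rho_cut & (e - min(e)) <= e_window]
  }
}

#' Iterative minimum-cluster-count clustering
#'
#' Repeats the seeded absorption pass (pick a random unclustered structure as
#' seed; absorb every unclustered structure within `cutoff` of it; repeat
#' until all are clustered) `restarts` times and returns the trial with the
#' fewest clusters; ties are broken by first occurrence under the seeded
#' order.
#'
#' @param similarity symmetric distance matrix (e.g. [similarity_matrix()]).
#' @param cutoff rmsd criterion in Angstrom (default 0.5).
#' @param restarts number of random restarts (default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `crystal_clustering`: `assignment` (integer per
#'   structure), `seeds` (structure index seeding each cluster), `n_clusters`,
#'   `restarts`.
#' @export
iterative_cluster <- function(similarity, cutoff = 0.5, restarts = 1000L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(similarity)
  n <- nrow(m)
  stopifnot(n == ncol(m))
  best <- NULL
  for (t in seq_len(restarts)) {
    unc <- seq_len(n)
    assign <- integer(n)
    seeds <- integer(0)
    cl <- 0L
    while (length(unc)) {
      s <- if (length(unc) == 1L) unc else unc[sample.int(length(unc), 1L)]
      cl <- cl + 1L
      members <- unc[m[s, unc] <= cutoff]
      members <- union(s, members)
      assign[members] <- cl
      seeds <- c(seeds, s)
      unc <- setdiff(unc, members)
    }
    if (is.null(best) || cl < best$n_clusters)
      best <- list(assignment = assign, seeds = seeds, n_clusters = cl)
  }
  structure(c(best, list(restarts = as.integer(restarts))),
            class = "crystal_clustering")
}

#' @export
print.crystal_clustering <- function(x, ...) {
  cat(sprintf("clustering: %d structures -> %d clusters (best of %d restarts)\n",
              length(x$assignment), x$n_clusters, x$restarts))
  invisible(x)
}

#' Classify a prediction against a reference structure
#'
#' `rmsd_20 <= 1.0` Angstrom counts as a match; `<= 1.5` is promotable (such
#' structures historically refine below 1.0 after dispersion-corrected DFT
#' minimization); anything larger is a miss.
#'
#' @param predicted,reference [crystal_state()] objects, or NULL when `rmsd`
#'   is given directly.
#' @param n_mol shell size (default 20).
#' @param rmsd optional precomputed rmsd (Angstrom); skips the computation.
#' @param match_cut,promote_cut category thresholds in Angstrom.
#' @return character scalar: "match", "promotable" or "miss", with the rmsd as
#'   attribute `rmsd`.
#' @export
match_assessment <- function(predicted = NULL, reference = NULL, n_mol = 20L,
                             rmsd = NULL, match_cut = 1.0, promote_cut = 1.5) {
  if (is.null(rmsd)) rmsd <- rmsd_n(predicted, reference, n_mol)
  cat_ <- if (rmsd <= match_cut) "match"
          else if (rmsd <= promote_cut) "promotable"
          else "miss"
  structure(cat_, rmsd = rmsd)
}

#' Progressive reduction report
#'
#' Tabulates per-space-group survivor counts after each pipeline stage.
#'
#' @param stages named list; each element is a character vector of space-group
#'   symbols of the structures surviving that stage, in pipeline order.
#' @return data.frame with one row per space group (plus a total row) and one
#'   column per stage.
#' @export
reduction_report <- function(stages) {
  stopifnot(is.list(stages), length(stages) >= 1, !is.null(names(stages)))
  groups <- unique(unlist(stages))
  if (!length(groups))
    return(data.frame(space_group = character(0)))
  tab <- data.frame(space_group = groups, stringsAsFactors = FALSE)
  for (s in names(stages))
    tab[[s]] <- vapply(groups, function(g) sum(stages[[s]] == g), integer(1))
  total <- c(space_group = "total",
             lapply(stages, length))
  tab <- rbind(tab, as.data.frame(total, stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  tab
}
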