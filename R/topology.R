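#' Molecular topology with surrogate force-field parameters
#'
#' The asymmetric-unit content: per-atom nonbonded parameters plus harmonic
#' bond/angle terms and cosine-series torsions.
#'
#' @param element character vector of element symbols.
#' @param mass atomic masses (amu).
#' @param eps van der Waals well depths (kcal/mol).
#' @param r0 van der Waals minimum-energy distances (Angstrom).
#' @param charge partial charges (e); must sum to `total_charge` within 1e-9.
#' @param bonds data.frame with columns `i, j, k, b0` (k in kcal/mol/A^2, b0 in
#'   Angstrom; energy `k*(b-b0)^2`), or NULL.
#' @param angles data.frame with columns `i, j, k, ktheta, theta0` (ktheta in
#'   kcal/mol/rad^2, theta0 in degrees; energy `ktheta*(theta-theta0)^2`), or NULL.
#' @param torsions data.frame with columns `i, j, k, l, amp, per, phase`
#'   (amplitude kcal/mol, integer periodicity, phase degrees; energy
#'   `amp*(1+cos(per*phi - phase))`), or NULL.
#' @param total_charge declared integer net charge (e).
#' @return object of class `molecule_topology`.
#' @export
molecule_topology <- function(element, mass, eps, r0, charge,
                              bonds = NULL, angles = NULL, torsions = NULL,
                              total_charge = 0L) {
  n <- length(element)
  stopifnot(length(mass) == n, length(eps) == n, length(r0) == n,
            length(charge) == n, n >= 1L)
  if (any(mass <= 0)) stop("molecule_topology: masses must be positive")
  if (abs(sum(charge) - total_charge) > 1e-9)
    stop(sprintf("molecule_topology: net charge %.3e != declared %d",
                 sum(charge), total_charge))
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  bonds <- bonds %||% empty(c("i", "j", "k", "b0"))
  angles <- angles %||% empty(c("i", "j", "k", "ktheta", "theta0"))
  torsions <- torsions %||% empty(c("i", "j", "k", "l", "amp", "per", "phase"))
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           torsions$i, torsions$j, torsions$k, torsions$l)
  if (length(idx) && (any(idx < 1) || any(idx > n) || any(idx != round(idx))))
    stop("molecule_topology: bonded term references an invalid atom index")
  structure(list(element = as.character(element), mass = as.numeric(mass),
                 eps = as.numeric(eps), r0 = as.numeric(r0),
                 charge = as.numeric(charge), bonds = bonds, angles = angles,
                 torsions = torsions, total_charge = as.integer(total_charge),
                 n_atoms = n),
            class = "molecule_topology")
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), mass %.3f amu, %d bonds, %d angles, %d torsions\n",
              x$n_atoms, paste(unique(x$element), collapse = ","),
              sum(x$mass), nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}

#' Total molecular mass
#' @param topology a [molecule_topology()].
#' @return mass in amu.
#' @export
molecule_mass <- function(topology) sum(topology$mass)

## Bonded-neighbour classification used for intramolecular nonbonded exclusion:
## pairs separated by 1 (bond), 2 (angle) or 3 (torsion) bonds are excluded;
## more distant intramolecular pairs interact at full coupling.
excluded_pairs <- function(topology) {
  n <- topology$n_atoms
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  adj <- vector("list", n)
  for (r in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds$i[r]; j <- topology$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ## graph distance up to 3 via breadth-first search from every atom
  out <- list()
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.finite(nxt) & dist[nxt] == Inf]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    hit <- which(dist >= 1 & dist <= 3)
    hit <- hit[hit > s]
    if (length(hit)) out[[length(out) + 1L]] <- cbind(s, hit)
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

## All intramolecular nonbonded pairs (beyond 3 bonds), i < j
intra_nb_pairs <- function(topology) {
  n <- topology$n_atoms
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  all_pairs <- cbind(all_pairs[, 1], all_pairs[, 2])
  exc <- excluded_pairs(topology)
  if (nrow(exc)) {
    key <- paste(all_pairs[, 1], all_pairs[, 2])
    exck <- paste(pmin(exc[, 1], exc[, 2]), pmax(exc[, 1], exc[, 2]))
    all_pairs <- all_pairs[!(key %in% exck), , drop = FALSE]
  }
  all_pairs
}

## ---- parameter file --------------------------------------------------------

#' Write / read the plain-text force-field parameter file
#'
#' Whitespace-delimited sections `[atoms]`, `[bonds]`, `[angles]`, `[torsions]`
#' with `#` comments and a versioned header line. Atom indices are 1-based.
#'
#' @param topology a [molecule_topology()].
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   [molecule_topology()].
#' @export
write_params <- function(topology, path) {
  ln <- c("# xtalpath parameters v1",
          sprintf("# net_charge %d", topology$total_charge),
          "[atoms]",
          sprintf("%-4s %10.5f %10.6f %10.6f %12.8f",
                  topology$element, topology$mass, topology$eps,
                  topology$r0, topology$charge))
  if (nrow(topology$bonds)) ln <- c(ln, "[bonds]",
    sprintf("%d %d %.6f %.6f", topology$bonds$i, topology$bonds$j,
            topology$bonds$k, topology$bonds$b0))
  if (nrow(topology$angles)) ln <- c(ln, "[angles]",
    sprintf("%d %d %d %.6f %.6f", topology$angles$i, topology$angles$j,
            topology$angles$k, topology$angles$ktheta, topology$angles$theta0))
  if (nrow(topology$torsions)) ln <- c(ln, "[torsions]",
    sprintf("%d %d %d %d %.6f %d %.6f", topology$torsions$i,
            topology$torsions$j, topology$torsions$k, topology$torsions$l,
            topology$torsions$amp, as.integer(topology$torsions$per),
            topology$torsions$phase))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- readLines(path)
  if (!length(raw) || !grepl("^# xtalpath parameters", raw[1]))
    stop(sprintf("%s:1: missing parameter-file header", path))
  net <- 0L
  m <- grep("^# net_charge", raw, value = TRUE)
  if (length(m)) net <- as.integer(sub("^# net_charge\\s+", "", m[1]))
  lines <- raw
  section <- ""
  atoms <- list(); bonds <- list(); angles <- list(); torsions <- list()
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- gsub("[][]", "", ln)
      if (!section %in% c("atoms", "bonds", "angles", "torsions"))
        stop(sprintf("%s:%d: unknown section '%s'", path, k, section))
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    ok <- switch(section,
      atoms = length(f) == 5, bonds = length(f) == 4,
      angles = length(f) == 5, torsions = length(f) == 7, FALSE)
    if (!ok) stop(sprintf("%s:%d: malformed %s record", path, k,
                          if (nzchar(section)) section else "header"))
    val <- switch(section,
      atoms = list(element = f[1], mass = as.numeric(f[2]),
                   eps = as.numeric(f[3]), r0 = as.numeric(f[4]),
                   charge = as.numeric(f[5])),
      bonds = as.numeric(f), angles = as.numeric(f), torsions = as.numeric(f))
    switch(section,
      atoms = { atoms[[length(atoms) + 1L]] <- val },
      bonds = { bonds[[length(bonds) + 1L]] <- val },
      angles = { angles[[length(angles) + 1L]] <- val },
      torsions = { torsions[[length(torsions) + 1L]] <- val })
  }
  if (!length(atoms)) stop(sprintf("%s: no [atoms] section", path))
  df <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    out <- as.data.frame(m)
    names(out) <- cols
    out
  }
  molecule_topology(
    element = vapply(atoms, `[[`, character(1), "element"),
    mass = vapply(atoms, `[[`, numeric(1), "mass"),
    eps = vapply(atoms, `[[`, numeric(1), "eps"),
    r0 = vapply(atoms, `[[`, numeric(1), "r0"),
    charge = vapply(atoms, `[[`, numeric(1), "charge"),
    bonds = df(bonds, c("i", "j", "k", "b0")),
    angles = df(angles, c("i", "j", "k", "ktheta", "theta0")),
    torsions = df(torsions, c("i", "j", "k", "l", "amp", "per", "phase")),
    total_charge = net
  )
}
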