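## Readers and writers: extended XYZ, CIF, snapshot index, similarity TSV and
## the run configuration file. All formats are plain text with a versioned or
## self-describing header; malformed input produces line-numbered diagnostics.

#' Write an extended-XYZ file
#'
#' One or more frames; each frame carries the cell as a
#' `Lattice="ax ay az bx by bz cx cy cz"` header entry (row-major cell
#' vectors) plus free-form `key=value` metadata (lambda, energy, ...).
#'
#' @param states a [crystal_state()] or list of them.
#' @param path output file.
#' @param info optional named list (or list of named lists, one per frame) of
#'   scalar metadata written into the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(states, path, info = NULL) {
  if (inherits(states, "crystal_state")) states <- list(states)
  if (!is.null(info) && !is.null(names(info))) info <- list(info)
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(states)) {
    st <- states[[fi]]
    lat <- t(st$cell$m)  # rows are the cell vectors a, b, c
    meta <- sprintf('Lattice="%s" Properties=species:S:1:pos:R:3 lambda=%.10g',
                    paste(sprintf("%.10g", as.numeric(t(lat))), collapse = " "),
                    st$lambda)
    extra <- if (!is.null(info) && fi <= length(info)) info[[fi]] else NULL
    if (length(extra))
      meta <- paste(meta, paste(sprintf("%s=%.10g", names(extra),
                                        as.numeric(extra)), collapse = " "))
    el <- rep(st$topology$element, st$n_molecules)
    writeLines(as.character(nrow(st$coords)), con)
    writeLines(meta, con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", el,
                       st$coords[, 1], st$coords[, 2], st$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ file
#'
#' @param path input file.
#' @return list of frames; each frame has `element`, `coords`, `cell` (a
#'   [unit_cell()] or NULL when no Lattice entry is present) and `info` (named
#'   numeric vector of the remaining metadata). An empty file signals an
#'   explicit empty result (`list()`).
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list()
  k <- 1L
  while (k <= length(ln)) {
    if (!nzchar(trimws(ln[k]))) { k <- k + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(ln[k])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("%s:%d: expected an atom count, got '%s'", path, k, ln[k]))
    if (k + 1L + nat > length(ln))
      stop(sprintf("%s:%d: truncated frame (%d atoms declared)", path, k, nat))
    comment <- ln[k + 1L]
    cell <- NULL
    lat_m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat_m)) {
      v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat_m), "\\s+")[[1]])
      if (length(v) != 9)
        stop(sprintf("%s:%d: Lattice entry must have 9 numbers", path, k + 1L))
      m <- t(matrix(v, 3, 3, byrow = TRUE))  # columns = cell vectors
      cell <- cell_from_matrix(m)
    }
    rest <- gsub('Lattice="[^"]*"', "", comment)
    kv <- regmatches(rest, gregexpr("[A-Za-z_][A-Za-z0-9_]*=[-+0-9.eE]+", rest))[[1]]
    info <- numeric(0)
    if (length(kv)) {
      parts <- strsplit(kv, "=")
      info <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
      names(info) <- vapply(parts, `[[`, character(1), 1)
    }
    rows <- ln[(k + 2L):(k + 1L + nat)]
    f <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(f, length, integer(1)) < 4)
    if (length(bad))
      stop(sprintf("%s:%d: malformed atom record", path, k + 1L + bad[1]))
    frames[[length(frames) + 1L]] <- list(
      element = vapply(f, `[[`, character(1), 1),
      coords = do.call(rbind, lapply(f, function(x) as.numeric(x[2:4]))),
      cell = cell, info = info)
    k <- k + 2L + nat
  }
  frames
}

## rebuild a unit_cell from a frac->cart matrix (columns = cell vectors)
cell_from_matrix <- function(m) {
  a <- sqrt(sum(m[, 1]^2)); b <- sqrt(sum(m[, 2]^2)); c <- sqrt(sum(m[, 3]^2))
  ang <- function(u, v) rad2deg(acos(sum(u * v) / (sqrt(sum(u^2) * sum(v^2)))))
  unit_cell(a, b, c, ang(m[, 2], m[, 3]), ang(m[, 1], m[, 3]),
            ang(m[, 1], m[, 2]))
}

## ---- CIF --------------------------------------------------------------------

#' Write a crystal state as CIF
#'
#' Cell, symmetry operators and fractional atom sites. Fractional coordinates
#' are wrapped to [0, 1) at this boundary only (never during dynamics).
#'
#' @param state a [crystal_state()].
#' @param path output file.
#' @param data_name CIF data block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(state, path, data_name = "xtalpath") {
  el <- rep(state$topology$element, state$n_molecules)
  frac <- cart_to_frac(state$cell, state$coords) %% 1
  ln <- c(
    sprintf("data_%s", data_name),
    "# written by xtalpath v1",
    sprintf("_cell_length_a    %.8f", state$cell$a),
    sprintf("_cell_length_b    %.8f", state$cell$b),
    sprintf("_cell_length_c    %.8f", state$cell$c),
    sprintf("_cell_angle_alpha %.8f", state$cell$alpha),
    sprintf("_cell_angle_beta  %.8f", state$cell$beta),
    sprintf("_cell_angle_gamma %.8f", state$cell$gamma),
    sprintf("_symmetry_space_group_name_H-M '%s'", state$sg$symbol),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    sprintf("  '%s'", state$sg$triplets),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s%d %s %.8f %.8f %.8f", el, seq_along(el), el,
            frac[, 1], frac[, 2], frac[, 3])
  )
  writeLines(ln, path)
  invisible(path)
}

#' Read a CIF file
#'
#' Parses the cell, the space-group symbol and/or explicit symmetry operator
#' triplets, and fractional atom sites (P1 and symmetry-bearing dialects).
#'
#' @param path input file.
#' @return list `cell`, `sg_symbol`, `symops` (character triplets or NULL),
#'   `element`, `frac` (n x 3 fractional coordinates).
#' @export
read_cif <- function(path) {
  ln <- readLines(path)
  val <- function(tag) {
    i <- grep(paste0("^\\s*", tag, "\\b"), ln)
    if (!length(i)) return(NULL)
    as.numeric(strsplit(trimws(ln[i[1]]), "\\s+")[[1]][2])
  }
  cellp <- c(val("_cell_length_a"), val("_cell_length_b"), val("_cell_length_c"),
             val("_cell_angle_alpha"), val("_cell_angle_beta"),
             val("_cell_angle_gamma"))
  if (length(cellp) != 6 || any(is.na(cellp)))
    stop(sprintf("%s: missing or malformed _cell_* items", path))
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  sg_symbol <- NULL
  i <- grep("_symmetry_space_group_name_H-M|_space_group_name_H-M_alt", ln)
  if (length(i)) {
    raw <- sub("^[^'\"]*['\"]?([^'\"]*)['\"]?\\s*$", "\\1",
               sub("^\\s*_\\S+\\s+", "", ln[i[1]]))
    sg_symbol <- gsub(" ", "", raw)
  }
  ## explicit operator loop
  symops <- NULL
  iop <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz", ln)
  if (length(iop)) {
    k <- iop[1] + 1L
    ops <- character(0)
    while (k <= length(ln)) {
      s <- trimws(ln[k])
      if (!nzchar(s) || startsWith(s, "loop_") || startsWith(s, "_") ||
          startsWith(s, "data_")) break
      s <- gsub("^\\s*\\d+\\s+", "", s)        # optional leading id
      s <- gsub("['\"]", "", s)
      ops <- c(ops, gsub(" ", "", s))
      k <- k + 1L
    }
    if (length(ops)) symops <- ops
  }
  ## atom site loop: find the loop_ block declaring _atom_site_fract_x
  ifr <- grep("^\\s*_atom_site_fract_x", ln)
  if (!length(ifr)) stop(sprintf("%s: no _atom_site_fract_x loop", path))
  ## collect the header tags of this loop
  start <- ifr[1]
  h0 <- start
  while (h0 > 1 && grepl("^\\s*_atom_site", ln[h0 - 1L])) h0 <- h0 - 1L
  hend <- start
  while (hend < length(ln) && grepl("^\\s*_atom_site", ln[hend + 1L]))
    hend <- hend + 1L
  tags <- trimws(ln[h0:hend])
  rows <- list()
  k <- hend + 1L
  while (k <= length(ln)) {
    s <- trimws(ln[k])
    if (!nzchar(s) || startsWith(s, "loop_") || startsWith(s, "_") ||
        startsWith(s, "data_") || startsWith(s, "#")) break
    f <- strsplit(s, "\\s+")[[1]]
    if (length(f) != length(tags))
      stop(sprintf("%s:%d: atom site row has %d fields, header declares %d",
                   path, k, length(f), length(tags)))
    rows[[length(rows) + 1L]] <- f
    k <- k + 1L
  }
  if (!length(rows)) stop(sprintf("%s: empty atom site loop", path))
  m <- do.call(rbind, rows)
  col <- function(tag) match(tag, tags)
  elc <- col("_atom_site_type_symbol")
  if (is.na(elc)) elc <- col("_atom_site_label")
  list(cell = cell, sg_symbol = sg_symbol, symops = symops,
       element = gsub("[0-9]+$", "", m[, elc]),
       frac = matrix(as.numeric(m[, c(col("_atom_site_fract_x"),
                                      col("_atom_site_fract_y"),
                                      col("_atom_site_fract_z"))]),
                     ncol = 3))
}

#' Build a crystal state from parsed CIF content
#'
#' Atom sites must be whole molecules in the topology's atom order
#' (molecule-major for multi-molecule cells).
#'
#' @param cif result of [read_cif()].
#' @param topology a [molecule_topology()].
#' @param lambda coupling value for the new state.
#' @return a [crystal_state()].
#' @export
cif_to_state <- function(cif, topology, lambda = 1) {
  n <- nrow(cif$frac)
  if (n %% topology$n_atoms != 0)
    stop("cif_to_state: site count is not a multiple of the molecule size")
  nmol <- n %/% topology$n_atoms
  sg <- if (!is.null(cif$symops)) {
    sym <- cif$sg_symbol %||% "custom"
    if (!is.null(cif$sg_symbol) && cif$sg_symbol %in% space_group_names())
      space_group(cif$sg_symbol)
    else space_group(sym, ops = cif$symops)
  } else if (!is.null(cif$sg_symbol)) space_group(cif$sg_symbol)
  else space_group("P1")
  crystal_state(topology, frac_to_cart(cif$cell, cif$frac), cif$cell, sg,
                lambda = lambda, n_molecules = nmol)
}

## ---- tabular records --------------------------------------------------------

#' Write / read the snapshot index
#'
#' Tab-separated table of snapshot records: structure file, minimized energy,
#' density, lambda and MD step.
#'
#' @param index data.frame with columns `file, energy, density, lambda, step`.
#' @param path file path.
#' @return `read_snapshot_index` returns the data.frame.
#' @export
write_snapshot_index <- function(index, path) {
  stopifnot(all(c("file", "energy", "density", "lambda", "step") %in%
                  names(index)))
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot_index
#' @export
read_snapshot_index <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a similarity matrix as TSV with header labels
#'
#' @param m a [similarity_matrix()] (or plain symmetric matrix with dimnames).
#' @param path file path.
#' @return `read_similarity_tsv` returns the matrix.
#' @export
write_similarity_tsv <- function(m, path) {
  utils::write.table(as.matrix(unclass(m)), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  class(m) <- c("similarity_matrix", class(m))
  m
}

## ---- run configuration ------------------------------------------------------

CONFIG_SCHEMA <- list(
  thermo = c("temperature", "pressure"),
  barostat = c("rho_min", "rho_max", "v_max", "a_max", "interval"),
  ost = c("h0", "dl", "df", "w1", "w2", "trunc", "v_th", "dT", "stride",
          "fm_stride"),
  dynamics = c("dt", "friction", "lambda_mass", "seed", "n_steps",
               "snapshot_stride"),
  alchemy = c("alpha", "n", "cutoff", "taper_width", "kappa", "use_elec"),
  search = c("space_groups", "csd_cutoff", "walkers", "lambda_min",
             "energy_window", "rho_cut", "cluster_cutoff", "restarts")
)

#' Read a run configuration file
#'
#' Sectioned `key = value` text (`[thermo]`, `[barostat]`, `[ost]`,
#' `[dynamics]`, `[alchemy]`, `[search]`), `#` comments. Unknown sections or
#' keys are rejected with a line-numbered diagnostic. Every omitted key takes
#' the package default, which equals the production value wherever one is
#' defined.
#'
#' @param path file path.
#' @return object of class `run_config`: the parameter objects `conditions`,
#'   `barostat`, `ost`, `dynamics`, `alchemy` plus the `search` list.
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  sect <- ""
  vals <- list()
  for (k in seq_along(ln)) {
    s <- trimws(sub("#.*$", "", ln[k]))
    if (!nzchar(s)) next
    if (grepl("^\\[", s)) {
      sect <- gsub("[][]", "", s)
      if (!sect %in% names(CONFIG_SCHEMA))
        stop(sprintf("%s:%d: unknown section '[%s]'", path, k, sect))
      next
    }
    if (!grepl("=", s))
      stop(sprintf("%s:%d: expected 'key = value'", path, k))
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); v <- trimws(paste(kv[-1], collapse = "="))
    if (!nzchar(sect))
      stop(sprintf("%s:%d: key '%s' outside any section", path, k, key))
    if (!key %in% CONFIG_SCHEMA[[sect]])
      stop(sprintf("%s:%d: unknown key '%s' in section '[%s]'",
                   path, k, key, sect))
    num <- suppressWarnings(as.numeric(v))
    vals[[sect]][[key]] <- if (!is.na(num)) num
      else if (v %in% c("true", "false")) v == "true"
      else v
  }
  build <- function(ctor, sect) do.call(ctor, vals[[sect]] %||% list())
  structure(list(
    conditions = build(thermo_conditions, "thermo"),
    barostat = build(barostat_params, "barostat"),
    ost = build(ost_params, "ost"),
    dynamics = build(dynamics_params, "dynamics"),
    alchemy = build(alchemical_params, "alchemy"),
    search = utils::modifyList(
      list(space_groups = paste(space_group_names(), collapse = ","),
           csd_cutoff = 0.5, walkers = 12, lambda_min = 0.8,
           energy_window = 10, rho_cut = 1.25, cluster_cutoff = 0.5,
           restarts = 1000),
      vals[["search"]] %||% list())
  ), class = "run_config")
}

#' Write a run configuration file with every effective value
#'
#' @param config a `run_config` (from [read_run_config()] or assembled from
#'   the parameter constructors).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 12)
  }
  sec <- function(name, obj, keys) {
    c(sprintf("[%s]", name),
      vapply(keys, function(k) sprintf("%s = %s", k, fmt(obj[[k]])),
             character(1)),
      "")
  }
  ln <- c("# xtalpath run configuration v1",
          sec("thermo", config$conditions, CONFIG_SCHEMA$thermo),
          sec("barostat", config$barostat, CONFIG_SCHEMA$barostat),
          sec("ost", config$ost, CONFIG_SCHEMA$ost),
          sec("dynamics", config$dynamics, CONFIG_SCHEMA$dynamics),
          sec("alchemy", config$alchemy, CONFIG_SCHEMA$alchemy),
          sec("search", config$search, names(config$search)))
  writeLines(ln, path)
  invisible(path)
}

#' Default run configuration
#' @return a `run_config` with every parameter at its default.
#' @export
default_run_config <- function() {
  structure(list(conditions = thermo_conditions(), barostat = barostat_params(),
                 ost = ost_params(), dynamics = dynamics_params(),
                 alchemy = alchemical_params(),
                 search = list(space_groups = paste(space_group_names(),
                                                    collapse = ","),
                               csd_cutoff = 0.5, walkers = 12,
                               lambda_min = 0.8, energy_window = 10,
                               rho_cut = 1.25, cluster_cutoff = 0.5,
                               restarts = 1000)),
            class = "run_config")
}

#' Prepare per-space-group search directories
#'
#' Creates one subdirectory per shipped space group whose CSD frequency
#' exceeds the probability cutoff, each containing the molecule coordinates,
#' the parameter file and a run configuration. Deterministic: regenerating
#' with the same inputs yields identical trees.
#'
#' @param topology a [molecule_topology()].
#' @param coords reference molecular geometry (n x 3).
#' @param outdir output directory (created).
#' @param cutoff CSD probability cutoff in percent (default 0.5).
#' @param config a `run_config` (defaults written into each directory).
#' @return character vector of created directories, invisibly.
#' @export
prepare_space_groups <- function(topology, coords, outdir, cutoff = 0.5,
                                 config = default_run_config()) {
  tab <- space_group_table()
  keep <- tab$symbol[tab$csd_freq > cutoff]
  dirs <- character(0)
  for (symbol in keep) {
    d <- file.path(outdir, gsub("[^A-Za-z0-9-]", "_", symbol))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    st <- crystal_state(topology, coords,
                        unit_cell(50, 50, 50, 90, 90, 90), "P1", lambda = 0)
    write_xyz(st, file.path(d, "molecule.xyz"))
    write_params(topology, file.path(d, "molecule.prm"))
    cfg <- config
    cfg$search$space_groups <- symbol
    write_run_config(cfg, file.path(d, "config.ini"))
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}
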