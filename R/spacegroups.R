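## Space-group symmetry for the 15 most populated Z' = 1 search groups.
##
## Operators are stored explicitly as Jones-faithful triplet strings (general
## positions including centering translations) from a vetted table; they are
## parsed into integer rotation matrices and fractional translations at load
## time. There is no runtime dependency on an external symmetry library.

SG_TABLE <- list(
  ## symbol, lattice system used by the barostat, approximate CSD frequency (%)
  ## of organic Z'=1 structures (used only for ordering / probability cutoff),
  ## and the general-position operator triplets.
  "P1" = list(system = "triclinic", csd = 1.0, ops = c("x,y,z")),
  "P-1" = list(system = "triclinic", csd = 24.8, ops = c(
    "x,y,z", "-x,-y,-z")),
  "P21" = list(system = "monoclinic", csd = 5.2, ops = c(
    "x,y,z", "-x,y+1/2,-z")),
  "C2" = list(system = "monoclinic", csd = 0.9, ops = c(
    "x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z")),
  "Cc" = list(system = "monoclinic", csd = 1.1, ops = c(
    "x,y,z", "x,-y,z+1/2", "x+1/2,y+1/2,z", "x+1/2,-y+1/2,z+1/2")),
  "P2/c" = list(system = "monoclinic", csd = 0.8, ops = c(
    "x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2")),
  "P21/c" = list(system = "monoclinic", csd = 34.9, ops = c(
    "x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2")),
  "C2/c" = list(system = "monoclinic", csd = 8.3, ops = c(
    "x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
    "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2", "-x+1/2,-y+1/2,-z",
    "x+1/2,-y+1/2,z+1/2")),
  "P212121" = list(system = "orthorhombic", csd = 7.2, ops = c(
    "x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2")),
  "Pca21" = list(system = "orthorhombic", csd = 0.7, ops = c(
    "x,y,z", "-x,-y,z+1/2", "-x+1/2,y,z+1/2", "x+1/2,-y,z")),
  "Pna21" = list(system = "orthorhombic", csd = 1.3, ops = c(
    "x,y,z", "-x,-y,z+1/2", "-x+1/2,y+1/2,z+1/2", "x+1/2,-y+1/2,z")),
  "Pbcn" = list(system = "orthorhombic", csd = 0.9, ops = c(
    "x,y,z", "-x+1/2,-y+1/2,z+1/2", "x+1/2,-y+1/2,-z", "-x,y,-z+1/2",
    "-x,-y,-z", "x+1/2,y+1/2,-z+1/2", "-x+1/2,y+1/2,z", "x,-y,z+1/2")),
  "Pbca" = list(system = "orthorhombic", csd = 3.3, ops = c(
    "x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
    "-x,-y,-z", "x+1/2,y,-z+1/2", "-x+1/2,y+1/2,z", "x,-y+1/2,z+1/2")),
  "Pnma" = list(system = "orthorhombic", csd = 1.2, ops = c(
    "x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z+1/2", "-x,y+1/2,-z",
    "-x,-y,-z", "x+1/2,y,-z+1/2", "-x+1/2,y+1/2,z+1/2", "x,-y+1/2,z")),
  ## R-3 in the hexagonal setting (obverse); hexagonal lattice constraints.
  "R-3" = list(system = "hexagonal", csd = 0.8, ops = c(
    "x,y,z", "-y,x-y,z", "-x+y,-x,z", "-x,-y,-z", "y,-x+y,-z", "x-y,x,-z",
    "x+2/3,y+1/3,z+1/3", "-y+2/3,x-y+1/3,z+1/3", "-x+y+2/3,-x+1/3,z+1/3",
    "-x+2/3,-y+1/3,-z+1/3", "y+2/3,-x+y+1/3,-z+1/3", "x-y+2/3,x+1/3,-z+1/3",
    "x+1/3,y+2/3,z+2/3", "-y+1/3,x-y+2/3,z+2/3", "-x+y+1/3,-x+2/3,z+2/3",
    "-x+1/3,-y+2/3,-z+2/3", "y+1/3,-x+y+2/3,-z+2/3", "x-y+1/3,x+2/3,-z+2/3"))
)

#' Names of the shipped space groups
#'
#' The 15 space groups most frequently adopted by organic molecular crystals,
#' in Hermann-Mauguin notation (short symbols; "R-3" in the hexagonal setting).
#'
#' @return character vector of 15 symbols.
#' @export
space_group_names <- function() names(SG_TABLE)

#' Parse a Jones-faithful symmetry triplet
#'
#' Converts e.g. `"-x,y+1/2,-z+1/2"` into an integer 3x3 rotation part (acting
#' on fractional coordinates) and a fractional translation 3-vector.
#'
#' @param triplet character scalar.
#' @return list with `rot` (3x3 integer matrix) and `trans` (numeric 3).
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", triplet), ",")[[1]]
  if (length(parts) != 3L) stop("parse_symop: expected three components")
  rot <- matrix(0L, 3, 3)
  trans <- numeric(3)
  axes <- c(x = 1L, y = 2L, z = 3L)
  for (i in 1:3) {
    expr <- parts[i]
    ## tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tk in toks) {
      sign <- if (startsWith(tk, "-")) -1L else 1L
      body <- sub("^[+-]", "", tk)
      if (body %in% names(axes)) {
        rot[i, axes[[body]]] <- rot[i, axes[[body]]] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        trans[i] <- trans[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else stop(sprintf("parse_symop: cannot parse term '%s'", tk))
    }
  }
  list(rot = rot, trans = trans)
}

symop_to_triplet <- function(op) {
  ax <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$rot[i, j]
      if (r != 0) {
        pre <- if (r > 0) (if (nzchar(s)) "+" else "") else "-"
        mult <- if (abs(r) == 1) "" else as.character(abs(r))
        s <- paste0(s, pre, mult, ax[j])
      }
    }
    tr <- op$trans[i] %% 1
    if (abs(tr) > 1e-9) {
      fr <- c("1/2" = 0.5, "1/3" = 1/3, "2/3" = 2/3, "1/4" = 0.25,
              "3/4" = 0.75, "1/6" = 1/6, "5/6" = 5/6)
      k <- which(abs(fr - tr) < 1e-9)
      lab <- if (length(k)) names(fr)[k[1]] else sprintf("%.6f", tr)
      s <- paste0(s, "+", lab)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

#' Space group with explicit symmetry operators
#'
#' @param symbol Hermann-Mauguin symbol, one of [space_group_names()], or a
#'   custom symbol when `ops` is supplied.
#' @param ops optional character vector of operator triplets (for custom
#'   groups, e.g. a P1 cell produced by expansion).
#' @param system lattice system; inferred from the table when omitted.
#' @return object of class `space_group`: `symbol`, `system`, `csd_freq`,
#'   `ops` (list of parsed operators), `n_ops` (general-position multiplicity).
#' @examples
#' sg <- space_group("P21/c")
#' sg$n_ops  # 4
#' @export
space_group <- function(symbol, ops = NULL, system = NULL) {
  if (is.null(ops)) {
    entry <- SG_TABLE[[symbol]]
    if (is.null(entry))
      stop(sprintf("space_group: unknown symbol '%s' (shipped: %s)",
                   symbol, paste(names(SG_TABLE), collapse = ", ")))
    ops <- entry$ops
    system <- system %||% entry$system
    csd <- entry$csd
  } else {
    system <- system %||% "triclinic"
    csd <- NA_real_
  }
  parsed <- lapply(ops, parse_symop)
  dets <- vapply(parsed, function(o) det(o$rot), numeric(1))
  if (any(abs(abs(dets) - 1) > 1e-12))
    stop("space_group: operator rotation determinant must be +/-1")
  structure(list(symbol = symbol, system = system, csd_freq = csd,
                 triplets = ops, ops = parsed, n_ops = length(parsed)),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%s, %d general positions)\n",
              x$symbol, x$system, x$n_ops))
  invisible(x)
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op parsed operator (list with `rot`, `trans`).
#' @param frac numeric 3-vector or n x 3 matrix of fractional coordinates.
#' @return transformed fractional coordinates (not wrapped).
#' @export
apply_symop <- function(op, frac) {
  if (is.matrix(frac)) t(op$rot %*% t(frac) + op$trans)
  else as.numeric(op$rot %*% frac + op$trans)
}

## compose two operators: (R1,t1) o (R2,t2) = (R1 R2, R1 t2 + t1)
compose_symops <- function(op1, op2) {
  list(rot = op1$rot %*% op2$rot,
       trans = as.numeric(op1$rot %*% op2$trans + op1$trans))
}

## TRUE if two operators are equal modulo lattice translations
symops_equal_mod_lattice <- function(a, b, tol = 1e-9) {
  all(a$rot == b$rot) && all(abs((a$trans - b$trans) %% 1) < tol |
                             abs(((a$trans - b$trans) %% 1) - 1) < tol)
}

#' Verify group closure of a space group's operator list
#'
#' Composes every pair of operators and checks that the result equals a listed
#' operator modulo lattice translations.
#'
#' @param sg a [space_group()].
#' @return TRUE (invisibly) or an error.
#' @export
check_group_closure <- function(sg) {
  for (a in sg$ops) for (b in sg$ops) {
    comp <- compose_symops(a, b)
    ok <- any(vapply(sg$ops, symops_equal_mod_lattice, logical(1), b = comp))
    if (!ok) stop(sprintf("group %s not closed under composition", sg$symbol))
  }
  invisible(TRUE)
}

#' Table of shipped space groups
#'
#' @return data.frame with symbol, lattice system, multiplicity and the CSD
#'   frequency weight used by [prepare_space_groups()].
#' @export
space_group_table <- function() {
  data.frame(
    symbol = names(SG_TABLE),
    system = vapply(SG_TABLE, `[[`, character(1), "system"),
    multiplicity = vapply(SG_TABLE, function(e) length(e$ops), integer(1)),
    csd_freq = vapply(SG_TABLE, `[[`, numeric(1), "csd"),
    row.names = NULL
  )
}
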