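#' Orthogonal space tempering parameters
#'
#' Tunables of the 2D metadynamics bias over `(lambda, F_lambda)` with
#' transition tempering. Defaults are the production values: lambda bins of
#' width 0.005, F_lambda bins of 2 kcal/mol, initial hill height 0.05
#' kcal/mol, Gaussian widths of two bins per axis (w1 = 0.01, w2 = 4 kcal/mol),
#' truncation after five bins, tempering threshold V_th = 1 kcal/mol and
#' tempering rate dT = 2 k_B T.
#'
#' @param h0 initial Gaussian hill height (kcal/mol).
#' @param dl lambda bin width.
#' @param df F_lambda bin width (kcal/mol).
#' @param w1,w2 Gaussian standard deviations along lambda and F_lambda.
#' @param trunc truncation radius in bins.
#' @param v_th tempering threshold (kcal/mol).
#' @param dT tempering rate in multiples of k_B T.
#' @param stride hill deposition stride in MD steps.
#' @param fm_stride number of hill depositions between rebuilds of the 1D bias.
#' @return object of class `ost_params`.
#' @export
ost_params <- function(h0 = 0.05, dl = 0.005, df = 2.0, w1 = 0.01, w2 = 4.0,
                       trunc = 5L, v_th = 1.0, dT = 2.0, stride = 10L,
                       fm_stride = 20L) {
  vals <- c(h0, dl, df, w1, w2, trunc, v_th, dT, stride, fm_stride)
  if (any(!is.finite(vals)) || any(c(h0, dl, df, w1, w2, trunc, dT, stride) <= 0)
      || v_th < 0)
    stop("ost_params: all parameters must be positive (v_th >= 0)")
  structure(list(h0 = h0, dl = dl, df = df, w1 = w1, w2 = w2,
                 trunc = as.integer(trunc), v_th = v_th, dT = dT,
                 stride = as.integer(stride), fm_stride = as.integer(fm_stride)),
            class = "ost_params")
}

#' Create an empty OST bias grid
#'
#' A mutable accumulator (environment) for the 2D histogram of deposited hill
#' heights over `(lambda, F_lambda)`, per-bin visit counts and sums of
#' F_lambda, and a cache of the smooth bias evaluated at bin centers. The
#' lambda axis covers `[0, 1]` exactly; the F_lambda axis starts at
#' `[-f_init, +f_init]` and doubles outward on demand, preserving previously
#' deposited bias.
#'
#' @param params an [ost_params()].
#' @param f_init initial half-range of the F_lambda axis (kcal/mol).
#' @return object of classes `ost_grid` (an environment).
#' @export
ost_grid <- function(params = ost_params(), f_init = 100) {
  g <- new.env(parent = emptyenv())
  g$params <- params
  g$nl <- as.integer(round(1 / params$dl))
  if (abs(g$nl * params$dl - 1) > 1e-9)
    stop("ost_grid: 1/dl must be an integer so the grid covers [0,1] exactly")
  g$fmin <- -abs(f_init)
  g$nf <- as.integer(ceiling(2 * abs(f_init) / params$df))
  g$H <- matrix(0, g$nl, g$nf)       # accumulated hill heights (snapped)
  g$counts <- matrix(0, g$nl, g$nf)  # visits
  g$fsum <- matrix(0, g$nl, g$nf)    # sum of sampled F_lambda per bin
  g$gc <- matrix(0, g$nl, g$nf)      # smooth 2D bias at bin centers
  g$n_hills <- 0L
  g$heights <- numeric(0)            # deposited heights, in order
  g$fm <- NULL                       # cached 1D bias per lambda bin
  g$fm_dirty <- TRUE
  class(g) <- c("ost_grid", "environment")
  g
}

#' @export
print.ost_grid <- function(x, ...) {
  cat(sprintf("OST bias grid: %d lambda bins x %d F bins (F in [%.0f, %.0f]), %d hills, coverage V=%.4f\n",
              x$nl, x$nf, x$fmin, x$fmin + x$nf * x$params$df, x$n_hills,
              coverage_statistic(x)))
  invisible(x)
}

lambda_bin <- function(grid, lambda) {
  max(1L, min(grid$nl, as.integer(floor(lambda / grid$params$dl)) + 1L))
}

f_bin_raw <- function(grid, f) as.integer(floor((f - grid$fmin) / grid$params$df)) + 1L

lambda_centers <- function(grid) (seq_len(grid$nl) - 0.5) * grid$params$dl

f_centers <- function(grid) grid$fmin + (seq_len(grid$nf) - 0.5) * grid$params$df

## grow the F axis (doubling outward) until `f` is inside
ensure_f_range <- function(grid, f) {
  while (f_bin_raw(grid, f) < 1L || f_bin_raw(grid, f) > grid$nf) {
    half <- grid$nf %/% 2L
    pad <- matrix(0, grid$nl, half)
    grid$H <- cbind(pad, grid$H, pad)
    grid$counts <- cbind(pad, grid$counts, pad)
    grid$fsum <- cbind(pad, grid$fsum, pad)
    grid$fmin <- grid$fmin - half * grid$params$df
    grid$nf <- grid$nf + 2L * half
    ## recompute the smooth cache so spill into the new margin is included
    grid$gc <- convolve_hills(grid)
    grid$fm_dirty <- TRUE
  }
  invisible(grid)
}

## truncated Gaussian kernel on the bin lattice (odd square, trunc bins radius)
ost_kernel <- function(params) {
  k <- params$trunc
  dL <- (-k:k) * params$dl
  dF <- (-k:k) * params$df
  outer(exp(-dL^2 / (2 * params$w1^2)), exp(-dF^2 / (2 * params$w2^2)))
}

## smooth bias at every bin center, by shift-and-add convolution of H
convolve_hills <- function(grid) {
  p <- grid$params
  ker <- ost_kernel(p)
  k <- p$trunc
  out <- matrix(0, grid$nl, grid$nf)
  nz <- which(grid$H != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(out)
  for (a in -k:k) for (b in -k:k) {
    w <- ker[a + k + 1L, b + k + 1L]
    ii <- nz[, 1] + a; jj <- nz[, 2] + b
    ok <- ii >= 1L & ii <= grid$nl & jj >= 1L & jj <= grid$nf
    if (!any(ok)) next
    idx <- cbind(ii[ok], jj[ok])
    out[idx] <- out[idx] + w * grid$H[nz[ok, , drop = FALSE]]
  }
  out
}

#' Deposit one repulsive Gaussian hill
#'
#' The hill is accumulated at the center of the bin containing
#' `(lambda, F_lambda)` (grid-snapped deposition); evaluation spreads it as a
#' truncated 2D Gaussian.
#'
#' @param grid an [ost_grid()] (modified in place and returned invisibly).
#' @param lambda current coupling value in `[0, 1]`.
#' @param f_lambda current dU/dlambda (kcal/mol); must be finite.
#' @param height hill height (kcal/mol); typically [tempering_height()].
#' @return the grid, invisibly.
#' @export
deposit_hill <- function(grid, lambda, f_lambda, height) {
  if (!is.finite(f_lambda)) stop("deposit_hill: non-finite F_lambda")
  if (lambda < 0 || lambda > 1) stop("deposit_hill: lambda outside [0, 1]")
  ensure_f_range(grid, f_lambda)
  il <- lambda_bin(grid, lambda)
  jf <- f_bin_raw(grid, f_lambda)
  grid$H[il, jf] <- grid$H[il, jf] + height
  ## incremental update of the smooth cache over the truncated patch
  p <- grid$params
  k <- p$trunc
  ker <- ost_kernel(p)
  ii <- (il - k):(il + k); jj <- (jf - k):(jf + k)
  oki <- ii >= 1L & ii <= grid$nl
  okj <- jj >= 1L & jj <= grid$nf
  grid$gc[ii[oki], jj[okj]] <- grid$gc[ii[oki], jj[okj]] +
    height * ker[oki, okj, drop = FALSE]
  grid$n_hills <- grid$n_hills + 1L
  grid$heights <- c(grid$heights, height)
  grid$fm_dirty <- TRUE
  invisible(grid)
}

#' Record a visit for the thermodynamic-integration estimator
#'
#' Increments the visit count of the bin containing `(lambda, f_lambda)` and
#' accumulates the sampled F_lambda; called every MD step.
#'
#' @inheritParams deposit_hill
#' @return the grid, invisibly.
#' @export
record_visit <- function(grid, lambda, f_lambda) {
  if (!is.finite(f_lambda)) return(invisible(grid))
  ensure_f_range(grid, f_lambda)
  il <- lambda_bin(grid, lambda)
  jf <- f_bin_raw(grid, f_lambda)
  grid$counts[il, jf] <- grid$counts[il, jf] + 1
  grid$fsum[il, jf] <- grid$fsum[il, jf] + f_lambda
  grid$fm_dirty <- TRUE
  invisible(grid)
}

#' Evaluate the 2D bias and its partial derivatives
#'
#' Analytic sum of the truncated Gaussians of all hills within the truncation
#' radius of the evaluation point (smooth in both arguments, not a bin
#' lookup).
#'
#' @param grid an [ost_grid()].
#' @param lambda evaluation coupling value.
#' @param f_lambda evaluation dU/dlambda (kcal/mol).
#' @return list `energy`, `ddl` (d/dlambda), `ddf` (d/dF_lambda).
#' @export
bias_energy_and_gradient <- function(grid, lambda, f_lambda) {
  p <- grid$params
  k <- p$trunc
  il <- as.integer(floor(lambda / p$dl)) + 1L
  jf <- f_bin_raw(grid, f_lambda)
  ii <- max(1L, il - k):min(grid$nl, il + k)
  jj <- max(1L, jf - k):min(grid$nf, jf + k)
  if (jf + k < 1L || jf - k > grid$nf || !length(ii) || !length(jj))
    return(list(energy = 0, ddl = 0, ddf = 0))
  Hsub <- grid$H[ii, jj, drop = FALSE]
  if (all(Hsub == 0)) return(list(energy = 0, ddl = 0, ddf = 0))
  lc <- (ii - 0.5) * p$dl
  fc <- grid$fmin + (jj - 0.5) * p$df
  dL <- lambda - lc
  dF <- f_lambda - fc
  gl <- exp(-dL^2 / (2 * p$w1^2))
  gf <- exp(-dF^2 / (2 * p$w2^2))
  G <- outer(gl, gf)
  e <- sum(Hsub * G)
  ddl <- sum(Hsub * outer(-dL / p$w1^2 * gl, gf))
  ddf <- sum(Hsub * outer(gl, -dF / p$w2^2 * gf))
  list(energy = e, ddl = ddl, ddf = ddf)
}

#' Coverage statistic of the bias grid
#'
#' For each lambda bin take the maximum deposited bias over the F_lambda bins,
#' then the minimum of those maxima over lambda: the whole path must be at
#' least lightly covered before tempering starts.
#'
#' @param grid an [ost_grid()].
#' @return V(t) in kcal/mol.
#' @export
coverage_statistic <- function(grid) {
  min(apply(grid$H, 1, max))
}

#' Transition-tempered hill height
#'
#' Constant at `h0` until the coverage statistic exceeds the threshold, then
#' decays exponentially: `h = h0 * exp(-(V - V_th) / (dT * kB * T))`.
#'
#' @param params an [ost_params()].
#' @param v_t coverage statistic (kcal/mol, >= 0).
#' @param temperature simulation temperature (K).
#' @return hill height in kcal/mol; nonincreasing in `v_t`.
#' @export
tempering_height <- function(params, v_t, temperature = 298.15) {
  if (v_t <= params$v_th) return(params$h0)
  params$h0 * exp(-(v_t - params$v_th) / (params$dT * KB * temperature))
}

#' Free-energy profile along lambda by bias-reweighted thermodynamic
#' integration
#'
#' Per lambda bin, the bias-reweighted average of the sampled F_lambda
#' (weights proportional to visit count times `exp(beta * g_m)`) is integrated
#' from 0 by the midpoint rule: `G(lambda) = int_0^lambda <F> dlambda'`,
#' `G(0) = 0`. Lambda bins never visited inherit the average of their nearest
#' visited neighbours and are flagged in the `filled` attribute.
#'
#' @param grid an [ost_grid()].
#' @param beta inverse temperature 1/(kB T) in mol/kcal.
#' @return numeric vector of length `nl` (profile at bin centers), with
#'   attributes `fbar` (the per-bin averages) and `filled` (logical).
#' @export
ost_lambda_profile <- function(grid, beta) {
  w <- grid$counts * exp(pmin(beta * grid$gc, 500))
  num <- rowSums(grid$fsum * exp(pmin(beta * grid$gc, 500)))
  den <- rowSums(w)
  visited <- den > 0
  fbar <- ifelse(visited, num / pmax(den, .Machine$double.xmin), NA_real_)
  filled <- !visited
  if (any(filled)) {
    if (!any(visited)) {
      fbar[] <- 0
    } else {
      vis_idx <- which(visited)
      for (i in which(filled)) {
        near <- vis_idx[abs(vis_idx - i) == min(abs(vis_idx - i))]
        fbar[i] <- mean(fbar[near])
      }
    }
  }
  dl <- grid$params$dl
  ## midpoint cumulative integral: exact for constant integrands
  cum <- cumsum(fbar) * dl
  prof <- cum - fbar * dl / 2
  attr(prof, "fbar") <- fbar
  attr(prof, "filled") <- filled
  prof
}

#' The derived 1D bias along lambda
#'
#' The negative of the thermodynamic-integration profile, so that adding it to
#' the potential flattens the lambda landscape; cached and rebuilt lazily.
#'
#' @param grid an [ost_grid()].
#' @param beta inverse temperature 1/(kB T).
#' @return numeric vector of length `nl` (bias at lambda-bin centers).
#' @export
one_d_bias <- function(grid, beta) {
  if (grid$fm_dirty || is.null(grid$fm)) {
    prof <- ost_lambda_profile(grid, beta)
    grid$fm <- structure(-as.numeric(prof), fbar = attr(prof, "fbar"))
    grid$fm_dirty <- FALSE
  }
  grid$fm
}

## interpolate a 1D-bias vector (values at lambda-bin centers) at lambda
fm_interp <- function(fm, dl, lambda) {
  nl <- length(fm)
  lc <- (seq_len(nl) - 0.5) * dl
  if (lambda <= lc[1]) {
    slope <- (fm[2] - fm[1]) / dl
    return(list(energy = fm[1] + (lambda - lc[1]) * slope, ddl = slope))
  }
  if (lambda >= lc[nl]) {
    slope <- (fm[nl] - fm[nl - 1]) / dl
    return(list(energy = fm[nl] + (lambda - lc[nl]) * slope, ddl = slope))
  }
  k <- findInterval(lambda, lc)
  t <- (lambda - lc[k]) / dl
  slope <- (fm[k + 1] - fm[k]) / dl
  list(energy = fm[k] * (1 - t) + fm[k + 1] * t, ddl = slope)
}

## interpolate the cached 1D bias and its slope at arbitrary lambda
one_d_bias_at <- function(grid, beta, lambda) {
  fm_interp(one_d_bias(grid, beta), grid$params$dl, lambda)
}

#' Total OST bias at a point
#'
#' Sum of the 1D bias along lambda and the 2D `(lambda, F_lambda)` bias;
#' `U_OST = U + total_bias`.
#'
#' @param grid an [ost_grid()].
#' @param lambda coupling value.
#' @param f_lambda dU/dlambda (kcal/mol).
#' @param beta inverse temperature 1/(kB T); needed for the reweighted 1D part.
#' @return energy in kcal/mol.
#' @export
total_bias <- function(grid, lambda, f_lambda, beta) {
  td <- bias_energy_and_gradient(grid, lambda, f_lambda)
  od <- if (grid$n_hills > 0 || any(grid$counts > 0))
    one_d_bias_at(grid, beta, lambda)$energy else 0
  od + td$energy
}

## ---- checkpointing ----------------------------------------------------------

#' Write / read / merge OST bias checkpoints
#'
#' Versioned plain-text dump of the grid bounds, bin widths, accumulated hill
#' heights, visit counts and F_lambda sums. `merge_ost_checkpoints` adds the
#' histograms of several walkers (grids must share bin widths; F ranges are
#' unioned).
#'
#' @param grid an [ost_grid()].
#' @param path file path.
#' @param paths character vector of checkpoint files to merge.
#' @return `read_ost_checkpoint` and `merge_ost_checkpoints` return an
#'   [ost_grid()].
#' @export
write_ost_checkpoint <- function(grid, path) {
  p <- grid$params
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# xtalpath ost checkpoint v1",
               sprintf("dl %g", p$dl), sprintf("df %g", p$df),
               sprintf("w1 %g", p$w1), sprintf("w2 %g", p$w2),
               sprintf("h0 %g", p$h0), sprintf("trunc %d", p$trunc),
               sprintf("v_th %g", p$v_th), sprintf("dT %g", p$dT),
               sprintf("fmin %.10g", grid$fmin),
               sprintf("nl %d", grid$nl), sprintf("nf %d", grid$nf),
               sprintf("n_hills %d", grid$n_hills)), con)
  write_mat <- function(tag, m) {
    writeLines(sprintf("[%s]", tag), con)
    writeLines(apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  write_mat("H", grid$H)
  write_mat("counts", grid$counts)
  write_mat("fsum", grid$fsum)
  invisible(path)
}

#' @rdname write_ost_checkpoint
#' @export
read_ost_checkpoint <- function(path) {
  ln <- readLines(path)
  if (!grepl("^# xtalpath ost checkpoint", ln[1]))
    stop(sprintf("%s:1: not an OST checkpoint", path))
  getv <- function(key) {
    m <- grep(paste0("^", key, " "), ln, value = TRUE)[1]
    as.numeric(strsplit(m, " ")[[1]][2])
  }
  p <- ost_params(h0 = getv("h0"), dl = getv("dl"), df = getv("df"),
                  w1 = getv("w1"), w2 = getv("w2"), trunc = getv("trunc"),
                  v_th = getv("v_th"), dT = getv("dT"))
  nl <- as.integer(getv("nl")); nf <- as.integer(getv("nf"))
  g <- ost_grid(p, f_init = 1)
  read_mat <- function(tag) {
    start <- grep(sprintf("^\\[%s\\]$", tag), ln) + 1L
    block <- ln[start:(start + nl - 1L)]
    m <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
    stopifnot(ncol(m) == nf)
    m
  }
  g$fmin <- getv("fmin"); g$nl <- nl; g$nf <- nf
  g$H <- read_mat("H"); g$counts <- read_mat("counts"); g$fsum <- read_mat("fsum")
  g$n_hills <- as.integer(getv("n_hills"))
  g$gc <- convolve_hills(g)
  g$fm_dirty <- TRUE
  g
}

#' @rdname write_ost_checkpoint
#' @export
merge_ost_checkpoints <- function(paths) {
  grids <- lapply(paths, read_ost_checkpoint)
  base <- grids[[1]]
  for (g in grids[-1]) {
    stopifnot(g$params$dl == base$params$dl, g$params$df == base$params$df)
    ensure_f_range(base, g$fmin + 0.5 * g$params$df)
    ensure_f_range(base, g$fmin + (g$nf - 0.5) * g$params$df)
    off <- as.integer(round((g$fmin - base$fmin) / base$params$df))
    cols <- (off + 1L):(off + g$nf)
    base$H[, cols] <- base$H[, cols] + g$H
    base$counts[, cols] <- base$counts[, cols] + g$counts
    base$fsum[, cols] <- base$fsum[, cols] + g$fsum
    base$n_hills <- base$n_hills + g$n_hills
  }
  base$gc <- convolve_hills(base)
  base$fm_dirty <- TRUE
  base
}
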