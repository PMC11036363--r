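#' Thermodynamic conditions
#'
#' @param temperature temperature in K (> 0; default 298.15).
#' @param pressure pressure in atm (>= 0; default 1).
#' @return object of class `thermo_conditions` with derived `beta = 1/(kB T)`.
#' @export
thermo_conditions <- function(temperature = 298.15, pressure = 1) {
  if (temperature <= 0) stop("thermo_conditions: temperature must be positive")
  if (pressure < 0) stop("thermo_conditions: pressure must be nonnegative")
  structure(list(temperature = temperature, pressure = pressure,
                 beta = 1 / (KB * temperature)),
            class = "thermo_conditions")
}

#' Monte Carlo barostat parameters
#'
#' @param rho_min,rho_max density bounds in g/cm^3 (defaults 0.75 and 1.6);
#'   proposals leaving the band are rejected before any energy evaluation.
#' @param v_max maximum asymmetric-unit volume move in Angstrom^3 (default 1).
#' @param a_max maximum lattice-angle move in degrees (default 0.5).
#' @param interval mean number of MD steps between trial moves (default 10);
#'   trials are attempted with probability 1/interval per step.
#' @return object of class `barostat_params`.
#' @export
barostat_params <- function(rho_min = 0.75, rho_max = 1.6, v_max = 1,
                            a_max = 0.5, interval = 10L) {
  if (!(rho_min > 0 && rho_min < rho_max))
    stop("barostat_params: need 0 < rho_min < rho_max")
  if (v_max <= 0 || a_max <= 0 || interval < 1)
    stop("barostat_params: v_max, a_max, interval must be positive")
  structure(list(rho_min = rho_min, rho_max = rho_max, v_max = v_max,
                 a_max = a_max, interval = as.integer(interval)),
            class = "barostat_params")
}

#' Dynamics parameters
#'
#' @param dt timestep in fs (default 1).
#' @param friction Langevin friction in 1/ps (default 10; 0 gives NVE
#'   velocity-Verlet dynamics).
#' @param lambda_mass fictitious mass of the theta variable propagating lambda
#'   (kcal/mol fs^2; default 1e5, giving diffusive lambda crossings on the
#'   10 ps scale for a flat landscape at room temperature).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param n_steps total MD steps.
#' @param snapshot_stride steps between snapshot checks (default 10000, i.e.
#'   10 ps at a 1 fs timestep).
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(dt = 1, friction = 10, lambda_mass = 1e5,
                            seed = 1L, n_steps = 1000L,
                            snapshot_stride = 10000L) {
  if (dt <= 0) stop("dynamics_params: dt must be positive")
  if (friction < 0) stop("dynamics_params: friction must be nonnegative")
  structure(list(dt = dt, friction = friction, lambda_mass = lambda_mass,
                 seed = as.integer(seed), n_steps = as.integer(n_steps),
                 snapshot_stride = as.integer(snapshot_stride)),
            class = "dynamics_params")
}

## ---- Langevin (BAOAB) -------------------------------------------------------

## One BAOAB step for Cartesian particles. `gradient_fn(coords)` returns the
## potential gradient (kcal/mol/A). Units: coords A, velocities A/fs, masses
## amu. friction is per ps. Uses R's global RNG stream.
#' Langevin dynamics step (BAOAB splitting)
#'
#' @param coords n x 3 coordinates (Angstrom).
#' @param velocities n x 3 velocities (Angstrom/fs).
#' @param gradient_fn function of coords returning the n x 3 potential
#'   gradient in kcal/mol/Angstrom.
#' @param masses length-n atomic masses (amu).
#' @param dt timestep (fs).
#' @param friction Langevin friction (1/ps); 0 gives velocity Verlet.
#' @param temperature temperature (K).
#' @param gradient optional pre-computed gradient at `coords` (saves one call).
#' @return list `coords`, `velocities`, `gradient` (at the new coords).
#' @export
langevin_step <- function(coords, velocities, gradient_fn, masses, dt,
                          friction, temperature, gradient = NULL) {
  if (is.null(gradient)) gradient <- gradient_fn(coords)
  if (any(!is.finite(coords)))
    stop("langevin_step: non-finite coordinates")
  a <- -gradient / masses * KCAL_MOL_A_AMU
  v <- velocities + 0.5 * dt * a                  # B
  x <- coords + 0.5 * dt * v                      # A
  if (friction > 0) {                             # O
    c1 <- exp(-friction * 1e-3 * dt)
    c2 <- sqrt(1 - c1^2)
    sig <- sqrt(KB * temperature * KCAL_MOL_A_AMU / masses)
    v <- c1 * v + c2 * sig * matrix(stats::rnorm(length(v)), nrow(v), 3)
  }
  x <- x + 0.5 * dt * v                           # A
  g2 <- gradient_fn(x)
  a2 <- -g2 / masses * KCAL_MOL_A_AMU
  v <- v + 0.5 * dt * a2                          # B
  list(coords = x, velocities = v, gradient = g2)
}

## BAOAB update for the scalar theta variable (lambda = sin^2 theta).
## mass in kcal/mol fs^2; force_fn(theta) returns -d(U+bias)/dtheta.
theta_step <- function(theta, vtheta, force_fn, mass, dt, friction,
                       temperature, force = NULL) {
  if (is.null(force)) force <- force_fn(theta)
  v <- vtheta + 0.5 * dt * force / mass
  th <- theta + 0.5 * dt * v
  if (friction > 0) {
    c1 <- exp(-friction * 1e-3 * dt)
    c2 <- sqrt(1 - c1^2)
    v <- c1 * v + c2 * sqrt(KB * temperature / mass) * stats::rnorm(1)
  }
  th <- th + 0.5 * dt * v
  f2 <- force_fn(th)
  v <- v + 0.5 * dt * f2 / mass
  list(theta = th, vtheta = v, force = f2)
}

#' Propagate the coupling variable lambda
#'
#' Lambda is driven as an auxiliary Langevin particle through the bounded
#' mapping `lambda = sin^2(theta)`; the chain rule `dlambda/dtheta =
#' sin(2 theta)` vanishes at the endpoints, so no hard reflection is needed.
#'
#' @param theta,vtheta current theta coordinate and velocity.
#' @param dU_dlambda total derivative of potential plus bias with respect to
#'   lambda (kcal/mol).
#' @param params a [dynamics_params()].
#' @param temperature temperature (K).
#' @return list `theta`, `vtheta`, `lambda`.
#' @export
lambda_step <- function(theta, vtheta, dU_dlambda, params, temperature) {
  force_fn <- function(th) -dU_dlambda * sin(2 * th)
  st <- theta_step(theta, vtheta, force_fn, params$lambda_mass, params$dt,
                   params$friction, temperature)
  list(theta = st$theta, vtheta = st$vtheta, lambda = sin(st$theta)^2)
}

## ---- Monte Carlo barostat ---------------------------------------------------

#' Propose a lattice trial move
#'
#' Chooses one free lattice degree of freedom uniformly at random. A length
#' move changes the asymmetric-unit volume by `dV = v_max (2x - 1)` by scaling
#' the chosen axis group; an angle move changes the chosen angle (group) by
#' `da = a_max (2x - 1)` and then rescales all lengths uniformly so the volume
#' is unchanged. Constrained parameters remain exactly at their constrained
#' values.
#'
#' @param cell current [unit_cell()].
#' @param system lattice system name.
#' @param params a [barostat_params()].
#' @param n_ops space-group multiplicity (converts between cell and
#'   asymmetric-unit volume).
#' @return the proposed [unit_cell()], or NULL for a degenerate proposal, with
#'   attribute `kind` ("length" or "angle").
#' @export
propose_lattice_move <- function(cell, system, params, n_ops = 1L) {
  dof <- lattice_free_dof(system)
  mv <- dof[[sample.int(length(dof), 1L)]]
  x <- stats::runif(1)
  vals <- free_params_from_cell(system, cell)
  names(vals) <- NULL
  idx <- which(vapply(dof, function(d) identical(d, mv), logical(1)))
  if (mv$kind == "length") {
    dV <- params$v_max * (2 * x - 1)
    v_asu <- cell_volume(cell) / n_ops
    v_new <- v_asu + dV
    if (v_new <= 0) return(NULL)
    f <- (v_new / v_asu)^(1 / length(mv$par))
    vals[idx] <- vals[idx] * f
  } else {
    da <- params$a_max * (2 * x - 1)
    vals[idx] <- vals[idx] + da
    if (vals[idx] <= 1 || vals[idx] >= 179) return(NULL)
  }
  out <- tryCatch(cell_from_free_params(system, vals), error = function(e) NULL)
  if (is.null(out)) return(NULL)
  if (mv$kind == "angle") {
    ## restore the volume exactly by uniform scaling of all lengths
    s <- (cell_volume(cell) / cell_volume(out))^(1 / 3)
    lidx <- vapply(dof, function(d) d$kind == "length", logical(1))
    vals[lidx] <- vals[lidx] * s
    out <- cell_from_free_params(system, vals)
  }
  attr(out, "kind") <- mv$kind
  out
}

#' Barostat trial energy
#'
#' `dE = dU + p dV - n_molecules kB T ln(V_proposed / V_current)`, with the
#' pressure-volume term converted from atm Angstrom^3 to kcal/mol. Volumes are
#' asymmetric-unit volumes.
#'
#' @param dU potential-energy change (kcal/mol).
#' @param v_current,v_proposed asymmetric-unit volumes (Angstrom^3, > 0).
#' @param n_molecules number of molecules in the asymmetric unit.
#' @param conditions a [thermo_conditions()].
#' @return dE in kcal/mol.
#' @export
barostat_delta_e <- function(dU, v_current, v_proposed, n_molecules,
                             conditions) {
  if (v_current <= 0 || v_proposed <= 0)
    stop("barostat_delta_e: volumes must be positive")
  dU + conditions$pressure * (v_proposed - v_current) * ATM_A3_TO_KCAL -
    n_molecules * KB * conditions$temperature * log(v_proposed / v_current)
}

#' Metropolis acceptance for a barostat move
#'
#' Accept if `dE < 0`, otherwise with probability `exp(-dE / kB T)`.
#'
#' @param dE trial energy (kcal/mol).
#' @param conditions a [thermo_conditions()].
#' @return logical.
#' @export
barostat_accept <- function(dE, conditions) {
  if (!is.finite(dE)) stop("barostat_accept: non-finite dE")
  dE < 0 || stats::runif(1) < exp(-dE / (KB * conditions$temperature))
}

## One full barostat trial on a crystal state. energy_fn(state) -> scalar
## potential, or NULL for noninteracting (ideal-gas) sampling. Returns
## list(state, accepted, skipped).
barostat_trial <- function(state, bparams, conditions, energy_fn = NULL,
                           current_energy = NULL) {
  cell_new <- propose_lattice_move(state$cell, state$sg$system, bparams,
                                   n_ops = state$sg$n_ops)
  if (is.null(cell_new))
    return(list(state = state, accepted = FALSE, skipped = TRUE))
  trial <- state
  trial$cell <- cell_new
  ## density bounds before any energy evaluation
  rho <- crystal_density(trial)
  if (rho < bparams$rho_min || rho > bparams$rho_max)
    return(list(state = state, accepted = FALSE, skipped = TRUE))
  trial$coords <- rescale_coordinates(state, cell_new)
  v_cur <- asu_volume(state)
  v_new <- asu_volume(trial)
  dU <- 0
  e_new <- current_energy
  if (!is.null(energy_fn)) {
    e_cur <- current_energy %||% energy_fn(state)
    e_new <- energy_fn(trial)
    dU <- e_new - e_cur
  }
  dE <- barostat_delta_e(dU, v_cur, v_new, state$n_molecules, conditions)
  if (barostat_accept(dE, conditions))
    list(state = trial, accepted = TRUE, skipped = FALSE, energy = e_new)
  else
    list(state = state, accepted = FALSE, skipped = FALSE)
}

#' Run the barostat alone (no coordinate dynamics)
#'
#' Repeated lattice trial moves on a state. With `energy_fn = NULL` the system
#' is noninteracting and the stationary asymmetric-unit volume distribution is
#' the analytic NPT ideal-gas law `p(V) ~ V^n exp(-beta p V)`; used to verify
#' detailed balance of the acceptance rule.
#'
#' @param state a [crystal_state()].
#' @param bparams a [barostat_params()].
#' @param conditions a [thermo_conditions()].
#' @param n_trials number of trial moves.
#' @param energy_fn optional function(state) -> potential (kcal/mol).
#' @return list `state` (final), `volumes` (ASU volume after every trial),
#'   `accepted` (count), `cells` (final cell).
#' @export
run_barostat_only <- function(state, bparams, conditions, n_trials,
                              energy_fn = NULL) {
  volumes <- numeric(n_trials)
  acc <- 0L
  for (k in seq_len(n_trials)) {
    tr <- barostat_trial(state, bparams, conditions, energy_fn)
    state <- tr$state
    if (tr$accepted) acc <- acc + 1L
    volumes[k] <- asu_volume(state)
  }
  list(state = state, volumes = volumes, accepted = acc)
}

#' Snapshot acceptance criterion
#'
#' A structure encountered at a snapshot boundary is saved iff lambda exceeds
#' the coupling threshold and its locally minimized potential energy is within
#' the energy window of the lowest minimized energy observed so far.
#'
#' @param lambda current coupling value.
#' @param minimized_energy locally minimized potential (kcal/mol).
#' @param best_energy lowest minimized potential previously observed
#'   (kcal/mol; `Inf` if none).
#' @param lambda_min coupling threshold (default 0.8).
#' @param window energy window (kcal/mol, default 10).
#' @return logical.
#' @export
snapshot_criterion <- function(lambda, minimized_energy, best_energy,
                               lambda_min = 0.8, window = 10) {
  lambda > lambda_min && (minimized_energy - min(best_energy, minimized_energy)) <= window
}

## ---- walker -----------------------------------------------------------------

#' Random initial crystal state
#'
#' Unit cell drawn uniformly in each free lattice degree of freedom within the
#' bounds implied by the density band (angles in [60, 120] degrees where
#' free), molecule placed with a uniform random rotation (quaternion) and
#' uniform fractional center of mass.
#'
#' @param topology a [molecule_topology()].
#' @param coords0 reference molecular geometry (n x 3).
#' @param sg a [space_group()] or symbol.
#' @param bparams a [barostat_params()] (density band).
#' @param lambda initial coupling value.
#' @return a [crystal_state()].
#' @export
random_crystal_state <- function(topology, coords0, sg, bparams, lambda = 0) {
  if (is.character(sg)) sg <- space_group(sg)
  rho <- stats::runif(1, bparams$rho_min, bparams$rho_max)
  v_cell <- molecule_mass(topology) * sg$n_ops * AMU_A3_TO_GCC / rho
  dof <- lattice_free_dof(sg$system)
  ## draw shape, then scale lengths to the target volume
  vals <- vapply(dof, function(d) {
    if (d$kind == "length") stats::runif(1, 0.8, 1.25) else stats::runif(1, 60, 120)
  }, numeric(1))
  lidx <- vapply(dof, function(d) d$kind == "length", logical(1))
  cl <- cell_from_free_params(sg$system, ifelse(lidx, vals * 5, vals))
  s <- (v_cell / cell_volume(cl))^(1 / 3)
  vals[lidx] <- vals[lidx] * 5 * s
  cl <- cell_from_free_params(sg$system, vals)
  ## uniform random rotation from a random unit quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
  co <- as.matrix(coords0)
  com <- colSums(co * topology$mass) / sum(topology$mass)
  co <- sweep(co, 2, com) %*% t(R)
  com_new <- frac_to_cart(cl, stats::runif(3))
  co <- sweep(co, 2, com_new, "+")
  crystal_state(topology, co, cl, sg, lambda = lambda)
}

#' Run one search walker
#'
#' Orchestrates Langevin dynamics on coordinates, lambda-dynamics on the
#' coupling variable, OST hill deposition, Monte Carlo barostat trials
#' (Bernoulli with probability 1/interval per step) and conditional snapshot
#' saving. Fully reproducible under a fixed seed in
#' [dynamics_params()]`$seed`.
#'
#' @param state initial [crystal_state()].
#' @param aparams an [alchemical_params()].
#' @param ostp an [ost_params()].
#' @param bparams a [barostat_params()].
#' @param dynp a [dynamics_params()].
#' @param conditions a [thermo_conditions()].
#' @param grid optional shared [ost_grid()] (multi-walker bias); a fresh grid
#'   is created when NULL.
#' @param traj_stride steps between trajectory records (default 100).
#' @param snapshot_lambda_min,snapshot_window snapshot criterion settings.
#' @param minimize_snapshots logical; locally minimize candidate snapshots
#'   (rms gradient 0.1 kcal/mol/A) before applying the energy window.
#' @return list with `state`, `trajectory` (data.frame: step, lambda, energy,
#'   f_lambda, volume, density), `snapshots` (list of records with the
#'   minimized state and metadata), `grid`, `barostat` (trial/accept counts),
#'   `status` (0 on success) and `error` (message, on failure).
#' @export
run_walker <- function(state, aparams = alchemical_params(),
                       ostp = ost_params(), bparams = barostat_params(),
                       dynp = dynamics_params(), conditions = thermo_conditions(),
                       grid = NULL, traj_stride = 100L,
                       snapshot_lambda_min = 0.8, snapshot_window = 10,
                       minimize_snapshots = TRUE) {
  set.seed(dynp$seed)
  if (is.null(grid)) grid <- ost_grid(ostp)
  n <- dynp$n_steps
  top <- state$topology
  masses <- rep(top$mass, state$n_molecules)
  nm <- length(masses) * 3L
  traj <- list()
  snapshots <- list()
  best_e <- Inf
  ntr <- 0L; nacc <- 0L
  result_status <- 0L
  err_msg <- NULL

  ## thermalized initial velocities
  sig <- sqrt(KB * conditions$temperature * KCAL_MOL_A_AMU / masses)
  vel <- sig * matrix(stats::rnorm(nm), length(masses), 3)
  theta <- asin(sqrt(min(1, max(0, state$lambda))))
  vtheta <- sqrt(KB * conditions$temperature / dynp$lambda_mass) * stats::rnorm(1)

  eval_all <- function(st) total_potential(st, aparams)

  ## the 1D bias along lambda is refreshed every `fm_stride` hills; between
  ## refreshes the cached vector is interpolated
  fm_cache <- NULL
  out <- tryCatch({
    er <- eval_all(state)
    for (step in seq_len(n)) {
      ## assemble biased forces
      b2 <- bias_energy_and_gradient(grid, state$lambda, er$dU_dl)
      fm <- if (!is.null(fm_cache))
        fm_interp(fm_cache, ostp$dl, state$lambda) else list(energy = 0, ddl = 0)
      grad_x <- er$gradient + b2$ddf * er$d2U_dldx
      dudl_tot <- er$dU_dl + b2$ddl + b2$ddf * er$d2U_dl2 + fm$ddl

      ## theta (lambda) update with frozen generalized force over the step
      lam_new <- lambda_step(theta, vtheta, dudl_tot, dynp,
                             conditions$temperature)
      theta <- lam_new$theta; vtheta <- lam_new$vtheta

      ## coordinate BAOAB; gradient at the new coordinates reuses new lambda
      state$lambda <- lam_new$lambda
      stepped <- langevin_step(
        state$coords, vel,
        gradient_fn = function(x) {
          st <- state; st$coords <- x
          e <- eval_all(st)
          b <- bias_energy_and_gradient(grid, st$lambda, e$dU_dl)
          er <<- e
          e$gradient + b$ddf * e$d2U_dldx
        },
        masses = masses, dt = dynp$dt, friction = dynp$friction,
        temperature = conditions$temperature, gradient = grad_x)
      state$coords <- stepped$coords
      vel <- stepped$velocities

      record_visit(grid, state$lambda, er$dU_dl)
      if (step %% ostp$stride == 0L) {
        h <- tempering_height(ostp, coverage_statistic(grid),
                              conditions$temperature)
        deposit_hill(grid, state$lambda, er$dU_dl, h)
        if (grid$n_hills %% ostp$fm_stride == 0L)
          fm_cache <- as.numeric(one_d_bias(grid, conditions$beta))
      }

      ## barostat trial
      if (stats::runif(1) < 1 / bparams$interval) {
        ntr <- ntr + 1L
        tr <- barostat_trial(state, bparams, conditions,
                             energy_fn = function(st) total_potential(st, aparams)$total,
                             current_energy = er$total)
        if (tr$accepted) {
          nacc <- nacc + 1L
          state <- tr$state
          er <- eval_all(state)
        }
      }

      if (step %% traj_stride == 0L) {
        traj[[length(traj) + 1L]] <- data.frame(
          step = step, lambda = state$lambda, energy = er$total,
          f_lambda = er$dU_dl, volume = asu_volume(state),
          density = crystal_density(state))
      }

      if (step %% dynp$snapshot_stride == 0L &&
          state$lambda > snapshot_lambda_min) {
        cand <- state; cand$lambda <- 1
        e_min <- if (minimize_snapshots) {
          mr <- minimize_crystal(cand, rms_target = 0.1, max_iter = 200,
                                 params = aparams)
          cand <- mr$state
          mr$energy
        } else total_potential(cand, aparams)$total
        if (snapshot_criterion(state$lambda, e_min, best_e,
                               snapshot_lambda_min, snapshot_window)) {
          snapshots[[length(snapshots) + 1L]] <- list(
            state = cand, energy = e_min, density = crystal_density(cand),
            lambda = state$lambda, step = step)
        }
        best_e <- min(best_e, e_min)
      }
    }
    list(ok = TRUE)
  }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))

  if (!isTRUE(out$ok)) {
    result_status <- 1L
    err_msg <- out$msg
  }
  list(state = state,
       trajectory = if (length(traj)) do.call(rbind, traj) else
         data.frame(step = integer(0), lambda = numeric(0), energy = numeric(0),
                    f_lambda = numeric(0), volume = numeric(0), density = numeric(0)),
       snapshots = snapshots, grid = grid,
       barostat = c(trials = ntr, accepted = nacc),
       status = result_status, error = err_msg)
}

#' Orthogonal space tempering on a one-dimensional analytic lambda potential
#'
#' Runs lambda-dynamics plus OST hill deposition on a potential `U(lambda)`
#' with no coordinate degrees of freedom; used to validate free-energy
#' recovery against closed forms.
#'
#' @param potential list with functions `u(lambda)` and `dudl(lambda)` (e.g.
#'   from [make_analytic_lambda_well()]).
#' @param ostp an [ost_params()].
#' @param dynp a [dynamics_params()] (`n_steps`, `dt`, `friction`,
#'   `lambda_mass`, `seed`).
#' @param conditions a [thermo_conditions()].
#' @return list `grid`, `lambdas` (sampled every 10 steps), `profile`
#'   (thermodynamic-integration estimate at lambda-bin centers), `delta_g`
#'   (profile at lambda = 1).
#' @export
run_ost_lambda <- function(potential, ostp = ost_params(),
                           dynp = dynamics_params(n_steps = 200000L),
                           conditions = thermo_conditions()) {
  set.seed(dynp$seed)
  grid <- ost_grid(ostp, f_init = 50)
  theta <- asin(sqrt(0.0))
  vtheta <- sqrt(KB * conditions$temperature / dynp$lambda_mass) * stats::rnorm(1)
  lambdas <- numeric(dynp$n_steps %/% 10L)
  lam <- 0
  fm_cache <- NULL
  for (step in seq_len(dynp$n_steps)) {
    fl <- potential$dudl(lam)
    b2 <- bias_energy_and_gradient(grid, lam, fl)
    fm <- if (!is.null(fm_cache)) fm_interp(fm_cache, ostp$dl, lam)
          else list(ddl = 0)
    dudl_tot <- fl + b2$ddl + fm$ddl
    st <- lambda_step(theta, vtheta, dudl_tot, dynp, conditions$temperature)
    theta <- st$theta; vtheta <- st$vtheta; lam <- st$lambda
    record_visit(grid, lam, potential$dudl(lam))
    if (step %% ostp$stride == 0L) {
      h <- tempering_height(ostp, coverage_statistic(grid),
                            conditions$temperature)
      deposit_hill(grid, lam, potential$dudl(lam), h)
      if (grid$n_hills %% ostp$fm_stride == 0L)
        fm_cache <- as.numeric(one_d_bias(grid, conditions$beta))
    }
    if (step %% 10L == 0L) lambdas[step %/% 10L] <- lam
  }
  prof <- ost_lambda_profile(grid, conditions$beta)
  list(grid = grid, lambdas = lambdas, profile = prof,
       delta_g = sum(attr(prof, "fbar")) * grid$params$dl)
}
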