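#' Full polymorph search pipeline on one space group
#'
#' Runs several independent walkers from random rigid-body starts, minimizes
#' the saved snapshots post hoc (rms gradient 0.03 kcal/mol/A), filters by
#' density and relative energy, builds the rmsd_N similarity matrix, removes
#' duplicates by iterative minimum-cluster-count clustering, and emits the
#' progressive reduction report.
#'
#' @param topology a [molecule_topology()].
#' @param coords reference molecular geometry (n x 3).
#' @param sg space-group symbol or [space_group()].
#' @param n_walkers number of independent walkers.
#' @param n_steps MD steps per walker.
#' @param seed master seed; walker w uses `seed + w`.
#' @param aparams an [alchemical_params()].
#' @param ostp,bparams,conditions parameter objects (defaults are the
#'   production values).
#' @param dynp a [dynamics_params()] template (`seed`/`n_steps` overridden).
#' @param lambda_init initial coupling for each walker (default 0, the vacuum
#'   end of the deposition path).
#' @param rho_cut,energy_window filter settings ([filter_snapshots()]).
#' @param n_mol shell size for [rmsd_n()] (default 20).
#' @param cluster_cutoff,restarts clustering settings ([iterative_cluster()]).
#' @param snapshot_lambda_min,snapshot_window snapshot criterion settings.
#' @return list: `snapshots` (list of minimized snapshot records), `table`
#'   (snapshot data.frame), `survivors` (filtered rows), `similarity`,
#'   `clustering`, `representatives` (lowest-energy member per cluster),
#'   `report` (reduction table), `best_energy`, `walkers` (per-walker status).
#' @export
run_polymorph_search <- function(topology, coords, sg, n_walkers = 4L,
                                 n_steps = 20000L, seed = 1L,
                                 aparams = alchemical_params(),
                                 ostp = ost_params(),
                                 bparams = barostat_params(),
                                 conditions = thermo_conditions(),
                                 dynp = dynamics_params(),
                                 lambda_init = 0,
                                 rho_cut = 1.25, energy_window = 10,
                                 n_mol = 20L, cluster_cutoff = 0.5,
                                 restarts = 1000L,
                                 snapshot_lambda_min = 0.8,
                                 snapshot_window = 10) {
  if (is.character(sg)) sg <- space_group(sg)
  snapshots <- list()
  walker_status <- integer(n_walkers)
  for (w in seq_len(n_walkers)) {
    set.seed(seed + w)
    st0 <- random_crystal_state(topology, coords, sg, bparams,
                                lambda = lambda_init)
    dw <- dynp
    dw$seed <- seed + w
    dw$n_steps <- as.integer(n_steps)
    res <- run_walker(st0, aparams = aparams, ostp = ostp, bparams = bparams,
                      dynp = dw, conditions = conditions,
                      snapshot_lambda_min = snapshot_lambda_min,
                      snapshot_window = snapshot_window)
    walker_status[w] <- res$status
    snapshots <- c(snapshots, res$snapshots)
  }
  if (!length(snapshots)) {
    return(list(snapshots = list(), table = NULL, survivors = NULL,
                similarity = NULL, clustering = NULL, representatives = list(),
                report = reduction_report(list(snapshots = character(0))),
                best_energy = NA_real_, walkers = walker_status))
  }
  ## post hoc minimization at the tight threshold
  for (k in seq_along(snapshots)) {
    mr <- minimize_crystal(snapshots[[k]]$state, rms_target = "posthoc",
                           params = aparams)
    snapshots[[k]]$state <- mr$state
    snapshots[[k]]$energy <- mr$energy
    snapshots[[k]]$density <- crystal_density(mr$state)
    snapshots[[k]]$converged <- mr$converged
  }
  tab <- data.frame(
    id = seq_along(snapshots),
    energy = vapply(snapshots, `[[`, numeric(1), "energy"),
    density = vapply(snapshots, `[[`, numeric(1), "density"),
    lambda = vapply(snapshots, `[[`, numeric(1), "lambda"),
    step = vapply(snapshots, `[[`, numeric(1), "step"),
    space_group = sg$symbol)
  surv <- filter_snapshots(tab, rho_cut = rho_cut, e_window = energy_window)
  sim <- NULL; clus <- NULL; reps <- list()
  if (nrow(surv) >= 1) {
    states <- lapply(snapshots[surv$id], `[[`, "state")
    sim <- similarity_matrix(states, n_mol = n_mol,
                             labels = sprintf("s%03d", surv$id))
    clus <- iterative_cluster(sim, cutoff = cluster_cutoff,
                              restarts = restarts, seed = seed)
    for (cl in seq_len(clus$n_clusters)) {
      members <- surv$id[clus$assignment == cl]
      best <- members[which.min(tab$energy[members])]
      reps[[cl]] <- snapshots[[best]]
    }
  }
  rep_ids <- vapply(reps, function(r) r$step, numeric(1))
  report <- reduction_report(list(
    snapshots = tab$space_group,
    energy_density = surv$space_group,
    packing_similarity = rep(sg$symbol, length(reps))))
  list(snapshots = snapshots, table = tab, survivors = surv,
       similarity = sim, clustering = clus, representatives = reps,
       report = report,
       best_energy = if (length(reps))
         min(vapply(reps, `[[`, numeric(1), "energy")) else min(tab$energy),
       walkers = walker_status)
}
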