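# Config-driven reproduction of the condition matrix
# (PE mode x salt x confinement), plus deterministic test fixtures.

#' Default run configuration
#'
#' Desk-scale defaults use a smaller box (L = 30 sigma) with the same
#' (intensive) salt concentrations and reduced sweep counts; the box still
#' exceeds the 20 mM Debye length (about 2.2 nm = 5.2 sigma) many times
#' over. `full = TRUE` restores the full-size study conditions
#' (L = 62 sigma, long runs).
#'
#' @param full Use full-size settings.
#' @return A named list understood by [run_condition()] and [run_matrix()].
#' @export
default_config <- function(full = FALSE) {
  cfg <- list(mode = "parallel_rigid", P_nm = Inf,
              x_grid = seq(2, 8, by = 0.5),
              c11_mM = 20, c33_mM = 0, confinement = TRUE,
              L = if (full) 62 else 30, N = 21, seed = 1,
              sweeps_equil = if (full) 20000 else 1500,
              sweeps_prod = if (full) 50000 else 3000,
              window = if (full) 5000 else 500,
              snapshot_stride = 10,
              ion_step = 0.5, pivot_max_angle = 0.5,
              move_mix = c(ion = 0.9, pivot = 0.1),
              outdir = NULL)
  cfg
}

#' Read a run configuration file
#'
#' YAML key-value file with any subset of the [default_config()] fields;
#' missing fields take their defaults.
#'
#' @param path YAML file path.
#' @param full Baseline defaults to merge into (see [default_config()]).
#' @return Configuration list.
#' @export
read_run_config <- function(path, full = FALSE) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(full), user)
  if (!is.null(user$move_mix)) cfg$move_mix <- unlist(user$move_mix)
  if (identical(cfg$P_nm, "Inf") || identical(cfg$P_nm, ".inf")) {
    cfg$P_nm <- Inf
  }
  cfg
}

.condition_label <- function(cfg) {
  sprintf("%s_P%s_c33-%g_conf%d", cfg$mode,
          if (is.finite(cfg$P_nm)) format(cfg$P_nm) else "Inf",
          cfg$c33_mM, as.integer(isTRUE(cfg$confinement)))
}

#' Run one condition over a separation grid
#'
#' For one (PE mode, persistence length, salt, confinement) combination:
#' builds the system at every grid separation, equilibrates it by the
#' force-symmetry criterion (proceeding with a warning when the criterion
#' is not met within the sweep budget), runs production, and assembles
#' mean forces, the integrated PMF, and the structural observables
#' (effective separation D, bridging-ion count, and charge-fraction
#' profiles at the closest and reference separations).
#'
#' @param config Configuration list (see [default_config()]).
#' @return List of class `pe_condition`: `forces` (one record per x),
#'   `pmf`, `observables` (data.frame per x), `profiles` (list of
#'   charge-fraction profiles keyed by x), `delta_f` (between the closest
#'   grid point and x_ref, when both are present) and `config`.
#' @export
run_condition <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  params <- model_parameters()
  x_ref <- params$reference_separation
  recs <- NULL
  obs <- NULL
  profiles <- list()
  for (j in seq_along(config$x_grid)) {
    x <- config$x_grid[j]
    sys <- build_system(config$mode, x = x, P_nm = config$P_nm,
                        c11_mM = config$c11_mM, c33_mM = config$c33_mM,
                        L = config$L, confinement = config$confinement,
                        N = config$N, seed = config$seed + 1000 * j,
                        params = params)
    moves <- move_spec(ion_step = config$ion_step,
                       pivot_max_angle = config$pivot_max_angle,
                       move_mix = config$move_mix,
                       sweeps_equil = config$sweeps_equil,
                       sweeps_prod = config$sweeps_prod,
                       seed = config$seed + 1000 * j + 1)
    eq <- suppressWarnings(
      run_until_equilibrium(sys, moves, window = config$window,
                            on_fail = "warn"))
    run <- run_production(eq, snapshot_stride = config$snapshot_stride)
    recs <- rbind(recs, mean_force(run))
    ds <- effective_separation(run$trajectory)
    nb <- bridging_ions(run$trajectory)
    obs <- rbind(obs, data.frame(
      separation_x = x, D_mean = ds$D_mean, D_sd = ds$D_sd,
      Nb_mean = nb$Nb_mean, Nb_sd = nb$Nb_sd,
      bridging_charge_fraction = nb$charge_fraction,
      equil_sweeps = eq$sweeps, equil_converged = eq$converged,
      acc_ion = unname(run$acceptance["ion"]),
      acc_pivot = unname(run$acceptance["pivot"]),
      confinement_violations = run$confinement_violations))
    if (x == min(config$x_grid) || abs(x - x_ref) < 1e-9) {
      profiles[[format(x)]] <- charge_fraction_profile(
        run$trajectory, r_max = config$L / 2)
    }
  }
  pmf <- if (any(abs(config$x_grid - x_ref) < 1e-9)) {
    integrate_pmf(recs, x_ref)
  } else NULL
  dfr <- NULL
  xc <- format(min(config$x_grid))
  xr <- format(x_ref)
  if (!identical(xc, xr) && all(c(xc, xr) %in% names(profiles))) {
    dfr <- delta_f(profiles[[xc]], profiles[[xr]])
  }
  out <- list(forces = recs, pmf = pmf, observables = obs,
              profiles = profiles, delta_f = dfr, config = config,
              label = .condition_label(config))
  class(out) <- "pe_condition"
  if (!is.null(config$outdir)) .write_condition(out, config$outdir)
  out
}

.write_condition <- function(cond, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(outdir, cond$label)
  write.csv(cond$forces, paste0(base, "_forces.csv"), row.names = FALSE)
  if (!is.null(cond$pmf)) {
    write.csv(cond$pmf, paste0(base, "_pmf.csv"), row.names = FALSE)
  }
  write.csv(cond$observables, paste0(base, "_observables.csv"),
            row.names = FALSE)
  if (!is.null(cond$delta_f)) {
    write.csv(cond$delta_f, paste0(base, "_delta_f.csv"), row.names = FALSE)
  }
  cfg <- cond$config
  cfg$move_mix <- as.list(cfg$move_mix)
  yaml::write_yaml(cfg, paste0(base, "_config.yaml"))
  invisible(base)
}

#' Run a grid of conditions
#'
#' Sequentially executes [run_condition()] over the cross product of PE
#' modes (with their persistence lengths), trivalent salt concentrations
#' and confinement settings. When `config$outdir` is set, completed cells
#' (identified by their condition label) are skipped on re-run, making the
#' matrix resumable.
#'
#' @param config Base configuration; the fields `modes` (named list
#'   mapping mode label to P_nm), `c33_list` and `confinement_list` define
#'   the grid.
#' @return Named list of `pe_condition` results plus `summary`, a combined
#'   observables table.
#' @export
run_matrix <- function(config = default_config()) {
  config <- utils::modifyList(default_config(), config)
  if (is.null(config$modes)) {
    config$modes <- list(parallel_rigid = Inf, rotatable_rigid = Inf,
                         bendable_P10 = 10, bendable_P2 = 2)
  }
  if (is.null(config$c33_list)) config$c33_list <- c(0, 0.5, 5)
  if (is.null(config$confinement_list)) config$confinement_list <- TRUE
  cells <- list()
  summary <- NULL
  for (mlab in names(config$modes)) {
    mode <- if (grepl("^bendable", mlab)) "bendable" else mlab
    for (c33 in config$c33_list) {
      for (conf in config$confinement_list) {
        cfg <- config
        cfg$mode <- mode
        cfg$P_nm <- config$modes[[mlab]]
        cfg$c33_mM <- c33
        cfg$confinement <- conf
        cfg$modes <- cfg$c33_list <- cfg$confinement_list <- NULL
        lab <- .condition_label(cfg)
        done <- !is.null(cfg$outdir) &&
          file.exists(file.path(cfg$outdir, paste0(lab, "_forces.csv")))
        if (done) {
          cells[[lab]] <- .read_condition(cfg$outdir, lab)
        } else {
          cells[[lab]] <- run_condition(cfg)
        }
        so <- cells[[lab]]$observables
        so$condition <- lab
        so$mode <- mlab
        so$c33_mM <- c33
        so$confinement <- conf
        summary <- rbind(summary, so)
      }
    }
  }
  list(cells = cells, summary = summary)
}

.read_condition <- function(outdir, label) {
  base <- file.path(outdir, label)
  pmf_file <- paste0(base, "_pmf.csv")
  out <- list(forces = read.csv(paste0(base, "_forces.csv")),
              pmf = if (file.exists(pmf_file)) read.csv(pmf_file) else NULL,
              observables = read.csv(paste0(base, "_observables.csv")),
              profiles = list(), delta_f = NULL,
              config = yaml::read_yaml(paste0(base, "_config.yaml")),
              label = label)
  class(out) <- "pe_condition"
  out
}

#' Deterministic toy fixtures
#'
#' Small systems used by unit tests and examples. Kinds:
#' \describe{
#'   \item{`two_charges`}{Two +1 unit charges held as two static
#'     single-bead "chains" at separation `r` (default: the Bjerrum
#'     length, so their Coulomb energy is exactly 1 kB*T).}
#'   \item{`ion_pair`}{Two mobile +1 ions at separation `r` in a periodic
#'     box (`L`, default 10 sigma); used for Boltzmann-sampling checks.}
#'   \item{`random10`}{Ten neutral-summing ions (3:3 and 1:1 species)
#'     placed at random in an `L` = 10 sigma box.}
#'   \item{`random50`}{Fifty ions in an `L` = 14 sigma box, for
#'     incremental-energy stress tests.}
#'   \item{`bridge_toy`}{Two parallel 5-bead rods at x = 2 sigma with one
#'     trivalent cation at the midpoint: exactly one bridging ion.}
#'   \item{`wlc_chain`}{A single free bendable chain with zero charges and
#'     zero excluded volume (an ideal discrete worm-like chain), for
#'     recovery of the closed-form angle statistics; `P_nm` sets the
#'     persistence length.}
#' }
#'
#' @param kind Fixture name.
#' @param seed RNG seed for the random fixtures.
#' @param r,L,P_nm,N Optional geometry overrides (see above).
#' @return A `pe_system`.
#' @export
make_fixture <- function(kind = c("two_charges", "ion_pair", "random10",
                                  "random50", "bridge_toy", "wlc_chain"),
                         seed = 1, r = NULL, L = NULL, P_nm = 2, N = 21) {
  kind <- match.arg(kind)
  params <- model_parameters()
  if (kind == "two_charges") {
    if (is.null(r)) r <- params$bjerrum
    if (is.null(L)) L <- 1000
    chains <- lapply(1:2, function(k) {
      list(idx = k, mode = "parallel_rigid", mode_code = 0L,
           persistence = Inf, P_nm = Inf, central_ord = 1L, central = k,
           axis = c(c(-r, r)[k] / 2, 0), confinement_radius = Inf,
           label = k, fsign = if (k == 1) -1 else 1)
    })
    return(.new_state(rbind(c(-r / 2, 0, 0), c(r / 2, 0, 0)),
                      valence = c(1L, 1L),
                      kind = c("mono_cation", "mono_cation"),
                      chain_id = 1:2, chains = chains, L = L,
                      periodic = FALSE, params = params,
                      separation_x = r))
  }
  if (kind == "ion_pair") {
    if (is.null(r)) r <- 2
    if (is.null(L)) L <- 10
    return(.new_state(rbind(c(-r / 2, 0, 0), c(r / 2, 0, 0)),
                      valence = c(1L, 1L),
                      kind = c("mono_cation", "mono_cation"),
                      chain_id = c(0L, 0L), chains = list(), L = L,
                      periodic = TRUE, params = params))
  }
  if (kind %in% c("random10", "random50")) {
    if (is.null(L)) L <- if (kind == "random10") 10 else 14
    counts <- if (kind == "random10") {
      c(mono_cation = 3L, mono_anion = 3L, tri_cation = 2L, tri_anion = 2L)
    } else {
      c(mono_cation = 15L, mono_anion = 15L, tri_cation = 10L,
        tri_anion = 10L)
    }
    state <- .new_state(matrix(numeric(0), 0, 3), integer(0), character(0),
                        integer(0), list(), L = L, periodic = TRUE,
                        params = params)
    return(place_ions(state, counts, seed = seed))
  }
  if (kind == "bridge_toy") {
    if (is.null(L)) L <- 30
    ch <- build_chains("parallel_rigid", x = 2, N = 5, params = params)
    state <- .new_state(ch$pos, valence = rep(-1L, 10),
                        kind = rep("monomer", 10),
                        chain_id = rep(1:2, each = 5), chains = ch$chains,
                        L = L, periodic = TRUE, params = params,
                        separation_x = 2)
    state$pos <- rbind(state$pos, c(0, 0, 0))
    state$valence <- c(state$valence, 3L)
    state$kind <- c(state$kind, "tri_cation")
    state$chain_id <- c(state$chain_id, 0L)
    return(state)
  }
  # wlc_chain: ideal discrete worm-like chain (phantom, uncharged)
  if (is.null(L)) L <- 1000
  params$lj_epsilon <- 0  # phantom chain: bending is the whole Hamiltonian
  ch <- build_chains("bendable", x = 4, P_nm = P_nm, confinement = FALSE,
                     N = N, params = params)
  chain <- ch$chains[[1]]
  chain$idx <- seq_len(N)
  chain$central <- chain$idx[chain$central_ord]
  chain$axis <- c(0, 0)
  pos <- ch$pos[seq_len(N), , drop = FALSE]
  pos[, 1] <- 0
  .new_state(pos, valence = rep(0L, N), kind = rep("monomer", N),
             chain_id = rep(1L, N), chains = list(chain), L = L,
             periodic = FALSE, params = params)
}

#' Snapshot trajectory from a single state
#'
#' Wraps the current configuration of a system as a one-snapshot
#' `pe_trajectory`, so the observable functions can be applied to a
#' deterministic configuration.
#'
#' @param state A `pe_system`.
#' @return A `pe_trajectory` with one snapshot.
#' @export
as_trajectory <- function(state) {
  traj <- list(positions = list(state$pos), sweeps = 0L,
               valence = state$valence, kind = state$kind,
               chain_id = state$chain_id, chains = state$chains,
               box = state$box, params = state$params,
               separation_x = state$separation_x,
               n_chain_beads = state$n_chain_beads)
  class(traj) <- "pe_trajectory"
  traj
}
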