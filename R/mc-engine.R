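# Metropolis sampling: ion translations, rigid chain rotations, pivot moves.

#' Monte Carlo move specification
#'
#' Step sizes, move mix and sweep counts for a run. One sweep attempts one
#' translation per mobile ion plus a number of chain (pivot / rigid
#' rotation) attempts derived from `move_mix`.
#'
#' @param ion_step Half-width of the cubic ion displacement, sigma.
#' @param pivot_max_angle Maximum pivot/rotation angle, radians.
#' @param move_mix Named probabilities `c(ion =, pivot =)` summing to 1;
#'   sets the ratio of chain-move attempts to ion-move attempts per sweep.
#' @param sweeps_equil Equilibration sweep budget.
#' @param sweeps_prod Production sweeps.
#' @param seed Integer RNG seed recorded with the run (`NULL` to continue
#'   the current RNG stream).
#' @return An object of class `pe_moves`.
#' @export
move_spec <- function(ion_step = 0.5, pivot_max_angle = 0.5,
                      move_mix = c(ion = 0.9, pivot = 0.1),
                      sweeps_equil = 5000, sweeps_prod = 10000, seed = 1) {
  stopifnot(ion_step > 0, pivot_max_angle > 0,
            all(c("ion", "pivot") %in% names(move_mix)),
            all(move_mix >= 0), abs(sum(move_mix) - 1) < 1e-8)
  m <- list(ion_step = ion_step, pivot_max_angle = pivot_max_angle,
            move_mix = move_mix, sweeps_equil = sweeps_equil,
            sweeps_prod = sweeps_prod, seed = seed)
  class(m) <- "pe_moves"
  m
}

.pivots_per_sweep <- function(state, moves) {
  movable <- any(vapply(state$chains, function(ch) ch$mode_code > 0L,
                        logical(1)))
  if (!movable) return(0L)
  n_ions <- length(.ion_indices(state))
  mix <- moves$move_mix
  if (mix[["pivot"]] <= 0) return(0L)
  if (n_ions == 0 || mix[["ion"]] <= 0) {
    return(max(2L * state$n_chain_beads, 10L))
  }
  max(1L, as.integer(round(n_ions * mix[["pivot"]] / mix[["ion"]])))
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move with probability `min(1, exp(-delta_U))`
#' (energies in kB*T). Vectorised; draws one uniform variate per element.
#'
#' @param delta_U Energy change(s) of the proposed move(s), kB*T.
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(delta_U) {
  acc <- delta_U <= 0
  hot <- !acc & is.finite(delta_U)
  if (any(hot)) acc[hot] <- runif(sum(hot)) < exp(-delta_U[hot])
  acc
}

#' Attempt one ion translation move
#'
#' Uniform displacement in a cube of half-width `ion_step`, wrapped by the
#' periodic boundary, accepted by the Metropolis rule on the incremental
#' energy change.
#'
#' @param state A `pe_system`.
#' @param ion_index Particle index of a free ion.
#' @param moves A [move_spec()] (only `ion_step` is used).
#' @return List with the updated `state` and logical `accepted`.
#' @export
ion_translation_move <- function(state, ion_index, moves = move_spec()) {
  if (state$chain_id[ion_index] != 0L) stop("particle is not a free ion")
  res <- cpp_ion_move_one(state$pos, state$valence, state$box$L,
                          state$box$periodic, state$params$bjerrum,
                          state$params$lj_epsilon, ion_index,
                          moves$ion_step)
  state$pos <- res$pos
  list(state = state, accepted = res$accepted)
}

#' Attempt one chain pivot / rigid-rotation move
#'
#' For rotatable rigid chains: a rigid rotation of the whole chain about
#' its fixed central bead around a random axis. For bendable chains: a
#' pivot rotation of the arm on the side of the pivot bead away from the
#' fixed central bead. Bond lengths are preserved exactly; the move is
#' rejected outright if any bead would leave the confinement cylinder, and
#' the fixed central bead never moves.
#'
#' @param state A `pe_system`.
#' @param chain Chain index (1 or 2).
#' @param moves A [move_spec()] (only `pivot_max_angle` is used).
#' @return List with the updated `state` and logical `accepted`.
#' @export
pivot_move <- function(state, chain = 1, moves = move_spec()) {
  ch <- state$chains[[chain]]
  if (ch$mode == "parallel_rigid") {
    stop("parallel_rigid chains are static: no pivot moves")
  }
  res <- cpp_pivot_move_one(state$pos, state$valence, state$chain_id,
                            .cpp_chains(state)[[chain]], state$box$L,
                            state$box$periodic, state$params$bjerrum,
                            state$params$lj_epsilon,
                            state$params$bond_length,
                            moves$pivot_max_angle)
  state$pos <- res$pos
  list(state = state, accepted = res$accepted)
}

# run a block of sweeps through the C++ engine and fold results back
.run_chunk <- function(state, moves, nsweeps, force_every = 1,
                       snap_every = 0, check_confinement = TRUE,
                       pivots_per_sweep = .pivots_per_sweep(state, moves)) {
  res <- cpp_run_sweeps(state$pos, state$valence, state$chain_id,
                        .cpp_chains(state), .ion_indices(state),
                        state$box$L, state$box$periodic,
                        state$params$bjerrum, state$params$lj_epsilon,
                        state$params$bond_length, as.integer(nsweeps),
                        moves$ion_step, moves$pivot_max_angle,
                        as.integer(pivots_per_sweep),
                        as.integer(force_every), as.integer(snap_every),
                        check_confinement)
  state$pos <- res$pos
  list(state = state, res = res)
}

.acc_rate <- function(acc, att) if (att > 0) acc / att else NA_real_

# step-size tuning toward 30-50% acceptance, used during equilibration only
.tune_moves <- function(moves, res, L) {
  ri <- .acc_rate(res$ion_accepts, res$ion_attempts)
  if (!is.na(ri)) {
    if (ri < 0.3) moves$ion_step <- max(moves$ion_step * 0.8, 0.01)
    if (ri > 0.5) moves$ion_step <- min(moves$ion_step * 1.2, L / 4)
  }
  rp <- .acc_rate(res$pivot_accepts, res$pivot_attempts)
  if (!is.na(rp)) {
    if (rp < 0.3) moves$pivot_max_angle <- max(moves$pivot_max_angle * 0.8,
                                               1e-4)
    if (rp > 0.5) moves$pivot_max_angle <- min(moves$pivot_max_angle * 1.2,
                                               pi)
  }
  moves
}

#' Equilibrate a system by the force-symmetry criterion
#'
#' Alternates Monte Carlo sweeps with accumulation of the per-chain
#' inter-chain forces, and declares equilibrium when the two window-averaged
#' repulsive forces agree to a relative tolerance (default 0.5%):
#' `|<F1> - <F2>| / max(|<Fbar>|, force_floor) < tol`, with the floor
#' guarding the near-zero-force crossover where a relative test is
#' ill-posed. Step sizes are auto-tuned toward 30-50% acceptance during
#' this stage and frozen afterwards.
#'
#' @param state A `pe_system` with two chains.
#' @param moves A [move_spec()]; `sweeps_equil` caps the total sweeps.
#' @param window Sliding window length (sweeps) for the force averages.
#' @param check_every Criterion evaluation period, sweeps.
#' @param tol Relative force-agreement tolerance (default 0.005).
#' @param force_floor Force scale floor, kB*T/sigma (default 0.01).
#' @param tune Auto-tune step sizes during equilibration.
#' @param on_fail `"error"` (default) to fail when the criterion is not met
#'   within `sweeps_equil`, `"warn"` to proceed with the trace attached.
#' @return List of class `pe_equilibration`: updated `state`, frozen
#'   `moves`, logical `converged`, `sweeps` used, and the force `trace`
#'   (data.frame sweep/F1/F2).
#' @export
run_until_equilibrium <- function(state, moves = move_spec(),
                                  window = 1000,
                                  check_every = max(window %/% 5, 1),
                                  tol = 0.005, force_floor = 0.01,
                                  tune = TRUE,
                                  on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  if (length(state$chains) != 2) stop("need a two-chain system")
  if (!is.null(moves$seed)) set.seed(moves$seed)
  max_sweeps <- moves$sweeps_equil
  f1 <- f2 <- sw <- numeric(0)
  total <- 0
  converged <- FALSE
  acc <- c(ion_attempts = 0, ion_accepts = 0,
           pivot_attempts = 0, pivot_accepts = 0)
  while (total < max_sweeps) {
    n <- min(check_every, max_sweeps - total)
    out <- .run_chunk(state, moves, n, force_every = 1)
    state <- out$state
    f1 <- c(f1, out$res$f1); f2 <- c(f2, out$res$f2)
    sw <- c(sw, total + out$res$force_sweep)
    total <- total + n
    acc <- acc + c(out$res$ion_attempts, out$res$ion_accepts,
                   out$res$pivot_attempts, out$res$pivot_accepts)
    if (tune) moves <- .tune_moves(moves, out$res, state$box$L)
    if (total >= window) {
      keep <- seq.int(length(f1) - window + 1, length(f1))
      m1 <- mean(f1[keep]); m2 <- mean(f2[keep])
      scale <- max(abs((m1 + m2) / 2), force_floor)
      if (abs(m1 - m2) / scale < tol) {
        converged <- TRUE
        break
      }
    }
  }
  trace <- data.frame(sweep = sw, F1 = f1, F2 = f2)
  if (!converged) {
    msg <- sprintf(paste0("force-symmetry criterion (%.3g) not met after ",
                          "%d sweeps"), tol, total)
    if (on_fail == "error") {
      cond <- simpleError(msg)
      cond$trace <- trace
      stop(cond)
    }
    warning(msg)
  }
  out <- list(state = state, moves = moves, converged = converged,
              sweeps = total, trace = trace,
              acceptance = c(ion = .acc_rate(acc[["ion_accepts"]],
                                             acc[["ion_attempts"]]),
                             pivot = .acc_rate(acc[["pivot_accepts"]],
                                               acc[["pivot_attempts"]])))
  class(out) <- "pe_equilibration"
  out
}

#' Production sampling
#'
#' Runs production sweeps with frozen step sizes, recording the per-sweep
#' inter-chain forces and periodic configuration snapshots.
#'
#' @param state An equilibrated `pe_system` (or a `pe_equilibration`, whose
#'   state and tuned moves are then used).
#' @param moves A [move_spec()]; `sweeps_prod` sets the length.
#' @param snapshot_stride Sweeps between stored snapshots (default 10).
#' @param force_every Sweeps between force samples (default 1; 0 disables).
#' @param seed Optional seed; by default the RNG stream continues.
#' @return A list of class `pe_run`: final `state`, `forces` (data.frame
#'   sweep/F1/F2/Fbar), `trajectory` (class `pe_trajectory`), acceptance
#'   rates and the confinement-violation count (always 0 in a correct run).
#' @export
run_production <- function(state, moves = move_spec(), snapshot_stride = 10,
                           force_every = 1, seed = NULL) {
  if (inherits(state, "pe_equilibration")) {
    moves <- state$moves
    state <- state$state
  }
  if (!is.null(seed)) set.seed(seed)
  out <- .run_chunk(state, moves, moves$sweeps_prod,
                    force_every = force_every,
                    snap_every = snapshot_stride)
  res <- out$res
  forces <- if (length(res$f1)) {
    data.frame(sweep = res$force_sweep, F1 = res$f1, F2 = res$f2,
               Fbar = (res$f1 + res$f2) / 2)
  } else {
    data.frame(sweep = integer(0), F1 = numeric(0), F2 = numeric(0),
               Fbar = numeric(0))
  }
  traj <- list(positions = res$snapshots, sweeps = res$snapshot_sweep,
               valence = state$valence, kind = state$kind,
               chain_id = state$chain_id, chains = state$chains,
               box = state$box, params = state$params,
               separation_x = state$separation_x,
               n_chain_beads = state$n_chain_beads)
  class(traj) <- "pe_trajectory"
  run <- list(state = out$state, forces = forces, trajectory = traj,
              acceptance = c(ion = .acc_rate(res$ion_accepts,
                                             res$ion_attempts),
                             pivot = .acc_rate(res$pivot_accepts,
                                               res$pivot_attempts)),
              confinement_violations = res$confinement_violations,
              moves = moves)
  class(run) <- "pe_run"
  run
}

#' @export
print.pe_run <- function(x, ...) {
  cat(sprintf("pe_run: %d force samples, %d snapshots at x = %g sigma\n",
              nrow(x$forces), length(x$trajectory$positions),
              x$trajectory$separation_x))
  if (nrow(x$forces)) {
    cat(sprintf("  mean Fbar = %.4g kT/sigma\n", mean(x$forces$Fbar)))
  }
  invisible(x)
}
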