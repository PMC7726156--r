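# Energy terms of the Hamiltonian. All lengths in sigma, energies in kB*T.

#' Coulomb pair energy
#'
#' Bare Coulomb interaction `lB * zi * zj / r` between two center-charged
#' particles, in kB*T. Vectorised over its arguments.
#'
#' @param zi,zj Integer particle valences (units of e; monomers are -1).
#' @param r Center-to-center distance in sigma; must be > 0.
#' @param params A [model_parameters()] object.
#' @return Energy in kB*T (positive for like charges).
#' @examples
#' p <- model_parameters()
#' coulomb_energy(1, 1, p$bjerrum, p)   # exactly 1 kT at r = l_B
#' @export
coulomb_energy <- function(zi, zj, r, params = model_parameters()) {
  if (any(r <= 0)) stop("r must be strictly positive (particle overlap)")
  params$bjerrum * zi * zj / r
}

#' Excluded-volume (WCA) pair energy
#'
#' Purely repulsive cut-and-shifted Lennard-Jones potential:
#' `4*eps*(1/r^12 - 1/r^6) + eps` for `r < 2^(1/6)` sigma, zero beyond the
#' cutoff (continuous there). Vectorised over `r`.
#'
#' @param r Center-to-center distance in sigma; must be > 0.
#' @param params A [model_parameters()] object.
#' @return Energy in kB*T.
#' @export
excluded_volume_energy <- function(r, params = model_parameters()) {
  if (any(r <= 0)) stop("r must be strictly positive")
  eps <- params$lj_epsilon
  u <- numeric(length(r))
  in_core <- r < 2^(1 / 6)
  rr <- r[in_core]
  u[in_core] <- 4 * eps * (rr^-12 - rr^-6) + eps
  u
}

#' Excluded-volume (WCA) pair force magnitude
#'
#' Radial force `-dU/dr` of [excluded_volume_energy()]:
#' `4*eps*(12/r^13 - 6/r^7)` inside the cutoff, zero beyond. Positive values
#' push the pair apart.
#'
#' @inheritParams excluded_volume_energy
#' @return Force in kB*T / sigma.
#' @export
excluded_volume_force <- function(r, params = model_parameters()) {
  if (any(r <= 0)) stop("r must be strictly positive")
  eps <- params$lj_epsilon
  f <- numeric(length(r))
  in_core <- r < 2^(1 / 6)
  rr <- r[in_core]
  f[in_core] <- 4 * eps * (12 * rr^-13 - 6 * rr^-7)
  f
}

#' Discrete worm-like-chain bending energy
#'
#' `(P / l0) * sum_i (1 - cos(theta_i))` over the internal bend angles of a
#' bead chain, where `theta_i` is the deviation-from-straight angle at bead
#' i. Rigid chains (infinite or missing persistence length) contribute zero.
#'
#' @param positions Numeric N x 3 matrix of bead positions in chain order
#'   (N >= 3 for a non-trivial result), in sigma.
#' @param persistence Persistence length P in sigma units (`Inf` for rigid).
#' @param params A [model_parameters()] object (supplies the bond length l0).
#' @return Energy in kB*T.
#' @examples
#' p <- model_parameters()
#' # one 90-degree bend at persistence 10 nm: (10 / 0.462) * 1 kT
#' pos <- rbind(c(0, 0, 0), c(0, 0, 1.1), c(1.1, 0, 1.1))
#' bending_energy(pos, persistence_sigma(10), p)
#' @export
bending_energy <- function(positions, persistence,
                           params = model_parameters()) {
  if (!is.finite(persistence)) return(0)
  if (nrow(positions) < 3) return(0)
  cpp_bending_energy(positions, persistence / params$bond_length)
}

.state_bending <- function(state) {
  u <- 0
  for (ch in state$chains) {
    if (ch$mode == "bendable" && is.finite(ch$persistence)) {
      u <- u + bending_energy(state$pos[ch$idx, , drop = FALSE],
                              ch$persistence, state$params)
    }
  }
  u
}

#' Total system energy
#'
#' Sum of Coulomb and excluded-volume terms over all distinct particle
#' pairs (minimum-image convention when the box is periodic) plus the
#' bending energy of every bendable chain. Bonded neighbours contribute
#' both pair terms like any other pair; with fixed bond lengths these are
#' constants that cancel in Metropolis energy differences.
#'
#' @param state A `pe_system` (see [build_system()] or [make_fixture()]).
#' @return Energy in kB*T.
#' @export
total_energy <- function(state) {
  u <- cpp_total_pair_energy(state$pos, state$valence, state$box$L,
                             state$box$periodic, state$params$bjerrum,
                             state$params$lj_epsilon)
  if (!is.finite(u)) stop("non-finite energy: overlapping point charges")
  u + .state_bending(state)
}

#' Incremental energy change of a single-particle move
#'
#' Energy difference of moving one particle to a proposed position,
#' evaluated incrementally (only pairs involving the moved particle, plus
#' the bending terms of its chain when it is a monomer of a bendable
#' chain). Agrees with `total_energy(after) - total_energy(before)` to
#' floating precision.
#'
#' @param state A `pe_system`.
#' @param i Particle index.
#' @param new_position Numeric length-3 proposed position (sigma units),
#'   inside the box.
#' @return Energy difference in kB*T.
#' @export
move_energy_delta <- function(state, i, new_position) {
  stopifnot(length(new_position) == 3)
  du <- cpp_move_delta_pair(state$pos, state$valence, state$box$L,
                            state$box$periodic, state$params$bjerrum,
                            state$params$lj_epsilon, i,
                            as.numeric(new_position))
  cid <- state$chain_id[i]
  if (cid > 0) {
    ch <- state$chains[[cid]]
    if (ch$mode == "bendable" && is.finite(ch$persistence)) {
      old_pos <- state$pos[ch$idx, , drop = FALSE]
      new_pos <- old_pos
      new_pos[match(i, ch$idx), ] <- new_position
      du <- du +
        bending_energy(new_pos, ch$persistence, state$params) -
        bending_energy(old_pos, ch$persistence, state$params)
    }
  }
  du
}
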