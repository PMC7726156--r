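# Construction of neutral, non-overlapping initial simulation states.

PE_MODES <- c(parallel_rigid = 0L, rotatable_rigid = 1L, bendable = 2L)

#' Particle kind labels
#'
#' @return Character vector of the five particle kinds used by the model:
#'   chain monomers (valence -1), monovalent cations/anions (+1/-1) and
#'   trivalent cations/anions (+3/-3).
#' @export
particle_kinds <- function() {
  c("monomer", "mono_cation", "mono_anion", "tri_cation", "tri_anion")
}

KIND_VALENCE <- c(monomer = -1L, mono_cation = 1L, mono_anion = -1L,
                  tri_cation = 3L, tri_anion = -3L)

#' Number of salt ion pairs for a bulk concentration
#'
#' Number of cation-anion pairs of one salt species to place in the cubic
#' box: `round(c * N_A * L^3)`. Adding cations and anions in equal numbers
#' keeps the system neutrality exact regardless of rounding.
#'
#' @param concentration_mM Salt concentration in mmol/L (>= 0).
#' @param L Box side length in sigma.
#' @param params A [model_parameters()] object (supplies sigma in nm).
#' @return Integer pair count.
#' @examples
#' ion_counts(20, 62)   # 213 pairs of 1:1 salt in the default box
#' ion_counts(5, 62)    # 53 pairs of 3:3 salt
#' @export
ion_counts <- function(concentration_mM, L, params = model_parameters()) {
  if (concentration_mM < 0) stop("concentration must be non-negative")
  side_dm <- L * params$sigma_nm * 1e-8  # nm -> dm
  volume_litre <- side_dm^3
  as.integer(round(concentration_mM * 1e-3 * 6.02214076e23 * volume_litre))
}

#' Build the two polyelectrolyte chains
#'
#' Initialises two straight N-bead chains parallel to z, centred at
#' (-x/2, 0, 0) and (+x/2, 0, 0). The central bead (ordinal (N+1)/2) of
#' each chain is fixed for the whole run. With confinement on, each chain
#' is restricted to a hard cylinder of radius R = x around its own axis,
#' modelling the steric exclusion by neighbours in a hexagonal PE array.
#'
#' @param mode One of `"parallel_rigid"` (both chains static),
#'   `"rotatable_rigid"` (rigid rods rotating about their fixed central
#'   bead; persistence length infinite) or `"bendable"` (discrete worm-like
#'   chains sampled by pivot moves).
#' @param x Center-to-center separation of the fixed central beads, sigma.
#' @param P_nm Persistence length in nm (finite for `"bendable"`; forced to
#'   `Inf` for the rigid modes).
#' @param confinement Logical; when `TRUE` the confinement radius is R = x,
#'   otherwise infinite (free chains).
#' @param N Beads per chain (odd; default 21).
#' @param params A [model_parameters()] object.
#' @return List with `pos` (2N x 3 monomer positions) and `chains` (a list
#'   of two chain descriptors).
#' @export
build_chains <- function(mode = names(PE_MODES), x, P_nm = Inf,
                         confinement = TRUE, N = 21,
                         params = model_parameters()) {
  mode <- match.arg(mode)
  if (x <= 1) stop("chains overlap: separation x must exceed sigma")
  if (N < 3 || N %% 2 == 0) stop("N must be odd and >= 3")
  if (mode == "bendable" && !is.finite(P_nm)) {
    stop("bendable chains need a finite persistence length")
  }
  if (mode != "bendable") P_nm <- Inf
  l0 <- params$bond_length
  cord <- (N + 1) / 2
  zs <- (seq_len(N) - cord) * l0
  centers <- c(-x / 2, x / 2)
  pos <- rbind(cbind(centers[1], 0, zs), cbind(centers[2], 0, zs))
  dimnames(pos) <- NULL
  chains <- lapply(1:2, function(k) {
    list(idx = (k - 1) * N + seq_len(N),
         mode = mode,
         mode_code = unname(PE_MODES[mode]),
         persistence = persistence_sigma(P_nm, params),
         P_nm = P_nm,
         central_ord = as.integer(cord),
         central = as.integer((k - 1) * N + cord),
         axis = c(centers[k], 0),
         confinement_radius = if (confinement) x else Inf,
         label = k,
         fsign = if (k == 1) -1 else 1)
  })
  list(pos = pos, chains = chains)
}

.min_image_dist2 <- function(p, mat, L, periodic) {
  d <- sweep(mat, 2, p)
  if (periodic) d <- d - L * round(d / L)
  rowSums(d^2)
}

#' Place ions uniformly at random without overlap
#'
#' Appends ions of the given kinds to a state, drawing uniform positions in
#' the box and rejecting any placement closer than sigma to an existing
#' particle. Deterministic for a given seed.
#'
#' @param state A `pe_system` (possibly containing only the chains).
#' @param counts Named integer vector of ion counts; names from
#'   [particle_kinds()] (excluding `"monomer"`).
#' @param seed Integer RNG seed (`NULL` to use the current RNG stream).
#' @param max_tries Placement attempts per ion before giving up.
#' @return The state with ions appended.
#' @export
place_ions <- function(state, counts, seed = NULL, max_tries = 2000) {
  stopifnot(all(names(counts) %in% setdiff(particle_kinds(), "monomer")))
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(state)
  L <- state$box$L
  kinds <- rep(names(counts), counts)
  n_new <- length(kinds)
  new_pos <- matrix(NA_real_, n_new, 3)
  all_pos <- state$pos
  for (a in seq_len(n_new)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- runif(3, -L / 2, L / 2)
      if (nrow(all_pos) == 0 ||
          min(.min_image_dist2(p, all_pos, L, state$box$periodic)) >= 1) {
        new_pos[a, ] <- p
        all_pos <- rbind(all_pos, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("ion placement failed: box too crowded")
  }
  state$pos <- unname(rbind(state$pos, new_pos))
  state$valence <- c(state$valence, unname(KIND_VALENCE[kinds]))
  state$kind <- c(state$kind, kinds)
  state$chain_id <- c(state$chain_id, rep(0L, n_new))
  state
}

.new_state <- function(pos, valence, kind, chain_id, chains, L,
                       periodic = TRUE, params = model_parameters(),
                       separation_x = NA_real_) {
  state <- list(pos = unname(pos), valence = as.integer(valence),
                kind = kind, chain_id = as.integer(chain_id),
                chains = chains, box = list(L = L, periodic = periodic),
                params = params, separation_x = separation_x,
                n_chain_beads = if (length(chains)) length(chains[[1]]$idx)
                                else 0L)
  class(state) <- "pe_system"
  state
}

#' Build a complete neutral simulation state
#'
#' Assembles two PE chains, their neutralising monovalent counterions
#' (2N, one per monomer charge), 1:1 buffer salt and 3:3 trivalent salt at
#' the requested bulk concentrations, in a periodic cubic box. The
#' resulting system is exactly neutral.
#'
#' @inheritParams build_chains
#' @param c11_mM 1:1 monovalent salt concentration, mM (default 20).
#' @param c33_mM 3:3 trivalent salt concentration, mM (default 0).
#' @param L Box side length in sigma (default 62).
#' @param seed Integer seed for the random ion placement.
#' @return A `pe_system` object.
#' @examples
#' \donttest{
#' sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 30, seed = 1)
#' sum(sys$valence)  # 0: exact neutrality
#' }
#' @export
build_system <- function(mode = names(PE_MODES), x, P_nm = Inf,
                         c11_mM = 20, c33_mM = 0, L = 62,
                         confinement = TRUE, N = 21, seed = 1,
                         params = model_parameters()) {
  mode <- match.arg(mode)
  ch <- build_chains(mode, x, P_nm, confinement, N, params)
  n_mono <- 2 * N
  state <- .new_state(ch$pos,
                      valence = rep(-1L, n_mono),
                      kind = rep("monomer", n_mono),
                      chain_id = rep(1:2, each = N),
                      chains = ch$chains, L = L, periodic = TRUE,
                      params = params, separation_x = x)
  n11 <- ion_counts(c11_mM, L, params)
  n33 <- ion_counts(c33_mM, L, params)
  counts <- c(mono_cation = n_mono + n11, mono_anion = n11,
              tri_cation = n33, tri_anion = n33)
  state <- place_ions(state, counts, seed = seed)
  stopifnot(sum(state$valence) == 0L)
  state
}

#' @export
print.pe_system <- function(x, ...) {
  n <- nrow(x$pos)
  cat(sprintf("pe_system: %d particles in L = %g sigma box (%s)\n",
              n, x$box$L, if (x$box$periodic) "periodic" else "open"))
  if (length(x$chains)) {
    ch <- x$chains[[1]]
    cat(sprintf("  chains  : 2 x %d beads, mode %s, P = %s nm, R_conf = %s\n",
                length(ch$idx), ch$mode,
                format(ch$P_nm), format(ch$confinement_radius)))
    cat(sprintf("  x       : %g sigma\n", x$separation_x))
  }
  tb <- table(x$kind)
  cat("  kinds   :", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  net charge: %d e\n", sum(x$valence)))
  invisible(x)
}

# chain descriptors in the form consumed by the C++ engine
.cpp_chains <- function(state) {
  lapply(state$chains, function(ch) {
    kb <- if (ch$mode == "bendable" && is.finite(ch$persistence)) {
      ch$persistence / state$params$bond_length
    } else 0
    list(idx = as.integer(ch$idx), mode_code = ch$mode_code, kbend = kb,
         central_ord = ch$central_ord, axis_x = ch$axis[1],
         axis_y = ch$axis[2], confinement_radius = ch$confinement_radius,
         fsign = ch$fsign, label = ch$label)
  })
}

.ion_indices <- function(state) {
  which(state$chain_id == 0L)
}
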