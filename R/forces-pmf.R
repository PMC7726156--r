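# Mean inter-chain forces and their integration into potentials of mean force.

#' Instantaneous inter-chain force on one chain
#'
#' Sums the Coulomb and excluded-volume forces exerted on every monomer of
#' the chain by all particles not belonging to it (the other chain's
#' monomers, counterions and salt ions; intra-chain interactions are
#' internal and excluded), and projects the net force on the x-axis with
#' the repulsive direction (away from the other chain) counted positive.
#'
#' @param state A `pe_system`.
#' @param chain Chain index (1 or 2).
#' @param project Return the signed x-projection (default); `FALSE` returns
#'   the raw force vector.
#' @return Force in kB*T/sigma (positive = repulsive), or a length-3 vector.
#' @export
chain_force <- function(state, chain = 1, project = TRUE) {
  ch <- state$chains[[chain]]
  fv <- cpp_chain_force_vec(state$pos, state$valence, state$chain_id,
                            ch$label, state$box$L, state$box$periodic,
                            state$params$bjerrum, state$params$lj_epsilon)
  if (!all(is.finite(fv))) stop("non-finite force: particle overlap")
  if (!project) return(fv)
  ch$fsign * fv[1]
}

.block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  n_blocks <- max(2, min(n_blocks, n))
  blk <- floor(seq_along(x) * n_blocks / n - 1e-9) + 1
  bm <- tapply(x, blk, mean)
  sd(bm) / sqrt(length(bm))
}

#' Ensemble-averaged inter-chain force
#'
#' Averages the two-chain mean force `Fbar = (F1 + F2)/2` over production
#' samples, with a block-averaged standard error.
#'
#' @param run A `pe_run` (from [run_production()]) or a data.frame with an
#'   `Fbar` column.
#' @param separation_x Chain separation in sigma (taken from the run when
#'   available).
#' @param n_blocks Number of blocks for the standard error (default 20).
#' @return A one-row data.frame of class `pe_force_record`:
#'   `separation_x`, `mean_force`, `std_error`, `n_samples`.
#' @export
mean_force <- function(run, separation_x = NULL, n_blocks = 20) {
  if (inherits(run, "pe_run")) {
    if (is.null(separation_x)) separation_x <- run$trajectory$separation_x
    samples <- run$forces$Fbar
  } else {
    samples <- run$Fbar
  }
  if (length(samples) == 0) stop("no force samples")
  rec <- data.frame(separation_x = separation_x,
                    mean_force = mean(samples),
                    std_error = .block_se(samples, n_blocks),
                    n_samples = length(samples))
  class(rec) <- c("pe_force_record", "data.frame")
  rec
}

#' Integrate mean forces into a potential of mean force
#'
#' Trapezoidal integration of the ensemble-averaged force from the outer
#' reference separation down the grid:
#' `PMF(x) = integral from x to x_ref of <Fbar> dx`, with
#' `PMF(x_ref) = 0` exactly. Standard errors are propagated assuming
#' independent grid points.
#'
#' @param records Force records (rows of [mean_force()] output, or any
#'   data.frame with `separation_x`, `mean_force` and optionally
#'   `std_error`), covering `x_ref`.
#' @param x_ref Reference separation in sigma (default 8).
#' @return Data.frame of class `pe_pmf` with columns `separation_x`, `pmf`
#'   (kB*T) and `std_error`; attribute `x_ref`.
#' @export
integrate_pmf <- function(records, x_ref = 8) {
  records <- records[order(records$separation_x), , drop = FALSE]
  x <- records$separation_x
  f <- records$mean_force
  se <- if ("std_error" %in% names(records)) records$std_error else
    rep(0, length(x))
  se[is.na(se)] <- 0
  if (!any(abs(x - x_ref) < 1e-9)) {
    stop("separation grid must include the reference separation x_ref")
  }
  cum <- pracma::cumtrapz(x, f)[, 1]       # integral from x[1] to x[k]
  ref <- cum[which.min(abs(x - x_ref))]
  pmf <- ref - cum                          # = integral from x[k] to x_ref
  # variance of each trapezoid term, accumulated away from x_ref
  k_ref <- which.min(abs(x - x_ref))
  var_step <- c(0, (diff(x) / 2)^2 * (se[-length(se)]^2 + se[-1]^2))
  pvar <- numeric(length(x))
  if (k_ref > 1) {
    for (k in seq(k_ref - 1, 1)) pvar[k] <- pvar[k + 1] + var_step[k + 1]
  }
  if (k_ref < length(x)) {
    for (k in seq(k_ref + 1, length(x))) pvar[k] <- pvar[k - 1] + var_step[k]
  }
  out <- data.frame(separation_x = x, pmf = pmf, std_error = sqrt(pvar))
  attr(out, "x_ref") <- x_ref
  class(out) <- c("pe_pmf", "data.frame")
  out
}
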