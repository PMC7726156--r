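#' Physical model parameters
#'
#' Collects the physical constants and pair-potential parameters of the
#' coarse-grained model. All chain/ion beads share one diameter `sigma`;
#' monomers carry charge -e. Lengths other than `sigma_nm` and
#' `bjerrum_nm` are given in units of sigma, energies in kB*T.
#'
#' @param sigma_nm Bead/ion diameter in nm (default 0.42).
#' @param bjerrum_nm Bjerrum length in nm (default 0.714, water at 300 K).
#' @param temperature Absolute temperature in K (default 300; informational,
#'   since energies are expressed in kB*T).
#' @param lj_epsilon WCA (truncated Lennard-Jones) epsilon in kB*T
#'   (default 5/6).
#' @param bond_length Fixed bond length l0 between adjacent monomers, in
#'   sigma (default 1.1).
#' @param bridging_cutoff Cutoff r_c used to classify bridging ions, in
#'   sigma (default 1.5).
#' @param reference_separation Outer reference separation x_ref for PMF
#'   integration, in sigma (default 8).
#'
#' @return An object of class `pe_params`: a list with the above fields plus
#'   `bjerrum`, the Bjerrum length converted to sigma units.
#' @examples
#' p <- model_parameters()
#' p$bjerrum  # 0.714 / 0.42 = 1.7 sigma
#' @export
model_parameters <- function(sigma_nm = 0.42, bjerrum_nm = 0.714,
                             temperature = 300, lj_epsilon = 5 / 6,
                             bond_length = 1.1, bridging_cutoff = 1.5,
                             reference_separation = 8) {
  vals <- c(sigma_nm = sigma_nm, bjerrum_nm = bjerrum_nm,
            temperature = temperature, lj_epsilon = lj_epsilon,
            bond_length = bond_length, bridging_cutoff = bridging_cutoff,
            reference_separation = reference_separation)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all model parameters must be finite and strictly positive")
  }
  p <- list(sigma_nm = sigma_nm, bjerrum_nm = bjerrum_nm,
            bjerrum = bjerrum_nm / sigma_nm, temperature = temperature,
            lj_epsilon = lj_epsilon, bond_length = bond_length,
            bridging_cutoff = bridging_cutoff,
            reference_separation = reference_separation)
  class(p) <- "pe_params"
  p
}

#' @export
print.pe_params <- function(x, ...) {
  cat("Coarse-grained PE model parameters\n")
  cat(sprintf("  sigma            : %.4g nm\n", x$sigma_nm))
  cat(sprintf("  Bjerrum length   : %.4g nm = %.4g sigma\n",
              x$bjerrum_nm, x$bjerrum))
  cat(sprintf("  temperature      : %g K\n", x$temperature))
  cat(sprintf("  WCA epsilon      : %.4g kT\n", x$lj_epsilon))
  cat(sprintf("  bond length l0   : %.4g sigma\n", x$bond_length))
  cat(sprintf("  bridging cutoff  : %.4g sigma\n", x$bridging_cutoff))
  cat(sprintf("  reference x_ref  : %.4g sigma\n", x$reference_separation))
  invisible(x)
}

#' Convert a persistence length in nm to sigma units
#'
#' @param P_nm Persistence length in nm (may be `Inf`).
#' @param params A [model_parameters()] object.
#' @return Persistence length in sigma units.
#' @export
persistence_sigma <- function(P_nm, params = model_parameters()) {
  P_nm / params$sigma_nm
}
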