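# Extended-XYZ trajectory output; species column encodes the particle kind.

XYZ_SPECIES <- c(monomer = "M", mono_cation = "C1", mono_anion = "A1",
                 tri_cation = "C3", tri_anion = "A3")

#' Write a trajectory in extended-XYZ format
#'
#' One frame per snapshot; the comment line carries the (cubic) lattice,
#' the column layout, the sweep index and the imposed separation. Columns:
#' species token (encodes the particle kind), x, y, z (sigma units) and
#' the chain id (0 for free ions).
#'
#' @param traj A `pe_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "pe_trajectory"))
  n <- nrow(traj$positions[[1]])
  sp <- unname(XYZ_SPECIES[traj$kind])
  L <- traj$box$L
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_along(traj$positions)) {
    p <- traj$positions[[s]]
    writeLines(as.character(n), con)
    writeLines(sprintf(
      paste0("Lattice=\"%g 0 0 0 %g 0 0 0 %g\" ",
             "Properties=species:S:1:pos:R:3:chain:I:1 ",
             "sweep=%d separation_x=%g"),
      L, L, L, traj$sweeps[s], traj$separation_x), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %d", sp, p[, 1], p[, 2],
                       p[, 3], traj$chain_id), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_xyz()]
#'
#' Rebuilds a minimal `pe_trajectory` (positions, kinds, valences, chain
#' membership, box) sufficient for the observable functions.
#'
#' @param path File path.
#' @param params A [model_parameters()] object for the reconstructed
#'   trajectory.
#' @return A `pe_trajectory`.
#' @export
read_xyz <- function(path, params = model_parameters()) {
  lines <- readLines(path)
  pos_list <- list()
  sweeps <- integer(0)
  i <- 1
  first <- TRUE
  kind <- chain_id <- NULL
  L <- NA_real_
  sep_x <- NA_real_
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    body <- lines[(i + 2):(i + 1 + n)]
    fields <- strsplit(body, " +")
    p <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (first) {
      sp <- vapply(fields, `[`, character(1), 1)
      kind <- names(XYZ_SPECIES)[match(sp, XYZ_SPECIES)]
      chain_id <- as.integer(vapply(fields, `[`, character(1), 5))
      L <- as.numeric(sub(".*Lattice=\"([0-9.eE+-]+) .*", "\\1", comment))
      sx <- sub(".*separation_x=([0-9.eE+-]+).*", "\\1", comment)
      sep_x <- suppressWarnings(as.numeric(sx))
      first <- FALSE
    }
    sweeps <- c(sweeps,
                as.integer(sub(".*sweep=([0-9]+).*", "\\1", comment)))
    pos_list[[length(pos_list) + 1]] <- p
    i <- i + 2 + n
  }
  chains <- lapply(sort(unique(chain_id[chain_id > 0])), function(k) {
    idx <- which(chain_id == k)
    list(idx = idx, mode = "unknown", mode_code = 0L, persistence = Inf,
         P_nm = Inf, central_ord = as.integer((length(idx) + 1) / 2),
         central = idx[(length(idx) + 1) / 2], axis = c(NA_real_, NA_real_),
         confinement_radius = Inf, label = k,
         fsign = if (k == 1) -1 else 1)
  })
  traj <- list(positions = pos_list, sweeps = sweeps,
               valence = unname(KIND_VALENCE[kind]), kind = kind,
               chain_id = chain_id, chains = chains,
               box = list(L = L, periodic = TRUE), params = params,
               separation_x = sep_x,
               n_chain_beads = if (length(chains))
                 length(chains[[1]]$idx) else 0L)
  class(traj) <- "pe_trajectory"
  traj
}
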