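# Independent brute-force oracles coded at the R level, used to check the
# compiled energy/force kernels.

# total pair energy: explicit double loop, minimum image, Coulomb + WCA
oracle_pair_energy <- function(state) {
  pos <- state$pos
  z <- state$valence
  L <- state$box$L
  per <- state$box$periodic
  lB <- state$params$bjerrum
  eps <- state$params$lj_epsilon
  n <- nrow(pos)
  u <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- pos[i, ] - pos[j, ]
      if (per) d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      u <- u + lB * z[i] * z[j] / r
      if (r < 2^(1 / 6)) u <- u + 4 * eps * (r^-12 - r^-6) + eps
    }
  }
  u
}

# force vector on the beads of one chain from all off-chain particles
oracle_chain_force <- function(state, chain) {
  pos <- state$pos
  z <- state$valence
  L <- state$box$L
  per <- state$box$periodic
  lB <- state$params$bjerrum
  eps <- state$params$lj_epsilon
  lab <- state$chains[[chain]]$label
  f <- c(0, 0, 0)
  for (i in which(state$chain_id == lab)) {
    for (j in which(state$chain_id != lab)) {
      d <- pos[i, ] - pos[j, ]
      if (per) d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      fmag <- lB * z[i] * z[j] / r^2
      if (r < 2^(1 / 6)) fmag <- fmag + 4 * eps * (12 * r^-13 - 6 * r^-7)
      f <- f + fmag * d / r
    }
  }
  f
}

# internal deviation-from-straight angles of a bead chain
chain_angles <- function(pos) {
  n <- nrow(pos)
  b <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  vapply(seq_len(n - 2), function(m) {
    c1 <- sum(b[m, ] * b[m + 1, ]) /
      sqrt(sum(b[m, ]^2) * sum(b[m + 1, ]^2))
    acos(pmin(pmax(c1, -1), 1))
  }, numeric(1))
}

bond_lengths <- function(pos) {
  n <- nrow(pos)
  sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
}

# minimum pairwise distance under the minimum-image convention
min_pair_dist <- function(pos, L, periodic) {
  n <- nrow(pos)
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[seq.int(i + 1, n), , drop = FALSE], 2, pos[i, ])
    if (periodic) d <- d - L * round(d / L)
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}
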