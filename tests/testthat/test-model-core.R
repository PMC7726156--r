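# Energy terms of the Hamiltonian: pair potentials, bending, totals,
# incremental deltas.

p <- model_parameters()

test_that("Coulomb pair energy follows lB * zi * zj / r", {
  expect_equal(coulomb_energy(1, 1, p$bjerrum), 1.0)
  expect_equal(coulomb_energy(3, -1, p$bjerrum), -3.0)
  expect_equal(coulomb_energy(1, 1, 2 * p$bjerrum), 0.5)
  # symmetry under particle exchange
  expect_identical(coulomb_energy(3, -1, 0.8), coulomb_energy(-1, 3, 0.8))
  expect_error(coulomb_energy(1, 1, 0), "overlap")
})

test_that("excluded-volume energy is the shifted LJ core, zero past 2^(1/6)", {
  expect_equal(excluded_volume_energy(1), p$lj_epsilon)       # 5/6 at contact
  expect_identical(excluded_volume_energy(2^(1 / 6)), 0)
  expect_identical(excluded_volume_energy(3), 0)
  # direct evaluation of the formula at r = 0.9 sigma
  eps <- p$lj_epsilon
  expect_equal(excluded_volume_energy(0.9),
               4 * eps * (0.9^-12 - 0.9^-6) + eps)
  # continuity approaching the cutoff from inside
  expect_lt(abs(excluded_volume_energy(2^(1 / 6) - 1e-8)), 1e-6)
  # repulsive force is the analytic derivative, continuous at the cutoff
  expect_equal(excluded_volume_force(0.9),
               4 * eps * (12 * 0.9^-13 - 6 * 0.9^-7))
  expect_lt(excluded_volume_force(2^(1 / 6) - 1e-8), 1e-6)
  expect_identical(excluded_volume_force(1.2), 0)
})

test_that("bending energy is (P/l0) * sum(1 - cos theta)", {
  l0 <- p$bond_length
  straight <- cbind(0, 0, (0:4) * l0)
  expect_identical(bending_energy(straight, persistence_sigma(10)), 0)
  expect_identical(bending_energy(straight, Inf), 0)
  # one 90-degree bend, P = 10 nm, l0 = 0.462 nm -> (10 / 0.462) * 1
  bent90 <- rbind(c(0, 0, 0), c(0, 0, l0), c(l0, 0, l0))
  expect_equal(bending_energy(bent90, persistence_sigma(10)),
               10 / (0.462), tolerance = 1e-10)
  # one 60-degree bend, P = 2 nm -> (2 / 0.462) * 0.5
  b2 <- c(sin(pi / 3), 0, cos(pi / 3)) * l0
  bent60 <- rbind(c(0, 0, 0), c(0, 0, l0), c(0, 0, l0) + b2)
  expect_equal(bending_energy(bent60, persistence_sigma(2)),
               (2 / 0.462) * 0.5, tolerance = 1e-10)
})

test_that("total energy matches a hand-coded pair sum", {
  # two isolated +1 charges at r = l_B
  two <- make_fixture("two_charges")
  expect_equal(total_energy(two), 1.0)
  # 3-particle fixture: +3, -1, +1 in an open box
  st <- make_fixture("two_charges")
  st$pos <- rbind(c(0, 0, 0), c(1.05, 0, 0), c(0, 2, 0))
  st$valence <- c(3L, -1L, 1L)
  st$kind <- c("tri_cation", "mono_anion", "mono_cation")
  st$chain_id <- c(0L, 0L, 0L)
  st$chains <- list()
  expect_equal(total_energy(st), oracle_pair_energy(st), tolerance = 1e-12)
  # random neutral ion mixtures under periodic boundaries
  for (seed in 1:3) {
    st <- make_fixture("random10", seed = seed)
    expect_equal(total_energy(st), oracle_pair_energy(st), tolerance = 1e-10)
  }
})

test_that("energy is invariant under whole-lattice translations", {
  st <- make_fixture("random50", seed = 4)
  u0 <- total_energy(st)
  for (shift in list(c(st$box$L, 0, 0), c(0, -st$box$L, 0),
                     c(st$box$L, st$box$L, -st$box$L))) {
    st2 <- st
    st2$pos <- sweep(st$pos, 2, shift, `+`)
    expect_equal(total_energy(st2), u0, tolerance = 1e-9)
  }
})

test_that("incremental move delta equals the full recomputation", {
  st <- make_fixture("random50", seed = 7)
  # null move
  expect_equal(move_energy_delta(st, 5, st$pos[5, ]), 0)
  set.seed(99)
  u <- total_energy(st)
  n_done <- 0
  while (n_done < 50) {
    i <- sample(nrow(st$pos), 1)
    newp <- st$pos[i, ] + runif(3, -1, 1)
    newp <- newp - st$box$L * floor(newp / st$box$L + 0.5)
    # skip proposals into a hard-core overlap: those are always rejected by
    # the sampler, and the astronomically large WCA terms they create make
    # any finite-precision comparison vacuous
    d2 <- pebridge:::.min_image_dist2(newp, st$pos[-i, , drop = FALSE],
                                      st$box$L, TRUE)
    if (min(d2) < 0.25) next
    du <- move_energy_delta(st, i, newp)
    st2 <- st
    st2$pos[i, ] <- newp
    u2 <- total_energy(st2)
    expect_lt(abs(du - (u2 - u)), 1e-9)
    st <- st2
    u <- u2
    n_done <- n_done + 1
  }
})

test_that("deltas telescope along a reversible move path", {
  st <- make_fixture("random10", seed = 2)
  u0 <- total_energy(st)
  set.seed(3)
  path <- lapply(1:10, function(k) {
    i <- sample(nrow(st$pos), 1)
    list(i = i, to = st$pos[i, ] + runif(3, -0.5, 0.5))
  })
  total_du <- 0
  for (stp in path) {
    total_du <- total_du + move_energy_delta(st, stp$i, stp$to)
    st$pos[stp$i, ] <- stp$to
  }
  expect_equal(u0 + total_du, total_energy(st), tolerance = 1e-9)
})

test_that("delta of an expanding like-charge system is negative", {
  st <- make_fixture("random10", seed = 5)
  # strip to cations only so every interaction is repulsive
  keep <- st$valence > 0
  st$pos <- st$pos[keep, , drop = FALSE]
  st$valence <- st$valence[keep]
  st$kind <- st$kind[keep]
  st$chain_id <- st$chain_id[keep]
  st$box$periodic <- FALSE
  # push one particle directly away from the cloud centre
  ctr <- colMeans(st$pos)
  i <- 1
  dir <- st$pos[i, ] - ctr
  dir <- dir / sqrt(sum(dir^2))
  expect_lt(move_energy_delta(st, i, st$pos[i, ] + 5 * dir), 0)
})

test_that("bendable-chain move delta includes the bending term", {
  st <- make_fixture("wlc_chain", P_nm = 10, N = 5)
  i <- st$chains[[1]]$idx[1]  # end bead
  newp <- st$pos[i, ] + c(0.4, 0, 0)
  du <- move_energy_delta(st, i, newp)
  st2 <- st
  st2$pos[i, ] <- newp
  expect_equal(du, total_energy(st2) - total_energy(st), tolerance = 1e-9)
  expect_gt(du, 0)  # bending a straight stiff chain costs energy
})
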