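# Structural observables: charge fraction profiles, effective separation,
# bridging ions.

# two 21-bead rods with all ions stripped; helper for deterministic profiles
bare_rods <- function(x = 2, L = 30) {
  sys <- build_system("parallel_rigid", x = x, c11_mM = 0, c33_mM = 0,
                      L = L, seed = 1)
  keep <- sys$chain_id > 0
  sys$pos <- sys$pos[keep, , drop = FALSE]
  sys$valence <- sys$valence[keep]
  sys$kind <- sys$kind[keep]
  sys$chain_id <- sys$chain_id[keep]
  sys
}

add_ion <- function(sys, at, kind) {
  val <- c(monomer = -1L, mono_cation = 1L, mono_anion = -1L,
           tri_cation = 3L, tri_anion = -3L)[[kind]]
  sys$pos <- rbind(sys$pos, at)
  sys$valence <- c(sys$valence, val)
  sys$kind <- c(sys$kind, kind)
  sys$chain_id <- c(sys$chain_id, 0L)
  sys
}

test_that("a single cation at 0.5 sigma contributes f = 1/42 beyond it", {
  sys <- bare_rods()
  # 0.5 sigma from the central bead of chain 1, on its outward side
  sys <- add_ion(sys, c(-1.5, 0, 0), "mono_cation")
  prof <- charge_fraction_profile(as_trajectory(sys), r_max = 3)
  expect_equal(prof$f[prof$r >= 0.5], rep(1 / 42, sum(prof$r >= 0.5)))
  expect_equal(prof$f[prof$r < 0.45], rep(0, sum(prof$r < 0.45)))
})

test_that("anion-only configurations give non-positive f everywhere", {
  sys <- bare_rods()
  sys <- add_ion(sys, c(-1.6, 0, 0), "mono_anion")
  sys <- add_ion(sys, c(2.2, 0.4, 3), "tri_anion")
  prof <- charge_fraction_profile(as_trajectory(sys))
  expect_true(all(prof$f <= 0))
})

test_that("f reaches 1 at full range for any neutral configuration", {
  sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 20, seed = 3)
  prof <- charge_fraction_profile(as_trajectory(sys))
  expect_equal(prof$f[nrow(prof)], 1, tolerance = 1e-12)
})

test_that("delta_f is zero for identical profiles and checks grids", {
  sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 20, seed = 3)
  prof <- charge_fraction_profile(as_trajectory(sys), r_max = 5)
  d <- delta_f(prof, prof)
  expect_equal(d$delta_f, rep(0, nrow(d)))
  shifted <- prof
  shifted$r <- shifted$r + 0.05
  expect_error(delta_f(prof, shifted), "grid")
})

test_that("effective separation equals x exactly for parallel rods", {
  for (x in c(2, 3.5, 8)) {
    sys <- bare_rods(x = x)
    ds <- effective_separation(as_trajectory(sys))
    expect_identical(ds$D_mean, x)
    expect_identical(ds$D_sd, NA_real_)  # single snapshot
  }
})

test_that("effective separation of perpendicular rods matches geometry", {
  sys <- bare_rods(x = 10, L = 60)
  idx2 <- sys$chains[[2]]$idx
  l0 <- sys$params$bond_length
  # rotate chain 2 by 90 degrees about its centre: now along the x axis
  sys$pos[idx2, ] <- cbind(5 + ((1:21) - 11) * l0, 0, 0)
  ds <- effective_separation(as_trajectory(sys))
  i <- (1:21) - 11
  exact <- mean(sqrt((10 + i * l0)^2 + (i * l0)^2))
  expect_equal(ds$D_mean, exact, tolerance = 1e-12)
  expect_gt(ds$D_mean, 10)  # rotation increases the effective separation
})

test_that("bridging ions are counted when within cutoff of both chains", {
  toy <- make_fixture("bridge_toy")   # one trivalent at the midpoint
  nb <- bridging_ions(as_trajectory(toy))
  expect_identical(nb$per_snapshot, 1L)
  expect_equal(nb$Nb_mean, 1)
  # ion near only one chain is not a bridge
  toy2 <- toy
  toy2$pos[nrow(toy2$pos), ] <- c(-3, 0, 0)  # outside chain 2's cutoff
  expect_identical(bridging_ions(as_trajectory(toy2))$per_snapshot, 0L)
  expect_error(bridging_ions(as_trajectory(toy), cutoff = -1), "positive")
})

test_that("seven bridging trivalents carry half the chain charge", {
  sys <- bare_rods(x = 2)
  for (z in seq(-7.5, 7.5, by = 2.5)) {
    sys <- add_ion(sys, c(0, 0, z), "tri_cation")
  }
  nb <- bridging_ions(as_trajectory(sys))
  expect_equal(nb$Nb_mean, 7)
  expect_equal(nb$charge_fraction, 0.5)  # 3 * 7 / 42
})

test_that("bridging counts from a sampled run are integers in range", {
  sys <- build_system("parallel_rigid", x = 2, c33_mM = 5, L = 16, seed = 4)
  n_tri <- sum(sys$kind == "tri_cation")
  run <- run_production(sys, move_spec(sweeps_prod = 150, seed = 9),
                        snapshot_stride = 5)
  nb <- bridging_ions(run$trajectory)
  expect_type(nb$per_snapshot, "integer")
  expect_true(all(nb$per_snapshot >= 0 & nb$per_snapshot <= n_tri))
  expect_equal(nb$charge_fraction, 3 * nb$Nb_mean / 42)
})
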