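test_that("both kernels vanish with zero force at the cutoff", {
  expect_identical(lj_shifted(1.2, 0.47, 3.5), 0)
  expect_identical(lj_shifted(1.5, 0.47, 3.5), 0)
  expect_identical(coulomb_shifted(1.2, -1, 1), 0)
  expect_identical(coulomb_shifted(2, -1, 1), 0)
  # C1 continuity approaching the cutoff
  d <- 1e-6
  expect_lt(abs(lj_shifted(1.2 - d, 0.47, 3.5)), 1e-8)
  expect_lt(abs(lj_force_shifted(1.2 - d, 0.47, 3.5)), 1e-6)
  expect_lt(abs(coulomb_shifted(1.2 - d, -1, 1)), 1e-8)
  expect_lt(abs(coulomb_force_shifted(1.2 - d, -1, 1)), 1e-6)
  expect_error(lj_shifted(-0.1, 0.47, 3.5), "positive")
  expect_error(coulomb_shifted(0.5, 1, 1, eps_r = 0), "eps_r")
})

test_that("shifted potentials equal the quadrature of their shifted forces", {
  for (r0 in c(0.5, 0.8, 1.0)) {
    q <- stats::integrate(function(s) lj_force_shifted(s, 0.47, 3.5), r0, 1.2,
                          rel.tol = 1e-11)$value
    expect_equal(lj_shifted(r0, 0.47, 3.5), q, tolerance = 1e-8)
  }
  for (r0 in c(0.4, 0.6, 1.1)) {
    q <- stats::integrate(function(s) coulomb_force_shifted(s, -1, 1, 15), r0, 1.2,
                          rel.tol = 1e-11)$value
    expect_equal(coulomb_shifted(r0, -1, 1, 15), q, tolerance = 1e-8)
  }
  # like charges repel everywhere inside the cutoff
  r <- seq(0.05, 1.19, by = 0.02)
  expect_true(all(coulomb_shifted(r, 1, 1) > 0))
})

test_that("group interactions match the brute-force O(N^2) oracle exactly", {
  # <= 50-bead toy frame
  sys <- small_system(n_lipids = 4, chol_fraction = 0.25, n_frames = 1, seed = 81)
  fr <- npmembrane:::traj_frames(sys$traj)[[1]]
  top <- sys$topology
  a <- select_beads(top, species = "DPPC")
  b <- select_beads(top, species = "CHOL")
  got <- group_interaction(fr, top, a, b)
  want <- brute_force_energy(fr, top, a, b)
  expect_equal(got$total, want$total, tolerance = 1e-12)
  expect_equal(got$vdw, want$vdw, tolerance = 1e-12)
  expect_equal(got$coulomb, want$coulomb, tolerance = 1e-12)
  expect_equal(got$n_molecules, want$n_molecules)
  # ~500-bead frame with an NP
  sys2 <- small_system(n_lipids = 30, chol_fraction = 0.2, n_frames = 1, seed = 82)
  np <- gen_np(np_spec(core_diameter = 1.6, n_mus = 8, n_ot = 4,
                       ligand_length_beads = c(mus = 3, ot = 2)), seed = 83)
  comb <- insert_np(sys2$traj, sys2$topology, np)
  fr2 <- npmembrane:::traj_frames(comb$traj)[[1]]
  a2 <- select_beads(comb$topology, species = c("NP_core", "MUS", "OT"))
  b2 <- select_beads(comb$topology, species = c("DPPC", "CHOL"))
  expect_lte(length(unique(comb$traj$bead)), 520)
  got2 <- group_interaction(fr2, comb$topology, a2, b2)
  want2 <- brute_force_energy(fr2, comb$topology, a2, b2)
  expect_equal(got2$total, want2$total, tolerance = 1e-12)
  expect_equal(got2$n_molecules, want2$n_molecules)
})

test_that("group energy is symmetric, cutoff-local, and guards its inputs", {
  sys <- small_system(n_lipids = 16, chol_fraction = 0.25, n_frames = 1, seed = 84)
  fr <- npmembrane:::traj_frames(sys$traj)[[1]]
  top <- sys$topology
  a <- select_beads(top, species = "DPPC")
  b <- select_beads(top, species = "CHOL")
  expect_equal(group_interaction(fr, top, a, b)$total,
               group_interaction(fr, top, b, a)$total, tolerance = 1e-9)
  expect_error(group_interaction(fr, top, a, a), "disjoint")
  # two isolated beads beyond the cutoff: zero energy, undefined normalization
  top2 <- topology(bead = 1:2, molecule_id = 1:2, species = "W",
                   role = c("tail", "tail"))
  fr2 <- tibble::tibble(time = 0, bead = 1:2, x = c(1, 3), y = 1, z = 1)
  attr(fr2, "box") <- c(10, 10, 10)
  res <- group_interaction(fr2, top2, 1L, 2L)
  expect_equal(res$total, 0)
  expect_equal(res$n_molecules, 0)
  expect_true(is.na(res$normalized))
  # cutoff locality: moving a bead farther than cutoff + displacement from
  # both groups leaves the energy bitwise unchanged
  top4 <- topology(bead = 1:4, molecule_id = c(1, 1, 2, 3),
                   species = c("DPPC", "DPPC", "CHOL", "CHOL"),
                   role = c("tail", "tail", "sterol", "sterol"))
  fr4 <- tibble::tibble(time = 0, bead = 1:4,
                        x = c(1, 1.5, 2, 7), y = c(1, 1, 1, 7), z = c(1, 1, 1, 7))
  attr(fr4, "box") <- c(15, 15, 15)
  base <- group_interaction(fr4, top4, 1:2, 3:4)
  fr5 <- fr4
  fr5$z[4] <- fr5$z[4] + 1.5   # still beyond cutoff of everything
  attr(fr5, "box") <- attr(fr4, "box")
  expect_identical(group_interaction(fr5, top4, 1:2, 3:4), base)
})

test_that("epsilon scaling is exactly linear in the vdW component", {
  sys <- small_system(n_lipids = 10, chol_fraction = 0.2, n_frames = 1, seed = 85)
  fr <- npmembrane:::traj_frames(sys$traj)[[1]]
  a <- select_beads(sys$topology, species = "DPPC")
  b <- select_beads(sys$topology, species = "CHOL")
  p1 <- pair_params()
  t2 <- p1$table; t2$epsilon <- 2 * t2$epsilon
  p2 <- pair_params(table = t2)
  r1 <- group_interaction(fr, sys$topology, a, b, p1)
  r2 <- group_interaction(fr, sys$topology, a, b, p2)
  expect_equal(r2$vdw, 2 * r1$vdw, tolerance = 1e-12)
  expect_equal(r2$coulomb, r1$coulomb, tolerance = 1e-12)
})

test_that("interaction report averages frames and prints N/A for absent CHOL", {
  sys <- small_system(n_lipids = 40, chol_fraction = 0, n_frames = 3, seed = 86)
  np <- gen_np(np_spec(core_diameter = 1.6, n_mus = 8, n_ot = 4,
                       ligand_length_beads = c(mus = 3, ot = 2)), seed = 87)
  comb <- insert_np(sys$traj, sys$topology, np)
  rep0 <- interaction_report(comb$traj, comb$topology)
  expect_equal(rep0$label[rep0$component == "CHOL"], "N/A")
  expect_true(is.na(rep0$energy[rep0$component == "CHOL"]))
  # single-frame report equals the direct group_interaction value
  fr <- npmembrane:::traj_frames(comb$traj)[[1]]
  one <- interaction_report(fr, comb$topology, components = "DPPC head")
  a <- select_beads(comb$topology, species = c("NP_core", "MUS", "OT"))
  hb <- select_beads(comb$topology, species = "DPPC", role = c("PO4", "choline"))
  direct <- group_interaction(fr, comb$topology, a, hb)
  expect_equal(one$energy, direct$normalized, tolerance = 1e-12)
  expect_error(interaction_report(comb$traj, comb$topology, components = "WATER"),
               "unknown component")
})
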