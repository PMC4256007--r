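test_that("bilayer composition follows the spec and leaflets are symmetric", {
  sys <- gen_bilayer(bilayer_spec(n_lipids = 100, chol_fraction = 0.30), seed = 1)
  mol <- dplyr::distinct(sys$topology[, c("molecule_id", "species", "leaflet")])
  expect_equal(sum(mol$species == "DPPC"), 70)
  expect_equal(sum(mol$species == "CHOL"), 30)
  by_leaf <- table(mol$species, mol$leaflet)
  expect_true(all(abs(by_leaf[, "upper"] - by_leaf[, "lower"]) <= 10))
  # cholesterol-free system carries no CHOL beads at all
  sys0 <- gen_bilayer(bilayer_spec(n_lipids = 50, chol_fraction = 0), seed = 1)
  expect_equal(sum(sys0$topology$species == "CHOL"), 0)
})

test_that("generators are pure functions of (spec, seed)", {
  a <- gen_bilayer(bilayer_spec(n_lipids = 40, chol_fraction = 0.2), seed = 7, n_frames = 2)
  b <- gen_bilayer(bilayer_spec(n_lipids = 40, chol_fraction = 0.2), seed = 7, n_frames = 2)
  expect_identical(a$traj, b$traj)
  expect_identical(a$topology, b$topology)
  c <- gen_bilayer(bilayer_spec(n_lipids = 40, chol_fraction = 0.2), seed = 8, n_frames = 2)
  expect_false(identical(a$traj$x, c$traj$x))
  n1 <- gen_np(np_spec(), seed = 3)
  n2 <- gen_np(np_spec(), seed = 3)
  expect_identical(n1$frame, n2$frame)
  u1 <- gen_umbrella_samples(pmf_flat(7), centers = c(1, 2), n_per_window = 50, seed = 4)
  u2 <- gen_umbrella_samples(pmf_flat(7), centers = c(1, 2), n_per_window = 50, seed = 4)
  expect_identical(u1$xi, u2$xi)
  g1 <- gen_brownian2d(1e-7, 1, 10, 5, seed = 5)
  g2 <- gen_brownian2d(1e-7, 1, 10, 5, seed = 5)
  expect_identical(g1, g2)
})

test_that("optional water beads fill the solvent slabs only", {
  sys <- gen_bilayer(bilayer_spec(n_lipids = 20, waters_per_lipid = 28), seed = 3,
                     n_frames = 1, waters = TRUE)
  w <- sys$topology$bead[sys$topology$species == "W"]
  expect_equal(length(w), 560)   # 28 CG waters per lipid
  zmid <- attr(sys$traj, "box")[3] / 2
  zw <- sys$traj$z[sys$traj$bead %in% w]
  expect_true(all(abs(zw - zmid) >= 2.5))   # clear of the 4 nm membrane
})

test_that("invalid generator specs are rejected", {
  expect_error(bilayer_spec(n_lipids = 100, chol_fraction = 1.2), "chol_fraction")
  expect_error(bilayer_spec(n_lipids = 0), "n_lipids")
  expect_error(np_spec(n_mus = 10, n_ot = 3), "2:1")
})

test_that("nanoparticle geometry, ligand ratio, and charge are as specified", {
  np <- gen_np(np_spec(n_mus = 134, n_ot = 67), seed = 1)
  expect_equal(sum(np$topology$charge), -134)
  expect_equal(sum(np$topology$species == "MUS" & np$topology$role == "terminal"), 134)
  expect_equal(sum(np$topology$species == "OT" & np$topology$role == "terminal"), 67)
  small <- gen_np(np_spec(core_diameter = 2, n_mus = 2, n_ot = 1,
                          ligand_length_beads = c(mus = 3, ot = 2)), seed = 2)
  expect_equal(sum(small$topology$charge), -2)
  expect_equal(length(unique(paste(small$topology$species, small$topology$role))[
    grepl("terminal", unique(paste(small$topology$species, small$topology$role)))]), 2)
  # every MUS terminal inside core radius + ligand extension
  spec <- np_spec()
  np_term <- np$frame[np$topology$species == "MUS" & np$topology$role == "terminal", ]
  rmax <- spec$core_diameter / 2 + 0.23 + 0.35 * spec$ligand_length_beads[["mus"]] + 0.2
  expect_true(all(sqrt(np_term$x^2 + np_term$y^2 + np_term$z^2) <= rmax))
})

test_that("orientation sampler hits its target P2 (Monte-Carlo oracle)", {
  # sigma of a single-bond P2 is at most sqrt(Var[P2]) <= sqrt(0.2)
  for (target in c(-0.5, 0, 0.4, 0.7, 1.0)) {
    u <- withr::with_seed(100 + round(target * 10), sample_bond_cosines(2e4, target))
    p2 <- (3 * u^2 - 1) / 2
    expect_lt(abs(mean(p2) - target), 0.02)
    expect_true(all(p2 >= -0.5 - 1e-12 & p2 <= 1 + 1e-12))
  }
  # degenerate limits are exact
  expect_equal(sample_bond_cosines(10, 1), rep(1, 10))
  expect_equal(sample_bond_cosines(10, -0.5), rep(0, 10))
  expect_error(sample_bond_cosines(10, 1.2), "\\[-0.5, 1\\]")
})

test_that("constant planted P2 = 1 makes every tail bond parallel to z", {
  sys <- small_system(n_lipids = 30, chol_fraction = 0, n_frames = 1)
  tr <- plant_structure(sys$traj, sys$topology,
                        planted_structure(p2_field = function(d) rep(1, length(d))),
                        seed = 3)
  pb <- p2_of_bonds(npmembrane:::traj_frames(tr)[[1]], tail_bonds(sys$topology))
  expect_equal(pb$p2, rep(1, nrow(pb)), tolerance = 1e-10)
})

test_that("chol_depletion of 1 leaves cholesterol spatially uniform (chi-square)", {
  sys <- gen_bilayer(bilayer_spec(n_lipids = 1200, chol_fraction = 0.5), seed = 11,
                     n_frames = 10)
  tr <- plant_structure(sys$traj, sys$topology,
                        planted_structure(chol_depletion = function(d) rep(1, length(d))),
                        seed = 12)
  box <- attr(tr, "box")
  roh <- sys$topology$bead[sys$topology$atom == "ROH"]
  sel <- tr[tr$bead %in% roh, ]
  nx <- 5
  cell <- findInterval(sel$x, seq(0, box[1], length.out = nx + 1),
                       rightmost.closed = TRUE) +
    nx * (findInterval(sel$y, seq(0, box[2], length.out = nx + 1),
                       rightmost.closed = TRUE) - 1)
  counts <- tabulate(cell, nx * nx)
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("umbrella samples match closed-form biased densities", {
  kt <- kBT(323)
  # flat pmf: Gaussian at the centre with variance kBT/k
  w <- gen_umbrella_samples(pmf_flat(7), centers = 3.0, k = 750,
                            n_per_window = 20000, seed = 1)
  se_mean <- sqrt(kt / 750) / sqrt(20000)
  expect_lt(abs(mean(w$xi) - 3.0), 3 * se_mean)
  expect_lt(abs(var(w$xi) - kt / 750), 3 * sqrt(2 / 20000) * kt / 750)
  # harmonic pmf a(xi-c)^2 biased at c: variance kBT/(2a + k)
  a <- 120
  w2 <- gen_umbrella_samples(pmf_harmonic(a, 3.0), centers = 3.0, k = 750,
                             n_per_window = 20000, seed = 2)
  v_true <- kt / (2 * a + 750)
  expect_lt(abs(var(w2$xi) - v_true), 3 * sqrt(2 / 20000) * v_true)
})

test_that("double-well window histograms match the quadrature oracle (KS)", {
  dw <- pmf_double_well()
  kt <- kBT(323)
  for (ctr in c(1.4, 4.6)) {
    w <- gen_umbrella_samples(dw, centers = ctr, k = 750, n_per_window = 4000,
                              seed = 30 + round(ctr))
    # independent quadrature of the biased density on a fine grid
    grid <- seq(ctr - 0.6, ctr + 0.6, length.out = 20001)
    dens <- exp(-(dw(grid) + 0.5 * 750 * (grid - ctr)^2) / kt)
    cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2)
    cdf <- c(0, cdf / cdf[length(cdf)])
    cdf_fun <- stats::approxfun(grid, cdf, yleft = 0, yright = 1)
    ks <- suppressWarnings(stats::ks.test(w$xi, cdf_fun))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("umbrella window moments agree with quadrature within 3 SE", {
  dw <- pmf_double_well()
  kt <- kBT(323)
  lay <- make_windows(7, 0.2)
  w <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                            n_per_window = 2000, seed = 6)
  for (i in seq(1, 36, by = 7)) {
    ctr <- lay$center[i]
    xi <- w$xi[w$window == i]
    grid <- seq(ctr - 0.6, ctr + 0.6, length.out = 20001)
    dens <- exp(-(dw(grid) + 0.5 * 750 * (grid - ctr)^2) / kt)
    dens <- dens / sum(dens)
    m1 <- sum(grid * dens)
    v1 <- sum((grid - m1)^2 * dens)
    expect_lt(abs(mean(xi) - m1), 3 * sqrt(v1 / length(xi)))
    expect_lt(abs(var(xi) - v1), 3 * sqrt(2 / length(xi)) * v1)
  }
})

test_that("planted PMF constructors expose exact features", {
  dw <- pmf_double_well(barrier = 28, span = 7)
  expect_equal(attr(dw, "barrier"), 28, tolerance = 1e-4)
  expect_equal(dw(7), 0, tolerance = 1e-12)   # referenced to water phase
  expect_error(gen_umbrella_samples(dw, centers = 8, n_per_window = 10, seed = 1),
               "centers")
})

test_that("Brownian generator obeys its closed forms", {
  still <- gen_brownian2d(0, 1, 20, 10, seed = 1)
  expect_equal(var(still$x), 0)
  one <- gen_brownian2d(5e-7, 1, 1, 4000, seed = 2)
  # single step: <dx^2 + dy^2> = 4 D dt (in nm^2: 4 * 0.05)
  stepsq <- with(one[one$time == 1, ], x^2 + y^2)
  expect_lt(abs(mean(stepsq) - 4 * 5e-7 * 1e5), 3 * sd(stepsq) / sqrt(4000))
})
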