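test_that("window layouts follow the inclusive-endpoint convention", {
  lay <- make_windows(7, 0.2)
  expect_equal(nrow(lay), 36)
  expect_equal(lay$center[1], 0)
  expect_equal(lay$center[36], 7)
  expect_equal(make_windows(1, 0.5)$center, c(0, 0.5, 1))
  expect_equal(nrow(make_windows(0.2, 0.2)), 2)
  expect_error(make_windows(1, 0.3), "integer multiple")
  expect_error(make_windows(-1, 0.2), "positive")
})

test_that("campaign-time bookkeeping reproduces the protocol totals", {
  expect_equal(campaign_time(36, 200, 400), 21.6)
  expect_equal(campaign_time(36, 200, 300), 18)
  expect_equal(campaign_time(make_windows(7, 0.2), 200, 400), 21.6)
})

test_that("WHAM degenerates to the histogram estimate for one unbiased window", {
  withr::with_seed(91, { xi <- rnorm(20000, 3, 0.5) })
  w <- npmembrane:::new_umbrella_windows(
    tibble::tibble(window = 1L, center = 3, k = 0,
                   time = seq_along(xi) * 0.1, xi = xi), 323)
  prof <- wham(w, n_bins = 40, tolerance = 1e-10)
  kt <- kBT(323)
  h <- prof$count / sum(prof$count)
  g_ref <- -kt * log(h)
  g_ref <- g_ref - g_ref[which.max(prof$count)]
  g_got <- prof$G - prof$G[which.max(prof$count)]
  ok <- is.finite(g_ref) & is.finite(g_got)
  expect_equal(g_got[ok], g_ref[ok], tolerance = 1e-9)
})

test_that("WHAM recovers a planted harmonic PMF (closed form)", {
  a <- 3
  hp <- pmf_harmonic(a, 3.5)
  lay <- make_windows(7, 0.2)
  # replicate-averaged curve RMSE at the protocol scale (see vignette)
  rmse <- vapply(0:2, function(r) {
    w <- gen_umbrella_samples(hp, centers = lay$center, k = 750,
                              n_per_window = 1e4, seed = 92 + r)
    prof <- wham(w, tolerance = 1e-7)
    sup <- prof$xi >= 0 & prof$xi <= 7 & is.finite(prof$G)
    diff <- prof$G[sup] - a * (prof$xi[sup] - 3.5)^2
    diff <- diff - mean(diff)
    sqrt(mean(diff^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.3)
})

test_that("histograms are conserved and the fixed point verifies", {
  dw <- pmf_double_well()
  lay <- make_windows(7, 0.2)
  w <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                            n_per_window = 1000, seed = 93)
  prof <- wham(w, n_bins = 150, tolerance = 1e-9)
  counts <- attr(prof, "counts")
  expect_equal(rowSums(counts), rep(1000, 36))   # sum_b n_i(b) = N_i exactly
  # both WHAM equations hold at convergence within 10x tolerance
  kt <- attr(prof, "kBT")
  ew <- attr(prof, "bias_weight")
  F <- attr(prof, "F")
  Ni <- rowSums(counts); Mb <- colSums(counts)
  denom <- colSums(Ni * exp(F / kt) * ew)
  p <- ifelse(denom > 0, Mb / denom, 0)
  F_re <- -kt * log(as.vector(ew %*% p))
  F_re <- F_re - F_re[1]
  expect_lt(max(abs(F_re - F)), 10 * 1e-9 * kt)
  # gauge invariance: a constant added to all window free energies leaves
  # the re-referenced profile unchanged
  p_shift <- Mb / colSums(Ni * exp((F + 5) / kt) * ew)
  g1 <- -kt * log(p / sum(p)); g2 <- -kt * log(p_shift / sum(p_shift))
  ok <- is.finite(g1) & is.finite(g2)
  expect_equal(npmembrane:::rereference_pmf(g1, prof$xi),
               npmembrane:::rereference_pmf(g2, prof$xi), tolerance = 1e-9)
})

test_that("2-window/10-bin WHAM matches an independent root-finder solve", {
  w <- gen_umbrella_samples(pmf_harmonic(5, 3.5), centers = c(3.2, 3.6), k = 200,
                            n_per_window = 4000, seed = 94)
  prof <- wham(w, n_bins = 10, tolerance = 1e-12)
  counts <- attr(prof, "counts"); ew <- attr(prof, "bias_weight")
  kt <- attr(prof, "kBT")
  Ni <- rowSums(counts); Mb <- colSums(counts)
  pfun <- function(F) Mb / colSums(Ni * exp(F / kt) * ew)
  gfun <- function(F2) {
    p <- pfun(c(0, F2))
    -kt * log(sum(p * ew[2, ])) - F2
  }
  F2 <- uniroot(gfun, c(-50, 50), tol = 1e-14)$root
  p <- pfun(c(0, F2)); p <- p / sum(p)
  g_or <- -kt * log(p)
  rel <- abs((g_or - mean(g_or)) - (prof$G - mean(prof$G))) / max(abs(g_or - mean(g_or)))
  expect_lt(max(rel), 1e-8)
  expect_equal(attr(prof, "F")[2], F2, tolerance = 1e-8)
})

test_that("non-overlapping windows are rejected as disconnected", {
  withr::with_seed(90, {
    xi <- c(rnorm(100, 0, 0.05), rnorm(100, 5, 0.05))
  })
  w <- npmembrane:::new_umbrella_windows(
    tibble::tibble(window = rep(1:2, each = 100),
                   center = rep(c(0, 5), each = 100), k = 750,
                   time = rep(1:100, 2) * 0.1, xi = xi), 323)
  expect_error(wham(w, n_bins = 50), "overlap|disconnected")
})

test_that("bootstrap errors are deterministic and shrink as 1/sqrt(n)", {
  dw <- pmf_double_well()
  lay <- make_windows(7, 0.2)
  w1 <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                             n_per_window = 1000, seed = 95)
  b1 <- bootstrap_pmf(w1, n_boot = 24, seed = 96, n_bins = 100)
  b1b <- bootstrap_pmf(w1, n_boot = 24, seed = 96, n_bins = 100)
  expect_identical(b1$sd, b1b$sd)
  w4 <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                             n_per_window = 4000, seed = 95)
  b4 <- bootstrap_pmf(w4, n_boot = 24, seed = 96, n_bins = 100)
  ok <- b1$xi > 0.5 & b1$xi < 6.5 & is.finite(b1$sd) & is.finite(b4$sd)
  ratio <- stats::median(b1$sd[ok] / b4$sd[ok])
  expect_gt(ratio, 1.5)   # 4x samples -> sd ratio ~ 2 +- 0.5
  expect_lt(ratio, 2.5)
})

test_that("bootstrap SD vanishes in the no-sampling-variance limit", {
  withr::with_seed(97, { xi <- rnorm(30000, 3.0, sqrt(kBT(323) / 750)) })
  w <- npmembrane:::new_umbrella_windows(
    dplyr::bind_rows(
      tibble::tibble(window = 1L, center = 3.0, k = 750,
                     time = seq_along(xi) * 0.1, xi = xi),
      tibble::tibble(window = 2L, center = 3.0, k = 750,
                     time = seq_along(xi) * 0.1, xi = xi)), 323)
  b <- bootstrap_pmf(w, n_boot = 2, seed = 98, n_bins = 30, block_ns = 1)
  mid <- b$count > 2000
  expect_lt(stats::median(b$sd[mid]), 0.1)
})

test_that("PMF features extract minima and barriers with stated tie-breaks", {
  # monotone decreasing G: barrier = G(0) - G(min)
  prof <- structure(tibble::tibble(xi = seq(0, 7, 0.1), G = 10 - seq(0, 7, 0.1)),
                    class = c("pmf_profile", class(tibble::tibble())))
  ft <- pmf_features(prof, interface_region = c(3, 7))
  expect_equal(ft$min_xi, 7)
  expect_equal(ft$barrier, prof$G[1] - ft$min_G)   # = G(0) - G(min) = 7
  # flat G: zero barrier, first-bin tie-break
  pf <- structure(tibble::tibble(xi = seq(0, 7, 0.1), G = 0),
                  class = c("pmf_profile", class(tibble::tibble())))
  ftf <- pmf_features(pf, interface_region = c(3, 7))
  expect_equal(ftf$barrier, 0)
  expect_equal(ftf$min_xi, 3)
  expect_error(pmf_features(pf, interface_region = c(8, 9)), "no sampled bins")
})

test_that("convergence scan truncates windows and matches full-data WHAM", {
  dw <- pmf_double_well()
  lay <- make_windows(7, 0.2)
  w <- gen_umbrella_samples(dw, centers = lay$center, k = 750,
                            n_per_window = 1500, seed = 99, dt = 0.1)
  full <- wham(w, n_bins = 100)
  sc <- convergence_scan(w, sampling_times = 150, n_bins = 100)
  expect_equal(sc$barrier, pmf_features(full)$barrier, tolerance = 1e-12)
  expect_error(convergence_scan(w, sampling_times = 0.1, n_bins = 100),
               "fewer than 2")
  # barrier deviations settle as sampling accumulates
  sc2 <- convergence_scan(w, sampling_times = c(30, 60, 150), n_bins = 100)
  dev <- abs(sc2$barrier - attr(dw, "barrier"))
  expect_lt(dev[3], dev[1] + 1)
})
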