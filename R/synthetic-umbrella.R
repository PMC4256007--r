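#' Planted potentials of mean force
#'
#' Analytic free-energy curves along the NP-to-bilayer-centre distance xi,
#' referenced to zero in the water phase (`xi = span`). `pmf_double_well()`
#' builds the study's characteristic shape: an interfacial minimum (default
#' at 4.5 nm) below the water plateau and a translocation barrier between
#' the bilayer core and that minimum, whose height (max over
#' `[0, min]` minus the minimum) is set exactly to `barrier` by a 1D solve.
#' The true curve and its features are attached as attributes so recovery
#' tests can compare against exact values.
#'
#' @param barrier Barrier height, kJ/mol (max over \[0, min_pos\] relative
#'   to the minimum).
#' @param min_pos Location of the interfacial minimum (nm).
#' @param min_depth Depth of the minimum below the water plateau (kJ/mol).
#' @param barrier_pos Location of the barrier top (nm).
#' @param width_barrier,width_min Gaussian widths (nm).
#' @param span Domain end (nm); the curve is referenced to 0 there.
#' @return A function xi -> kJ/mol with attributes `barrier`, `min_pos`,
#'   `min_value` (evaluated on a fine grid).
#' @export
pmf_double_well <- function(barrier = 28, min_pos = 4.5, min_depth = 5,
                            barrier_pos = 1.5, width_barrier = 1.0,
                            width_min = 0.8, span = 7) {
  base <- function(A) {
    function(xi) {
      g <- A * exp(-(xi - barrier_pos)^2 / (2 * width_barrier^2)) -
        min_depth * exp(-(xi - min_pos)^2 / (2 * width_min^2))
      g - (A * exp(-(span - barrier_pos)^2 / (2 * width_barrier^2)) -
             min_depth * exp(-(span - min_pos)^2 / (2 * width_min^2)))
    }
  }
  grid <- seq(0, span, length.out = 4001)
  reg <- grid >= barrier_pos   # search region for the interfacial minimum
  feat <- function(A) {
    g <- base(A)(grid)
    xm <- grid[reg][which.min(g[reg])]
    max(g[grid <= xm]) - min(g[reg])
  }
  A <- uniroot(function(A) feat(A) - barrier, c(1, 3 * barrier))$root
  f <- base(A)
  g <- f(grid)
  xm <- grid[reg][which.min(g[reg])]
  attr(f, "barrier") <- max(g[grid <= xm]) - min(g[reg])
  attr(f, "min_pos") <- xm
  attr(f, "min_value") <- min(g[reg])
  attr(f, "span") <- span
  f
}

#' @rdname pmf_double_well
#' @param a Curvature, kJ/mol/nm^2.
#' @param center Minimum location (nm).
#' @export
pmf_harmonic <- function(a, center, span = 7) {
  force(a); force(center); force(span)
  f <- function(xi) a * (xi - center)^2 - a * (span - center)^2
  attr(f, "span") <- span
  f
}

#' @rdname pmf_double_well
#' @export
pmf_flat <- function(span = 7) {
  force(span)
  f <- function(xi) rep(0, length(xi))
  attr(f, "span") <- span
  f
}

#' Generate umbrella-sampling window records from a planted PMF
#'
#' For window i with harmonic bias `w_i(xi) = (k/2)(xi - c_i)^2`, samples are
#' drawn i.i.d. from the biased Boltzmann density
#' `p_i(xi) ~ exp(-(pmf(xi) + w_i(xi)) / kBT)` by inverse-CDF sampling on a
#' fine grid. Defaults mirror the study's umbrella protocol: force constant
#' 750 kJ/mol/nm^2 and 0.2 nm window spacing over a 7 nm span.
#'
#' @param pmf Function xi -> kJ/mol (e.g. [pmf_double_well()]).
#' @param centers Window centres (nm), e.g. from [make_windows()].
#' @param k Bias force constant, kJ/mol/nm^2.
#' @param n_per_window Samples per window.
#' @param temperature Temperature, K.
#' @param dt Sample spacing (ns) used for the attached time stamps.
#' @param seed Integer seed.
#' @param span Domain end (nm); defaults to the pmf's `span` attribute.
#' @return An `umbrella_windows` tibble (`window`, `center`, `k`, `time`,
#'   `xi`) with a `"temperature"` attribute.
#' @export
gen_umbrella_samples <- function(pmf, centers, k = 750, n_per_window = 1000,
                                 temperature = DEFAULT_TEMPERATURE, dt = 0.1,
                                 seed = 1L, span = NULL) {
  span <- span %||% attr(pmf, "span") %||% max(centers)
  if (k <= 0) abort("force constant k must be positive")
  if (n_per_window < 1) abort("n_per_window must be at least 1")
  if (any(centers < 0 | centers > span)) abort("window centers must lie in [0, span]")
  kt <- kBT(temperature)
  sig <- sqrt(kt / k)
  lo <- min(centers) - 6 * sig
  hi <- max(centers) + 6 * sig
  grid <- seq(lo, hi, length.out = 8001)
  g <- pmf(grid)
  if (any(!is.finite(g))) abort("pmf must be finite on the sampling domain")
  withr::local_seed(seed)
  rows <- lapply(seq_along(centers), function(i) {
    e <- g + 0.5 * k * (grid - centers[i])^2
    w <- exp(-(e - min(e)) / kt)
    # trapezoidal CDF at the grid nodes (a one-sided cumsum would shift
    # every draw by half a grid cell, which the bias k amplifies)
    cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    keep <- c(TRUE, diff(cdf) > 0)
    xi <- approx(cdf[keep], grid[keep], runif(n_per_window), rule = 2)$y
    tibble(window = i, center = centers[i], k = k,
           time = dt * seq_len(n_per_window), xi = xi)
  })
  new_umbrella_windows(bind_rows(rows), temperature)
}

#' Generate planted 2D Brownian trajectories
#'
#' Independent particles with Gaussian increments of per-axis variance
#' `2 D dt` per step (1 cm^2/s = 1e5 nm^2/ns), starting at the origin.
#' The returned trajectory is unwrapped (no periodic box), ready for
#' [msd()] / [fit_diffusion()] recovery tests.
#'
#' @param D Diffusion coefficient, cm^2/s.
#' @param dt Time step, ns.
#' @param n_steps Number of steps (frames = n_steps + 1).
#' @param n_particles Number of particles.
#' @param seed Integer seed.
#' @return A trajectory tibble (`time`, `bead`, `x`, `y`, `z = 0`) without a
#'   box attribute.
#' @export
gen_brownian2d <- function(D, dt, n_steps, n_particles, seed) {
  if (D < 0) abort("D must be non-negative")
  sig <- sqrt(2 * D * 1e5 * dt)   # nm per axis per step
  nf <- n_steps + 1L
  withr::local_seed(seed)
  step_mat <- function() {
    if (sig == 0) matrix(0, nf, n_particles)
    else apply(rbind(0, matrix(rnorm(n_steps * n_particles, 0, sig),
                               n_steps, n_particles)), 2, cumsum)
  }
  X <- step_mat(); Y <- step_mat()
  tibble(
    time = rep((0:n_steps) * dt, each = n_particles),
    bead = rep(seq_len(n_particles), nf),
    x = as.vector(t(X)), y = as.vector(t(Y)), z = 0
  )
}
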