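#' Umbrella window layout
#'
#' Inclusive endpoint ladder of harmonic-bias centres: `0, spacing, ...,
#' span`, i.e. `round(span/spacing) + 1` windows. The study protocol --
#' a 7 nm span at 0.2 nm spacing with k = 750 kJ/mol/nm^2 -- gives 36
#' windows.
#'
#' @param span Reaction-coordinate span (nm).
#' @param spacing Window spacing (nm); `span/spacing` must be integral.
#' @param k Bias force constant (kJ/mol/nm^2).
#' @return A `window_layout` tibble (`window`, `center`) with attributes
#'   `k`, `span`, `spacing`.
#' @export
#' @examples
#' nrow(make_windows(7, 0.2))  # 36
make_windows <- function(span, spacing, k = 750) {
  if (span <= 0 || spacing <= 0) abort("span and spacing must be positive")
  m <- span / spacing
  if (abs(m - round(m)) > 1e-9) abort("span must be an integer multiple of spacing")
  if (k <= 0) abort("force constant k must be positive")
  centers <- seq(0, by = spacing, length.out = round(m) + 1)
  out <- tibble(window = seq_along(centers), center = centers)
  attr(out, "k") <- k
  attr(out, "span") <- span
  attr(out, "spacing") <- spacing
  class(out) <- unique(c("window_layout", class(out)))
  out
}

#' Umbrella campaign time bookkeeping
#'
#' Total simulated time of an umbrella campaign: `n_windows *
#' (equilibration + production)`, reported in microseconds. The study's 36
#' windows at 200 ns equilibration + 400 ns production give 21.6 us (18 us
#' with 300 ns production).
#'
#' @param n_windows Number of windows (or a [make_windows()] layout).
#' @param equilibration_ns,production_ns Per-window times (ns).
#' @return Total time in microseconds.
#' @export
campaign_time <- function(n_windows, equilibration_ns = 200, production_ns = 400) {
  if (is.data.frame(n_windows)) n_windows <- nrow(n_windows)
  n_windows * (equilibration_ns + production_ns) / 1000
}

#' WHAM reconstruction of a free-energy profile
#'
#' Solves the weighted histogram analysis equations by damped fixed-point
#' iteration: with per-window histograms `n_i(b)` over a common bin grid and
#' biases `w_i(xi_b) = (k_i/2)(xi_b - c_i)^2`,
#' `p(b) = sum_i n_i(b) / sum_i N_i exp((F_i - w_i(b)) / kBT)` and
#' `F_i = -kBT log sum_b p(b) exp(-w_i(b) / kBT)`, iterated from `F_i = 0`
#' until `max |dF_i| < tolerance * kBT`. The free energy is
#' `G(xi) = -kBT log p(xi)`, re-referenced to zero as the mean over the
#' outermost 0.5 nm of sampled xi (the water-phase plateau convention).
#'
#' @param windows An `umbrella_windows` set ([gen_umbrella_samples()] or
#'   [read_window_records()]).
#' @param n_bins Number of uniform bins spanning the pooled sample range
#'   (or `bin_range`).
#' @param tolerance Convergence tolerance in units of kBT.
#' @param max_iterations Iteration cap.
#' @param damping Fixed-point damping in (0, 1\]; 1 = undamped.
#' @param bin_range Optional `c(lo, hi)` overriding the bin span (used to
#'   keep bootstrap replicates on a common grid).
#' @return A `pmf_profile` tibble (`xi`, `G`, `count`) with attributes
#'   `F` (window free energies), `counts`, `bias`, `breaks`, `kBT`,
#'   `converged`, `iterations`.
#' @export
wham <- function(windows, n_bins = 200, tolerance = 1e-7,
                 max_iterations = 100000, damping = 1, bin_range = NULL) {
  stopifnot(inherits(windows, "umbrella_windows"))
  if (n_bins < 2) abort("n_bins must be at least 2")
  if (tolerance <= 0) abort("tolerance must be positive")
  kt <- kBT(attr(windows, "temperature") %||% DEFAULT_TEMPERATURE)
  info <- dplyr::distinct(as_tibble(windows)[, c("window", "center", "k")])
  info <- info[order(info$window), ]
  nw <- nrow(info)
  rng <- bin_range %||% range(windows$xi)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  counts <- matrix(0, nw, n_bins)
  for (i in seq_len(nw)) {
    xi <- windows$xi[windows$window == info$window[i]]
    ix <- findInterval(xi, breaks, rightmost.closed = TRUE)
    ix[ix < 1] <- 1L; ix[ix > n_bins] <- n_bins
    counts[i, ] <- tabulate(ix, n_bins)
  }
  check_window_overlap(counts)
  bias <- 0.5 * info$k * outer(info$center, mids, function(c, x) (x - c)^2)
  expw <- exp(-bias / kt)   # bias Boltzmann weight at bin centres
  sol <- wham_iterate(counts, expw, kt, tolerance, max_iterations, damping)
  if (!sol$converged) {
    warn(sprintf("WHAM did not converge in %d iterations (max |dF| = %.3g kBT)",
                 max_iterations, sol$delta / kt))
  }
  G <- -kt * log(sol$p)
  G[!is.finite(G)] <- NA_real_
  out <- tibble(xi = mids, G = rereference_pmf(G, mids), count = colSums(counts))
  attr(out, "F") <- sol$F
  attr(out, "counts") <- counts
  attr(out, "bias") <- bias
  attr(out, "bias_weight") <- expw
  attr(out, "breaks") <- breaks
  attr(out, "kBT") <- kt
  attr(out, "centers") <- info$center
  attr(out, "converged") <- sol$converged
  attr(out, "iterations") <- sol$iter
  class(out) <- unique(c("pmf_profile", class(out)))
  out
}

# windows must form one connected component through shared occupied bins;
# otherwise the relative free energies between islands are undetermined
check_window_overlap <- function(counts) {
  nw <- nrow(counts)
  if (nw < 2) return(invisible(TRUE))
  occ <- counts > 0
  adj <- (occ %*% t(occ)) > 0
  reached <- rep(FALSE, nw)
  reached[1] <- TRUE
  repeat {
    new <- (adj %*% reached) > 0
    new <- as.vector(new) & !reached
    if (!any(new)) break
    reached <- reached | new
  }
  if (!all(reached)) {
    abort("umbrella windows do not overlap (disconnected histogram support)")
  }
  invisible(TRUE)
}

# core fixed-point iteration on the window free energies; expw holds the
# bin-averaged Boltzmann weights exp(-w_i(bin)/kT)
wham_iterate <- function(counts, expw, kt, tolerance, max_iterations, damping) {
  nw <- nrow(counts)
  Ni <- rowSums(counts)
  Mb <- colSums(counts)
  F <- rep(0, nw)
  delta <- Inf
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    gi <- Ni * exp(F / kt)
    denom <- as.vector(crossprod(expw, gi))   # sum_i N_i e^{(F_i - w_ib)/kT}
    p <- ifelse(denom > 0, Mb / denom, 0)
    Fi_new <- -kt * log(as.vector(expw %*% p))
    Fi_new <- Fi_new - Fi_new[1]
    Fi_new <- F + damping * (Fi_new - F)
    delta <- max(abs(Fi_new - F))
    F <- Fi_new
    if (delta < tolerance * kt) break
  }
  gi <- Ni * exp(F / kt)
  denom <- as.vector(crossprod(expw, gi))
  p <- ifelse(denom > 0, Mb / denom, 0)
  p <- p / sum(p)
  list(F = F, p = p, converged = delta < tolerance * kt, iter = iter,
       delta = delta)
}

# zero reference: mean G over the outermost 0.5 nm of sampled xi
rereference_pmf <- function(G, mids, width = 0.5) {
  ok <- is.finite(G)
  hi <- max(mids[ok])
  ref <- ok & mids >= hi - width
  G - mean(G[ref])
}

#' Bootstrap errors for a WHAM profile
#'
#' Block bootstrap within each window: the xi series is cut into contiguous
#' blocks of `block_ns` (10 ns default; umbrella series are autocorrelated,
#' so naive resampling underestimates the error), blocks are resampled with
#' replacement, WHAM is re-run on a common bin grid, each replicate is
#' re-referenced, and the per-bin standard deviation across replicates is
#' attached to the profile. Replicates that fail to converge are dropped
#' with a warning; more than 50 percent failures is an error.
#'
#' @param windows An `umbrella_windows` set.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param block_ns Block length (ns).
#' @param ... Passed to [wham()] (`n_bins`, `tolerance`, ...).
#' @return The full-data `pmf_profile` with an added `sd` column and a
#'   `"replicates"` attribute (matrix bins x replicates).
#' @export
bootstrap_pmf <- function(windows, n_boot = 50, seed = 1L, block_ns = 10, ...) {
  if (n_boot < 2) abort("n_boot must be at least 2")
  dots <- list(...)
  full <- do.call(wham, c(list(windows), dots))
  dots$n_bins <- NULL
  dots$bin_range <- NULL
  rng <- range(attr(full, "breaks"))
  n_bins <- length(attr(full, "breaks")) - 1L
  dt <- min(diff(sort(unique(windows$time[windows$window == windows$window[1]]))))
  bl <- max(1L, round(block_ns / dt))
  wsplit <- split(as_tibble(windows), windows$window)
  temperature <- attr(windows, "temperature")
  withr::local_seed(seed)
  reps <- vector("list", n_boot)
  fails <- 0L
  for (b in seq_len(n_boot)) {
    resampled <- bind_rows(lapply(wsplit, function(w) {
      n <- nrow(w)
      starts <- seq(1L, n, by = bl)
      pick <- sample(starts, ceiling(n / bl), replace = TRUE)
      idx <- unlist(lapply(pick, function(s) s:min(s + bl - 1L, n)))[seq_len(n)]
      idx[is.na(idx)] <- sample(n, sum(is.na(idx)), replace = TRUE)
      w$xi <- w$xi[idx]
      w
    }))
    rep_prof <- tryCatch(
      withCallingHandlers(
        do.call(wham, c(list(new_umbrella_windows(resampled, temperature),
                             n_bins = n_bins, bin_range = rng), dots)),
        warning = function(w) {
          if (grepl("did not converge", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    if (is.null(rep_prof) || !attr(rep_prof, "converged")) {
      fails <- fails + 1L
      reps[[b]] <- NULL
    } else {
      reps[[b]] <- rep_prof$G
    }
  }
  if (fails > 0) warn(sprintf("%d bootstrap replicate(s) discarded (non-convergence)", fails))
  if (fails > n_boot / 2) abort("more than half of the bootstrap replicates failed")
  R <- do.call(cbind, reps[!vapply(reps, is.null, logical(1))])
  full$sd <- apply(R, 1, stats::sd, na.rm = TRUE)
  attr(full, "replicates") <- R
  full
}

#' Extract PMF features: minimum and translocation barrier
#'
#' The minimum is the lowest free energy over the bilayer-water interface
#' region; the barrier is the maximum free energy between the bilayer
#' centre (`xi = 0`) and that minimum, relative to the minimum. Ties take
#' the first (smallest-xi) bin.
#'
#' @param pmf A `pmf_profile` (or tibble with `xi`, `G`).
#' @param interface_region `c(lo, hi)` in nm to search for the minimum.
#' @return One-row tibble: `min_xi`, `min_G`, `barrier_xi`, `barrier`.
#' @export
pmf_features <- function(pmf, interface_region = c(3, 6)) {
  ok <- is.finite(pmf$G)
  reg <- ok & pmf$xi >= interface_region[1] & pmf$xi <= interface_region[2]
  if (!any(reg)) abort("interface region contains no sampled bins")
  i_min <- which(reg)[which.min(pmf$G[reg])]
  core <- ok & pmf$xi <= pmf$xi[i_min]
  if (!any(core)) abort("no sampled bins between the bilayer centre and the minimum")
  i_max <- which(core)[which.max(pmf$G[core])]
  tibble(min_xi = pmf$xi[i_min], min_G = pmf$G[i_min],
         barrier_xi = pmf$xi[i_max],
         barrier = pmf$G[i_max] - pmf$G[i_min])
}

#' Barrier convergence against sampling time
#'
#' Truncates every window's series to successive sampling times (after an
#' equilibration discard), re-runs WHAM, and reports the barrier for each
#' truncation -- the standard check that the reconstructed barrier has
#' stopped drifting with more sampling.
#'
#' @param windows An `umbrella_windows` set with time stamps.
#' @param sampling_times Vector of production times (ns).
#' @param equilibration Initial discard (ns).
#' @param interface_region Passed to [pmf_features()].
#' @param ... Passed to [wham()].
#' @return Tibble: `sampling_time`, `barrier`, `min_xi`.
#' @export
convergence_scan <- function(windows, sampling_times, equilibration = 0,
                             interface_region = c(3, 6), ...) {
  purrr::map_dfr(sampling_times, function(st) {
    keep <- windows$time > equilibration & windows$time <= equilibration + st
    sub <- as_tibble(windows)[keep, ]
    n_min <- min(table(sub$window))
    if (length(unique(sub$window)) < length(unique(windows$window)) || n_min < 2) {
      abort("sampling time leaves fewer than 2 samples in some window")
    }
    prof <- wham(new_umbrella_windows(sub, attr(windows, "temperature")), ...)
    ft <- pmf_features(prof, interface_region)
    tibble(sampling_time = st, barrier = ft$barrier, min_xi = ft$min_xi)
  })
}
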