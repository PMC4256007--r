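#' Unwrap a periodic trajectory
#'
#' Removes periodic jumps by accumulating minimum-image displacements per
#' bead along the frame sequence. Valid when the true per-frame displacement
#' of every bead is below half the box edge (documented precondition).
#'
#' @param traj Trajectory with a `"box"` attribute.
#' @return The unwrapped trajectory (box attribute retained for geometry,
#'   but coordinates are continuous).
#' @export
unwrap_trajectory <- function(traj) {
  box <- validate_box(traj_box(traj))
  arr <- traj_arrays(traj)
  for (ax in 1:3) {
    X <- arr[[ax]]
    if (nrow(X) > 1) {
      d <- diff(X)
      d <- d - box[ax] * ceiling(d / box[ax] - 0.5)   # min-image per-frame steps
      cs <- apply(d, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
      X <- rbind(X[1, , drop = FALSE], sweep(cs, 2, X[1, ], "+"))
    }
    arr[[ax]] <- X
  }
  arrays_to_traj(arr, traj)
}

# trajectory -> list(x, y, z) of frame x particle matrices + metadata
traj_arrays <- function(traj) {
  times <- sort(unique(traj$time))
  beads <- sort(unique(traj$bead))
  o <- order(traj$time, traj$bead)
  nt <- length(times); nb <- length(beads)
  if (nrow(traj) != nt * nb) abort("trajectory is not a complete time x bead grid")
  list(x = matrix(traj$x[o], nt, nb, byrow = TRUE),
       y = matrix(traj$y[o], nt, nb, byrow = TRUE),
       z = matrix(traj$z[o], nt, nb, byrow = TRUE),
       times = times, beads = beads)
}

arrays_to_traj <- function(arr, template) {
  nt <- length(arr$times); nb <- length(arr$beads)
  out <- tibble(time = rep(arr$times, each = nb),
                bead = rep(arr$beads, nt),
                x = as.vector(t(arr$x)), y = as.vector(t(arr$y)),
                z = as.vector(t(arr$z)))
  attr(out, "box") <- traj_box(template)
  out
}

#' Mean square displacement with multiple time origins
#'
#' `MSD(tau) = <|r(t + tau) - r(t)|^2>` averaged over every admissible time
#' origin and over the selected beads, using the lateral (x, y) components
#' by default. Wrapped trajectories (per-frame jump above half a box edge)
#' are rejected unless `unwrap = TRUE`.
#'
#' @param traj Trajectory (e.g. from [gen_brownian2d()], or lipid-COM
#'   trajectories via [molecule_com_traj()]).
#' @param beads Optional bead subset.
#' @param lags Lag times (ns) or `NULL` for a pseudo-logarithmic grid of
#'   `n_lags` points up to half the trajectory length.
#' @param n_lags Size of the default lag grid.
#' @param use_xy_only Use lateral components only (2D membrane convention).
#' @param unwrap Unwrap a periodic trajectory first.
#' @return An `msd_curve` tibble (`lag`, `msd`, `n_pairs`) with a
#'   `"per_particle"` attribute (lag x particle MSD matrix) used for
#'   particle-resolved error estimates.
#' @export
msd <- function(traj, beads = NULL, lags = NULL, n_lags = 30,
                use_xy_only = TRUE, unwrap = FALSE) {
  if (!is.null(beads)) traj <- structure(traj[traj$bead %in% beads, ],
                                         box = traj_box(traj))
  box <- traj_box(traj)
  if (unwrap) {
    traj <- unwrap_trajectory(traj)
    box <- NULL
  }
  arr <- traj_arrays(traj)
  nt <- length(arr$times)
  if (nt < 2) abort("need at least 2 frames")
  dt <- diff(arr$times)
  if (max(dt) - min(dt) > 1e-9 * max(dt)) abort("frames must be evenly spaced")
  dt <- dt[1]
  if (!is.null(box)) {
    for (ax in if (use_xy_only) 1:2 else 1:3) {
      if (any(abs(diff(arr[[ax]])) > box[ax] / 2)) {
        abort("trajectory appears wrapped (jump > L/2 between frames); pass unwrap = TRUE")
      }
    }
  }
  if (is.null(lags)) {
    max_step <- max(1L, floor((nt - 1) / 2))
    steps <- unique(round(exp(seq(log(1), log(max_step), length.out = n_lags))))
  } else {
    steps <- unique(round(lags / dt))
    steps <- steps[steps >= 1 & steps <= nt - 1]
    if (!length(steps)) abort("no valid lags within the trajectory length")
  }
  axes <- if (use_xy_only) c("x", "y") else c("x", "y", "z")
  nb <- length(arr$beads)
  per <- matrix(0, length(steps), nb)
  n_pairs <- integer(length(steps))
  for (si in seq_along(steps)) {
    s <- steps[si]
    acc <- 0
    for (ax in axes) {
      X <- arr[[ax]]
      D <- X[(s + 1):nt, , drop = FALSE] - X[1:(nt - s), , drop = FALSE]
      acc <- acc + D^2
    }
    per[si, ] <- colMeans(acc)
    n_pairs[si] <- (nt - s) * nb
  }
  out <- tibble(lag = steps * dt, msd = rowMeans(per), n_pairs = n_pairs)
  attr(out, "per_particle") <- per
  attr(out, "n_dim") <- length(axes)
  class(out) <- unique(c("msd_curve", class(out)))
  out
}

#' Centre-of-mass trajectory per molecule
#'
#' Collapses a bead trajectory to one COM "bead" per molecule of the given
#' species -- the input convention for lipid self-diffusion.
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param species Species to keep.
#' @return A trajectory tibble whose `bead` column holds molecule ids.
#' @export
molecule_com_traj <- function(traj, top, species) {
  beads <- select_beads(top, species = species)
  if (!length(beads)) abort(paste0("species ", species, " not present"))
  sub <- as_tibble(traj)[traj$bead %in% beads, ]
  sub$mol <- top$molecule_id[match(sub$bead, top$bead)]
  out <- sub %>%
    group_by(.data$time, .data$mol) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop") %>%
    rename(bead = "mol")
  attr(out, "box") <- traj_box(traj)
  out
}

#' Fit a lateral self-diffusion coefficient
#'
#' Least-squares line through the MSD curve over `fit_range`;
#' `D = slope / (2 * dim)`, converted from nm^2/ns to cm^2/s
#' (1 nm^2/ns = 1e-5 cm^2/s). When the curve carries per-particle MSDs the
#' standard error comes from the spread of per-particle slopes (independent
#' particles), otherwise from the regression. A negative fitted slope is
#' reported as D = 0 with a warning.
#'
#' @param curve An `msd_curve`.
#' @param fit_range `c(lo, hi)` lag window (ns); default the 10-50 percent
#'   span of the available lags (excludes the short-lag region).
#' @param dim Dimensionality of the displacement (2 for lateral).
#' @return A `diffusion_fit` list: `D` (cm^2/s), `se`, `ci` (95 percent),
#'   `slope` (nm^2/ns), `fit_range`, `dim`, `n_particles`.
#' @export
fit_diffusion <- function(curve, fit_range = NULL, dim = 2) {
  lmax <- max(curve$lag)
  fit_range <- fit_range %||% c(0.1 * lmax, 0.5 * lmax)
  sel <- curve$lag >= fit_range[1] & curve$lag <= fit_range[2]
  if (sum(sel) < 2) abort("need at least 2 lags in the fit range")
  x <- curve$lag[sel]
  slope_of <- function(y) {
    cv <- stats::cov(x, y)
    cv / stats::var(x)
  }
  slope <- slope_of(curve$msd[sel])
  per <- attr(curve, "per_particle", exact = TRUE)
  unit <- 1e-5 / (2 * dim)   # nm^2/ns slope -> cm^2/s
  if (!is.null(per) && ncol(per) > 1) {
    d_i <- apply(per[sel, , drop = FALSE], 2, slope_of) * unit
    D <- mean(d_i)
    se <- sd(d_i) / sqrt(length(d_i))
    npart <- length(d_i)
  } else {
    y <- curve$msd[sel]
    D <- slope * unit
    res <- y - mean(y) - slope * (x - mean(x))
    sxx <- sum((x - mean(x))^2)
    se <- if (length(x) > 2) sqrt(sum(res^2) / (length(x) - 2) / sxx) * unit else 0
    npart <- 1L
  }
  if (D < 0) {
    warn("negative fitted slope; reporting D = 0")
    D <- 0
  }
  structure(list(D = D, se = se, ci = c(D - 1.96 * se, D + 1.96 * se),
                 slope = slope, fit_range = fit_range, dim = dim,
                 n_particles = npart),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Lateral diffusion fit (dim = %d)\n", x$dim))
  cat(sprintf("  D = %.3g cm^2/s (SE %.2g), 95%% CI [%.3g, %.3g]\n",
              x$D, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  fit range %.3g-%.3g ns, %d particles\n",
              x$fit_range[1], x$fit_range[2], x$n_particles))
  invisible(x)
}
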