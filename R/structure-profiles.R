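#' Number-density map in the x-z plane
#'
#' Mean per-frame bead count per cell divided by cell area (nm^-2, the y
#' direction projected out). Mass is conserved exactly: the sum of cell
#' values times the cell area equals the mean selected-bead count per frame.
#' Cells never visited are reported with `value = 0` and `n = 0` ("zero
#' density"), distinguishable from visited cells through `n`.
#'
#' @param traj Trajectory.
#' @param beads Integer bead selection (e.g. from [select_beads()]).
#' @param bin_width Cell widths `c(x, z)` in nm.
#' @param begin,end Optional time window (ns).
#' @return A `scalar_field2d` tibble: `a` (x-bin centre), `z`, `value`, `n`.
#' @export
number_density_map <- function(traj, beads, bin_width = c(0.2, 0.2),
                               begin = NULL, end = NULL) {
  if (!length(beads)) abort("empty bead selection")
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  bin_width <- rep(bin_width, length.out = 2)
  sel <- traj[traj$bead %in% beads, ]
  nf <- length(unique(traj$time))
  fld <- field_from_points(sel$x %% box[1], sel$z, rep(1, nrow(sel)),
                           bin_width, a_range = c(0, box[1]),
                           z_range = c(0, box[3]), alab = "x")
  area <- bin_width[1] * bin_width[2]
  fld$value <- fld$n / (nf * area)
  attr(fld, "cell_area") <- area
  attr(fld, "n_frames") <- nf
  fld
}

#' Snorkeling fraction of charged ligand termini
#'
#' Fraction of MUS terminal beads outside the hydrophobic core band, i.e.
#' in the head-group slabs or the water phase -- the signature of charged
#' termini "snorkeling" up to the lipid head groups while the NP sits in
#' the bilayer core.
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param termini Bead selection; defaults to MUS terminal beads.
#' @param core_halfwidth Half-width (nm) of the core band around the
#'   bilayer midplane (the complement of head-group slabs + water).
#' @param begin,end Optional time window (ns).
#' @return `list(fraction, series)`: the frame-averaged fraction and a
#'   per-frame tibble (`time`, `fraction`).
#' @export
snorkel_fraction <- function(traj, top, termini = NULL, core_halfwidth = 1.0,
                             begin = NULL, end = NULL) {
  if (core_halfwidth <= 0) abort("core half-width must be positive")
  termini <- termini %||% select_beads(top, species = "MUS", role = "terminal")
  if (!length(termini)) abort("empty termini selection")
  traj <- time_window(traj, begin, end)
  po4 <- select_beads(top, role = "PO4")
  series <- purrr::map_dfr(traj_frames(traj), function(fr) {
    zmid <- if (length(po4)) mean(fr$z[fr$bead %in% po4]) else traj_box(fr)[3] / 2
    zt <- fr$z[fr$bead %in% termini]
    tibble(time = fr$time[1],
           fraction = mean(abs(zt - zmid) >= core_halfwidth))
  })
  list(fraction = mean(series$fraction), series = series)
}

#' Radial concentration profile around the NP centre
#'
#' Molecule (COM) or bead counts per lateral annulus area, frame-averaged
#' and normalized by the bulk concentration `c_bulk`, estimated as the mean
#' annulus concentration over d in `[6, min(lx, ly)/2 - 1]` nm (override via
#' `bulk_range`). Standard errors come from block averaging over 5 equal
#' time blocks.
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param species Species to profile (e.g. `"CHOL"`); must be present.
#' @param center Lateral centre `c(x, y)`; defaults to the NP core COM,
#'   else the box centre.
#' @param bin_width Annulus width, nm.
#' @param mode `"molecule"` (count molecule COMs, the default) or `"bead"`.
#' @param bulk_range `c(lo, hi)` in nm for the bulk reference region.
#' @param begin,end Optional time window (ns).
#' @return A `radial_profile` tibble (`d`, `value`, `se`, `n`) with
#'   attribute `"c_bulk"` (nm^-2).
#' @export
radial_concentration <- function(traj, top, species, center = NULL,
                                 bin_width = 0.5, mode = c("molecule", "bead"),
                                 bulk_range = NULL, begin = NULL, end = NULL) {
  mode <- match.arg(mode)
  beads <- select_beads(top, species = species)
  if (!length(beads)) abort(paste0("species ", species, " not present in topology"))
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  center <- center %||% default_center(traj, top, box)
  d_max <- min(box[1], box[2]) / 2
  breaks <- seq(0, d_max, by = bin_width)
  n_bins <- length(breaks) - 1L
  mol_of <- top$molecule_id[match(beads, top$bead)]
  per_frame <- lapply(traj_frames(traj), function(fr) {
    sel <- fr[match(beads, fr$bead), ]
    if (mode == "molecule") {
      xs <- tapply(sel$x, mol_of, mean)
      ys <- tapply(sel$y, mol_of, mean)
      pos <- cbind(as.numeric(xs), as.numeric(ys))
    } else pos <- cbind(sel$x, sel$y)
    d <- lateral_distance(pos, center, box)
    i <- findInterval(d, breaks)
    keep <- i >= 1 & i <= n_bins
    list(sum = tapply_full(rep(1, sum(keep)), i[keep], n_bins, sum),
         n = tapply_full(rep(1, sum(keep)), i[keep], n_bins, length))
  })
  area <- pi * (tail(breaks, -1)^2 - head(breaks, -1)^2)
  prof <- block_profile(per_frame, breaks, ratio_of = "density",
                        annulus_area = area)
  bulk_range <- bulk_range %||% c(6, d_max - 1)
  in_bulk <- prof$d >= bulk_range[1] & prof$d <= bulk_range[2]
  if (!any(in_bulk)) abort("bulk reference region is empty; widen the box or pass bulk_range")
  c_bulk <- mean(prof$value[in_bulk], na.rm = TRUE)
  if (!is.finite(c_bulk) || c_bulk <= 0) abort("bulk reference concentration is not positive")
  prof$value <- prof$value / c_bulk
  prof$se <- prof$se / c_bulk
  attr(prof, "c_bulk") <- c_bulk
  prof
}

#' Lateral (2D) radial distribution function
#'
#' g(r) between two bead groups using in-plane minimum-image distances,
#' normalized by the ideal-gas expectation from the mean planar density of
#' group B: `g(r) = n_pairs(r) / (N_A * rho_B * annulus_area)`, frame
#' averaged. Self-pairs (identical bead indices) are excluded.
#'
#' @param traj Trajectory.
#' @param beads_a,beads_b Bead index selections.
#' @param bin_width Annulus width, nm.
#' @param r_max Maximum distance; must not exceed half the smaller lateral
#'   box edge.
#' @param begin,end Optional time window (ns).
#' @return A `radial_profile` tibble (`d`, `value`, `se`, `n`).
#' @export
rdf_2d <- function(traj, beads_a, beads_b, bin_width = 0.1, r_max = NULL,
                   begin = NULL, end = NULL) {
  if (!length(beads_a) || !length(beads_b)) abort("both groups must be nonempty")
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  half <- min(box[1], box[2]) / 2
  r_max <- r_max %||% half
  if (r_max > half + 1e-9) abort("r_max exceeds half the smallest lateral box edge")
  breaks <- seq(0, r_max, by = bin_width)
  n_bins <- length(breaks) - 1L
  area <- pi * (tail(breaks, -1)^2 - head(breaks, -1)^2)
  rho_scale <- length(beads_a) * (length(beads_b) / (box[1] * box[2]))
  per_frame <- lapply(traj_frames(traj), function(fr) {
    A <- fr[match(beads_a, fr$bead), ]
    B <- fr[match(beads_b, fr$bead), ]
    dx <- wrap_component(outer(B$x, A$x, "-"), box[1])
    dy <- wrap_component(outer(B$y, A$y, "-"), box[2])
    r <- sqrt(dx^2 + dy^2)
    self <- outer(beads_b, beads_a, "==")
    r <- r[!self]
    i <- findInterval(r, breaks)
    keep <- i >= 1 & i <= n_bins & r > 0
    list(sum = tapply_full(rep(1, sum(keep)), i[keep], n_bins, sum),
         n = tapply_full(rep(1, sum(keep)), i[keep], n_bins, length))
  })
  prof <- block_profile(per_frame, breaks, ratio_of = "density",
                        annulus_area = area * rho_scale)
  prof
}

#' Bilayer thickness profile around the NP centre
#'
#' Per lateral annulus, the distance between the mean phosphate (PO4) z of
#' the upper and lower leaflets, frame-averaged with block-averaged standard
#' errors. Leaflets are assigned per frame from the sign of z(PO4) relative
#' to the midplane (excluding the NP's lateral vicinity from the midplane
#' estimate), and ordered canonically (upper minus lower), so the value is
#' positive for an intact bilayer. Annuli lacking PO4 beads in either
#' leaflet are flagged empty (`NA`).
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param center Lateral centre `c(x, y)`; defaults to NP core COM else box
#'   centre.
#' @param bin_width Annulus width, nm.
#' @param exclude_radius Lateral radius excluded from the midplane estimate.
#' @param begin,end Optional time window (ns).
#' @return A `thickness_profile` tibble (`d`, `value`, `se`, `n`).
#' @export
thickness_profile <- function(traj, top, center = NULL, bin_width = 0.5,
                              exclude_radius = 2.15, begin = NULL, end = NULL) {
  po4 <- select_beads(top, role = "PO4")
  if (!length(po4)) abort("topology has no PO4 beads (leaflet labels unavailable)")
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  center <- center %||% default_center(traj, top, box)
  d_max <- min(box[1], box[2]) / 2
  breaks <- seq(0, d_max, by = bin_width)
  n_bins <- length(breaks) - 1L
  per_frame <- lapply(traj_frames(traj), function(fr) {
    sel <- fr[match(po4, fr$bead), ]
    d <- lateral_distance(cbind(sel$x, sel$y), center, box)
    far <- d > exclude_radius
    zmid <- if (any(far)) mean(sel$z[far]) else mean(sel$z)
    upper <- sel$z >= zmid
    i <- findInterval(d, breaks)
    keep <- i >= 1 & i <= n_bins
    zu <- tapply_full(sel$z[keep & upper], i[keep & upper], n_bins, mean)
    nu <- tapply_full(sel$z[keep & upper], i[keep & upper], n_bins, length)
    zl <- tapply_full(sel$z[keep & !upper], i[keep & !upper], n_bins, mean)
    nl <- tapply_full(sel$z[keep & !upper], i[keep & !upper], n_bins, length)
    th <- ifelse(nu > 0 & nl > 0, abs(zu - zl), NA_real_)
    list(sum = ifelse(is.na(th), 0, th), n = as.integer(!is.na(th)))
  })
  prof <- block_profile(per_frame, breaks, ratio_of = "mean")
  class(prof) <- unique(c("thickness_profile", class(prof)))
  prof
}

#' Fit a Gaussian well to a radial profile
#'
#' Least-squares fit of `value(d) = bulk - depth * exp(-d^2 / (2 sigma^2))`,
#' the model used by the planted depletion and thinning fields. Used to
#' quantify recovered well depths.
#'
#' @param profile A `radial_profile` (columns `d`, `value`). Bins are
#'   weighted by annulus area (proportional to d): the statistical exposure
#'   of an annulus grows with its area, so equal weights would let the noisy
#'   innermost bins dominate.
#' @param sigma_start,depth_start,bulk_start Starting values.
#' @return A one-row tibble: `depth`, `sigma`, `bulk`, `rss`.
#' @export
fit_gaussian_well <- function(profile, sigma_start = 2,
                              depth_start = NULL, bulk_start = NULL) {
  ok <- is.finite(profile$value)
  d <- profile$d[ok]; v <- profile$value[ok]
  w <- d / mean(d)
  if (length(v) < 4) abort("too few finite bins to fit a well")
  bulk0 <- bulk_start %||% mean(v[d >= stats::quantile(d, 0.7)])
  depth0 <- depth_start %||% (bulk0 - min(v))
  sse <- function(p) {
    pred <- p[3] - p[1] * exp(-d^2 / (2 * p[2]^2))
    sum(w * (v - pred)^2)
  }
  fit <- stats::optim(c(depth0, sigma_start, bulk0), sse, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  tibble(depth = fit$par[1], sigma = abs(fit$par[2]), bulk = fit$par[3],
         rss = fit$value)
}
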