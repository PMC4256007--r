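#' Tail-bond selection for order-parameter analysis
#'
#' Returns the bead-index pairs whose orientation defines the lipid tail
#' order parameter: for each DPPC, all consecutive tail-bead bonds plus the
#' glycerol-to-first-tail bond of each chain (8 bonds per lipid), each
#' weighted equally -- the standard convention for 4-bead CG tails.
#'
#' @param top Topology.
#' @return Tibble with columns `i`, `j` (bead indices) and `molecule_id`.
#' @export
tail_bonds <- function(top) {
  chains <- list(c("GL1", "C1A", "C2A", "C3A", "C4A"),
                 c("GL2", "C1B", "C2B", "C3B", "C4B"))
  dppc <- top[top$species == "DPPC", ]
  if (!nrow(dppc)) abort("no DPPC molecules in topology")
  mols <- sort(unique(dppc$molecule_id))
  rows <- list()
  for (chain in chains) {
    beads <- lapply(chain, function(a) {
      b <- dppc$bead[dppc$atom == a]
      b[match(mols, dppc$molecule_id[dppc$atom == a])]
    })
    for (k in seq_len(length(chain) - 1)) {
      rows[[length(rows) + 1L]] <- tibble(i = beads[[k]], j = beads[[k + 1]],
                                          molecule_id = mols)
    }
  }
  out <- bind_rows(rows)
  out[stats::complete.cases(out), ]
}

#' Per-bond P2 order parameter
#'
#' `P2 = (3 cos^2(alpha) - 1) / 2`, with alpha the angle between the bond
#' vector (minimum image) and the bilayer normal (z). Values lie in
#' \[-0.5, 1\]: 1 for a bond along the normal, -0.5 in-plane, 0 on average
#' for isotropic orientations.
#'
#' @param frame One-frame trajectory.
#' @param bonds Bond table from [tail_bonds()] (columns `i`, `j`).
#' @return The bond table with added midpoint columns `mx`, `my`, `mz` and
#'   the per-bond `p2`.
#' @export
p2_of_bonds <- function(frame, bonds) {
  box <- validate_box(traj_box(frame))
  fi <- match(bonds$i, frame$bead)
  fj <- match(bonds$j, frame$bead)
  if (anyNA(fi) || anyNA(fj)) abort("bond beads missing from frame")
  a <- cbind(frame$x[fi], frame$y[fi], frame$z[fi])
  b <- cbind(frame$x[fj], frame$y[fj], frame$z[fj])
  d <- min_image_disp(a, b, box)
  d <- rbind(d)
  len2 <- rowSums(d^2)
  if (any(len2 == 0)) abort("zero-length bond")
  cos2 <- d[, 3]^2 / len2
  mid <- a + d / 2
  out <- as_tibble(bonds)
  out$mx <- unname(mid[, 1] %% box[1])
  out$my <- unname(mid[, 2] %% box[2])
  out$mz <- unname(mid[, 3])
  out$p2 <- unname((3 * cos2 - 1) / 2)
  out
}

#' Spatial map of the P2 order parameter
#'
#' Ensemble average of per-bond P2 binned by bond midpoint, either on a
#' (lateral distance from centre) x z grid (`mode = "radial"`) or a
#' Cartesian x-z grid (`mode = "xz"`). Cells never visited are flagged
#' empty (`NA` value, `n = 0`), not zero.
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param bonds Bond table; defaults to [tail_bonds()].
#' @param mode `"radial"` or `"xz"`.
#' @param center Lateral centre `c(x, y)` for radial mode; defaults to the
#'   NP core COM of the first frame, else the box centre.
#' @param bin_width Bin width(s) in nm (first axis, z). Default 0.2 nm.
#' @param begin,end Optional time window (ns).
#' @return A `scalar_field2d` tibble: `a` (first-axis centre), `z` (z-bin
#'   centre), `value`, `n`.
#' @export
p2_map <- function(traj, top, bonds = tail_bonds(top), mode = c("radial", "xz"),
                   center = NULL, bin_width = c(0.2, 0.2),
                   begin = NULL, end = NULL) {
  mode <- match.arg(mode)
  if (!nrow(bonds)) abort("empty bond selection")
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  bin_width <- rep(bin_width, length.out = 2)
  center <- center %||% default_center(traj, top, box)
  per <- lapply(traj_frames(traj), function(fr) {
    pb <- p2_of_bonds(fr, bonds)
    a <- if (mode == "radial") {
      lateral_distance(cbind(pb$mx, pb$my), center, box)
    } else pb$mx
    tibble(a = a, z = pb$mz, p2 = pb$p2)
  })
  dat <- bind_rows(per)
  a_max <- if (mode == "radial") min(box[1], box[2]) / 2 else box[1]
  field_from_points(dat$a, dat$z, dat$p2, bin_width,
                    a_range = c(0, a_max), z_range = c(0, box[3]),
                    alab = if (mode == "radial") "d" else "x")
}

default_center <- function(traj, top, box) {
  np_beads <- top$bead[top$species == "NP_core"]
  if (length(np_beads)) {
    fr <- traj[traj$time == min(traj$time), ]
    attr(fr, "box") <- box
    bead_com(fr, np_beads)[1:2]
  } else box[1:2] / 2
}

field_from_points <- function(a, z, value, bin_width, a_range, z_range, alab) {
  nA <- max(1L, ceiling((a_range[2] - a_range[1]) / bin_width[1] - 1e-9))
  nZ <- max(1L, ceiling((z_range[2] - z_range[1]) / bin_width[2] - 1e-9))
  brA <- a_range[1] + bin_width[1] * (0:nA)
  brZ <- z_range[1] + bin_width[2] * (0:nZ)
  ia <- findInterval(a, brA, rightmost.closed = TRUE)
  iz <- findInterval(z, brZ, rightmost.closed = TRUE)
  ok <- ia >= 1 & ia < length(brA) & iz >= 1 & iz < length(brZ)
  ia <- ia[ok]; iz <- iz[ok]; value <- value[ok]
  key <- (iz - 1L) * (length(brA) - 1L) + ia
  ncell <- (length(brA) - 1L) * (length(brZ) - 1L)
  sums <- rep(0, ncell); cnt <- rep(0L, ncell)
  tb <- tapply(value, key, sum)
  ct <- tapply(value, key, length)
  idx <- as.integer(names(tb))
  sums[idx] <- tb; cnt[idx] <- ct
  grid <- expand.grid(a = (head(brA, -1) + tail(brA, -1)) / 2,
                      z = (head(brZ, -1) + tail(brZ, -1)) / 2)
  out <- tibble(a = grid$a, z = grid$z,
                value = ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_),
                n = cnt)
  attr(out, "axis_label") <- alab
  attr(out, "bin_width") <- bin_width
  class(out) <- unique(c("scalar_field2d", class(out)))
  out
}

#' Radial profile of the P2 order parameter
#'
#' Mean per-bond P2 in lateral annuli around a centre, with block-averaged
#' standard errors (5 time blocks).
#'
#' @inheritParams p2_map
#' @param bin_width Annulus width, nm.
#' @return A `radial_profile` tibble: `d`, `value`, `se`, `n`.
#' @export
p2_profile <- function(traj, top, bonds = tail_bonds(top), center = NULL,
                       bin_width = 0.5, begin = NULL, end = NULL) {
  traj <- time_window(traj, begin, end)
  box <- validate_box(traj_box(traj))
  center <- center %||% default_center(traj, top, box)
  d_max <- min(box[1], box[2]) / 2
  breaks <- seq(0, d_max, by = bin_width)
  per_frame <- lapply(traj_frames(traj), function(fr) {
    pb <- p2_of_bonds(fr, bonds)
    d <- lateral_distance(cbind(pb$mx, pb$my), center, box)
    i <- findInterval(d, breaks)
    keep <- i >= 1 & i < length(breaks)
    list(sum = tapply_full(pb$p2[keep], i[keep], length(breaks) - 1L, sum),
         n = tapply_full(pb$p2[keep], i[keep], length(breaks) - 1L, length))
  })
  block_profile(per_frame, breaks, ratio_of = "mean")
}

tapply_full <- function(x, idx, n_bins, fun) {
  out <- rep(0, n_bins)
  if (length(x)) {
    tb <- tapply(x, idx, fun)
    out[as.integer(names(tb))] <- tb
  }
  out
}

# contiguous near-equal blocks of 1..n (k <= n guaranteed)
split_blocks <- function(n, k) {
  k <- max(1L, min(k, n))
  split(seq_len(n), ((seq_len(n) - 1L) * k) %/% n + 1L)
}

# combine per-frame {sum, n} lists into a profile with 5-block SEs
block_profile <- function(per_frame, breaks, ratio_of = c("mean", "density"),
                          annulus_area = NULL) {
  n_bins <- length(breaks) - 1L
  nf <- length(per_frame)
  blocks <- split_blocks(nf, 5L)
  block_vals <- vapply(blocks, function(ix) {
    s <- Reduce(`+`, lapply(per_frame[ix], `[[`, "sum"))
    n <- Reduce(`+`, lapply(per_frame[ix], `[[`, "n"))
    if (ratio_of[1] == "mean") ifelse(n > 0, s / n, NA_real_)
    else (n / length(ix)) / annulus_area
  }, numeric(n_bins))
  block_vals <- rbind(block_vals)
  if (n_bins == 1L) block_vals <- matrix(block_vals, nrow = 1)
  value <- rowMeans(block_vals, na.rm = TRUE)
  se <- apply(block_vals, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  n_tot <- Reduce(`+`, lapply(per_frame, `[[`, "n"))
  out <- tibble(d = (head(breaks, -1) + tail(breaks, -1)) / 2,
                value = ifelse(n_tot > 0 | ratio_of[1] == "density", value, NA_real_),
                se = se, n = n_tot)
  class(out) <- unique(c("radial_profile", class(out)))
  out
}

#' Classify a P2 value into a bilayer phase
#'
#' Liquid-disordered (Ld) for P2 in \[0.2, 0.5\], liquid-ordered (Lo) for
#' \[0.7, 1\], `"intermediate"` otherwise (including the (0.5, 0.7) gap and
#' values below 0.2). Total and piecewise-constant over \[-0.5, 1\].
#'
#' @param p2 Numeric vector of order parameters in \[-0.5, 1\].
#' @return Character vector in `{"Ld", "intermediate", "Lo"}`.
#' @export
#' @examples
#' classify_phase(c(0.4, 0.85, 0.6))
classify_phase <- function(p2) {
  if (any(!is.finite(p2)) || any(p2 < -0.5 - 1e-9 | p2 > 1 + 1e-9)) {
    abort("P2 values must lie in [-0.5, 1]")
  }
  ifelse(p2 >= 0.2 & p2 <= 0.5, "Ld",
         ifelse(p2 >= 0.7, "Lo", "intermediate"))
}
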