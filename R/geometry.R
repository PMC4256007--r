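#' Periodic box utilities and minimum-image geometry
#'
#' All coordinates in this package are in nm, in orthorhombic periodic boxes.
#' A box is a numeric vector `c(lx, ly, lz)`; trajectories carry it as the
#' `"box"` attribute.
#'
#' @name geometry
NULL

validate_box <- function(box) {
  if (is.null(box)) {
    abort("this operation requires a periodic box, but the trajectory has none")
  }
  if (!is.numeric(box) || length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("`box` must be three positive finite edge lengths (nm)")
  }
  invisible(box)
}

# wrap a displacement component into (-L/2, L/2]
wrap_component <- function(d, L) {
  d - L * ceiling(d / L - 0.5)
}

#' Minimum-image displacement
#'
#' Displacement `b - a` with each component wrapped into `(-L/2, L/2]`.
#'
#' @param a,b Numeric 3-vectors, or matrices with 3 columns (one row per bead).
#' @param box Box edge lengths `c(lx, ly, lz)` in nm.
#' @return A vector or matrix of wrapped displacement components.
#' @export
#' @examples
#' min_image_disp(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10)) # x component -2
min_image_disp <- function(a, b, box) {
  validate_box(box)
  a <- rbind(a); b <- rbind(b)
  d <- unname(b - a)
  for (k in 1:3) d[, k] <- wrap_component(d[, k], box[k])
  if (nrow(d) == 1L) drop(d) else d
}

#' Lateral (in-plane) minimum-image distance
#'
#' Distance in the bilayer (x, y) plane between positions and a reference
#' point, ignoring z. Used for all NP-centred radial profiles.
#'
#' @param xy Matrix with columns x, y (a third column is ignored), or a
#'   2/3-vector.
#' @param ref Reference point (x, y) -- typically the NP centre of mass.
#' @param box Box edge lengths.
#' @return Numeric vector of distances (nm).
#' @export
lateral_distance <- function(xy, ref, box) {
  validate_box(box)
  xy <- unname(rbind(xy))
  dx <- wrap_component(xy[, 1] - unname(ref[1]), box[1])
  dy <- wrap_component(xy[, 2] - unname(ref[2]), box[2])
  unname(sqrt(dx^2 + dy^2))
}

#' Full minimum-image distance
#'
#' @inheritParams min_image_disp
#' @return Numeric vector of 3D minimum-image distances (nm).
#' @export
min_image_dist <- function(a, b, box) {
  d <- min_image_disp(a, b, box)
  d <- rbind(d)
  sqrt(rowSums(d^2))
}

traj_box <- function(traj) attr(traj, "box", exact = TRUE)

`traj_box<-` <- function(traj, value) {
  if (!is.null(value)) validate_box(value)
  attr(traj, "box") <- value
  traj
}

# coordinate matrix of one frame (rows ordered by bead index)
frame_coords <- function(frame) {
  as.matrix(frame[order(frame$bead), c("x", "y", "z")])
}
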