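#' Plant known radial structure into a bilayer trajectory
#'
#' Rewrites a generated bilayer so that its ensemble structure around a
#' lateral centre point matches analytically known targets, giving every
#' downstream estimator an exact recovery test:
#'
#' * `p2_field`: DPPC tail-bond orientations are redrawn per lipid from the
#'   maximum-entropy orientation distribution whose mean P2 equals the field
#'   value at the lipid's lateral distance d.
#' * `chol_depletion`: cholesterol positions are resampled by rejection so
#'   the lateral cholesterol density is proportional to the depletion
#'   profile (uniform where the profile is 1).
#' * `thinning`: each leaflet's phosphate plane is displaced so the local
#'   PO4-PO4 thickness equals the profile value; whole molecules translate
#'   with their phosphate.
#' * `snorkel_fraction`: MUS terminal beads are placed so that exactly the
#'   rounded target fraction sits in the head-group slabs and the rest in
#'   the hydrophobic core band.
#'
#' Every frame is re-planted independently. Deterministic given `seed`.
#'
#' @param traj Trajectory from [gen_bilayer()] (optionally with an inserted
#'   NP).
#' @param top Its topology.
#' @param planted A [planted_structure()].
#' @param np_center Lateral centre `c(x, y)` the radial fields refer to;
#'   defaults to the NP core centre of mass if NP beads are present, else
#'   the box centre.
#' @param seed Integer seed.
#' @return The modified trajectory (same beads, same box).
#' @export
plant_structure <- function(traj, top, planted, np_center = NULL, seed = 1L) {
  stopifnot(inherits(planted, "planted_structure"))
  box <- validate_box(traj_box(traj))
  withr::local_seed(seed)
  frames <- lapply(traj_frames(traj), function(fr) {
    plant_frame(fr, top, planted, np_center, box)
  })
  out <- bind_rows(frames)
  attr(out, "box") <- box
  out
}

plant_frame <- function(fr, top, planted, np_center, box) {
  fr <- fr[order(fr$bead), ]
  if (!identical(fr$bead, top$bead)) {
    fr <- fr[match(top$bead, fr$bead), ]
    if (anyNA(fr$bead)) abort("frame beads do not match topology")
  }
  if (is.null(np_center)) {
    np_beads <- top$bead[top$species == "NP_core"]
    np_center <- if (length(np_beads)) bead_com(fr, np_beads)[1:2] else box[1:2] / 2
  }
  po4_rows <- which(top$role == "PO4")
  zmid <- if (length(po4_rows)) mean(fr$z[po4_rows]) else box[3] / 2
  x <- fr$x; y <- fr$y; z <- fr$z

  # --- cholesterol depletion: lateral rejection resampling -----------------
  if (!is.null(planted$chol_depletion)) {
    roh_rows <- which(top$atom == "ROH")
    if (length(roh_rows)) {
      dep <- planted$chol_depletion
      d0 <- lateral_distance(cbind(x[roh_rows], y[roh_rows]), np_center, box)
      p0 <- dep(d0)
      if (any(p0 < -1e-9 | p0 > 1 + 1e-9)) {
        abort("chol_depletion values must lie in [0, 1]")
      }
      need <- which(runif(length(roh_rows)) >= p0)
      newx <- x[roh_rows]; newy <- y[roh_rows]
      it <- 0L
      while (length(need) && it < 1000L) {
        px <- runif(length(need), 0, box[1])
        py <- runif(length(need), 0, box[2])
        pd <- lateral_distance(cbind(px, py), np_center, box)
        acc <- runif(length(need)) < dep(pd)
        newx[need[acc]] <- px[acc]; newy[need[acc]] <- py[acc]
        need <- need[!acc]
        it <- it + 1L
      }
      if (length(need)) abort("cholesterol depletion rejection sampling failed to converge")
      mol_of <- top$molecule_id[roh_rows]
      dx <- newx - x[roh_rows]; dy <- newy - y[roh_rows]
      chol_rows <- which(top$species == "CHOL")
      i <- match(top$molecule_id[chol_rows], mol_of)
      x[chol_rows] <- (x[chol_rows] + dx[i]) %% box[1]
      y[chol_rows] <- (y[chol_rows] + dy[i]) %% box[2]
    }
  }

  # --- thickness field: translate molecules with their reference bead -----
  if (!is.null(planted$thinning)) {
    th <- planted$thinning
    for (sp in c("DPPC", "CHOL")) {
      ref_atom <- if (sp == "DPPC") "PO4" else "ROH"
      ref_rows <- which(top$species == sp & top$atom == ref_atom)
      if (!length(ref_rows)) next
      s <- ifelse(top$leaflet[ref_rows] == "upper", 1, -1)
      d <- lateral_distance(cbind(x[ref_rows], y[ref_rows]), np_center, box)
      half <- th(d) / 2
      if (any(!is.finite(half) | half <= 0)) abort("thinning profile must be positive")
      inset <- if (sp == "DPPC") 0 else 0.3
      zt <- zmid + s * (half - inset) + rnorm(length(ref_rows), 0, PO4_Z_NOISE)
      dz <- zt - z[ref_rows]
      sp_rows <- which(top$species == sp)
      i <- match(top$molecule_id[sp_rows], top$molecule_id[ref_rows])
      z[sp_rows] <- z[sp_rows] + dz[i]
    }
  }

  # --- order-parameter field: redraw tail chains --------------------------
  if (!is.null(planted$p2_field)) {
    po4 <- which(top$species == "DPPC" & top$atom == "PO4")
    if (length(po4)) {
      d <- lateral_distance(cbind(x[po4], y[po4]), np_center, box)
      targets <- planted$p2_field(d)
      if (any(targets < -0.5 - 1e-9 | targets > 1 + 1e-9)) {
        abort("p2_field target outside [-0.5, 1]")
      }
      s <- ifelse(top$leaflet[po4] == "upper", 1, -1)
      mol_ids <- top$molecule_id[po4]
      for (chain in list(c("GL1", paste0("C", 1:4, "A")),
                         c("GL2", paste0("C", 1:4, "B")))) {
        rows_by_atom <- lapply(chain, function(a) {
          r <- which(top$species == "DPPC" & top$atom == a)
          r[match(mol_ids, top$molecule_id[r])]
        })
        anchor <- rows_by_atom[[1]]
        ch <- tail_chain_block(x[anchor], y[anchor], z[anchor], s, targets)
        for (j in 1:4) {
          rj <- rows_by_atom[[j + 1]]
          x[rj] <- ch$x[, j] %% box[1]
          y[rj] <- ch$y[, j] %% box[2]
          z[rj] <- ch$z[, j]
        }
      }
    }
  }

  # --- snorkeling: place MUS termini in / out of the core band ------------
  if (!is.null(planted$snorkel_fraction)) {
    term <- which(top$species == "MUS" & top$role == "terminal")
    if (length(term)) {
      f <- planted$snorkel_fraction
      if (f < 0 || f > 1) abort("snorkel_fraction must be in [0, 1]")
      n <- length(term)
      n_out <- round(f * n)
      out_idx <- sample(n, n_out)
      hw <- planted$headgroup_halfwidth
      if (hw <= 0) abort("headgroup half-width must be positive")
      z_up <- if (length(po4_rows)) mean(fr$z[po4_rows][fr$z[po4_rows] >= zmid]) else zmid + 2
      z_lo <- if (length(po4_rows)) mean(fr$z[po4_rows][fr$z[po4_rows] < zmid]) else zmid - 2
      slab <- ifelse(runif(n_out) < 0.5, z_up, z_lo)
      znew <- rep(NA_real_, n)
      znew[out_idx] <- slab + runif(n_out, -hw, hw)
      core_idx <- setdiff(seq_len(n), out_idx)
      znew[core_idx] <- zmid + runif(length(core_idx), -planted$core_halfwidth,
                                     planted$core_halfwidth)
      z[term] <- znew
    }
  }

  tibble(time = fr$time, bead = top$bead, x = x, y = y, z = z)
}
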