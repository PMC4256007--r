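#' Generate a ligand-coated nanoparticle
#'
#' Core beads are distributed quasi-uniformly (Fibonacci lattice) on a sphere
#' of `core_diameter`; MUS and OT ligands are attached as radial bead strings
#' at 2:1 ratio, with the MUS terminal bead flagged charged (-1e). The total
#' charge therefore equals `-n_mus` (the default reproduces -134 e).
#'
#' @param spec An [np_spec()].
#' @param seed Integer seed (chain-bead jitter).
#' @param center Core centre `c(x, y, z)` in nm.
#' @param bead_offset,molecule_id Index offsets used when inserting into an
#'   existing system.
#' @return `list(frame, topology)`: a one-frame coordinate tibble and the
#'   topology fragment.
#' @export
gen_np <- function(spec, seed, center = c(0, 0, 0), bead_offset = 0L,
                   molecule_id = 1L) {
  stopifnot(inherits(spec, "np_spec"))
  r_core <- spec$core_diameter / 2
  n_core <- max(12L, round(4 * pi * r_core^2 / 0.21))
  n_lig <- spec$n_mus + spec$n_ot
  lig_species <- rep(c("MUS", "MUS", "OT"), length.out = n_lig)
  if (sum(lig_species == "MUS") != spec$n_mus) {
    lig_species <- c(rep("MUS", spec$n_mus), rep("OT", spec$n_ot))
  }
  len <- spec$ligand_length_beads

  core <- fibonacci_sphere(n_core, r_core)
  anchors <- fibonacci_sphere(n_lig, 1)   # unit directions

  withr::local_seed(seed)
  lig_rows <- lapply(seq_len(n_lig), function(i) {
    L <- unname(len[tolower(lig_species[i])])
    radii <- r_core + 0.23 + 0.35 * seq_len(L)
    pos <- outer(radii, anchors[i, ]) + matrix(rnorm(3 * L, 0, 0.02), ncol = 3)
    roles <- c(rep("chain", L - 1), "terminal")
    charge <- c(rep(0, L - 1),
                if (lig_species[i] == "MUS") spec$mus_charge else 0)
    tibble(species = lig_species[i], role = roles, atom = paste0("L", seq_len(L)),
           charge = charge, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  lig <- bind_rows(lig_rows)

  n_beads <- n_core + nrow(lig)
  top <- topology(
    bead = bead_offset + seq_len(n_beads),
    molecule_id = molecule_id,
    species = c(rep("NP_core", n_core), lig$species),
    role = c(rep("core", n_core), lig$role),
    atom = c(rep("CORE", n_core), lig$atom),
    charge = c(rep(0, n_core), lig$charge),
    leaflet = "none"
  )
  frame <- tibble(
    time = 0, bead = top$bead,
    x = center[1] + c(core[, 1], lig$x),
    y = center[2] + c(core[, 2], lig$y),
    z = center[3] + c(core[, 3], lig$z)
  )
  list(frame = frame, topology = top)
}

# quasi-uniform points on a sphere of radius r
fibonacci_sphere <- function(n, r) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  r * cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Insert a nanoparticle into a bilayer system
#'
#' Re-indexes the NP beads and molecule, translates its core centre of mass
#' to `center` (default: lateral box centre at the bilayer midplane), and
#' replicates the NP coordinates into every frame of the trajectory.
#'
#' @param traj Bilayer trajectory.
#' @param top Bilayer topology.
#' @param np Output of [gen_np()].
#' @param center Target `c(x, y, z)` for the core centre.
#' @return `list(traj, topology)` of the combined system.
#' @export
insert_np <- function(traj, top, np, center = NULL) {
  box <- validate_box(traj_box(traj))
  if (is.null(center)) center <- c(box[1] / 2, box[2] / 2, box[3] / 2)
  np_top <- np$topology
  np_fr <- np$frame
  core_beads <- np_top$bead[np_top$role == "core"]
  com <- bead_com(np_fr, core_beads)
  offset_b <- max(top$bead)
  offset_m <- max(top$molecule_id)
  np_top$bead <- np_top$bead - min(np_top$bead) + 1L + offset_b
  np_top$molecule_id <- np_top$molecule_id - min(np_top$molecule_id) + 1L + offset_m
  shift <- center - com
  times <- unique(traj$time)
  np_frames <- bind_rows(lapply(times, function(tm) {
    tibble(time = tm, bead = np_top$bead,
           x = (np_fr$x + shift[1]) %% box[1],
           y = (np_fr$y + shift[2]) %% box[2],
           z = np_fr$z + shift[3])
  }))
  out <- bind_rows(as_tibble(traj), np_frames)
  out <- out[order(out$time, out$bead), ]
  attr(out, "box") <- box
  list(traj = out, topology = validate_topology(bind_rows(as_tibble(top), np_top)))
}
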