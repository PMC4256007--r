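SPECIES_LEVELS <- c("DPPC", "CHOL", "NP_core", "MUS", "OT", "W", "ION")
ROLE_LEVELS <- c("PO4", "choline", "glycerol", "tail", "hydroxyl", "sterol",
                 "terminal", "chain", "core")

#' Construct and validate a bead topology
#'
#' The topology is the semantic layer over raw coordinates: one row per bead,
#' giving the molecule it belongs to, its chemical species, its structural
#' role, partial charge (units of e) and leaflet label. Every analysis
#' function takes a trajectory together with its topology.
#'
#' @param bead Integer bead indices (1-based, unique).
#' @param molecule_id Integer molecule identifier per bead.
#' @param species One of `r paste(SPECIES_LEVELS, collapse = ", ")`.
#' @param role One of `r paste(ROLE_LEVELS, collapse = ", ")`.
#' @param atom Short atom/bead name (e.g. "PO4", "C1A"); used to build bond
#'   lists.
#' @param charge Partial charge in e.
#' @param leaflet `"upper"`, `"lower"` or `"none"`.
#' @return A tibble of class `np_topology`.
#' @export
topology <- function(bead, molecule_id, species, role, atom = role,
                     charge = 0, leaflet = "none") {
  top <- tibble(
    bead = as.integer(bead),
    molecule_id = as.integer(molecule_id),
    species = as.character(species),
    role = as.character(role),
    atom = as.character(atom),
    charge = as.numeric(charge),
    leaflet = as.character(leaflet)
  )
  validate_topology(top)
}

validate_topology <- function(top) {
  if (anyDuplicated(top$bead)) abort("duplicate bead indices in topology")
  bad_sp <- setdiff(unique(top$species), SPECIES_LEVELS)
  if (length(bad_sp)) abort(paste0("unknown species: ", paste(bad_sp, collapse = ", ")))
  bad_role <- setdiff(unique(top$role), ROLE_LEVELS)
  if (length(bad_role)) abort(paste0("unknown role: ", paste(bad_role, collapse = ", ")))
  bad_leaf <- setdiff(unique(top$leaflet), c("upper", "lower", "none"))
  if (length(bad_leaf)) abort(paste0("unknown leaflet label: ", paste(bad_leaf, collapse = ", ")))
  mus_term <- top$species == "MUS" & top$role == "terminal"
  if (any(mus_term) && any(top$charge[mus_term] != -1)) {
    abort("every MUS terminal bead must carry charge -1e")
  }
  class(top) <- unique(c("np_topology", class(top)))
  top
}

#' Select bead indices by species and role
#'
#' @param top A topology.
#' @param species,role,atom Optional character vectors to filter on; `NULL`
#'   keeps everything.
#' @return Integer vector of bead indices (possibly empty).
#' @export
select_beads <- function(top, species = NULL, role = NULL, atom = NULL) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(species)) keep <- keep & top$species %in% species
  if (!is.null(role)) keep <- keep & top$role %in% role
  if (!is.null(atom)) keep <- keep & top$atom %in% atom
  top$bead[keep]
}

#' Assign leaflet labels per frame
#'
#' Labels each PO4-bearing lipid (and, by molecule, all of its beads) as upper
#' or lower by the sign of z(PO4) minus the bilayer midplane. The midplane is
#' the mean PO4 z over beads farther laterally than `exclude_radius` from
#' `np_com`, so the locally deformed region around a nanoparticle does not
#' bias the reference plane.
#'
#' @param frame One-frame trajectory tibble (bead, x, y, z).
#' @param top Topology.
#' @param np_com Optional `c(x, y)` nanoparticle centre; with
#'   `exclude_radius`, PO4 beads within that lateral distance are excluded
#'   from the midplane estimate.
#' @param exclude_radius Lateral exclusion radius, nm.
#' @return The topology with refreshed `leaflet` labels.
#' @export
assign_leaflets <- function(frame, top, np_com = NULL, exclude_radius = 2.15) {
  po4 <- top$bead[top$role == "PO4"]
  if (!length(po4)) abort("no PO4 beads in topology; cannot assign leaflets")
  fr <- frame[match(po4, frame$bead), ]
  use <- rep(TRUE, nrow(fr))
  if (!is.null(np_com)) {
    d <- lateral_distance(as.matrix(fr[, c("x", "y")]), np_com, traj_box(frame))
    use <- d > exclude_radius
    if (!any(use)) use <- rep(TRUE, nrow(fr))
  }
  z_mid <- mean(fr$z[use])
  side <- ifelse(fr$z >= z_mid, "upper", "lower")
  mol_side <- setNames(side, top$molecule_id[match(po4, top$bead)])
  top$leaflet <- ifelse(as.character(top$molecule_id) %in% names(mol_side),
                        mol_side[as.character(top$molecule_id)], top$leaflet)
  top
}

# molecules of a species, as a tibble(molecule_id)
species_molecules <- function(top, species) {
  unique(top$molecule_id[top$species %in% species])
}

#' Centre of mass of a bead selection in one frame
#'
#' Equal bead masses are assumed (CG beads of a single type class). By the
#' package default the NP centre is computed from core beads only; pass
#' ligand beads too if the alternative convention is wanted.
#'
#' @param frame One-frame trajectory.
#' @param beads Integer bead indices.
#' @return Numeric `c(x, y, z)`.
#' @export
bead_com <- function(frame, beads) {
  fr <- frame[frame$bead %in% beads, ]
  if (!nrow(fr)) abort("empty bead selection for centre of mass")
  c(x = mean(fr$x), y = mean(fr$y), z = mean(fr$z))
}

#' Nanoparticle centre of mass
#'
#' @param frame One-frame trajectory.
#' @param top Topology.
#' @param include_ligands If `TRUE`, ligand (MUS/OT) beads enter the average;
#'   the default uses the rigid core only.
#' @return Numeric `c(x, y, z)`.
#' @export
np_com <- function(frame, top, include_ligands = FALSE) {
  sp <- if (include_ligands) c("NP_core", "MUS", "OT") else "NP_core"
  beads <- select_beads(top, species = sp)
  if (!length(beads)) abort("no nanoparticle beads in topology")
  bead_com(frame, beads)
}

# split a trajectory tibble into per-frame tibbles preserving box
traj_frames <- function(traj) {
  box <- traj_box(traj)
  out <- split(traj, traj$time)
  lapply(out, function(fr) { attr(fr, "box") <- box; fr })
}

# restrict to a time window [begin, end]
time_window <- function(traj, begin = NULL, end = NULL) {
  if (!is.null(begin)) traj <- traj[traj$time >= begin, ]
  if (!is.null(end)) traj <- traj[traj$time <= end, ]
  if (!nrow(traj)) abort("time window selects no frames")
  traj
}
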