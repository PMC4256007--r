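#' Bilayer generator specification
#'
#' Parameters of the synthetic two-leaflet DPPC/cholesterol bilayer. Defaults
#' reflect the study conditions this package targets: a fluid DPPC bilayer at
#' 323 K with a bulk phosphate-to-phosphate separation of 4.0 nm and an area
#' per lipid of 0.64 nm^2. `n_lipids` counts molecules (DPPC + cholesterol);
#' cholesterol fractions from 0 to 0.5 are supported and the two leaflets are
#' populated symmetrically to within one molecule per species.
#'
#' @param n_lipids Total number of lipid molecules (DPPC + CHOL).
#' @param chol_fraction Cholesterol mole fraction in \[0, 1\].
#' @param box_xy Lateral box edge (nm); if `NULL`, derived from
#'   `area_per_lipid` and the per-leaflet molecule count.
#' @param leaflet_separation_bulk Bulk PO4-to-PO4 distance (nm).
#' @param area_per_lipid Area per molecule (nm^2).
#' @param temperature Temperature (K).
#' @param p2_bulk Default tail order parameter away from any planted
#'   structure (0.4 = liquid-disordered).
#' @param waters_per_lipid CG waters per lipid if explicit water beads are
#'   requested at generation time (I/O realism only; analyses never use
#'   them). Exposed as a free parameter.
#' @return A `bilayer_spec` list.
#' @export
bilayer_spec <- function(n_lipids = 512, chol_fraction = 0,
                         box_xy = NULL, leaflet_separation_bulk = 4.0,
                         area_per_lipid = 0.64,
                         temperature = DEFAULT_TEMPERATURE,
                         p2_bulk = 0.4, waters_per_lipid = 28) {
  if (chol_fraction < 0 || chol_fraction > 1) abort("chol_fraction must be in [0, 1]")
  if (n_lipids < 2) abort("n_lipids must be at least 2")
  if (!is.null(box_xy) && box_xy <= 0) abort("box_xy must be positive")
  structure(list(n_lipids = as.integer(n_lipids), chol_fraction = chol_fraction,
                 box_xy = box_xy,
                 leaflet_separation_bulk = leaflet_separation_bulk,
                 area_per_lipid = area_per_lipid, temperature = temperature,
                 p2_bulk = p2_bulk, waters_per_lipid = waters_per_lipid),
            class = "bilayer_spec")
}

#' Nanoparticle generator specification
#'
#' A spherical core decorated with hydrophilic anionic (MUS, terminal charge
#' -1e) and hydrophobic (OT) ligands in the fixed 2:1 MUS:OT ratio. Defaults
#' give the 4.3 nm core with 134 MUS and 67 OT ligands, i.e. total charge
#' -134 e. Ligand counts, not surface charge density, are the primary
#' quantities.
#'
#' @param core_diameter Core diameter (nm).
#' @param n_mus,n_ot Ligand counts; `n_mus` must equal `2 * n_ot`.
#' @param mus_charge Charge per MUS terminal bead (e).
#' @param ligand_length_beads Named counts of beads per ligand chain
#'   (including the terminal bead).
#' @return An `np_spec` list.
#' @export
np_spec <- function(core_diameter = 4.3, n_mus = 134, n_ot = 67,
                    mus_charge = -1,
                    ligand_length_beads = c(mus = 4, ot = 2)) {
  if (n_mus != 2 * n_ot) abort("MUS:OT ratio must be 2:1 (n_mus = 2 * n_ot)")
  if (core_diameter <= 0) abort("core_diameter must be positive")
  structure(list(core_diameter = core_diameter, n_mus = as.integer(n_mus),
                 n_ot = as.integer(n_ot), mus_charge = mus_charge,
                 ligand_length_beads = ligand_length_beads),
            class = "np_spec")
}

#' Planted structural targets around a nanoparticle
#'
#' Encodes, as generative targets, the structural perturbations a membrane-
#' embedded NP induces: a radially varying tail order parameter, cholesterol
#' depletion, bilayer thinning, and snorkeling of charged ligand termini.
#' Each radial field is a function of the lateral distance d (nm) from the
#' NP centre and must relax to its bulk value as d grows.
#'
#' @param p2_field Function d -> target P2 in \[-0.5, 1\], or `NULL`.
#' @param chol_depletion Function d -> relative concentration c(d)/c_bulk in
#'   \[0, 1\], or `NULL`.
#' @param thinning Function d -> PO4-PO4 thickness (nm), or `NULL`.
#' @param snorkel_fraction Target fraction of MUS termini outside the
#'   hydrophobic core band, or `NULL`.
#' @param headgroup_halfwidth Half-width (nm) of the head-group slabs around
#'   each leaflet's mean PO4 plane.
#' @param core_halfwidth Half-width (nm) of the hydrophobic core band around
#'   the bilayer midplane.
#' @return A `planted_structure` list.
#' @export
planted_structure <- function(p2_field = NULL, chol_depletion = NULL,
                              thinning = NULL, snorkel_fraction = NULL,
                              headgroup_halfwidth = 0.5, core_halfwidth = 1.0) {
  structure(list(p2_field = p2_field, chol_depletion = chol_depletion,
                 thinning = thinning, snorkel_fraction = snorkel_fraction,
                 headgroup_halfwidth = headgroup_halfwidth,
                 core_halfwidth = core_halfwidth),
            class = "planted_structure")
}

#' Gaussian radial well
#'
#' `f(d) = bulk - depth * exp(-d^2 / (2 sigma^2))`: the canonical planted
#' perturbation profile. The default width sigma = 2 nm matches the 2-3 nm
#' range over which an embedded NP perturbs the surrounding bilayer.
#'
#' @param depth Well depth (same units as `bulk`).
#' @param sigma Gaussian width (nm).
#' @param bulk Asymptotic bulk value.
#' @return A function of lateral distance d.
#' @export
gaussian_well <- function(depth, sigma = 2, bulk = 1) {
  force(depth); force(sigma); force(bulk)
  function(d) bulk - depth * exp(-d^2 / (2 * sigma^2))
}

# split a species count over two leaflets as evenly as possible
leaflet_split <- function(n) c(upper = ceiling(n / 2), lower = floor(n / 2))

DPPC_ATOMS <- c("NC3", "PO4", "GL1", "C1A", "C2A", "C3A", "C4A",
                "GL2", "C1B", "C2B", "C3B", "C4B")
DPPC_ROLES <- c("choline", "PO4", "glycerol", rep("tail", 4),
                "glycerol", rep("tail", 4))
DPPC_CHARGES <- c(1, -1, rep(0, 10))
CHOL_ATOMS <- c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2")
CHOL_ROLES <- c("hydroxyl", rep("sterol", 7))
BOND_LENGTH <- 0.47   # CG bond length, nm
PO4_Z_NOISE <- 0.05   # thermal roughness of the phosphate plane, nm

#' Generate a synthetic bilayer trajectory
#'
#' Builds a two-leaflet DPPC/cholesterol bilayer with the composition of
#' `spec`, symmetric between leaflets to within one molecule per species.
#' Each DPPC carries choline (NC3, +1e), phosphate (PO4, -1e), two glycerol
#' beads, and two 4-bead tails whose bond orientations are drawn to realise
#' the bulk order parameter `spec$p2_bulk`; cholesterol carries a hydroxyl
#' bead near the head-group region and a 7-bead sterol body. Frames are
#' independent statistical draws (no dynamics) at times `0, dt, ...`, which
#' makes ensemble averages exact and every estimator testable against the
#' planted truth. Deterministic given `seed`.
#'
#' @param spec A [bilayer_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param n_frames Number of frames.
#' @param dt Frame spacing (ns).
#' @param waters If `TRUE`, add `spec$waters_per_lipid * n_lipids` CG water
#'   beads (species `"W"`) uniformly in the solvent slabs. For I/O realism
#'   only: no analysis in this package consumes water beads.
#' @return `list(traj, topology)`: a trajectory tibble (`time`, `bead`, `x`,
#'   `y`, `z`, with a `"box"` attribute) and its topology.
#' @export
gen_bilayer <- function(spec, seed, n_frames = 1, dt = 1, waters = FALSE) {
  stopifnot(inherits(spec, "bilayer_spec"))
  n_chol <- round(spec$n_lipids * spec$chol_fraction)
  n_dppc <- spec$n_lipids - n_chol
  dppc_split <- leaflet_split(n_dppc)
  chol_split <- leaflet_split(n_chol)
  per_leaflet <- max(dppc_split + chol_split)
  lx <- spec$box_xy %||% sqrt(per_leaflet * spec$area_per_lipid)
  lz <- spec$leaflet_separation_bulk + 6
  box <- c(lx, lx, lz)

  mol <- tibble(
    molecule_id = seq_len(spec$n_lipids),
    species = c(rep("DPPC", n_dppc), rep("CHOL", n_chol)),
    leaflet = c(rep(c("upper", "lower"), dppc_split),
                rep(c("upper", "lower"), chol_split))
  )
  top <- build_lipid_topology(mol)
  n_w <- if (waters) round(spec$waters_per_lipid * spec$n_lipids) else 0L
  if (n_w > 0) {
    w_top <- topology(bead = max(top$bead) + seq_len(n_w),
                      molecule_id = max(top$molecule_id) + seq_len(n_w),
                      species = "W", role = "chain", atom = "W",
                      charge = 0, leaflet = "none")
    top <- validate_topology(bind_rows(as_tibble(top), w_top))
  }

  frames <- withr::with_seed(seed, {
    lapply(seq_len(n_frames) - 1L, function(f) {
      fr <- draw_bilayer_frame(mol, spec, box)
      if (n_w > 0) {
        # solvent slabs outside the membrane, 0.5 nm clear of the phosphates
        half <- spec$leaflet_separation_bulk / 2 + 0.5
        zw <- runif(n_w, 0, box[3] - 2 * half)
        zw <- ifelse(zw < box[3] / 2 - half, zw, zw + 2 * half)
        fr <- bind_rows(fr, tibble(time = 0, bead = max(fr$bead) + seq_len(n_w),
                                   x = runif(n_w, 0, box[1]),
                                   y = runif(n_w, 0, box[2]), z = zw))
      }
      fr$time <- f * dt
      fr
    })
  })
  traj <- bind_rows(frames)[, c("time", "bead", "x", "y", "z")]
  attr(traj, "box") <- box
  list(traj = traj, topology = top)
}

build_lipid_topology <- function(mol) {
  n_dppc <- sum(mol$species == "DPPC")
  n_chol <- sum(mol$species == "CHOL")
  nb <- ifelse(mol$species == "DPPC", length(DPPC_ATOMS), length(CHOL_ATOMS))
  top <- tibble(
    bead = seq_len(sum(nb)),
    molecule_id = rep(mol$molecule_id, nb),
    species = rep(mol$species, nb),
    role = c(rep(DPPC_ROLES, n_dppc), rep(CHOL_ROLES, n_chol)),
    atom = c(rep(DPPC_ATOMS, n_dppc), rep(CHOL_ATOMS, n_chol)),
    charge = c(rep(DPPC_CHARGES, n_dppc), rep(0, n_chol * length(CHOL_ATOMS))),
    leaflet = rep(mol$leaflet, nb)
  )
  validate_topology(top)
}

# one independent configuration draw (consumes the current RNG stream)
draw_bilayer_frame <- function(mol, spec, box) {
  zmid <- box[3] / 2
  sep <- spec$leaflet_separation_bulk
  is_dppc <- mol$species == "DPPC"
  n_dppc <- sum(is_dppc); n_chol <- sum(!is_dppc)
  s <- ifelse(mol$leaflet == "upper", 1, -1)
  mx <- runif(nrow(mol), 0, box[1])
  my <- runif(nrow(mol), 0, box[2])

  out_x <- out_y <- out_z <- list()
  if (n_dppc) {
    po4_z <- zmid + s[is_dppc] * sep / 2 + rnorm(n_dppc, 0, PO4_Z_NOISE)
    d <- dppc_coord_block(mx[is_dppc], my[is_dppc], po4_z, s[is_dppc],
                          rep(spec$p2_bulk, n_dppc))
    out_x$d <- d$x; out_y$d <- d$y; out_z$d <- d$z
  }
  if (n_chol) {
    roh_z <- zmid + s[!is_dppc] * (sep / 2 - 0.3) + rnorm(n_chol, 0, PO4_Z_NOISE)
    ch <- chol_coord_block(mx[!is_dppc], my[!is_dppc], roh_z, s[!is_dppc])
    out_x$c <- ch$x; out_y$c <- ch$y; out_z$c <- ch$z
  }
  x <- unlist(out_x, use.names = FALSE) %% box[1]
  y <- unlist(out_y, use.names = FALSE) %% box[2]
  z <- unlist(out_z, use.names = FALSE)
  tibble(time = 0, bead = seq_along(x), x = x, y = y, z = z)
}

# vectorised coordinates for a block of DPPC molecules; returns per-component
# vectors in bead order (12 beads per molecule, DPPC_ATOMS order)
dppc_coord_block <- function(mx, my, po4_z, s, p2_targets) {
  n <- length(mx)
  jit <- function() rnorm(n, 0, 0.05)
  # head/backbone slots: NC3, PO4, GL1, GL2
  hx <- cbind(mx + jit(), mx, mx + jit(), mx + jit())
  hy <- cbind(my + jit(), my, my + jit(), my + jit())
  hz <- cbind(po4_z + 0.3 * s, po4_z, po4_z - 0.3 * s, po4_z - 0.35 * s)
  chA <- tail_chain_block(hx[, 3], hy[, 3], hz[, 3], s, p2_targets)
  chB <- tail_chain_block(hx[, 4], hy[, 4], hz[, 4], s, p2_targets)
  X <- cbind(hx[, 1:3], chA$x, hx[, 4], chB$x)
  Y <- cbind(hy[, 1:3], chA$y, hy[, 4], chB$y)
  Z <- cbind(hz[, 1:3], chA$z, hz[, 4], chB$z)
  list(x = as.vector(t(X)), y = as.vector(t(Y)), z = as.vector(t(Z)))
}

# grow 4-bond tail chains for n molecules at once; anchor vectors ax/ay/az
tail_chain_block <- function(ax, ay, az, s, p2_targets, n_bonds = 4) {
  n <- length(ax)
  u <- matrix(sample_bond_cosines_vec(rep(p2_targets, each = n_bonds)),
              nrow = n, byrow = TRUE)
  phi <- matrix(runif(n * n_bonds, 0, 2 * pi), nrow = n)
  sa <- sqrt(pmax(0, 1 - u^2))
  cum <- upper.tri(diag(n_bonds), diag = TRUE)  # running sum along the chain
  dx <- (BOND_LENGTH * sa * cos(phi)) %*% cum
  dy <- (BOND_LENGTH * sa * sin(phi)) %*% cum
  dz <- (-s * BOND_LENGTH * u) %*% cum
  list(x = ax + dx, y = ay + dy, z = az + dz)
}

chol_coord_block <- function(mx, my, roh_z, s) {
  n <- length(mx)
  n_body <- length(CHOL_ATOMS) - 1L
  X <- cbind(mx, mx + matrix(rnorm(n * n_body, 0, 0.05), nrow = n))
  Y <- cbind(my, my + matrix(rnorm(n * n_body, 0, 0.05), nrow = n))
  Z <- roh_z + outer(-s * 0.25, c(0, seq_len(n_body)))
  list(x = as.vector(t(X)), y = as.vector(t(Y)), z = as.vector(t(Z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
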