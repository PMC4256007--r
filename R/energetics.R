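#' Cutoff-and-shift nonbonded kernels
#'
#' Pair potentials in the "shift" scheme of CG membrane simulations: the
#' plain interaction is modified by a cubic/quartic polynomial so that both
#' the potential and the force decay smoothly to exactly zero at the cutoff
#' `r_cut` (1.2 nm), the modification being active from `r_shift` (0.9 nm)
#' for van der Waals terms and from r = 0 for electrostatics. For each
#' power-law term 1/r^p the polynomial coefficients A, B are solved from the
#' boundary conditions F(r_cut) = 0 and F'(r_cut) = 0, and the constant C
#' from V(r_cut) = 0, making both kernels C^1 at the cutoff.
#'
#' `lj_shifted()` is the 12-6 Lennard-Jones form `4 eps (sigma^12/r^12 -
#' sigma^6/r^6)` with each power shifted; `coulomb_shifted()` is
#' `f q_i q_j / (eps_r r)` with the p = 1 term shifted from r = 0, with
#' `f = 138.935` kJ mol^-1 nm e^-2. The `*_force_*` variants return
#' -dV/dr, used by the quadrature cross-checks.
#'
#' @param r Distance(s), nm; must be positive.
#' @param sigma,epsilon LJ parameters (nm, kJ/mol).
#' @param q_i,q_j Charges (e).
#' @param eps_r Relative dielectric constant.
#' @param r_shift Onset of the vdW shift (nm).
#' @param r_cut Cutoff (nm).
#' @return Energy in kJ/mol (or force in kJ/mol/nm).
#' @export
#' @examples
#' lj_shifted(1.2, 0.47, 3.5)  # exactly 0 at the cutoff
lj_shifted <- function(r, sigma, epsilon, r_shift = 0.9, r_cut = 1.2) {
  check_r(r, r_shift, r_cut)
  4 * epsilon * (sigma^12 * shifted_pot(r, 12, r_shift, r_cut) -
                   sigma^6 * shifted_pot(r, 6, r_shift, r_cut))
}

#' @rdname lj_shifted
#' @export
lj_force_shifted <- function(r, sigma, epsilon, r_shift = 0.9, r_cut = 1.2) {
  check_r(r, r_shift, r_cut)
  4 * epsilon * (sigma^12 * shifted_force(r, 12, r_shift, r_cut) -
                   sigma^6 * shifted_force(r, 6, r_shift, r_cut))
}

#' @rdname lj_shifted
#' @export
coulomb_shifted <- function(r, q_i, q_j, eps_r = 15, r_cut = 1.2) {
  check_r(r, 0, r_cut)
  if (eps_r <= 0) abort("eps_r must be positive")
  (COULOMB_F * q_i * q_j / eps_r) * shifted_pot(r, 1, 0, r_cut)
}

#' @rdname lj_shifted
#' @export
coulomb_force_shifted <- function(r, q_i, q_j, eps_r = 15, r_cut = 1.2) {
  check_r(r, 0, r_cut)
  if (eps_r <= 0) abort("eps_r must be positive")
  (COULOMB_F * q_i * q_j / eps_r) * shifted_force(r, 1, 0, r_cut)
}

check_r <- function(r, r_shift, r_cut) {
  if (any(r <= 0)) abort("r must be positive")
  if (!(r_shift >= 0 && r_shift < r_cut)) abort("need 0 <= r_shift < r_cut")
  invisible(r)
}

# polynomial shift coefficients for a 1/r^p term: F(rc) = F'(rc) = 0
shift_coeffs <- function(p, r1, rc) {
  D <- rc - r1
  M <- rbind(c(D^2, D^3), c(2 * D, 3 * D^2))
  rhs <- c(-p / rc^(p + 1), p * (p + 1) / rc^(p + 2))
  ab <- solve(M, rhs)
  C <- rc^(-p) - ab[1] / 3 * D^3 - ab[2] / 4 * D^4
  list(A = ab[1], B = ab[2], C = C)
}

# shifted potential for the term 1/r^p (zero value and force at rc)
shifted_pot <- function(r, p, r1, rc) {
  co <- shift_coeffs(p, r1, rc)
  dr <- pmax(r - r1, 0)
  v <- r^(-p) - co$A / 3 * dr^3 - co$B / 4 * dr^4 - co$C
  ifelse(r >= rc, 0, v)
}

# -dV/dr of the shifted term
shifted_force <- function(r, p, r1, rc) {
  co <- shift_coeffs(p, r1, rc)
  dr <- pmax(r - r1, 0)
  f <- p * r^(-(p + 1)) + co$A * dr^2 + co$B * dr^3
  ifelse(r >= rc, 0, f)
}

#' Pair-parameter set for group interaction energies
#'
#' Sigma/epsilon per role pair (symmetric lookup, with a `"default"`
#' fallback row), the relative dielectric, and the shift/cutoff radii.
#' The bundled table is an illustrative CG-scale parameter set (sigma 0.47
#' nm, epsilon 2-5 kJ/mol, stronger for the charged-terminus/choline
#' contact); override any pair via `table` (columns `role_a`, `role_b`,
#' `sigma`, `epsilon`).
#'
#' @param table Data frame of per-pair parameters; rows with `role_a =
#'   "default"` provide the fallback.
#' @param eps_r Relative dielectric constant (15, the CG convention for
#'   screened electrostatics).
#' @param r_shift,r_cut Shift onset and cutoff (nm).
#' @return A `pair_params` list.
#' @export
pair_params <- function(table = default_pair_table(), eps_r = 15,
                        r_shift = 0.9, r_cut = 1.2) {
  table <- as_tibble(table)
  if (!all(c("role_a", "role_b", "sigma", "epsilon") %in% names(table))) {
    abort("pair table needs columns role_a, role_b, sigma, epsilon")
  }
  if (any(table$epsilon < 0)) abort("epsilon must be non-negative")
  if (!(r_shift > 0 && r_shift < r_cut)) abort("need 0 < r_shift < r_cut")
  structure(list(table = table, eps_r = eps_r, r_shift = r_shift,
                 r_cut = r_cut), class = "pair_params")
}

#' @rdname pair_params
#' @export
default_pair_table <- function() {
  tibble(
    role_a = c("tail", "tail", "tail", "sterol", "terminal", "terminal",
               "choline", "PO4", "core", "default"),
    role_b = c("tail", "chain", "sterol", "sterol", "choline", "PO4",
               "PO4", "PO4", "tail", "default"),
    sigma = 0.47,
    epsilon = c(3.5, 3.5, 3.4, 3.9, 4.5, 4.0, 4.0, 4.0, 3.5, 3.0)
  )
}

# epsilon/sigma lookup for role pairs, vectorised
lookup_pairs <- function(roles_a, roles_b, params) {
  tb <- params$table
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  map <- setNames(seq_len(nrow(tb)), key(tb$role_a, tb$role_b))
  idx <- map[key(roles_a, roles_b)]
  dflt <- map["default default"]
  idx[is.na(idx)] <- if (!is.na(dflt)) dflt else NA
  if (anyNA(idx)) abort("no parameters (and no default row) for some role pair")
  list(sigma = tb$sigma[idx], epsilon = tb$epsilon[idx])
}

#' Group-group interaction energy within a cutoff
#'
#' Sums shifted LJ + Coulomb pair energies over minimum-image pairs between
#' two disjoint bead groups within `r_cut`, and normalizes by the number of
#' group-B molecules "within the cutoff" (any bead of the molecule within
#' `r_cut` of any group-A bead). With no molecule in range the normalized
#' energy is undefined and reported `NA`.
#'
#' @param frame One-frame trajectory.
#' @param top Topology.
#' @param beads_a,beads_b Disjoint bead selections.
#' @param params A [pair_params()].
#' @return One-row tibble: `total`, `vdw`, `coulomb` (kJ/mol),
#'   `n_molecules`, `normalized` (kJ/mol per molecule).
#' @export
group_interaction <- function(frame, top, beads_a, beads_b,
                              params = pair_params()) {
  if (length(intersect(beads_a, beads_b))) abort("groups must be disjoint at bead level")
  if (!length(beads_a) || !length(beads_b)) abort("both groups must be nonempty")
  box <- validate_box(traj_box(frame))
  A <- frame[match(beads_a, frame$bead), ]
  B <- frame[match(beads_b, frame$bead), ]
  dx <- wrap_component(outer(B$x, A$x, "-"), box[1])
  dy <- wrap_component(outer(B$y, A$y, "-"), box[2])
  dz <- wrap_component(outer(B$z, A$z, "-"), box[3])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  within <- which(r < params$r_cut, arr.ind = TRUE)
  roles_a <- top$role[match(beads_a, top$bead)]
  roles_b <- top$role[match(beads_b, top$bead)]
  qa <- top$charge[match(beads_a, top$bead)]
  qb <- top$charge[match(beads_b, top$bead)]
  mol_b <- top$molecule_id[match(beads_b, top$bead)]
  if (nrow(within)) {
    rr <- r[within]
    pp <- lookup_pairs(roles_b[within[, 1]], roles_a[within[, 2]], params)
    vdw_pairs <- lj_shifted(rr, pp$sigma, pp$epsilon, params$r_shift, params$r_cut)
    cou_pairs <- coulomb_shifted(rr, qb[within[, 1]], qa[within[, 2]],
                                 params$eps_r, params$r_cut)
    vdw <- sum(vdw_pairs); cou <- sum(cou_pairs)
    n_mol <- length(unique(mol_b[within[, 1]]))
  } else {
    vdw <- 0; cou <- 0; n_mol <- 0L
  }
  total <- vdw + cou
  tibble(total = total, vdw = vdw, coulomb = cou, n_molecules = n_mol,
         normalized = if (n_mol > 0) total / n_mol else NA_real_)
}

#' Normalized NP-component interaction energies
#'
#' For each bilayer component, the NP-component interaction energy
#' normalized per molecule within the 1.2 nm cutoff, frame-averaged (the
#' per-frame ratio is averaged) with block-averaged standard errors over 5
#' time blocks. Components absent from the system (e.g. cholesterol in a
#' cholesterol-free bilayer) are reported `"N/A"`.
#'
#' @param traj Trajectory.
#' @param top Topology.
#' @param components Subset of `"DPPC head"`, `"DPPC tail"`, `"CHOL"`.
#' @param np_beads NP bead selection; defaults to all NP_core/MUS/OT beads.
#' @param params A [pair_params()].
#' @param begin,end Optional time window (ns).
#' @return Tibble: `component`, `energy` (kJ/mol per molecule), `se`,
#'   `n_molecules` (mean count), `label` (formatted, `"N/A"` when absent).
#' @export
interaction_report <- function(traj, top, components = c("DPPC head", "DPPC tail", "CHOL"),
                               np_beads = NULL, params = pair_params(),
                               begin = NULL, end = NULL) {
  known <- c("DPPC head", "DPPC tail", "CHOL")
  if (!all(components %in% known)) {
    abort(paste0("unknown component label; use ", paste(known, collapse = ", ")))
  }
  np_beads <- np_beads %||% select_beads(top, species = c("NP_core", "MUS", "OT"))
  if (!length(np_beads)) abort("no NP beads found")
  traj <- time_window(traj, begin, end)
  frames <- traj_frames(traj)
  sel_of <- list(
    "DPPC head" = function(t) select_beads(t, species = "DPPC",
                                           role = c("PO4", "choline")),
    "DPPC tail" = function(t) select_beads(t, species = "DPPC",
                                           role = c("tail", "glycerol")),
    "CHOL" = function(t) select_beads(t, species = "CHOL")
  )
  purrr::map_dfr(components, function(comp) {
    beads <- sel_of[[comp]](top)
    if (!length(beads)) {
      return(tibble(component = comp, energy = NA_real_, se = NA_real_,
                    n_molecules = NA_real_, label = "N/A"))
    }
    per <- purrr::map_dfr(frames, function(fr) {
      group_interaction(fr, top, np_beads, beads, params)
    })
    vals <- per$normalized
    blocks <- lapply(split_blocks(length(vals), 5L), function(ix) vals[ix])
    bm <- vapply(blocks, function(v) mean(v, na.rm = TRUE), numeric(1))
    bm <- bm[is.finite(bm)]
    e <- mean(vals, na.rm = TRUE)
    se <- if (length(bm) > 1) sd(bm) / sqrt(length(bm)) else NA_real_
    tibble(component = comp, energy = e, se = se,
           n_molecules = mean(per$n_molecules),
           label = if (is.finite(e)) {
             sprintf("%.2f%s", e, if (is.finite(se)) sprintf("±%.2f", se) else "")
           } else "N/A")
  })
}
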