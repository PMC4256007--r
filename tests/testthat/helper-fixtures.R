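# shared fixtures and independent oracles, built in code at test time

small_system <- function(n_lipids = 60, chol_fraction = 0.3, n_frames = 2,
                         seed = 42, ...) {
  gen_bilayer(bilayer_spec(n_lipids = n_lipids, chol_fraction = chol_fraction, ...),
              seed = seed, n_frames = n_frames)
}

# brute-force O(N^2) group energy: plain double loop over bead pairs,
# independent of the production implementation's vectorised path
brute_force_energy <- function(frame, top, beads_a, beads_b, params = pair_params()) {
  box <- attr(frame, "box")
  wrap1 <- function(d, L) d - L * ceiling(d / L - 0.5)
  total_vdw <- 0; total_cou <- 0
  mols <- c()
  for (ia in beads_a) {
    ra <- frame[frame$bead == ia, ]
    roa <- top$role[top$bead == ia]; qa <- top$charge[top$bead == ia]
    for (ib in beads_b) {
      rb <- frame[frame$bead == ib, ]
      r <- sqrt(wrap1(rb$x - ra$x, box[1])^2 + wrap1(rb$y - ra$y, box[2])^2 +
                  wrap1(rb$z - ra$z, box[3])^2)
      if (r < params$r_cut) {
        rob <- top$role[top$bead == ib]; qb <- top$charge[top$bead == ib]
        key <- paste(sort(c(roa, rob)), collapse = " ")
        tb <- params$table
        hit <- which(paste(pmin(tb$role_a, tb$role_b), pmax(tb$role_a, tb$role_b)) == key)
        if (!length(hit)) hit <- which(tb$role_a == "default")
        total_vdw <- total_vdw + lj_shifted(r, tb$sigma[hit[1]], tb$epsilon[hit[1]],
                                            params$r_shift, params$r_cut)
        total_cou <- total_cou + coulomb_shifted(r, qa, qb, params$eps_r, params$r_cut)
        mols <- c(mols, top$molecule_id[top$bead == ib])
      }
    }
  }
  list(total = total_vdw + total_cou, vdw = total_vdw, coulomb = total_cou,
       n_molecules = length(unique(mols)))
}

# brute-force 2D pair histogram for the RDF oracle
brute_force_rdf_counts <- function(frame, beads_a, beads_b, breaks) {
  box <- attr(frame, "box")
  wrap1 <- function(d, L) d - L * ceiling(d / L - 0.5)
  counts <- rep(0, length(breaks) - 1)
  for (ia in beads_a) {
    ra <- frame[frame$bead == ia, ]
    for (ib in beads_b) {
      if (ib == ia) next
      rb <- frame[frame$bead == ib, ]
      r <- sqrt(wrap1(rb$x - ra$x, box[1])^2 + wrap1(rb$y - ra$y, box[2])^2)
      k <- findInterval(r, breaks)
      if (r > 0 && k >= 1 && k <= length(counts)) counts[k] <- counts[k] + 1
    }
  }
  counts
}

# uniform random trajectory of unconnected beads
uniform_traj <- function(n_beads, n_frames, box, seed = 1) {
  withr::with_seed(seed, {
    out <- dplyr::bind_rows(lapply(seq_len(n_frames), function(f) {
      tibble::tibble(time = f - 1, bead = seq_len(n_beads),
                     x = runif(n_beads, 0, box[1]),
                     y = runif(n_beads, 0, box[2]),
                     z = runif(n_beads, 0, box[3]))
    }))
    attr(out, "box") <- box
    out
  })
}
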