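#' Read a GRO coordinate file
#'
#' Fixed-column GRO as written by common MD engines: title line, atom count,
#' one line per atom (residue number/name, atom name, atom number, x y z in nm
#' to three decimals, optional velocities which are ignored), then the box
#' line. Only orthorhombic boxes are supported; a triclinic box line with
#' non-zero off-diagonal terms is rejected.
#'
#' @param path Path to a .gro file.
#' @return A one-frame trajectory tibble with columns `time`, `bead`,
#'   `resid`, `resname`, `atomname`, `x`, `y`, `z`, a `"box"` attribute and a
#'   `"title"` attribute.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("malformed GRO file: fewer than 3 lines")
  title <- lines[1]
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1) abort("malformed GRO file: bad or zero atom count")
  if (length(lines) < 2 + natoms + 1) abort("malformed GRO file: truncated atom block")
  at <- lines[3:(2 + natoms)]
  if (any(nchar(at) < 44)) abort("malformed GRO file: short atom line")
  num <- function(s, a, b) as.numeric(substr(s, a, b))
  frame <- tibble(
    time = 0,
    bead = seq_len(natoms),
    resid = as.integer(substr(at, 1, 5)),
    resname = trimws(substr(at, 6, 10)),
    atomname = trimws(substr(at, 11, 15)),
    x = num(at, 21, 28),
    y = num(at, 29, 36),
    z = num(at, 37, 44)
  )
  if (any(!is.finite(frame$x) | !is.finite(frame$y) | !is.finite(frame$z))) {
    abort("malformed GRO file: non-numeric coordinates")
  }
  boxv <- as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]])
  if (length(boxv) >= 9 && any(boxv[4:9] != 0)) {
    abort("triclinic box with off-diagonal terms is not supported (orthorhombic only)")
  }
  if (length(boxv) < 3 || any(!is.finite(boxv[1:3])) || any(boxv[1:3] <= 0)) {
    abort("malformed GRO box line")
  }
  attr(frame, "box") <- boxv[1:3]
  attr(frame, "title") <- title
  frame
}

#' Write a GRO coordinate file
#'
#' Coordinates are written with the format's native three-decimal precision,
#' so write-then-read round trips agree to 0.001 nm and a second round trip
#' is byte-identical.
#'
#' @param frame One-frame trajectory with a `"box"` attribute. Optional
#'   columns `resid`, `resname`, `atomname` are used when present; otherwise
#'   generic names are emitted.
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "npmembrane frame") {
  box <- validate_box(traj_box(frame))
  fr <- frame[order(frame$bead), ]
  n <- nrow(fr)
  if (!n) abort("refusing to write an empty frame")
  resid <- if ("resid" %in% names(fr)) fr$resid else fr$bead
  resname <- if ("resname" %in% names(fr)) fr$resname else "BEAD"
  atomname <- if ("atomname" %in% names(fr)) fr$atomname else "B"
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid %% 100000L, substr(resname, 1, 5), substr(atomname, 1, 5),
            fr$bead %% 100000L, fr$x, fr$y, fr$z),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a bead species table
#'
#' Sidecar TSV mapping bead indices to molecule, species, role, atom name,
#' charge and leaflet -- the semantic companion of a GRO file.
#'
#' @param top Topology.
#' @param path File path.
#' @return `write_species_table()` returns `path` invisibly;
#'   `read_species_table()` returns a validated topology.
#' @export
write_species_table <- function(top, path) {
  readr::write_tsv(as_tibble(top)[, c("bead", "molecule_id", "species", "role",
                                      "atom", "charge", "leaflet")], path)
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  top <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           bead = "i", molecule_id = "i", species = "c",
                           role = "c", atom = "c", charge = "d", leaflet = "c"))
  validate_topology(as_tibble(top))
}

#' Write / read a multi-frame trajectory
#'
#' Plain whitespace text: per frame a header line `t <time_ns> <n_beads>`,
#' then one `bead x y z` line per bead; a box line `box lx ly lz` opens the
#' file. Binary trajectory codecs (XTC/TRR) are out of scope; convert
#' externally and import through this format or concatenated GRO.
#'
#' @param traj Trajectory tibble (`time`, `bead`, `x`, `y`, `z`).
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a trajectory tibble with a `"box"` attribute.
#' @export
write_trajectory <- function(traj, path) {
  box <- traj_box(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box)) writeLines(sprintf("box %.6f %.6f %.6f", box[1], box[2], box[3]), con)
  for (fr in traj_frames(traj)) {
    writeLines(sprintf("t %.6f %d", fr$time[1], nrow(fr)), con)
    writeLines(sprintf("%d %.6f %.6f %.6f", fr$bead, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) abort("empty trajectory file")
  box <- NULL
  i <- 1L
  if (startsWith(lines[1], "box ")) {
    box <- as.numeric(strsplit(lines[1], "\\s+")[[1]][2:4])
    i <- 2L
  }
  frames <- list()
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], "\\s+")[[1]]
    if (hd[1] != "t") abort("malformed trajectory: expected frame header")
    tm <- as.numeric(hd[2]); nb <- as.integer(hd[3])
    block <- lines[(i + 1):(i + nb)]
    m <- matrix(as.numeric(unlist(strsplit(block, "\\s+"))), ncol = 4, byrow = TRUE)
    frames[[length(frames) + 1L]] <- tibble(
      time = tm, bead = as.integer(m[, 1]), x = m[, 2], y = m[, 3], z = m[, 4])
    i <- i + nb + 1L
  }
  traj <- bind_rows(frames)
  attr(traj, "box") <- box
  traj
}

#' Read umbrella-sampling window records
#'
#' Each file is a two-column whitespace text series (time in ns, reaction
#' coordinate xi in nm) -- the de facto pull-output dialect. Window metadata
#' (bias centre and force constant) comes from a companion table.
#'
#' @param paths Character vector of series files.
#' @param metadata Data frame with columns `file`, `center`, `k` (one row per
#'   path; matched by file name).
#' @param temperature Temperature in K.
#' @param begin Optional equilibration cutoff: samples with `time <= begin`
#'   (ns) are discarded.
#' @return An `umbrella_windows` tibble with columns `window`, `center`, `k`,
#'   `time`, `xi` and a `"temperature"` attribute.
#' @export
read_window_records <- function(paths, metadata, temperature = DEFAULT_TEMPERATURE,
                                begin = NULL) {
  metadata <- as_tibble(metadata)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    m <- metadata[metadata$file == basename(paths[i]) | metadata$file == paths[i], ]
    if (nrow(m) != 1) abort(paste0("missing or ambiguous metadata for ", paths[i]))
    dat <- tryCatch(
      as.matrix(utils::read.table(paths[i], col.names = c("time", "xi"))),
      error = function(e) abort(paste0("cannot read window series ", paths[i], ": ",
                                       conditionMessage(e))))
    if (!nrow(dat)) abort(paste0("empty window series: ", paths[i]))
    keep <- if (is.null(begin)) rep(TRUE, nrow(dat)) else dat[, "time"] > begin
    if (!any(keep)) abort(paste0("equilibration cutoff removes all samples in ", paths[i]))
    out[[i]] <- tibble(window = i, center = m$center, k = m$k,
                       time = dat[keep, "time"], xi = dat[keep, "xi"])
  }
  new_umbrella_windows(bind_rows(out), temperature)
}

new_umbrella_windows <- function(df, temperature) {
  if (any(df$k < 0)) abort("force constant k must be non-negative")
  if (!nrow(df)) abort("umbrella window set has no samples")
  attr(df, "temperature") <- temperature
  class(df) <- unique(c("umbrella_windows", class(df)))
  df
}
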