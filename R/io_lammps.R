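#' Write a LAMMPS data file (atoms, bonds, angles)
#'
#' Emits a molecular-style data file with Masses, Atoms (id mol type x y z),
#' Velocities, Bonds and Angles sections, in reduced units, for
#' interoperability with LAMMPS-ecosystem tools.  Bead species are numbered
#' in the order H, T, N.
#'
#' @param topology a `dpd_topology`.
#' @param frame matching [dpd_frame()].
#' @param path output file path.
#' @param mass bead mass written to the Masses section.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(topology, frame, path, mass = 1) {
  stopifnot(n_beads(topology) == nrow(frame$positions))
  types <- c("H", "T", "N")
  ti <- match(topology$type, types)
  mol <- ifelse(is.na(topology$chain_id), 0L, topology$chain_id)
  n <- n_beads(topology)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file (dpdlipid, reduced units: rc / kBT / m / tau)")
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(topology$bonds))
  w("%d angles", nrow(topology$angles))
  w("%d atom types", length(types))
  w("%d bond types", if (nrow(topology$bonds)) 1L else 0L)
  w("%d angle types", if (nrow(topology$angles)) 1L else 0L)
  w("")
  w("0 %.10g xlo xhi", frame$box)
  w("0 %.10g ylo yhi", frame$box)
  w("0 %.10g zlo zhi", frame$box)
  w("")
  w("Masses")
  w("")
  for (k in seq_along(types)) w("%d %.10g", k, mass)
  w("")
  w("Atoms # molecular")
  w("")
  p <- frame$positions
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g",
                     seq_len(n), mol, ti, p[, 1], p[, 2], p[, 3]), con)
  w("")
  w("Velocities")
  w("")
  v <- frame$velocities
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(n), v[, 1], v[, 2], v[, 3]), con)
  if (nrow(topology$bonds)) {
    w("")
    w("Bonds")
    w("")
    b <- topology$bonds
    writeLines(sprintf("%d 1 %d %d", seq_len(nrow(b)), b[, 1], b[, 2]), con)
  }
  if (nrow(topology$angles)) {
    w("")
    w("Angles")
    w("")
    a <- topology$angles
    writeLines(sprintf("%d 1 %d %d %d", seq_len(nrow(a)), a[, 1], a[, 2], a[, 3]), con)
  }
  invisible(path)
}

#' Write frames as a LAMMPS dump file
#'
#' Standard text dump with `ITEM:` headers and per-atom columns
#' `id type x y z vx vy vz` (velocities optional).
#'
#' @param frames a frame, list of frames or `dpd_trajectory`.
#' @param topology matching `dpd_topology`.
#' @param path output file path.
#' @param velocities include velocity columns (default TRUE).
#' @param dt time step used to convert frame times to integer step numbers.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(frames, topology, path, velocities = TRUE,
                              dt = 0.01) {
  fl <- as_frame_list(frames)
  types <- c("H", "T", "N")
  ti <- match(topology$type, types)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in fl) {
    n <- nrow(fr$positions)
    writeLines(c("ITEM: TIMESTEP", sprintf("%d", round(fr$time / dt)),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0 %.10g", fr$box), sprintf("0 %.10g", fr$box),
                 sprintf("0 %.10g", fr$box)), con)
    if (velocities) {
      writeLines("ITEM: ATOMS id type x y z vx vy vz", con)
      p <- fr$positions; v <- fr$velocities
      writeLines(sprintf("%d %d %.10g %.10g %.10g %.10g %.10g %.10g",
                         seq_len(n), ti, p[, 1], p[, 2], p[, 3],
                         v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines("ITEM: ATOMS id type x y z", con)
      p <- fr$positions
      writeLines(sprintf("%d %d %.10g %.10g %.10g",
                         seq_len(n), ti, p[, 1], p[, 2], p[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a LAMMPS dump file into a trajectory
#'
#' Parses the text dump format (`ITEM: TIMESTEP` / `NUMBER OF ATOMS` /
#' `BOX BOUNDS` / `ATOMS` with named columns).  Atoms are reordered by id.
#' If the velocity columns are absent the returned trajectory carries
#' `attr(, "has_velocities") = FALSE` and velocity-requiring analyses
#' (pressure, tension) should refuse it.
#'
#' @param path dump file path.
#' @param dt time step used to convert step numbers back to times.
#' @return a `dpd_trajectory` with attributes `types` (character per bead)
#'   and `has_velocities`.
#' @export
read_lammps_dump <- function(path, dt = 0.01) {
  lines <- readLines(path)
  frames <- list()
  types <- NULL
  has_vel <- TRUE
  i <- 1L
  species <- c("H", "T", "N")
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("malformed dump at line ", i, ": expected ITEM: TIMESTEP", call. = FALSE)
    step <- as.numeric(lines[i + 1L])
    if (!startsWith(lines[i + 2L], "ITEM: NUMBER OF ATOMS"))
      stop("malformed dump at line ", i + 2L, call. = FALSE)
    n <- as.integer(lines[i + 3L])
    if (!startsWith(lines[i + 4L], "ITEM: BOX BOUNDS"))
      stop("malformed dump at line ", i + 4L, call. = FALSE)
    bb <- as.numeric(strsplit(trimws(lines[i + 5L]), "\\s+")[[1]])
    box <- bb[2] - bb[1]
    hdr <- lines[i + 8L]
    if (!startsWith(hdr, "ITEM: ATOMS"))
      stop("malformed dump at line ", i + 8L, ": expected ITEM: ATOMS", call. = FALSE)
    cols <- strsplit(trimws(sub("ITEM: ATOMS", "", hdr)), "\\s+")[[1]]
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% cols))
      stop("dump missing required columns at line ", i + 8L, call. = FALSE)
    body <- lines[(i + 9L):(i + 8L + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n, byrow = TRUE)
    colnames(m) <- cols
    m <- m[order(m[, "id"]), , drop = FALSE]
    pos <- m[, c("x", "y", "z"), drop = FALSE]
    if (all(c("vx", "vy", "vz") %in% cols)) {
      vel <- m[, c("vx", "vy", "vz"), drop = FALSE]
    } else {
      vel <- NULL
      has_vel <- FALSE
    }
    if (is.null(types)) types <- species[as.integer(m[, "type"])]
    fr <- dpd_frame(pos, box = box, velocities = vel, time = step * dt)
    if (is.null(vel)) attr(fr, "has_velocities") <- FALSE
    frames[[length(frames) + 1L]] <- fr
    i <- i + 9L + n
  }
  traj <- structure(list(frames = frames,
                         times = vapply(frames, function(f) f$time, 0)),
                    class = "dpd_trajectory")
  attr(traj, "types") <- types
  attr(traj, "has_velocities") <- has_vel
  traj
}

#' Write an extended-XYZ snapshot
#'
#' One frame in extended XYZ: a `Lattice` + `Properties` comment line and
#' per-bead `species x y z` rows.
#'
#' @inheritParams write_lammps_data
#' @return `path`, invisibly.
#' @export
write_xyz <- function(topology, frame, path) {
  stopifnot(n_beads(topology) == nrow(frame$positions))
  n <- n_beads(topology)
  D <- frame$box
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  writeLines(sprintf(
    'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
    D, D, D, frame$time), con)
  p <- frame$positions
  writeLines(sprintf("%s %.10g %.10g %.10g", topology$type, p[, 1], p[, 2], p[, 3]),
             con)
  invisible(path)
}
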