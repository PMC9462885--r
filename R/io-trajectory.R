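#' Trajectory container
#'
#' A minimal container for an orthorhombic-box MD trajectory: positions in
#' Angstrom, times in ps. Analyses on trajectories ([rdf()],
#' [incoherent_isf()], [hbond_timeseries()], ...) consume this object and
#' return tibbles.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param box Numeric matrix `n_frames x 3` of orthorhombic edge lengths
#'   (Angstrom), or a length-3 vector recycled to all frames.
#' @param timestep Frame spacing in ps.
#' @param times Optional frame times in ps; defaults to
#'   `(0:(n_frames-1)) * timestep`.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, box, timestep, times = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  n_frames <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, n_frames, 3, byrow = TRUE)
  if (any(box <= 0)) abort("box edges must be positive")
  if (!all(is.finite(coords))) abort("positions must be finite")
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * timestep
  structure(list(coords = coords, box = box, timestep = timestep,
                 times = times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, timestep %g ps, box %s A\n",
              dim(x$coords)[1], dim(x$coords)[2], x$timestep,
              paste(format(x$box[1, ], digits = 6), collapse = " x ")))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

#' Load a trajectory plus its topology sidecar
#'
#' Frames come from an extended-XYZ file (comment line carrying `Lattice=`
#' and `time=`) or a GRO file (positions converted nm to Angstrom, time read
#' from a `t=` tag on the title line); the format is chosen by file
#' extension. Molecule identity and atom roles come from a tab-separated
#' sidecar read by [read_topology()], because XYZ carries neither.
#'
#' The frame times must be uniformly spaced to within 1e-6 ps; the common
#' spacing becomes the trajectory timestep. Only orthorhombic boxes are
#' accepted.
#'
#' @param frames_path Path to the `.xyz`/`.extxyz` or `.gro` file.
#' @param topology_path Path to the topology TSV.
#' @return A list with elements `trajectory` ([md_trajectory]) and
#'   `topology` (tibble).
#' @export
load_trajectory <- function(frames_path, topology_path) {
  ext <- tolower(tools::file_ext(frames_path))
  traj <- switch(ext,
    xyz = ,
    extxyz = read_trajectory_xyz(frames_path),
    gro = read_trajectory_gro(frames_path),
    abort(sprintf("unknown trajectory extension '.%s'", ext))
  )
  top <- read_topology(topology_path)
  if (nrow(top) != n_atoms(traj)) {
    abort(sprintf("topology lists %d atoms but frames have %d",
                  nrow(top), n_atoms(traj)))
  }
  list(trajectory = traj, topology = top)
}

#' Read an extended-XYZ trajectory
#'
#' @param path Path to the file. Each frame is `n`, a comment line with
#'   `Lattice="xx 0 0 0 yy 0 0 0 zz"` and `time=<ps>`, then `n` rows of
#'   `element x y z` in Angstrom. Triclinic lattices are rejected.
#' @return An [md_trajectory].
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  boxes <- list()
  times <- numeric()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(sprintf("'%s': expected atom count on line %d", path, i))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1L]]
    if (length(lat) < 2L) abort(sprintf("'%s': frame comment on line %d lacks Lattice=", path, i + 1L))
    cell <- as.numeric(strsplit(trimws(lat[2L]), "\\s+")[[1L]])
    if (length(cell) != 9L) abort(sprintf("'%s': Lattice= needs 9 numbers (line %d)", path, i + 1L))
    offdiag <- cell[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(offdiag) > 1e-9)) {
      abort(sprintf("'%s': triclinic lattice on line %d; only orthorhombic boxes are supported",
                    path, i + 1L))
    }
    tm <- regmatches(comment, regexec("time=([-+0-9.eE]+)", comment))[[1L]]
    if (length(tm) < 2L) abort(sprintf("'%s': frame comment on line %d lacks time=", path, i + 1L))
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- cell[c(1, 5, 9)]
    times <- c(times, as.numeric(tm[2L]))
    i <- i + 2L + n
  }
  assemble_trajectory(frames, boxes, times, path)
}

#' Read a GRO trajectory
#'
#' @param path Path to a (possibly multi-frame) GRO file. Positions are
#'   converted from nm to Angstrom; the frame time is taken from a
#'   `t= <ps>` tag on the title line. Box lines with triclinic components
#'   are rejected.
#' @return An [md_trajectory].
#' @export
read_trajectory_gro <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); boxes <- list(); times <- numeric()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    tm <- regmatches(title, regexec("t=\\s*([-+0-9.eE]+)", title))[[1L]]
    if (length(tm) < 2L) abort(sprintf("'%s': title line %d lacks 't=' time tag", path, i))
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) abort(sprintf("'%s': expected atom count on line %d", path, i + 1L))
    rows <- lines[(i + 2L):(i + 1L + n)]
    xyz <- t(vapply(rows, function(r) {
      as.numeric(c(substr(r, 21, 28), substr(r, 29, 36), substr(r, 37, 44)))
    }, numeric(3), USE.NAMES = FALSE)) * 10  # nm -> Angstrom
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]])
    if (length(boxline) > 3L && any(abs(boxline[-(1:3)]) > 1e-9)) {
      abort(sprintf("'%s': triclinic box on line %d; only orthorhombic boxes are supported",
                    path, i + 2L + n))
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- boxline[1:3] * 10
    times <- c(times, as.numeric(tm[2L]))
    i <- i + 3L + n
  }
  assemble_trajectory(frames, boxes, times, path)
}

assemble_trajectory <- function(frames, boxes, times, path) {
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    abort(sprintf("'%s': atom count varies across frames (%s)", path,
                  paste(unique(counts), collapse = ", ")))
  }
  nf <- length(frames)
  if (nf >= 2L) {
    dt <- diff(times)
    if (any(abs(dt - dt[1L]) > 1e-6)) {
      abort(sprintf("'%s': frame times not uniformly spaced (max deviation %g ps)",
                    path, max(abs(dt - dt[1L]))))
    }
    timestep <- dt[1L]
  } else {
    timestep <- NA_real_
  }
  coords <- array(NA_real_, c(nf, counts[1L], 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  md_trajectory(coords, do.call(rbind, boxes), timestep, times)
}

#' Write an extended-XYZ trajectory
#'
#' @param traj An [md_trajectory].
#' @param path Output path.
#' @param elements Optional per-atom element symbols (default "X").
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, elements = NULL) {
  na <- n_atoms(traj)
  if (is.null(elements)) elements <- rep("X", na)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    b <- traj$box[f, ]
    writeLines(as.character(na), con)
    writeLines(sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" time=%s',
                       num15(b[1]), num15(b[2]), num15(b[3]),
                       num15(traj$times[f])), con)
    writeLines(paste(elements,
                     num15(traj$coords[f, , 1]),
                     num15(traj$coords[f, , 2]),
                     num15(traj$coords[f, , 3])), con)
  }
  invisible(path)
}

#' Read or write an atom-role topology table
#'
#' The topology sidecar assigns each trajectory atom a molecule and a role.
#' It is a TSV with header `index molecule_id molecule_type role`, 0-based
#' atom indices, `molecule_type` in `{WAT, PEG}` and `role` in
#' `{OW, HW, O_ether, C, H_peg}`. Every water molecule must have exactly one
#' OW and two HW atoms.
#'
#' @param path File path.
#' @return A tibble with columns `index`, `molecule_id`, `molecule_type`,
#'   `role`.
#' @export
read_topology <- function(path) {
  df <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  validate_topology(df)
}

#' @rdname read_topology
#' @param topology Topology tibble to write.
#' @export
write_topology <- function(topology, path) {
  write.table(topology, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_topology <- function(df) {
  needed <- c("index", "molecule_id", "molecule_type", "role")
  if (!all(needed %in% names(df))) {
    abort(sprintf("topology missing column(s): %s",
                  paste(setdiff(needed, names(df)), collapse = ", ")))
  }
  roles <- c("OW", "HW", "O_ether", "C", "H_peg")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad)) abort(sprintf("unknown role token(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(df$molecule_type), c("WAT", "PEG"))
  if (length(bad)) abort(sprintf("unknown molecule_type: %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(df$index)) abort("duplicate atom index in topology")
  if (!setequal(df$index, seq_len(nrow(df)) - 1L)) {
    abort("topology indices must be 0-based and cover every atom exactly once")
  }
  wat <- df[df$molecule_type == "WAT", ]
  if (nrow(wat)) {
    counts <- table(wat$molecule_id, wat$role)
    ow <- if ("OW" %in% colnames(counts)) counts[, "OW"] else rep(0, nrow(counts))
    hw <- if ("HW" %in% colnames(counts)) counts[, "HW"] else rep(0, nrow(counts))
    # O-only coarse water (synthetic walkers) is allowed: 0 HW instead of 2
    if (any(ow != 1) || any(!hw %in% c(0, 2))) {
      abort("each WAT molecule needs exactly one OW and zero or two HW atoms")
    }
  }
  df[order(df$index), ]
}
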