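#' Unwrap periodic coordinates by displacement accumulation
#'
#' Reconstructs continuous trajectories from wrapped coordinates by
#' accumulating per-step minimum-image displacements — valid as long as no
#' atom moves more than half a box edge between consecutive frames.
#'
#' @param traj An [md_trajectory].
#' @param atoms Atom indices (1-based rows of the coordinate array) to
#'   unwrap; default all.
#' @return Array `n_frames x length(atoms) x 3` of unwrapped positions.
#' @export
unwrap_coords <- function(traj, atoms = seq_len(n_atoms(traj))) {
  nf <- n_frames(traj)
  u <- traj$coords[, atoms, , drop = FALSE]
  if (nf < 2L) return(u)
  for (f in 2:nf) {
    step <- traj$coords[f, atoms, , drop = FALSE] -
      traj$coords[f - 1L, atoms, , drop = FALSE]
    for (k in 1:3) step[, , k] <- min_image(step[, , k], traj$box[f, k])
    u[f, , ] <- u[f - 1L, , ] + step[1, , ]
  }
  u
}

select_atoms <- function(traj, topology, roles) {
  if (is.null(topology) || is.null(roles)) return(seq_len(n_atoms(traj)))
  top <- topology[order(topology$index), ]
  idx <- which(top$role %in% roles)
  if (!length(idx)) abort(sprintf("no atoms with role(s) %s", paste(roles, collapse = ", ")))
  idx
}

#' Self intermediate scattering function from a trajectory
#'
#' Isotropically averaged incoherent ISF,
#' \deqn{F(q,t) = \left\langle \frac{\sin(q\,|\Delta r(t)|)}{q\,|\Delta r(t)|} \right\rangle,}
#' averaged over the selected atoms and multiple time origins, with
#' displacements taken on unwrapped coordinates. The same observable the
#' spectrometer measures in the time domain, so trajectory and experiment
#' ISFs can be compared directly.
#'
#' @param traj An [md_trajectory].
#' @param topology Topology tibble (or NULL to use all atoms).
#' @param q Momentum transfer values (1/Angstrom, > 0).
#' @param roles Roles to include (default `"OW"`).
#' @param max_lag Largest lag in frames (default half the trajectory).
#' @param origin_stride Use every `origin_stride`-th frame as a time origin
#'   (default 1).
#' @return Tibble with columns `q`, `t` (ps) and `F`.
#' @export
incoherent_isf <- function(traj, topology = NULL, q, roles = "OW",
                           max_lag = NULL, origin_stride = 1L) {
  if (any(q <= 0)) abort("q must be positive")
  atoms <- select_atoms(traj, topology, roles)
  u <- unwrap_coords(traj, atoms)
  nf <- dim(u)[1]
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  max_lag <- min(max_lag, nf - 1L)
  lags <- 0:max_lag
  rows <- purrr::map_dfr(lags, function(l) {
    origins <- seq(1L, nf - l, by = origin_stride)
    d <- u[origins + l, , , drop = FALSE] - u[origins, , , drop = FALSE]
    r <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    purrr::map_dfr(q, function(qv) {
      x <- qv * r
      s <- ifelse(x < 1e-12, 1, sin(x) / x)
      tibble::tibble(q = qv, t = l * traj$timestep, F = mean(s))
    })
  })
  dplyr::arrange(rows, .data$q, .data$t)
}

#' Mean-squared displacement, jump counts and residence times
#'
#' Computes the multiple-origin MSD on unwrapped coordinates, then
#' coarse-grains each atom's position by block averaging over
#' `coarse_window` frames to suppress in-trap libration; a displacement
#' larger than `jump_threshold` between consecutive blocks is counted as a
#' jump between trapping sites, and the residence time is the duration
#' between successive jumps. This quantifies the trap-and-jump
#' (trapping-site diffusion) picture of confined water: libration inside a
#' pool, occasional long jumps to the next one.
#'
#' @param traj An [md_trajectory].
#' @param topology Topology tibble (or NULL).
#' @param roles Roles to include (default `"OW"`).
#' @param coarse_window Block length in frames (>= 2).
#' @param jump_threshold Coarse-grained displacement (Angstrom) counted as
#'   a jump (> 0).
#' @param max_lag Largest MSD lag in frames (default half the trajectory).
#' @param origin_stride Origin stride for the MSD (default 1).
#' @return List of class `msd_jumps` with tibbles `msd` (`t`, `msd`),
#'   `jumps` (`atom`, `n_jumps`) and `residence` (`atom`, `residence` in
#'   ps, one row per completed inter-jump interval).
#' @export
msd_and_jumps <- function(traj, topology = NULL, roles = "OW",
                          coarse_window = 2L, jump_threshold = 1,
                          max_lag = NULL, origin_stride = 1L) {
  if (coarse_window < 2L) abort("coarse_window must be at least 2 frames")
  if (jump_threshold <= 0) abort("jump_threshold must be positive")
  atoms <- select_atoms(traj, topology, roles)
  u <- unwrap_coords(traj, atoms)
  nf <- dim(u)[1]; na <- dim(u)[2]
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  max_lag <- min(max_lag, nf - 1L)
  msd <- purrr::map_dfr(0:max_lag, function(l) {
    origins <- seq(1L, nf - l, by = origin_stride)
    d <- u[origins + l, , , drop = FALSE] - u[origins, , , drop = FALSE]
    tibble::tibble(t = l * traj$timestep, msd = mean(d^2) * 3)
  })
  nb <- nf %/% coarse_window
  if (nb < 2L) abort("trajectory shorter than two coarse-graining blocks")
  blk <- array(NA_real_, c(nb, na, 3))
  for (b in seq_len(nb)) {
    rows <- ((b - 1L) * coarse_window + 1L):(b * coarse_window)
    blk[b, , ] <- apply(u[rows, , , drop = FALSE], c(2, 3), mean)
  }
  step <- sqrt(apply((blk[-1L, , , drop = FALSE] - blk[-nb, , , drop = FALSE])^2,
                     c(1, 2), sum))
  step <- matrix(step, nb - 1L, na)
  block_dt <- coarse_window * traj$timestep
  jumps <- tibble::tibble(atom = atoms, n_jumps = colSums(step > jump_threshold))
  residence <- purrr::map_dfr(seq_len(na), function(j) {
    at <- which(step[, j] > jump_threshold)
    if (length(at) < 2L) return(tibble::tibble(atom = integer(), residence = numeric()))
    tibble::tibble(atom = atoms[j], residence = diff(at) * block_dt)
  })
  structure(list(msd = msd, jumps = jumps, residence = residence),
            class = "msd_jumps")
}

#' @export
print.msd_jumps <- function(x, ...) {
  cat(sprintf("<msd_jumps> %d atoms, %d jumps, mean residence %.4g ps\n",
              nrow(x$jumps), sum(x$jumps$n_jumps),
              if (nrow(x$residence)) mean(x$residence$residence) else NA_real_))
  invisible(x)
}
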