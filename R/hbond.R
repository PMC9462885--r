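#' Geometric hydrogen-bond criterion
#'
#' A donor O–H donates to an acceptor O when the donor–acceptor oxygen
#' distance is within `max_da_distance` and the angle at the hydrogen along
#' O–H···O (180 degrees = linear) is at least `min_angle`. The angle vertex
#' is the hydrogen — the standard reading of the O–H···O notation.
#'
#' @param max_da_distance Donor–acceptor O···O cutoff in Angstrom
#'   (default 3.5).
#' @param min_angle Minimum O–H···O angle at the hydrogen in degrees
#'   (default 150; must lie in (90, 180]).
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 3.5, min_angle = 150) {
  if (max_da_distance <= 0) abort("max_da_distance must be positive")
  if (min_angle <= 90 || min_angle > 180) abort("min_angle must lie in (90, 180]")
  structure(list(max_da_distance = max_da_distance, min_angle = min_angle),
            class = "hbond_criterion")
}

min_image <- function(d, L) d - L * round(d / L)

hbond_selection_sets <- function(topology, selection) {
  top <- topology[order(topology$index), ]
  hw <- which(top$role == "HW")
  if (!length(hw) && selection != "none") abort("topology has no HW atoms to donate")
  # donor O for each HW = the OW of the same water molecule
  ow_by_mol <- setNames(which(top$role == "OW"),
                        top$molecule_id[top$role == "OW"])
  donor_o <- ow_by_mol[as.character(top$molecule_id[hw])]
  if (any(is.na(donor_o))) abort("HW atom without an OW in its molecule")
  acc <- switch(selection,
    water_peg = which(top$role == "O_ether"),
    water_water = which(top$role == "OW"),
    abort(sprintf("unknown selection '%s' (use 'water_peg' or 'water_water')", selection))
  )
  if (!length(acc)) abort(sprintf("no acceptor atoms for selection '%s'", selection))
  list(top = top, h = hw, donor_o = unname(donor_o), acceptor = acc)
}

#' Find hydrogen bonds in one frame
#'
#' Applies the geometric criterion with minimum-image distances in an
#' orthorhombic box. By default water donates to the polymer's ether
#' oxygens (`selection = "water_peg"`; the polymer roles carry no O–H so it
#' cannot donate); `"water_water"` detects water–water bonds, excluding the
#' donor's own molecule.
#'
#' @param coords `n_atoms x 3` matrix of positions (Angstrom) for one
#'   frame, ordered by the 0-based topology index.
#' @param box Length-3 orthorhombic box edges (Angstrom).
#' @param topology Topology tibble ([read_topology()]).
#' @param criterion An [hbond_criterion()].
#' @param selection `"water_peg"` (default) or `"water_water"`.
#' @return Tibble with 0-based atom indices `donor_o`, `h`, `acceptor_o`
#'   and the geometric columns `distance` (Angstrom) and `angle` (degrees).
#' @export
find_hbonds <- function(coords, box, topology, criterion = hbond_criterion(),
                        selection = "water_peg") {
  sel <- hbond_selection_sets(topology, selection)
  nd <- length(sel$h); na <- length(sel$acceptor)
  if (!nd || !na) {
    return(tibble::tibble(donor_o = integer(), h = integer(),
                          acceptor_o = integer(), distance = numeric(),
                          angle = numeric()))
  }
  od <- coords[sel$donor_o, , drop = FALSE]
  hx <- coords[sel$h, , drop = FALSE]
  ax <- coords[sel$acceptor, , drop = FALSE]
  # donor-O to acceptor-O minimum-image distances, nd x na
  d2 <- matrix(0, nd, na)
  for (k in 1:3) {
    dk <- min_image(outer(od[, k], ax[, k], "-"), box[k])
    d2 <- d2 + dk^2
  }
  dist <- sqrt(d2)
  cand <- which(dist <= criterion$max_da_distance, arr.ind = TRUE)
  if (nrow(cand)) {
    # drop pairs whose acceptor is the donor's own oxygen
    same <- sel$donor_o[cand[, 1]] == sel$acceptor[cand[, 2]]
    cand <- cand[!same, , drop = FALSE]
  }
  if (!nrow(cand)) {
    return(tibble::tibble(donor_o = integer(), h = integer(),
                          acceptor_o = integer(), distance = numeric(),
                          angle = numeric()))
  }
  hi <- cand[, 1]; ai <- cand[, 2]
  v1 <- min_image(od[hi, , drop = FALSE] - hx[hi, , drop = FALSE],
                  matrix(box, nrow(cand), 3, byrow = TRUE))
  v2 <- min_image(ax[ai, , drop = FALSE] - hx[hi, , drop = FALSE],
                  matrix(box, nrow(cand), 3, byrow = TRUE))
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  keep <- ang >= criterion$min_angle
  tibble::tibble(
    donor_o = sel$top$index[sel$donor_o[hi[keep]]],
    h = sel$top$index[sel$h[hi[keep]]],
    acceptor_o = sel$top$index[sel$acceptor[ai[keep]]],
    distance = dist[cand][keep],
    angle = ang[keep]
  )
}

#' Hydrogen-bond on/off time series over a trajectory
#'
#' Runs [find_hbonds()] on every frame and assembles the binary bond matrix
#' `h[pair, frame]`. The pair universe is every (donor O, H, acceptor O)
#' triple bonded in at least one frame — the population average `<h>` in
#' the correlation functions is taken over that universe, which is the only
#' way to make it well defined for pairs that are never bonded.
#'
#' @param traj An [md_trajectory].
#' @param topology Topology tibble.
#' @param criterion An [hbond_criterion()].
#' @param selection Donor/acceptor selection as in [find_hbonds()].
#' @return Object of class `hbond_series`: list with `pairs` (tibble of
#'   triples), binary matrix `h` (pairs x frames) and `timestep` (ps). An
#'   empty series (no bonds anywhere) has zero rows and is not an error.
#' @export
hbond_timeseries <- function(traj, topology, criterion = hbond_criterion(),
                             selection = "water_peg") {
  nf <- n_frames(traj)
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    b <- find_hbonds(traj$coords[f, , ], traj$box[f, ], topology, criterion,
                     selection)
    per_frame[[f]] <- paste(b$donor_o, b$h, b$acceptor_o, sep = ":")
  }
  keys <- unique(unlist(per_frame))
  h <- matrix(0L, length(keys), nf, dimnames = list(keys, NULL))
  for (f in seq_len(nf)) {
    h[match(per_frame[[f]], keys), f] <- 1L
  }
  parts <- if (length(keys)) do.call(rbind, strsplit(keys, ":")) else
    matrix(integer(), 0, 3)
  structure(list(
    pairs = tibble::tibble(donor_o = as.integer(parts[, 1]),
                           h = as.integer(parts[, 2]),
                           acceptor_o = as.integer(parts[, 3])),
    h = h, timestep = traj$timestep), class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("<hbond_series> %d pairs x %d frames, timestep %g ps, <h> = %.3f\n",
              nrow(x$h), ncol(x$h), x$timestep,
              if (nrow(x$h)) mean(x$h) else NA_real_))
  invisible(x)
}

# exact integer autocorrelation sums of a binary vector for lags 0..max_lag
binary_autocorr <- function(h, max_lag) {
  n <- length(h)
  m <- stats::nextn(2L * n, 2)
  a <- fft(c(h, rep(0, m - n)))
  ac <- Re(fft(a * Conj(a), inverse = TRUE)) / m
  round(ac[seq_len(max_lag + 1L)])
}

#' Intermittent and continuous hydrogen-bond correlation functions
#'
#' Multiple-time-origin estimators of the intermittent correlator
#' \deqn{C(t) = \langle h(t_0) h(t_0+t) \rangle / \langle h \rangle,}
#' which counts a bond as correlated even if it broke and reformed in
#' between, and the continuous (survival) correlator
#' \deqn{S(t) = \langle h(t_0) \prod_{t' \le t} h(t_0+t') \rangle / \langle h \rangle,}
#' which requires the bond to persist through every intermediate frame
#' (strict continuity; no grace period unless `tolerance_frames > 0`).
#' Both averages run over all pairs in the series and all valid time
#' origins for each lag, and `<h>` is taken over the same origins, so both
#' curves equal 1 at t = 0 and \eqn{C(t) \ge S(t)} holds exactly. The 1/e
#' times of C and S are the structural relaxation time and the bond
#' lifetime respectively.
#'
#' @param series An [hbond_timeseries()] result.
#' @param max_lag Largest lag in frames (default: half the series).
#' @param tolerance_frames Number of consecutive broken frames S(t) may
#'   bridge (default 0, strict continuity).
#' @return Tibble with columns `t` (ps), `C` and `S`, truncated at the
#'   first lag with no bonded origins left.
#' @export
correlation_functions <- function(series, max_lag = NULL, tolerance_frames = 0L) {
  h <- series$h
  n <- ncol(h)
  if (n < 2L) abort("need at least 2 frames")
  if (!nrow(h) || sum(h) == 0) abort("mean bond occupancy <h> is zero")
  if (is.null(max_lag)) max_lag <- n %/% 2L
  max_lag <- min(max_lag, n - 1L)
  lags <- 0:max_lag
  num_c <- numeric(max_lag + 1L)
  num_s <- numeric(max_lag + 1L)
  den <- numeric(max_lag + 1L)
  for (p in seq_len(nrow(h))) {
    hp <- h[p, ]
    num_c <- num_c + binary_autocorr(hp, max_lag)
    hp_s <- if (tolerance_frames > 0L) bridge_gaps(hp, tolerance_frames) else hp
    r <- rle(hp_s)
    lens <- r$lengths[r$values == 1L]
    if (length(lens)) {
      # a run of L ones supplies max(0, L - lag) origins surviving the lag
      num_s <- num_s + vapply(lags, function(l) sum(pmax(lens - l, 0)), numeric(1))
    }
    cs <- cumsum(hp)
    den <- den + cs[n - lags]
  }
  ok <- den > 0
  last <- if (all(ok)) max_lag + 1L else which(!ok)[1L] - 1L
  idx <- seq_len(last)
  tibble::tibble(t = lags[idx] * series$timestep,
                 C = num_c[idx] / den[idx],
                 S = num_s[idx] / den[idx])
}

bridge_gaps <- function(h, tol) {
  r <- rle(h)
  inner <- seq_along(r$values)[-c(1, length(r$values))]
  fill <- r$values == 0L & r$lengths <= tol & seq_along(r$values) %in% inner
  r$values[fill] <- 1L
  inverse.rle(r)
}

#' 1/e relaxation time of a correlation curve
#'
#' Locates the first crossing of 1/e by linear interpolation between the
#' bracketing samples. Applied to the intermittent correlator this gives
#' the structural relaxation time; applied to the continuous correlator,
#' the mean hydrogen-bond lifetime.
#'
#' @param t Times (ps), starting at 0.
#' @param value Correlation values; `value[1]` must be 1.
#' @return The 1/e time in ps.
#' @export
relax_time_1e <- function(t, value) {
  if (abs(value[1L] - 1) > 1e-8) abort("correlation curve must start at 1")
  thr <- exp(-1)
  below <- which(value < thr)
  if (!length(below)) {
    abort(sprintf("curve never crosses 1/e in the sampled window (last value %.4g)",
                  value[length(value)]))
  }
  i <- below[1L]
  t[i - 1L] + (value[i - 1L] - thr) / (value[i - 1L] - value[i]) * (t[i] - t[i - 1L])
}
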