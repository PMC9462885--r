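#' Radial distribution function between two atom roles
#'
#' Standard minimum-image pair histogram in an orthorhombic box, normalized
#' per frame by the ideal-gas shell count and averaged over frames. For the
#' oxygen–oxygen distribution of water, the second and third peak positions
#' distinguish low-density-liquid-like from high-density-liquid-like
#' ordering.
#'
#' @param traj An [md_trajectory].
#' @param topology Topology tibble.
#' @param pair Length-2 character vector of roles, e.g. `c("OW", "OW")`.
#' @param dr Bin width, Angstrom.
#' @param r_max Histogram range; must not exceed half the smallest box edge.
#' @param frames Frame indices to use (default all).
#' @return Tibble of class `rdf_result` with columns `r` (bin centers) and
#'   `g`, plus `pair` and `frames_used` attributes.
#' @export
rdf <- function(traj, topology, pair = c("OW", "OW"), dr = 0.1, r_max = NULL,
                frames = seq_len(n_frames(traj))) {
  top <- topology[order(topology$index), ]
  ia <- which(top$role == pair[1L])
  ib <- which(top$role == pair[2L])
  if (!length(ia)) abort(sprintf("no atoms with role '%s'", pair[1L]))
  if (!length(ib)) abort(sprintf("no atoms with role '%s'", pair[2L]))
  half_box <- min(traj$box[frames, ]) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-9) {
    abort(sprintf("r_max = %g exceeds half the smallest box edge (%g)", r_max, half_box))
  }
  nbins <- ceiling(r_max / dr)
  edges3 <- (0:nbins) * dr
  counts <- numeric(nbins)
  norm <- numeric(nbins)
  same <- identical(pair[1L], pair[2L])
  for (f in frames) {
    box <- traj$box[f, ]
    A <- traj$coords[f, ia, , drop = TRUE]
    B <- traj$coords[f, ib, , drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, ncol = 3)
    if (is.null(dim(B))) B <- matrix(B, ncol = 3)
    d2 <- matrix(0, nrow(A), nrow(B))
    for (k in 1:3) {
      dk <- min_image(outer(A[, k], B[, k], "-"), box[k])
      d2 <- d2 + dk^2
    }
    d <- sqrt(d2)
    if (same) diag(d) <- Inf  # exclude self pairs
    d <- d[d <= r_max]
    counts <- counts + tabulate(pmin(pmax(ceiling(d / dr), 1L), nbins), nbins)
    vol <- prod(box)
    shell <- 4 / 3 * pi * (edges3[-1L]^3 - edges3[-(nbins + 1L)]^3)
    n_pairs <- length(ia) * (if (same) length(ib) - 1L else length(ib))
    norm <- norm + n_pairs * shell / vol
  }
  out <- tibble::tibble(r = (seq_len(nbins) - 0.5) * dr, g = counts / norm)
  structure(out, class = c("rdf_result", class(out)),
            pair = pair, frames_used = length(frames), dr = dr)
}

#' Water volume-distribution function
#'
#' Characterizes the geometry of the percolated water network: the water
#' region is the union of spheres of radius `water_radius` around the water
#' oxygens (with periodic images). `V(r)` is the Monte-Carlo estimate, over
#' probe centers drawn uniformly inside the water region, of the fraction
#' of a radius-`r` sphere around the probe that lies inside the water
#' region. Small-r behavior measures the lateral extent of a water pool
#' (see [confining_length()]); the large-r asymptote equals the volume
#' fraction of water in the box.
#'
#' @param traj An [md_trajectory] (one frame is analyzed).
#' @param topology Topology tibble; water oxygens are the `OW` role.
#' @param radii Probe sphere radii in Angstrom (> 0).
#' @param water_radius Radius of the sphere carried by each water oxygen
#'   (default 1.7 Angstrom, about water's van der Waals radius).
#' @param n_probes Number of probe centers (default 200).
#' @param n_sphere_samples Sample points per probe sphere (default 64).
#' @param frame Frame index (default 1).
#' @param seed Optional integer seed making the estimate reproducible.
#' @return Tibble of class `volume_distribution` with columns `r`, `V` and
#'   `se` (Monte-Carlo standard error over probes).
#' @export
water_volume_distribution <- function(traj, topology, radii,
                                      water_radius = 1.7, n_probes = 200,
                                      n_sphere_samples = 64, frame = 1,
                                      seed = NULL) {
  if (any(radii <= 0)) abort("radii must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  top <- topology[order(topology$index), ]
  iw <- which(top$role == "OW")
  if (!length(iw)) abort("no water oxygen (OW) atoms in topology")
  W <- traj$coords[frame, iw, , drop = TRUE]
  if (is.null(dim(W))) W <- matrix(W, ncol = 3)
  box <- traj$box[frame, ]

  inside <- function(P) {  # nearest min-image water O within water_radius?
    res <- logical(nrow(P))
    chunk <- max(1L, floor(2e6 / nrow(W)))
    for (s in seq(1L, nrow(P), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(P))
      d2 <- matrix(0, length(idx), nrow(W))
      for (k in 1:3) {
        dk <- min_image(outer(P[idx, k], W[, k], "-"), box[k])
        d2 <- d2 + dk^2
      }
      res[idx] <- matrixStats_rowMins(d2) <= water_radius^2
    }
    res
  }

  # probe centers: rejection-sample uniform box points lying in the region
  centers <- matrix(numeric(), 0, 3)
  tries <- 0L
  batch <- max(2L * n_probes, 4000L)
  while (nrow(centers) < n_probes && tries < 200L) {
    cand <- cbind(runif(batch, 0, box[1]),
                  runif(batch, 0, box[2]),
                  runif(batch, 0, box[3]))
    centers <- rbind(centers, cand[inside(cand), , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(centers) < n_probes) abort("could not sample probe centers inside the water region")
  centers <- centers[seq_len(n_probes), , drop = FALSE]

  # independent unit-ball offsets per probe (shared across radii, so V(r)
  # curves are smooth in r); per-probe fractions stay independent
  m <- n_probes * n_sphere_samples
  u <- matrix(rnorm(3L * m), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(m)^(1 / 3)

  rows <- purrr::map_dfr(radii, function(r) {
    pts <- centers[rep(seq_len(n_probes), each = n_sphere_samples), ] + u * r
    hit <- inside(pts)
    per_probe <- colMeans(matrix(hit, n_sphere_samples, n_probes))
    tibble::tibble(r = r, V = mean(per_probe),
                   se = sd(per_probe) / sqrt(n_probes))
  })
  structure(rows, class = c("volume_distribution", class(rows)),
            water_radius = water_radius, n_probes = n_probes)
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Confining length of the water network
#'
#' Fits a straight line to the small-r part of the volume-distribution
#' function and reports its x-axis intercept — the lateral extent of a
#' water pool. The line must be decreasing.
#'
#' @param vd A [water_volume_distribution()] result (or tibble with `r`,
#'   `V`).
#' @param window Length-2 range of r (Angstrom) used for the fit; needs at
#'   least 3 points.
#' @return The confining length in Angstrom.
#' @export
confining_length <- function(vd, window = c(0, 2)) {
  df <- vd[vd$r >= window[1] & vd$r <= window[2], ]
  if (nrow(df) < 3L) abort("need at least 3 points in the small-r window")
  fit <- lm(V ~ r, data = df)
  slope <- coef(fit)[[2L]]
  if (slope >= -1e-12) abort("volume distribution is not decreasing on the window")
  -coef(fit)[[1L]] / slope
}
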