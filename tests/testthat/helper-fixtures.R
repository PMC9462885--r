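# shared fixtures and independent oracles, built in code at test time

# topology for n_w three-atom waters followed by n_p polymer ether oxygens
make_water_peg_topology <- function(n_w, n_p) {
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_w) - 1L, function(m) tibble::tibble(
      index = 3L * m + 0:2, molecule_id = m, molecule_type = "WAT",
      role = c("OW", "HW", "HW"))),
    if (n_p > 0)
      tibble::tibble(index = 3L * n_w + 0:(n_p - 1L),
                     molecule_id = 1000L + 0:(n_p - 1L),
                     molecule_type = "PEG", role = "O_ether")
  )
}

# brute-force all-pairs hydrogen-bond checker (independent of find_hbonds)
brute_force_hbonds <- function(coords, box, topology, cutoff = 3.5,
                               min_angle = 150, selection = "water_peg") {
  mi <- function(d, L) d - L * round(d / L)
  top <- topology[order(topology$index), ]
  acc_role <- if (selection == "water_peg") "O_ether" else "OW"
  acceptors <- which(top$role == acc_role)
  out <- list()
  for (ih in which(top$role == "HW")) {
    io <- which(top$role == "OW" & top$molecule_id == top$molecule_id[ih])
    for (ia in acceptors) {
      if (ia == io) next
      dv <- mapply(function(k) mi(coords[io, k] - coords[ia, k], box[k]), 1:3)
      dd <- sqrt(sum(dv^2))
      if (dd > cutoff) next
      v1 <- mapply(function(k) mi(coords[io, k] - coords[ih, k], box[k]), 1:3)
      v2 <- mapply(function(k) mi(coords[ia, k] - coords[ih, k], box[k]), 1:3)
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= min_angle) {
        out[[length(out) + 1L]] <- c(top$index[io], top$index[ih], top$index[ia])
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# noiseless piecewise-linear elastic scan
bilinear_scan <- function(Tg = seq(10, 300, by = 2), t_break = 220,
                          s1 = -1e-3, s2 = -4e-3, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- ifelse(Tg <= t_break, 1 + s1 * (Tg - Tg[1]),
              1 + s1 * (t_break - Tg[1]) + s2 * (Tg - t_break))
  tibble::tibble(temperature = Tg, intensity = y + sd * rnorm(length(Tg)))
}

# brute-force correlation estimators by explicit origin enumeration
brute_force_correlators <- function(h, max_lag) {
  n <- length(h)
  purrr::map_dfr(0:max_lag, function(l) {
    org <- seq_len(n - l)
    den <- sum(h[org])
    numc <- sum(h[org] * h[org + l])
    nums <- sum(vapply(org, function(t0) prod(h[t0:(t0 + l)]), numeric(1)))
    tibble::tibble(lag = l, C = numc / den, S = nums / den)
  })
}

# Brownian-walker trajectory with wrapped coordinates
brownian_trajectory <- function(n_frames, n_atoms, D, dt, box, seed) {
  set.seed(seed)
  steps <- array(rnorm(n_frames * n_atoms * 3, sd = sqrt(2 * D * dt)),
                 c(n_frames, n_atoms, 3))
  steps[1, , ] <- 0
  u <- apply(steps, c(2, 3), cumsum)
  md_trajectory((u + box / 2) %% box, box, dt)
}

ow_topology <- function(n) {
  tibble::tibble(index = 0:(n - 1L), molecule_id = 0:(n - 1L),
                 molecule_type = "WAT", role = "OW")
}
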