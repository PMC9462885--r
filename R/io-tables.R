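#' Read a reduced QENS spectrum table
#'
#' Reads one temperature's worth of reduced spectra S(q, dE) from the
#' package's columnar CSV dialect: a header line `q,dE,S,err`, data rows in
#' comma-separated decimal-point notation, and `#`-prefixed metadata lines,
#' one of which must be `# temperature=<K>`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `temperature` (K), `q` (1/Angstrom),
#'   `dE` (micro-eV), `S` (intensity, arbitrary units) and `err` (same units
#'   as `S`), validated so that `q > 0`, the `dE` grid within each `q` group
#'   is strictly increasing, and `err >= 0`.
#' @seealso [write_qens_spectrum()], [sum_elastic()], [isf_from_spectrum()]
#' @export
read_qens_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_metadata(lines)
  if (is.null(meta$temperature)) {
    abort(sprintf("spectrum file '%s' lacks a '# temperature=' line", path))
  }
  body_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) abort(sprintf("spectrum file '%s' has no data rows", path))
  header <- strsplit(trimws(lines[body_idx[1L]]), ",")[[1L]]
  needed <- c("q", "dE", "S", "err")
  if (!all(needed %in% trimws(header))) {
    abort(sprintf("spectrum file '%s': missing column(s) %s (line %d)",
                  path, paste(setdiff(needed, trimws(header)), collapse = ", "),
                  body_idx[1L]))
  }
  rows <- body_idx[-1L]
  mat <- do.call(rbind, strsplit(trimws(lines[rows]), ","))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- trimws(header)
  df <- tibble::as_tibble(lapply(df[needed], as.numeric))
  df$line <- rows
  bad <- which(!complete.cases(df[needed]))
  if (length(bad)) {
    abort(sprintf("spectrum file '%s': non-numeric field on line %d", path, df$line[bad[1L]]))
  }
  validate_spectrum_rows(df, path)
  tibble::tibble(temperature = as.numeric(meta$temperature),
                 q = df$q, dE = df$dE, S = df$S, err = df$err)
}

validate_spectrum_rows <- function(df, path) {
  bad <- which(df$q <= 0)
  if (length(bad)) abort(sprintf("'%s': non-positive q on line %d", path, df$line[bad[1L]]))
  bad <- which(df$err < 0)
  if (length(bad)) abort(sprintf("'%s': negative err on line %d", path, df$line[bad[1L]]))
  for (qv in unique(df$q)) {
    sub <- df[df$q == qv, ]
    dd <- diff(sub$dE)
    if (any(dd <= 0)) {
      at <- sub$line[which(dd <= 0)[1L] + 1L]
      abort(sprintf("'%s': dE grid not strictly increasing for q=%g on line %d", path, qv, at))
    }
  }
  invisible(df)
}

#' Write a QENS spectrum table
#'
#' Inverse of [read_qens_spectrum()]; the written file round-trips through
#' the reader to the printed precision (15 significant digits).
#'
#' @param spectrum Tibble with columns `temperature`, `q`, `dE`, `S`, `err`
#'   (one temperature only).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qens_spectrum <- function(spectrum, path) {
  stopifnot(all(c("temperature", "q", "dE", "S", "err") %in% names(spectrum)))
  temp <- unique(spectrum$temperature)
  if (length(temp) != 1L) abort("one temperature per spectrum file")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature=%s", format(temp, digits = 15)), con)
  writeLines("q,dE,S,err", con)
  writeLines(paste(num15(spectrum$q), num15(spectrum$dE),
                   num15(spectrum$S), num15(spectrum$err), sep = ","), con)
  invisible(path)
}

#' Read or write a generic x/y/err curve table
#'
#' The curve dialect carries any 1-D observable of the pipeline — I(q),
#' F(q,t), elastic scans, correlation functions — as `x,y,err` columns plus
#' `# key=value` metadata lines (temperature, q, label, truth records).
#'
#' @param path File path.
#' @return For `read_curve`, a tibble with columns `x`, `y`, `err` and the
#'   metadata in `attr(, "metadata")`; `x` is required strictly increasing
#'   and `err` non-negative.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_metadata(lines)
  body_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  header <- strsplit(trimws(lines[body_idx[1L]]), ",")[[1L]]
  if (!all(c("x", "y") %in% trimws(header))) {
    abort(sprintf("curve file '%s': needs x,y columns (line %d)", path, body_idx[1L]))
  }
  rows <- body_idx[-1L]
  mat <- do.call(rbind, strsplit(trimws(lines[rows]), ","))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- trimws(header)
  out <- tibble::tibble(x = as.numeric(df$x), y = as.numeric(df$y),
                        err = if ("err" %in% names(df)) as.numeric(df$err) else NA_real_)
  if (any(diff(out$x) <= 0)) {
    at <- rows[which(diff(out$x) <= 0)[1L] + 1L]
    abort(sprintf("curve file '%s': x not strictly increasing on line %d", path, at))
  }
  if (any(!is.na(out$err) & out$err < 0)) {
    at <- rows[which(!is.na(out$err) & out$err < 0)[1L]]
    abort(sprintf("curve file '%s': negative err on line %d", path, at))
  }
  attr(out, "metadata") <- meta
  out
}

#' @rdname read_curve
#' @param curve Tibble with columns `x`, `y` and optionally `err`.
#' @param metadata Named list written as `# key=value` lines.
#' @export
write_curve <- function(curve, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s=%s", k, format(metadata[[k]], digits = 15)), con)
  }
  writeLines("x,y,err", con)
  err <- if ("err" %in% names(curve)) curve$err else rep(0, nrow(curve))
  writeLines(paste(num15(curve$x), num15(curve$y), num15(err), sep = ","), con)
  invisible(path)
}

parse_hash_metadata <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  meta
}

num15 <- function(x) trimws(formatC(x, digits = 15, format = "g"))
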