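#' Construct a scattering curve
#'
#' The universal 1-D SAXS input: a strictly increasing grid of scattering
#' vector magnitudes `q` (in inverse Angstroms), intensities `I(q)` in
#' arbitrary units, and optional per-point uncertainties.
#'
#' @param q Numeric vector of scattering vector magnitudes, strictly
#'   increasing and non-negative.
#' @param intensity Numeric vector of intensities, same length as `q`,
#'   all finite.
#' @param sigma Optional numeric vector of non-negative uncertainties.
#' @param label Free-text identifier.
#' @return An object of class `scattering_curve` with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `label`.
#' @examples
#' q <- seq(0.005, 0.25, length.out = 100)
#' crv <- scattering_curve(q, exp(-q^2 * 30^2 / 3))
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = "curve") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("q and intensity must have the same length", call. = FALSE)
  }
  if (length(q) < 8L) {
    stop("a scattering curve needs at least 8 points", call. = FALSE)
  }
  if (anyNA(q) || any(!is.finite(q)) || any(q < 0)) {
    stop("q values must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(q) <= 0)) {
    stop("non-monotone q: q values must be strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      stop("sigma must match the length of q", call. = FALSE)
    }
    if (any(!is.finite(sigma)) || any(sigma < 0)) {
      stop("sigma values must be finite and >= 0", call. = FALSE)
    }
  }
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = as.character(label)[1]),
    class = "scattering_curve"
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> '%s': %d points, q in [%.4g, %.4g] 1/A%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with sigma"))
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Construct a pair-distribution function
#'
#' `P(r)` is the histogram of all intraparticle pair distances; it is zero
#' at `r = 0` and beyond the maximum intraparticle distance `Dmax`.  Unless
#' supplied, `dmax` is set to the last grid point where `p` exceeds
#' `1e-6 * max(p)`, which tolerates truncation noise in deposited files.
#'
#' @param r Distance grid in Angstroms, starting at 0, strictly increasing.
#' @param p `P(r)` values; small negative values (truncation artifacts)
#'   are permitted and handled downstream.
#' @param dmax Maximum intraparticle distance; derived from `p` if `NULL`.
#' @param label Free-text identifier.
#' @return An object of class `pair_distribution` with elements `r`, `p`,
#'   `dmax`, `label`.
#' @export
pair_distribution <- function(r, p, dmax = NULL, label = "pr") {
  r <- as.numeric(r)
  p <- as.numeric(p)
  if (length(r) != length(p)) {
    stop("r and p must have the same length", call. = FALSE)
  }
  if (length(r) < 8L) {
    stop("a pair distribution needs at least 8 points", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(!is.finite(p))) {
    stop("r and p must be finite", call. = FALSE)
  }
  if (abs(r[1]) > .Machine$double.eps * 100) {
    stop("r grid must start at 0", call. = FALSE)
  }
  r[1] <- 0
  if (any(diff(r) <= 0)) {
    stop("r must be strictly increasing", call. = FALSE)
  }
  pmax_ <- max(p)
  if (pmax_ <= 0) stop("P(r) is all zero or negative", call. = FALSE)
  if (is.null(dmax)) {
    # support limit: the grid point where P has just decayed below
    # tolerance (one past the last point above it, so a triangle ending
    # in an exact zero keeps its full base)
    tol <- 1e-6 * pmax_
    dmax <- r[min(length(r), max(which(p > tol)) + 1L)]
  }
  structure(
    list(r = r, p = p, dmax = as.numeric(dmax)[1],
         label = as.character(label)[1]),
    class = "pair_distribution"
  )
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> '%s': %d points, Dmax = %.4g A\n",
              x$label, length(x$r), x$dmax))
  invisible(x)
}

#' Construct an Rg / I(0) annotation
#'
#' Houses the two parameters that scale a curve into the dimensionless
#' Guinier-peak plot: the radius of gyration and the forward scattering.
#'
#' @param rg Radius of gyration, Angstroms, > 0.
#' @param i0 Forward scattering `I(0)`, same units as the curve intensity,
#'   > 0.
#' @param source One of `"guinier"` (reciprocal-space fit), `"pr"`
#'   (real-space moments) or `"external"` (deposited / user-supplied).
#' @return Object of class `annotation`.
#' @export
annotation <- function(rg, i0, source = c("external", "guinier", "pr")) {
  source <- match.arg(source)
  rg <- as.numeric(rg)[1]
  i0 <- as.numeric(i0)[1]
  if (!is.finite(rg) || rg <= 0) stop("rg must be > 0", call. = FALSE)
  if (!is.finite(i0) || i0 <= 0) stop("i0 must be > 0", call. = FALSE)
  structure(list(rg = rg, i0 = i0, source = source), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> Rg = %.4g A, I(0) = %.4g (%s)\n",
              x$rg, x$i0, x$source))
  invisible(x)
}

# Tokenize one line of an ASCII data file: comma or whitespace separated.
.split_fields <- function(line) {
  line <- sub("#.*$", "", line)
  strsplit(trimws(gsub(",", " ", line)), "[[:space:]]+")[[1]]
}

# Parse numeric rows with ncol_min..ncol_max columns from a text file.
# Header lines (non-numeric) are skipped; returns a matrix padded with NA.
.read_numeric_table <- function(path, ncol_min, ncol_max) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  rows <- vector("list", length(lines))
  n <- 0L
  for (ln in lines) {
    f <- .split_fields(ln)
    if (length(f) < ncol_min || length(f) > ncol_max) next
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) next
    n <- n + 1L
    rows[[n]] <- c(v, rep(NA_real_, ncol_max - length(v)))
  }
  if (n == 0L) {
    stop(sprintf("no numeric data rows found in '%s'", path), call. = FALSE)
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Read a scattering curve from a 2- or 3-column ASCII file
#'
#' Accepts the common beamline `.dat` layout: whitespace- or
#' comma-delimited columns `q, I(q)[, sigma]`, with `#` comments and
#' free-text header lines skipped automatically.  Rows containing
#' non-finite values are dropped (with a message reporting the count).
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (default) or `"plain3col"`; both currently use
#'   the same tolerant parser, the enum reserves room for stricter
#'   dialects.
#' @param q_units `"angstrom"` (default) or `"nm"`; nm^-1 grids are
#'   divided by 10 on load so all downstream code sees inverse Angstroms.
#' @param label Identifier; defaults to the file base name.
#' @return A [scattering_curve].
#' @export
read_curve <- function(path, dialect = c("auto", "plain3col"),
                       q_units = c("angstrom", "nm"), label = NULL) {
  dialect <- match.arg(dialect)
  q_units <- match.arg(q_units)
  m <- .read_numeric_table(path, ncol_min = 2L, ncol_max = 3L)
  keep <- is.finite(m[, 1]) & is.finite(m[, 2])
  has_sigma <- !all(is.na(m[, 3]))
  if (has_sigma) keep <- keep & is.finite(m[, 3])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_curve: dropped %d row(s) with non-finite values",
                    dropped))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 8L) {
    stop(sprintf("'%s': fewer than 8 valid data rows", path), call. = FALSE)
  }
  q <- m[, 1]
  if (q_units == "nm") q <- q / 10
  scattering_curve(q, m[, 2], sigma = if (has_sigma) m[, 3] else NULL,
                   label = label %||% basename(path))
}

#' Read a pair-distribution function from a 2-column ASCII file
#'
#' Expects columns `r, P(r)`; comments and header lines are skipped as in
#' [read_curve].  A leading `(0, 0)` row is prepended when absent so the
#' grid always starts at zero.
#'
#' @inheritParams read_curve
#' @return A [pair_distribution] with `dmax` set to the last `r` where
#'   `p > 1e-6 * max(p)`.
#' @export
read_pr <- function(path, label = NULL) {
  m <- .read_numeric_table(path, ncol_min = 2L, ncol_max = 3L)
  keep <- is.finite(m[, 1]) & is.finite(m[, 2])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_pr: dropped %d row(s) with non-finite values",
                    dropped))
  }
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 8L) {
    stop(sprintf("'%s': fewer than 8 valid data rows", path), call. = FALSE)
  }
  r <- m[, 1]
  p <- m[, 2]
  if (r[1] > .Machine$double.eps * 100) {
    r <- c(0, r)
    p <- c(0, p)
  }
  pair_distribution(r, p, label = label %||% basename(path))
}

#' Write a scattering curve to a 3-column ASCII file
#'
#' @param curve A [scattering_curve].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- sprintf("# %s", curve$label)
  if (is.null(curve$sigma)) {
    body <- sprintf("%.8g %.8g", curve$q, curve$intensity)
  } else {
    body <- sprintf("%.8g %.8g %.8g", curve$q, curve$intensity, curve$sigma)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a pair distribution to a 2-column ASCII file
#'
#' @param pr A [pair_distribution].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pr <- function(pr, path) {
  stopifnot(inherits(pr, "pair_distribution"))
  writeLines(c(sprintf("# %s", pr$label),
               sprintf("%.8g %.8g", pr$r, pr$p)), path)
  invisible(path)
}

#' Write a screening report to JSON or CSV
#'
#' The JSON layout carries a `schema` version tag, per-curve records and
#' the collection statistics; CSV is one flat row per curve.
#'
#' @param report A `screen_report` as returned by [screen_collection] /
#'   [hampel_flag].
#' @param path Output path.
#' @param fmt `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, fmt = c("json", "csv")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(report, "screen_report"))
  if (length(report$records) == 0L) {
    stop("cannot write an empty report", call. = FALSE)
  }
  df <- as.data.frame(report)
  if (fmt == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    payload <- list(
      schema = "saxsgpa-screen/1",
      theoretical = list(x = gpa_theoretical_peak()[["x"]],
                         y = gpa_theoretical_peak()[["y"]]),
      stats = report$stats,
      records = df
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a screening report written by [write_report]
#'
#' @param path Path to a JSON or CSV report.
#' @return A data frame of per-curve records.
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE)$records)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
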