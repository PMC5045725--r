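#' Theoretical dimensionless Guinier-peak position
#'
#' For an exact Guinier scatterer the dimensionless plot
#' `qRg I(q)/I(0)` versus `(qRg)^2` peaks at `x = 1.5`,
#' `y = sqrt(1.5) exp(-0.5) = 0.7428`, independent of size and scale.
#'
#' @return Named numeric vector `c(x = 1.5, y = sqrt(1.5) * exp(-0.5))`.
#' @export
gpa_theoretical_peak <- function() {
  c(x = 1.5, y = sqrt(1.5) * exp(-0.5))
}

#' Fit the Guinier approximation to the low-q region of a curve
#'
#' Least-squares line on `(q^2, ln I)`; `Rg = sqrt(-3 * slope)`,
#' `I(0) = exp(intercept)`.  The fit window is chosen iteratively: an
#' initial fit over the lowest 20% of points provides a first `Rg`
#' estimate, after which the window is restricted to
#' `qrg_min <= q * Rg <= qrg_max` and the fit repeated until the point set
#' is stable (at most 10 iterations; a non-converged window is flagged).
#'
#' @param curve A [scattering_curve].
#' @param qrg_max Upper `q * Rg` cap for the window.  1.3 is the standard
#'   guideline for globular scatterers; use 1.1 for extended samples.
#' @param qrg_min Lower `q * Rg` cut, default 0 (keep everything from the
#'   instrument minimum up).
#' @param weighted If `TRUE` and the curve carries `sigma`, weight the
#'   linear fit by `1/sigma^2` (propagated to ln I).  Default unweighted.
#' @return Object of class `guinier_fit`: `rg`, `i0`, `q2_window`,
#'   `qrg_range`, `r_squared`, `n_points`, `window_stable`.
#' @examples
#' q <- seq(0.005, 0.12, length.out = 200)
#' crv <- scattering_curve(q, 100 * exp(-q^2 * 30^2 / 3))
#' guinier_fit(crv)
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, qrg_min = 0,
                        weighted = FALSE) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (qrg_max <= qrg_min) stop("qrg_max must exceed qrg_min", call. = FALSE)
  q <- curve$q
  I <- curve$intensity
  n <- length(q)

  fit_window <- function(idx) {
    if (length(idx) < 5L) {
      stop("Guinier window collapsed below 5 points", call. = FALSE)
    }
    if (any(I[idx] <= 0)) {
      stop("non-positive intensities in the Guinier window", call. = FALSE)
    }
    x <- q[idx]^2
    y <- log(I[idx])
    w <- NULL
    if (weighted && !is.null(curve$sigma)) {
      s <- curve$sigma[idx]
      if (all(s > 0)) w <- (I[idx] / s)^2  # var(ln I) ~ (sigma/I)^2
    }
    fit <- if (is.null(w)) stats::lm.fit(cbind(1, x), y)
           else stats::lm.wfit(cbind(1, x), y, w)
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) {
      stop("Rg undefined: non-negative Guinier slope (intensity not ",
           "decreasing at low q)", call. = FALSE)
    }
    ybar <- if (is.null(w)) mean(y) else sum(w * y) / sum(w)
    ss_tot <- if (is.null(w)) sum((y - ybar)^2) else sum(w * (y - ybar)^2)
    ss_res <- if (is.null(w)) sum(fit$residuals^2)
              else sum(w * fit$residuals^2)
    r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
    list(rg = sqrt(-3 * slope), i0 = exp(fit$coefficients[1]),
         r_squared = min(1, r2))
  }

  idx <- seq_len(max(5L, ceiling(0.2 * n)))
  stable <- FALSE
  res <- fit_window(idx)
  for (iter in seq_len(10L)) {
    qrg <- q * res$rg
    new_idx <- which(qrg >= qrg_min & qrg <= qrg_max)
    if (identical(new_idx, idx)) {
      stable <- TRUE
      break
    }
    idx <- new_idx
    res <- fit_window(idx)
  }
  structure(
    list(rg = unname(res$rg), i0 = unname(res$i0),
         q2_window = c(min(q[idx])^2, max(q[idx])^2),
         qrg_range = unname(c(min(q[idx]), max(q[idx])) * res$rg),
         r_squared = unname(res$r_squared), n_points = length(idx),
         window_stable = stable),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.4g A, I(0) = %.6g, qRg in [%.3g, %.3g], %d pts, R2 = %.6g%s\n",
    x$rg, x$i0, x$qrg_range[1], x$qrg_range[2], x$n_points, x$r_squared,
    if (x$window_stable) "" else " [window unstable]"))
  invisible(x)
}

#' @export
as.list.guinier_fit <- function(x, ...) unclass(x)

# Internal constructor for GPA-family curves.
.gpa_curve <- function(x, y, q, variant, label) {
  structure(list(x = x, y = y, q = q, variant = variant, label = label),
            class = "gpa_curve")
}

#' @export
print.gpa_curve <- function(x, ...) {
  cat(sprintf("<gpa_curve> '%s' (%s): %d points\n",
              x$label, x$variant, length(x$x)))
  invisible(x)
}

#' Guinier-peak transforms of a scattering curve
#'
#' Multiplying the Guinier approximation by `q` turns the monotone
#' Guinier region into a peak: `qI(q)` versus `q^2` has its theoretical
#' maximum at `q^2 = 1.5 / Rg^2` (equivalently `q_max * Rg = 1.22`).  The
#' natural-log variant peaks at the same abscissa; the `qI(q)` versus `q`
#' variant peaks at `q_max = sqrt(1.5) / Rg`.  The transform is an exact
#' pointwise map of the input grid — no resampling.
#'
#' @param curve A [scattering_curve].
#' @param variant `"qiq_vs_q2"` (default), `"ln_qiq_vs_q2"` or
#'   `"qiq_vs_q"`.  For the log variant, points with `qI(q) <= 0` are
#'   dropped (with a message).
#' @return A `gpa_curve` with fields `x`, `y`, the originating `q` grid,
#'   and `variant`.
#' @export
gpa_transform <- function(curve,
                          variant = c("qiq_vs_q2", "ln_qiq_vs_q2",
                                      "qiq_vs_q")) {
  stopifnot(inherits(curve, "scattering_curve"))
  variant <- match.arg(variant)
  q <- curve$q
  qi <- q * curve$intensity
  if (variant == "ln_qiq_vs_q2") {
    keep <- qi > 0
    ndrop <- sum(!keep)
    if (ndrop > 0L) {
      message(sprintf("gpa_transform: dropped %d non-positive qI point(s)",
                      ndrop))
    }
    if (!any(keep)) {
      stop("no positive qI(q) points remain for the ln variant",
           call. = FALSE)
    }
    return(.gpa_curve(q[keep]^2, log(qi[keep]), q[keep], variant,
                      curve$label))
  }
  x <- if (variant == "qiq_vs_q") q else q^2
  .gpa_curve(x, qi, q, variant, curve$label)
}

#' Dimensionless GPA transform
#'
#' Scales a curve by its annotated `(Rg, I0)` into
#' `qRg I(q)/I(0)` versus `(qRg)^2`, in which every exact Guinier
#' scatterer peaks at `(1.5, 0.7428)` regardless of size or intensity
#' scale.  Deviations of the measured peak from that point flag
#' annotation errors or non-Guinier behaviour.
#'
#' @param curve A [scattering_curve].
#' @param ann An [annotation] carrying `rg` and `i0`.
#' @return A `gpa_curve` with `variant = "dimensionless"`.
#' @export
dimensionless_gpa <- function(curve, ann) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(ann, "annotation"))
  qrg <- curve$q * ann$rg
  .gpa_curve(qrg^2, qrg * curve$intensity / ann$i0, curve$q,
             "dimensionless", curve$label)
}

#' Dimensionless Kratky transform
#'
#' `(qRg)^2 I(q)/I(0)` versus `qRg`.  An exact Guinier scatterer peaks at
#' `qRg = sqrt(3)` with height `3/e`; the peak position of real bodies
#' correlates with the elongation ratio.
#'
#' @inheritParams dimensionless_gpa
#' @return A `gpa_curve` with `variant = "kratky_dimensionless"`.
#' @export
dimensionless_kratky <- function(curve, ann) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(ann, "annotation"))
  qrg <- curve$q * ann$rg
  .gpa_curve(qrg, qrg^2 * curve$intensity / ann$i0, curve$q,
             "kratky_dimensionless", curve$label)
}

#' Map a Guinier-peak position into dimensionless coordinates
#'
#' Given a peak located on the `qI(q)` versus `q^2` plot at
#' `(peak_x, peak_y)` and an annotation, the dimensionless image is
#' `x' = peak_x * Rg^2`, `y' = peak_y * Rg / I(0)`, to be compared with
#' the theoretical `(1.5, 0.7428)`.
#'
#' @param peak_x Peak abscissa in `q^2` units, > 0.
#' @param peak_y Peak ordinate in `qI(q)` units.
#' @param ann An [annotation].
#' @return Object of class `dimensionless_peak` with `x_prime`, `y_prime`,
#'   and deviations `dx = x' - 1.5`, `dy = y' - 0.7428`.
#' @export
peak_to_dimensionless <- function(peak_x, peak_y, ann) {
  stopifnot(inherits(ann, "annotation"))
  if (!is.finite(peak_x) || peak_x <= 0) {
    stop("peak_x must be > 0", call. = FALSE)
  }
  th <- gpa_theoretical_peak()
  xp <- peak_x * ann$rg^2
  yp <- peak_y * ann$rg / ann$i0
  structure(
    list(x_prime = xp, y_prime = yp,
         dx = xp - th[["x"]], dy = yp - th[["y"]]),
    class = "dimensionless_peak"
  )
}

#' @export
print.dimensionless_peak <- function(x, ...) {
  cat(sprintf(
    "<dimensionless_peak> (x', y') = (%.4f, %.4f); d = (%+.4f, %+.4f) from (1.5, 0.7428)\n",
    x$x_prime, x$y_prime, x$dx, x$dy))
  invisible(x)
}

#' Estimate Rg and I(0) from the Guinier-peak position
#'
#' Inverts the ideal peak relations: `Rg = sqrt(1.5 / peak_x)` and
#' `I(0) = peak_y * exp(0.5) / sqrt(peak_x)`.  The estimate is exact for
#' ideal Guinier scatterers but biased for elongated bodies, for which
#' the Guinier approximation breaks down before `(qRg)^2 = 1.5`; it also
#' uses only data near the peak, so a traditional Guinier fit is
#' preferred when the Guinier region is well measured.
#'
#' @param peak_x Peak abscissa in `q^2` units, > 0.
#' @param peak_y Peak ordinate in `qI(q)` units, > 0.
#' @return An [annotation] with `source = "guinier"`.
#' @export
estimate_from_peak <- function(peak_x, peak_y) {
  if (!is.finite(peak_x) || peak_x <= 0) {
    stop("peak_x must be > 0", call. = FALSE)
  }
  if (!is.finite(peak_y) || peak_y <= 0) {
    stop("peak_y must be > 0", call. = FALSE)
  }
  annotation(rg = sqrt(1.5 / peak_x),
             i0 = peak_y * exp(0.5) / sqrt(peak_x),
             source = "guinier")
}

#' Sliding-window local Guinier estimates
#'
#' Fits the Guinier line in overlapping windows across the Guinier
#' region and tracks the per-window `Rg` and `I(0)`.  On ideal curves
#' the track is flat; polydispersity makes local `Rg` fall as the window
#' moves to higher q, while interparticle repulsion makes it rise — the
#' two classic diagnostics for non-ideal low-q behaviour.  The overall
#' trend is summarized by the sign of the Theil-Sen slope of `rg`
#' against window center (robust to a single bad window).
#'
#' @param curve A [scattering_curve].
#' @param window_pts Points per window, >= 5.
#' @param qrg_cap Windows whose upper edge exceeds
#'   `q * Rg_global > qrg_cap` are excluded; `Rg_global` comes from a
#'   standard [guinier_fit] of the curve.
#' @return Object of class `local_guinier_track`: data frame `track`
#'   (`center_q2`, `rg`, `i0`), `rg_global`, `trend` in
#'   `c("increasing", "decreasing", "flat")` and `theil_sen_slope`.
#' @export
local_guinier_track <- function(curve, window_pts = 11L, qrg_cap = 1.3) {
  stopifnot(inherits(curve, "scattering_curve"))
  window_pts <- as.integer(window_pts)
  if (window_pts < 5L) stop("window_pts must be >= 5", call. = FALSE)
  gf <- guinier_fit(curve, qrg_max = qrg_cap)
  q <- curve$q
  I <- curve$intensity
  usable <- which(q * gf$rg <= qrg_cap & I > 0)
  step <- max(1L, window_pts %/% 2L)  # half-window overlap
  starts <- seq(1L, length(usable) - window_pts + 1L, by = step)
  rows <- lapply(starts, function(s) {
    idx <- usable[s:(s + window_pts - 1L)]
    x <- q[idx]^2
    fit <- stats::lm.fit(cbind(1, x), log(I[idx]))
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) return(NULL)
    c(center_q2 = mean(x), rg = sqrt(-3 * slope),
      i0 = exp(fit$coefficients[1]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L) {
    stop("fewer than 2 valid local Guinier windows", call. = FALSE)
  }
  track <- as.data.frame(do.call(rbind, rows))
  ts <- .theil_sen_slope(track$center_q2, track$rg)
  rel <- ts * diff(range(track$center_q2)) / stats::median(track$rg)
  trend <- if (abs(rel) < 1e-6) "flat"
           else if (ts > 0) "increasing" else "decreasing"
  structure(
    list(track = track, rg_global = gf$rg, window_pts = window_pts,
         theil_sen_slope = unname(ts), trend = trend),
    class = "local_guinier_track"
  )
}

#' @export
print.local_guinier_track <- function(x, ...) {
  cat(sprintf("<local_guinier_track> %d windows of %d pts; rg trend: %s\n",
              nrow(x$track), x$window_pts, x$trend))
  invisible(x)
}

# Theil-Sen slope: median of all pairwise slopes.
.theil_sen_slope <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  stats::median((y[ij[2, ]] - y[ij[1, ]]) / (x[ij[2, ]] - x[ij[1, ]]))
}
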