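# Gaussian smoothing with reflected boundaries; kernel truncated at 4 sigma.
.gaussian_smooth <- function(y, sigma) {
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  # reflect: y[2], ..., y[h+1] mirrored on the left, symmetric on the right
  left <- y[pmin(n, h + 1L):2L]
  right <- y[(n - 1L):pmax(1L, n - h)]
  if (h + 1L > n) {  # short signals: clamp reflection
    left <- rev(y[-1])[seq_len(min(h, n - 1L))]
    right <- rev(y[-n])[seq_len(min(h, n - 1L))]
    pad_l <- c(rep(y[1], h - length(left)), left)
    pad_r <- c(right, rep(y[n], h - length(right)))
    ext <- c(pad_l, y, pad_r)
  } else {
    ext <- c(left, y, right)
  }
  stats::convolve(ext, rev(k), type = "filter")
}

# Indices of local maxima (plateau-tolerant: >= both neighbours and
# strictly > at least one side or an endpoint of a plateau).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(y[2:(n - 1L)] >= y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  idx[y[idx] > min(y)]
}

#' Scale-space peak criterion for a 1-D signal
#'
#' Scores each point of an ordered signal by its ability to remain at or
#' near a local maximum under successive rounds of Gaussian smoothing.
#' The smoothing scales are a doubling ladder (sd = 1, 2, 4, ... bins, up
#' to a quarter of the signal length); at each scale a point earns one
#' unit of score if it lies within a drift radius (2 bins per scale
#' octave) of a local maximum of the smoothed signal.  Genuine broad
#' peaks survive many scales; single-bin noise spikes die after the first
#' smoothing and score low.
#'
#' @param y Numeric signal on an ordered grid, length >= 16.
#' @return Integer vector of per-point survival scores, same length as
#'   `y`.
#' @export
scale_space_criterion <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 16L) stop("signal too short for scale-space analysis (< 16)",
                    call. = FALSE)
  if (any(!is.finite(y))) stop("signal must be finite", call. = FALSE)
  score <- integer(n)
  if (diff(range(y)) == 0) return(score)  # constant: no distinguished peak
  sigma <- 1
  octave <- 1L
  pos <- seq_len(n)
  while (sigma <= n / 4) {
    ys <- .gaussian_smooth(y, sigma)
    mx <- .local_maxima(ys)
    if (length(mx) > 0L) {
      radius <- 2L * octave
      near <- vapply(pos, function(i) min(abs(i - mx)) <= radius,
                     logical(1))
      score <- score + as.integer(near)
    }
    sigma <- sigma * 2
    octave <- octave + 1L
  }
  score
}

#' Locate the Guinier peak in a GPA curve
#'
#' Model-free localization of the Guinier peak, independent of any
#' Guinier fit.  Each point receives two ranks: `r_c` by its scale-space
#' criterion score (rank 1 = highest score) and `r_qI` by its raw `y`
#' value (rank 1 = highest).  The peak is the point minimizing
#' `r_c * r_qI` — the rank product rewards points that are both high and
#' persistent under smoothing, which discriminates the broad Guinier
#' bump from sharp noise spikes.  Because a single point's intensity is
#' noisy, the reported peak height `y_smooth` comes from a local
#' least-squares polynomial fit around the winner, evaluated at the
#' winner's abscissa.
#'
#' A winner in the first or last two grid points means the curve only
#' falls (or only rises): the Guinier region was likely not measured,
#' and the result is flagged `ok = FALSE` with reason
#' `"no interior peak"` rather than guessed.
#'
#' For quantitative parameter estimation the single grid point is too
#' noisy in both coordinates, so the result also carries a refined peak
#' `(x_refined, y_refined)` from a wider local fit of the transformed
#' Guinier form: regressing `ln y - ln sqrt(x)` on `x` over
#' `+/- refine_halfwidth` points is exact for an ideal Guinier scatterer
#' at any window width (no Taylor truncation bias, unlike a quadratic
#' vertex) and averages noise over the whole peak region.  Feed the
#' refined coordinates to [estimate_from_peak]; the raw winner and
#' polynomial `y_smooth` remain the model-free validation coordinates.
#'
#' @param gpa A `gpa_curve` from [gpa_transform] or [dimensionless_gpa]
#'   (any variant with `y` on a linear scale; the ln variant works too
#'   since ranks are monotone-invariant).
#' @param poly_degree Degree of the local smoothing polynomial
#'   (default 2).
#' @param poly_halfwidth Half-width in points of the polynomial window
#'   (default 5, i.e. up to 11 points).
#' @param refine_halfwidth Half-width in points of the shape-aware
#'   refinement window (default 50; clipped to the grid).
#' @param trim Optional `c(qmin, qmax)` pre-filter on the underlying q
#'   grid, for curves whose noisy extremes defeat the heuristic.
#' @return Object of class `peak_result`: `index`, `x`, `q`, `y_raw`,
#'   `y_smooth`, `x_refined`, `y_refined`, `criterion`, `rank_product`,
#'   `ok`, `reason`.
#' @export
find_guinier_peak <- function(gpa, poly_degree = 2L, poly_halfwidth = 5L,
                              refine_halfwidth = 50L, trim = NULL) {
  stopifnot(inherits(gpa, "gpa_curve"))
  x <- gpa$x
  y <- gpa$y
  q <- gpa$q
  if (!is.null(trim)) {
    keep <- q >= trim[1] & q <= trim[2]
    x <- x[keep]; y <- y[keep]; q <- q[keep]
  }
  n <- length(x)
  fail <- function(reason) {
    structure(list(index = NA_integer_, x = NA_real_, q = NA_real_,
                   y_raw = NA_real_, y_smooth = NA_real_,
                   x_refined = NA_real_, y_refined = NA_real_,
                   criterion = NA_real_, rank_product = NA_real_,
                   ok = FALSE, reason = reason),
              class = "peak_result")
  }
  if (n < 16L) return(fail("curve too short (< 16 points)"))
  if (diff(range(y)) == 0) return(fail("flat signal"))

  crit <- scale_space_criterion(y)
  r_c <- rank(-crit, ties.method = "average")
  r_qi <- rank(-y, ties.method = "average")
  rp <- r_c * r_qi
  winners <- which(rp == min(rp))
  idx <- winners[which.min(x[winners])]  # ties broken toward lower q

  if (idx <= 2L || idx >= n - 1L) return(fail("no interior peak"))

  lo <- max(1L, idx - poly_halfwidth)
  hi <- min(n, idx + poly_halfwidth)
  xi <- x[lo:hi] - x[idx]  # center for conditioning
  deg <- min(poly_degree, length(xi) - 1L)
  X <- stats::poly(xi, degree = deg, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y[lo:hi])
  y_smooth <- unname(fit$coefficients[1])  # polynomial value at x[idx]

  ref <- .refine_peak_shape(x, y, idx, refine_halfwidth)

  structure(
    list(index = idx, x = x[idx], q = q[idx], y_raw = y[idx],
         y_smooth = y_smooth,
         x_refined = ref[["x"]], y_refined = ref[["y"]],
         criterion = crit[idx],
         rank_product = unname(rp[idx]), ok = TRUE, reason = NULL),
    class = "peak_result"
  )
}

# Local fit of the transformed Guinier form y = a sqrt(x) exp(-b x)
# around the winning index: linear LS of ln y - 0.5 ln x on x.  Returns
# the fitted peak (x = 1/(2b), clamped to the window) or the raw point
# when the fit is degenerate.
.refine_peak_shape <- function(x, y, idx, halfwidth) {
  n <- length(x)
  lo <- max(1L, idx - halfwidth)
  hi <- min(n, idx + halfwidth)
  xs <- x[lo:hi]
  ys <- y[lo:hi]
  keep <- is.finite(ys) & ys > 0 & xs > 0
  if (sum(keep) < 5L) return(c(x = x[idx], y = y[idx]))
  fit <- stats::lm.fit(cbind(1, xs[keep]),
                       log(ys[keep]) - 0.5 * log(xs[keep]))
  b <- -fit$coefficients[2]
  if (!is.finite(b) || b <= 0) return(c(x = x[idx], y = y[idx]))
  xpk <- min(max(1 / (2 * b), min(xs)), max(xs))
  c(x = unname(xpk),
    y = unname(exp(fit$coefficients[1]) * sqrt(xpk) * exp(-b * xpk)))
}

#' @export
print.peak_result <- function(x, ...) {
  if (!x$ok) {
    cat(sprintf("<peak_result> FAILED: %s\n", x$reason))
  } else {
    cat(sprintf(
      "<peak_result> index %d, x = %.6g, y_raw = %.6g, y_smooth = %.6g (crit %d, rank prod %.1f)\n",
      x$index, x$x, x$y_raw, x$y_smooth, x$criterion, x$rank_product))
  }
  invisible(x)
}
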