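#' Screen a single scattering curve against its annotation
#'
#' Runs the full model-free pipeline on one curve: GPA transform
#' (`qI(q)` vs `q^2`), scale-space peak localization with polynomial
#' smoothing, and mapping of the located peak into dimensionless
#' coordinates using the supplied annotation.  If a pair distribution is
#' provided, the elongation ratio is attached.  A fresh traditional
#' Guinier fit of the curve and the peak-based parameter re-estimate are
#' stored for later triage by [classify].
#'
#' @param curve A [scattering_curve].
#' @param ann An [annotation] (the values under validation, e.g. the
#'   deposited Rg and I(0)).
#' @param pr Optional [pair_distribution] for the same sample.
#' @param ... Passed to [find_guinier_peak] (e.g. `trim`).
#' @return Object of class `screen_record` with the located raw and
#'   dimensionless peak, `rise_present`, optional `er`, the curve's own
#'   `refit` Guinier parameters (`NULL` when the fit fails) and the
#'   peak-based `reestimate`.  Outlier flags and `class_hint` are filled
#'   in by [hampel_flag] / [classify].
#' @export
screen_curve <- function(curve, ann, pr = NULL, ...) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(ann, "annotation"))
  gpa <- gpa_transform(curve, "qiq_vs_q2")
  peak <- find_guinier_peak(gpa, ...)
  er <- if (!is.null(pr)) {
    tryCatch(elongation_ratio(pr), error = function(e) NULL)
  }
  rec <- list(label = curve$label, ann = ann, peak_raw = peak,
              dimensionless = NULL, rise_present = peak$ok, er = er,
              refit = NULL, reestimate = NULL,
              outlier_x = NA, outlier_y = NA, class_hint = NA_character_)
  if (peak$ok) {
    # screening uses the refined coordinates: the raw winner's x wanders
    # by ~0.1 in (qRg)^2 under realistic noise (the peak top is flat),
    # which would dominate the MADs of a clean synthetic collection
    rec$dimensionless <- peak_to_dimensionless(peak$x_refined,
                                               peak$y_refined, ann)
    rec$reestimate <- tryCatch(
      estimate_from_peak(peak$x_refined, peak$y_refined),
      error = function(e) NULL)
    rec$refit <- tryCatch(guinier_fit(curve), error = function(e) NULL)
  } else {
    rec$class_hint <- "no_guinier_region"
  }
  structure(rec, class = "screen_record")
}

#' @export
print.screen_record <- function(x, ...) {
  if (!x$rise_present) {
    cat(sprintf("<screen_record> '%s': no Guinier region detected\n",
                x$label))
  } else {
    cat(sprintf(
      "<screen_record> '%s': (x', y') = (%.3f, %.4f)%s%s\n", x$label,
      x$dimensionless$x_prime, x$dimensionless$y_prime,
      if (!is.null(x$er)) sprintf(", ER = %.2f", x$er$er) else "",
      if (!is.na(x$class_hint)) sprintf(" [%s]", x$class_hint) else ""))
  }
  invisible(x)
}

#' Hampel (3-MAD) outlier flagging across a curve collection
#'
#' Robust screening of dimensionless Guinier-peak positions: the spread
#' of the collection is measured by the unscaled median absolute
#' deviation of `x'` and `y'` (medians and MADs, not means and standard
#' deviations, so that the outliers being hunted do not inflate the
#' yardstick), and a record is flagged when its deviation from the
#' THEORETICAL position `(1.5, 0.7428)` reaches `k = 3` MADs in either
#' axis.  A floor of `0.01 * |theoretical|` guards against the
#' zero-spread degeneracy of synthetic collections.
#'
#' @param records List of [screen_curve] results; at least 5 must have
#'   `rise_present`.
#' @param k MAD multiplier (default 3, the Hampel identifier).
#' @return Object of class `screen_report`: `records` (with `outlier_x`,
#'   `outlier_y` filled in), `stats` (`median_x`, `mad_x`, `median_y`,
#'   `mad_y`, `k`).
#' @export
hampel_flag <- function(records, k = 3) {
  if (inherits(records, "screen_record")) records <- list(records)
  if (length(records) == 0L) stop("empty record collection", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "screen_record")))
  ok <- vapply(records, function(r) isTRUE(r$rise_present), logical(1))
  if (sum(ok) < 5L) {
    stop("need at least 5 records with a detected Guinier peak",
         call. = FALSE)
  }
  xs <- vapply(records[ok], function(r) r$dimensionless$x_prime, numeric(1))
  ys <- vapply(records[ok], function(r) r$dimensionless$y_prime, numeric(1))
  th <- gpa_theoretical_peak()
  mad_x <- max(stats::median(abs(xs - stats::median(xs))), 0.01 * th[["x"]])
  mad_y <- max(stats::median(abs(ys - stats::median(ys))), 0.01 * th[["y"]])
  stats_ <- list(median_x = stats::median(xs), mad_x = mad_x,
                 median_y = stats::median(ys), mad_y = mad_y, k = k)
  records <- lapply(records, function(r) {
    if (isTRUE(r$rise_present)) {
      r$outlier_x <- abs(r$dimensionless$dx) >= k * mad_x
      r$outlier_y <- abs(r$dimensionless$dy) >= k * mad_y
    }
    r
  })
  structure(list(records = records, stats = stats_),
            class = "screen_report")
}

#' Classify a flagged screening record
#'
#' Triage of a record after [hampel_flag], into the four expected
#' classes of curves whose dimensionless Guinier peak misses the
#' theoretical position, plus `"ok"`:
#'
#' * `no_guinier_region` — no interior peak was found; the rise that
#'   evidences the Guinier region is absent.
#' * `elongated` — outlier in either axis with elongation ratio above
#'   `er_cutoff` (default 5): the Guinier approximation legitimately
#'   breaks down before the Guinier peak for such bodies.
#' * `annotation_suspect` — outlier whose peak-based parameter
#'   re-estimate agrees with a fresh traditional Guinier fit of the
#'   curve itself: the curve is internally consistent and the supplied
#'   annotation is the odd one out.
#' * `problematic_guinier` — outlier for which even the curve's own
#'   Guinier fit disagrees with the peak-based estimate: the low-q
#'   intensities themselves are suspect (polydispersity, interparticle
#'   interference, parasitic scattering...).
#' * `ok` — not an outlier.
#'
#' The annotation_suspect / problematic_guinier discriminator is a
#' heuristic of this package (the class list itself does not come with
#' one): the peak-based re-estimate is deemed to "reconcile" the peak
#' when substituting the refit parameters moves the dimensionless peak
#' within the Hampel limits.
#'
#' @param record A [screen_curve] record with outlier flags set.
#' @param stats The `stats` element of a [hampel_flag] report (supplies
#'   the MAD limits for the reconciliation test).
#' @param er_cutoff Elongation-ratio threshold for the `elongated` class.
#' @return The record with `class_hint` set.
#' @export
classify <- function(record, stats, er_cutoff = 5.0) {
  stopifnot(inherits(record, "screen_record"))
  if (!isTRUE(record$rise_present)) {
    record$class_hint <- "no_guinier_region"
    return(record)
  }
  if (is.na(record$outlier_x) || is.na(record$outlier_y)) {
    stop("record has no outlier flags; run hampel_flag() first",
         call. = FALSE)
  }
  th <- gpa_theoretical_peak()
  if (!record$outlier_x && !record$outlier_y) {
    record$class_hint <- "ok"
    return(record)
  }
  if (!is.null(record$er) && record$er$er > er_cutoff) {
    record$class_hint <- "elongated"
    return(record)
  }
  reconciled <- FALSE
  if (!is.null(record$refit)) {
    refit_ann <- annotation(record$refit$rg, record$refit$i0, "guinier")
    dp <- peak_to_dimensionless(record$peak_raw$x_refined,
                                record$peak_raw$y_refined, refit_ann)
    reconciled <- abs(dp$dx) < stats$k * stats$mad_x &&
                  abs(dp$dy) < stats$k * stats$mad_y
  }
  record$class_hint <- if (reconciled) "annotation_suspect"
                       else "problematic_guinier"
  record
}

#' Screen a collection of curves end to end
#'
#' Convenience wrapper: [screen_curve] on every curve, [hampel_flag]
#' across the collection, then [classify] on every record.
#'
#' @param curves List of [scattering_curve]s.
#' @param anns List of [annotation]s, one per curve.
#' @param prs Optional list of [pair_distribution]s (or `NULL` entries).
#' @param er_cutoff Passed to [classify].
#' @param k Passed to [hampel_flag].
#' @return A `screen_report` with classified records.
#' @export
screen_collection <- function(curves, anns, prs = NULL, er_cutoff = 5.0,
                              k = 3) {
  stopifnot(length(curves) == length(anns))
  if (is.null(prs)) prs <- vector("list", length(curves))
  records <- Map(function(cu, an, pr) screen_curve(cu, an, pr),
                 curves, anns, prs)
  report <- hampel_flag(records, k = k)
  report$records <- lapply(report$records, classify, stats = report$stats,
                           er_cutoff = er_cutoff)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<screen_report> %d curves; medians (x', y') = (%.3f, %.4f), MADs = (%.3f, %.4f)\n",
              nrow(df), x$stats$median_x, x$stats$median_y,
              x$stats$mad_x, x$stats$mad_y))
  print(df, digits = 4)
  invisible(x)
}

#' Flatten a screen report to one row per curve
#'
#' @param x A `screen_report`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `label`, `x_prime`, `y_prime`,
#'   `dx`, `dy`, `er`, `rise_present`, `outlier_x`, `outlier_y`,
#'   `outlier`, `class_hint`.
#' @export
as.data.frame.screen_report <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  rows <- lapply(x$records, function(r) {
    data.frame(
      label = r$label,
      x_prime = if (r$rise_present) r$dimensionless$x_prime else NA_real_,
      y_prime = if (r$rise_present) r$dimensionless$y_prime else NA_real_,
      dx = if (r$rise_present) r$dimensionless$dx else NA_real_,
      dy = if (r$rise_present) r$dimensionless$dy else NA_real_,
      er = if (!is.null(r$er)) r$er$er else NA_real_,
      rise_present = r$rise_present,
      outlier_x = r$outlier_x,
      outlier_y = r$outlier_y,
      outlier = isTRUE(r$outlier_x) | isTRUE(r$outlier_y),
      class_hint = r$class_hint,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
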