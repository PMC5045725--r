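# Shared fixtures, all generated in code.

# Exact Guinier-model curve on a grid spanning qrg_range (in q*Rg units).
ideal_curve <- function(rg = 30, i0 = 1, n = 400, qrg_range = c(0.1, 2.5),
                        label = sprintf("ideal_rg%g", rg)) {
  q <- seq(qrg_range[1] / rg, qrg_range[2] / rg, length.out = n)
  scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3), label = label)
}

# Synthetic-body curve on a grid spanning qrg_range of its true Rg.
body_curve <- function(spec, n = 400, qrg_range = c(0.1, 2.5)) {
  q <- seq(qrg_range[1] / spec$rg_true, qrg_range[2] / spec$rg_true,
           length.out = n)
  synth_intensity(spec, q)
}

# Piecewise-linear P(r): rise 0 -> 1 on [0, peak], fall 1 -> 0 on
# [peak, dmax].
triangle_pr <- function(peak = 1, dmax = 4, n = 81, label = "triangle") {
  r <- seq(0, dmax, length.out = n)
  p <- ifelse(r <= peak, r / peak, (dmax - r) / (dmax - peak))
  pair_distribution(r, p, dmax = dmax, label = label)
}

# Minimal forged screen record at a given dimensionless position, for
# exercising hampel_flag()/classify() mechanics directly.
fake_record <- function(x_prime, y_prime, label = "fake", er = NULL,
                        rise = TRUE) {
  th <- gpa_theoretical_peak()
  structure(
    list(label = label, ann = annotation(30, 1),
         peak_raw = NULL,
         dimensionless = if (rise) {
           structure(list(x_prime = x_prime, y_prime = y_prime,
                          dx = x_prime - th[["x"]],
                          dy = y_prime - th[["y"]]),
                     class = "dimensionless_peak")
         },
         rise_present = rise,
         er = if (!is.null(er)) {
           structure(list(er = er, r_largest = 1, area_before = 1,
                          area_after = er), class = "er_result")
         },
         refit = NULL, reestimate = NULL,
         outlier_x = NA, outlier_y = NA, class_hint = NA_character_),
    class = "screen_record")
}

# The screening fixture collection used by qc tests and acceptance
# criterion 7: 20 noisy ideal-Guinier "globular" curves plus named
# problem cases (see the methods vignette for the stated world).
screening_fixture <- function(seed_base = 100L) {
  curves <- list()
  anns <- list()
  prs <- list()
  for (i in 1:20) {
    rg <- 15 + 3 * i
    crv <- add_noise(ideal_curve(rg, i0 = 10, label = sprintf("glob%02d", i)),
                     0.02, seed = seed_base + i)
    curves[[i]] <- crv
    anns[[i]] <- annotation(rg, 10)
    prs[[i]] <- NULL
  }
  list(curves = curves, anns = anns, prs = prs)
}
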