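test_that("guinier_fit recovers exact-model parameters to machine precision", {
  # property: exact Guinier model on assorted grids/windows
  for (case in list(c(30, 100, 1.3), c(75, 1, 1.1), c(10, 340, 1.0))) {
    rg <- case[1]; i0 <- case[2]; cap <- case[3]
    crv <- ideal_curve(rg, i0, n = 250)
    gf <- guinier_fit(crv, qrg_max = cap)
    expect_equal(gf$rg, rg, tolerance = 1e-8)
    expect_equal(gf$i0, i0, tolerance = 1e-8)
    expect_equal(gf$r_squared, 1, tolerance = 1e-9)
    expect_lte(gf$qrg_range[2], cap * (1 + 1e-9))
    expect_true(gf$window_stable)
  }
})

test_that("guinier_fit agrees with a brute-force lm oracle on the sphere", {
  # true Rg = sqrt(3/5) * 38.72983 = 30; the fit window's upper cap of
  # qRg = 1.3 includes mild form-factor curvature, so the recovered Rg
  # carries a small positive bias (< 2%); implementation must agree with
  # an independent fixed-window fit exactly.
  sp <- shape_spec("sphere", radius = 38.72983)
  crv <- body_curve(sp, n = 800, qrg_range = c(0.02, 2.5))
  gf <- guinier_fit(crv, qrg_max = 1.3)
  # oracle: plain lm on the converged window
  idx <- which(crv$q * gf$rg <= 1.3)
  om <- stats::lm(log(crv$intensity[idx]) ~ I(crv$q[idx]^2))
  expect_equal(gf$rg, sqrt(-3 * coef(om)[[2]]), tolerance = 1e-10)
  expect_equal(gf$i0, exp(coef(om)[[1]]), tolerance = 1e-10)
  expect_equal(gf$rg, 30, tolerance = 0.02)
})

test_that("guinier_fit rejects rising or non-positive low-q intensity", {
  q <- seq(0.005, 0.1, length.out = 50)
  rising <- scattering_curve(q, exp(+q^2 * 900 / 3))
  expect_error(guinier_fit(rising), "Rg undefined")
  negI <- scattering_curve(q, c(-1, exp(-q[-1]^2 * 300)))
  expect_error(guinier_fit(negI), "non-positive")
})

test_that("gpa_transform variants are exact pointwise maps with known argmax", {
  rg <- 30
  crv <- ideal_curve(rg, i0 = 1, n = 2000, qrg_range = c(0.05, 2.5))
  g2 <- gpa_transform(crv, "qiq_vs_q2")
  expect_equal(g2$x, crv$q^2)
  expect_equal(g2$y, crv$q * crv$intensity)
  # argmax at q^2 = 1.5 / Rg^2
  expect_equal(g2$x[which.max(g2$y)], 1.5 / rg^2, tolerance = 2e-3)

  g1 <- gpa_transform(crv, "qiq_vs_q")
  expect_equal(g1$x[which.max(g1$y)], sqrt(1.5) / rg, tolerance = 1e-3)

  # ln variant peaks at the same abscissa as the linear one (monotone map)
  set.seed(42)
  for (i in 1:20) {
    rg_i <- runif(1, 10, 150)
    crv_i <- ideal_curve(rg_i, i0 = runif(1, 0.5, 500), n = 300)
    a <- gpa_transform(crv_i, "qiq_vs_q2")
    b <- gpa_transform(crv_i, "ln_qiq_vs_q2")
    expect_equal(b$x[which.max(b$y)], a$x[which.max(a$y)])
  }
})

test_that("q = 0 maps to the origin and non-positive qI is dropped in ln variant", {
  q <- c(0, seq(0.01, 0.2, length.out = 19))
  crv <- scattering_curve(q, c(50, exp(-q[-1]^2 * 300) * 50))
  g <- gpa_transform(crv, "qiq_vs_q2")
  expect_identical(g$y[1], 0)
  expect_identical(g$x[1], 0)
  expect_message(gl <- gpa_transform(crv, "ln_qiq_vs_q2"), "dropped 1")
  expect_length(gl$x, 19)
})

test_that("dimensionless GPA peaks at (1.5, 0.7428) on exact-model curves", {
  # grid constructed to contain q = sqrt(1.5)/Rg exactly
  rg <- 30
  qpk <- sqrt(1.5) / rg
  q <- sort(unique(c(seq(0.1, 2.5, length.out = 400) / rg, qpk)))
  crv <- scattering_curve(q, 7 * exp(-q^2 * rg^2 / 3))
  dg <- dimensionless_gpa(crv, annotation(rg, 7))
  i <- which.max(dg$y)
  expect_equal(dg$x[i], 1.5, tolerance = 1e-6)
  expect_equal(dg$y[i], sqrt(1.5) * exp(-0.5), tolerance = 1e-6)
  # doubling the I0 annotation halves y
  dg2 <- dimensionless_gpa(crv, annotation(rg, 14))
  expect_equal(dg2$y, dg$y / 2)
})

test_that("dimensionless Kratky peaks at sqrt(3) with height 3/e", {
  rg <- 40
  qpk <- sqrt(3) / rg
  q <- sort(unique(c(seq(0.05, 3.5, length.out = 500) / rg, qpk)))
  crv <- scattering_curve(q, exp(-q^2 * rg^2 / 3))
  kr <- dimensionless_kratky(crv, annotation(rg, 1))
  i <- which.max(kr$y)
  expect_equal(kr$x[i], sqrt(3), tolerance = 1e-6)
  expect_equal(kr$y[i], 3 / exp(1), tolerance = 1e-6)
  # solid sphere: peak sits 7% below sqrt(3) (form-factor concavity);
  # brute-force oracle on the closed form
  u <- seq(0.5, 4, length.out = 1e5)
  phi <- 3 * (sin(u) - u * cos(u)) / u^3
  xo <- (u * sqrt(3 / 5))[which.max((u * sqrt(3 / 5))^2 * phi^2)]
  sp <- shape_spec("sphere", radius = 30)
  crs <- body_curve(sp, n = 600, qrg_range = c(0.05, 3.0))
  ks <- dimensionless_kratky(crs, annotation(sp$rg_true, 1))
  expect_equal(ks$x[which.max(ks$y)], xo, tolerance = 0.01)
})

test_that("peak_to_dimensionless and estimate_from_peak are mutual inverses", {
  # exact algebra on the ideal peak
  rg <- 30
  px <- 1.5 / rg^2
  py <- sqrt(1.5) / rg * exp(-0.5)
  dp <- peak_to_dimensionless(px, py, annotation(rg, 1))
  expect_equal(dp$x_prime, 1.5, tolerance = 1e-12)
  expect_equal(dp$y_prime, 0.7428, tolerance = 1e-4)
  expect_equal(dp$dx, 0, tolerance = 1e-12)

  est <- estimate_from_peak(px, py)
  expect_equal(est$rg, rg, tolerance = 1e-12)
  expect_equal(est$i0, 1, tolerance = 1e-12)

  # scaling laws
  dp_rg <- peak_to_dimensionless(px, py, annotation(rg * 1.2, 1))
  expect_equal(dp_rg$x_prime, 1.5 * 1.44, tolerance = 1e-10)
  dp_i0 <- peak_to_dimensionless(px, py, annotation(rg, 2))
  expect_equal(dp_i0$y_prime, dp$y_prime / 2)
  expect_equal(dp_i0$x_prime, dp$x_prime)
  expect_equal(estimate_from_peak(4 * px, py)$rg, est$rg / 2)

  # property: round trip on random consistent peaks
  set.seed(7)
  for (i in 1:20) {
    x <- runif(1, 1e-5, 1e-2)
    y <- runif(1, 1e-3, 10)
    e <- estimate_from_peak(x, y)
    d <- peak_to_dimensionless(x, y, e)
    expect_equal(d$x_prime, 1.5, tolerance = 1e-10)
    expect_equal(d$y_prime, sqrt(1.5) * exp(-0.5), tolerance = 1e-10)
  }
})

test_that("estimate_from_peak recovers dense-grid ideal parameters within 0.5%", {
  for (rg in c(30, 75)) {
    crv <- ideal_curve(rg, i0 = 340, n = 400, qrg_range = c(0.2, 2.5))
    pk <- find_guinier_peak(gpa_transform(crv))
    est <- estimate_from_peak(pk$x_refined, pk$y_refined)
    expect_equal(est$rg, rg, tolerance = 5e-3)
    expect_equal(est$i0, 340, tolerance = 5e-3)
  }
})

test_that("local Guinier track is flat on ideal curves and detects trends", {
  lt <- local_guinier_track(ideal_curve(30, 10, n = 300))
  expect_equal(diff(range(lt$track$rg)) / 30, 0, tolerance = 1e-7)
  expect_identical(lt$trend, "flat")
  expect_error(local_guinier_track(ideal_curve(30), window_pts = 4),
               ">= 5")

  # strongly polydisperse spheres: local Rg falls with q (concave-up
  # Guinier plot)
  pd <- shape_spec("polydisperse_spheres", mean_radius = 30,
                   sigma_radius = 30)
  lt_pd <- local_guinier_track(body_curve(pd))
  expect_identical(lt_pd$trend, "decreasing")
  expect_true(all(diff(lt_pd$track$rg) < 0))

  # repulsion-suppressed curve: local Rg rises with q (concave-down)
  rp <- shape_spec("repulsion_emulated",
                   base = shape_spec("ideal_guinier", rg = 30),
                   amp = 0.3, xi = 20)
  lt_rp <- local_guinier_track(body_curve(rp))
  expect_identical(lt_rp$trend, "increasing")
  expect_true(all(diff(lt_rp$track$rg) > 0))
})

test_that("weighted Guinier fit accepts sigma and matches unweighted on ideal data", {
  crv <- add_noise(ideal_curve(30, 100, n = 300), 0.001, seed = 1)
  gf_u <- guinier_fit(crv)
  gf_w <- guinier_fit(crv, weighted = TRUE)
  expect_equal(gf_w$rg, 30, tolerance = 5e-3)
  expect_equal(gf_w$rg, gf_u$rg, tolerance = 5e-3)
})
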