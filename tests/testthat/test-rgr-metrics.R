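test_that("RGR is the corrected red over green ratio, with paired variant", {
  expect_equal(compute_rgr(95, 33.5), 33.5 / 95)
  expect_equal(compute_rgr(80, 20, r_pre = 20, variant = "paired"), 0)
  expect_equal(compute_rgr(80, 28, r_pre = 8, variant = "paired"), 0.25)
  expect_true(is.na(compute_rgr(-2, 10)))
  expect_error(compute_rgr(1, 1, variant = "paired"), "r_pre")
})

test_that("end-to-end RGR recovery: exact without noise, rank-faithful with", {
  sc <- make_scene(n_cells = 40, dim = c(160L, 160L, 10L), seed = 50)
  pc <- pc_model()

  # noiseless: recovered RGR equals the generative true RGR exactly
  opt0 <- noiseless_optical()
  pre <- render_scene(sc, opt0, pc, phase = "pre")
  post <- render_scene(sc, opt0, pc, dose = 300, phase = "post")
  pt <- extract_truth_means(pre)
  est <- estimate_corrections(pt$mean_green, pt$mean_red,
                              rep("L", nrow(pt)),
                              dark_green = 5, dark_red = 8)
  tt <- extract_truth_means(post)
  corr <- apply_corrections(tt$mean_green, tt$mean_red, est, "L")
  rgr <- compute_rgr(corr$g_corr, corr$r_corr)
  expect_equal(rgr, post$cells$true_rgr, tolerance = 1e-9)

  # default noise: rank correlation with the latent activity stays >= 0.95
  optn <- optical_model()
  pre_n <- render_scene(sc, optn, pc, phase = "pre", seed = 51)
  post_n <- render_scene(sc, optn, pc, dose = 300, phase = "post", seed = 52)
  ptn <- extract_truth_means(pre_n)
  set.seed(53)
  darks <- estimate_dark_current(
    matrix(rnorm(1e4, 5, 1), 100, 100),
    matrix(rnorm(1e4, 8, 1), 100, 100))
  estn <- estimate_corrections(ptn$mean_green, ptn$mean_red,
                               rep("L", nrow(ptn)),
                               dark_green = darks$dark_green,
                               dark_red = darks$dark_red)
  ttn <- extract_truth_means(post_n)
  corrn <- apply_corrections(ttn$mean_green, ttn$mean_red, estn, "L")
  rgrn <- compute_rgr(corrn$g_corr, corrn$r_corr)
  expect_gte(cor(rgrn, sc$cells$activity, method = "spearman"), 0.95)
})

test_that("region summaries report order statistics with interpolation", {
  s <- summarize_region(c(0.1, 0.2, 0.3))
  expect_equal(s$median, 0.2)
  expect_equal(s$n_cells, 3)

  flat <- summarize_region(rep(0.4, 10))
  expect_equal(flat$range_5_95, 0)
  expect_equal(flat$variance, 0)

  set.seed(60)
  v <- rlnorm(2e5, meanlog = -1, sdlog = 0.5)
  s2 <- summarize_region(v)
  qs <- qlnorm(c(0.05, 0.25, 0.75, 0.95), -1, 0.5)
  expect_equal(s2$p5, qs[1], tolerance = 0.01)
  expect_equal(s2$p25, qs[2], tolerance = 0.01)
  expect_equal(s2$p75, qs[3], tolerance = 0.01)
  expect_equal(s2$p95, qs[4], tolerance = 0.01)

  two <- summarize_region(c(1, 2, 3, 4), region = c("a", "a", "b", "b"))
  expect_equal(two$region, c("a", "b"))
  expect_equal(two$median, c(1.5, 3.5))
  expect_error(summarize_region(numeric(0)), "no cells")
})

test_that("d' matches hand arithmetic and the sum-based oracle", {
  a <- c(0.2, 0.4, 0.6); b <- c(0.0, 0.1, 0.2)
  expect_equal(dprime(a, b), 0.3 / sqrt(0.5 * (0.04 + 0.01)))
  expect_equal(dprime(a, b), 1.8973665961, tolerance = 1e-9)

  set.seed(70)
  for (i in 1:1000) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    x <- rnorm(na, sd = runif(1, 0.5, 2))
    y <- rnorm(nb, mean = runif(1, -1, 1))
    expect_equal(dprime(x, y), dprime_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("d' is symmetric at zero and invariant to common affine maps", {
  g <- c(0.1, 0.5, 0.9)
  expect_equal(dprime(g, g), 0)
  set.seed(71)
  a <- rnorm(20); b <- rnorm(15, 1)
  for (i in 1:20) {
    cc <- runif(1, 0.1, 5); k <- rnorm(1, 0, 3)
    expect_equal(dprime(cc * a + k, cc * b + k), dprime(a, b),
                 tolerance = 1e-10)
  }
  expect_warning(out <- dprime(c(1, 1), c(0, 0)), "infinite")
  expect_true(is.infinite(out) && out > 0)
  expect_equal(dprime(c(2, 2), c(2, 2)), 0)
})

test_that("light-dose arithmetic reproduces the protocol intensities", {
  head_fixed <- light_dose(200, 6.5)
  expect_equal(head_fixed$intensity_mw_mm2, 200 / (pi * 3.25^2))
  expect_equal(head_fixed$intensity_mw_mm2, 6.03, tolerance = 0.01)

  freely <- light_dose(485, 152.5)
  expect_equal(freely$intensity_mw_cm2, 2.655, tolerance = 0.01)

  none <- light_dose(200, 6.5, cycle_duration = 1, n_cycles = 0)
  expect_equal(none$cumulative_dose, 0)
  expect_error(light_dose(-1, 6.5), "power")
})

test_that("cumulative dose is linear in cycles and duration", {
  base <- light_dose(120, 5, cycle_duration = 1, n_cycles = 7)
  expect_equal(light_dose(120, 5, 1, 14)$cumulative_dose,
               2 * base$cumulative_dose)
  expect_equal(light_dose(120, 5, 2, 7)$cumulative_dose,
               2 * base$cumulative_dose)
  expect_equal(cycles_for_dose(10 * base$per_cycle_dose,
                               base$per_cycle_dose), 10L)
})

test_that("decay fitting is exact on exact exponentials", {
  f <- fit_decay(c(0, 1, 2), c(1, 0.5, 0.25))
  expect_equal(f$half_life, 1, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(predict(f, f$half_life), 0.5, tolerance = 1e-8)
  expect_equal(decay_loss(f, 2), 0.75, tolerance = 1e-8)
})

test_that("decay fitting is a fixed point of its own model", {
  days <- c(0, 1, 2, 3, 5, 7, 10, 15)
  f1 <- fit_decay(days, 2^(-days / 1.7))
  regen <- predict(f1, days)
  f2 <- fit_decay(days, regen)
  expect_equal(f2$half_life, f1$half_life, tolerance = 1e-8)
  expect_equal(f1$half_life, 1.7, tolerance = 1e-8)
})

test_that("decay fitting recovers the cohort half-life within 10%", {
  coh <- simulate_decay_cohort(seed = 81)
  med <- aggregate(rgr_norm ~ day, coh, median)
  f <- fit_decay(med$day, med$rgr_norm)
  expect_lt(abs(f$half_life - 1.04) / 1.04, 0.10)
  expect_true(is.finite(f$half_life_se))
  expect_warning(fit_decay(c(0, 1, 2), c(1, 1.5, 2)), "non-decreasing")
})

test_that("free amplitude and offset variants behave", {
  days <- c(0, 1, 2, 4, 7)
  y <- 0.8 * 2^(-days / 1.5) + 0.05
  f <- fit_decay(days, y, fix_amplitude = FALSE, fit_offset = TRUE)
  expect_equal(f$half_life, 1.5, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.8, tolerance = 1e-6)
  expect_equal(f$offset, 0.05, tolerance = 1e-6)
})

test_that("polynomial dose-response fits interpolate and locate maxima", {
  x <- c(0, 1, 2, 3, 4)
  cubic <- fit_dose_response(x, x^3, degree = 3)
  expect_equal(cubic$coefficients, c(0, 0, 0, 1), tolerance = 1e-8)

  line <- fit_dose_response(c(0, 2), c(1, 5), degree = 1)
  expect_equal(line$coefficients, c(1, 2), tolerance = 1e-10)

  # concave curve peaked at 300 on a realistic dose range
  doses <- c(0, 50, 150, 300, 600, 900, 1150)
  y <- -(doses - 300)^2
  quad <- fit_dose_response(doses, y, degree = 2, grid_spacing = 1)
  expect_lte(abs(quad$fitted_max_dose - 300), 1)
  expect_error(fit_dose_response(c(1, 2), c(1, 2), degree = 3),
               "distinct doses")
})

test_that("grating-response integration nulls constants and scores steps", {
  fr <- 30
  epochs <- data.frame(epoch = 1:2, onset = c(91, 451),
                       offset = c(210, 570))  # 4-s windows at 30 fps
  const <- rep(5, 600)
  res <- integrate_grating_response(const, epochs, fr)
  expect_equal(res$total, 0)
  expect_equal(res$per_epoch$value, c(0, 0))

  step <- rep(5, 600)
  for (e in 1:2) step[epochs$onset[e]:epochs$offset[e]] <- 10
  res2 <- integrate_grating_response(step, epochs, fr)
  # per appearance: 120 * (2c/2) - 60 * c = 60c with c = 5
  expect_equal(res2$per_epoch$value, c(300, 300))
  expect_equal(res2$total, 600)
})

test_that("appearances without a full baseline are skipped with a warning", {
  fr <- 15
  epochs <- data.frame(epoch = 1:2, onset = c(1, 181), offset = c(60, 240))
  trace <- rep(3, 360)
  expect_warning(res <- integrate_grating_response(trace, epochs, fr),
                 "skipped")
  expect_true(res$per_epoch$skipped[1])
  expect_equal(res$n_used, 1)
})

test_that("integrated response is monotone in the generated amplitude", {
  amps <- c(0, 5, 10, 20, 40)
  sim <- simulate_grating_traces(stimulus_protocol(),
                                 response_amplitude = amps,
                                 baseline = 100, noise_sd = 2, seed = 90)
  totals <- vapply(seq_along(amps), function(i) {
    suppressWarnings(
      integrate_grating_response(sim$traces[i, ], sim$epochs,
                                 sim$frame_rate)$total)
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})
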