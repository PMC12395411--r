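test_that("difference maps are zero for identical inputs and linear", {
  cfg <- quick_config(kinetics = list(f = 0))
  pn <- generate_map_pair(cfg, noise = FALSE)
  d <- difference_map(pn)
  expect_true(all(d$diff == 0))

  cfg2 <- quick_config()
  p <- generate_map_pair(cfg2, noise = FALSE)
  d1 <- difference_map(p)
  p3 <- p
  p3$on <- 3 * p$on; p3$off <- 3 * p$off
  expect_equal(difference_map(p3)$diff, 3 * d1$diff)

  # sign pattern at 150 fs: depletion at the GS line, gain at the S1 line
  at150 <- d1[d1$delay == 150, ]
  gs_px <- which.min(abs(at150$energy - 537.6))
  s1_px <- which.min(abs(at150$energy - 541.8))
  expect_lt(at150$diff[gs_px], 0)
  expect_gt(at150$diff[s1_px], 0)
})

test_that("plain estimator recovers f when the window is uncontaminated", {
  # no HGS branch; at >= 10 ps the S1/S2 populations have decayed and the
  # triplet lines lie outside the ground-state window
  cfg <- quick_config(kinetics = list(phi_hgs = 0))
  pn <- generate_map_pair(cfg, noise = FALSE)
  est <- estimate_excited_fraction(pn, gs_window = c(536, 539),
                                   delay_window = c(5e3, 2e6))
  expect_equal(est$f, 0.09, tolerance = 1e-3)

  # on == off
  cfg0 <- quick_config(kinetics = list(f = 0))
  p0 <- generate_map_pair(cfg0, noise = FALSE)
  expect_equal(estimate_excited_fraction(p0, c(536, 539),
                                         c(5e3, 2e6))$f, 0)

  # scale invariance
  p2 <- pn
  p2$on <- pn$on * 7.3; p2$off <- pn$off * 7.3
  est2 <- estimate_excited_fraction(p2, c(536, 539), c(5e3, 2e6))
  expect_equal(est2$f, est$f, tolerance = 1e-12)

  expect_error(estimate_excited_fraction(pn, c(520, 521), c(1e6, 2e6)),
               class = "trxps_estimation_error")
})

test_that("plain estimator is unbiased under Poisson noise", {
  cfg <- quick_config(kinetics = list(phi_hgs = 0))
  fs <- vapply(1:60, function(s) {
    p <- generate_map_pair(cfg, seed = s)
    estimate_excited_fraction(p, c(536, 539), c(5e3, 2e6))$f
  }, numeric(1))
  expect_lt(abs(mean(fs) - 0.09), 0.005)
})

test_that("model-based estimator handles the overlapped uracil window", {
  cfg <- quick_config()
  pn <- generate_map_pair(cfg, noise = FALSE)
  eg <- sort(unique(pn$energy))
  eg <- eg[eg >= 536 & eg < 539]
  comp <- f_estimator_components(cfg, eg)
  est <- estimate_excited_fraction(pn, c(536, 539), c(200, 450), comp)
  expect_equal(est$f, 0.09, tolerance = 0.01)
  expect_match(est$method, "model-based")
})

test_that("scaled subtraction eliminates the depletion at the truth f", {
  cfg <- quick_config()
  pn <- generate_map_pair(cfg, noise = FALSE)
  f <- map_truth(pn)$f
  sc <- scaled_subtract(pn, f)
  late <- sc[sc$delay >= 200 & sc$delay <= 500, ]
  expect_gt(min(late$value), -1e-8 * max(late$value))

  # identity at f = 1
  expect_equal(scaled_subtract(pn, 1)$value, pn$on)

  # under-estimated f leaves a dip, over-estimated a spike at the GS line
  gs_val <- function(fx) {
    s <- scaled_subtract(pn, fx)
    s$value[s$delay == 500][which.min(abs(
      s$energy[s$delay == 500] - 537.6))]
  }
  expect_lt(gs_val(0.05), 0)
  expect_gt(gs_val(0.15), gs_val(f))
  expect_error(scaled_subtract(pn, 0), class = "trxps_domain_error")
})

test_that("region integration is additive and propagates Poisson errors", {
  cfg <- quick_config()
  p <- generate_map_pair(cfg)
  d <- difference_map(p)
  regions <- tibble::tibble(region = c("lo", "hi"),
                            lo = c(528, 539), hi = c(539, 550.001))
  tr <- integrate_regions(d, regions)
  tot <- tapply(d$diff, d$delay, sum)
  by_delay <- tapply(tr$value, tr$delay, sum)
  expect_equal(as.numeric(by_delay), as.numeric(tot))

  # constant map
  cm <- tibble::tibble(delay = rep(c(0, 20), each = 5),
                       energy = rep(1:5, 2), value = 2)
  trc <- integrate_regions(cm, tibble::tibble(region = "all", lo = 1,
                                              hi = 6), value_col = "value")
  expect_true(all(trc$value == 10))

  expect_error(integrate_regions(d, tibble::tibble(region = "x", lo = 1,
                                                   hi = 2)),
               class = "trxps_config_error")

  # the S1 shakeup band (region F, no triplet content) decays with the
  # configured intersystem-crossing constant
  pnz <- generate_map_pair(cfg, noise = FALSE)
  dn <- difference_map(pnz)
  f_tr <- integrate_regions(dn, default_regions("O1s"))
  f_tr <- f_tr[f_tr$region == "F" & f_tr$delay >= 300 & f_tr$delay <= 1e4, ]
  fitexp <- suppressWarnings(
    nls(value ~ a * exp(-delay / tau), data = f_tr,
        start = list(a = max(f_tr$value), tau = 1000),
        control = list(warnOnly = TRUE)))
  expect_equal(coef(fitexp)[["tau"]], 1600, tolerance = 0.1)
})

test_that("sideband correction restores the monotone N 1s depletion", {
  cfg <- preset("n1s_paper")
  pn <- generate_map_pair(cfg, noise = FALSE)
  dn <- difference_map(pn)
  regions <- tibble::tibble(region = c("B", "SBlow", "SBhigh"),
                            lo = c(406.3, 400.9, 410.5),
                            hi = c(408.3, 403.2, 412.9))
  tr <- integrate_regions(dn, regions)
  dep <- tr[tr$region == "B", ]
  sb_lo <- tr[tr$region == "SBlow", ]
  sb_hi <- tr[tr$region == "SBhigh", ]
  sb <- sb_lo
  sb$value <- sb_lo$value + sb_hi$value
  sb$sigma <- sqrt(sb_lo$sigma^2 + sb_hi$sigma^2)
  # uncorrected depletion over-shoots during pulse overlap and recovers
  dense <- dep$delay <= 500
  i_min <- which.min(dep$value[dense])
  expect_lt(abs(dep$delay[dense][i_min]), 60)
  expect_gt(dep$value[dense][sum(dense)], min(dep$value[dense]))

  # the correction removes the overlap transient: the corrected dip is a
  # small fraction of the raw one, and late delays are untouched
  corr <- sideband_corrected_depletion(dep[c("delay", "value", "sigma")],
                                       sb[c("delay", "value", "sigma")])
  expect_gt(min(corr$value[dense]), 0.05 * min(dep$value[dense]))
  expect_equal(corr$value[corr$delay == 300], dep$value[dep$delay == 300],
               tolerance = 1e-4)

  # identity for a zero sideband trace and scalar commutation
  zero <- sb; zero$value <- 0; zero$sigma <- 0
  expect_equal(sideband_corrected_depletion(
    dep[c("delay", "value", "sigma")],
    zero[c("delay", "value", "sigma")])$value, dep$value)
  half <- function(x) { x$value <- x$value * 0.5; x$sigma <- x$sigma * 0.5; x }
  expect_equal(
    sideband_corrected_depletion(half(dep[c("delay", "value", "sigma")]),
                                 half(sb[c("delay", "value", "sigma")]))$value,
    0.5 * corr$value)

  bad <- sb[c("delay", "value", "sigma")]
  bad$delay <- bad$delay + 1
  expect_error(sideband_corrected_depletion(
    dep[c("delay", "value", "sigma")], bad),
    class = "trxps_alignment_error")
})

test_that("peak tracking recovers a known Gaussian exactly", {
  eg <- seq(535, 540, by = 0.02)
  tg <- c(0, 100)
  map <- tidyr::crossing(delay = tg, energy = eg)
  map$value <- 50 * exp(-(map$energy - 537.62)^2 / (2 * 0.41^2)) +
    3 + 0.1 * (map$energy - 537)
  pt <- track_gs_peak(map, window = c(535.5, 539.5),
                      smooth_sigma_t = 0, smooth_sigma_e = 0)
  expect_true(all(pt$converged))
  expect_equal(pt$mean, rep(537.62, 2), tolerance = 1e-6)
  expect_equal(pt$sigma_width, rep(0.41, 2), tolerance = 1e-6)
  expect_equal(pt$baseline_slope, rep(0.1, 2), tolerance = 1e-6)

  # zero-width smoothing kernels leave the fit unchanged
  pt2 <- track_gs_peak(map, window = c(535.5, 539.5),
                       smooth_sigma_t = 18, smooth_sigma_e = 0.2)
  expect_equal(pt2$mean, pt$mean, tolerance = 1e-9)
})

test_that("peak tracking follows the hot-ground-state drift", {
  # pure HGS branch: the scaled-subtracted map contains only the hot line
  cfg <- quick_config(kinetics = list(phi_hgs = 1),
                      vibration = list(hgs_coupling_eV_per_A = 0))
  pn <- generate_map_pair(cfg, noise = FALSE)
  sc <- scaled_subtract(pn, map_truth(pn)$f)
  pt <- track_gs_peak(sc, window = c(536, 539.4),
                      smooth_sigma_t = 0, smooth_sigma_e = 0)
  early <- pt$mean[pt$delay == 100]
  late <- pt$mean[pt$delay == 1000]
  drift_cfg <- cfg$spectra$hgs$offset_max_eV
  expect_equal(late - early, drift_cfg * (1 - 100 / 1000), tolerance = 0.05)
})

test_that("windowed spectra are stable for constant maps and track maxima", {
  eg <- seq(535, 540, by = 0.05)
  tg <- seq(0, 400, by = 20)
  cmap <- tidyr::crossing(delay = tg, energy = eg)
  cmap$value <- exp(-(cmap$energy - 537.5)^2)
  ws <- windowed_spectra(cmap, centers = c(100, 300), width = 108,
                         smooth_sigma = 0.15)
  w1 <- ws$value[ws$center == 100]
  w2 <- ws$value[ws$center == 300]
  expect_equal(w1, w2)

  cfg <- quick_config(kinetics = list(phi_hgs = 1),
                      vibration = list(hgs_coupling_eV_per_A = 0))
  pn <- generate_map_pair(cfg, noise = FALSE)
  sc <- scaled_subtract(pn, map_truth(pn)$f)
  ws2 <- windowed_spectra(sc, centers = c(100, 400), width = 108,
                          smooth_sigma = 0.15)
  mx <- attr(ws2, "maxima")
  expect_gt(mx$max_energy[mx$center == 400],
            mx$max_energy[mx$center == 100])
  expect_error(windowed_spectra(cmap, centers = 5000, width = 108),
               class = "trxps_config_error")
})
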