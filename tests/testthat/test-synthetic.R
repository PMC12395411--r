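test_that("bond series carry the step extension and damped oscillation", {
  modes <- list(list(freq_cm1 = 292.7, bond = "C5C6", amp_A = 0.1,
                     damp_fs = 600, phase = 0))
  tg <- seq(-50, 600, by = 1)
  b <- simulate_bond_series(modes, tg)
  expect_true(all(b$length[b$t < 0] == 1.34))
  # successive maxima separated by the 114 fs period
  y <- b$length
  loc <- which(diff(sign(diff(y))) == -2) + 1
  expect_gt(length(loc), 3)
  expect_equal(mean(diff(tg[loc])), wavenumber_to_period(292.7),
               tolerance = 0.02)
  # oscillation amplitude decays with the configured damping
  period <- wavenumber_to_period(292.7)
  dev <- abs(y - 1.34 - 0.1)
  expect_equal(dev[tg == round(period)] / dev[tg == round(5 * period)],
               exp(4 * period / 600), tolerance = 0.05)

  flat <- simulate_bond_series(list(list(freq_cm1 = 100, bond = "C4O8",
                                         amp_A = 0, damp_fs = 500,
                                         phase = 0)), tg)
  expect_true(all(flat$length == 1.22))
})

test_that("stick modulation is linear in bond deviation", {
  sticks <- load_stick_tables("O1s")
  sticks <- sticks[sticks$state == "S1_npi", ]
  bonds <- tibble::tibble(t = c(0, 10), bond = "C5C6",
                          length = c(1.34, 1.44))
  coup <- list(list(state = "S1_npi", energy_eV = 544.02, bond = "C5C6",
                    slope_eV_per_A = 2))
  mod <- modulated_sticks(sticks, bonds, coup)
  m <- mod[abs(mod$energy_base - 544.02) < 1e-9, ]
  expect_equal(m$energy[m$t == 0], 544.02)
  expect_equal(m$energy[m$t == 10], 544.22)
  other <- mod[abs(mod$energy_base - 546.40) < 1e-9, ]
  expect_true(all(other$energy == 546.40))
  expect_true(all(mod$strength %in% sticks$strength))  # strengths untouched
  bad <- list(list(state = "S1_npi", energy_eV = 999, bond = "C5C6",
                   slope_eV_per_A = 2))
  expect_error(modulated_sticks(sticks, bonds, bad),
               class = "trxps_config_error")
})

test_that("sidebands are pump-displaced replicas gated by the overlap", {
  o <- apply_rigid_shift(load_stick_tables("O1s"), -2.4)
  gs <- broaden(o[o$state == "GS", ], lineshape("gaussian", 0.8),
                seq(528, 550, 0.02))
  sb0 <- sideband_component(gs, 4.70, t = 0, t0 = 0, sigma_cc = 34.2,
                            ratio = 0.23, amplitude_scale = 0.09)
  low <- sb0[sb0$energy < 535, ]
  up <- sb0[sb0$energy > 540, ]
  expect_equal(low$energy[which.max(low$intensity)], 532.9,
               tolerance = 0.025)
  expect_equal(up$energy[which.max(up$intensity)], 542.3,
               tolerance = 0.025)
  # borrowed intensity balances the replicas
  expect_equal(sum(sb0$intensity), 0, tolerance = 1e-6 * sum(abs(sb0$intensity)))
  # Gaussian gate: negligible 5 sigma away from overlap
  sb5 <- sideband_component(gs, 4.70, t = 5 * 34.2, t0 = 0,
                            sigma_cc = 34.2, ratio = 0.23,
                            amplitude_scale = 0.09)
  expect_lt(max(abs(sb5$intensity)), 4e-6 * max(abs(sb0$intensity)))
  none <- sideband_component(gs, 4.70, 0, 0, 34.2, ratio = 0)
  expect_true(all(none$intensity == 0))
  expect_error(sideband_component(gs, 4.70, 0, 0, 34.2, ratio = -1),
               class = "trxps_domain_error")
})

test_that("map pairs are deterministic and conserve counts when noiseless", {
  cfg <- quick_config()
  p1 <- generate_map_pair(cfg, seed = 7)
  p2 <- generate_map_pair(cfg, seed = 7)
  expect_identical(p1$on, p2$on)
  expect_identical(p1$off, p2$off)
  p3 <- generate_map_pair(cfg, seed = 8)
  expect_false(identical(p1$on, p3$on))

  # f = 0, no noise: UV-on equals UV-off exactly
  cfg0 <- quick_config(kinetics = list(f = 0))
  pn <- generate_map_pair(cfg0, noise = FALSE)
  expect_equal(pn$on, pn$off)

  # noiseless difference integrates to zero at every delay
  pnz <- generate_map_pair(cfg, noise = FALSE)
  net <- tapply(pnz$on - pnz$off, pnz$delay, sum)
  scale <- tapply(pnz$off, pnz$delay, sum)
  expect_lt(max(abs(net / scale)), 1e-6)
})

test_that("sideband-to-depletion amplitude follows the configured ratio", {
  cfg <- quick_config()
  pn <- generate_map_pair(cfg, noise = FALSE)
  d <- pn$on - pn$off
  at0 <- d[pn$delay == 0]
  e <- pn$energy[pn$delay == 0]
  sb_peak <- max(at0[e >= 531.5 & e < 533.5])
  # construction: replica peak = ratio x (asymptotic depletion of the
  # unrefilled main line) = ratio x f x max(off)
  truth <- map_truth(pn)
  dep_naive <- truth$f * max(pn$off[pn$delay == 500])
  expect_equal(sb_peak / dep_naive, 0.23, tolerance = 0.02)
})

test_that("pixel expectations match the Monte-Carlo mean", {
  cfg <- quick_config()
  cfg$delays <- c(-50, 0, 150)
  attr(cfg, "validated") <- NULL
  cfg <- validate_config(cfg)
  mu <- generate_map_pair(cfg, noise = FALSE)
  sel <- mu$energy >= 535 & mu$energy <= 543
  n_mc <- 150
  acc <- 0
  for (s in seq_len(n_mc)) {
    acc <- acc + generate_map_pair(cfg, seed = s)$on[sel]
  }
  mean_mc <- acc / n_mc
  se <- sqrt(pmax(mu$on[sel], 1) / n_mc)
  frac_bad <- mean(abs(mean_mc - mu$on[sel]) > 3 * se)
  expect_lt(frac_bad, 0.01)
})

test_that("truth record reproduces the generator parameters", {
  cfg <- preset("fast_smoke")
  pair <- generate_map_pair(cfg)
  tr <- map_truth(pair)
  expect_equal(tr$f, 0.09)
  expect_equal(tr$tau_ic, 17)
  expect_equal(tr$tau_isc, 1600)
  expect_equal(tr$cc_fwhm, 80.5)
  expect_equal(tr$irf_convention, "fwhm")
  expect_equal(tr$seed, 301L)
})

test_that("delay rebinning conserves counts and corrects jitter", {
  set.seed(42)
  shots <- tidyr::crossing(
    shot = 1:400,
    energy = c(537.0, 537.5)
  )
  shots$delay <- rep(runif(400, -90, 90), each = 2)
  shots$counts <- rpois(nrow(shots), 50 * exp(-shots$delay^2 / (2 * 34.2^2)))
  out <- rebin_delays(shots, bin_width = 18)
  expect_equal(sum(out$counts), sum(shots$counts))
  expect_true(all(diff(unique(out$delay)) > 0))

  # arrival-time-corrected Gaussian profile keeps its width after binning
  v <- tapply(out$counts, out$delay, sum)
  prof <- data.frame(delay = as.numeric(names(v)), v = as.numeric(v))
  fit <- suppressWarnings(
    nls(v ~ a * exp(-(delay - m)^2 / (2 * s^2)), data = prof,
        start = list(a = max(prof$v), m = 0, s = 30)))
  expect_equal(abs(coef(fit)[["s"]]), 34.2, tolerance = 0.15)

  # delays already on bin centres pass through up to binning
  shots2 <- tibble::tibble(shot = 1, delay = rep(c(0, 18, 36), 2),
                           energy = rep(c(537, 538), each = 3),
                           counts = 10)
  out2 <- rebin_delays(shots2, 18)
  expect_setequal(out2$delay, c(0, 18, 36))
  expect_true(all(out2$counts == 10))
})

test_that("the S2 ramp moves early region-A signal toward region B", {
  cfg_drift <- quick_config(spectra = list(s2_drift_eV = 1.7,
                                           s2_drift_fs = 25))
  cfg_plain <- quick_config()
  d_drift <- generate_map_pair(cfg_drift, noise = FALSE)
  d_plain <- generate_map_pair(cfg_plain, noise = FALSE)
  a_sel <- function(p, t) {
    sum((p$on - p$off)[p$energy >= 535.9 & p$energy < 536.6 & p$delay == t])
  }
  # with the ramp the S2 line has left region A by ~50 fs
  expect_lt(a_sel(d_drift, 50), 0.5 * a_sel(d_plain, 50))
})
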