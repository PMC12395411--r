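test_that("packaged stick tables hold the published energies", {
  o <- load_stick_tables("O1s")
  expect_setequal(o$energy[o$state == "GS"], c(539.95, 540.05))
  expect_setequal(o$energy[o$state == "S1_npi"], c(539.86, 544.02, 546.40))
  expect_setequal(o$energy[o$state == "S2_pipi"],
                  c(534.20, 538.26, 539.17, 540.41))
  n <- load_stick_tables("N1s")
  expect_setequal(n$energy[n$state == "GS"], c(408.77, 409.10))
  expect_setequal(n$energy[n$state == "S2_pipi"], c(408.38, 410.24))
  expect_error(load_stick_tables("C1s"), class = "trxps_lookup_error")
})

test_that("table arithmetic matches the quoted spectral separations", {
  o <- load_stick_tables("O1s")
  s1_o8 <- sort(o$energy[o$state == "S1_npi" & o$site == "O8"])
  # asymmetric doublet separation, 'approximately 2.4 eV'
  expect_equal(s1_o8[2] - s1_o8[1], 2.38, tolerance = 1e-9)
  expect_equal(round(s1_o8[2] - s1_o8[1], 1), 2.4)
  # S1 O8 line relative to the GS O8 line, '4 eV higher'
  gs_o8 <- o$energy[o$state == "GS" & o$site == "O8"]
  expect_equal(s1_o8[1] - gs_o8, 4.07, tolerance = 1e-9)
})

test_that("rigid shifts are additive, invertible and exact", {
  o <- load_stick_tables("O1s")
  sh <- apply_rigid_shift(o, -2.4)
  expect_equal(sh$energy[o$state == "GS" & o$site == "O8"], 537.55)
  expect_equal(apply_rigid_shift(o, 0), o)
  expect_equal(apply_rigid_shift(sh, 2.4)$energy, o$energy)
  two <- apply_rigid_shift(apply_rigid_shift(o, -1.0), -1.4)
  expect_equal(two$energy, sh$energy)
})

test_that("broadening conserves area, is linear, and resolves the doublet", {
  o <- load_stick_tables("O1s")
  shape <- lineshape("lorentzian", 0.4)
  grid <- seq(528, 560, by = 0.01)
  one <- o[o$state == "GS" & o$site == "O8", ]
  b1 <- broaden(one, shape, grid)
  expect_equal(b1$energy[which.max(b1$intensity)], 539.95, tolerance = 0.011)
  quad <- function(b) sum(diff(b$energy) *
                            (b$intensity[-1] + b$intensity[-nrow(b)]) / 2)
  expect_equal(quad(b1), 1, tolerance = 0.01)

  expect_true(all(broaden(o[0, ], shape, grid)$intensity == 0))

  gs <- o[o$state == "GS", ]
  expect_equal(broaden(gs, shape, grid)$intensity,
               broaden(gs[1, ], shape, grid)$intensity +
                 broaden(gs[2, ], shape, grid)$intensity,
               tolerance = 1e-12)

  # S1 O8 doublet, equal strengths: two maxima separated by 2.38 eV
  dbl <- o[o$state == "S1_npi" & o$site == "O8", ]
  bd <- broaden(dbl, shape, grid)
  y <- bd$intensity
  loc <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(loc, 2)
  expect_equal(diff(bd$energy[loc]), 2.38, tolerance = 0.011)

  # area invariant under rigid shift and grid refinement (Richardson)
  b_shift <- broaden(apply_rigid_shift(gs, -2.4), shape, grid)
  expect_equal(quad(b_shift), quad(broaden(gs, shape, grid)),
               tolerance = 1e-3)
  grid2 <- seq(528, 560, by = 0.005)
  expect_equal(quad(broaden(gs, shape, grid2)),
               quad(broaden(gs, shape, grid)), tolerance = 1e-3)

  expect_warning(broaden(gs, shape, seq(539, 541, 0.01)),
                 "margin")
  expect_error(broaden(gs, shape, c(1, 1, 2)),
               class = "trxps_domain_error")
})

test_that("composite spectra balance depletion against excited signal", {
  o <- load_stick_tables("O1s")
  shape <- lineshape("gaussian", 0.8)
  grid <- seq(528, 552, by = 0.02)
  spectra <- list(
    GS = broaden(o[o$state == "GS", ], shape, grid),
    S1_npi = broaden(o[o$state == "S1_npi", ], shape, grid)
  )
  quad <- function(y) sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)

  zero <- composite_spectrum(spectra, c(S1_npi = 0), f = 0)
  expect_true(all(zero$intensity == 0))

  full <- composite_spectrum(spectra, c(S1_npi = 1), f = 1)
  expect_equal(quad(full$intensity), 0, tolerance = 1e-6)

  part <- composite_spectrum(spectra, c(S1_npi = 0.06), f = 0.09)
  pos <- pmax(part$intensity, 0); neg <- pmin(part$intensity, 0)
  expect_equal(quad(pos) + quad(neg), 0, tolerance = 1e-6 * quad(pos))

  expect_error(composite_spectrum(spectra, c(S1_npi = 0.2), f = 0.1),
               class = "trxps_domain_error")
  bad <- spectra
  bad$S1_npi <- broaden(o[o$state == "S1_npi", ], shape, grid + 1)
  expect_error(composite_spectrum(bad, c(S1_npi = 0.05), f = 0.09),
               class = "trxps_alignment_error")
})

test_that("hot-ground-state line has the stated width and skew behaviour", {
  grid <- seq(530, 546, by = 0.005)
  sym <- hgs_spectrum(grid, center = 537.6, width_sigma = fwhm_to_sigma(1.6),
                      asymmetry = 0)
  ymax <- max(sym$intensity)
  half <- range(grid[sym$intensity >= ymax / 2])
  expect_equal(diff(half), 1.6, tolerance = 0.01)
  expect_equal(grid[which.max(sym$intensity)], 537.6, tolerance = 0.006)

  skew <- hgs_spectrum(grid, center = 537.6,
                       width_sigma = fwhm_to_sigma(1.6), asymmetry = 2)
  dx <- 0.005
  area <- sum(skew$intensity) * dx
  expect_equal(area, 1, tolerance = 1e-3)
  mean_e <- sum(grid * skew$intensity) * dx / area
  mode_e <- grid[which.max(skew$intensity)]
  expect_gt(mean_e, mode_e)

  expect_error(hgs_spectrum(grid, 537.6, width_sigma = -1),
               class = "trxps_domain_error")
  expect_error(hgs_spectrum(grid, 537.6, asymmetry = -1),
               class = "trxps_domain_error")
})
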