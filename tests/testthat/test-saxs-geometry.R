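# Minimal-surface geometry: channel size, lipid length, interfacial
# water fraction.

test_that("channel radius follows the minimal-surface closed form", {
  # diamond phase, a = 10 nm, l = 1.7 nm
  cd <- channel_diameter(10, 1.7, "Pn3m")
  expect_equal(cd$channel_radius, sqrt(1.919 / (4 * pi)) * 10 - 1.7,
               tolerance = 1e-12)
  expect_equal(cd$channel_radius, 2.2078, tolerance = 1e-4)
  expect_equal(cd$channel_diameter, 2 * cd$channel_radius)

  # primitive phase
  cd <- channel_diameter(10, 1.7, "Im3m")
  expect_equal(cd$channel_radius, sqrt(2.345 / (8 * pi)) * 10 - 1.7,
               tolerance = 1e-12)
  expect_equal(cd$channel_radius, 1.3548, tolerance = 1e-3)

  # closed-channel limit
  l_max <- sqrt(1.919 / (4 * pi)) * 10
  cd <- channel_diameter(10, l_max, "Pn3m")
  expect_equal(cd$channel_radius, 0, tolerance = 1e-12)
  expect_error(channel_diameter(10, l_max + 0.01, "Pn3m"), "exceeds")
})

test_that("channel radius is affine in a and in l with the expected slopes", {
  set.seed(9)
  for (g in c("Ia3d", "Pn3m", "Im3m")) {
    sg <- space_group(g)
    coef_a <- sqrt(sg$A0 / (-2 * pi * sg$chi))
    a <- runif(5, 9, 20); l <- runif(5, 0.5, 1.6)
    for (k in 1:5) {
      r0 <- channel_diameter(a[k], l[k], sg)$channel_radius
      r_da <- channel_diameter(a[k] + 1, l[k], sg)$channel_radius
      r_dl <- channel_diameter(a[k], l[k] + 0.1, sg)$channel_radius
      expect_equal(r_da - r0, coef_a, tolerance = 1e-10)
      expect_equal(r_dl - r0, -0.1, tolerance = 1e-10)
    }
  }
})

test_that("lipid length inverts the volume-fraction cubic on the physical branch", {
  # Pn3m, phi_L = 0.5, a = 10 nm: root of 3.838 x - 8.3776 x^3 = 0.5
  l <- lipid_length(0.5, 10, "Pn3m")
  expect_equal(l, 1.357, tolerance = 1e-3)
  x <- l / 10
  expect_lt(abs(2 * 1.919 * x + (4 * pi * -2 / 3) * x^3 - 0.5), 1e-12)

  # round trip over the physical branch, all groups
  set.seed(11)
  for (g in c("Ia3d", "Pn3m", "Im3m")) {
    sg <- space_group(g)
    x_turn <- sqrt(sg$A0 / (-2 * pi * sg$chi))
    for (x_true in runif(20, 0.01, 0.9) * x_turn) {
      phi <- 2 * sg$A0 * x_true + (4 * pi * sg$chi / 3) * x_true^3
      x_rec <- lipid_length(phi, 1, sg)
      expect_lt(abs(x_rec - x_true), 1e-10)
    }
  }

  # the primitive surface cannot accommodate phi_L above ~0.955
  expect_error(lipid_length(0.97, 10, "Im3m"), "exceeds")
  expect_error(lipid_length(0, 10, "Pn3m"))
})

test_that("interfacial water fraction matches the analytic calibration", {
  # zero numerator: K0 = -2.092/0.543
  iw <- interfacial_water_fraction(0.5, 10, "Pn3m", K0 = -2.092 / 0.543)
  expect_equal(iw$f_w_int, 0, tolerance = 1e-12)

  # direct evaluation under the K0 = 2 pi chi / A0 convention
  iw <- interfacial_water_fraction(0.5, 10, "Pn3m", k0_convention = TRUE)
  expect_equal(iw$K0, 2 * pi * -2 / 1.919, tolerance = 1e-12)
  expect_equal(iw$Gamma, 0.5 * 1000 / (8 * pi), tolerance = 1e-10)
  expect_equal(iw$f_w_int, 0.0736, tolerance = 1e-3)
  expect_false(iw$clamped)

  # clamping: tiny Gamma drives the raw value above 1
  iw <- interfacial_water_fraction(0.01, 1, "Pn3m", K0 = -40)
  expect_equal(iw$f_w_int, 1)
  expect_true(iw$clamped)
})

test_that("unclamped interfacial fraction decreases with a and with f_w", {
  set.seed(13)
  for (k in 1:20) {
    g <- sample(c("Ia3d", "Pn3m", "Im3m"), 1)
    a <- runif(1, 8, 18); fw <- runif(1, 0.3, 0.9)
    base <- interfacial_water_fraction(fw, a, g, k0_convention = TRUE)
    up_a <- interfacial_water_fraction(fw, a * 1.1, g, k0_convention = TRUE)
    up_f <- interfacial_water_fraction(min(fw * 1.1, 1), a, g,
                                       k0_convention = TRUE)
    if (!base$clamped && !up_a$clamped) expect_lt(up_a$f_w_int, base$f_w_int)
    if (!base$clamped && !up_f$clamped) expect_lt(up_f$f_w_int, base$f_w_int)
  }
})

test_that("geometry series composes per temperature and marks coexistence", {
  pk <- 2 * pi * sqrt(c(2, 3, 4, 6)) / 100
  fit_pn <- index_phase(pk)
  fit_ia <- index_phase(2 * pi * sqrt(c(6, 8, 14)) / 120,
                        candidates = list("Ia3d"))
  tab <- geometry_series(list(fit_pn, list(fit_pn, fit_ia)), c(298, 310),
                         phi_L = 0.5, k0_convention = TRUE)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$l_nm[1L], 1.357, tolerance = 1e-3)
  expect_equal(tab$d_nm[1L],
               channel_diameter(10, tab$l_nm[1L], "Pn3m")$channel_diameter,
               tolerance = 1e-9)
  expect_true(is.na(tab$d_nm[2L]))
  expect_match(tab$flag[2L], "coexistence")
  expect_equal(nrow(geometry_series(list(), numeric(0), 0.5,
                                    k0_convention = TRUE)), 0L)
})
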