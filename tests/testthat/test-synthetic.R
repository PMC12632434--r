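# Generator contracts: determinism, invariant-passing outputs, and
# ground-truth sufficiency.

test_that("generators are deterministic under a fixed seed", {
  s1 <- gen_saxs("Ia3d", 14, seed = 12)
  s2 <- gen_saxs("Ia3d", 14, seed = 12)
  expect_identical(s1, s2)
  t1 <- gen_thz_series(T_grid = c(298, 310), seed = 12)
  t2 <- gen_thz_series(T_grid = c(298, 310), seed = 12)
  expect_identical(t1, t2)
  g1 <- gen_slab_frames(T_grid = 308, frames_per_T = 2, seed = 12)
  g2 <- gen_slab_frames(T_grid = 308, frames_per_T = 2, seed = 12)
  expect_identical(g1, g2)
  # and distinct seeds differ
  expect_false(identical(s1$profile$intensity,
                         gen_saxs("Ia3d", 14, seed = 13)$profile$intensity))
})

test_that("noiseless SAXS output closes the loop through detection and indexing", {
  sim <- gen_saxs("Pn3m", 11, n_peaks = 4L, noise_sd = 0, seed = 1)
  expect_s3_class(sim$profile, "saxs_profile")
  fit <- index_phase(detect_peaks(sim$profile))
  expect_identical(fit$space_group$name, "Pn3m")
  expect_lt(abs(fit$a_nm - 11) / 11, 1e-3)  # grid-step limited
  # peaks outside the acquisition window are refused
  expect_error(gen_saxs("Pn3m", 40, n_peaks = 4L), "outside")
})

test_that("near-degenerate first peaks are separated with three or more reflections", {
  # gyroid at a chosen so its first peak overlays the diamond first peak
  a_pn <- 10
  a_ia <- a_pn * sqrt(6) / sqrt(2)
  pk_ia <- 2 * pi * sqrt(c(6, 8, 14)) / (10 * a_ia)
  pk_pn <- 2 * pi * sqrt(c(2, 3, 4)) / (10 * a_pn)
  expect_equal(pk_ia[1L], pk_pn[1L], tolerance = 1e-12)
  fit_ia <- index_phase(pk_ia)
  fit_pn <- index_phase(pk_pn)
  expect_identical(fit_ia$space_group$name, "Ia3d")
  expect_identical(fit_pn$space_group$name, "Pn3m")
  expect_false(fit_ia$ambiguous)
  expect_false(fit_pn$ambiguous)
})

test_that("raw THz output inverts exactly through the conversion chain", {
  sim <- gen_thz_series(T_grid = 298, noise_sd = 0, seed = 3, raw = TRUE,
                        phi_m = 0.5, n_s = 1.41)
  expect_s3_class(sim$spectra[[1L]], "atr_spectrum")
  ws <- subtract_lipid(absorption_from_atr(sim$spectra[[1L]]),
                       sim$lipid_ref, 0.5)
  ref <- gen_thz_series(T_grid = 298, noise_sd = 0, seed = 3)$spectra[[1L]]
  expect_lt(max(abs(ws$delta_alpha - ref$delta_alpha)), 1e-10)
})

test_that("THz ground truth suffices to reconstruct the noiseless series", {
  sim <- gen_thz_series(T_grid = c(298, 313), noise_sd = 0, seed = 9)
  gt <- sim$ground_truth
  for (k in 1:2) {
    m <- thz_model(
      stretching = list(a = gt$mode_truth$stretching$a,
                        nu0 = gt$mode_truth$stretching$nu0,
                        omega = gt$widths_cm1[k, "stretching"]),
      libration = list(a = gt$mode_truth$libration$a,
                       nu0 = gt$mode_truth$libration$nu0,
                       omega = gt$widths_cm1[k, "libration"]),
      a_LF = gt$a_LF, a_HF = gt$a_HF, lf = gt$lf, hf = gt$hf)
    expect_equal(eval_thz_model(m, sim$spectra[[k]]$nu),
                 sim$spectra[[k]]$delta_alpha, tolerance = 1e-12)
  }
  # implied lifetimes out of physical range are refused
  bad <- list(
    stretching = list(a = 3000, nu0 = 147, E_a_kJmol = 25,
                      tau_pref_fs = 42.7),
    libration = list(a = 5000, nu0 = 412, E_a_kJmol = 7.4,
                     tau_pref_fs = 6.0))
  expect_error(gen_thz_series(T_grid = 298, mode_truth = bad, seed = 1),
               "leaves")
})

test_that("slab generator output passes the consuming module invariants", {
  sim <- gen_slab_frames(T_grid = 308, frames_per_T = 3, seed = 14)
  for (f in c(sim$slab[[1L]], sim$bulk[[1L]])) {
    expect_s3_class(f, "md_frame")
    # md_frame construction already enforces water topology; check box
    expect_true(all(f$box > 2 * 0.35))
    expect_true(all(f$positions >= 0 &
                      f$positions <= matrix(f$box, nrow(f$positions), 3,
                                            byrow = TRUE)))
  }
  expect_true(all(vapply(sim$bulk[[1L]], function(f)
    all(f$role %in% c("water_O", "water_H")), logical(1))))
})

test_that("a zero-depth deficit produces a statistically flat profile", {
  sim <- gen_slab_frames(T_grid = 308, frames_per_T = 8,
                         deficit_depth = 0, seed = 22)
  bk <- bulk_value(sim$bulk[[1L]])
  p <- hb_profile(sim$slab[[1L]], n_HB_bulk = bk)
  r <- bulk_recovery_distance(p)
  expect_false(r$unreached)
  expect_equal(r$x_c, min(p$bins$bin_center[!p$bins$empty]))
})

test_that("slab profiles match ground-truth expectations within sampling error", {
  sim <- gen_slab_frames(T_grid = c(308, 338), frames_per_T = 8, seed = 33)
  for (k in 1:2) {
    TK <- sim$ground_truth$T_grid[k]
    p <- hb_profile(sim$slab[[k]])
    occ <- p$bins[!p$bins$empty & p$bins$count >= 20, ]
    exp_prof <- expected_hb_profile(sim$ground_truth, occ$bin_center, TK)
    # binomial-scale 3-sigma bars on the per-bin means
    sigma <- sqrt(pmax(exp_prof$n_HB * (1 - exp_prof$n_HB / 2), 0.05) /
                    occ$count)
    expect_true(all(abs(occ$n_total - exp_prof$n_HB) < 3.5 * sigma))
    # frame-wide mean tracks the imposed bulk law scaled by the deficit
    expect_lt(abs(bulk_value(sim$bulk[[k]]) - exp_prof$n_HB_bulk) /
                exp_prof$n_HB_bulk, 0.03)
  }
})

test_that("ground truth serializes to JSON alongside the dataset", {
  sim <- gen_saxs("Im3m", 13, seed = 2)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ground_truth(sim$ground_truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$a_nm, 13)
  expect_identical(back$space_group, "Im3m")
})
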