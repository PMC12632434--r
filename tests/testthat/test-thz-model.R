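# Damped-harmonic-oscillator decomposition and lifetimes.

test_that("DHO line shape has the closed-form landmarks", {
  nu <- seq(10, 550, by = 2)
  expect_true(all(eval_dho(nu, 0, 147, 190) == 0))

  # at the center the line equals a/(4 pi), independent of width
  for (w in c(50, 190, 800))
    expect_equal(eval_dho(147, 3.2, 147, w), 3.2 / (4 * pi),
                 tolerance = 1e-12)

  # quadratic vanishing at nu -> 0
  lo <- eval_dho(c(1e-3, 2e-3), 100, 147, 190)
  expect_equal(lo[2] / lo[1], 4, tolerance = 1e-4)

  expect_error(eval_dho(100, 1, 147, 0), "positive")
})

test_that("background terms vanish with their amplitudes and stay smooth", {
  nu <- seq(50, 550, by = 2)
  lf <- list(a0 = 120, nu0 = 150, omega0 = 40)
  hf <- list(t2 = list(a = 5000, nu_b = 600, omega = 300),
             t3 = list(a = 4000, nu_b = 800, omega = 400))
  expect_true(all(eval_background(nu, lf, hf, 0, 0) == 0))
  hf0 <- lapply(hf, function(t) { t$a <- 0; t })
  expect_equal(eval_background(nu, lf, hf0, 1, 1),
               120 * exp(-nu / 150) * nu^2 / (nu^2 + 40^2),
               tolerance = 1e-12)
  # low-frequency line plateaus near a0 for omega0 << nu << nu0
  lf_wide <- list(a0 = 10, nu0 = 5000, omega0 = 2)
  val <- eval_background(60, lf_wide, hf0, 1, 0)
  expect_equal(val, 10, tolerance = 0.02)
})

test_that("the full model is non-negative for non-negative amplitudes", {
  set.seed(3)
  nu <- seq(50, 550, by = 2)
  for (k in 1:20) {
    m <- thz_model(
      stretching = list(a = runif(1, 0, 5000), nu0 = runif(1, 100, 200),
                        omega = runif(1, 50, 500)),
      libration = list(a = runif(1, 0, 8000), nu0 = runif(1, 350, 480),
                       omega = runif(1, 50, 600)),
      a_LF = runif(1, 0, 3), a_HF = runif(1, 0, 3))
    expect_true(all(eval_thz_model(m, nu) >= 0))
  }
})

test_that("the model constructor enforces mode ordering and positivity", {
  expect_error(thz_model(stretching = list(a = 1, nu0 = 420, omega = 100),
                         libration = list(a = 1, nu0 = 410, omega = 100)),
               "below")
  expect_error(thz_model(stretching = list(a = 1, nu0 = 147, omega = -5),
                         libration = list(a = 1, nu0 = 412, omega = 100)),
               "positive")
})

test_that("a noiseless spectrum is a fixed point of the least-squares fit", {
  truth <- thz_model(
    stretching = list(a = 3000, nu0 = 147, omega = 190),
    libration = list(a = 5000, nu0 = 412, omega = 280),
    a_LF = 1.2, a_HF = 0.8)
  ws <- make_water_spectrum(truth)
  init <- thz_model(
    stretching = list(a = 3300, nu0 = 152, omega = 170),
    libration = list(a = 4600, nu0 = 405, omega = 300))
  fit <- fit_thz_model(ws, init)
  expect_true(fit$converged)
  p <- coef(fit); p0 <- mesowater:::.model_to_par(truth)
  expect_lt(max(abs(p - p0) / abs(p0)), 1e-6)
})

test_that("fit contracts: coverage precondition and ordering are enforced", {
  truth <- thz_model(stretching = list(a = 3000, nu0 = 147, omega = 190),
                     libration = list(a = 5000, nu0 = 412, omega = 280))
  short <- make_water_spectrum(truth)
  short$nu <- short$nu[short$nu <= 400]
  short$delta_alpha <- short$delta_alpha[seq_along(short$nu)]
  expect_error(fit_thz_model(short, truth), "cover")
})

test_that("DHO parameters are recovered from noisy spectra (random draws)", {
  set.seed(91)
  n_draws <- 8L
  ok <- logical(n_draws)
  for (k in seq_len(n_draws)) {
    truth <- thz_model(
      stretching = list(a = runif(1, 2000, 4000), nu0 = runif(1, 135, 160),
                        omega = runif(1, 160, 220)),
      libration = list(a = runif(1, 4000, 6500), nu0 = runif(1, 395, 430),
                       omega = runif(1, 240, 320)))
    ws <- make_water_spectrum(truth, noise_sd = 0.01)
    init <- thz_model(
      stretching = lapply(truth$modes$stretching, function(v) v * 1.1),
      libration = lapply(truth$modes$libration, function(v) v * 0.9))
    fit <- fit_thz_model(ws, init)
    m <- fit$model$modes; t <- truth$modes
    ok[k] <- fit$converged &&
      abs(m$stretching$nu0 - t$stretching$nu0) < 1 &&
      abs(m$libration$nu0 - t$libration$nu0) < 1 &&
      abs(m$stretching$omega / t$stretching$omega - 1) < 0.02 &&
      abs(m$libration$omega / t$libration$omega - 1) < 0.02
  }
  expect_gte(mean(ok), 7 / 8)
})

test_that("lifetimes obey the reciprocal width law with unit identity", {
  m <- thz_model(stretching = list(a = 3000, nu0 = 147, omega = 180),
                 libration = list(a = 5000, nu0 = 412, omega = 360))
  lt <- lifetimes(m)
  expect_equal(lt$tau_fs[lt$mode == "stretching"], 185.3, tolerance = 1e-3)
  # doubling the width halves the lifetime exactly
  expect_equal(lt$tau_fs[lt$mode == "libration"] * 2,
               lt$tau_fs[lt$mode == "stretching"], tolerance = 1e-12)
  # unit identity tau * omega * c = 1 for every reported lifetime
  c_cm <- 2.99792458e10
  expect_equal(lt$tau_fs * 1e-15 * lt$omega_cm1 * c_cm, c(1, 1),
               tolerance = 1e-12)

  # slow modes outside the plausibility band are flagged, not rejected
  m2 <- thz_model(stretching = list(a = 1, nu0 = 53, omega = 53),
                  libration = list(a = 1, nu0 = 412, omega = 280))
  lt2 <- lifetimes(m2)
  expect_equal(lt2$tau_fs[1L], 629, tolerance = 1e-2)
  expect_match(lt2$flag[1L], "band")
})
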