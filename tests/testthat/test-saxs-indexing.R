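# Peak detection and cubic space-group indexing.

test_that("flat profiles yield no peaks and real peaks are located to a grid step", {
  q <- seq(0.05, 0.45, by = 5e-4)
  expect_length(detect_peaks(saxs_profile(q, rep(3, length(q)))), 0L)

  # single Gaussian on a flat background
  y <- 1 + 10 * exp(-(q - 0.0889)^2 / (2 * 0.002^2))
  pk <- detect_peaks(saxs_profile(q, y))
  expect_length(pk, 1L)
  expect_lt(abs(pk - 0.0889), 5e-4 + 1e-12)

  # synthetic 4-peak profile at moderate noise: all four found near truth
  sim <- gen_saxs("Pn3m", 12, n_peaks = 4L, noise_sd = 0.02, seed = 5)
  pk <- detect_peaks(sim$profile)
  truth <- sim$ground_truth$q_peaks
  expect_length(pk, 4L)
  expect_true(all(abs(pk - truth) <= 2 * 5e-4))
})

test_that("profile constructor rejects invalid grids", {
  expect_error(saxs_profile(c(0.1, 0.1, 0.2), c(1, 1, 1)), "increasing")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, -1)), "non-negative")
})

test_that("exact sqrt(2):sqrt(3) peaks index as the diamond phase with zero residual", {
  a_A <- 100  # 10 nm
  pk <- 2 * pi * sqrt(c(2, 3)) / a_A
  fit <- index_phase(pk)
  expect_s3_class(fit, "phase_fit")
  expect_identical(fit$space_group$name, "Pn3m")
  expect_equal(fit$a_nm, 10, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-12)
  expect_equal(unname(coef(fit)), 10, tolerance = 1e-12)
})

test_that("noiseless peaks from any group recover the lattice parameter to 1e-10", {
  set.seed(41)
  for (g in c("Ia3d", "Pn3m", "Im3m")) {
    for (a_nm in c(8.3, 12, 17.9)) {
      sg <- space_group(g)
      pk <- 2 * pi * sqrt(sg$reflections[1:4]) / (10 * a_nm)
      fit <- index_phase(pk)
      expect_identical(fit$space_group$name, g)
      expect_lt(abs(fit$a_nm - a_nm) / a_nm, 1e-10)
      expect_lt(fit$residual, 1e-10)
    }
  }
})

test_that("gyroid peaks with 0.3% noise select Ia3d and recover a within 0.5%", {
  set.seed(17)
  a_nm <- 12
  pk <- 2 * pi * sqrt(c(6, 8, 14, 16)) / (10 * a_nm) *
    (1 + rnorm(4, sd = 0.003))
  fit <- index_phase(pk)
  expect_identical(fit$space_group$name, "Ia3d")
  expect_lt(abs(fit$a_nm - a_nm) / a_nm, 0.005)
})

test_that("degenerate doublets are flagged as ambiguous near-ties", {
  # a 2-peak spacing ratio midway between the gyroid (sqrt(8/6)) and
  # diamond (sqrt(3/2)) signatures: neither fits, residuals near-tie
  pk <- c(0.10, 0.10 * 1.19)
  fit <- index_phase(pk)
  expect_true(fit$ambiguous)
  expect_gt(sum(fit$residual_table$near_tie), 1L)
  # whereas clean 2-peak signatures are unambiguous
  expect_false(index_phase(c(0.10, 0.10 * sqrt(3 / 2)))$ambiguous)
})

test_that("indexing refuses fewer than 2 peaks and empty candidate lists", {
  expect_error(index_phase(0.1), "at least 2")
  expect_error(index_phase(c(0.1, 0.12), candidates = list()), "candidate")
})

test_that("space-group selection is >= 95% correct over noisy synthetic profiles", {
  set.seed(2024)
  n_trials <- 200L
  groups <- c("Ia3d", "Pn3m", "Im3m")
  correct <- logical(n_trials); flagged <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    g <- sample(groups, 1)
    a_nm <- runif(1, 8, 20)
    sg <- space_group(g)
    npk <- sample(3:5, 1)
    pk <- 2 * pi * sqrt(sg$reflections[seq_len(npk)]) / (10 * a_nm) *
      (1 + rnorm(npk, sd = 0.005))
    fit <- index_phase(pk)
    correct[i] <- fit$space_group$name == g
    flagged[i] <- fit$ambiguous
  }
  expect_gte(mean(correct), 0.95)
  # misclassifications must coincide with flagged residual near-ties
  expect_true(all(flagged[!correct]))
})
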