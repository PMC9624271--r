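test_that("degenerate mixtures produce degenerate deviations", {
  d <- sample_vmmm_deviations(vmmm_params(1, 0, 0, mu = 0, kappa1 = 1e6),
                              n = 100, seed = 1)
  expect_true(all(abs(d$deviation_deg) < 0.5))
  expect_true(all(d$component == "detection"))

  expect_equal(nrow(sample_vmmm_deviations(vmmm_params(r3 = 1), 0)), 0)
})

test_that("pure guessing deviations are uniform on the circle", {
  d <- sample_vmmm_deviations(vmmm_params(0, 0, 1), n = 1e4, seed = 2)
  expect_true(all(d$component == "guess"))
  expect_gt(rayleigh_p(d$deviation_deg), 0.01)
  expect_true(all(d$deviation_deg > -180 & d$deviation_deg <= 180))
})

test_that("component frequencies converge to the mixture coefficients", {
  pars <- vmmm_params(0.6, 0.1, 0.3, mu = 5, kappa1 = 8, kappa2 = 4)
  d <- sample_vmmm_deviations(pars, n = 2e4, seed = 3)
  freq <- table(d$component) / nrow(d)
  expect_lt(abs(freq[["detection"]] - 0.6), 0.02)
  expect_lt(abs(freq[["rood"]] - 0.1), 0.02)
  expect_lt(abs(freq[["guess"]] - 0.3), 0.02)
  # ROOD deviations cluster near 180 + mu
  rood <- d$deviation_deg[d$component == "rood"]
  expect_lt(abs(wrap_signed(circular_mean(rood) - 185)), 5)
})

test_that("von Mises draws have the right concentration", {
  x <- rvonmises(2e4, mu_deg = 20, kappa = 8)
  expect_lt(abs(circular_mean(x) - 20), 1)
  # A1(kappa) = I1/I0: expected resultant length
  a1 <- besselI(8, 1) / besselI(8, 0)
  expect_equal(circular_resultant(x), a1, tolerance = 0.01)
})

test_that("presets respect the documented structure", {
  for (mode in c("trackball", "rotating_bar")) {
    for (rdk in c("tm", "bm", "wm")) {
      pr <- preset_profile(mode, rdk)
      expect_equal(pr$r1 + pr$r2 + pr$r3, rep(1, 5), tolerance = 1e-12)
      expect_true(all(pr$kappa1 >= 0 & pr$kappa2 >= 0))
      # guessing dominates without motion signal
      expect_gte(pr$r3[pr$coherence == 0], 0.95)
      # detections increase with coherence
      expect_true(all(diff(pr$r1) > 0))
      if (mode == "trackball") {
        expect_equal(unique(pr$mu), 6.58)
        expect_true(all(pr$kappa1 >= 2 & pr$kappa1 <= 10))
      } else {
        expect_equal(unique(pr$mu), 0)
        expect_true(all(pr$kappa1 >= 5 & pr$kappa1 <= 30))
      }
    }
  }
  # transparent motion induces the most opposite-direction reports
  for (mode in c("trackball", "rotating_bar")) {
    tm <- preset_profile(mode, "tm")$r2[-1]
    bm <- preset_profile(mode, "bm")$r2[-1]
    wm <- preset_profile(mode, "wm")$r2[-1]
    expect_true(all(tm > bm))
    expect_true(all(tm > wm))
  }
  expect_error(preset_profile("joystick", "tm"))
})

test_that("simulated responses compose design and deviations consistently", {
  design <- generate_design(design_config(n_runs = 2, trials_per_run = 40,
                                          seed = 2))
  profile <- preset_profile("rotating_bar", "bm")
  resp <- simulate_responses(design, profile, seed = 10)
  expect_equal(nrow(resp), 80)
  expect_equal(resp$deviation_deg,
               wrap_deviation(resp$direction_deg, resp$reported_deg),
               tolerance = 1e-9)
  # determinism
  resp2 <- simulate_responses(design, profile, seed = 10)
  expect_identical(resp, resp2)

  # degenerate detection: reports reproduce the presented directions
  perfect <- profile
  perfect$r1 <- 1; perfect$r2 <- 0; perfect$r3 <- 0
  perfect$mu <- 0; perfect$kappa1 <- 1e8
  r3 <- simulate_responses(design, perfect, seed = 1)
  expect_lt(max(abs(r3$deviation_deg)), 0.05)

  # full cardinal attraction with huge concentration pins reports to axes
  pinned <- profile
  pinned$r1 <- 1; pinned$r2 <- 0; pinned$r3 <- 0
  pinned$cardinal_attraction <- 1; pinned$cardinal_kappa <- 1e9
  r4 <- simulate_responses(design, pinned, seed = 1)
  expect_true(all(wrap_angle(round(r4$reported_deg)) %% 90 == 0))

  # missing coherence parameters are an explicit error
  expect_error(simulate_responses(design, profile[profile$coherence > 0.2, ]),
               "lacks parameters")
})

test_that("trackball presets bias reports while rotating-bar presets do not", {
  # mirrors the pooled-cohort report-vs-stimulus comparison: 12 simulated
  # subjects' 0%-coherence trials per seed
  rejections <- function(mode, seeds) {
    vapply(seeds, function(s) {
      pool <- cohort_zero_coherence(mode, n_subjects = 12, seed = s)
      cvm_test(pool$direction_deg, pool$reported_deg,
               n_permutations = 299, seed = s)$p_value < 0.05
    }, logical(1))
  }
  expect_gte(sum(rejections("trackball", 1:3)), 2)
  expect_lte(sum(rejections("rotating_bar", 1:3)), 1)
})

test_that("response tables round-trip and hide ground truth by default", {
  design <- generate_design(design_config(n_runs = 1, trials_per_run = 40,
                                          seed = 4))
  resp <- simulate_responses(design, preset_profile("rotating_bar", "wm"),
                             seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, path)
  back <- read_responses(path)
  expect_false("component" %in% names(back))
  expect_equal(back$reported_deg, resp$reported_deg)
  write_responses(resp, path, include_component = TRUE)
  expect_true("component" %in% names(read_responses(path)))
})
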