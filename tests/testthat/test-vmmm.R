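test_that("the von Mises density per degree matches closed forms", {
  expect_equal(von_mises_pdf(37, 0, 0), 1 / 360)
  # at the mode with kappa = 2: e^2 / (360 I0(2)), I0 from an independent
  # power-series oracle
  expect_equal(von_mises_pdf(0, 0, 2), exp(2) / (360 * oracle_bessel_i0(2)),
               tolerance = 1e-12)
  expect_equal(von_mises_pdf(0, 0, 2), 0.00900389900273932, tolerance = 1e-12)
  # symmetry about the mode
  x <- seq(0, 180, by = 7)
  expect_equal(von_mises_pdf(30 + x, 30, 5), von_mises_pdf(30 - x, 30, 5))
  # integrates to 1, also at extreme concentration
  for (kap in c(0, 2, 50, 500)) {
    int <- stats::integrate(von_mises_pdf, -180, 180, mu_deg = 10, kappa = kap,
                            rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
  expect_error(von_mises_pdf(0, 0, -1), "non-negative")
})

test_that("the mixture density sums its components and integrates to 1", {
  expect_equal(mixture_pdf(123, vmmm_params(0, 0, 1), "m00"), 1 / 360)
  pars <- vmmm_params(0.5, 0.2, 0.3, mu = 0, kappa1 = 4, kappa2 = 2)
  # frozen from the Bessel-series oracle: r1 e^4/(360 I0(4)) +
  # r2 e^-2/(360 I0(2)) + r3/360
  expect_equal(mixture_pdf(0, pars, "m11"), 0.00757586165161933,
               tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    w <- as.numeric(stats::rmultinom(1, 100, c(1, 1, 1))) / 100
    pars <- vmmm_params(w[1], w[2], w[3], mu = runif(1, -20, 20),
                        kappa1 = runif(1, 0.5, 30), kappa2 = runif(1, 0.5, 30))
    int <- stats::integrate(mixture_pdf, -180, 180, params = pars,
                            model = "m11", rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
})

test_that("pinned coefficients are enforced by name", {
  expect_error(mixture_pdf(0, vmmm_params(0.5, 0, 0.5, 0, 4, 0), "m01"),
               "pins r1")
  expect_error(mixture_pdf(0, vmmm_params(0, 0.5, 0.5, 0, 0, 4), "m10"),
               "pins r2")
})

test_that("the log-likelihood matches closed forms and naive summation", {
  dev <- rep(0, 400)
  expect_equal(vmmm_loglik(dev, vmmm_params(0, 0, 1), "m00"),
               -400 * log(360))
  expect_equal(-400 * log(360), -2354.44161258006, tolerance = 1e-10)

  # additivity: duplicating one observation adds exactly its log density
  pars <- vmmm_params(0.4, 0.1, 0.5, mu = 3, kappa1 = 6, kappa2 = 2)
  base <- c(-20, 5, 170)
  expect_equal(vmmm_loglik(c(base, 5), pars, "m11"),
               vmmm_loglik(base, pars, "m11") + log(mixture_pdf(5, pars, "m11")))

  set.seed(9)
  for (i in 1:100) {
    dev <- runif(sample(5:50, 1), -180, 180)
    pars <- vmmm_params(0.5, 0.1, 0.4, mu = runif(1, -10, 10),
                        kappa1 = runif(1, 1, 20), kappa2 = runif(1, 1, 20))
    naive <- 0
    for (d in dev) naive <- naive + log(mixture_pdf(d, pars, "m11"))
    expect_equal(vmmm_loglik(dev, pars, "m11"), naive, tolerance = 1e-10)
  }
  expect_error(vmmm_loglik(numeric(0), pars, "m11"), "empty")
})

test_that("model specs carry the free-parameter counts", {
  expect_equal(model_spec("m00")$k, 0L)
  expect_equal(model_spec("m01")$k, 3L)
  expect_equal(model_spec("m10")$k, 3L)
  expect_equal(model_spec("m11")$k, 5L)
})

test_that("the guessing-only fit is exact and small samples are refused", {
  dev <- runif(50, -180, 180)
  fit <- fit_vmmm(dev, "m00")
  expect_equal(fit$log_likelihood, -50 * log(360))
  expect_equal(fit$k, 0L)
  expect_error(fit_vmmm(dev[1:5], "m11"), "at least 10")
})

test_that("fits accept data frames with tidy column selection", {
  df <- sample_vmmm_deviations(vmmm_params(0.7, 0, 0.3, 2, 10, 0),
                               n = 200, seed = 6)
  fit <- fit_vmmm(df, "m10")
  expect_s3_class(fit, "vmmm_fit")
  expect_gt(fit$params$r1, 0.5)
  # same data as a bare vector gives the same fit
  fit2 <- fit_vmmm(df$deviation_deg, "m10")
  expect_equal(fit$log_likelihood, fit2$log_likelihood)
})

test_that("the full model nests the reduced models in likelihood", {
  for (s in 1:5) {
    dev <- sample_vmmm_deviations(
      vmmm_params(0.45, 0.15, 0.4, mu = 5, kappa1 = 7, kappa2 = 3),
      n = 200, seed = 40 + s)
    fits <- fit_vmmm_all(dev)
    ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
    expect_gte(ll[["m11"]] + 1e-6, ll[["m10"]])
    expect_gte(ll[["m11"]] + 1e-6, ll[["m01"]])
    expect_gte(ll[["m10"]] + 1e-6, ll[["m00"]])
    expect_gte(ll[["m01"]] + 1e-6, ll[["m00"]])
  }
})

test_that("rotating the data shifts the fitted bias equivariantly", {
  dev <- sample_vmmm_deviations(
    vmmm_params(0.6, 0.1, 0.3, mu = 0, kappa1 = 8, kappa2 = 4),
    n = 400, seed = 13)
  f0 <- fit_vmmm(dev, "m11")
  shift <- 5
  f1 <- fit_vmmm(wrap_signed(dev$deviation_deg + shift), "m11")
  expect_equal(f1$params$mu, f0$params$mu + shift, tolerance = 0.5)
  expect_equal(f1$params$r1, f0$params$r1, tolerance = 0.02)
  expect_equal(f1$params$kappa1, f0$params$kappa1, tolerance = 0.2)
  expect_equal(f1$log_likelihood, f0$log_likelihood, tolerance = 0.05)
})

test_that("uniform data drives the von Mises components toward nothing", {
  dev <- sample_vmmm_deviations(vmmm_params(r3 = 1), n = 400, seed = 17)
  f <- fit_vmmm(dev, "m10")
  m00 <- -400 * log(360)
  # the vM component can only soak up sampling noise: within a few units
  # of the uniform log-likelihood, with a small weight or concentration
  expect_lt(f$log_likelihood - m00, 5)
  expect_true(f$params$r1 < 0.2 || f$params$kappa1 < 0.5)
})

test_that("fit results serialize to JSON", {
  dev <- sample_vmmm_deviations(vmmm_params(0.7, 0, 0.3, 0, 10, 0), 100, seed = 2)
  fit <- fit_vmmm(dev, "m10")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  x <- jsonlite::read_json(path)
  expect_equal(x$model, "m10")
  expect_equal(x$n, 100L)
})

test_that("tidy and glance methods expose fits in broom style", {
  dev <- sample_vmmm_deviations(vmmm_params(0.7, 0, 0.3, 0, 10, 0), 150, seed = 3)
  fit <- fit_vmmm(dev, "m10")
  td <- tidy(fit)
  expect_equal(td$term, c("r1", "r2", "r3", "mu", "kappa1", "kappa2"))
  expect_true(td$fixed[td$term == "r2"])
  gl <- glance(fit)
  expect_equal(gl$aic, 2 * 3 - 2 * fit$log_likelihood)
})
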