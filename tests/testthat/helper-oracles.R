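# Independent reference implementations used to check the package's
# computational paths. These deliberately use different algorithms from the
# implementation (series expansions, double loops, exhaustive grids).

# modified Bessel function of order 0 by power series
oracle_bessel_i0 <- function(x) {
  s <- 0
  for (k in 0:80) s <- s + (x / 2)^(2 * k) / factorial(k)^2
  s
}

# two-sample Cramer-von Mises by explicit double-loop ECDF evaluation
oracle_cvm <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  s <- 0
  for (z in pooled) {
    fn <- sum(a <= z) / n
    fm <- sum(b <= z) / m
    s <- s + (fn - fm)^2
  }
  n * m / (n + m)^2 * s
}

# Anderson's rank form of the same statistic (untied samples only)
oracle_cvm_rank <- function(a, b) {
  n <- length(a)
  m <- length(b)
  N <- n + m
  rk <- rank(c(a, b))
  r <- sort(rk[seq_len(n)])
  s <- sort(rk[n + seq_len(m)])
  U <- n * sum((r - seq_len(n))^2) + m * sum((s - seq_len(m))^2)
  U / (n * m * N) - (4 * m * n - 1) / (6 * N)
}

# exhaustive fine-grid maximum likelihood for a one-component-plus-uniform
# mixture (detection or ROOD variant) over the same parameter space the
# fitter searches, vectorized over the weight grid
oracle_grid_loglik <- function(dev, rood = FALSE,
                               r_grid = seq(0, 1, by = 0.02),
                               mu_grid = seq(-10, 10, by = 0.5),
                               kappa_grid = exp(seq(log(3), log(32),
                                                    length.out = 40))) {
  best <- -Inf
  th <- dev * pi / 180
  for (mu in mu_grid) {
    center <- (mu + if (rood) 180 else 0) * pi / 180
    for (kap in kappa_grid) {
      d <- exp(kap * (cos(th - center) - 1)) /
        (360 * besselI(kap, 0, expon.scaled = TRUE))
      for (r in r_grid) {
        ll <- sum(log(r * d + (1 - r) / 360))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Rayleigh test p-value (large-sample approximation)
rayleigh_p <- function(angles_deg) {
  n <- length(angles_deg)
  rbar <- circular_resultant(angles_deg)
  z <- n * rbar^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# draw reports concentrated at the cardinal axes (trackball-like anisotropy)
sample_cardinal_reports <- function(n, attraction = 1, kappa = 100) {
  hit <- stats::runif(n) < attraction
  out <- stats::runif(n, 0, 360)
  k <- sum(hit)
  if (k) {
    axes <- sample(c(0, 90, 180, 270), k, replace = TRUE)
    out[hit] <- wrap_angle(axes + rvonmises(k, 0, kappa))
  }
  out
}

# pooled 0%-coherence reports of a simulated multi-subject cohort
cohort_zero_coherence <- function(mode, n_subjects = 12, seed = 1) {
  design <- generate_design(design_config(seed = seed))
  profile <- preset_profile(mode, "bm")
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    resp <- simulate_responses(design, profile, seed = seed * 1000 + i)
    resp[resp$coherence == 0, c("direction_deg", "reported_deg")]
  }))
}
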