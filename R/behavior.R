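#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler, parameterized in degrees. `kappa = 0`
#' returns circular-uniform draws. Reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction, degrees.
#' @param kappa Concentration, `>= 0`.
#' @return Angles in degrees, wrapped to `(-180, 180]`.
#' @export
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    return(wrap_signed(stats::runif(n, 0, 360)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5)[keep] * acos(pmin(pmax(f[keep], -1), 1))
    out <- c(out, th)
  }
  wrap_signed(mu_deg + rad2deg(out[seq_len(n)]))
}

#' Sample response deviations from the mixture model
#'
#' Draws wrapped response deviations from the three-component generating
#' process: with probability `r1` a detection deviation from
#' `vM(mu, kappa1)`, with probability `r2` a report-of-opposite-direction
#' deviation from `vM(180 + mu, kappa2)`, and with probability `r3` a
#' uniform guess. The ground-truth component of every draw is returned for
#' parameter-recovery accounting.
#'
#' @param params A [vmmm_params()].
#' @param n Number of deviations.
#' @param seed Optional integer seed.
#' @return A tibble with `deviation_deg` in `(-180, 180]` and `component`
#'   (`"detection"`, `"rood"`, `"guess"`).
#' @export
sample_vmmm_deviations <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "vmmm_params"), n >= 0)
  run <- function() {
    if (n == 0) {
      return(tibble::tibble(deviation_deg = numeric(0), component = character(0)))
    }
    comp <- sample(c("detection", "rood", "guess"), n, replace = TRUE,
                   prob = c(params$r1, params$r2, params$r3))
    dev <- numeric(n)
    i <- comp == "detection"
    dev[i] <- rvonmises(sum(i), params$mu, params$kappa1)
    i <- comp == "rood"
    dev[i] <- rvonmises(sum(i), params$mu + 180, params$kappa2)
    i <- comp == "guess"
    dev[i] <- wrap_signed(stats::runif(sum(i), 0, 360))
    tibble::tibble(deviation_deg = dev, component = comp)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# per-mode, per-stimulus generating parameter tables. Values are fixed
# presets chosen to match the qualitative pattern of continuous-report RDK
# data: guessing dominates without signal, detections grow with coherence,
# transparent motion yields the most opposite-direction reports, trackball
# reports carry a 6.58 deg rotational bias and lower precision plus an
# attraction toward the cardinal axes, rotating-bar reports are unbiased
# and more precise.
preset_table <- function(mode, rdk) {
  coh <- c(0, 0.125, 0.25, 0.5, 1)
  tab <- switch(paste(mode, rdk, sep = "."),
    trackball.tm = list(r1 = c(.02, .22, .40, .65, .78),
                        r2 = c(.02, .08, .10, .11, .10),
                        kappa1 = c(4, 4, 5, 5, 6), kappa2 = 2.5),
    trackball.bm = list(r1 = c(.02, .35, .55, .80, .88),
                        r2 = c(.01, .04, .05, .05, .04),
                        kappa1 = c(3, 3, 4, 4, 5), kappa2 = 2),
    trackball.wm = list(r1 = c(.02, .28, .48, .72, .86),
                        r2 = c(.01, .04, .06, .05, .03),
                        kappa1 = c(3, 4, 4, 5, 6), kappa2 = 2),
    rotating_bar.tm = list(r1 = c(.02, .20, .40, .65, .85),
                           r2 = c(.02, .09, .11, .12, .10),
                           kappa1 = c(12, 14, 15, 15, 16), kappa2 = 4),
    rotating_bar.bm = list(r1 = c(.02, .35, .60, .85, .93),
                           r2 = c(.01, .04, .05, .04, .03),
                           kappa1 = c(5, 8, 12, 20, 28), kappa2 = 3),
    rotating_bar.wm = list(r1 = c(.02, .30, .55, .80, .92),
                           r2 = c(.01, .04, .06, .04, .02),
                           kappa1 = c(5, 7, 10, 16, 24), kappa2 = 3))
  tibble::tibble(
    coherence = coh,
    r1 = tab$r1,
    r2 = tab$r2,
    r3 = 1 - tab$r1 - tab$r2,
    mu = if (mode == "trackball") 6.58 else 0,
    kappa1 = tab$kappa1,
    kappa2 = tab$kappa2,
    cardinal_attraction = if (mode == "trackball") 0.5 else 0,
    cardinal_kappa = if (mode == "trackball") 32 else 0,
    cardinal_vertical_share = if (mode == "trackball") 0.8 else 0.5
  )
}

#' Generating-parameter presets per response mode and stimulus
#'
#' Returns a per-coherence table of mixture parameters emulating the two
#' response methods (trackball: rotational bias of 6.58 degrees, lower
#' precision, attraction toward the cardinal axes; rotating bar: no bias,
#' higher precision) crossed with the three RDK variants (transparent motion
#' induces the most reports of the opposite direction). Guessing dominates
#' at 0% coherence and detections increase with coherence.
#'
#' The cardinal-attraction columns drive an explicitly synthetic anisotropy
#' model (see [simulate_responses()]): it exists to exercise the report-bias
#' test, not as a mechanistic claim.
#'
#' @param mode `"trackball"` or `"rotating_bar"`.
#' @param rdk `"tm"`, `"bm"` or `"wm"`.
#' @return A tibble with one row per coherence level and columns
#'   `coherence`, `r1`, `r2`, `r3`, `mu`, `kappa1`, `kappa2`,
#'   `cardinal_attraction`, `cardinal_kappa`, `cardinal_vertical_share`.
#' @export
preset_profile <- function(mode = c("trackball", "rotating_bar"),
                           rdk = c("tm", "bm", "wm")) {
  mode <- match.arg(mode)
  rdk <- match.arg(rdk)
  preset_table(mode, rdk)
}

#' Simulate continuous direction reports for a trial design
#'
#' Composes a trial design with the generating mixture: for every trial a
#' deviation is drawn from the coherence-specific mixture in `profile` and
#' added to the presented direction. With probability `cardinal_attraction`
#' a detection or guess report is replaced by a draw from a von Mises
#' centered on a cardinal axis near the report, emulating the anisotropy of
#' motor trackball reports: with probability `cardinal_vertical_share` the
#' target is the nearest vertical axis (0 or 180 degrees, the dominant
#' attractors of trackball responding), otherwise the nearest horizontal
#' axis (90 or 270 degrees). A missing `cardinal_vertical_share` column is
#' read as 0.5, which reduces to attraction toward the nearest of the four
#' axes.
#'
#' @param design Trial tibble from [generate_design()] (columns `run`,
#'   `trial`, `coherence`, `direction_deg`).
#' @param profile Per-coherence parameter tibble, e.g. [preset_profile()].
#' @param seed Optional integer seed.
#' @return The design with added columns `reported_deg` in `[0, 360)`,
#'   `deviation_deg` in `(-180, 180]` and ground-truth `component`.
#' @export
simulate_responses <- function(design, profile, seed = NULL) {
  stopifnot(nrow(design) > 0)
  missing_coh <- setdiff(unique(design$coherence), profile$coherence)
  if (length(missing_coh)) {
    stop("profile lacks parameters for coherence(s): ",
         paste(missing_coh, collapse = ", "), call. = FALSE)
  }
  run <- function() {
    out <- design
    out$deviation_deg <- NA_real_
    out$component <- NA_character_
    for (coh in sort(unique(design$coherence))) {
      idx <- which(design$coherence == coh)
      pr <- profile[profile$coherence == coh, ][1, ]
      pars <- vmmm_params(pr$r1, pr$r2, pr$r3, pr$mu, pr$kappa1, pr$kappa2)
      draw <- sample_vmmm_deviations(pars, length(idx))
      out$deviation_deg[idx] <- draw$deviation_deg
      out$component[idx] <- draw$component
      if (pr$cardinal_attraction > 0) {
        vshare <- if ("cardinal_vertical_share" %in% names(pr)) {
          pr$cardinal_vertical_share
        } else {
          0.5
        }
        rep0 <- wrap_angle(design$direction_deg[idx] + draw$deviation_deg)
        eligible <- draw$component != "rood"
        hit <- eligible & stats::runif(length(idx)) < pr$cardinal_attraction
        if (any(hit)) {
          base <- rep0[hit]
          vert <- stats::runif(sum(hit)) < vshare
          axis <- ifelse(vert,
                         ifelse(abs(wrap_signed(base)) < 90, 0, 180),
                         ifelse(wrap_signed(base) > 0, 90, 270))
          new_rep <- wrap_angle(
            axis + rvonmises(sum(hit), 0, pr$cardinal_kappa))
          out$deviation_deg[idx[hit]] <-
            wrap_deviation(design$direction_deg[idx[hit]], new_rep)
        }
      }
    }
    out$reported_deg <- wrap_angle(out$direction_deg + out$deviation_deg)
    dplyr::relocate(out, "reported_deg", .before = "deviation_deg")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Read and write response tables
#'
#' Responses travel as CSV with columns
#' `subject,run,trial,coherence,direction_deg,reported_deg,deviation_deg`;
#' the ground-truth `component` column is suppressed unless requested.
#'
#' @param responses Response tibble from [simulate_responses()].
#' @param path File path.
#' @param subject Subject id added when missing.
#' @param include_component Keep the ground-truth component column.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   a tibble.
#' @export
write_responses <- function(responses, path, subject = "s01",
                            include_component = FALSE) {
  if (!"subject" %in% names(responses)) {
    responses <- dplyr::mutate(responses, subject = subject, .before = 1)
  }
  if (!include_component) {
    responses <- dplyr::select(responses, -dplyr::any_of("component"))
  }
  readr::write_csv(responses, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
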