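#' Stimulus parameters for the random dot kinematograms
#'
#' Geometry and timing of the dot displays. Defaults reproduce the reference
#' stimulus: 275 dots in an annular aperture of inner diameter 2.5 and outer
#' diameter 15 degrees of visual angle (dva), dot step 0.1 dva per frame at
#' 60 Hz (6 dva/s), a 6-frame (100 ms) transparent-motion cycle, a 34-degree
#' per-100-ms heading-change threshold for Brownian motion, and three
#' interleaved dot sets with a 4-frame (67 ms) lifetime for white-noise
#' motion. The dot count follows from the density of 1.6 dots per square dva
#' over the annulus area.
#'
#' @param n_dots Number of dots plotted per frame.
#' @param inner_diameter_dva,outer_diameter_dva Aperture diameters, dva.
#' @param dot_step_dva Displacement per frame, dva.
#' @param refresh_hz Display refresh rate, Hz.
#' @param speed_dva_per_s Dot speed; must equal `dot_step_dva * refresh_hz`.
#' @param tm_cycle_frames Transparent-motion identity/direction cycle, frames.
#' @param bm_direction_threshold_deg Brownian-motion erase threshold:
#'   accumulated heading change within a trailing 100 ms window, degrees.
#' @param wm_n_sets Number of interleaved white-noise-motion dot sets.
#' @param wm_lifetime_frames White-noise-motion dot identity lifetime, frames.
#' @param alpha_band_fraction Fraction of the annulus width over which dots
#'   are faded at each border.
#' @param seed Integer seed for dot placement and identity draws.
#' @return A list of class `stimulus_params`.
#' @export
stimulus_params <- function(n_dots = 275,
                            inner_diameter_dva = 2.5,
                            outer_diameter_dva = 15,
                            dot_step_dva = 0.1,
                            refresh_hz = 60,
                            speed_dva_per_s = 6,
                            tm_cycle_frames = 6,
                            bm_direction_threshold_deg = 34,
                            wm_n_sets = 3,
                            wm_lifetime_frames = 4,
                            alpha_band_fraction = 0.1,
                            seed = 1L) {
  stopifnot(n_dots >= 1, tm_cycle_frames >= 1, wm_n_sets >= 1,
            wm_lifetime_frames >= 1)
  if (inner_diameter_dva >= outer_diameter_dva) {
    stop("inner diameter must be smaller than outer diameter", call. = FALSE)
  }
  if (abs(dot_step_dva * refresh_hz - speed_dva_per_s) > 1e-9) {
    stop("dot_step_dva * refresh_hz must equal speed_dva_per_s", call. = FALSE)
  }
  structure(
    list(n_dots = as.integer(n_dots),
         inner_diameter_dva = inner_diameter_dva,
         outer_diameter_dva = outer_diameter_dva,
         dot_step_dva = dot_step_dva,
         refresh_hz = refresh_hz,
         speed_dva_per_s = speed_dva_per_s,
         tm_cycle_frames = as.integer(tm_cycle_frames),
         bm_direction_threshold_deg = bm_direction_threshold_deg,
         wm_n_sets = as.integer(wm_n_sets),
         wm_lifetime_frames = as.integer(wm_lifetime_frames),
         alpha_band_fraction = alpha_band_fraction,
         seed = as.integer(seed)),
    class = "stimulus_params"
  )
}

#' Implied dot count from density
#'
#' Dot count implied by a dot density over the annulus area,
#' `round(density * pi * (r_out^2 - r_in^2))`.
#'
#' @param p A [stimulus_params()].
#' @param density_dots_per_dva2 Dot density, dots per square dva.
#' @return Integer dot count.
#' @export
implied_dot_count <- function(p = stimulus_params(), density_dots_per_dva2 = 1.6) {
  r_out <- p$outer_diameter_dva / 2
  r_in <- p$inner_diameter_dva / 2
  as.integer(round(density_dots_per_dva2 * pi * (r_out^2 - r_in^2)))
}

# round-half-up signal dot count
signal_count <- function(n_dots, coherence) {
  as.integer(floor(n_dots * coherence + 0.5))
}

#' Border alpha blending profile
#'
#' Dot transparency as a function of radial position in the annulus: 0 at and
#' inside the inner aperture radius and at and outside the outer radius, 1 on
#' the interior plateau, with a logarithmic ramp over a band covering
#' `alpha_band_fraction` of the annulus width at each border. This fading
#' reduces end-stopping cues at the aperture borders.
#'
#' @param radius_dva Radial distance(s) from the aperture center, dva.
#' @param p A [stimulus_params()].
#' @return Alpha value(s) in `[0, 1]`.
#' @export
border_alpha <- function(radius_dva, p = stimulus_params()) {
  stopifnot(all(radius_dva >= 0))
  r_in <- p$inner_diameter_dva / 2
  r_out <- p$outer_diameter_dva / 2
  band <- p$alpha_band_fraction * (r_out - r_in)
  ramp <- function(t) log1p(9 * pmax(0, pmin(1, t))) / log(10)
  a <- pmin(ramp((radius_dva - r_in) / band), ramp((r_out - radius_dva) / band))
  a[radius_dva <= r_in | radius_dva >= r_out] <- 0
  a
}

# uniform-by-area placement in the annulus
place_dots <- function(n, r_in, r_out) {
  r <- sqrt(stats::runif(n, r_in^2, r_out^2))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * sin(th), y = r * cos(th))
}

# screen displacement for a motion direction (0 deg = up, clockwise positive)
step_vector <- function(direction_deg, step) {
  th <- deg2rad(direction_deg)
  cbind(x = step * sin(th), y = step * cos(th))
}

# advance positions one step; outer-border wrap re-enters diametrically
advance <- function(pos, headings_deg, step, r_out) {
  pos <- pos + step_vector(headings_deg, step)
  r <- sqrt(rowSums(pos^2))
  out <- r > r_out
  pos[out, ] <- -pos[out, , drop = FALSE]
  pos
}

frame_tibble <- function(frame, pos, identity, p, set = NA_integer_) {
  r <- sqrt(rowSums(pos^2))
  tibble::tibble(
    frame = frame,
    dot = seq_len(nrow(pos)),
    set = set,
    x = pos[, 1],
    y = pos[, 2],
    identity = ifelse(identity, "signal", "noise"),
    alpha = border_alpha(r, p)
  )
}

#' Simulate a random dot kinematogram
#'
#' Generates frame-by-frame dot positions, signal/noise identities and border
#' alphas for one stimulus presentation, under one of three motion rules:
#'
#' * `"tm"` (transparent motion): identities and per-dot directions are fixed
#'   for each 6-frame (100 ms) cycle, so signal dots trace straight paths and
#'   noise dots trace straight random paths, then everything is redrawn.
#' * `"bm"` (Brownian motion): identities are reshuffled every frame with a
#'   constant signal proportion and noise dots take fresh random directions
#'   each frame; any dot whose accumulated heading change within the trailing
#'   100 ms exceeds `bm_direction_threshold_deg` is erased and redrawn at a
#'   uniform random position.
#' * `"wm"` (white-noise motion): three independent dot sets are plotted
#'   cyclically, one per frame; a set's dots advance one motion step between
#'   their own consecutive appearances, and identities are reshuffled after a
#'   set's second presentation, giving each dot a 4-frame (67 ms) lifetime
#'   conveying a single step of motion.
#'
#' The signal dot count per assignment epoch is `round(n_dots * coherence)`
#' (half up). Dots leaving the outer border re-enter diametrically; the inner
#' aperture is traversed invisibly (alpha 0).
#'
#' @param type One of `"tm"`, `"bm"`, `"wm"`.
#' @param direction_deg Signal motion direction in degrees (0 = up, clockwise).
#' @param coherence Proportion of signal dots, in `[0, 1]`.
#' @param n_frames Number of frames to simulate.
#' @param p A [stimulus_params()].
#' @param seed Optional seed; defaults to `p$seed`.
#' @return A tibble with one row per plotted dot per frame: `frame`, `dot`,
#'   `set` (white-noise motion only), `x`, `y`, `identity`, `alpha`.
#' @export
simulate_rdk <- function(type = c("tm", "bm", "wm"), direction_deg, coherence,
                         n_frames, p = stimulus_params(), seed = NULL) {
  type <- match.arg(type)
  stopifnot(coherence >= 0, coherence <= 1, n_frames >= 1)
  if (is.null(seed)) seed <- p$seed
  withr::with_seed(seed, {
    switch(type,
      tm = simulate_tm_impl(direction_deg, coherence, n_frames, p),
      bm = simulate_bm_impl(direction_deg, coherence, n_frames, p),
      wm = simulate_wm_impl(direction_deg, coherence, n_frames, p))
  })
}

simulate_tm_impl <- function(direction_deg, coherence, n_frames, p) {
  r_in <- p$inner_diameter_dva / 2
  r_out <- p$outer_diameter_dva / 2
  n_sig <- signal_count(p$n_dots, coherence)
  pos <- place_dots(p$n_dots, r_in, r_out)
  identity <- logical(p$n_dots)
  headings <- numeric(p$n_dots)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if ((f - 1L) %% p$tm_cycle_frames == 0L) {
      identity <- logical(p$n_dots)
      identity[sample.int(p$n_dots, n_sig)] <- TRUE
      headings <- ifelse(identity, direction_deg, stats::runif(p$n_dots, 0, 360))
    }
    if (f > 1L) pos <- advance(pos, headings, p$dot_step_dva, r_out)
    frames[[f]] <- frame_tibble(f, pos, identity, p)
  }
  dplyr::bind_rows(frames)
}

simulate_bm_impl <- function(direction_deg, coherence, n_frames, p) {
  r_in <- p$inner_diameter_dva / 2
  r_out <- p$outer_diameter_dva / 2
  n_sig <- signal_count(p$n_dots, coherence)
  window <- p$tm_cycle_frames  # 100 ms trailing window, in frames
  pos <- place_dots(p$n_dots, r_in, r_out)
  age <- integer(p$n_dots)
  hist <- matrix(NA_real_, p$n_dots, window)  # rolling heading history
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    identity <- logical(p$n_dots)
    identity[sample.int(p$n_dots, n_sig)] <- TRUE
    if (f > 1L) {
      headings <- ifelse(identity, direction_deg, stats::runif(p$n_dots, 0, 360))
      pos <- advance(pos, headings, p$dot_step_dva, r_out)
      hist <- cbind(hist[, -1, drop = FALSE], headings)
      age <- age + 1L
      full <- age >= window
      if (any(full)) {
        dh <- abs(wrap_signed(hist[full, -1, drop = FALSE] -
                                hist[full, -window, drop = FALSE]))
        erase <- which(full)[rowSums(dh) > p$bm_direction_threshold_deg]
        if (length(erase)) {
          pos[erase, ] <- place_dots(length(erase), r_in, r_out)
          age[erase] <- 0L
          hist[erase, ] <- NA_real_
        }
      }
    }
    frames[[f]] <- frame_tibble(f, pos, identity, p)
  }
  dplyr::bind_rows(frames)
}

simulate_wm_impl <- function(direction_deg, coherence, n_frames, p) {
  r_in <- p$inner_diameter_dva / 2
  r_out <- p$outer_diameter_dva / 2
  n_sig <- signal_count(p$n_dots, coherence)
  k <- p$wm_n_sets
  sets <- lapply(seq_len(k), function(i) {
    identity <- logical(p$n_dots)
    identity[sample.int(p$n_dots, n_sig)] <- TRUE
    list(pos = place_dots(p$n_dots, r_in, r_out),
         identity = identity,
         headings = ifelse(identity, direction_deg, stats::runif(p$n_dots, 0, 360)),
         shown = 0L)
  })
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    s <- (f - 1L) %% k + 1L
    st <- sets[[s]]
    if (st$shown >= 1L) {
      st$pos <- advance(st$pos, st$headings, p$dot_step_dva, r_out)
    }
    st$shown <- st$shown + 1L
    frames[[f]] <- frame_tibble(f, st$pos, st$identity, p, set = s)
    if (st$shown %% 2L == 0L) {  # identity epoch over: one step of motion conveyed
      st$identity <- logical(p$n_dots)
      st$identity[sample.int(p$n_dots, n_sig)] <- TRUE
      st$headings <- ifelse(st$identity, direction_deg,
                            stats::runif(p$n_dots, 0, 360))
    }
    sets[[s]] <- st
  }
  dplyr::bind_rows(frames)
}

#' Write a dot movie and its stimulus manifest
#'
#' @param movie Tibble from [simulate_rdk()].
#' @param path CSV output path for the long-format movie.
#' @param manifest_path Optional JSON path for the stimulus parameters.
#' @param p The [stimulus_params()] used (written to the manifest).
#' @return `path`, invisibly.
#' @export
write_dot_movie <- function(movie, path, manifest_path = NULL, p = NULL) {
  readr::write_csv(movie, path)
  if (!is.null(manifest_path) && !is.null(p)) {
    jsonlite::write_json(unclass(p), manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
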