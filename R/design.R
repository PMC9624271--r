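#' Experimental design configuration
#'
#' Describes a constrained randomized session: a number of runs of equal
#' length, a set of motion coherence levels, and a partition of the circle
#' into equal directional randomization bins. The defaults reproduce the
#' reference design: 14 runs of 40 trials, five coherence levels, and eight
#' 45-degree bins with borders at 22.5, 67.5, ..., 337.5 degrees.
#'
#' Bin sectors are half-open `[low, high)`: a direction exactly on a border
#' belongs to the higher bin. Bin `i` starts at `bin_borders[i]`; the last
#' bin wraps through 0 degrees (so with the default borders, bin 8 covers
#' directions around "up").
#'
#' @param n_runs Number of runs.
#' @param trials_per_run Trials per run.
#' @param coherence_levels Distinct motion coherences, each in `[0, 1]`.
#' @param n_bins Number of equal directional bins.
#' @param bin_borders Bin borders in degrees, strictly increasing, partitioning
#'   the circle into `n_bins` equal sectors.
#' @param seed Integer seed for design randomization.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_runs = 14,
                          trials_per_run = 40,
                          coherence_levels = c(0, 0.125, 0.25, 0.5, 1),
                          n_bins = 8,
                          bin_borders = 22.5 + 45 * (0:7),
                          seed = 1L) {
  stopifnot(n_runs >= 1, trials_per_run >= 1, n_bins >= 1)
  if (anyDuplicated(coherence_levels) ||
      any(coherence_levels < 0 | coherence_levels > 1)) {
    stop("coherence_levels must be distinct proportions in [0, 1]", call. = FALSE)
  }
  bin_borders <- sort(wrap_angle(bin_borders))
  if (length(bin_borders) != n_bins) {
    stop("need exactly one border per bin", call. = FALSE)
  }
  widths <- diff(c(bin_borders, bin_borders[1] + 360))
  if (n_bins > 1 && max(abs(widths - 360 / n_bins)) > 1e-9) {
    stop("bin borders must partition the circle into equal sectors", call. = FALSE)
  }
  structure(
    list(n_runs = as.integer(n_runs),
         trials_per_run = as.integer(trials_per_run),
         coherence_levels = as.numeric(coherence_levels),
         n_bins = as.integer(n_bins),
         bin_borders = as.numeric(bin_borders),
         seed = as.integer(seed)),
    class = "design_config"
  )
}

#' Assign directions to randomization bins
#'
#' @param direction_deg Directions in degrees.
#' @param config A [design_config()].
#' @return Integer bin indices in `1..n_bins`.
#' @export
bin_of_direction <- function(direction_deg, config) {
  d <- wrap_angle(direction_deg)
  b <- config$bin_borders
  idx <- findInterval(d, b)
  # directions below the first border fall in the wrap-around (last) bin
  idx[idx == 0L] <- config$n_bins
  idx
}

# sequentially draw a balanced sequence with a run-length cap; NULL on dead end
draw_capped_sequence <- function(counts, max_run) {
  n <- sum(counts)
  k <- length(counts)
  out <- integer(n)
  run_len <- 0L
  last <- 0L
  for (i in seq_len(n)) {
    avail <- which(counts > 0L)
    if (run_len >= max_run) avail <- setdiff(avail, last)
    if (length(avail) == 0L) return(NULL)
    pick <- if (length(avail) == 1L) avail else {
      avail[sample.int(length(avail), 1L, prob = counts[avail])]
    }
    out[i] <- pick
    counts[pick] <- counts[pick] - 1L
    run_len <- if (pick == last) run_len + 1L else 1L
    last <- pick
  }
  out
}

#' Generate a constrained randomized trial sequence
#'
#' Produces the full session-level trial list under the design constraints:
#' equal trial counts per directional bin and per coherence level over the
#' whole design, never more than two consecutive trials from the same bin,
#' never more than three consecutive trials at the same coherence, and
#' per-trial directions drawn uniformly within the assigned bin sector.
#'
#' Sequences are drawn by seed-reproducible sequential sampling from the
#' remaining balanced pool, restarting on a dead end (rejection resampling
#' with a retry cap).
#'
#' @param config A [design_config()].
#' @param max_retries Restart cap for the constrained sequence draw.
#' @return A tibble with columns `run`, `trial`, `coherence`, `bin`,
#'   `direction_deg`, one row per trial in presentation order.
#' @export
generate_design <- function(config = design_config(), max_retries = 10000L) {
  stopifnot(inherits(config, "design_config"))
  n_total <- config$n_runs * config$trials_per_run
  n_coh <- length(config$coherence_levels)
  if (n_total %% config$n_bins != 0L) {
    stop("total trial count must be divisible by the number of bins", call. = FALSE)
  }
  if (n_total %% n_coh != 0L) {
    stop("total trial count must be divisible by the number of coherence levels",
         call. = FALSE)
  }
  withr::with_seed(config$seed, {
    draw <- function(k, max_run, what) {
      # a single category makes the run-length constraint vacuous
      if (k == 1L) return(rep(1L, n_total))
      counts <- rep(n_total %/% k, k)
      for (try in seq_len(max_retries)) {
        s <- draw_capped_sequence(counts, max_run)
        if (!is.null(s)) return(s)
      }
      stop(sprintf("could not satisfy the %s run-length constraint after %d retries",
                   what, max_retries), call. = FALSE)
    }
    bins <- draw(config$n_bins, 2L, "bin")
    cohs <- draw(n_coh, 3L, "coherence")
    lo <- config$bin_borders[bins]
    dirs <- wrap_angle(lo + stats::runif(n_total, 0, 360 / config$n_bins))
    tibble::tibble(
      run = rep(seq_len(config$n_runs), each = config$trials_per_run),
      trial = rep(seq_len(config$trials_per_run), times = config$n_runs),
      coherence = config$coherence_levels[cohs],
      bin = bins,
      direction_deg = dirs
    )
  })
}

#' Validate a trial sequence against the design constraints
#'
#' Checks whole-design bin and coherence balance, the bin run-length rule
#' (no three consecutive trials from the same bin), the coherence run-length
#' rule (no four in a row), membership of each direction in its bin sector,
#' and that each coherence is a configured level.
#'
#' @param trials A tibble as returned by [generate_design()].
#' @param config The [design_config()] the sequence claims to follow.
#' @return A tibble of violations with columns `rule`, `position`, `run`,
#'   `detail`; zero rows when the design is valid.
#' @export
validate_design <- function(trials, config) {
  stopifnot(nrow(trials) > 0, inherits(config, "design_config"))
  viol <- list()
  add <- function(rule, position, run, detail) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      rule = rule, position = as.integer(position),
      run = as.integer(run), detail = detail)
  }

  bin_counts <- table(factor(trials$bin, levels = seq_len(config$n_bins)))
  if (length(unique(as.integer(bin_counts))) != 1L) {
    add("bin-balance", NA, NA,
        paste0("per-bin counts: ", paste(as.integer(bin_counts), collapse = ",")))
  }
  coh_counts <- table(factor(trials$coherence, levels = config$coherence_levels))
  if (length(unique(as.integer(coh_counts))) != 1L) {
    add("coherence-balance", NA, NA,
        paste0("per-coherence counts: ", paste(as.integer(coh_counts), collapse = ",")))
  }

  # run-length rules are vacuous when only one category is configured
  if (config$n_bins > 1L) {
    r <- rle(trials$bin)
    ends <- cumsum(r$lengths)
    for (j in which(r$lengths >= 3L)) {
      add("bin-run-length", ends[j], trials$run[ends[j]],
          sprintf("bin %d repeated %d times", r$values[j], r$lengths[j]))
    }
  }
  if (length(config$coherence_levels) > 1L) {
    r <- rle(trials$coherence)
    ends <- cumsum(r$lengths)
    for (j in which(r$lengths >= 4L)) {
      add("coherence-run-length", ends[j], trials$run[ends[j]],
          sprintf("coherence %g repeated %d times", r$values[j], r$lengths[j]))
    }
  }

  bad_bin <- which(bin_of_direction(trials$direction_deg, config) != trials$bin)
  for (i in bad_bin) {
    add("direction-outside-bin", i, trials$run[i],
        sprintf("direction %.2f not in bin %d", trials$direction_deg[i], trials$bin[i]))
  }
  bad_coh <- which(!trials$coherence %in% config$coherence_levels)
  for (i in bad_coh) {
    add("unknown-coherence", i, trials$run[i],
        sprintf("coherence %g not configured", trials$coherence[i]))
  }

  if (length(viol) == 0L) {
    tibble::tibble(rule = character(), position = integer(),
                   run = integer(), detail = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Read and write trial tables
#'
#' Trials travel as plain CSV with columns
#' `subject,run,trial,coherence,bin,direction_deg`.
#'
#' @param trials Trial tibble (a `subject` column is added if missing).
#' @param path File path.
#' @param subject Subject identifier used when the table has none.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a tibble.
#' @export
write_trials <- function(trials, path, subject = "s01") {
  if (!"subject" %in% names(trials)) {
    trials <- dplyr::mutate(trials, subject = subject, .before = 1)
  }
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a design configuration from JSON
#'
#' @param path Path to a JSON file with any subset of the [design_config()]
#'   fields; missing fields take the defaults.
#' @return A `design_config`.
#' @export
read_design_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(design_config))
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown design config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(design_config, x)
}
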