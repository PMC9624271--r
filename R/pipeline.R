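#' Analyze one subject's continuous-report data
#'
#' Runs the complete per-subject analysis: for every coherence level with
#' enough trials, the four nested mixture models are fitted by maximum
#' likelihood, compared with Akaike weights and model-averaged; the
#' distribution of reported directions is tested against the distribution of
#' presented directions (pooled over coherences and per coherence) with the
#' permutation Cramér–von Mises test. Training runs are assumed to be
#' excluded upstream.
#'
#' The model-averaged mixture coefficients are the subject's detection, ROOD
#' and guess frequencies. Bias and precision estimates at 0% coherence are
#' reported but flagged non-interpretable (no stimulus information is
#' present at that level).
#'
#' @param responses Tibble with columns `coherence`, `direction_deg`,
#'   `reported_deg` (and/or `deviation_deg`).
#' @param options [vmmm_options()] passed to the fits.
#' @param n_min Minimum trials per coherence for fitting; smaller cells are
#'   flagged and skipped, not fatal.
#' @param n_permutations Permutations for the bias tests.
#' @param seed Seed for the permutation tests.
#' @return An object of class `subject_results`: a list with tibbles
#'   `averaged` (coherence x parameter model-averaged estimates, with an
#'   `interpretable` flag), `comparison` (coherence x model AICs and
#'   weights), `bias_tests` (pooled and per-coherence test rows), the raw
#'   `fits`, and `skipped` coherence levels.
#' @export
analyze_subject <- function(responses, options = vmmm_options(),
                            n_min = 30, n_permutations = 999, seed = 1L) {
  stopifnot(nrow(responses) > 0, "coherence" %in% names(responses))
  if (!"deviation_deg" %in% names(responses)) {
    responses$deviation_deg <-
      wrap_deviation(responses$direction_deg, responses$reported_deg)
  }
  cohs <- sort(unique(responses$coherence))
  counts <- vapply(cohs, function(ch) sum(responses$coherence == ch), numeric(1))
  usable <- cohs[counts >= n_min]
  skipped <- cohs[counts < n_min]
  if (length(usable) == 0) {
    stop(sprintf("no coherence level has the %d trials required for fitting",
                 n_min), call. = FALSE)
  }

  fits <- list()
  cmp_rows <- list()
  avg_rows <- list()
  for (ch in usable) {
    dev <- responses$deviation_deg[responses$coherence == ch]
    cmp <- compare_vmmm(dev, options = options)
    fits[[as.character(ch)]] <- cmp
    cmp_rows[[as.character(ch)]] <- dplyr::mutate(
      dplyr::select(tibble::as_tibble(cmp), -"fit"),
      coherence = ch, .before = 1)
    avg <- model_average(cmp)
    avg_rows[[as.character(ch)]] <- dplyr::mutate(
      avg, coherence = ch,
      interpretable = avg$parameter %in% c("r1", "r2", "r3") | ch > 0,
      .before = 1)
  }

  bias <- list()
  if (all(c("direction_deg", "reported_deg") %in% names(responses))) {
    bias[["pooled"]] <- dplyr::mutate(
      cvm_test(responses$direction_deg, responses$reported_deg,
               n_permutations = n_permutations, seed = seed),
      coherence = NA_real_, scope = "pooled", .before = 1)
    for (ch in usable) {
      sub <- responses[responses$coherence == ch, ]
      bias[[as.character(ch)]] <- dplyr::mutate(
        cvm_test(sub$direction_deg, sub$reported_deg,
                 n_permutations = n_permutations, seed = seed),
        coherence = ch, scope = "per-coherence", .before = 1)
    }
  }

  structure(
    list(averaged = dplyr::bind_rows(avg_rows),
         comparison = dplyr::bind_rows(cmp_rows),
         bias_tests = if (length(bias)) dplyr::bind_rows(bias) else NULL,
         fits = fits,
         skipped = skipped,
         n_min = n_min),
    class = "subject_results"
  )
}

#' @export
print.subject_results <- function(x, ...) {
  cohs <- unique(x$averaged$coherence)
  cat(sprintf("<subject_results> %d coherence level(s) analyzed", length(cohs)))
  if (length(x$skipped)) {
    cat(sprintf(", %d skipped (< %d trials)", length(x$skipped), x$n_min))
  }
  cat("\nmodel-averaged frequencies (guess = r3):\n")
  freq <- tidyr::pivot_wider(
    dplyr::filter(x$averaged, .data$parameter %in% c("r1", "r2", "r3")),
    id_cols = "coherence", names_from = "parameter", values_from = "estimate")
  print(freq)
  invisible(x)
}

#' Group-level summary of model-averaged estimates
#'
#' Aggregates per-subject model-averaged parameter estimates to group means
#' with standard errors of the mean (`sd / sqrt(n)`), per coherence level
#' and parameter. The bias `mu` is aggregated circularly (mean direction of
#' the subject-wise biases; its SEM is the circular SD over subjects divided
#' by `sqrt(n)`).
#'
#' @param results A list of [analyze_subject()] results (>= 2 subjects).
#' @return A tibble with `coherence`, `parameter`, `mean`, `sem`,
#'   `n_subjects`.
#' @export
summarize_group <- function(results) {
  if (length(results) < 2) {
    stop("group summaries need at least 2 subjects", call. = FALSE)
  }
  long <- dplyr::bind_rows(
    lapply(seq_along(results), function(i) {
      dplyr::mutate(results[[i]]$averaged, subject = i, .before = 1)
    })
  )
  long <- dplyr::filter(long, .data$defined)
  dplyr::summarise(
    dplyr::group_by(long, .data$coherence, .data$parameter),
    mean = if (dplyr::first(.data$parameter) == "mu") {
      circular_mean(.data$estimate)
    } else {
      mean(.data$estimate)
    },
    sem = if (dplyr::n() < 2) {
      NA_real_
    } else if (dplyr::first(.data$parameter) == "mu") {
      circular_sd(.data$estimate) / sqrt(dplyr::n())
    } else {
      stats::sd(.data$estimate) / sqrt(dplyr::n())
    },
    n_subjects = dplyr::n(),
    .groups = "drop"
  )
}
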