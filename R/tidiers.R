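#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixture model fit
#'
#' @param x A `vmmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `fixed` indicating coefficients pinned by the model).
#' @export
tidy.vmmm_fit <- function(x, ...) {
  spec <- model_spec(x$model)
  terms <- c("r1", "r2", "r3", "mu", "kappa1", "kappa2")
  fixed <- c(!spec$use_det, !spec$use_rood, FALSE,
             !(spec$use_det || spec$use_rood),
             !spec$use_det, !spec$use_rood)
  tibble::tibble(
    term = terms,
    estimate = vapply(terms, function(t) x$params[[t]], numeric(1)),
    fixed = fixed
  )
}

#' Glance at a mixture model fit
#'
#' @param x A `vmmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `k`, `n`, `log_likelihood`, `aic`,
#'   `converged`.
#' @export
glance.vmmm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, k = x$k, n = x$n,
                 log_likelihood = x$log_likelihood, aic = aic(x),
                 converged = x$converged)
}

#' Tidy a subject analysis
#'
#' @param x A `subject_results` object.
#' @param ... Unused.
#' @return The long tibble of model-averaged estimates per coherence.
#' @export
tidy.subject_results <- function(x, ...) {
  x$averaged
}

#' Glance at a subject analysis
#'
#' @param x A `subject_results` object.
#' @param ... Unused.
#' @return A one-row tibble with counts of analyzed and skipped coherence
#'   levels and the pooled bias-test result, when available.
#' @export
glance.subject_results <- function(x, ...) {
  pooled <- if (!is.null(x$bias_tests)) {
    dplyr::filter(x$bias_tests, .data$scope == "pooled")
  } else {
    NULL
  }
  tibble::tibble(
    n_coherences = length(unique(x$averaged$coherence)),
    n_skipped = length(x$skipped),
    bias_statistic = if (!is.null(pooled) && nrow(pooled)) pooled$statistic else NA_real_,
    bias_p_value = if (!is.null(pooled) && nrow(pooled)) pooled$p_value else NA_real_
  )
}
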