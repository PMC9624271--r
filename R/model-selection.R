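#' Akaike information criterion of a mixture fit
#'
#' `AIC = 2k - 2 logL` with `k` the model's free-parameter count
#' (0/3/3/5 for m00/m01/m10/m11).
#'
#' @param fit A `vmmm_fit`.
#' @return Scalar AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "vmmm_fit"))
  2 * fit$k - 2 * fit$log_likelihood
}

#' Akaike weights
#'
#' Normalized relative likelihoods `w_i = exp(-delta_i / 2) / sum_j
#' exp(-delta_j / 2)` with `delta_i = AIC_i - min AIC`, interpretable as
#' posterior model probabilities over the candidate set and invariant to
#' adding a constant to every AIC.
#'
#' @param aics Numeric vector of AIC values, optionally named by model;
#'   at least one must be finite.
#' @return A tibble with columns `model`, `aic`, `delta`, `weight`.
#' @examples
#' akaike_weights(c(m10 = 100, m11 = 102))
#' @export
akaike_weights <- function(aics) {
  if (length(aics) == 0 || all(!is.finite(aics))) {
    stop("need at least one finite AIC", call. = FALSE)
  }
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tibble::tibble(
    model = if (is.null(names(aics))) paste0("model", seq_along(aics)) else names(aics),
    aic = as.numeric(aics),
    delta = as.numeric(delta),
    weight = as.numeric(w)
  )
}

#' Compare the four nested mixture models on one deviation set
#'
#' Fits `m00`, `m01`, `m10` and `m11`, computes AICs and Akaike weights.
#'
#' @inheritParams fit_vmmm
#' @return A tibble of class `vmmm_comparison` with one row per model
#'   (`model`, `k`, `n`, `log_likelihood`, `aic`, `delta`, `weight`) and the
#'   fit objects in the `fit` list-column.
#' @examples
#' dev <- sample_vmmm_deviations(vmmm_params(r3 = 1), n = 100, seed = 1)
#' compare_vmmm(dev)
#' @export
compare_vmmm <- function(data, deviation = deviation_deg,
                         options = vmmm_options()) {
  fits <- fit_vmmm_all(data, {{ deviation }}, options = options)
  aics <- vapply(fits, aic, numeric(1))
  cmp <- akaike_weights(aics)
  cmp$k <- vapply(fits, function(f) f$k, integer(1))
  cmp$n <- vapply(fits, function(f) f$n, integer(1))
  cmp$log_likelihood <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  cmp$fit <- unname(fits)
  cmp <- dplyr::relocate(cmp, "model", "k", "n", "log_likelihood",
                         "aic", "delta", "weight")
  class(cmp) <- c("vmmm_comparison", class(cmp))
  cmp
}

# models in which each parameter is free
free_in <- list(
  mu = c("m01", "m10", "m11"),
  kappa1 = c("m10", "m11"),
  kappa2 = c("m01", "m11")
)

#' Model-averaged parameter estimates
#'
#' Averages the model-wise parameter estimates with the Akaike weights as
#' posterior model probabilities. Mixture coefficients are averaged over all
#' models, with coefficients pinned to zero in reduced models contributing
#' zero (that is how the reduced models are defined). The bias and the
#' concentrations are only defined in models containing the corresponding
#' component, so they are averaged over those models with the weights
#' renormalized over that subset; the bias is averaged circularly. A
#' parameter that is free in no positively weighted model is returned as
#' `NA` with `defined = FALSE`.
#'
#' @param comparison A [compare_vmmm()] result, or a named list of
#'   `vmmm_fit` objects together with `weights`.
#' @param weights Optional named Akaike weights when `comparison` is a list
#'   of fits.
#' @return A tibble with columns `parameter`, `estimate`, `weight_mass`
#'   (total weight of the models defining the parameter) and `defined`.
#' @export
model_average <- function(comparison, weights = NULL) {
  if (inherits(comparison, "vmmm_comparison")) {
    fits <- stats::setNames(comparison$fit, comparison$model)
    w <- stats::setNames(comparison$weight, comparison$model)
  } else {
    fits <- comparison
    if (is.null(weights)) stop("weights required with a plain fit list", call. = FALSE)
    w <- weights[names(fits)]
  }
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  get <- function(param) vapply(fits, function(f) f$params[[param]], numeric(1))

  rows <- list()
  for (param in c("r1", "r2", "r3")) {
    rows[[param]] <- tibble::tibble(
      parameter = param,
      estimate = sum(w * get(param)),
      weight_mass = 1,
      defined = TRUE
    )
  }
  for (param in c("mu", "kappa1", "kappa2")) {
    models <- intersect(free_in[[param]], names(fits))
    mass <- sum(w[models])
    if (mass <= 0) {
      rows[[param]] <- tibble::tibble(parameter = param, estimate = NA_real_,
                                      weight_mass = 0, defined = FALSE)
      next
    }
    vals <- get(param)[models]
    est <- if (param == "mu") {
      circular_mean(vals, weights = w[models] / mass)
    } else {
      sum(w[models] / mass * vals)
    }
    rows[[param]] <- tibble::tibble(parameter = param, estimate = est,
                                    weight_mass = mass, defined = TRUE)
  }
  dplyr::bind_rows(rows)
}

#' Serialize comparison and averaged estimates to JSON
#'
#' @param comparison A [compare_vmmm()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(comparison, path) {
  avg <- model_average(comparison)
  x <- list(
    models = lapply(seq_len(nrow(comparison)), function(i) {
      f <- comparison$fit[[i]]
      list(model = comparison$model[i], k = comparison$k[i],
           log_likelihood = comparison$log_likelihood[i],
           aic = comparison$aic[i], delta = comparison$delta[i],
           weight = comparison$weight[i], params = unclass(f$params))
    }),
    averaged = stats::setNames(as.list(avg$estimate), avg$parameter)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
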