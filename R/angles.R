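#' Wrap an angle to \[0, 360)
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @examples
#' wrap_angle(c(-10, 370, 360))
#' @export
wrap_angle <- function(deg) {
  deg %% 360
}

#' Wrapped response deviation
#'
#' Computes the signed deviation of a reported direction from a presented
#' direction, wrapped to the half-open interval `(-180, 180]`. An exactly
#' antipodal report maps to `+180`.
#'
#' @param presented_deg Presented direction(s), degrees.
#' @param reported_deg Reported direction(s), degrees.
#' @return Numeric vector of deviations in `(-180, 180]`.
#' @examples
#' wrap_deviation(350, 10)  # +20
#' wrap_deviation(90, 270)  # +180
#' @export
wrap_deviation <- function(presented_deg, reported_deg) {
  stopifnot(is.finite(presented_deg), is.finite(reported_deg))
  d <- (reported_deg - presented_deg) %% 360
  ifelse(d > 180, d - 360, d)
}

# wrap any signed angle to (-180, 180]
wrap_signed <- function(deg) {
  d <- deg %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Mean resultant length of circular data
#'
#' @param angles_deg Angles in degrees.
#' @return Scalar in `[0, 1]`.
#' @export
circular_resultant <- function(angles_deg) {
  th <- deg2rad(angles_deg)
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Circular mean direction
#'
#' @param angles_deg Angles in degrees.
#' @param weights Optional non-negative weights (default equal).
#' @return Mean direction in degrees, wrapped to `(-180, 180]`.
#' @export
circular_mean <- function(angles_deg, weights = NULL) {
  th <- deg2rad(angles_deg)
  if (is.null(weights)) weights <- rep(1, length(th))
  s <- sum(weights * sin(th))
  c_ <- sum(weights * cos(th))
  wrap_signed(rad2deg(atan2(s, c_)))
}

#' Circular standard deviation
#'
#' Mardia's circular standard deviation `sqrt(-2 log Rbar)`, returned in
#' degrees. Used by the adaptive feedback criterion, which doubles the spread
#' of the full-coherence response deviations.
#'
#' @param angles_deg Angles in degrees, length >= 2.
#' @return Circular SD in degrees; `Inf` when the resultant length is 0.
#' @export
circular_sd <- function(angles_deg) {
  if (length(angles_deg) < 2) {
    stop("circular_sd() needs at least 2 angles", call. = FALSE)
  }
  rbar <- circular_resultant(angles_deg)
  if (rbar <= 0) {
    warning("zero resultant length: circular spread is infinite")
    return(Inf)
  }
  rad2deg(sqrt(-2 * log(rbar)))
}
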