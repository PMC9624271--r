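#' Two-sample Cramér–von Mises statistic
#'
#' Integrated squared difference between the empirical cumulative
#' distributions of two samples, operationalized in the symmetric rank-based
#' form evaluated at the pooled observations:
#' `T = n m / N^2 * sum_k (F_n(z_k) - F_m(z_k))^2` over all pooled values
#' `z_k`. Angles are treated with a fixed origin at 0 degrees (the natural
#' "up" origin of the direction space), so the ECDFs are ordinary ECDFs on
#' `[0, 360)`. The statistic is tie-aware: it is 0 exactly when the two
#' samples are identical multisets. [watson_u2()] provides the
#' rotation-invariant variant.
#'
#' @param sample_a,sample_b Numeric vectors of angles in degrees (or any
#'   reals; only the ordering on the fixed scale matters). Both non-empty.
#' @return The scalar statistic `T >= 0`.
#' @export
cvm_statistic <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  a <- wrap_angle(sample_a)
  b <- wrap_angle(sample_b)
  pooled <- c(a, b)
  grp <- rep(c(0L, 1L), c(length(a), length(b)))
  o <- order(pooled)
  .cvm_stat_cpp(pooled[o], grp[o], length(a), length(b))
}

#' Watson's two-sample U-squared statistic
#'
#' Rotation-invariant variant of the two-sample Cramér–von Mises statistic:
#' the squared ECDF differences are centered on their pooled mean before
#' summation, which removes the dependence on the circular origin.
#'
#' @inheritParams cvm_statistic
#' @return The scalar statistic `U^2 >= 0`.
#' @export
watson_u2 <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  a <- wrap_angle(sample_a)
  b <- wrap_angle(sample_b)
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  o <- order(pooled)
  g <- rep(c(TRUE, FALSE), c(n, m))[o]
  d <- cumsum(g) / n - cumsum(!g) / m
  n * m / (n + m)^2 * sum((d - mean(d))^2)
}

#' Permutation test for a difference between two circular distributions
#'
#' Tests whether two samples of directions come from the same distribution,
#' as used to compare the distribution of reported directions against the
#' near-uniform distribution of presented directions. The p-value is
#' obtained by Monte-Carlo permutation of the group labels:
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_permutations)`.
#'
#' @inheritParams cvm_statistic
#' @param n_permutations Number of label permutations, `>= 99`.
#' @param seed Optional integer seed for the permutations.
#' @param statistic `"cvm"` (fixed origin, the default) or `"watson"`
#'   (rotation invariant).
#' @return A one-row tibble: `statistic`, `p_value`, `n`, `m`,
#'   `n_permutations`, `seed`, `method`.
#' @examples
#' x <- runif(50, 0, 360)
#' cvm_test(x, x, n_permutations = 99)$p_value  # 1: identical samples
#' @export
cvm_test <- function(sample_a, sample_b, n_permutations = 9999, seed = NULL,
                     statistic = c("cvm", "watson")) {
  statistic <- match.arg(statistic)
  if (n_permutations < 99) stop("use at least 99 permutations", call. = FALSE)
  obs <- if (statistic == "cvm") {
    cvm_statistic(sample_a, sample_b)
  } else {
    watson_u2(sample_a, sample_b)
  }
  a <- wrap_angle(sample_a)
  b <- wrap_angle(sample_b)
  n <- length(a)
  m <- length(b)
  perm <- function() {
    if (statistic == "cvm") {
      pooled <- sort(c(a, b))
      .cvm_perm_cpp(pooled, n, m, as.integer(n_permutations))
    } else {
      pooled <- c(a, b)
      vapply(seq_len(n_permutations), function(i) {
        idx <- sample.int(n + m, n)
        watson_u2(pooled[idx], pooled[-idx])
      }, numeric(1))
    }
  }
  method_name <- statistic
  ts <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  p <- (1 + sum(ts >= obs - 1e-12)) / (1 + n_permutations)
  tibble::tibble(statistic = obs, p_value = p, n = n, m = m,
                 n_permutations = as.integer(n_permutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 method = method_name)
}

#' Adaptive feedback criterion
#'
#' During testing, block feedback counts a response as correct when its
#' absolute deviation is below a criterion, initialized at 60 degrees. After
#' designated runs the criterion is re-estimated as twice the circular
#' standard deviation of the full-coherence response deviations, but only
#' adopted when smaller than 60 degrees (lenient cap for low performers).
#'
#' @param deviations_at_full_coherence Wrapped deviations (degrees) from
#'   100% coherence trials.
#' @param current_criterion_deg Criterion currently in force (degrees).
#' @return Updated criterion in degrees.
#' @export
adapt_feedback_criterion <- function(deviations_at_full_coherence,
                                     current_criterion_deg = 60) {
  if (length(deviations_at_full_coherence) < 2) {
    return(current_criterion_deg)
  }
  candidate <- 2 * circular_sd(deviations_at_full_coherence)
  if (is.finite(candidate) && candidate < 60) candidate else current_criterion_deg
}

#' Feedback accuracy over a window of trials
#'
#' Fraction of deviations whose magnitude is below the feedback criterion.
#'
#' @param deviations Wrapped deviations, degrees.
#' @param criterion_deg Feedback criterion, degrees.
#' @return Proportion in `[0, 1]`.
#' @export
feedback_accuracy <- function(deviations, criterion_deg = 60) {
  mean(abs(wrap_signed(deviations)) < criterion_deg)
}
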