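#' Empirical-Bayes surrogate for ABP adaptive reference limits
#'
#' The official ABP limits are produced inside ADAMS by a proprietary
#' Bayesian model. The correction procedure in this package only needs
#' individual limits that adapt (narrow) with accumulating history, so we
#' use the standard normal-normal empirical-Bayes predictive interval as a
#' surrogate: marker values of subject i are N(theta_i, sigma_w^2) around an
#' individual mean theta_i ~ N(mu_pop, sigma_b^2). After n observations with
#' mean xbar, the predictive distribution of the next value is normal with
#'
#'   m_n = (n * xbar / sigma_w^2 + mu_pop / sigma_b^2) /
#'         (n / sigma_w^2 + 1 / sigma_b^2)
#'   v_n = sigma_w^2 + 1 / (n / sigma_w^2 + 1 / sigma_b^2)
#'
#' and the limit pair is `m_n -/+ z * sqrt(v_n)` with
#' `z = qnorm((1 + specificity) / 2)`. Limits for visit i are prequential:
#' they use history strictly before i, matching passport practice where each
#' new sample is tested against prior evidence.
#'
#' @name adaptive-limits
NULL

#' Population prior for one marker and sex
#'
#' @param marker `"hb"` or `"offs"`.
#' @param sex `"male"` or `"female"`.
#' @param mu_pop Population mean, marker units.
#' @param sigma_between Between-subject SD (> 0).
#' @param sigma_within Within-subject SD, biological + analytical (> 0).
#' @return An object of class `abp_prior`.
#' @export
population_prior <- function(marker, sex, mu_pop, sigma_between,
                             sigma_within) {
  marker <- match.arg(marker, c("hb", "offs"))
  sex <- match.arg(sex, c("male", "female"))
  if (sigma_between <= 0 || sigma_within <= 0) {
    stop("sigma_between and sigma_within must be > 0", call. = FALSE)
  }
  structure(
    list(marker = marker, sex = sex, mu_pop = mu_pop,
         sigma_between = sigma_between, sigma_within = sigma_within),
    class = "abp_prior"
  )
}

#' @export
print.abp_prior <- function(x, ...) {
  cat(sprintf("<abp_prior> %s/%s: mu = %.2f, sigma_b = %.2f, sigma_w = %.2f\n",
              x$marker, x$sex, x$mu_pop, x$sigma_between, x$sigma_within))
  invisible(x)
}

#' Default population priors
#'
#' Order-of-magnitude hematology norms used when no cohort-specific priors
#' are supplied: \[Hb\] male 15.2, female 13.4 g/dL (sigma_b 0.9, sigma_w
#' 0.45); OFF-score male 90, female 80 (sigma_b 12, sigma_w 8). These are
#' implementation defaults, configurable per marker and sex.
#'
#' @return Named list of `abp_prior` objects, keys `"<marker>.<sex>"`.
#' @export
default_priors <- function() {
  list(
    hb.male     = population_prior("hb", "male", 15.2, 0.9, 0.45),
    hb.female   = population_prior("hb", "female", 13.4, 0.9, 0.45),
    offs.male   = population_prior("offs", "male", 90, 12, 8),
    offs.female = population_prior("offs", "female", 80, 12, 8)
  )
}

#' Predictive reference limits for the next observation
#'
#' @param prior An [population_prior()] object.
#' @param history Numeric vector of the subject's previous marker values;
#'   may be empty (first sample: limits from the prior alone).
#' @param specificity Two-sided specificity of the limit pair, in (0.5, 1);
#'   default 0.99 (the conventional ABP operating point).
#' @return A one-row tibble with `lower`, `upper`, `specificity`.
#' @export
sequential_limits <- function(prior, history = numeric(),
                              specificity = 0.99) {
  stopifnot(inherits(prior, "abp_prior"))
  if (!is.numeric(specificity) || specificity <= 0.5 || specificity >= 1) {
    stop("specificity must be in (0.5, 1)", call. = FALSE)
  }
  n <- length(history)
  w2 <- prior$sigma_within^2
  b2 <- prior$sigma_between^2
  prec <- n / w2 + 1 / b2
  m_n <- (sum(history) / w2 + prior$mu_pop / b2) / prec
  v_n <- w2 + 1 / prec
  z <- stats::qnorm((1 + specificity) / 2)
  tibble::tibble(
    lower = m_n - z * sqrt(v_n),
    upper = m_n + z * sqrt(v_n),
    specificity = specificity
  )
}

#' Prequential limits along one subject's series
#'
#' Computes, for every visit i of a marker series, the predictive limits
#' based on values 1..(i-1). Vectorized via cumulative sums, so long series
#' are cheap.
#'
#' @inheritParams sequential_limits
#' @param values The subject's marker series in visit order.
#' @return Tibble with one row per visit: `lower`, `upper`, `specificity`.
#' @export
profile_limits <- function(prior, values, specificity = 0.99) {
  stopifnot(inherits(prior, "abp_prior"))
  if (!is.numeric(specificity) || specificity <= 0.5 || specificity >= 1) {
    stop("specificity must be in (0.5, 1)", call. = FALSE)
  }
  k <- length(values)
  n_prev <- seq_len(k) - 1                     # history size before visit i
  sum_prev <- c(0, cumsum(values))[seq_len(k)] # history sum before visit i
  w2 <- prior$sigma_within^2
  b2 <- prior$sigma_between^2
  prec <- n_prev / w2 + 1 / b2
  m_n <- (sum_prev / w2 + prior$mu_pop / b2) / prec
  v_n <- w2 + 1 / prec
  z <- stats::qnorm((1 + specificity) / 2)
  tibble::tibble(
    lower = m_n - z * sqrt(v_n),
    upper = m_n + z * sqrt(v_n),
    specificity = specificity
  )
}

#' Flag a value against an individual limit pair
#'
#' A value is an atypical passport finding (ATPF) iff it falls strictly
#' outside the limits; values exactly on a limit are not flagged (closed
#' interval inside).
#'
#' @param value Marker value(s).
#' @param lower,upper Limit pair(s), recycled against `value`.
#' @return Character vector, `"atpf"` or `"none"`.
#' @export
flag_atpf <- function(value, lower, upper) {
  if (any(upper <= lower)) stop("invalid limits: upper <= lower", call. = FALSE)
  ifelse(value < lower | value > upper, "atpf", "none")
}
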