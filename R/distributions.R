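# Parametric usual-intake distributions (log-normal / gamma), parameterised
# internally by (mean, cv).  Family-native parameters are derived on demand:
#   lognormal: sigma^2 = log(1 + cv^2), mu = log(mean) - sigma^2/2
#   gamma:     shape = 1/cv^2, scale = mean * cv^2
# A cv at or below `point_mass_cv` is treated as a point mass at the mean.

INTAKE_FAMILIES <- c("lognormal", "gamma")

# cv below this is numerically degenerate: cdf/quantile use a point mass
point_mass_cv <- 1e-6

check_family <- function(family) {
  bad <- setdiff(unique(family), INTAKE_FAMILIES)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown intake distribution family: ",
      paste(bad, collapse = ", "),
      " (must be one of ", paste(INTAKE_FAMILIES, collapse = ", "), ")"
    ))
  }
  invisible(family)
}

#' Build an intake distribution from its mean and coefficient of variation
#'
#' Usual-intake distributions are right-skewed and are re-parameterised here
#' by their analytic mean and CV, which is the natural parameterisation for
#' the mean-shift operation used to model fortification.  All arguments are
#' vectorised and recycled.
#'
#' @param family `"lognormal"` or `"gamma"`.
#' @param mean Analytic mean of daily intake (intake units/day), > 0.
#' @param cv Coefficient of variation (sd/mean), > 0.
#' @return A tibble with columns `family`, `mean`, `cv`, `param1`, `param2`
#'   where (`param1`, `param2`) are the family-native parameters
#'   (lognormal: meanlog, sdlog; gamma: shape, scale).
#' @examples
#' dist_from_mean_cv("gamma", mean = 2, cv = 0.5)  # shape 4, scale 0.5
#' @export
dist_from_mean_cv <- function(family, mean, cv) {
  check_family(family)
  if (any(!is.finite(mean) | mean <= 0)) {
    rlang::abort("intake distribution mean must be finite and > 0")
  }
  if (any(!is.finite(cv) | cv <= 0)) {
    rlang::abort("intake distribution cv must be finite and > 0")
  }
  p <- dist_native_params(family, mean, cv)
  tibble::tibble(family = family, mean = mean, cv = cv,
                 param1 = p$param1, param2 = p$param2)
}

# (mean, cv) -> family-native (param1, param2); vectorised
dist_native_params <- function(family, mean, cv) {
  n <- max(length(family), length(mean), length(cv))
  family <- rep_len(family, n); mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  ln <- family == "lognormal"
  param1 <- param2 <- numeric(n)
  s2 <- log1p(cv[ln]^2)
  param1[ln] <- log(mean[ln]) - s2 / 2
  param2[ln] <- sqrt(s2)
  param1[!ln] <- 1 / cv[!ln]^2
  param2[!ln] <- mean[!ln] * cv[!ln]^2
  list(param1 = param1, param2 = param2)
}

#' Recover (mean, cv) from family-native parameters
#'
#' Closed-form moments: lognormal mean `exp(mu + sigma^2/2)`,
#' `cv = sqrt(exp(sigma^2) - 1)`; gamma mean `shape * scale`,
#' `cv = 1/sqrt(shape)`.
#'
#' @param family `"lognormal"` or `"gamma"`.
#' @param param1 meanlog (lognormal) or shape (gamma).
#' @param param2 sdlog (lognormal) or scale (gamma); must be > 0.
#' @return A tibble with columns `family`, `mean`, `cv`, `param1`, `param2`.
#' @export
dist_from_native <- function(family, param1, param2) {
  check_family(family)
  if (any(!is.finite(param2) | param2 <= 0)) {
    rlang::abort("param2 (sdlog or scale) must be finite and > 0")
  }
  n <- max(length(family), length(param1), length(param2))
  family <- rep_len(family, n)
  param1 <- rep_len(param1, n); param2 <- rep_len(param2, n)
  if (any(family == "gamma" & param1 <= 0)) {
    rlang::abort("gamma shape must be > 0")
  }
  ln <- family == "lognormal"
  mean <- cv <- numeric(n)
  mean[ln] <- exp(param1[ln] + param2[ln]^2 / 2)
  cv[ln] <- sqrt(expm1(param2[ln]^2))
  mean[!ln] <- param1[!ln] * param2[!ln]
  cv[!ln] <- 1 / sqrt(param1[!ln])
  tibble::tibble(family = family, mean = mean, cv = cv,
                 param1 = param1, param2 = param2)
}

#' Analytic moments of an intake distribution
#'
#' @inheritParams dist_from_mean_cv
#' @return A tibble with columns `mean`, `sd`, `cv`.
#' @export
dist_moments <- function(family, mean, cv) {
  check_family(family)
  n <- max(length(family), length(mean), length(cv))
  mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  tibble::tibble(mean = mean, sd = mean * cv, cv = cv)
}

#' Shift an intake distribution to model a fortification contribution
#'
#' Fortification adds `delta` to the mean of the unfortified usual-intake
#' distribution while retaining its family and "the same amount of
#' variability".  The default convention preserves the CV; the `"sd"`
#' convention preserves the absolute standard deviation instead.
#'
#' @inheritParams dist_from_mean_cv
#' @param delta Non-negative intake contribution (intake units/day).
#' @param convention `"cv"` (default) or `"sd"`.
#' @return A tibble with columns `family`, `mean`, `cv` for the shifted
#'   distribution.
#' @export
shift_dist <- function(family, mean, cv, delta, convention = c("cv", "sd")) {
  convention <- match.arg(convention)
  check_family(family)
  if (any(!is.finite(delta) | delta < 0)) {
    rlang::abort("fortification contribution delta must be >= 0 (fortification never removes intake)")
  }
  n <- max(length(family), length(mean), length(cv), length(delta))
  family <- rep_len(family, n); mean <- rep_len(mean, n)
  cv <- rep_len(cv, n); delta <- rep_len(delta, n)
  new_mean <- mean + delta
  new_cv <- if (convention == "cv") cv else cv * mean / new_mean
  tibble::tibble(family = family, mean = new_mean, cv = new_cv)
}

#' Intake distribution CDF
#'
#' @param q Intake quantile (units/day), >= 0; vectorised.
#' @inheritParams dist_from_mean_cv
#' @return `P(intake <= q)`.
#' @export
pintake <- function(q, family, mean, cv) {
  check_family(family)
  n <- max(length(q), length(family), length(mean), length(cv))
  q <- rep_len(q, n); family <- rep_len(family, n)
  mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  out <- numeric(n)
  pm <- cv <= point_mass_cv
  out[pm] <- as.numeric(q[pm] >= mean[pm])
  ln <- !pm & family == "lognormal"
  ga <- !pm & family == "gamma"
  if (any(ln)) {
    p <- dist_native_params("lognormal", mean[ln], cv[ln])
    out[ln] <- stats::plnorm(q[ln], p$param1, p$param2)
  }
  if (any(ga)) {
    p <- dist_native_params("gamma", mean[ga], cv[ga])
    out[ga] <- stats::pgamma(q[ga], shape = p$param1, scale = p$param2)
  }
  out
}

#' Intake distribution quantile function
#'
#' @param p Probability in [0, 1]; vectorised.
#' @inheritParams dist_from_mean_cv
#' @export
qintake <- function(p, family, mean, cv) {
  check_family(family)
  n <- max(length(p), length(family), length(mean), length(cv))
  p <- rep_len(p, n); family <- rep_len(family, n)
  mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  out <- numeric(n)
  pm <- cv <= point_mass_cv
  out[pm] <- mean[pm]
  ln <- !pm & family == "lognormal"
  ga <- !pm & family == "gamma"
  if (any(ln)) {
    pr <- dist_native_params("lognormal", mean[ln], cv[ln])
    out[ln] <- stats::qlnorm(p[ln], pr$param1, pr$param2)
  }
  if (any(ga)) {
    pr <- dist_native_params("gamma", mean[ga], cv[ga])
    out[ga] <- stats::qgamma(p[ga], shape = pr$param1, scale = pr$param2)
  }
  out
}

#' Intake distribution density
#'
#' @param x Intake value (units/day); vectorised.
#' @inheritParams dist_from_mean_cv
#' @export
dintake <- function(x, family, mean, cv) {
  check_family(family)
  n <- max(length(x), length(family), length(mean), length(cv))
  x <- rep_len(x, n); family <- rep_len(family, n)
  mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  out <- numeric(n)
  ln <- family == "lognormal"
  if (any(ln)) {
    p <- dist_native_params("lognormal", mean[ln], cv[ln])
    out[ln] <- stats::dlnorm(x[ln], p$param1, p$param2)
  }
  if (any(!ln)) {
    p <- dist_native_params("gamma", mean[!ln], cv[!ln])
    out[!ln] <- stats::dgamma(x[!ln], shape = p$param1, scale = p$param2)
  }
  out
}

#' Draw random intakes (used by sampling oracles)
#'
#' @param n Number of draws.
#' @inheritParams dist_from_mean_cv
#' @export
rintake <- function(n, family, mean, cv) {
  check_family(family)
  if (cv <= point_mass_cv) return(rep(mean, n))
  p <- dist_native_params(family, mean, cv)
  if (family == "lognormal") stats::rlnorm(n, p$param1, p$param2)
  else stats::rgamma(n, shape = p$param1, scale = p$param2)
}
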