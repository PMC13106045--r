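# Probability approach: prevalence of inadequacy is the expectation of the
# requirement-exceedance risk curve over the usual-intake distribution.
# Excess intake is exceedance of the tolerable upper level (UL).

REQ_FAMILIES <- c("normal", "lognormal")

#' Risk of inadequacy at a given intake level
#'
#' The risk curve is `P(requirement > x)` for a requirement distribution
#' centred on the harmonised average requirement (AR).  The requirement is
#' normal by default; a lognormal (right-skewed) requirement, parameterised
#' so that its mean is the AR, is used where requirements are skewed
#' (iron in menstruating women).  The normal form is used untruncated: for
#' `req_cv <= 0.25` the mass below zero is negligible (< 1e-15).
#'
#' @param x Intake level (units/day); vectorised.
#' @param ar Average requirement (units/day), > 0.
#' @param req_cv Requirement CV; default 0.10, the conventional value for
#'   the probability approach.
#' @param req_family `"normal"` or `"lognormal"`.
#' @return `P(requirement > x)`, monotone non-increasing in `x`.
#' @export
risk_inadequate <- function(x, ar, req_cv = 0.1, req_family = "normal") {
  req_family <- match.arg(req_family, REQ_FAMILIES)
  if (any(!is.finite(ar) | ar <= 0)) rlang::abort("average requirement must be > 0")
  if (any(!is.finite(req_cv) | req_cv <= 0)) rlang::abort("requirement cv must be > 0")
  if (req_family == "normal") {
    stats::pnorm(x, mean = ar, sd = req_cv * ar, lower.tail = FALSE)
  } else {
    s2 <- log1p(req_cv^2)
    stats::plnorm(x, log(ar) - s2 / 2, sqrt(s2), lower.tail = FALSE)
  }
}

# scalar core: integrate f_intake(x) * P(req > x) over bounded support
prev_inadequate_one <- function(family, mean, cv, ar, req_cv, req_family,
                                label = NULL) {
  # degenerate intake: all mass at the mean
  if (cv <= point_mass_cv) {
    return(risk_inadequate(mean, ar, req_cv, req_family))
  }
  # degenerate requirement: EAR cut-point limit
  if (req_cv <= point_mass_cv) {
    return(pintake(ar, family, mean, cv))
  }
  upper <- qintake(1 - 1e-9, family, mean, cv)
  res <- tryCatch(
    stats::integrate(
      function(x) dintake(x, family, mean, cv) *
        risk_inadequate(x, ar, req_cv, req_family),
      lower = 0, upper = upper, abs.tol = 1e-8, subdivisions = 500L
    ),
    error = function(e) {
      rlang::abort(paste0(
        "probability-approach integration failed",
        if (!is.null(label)) paste0(" for stratum ", label),
        ": ", conditionMessage(e)
      ))
    }
  )
  min(max(res$value, 0), 1)
}

#' Prevalence of inadequate intake (probability approach)
#'
#' Computes `integral f_intake(x) * P(requirement > x) dx` by adaptive
#' quadrature on the bounded support `(0, Q(1 - 1e-9))`, assuming intake and
#' requirement are independent within a stratum.  All arguments are
#' vectorised and recycled.
#'
#' @inheritParams dist_from_mean_cv
#' @inheritParams risk_inadequate
#' @param label Optional stratum identifiers used in error messages.
#' @return Prevalence in [0, 1].
#' @export
prev_inadequate <- function(family, mean, cv, ar, req_cv = 0.1,
                            req_family = "normal", label = NULL) {
  check_family(family)
  n <- max(length(family), length(mean), length(cv), length(ar),
           length(req_cv), length(req_family))
  family <- rep_len(family, n); mean <- rep_len(mean, n); cv <- rep_len(cv, n)
  ar <- rep_len(ar, n); req_cv <- rep_len(req_cv, n)
  req_family <- rep_len(req_family, n)
  label <- if (is.null(label)) rep_len(list(NULL), n) else rep_len(label, n)
  vapply(seq_len(n), function(i) {
    prev_inadequate_one(family[i], mean[i], cv[i], ar[i], req_cv[i],
                        req_family[i], label[[i]])
  }, numeric(1))
}

#' Prevalence of excess intake (UL exceedance)
#'
#' The fraction of the stratum whose usual intake exceeds the tolerable
#' upper level: `1 - F_intake(ul)`.  Only nutrients with a harmonised UL are
#' assessed; a missing `ul` (`NA`) returns `NA` ("not assessed"), never 0 —
#' absence of a UL is not evidence of zero risk.
#'
#' @inheritParams dist_from_mean_cv
#' @param ul Tolerable upper level of intake (units/day), or `NA` if the
#'   nutrient has no harmonised UL.
#' @return Exceedance fraction in [0, 1], or `NA` where not assessed.
#' @export
prev_excess <- function(family, mean, cv, ul) {
  check_family(family)
  n <- max(length(family), length(mean), length(cv), length(ul))
  family <- rep_len(family, n); mean <- rep_len(mean, n)
  cv <- rep_len(cv, n); ul <- rep_len(ul, n)
  if (any(!is.na(ul) & ul <= 0)) rlang::abort("tolerable upper level must be > 0")
  out <- rep(NA_real_, n)
  ok <- !is.na(ul)
  out[ok] <- 1 - pintake(ul[ok], family[ok], mean[ok], cv[ok])
  out
}
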