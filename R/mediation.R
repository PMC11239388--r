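# Two-step mediation MR: decompose the total exposure->outcome effect into
# the mediator pathway and the direct remainder.

#' Two-step mediation Mendelian randomization
#'
#' Given three univariable MR estimates — the total effect `alpha`
#' (exposure -> outcome), `beta1` (exposure -> mediator) and `beta2`
#' (mediator -> outcome), each with its SE — computes:
#' \itemize{
#'   \item indirect effect `beta1 * beta2`, delta-method
#'     `se^2 = beta1^2 se(beta2)^2 + beta2^2 se(beta1)^2`
#'     (plus the `se1^2 se2^2` cross term when `second_order = TRUE`);
#'   \item direct effect `alpha - beta1*beta2`,
#'     `se^2 = se(alpha)^2 + se(indirect)^2`;
#'   \item proportion mediated `beta1*beta2 / alpha` with the ratio
#'     delta-method SE, normal CI and a two-sided normal p-value for
#'     proportion != 0.
#' }
#' The three inputs are assumed independent (non-overlapping GWAS samples).
#' A proportion outside `[0, 1]` (inconsistent mediation: pathways of
#' opposite sign, or an indirect effect exceeding the total) is returned
#' with a warning flag, not an error.
#'
#' @param alpha,beta1,beta2 each a numeric vector `c(estimate, se)` or a
#'   list with elements `beta` (or `estimate`) and `se`; an `mr_estimate`
#'   also works.
#' @param level confidence level (default 0.95).
#' @param second_order include the second-order `se1^2 se2^2` term in the
#'   product variance (default `FALSE`, the standard first-order form).
#' @return A `mediation_result`: list with `alpha`, `beta1`, `beta2` (each
#'   `estimate`/`se`), `indirect`, `direct` (each `estimate`/`se`),
#'   `proportion` (`estimate`, `se`, `ci_low`, `ci_high`, `pval`),
#'   `warning` (`NA` or `"inconsistent_mediation"`), `level`.
#' @export
two_step_mediation <- function(alpha, beta1, beta2, level = 0.95,
                               second_order = FALSE) {
  a <- as_effect(alpha, "alpha")
  b1 <- as_effect(beta1, "beta1")
  b2 <- as_effect(beta2, "beta2")
  if (a$estimate == 0) stopf("two_step_mediation: alpha = 0, proportion undefined")

  ind <- b1$estimate * b2$estimate
  var_ind <- b1$estimate^2 * b2$se^2 + b2$estimate^2 * b1$se^2
  if (second_order) var_ind <- var_ind + b1$se^2 * b2$se^2
  se_ind <- sqrt(var_ind)

  dir <- a$estimate - ind
  se_dir <- sqrt(a$se^2 + var_ind)

  prop <- ind / a$estimate
  # delta-method variance of the ratio, in the form stable at ind = 0:
  # var = var_ind / a^2 + ind^2 var_a / a^4
  se_prop <- sqrt(var_ind / a$estimate^2 + ind^2 * a$se^2 / a$estimate^4)
  crit <- z_crit(level)
  prop_p <- if (se_prop > 0) norm_pval(prop, se_prop) else as.numeric(prop == 0)

  structure(list(
    alpha = a, beta1 = b1, beta2 = b2,
    indirect = list(estimate = ind, se = se_ind),
    direct = list(estimate = dir, se = se_dir),
    proportion = list(estimate = prop, se = se_prop,
                      ci_low = prop - crit * se_prop,
                      ci_high = prop + crit * se_prop,
                      pval = prop_p),
    warning = if (prop < 0 || prop > 1) "inconsistent_mediation" else NA_character_,
    level = level), class = "mediation_result")
}

as_effect <- function(x, what) {
  if (inherits(x, "mr_estimate")) return(list(estimate = x$beta, se = x$se))
  if (is.list(x)) {
    est <- x$beta %||% x$estimate
    if (is.null(est) || is.null(x$se)) stopf("%s: need estimate/beta and se", what)
    return(list(estimate = est, se = x$se))
  }
  if (is.numeric(x) && length(x) == 2) {
    return(list(estimate = x[[1]], se = x[[2]]))
  }
  stopf("%s: supply c(estimate, se), a list(beta=, se=), or an mr_estimate", what)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation MR (log-odds scale)\n")
  cat(sprintf("  total (alpha)    = %.4f (se %.4f)\n", x$alpha$estimate, x$alpha$se))
  cat(sprintf("  indirect (b1*b2) = %.4f (se %.4f)\n",
              x$indirect$estimate, x$indirect$se))
  cat(sprintf("  direct           = %.4f (se %.4f)\n",
              x$direct$estimate, x$direct$se))
  cat(sprintf("  proportion mediated = %.1f%% [%.1f%%, %.1f%%], p = %.3g\n",
              100 * x$proportion$estimate, 100 * x$proportion$ci_low,
              100 * x$proportion$ci_high, x$proportion$pval))
  if (!is.na(x$warning)) cat(sprintf("  warning: %s\n", x$warning))
  invisible(x)
}
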