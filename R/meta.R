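# Inverse-variance meta-analysis of log odds ratios across datasets
# (discovery + replication pooling).

#' Standard error of a log-OR from a printed confidence interval
#'
#' `se = (ln ci_high - ln ci_low) / (2 z)` with `z` the two-sided normal
#' quantile at `level`. Lets published OR (CI) triplets feed the meta and
#' mediation machinery.
#'
#' @param ci_low,ci_high OR-scale confidence bounds, `0 < ci_low < ci_high`.
#' @param level the CI's confidence level (default 0.95).
#' @return SE of the log-OR.
#' @export
ci_to_se <- function(ci_low, ci_high, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (any(ci_low <= 0) || any(ci_low >= ci_high)) {
    stopf("ci_to_se: need 0 < ci_low < ci_high")
  }
  (log(ci_high) - log(ci_low)) / (2 * z_crit(level))
}

#' Build a meta-analysis input table
#'
#' @param label study labels.
#' @param beta,se log-OR estimates and SEs; alternatively supply
#'   `or`, `ci_low`, `ci_high` (converted via [ci_to_se()]).
#' @param or,ci_low,ci_high OR-scale triplets.
#' @param level confidence level of the supplied CIs.
#' @return Data frame with `label`, `beta`, `se`.
#' @export
meta_input <- function(label, beta = NULL, se = NULL,
                       or = NULL, ci_low = NULL, ci_high = NULL,
                       level = 0.95) {
  if (is.null(beta)) {
    stopifnot(!is.null(or), !is.null(ci_low), !is.null(ci_high))
    beta <- log(or)
    se <- ci_to_se(ci_low, ci_high, level)
  }
  if (any(se <= 0)) stopf("meta_input: se must be > 0")
  data.frame(label = label, beta = beta, se = se, stringsAsFactors = FALSE)
}

meta_core <- function(beta, se2, model, level) {
  w <- 1 / se2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  crit <- z_crit(level)
  list(model = model, beta = b, se = s,
       ci_low = b - crit * s, ci_high = b + crit * s,
       pval = norm_pval(b, s))
}

# Across-study Q against the fixed-effect center.
meta_q <- function(beta, se) {
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - b)^2)
  df <- length(beta) - 1
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = if (q > 0) max(0, (q - df) / q) else 0),
            class = "heterogeneity_result")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools log-OR estimates with weights `1/se^2`; across-study Cochran Q with
#' `k - 1` df; normal CI and p.
#'
#' @param studies data frame with `beta`, `se` (see [meta_input()]).
#' @param level confidence level.
#' @return A `meta_result`: list with `model`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `het` (a `heterogeneity_result`), `k`, `level`.
#' @export
meta_fixed <- function(studies, level = 0.95) {
  stopifnot(is.data.frame(studies), all(c("beta", "se") %in% names(studies)))
  k <- nrow(studies)
  if (k < 2) stopf("meta_fixed: at least 2 studies required, got %d", k)
  res <- meta_core(studies$beta, studies$se^2, "fixed", level)
  res$het <- meta_q(studies$beta, studies$se)
  res$k <- k
  res$level <- level
  res$tau2 <- 0
  structure(res, class = "meta_result")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of between-study variance
#' `tau^2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with fixed-effect
#' weights `w = 1/se^2`, then pooling with weights `1/(se^2 + tau^2)`.
#' Reduces to [meta_fixed()] when `Q <= df`.
#'
#' @inheritParams meta_fixed
#' @return A `meta_result` with `model = "random_dl"` and the `tau2` used.
#' @export
meta_random_dl <- function(studies, level = 0.95) {
  stopifnot(is.data.frame(studies), all(c("beta", "se") %in% names(studies)))
  k <- nrow(studies)
  if (k < 2) stopf("meta_random_dl: at least 2 studies required, got %d", k)
  het <- meta_q(studies$beta, studies$se)
  w <- 1 / studies$se^2
  tau2 <- max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  res <- meta_core(studies$beta, studies$se^2 + tau2, "random_dl", level)
  res$het <- het
  res$k <- k
  res$level <- level
  res$tau2 <- tau2
  structure(res, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Meta-analysis (%s, k = %d): OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$model, x$k, exp(x$beta), exp(x$ci_low), exp(x$ci_high), x$pval))
  cat(sprintf("  between-study Q = %.2f (df %d, p = %.3g), tau2 = %.4g\n",
              x$het$q, x$het$df, x$het$pval, x$tau2))
  invisible(x)
}
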