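# Causal-effect estimators for harmonized two-sample MR data.
#
# All estimators operate on the log-odds (or outcome-unit) scale; odds
# ratios appear only at the reporting boundary via exp().

mr_estimate <- function(method, beta, se, n_snp, level = 0.95,
                        df = Inf, pval = NULL) {
  crit <- if (is.finite(df)) stats::qt((1 + level) / 2, df) else z_crit(level)
  if (is.null(pval)) {
    pval <- if (is.finite(df)) 2 * stats::pt(-abs(beta / se), df) else norm_pval(beta, se)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval, n_snp = n_snp, level = level),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, exp(x$beta), exp(x$ci_low), exp(x$ci_high),
              x$pval, x$n_snp))
  invisible(x)
}

#' Coerce an MR estimate (or list of them) to a one-row data frame
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @return data frame with method, nsnp, beta, se, or, ci_low, ci_high, pval.
#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             or = exp(x$beta), or_ci_low = exp(x$ci_low),
             or_ci_high = exp(x$ci_high), pval = x$pval,
             stringsAsFactors = FALSE)
}

# Per-SNP Wald ratios and their first-order inverse-variance weights.
ratio_stats <- function(p) {
  r <- p$beta_out / p$beta_exp
  w <- p$beta_exp^2 / p$se_out^2   # 1 / first-order var(r) = 1/(se_out^2/beta_exp^2)
  list(r = r, w = w)
}

#' Single-SNP Wald ratio estimate
#'
#' `beta = beta_out / beta_exp` with first-order delta-method
#' `se = se_out / |beta_exp|`; normal CI and p-value.
#'
#' @param pair one harmonized pair: a list or one-row data frame with
#'   `beta_exp`, `beta_out`, `se_out` (and optionally `snp_id`).
#' @param level confidence level (default 0.95).
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(pair, level = 0.95) {
  if (is.data.frame(pair)) pair <- as.list(pair[1, ])
  if (is.na(pair$beta_exp) || pair$beta_exp == 0) {
    stopf("wald_ratio: beta_exp must be nonzero")
  }
  mr_estimate("wald_ratio",
              beta = pair$beta_out / pair$beta_exp,
              se = pair$se_out / abs(pair$beta_exp),
              n_snp = 1L, level = level)
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' through the origin with weights `1/se_out^2`:
#' `beta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`. Under `"fixed"`,
#' `se = 1/sqrt(sum(bx^2/sy^2))`; under `"multiplicative_random"` (the
#' default) that SE is inflated by the residual standard deviation, floored
#' at 1 so it never deflates. p-values are two-sided normal.
#'
#' @param h a `harmonized_set` (or data frame of pairs).
#' @param re_mode `"multiplicative_random"` or `"fixed"`.
#' @param level confidence level.
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
mr_ivw <- function(h, re_mode = c("multiplicative_random", "fixed"),
                   level = 0.95) {
  re_mode <- match.arg(re_mode)
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 2) stopf("mr_ivw: at least 2 SNPs required, got %d", n)
  w <- 1 / p$se_out^2
  sxx <- sum(w * p$beta_exp^2)
  beta <- sum(w * p$beta_exp * p$beta_out) / sxx
  se <- 1 / sqrt(sxx)
  if (re_mode == "multiplicative_random") {
    resid_sd <- sqrt(sum(w * (p$beta_out - beta * p$beta_exp)^2) / (n - 1))
    se <- se * max(1, resid_sd)
  }
  mr_estimate("ivw", beta = beta, se = se, n_snp = n, level = level)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting all pairs so
#' `beta_exp >= 0`. The slope estimates the causal effect; a nonzero
#' intercept indicates directional horizontal pleiotropy. SEs come from the
#' WLS covariance scaled by the residual SD floored at 1; p-values use the
#' t distribution with `n - 2` df.
#'
#' @inheritParams mr_ivw
#' @return An `egger_result`: list with `slope` (an `mr_estimate`, method
#'   `"egger"`) and `intercept` (`estimate`, `se`, `pval`).
#' @export
mr_egger <- function(h, level = 0.95) {
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 3) stopf("mr_egger: at least 3 SNPs required, got %d", n)
  flip <- sign(p$beta_exp)
  flip[flip == 0] <- 1
  bx <- p$beta_exp * flip
  by <- p$beta_out * flip
  w <- 1 / p$se_out^2
  # closed-form weighted regression with intercept
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  inter <- (sxx * swy - swx * sxy) / det
  resid <- by - inter - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (n - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_inter <- sqrt(sxx / det) * infl
  structure(list(
    slope = mr_estimate("egger", beta = slope, se = se_slope, n_snp = n,
                        level = level, df = n - 2),
    intercept = list(estimate = inter, se = se_inter,
                     pval = 2 * stats::pt(-abs(inter / se_inter), n - 2))),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.5f (se %.5f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pval))
  invisible(x)
}

# Interpolated weighted median of ratios r with weights w.
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  n <- length(r)
  if (cum[n] <= 0.5) return(r[n])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

# Parametric bootstrap SE for a point-estimator of (bx, by) pairs.
bootstrap_se <- function(p, point_fun, n_boot, seed) {
  if (is.null(seed)) stopf("a bootstrap seed is required (no silent nondeterminism)")
  n <- nrow(p)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, p$beta_exp, p$se_exp)
      by <- stats::rnorm(n, p$beta_out, p$se_out)
      point_fun(bx, by)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimate
#'
#' The weighted median of per-SNP Wald ratios, with weights equal to the
#' inverse first-order ratio variance (`beta_exp^2 / se_out^2`), linearly
#' interpolated between order statistics at cumulative normalized weight
#' 0.5. Consistent when instruments carrying at least half the weight are
#' valid. SE by seeded parametric bootstrap (exposure and outcome effects
#' resampled from their sampling distributions); normal CI and p.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL, level = 0.95) {
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 3) stopf("mr_weighted_median: at least 3 SNPs required, got %d", n)
  rs <- ratio_stats(p)
  beta <- weighted_median_point(rs$r, rs$w)
  se <- bootstrap_se(p, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / p$se_out^2)
  }, n_boot, seed)
  mr_estimate("weighted_median", beta = beta, se = se, n_snp = n, level = level)
}

# Kernel-density mode of ratios with weights w (normalized) and a
# modified-Silverman bandwidth scaled by phi.
mode_point <- function(r, w, phi) {
  if (max(r) - min(r) == 0) return(r[1])
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) / length(r)^(1 / 5)
  h <- max(1e-8, s * phi)
  d <- stats::density(r, weights = w / sum(w), bw = h)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple and weighted)
#'
#' The mode of the kernel-smoothed density of per-SNP Wald ratios (normal
#' kernel; bandwidth `phi` times a modified-Silverman scale
#' `0.9 * min(sd, mad) * n^{-1/5}`). The weighted variant weights each ratio
#' by its inverse first-order variance; the simple variant weights equally.
#' Consistent when the largest group of instruments sharing a ratio value
#' is valid (ZEMPA). SE by seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param variant `"weighted"` or `"simple"`.
#' @param bandwidth_phi bandwidth multiplier (default 1).
#' @return An `mr_estimate` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(h, variant = c("weighted", "simple"), bandwidth_phi = 1,
                    n_boot = 1000, seed = NULL, level = 0.95) {
  variant <- match.arg(variant)
  stopifnot(bandwidth_phi > 0)
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 3) stopf("mr_mode: at least 3 SNPs required, got %d", n)
  rs <- ratio_stats(p)
  w <- if (variant == "weighted") rs$w else rep(1, n)
  beta <- mode_point(rs$r, w, bandwidth_phi)
  se <- bootstrap_se(p, function(bx, by) {
    wb <- if (variant == "weighted") bx^2 / p$se_out^2 else rep(1, n)
    mode_point(by / bx, wb, bandwidth_phi)
  }, n_boot, seed)
  mr_estimate(if (variant == "weighted") "weighted_mode" else "simple_mode",
              beta = beta, se = se, n_snp = n, level = level)
}
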