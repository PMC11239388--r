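# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (r_j - b)^2` over per-SNP Wald ratios `r_j` with first-order
#' inverse-variance weights `w_j = beta_exp^2 / se_out^2`, centered on the
#' fixed-effect IVW estimate `b` computed with the same weights; upper-tail
#' chi-square p with `n - 1` df, and `I^2 = max(0, (Q - df)/Q)`.
#'
#' @inheritParams mr_ivw
#' @return A `heterogeneity_result`: list with `q`, `df`, `pval`, `i2`.
#' @export
cochran_q <- function(h) {
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 2) stopf("cochran_q: at least 2 SNPs required, got %d", n)
  rs <- ratio_stats(p)
  b <- sum(rs$w * rs$r) / sum(rs$w)
  q <- sum(rs$w * (rs$r - b)^2)
  df <- n - 1
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = if (q > 0) max(0, (q - df) / q) else 0),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran Q = %.2f on %d df, p = %.3g, I2 = %.1f%%\n",
              x$q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept triple from [mr_egger()]: a nonzero intercept indicates
#' that the instruments' average pleiotropic effect on the outcome differs
#' from zero. Two-sided t p-value with `n - 2` df.
#'
#' @inheritParams mr_ivw
#' @return List with `estimate`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  mr_egger(h)$intercept
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect dropping each SNP in turn, to detect single
#' variants driving the result.
#'
#' @inheritParams mr_ivw
#' @param re_mode IVW residual mode, as in [mr_ivw()].
#' @return Data frame, one row per retained SNP in input order:
#'   `dropped_snp_id`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `nsnp`.
#' @export
leave_one_out <- function(h, re_mode = c("multiplicative_random", "fixed"),
                          level = 0.95) {
  re_mode <- match.arg(re_mode)
  p <- harmonized_pairs(h)
  n <- nrow(p)
  if (n < 3) stopf("leave_one_out: at least 3 SNPs required, got %d", n)
  rows <- lapply(seq_len(n), function(i) {
    est <- mr_ivw(p[-i, , drop = FALSE], re_mode = re_mode, level = level)
    data.frame(dropped_snp_id = p$snp_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               nsnp = est$n_snp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-SNP (forest-plot) estimates
#'
#' Wald ratio per retained SNP, in input order. SNPs with `beta_exp = 0`
#' are reported with `NA` effect and a flag instead of aborting the batch.
#'
#' @inheritParams mr_ivw
#' @return Data frame with `snp_id`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `flag` (`NA` or `"zero_exposure_beta"`).
#' @export
single_snp <- function(h, level = 0.95) {
  p <- harmonized_pairs(h)
  if (nrow(p) < 1) stopf("single_snp: empty harmonized set")
  rows <- lapply(seq_len(nrow(p)), function(i) {
    if (is.na(p$beta_exp[i]) || p$beta_exp[i] == 0) {
      return(data.frame(snp_id = p$snp_id[i], beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                        flag = "zero_exposure_beta", stringsAsFactors = FALSE))
    }
    est <- wald_ratio(as.list(p[i, ]), level = level)
    data.frame(snp_id = p$snp_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
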