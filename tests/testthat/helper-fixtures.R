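# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no stored data files.

# A small valid sumstats data frame; fields overridable per test.
make_records <- function(n = 5, ...) {
  over <- list(...)
  df <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = rep("1", n),
    pos = seq_len(n) * 1e6,
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.1, 0.45, length.out = n),
    beta = seq(0.05, 0.15, length.out = n),
    se = rep(0.01, n),
    pval = rep(1e-8, n),
    n = rep(1e5, n),
    stringsAsFactors = FALSE
  )
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_table <- function(n = 5, trait_type = "binary", ...) {
  sumstats_table(make_records(n, ...), trait_type = trait_type)
}

# Harmonized-pairs frame straight from effect vectors (already aligned).
make_pairs <- function(beta_exp, beta_out, se_exp = rep(0.01, length(beta_exp)),
                       se_out = rep(0.01, length(beta_exp))) {
  data.frame(snp_id = sprintf("rs%03d", seq_along(beta_exp)),
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             stringsAsFactors = FALSE)
}

# Random harmonized instance for oracle-equivalence checks.
random_pairs <- function(n) {
  make_pairs(beta_exp = stats::runif(n, 0.02, 0.2) * sample(c(-1, 1), n, TRUE),
             beta_out = stats::rnorm(n, 0, 0.02),
             se_exp = stats::runif(n, 0.002, 0.01),
             se_out = stats::runif(n, 0.002, 0.01))
}

# --- independent oracles -------------------------------------------------

# Origin-constrained WLS via lm(); the generic solver the IVW estimator
# must agree with.
oracle_ivw_fixed <- function(p) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = p, weights = 1 / p$se_out^2)
  s <- summary(fit)
  sigma <- s$sigma
  list(beta = unname(stats::coef(fit)),
       se_fixed = unname(s$coefficients[1, 2] / sigma))
}

# WLS with intercept via lm(), pairs pre-oriented to beta_exp >= 0.
oracle_egger <- function(p) {
  flip <- ifelse(p$beta_exp < 0, -1, 1)
  d <- data.frame(bx = p$beta_exp * flip, by = p$beta_out * flip)
  fit <- stats::lm(by ~ bx, data = d, weights = 1 / p$se_out^2)
  s <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se_unscaled = unname(s$coefficients[, 2] / s$sigma),
       sigma = s$sigma)
}

# Interpolated weighted quantile at 0.5 found by root-finding on the
# piecewise-linear CDF rather than index arithmetic.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  if (cum[length(r)] <= 0.5) return(r[length(r)])
  cdf <- stats::approxfun(r, cum, rule = 2, ties = "ordered")
  stats::uniroot(function(x) cdf(x) - 0.5, range(r), tol = 1e-14)$root
}

# Dense grid search over the weighted normal-kernel mixture density.
oracle_mode <- function(r, w, h) {
  w <- w / sum(w)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, r, h)), numeric(1))
  grid[which.max(dens)]
}

# Strip volatile provenance so two reports can be compared for identity.
report_fingerprint <- function(rep) {
  rep$provenance$timestamp <- NULL
  rep
}
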