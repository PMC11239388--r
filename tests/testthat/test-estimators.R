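test_that("wald ratio: division, sign propagation, null numerator", {
  w <- wald_ratio(list(beta_exp = 0.1, beta_out = 0.05, se_out = 0.01))
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  neg <- wald_ratio(list(beta_exp = -0.1, beta_out = 0.05, se_out = 0.01))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.1)
  null <- wald_ratio(list(beta_exp = 0.2, beta_out = 0, se_out = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(wald_ratio(list(beta_exp = 0, beta_out = 0.1, se_out = 0.01)),
               "nonzero")
})

test_that("IVW: consensus, degenerate equivalence, WLS oracle agreement", {
  # identical ratios -> that ratio exactly, whatever the weights
  p <- make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15),
                  se_out = c(0.01, 0.02, 0.005))
  expect_equal(mr_ivw(p)$beta, 0.5, tolerance = 1e-12)

  # duplicated single SNP: point estimate equals the Wald ratio
  dup <- make_pairs(c(0.1, 0.1), c(0.04, 0.04))
  expect_equal(mr_ivw(dup)$beta,
               wald_ratio(list(beta_exp = 0.1, beta_out = 0.04,
                               se_out = 0.01))$beta)
  expect_error(mr_ivw(make_pairs(0.1, 0.05)), "at least 2")

  set.seed(31)
  for (rep in 1:5) {
    p <- random_pairs(sample(5:12, 1))
    o <- oracle_ivw_fixed(p)
    fixed <- mr_ivw(p, re_mode = "fixed")
    expect_equal(fixed$beta, o$beta, tolerance = 1e-10)
    expect_equal(fixed$se, o$se_fixed, tolerance = 1e-10)
    # multiplicative random effects never deflates the fixed SE
    expect_gte(mr_ivw(p, re_mode = "multiplicative_random")$se, fixed$se)
  }
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  bx <- c(0.05, 0.08, 0.11, 0.15, 0.2)
  exact <- make_pairs(bx, 0.02 + 0.5 * bx)
  e <- mr_egger(exact)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept$estimate, 0.02, tolerance = 1e-10)

  through_origin <- make_pairs(bx, 0.5 * bx)
  e0 <- mr_egger(through_origin)
  expect_equal(e0$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(e0$intercept$pval, 1, tolerance = 1e-6)

  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1))), "at least 3")

  set.seed(32)
  for (rep in 1:5) {
    p <- random_pairs(sample(6:15, 1))
    o <- oracle_egger(p)
    e <- mr_egger(p)
    expect_equal(e$slope$beta, o$slope, tolerance = 1e-10)
    expect_equal(e$intercept$estimate, o$intercept, tolerance = 1e-10)
    infl <- max(1, o$sigma)
    expect_equal(e$intercept$se, o$se_unscaled[1] * infl, tolerance = 1e-10)
    expect_equal(e$slope$se, o$se_unscaled[2] * infl, tolerance = 1e-10)
  }
})

test_that("weighted median: plain median, consensus, interpolation oracle", {
  eq <- make_pairs(c(0.1, 0.1, 0.1), c(0.01, 0.05, 0.09))
  wm <- mr_weighted_median(eq, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.5, tolerance = 1e-12)  # equal weights: plain median

  cons <- make_pairs(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2),
                     se_exp = rep(1e-6, 3), se_out = rep(1e-6, 3))
  cwm <- mr_weighted_median(cons, n_boot = 100, seed = 1)
  expect_equal(cwm$beta, 0.5, tolerance = 1e-9)
  expect_lt(cwm$se, 1e-4)  # bootstrap SE collapses with the input SEs

  set.seed(33)
  for (rep in 1:5) {
    p <- random_pairs(7)
    rs <- list(r = p$beta_out / p$beta_exp, w = p$beta_exp^2 / p$se_out^2)
    expect_equal(mr_weighted_median(p, n_boot = 10, seed = 1)$beta,
                 oracle_weighted_median(rs$r, rs$w), tolerance = 1e-8)
  }
})

test_that("mode-based estimate: majority cluster, atoms, weight degeneracy", {
  maj <- make_pairs(rep(0.1, 4), c(0.05, 0.05, 0.05, 0.2))
  sm <- mr_mode(maj, variant = "simple", n_boot = 50, seed = 1)
  expect_equal(sm$beta, 0.5, tolerance = 0.05)  # pulled to the 0.5 cluster
  # grid-search oracle at the same bandwidth
  r <- maj$beta_out / maj$beta_exp
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) / length(r)^(1 / 5)
  expect_equal(sm$beta, oracle_mode(r, rep(1, 4), max(1e-8, s)),
               tolerance = 1e-3)

  atom <- make_pairs(c(0.1, 0.2, 0.5), c(0.05, 0.1, 0.25))
  for (phi in c(0.25, 1, 4)) {
    expect_equal(mr_mode(atom, "simple", bandwidth_phi = phi,
                         n_boot = 10, seed = 1)$beta, 0.5)
  }

  # equal weights: weighted and simple variants coincide
  eqw <- make_pairs(rep(0.1, 5), c(0.03, 0.04, 0.05, 0.06, 0.2))
  expect_equal(mr_mode(eqw, "weighted", n_boot = 10, seed = 1)$beta,
               mr_mode(eqw, "simple", n_boot = 10, seed = 1)$beta)
})

test_that("scale and unit equivariance hold for every estimator", {
  set.seed(34)
  p <- random_pairs(9)
  cc <- 2.7
  outcome_scaled <- p
  outcome_scaled$beta_out <- p$beta_out * cc
  outcome_scaled$se_out <- p$se_out * cc
  exposure_scaled <- p
  exposure_scaled$beta_exp <- p$beta_exp * cc
  exposure_scaled$se_exp <- p$se_exp * cc

  fits <- function(q) list(
    ivw = mr_ivw(q),
    egger = mr_egger(q)$slope,
    wm = mr_weighted_median(q, n_boot = 200, seed = 7),
    mode = mr_mode(q, "weighted", n_boot = 200, seed = 7))
  base <- fits(p); out_sc <- fits(outcome_scaled); exp_sc <- fits(exposure_scaled)
  for (m in names(base)) {
    expect_equal(out_sc[[m]]$beta, base[[m]]$beta * cc, tolerance = 1e-7)
    expect_equal(out_sc[[m]]$se, base[[m]]$se * cc, tolerance = 1e-7)
    expect_equal(exp_sc[[m]]$beta, base[[m]]$beta / cc, tolerance = 1e-7)
  }

  # IVW and weighted median stay inside the ratio envelope
  r <- p$beta_out / p$beta_exp
  expect_gte(base$ivw$beta, min(r)); expect_lte(base$ivw$beta, max(r))
  expect_gte(base$wm$beta, min(r)); expect_lte(base$wm$beta, max(r))
})

test_that("bootstrap SEs are seed-deterministic and seed-stable", {
  set.seed(35)
  p <- random_pairs(10)
  a <- mr_weighted_median(p, n_boot = 400, seed = 99)
  b <- mr_weighted_median(p, n_boot = 400, seed = 99)
  expect_identical(a$se, b$se)
  c2 <- mr_weighted_median(p, n_boot = 400, seed = 100)
  expect_false(identical(a$se, c2$se))
  # different seeds agree within Monte-Carlo error of the bootstrap SD
  mc <- a$se / sqrt(2 * (400 - 1))
  expect_lt(abs(a$se - c2$se), 6 * mc)
  expect_error(mr_weighted_median(p, n_boot = 10), "seed")
})

test_that("with strong pleiotropy-free instruments every method converges", {
  true_b <- 0.25
  for (noise in c(0.004, 0.001)) {
    set.seed(36)
    n <- 40
    gamma <- stats::runif(n, 0.05, 0.2)
    p <- make_pairs(beta_exp = gamma + stats::rnorm(n, 0, noise),
                    beta_out = true_b * gamma + stats::rnorm(n, 0, noise),
                    se_exp = rep(noise, n), se_out = rep(noise, n))
    h <- p
    ests <- c(mr_ivw(h)$beta, mr_egger(h)$slope$beta,
              mr_weighted_median(h, n_boot = 50, seed = 2)$beta,
              mr_mode(h, "weighted", n_boot = 50, seed = 2)$beta,
              mr_mode(h, "simple", n_boot = 50, seed = 2)$beta)
    tol <- if (noise == 0.004) 0.08 else 0.02
    expect_true(all(abs(ests - true_b) < tol))
  }
})
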