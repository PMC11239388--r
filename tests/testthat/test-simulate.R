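# Smaller-than-default configs keep the module tests fast; the full-scale
# stated world is exercised in test-acceptance.R.

test_that("identical seeds give bit-identical studies; configs validate", {
  cfg <- simulation_config(m_snps = 30, m_med_snps = 10, seed = 7)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(simulation_config(m_snps = 30, m_med_snps = 10, seed = 8))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))

  expect_error(simulation_config(m_snps = 2, seed = 1), "m_snps")
  expect_error(simulation_config(maf_range = c(0.4, 0.1), seed = 1), "maf_range")
  expect_error(simulation_config(maf_range = c(0, 0.5), seed = 1), "maf_range")
  expect_error(simulation_config(n_exp = 0, seed = 1), "sample sizes")
  expect_error(simulation_config(seed = 1, pleiotropy = list(type = "weird")))
})

test_that("generated tables satisfy all invariants and round-trip", {
  sim <- simulate_study(simulation_config(m_snps = 25, m_med_snps = 15, seed = 9))
  for (tab in list(sim$exposure, sim$mediator, sim$outcome)) {
    expect_s3_class(tab, "sumstats_table")
    expect_equal(nrow(attr(tab, "drop_log")), 0)  # nothing invalid generated
    expect_equal(nrow(tab), 40)
    expect_true(all(tab$se > 0))
    expect_true(all(tab$pval > 0 & tab$pval <= 1))
    expect_true(all(tab$effect_allele != tab$other_allele))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_sumstats(tab, path)
    back <- read_sumstats(path, trait_type = attr(tab, "trait_type"))
    expect_equal(back$beta, tab$beta, tolerance = 1e-12)
  }
  # shared SNP universe and truth bookkeeping
  expect_identical(sim$exposure$snp_id, sim$outcome$snp_id)
  expect_identical(sim$exposure$snp_id, sim$mediator$snp_id)
  tt <- sim$truth
  expect_equal(tt$theta_total, tt$theta_direct + tt$delta * tt$kappa)
  expect_equal(tt$proportion_mediated,
               tt$delta * tt$kappa / tt$theta_total)
  expect_equal(sum(tt$gamma != 0), 25)
  expect_equal(sum(tt$eta != 0), 15)
})

test_that("observed SEs scale as 1/sqrt(n) and null z-scores are standard normal", {
  base <- simulate_study(simulation_config(m_snps = 50, m_med_snps = 0,
                                           n_out = 1e5, seed = 10))
  big <- simulate_study(simulation_config(m_snps = 50, m_med_snps = 0,
                                          n_out = 4e5, seed = 10))
  # same seed -> same mafs, so the SE ratio is exactly sqrt(4)
  expect_equal(base$outcome$se / big$outcome$se, rep(2, 50), tolerance = 1e-12)

  null <- simulate_study(simulation_config(
    m_snps = 300, m_med_snps = 0, theta_direct = 0, delta = 0, kappa = 0,
    gamma_sd = 1e-9, gamma_floor = 0, seed = 11))
  z <- null$outcome$beta / null$outcome$se
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("the global null is recovered and pleiotropic SNPs are flagged", {
  sim <- simulate_study(simulation_config(
    m_snps = 60, m_med_snps = 0, theta_direct = 0, delta = 0, kappa = 0,
    seed = 12))
  expect_equal(nrow(sim$confounder_ann), 0)
  inst <- select_instruments(sim$exposure, ld = sim$ld)
  h <- harmonize(inst_table(inst, sim$exposure), sim$outcome)
  est <- mr_ivw(h)
  expect_lt(abs(est$beta), 3 * est$se)

  plei <- simulate_study(simulation_config(
    m_snps = 40, m_med_snps = 0, pleiotropy = list(type = "balanced", sd = 0.01),
    seed = 13))
  expect_equal(nrow(plei$confounder_ann), 40)
  expect_true(all(plei$confounder_ann$trait_label == "pleiotropy"))
  expect_setequal(plei$confounder_ann$snp_id,
                  names(plei$truth$pleiotropy)[plei$truth$pleiotropy != 0])
})

test_that("LD blocks are materialized and collapse to one SNP under clumping", {
  sim <- simulate_study(simulation_config(
    m_snps = 20, m_med_snps = 0,
    ld_blocks = list(list(size = 4, r2 = 0.9), list(size = 3, r2 = 0.8)),
    seed = 14))
  ids <- sim$exposure$snp_id
  expect_equal(sim$ld$r2[ids[1], ids[2]], 0.9)
  expect_equal(sim$ld$r2[ids[5], ids[7]], 0.8)
  expect_equal(sim$ld$r2[ids[1], ids[5]], 0)
  expect_true(all(diag(sim$ld$r2) == 1))
  # block members share one signal, so clumping keeps exactly one per block
  kept <- clump(sim$exposure, sim$ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(sum(kept %in% ids[1:4]), 1)
  expect_equal(sum(kept %in% ids[5:7]), 1)
  expect_equal(length(kept), 1 + 1 + 13)
})

test_that("null calibration machinery reports sane rejection rates", {
  cfg <- simulation_config(m_snps = 40, m_med_snps = 0, theta_direct = 0,
                           delta = 0, kappa = 0, seed = 200)
  cal <- simulate_null_calibration(cfg, n_reps = 60)
  expect_equal(cal$n_used, 60)
  expect_lt(cal$ivw_rate, 0.25)   # loose sanity bound at 60 reps
  expect_gt(cal$ivw_rate_se, 0)
  expect_lt(abs(cal$mean_ivw_beta), 0.02)
})
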