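test_that("F statistic is beta^2/se^2 and rejects nonpositive SE", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_equal(f_statistic(-0.3, 0.1), 9)
  expect_equal(f_statistic(c(0.1, -0.3), c(0.02, 0.1)), c(25, 9))
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("clumping keeps independent SNPs and resolves forced pairs", {
  tab <- make_table(3, pval = c(1e-8, 1e-7, 1e-6))
  expect_equal(clump(tab), c("rs001", "rs002", "rs003"))

  two <- make_table(2, chrom = "2", pos = c(1e6, 1e6 + 5e3),
                    pval = c(1e-6, 1e-9))
  ld <- ld_info(two$snp_id, matrix(c(1, 0.9, 0.9, 1), 2))
  expect_equal(clump(two, ld, r2_threshold = 0.001, window_kb = 10000),
               "rs002")  # smaller p wins, partner discarded
})

test_that("clumped sets match a brute-force pairwise check (block LD)", {
  set.seed(11)
  n <- 6
  rec <- make_records(n,
                      chrom = c("1", "1", "1", "2", "2", "2"),
                      pos = c(1e6, 1.2e6, 1.4e6, 5e6, 5.1e6, 5.2e6),
                      pval = stats::runif(n, 1e-10, 1e-6))
  r2 <- diag(n)
  r2[1:3, 1:3] <- 0.8; r2[4:6, 4:6] <- 0.6; diag(r2) <- 1
  tab <- sumstats_table(rec)
  ld <- ld_info(rec$snp_id, r2)
  kept <- clump(tab, ld, r2_threshold = 0.1, window_kb = 10000)
  # brute force: no retained pair violates, every dropped SNP conflicts
  # with a retained SNP of smaller p
  pv <- stats::setNames(rec$pval, rec$snp_id)
  pos <- stats::setNames(rec$pos, rec$snp_id)
  chr <- stats::setNames(rec$chrom, rec$snp_id)
  viol <- function(a, b) chr[a] == chr[b] &&
    abs(pos[a] - pos[b]) <= 1e7 && ld$r2[a, b] >= 0.1
  for (a in kept) for (b in kept) if (a != b) expect_false(viol(a, b))
  for (d in setdiff(rec$snp_id, kept)) {
    expect_true(any(vapply(kept, function(k)
      viol(d, k) && pv[k] < pv[d], logical(1))))
  }
})

test_that("clump is idempotent and lowering p threshold is monotone", {
  set.seed(12)
  n <- 40
  rec <- make_records(n,
                      chrom = as.character(rep(1:4, each = 10)),
                      pos = rep(seq(1e6, by = 2e6, length.out = 10), 4),
                      pval = stats::runif(n, 1e-12, 1e-2),
                      beta = stats::rnorm(n, 0, 0.1))
  r2 <- diag(n)
  for (b in 0:7) {
    i <- (b * 5 + 1):(b * 5 + 5)
    r2[i, i] <- 0.5; diag(r2) <- 1
  }
  tab <- sumstats_table(rec)
  ld <- ld_info(rec$snp_id, r2)
  kept <- clump(tab, ld, r2_threshold = 0.2, window_kb = 10000)
  sub <- sumstats_table(rec[rec$snp_id %in% kept, ])
  expect_equal(clump(sub, ld, r2_threshold = 0.2, window_kb = 10000), kept)

  thresholds <- c(1e-2, 1e-4, 1e-6, 1e-8)
  counts <- vapply(thresholds, function(pt) {
    tryCatch(nrow(select_instruments(tab, p_threshold = pt, ld = ld,
                                     r2_threshold = 0.2, f_min = 0.001)$records),
             error = function(e) 0L)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("select_instruments composes the three filters with full accounting", {
  expect_error(select_instruments(make_table(10, pval = rep(0.5, 10))),
               "no instruments")

  one <- make_table(1, pval = 1e-8, beta = 0.1, se = 0.02)
  set <- select_instruments(one)
  expect_equal(nrow(set$records), 1)
  expect_equal(unname(set$f_stats), 25)

  # 200-SNP oracle: re-apply the three filters without the greedy shortcut
  set.seed(13)
  n <- 200
  rec <- make_records(n,
                      snp_id = sprintf("rs%04d", sample(n)),
                      chrom = as.character(rep(1:10, each = 20)),
                      pos = rep(seq(1e6, by = 5e5, length.out = 20), 10),
                      beta = stats::rnorm(n, 0, 0.05),
                      se = stats::runif(n, 0.005, 0.02),
                      pval = 10^stats::runif(n, -12, -3))
  r2 <- diag(n)
  for (b in 0:19) {
    i <- (b * 10 + 1):(b * 10 + 10)
    r2[i, i] <- 0.4; diag(r2) <- 1
  }
  tab <- sumstats_table(rec)
  ld <- ld_info(tab$snp_id, r2[match(tab$snp_id, rec$snp_id),
                               match(tab$snp_id, rec$snp_id)])
  got <- select_instruments(tab, p_threshold = 5e-6, ld = ld,
                            r2_threshold = 0.2, window_kb = 10000, f_min = 10)

  oracle <- local({
    d <- as.data.frame(tab)
    d <- d[d$pval < 5e-6, ]
    d <- d[order(d$pval, d$snp_id), ]
    kept <- character(0)
    while (nrow(d) > 0) {
      top <- d[1, ]
      kept <- c(kept, top$snp_id)
      conflict <- d$chrom == top$chrom & abs(d$pos - top$pos) <= 1e7 &
        vapply(d$snp_id, function(s) ld$r2[s, top$snp_id] >= 0.2, logical(1))
      d <- d[!conflict & d$snp_id != top$snp_id, ]
    }
    keep_f <- vapply(kept, function(s) {
      row <- tab[tab$snp_id == s, ]
      (row$beta / row$se)^2 >= 10
    }, logical(1))
    kept[keep_f]
  })
  expect_equal(got$records$snp_id, oracle)
  # retained + excluded partition the input
  expect_setequal(c(got$records$snp_id, unique(got$exclusions$snp_id)),
                  tab$snp_id)
})

test_that("confounder filtering mirrors the 101 -> 56 instrument screen", {
  rec <- make_records(101, snp_id = sprintf("rs%04d", 1:101),
                      chrom = as.character(rep(1:22, length.out = 101)),
                      pos = seq(1e6, by = 3e7, length.out = 101),
                      beta = rep(0.1, 101), se = rep(0.02, 101),
                      pval = rep(1e-7, 101))
  inst <- select_instruments(sumstats_table(rec))
  expect_equal(nrow(inst$records), 101)
  ann <- data.frame(snp_id = sprintf("rs%04d", 1:45),
                    trait_label = rep(c("BMI", "weight", "smoking"), 15),
                    stringsAsFactors = FALSE)
  kept <- filter_confounders(inst, ann, c("BMI", "weight", "smoking", "obesity"))
  expect_equal(nrow(kept$records), 56)
  expect_equal(sum(grepl("^confounder:", kept$exclusions$reason)), 45)

  # disjoint trait list leaves the set untouched
  same <- filter_confounders(inst, ann, "height")
  expect_equal(same$records$snp_id, inst$records$snp_id)

  # a SNP flagged for two listed traits: dropped once, one exclusion per trait
  ann2 <- data.frame(snp_id = c("rs0001", "rs0001"),
                     trait_label = c("BMI", "smoking"), stringsAsFactors = FALSE)
  two <- filter_confounders(inst, ann2, c("BMI", "smoking"))
  expect_equal(nrow(two$records), 100)
  expect_equal(sum(two$exclusions$snp_id == "rs0001" &
                     grepl("^confounder:", two$exclusions$reason)), 2)
})
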