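# Summary-level GWAS simulator with a known exposure -> mediator -> outcome
# causal structure, for calibration and parameter-recovery studies.
#
# Effects are generated directly at the summary-statistic level (no
# individual genotypes): per-SNP true effects plus sampling noise with
# SE = 1/sqrt(2 maf (1-maf) n), the standard large-sample per-allele
# approximation. The three GWAS samples are non-overlapping by
# construction, matching the independence assumed by the mediation SEs.

#' Simulation configuration
#'
#' Describes the generating world: `m_snps` exposure instruments with
#' per-SNP effects `gamma_j` (normal, SD `gamma_sd`, absolute value floored
#' at `gamma_floor` so every instrument is usable), `m_med_snps`
#' mediator-specific instruments with effects `eta_j` (same scheme), and the
#' causal chain: exposure effect `gamma_j`; mediator effect
#' `delta * gamma_j` (inherited) or `eta_j` (mediator-specific); outcome
#' effect `theta_direct * gamma_j + kappa * delta * gamma_j + a_j` for
#' exposure instruments and `kappa * eta_j` for mediator instruments, with
#' `a_j` the per-SNP horizontal pleiotropy. Defaults mirror the effect
#' scale of a large biobank OSA/BMI/OA analysis: `theta_direct = 0.077`,
#' `delta = 0.113`, `kappa = 0.399` (so the implied total effect is
#' `0.077 + 0.113 * 0.399 = 0.122` and the implied proportion mediated
#' `0.369`), with around 100 instruments and GWAS sample sizes of 3e5.
#'
#' @param m_snps exposure instrument count (>= 3; default 100).
#' @param m_med_snps mediator-specific instrument count (default 100; set 0
#'   to disable the mediator arm).
#' @param maf_range uniform minor-allele-frequency bounds within (0, 0.5].
#' @param gamma_sd,gamma_floor SD and minimum |effect| of SNP->exposure
#'   effects (log-odds per allele).
#' @param eta_sd,eta_floor same for SNP->mediator-specific effects
#'   (mediator-SD per allele).
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param theta_direct exposure->outcome direct effect (log-odds).
#' @param delta exposure->mediator effect (mediator SD per log-odds).
#' @param kappa mediator->outcome effect (log-odds per mediator SD).
#' @param pleiotropy `list(type = "none")`, `list(type = "balanced",
#'   sd = )`, or `list(type = "directional", mean = , sd = )`; applies to
#'   the exposure instruments' outcome effects.
#' @param ld_blocks optional list of `list(size = , r2 = )` blocks; the
#'   first `sum(size)` exposure SNPs are laid out in tight genomic blocks
#'   sharing one causal signal, with the stated pairwise r^2 recorded in
#'   the returned [ld_info].
#' @param seed RNG seed (required; the whole study is a deterministic
#'   function of the config).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(m_snps = 100, m_med_snps = 100,
                              maf_range = c(0.05, 0.5),
                              gamma_sd = 0.03, gamma_floor = 0.015,
                              eta_sd = 0.03, eta_floor = 0.015,
                              n_exp = 3e5, n_med = 3e5, n_out = 3e5,
                              theta_direct = 0.077, delta = 0.113,
                              kappa = 0.399,
                              pleiotropy = list(type = "none"),
                              ld_blocks = NULL, seed) {
  if (missing(seed)) stopf("simulation_config: a seed is required")
  if (m_snps < 3) stopf("simulation_config: m_snps must be >= 3")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] >= maf_range[2]) {
    stopf("simulation_config: maf_range must be increasing within (0, 0.5]")
  }
  if (any(c(n_exp, n_med, n_out) <= 0)) stopf("sample sizes must be > 0")
  stopifnot(pleiotropy$type %in% c("none", "balanced", "directional"))
  structure(list(m_snps = m_snps, m_med_snps = m_med_snps,
                 maf_range = maf_range,
                 gamma_sd = gamma_sd, gamma_floor = gamma_floor,
                 eta_sd = eta_sd, eta_floor = eta_floor,
                 n_exp = n_exp, n_med = n_med, n_out = n_out,
                 theta_direct = theta_direct, delta = delta, kappa = kappa,
                 pleiotropy = pleiotropy, ld_blocks = ld_blocks,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# |effect| floored draws: sign * max(|N(0, sd)|, floor)
floored_normal <- function(m, sd, floor) {
  x <- stats::rnorm(m, 0, sd)
  sign(ifelse(x == 0, 1, sign(x))) * pmax(abs(x), floor)
}

allele_pairs <- c("A/G", "A/C", "T/G", "T/C", "C/T", "G/A", "A/T", "C/G")

#' Simulate a two-sample MR study with a mediator
#'
#' Generates exposure, mediator and outcome summary-statistics tables over a
#' shared SNP universe, an [ld_info] with the configured block structure, a
#' confounder annotation flagging pleiotropic SNPs (trait `"pleiotropy"`),
#' and the generating truth (including the implied total effect
#' `theta_total = theta_direct + delta * kappa` and proportion mediated
#' `delta * kappa / theta_total`).
#'
#' @param config a [simulation_config()].
#' @return A `simulated_study`: list with `exposure`, `mediator`, `outcome`
#'   ([sumstats_table]s), `ld`, `confounder_ann`, `truth`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  m <- cfg$m_snps
  mm <- cfg$m_med_snps
  m_tot <- m + mm
  ids <- sprintf("snp_%04d", seq_len(m_tot))

  # genomic layout: block members 10 kb apart, blocks/singletons 20 Mb
  # apart (beyond any clumping window), round-robin over 22 chromosomes
  block_id <- seq_len(m_tot)
  block_r2 <- rep(0, m_tot)
  if (!is.null(cfg$ld_blocks)) {
    at <- 1
    for (bi in seq_along(cfg$ld_blocks)) {
      blk <- cfg$ld_blocks[[bi]]
      span <- at:(at + blk$size - 1)
      if (max(span) > m) stopf("ld_blocks cover more SNPs than m_snps")
      block_id[span] <- -bi
      block_r2[span] <- blk$r2
      at <- at + blk$size
    }
  }
  ublocks <- unique(block_id)
  chrom <- character(m_tot); pos <- numeric(m_tot)
  for (k in seq_along(ublocks)) {
    members <- which(block_id == ublocks[k])
    chrom[members] <- as.character(((k - 1) %% 22) + 1)
    base <- 1e6 + ((k - 1) %/% 22) * 2e7
    pos[members] <- base + (seq_along(members) - 1) * 1e4
  }

  maf <- stats::runif(m_tot, cfg$maf_range[1], cfg$maf_range[2])
  # exposure instruments: gamma per *block* (members tag one signal)
  gamma <- numeric(m_tot)
  exp_blocks <- unique(block_id[seq_len(m)])
  gdraw <- floored_normal(length(exp_blocks), cfg$gamma_sd, cfg$gamma_floor)
  for (k in seq_along(exp_blocks)) gamma[block_id == exp_blocks[k]] <- gdraw[k]
  gamma[seq_len(m_tot) > m] <- 0
  # mediator-specific instruments
  eta <- numeric(m_tot)
  if (mm > 0) eta[(m + 1):m_tot] <- floored_normal(mm, cfg$eta_sd, cfg$eta_floor)

  # Horizontal pleiotropy on the exposure instruments. "Directional" means
  # directional relative to the exposure-increasing allele (the orientation
  # the Egger intercept is defined in), so the draw is aligned with
  # sign(gamma); for the balanced type this leaves the distribution
  # unchanged.
  a <- numeric(m_tot)
  pl <- cfg$pleiotropy
  if (pl$type == "balanced") {
    a[seq_len(m)] <- stats::rnorm(m, 0, pl$sd)
  } else if (pl$type == "directional") {
    sg <- sign(gamma[seq_len(m)])
    sg[sg == 0] <- 1
    a[seq_len(m)] <- sg * stats::rnorm(m, pl$mean, pl$sd)
  }

  true_exp <- gamma
  true_med <- cfg$delta * gamma + eta
  true_out <- cfg$theta_direct * gamma + cfg$kappa * true_med + a

  se_of <- function(n) 1 / sqrt(2 * maf * (1 - maf) * n)
  se_exp <- se_of(cfg$n_exp); se_med <- se_of(cfg$n_med); se_out <- se_of(cfg$n_out)
  obs_exp <- stats::rnorm(m_tot, true_exp, se_exp)
  obs_med <- stats::rnorm(m_tot, true_med, se_med)
  obs_out <- stats::rnorm(m_tot, true_out, se_out)

  alleles <- sample(allele_pairs, m_tot, replace = TRUE)
  ea <- sub("/.*", "", alleles); oa <- sub(".*/", "", alleles)
  eaf <- pmin(pmax(maf + stats::rnorm(m_tot, 0, 0.002), 1e-3), 1 - 1e-3)

  mk <- function(beta, se, n, label, type) {
    sumstats_table(data.frame(
      snp_id = ids, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-320), n = n,
      stringsAsFactors = FALSE),
      trait_label = label, trait_type = type,
      provenance = sprintf("simulated(seed=%d)", cfg$seed))
  }
  exposure <- mk(obs_exp, se_exp, cfg$n_exp, "simulated exposure", "binary")
  mediator <- mk(obs_med, se_med, cfg$n_med, "simulated mediator", "continuous")
  outcome <- mk(obs_out, se_out, cfg$n_out, "simulated outcome", "binary")

  r2m <- diag(m_tot)
  for (b in unique(block_id[block_id < 0])) {
    members <- which(block_id == b)
    r2m[members, members] <- block_r2[members[1]]
    diag(r2m)[members] <- 1
  }
  ld <- ld_info(ids, r2m)

  flagged <- ids[a != 0]
  confounder_ann <- data.frame(snp_id = flagged,
                               trait_label = rep("pleiotropy", length(flagged)),
                               stringsAsFactors = FALSE)

  theta_total <- cfg$theta_direct + cfg$delta * cfg$kappa
  truth <- list(theta_direct = cfg$theta_direct, delta = cfg$delta,
                kappa = cfg$kappa, theta_total = theta_total,
                proportion_mediated = if (theta_total != 0)
                  cfg$delta * cfg$kappa / theta_total else NA_real_,
                gamma = stats::setNames(gamma, ids),
                eta = stats::setNames(eta, ids),
                pleiotropy = stats::setNames(a, ids),
                maf = stats::setNames(maf, ids))
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 ld = ld, confounder_ann = confounder_ann, truth = truth,
                 config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated two-sample MR study (seed %d): %d exposure + %d mediator instruments\n",
    x$config$seed, x$config$m_snps, x$config$m_med_snps))
  cat(sprintf("  truth: theta_direct %.3f, delta %.3f, kappa %.3f -> total %.3f, proportion mediated %.3f\n",
              x$truth$theta_direct, x$truth$delta, x$truth$kappa,
              x$truth$theta_total, x$truth$proportion_mediated))
  invisible(x)
}

#' Null / pleiotropy calibration of the MR chain
#'
#' Runs the full select -> harmonize -> estimate chain on `n_reps`
#' independently seeded replicates of `config` and reports the rejection
#' rates of the IVW causal test and the Egger intercept test at size
#' `alpha`, with binomial standard errors. Intended for a global-null or
#' pleiotropy variant of the config.
#'
#' @param config a [simulation_config()]; replicate r uses seed
#'   `config$seed + r`.
#' @param n_reps replicate count.
#' @param alpha nominal test size (default 0.05).
#' @param p_threshold instrument p-value cutoff used in each replicate.
#' @return List with `ivw_rate`, `egger_intercept_rate`, their binomial
#'   `*_se`, `n_reps`, `n_used` (replicates with >= 3 instruments) and the
#'   mean IVW estimate across replicates.
#' @export
simulate_null_calibration <- function(config, n_reps, alpha = 0.05,
                                      p_threshold = 5e-6) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 1)
  ivw_p <- egger_p <- ivw_b <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_study(cfg)
    inst <- tryCatch(
      select_instruments(sim$exposure, p_threshold = p_threshold, ld = sim$ld),
      error = function(e) NULL)
    if (is.null(inst) || nrow(inst$records) < 3) next
    h <- harmonize(inst_table(inst, sim$exposure), sim$outcome)
    if (nrow(h$pairs) < 3) next
    ivw <- mr_ivw(h)
    ivw_p[r] <- ivw$pval
    ivw_b[r] <- ivw$beta
    egger_p[r] <- egger_intercept_test(h)$pval
  }
  used <- !is.na(ivw_p)
  n_used <- sum(used)
  rate <- function(p) mean(p[used] < alpha)
  rse <- function(x) sqrt(x * (1 - x) / n_used)
  iv <- rate(ivw_p); eg <- rate(egger_p)
  list(ivw_rate = iv, ivw_rate_se = rse(iv),
       egger_intercept_rate = eg, egger_intercept_rate_se = rse(eg),
       mean_ivw_beta = mean(ivw_b[used]),
       alpha = alpha, n_reps = n_reps, n_used = n_used)
}

#' Subset a summary-statistics table to a selected instrument set
#'
#' Convenience for chaining [select_instruments()] into [harmonize()]:
#' returns `table` restricted to the instruments retained in `inst`.
#'
#' @param inst an `instrument_set`.
#' @param table the [sumstats_table] to subset (typically the exposure the
#'   instruments were selected from).
#' @return A [sumstats_table] with only the retained SNPs.
#' @export
inst_table <- function(inst, table) {
  df <- as.data.frame(table)
  sumstats_table(df[df$snp_id %in% inst$records$snp_id, , drop = FALSE],
                 trait_label = attr(table, "trait_label"),
                 trait_type = attr(table, "trait_type"),
                 provenance = attr(table, "provenance"))
}
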