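#!/usr/bin/env Rscript
# Step 1 — generate the synthetic two-sample study the rest of the workflow
# analyses: a binary exposure, a continuous mediator and a binary outcome
# linked exposure -> mediator -> outcome, at the effect scale of the
# motivating OSA/BMI/osteoarthritis analysis (direct effect 0.077 log-odds,
# exposure->mediator 0.113, mediator->outcome 0.399; ~100 instruments per
# trait arm; GWAS n = 3e5 per trait). Writes canonical TSVs plus the truth.

library(twostepmr)

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20240915,
                         ld_blocks = list(list(size = 5, r2 = 0.8),
                                          list(size = 4, r2 = 0.6)))
sim <- simulate_study(cfg)
print(sim)

write_sumstats(sim$exposure, file.path(out_dir, "exposure.tsv"))
write_sumstats(sim$mediator, file.path(out_dir, "mediator.tsv"))
write_sumstats(sim$outcome, file.path(out_dir, "outcome.tsv"))

# replication cohort for the meta-analysis step: same variants, an
# independently sampled outcome GWAS of 2e5
repl_cfg <- cfg
repl_cfg$n_out <- 2e5
repl_cfg$seed <- 20240916L
class(repl_cfg) <- "simulation_config"
repl <- simulate_study(repl_cfg)
write_sumstats(repl$outcome, file.path(out_dir, "outcome_replication.tsv"))

# LD matrix (long format) and confounder annotation
ld_long <- which(sim$ld$r2 > 0 & upper.tri(sim$ld$r2), arr.ind = TRUE)
write.table(data.frame(snp_a = sim$ld$snp_ids[ld_long[, 1]],
                       snp_b = sim$ld$snp_ids[ld_long[, 2]],
                       r2 = sim$ld$r2[ld_long]),
            file.path(out_dir, "ld.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$confounder_ann, file.path(out_dir, "confounders.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(sim$truth[c("theta_direct", "delta", "kappa",
                                 "theta_total", "proportion_mediated")],
                     file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("\nWrote %d-SNP study to %s; true total effect %.4f, true proportion mediated %.3f\n",
            nrow(sim$exposure), out_dir, sim$truth$theta_total,
            sim$truth$proportion_mediated))
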