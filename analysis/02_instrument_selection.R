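#!/usr/bin/env Rscript
# Step 2 — instrument selection on the simulated exposure GWAS: suggestive
# threshold p < 5e-6, greedy LD clumping at r2 < 0.001 within 10,000 kb,
# instrument-strength screen F > 10, then the confounder-annotation
# exclusion pass. Mirrors the screening that reduced 101 exposure
# instruments to 56 in the motivating analysis.

library(twostepmr)

exposure <- read_sumstats("results/data/exposure.tsv", trait_type = "binary")
ld_long <- read.table("results/data/ld.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
ids <- exposure$snp_id
r2 <- diag(length(ids)); dimnames(r2) <- list(ids, ids)
for (i in seq_len(nrow(ld_long))) {
  r2[ld_long$snp_a[i], ld_long$snp_b[i]] <- ld_long$r2[i]
  r2[ld_long$snp_b[i], ld_long$snp_a[i]] <- ld_long$r2[i]
}
ld <- ld_info(ids, r2)

inst <- select_instruments(exposure, p_threshold = 5e-6, ld = ld,
                           r2_threshold = 0.001, window_kb = 10000,
                           f_min = 10)
print(inst)

ann <- read.table("results/data/confounders.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
if (nrow(ann) > 0) {
  filtered <- filter_confounders(inst, ann, "pleiotropy")
  cat(sprintf("confounder screen: %d -> %d instruments\n",
              nrow(inst$records), nrow(filtered$records)))
} else {
  cat("confounder screen: no annotated SNPs, set unchanged\n")
}

dir.create("results", showWarnings = FALSE)
write.table(cbind(inst$records, f_stat = unname(inst$f_stats)),
            "results/instruments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(inst$exclusions, "results/instrument_exclusions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("retained %d instruments (min F %.1f); exclusions logged for %d SNPs\n",
            nrow(inst$records), min(inst$f_stats),
            length(unique(inst$exclusions$snp_id))))
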