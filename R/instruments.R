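#' Pairwise LD information
#'
#' Holds a symmetric matrix of pairwise squared correlations (r^2) between
#' SNPs, as produced by an external reference panel. SNP pairs absent from
#' the matrix are treated as unlinked (r^2 = 0) by [clump()].
#'
#' @param snp_ids character vector of SNP ids (matrix dimnames).
#' @param r2 symmetric numeric matrix in `[0,1]` with unit diagonal.
#' @return An `ld_info` object.
#' @export
ld_info <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < 0 | r2 > 1)) stopf("r2 values must lie in [0,1]")
  if (max(abs(r2 - t(r2))) > 1e-9) stopf("r2 matrix must be symmetric (tol 1e-9)")
  if (any(abs(diag(r2) - 1) > 1e-9)) stopf("r2 matrix must have unit diagonal")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2), class = "ld_info")
}

# r^2 between two SNP ids; 0 when either id is absent from the LD matrix.
ld_r2 <- function(ld, id1, id2) {
  if (is.null(ld)) return(0)
  if (!(id1 %in% ld$snp_ids) || !(id2 %in% ld$snp_ids)) return(0)
  ld$r2[id1, id2]
}

#' Instrument-strength F statistic
#'
#' The per-SNP approximate F statistic `beta^2 / se^2`; values above 10 are
#' the conventional weak-instrument floor.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), all > 0.
#' @return Numeric vector of F values (always >= 0).
#' @export
f_statistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) stopf("f_statistic: se must be > 0")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' Standard best-p-first clumping: SNPs are visited in ascending p-value
#' order (ties broken lexicographically by `snp_id`); each kept SNP discards
#' every not-yet-kept SNP on the same chromosome within `window_kb`
#' (center-to-center) whose r^2 with it is at least `r2_threshold`. Pairs
#' absent from `ld` count as r^2 = 0; SNPs with missing chromosome or
#' position never fall inside any window.
#'
#' @param table a [sumstats_table].
#' @param ld an [ld_info] or `NULL` (no LD -> everything independent).
#' @param r2_threshold clumping r^2 cutoff, in (0,1].
#' @param window_kb window half-width in kilobases, > 0.
#' @return Character vector of retained `snp_id`s in selection order.
#' @export
clump <- function(table, ld = NULL, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(character(0))
  ord <- order(df$pval, df$snp_id)
  df <- df[ord, , drop = FALSE]
  retained <- character(0)
  alive <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    retained <- c(retained, df$snp_id[i])
    alive[i] <- FALSE
    if (!any(alive)) break
    cand <- which(alive)
    same_chr <- !is.na(df$chrom[cand]) & !is.na(df$chrom[i]) &
      df$chrom[cand] == df$chrom[i]
    near <- same_chr & !is.na(df$pos[cand]) & !is.na(df$pos[i]) &
      abs(df$pos[cand] - df$pos[i]) <= window_kb * 1000
    for (j in cand[near]) {
      if (ld_r2(ld, df$snp_id[i], df$snp_id[j]) >= r2_threshold) alive[j] <- FALSE
    }
  }
  retained
}

#' Select independent, strong instruments from an exposure GWAS
#'
#' Three filters in sequence: (1) genome-wide/suggestive p-value threshold
#' (`pval < p_threshold`); (2) greedy LD [clump()]; (3) instrument-strength
#' screen dropping SNPs with [f_statistic()] below `f_min`. Every dropped
#' SNP is recorded with its stage and reason.
#'
#' @param table exposure [sumstats_table].
#' @param p_threshold selection p-value cutoff (default `5e-6`).
#' @param ld an [ld_info] or `NULL`.
#' @param r2_threshold clumping r^2 cutoff (default 0.001).
#' @param window_kb clumping window in kb (default 10000).
#' @param f_min minimum F statistic (default 10).
#' @return An `instrument_set`: list with `records` (retained rows, selection
#'   order), `f_stats` (named), the thresholds, and `exclusions`
#'   (`snp_id`, `stage`, `reason`).
#' @export
select_instruments <- function(table, p_threshold = 5e-6, ld = NULL,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  df <- as.data.frame(table)
  if (nrow(df) == 0) stopf("select_instruments: empty table")
  exclusions <- data.frame(snp_id = character(0), stage = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  note <- function(ids, stage, reason) {
    if (length(ids) > 0) {
      exclusions <<- rbind(exclusions,
                           data.frame(snp_id = ids, stage = stage,
                                      reason = reason, stringsAsFactors = FALSE))
    }
  }
  pass_p <- df$pval < p_threshold
  note(df$snp_id[!pass_p], "p_threshold",
       sprintf("pval >= %g", p_threshold))
  df <- df[pass_p, , drop = FALSE]
  if (nrow(df) == 0) {
    stopf("no instruments: no SNP passes p < %g", p_threshold)
  }
  kept_ids <- clump(df, ld = ld, r2_threshold = r2_threshold,
                    window_kb = window_kb)
  note(setdiff(df$snp_id, kept_ids), "clump",
       sprintf("r2 >= %g with a better SNP within %g kb", r2_threshold, window_kb))
  df <- df[match(kept_ids, df$snp_id), , drop = FALSE]
  f <- f_statistic(df$beta, df$se)
  names(f) <- df$snp_id
  weak <- f < f_min
  note(df$snp_id[weak], "f_statistic", sprintf("F < %g", f_min))
  df <- df[!weak, , drop = FALSE]
  f <- f[!weak]
  if (nrow(df) == 0) stopf("no instruments: all clumped SNPs have F < %g", f_min)
  rownames(df) <- NULL
  structure(list(records = df, f_stats = f,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, f_min = f_min,
                 exclusions = exclusions),
            class = "instrument_set")
}

#' Drop instruments annotated to confounder traits
#'
#' Local stand-in for a web lookup of secondary trait associations: removes
#' every instrument whose `snp_id` appears in the annotation table under one
#' of the listed traits, extending the exclusion log with one row per
#' matching trait.
#'
#' @param inst an `instrument_set` from [select_instruments()].
#' @param ann data frame with columns `snp_id`, `trait_label`.
#' @param traits character vector of confounder trait labels to exclude on.
#' @return A filtered `instrument_set`.
#' @export
filter_confounders <- function(inst, ann, traits) {
  stopifnot(inherits(inst, "instrument_set"), length(traits) > 0)
  if (is.null(ann) || nrow(ann) == 0) return(inst)
  stopifnot(all(c("snp_id", "trait_label") %in% names(ann)))
  hits <- ann[ann$trait_label %in% traits &
                ann$snp_id %in% inst$records$snp_id, , drop = FALSE]
  if (nrow(hits) == 0) return(inst)
  inst$exclusions <- rbind(
    inst$exclusions,
    data.frame(snp_id = hits$snp_id, stage = "confounder",
               reason = paste0("confounder:", hits$trait_label),
               stringsAsFactors = FALSE))
  keep <- !(inst$records$snp_id %in% hits$snp_id)
  inst$records <- inst$records[keep, , drop = FALSE]
  rownames(inst$records) <- NULL
  inst$f_stats <- inst$f_stats[inst$records$snp_id]
  inst
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "Instrument set: %d SNPs (p < %g, clump r2 < %g / %g kb, F >= %g)\n",
    nrow(x$records), x$p_threshold, x$r2_threshold, x$window_kb, x$f_min))
  cat(sprintf("  F statistics: min %.1f, median %.1f, max %.1f\n",
              min(x$f_stats), stats::median(x$f_stats), max(x$f_stats)))
  cat(sprintf("  %d exclusion record(s)\n", nrow(x$exclusions)))
  invisible(x)
}
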