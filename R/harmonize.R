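#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two GWAS tables to a shared effect-allele convention so that each
#' shared SNP contributes one (beta_exp, beta_out) pair on the same allele.
#' Rules, applied per SNP in the intersection:
#' \itemize{
#'   \item same allele pair, same orientation: kept as-is (`none`);
#'   \item same pair, swapped orientation: outcome beta negated and
#'     `eaf_out <- 1 - eaf_out` (`flipped_outcome`);
#'   \item pair matching only after strand complementation (e.g. A/G vs
#'     T/C): strand-flipped, then the two rules above;
#'   \item palindromic SNP (A/T or C/G): orientation is inferred from
#'     allele frequency, and only when both frequencies lie outside the
#'     ambiguity band `0.5 +/- palindromic_eaf_tol`; otherwise
#'     `dropped_palindromic`;
#'   \item anything irreconcilable by flipping (indels, multi-allelic,
#'     mismatched pairs): `dropped_incompatible`.
#' }
#'
#' @param exposure,outcome [sumstats_table]s.
#' @param palindromic_eaf_tol half-width of the frequency ambiguity band
#'   around 0.5 (default 0.08, i.e. band 0.42-0.58).
#' @return A `harmonized_set`: list with `pairs` (data frame `snp_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `action`), `dropped` (excluded SNPs with reasons), `exposure_label`,
#'   `outcome_label`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_tol = 0.08) {
  stopifnot(palindromic_eaf_tol >= 0, palindromic_eaf_tol < 0.5)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (length(shared) == 0) stopf("no overlapping SNPs between exposure and outcome")
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  nucs <- names(comp)
  band_lo <- 0.5 - palindromic_eaf_tol
  band_hi <- 0.5 + palindromic_eaf_tol

  for (i in seq_len(n)) {
    ea1 <- ex$effect_allele[i]; oa1 <- ex$other_allele[i]
    ea2 <- ou$effect_allele[i]; oa2 <- ou$other_allele[i]
    if (!all(c(ea1, oa1, ea2, oa2) %in% nucs)) {
      action[i] <- "dropped_incompatible"   # indel / multi-allelic record
      next
    }
    palindromic <- comp[ea1] == oa1
    if (palindromic) {
      if (!setequal(c(ea2, oa2), c(ea1, oa1))) {
        action[i] <- "dropped_incompatible"
        next
      }
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      ambiguous <- is.na(fe) || is.na(fo) ||
        (fe >= band_lo && fe <= band_hi) || (fo >= band_lo && fo <= band_hi)
      if (ambiguous) {
        action[i] <- "dropped_palindromic"
        next
      }
      # orient purely by frequency: align to the outcome allele whose
      # frequency falls on the same side of 0.5 as the exposure's
      aligned_same <- (ea2 == ea1)
      freq_agrees <- (fe < 0.5) == (fo < 0.5)
      keep_as_is <- aligned_same == freq_agrees
      if (keep_as_is && aligned_same) {
        action[i] <- "none"
      } else if (!aligned_same && freq_agrees) {
        # outcome effect allele is the complement letter but frequencies
        # agree: pure strand flip, orientation already matches
        action[i] <- "none"
      } else {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped_outcome"
      }
      next
    }
    # non-palindromic: try direct, swapped, strand-complement variants
    if (ea2 == ea1 && oa2 == oa1) {
      action[i] <- "none"
    } else if (ea2 == oa1 && oa2 == ea1) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped_outcome"
    } else if (comp[ea2] == ea1 && comp[oa2] == oa1) {
      action[i] <- "none"
    } else if (comp[ea2] == oa1 && comp[oa2] == ea1) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped_outcome"
    } else {
      action[i] <- "dropped_incompatible"
    }
  }

  pairs <- data.frame(snp_id = shared,
                      beta_exp = ex$beta, se_exp = ex$se,
                      beta_out = beta_out, se_out = ou$se,
                      eaf_exp = ex$eaf, eaf_out = eaf_out,
                      action = action, stringsAsFactors = FALSE)
  keep <- action %in% c("none", "flipped_outcome")
  dropped <- pairs[!keep, c("snp_id", "action"), drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  rownames(pairs) <- rownames(dropped) <- NULL
  structure(list(pairs = pairs, dropped = dropped,
                 exposure_label = attr(exposure, "trait_label") %||% "exposure",
                 outcome_label = attr(outcome, "trait_label") %||% "outcome"),
            class = "harmonized_set")
}

# Coerce a harmonized_set or bare data frame of pairs to the pair frame.
harmonized_pairs <- function(h) {
  if (inherits(h, "harmonized_set")) return(h$pairs)
  stopifnot(is.data.frame(h),
            all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(h)))
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n", x$exposure_label, x$outcome_label))
  cat(sprintf("  %d SNP pairs retained (%d flipped), %d dropped\n",
              nrow(x$pairs), sum(x$pairs$action == "flipped_outcome"),
              nrow(x$dropped)))
  invisible(x)
}
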