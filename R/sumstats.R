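#' GWAS summary-statistics tables
#'
#' A `sumstats_table` is a validated data frame of per-SNP association
#' records — the universal currency of the MR pipeline. Columns follow the
#' canonical dialect: `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. `beta` is the per-allele
#' additive effect (log-odds for binary traits, trait-SD units for
#' continuous traits), `se` its standard error, `eaf` the effect-allele
#' frequency. `chrom`, `pos`, `eaf` and `n` may be missing (`NA`).
#'
#' @param records data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optional `chrom`, `pos`, `eaf`,
#'   `n`.
#' @param trait_label free-text trait name.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param provenance source path or simulation seed, for the record.
#' @param drop_invalid drop rows violating record invariants (with a logged
#'   tally) instead of erroring.
#' @return A `sumstats_table`: a data frame with canonical columns and
#'   attributes `trait_label`, `trait_type`, `provenance`, `drop_log`.
#' @export
sumstats_table <- function(records, trait_label = "trait",
                           trait_type = c("binary", "continuous"),
                           provenance = NA_character_,
                           drop_invalid = TRUE) {
  trait_type <- match.arg(trait_type)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    snp_id = as.character(records$snp_id),
    chrom = if ("chrom" %in% names(records)) as.character(records$chrom) else NA_character_,
    pos = if ("pos" %in% names(records)) as.numeric(records$pos) else NA_real_,
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele = toupper(as.character(records$other_allele)),
    eaf = if ("eaf" %in% names(records)) as.numeric(records$eaf) else NA_real_,
    beta = as.numeric(records$beta),
    se = as.numeric(records$se),
    pval = as.numeric(records$pval),
    n = if ("n" %in% names(records)) as.numeric(records$n) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- validate_sumstats_rows(df)
  drop_log <- data.frame(snp_id = df$snp_id[bad$idx], reason = bad$reason,
                         stringsAsFactors = FALSE)
  if (nrow(drop_log) > 0) {
    if (!drop_invalid) {
      stopf("invalid sumstats rows: %s",
            paste(sprintf("%s (%s)", drop_log$snp_id, drop_log$reason), collapse = "; "))
    }
    df <- df[-bad$idx, , drop = FALSE]
  }
  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    drop_log <- rbind(drop_log, data.frame(snp_id = df$snp_id[dup],
                                           reason = "duplicate snp_id",
                                           stringsAsFactors = FALSE))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df,
            trait_label = trait_label,
            trait_type = trait_type,
            provenance = provenance,
            drop_log = drop_log,
            class = c("sumstats_table", "data.frame"))
}

# Indices and reasons of rows violating per-record invariants.
validate_sumstats_rows <- function(df) {
  idx <- integer(0); reason <- character(0)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    idx <<- c(idx, which(cond))
    reason <<- c(reason, rep(why, sum(cond)))
  }
  flag(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  flag(is.na(df$beta), "missing beta")
  flag(is.na(df$se) | df$se <= 0, "nonpositive SE")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "p-value outside (0,1]")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(is.na(df$effect_allele) | df$effect_allele == "" |
         is.na(df$other_allele) | df$other_allele == "", "missing allele")
  flag(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf outside (0,1)")
  keep <- !duplicated(idx)
  list(idx = idx[keep], reason = reason[keep])
}

canonical_sumstats_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                             "other_allele", "eaf", "beta", "se", "pval", "n")

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text table into a validated [sumstats_table]. The
#' canonical dialect is tab-delimited with one header line and `"."` or the
#' empty string for missing values; foreign dialects are accommodated via
#' `column_map`. Rows violating record invariants (nonpositive SE, p-value
#' outside (0,1], identical alleles, ...) are dropped with a tally reported
#' via [message()] and recorded in the `drop_log` attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical column names to
#'   the file's column names, e.g. `c(snp_id = "rsid", beta = "b")`. Columns
#'   not mentioned keep their canonical names.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param trait_label trait name; defaults to the file name.
#' @param sep field separator (tab for the canonical dialect).
#' @return A [sumstats_table].
#' @export
read_sumstats <- function(path, column_map = NULL,
                          trait_type = c("binary", "continuous"),
                          trait_label = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = c("NA", ".", ""),
                      colClasses = "character",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stopf("empty or unreadable file: %s (%s)",
                              path, conditionMessage(e)))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      foreign <- column_map[[canon]]
      if (!foreign %in% names(raw)) {
        stopf("column_map names column '%s' (for '%s') but the file has no such column",
              foreign, canon)
      }
      names(raw)[names(raw) == foreign] <- canon
    }
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  tab <- sumstats_table(raw,
                        trait_label = trait_label %||% basename(path),
                        trait_type = trait_type, provenance = path)
  n_drop <- nrow(attr(tab, "drop_log"))
  if (n_drop > 0) {
    message(sprintf("read_sumstats: dropped %d invalid row(s) of %d from %s",
                    n_drop, nrow(raw), basename(path)))
  }
  tab
}

#' Write a summary-statistics table in the canonical dialect
#'
#' Tab-delimited UTF-8 with the canonical header; missing values written as
#' empty fields. `read_sumstats(write_sumstats(t))` reproduces `t`
#' field-for-field (floats within 1e-12 relative).
#'
#' @param table a [sumstats_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats_table"))
  df <- as.data.frame(table)[, canonical_sumstats_cols, drop = FALSE]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        format(df[[col]], digits = 17, trim = TRUE, scientific = NA))
  }
  df$chrom[is.na(df$chrom)] <- ""
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to path: %s", path)
  invisible(path)
}

#' @export
print.sumstats_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  n_drop <- nrow(attr(x, "drop_log") %||% data.frame())
  if (n_drop > 0) cat(sprintf("  %d invalid row(s) dropped on construction\n", n_drop))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
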