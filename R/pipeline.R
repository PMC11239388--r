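# End-to-end orchestration of the study's analysis graph: forward MR per
# outcome, confounder-filtered rerun, reverse MR, replication meta-analysis,
# and two-step mediation, from a single configuration.

all_mr_methods <- c("ivw", "egger", "weighted_median", "weighted_mode",
                    "simple_mode")

#' Analysis configuration
#'
#' Collects every input and threshold of a full MR analysis. Tables may be
#' given as file paths (read via [read_sumstats()]) or as in-memory
#' [sumstats_table] objects; paths are checked at construction.
#'
#' @param exposure exposure table or path.
#' @param outcomes named list of outcome tables or paths (>= 1).
#' @param mediator optional mediator table or path (enables the mediation
#'   block against the first outcome).
#' @param replication optional replication outcome table or path (enables
#'   the meta block, pooled with the first outcome).
#' @param ld optional [ld_info] used for clumping.
#' @param p_threshold,r2_threshold,window_kb,f_min instrument-selection
#'   thresholds (defaults 5e-6, 0.001, 10000, 10).
#' @param mediator_p_threshold p-value cutoff for mediator instruments
#'   (default 5e-8, the genome-wide threshold conventional for large
#'   continuous-trait GWAS).
#' @param palindromic_eaf_tol harmonization ambiguity half-window.
#' @param methods estimator subset of
#'   `c("ivw","egger","weighted_median","weighted_mode","simple_mode")`.
#' @param ivw_re_mode `"multiplicative_random"` or `"fixed"`.
#' @param confounder_table optional data frame (`snp_id`, `trait_label`) or
#'   TSV path; with `confounder_traits`, triggers the filtered rerun.
#' @param confounder_traits trait labels to exclude on.
#' @param meta_model `"fixed"` or `"random_dl"`.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param seed RNG seed; mandatory when any bootstrap method is requested.
#' @param out_dir optional directory for TSV/JSON report export.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcomes, mediator = NULL,
                            replication = NULL, ld = NULL,
                            p_threshold = 5e-6, r2_threshold = 0.001,
                            window_kb = 10000, f_min = 10,
                            mediator_p_threshold = 5e-8,
                            palindromic_eaf_tol = 0.08,
                            methods = all_mr_methods,
                            ivw_re_mode = "multiplicative_random",
                            confounder_table = NULL,
                            confounder_traits = NULL,
                            meta_model = c("fixed", "random_dl"),
                            n_boot = 1000, seed = NULL, out_dir = NULL) {
  meta_model <- match.arg(meta_model)
  methods <- match.arg(methods, all_mr_methods, several.ok = TRUE)
  if (!is.list(outcomes) || length(outcomes) == 0) {
    stopf("analysis_config: outcomes must be a nonempty named list")
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- paste0("outcome_", seq_along(outcomes))
  }
  needs_boot <- any(methods %in% c("weighted_median", "weighted_mode", "simple_mode"))
  if (needs_boot && is.null(seed)) {
    stopf("analysis_config: seed is mandatory when bootstrap methods are requested")
  }
  for (x in c(list(exposure), outcomes, list(mediator), list(replication))) {
    if (is.character(x) && !file.exists(x)) stopf("path does not exist: %s", x)
  }
  structure(list(exposure = exposure, outcomes = outcomes,
                 mediator = mediator, replication = replication, ld = ld,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, f_min = f_min,
                 mediator_p_threshold = mediator_p_threshold,
                 palindromic_eaf_tol = palindromic_eaf_tol,
                 methods = methods, ivw_re_mode = ivw_re_mode,
                 confounder_table = confounder_table,
                 confounder_traits = confounder_traits,
                 meta_model = meta_model, n_boot = n_boot, seed = seed,
                 out_dir = out_dir),
            class = "analysis_config")
}

load_table <- function(x, trait_type = "binary") {
  if (is.null(x)) return(NULL)
  if (inherits(x, "sumstats_table")) return(x)
  read_sumstats(x, trait_type = trait_type)
}

load_confounders <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Estimator battery + diagnostics for one harmonized set.
analyse_harmonized <- function(h, cfg) {
  ests <- list()
  for (m in cfg$methods) {
    ests[[m]] <- switch(
      m,
      ivw = mr_ivw(h, re_mode = cfg$ivw_re_mode),
      egger = mr_egger(h)$slope,
      weighted_median = mr_weighted_median(h, n_boot = cfg$n_boot, seed = cfg$seed),
      weighted_mode = mr_mode(h, "weighted", n_boot = cfg$n_boot, seed = cfg$seed),
      simple_mode = mr_mode(h, "simple", n_boot = cfg$n_boot, seed = cfg$seed))
  }
  estimates <- do.call(rbind, lapply(ests, as.data.frame))
  rownames(estimates) <- NULL
  diagnostics <- list(
    heterogeneity = tryCatch(cochran_q(h), error = function(e) NULL),
    egger_intercept = tryCatch(egger_intercept_test(h), error = function(e) NULL),
    leave_one_out = tryCatch(leave_one_out(h, re_mode = cfg$ivw_re_mode),
                             error = function(e) NULL),
    single_snp = tryCatch(single_snp(h), error = function(e) NULL))
  list(n_snp = nrow(h$pairs), estimates = estimates, diagnostics = diagnostics)
}

# One direction of MR: select instruments on `exposure`, harmonize against
# each outcome, run the battery. Per-outcome errors are captured, not fatal.
mr_direction <- function(exposure, outcomes, cfg, p_threshold = cfg$p_threshold,
                         apply_confounder_filter = FALSE) {
  inst <- select_instruments(exposure, p_threshold = p_threshold, ld = cfg$ld,
                             r2_threshold = cfg$r2_threshold,
                             window_kb = cfg$window_kb, f_min = cfg$f_min)
  ann <- load_confounders(cfg$confounder_table)
  inst_filtered <- NULL
  if (apply_confounder_filter && !is.null(ann) &&
      length(cfg$confounder_traits %||% character(0)) > 0) {
    inst_filtered <- filter_confounders(inst, ann, cfg$confounder_traits)
  }
  exp_sub <- inst_table(inst, exposure)
  per_outcome <- lapply(outcomes, function(out) {
    tryCatch({
      h <- harmonize(exp_sub, out,
                     palindromic_eaf_tol = cfg$palindromic_eaf_tol)
      blk <- analyse_harmonized(h, cfg)
      blk$status <- "ok"
      if (!is.null(inst_filtered)) {
        hf <- harmonize(inst_table(inst_filtered, exposure), out,
                        palindromic_eaf_tol = cfg$palindromic_eaf_tol)
        blk$confounder_filtered <- analyse_harmonized(hf, cfg)
        blk$confounder_filtered$n_excluded <-
          nrow(inst$records) - nrow(inst_filtered$records)
      }
      blk
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
  })
  list(instruments = inst,
       instruments_filtered = inst_filtered,
       n_instruments = nrow(inst$records),
       outcomes = per_outcome)
}

#' Forward MR: exposure against every configured outcome
#'
#' Instrument selection on the exposure (with the optional confounder-
#' filtered second pass reported alongside, not replacing, the primary),
#' harmonization, the requested estimators and the full diagnostic block
#' per outcome. Identical config and seed give an identical fragment.
#'
#' @param config an [analysis_config()].
#' @return A report fragment (list); per-outcome failures are recorded with
#'   `status = "failed"` without aborting sibling outcomes.
#' @export
run_forward <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- load_table(config$exposure)
  outcomes <- lapply(config$outcomes, load_table)
  mr_direction(exposure, outcomes, config, apply_confounder_filter = TRUE)
}

#' Reverse MR: each outcome re-analysed as the exposure
#'
#' Re-selects instruments on each outcome table (never reusing the forward
#' instruments) and estimates its effect on the original exposure.
#'
#' @inheritParams run_forward
#' @return A list of report fragments, one per configured outcome.
#' @export
run_reverse <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  exposure <- load_table(config$exposure)
  outcomes <- lapply(config$outcomes, load_table)
  lapply(outcomes, function(out) {
    tryCatch(
      mr_direction(out, list(reverse_outcome = exposure), config),
      error = function(e) list(status = "failed", error = conditionMessage(e)))
  })
}

#' Run the full analysis graph
#'
#' Composes forward MR, reverse MR, the replication meta-analysis (if a
#' replication table is configured: the first outcome's IVW estimate pooled
#' with the replication IVW estimate) and two-step mediation (if a mediator
#' is configured: total effect from the first outcome's IVW; exposure ->
#' mediator IVW with exposure instruments; mediator -> outcome IVW with
#' mediator instruments at `mediator_p_threshold`). Blocks not requested
#' are marked skipped; blocks that fail are marked failed with the error,
#' and the run continues.
#'
#' @inheritParams run_forward
#' @return An `analysis_report`: list with `forward`, `reverse`, `meta`,
#'   `mediation` blocks and `provenance` (config hash, package version,
#'   seed, timestamp). If `config$out_dir` is set, writes `report.json`,
#'   `estimates_forward.tsv` and `estimates_reverse.tsv` there.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  report <- list()
  block <- function(expr) {
    tryCatch(expr, error = function(e)
      list(status = "failed", error = conditionMessage(e)))
  }
  report$forward <- block(run_forward(config))
  report$reverse <- block(run_reverse(config))

  first_outcome <- names(config$outcomes)[1]
  fwd_ivw <- function(frag, outcome) {
    blk <- frag$outcomes[[outcome]]
    if (is.null(blk) || !identical(blk$status, "ok")) {
      stopf("no IVW estimate available for outcome '%s'", outcome)
    }
    est <- blk$estimates[blk$estimates$method == "ivw", ]
    if (nrow(est) == 0) stopf("IVW not among requested methods")
    list(beta = est$beta, se = est$se)
  }

  if (is.null(config$replication)) {
    report$meta <- list(status = "skipped", reason = "no replication table configured")
  } else {
    report$meta <- block({
      exposure <- load_table(config$exposure)
      repl <- load_table(config$replication)
      disc <- fwd_ivw(report$forward, first_outcome)
      repl_frag <- mr_direction(exposure, list(replication = repl), config)
      rep_est <- fwd_ivw(repl_frag, "replication")
      studies <- meta_input(label = c(first_outcome, "replication"),
                            beta = c(disc$beta, rep_est$beta),
                            se = c(disc$se, rep_est$se))
      pooled <- if (config$meta_model == "fixed") meta_fixed(studies)
                else meta_random_dl(studies)
      list(status = "ok", studies = studies, pooled = pooled,
           replication_mr = repl_frag)
    })
  }

  if (is.null(config$mediator)) {
    report$mediation <- list(status = "skipped", reason = "no mediator table configured")
  } else {
    report$mediation <- block({
      exposure <- load_table(config$exposure)
      mediator <- load_table(config$mediator, trait_type = "continuous")
      outcome1 <- load_table(config$outcomes[[first_outcome]])
      alpha <- fwd_ivw(report$forward, first_outcome)
      b1_frag <- mr_direction(exposure, list(mediator = mediator), config)
      b1 <- fwd_ivw(b1_frag, "mediator")
      b2_frag <- mr_direction(mediator, list(outcome = outcome1), config,
                              p_threshold = config$mediator_p_threshold)
      b2 <- fwd_ivw(b2_frag, "outcome")
      med <- two_step_mediation(alpha = c(alpha$beta, alpha$se),
                                beta1 = c(b1$beta, b1$se),
                                beta2 = c(b2$beta, b2$se))
      list(status = "ok", result = med,
           n_mediator_instruments = b2_frag$n_instruments)
    })
  }

  report$provenance <- list(
    config_hash = digest::digest(strip_tables(config)),
    package_version = as.character(utils::packageVersion("twostepmr")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(report) <- "analysis_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Hash the configuration by content: in-memory tables are reduced to their
# data so the hash is stable across sessions.
strip_tables <- function(cfg) {
  unclass_deep <- function(x) {
    if (inherits(x, "sumstats_table")) return(as.matrix(as.data.frame(x)))
    if (inherits(x, "ld_info")) return(x$r2)
    if (is.list(x)) return(lapply(x, unclass_deep))
    x
  }
  unclass_deep(unclass(cfg))
}

estimates_frame <- function(frag_outcomes) {
  rows <- lapply(names(frag_outcomes), function(nm) {
    blk <- frag_outcomes[[nm]]
    if (!identical(blk$status, "ok")) return(NULL)
    cbind(outcome = nm, blk$estimates, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwd <- estimates_frame(report$forward$outcomes %||% list())
  if (!is.null(fwd)) {
    utils::write.table(fwd, file.path(out_dir, "estimates_forward.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rev_rows <- lapply(names(report$reverse %||% list()), function(nm) {
    frag <- report$reverse[[nm]]
    if (!is.null(frag$outcomes)) {
      df <- estimates_frame(frag$outcomes)
      if (!is.null(df)) cbind(reverse_exposure = nm, df) else NULL
    } else NULL
  })
  rev_df <- do.call(rbind, rev_rows)
  if (!is.null(rev_df)) {
    utils::write.table(rev_df, file.path(out_dir, "estimates_reverse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}

# JSON-safe view of a report (drops heavyweight instrument records).
report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "instrument_set")) {
      return(list(n = nrow(x$records), snp_ids = x$records$snp_id))
    }
    if (inherits(x, c("mr_estimate", "heterogeneity_result", "meta_result",
                      "mediation_result", "egger_result"))) {
      return(lapply(unclass(x), simplify))
    }
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, simplify))
    x
  }
  simplify(unclass(report))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("MR analysis report\n")
  fwd <- estimates_frame(x$forward$outcomes %||% list())
  if (!is.null(fwd)) {
    cat(sprintf("  forward: %d instrument(s)\n", x$forward$n_instruments))
    print(fwd, digits = 4)
  }
  for (blk in c("meta", "mediation")) {
    st <- x[[blk]]$status %||% "ok"
    cat(sprintf("  %s block: %s\n", blk, st))
  }
  cat(sprintf("  provenance: seed %s, config %s\n",
              x$provenance$seed %||% "none",
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}
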