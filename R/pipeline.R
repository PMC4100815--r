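# Pipeline orchestration: features -> variability -> distinctiveness.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its default. All defaults are
#' plain values, never hard-coded downstream, so a config round-trips
#' losslessly through YAML ([read_run_config()], [write_run_config()]).
#'
#' @param meta_csv Path to the call-record metadata CSV (columns
#'   `segment_id,caller_id,call_type,sequence_id,timestamp,audio_path,quality_ok`).
#' @param audio_dir Directory for relative `audio_path`s.
#' @param features_csv Optional precomputed feature table CSV; when given,
#'   audio is not read.
#' @param call_types_used Call types to analyse (`NULL` = all present).
#' @param min_calls,min_gap_s Inclusion filters, see [filter_call_records()].
#' @param band_threshold_db,tonal_cut,noisy_cut Feature extraction tuning,
#'   see [feature_options()].
#' @param f_in,f_out Stepwise DFA thresholds.
#' @param loading_cutoff Absolute structure-loading cutoff selecting the
#'   parameters tested by mixed models.
#' @param n_selections,n_permutations pDFA settings.
#' @param alpha Family-wise error level.
#' @param seed Integer seed for all randomness in the run.
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(meta_csv = NULL, audio_dir = NULL, features_csv = NULL,
                       call_types_used = NULL, min_calls = 4, min_gap_s = 3600,
                       band_threshold_db = -24, tonal_cut = 0.3,
                       noisy_cut = 0.7, f_in = 3.84, f_out = 2.71,
                       loading_cutoff = 0.45, n_selections = 100,
                       n_permutations = 1000, alpha = 0.05, seed = 1,
                       out_dir = NULL) {
  cfg <- list(meta_csv = meta_csv, audio_dir = audio_dir,
              features_csv = features_csv, call_types_used = call_types_used,
              min_calls = min_calls, min_gap_s = min_gap_s,
              band_threshold_db = band_threshold_db, tonal_cut = tonal_cut,
              noisy_cut = noisy_cut, f_in = f_in, f_out = f_out,
              loading_cutoff = loading_cutoff, n_selections = n_selections,
              n_permutations = n_permutations, alpha = alpha,
              seed = as.integer(seed), out_dir = out_dir)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_validation("alpha must be in (0, 1)")
  if (cfg$min_calls < 2) stop_validation("min_calls must be >= 2")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()] (or by hand).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full individual-distinctiveness pipeline
#'
#' Orchestrates: record filtering, feature extraction (unless a feature
#' table is supplied), per-call-type variability/PIC summaries, Friedman
#' comparisons of CV and PIC across call types, per-call-type stepwise DFA
#' with leave-one-out cross-validation, pDFA p-values, mixed-model tests of
#' the parameters loading above the cutoff (Hochberg-corrected), and the
#' cross-call-type comparison of cross-validated assignment. Writes
#' `features.csv`, `variability.csv`, `table_report.csv`,
#' `percaller_report.csv`, `friedman.csv`, `pdfa.json` and `run_log.txt`
#' into `out_dir` (if set). Identical config and seed reproduce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param records Optional in-memory call-record table (overrides
#'   `meta_csv`).
#' @param features Optional in-memory feature table (overrides
#'   `features_csv`).
#' @return A list of class `vocalid_run` with elements `features`,
#'   `variability` (named list of [variability_summary()]), `friedman`,
#'   `dfa` (named list of `dfa_result`), `pdfa` (named list of
#'   `pdfa_result`), `lmm` (named list of data frames), `report` (one row
#'   per call type), `per_caller`, `across_types`, `config`.
#' @export
run_pipeline <- function(config, records = NULL, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  opts <- feature_options(band_threshold_db = config$band_threshold_db,
                          tonal_cut = config$tonal_cut,
                          noisy_cut = config$noisy_cut)
  log_lines <- c(sprintf("vocalid %s", as.character(utils::packageVersion("vocalid"))),
                 sprintf("seed: %d", config$seed))

  # --- features ---------------------------------------------------------
  if (is.null(features) && !is.null(config$features_csv)) {
    features <- utils::read.csv(config$features_csv, stringsAsFactors = FALSE)
  }
  if (is.null(features)) {
    if (is.null(records)) {
      if (is.null(config$meta_csv)) stop_validation("no input configured")
      records <- utils::read.csv(config$meta_csv, stringsAsFactors = FALSE)
    }
    records <- call_records(records)
    log_lines <- c(log_lines, sprintf("records read: %d", nrow(records)))
    records <- filter_call_records(records, min_gap_s = config$min_gap_s,
                                   min_calls = config$min_calls)
    log_lines <- c(log_lines, sprintf("records after filters: %d", nrow(records)))
    if (nrow(records) == 0L) stop("nothing to analyze: no records survive the filters")
    features <- features_from_audio(records, audio_dir = config$audio_dir,
                                    opts = opts)
  } else {
    # a supplied feature table still honours the sample-size filters when
    # the metadata columns are present
    if (all(c("quality_ok") %in% names(features))) {
      features <- features[as.logical(features$quality_ok), , drop = FALSE]
    }
    cnt <- table(paste(features$caller_id, features$call_type, sep = "\r"))
    ok <- names(cnt)[cnt >= config$min_calls]
    features <- features[paste(features$caller_id, features$call_type,
                               sep = "\r") %in% ok, , drop = FALSE]
  }
  log_lines <- c(log_lines, sprintf("feature rows: %d", nrow(features)))

  types <- unique(features$call_type)
  if (!is.null(config$call_types_used)) {
    types <- intersect(types, config$call_types_used)
  }
  usable <- types[vapply(types, function(ct) {
    sub <- features[features$call_type == ct, ]
    sum(table(sub$caller_id) >= 2) >= 2
  }, logical(1))]
  if (!length(usable)) {
    counts <- vapply(types, function(ct) sum(features$call_type == ct), integer(1))
    stop("nothing to analyze: no call type has >= 2 callers with >= 2 calls (",
         paste(sprintf("%s: %d", types, counts), collapse = ", "), ")")
  }
  log_lines <- c(log_lines, sprintf("call types analysed: %s",
                                    paste(usable, collapse = ", ")))

  # --- variability ------------------------------------------------------
  variability <- lapply(stats::setNames(usable, usable), function(ct) {
    suppressWarnings(variability_summary(features, call_type = ct))
  })
  friedman <- NULL
  if (length(usable) >= 2L) {
    friedman <- do.call(rbind, lapply(c("cv_intra", "cv_inter", "pic"), function(w) {
      m <- cv_matrix(variability, w)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < 2L) return(NULL)
      ft <- friedman_test(m)
      data.frame(statistic = w, chi2 = ft$chi2, df = ft$df, p = ft$p,
                 n_parameters = nrow(m))
    }))
  }

  # --- distinctiveness --------------------------------------------------
  dfa_list <- list()
  pdfa_list <- list()
  lmm_list <- list()
  report <- list()
  per_caller <- list()
  for (ct in usable) {
    sub <- features[features$call_type == ct, , drop = FALSE]
    d <- tryCatch(
      suppressWarnings(stepwise_dfa(sub, caller = "caller_id",
                                    f_in = config$f_in, f_out = config$f_out,
                                    call_type = ct)),
      error = function(e) e
    )
    if (inherits(d, "error")) {
      warning("DFA failed for ", ct, ": ", conditionMessage(d))
      next
    }
    dfa_list[[ct]] <- d
    pd <- suppressWarnings(pdfa(sub, d$selected_parameters,
                                n_selections = config$n_selections,
                                n_permutations = config$n_permutations,
                                seed = config$seed))
    pdfa_list[[ct]] <- pd
    tested <- rownames(d$loadings)[apply(abs(d$loadings) > config$loading_cutoff,
                                         1, any)]
    lm_res <- if (length(tested)) {
      suppressWarnings(lmm_parameter_significance(sub, tested,
                                                  alpha = config$alpha))
    } else NULL
    lmm_list[[ct]] <- lm_res
    sig <- if (!is.null(lm_res)) lm_res$parameter[lm_res$reject] else character(0)
    report[[ct]] <- data.frame(
      call_type = ct, n = d$n,
      dfa_pct = d$resubstitution$overall, P1 = pd$P1,
      cdfa_pct = d$leave_one_out$overall, P2 = pd$P2,
      chance = d$chance, n_functions = d$n_functions,
      wilks_lambda = d$wilks_lambda, df = d$df, chi2 = d$chi2, p = d$p,
      n_models = length(tested),
      significant_parameters = paste(sig, collapse = " ")
    )
    pc <- merge(d$resubstitution$per_caller,
                d$leave_one_out$per_caller[c("caller", "pct")],
                by = "caller", suffixes = c("_dfa", "_cdfa"))
    pc <- cbind(call_type = ct, pc, chance = d$chance)
    per_caller[[ct]] <- pc
  }
  if (!length(report)) stop("nothing to analyze: every per-type DFA failed")
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  per_caller <- do.call(rbind, c(per_caller, list(make.row.names = FALSE)))

  across <- NULL
  if (length(dfa_list) >= 2L) {
    acc <- do.call(rbind, lapply(names(dfa_list), function(ct) {
      d <- dfa_list[[ct]]
      data.frame(caller_id = d$leave_one_out$per_caller$caller,
                 call_type = ct,
                 proportion = d$leave_one_out$per_caller$pct / 100,
                 n_calls = d$leave_one_out$per_caller$n)
    }))
    acc <- acc[!is.na(acc$proportion), , drop = FALSE]
    across <- tryCatch(suppressWarnings(compare_call_types(acc)),
                       error = function(e) NULL)
  }

  out <- structure(list(features = features, variability = variability,
                        friedman = friedman, dfa = dfa_list, pdfa = pdfa_list,
                        lmm = lmm_list, report = report,
                        per_caller = per_caller, across_types = across,
                        config = config, log = log_lines),
                   class = "vocalid_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  vtab <- do.call(rbind, lapply(names(run$variability), function(ct) {
    cbind(call_type = ct, run$variability[[ct]]$per_parameter)
  }))
  overall <- do.call(rbind, lapply(run$variability, function(s) s$overall))
  utils::write.csv(vtab, file.path(out_dir, "variability.csv"), row.names = FALSE)
  utils::write.csv(overall, file.path(out_dir, "variability_overall.csv"),
                   row.names = FALSE)
  utils::write.csv(run$report, file.path(out_dir, "table_report.csv"),
                   row.names = FALSE)
  utils::write.csv(run$per_caller, file.path(out_dir, "percaller_report.csv"),
                   row.names = FALSE)
  if (!is.null(run$friedman)) {
    utils::write.csv(run$friedman, file.path(out_dir, "friedman.csv"),
                     row.names = FALSE)
  }
  pd <- lapply(run$pdfa, function(p) {
    list(observed_fit = p$observed_fit, observed_cv = p$observed_cv,
         P1 = p$P1, P2 = p$P2, n_permutations = p$n_permutations,
         n_selections = p$n_selections, balanced = p$balanced,
         seed = p$seed, null_fit = p$null_fit, null_cv = p$null_cv)
  })
  jsonlite::write_json(pd, file.path(out_dir, "pdfa.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.vocalid_run <- function(x, ...) {
  cat("Individual-distinctiveness run\n")
  print(x$report[c("call_type", "n", "dfa_pct", "P1", "cdfa_pct", "P2",
                   "chance", "wilks_lambda", "significant_parameters")],
        digits = 3, row.names = FALSE)
  if (!is.null(x$across_types)) {
    cat(sprintf("Across call types: F(%g, %.1f) = %.3f, p = %.3f\n",
                x$across_types$df1, x$across_types$df2, x$across_types$F,
                x$across_types$p))
  }
  invisible(x)
}
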