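# End-to-end orchestration: simulate -> fit -> features -> classify ->
# report, plus schema validation of on-disk inputs. All tables are CSV with
# a header row; the report is JSON. Stage seeds are derived deterministically
# from the single global seed via derive_seed(), so a run is reproducible
# end to end.

#' Pipeline run configuration
#'
#' @param cohort A [cohort_config()] (the study conditions).
#' @param variants Model variants to fit (default the full model only; pass
#'   [model_variants()] for the full comparison).
#' @param n_starts Optimizer starts per fit.
#' @param feature_configs Named list of feature configurations (see
#'   [feature_set_configs()]); the first is also used for the chance level.
#' @param tree A [tree_config()].
#' @param n_perm Label shuffles per fold for the chance level (0 skips it).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       variants = "M0_full",
                       n_starts = 50,
                       feature_configs =
                         feature_set_configs()["payoff_s1to4_last"],
                       tree = tree_config(),
                       n_perm = 0,
                       seed = 1) {
  structure(list(cohort = cohort, variants = variants, n_starts = n_starts,
                 feature_configs = feature_configs, tree = tree,
                 n_perm = n_perm, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, fits the requested model variants to every eligible
#' participant, extracts gaze features, runs leave-one-subject-out
#' classification for each feature configuration (plus the permutation
#' chance level if requested), writes all tables under `out_dir`
#' (`design.csv`, `choices.csv`, `fixations.csv`, `truth.csv`, `fits.csv`,
#' `features.csv`, `gaze_summaries.csv`, `cv_predictions.csv`,
#' `scores.json`, `report.json`) and returns the report. Idempotent given
#' the seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  report <- list(seed = cfg$seed)
  tryCatch({
    cohort_cfg <- cfg$cohort
    cohort_cfg$seed <- derive_seed(cfg$seed, "cohort")
    ds <- simulate_cohort(cohort_cfg)
    write_cohort_csvs(ds, out_dir)
    report$n_games <- nrow(enumerate_games())
    report$n_participants <- nrow(ds$truth)
    report$n_trials <- nrow(ds$choices)
    report$calibration <- calibration_report(ds)

    stage <- "fit"
    eligible <- vapply(split(ds$choices, ds$choices$participant_id),
                       eligible_for_fit, logical(1))
    fit_rows <- list()
    for (pid in names(eligible)[eligible]) {
      rows <- ds$choices$participant_id == as.integer(pid)
      dat <- cbind(ds$design[rows, c("T", "R", "P", "S")],
                   choice = ds$choices$choice[rows])
      for (v in cfg$variants) {
        fit <- fit_mle(dat, model_spec(v),
                       seed = derive_seed(cfg$seed, paste0("fit-", pid)),
                       n_starts = cfg$n_starts)
        fit_rows[[length(fit_rows) + 1L]] <- tibble::tibble(
          participant_id = as.integer(pid), variant = v,
          alpha = unname(fit$params["alpha"]),
          p = unname(fit$params["p"]),
          rho = unname(fit$params["rho"]),
          beta = unname(fit$params["beta"]),
          extras = as.character(jsonlite::toJSON(
            as.list(fit$params[setdiff(names(fit$params),
                                       c("alpha", "p", "rho", "beta"))]),
            auto_unbox = TRUE, digits = NA)),
          loglik = fit$loglik, bic = fit$bic, k = fit$k,
          converged = fit$converged, n_starts = fit$n_starts_used)
      }
    }
    fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
    if (!is.null(fits)) {
      write_fits_csv(fits, file.path(out_dir, "fits.csv"))
      report$n_eligible <- sum(eligible)
      report$model_comparison <- stats::aggregate(
        bic ~ variant + k, data = fits, FUN = mean)
    }

    stage <- "features"
    summaries <- summarize_gaze(ds)
    utils::write.csv(summaries, file.path(out_dir, "gaze_summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    first_cfg <- cfg$feature_configs[[1]]
    feats <- build_features(ds, encoding = first_cfg$encoding,
                            slots = first_cfg$slots, summaries = summaries)
    write_features_csv(feats, file.path(out_dir, "features.csv"))

    stage <- "classify"
    preds <- loso_predict(feats, cfg$tree)
    utils::write.csv(preds, file.path(out_dir, "cv_predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    mse_tab <- compare_feature_sets(ds, cfg$feature_configs, cfg$tree)
    scores <- list(
      mse = mse_tab,
      participant_mse = aggregate_and_score(preds, "participant")$mse,
      game_mse = aggregate_and_score(preds, "game")$mse)
    if (cfg$n_perm > 0) {
      scores$chance <- chance_level(feats, cfg$tree, n_perm = cfg$n_perm,
                                    seed = derive_seed(cfg$seed,
                                                       "chance"))$chance
    }
    jsonlite::write_json(scores, file.path(out_dir, "scores.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    report$mse <- mse_tab
    report$chance <- scores$chance

    stage <- "report"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    invisible(report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Validate on-disk input tables
#'
#' Schema and sanity checks for `design.csv`, `choices.csv` and
#' `fixations.csv`: required columns, admissible games (grid and PD
#' inequalities), binary choices, positive durations, non-negative onsets.
#'
#' @param paths Named list/character vector with any of `design`, `choices`,
#'   `fixations`.
#' @return Tibble of diagnostics (`file`, `rule`, `n_bad`, `rows`); zero
#'   rows means all checks passed.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  flag <- function(file, rule, bad) {
    if (any(bad)) {
      diags[[length(diags) + 1L]] <<- tibble::tibble(
        file = file, rule = rule, n_bad = sum(bad),
        rows = paste(utils::head(which(bad), 5L), collapse = ","))
    }
  }
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    flag(file, paste0("missing columns: ", paste(miss, collapse = ",")),
         length(miss) > 0)
    length(miss) == 0
  }
  if (!is.null(paths[["design"]])) {
    d <- utils::read.csv(paths[["design"]])
    if (need(d, c("participant_id", "trial_idx", "game_id", "T", "R", "P",
                  "S", "col_pos", "row_pos"), "design")) {
      ok <- vapply(seq_len(nrow(d)),
                   function(i) validate_game(d[i, ]), logical(1))
      flag("design", "invalid game (grid or PD inequalities)", !ok)
      flag("design", "unknown col_pos",
           !d$col_pos %in% position_levels()$col_pos)
      flag("design", "unknown row_pos",
           !d$row_pos %in% position_levels()$row_pos)
    }
  }
  if (!is.null(paths[["choices"]])) {
    ch <- utils::read.csv(paths[["choices"]])
    if (need(ch, c("participant_id", "trial_idx", "choice"), "choices")) {
      flag("choices", "choice not binary", !ch$choice %in% c(0, 1))
      if ("rt_ms" %in% names(ch)) {
        flag("choices", "non-positive rt_ms", !(ch$rt_ms > 0))
      }
    }
  }
  if (!is.null(paths[["fixations"]])) {
    fx <- utils::read.csv(paths[["fixations"]])
    if (need(fx, c("participant_id", "trial_idx", "onset_ms",
                   "duration_ms"), "fixations")) {
      flag("fixations", "non-positive duration", !(fx$duration_ms > 0))
      flag("fixations", "negative onset", fx$onset_ms < 0)
    }
  }
  if (length(diags)) do.call(rbind, diags) else
    tibble::tibble(file = character(), rule = character(),
                   n_bad = integer(), rows = character())
}
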