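# From fixation tables to analysis-ready gaze summaries: duration filtering,
# AOI assignment from coordinates, relative dwell, fixation-slot sequences,
# dyad statistics and classifier feature matrices.

#' Filter fixations by duration and choice phase
#'
#' Keeps fixations lasting strictly longer than `min_dur` ms. If `rt` is
#' supplied, events must also start within the choice phase `[0, rt)`. Order
#' is preserved.
#'
#' @param fixations Fixations tibble (`participant_id`, `trial_idx`,
#'   `onset_ms`, `duration_ms`, ...).
#' @param min_dur Keep threshold in ms (default 100; strictly greater-than).
#' @param rt Optional response times: a scalar, or a data frame with
#'   `participant_id`, `trial_idx`, `rt_ms`.
#' @return The filtered fixations tibble.
#' @export
filter_fixations <- function(fixations, min_dur = 100, rt = NULL) {
  keep <- fixations$duration_ms > min_dur & fixations$onset_ms >= 0
  if (!is.null(rt)) {
    if (is.data.frame(rt)) {
      idx <- match(paste(fixations$participant_id, fixations$trial_idx),
                   paste(rt$participant_id, rt$trial_idx))
      keep <- keep & fixations$onset_ms < rt$rt_ms[idx]
    } else {
      keep <- keep & fixations$onset_ms < rt
    }
  }
  fixations[keep, , drop = FALSE]
}

#' Assign screen coordinates to a payoff AOI
#'
#' Returns the AOI whose half-open rectangle `[x0, x1) x [y0, y1)` contains
#' each point, or `NA` for points in no payoff AOI (including out-of-screen
#' points).
#'
#' @param x,y Numeric vectors of pixel coordinates.
#' @param layout A [layout_for()] table.
#' @return Character vector of AOI names (`NA` = none).
#' @export
assign_aoi <- function(x, y, layout) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(layout))) {
    hit <- x >= layout$x0[i] & x < layout$x1[i] &
      y >= layout$y0[i] & y < layout$y1[i]
    out[hit & !is.na(hit)] <- layout$aoi[i]
  }
  out
}

#' Per-trial gaze summaries for a dataset
#'
#' For every trial: relative dwell per AOI (summed kept-fixation duration
#' divided by the response time), the AOIs of fixation slots 1-5 and of the
#' last kept fixation, and the kept-fixation count. Trials with no kept
#' fixation get zero dwell and `NA` slots; slot k is `NA` whenever fewer than
#' k fixations were kept; `last` duplicates an earlier slot when 5 or fewer
#' fixations were kept.
#'
#' @param ds A `coop_cohort`, or a list with `fixations` and `choices`
#'   (choices must carry `rt_ms`).
#' @param min_dur Keep threshold in ms.
#' @return Tibble keyed by (`participant_id`, `trial_idx`) with `n_fix`,
#'   `dwell_<AOI>` columns and `slot1`..`slot5`, `slot_last`.
#' @export
summarize_gaze <- function(ds, min_dur = 100) {
  choices <- ds$choices
  if (any(!is.finite(choices$rt_ms)) || any(choices$rt_ms <= 0)) {
    stop("response times must be positive")
  }
  f <- filter_fixations(ds$fixations, min_dur = min_dur, rt = choices)
  f <- f[order(f$participant_id, f$trial_idx, f$onset_ms), ]
  fkey <- paste(f$participant_id, f$trial_idx)
  ckey <- paste(choices$participant_id, choices$trial_idx)
  out <- tibble::tibble(participant_id = choices$participant_id,
                        trial_idx = choices$trial_idx)
  cnt <- table(fkey)
  out$n_fix <- as.integer(cnt[ckey])
  out$n_fix[is.na(out$n_fix)] <- 0L
  # relative dwell per AOI
  for (a in aoi_names()) {
    sel <- f$aoi == a
    d <- tapply(f$duration_ms[sel], fkey[sel], sum)
    v <- as.numeric(d[ckey])
    v[is.na(v)] <- 0
    out[[paste0("dwell_", a)]] <- v / choices$rt_ms
  }
  # fixation slots
  pos <- stats::ave(seq_along(fkey), fkey, FUN = seq_along)
  for (j in 1:5) {
    sel <- pos == j
    out[[paste0("slot", j)]] <-
      f$aoi[sel][match(ckey, fkey[sel])]
  }
  lastsel <- !duplicated(fkey, fromLast = TRUE)
  out$slot_last <- f$aoi[lastsel][match(ckey, fkey[lastsel])]
  out
}

#' Summarize one trial's fixation sequence
#'
#' Single-trial convenience wrapper around the same logic as
#' [summarize_gaze()].
#'
#' @param seq Fixations tibble for one trial (already or not yet filtered).
#' @param rt Response time in ms (> 0).
#' @param min_dur Keep threshold in ms.
#' @return List with `dwell` (named length-8 vector), `slots` (named
#'   character vector `slot1`..`slot5`, `last`), `n_fix`.
#' @export
summarize_trial <- function(seq, rt, min_dur = 100) {
  if (!is.finite(rt) || rt <= 0) stop("response times must be positive")
  seq$participant_id <- seq$participant_id %||% 1L
  seq$trial_idx <- seq$trial_idx %||% 1L
  ds <- list(fixations = seq,
             choices = tibble::tibble(
               participant_id = seq$participant_id[1] %||% 1L,
               trial_idx = seq$trial_idx[1] %||% 1L,
               rt_ms = rt))
  s <- summarize_gaze(ds, min_dur = min_dur)
  list(dwell = stats::setNames(as.numeric(s[1, paste0("dwell_", aoi_names())]),
                               aoi_names()),
       slots = stats::setNames(
         as.character(s[1, c(paste0("slot", 1:5), "slot_last")]),
         c(paste0("slot", 1:5), "last")),
       n_fix = s$n_fix[1])
}

#' Build a classifier feature matrix
#'
#' Encodings:
#' \describe{
#'   \item{`dummy`}{8 indicator columns per fixation slot: AOI a fixated at
#'     slot s.}
#'   \item{`payoff`}{one column per (AOI, slot) pair carrying the payoff
#'     value displayed in that AOI when it was fixated at that slot, else 0.}
#'   \item{`dwell`}{the 8 relative dwell times (slots ignored).}
#'   \item{`payoffs`}{the four payoff values T, R, P, S of the trial's game
#'     (gaze-free baseline; slots ignored).}
#' }
#' Unfixated slots encode as all-zero. Column order is fixed: slots in the
#' order given, AOIs in [aoi_names()] order, named `s<slot>_<AOI>`.
#'
#' @param ds A `coop_cohort` (or list with `design`, `choices`, `fixations`).
#' @param encoding One of `"dummy"`, `"payoff"`, `"dwell"`, `"payoffs"`.
#' @param slots Slot identifiers out of `1:5` and `"last"` (default
#'   `c(1, 2, 3, 4, "last")`).
#' @param min_dur Keep threshold in ms.
#' @param summaries Optional precomputed [summarize_gaze()] table.
#' @return An object of class `coop_features`: list with `x` (numeric
#'   matrix), `y` (0/1 labels, cooperate = 1), `participant_id`, `game_id`,
#'   `trial_idx`, `encoding`, `slots`.
#' @export
build_features <- function(ds, encoding = c("dummy", "payoff", "dwell",
                                            "payoffs"),
                           slots = c(1, 2, 3, 4, "last"), min_dur = 100,
                           summaries = NULL) {
  encoding <- match.arg(encoding)
  slots <- as.character(slots)
  stopifnot(all(slots %in% c(as.character(1:5), "last")))
  if (is.null(summaries)) summaries <- summarize_gaze(ds, min_dur = min_dur)
  key <- paste(summaries$participant_id, summaries$trial_idx)
  dkey <- paste(ds$design$participant_id, ds$design$trial_idx)
  di <- match(key, dkey)
  ckey <- paste(ds$choices$participant_id, ds$choices$trial_idx)
  ci <- match(key, ckey)
  if (encoding %in% c("dummy", "payoff")) {
    cols <- as.vector(outer(aoi_names(), slots,
                            function(a, s) paste0("s", s, "_", a)))
    x <- matrix(0, nrow(summaries), length(cols),
                dimnames = list(NULL, cols))
    for (s in slots) {
      slot_col <- if (s == "last") "slot_last" else paste0("slot", s)
      v <- summaries[[slot_col]]
      for (a in aoi_names()) {
        hit <- !is.na(v) & v == a
        val <- if (encoding == "dummy") 1 else
          payoff_of_role(ds$design[di, ], rep(a, nrow(summaries)))
        x[hit, paste0("s", s, "_", a)] <- if (encoding == "dummy") 1 else
          val[hit]
      }
    }
  } else if (encoding == "dwell") {
    x <- as.matrix(summaries[, paste0("dwell_", aoi_names())])
  } else {
    x <- as.matrix(ds$design[di, c("T", "R", "P", "S")])
    colnames(x) <- c("T", "R", "P", "S")
  }
  structure(list(
    x = x,
    y = as_choice01(ds$choices$choice[ci]),
    participant_id = summaries$participant_id,
    game_id = ds$design$game_id[di],
    trial_idx = summaries$trial_idx,
    encoding = encoding,
    slots = slots
  ), class = "coop_features")
}

# roles sitting in the opponent-cooperates row (own-cooperate column roles
# are {R_Y, R_O, S_Y, T_O}); membership is position-invariant because roles
# are defined by outcomes, positions only move them on screen
coop_row_roles <- function() c("R_Y", "R_O", "T_Y", "S_O")

#' Aggregate dwell and first-fixation shares
#'
#' Mean relative dwell per AOI by participant or by trial, with derived
#' shares: summed dwell on the opponent's AOIs and on the
#' opponent-cooperates-row AOIs, plus the group's cooperation rate.
#'
#' @param ds A `coop_cohort`.
#' @param group_by `"participant"` or `"trial"`.
#' @param min_dur Keep threshold in ms.
#' @param summaries Optional precomputed [summarize_gaze()] table.
#' @return Tibble with one row per group.
#' @export
dwell_aggregates <- function(ds, group_by = c("participant", "trial"),
                             min_dur = 100, summaries = NULL) {
  group_by <- match.arg(group_by)
  if (is.null(summaries)) summaries <- summarize_gaze(ds, min_dur = min_dur)
  g <- if (group_by == "participant") summaries$participant_id else
    paste(summaries$participant_id, summaries$trial_idx)
  ckey <- paste(ds$choices$participant_id, ds$choices$trial_idx)
  skey <- paste(summaries$participant_id, summaries$trial_idx)
  coop <- as_choice01(ds$choices$choice)[match(skey, ckey)]
  dw <- summaries[, paste0("dwell_", aoi_names())]
  agg <- stats::aggregate(dw, by = list(group = g), FUN = mean)
  agg$other_dwell <- rowSums(agg[, paste0("dwell_",
                                          grep("_O$", aoi_names(),
                                               value = TRUE))])
  agg$own_dwell <- rowSums(agg[, paste0("dwell_",
                                        grep("_Y$", aoi_names(),
                                             value = TRUE))])
  agg$coop_row_dwell <- rowSums(agg[, paste0("dwell_", coop_row_roles())])
  agg$coop_rate <- stats::aggregate(coop, by = list(group = g),
                                    FUN = mean)$x
  tibble::as_tibble(agg)
}

#' Gaze-dyad statistics
#'
#' Frequency of each (first AOI, second AOI) pair over trials with at least
#' two kept fixations, overall and within each option-position stratum, and
#' the cooperation rate per dyad (mean of participant-level rates, each
#' participant contributing the mean of their own trials with that dyad).
#'
#' @param ds A `coop_cohort`.
#' @param min_dur Keep threshold in ms.
#' @param summaries Optional precomputed [summarize_gaze()] table.
#' @return Tibble: `col_pos`, `row_pos` (`"all"` for the overall stratum),
#'   `slot1`, `slot2`, `n_trials`, `freq`, `coop_rate`.
#' @export
dyad_stats <- function(ds, min_dur = 100, summaries = NULL) {
  if (is.null(summaries)) summaries <- summarize_gaze(ds, min_dur = min_dur)
  skey <- paste(summaries$participant_id, summaries$trial_idx)
  dkey <- paste(ds$design$participant_id, ds$design$trial_idx)
  ckey <- paste(ds$choices$participant_id, ds$choices$trial_idx)
  di <- match(skey, dkey)
  coop <- as_choice01(ds$choices$choice)[match(skey, ckey)]
  ok <- !is.na(summaries$slot1) & !is.na(summaries$slot2)
  d <- tibble::tibble(
    participant_id = summaries$participant_id[ok],
    col_pos = ds$design$col_pos[di][ok],
    row_pos = ds$design$row_pos[di][ok],
    slot1 = summaries$slot1[ok],
    slot2 = summaries$slot2[ok],
    coop = coop[ok])
  strata <- rbind(
    cbind(d, stratum_col = "all", stratum_row = "all"),
    cbind(d, stratum_col = d$col_pos, stratum_row = d$row_pos))
  out <- do.call(rbind, lapply(
    split(strata, list(strata$stratum_col, strata$stratum_row),
          drop = TRUE),
    function(s) {
      dy <- paste(s$slot1, s$slot2, sep = "->")
      tab <- table(dy)
      rate <- vapply(names(tab), function(k) {
        sel <- dy == k
        mean(tapply(s$coop[sel], s$participant_id[sel], mean))
      }, numeric(1))
      tibble::tibble(
        col_pos = s$stratum_col[1], row_pos = s$stratum_row[1],
        slot1 = sub("->.*", "", names(tab)),
        slot2 = sub(".*->", "", names(tab)),
        n_trials = as.integer(tab),
        freq = as.integer(tab) / sum(tab),
        coop_rate = unname(rate))
    }))
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Write a feature matrix to CSV
#'
#' Wide layout: identifier columns, label, then feature columns.
#'
#' @param features A `coop_features`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(participant_id = features$participant_id,
                   trial_idx = features$trial_idx,
                   game_id = features$game_id,
                   choice = features$y,
                   features$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
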