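# fixtures are built in code; nothing is read from disk

tiny_cohort <- function(n_participants = 6, seed = 1, ...) {
  simulate_cohort(cohort_config(n_participants = n_participants, seed = seed,
                                ...))
}

one_session <- function(seed = 7, participant_id = 1) {
  build_session(participant_id, seed)
}

# minimal hand-built dataset: one participant, trials taken from a real
# session so games/layouts are valid; fixations supplied by the caller as a
# list of data.frames (one per trial) with columns onset_ms, duration_ms,
# aoi (and optionally x, y)
manual_ds <- function(fix_list, rt_ms = 1000, seed = 3) {
  des <- build_session(1, seed)[seq_along(fix_list), ]
  fx <- do.call(rbind, lapply(seq_along(fix_list), function(i) {
    f <- fix_list[[i]]
    if (is.null(f) || nrow(f) == 0) return(NULL)
    f$participant_id <- 1L
    f$trial_idx <- i
    f$fix_idx <- seq_len(nrow(f))
    if (!"x" %in% names(f)) f$x <- 10
    if (!"y" %in% names(f)) f$y <- 10
    f
  }))
  ch <- tibble::tibble(participant_id = 1L,
                       trial_idx = seq_along(fix_list),
                       game_id = des$game_id,
                       choice = rep_len(c(1L, 0L), length(fix_list)),
                       rt_ms = rep_len(rt_ms, length(fix_list)))
  list(design = des, choices = ch, fixations = tibble::as_tibble(fx))
}
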