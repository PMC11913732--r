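# Synthetic cohorts: model-driven choices plus a gaze generator with the
# exogenous attention structure the analysis assumes (top-row / left-column /
# own-payoff / high-value first-fixation biases, reading-order saccade
# transitions, and a latent coupling between other-regarding preference and
# looking at the opponent's payoffs).
#
# Gaze and choices are conditionally independent given the agent parameters:
# choices depend on payoffs only through the utility model. An optional
# "gaze-causal" stress mode (gaze_causal_bonus > 0) adds a dwell-on-other
# bonus to the utility difference so classifier pipelines can be tested
# against a cohort where gaze genuinely carries extra information.

default_config_path <- function() {
  system.file("extdata", "cohort_defaults.yaml", package = "coopgaze")
}

#' Gaze generator configuration
#'
#' Returns the calibrated default gaze configuration, optionally overridden.
#' Logit biases act on the first fixation's softmax over the 8 payoff slots;
#' `transition_weights` is the move-type kernel for subsequent fixations;
#' duration parameters are in milliseconds.
#'
#' @param ... Named overrides of the defaults (see
#'   `inst/extdata/cohort_defaults.yaml`).
#' @return A list of class `gaze_config`.
#' @export
#' @examples
#' gaze_config(b_row = 0)$b_row
gaze_config <- function(...) {
  cfg <- yaml::read_yaml(default_config_path())$gaze
  cfg <- merge_config(cfg, list(...))
  w <- unlist(cfg$transition_weights)
  stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-8)
  structure(cfg, class = "gaze_config")
}

#' Synthetic cohort configuration
#'
#' Agent parameters are drawn per participant: `alpha ~ Beta`, belief
#' `p ~ Beta`, `rho ~` truncated normal, `beta ~` log-normal (upper-clamped).
#' The defaults are calibrated so that a default cohort reproduces the
#' study-scale aggregate statistics (mean cooperation near 23%, see the
#' package vignette).
#'
#' @param ... Named overrides; `gaze` may be a [gaze_config()] or a list of
#'   gaze overrides.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  defaults <- yaml::read_yaml(default_config_path())
  cfg <- defaults$cohort
  over <- list(...)
  gaze_over <- over$gaze
  over$gaze <- NULL
  cfg <- merge_config(cfg, over)
  cfg$gaze <- if (inherits(gaze_over, "gaze_config")) {
    gaze_over
  } else {
    do.call(gaze_config, as.list(gaze_over %||% list()))
  }
  structure(cfg, class = "cohort_config")
}

#' Draw agent parameters for a cohort
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return Tibble: `participant_id`, `alpha`, `p`, `rho`, `beta`.
#' @export
draw_agent_params <- function(cfg = cohort_config(), seed = cfg$seed) {
  n <- cfg$n_participants
  with_seed(derive_seed(seed, "agent-params"), {
    rho_cfg <- cfg$rho
    lo <- stats::pnorm(rho_cfg$lower, rho_cfg$mean, rho_cfg$sd)
    hi <- stats::pnorm(rho_cfg$upper, rho_cfg$mean, rho_cfg$sd)
    tibble::tibble(
      participant_id = seq_len(n),
      alpha = stats::rbeta(n, cfg$alpha$shape1, cfg$alpha$shape2),
      p = stats::rbeta(n, cfg$belief$shape1, cfg$belief$shape2),
      rho = stats::qnorm(stats::runif(n, lo, hi), rho_cfg$mean, rho_cfg$sd),
      beta = pmin(stats::rlnorm(n, cfg$beta$meanlog, cfg$beta$sdlog),
                  cfg$beta$upper)
    )
  })
}

#' Simulate choices for one session
#'
#' Bernoulli draws from the utility model's cooperation probability on each
#' trial. `delta_u_shift` adds a per-trial shift to the utility difference
#' before the softmax (used by the gaze-causal stress mode).
#'
#' @param session A [build_session()] table.
#' @param params Agent parameters (list with `alpha`, `p`, `rho`, `beta`).
#' @param seed Integer seed.
#' @param spec Model variant (default the full model).
#' @param delta_u_shift Scalar or per-trial numeric shift on `delta_u`.
#' @return Tibble: `participant_id`, `trial_idx`, `game_id`, `choice`
#'   (1 = cooperate).
#' @export
simulate_choices <- function(session, params, seed,
                             spec = model_spec("M0_full"),
                             delta_u_shift = 0) {
  u <- utilities(session, params, spec, validate = FALSE)
  params <- resolve_params(params, spec)
  pi <- stats::plogis(params$beta * (u$delta_u + delta_u_shift))
  ch <- with_seed(derive_seed(seed, "choices"),
                  stats::rbinom(nrow(session), 1L, pi))
  tibble::tibble(participant_id = session$participant_id,
                 trial_idx = session$trial_idx,
                 game_id = session$game_id,
                 choice = ch)
}

# vectorized gaze simulator over a design table; `alpha` is recycled to one
# value per trial. Returns the fixations table.
simulate_gaze <- function(design, alpha, gcfg, seed) {
  n <- nrow(design)
  alpha <- rep_len(alpha, n)
  geo <- slot_geometry(unlist(gcfg$screen), gcfg$inset_x, gcfg$inset_y)
  with_seed(derive_seed(seed, "gaze"), {
    # --- first fixation: softmax over the 8 slots -------------------------
    is_top <- rep(geo$cell_row == 1, each = n)
    is_left <- rep(geo$cell_col == 1, each = n)
    is_you <- rep(geo$person == "you", each = n)
    role_m <- matrix("", n, 8L)
    pay_m <- matrix(0, n, 8L)
    for (s in seq_len(8L)) {
      role_m[, s] <- role_at(geo$cell_row[s], geo$cell_col[s], geo$person[s],
                             design$col_pos, design$row_pos)
      pay_m[, s] <- payoff_of_role(design, role_m[, s])
    }
    logit <- gcfg$b_row * is_top + gcfg$b_col * is_left +
      gcfg$b_self * is_you + gcfg$b_val * c(pay_m) / 40 +
      gcfg$alpha_gaze_coupling * rep(alpha, 8L) * !is_you
    logit <- matrix(logit, n, 8L)
    gumbel <- -log(-log(matrix(stats::runif(n * 8L), n, 8L)))
    slot1 <- max.col(logit + gumbel, ties.method = "first")

    # --- fixation counts and subsequent slots via the move-type kernel ---
    n_fix <- pmin(1L + stats::rgeom(n, 1 / gcfg$n_fix_mean), gcfg$n_fix_max)
    max_k <- max(n_fix)
    w <- unlist(gcfg$transition_weights)[c("lateral", "vertical", "diagonal",
                                           "within_cell", "diagonal_between")]
    # state bits per trial
    row_b <- (slot1 - 1L) %/% 4L      # 0 = top
    col_b <- ((slot1 - 1L) %/% 2L) %% 2L  # 0 = left
    per_b <- (slot1 - 1L) %% 2L       # 0 = you
    slots <- matrix(NA_integer_, n, max_k)
    slots[, 1L] <- slot1
    if (max_k >= 2L) {
      for (k in 2:max_k) {
        mv <- sample.int(5L, n, replace = TRUE, prob = w)
        flip_row <- mv %in% c(2L, 3L, 5L)
        flip_col <- mv %in% c(1L, 3L, 5L)
        flip_per <- mv %in% c(4L, 5L)
        row_b <- ifelse(flip_row, 1L - row_b, row_b)
        col_b <- ifelse(flip_col, 1L - col_b, col_b)
        per_b <- ifelse(flip_per, 1L - per_b, per_b)
        s_k <- row_b * 4L + col_b * 2L + per_b + 1L
        slots[, k] <- ifelse(n_fix >= k, s_k, NA_integer_)
      }
    }

    # --- long table with durations, onsets, coordinates ------------------
    trial_of <- rep(seq_len(n), times = n_fix)
    fix_idx <- sequence(n_fix)
    slot_v <- slots[cbind(trial_of, fix_idx)]
    n_ev <- length(slot_v)
    noise <- stats::runif(n_ev) < gcfg$noise_share
    lo_q <- stats::plnorm(gcfg$min_dur_ms, gcfg$dur_meanlog, gcfg$dur_sdlog)
    dur <- ifelse(
      noise,
      stats::runif(n_ev, gcfg$noise_range_ms[[1]], gcfg$noise_range_ms[[2]]),
      stats::qlnorm(stats::runif(n_ev, lo_q, 1), gcfg$dur_meanlog,
                    gcfg$dur_sdlog))
    ends <- stats::ave(dur, trial_of, FUN = cumsum)
    onset <- ends - dur
    x <- geo$x0[slot_v] +
      stats::runif(n_ev) * (geo$x1[slot_v] - geo$x0[slot_v])
    y <- geo$y0[slot_v] +
      stats::runif(n_ev) * (geo$y1[slot_v] - geo$y0[slot_v])
    aoi <- role_at(geo$cell_row[slot_v], geo$cell_col[slot_v],
                   geo$person[slot_v], design$col_pos[trial_of],
                   design$row_pos[trial_of])
    tibble::tibble(
      participant_id = design$participant_id[trial_of],
      trial_idx = design$trial_idx[trial_of],
      fix_idx = fix_idx,
      onset_ms = onset,
      duration_ms = dur,
      aoi = aoi,
      x = x,
      y = y
    )
  })
}

#' Simulate the fixation sequence of one trial
#'
#' First AOI drawn from a softmax over the 8 payoff slots with logit
#' `b_row*[top] + b_col*[left] + b_self*[own] + b_val*payoff/40 +
#' coupling*alpha*[other]`; later AOIs follow the move-type kernel; durations
#' are i.i.d. log-normal (truncated above the keep threshold) with a
#' configurable share of sub-threshold noise events.
#'
#' @param trial One row of a session table.
#' @param params Agent parameters (only `alpha` is used by the generator).
#' @param gcfg A [gaze_config()].
#' @param seed Integer seed.
#' @return Fixations tibble (`participant_id`, `trial_idx`, `fix_idx`,
#'   `onset_ms`, `duration_ms`, `aoi`, `x`, `y`).
#' @export
simulate_gaze_trial <- function(trial, params, gcfg = gaze_config(), seed) {
  simulate_gaze(as.data.frame(trial), params$alpha %||% 0, gcfg, seed)
}

#' Simulate a full synthetic cohort
#'
#' Draws agent parameters, builds each participant's session, simulates
#' choices from the utility model and fixation sequences from the gaze
#' generator, and returns everything together with the ground truth. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `coop_cohort`: list with `design`, `choices`
#'   (incl. `rt_ms`), `fixations`, `truth`, `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  truth <- draw_agent_params(cfg)
  design <- do.call(rbind, lapply(truth$participant_id, function(pid) {
    build_session(pid, cfg$seed)
  }))
  alpha_trial <- truth$alpha[match(design$participant_id,
                                   truth$participant_id)]
  fixations <- simulate_gaze(design, alpha_trial, cfg$gaze,
                             seed = derive_seed(cfg$seed, "cohort-gaze"))
  # trial RT = summed fixation time + motor constant
  key <- paste(fixations$participant_id, fixations$trial_idx)
  rt <- tapply(fixations$duration_ms, key, sum) + cfg$gaze$motor_ms
  dkey <- paste(design$participant_id, design$trial_idx)
  rt_ms <- as.numeric(rt[dkey])
  shift <- 0
  if ((cfg$gaze_causal_bonus %||% 0) != 0) {
    # dwell-causal stress mode: utility bonus proportional to the share of
    # kept fixation time spent on the opponent's payoffs
    kept <- fixations$duration_ms > cfg$gaze$min_dur_ms
    oth <- kept & grepl("_O$", fixations$aoi)
    tot <- tapply(fixations$duration_ms[kept], key[kept], sum)
    osum <- tapply(fixations$duration_ms[oth], key[oth], sum)
    share <- as.numeric(osum[dkey]) / as.numeric(tot[dkey])
    share[!is.finite(share)] <- 0
    shift <- shift + cfg$gaze_causal_bonus * share
  }
  if ((cfg$gaze_seq_bonus %||% 0) != 0) {
    # sequence-causal stress mode: utility bonus when the opponent's reward
    # is the second payoff sampled (a timing signal aggregate dwell blurs)
    kf <- fixations[fixations$duration_ms > cfg$gaze$min_dur_ms, ]
    kf <- kf[order(kf$participant_id, kf$trial_idx, kf$onset_ms), ]
    kkey <- paste(kf$participant_id, kf$trial_idx)
    pos <- stats::ave(seq_along(kkey), kkey, FUN = seq_along)
    second <- kf$aoi[pos == 2][match(dkey, kkey[pos == 2])]
    shift <- shift +
      cfg$gaze_seq_bonus * as.numeric(!is.na(second) & second == "R_O")
  }
  choices <- do.call(rbind, lapply(truth$participant_id, function(pid) {
    rows <- design$participant_id == pid
    pars <- as.list(truth[truth$participant_id == pid,
                          c("alpha", "p", "rho", "beta")])
    simulate_choices(design[rows, ], pars,
                     seed = derive_seed(cfg$seed, paste0("choices-", pid)),
                     delta_u_shift = if (length(shift) > 1) shift[rows]
                                     else shift)
  }))
  choices$rt_ms <- rt_ms
  structure(list(design = design, choices = choices, fixations = fixations,
                 truth = truth, config = cfg),
            class = "coop_cohort")
}

#' @export
print.coop_cohort <- function(x, ...) {
  cat("<coop_cohort> ", nrow(x$truth), " participants, ",
      nrow(x$design), " trials, ", nrow(x$fixations), " fixations\n",
      sep = "")
  invisible(x)
}

# first kept (> min_dur) fixation of every trial, as a tibble
first_kept_fixations <- function(fixations, min_dur = 100) {
  kept <- fixations[fixations$duration_ms > min_dur, ]
  kept <- kept[order(kept$participant_id, kept$trial_idx, kept$onset_ms), ]
  key <- paste(kept$participant_id, kept$trial_idx)
  kept[!duplicated(key), ]
}

#' Calibration summary of a synthetic cohort
#'
#' Computes the aggregate statistics the generator is calibrated against:
#' the cooperation base rate, the shares of first (kept) fixations landing in
#' the top row, the left column, and on own-payoff AOIs, and the per-AOI
#' first-fixation histogram. Shares come with Monte-Carlo standard errors.
#'
#' @param ds A `coop_cohort`.
#' @return List with `coop_rate`, `coop_se`, `first_fix` (top/left/own shares
#'   and SEs), `first_aoi_hist` (named shares summing to 1), `n_trials`.
#' @export
calibration_report <- function(ds) {
  stopifnot(inherits(ds, "coop_cohort"))
  if (nrow(ds$choices) == 0L) stop("empty dataset")
  gcfg <- ds$config$gaze
  scr <- unlist(gcfg$screen)
  ff <- first_kept_fixations(ds$fixations, gcfg$min_dur_ms)
  n <- nrow(ff)
  share <- function(x) mean(x)
  se <- function(x) sqrt(mean(x) * (1 - mean(x)) / length(x))
  top <- ff$y < scr[2] / 2
  left <- ff$x < scr[1] / 2
  own <- grepl("_Y$", ff$aoi)
  hist <- table(factor(ff$aoi, levels = aoi_names())) / n
  coop <- as_choice01(ds$choices$choice)
  list(
    coop_rate = mean(coop),
    coop_se = stats::sd(coop) / sqrt(length(coop)),
    first_fix = list(
      top = share(top), top_se = se(top),
      left = share(left), left_se = se(left),
      own = share(own), own_se = se(own)),
    first_aoi_hist = as.numeric(hist) |> stats::setNames(aoi_names()),
    n_trials = n
  )
}

#' First-fixation marginals of the gaze generator
#'
#' Simulates approximately `n_trials` trials (whole sessions, agents drawn
#' from the cohort configuration) and returns the top-row, left-column and
#' own-payoff shares of the first kept fixation. This is the quantity the
#' default configuration is calibrated against.
#'
#' @param n_trials Target number of trials (default 10000).
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return Named numeric vector `c(top=, left=, own=)` of proportions.
#' @export
first_fix_shares <- function(n_trials = 10000, cfg = cohort_config(),
                             seed = cfg$seed) {
  n_part <- ceiling(n_trials / 192)
  cfg2 <- cfg
  cfg2$n_participants <- n_part
  cfg2$seed <- seed
  truth <- draw_agent_params(cfg2)
  design <- do.call(rbind, lapply(truth$participant_id, function(pid) {
    build_session(pid, seed)
  }))
  design <- design[seq_len(min(n_trials, nrow(design))), ]
  alpha_trial <- truth$alpha[match(design$participant_id,
                                   truth$participant_id)]
  fix <- simulate_gaze(design, alpha_trial, cfg2$gaze,
                       seed = derive_seed(seed, "marginals"))
  ff <- first_kept_fixations(fix, cfg2$gaze$min_dur_ms)
  scr <- unlist(cfg2$gaze$screen)
  c(top = mean(ff$y < scr[2] / 2),
    left = mean(ff$x < scr[1] / 2),
    own = mean(grepl("_Y$", ff$aoi)))
}

#' Write cohort tables to CSV
#'
#' Writes `design.csv`, `choices.csv`, `fixations.csv`, `truth.csv` into
#' `dir`.
#'
#' @param ds A `coop_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csvs <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$design, file.path(dir, "design.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$choices, file.path(dir, "choices.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$fixations, file.path(dir, "fixations.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
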