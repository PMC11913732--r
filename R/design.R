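# Game-set enumeration, session construction, and the payoff-to-screen AOI
# layout for the one-shot Prisoner's Dilemma task.
#
# Conventions used throughout the package:
#   * payoffs T (temptation), R (reward), P (punishment), S (sucker's) lie on
#     the grid {0, 5, ..., 40};
#   * screen columns encode the participant's own action (the key press
#     selects a column), rows encode the opponent's action;
#   * `col_pos` says which column holds the participant's cooperation option,
#     `row_pos` which row holds the opponent's cooperation;
#   * the 8 payoff AOIs are named by role: T_Y, R_Y, P_Y, S_Y for the
#     participant ("you") and T_O, R_O, P_O, S_O for the opponent ("other").

#' @name coopgaze-constants
#' @title Fixed conventions of the task design
#' @description `aoi_names()` returns the canonical ordering of the eight
#'   payoff AOIs used for feature columns and histograms; `payoff_grid()`
#'   returns the admissible payoff values.
NULL

#' @rdname coopgaze-constants
#' @export
aoi_names <- function() {
  c("T_Y", "R_Y", "P_Y", "S_Y", "T_O", "R_O", "P_O", "S_O")
}

#' @rdname coopgaze-constants
#' @export
payoff_grid <- function() seq(0, 40, by = 5)

#' Validate one Prisoner's Dilemma game
#'
#' A game is admissible when all four payoffs lie on the 0-40 step-5 grid and
#' satisfy the PD inequalities T > R, R > P, P > S, T > S together with the
#' efficiency condition 2R > T + S (mutual cooperation beats alternating
#' exploitation).
#'
#' @param g A list or one-row data frame with numeric fields `T`, `R`, `P`,
#'   `S`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' validate_game(list(T = 40, R = 30, P = 10, S = 0)) # TRUE
#' validate_game(list(T = 40, R = 20, P = 10, S = 5)) # FALSE: 2R <= T + S
validate_game <- function(g) {
  v <- c(g$T, g$R, g$P, g$S)
  if (length(v) != 4L || !all(is.finite(v))) return(FALSE)
  all(v %in% payoff_grid()) &&
    g$T > g$R && g$R > g$P && g$P > g$S && g$T > g$S && 2 * g$R > g$T + g$S
}

#' Enumerate the complete game set
#'
#' Scans all grid quadruples (T, R, P, S) on {0, 5, ..., 40} and keeps those
#' satisfying the five inequalities of [validate_game()]. There are exactly 96
#' such games. `game_id` is assigned in (T, R, P, S) lexicographic order, a
#' fixed package convention.
#'
#' @return A tibble with columns `game_id`, `T`, `R`, `P`, `S`.
#' @export
#' @examples
#' nrow(enumerate_games()) # 96
enumerate_games <- function() {
  grid <- payoff_grid()
  g <- expand.grid(S = grid, P = grid, R = grid, T = grid,
                   KEEP.OUT.ATTRS = FALSE)
  keep <- g$T > g$R & g$R > g$P & g$P > g$S & g$T > g$S & 2 * g$R > g$T + g$S
  g <- g[keep, c("T", "R", "P", "S")]
  g <- g[order(g$T, g$R, g$P, g$S), , drop = FALSE]
  tibble::tibble(game_id = seq_len(nrow(g)), T = g$T, R = g$R, P = g$P,
                 S = g$S)
}

position_levels <- function() {
  list(col_pos = c("cooperate-left", "cooperate-right"),
       row_pos = c("cooperate-up", "cooperate-down"))
}

#' Build one participant's 192-trial session
#'
#' Each of the 96 games is played once per block in an independently shuffled
#' order (two blocks by default). The four option-position conditions
#' (cooperate-left/right crossed with cooperate-up/down) are exactly
#' counterbalanced within each block: 24 trials per combination, assigned by a
#' seeded shuffle. The whole session is a deterministic function of
#' `(participant_id, seed)`.
#'
#' @param participant_id Integer or character participant identifier.
#' @param seed Integer seed.
#' @param n_blocks Number of blocks (default 2; each block replays the full
#'   game set).
#' @return A tibble with one row per trial: `participant_id`, `block`,
#'   `trial_idx`, `game_id`, `T`, `R`, `P`, `S`, `col_pos`, `row_pos`.
#' @export
build_session <- function(participant_id, seed, n_blocks = 2) {
  games <- enumerate_games()
  n <- nrow(games)
  stopifnot(n %% 4L == 0L)
  lev <- position_levels()
  combos <- expand.grid(col_pos = lev$col_pos, row_pos = lev$row_pos,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- derive_seed(seed, paste0("session-", participant_id))
  with_seed(s, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      ord <- sample.int(n)
      pos <- sample(rep(seq_len(4L), each = n %/% 4L))
      tibble::tibble(
        participant_id = participant_id,
        block = b,
        game_id = games$game_id[ord],
        T = games$T[ord], R = games$R[ord],
        P = games$P[ord], S = games$S[ord],
        col_pos = combos$col_pos[pos],
        row_pos = combos$row_pos[pos]
      )
    })
    out <- do.call(rbind, blocks)
    out$trial_idx <- seq_len(nrow(out))
    out[, c("participant_id", "block", "trial_idx", "game_id",
            "T", "R", "P", "S", "col_pos", "row_pos")]
  })
}

# geometry of the 8 payoff slots in screen space; slot index is
# (cell_row - 1) * 4 + (cell_col - 1) * 2 + person, person 1 = you, 2 = other
slot_geometry <- function(screen = c(1920, 1080), inset_x = 60,
                          inset_y = 70) {
  cw <- screen[1] / 2
  ch <- screen[2] / 2
  half <- cw / 2
  slots <- expand.grid(person = c("you", "other"), cell_col = 1:2,
                       cell_row = 1:2, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  sx0 <- (slots$cell_col - 1) * cw + ifelse(slots$person == "you", 0, half)
  tibble::tibble(
    slot = seq_len(8L),
    person = slots$person,
    cell_row = slots$cell_row,
    cell_col = slots$cell_col,
    x0 = sx0 + inset_x,
    x1 = sx0 + half - inset_x,
    y0 = (slots$cell_row - 1) * ch + inset_y,
    y1 = (slots$cell_row - 1) * ch + ch - inset_y
  )
}

# role displayed at a screen cell, given own/other actions implied by the cell
role_at <- function(cell_row, cell_col, person, col_pos, row_pos) {
  n <- max(length(cell_row), length(cell_col), length(person),
           length(col_pos), length(row_pos))
  cell_row <- rep_len(cell_row, n)
  cell_col <- rep_len(cell_col, n)
  person <- rep_len(person, n)
  col_pos <- rep_len(col_pos, n)
  row_pos <- rep_len(row_pos, n)
  own_c <- ifelse(col_pos == "cooperate-left", 1L, 2L)
  oth_c <- ifelse(row_pos == "cooperate-up", 1L, 2L)
  own_coop <- cell_col == own_c
  oth_coop <- cell_row == oth_c
  you <- ifelse(own_coop & oth_coop, "R_Y",
         ifelse(own_coop & !oth_coop, "S_Y",
         ifelse(!own_coop & oth_coop, "T_Y", "P_Y")))
  oth <- ifelse(own_coop & oth_coop, "R_O",
         ifelse(own_coop & !oth_coop, "T_O",
         ifelse(!own_coop & oth_coop, "S_O", "P_O")))
  ifelse(person == "you", you, oth)
}

# payoff value displayed in an AOI: the role's first letter names the payoff
payoff_of_role <- function(game, role) {
  key <- substr(role, 1L, 1L)
  n <- max(length(key), length(game$T))
  vals <- cbind(T = rep_len(game$T, n), R = rep_len(game$R, n),
                P = rep_len(game$P, n), S = rep_len(game$S, n))
  vals[cbind(seq_len(n), match(rep_len(key, n), colnames(vals)))]
}

#' AOI layout for one trial
#'
#' Maps the 8 payoff roles to screen rectangles. The screen (default
#' 1920x1080, origin top-left, y increasing downward) is tiled by four equal
#' cells. Within each cell the participant's own payoff occupies the left
#' slot and the opponent's the right slot (the task draws "you" bars left of
#' "other" bars); each payoff AOI is an inset rectangle of its slot, half-open
#' `[x0, x1) x [y0, y1)`, so points in a cell but outside both insets belong
#' to no payoff AOI.
#'
#' @param trial One row of a [build_session()] table (needs `col_pos`,
#'   `row_pos`, and the payoffs).
#' @param screen `c(width, height)` in pixels.
#' @param inset_x,inset_y Pixel margins between a slot and its AOI rectangle.
#' @return A tibble with columns `aoi`, `person`, `cell_row`, `cell_col`,
#'   `x0`, `x1`, `y0`, `y1`, `payoff`.
#' @export
layout_for <- function(trial, screen = c(1920, 1080), inset_x = 60,
                       inset_y = 70) {
  geo <- slot_geometry(screen, inset_x, inset_y)
  role <- role_at(geo$cell_row, geo$cell_col, geo$person,
                  trial$col_pos, trial$row_pos)
  tibble::tibble(
    aoi = role,
    person = geo$person,
    cell_row = geo$cell_row,
    cell_col = geo$cell_col,
    x0 = geo$x0, x1 = geo$x1, y0 = geo$y0, y1 = geo$y1,
    payoff = payoff_of_role(trial, role)
  )
}

#' Write a design table to CSV
#'
#' @param design A [build_session()] table (possibly row-bound across
#'   participants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
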