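# Trial-by-trial prediction of cooperation from gaze features: a single
# fully grown classification tree (Gini impurity, grown by the randomForest
# engine with ntree = 1, all features considered at every node, no depth
# cap) under leave-one-subject-out cross-validation, scored by participant-
# and game-level MSE against a label-permutation chance level.

#' Decision-tree configuration
#'
#' Defaults grow a fully grown tree (`min_leaf = 1`, unlimited depth),
#' the standard behaviour of single-tree classification routines: leaves are
#' pure unless identical feature rows carry different labels, in which case
#' the leaf votes its majority. Splits use Gini impurity; exact split ties
#' are broken by the seeded feature-scan order, so results are deterministic
#' given the seed.
#'
#' @param min_leaf Minimum training trials per leaf (default 1, fully
#'   grown).
#' @param max_leaves Optional cap on the number of leaves (`NULL` =
#'   unlimited).
#' @param predict_type `"label"` (hard 0/1 predictions, the default
#'   aggregation) or `"prob"` (leaf cooperation probabilities).
#' @param seed Integer seed for split tie-breaking.
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(min_leaf = 1, max_leaves = NULL,
                        predict_type = c("label", "prob"), seed = 1) {
  stopifnot(min_leaf >= 1)
  structure(list(min_leaf = min_leaf, max_leaves = max_leaves,
                 predict_type = match.arg(predict_type), seed = seed),
            class = "tree_config")
}

#' Train a classification tree on a feature matrix
#'
#' Greedy binary recursive partitioning on Gini impurity, grown to purity
#' (or to the `min_leaf`/`max_leaves` limits). A single-class label vector
#' yields a constant (only-class) classifier with a warning.
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels (cooperate = 1).
#' @param cfg A [tree_config()].
#' @return A fitted classifier (single-tree `randomForest` object).
#' @export
train_tree <- function(x, y, cfg = tree_config()) {
  stopifnot(nrow(x) > 0L, nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    warning("single-class labels: constant classifier")
    return(structure(list(constant = TRUE, label = y[1],
                          prob = mean(y)), class = "coop_tree"))
  }
  if (all(matrixStats_colconst(x))) {
    # no feature varies: majority-class predictor (ties go to defect)
    return(structure(list(constant = TRUE,
                          label = as.integer(mean(y) > 0.5),
                          prob = mean(y)), class = "coop_tree"))
  }
  yf <- factor(y, levels = c(0L, 1L))
  rf <- with_seed(derive_seed(cfg$seed, "tree"), {
    randomForest::randomForest(
      x, yf, ntree = 1L, mtry = ncol(x), replace = FALSE,
      sampsize = nrow(x), nodesize = cfg$min_leaf,
      maxnodes = cfg$max_leaves)
  })
  obj <- structure(list(constant = FALSE, rf = rf), class = "coop_tree")
  if (cfg$predict_type == "prob") {
    # leaf cooperation probabilities = training-label means per leaf
    tr <- randomForest::getTree(rf, 1L)
    leaf <- route_tree(tr, x)
    p <- tapply(y, leaf, mean)
    probs <- rep(mean(y), nrow(tr))
    probs[as.integer(names(p))] <- as.numeric(p)
    obj$tree <- tr
    obj$leaf_prob <- probs
  }
  obj
}

# TRUE for columns with no variation
matrixStats_colconst <- function(x) {
  vapply(seq_len(ncol(x)),
         function(j) all(x[, j] == x[1, j]), logical(1))
}

# route feature rows down a getTree() matrix; returns leaf node indices
route_tree <- function(tr, x) {
  cur <- rep(1L, nrow(x))
  repeat {
    active <- tr[cur, "status"] != -1L
    if (!any(active)) break
    i <- which(active)
    sv <- tr[cur[i], "split var"]
    goleft <- x[cbind(i, sv)] <= tr[cur[i], "split point"]
    cur[i] <- ifelse(goleft, tr[cur[i], "left daughter"],
                     tr[cur[i], "right daughter"])
  }
  cur
}

# predictions on new feature rows; hard labels or leaf probabilities
predict_tree <- function(fit, x, type = "label") {
  stopifnot(inherits(fit, "coop_tree"))
  if (fit$constant) {
    return(rep(if (type == "prob") fit$prob else as.integer(fit$label),
               nrow(x)))
  }
  if (type == "prob") {
    if (is.null(fit$leaf_prob)) {
      stop("tree was not trained with predict_type = 'prob'")
    }
    unname(fit$leaf_prob[route_tree(fit$tree, x)])
  } else {
    as.integer(as.character(stats::predict(fit$rf, x, type = "response")))
  }
}

#' Leave-one-subject-out predictions
#'
#' One fold per participant: a tree trained on all other participants'
#' trials predicts every trial of the left-out participant, so no
#' participant's predictions ever depend on their own data.
#'
#' @param features A `coop_features` from [build_features()].
#' @param cfg A [tree_config()].
#' @return Tibble: `participant_id`, `game_id`, `trial_idx`, `pred`,
#'   `truth`, `fold`.
#' @export
loso_predict <- function(features, cfg = tree_config()) {
  pids <- unique(features$participant_id)
  if (length(pids) < 2L) stop("leave-one-subject-out needs >= 2 participants")
  out <- lapply(seq_along(pids), function(f) {
    test <- features$participant_id == pids[f]
    fit <- train_tree(features$x[!test, , drop = FALSE],
                      features$y[!test], cfg)
    tibble::tibble(
      participant_id = features$participant_id[test],
      game_id = features$game_id[test],
      trial_idx = features$trial_idx[test],
      pred = predict_tree(fit, features$x[test, , drop = FALSE],
                          cfg$predict_type),
      truth = features$y[test],
      fold = f)
  })
  do.call(rbind, out)
}

#' Aggregate predictions and score against true rates
#'
#' Averages predicted and true cooperation within groups (participants or
#' games) and returns the mean squared error between the grouped rates.
#'
#' @param preds A [loso_predict()] table.
#' @param by `"participant"` or `"game"`.
#' @return List with `rates` (tibble: group, `pred_rate`, `true_rate`) and
#'   `mse`.
#' @export
aggregate_and_score <- function(preds, by = c("participant", "game")) {
  by <- match.arg(by)
  g <- if (by == "participant") preds$participant_id else preds$game_id
  pr <- tapply(preds$pred, g, mean)
  tr <- tapply(preds$truth, g, mean)
  rates <- tibble::tibble(group = names(pr),
                          pred_rate = as.numeric(pr),
                          true_rate = as.numeric(tr))
  list(rates = rates, mse = mean((rates$pred_rate - rates$true_rate)^2))
}

#' Permutation-null chance level
#'
#' On each leave-one-subject-out fold, shuffles the training labels
#' `n_perm` times, retrains the tree on each shuffle and predicts the
#' left-out participant; the chance level is the mean predicted cooperation
#' over all shuffles, folds and trials. For an imbalanced outcome this is
#' the relevant baseline for predicted cooperation rates.
#'
#' @param features A `coop_features`.
#' @param cfg A [tree_config()].
#' @param n_perm Label shuffles per fold (default 50).
#' @param seed Integer seed for the shuffles.
#' @return List with `chance` (overall mean) and `per_fold` (numeric
#'   vector of per-fold means).
#' @export
chance_level <- function(features, cfg = tree_config(), n_perm = 50,
                         seed = 1) {
  pids <- unique(features$participant_id)
  if (length(pids) < 2L) stop("leave-one-subject-out needs >= 2 participants")
  per_fold <- numeric(length(pids))
  n_pred <- numeric(length(pids))
  with_seed(derive_seed(seed, "chance-level"), {
    for (f in seq_along(pids)) {
      test <- features$participant_id == pids[f]
      xtr <- features$x[!test, , drop = FALSE]
      ytr <- features$y[!test]
      xte <- features$x[test, , drop = FALSE]
      acc <- 0
      for (j in seq_len(n_perm)) {
        fit <- train_tree(xtr, sample(ytr), cfg)
        acc <- acc + sum(predict_tree(fit, xte, cfg$predict_type))
      }
      per_fold[f] <- acc / (n_perm * sum(test))
      n_pred[f] <- sum(test)
    }
  })
  list(chance = sum(per_fold * n_pred) / sum(n_pred), per_fold = per_fold)
}

#' Default feature configurations for classifier comparison
#'
#' The sequence encodings crossed with slot sets used in the analysis, plus
#' the dwell-only and payoffs-only baselines.
#'
#' @return Named list of `list(encoding, slots)` configurations.
#' @export
feature_set_configs <- function() {
  list(
    dummy_s1 = list(encoding = "dummy", slots = "1"),
    dummy_s1_last = list(encoding = "dummy", slots = c("1", "last")),
    dummy_s1to4_last = list(encoding = "dummy",
                            slots = c("1", "2", "3", "4", "last")),
    dummy_s1to5_last = list(encoding = "dummy",
                            slots = c("1", "2", "3", "4", "5", "last")),
    payoff_s1 = list(encoding = "payoff", slots = "1"),
    payoff_s1_last = list(encoding = "payoff", slots = c("1", "last")),
    payoff_s1to4_last = list(encoding = "payoff",
                             slots = c("1", "2", "3", "4", "last")),
    payoff_s1to5_last = list(encoding = "payoff",
                             slots = c("1", "2", "3", "4", "5", "last")),
    dwell_only = list(encoding = "dwell", slots = "1"),
    payoffs_only = list(encoding = "payoffs", slots = "1")
  )
}

#' Compare feature sets under leave-one-subject-out prediction
#'
#' Builds each feature configuration, runs [loso_predict()], and tabulates
#' participant- and game-level MSE.
#'
#' @param ds A `coop_cohort`.
#' @param configs Named list of `list(encoding, slots)` (default
#'   [feature_set_configs()]).
#' @param cfg A [tree_config()].
#' @param min_dur Keep threshold in ms.
#' @return Tibble: `config`, `encoding`, `slots`, `mse_participant`,
#'   `mse_game`.
#' @export
compare_feature_sets <- function(ds, configs = feature_set_configs(),
                                 cfg = tree_config(), min_dur = 100) {
  stopifnot(length(configs) >= 1L)
  summaries <- summarize_gaze(ds, min_dur = min_dur)
  rows <- lapply(names(configs), function(nm) {
    fc <- configs[[nm]]
    feats <- build_features(ds, encoding = fc$encoding, slots = fc$slots,
                            min_dur = min_dur, summaries = summaries)
    preds <- loso_predict(feats, cfg)
    tibble::tibble(
      config = nm,
      encoding = fc$encoding,
      slots = paste(fc$slots, collapse = ","),
      mse_participant = aggregate_and_score(preds, "participant")$mse,
      mse_game = aggregate_and_score(preds, "game")$mse)
  })
  do.call(rbind, rows)
}
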