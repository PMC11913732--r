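test_that("tree training separates separable data and handles degenerate
           input", {
  set.seed(1)
  x <- cbind(a = rep(c(0, 1), each = 50), b = runif(100))
  y <- as.integer(x[, "a"] == 1)
  fit <- coopgaze:::train_tree(x, y, tree_config())
  expect_equal(coopgaze:::predict_tree(fit, x), y)
  # constant features: majority-class predictor
  xc <- matrix(0, 60, 2, dimnames = list(NULL, c("a", "b")))
  yc <- rep(c(0L, 1L), c(40, 20))
  fitc <- coopgaze:::train_tree(xc, yc, tree_config())
  expect_true(all(coopgaze:::predict_tree(fitc, xc) == 0L))
  # single-class labels: constant classifier with a warning
  expect_warning(fit1 <- coopgaze:::train_tree(xc, rep(1L, 60),
                                               tree_config()),
                 "single-class")
  expect_true(all(coopgaze:::predict_tree(fit1, xc) == 1L))
  # leaf probabilities average the training labels
  fitp <- coopgaze:::train_tree(xc, yc, tree_config(predict_type = "prob"))
  expect_equal(coopgaze:::predict_tree(fitp, xc, "prob"), rep(1 / 3, 60))
})

test_that("leave-one-subject-out folds are leakage-free", {
  ds <- tiny_cohort(4, seed = 17)
  feats <- build_features(ds, encoding = "payoff", slots = c(1:4, "last"))
  preds <- loso_predict(feats)
  expect_equal(nrow(preds), nrow(ds$choices))
  expect_equal(sort(unique(preds$fold)), 1:4)
  # corrupting the left-out participant's labels cannot change their
  # predictions (their labels never enter their fold's training set)
  pid <- unique(feats$participant_id)[2]
  feats2 <- feats
  feats2$y[feats2$participant_id == pid] <-
    1L - feats2$y[feats2$participant_id == pid]
  preds2 <- loso_predict(feats2)
  expect_equal(preds2$pred[preds2$participant_id == pid],
               preds$pred[preds$participant_id == pid])
  expect_error(loso_predict(
    build_features(list(design = ds$design[1:192, ],
                        choices = ds$choices[1:192, ],
                        fixations = ds$fixations),
                   encoding = "payoff")), ">= 2")
})

test_that("fold predictions do not depend on participant order", {
  ds <- tiny_cohort(3, seed = 19)
  feats <- build_features(ds, encoding = "dummy", slots = c(1, "last"))
  preds <- loso_predict(feats)
  perm <- order(-feats$participant_id, feats$trial_idx)
  featsp <- list(x = feats$x[perm, ], y = feats$y[perm],
                 participant_id = feats$participant_id[perm],
                 game_id = feats$game_id[perm],
                 trial_idx = feats$trial_idx[perm],
                 encoding = feats$encoding, slots = feats$slots)
  class(featsp) <- "coop_features"
  predsp <- loso_predict(featsp)
  k1 <- paste(preds$participant_id, preds$trial_idx)
  k2 <- paste(predsp$participant_id, predsp$trial_idx)
  expect_equal(predsp$pred[match(k1, k2)], preds$pred)
})

test_that("aggregation and scoring behave on exact and constant
           predictions", {
  preds <- tibble::tibble(participant_id = rep(1:2, each = 4),
                          game_id = rep(1:4, 2),
                          trial_idx = 1:8,
                          pred = c(1, 0, 1, 0, 1, 1, 0, 0),
                          truth = c(1, 0, 1, 0, 1, 1, 0, 0))
  expect_equal(aggregate_and_score(preds, "participant")$mse, 0)
  expect_equal(aggregate_and_score(preds, "game")$mse, 0)
  preds$pred <- 0
  sc <- aggregate_and_score(preds, "participant")
  expect_equal(sc$mse, mean(sc$rates$true_rate^2))
  expect_true(all(sc$rates$pred_rate >= 0 & sc$rates$pred_rate <= 1))
})

test_that("null features predict the base rate and chance matches it", {
  ds <- tiny_cohort(6, seed = 23)
  feats <- build_features(ds, encoding = "payoff", slots = c(1:4, "last"))
  # labels independent of all features
  set.seed(42)
  feats$y <- stats::rbinom(length(feats$y), 1, 0.3)
  preds <- loso_predict(feats)
  expect_lt(abs(mean(preds$pred) - 0.3), 0.05)
  # balanced null: chance level ~ 0.5
  feats$y <- stats::rbinom(length(feats$y), 1, 0.5)
  ch <- chance_level(feats, n_perm = 8, seed = 1)
  expect_lt(abs(ch$chance - 0.5), 0.05)
  # chance is invariant to the feature encoding under shuffled labels
  featsd <- build_features(ds, encoding = "dummy", slots = c(1:4, "last"))
  featsd$y <- feats$y
  chd <- chance_level(featsd, n_perm = 8, seed = 1)
  expect_lt(abs(chd$chance - ch$chance), 0.05)
})

test_that("a gaze-causal cohort is predictable above the permutation
           null", {
  ds <- simulate_cohort(cohort_config(n_participants = 8, seed = 31,
                                      gaze_seq_bonus = 12))
  feats <- build_features(ds, encoding = "payoff", slots = c(1:4, "last"))
  preds <- loso_predict(feats)
  acc <- mean(preds$pred == preds$truth)
  # accuracy of label-shuffled classifiers on the same folds
  set.seed(7)
  null_feats <- feats
  null_feats$y <- sample(feats$y)
  null_preds <- loso_predict(null_feats)
  null_acc <- mean(null_preds$pred == feats$y)
  expect_gt(acc, null_acc + 0.02)
})

test_that("feature-set comparison reproduces the expected orderings", {
  # sequence-causal cohort: slot-sequence features beat aggregate dwell
  ds <- simulate_cohort(cohort_config(n_participants = 10, seed = 3,
                                      gaze_seq_bonus = 12))
  cmp <- compare_feature_sets(
    ds, feature_set_configs()[c("payoff_s1to4_last", "dwell_only")])
  expect_lt(cmp$mse_game[cmp$config == "payoff_s1to4_last"],
            cmp$mse_game[cmp$config == "dwell_only"])
  # determinism: duplicated configs give identical rows
  cmp2 <- compare_feature_sets(
    ds, list(a = list(encoding = "dwell", slots = "1"),
             b = list(encoding = "dwell", slots = "1")))
  expect_equal(cmp2$mse_participant[1], cmp2$mse_participant[2])
  expect_equal(cmp2$mse_game[1], cmp2$mse_game[2])
  expect_true(all(c("mse_participant", "mse_game") %in% names(cmp2)))
  # decoupled gaze: the payoffs-only baseline dominates gaze features at
  # the game level (choices depend on payoffs alone in that regime);
  # pruned probabilistic trees so game rates are non-degenerate
  ds0 <- simulate_cohort(cohort_config(n_participants = 10, seed = 4,
                                       gaze = list(alpha_gaze_coupling = 0)))
  cmp0 <- compare_feature_sets(
    ds0, feature_set_configs()[c("payoff_s1to4_last", "dwell_only",
                                 "payoffs_only")],
    tree_config(min_leaf = 50, predict_type = "prob"))
  expect_lt(cmp0$mse_game[cmp0$config == "payoffs_only"],
            min(cmp0$mse_game[cmp0$config != "payoffs_only"]))
})
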