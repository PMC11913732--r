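games96 <- enumerate_games()

test_that("utility equations match closed forms and a frozen oracle value", {
  g <- list(T = 40, R = 30, P = 10, S = 0)
  # alpha = 1/2, rho = 1: delta_u = p(R - (T+S)/2) + (1-p)((T+S)/2 - P)
  for (p in c(0.2, 0.5, 0.8)) {
    u <- utilities(games96, list(alpha = 0.5, p = p, rho = 1, beta = 1))
    expect_equal(u$delta_u,
                 p * (games96$R - (games96$T + games96$S) / 2) +
                   (1 - p) * ((games96$T + games96$S) / 2 - games96$P))
  }
  expect_equal(utilities(g, list(alpha = .5, p = .5, rho = 1,
                                 beta = .1))$delta_u, 10)
  # frozen value computed by direct arithmetic evaluation of the equations
  u <- utilities(g, list(alpha = 0.3, p = 0.4, rho = 0.9, beta = 1))
  expect_equal(u$delta_u, 1.0082402444, tolerance = 1e-9)
  # dominant-strategy limit: selfish agent certain the opponent cooperates
  u <- utilities(games96, list(alpha = 0, p = 1, rho = 1, beta = 1))
  expect_equal(u$u_coop, games96$R)
  expect_equal(u$u_defect, games96$T)
  expect_true(all(u$delta_u < 0))
  # delta_u identity holds for every variant
  for (v in model_variants()) {
    pars <- list(alpha = .4, p = .4, rho = .8, beta = .5, c = 1, a = .05,
                 r = .5, lam_ahead = .2, lam_behind = .4, gamma0 = 0,
                 gamma1 = .1)
    u <- utilities(games96, pars, model_spec(v))
    expect_equal(u$delta_u, u$u_coop - u$u_defect)
  }
})

test_that("utilities reject invalid games and out-of-bounds parameters", {
  expect_error(utilities(list(T = 40, R = 20, P = 10, S = 5),
                         list(alpha = .5, p = .5, rho = 1, beta = 1)),
               "invalid game")
  expect_error(utilities(list(T = 40, R = 30, P = 10, S = 0),
                         list(alpha = 1.4, p = .5, rho = 1, beta = 1)),
               "bounds")
  expect_error(utilities(list(T = 40, R = 30, P = 10, S = 0),
                         list(alpha = .5, p = .5, beta = 1)),
               "missing")
})

test_that("softmax choice rule is exact at beta 0 and overflow-safe", {
  g <- list(T = 40, R = 30, P = 10, S = 0)
  expect_identical(prob_cooperate(g, list(alpha = .3, p = .7, rho = .8,
                                          beta = 0)), 0.5)
  expect_equal(prob_cooperate(g, list(alpha = .5, p = .5, rho = 1,
                                      beta = 0.1)),
               0.7310585786, tolerance = 1e-9)
  # monotone in beta for positive delta_u, approaching 1
  ps <- vapply(c(0.1, 0.5, 2, 20),
               function(b) prob_cooperate(g, list(alpha = .5, p = .5,
                                                  rho = 1, beta = b)),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[4], 1 - 1e-6)
  pe <- prob_cooperate(games96, list(alpha = 0, p = 0, rho = 2, beta = 20))
  expect_true(all(!is.nan(pe) & pe >= 0 & pe <= 1))
})

test_that("cooperation probability is monotone in payoffs as the model
           predicts", {
  pars <- list(alpha = 0.3, p = 0.4, rho = 0.9, beta = 0.5)
  step <- function(col, delta) {
    g2 <- games96
    g2[[col]] <- g2[[col]] + delta
    ok <- vapply(seq_len(nrow(g2)),
                 function(i) validate_game(g2[i, ]), logical(1))
    list(base = prob_cooperate(games96[ok, ], pars),
         pert = prob_cooperate(g2[ok, ], pars, validate = FALSE))
  }
  r <- step("R", 5); expect_true(all(r$pert > r$base))   # reward up
  p <- step("P", 5); expect_true(all(p$pert < p$base))   # punishment up
  # S direction: increases iff (1-p)(1-alpha) > p*alpha (true here)
  s <- step("S", 5); expect_true(all(s$pert > s$base))
  # T direction: increases iff (1-p)*alpha > p*(1-alpha) (false here)
  tt <- step("T", 5); expect_true(all(tt$pert < tt$base))
})

test_that("negative log-likelihood matches hand values and is
           order-invariant", {
  g1 <- cbind(games96[1, c("T", "R", "P", "S")], choice = 1L)
  pars <- list(alpha = .5, p = .5, rho = 1, beta = 0)
  expect_equal(negloglik(g1, pars), log(2))
  gN <- cbind(games96[, c("T", "R", "P", "S")],
              choice = rep_len(c(0L, 1L), 96))
  expect_equal(negloglik(gN, pars), 96 * log(2))
  pars2 <- list(alpha = .3, p = .4, rho = .9, beta = .6)
  expect_equal(negloglik(gN, pars2),
               negloglik(gN[sample.int(96), ], pars2))
  expect_error(negloglik(gN[0, ], pars), "empty")
  expect_error(negloglik(cbind(games96[1:2, ], choice = c("yes", "no")),
                         pars), "cooperate")
})

test_that("eligibility requires two cooperation and two defection trials", {
  mk <- function(nc, nd) tibble::tibble(choice = rep(c(1L, 0L), c(nc, nd)))
  expect_false(eligible_for_fit(mk(1, 191)))
  expect_true(eligible_for_fit(mk(2, 190)))
  expect_false(eligible_for_fit(mk(0, 192)))
  expect_false(eligible_for_fit(mk(192, 0)))
  expect_true(eligible_for_fit(mk(2, 2)))
  expect_false(eligible_for_fit(mk(0, 0)))
})

test_that("the variant ledger pins free parameters and fixed constants", {
  ks <- vapply(model_variants(), function(v) model_spec(v)$k, integer(1))
  expect_equal(unname(ks), c(4, 4, 5, 3, 3, 4, 4, 4, 3, 5, 5))
  for (v in model_variants()) {
    sp <- model_spec(v)
    expect_equal(sp$k, length(sp$free))
    expect_length(intersect(names(sp$fixed), sp$free), 0)
  }
  expect_equal(model_spec("M3_selfish")$fixed$alpha, 0)
  expect_equal(model_spec("M4_risk_neutral")$fixed$rho, 1)
  expect_equal(model_spec("M8_rho_1.1")$fixed$rho, 1.1)
})

test_that("MLE fitting is deterministic, dominant over the truth, and
           enforces exclusion", {
  des <- one_session(7)
  truth <- list(alpha = 0.6, p = 0.3, rho = 1.0, beta = 0.4)
  dat <- cbind(des[, c("T", "R", "P", "S")],
               choice = simulate_choices(des, truth, seed = 21)$choice)
  f1 <- fit_mle(dat, model_spec("M0_full"), seed = 5, n_starts = 10)
  f2 <- fit_mle(dat, model_spec("M0_full"), seed = 5, n_starts = 10)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  # optimizer dominance: fitted likelihood at least as good as the truth
  expect_lte(-f1$loglik, negloglik(dat, truth) + 1e-6)
  # BIC identity
  expect_equal(f1$bic, f1$k * log(f1$n_trials) - 2 * f1$loglik)
  expect_equal(bic_of(f1), f1$bic)
  bad <- tibble::tibble(T = 40, R = 30, P = 10, S = 0, choice = 0L)
  expect_error(fit_mle(bad), "excluded")
})

test_that("BIC formula and penalty ordering", {
  fake <- structure(list(loglik = -100, k = 4, n_trials = 192,
                         converged = TRUE), class = "coop_fit")
  expect_equal(bic_of(fake), 4 * log(192) + 200, tolerance = 1e-6)
  # equal loglik, fewer parameters -> smaller BIC
  expect_lt(bic_of(fake, model_spec("M3_selfish")), bic_of(fake))
})

test_that("model comparison returns one row per variant with delta BIC", {
  des <- one_session(3)
  dat <- cbind(des[, c("T", "R", "P", "S")],
               choice = simulate_choices(des, list(alpha = .4, p = .3,
                                                   rho = 1, beta = .5),
                                         seed = 2)$choice)
  cm <- compare_models(dat, variants = c("M0_full", "M4_risk_neutral"),
                       seed = 1, n_starts = 6)
  expect_equal(nrow(cm), 2)
  expect_equal(min(cm$delta_bic), 0)
  cm1 <- compare_models(dat, variants = "M0_full", seed = 1, n_starts = 6)
  expect_equal(cm1$delta_bic, 0)
})
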