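# Utility model of cooperation and its ten alternative specifications.
#
# The core model (M0_full) evaluates the expected utility of cooperating and
# defecting in a one-shot PD given four agent parameters:
#   alpha - other-regarding preference in [0, 1] (0 = selfish, 1 = fully
#           other-directed), mixing own and opponent payoffs in the outcomes
#           where the two players' payoffs differ;
#   p     - fixed belief that the opponent cooperates, in [0, 1];
#   rho   - risk curvature of the power utility x^rho, in (0, 2];
#   beta  - softmax inverse temperature in [0, 20].
#
#   U(Cooperate) = p * R^rho + (1 - p) * ((1 - alpha) * S^rho + alpha * T^rho)
#   U(Defect)    = p * ((1 - alpha) * T^rho + alpha * S^rho) + (1 - p) * P^rho
#   P(Cooperate) = 1 / (1 + exp(-beta * (U(C) - U(D))))
#
# Alternative specifications (free-parameter count k in brackets):
#   M1_risk_after_orp [4] risk transform applied after the alpha mixing
#   M2_bias           [5] adds a constant bias c to the utility difference
#   M3_selfish        [3] alpha fixed at 0
#   M4_risk_neutral   [3] rho fixed at 1
#   M5_selfish_bias   [4] alpha = 0 plus bias c
#   M6_cara           [4] CARA utility u(x) = (1 - exp(-a x)) / a
#   M7_crra           [4] CRRA utility u(x) = (x + 1)^(1 - r) / (1 - r),
#                         evaluated on x + 1 so x = 0 is finite; ln(x + 1)
#                         at r = 1
#   M8_rho_1.1        [3] constant risk seeking, rho fixed at 1.1
#   M9_charness_rabin [5] piecewise weight on the other's payoff:
#                         lam_behind when own payoff >= other's (the other is
#                         behind), lam_ahead otherwise, per outcome cell
#   M10_belief_RP     [5] belief varies with the trial's reward-punishment
#                         gap: p_t = logistic(gamma0 + gamma1 * (R - P))

#' Model variant identifiers
#' @return Character vector of the 11 variant ids, M0 first.
#' @export
model_variants <- function() {
  c("M0_full", "M1_risk_after_orp", "M2_bias", "M3_selfish",
    "M4_risk_neutral", "M5_selfish_bias", "M6_cara", "M7_crra",
    "M8_rho_1.1", "M9_charness_rabin", "M10_belief_RP")
}

#' Parameter bounds used for fitting
#'
#' The task payoffs are bounded (0-40 points), so these boxes comfortably
#' cover all behaviourally distinguishable parameter values while keeping
#' `0^rho` well defined (`rho > 0`) and the CARA coefficient away from the
#' removable singularity at 0 (handled by its linear limit).
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
param_bounds <- function() {
  list(alpha = c(0, 1), p = c(0, 1), rho = c(0.05, 2), beta = c(0, 20),
       c = c(-20, 20), a = c(-0.25, 0.25), r = c(0, 2),
       lam_ahead = c(0, 1), lam_behind = c(0, 1),
       gamma0 = c(-5, 5), gamma1 = c(-0.5, 0.5))
}

#' Model specification for one variant
#'
#' @param variant One of [model_variants()].
#' @return A list with `variant`, `free` (names of free parameters), `fixed`
#'   (named list of pinned parameters) and `k` (number of free parameters).
#' @export
#' @examples
#' model_spec("M0_full")$k # 4
model_spec <- function(variant = model_variants()) {
  variant <- match.arg(variant)
  free <- switch(variant,
    M0_full           = c("alpha", "p", "rho", "beta"),
    M1_risk_after_orp = c("alpha", "p", "rho", "beta"),
    M2_bias           = c("alpha", "p", "rho", "beta", "c"),
    M3_selfish        = c("p", "rho", "beta"),
    M4_risk_neutral   = c("alpha", "p", "beta"),
    M5_selfish_bias   = c("p", "rho", "beta", "c"),
    M6_cara           = c("alpha", "p", "a", "beta"),
    M7_crra           = c("alpha", "p", "r", "beta"),
    `M8_rho_1.1`      = c("alpha", "p", "beta"),
    M9_charness_rabin = c("lam_ahead", "lam_behind", "p", "rho", "beta"),
    M10_belief_RP     = c("alpha", "rho", "beta", "gamma0", "gamma1")
  )
  fixed <- switch(variant,
    M3_selfish      = list(alpha = 0),
    M4_risk_neutral = list(rho = 1),
    M5_selfish_bias = list(alpha = 0),
    `M8_rho_1.1`    = list(rho = 1.1),
    list()
  )
  list(variant = variant, free = free, fixed = fixed, k = length(free))
}

# merge fixed parameters into a user-supplied parameter list
resolve_params <- function(params, spec) {
  params <- as.list(params)
  for (nm in names(spec$fixed)) params[[nm]] <- spec$fixed[[nm]]
  params
}

check_params <- function(params, spec) {
  b <- param_bounds()
  for (nm in spec$free) {
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v)) {
      stop("missing or non-finite parameter '", nm, "' for variant ",
           spec$variant)
    }
    if (v < b[[nm]][1] - 1e-9 || v > b[[nm]][2] + 1e-9) {
      stop("parameter '", nm, "' = ", v, " outside bounds [",
           b[[nm]][1], ", ", b[[nm]][2], "]")
    }
  }
  invisible(TRUE)
}

# CARA utility with its linear limit at a -> 0
u_cara <- function(x, a) {
  if (abs(a) < 1e-8) x else (1 - exp(-a * x)) / a
}

# CRRA utility on the shifted payoff x + 1 (finite at x = 0); log at r = 1
u_crra <- function(x, r) {
  if (abs(r - 1) < 1e-8) log(x + 1) else (x + 1)^(1 - r) / (1 - r)
}

#' Expected utilities of cooperating and defecting
#'
#' Evaluates the variant's utility equations for one or more games.
#'
#' @param g A game (list with `T`, `R`, `P`, `S`) or a data frame of games.
#' @param params Named list/vector of parameters (free parameters of the
#'   variant; fixed ones are filled in automatically).
#' @param spec A [model_spec()]; defaults to the full model.
#' @param validate Check games and parameter bounds (default `TRUE`).
#' @return A tibble with `u_coop`, `u_defect`, `delta_u` (one row per game).
#' @export
#' @examples
#' g <- list(T = 40, R = 30, P = 10, S = 0)
#' utilities(g, list(alpha = 0.5, p = 0.5, rho = 1, beta = 0.1))$delta_u # 10
utilities <- function(g, params, spec = model_spec("M0_full"),
                      validate = TRUE) {
  g <- as.data.frame(g)
  params <- resolve_params(params, spec)
  if (validate) {
    check_params(params, spec)
    ok <- vapply(seq_len(nrow(g)),
                 function(i) validate_game(g[i, , drop = FALSE]),
                 logical(1))
    if (!all(ok)) stop("invalid game(s) at row(s): ",
                       paste(which(!ok), collapse = ", "))
  }
  u <- compute_utils(g$T, g$R, g$P, g$S, params, spec$variant)
  tibble::tibble(u_coop = u$u_c, u_defect = u$u_d,
                 delta_u = u$u_c - u$u_d)
}

# numeric core of the utility equations; payoffs as plain vectors,
# `params` a fully resolved list. Kept free of data-frame overhead so the
# optimizer can call it thousands of times.
compute_utils <- function(gT, gR, gP, gS, params, variant) {
  al <- params$alpha %||% 0
  if (variant == "M1_risk_after_orp") {
    rho <- params$rho
    p <- params$p
    u_c <- p * gR^rho + (1 - p) * ((1 - al) * gS + al * gT)^rho
    u_d <- p * ((1 - al) * gT + al * gS)^rho + (1 - p) * gP^rho
  } else if (variant == "M9_charness_rabin") {
    rho <- params$rho
    p <- params$p
    cell <- function(own, other) {
      lam <- ifelse(own >= other, params$lam_behind, params$lam_ahead)
      (1 - lam) * own^rho + lam * other^rho
    }
    u_c <- p * cell(gR, gR) + (1 - p) * cell(gS, gT)
    u_d <- p * cell(gT, gS) + (1 - p) * cell(gP, gP)
  } else {
    # M0-structured family: choice of payoff transform and belief
    u <- switch(variant,
      M6_cara = function(x) u_cara(x, params$a),
      M7_crra = function(x) u_crra(x, params$r),
      function(x) x^params$rho
    )
    p <- if (variant == "M10_belief_RP") {
      stats::plogis(params$gamma0 + params$gamma1 * (gR - gP))
    } else {
      params$p
    }
    u_c <- p * u(gR) + (1 - p) * ((1 - al) * u(gS) + al * u(gT))
    u_d <- p * ((1 - al) * u(gT) + al * u(gS)) + (1 - p) * u(gP)
  }
  if (variant %in% c("M2_bias", "M5_selfish_bias")) u_c <- u_c + params$c
  list(u_c = u_c, u_d = u_d)
}

#' Probability of cooperation
#'
#' Softmax (logistic) choice rule on the utility difference. `beta = 0`
#' returns exactly 0.5 (random choice); evaluation is overflow-safe for any
#' finite `beta * delta_u`.
#'
#' @inheritParams utilities
#' @return Numeric vector of probabilities in (0, 1).
#' @export
prob_cooperate <- function(g, params, spec = model_spec("M0_full"),
                           validate = TRUE) {
  u <- utilities(g, params, spec, validate = validate)
  params <- resolve_params(params, spec)
  stats::plogis(params$beta * u$delta_u)
}

# normalize a choice column to 0/1 with cooperate = 1
as_choice01 <- function(choice) {
  if (is.character(choice) || is.factor(choice)) {
    ch <- as.character(choice)
    if (!all(ch %in% c("cooperate", "defect"))) {
      stop("character choices must be 'cooperate' or 'defect'")
    }
    as.integer(ch == "cooperate")
  } else {
    if (!all(choice %in% c(0, 1))) stop("numeric choices must be 0/1")
    as.integer(choice)
  }
}

#' Negative log-likelihood of a choice dataset
#'
#' Bernoulli log-likelihood of the observed cooperate/defect choices under
#' the variant's softmax probabilities, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` so extreme inverse temperatures cannot produce
#' infinite values.
#'
#' @param data Data frame with game payoffs `T`, `R`, `P`, `S` and a `choice`
#'   column (0/1 with cooperate = 1, or "cooperate"/"defect").
#' @inheritParams utilities
#' @return A single non-negative number.
#' @export
negloglik <- function(data, params, spec = model_spec("M0_full"),
                      validate = TRUE) {
  if (is.null(data) || nrow(data) == 0L) stop("empty choice dataset")
  y <- as_choice01(data$choice)
  pi <- prob_cooperate(data, params, spec, validate = validate)
  eps <- 1e-12
  pi <- pmin(pmax(pi, eps), 1 - eps)
  -sum(y * log(pi) + (1 - y) * log(1 - pi))
}

#' Is a participant eligible for model fitting?
#'
#' Participants with fewer than two cooperation or fewer than two defection
#' trials carry too little choice variability for the model to fit and are
#' excluded.
#'
#' @param data Choice data frame for one participant.
#' @return `TRUE` or `FALSE`.
#' @export
eligible_for_fit <- function(data) {
  if (is.null(data) || nrow(data) == 0L) return(FALSE)
  y <- as_choice01(data$choice)
  sum(y) >= 2L && sum(1L - y) >= 2L
}

#' Maximum-likelihood fit of one variant to one participant
#'
#' Random multistart: `n_starts` uniform draws within [param_bounds()], each
#' refined by bounded L-BFGS-B on the negative log-likelihood; the best
#' refined solution is returned. Deterministic given `seed`.
#'
#' @param data Choice data frame for one participant (see [negloglik()]).
#' @param spec A [model_spec()].
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of random initial points (default 200).
#' @return An object of class `coop_fit`: list with `variant`, `params`
#'   (named vector, fixed parameters included), `loglik`, `bic`, `k`,
#'   `n_trials`, `converged`, `n_starts_used`.
#' @export
fit_mle <- function(data, spec = model_spec("M0_full"), seed = 1,
                    n_starts = 200) {
  if (!eligible_for_fit(data)) {
    stop("participant excluded: fewer than two cooperation or two defection ",
         "trials (exclusion rule for model fitting)")
  }
  y <- as_choice01(data$choice)
  gT <- data$T; gR <- data$R; gP <- data$P; gS <- data$S
  b <- param_bounds()
  lower <- vapply(spec$free, function(nm) b[[nm]][1], numeric(1))
  upper <- vapply(spec$free, function(nm) b[[nm]][2], numeric(1))
  eps <- 1e-12
  obj <- function(theta) {
    pars <- resolve_params(stats::setNames(as.list(theta), spec$free), spec)
    u <- compute_utils(gT, gR, gP, gS, pars, spec$variant)
    pi <- stats::plogis(pars$beta * (u$u_c - u$u_d))
    pi <- pmin(pmax(pi, eps), 1 - eps)
    val <- -sum(y * log(pi) + (1 - y) * log(1 - pi))
    if (!is.finite(val)) 1e10 else val
  }
  s <- derive_seed(seed, paste0("fit-", spec$variant))
  starts <- with_seed(s, {
    m <- matrix(stats::runif(n_starts * spec$k), nrow = n_starts)
    sweep(sweep(m, 2, upper - lower, `*`), 2, lower, `+`)
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed for ", spec$variant)
  n <- nrow(data)
  loglik <- -best$value
  params <- resolve_params(stats::setNames(as.list(best$par), spec$free),
                           spec)
  structure(list(
    variant = spec$variant,
    params = unlist(params),
    loglik = loglik,
    k = spec$k,
    bic = spec$k * log(n) - 2 * loglik,
    n_trials = n,
    converged = identical(best$convergence, 0L) || best$convergence == 0,
    n_starts_used = n_starts,
    seed = seed
  ), class = "coop_fit")
}

#' @export
print.coop_fit <- function(x, ...) {
  cat("<coop_fit> ", x$variant, ": loglik = ", sprintf("%.2f", x$loglik),
      ", BIC = ", sprintf("%.2f", x$bic), ", n = ", x$n_trials,
      if (!x$converged) " (not converged)", "\n", sep = "")
  print(round(x$params, 4))
  invisible(x)
}

#' Bayesian Information Criterion of a fit
#'
#' `BIC = k * ln(n) - 2 * loglik`; lower is better.
#'
#' @param fit A `coop_fit`.
#' @param spec Optional [model_spec()] (defaults to the fit's own variant).
#' @return A single number.
#' @export
bic_of <- function(fit, spec = NULL) {
  k <- if (is.null(spec)) fit$k else spec$k
  k * log(fit$n_trials) - 2 * fit$loglik
}

#' Fit and compare model variants on one participant
#'
#' Fits each requested variant independently and tabulates log-likelihood,
#' free-parameter count, BIC and the BIC difference to the best variant.
#' A variant whose fit fails is recorded as a non-converged row with `NA`
#' statistics rather than aborting the comparison.
#'
#' @param data Choice data frame for one participant.
#' @param variants Character vector of variant ids (default all 11).
#' @param seed Integer seed.
#' @param n_starts Starts per variant fit.
#' @return A tibble with one row per variant: `variant`, `k`, `loglik`,
#'   `bic`, `delta_bic`, `converged`.
#' @export
compare_models <- function(data, variants = model_variants(), seed = 1,
                           n_starts = 50) {
  rows <- lapply(variants, function(v) {
    spec <- model_spec(v)
    fit <- tryCatch(fit_mle(data, spec, seed = seed, n_starts = n_starts),
                    error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(variant = v, k = spec$k, loglik = NA_real_,
                     bic = NA_real_, converged = FALSE)
    } else {
      tibble::tibble(variant = v, k = fit$k, loglik = fit$loglik,
                     bic = fit$bic, converged = fit$converged)
    }
  })
  out <- do.call(rbind, rows)
  out$delta_bic <- out$bic - min(out$bic, na.rm = TRUE)
  out[, c("variant", "k", "loglik", "bic", "delta_bic", "converged")]
}

#' Parameter-recovery study for the full model
#'
#' For each row of `param_grid` and each replicate, simulates choices over
#' `design` from the full model at those parameters, refits the model, and
#' records true and recovered values. Replicates whose simulated choices fail
#' the eligibility rule are recorded as skipped.
#'
#' @param design A session table from [build_session()] (or several bound
#'   together for longer datasets).
#' @param param_grid Data frame with columns `alpha`, `p`, `rho`, `beta`.
#' @param n_reps Replicates per grid point.
#' @param seed Integer seed.
#' @param n_starts Starts per fit.
#' @return List with `results` (per-replicate true/estimated values and an
#'   `eligible` flag) and `summary` (per-parameter Pearson correlation, mean
#'   bias and RMSE over eligible replicates).
#' @export
recovery_study <- function(design, param_grid, n_reps = 10, seed = 1,
                           n_starts = 30) {
  spec <- model_spec("M0_full")
  rows <- list()
  for (i in seq_len(nrow(param_grid))) {
    truth <- as.list(param_grid[i, c("alpha", "p", "rho", "beta")])
    for (j in seq_len(n_reps)) {
      s <- derive_seed(seed, paste0("recovery-", i, "-", j))
      choices <- simulate_choices(design, truth, seed = s)
      dat <- cbind(design[, c("T", "R", "P", "S")],
                   choice = choices$choice)
      if (!eligible_for_fit(dat)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          grid_point = i, rep = j, eligible = FALSE,
          true_alpha = truth$alpha, true_p = truth$p, true_rho = truth$rho,
          true_beta = truth$beta, est_alpha = NA_real_, est_p = NA_real_,
          est_rho = NA_real_, est_beta = NA_real_)
        next
      }
      fit <- fit_mle(dat, spec, seed = s, n_starts = n_starts)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        grid_point = i, rep = j, eligible = TRUE,
        true_alpha = truth$alpha, true_p = truth$p, true_rho = truth$rho,
        true_beta = truth$beta,
        est_alpha = unname(fit$params["alpha"]),
        est_p = unname(fit$params["p"]),
        est_rho = unname(fit$params["rho"]),
        est_beta = unname(fit$params["beta"]))
    }
  }
  results <- do.call(rbind, rows)
  ok <- results$eligible
  summ <- do.call(rbind, lapply(c("alpha", "p", "rho", "beta"), function(nm) {
    tr <- results[[paste0("true_", nm)]][ok]
    es <- results[[paste0("est_", nm)]][ok]
    tibble::tibble(
      param = nm,
      corr = if (stats::sd(tr) > 0 && stats::sd(es) > 0)
        stats::cor(tr, es) else NA_real_,
      bias = mean(es - tr),
      rmse = sqrt(mean((es - tr)^2)))
  }))
  list(results = results, summary = summ)
}

#' Write participant-level fits to CSV
#'
#' @param fits A list of `coop_fit` objects or a data frame of fit rows with
#'   a `participant_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  if (is.data.frame(fits)) {
    utils::write.csv(fits, path, row.names = FALSE)
    return(invisible(path))
  }
  core <- c("alpha", "p", "rho", "beta")
  rows <- lapply(fits, function(f) {
    extras <- f$params[setdiff(names(f$params), core)]
    tibble::tibble(
      participant_id = f$participant_id %||% NA,
      variant = f$variant,
      alpha = unname(f$params["alpha"]),
      p = unname(f$params["p"]),
      rho = unname(f$params["rho"]),
      beta = unname(f$params["beta"]),
      extras = as.character(jsonlite::toJSON(as.list(extras),
                                             auto_unbox = TRUE, digits = NA)),
      loglik = f$loglik, bic = f$bic, converged = f$converged,
      n_starts = f$n_starts_used)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
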