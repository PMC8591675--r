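#' Step survival curve
#'
#' Right-continuous non-increasing step function with value 1 at t = 0,
#' with helpers for evaluation and left limits.
#'
#' @param times Sorted jump times.
#' @param values Curve values right of each jump, in [0, 1], non-increasing.
#' @return A `step_surv_curve` list with `eval(t)` and `eval_left(t)`
#'   accessors.
#' @export
step_surv_curve <- function(times, values) {
  o <- order(times)
  times <- times[o]; values <- values[o]
  stopifnot(all(values >= -1e-12), all(values <= 1 + 1e-12),
            all(diff(values) <= 1e-12))
  ev <- function(t) {
    i <- findInterval(t, times)         # right-continuous
    c(1, values)[i + 1L]
  }
  evl <- function(t) {                  # left limit G(t-)
    i <- findInterval(t, times, left.open = TRUE)
    c(1, values)[i + 1L]
  }
  structure(list(times = times, values = values, eval = ev,
                 eval_left = evl), class = "step_surv_curve")
}

#' Kaplan-Meier curve of the censoring distribution
#'
#' Kaplan-Meier estimate based on the flipped observations
#' \eqn{(t_i, 1 - \delta_i)}: the IPCW weight source \eqn{\hat G(t)} used by
#' the weighted Brier and Schmid scores.
#'
#' @param outcome A [surv_outcome()].
#' @return A [step_surv_curve()].
#' @export
km_censoring <- function(outcome) {
  outcome <- as_surv_outcome(outcome)
  sf <- survival::survfit(
    survival::Surv(outcome$time, 1 - outcome$status) ~ 1)
  step_surv_curve(sf$time, sf$surv)
}

#' Kaplan-Meier curve of the event-time distribution
#'
#' @param outcome A [surv_outcome()].
#' @return A [step_surv_curve()].
#' @export
km_event <- function(outcome) {
  outcome <- as_surv_outcome(outcome)
  sf <- survival::survfit(
    survival::Surv(outcome$time, outcome$status) ~ 1)
  step_surv_curve(sf$time, sf$surv)
}

default_grid <- function(outcome) {
  g <- sort(unique(outcome$time[outcome$status == 1]))
  g[g > 0 & g <= max(outcome$time)]
}

#' Metric curve container
#'
#' @param times Strictly increasing evaluation grid.
#' @param values Pointwise metric values.
#' @param max_time Upper integration limit (max observed time).
#' @param weighted IPCW-weighted flag.
#' @param dropped Count of subject-terms dropped because of zero IPCW
#'   denominators.
#' @return A `metric_curve` with an `integrated` field per the
#'   \eqn{(1/\max t_i)\int_0^{\max t_i}} contract.
#' @export
metric_curve <- function(times, values, max_time, weighted = TRUE,
                         dropped = 0L) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  mc <- structure(list(times = times, values = values, max_time = max_time,
                       weighted = weighted, dropped = dropped,
                       integrated = NA_real_), class = "metric_curve")
  mc$integrated <- integrate_curve(mc)
  mc
}

#' Integrate a metric curve
#'
#' \eqn{(1/\max t_i) \int_0^{\max t_i} m(t)\,dt} by the trapezoidal rule,
#' extending the curve constantly left of the first grid point and right of
#' the last.
#'
#' @param curve A [metric_curve()].
#' @return Scalar integral.
#' @export
integrate_curve <- function(curve) {
  tt <- c(0, curve$times, curve$max_time)
  vv <- c(curve$values[1], curve$values, curve$values[length(curve$values)])
  keep <- tt <= curve$max_time
  tt <- tt[keep]; vv <- vv[keep]
  if (tt[length(tt)] < curve$max_time) {
    tt <- c(tt, curve$max_time); vv <- c(vv, vv[length(vv)])
  }
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2) /
    curve$max_time
}

# shared IPCW machinery for the three prediction-error curves.
# event_denom: per-subject denominator for the event term ("G_ti" or
# "G_ti_minus"); atrisk_denom: "G_t" (standard IPCW) or "G_ti" (as printed
# in the Schemper-Henderson formula).
pred_error_curve <- function(S_pred, outcome, times, weighted,
                             transform, event_denom, atrisk_denom) {
  outcome <- as_surv_outcome(outcome)
  if (is.null(times)) times <- default_grid(outcome)
  if (length(times) == 0) stop("no event times in (0, max t]")
  S_pred <- as.matrix(S_pred)
  stopifnot(nrow(S_pred) == outcome$n, ncol(S_pred) == length(times))
  G <- km_censoring(outcome)
  gi <- G$eval(outcome$time)
  gim <- G$eval_left(outcome$time)
  n <- outcome$n
  dropped <- 0L
  vals <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    s <- S_pred[, k]
    ev <- outcome$time <= t & outcome$status == 1
    ar <- outcome$time > t
    gt <- G$eval(t)
    d_ev <- if (!weighted) rep(1, n)
            else if (event_denom == "G_ti") gi else gim
    d_ar <- if (!weighted) rep(1, n)
            else if (atrisk_denom == "G_t") rep(gt, n) else gi
    term <- numeric(n)
    ok_ev <- ev & d_ev > 0
    ok_ar <- ar & d_ar > 0
    dropped <- dropped + sum(ev & d_ev <= 0) + sum(ar & d_ar <= 0)
    term[ok_ev] <- transform(s[ok_ev], 0) / d_ev[ok_ev]
    term[ok_ar] <- transform(s[ok_ar], 1) / d_ar[ok_ar]
    vals[k] <- sum(term) / n
  }
  metric_curve(times, vals, max_time = max(outcome$time),
               weighted = weighted, dropped = dropped)
}

#' IPCW Brier score curve
#'
#' Squared deviation between predicted survival and observed status,
#' \eqn{BS_w(t)}: event term \eqn{\hat S(t|X_i)^2 / \hat G(t_i)}, at-risk
#' term \eqn{(1 - \hat S(t|X_i))^2 / \hat G(t)}. `weighted = FALSE` clears
#' the IPCW denominators, giving values in [0, 1].
#'
#' @param S_pred n x length(times) matrix of \eqn{\hat S(t|X_i)}.
#' @param outcome A [surv_outcome()].
#' @param times Evaluation grid; default = unique event times.
#' @param weighted IPCW weighting flag.
#' @return A [metric_curve()].
#' @export
brier_curve <- function(S_pred, outcome, times = NULL, weighted = TRUE) {
  pred_error_curve(S_pred, outcome, times, weighted,
                   transform = function(s, target) (target - s)^2,
                   event_denom = "G_ti", atrisk_denom = "G_t")
}

#' IPCW Schmid (absolute deviation) score curve
#'
#' \eqn{SS(t)}: absolute-deviation analogue of the Brier score; event term
#' weighted by \eqn{1/\hat G(t_i^-)}, at-risk term by \eqn{1/\hat G(t)}.
#'
#' @inheritParams brier_curve
#' @return A [metric_curve()].
#' @export
schmid_curve <- function(S_pred, outcome, times = NULL, weighted = TRUE) {
  pred_error_curve(S_pred, outcome, times, weighted,
                   transform = function(s, target) abs(target - s),
                   event_denom = "G_ti_minus", atrisk_denom = "G_t")
}

#' Schemper-Henderson absolute-deviation curve
#'
#' \eqn{SH(t)}: the absolute-deviation predecessor of the Schmid score,
#' with both terms weighted by \eqn{1/\hat G(t_i)} as printed.
#'
#' @inheritParams brier_curve
#' @return A [metric_curve()].
#' @export
schemper_henderson_curve <- function(S_pred, outcome, times = NULL,
                                     weighted = TRUE) {
  pred_error_curve(S_pred, outcome, times, weighted,
                   transform = function(s, target) abs(target - s),
                   event_denom = "G_ti", atrisk_denom = "G_ti")
}

#' Integrated R-squared of a prediction-error curve
#'
#' Pointwise \eqn{R(t) = 1 - m(t)/m_0(t)} against a null-model reference
#' curve on the same grid, integrated by the same
#' \eqn{(1/\max t_i)\int} rule. Applied to Brier curves this yields iR2BSw;
#' applied to Schmid curves it yields the integrated R Schmid Score
#' weighted (iRSSw), the package's robust least-absolute-deviation
#' coefficient of determination.
#'
#' @param curve,null_curve [metric_curve()]s on the same grid; `null_curve`
#'   is typically computed from the Kaplan-Meier prediction.
#' @return Scalar integrated R-squared (1 = oracle, 0 = no improvement).
#' @export
r2_curve_integrated <- function(curve, null_curve) {
  stopifnot(identical(curve$times, null_curve$times))
  if (all(null_curve$values == 0)) stop("null curve identically 0")
  keep <- null_curve$values > 0
  r <- 1 - curve$values[keep] / null_curve$values[keep]
  integrate_curve(metric_curve(curve$times[keep], r,
                               max_time = curve$max_time,
                               weighted = curve$weighted))
}

#' Likelihood-based R-squared coefficients for Cox models
#'
#' `nagelkerke`: \eqn{1 - \exp(-2(l_\beta - l_0)/n)}; `oxs` replaces n by
#' the number of events e; `xo` is the Schoenfeld-residual ratio
#' \eqn{1 - J_\beta/J_0}.
#'
#' @param l0,lbeta Null and fitted log partial likelihoods.
#' @param n Number of subjects; `e` number of events.
#' @param kind One of `"nagelkerke"`, `"xo"`, `"oxs"`.
#' @param J0,Jbeta Schoenfeld-residual sums of squares (xo only).
#' @param e Number of events (oxs only).
#' @return Scalar R-squared.
#' @export
r2_likelihood <- function(l0, lbeta, n, e = NULL,
                          kind = c("nagelkerke", "xo", "oxs"),
                          J0 = NULL, Jbeta = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    nagelkerke = {
      if (is.null(n) || n == 0) stop("n required")
      1 - exp(-2 * (lbeta - l0) / n)
    },
    oxs = {
      if (is.null(e) || e == 0) stop("e required")
      1 - exp(-2 * (lbeta - l0) / e)
    },
    xo = {
      if (is.null(J0) || is.null(Jbeta)) stop("J0 and Jbeta required")
      if (J0 == 0) stop("J0 is zero")
      1 - Jbeta / J0
    })
}

# Schoenfeld-residual sum of squares of a single-covariate Cox model at a
# given beta: sum over events of (x_i - xbar(t_i; beta))^2
schoenfeld_ss <- function(beta, x, outcome) {
  w <- exp(beta * x)
  ss <- 0
  for (tk in sort(unique(outcome$time[outcome$status == 1]))) {
    at_risk <- outcome$time >= tk
    xbar <- sum(w[at_risk] * x[at_risk]) / sum(w[at_risk])
    dead <- outcome$time == tk & outcome$status == 1
    ss <- ss + sum((x[dead] - xbar)^2)
  }
  ss
}

#' Xu-O'Quigley R-squared of a risk score
#'
#' Fits a single-covariate Cox model of the outcome on the risk score and
#' returns \eqn{1 - J(\hat\beta)/J(0)} where J is the sum of squared
#' Schoenfeld residuals. A flagged/degenerate fit returns 0.
#'
#' @param risk Risk-score vector.
#' @param outcome A [surv_outcome()].
#' @return Scalar R2XO.
#' @export
r2_xo <- function(risk, outcome) {
  outcome <- as_surv_outcome(outcome)
  if (stats::sd(risk) < 1e-12) return(0)
  ft <- fit_cox(matrix(risk, ncol = 1), outcome)
  b <- if (ft$flagged) 0 else ft$beta
  J0 <- schoenfeld_ss(0, risk, outcome)
  if (J0 == 0) return(0)
  r2_likelihood(kind = "xo", J0 = J0, Jbeta = schoenfeld_ss(b, risk, outcome))
}

#' Harrell's concordance index
#'
#' Pairwise concordance over usable pairs (the smaller follow-up time is an
#' event): 0.5 = no discrimination, 1.0 = perfect separation. Tied risk
#' scores contribute 0 by default (`ties = "half"` scores them 0.5).
#'
#' @param risk Risk scores (higher = shorter expected survival).
#' @param outcome A [surv_outcome()].
#' @param ties `"zero"` or `"half"`.
#' @return Concordance in [0, 1].
#' @export
harrell_c <- function(risk, outcome, ties = c("zero", "half")) {
  ties <- match.arg(ties)
  outcome <- as_surv_outcome(outcome)
  y <- outcome$time; d <- outcome$status; r <- risk
  lt <- outer(y, y, "<")                       # y_i < y_j
  usable <- lt & matrix(d == 1, length(y), length(y))
  if (!any(usable)) stop("no usable pairs")
  conc <- outer(r, r, ">")
  num <- sum(usable & conc)
  if (ties == "half") num <- num + 0.5 * sum(usable & outer(r, r, "=="))
  num / sum(usable)
}

#' Gonen-Heller concordance probability (GHCI)
#'
#' Covariate-only concordance estimator for Cox-type models: uses only the
#' linear-predictor differences, never the observed times, hence robust to
#' censoring and invariant under monotone time transforms.
#'
#' @param risk Linear predictors \eqn{\hat\beta' X_i}; alternatively pass
#'   `beta` and `X`.
#' @param beta,X Coefficients and design matrix (used when `risk` missing).
#' @return \eqn{K_n(\hat\beta)}; 0 when all predictors are tied (as the
#'   strict indicators vanish).
#' @export
gonen_heller_c <- function(risk = NULL, beta = NULL, X = NULL) {
  if (is.null(risk)) risk <- drop(as.matrix(X) %*% beta)
  n <- length(risk)
  if (n < 2) stop("need at least 2 subjects")
  D <- outer(risk, risk, "-")         # D[i,j] = eta_i - eta_j
  A <- (D > 0) / (1 + exp(-D))        # I(eta_j - eta_i < 0)/(1+exp(eta_j-eta_i))
  diag(A) <- 0
  2 * sum(A) / (n * (n - 1))
}

#' Uno's IPCW concordance
#'
#' Inverse-probability-of-censoring-weighted concordance truncated at
#' `tau`; with no censoring it reduces to Harrell's C restricted to pairs
#' with the smaller time below `tau`.
#'
#' @param risk Risk scores.
#' @param outcome A [surv_outcome()].
#' @param tau Truncation time (<= max observed time); default max time.
#' @return Concordance in [0, 1].
#' @export
uno_c <- function(risk, outcome, tau = NULL) {
  outcome <- as_surv_outcome(outcome)
  y <- outcome$time; d <- outcome$status
  if (is.null(tau)) tau <- max(y)
  if (tau > max(y)) stop("tau exceeds max observed time")
  G <- km_censoring(outcome)
  gm <- G$eval_left(y)
  usable_i <- d == 1 & y < tau
  if (any(usable_i & gm <= 0)) stop("censoring KM reaches 0 before tau")
  w <- ifelse(usable_i, 1 / gm^2, 0)
  lt <- outer(y, y, "<")
  conc <- outer(risk, risk, ">")
  W <- matrix(w, length(y), length(y)) * lt
  num <- sum(W * conc)
  den <- sum(W)
  if (den == 0) stop("no usable pairs before tau")
  num / den
}

# pointwise cumulative/dynamic AUC at time t.
# case_w: per-subject case weights (for subjects with t_i <= t, delta = 1);
# controls are subjects with t_j > t, equally weighted unless ctrl_w given.
cd_auc_at <- function(t, risk, y, d, case_w, ctrl_w = NULL) {
  cases <- which(y <= t & d == 1)
  ctrls <- which(y > t)
  if (!length(cases) || !length(ctrls)) return(NA_real_)
  cw <- case_w[cases]
  vw <- if (is.null(ctrl_w)) rep(1, length(ctrls)) else ctrl_w[ctrls]
  if (sum(cw) <= 0 || sum(vw) <= 0) return(NA_real_)
  cmpg <- outer(risk[cases], risk[ctrls], ">") +
          0.5 * outer(risk[cases], risk[ctrls], "==")
  sum((cw %o% vw) * cmpg) / (sum(cw) * sum(vw))
}

#' Integrated time-dependent AUC for censored data
#'
#' Six integrated cumulative/dynamic (or, for `"HZ"`, incident/dynamic)
#' AUC estimators. All evaluate a pointwise AUC(t) on the test-set event
#' time grid and integrate it: with the event-density weight
#' \eqn{w(t) \propto 2 \hat f(t) \hat S(t)} for `"CD"`, `"HZ"` and
#' `"survROC"`, and uniformly (trapezoid over \eqn{[0, \max t]}) for
#' `"Uno"`, `"SH"` and `"HC"`. Pointwise estimators: `"survROC"`/`"Uno"`
#' weight cases by \eqn{1/\hat G(t_i^-)}, `"HC"` by \eqn{1/\hat G(t_i)},
#' `"SH"` uses the plain empirical case set, `"CD"` weights cases by their
#' Kaplan-Meier mass, and `"HZ"` compares each event to its risk set.
#'
#' @param risk Risk scores of the test subjects.
#' @param outcome_train Training outcome (reserved; grids and censoring
#'   weights are estimated on the test set).
#' @param outcome_test Test [surv_outcome()]; needs >= 2 event times.
#' @param method One of `"CD"`, `"HC"`, `"SH"`, `"Uno"`, `"HZ"`,
#'   `"survROC"`.
#' @return Integrated AUC clipped to [0, 1].
#' @export
iauc <- function(risk, outcome_train = NULL, outcome_test,
                 method = c("CD", "HC", "SH", "Uno", "HZ", "survROC")) {
  method <- match.arg(method)
  outcome_test <- as_surv_outcome(outcome_test)
  y <- outcome_test$time; d <- outcome_test$status
  grid <- sort(unique(y[d == 1]))
  grid <- grid[grid < max(y)]   # need a non-empty control set
  if (length(grid) < 2) stop("fewer than 2 usable event times in test data")
  G <- km_censoring(outcome_test)
  S <- km_event(outcome_test)
  gm <- G$eval_left(y); gr <- G$eval(y)
  km_before <- S$eval_left(y); km_at <- S$eval(y)
  f_mass <- km_before - km_at            # KM jump mass at each subject time
  case_w <- switch(method,
    survROC = ifelse(gm > 0, 1 / gm, 0),
    Uno     = ifelse(gm > 0, 1 / gm, 0),
    HC      = ifelse(gr > 0, 1 / gr, 0),
    SH      = rep(1, length(y)),
    CD      = f_mass,
    HZ      = NULL)
  if (method == "HZ") {
    auc <- vapply(grid, function(t) {
      cases <- which(y == t & d == 1)
      ctrls <- which(y > t)
      if (!length(cases) || !length(ctrls)) return(NA_real_)
      cmpg <- outer(risk[cases], risk[ctrls], ">") +
              0.5 * outer(risk[cases], risk[ctrls], "==")
      mean(cmpg)
    }, numeric(1))
  } else {
    auc <- vapply(grid, function(t) cd_auc_at(t, risk, y, d, case_w),
                  numeric(1))
  }
  ok <- is.finite(auc)
  if (sum(ok) < 2) stop("too few defined AUC(t) values")
  grid <- grid[ok]; auc <- auc[ok]
  if (method %in% c("CD", "HZ", "survROC")) {
    wts <- 2 * (S$eval_left(grid) - S$eval(grid)) * S$eval(grid)
    if (sum(wts) <= 0) wts <- rep(1, length(grid))
    val <- sum(wts * auc) / sum(wts)
  } else {
    val <- integrate_curve(metric_curve(grid, auc, max_time = max(y)))
  }
  min(max(val, 0), 1)
}

#' Performance-measure panel for a fitted model on test data
#'
#' Computes the benchmark's reported indices on a held-out test set:
#' likelihood R-squareds, iR2BSw/iRSSw, concordance indices and integrated
#' AUCs, plus the integrated (un)weighted Brier and Schmid scores.
#'
#' @param model A `plsdr_model`.
#' @param X_test,outcome_test Held-out data.
#' @param measures Character vector of measure names; default the six
#'   reported indices.
#' @return Named numeric vector.
#' @export
performance_measures <- function(model, X_test, outcome_test,
                                 measures = c("R2XO", "iRSSw", "GHCI",
                                              "iAUCCD", "iAUCsurvROC",
                                              "iSSw")) {
  outcome_test <- as_surv_outcome(outcome_test)
  risk <- predict_risk(model, X_test)
  grid <- default_grid(outcome_test)
  S_pred <- predict_survival(model, X_test,
                             pmin(grid, max(model$outcome$time)))
  km <- km_event(outcome_test)
  S_null <- matrix(km$eval(grid), nrow = outcome_test$n,
                   ncol = length(grid), byrow = TRUE)
  out <- numeric(0)
  has_signal <- stats::sd(risk) > 1e-12
  for (m in measures) {
    v <- tryCatch(switch(m,
      R2XO = r2_xo(risk, outcome_test),
      R2Nag = {
        ft <- if (has_signal) fit_cox(matrix(risk, ncol = 1), outcome_test)
              else fit_cox(matrix(0, outcome_test$n, 0), outcome_test)
        r2_likelihood(ft$log_pl_null, ft$log_pl, n = outcome_test$n,
                      kind = "nagelkerke")
      },
      R2OXS = {
        ft <- if (has_signal) fit_cox(matrix(risk, ncol = 1), outcome_test)
              else fit_cox(matrix(0, outcome_test$n, 0), outcome_test)
        r2_likelihood(ft$log_pl_null, ft$log_pl, n = outcome_test$n,
                      e = sum(outcome_test$status), kind = "oxs")
      },
      GHCI = gonen_heller_c(risk),
      C = harrell_c(risk, outcome_test),
      UnoC = uno_c(risk, outcome_test),
      iAUCCD = iauc(risk, NULL, outcome_test, "CD"),
      iAUCHC = iauc(risk, NULL, outcome_test, "HC"),
      iAUCSH = iauc(risk, NULL, outcome_test, "SH"),
      iAUCUno = iauc(risk, NULL, outcome_test, "Uno"),
      iAUCHZ = iauc(risk, NULL, outcome_test, "HZ"),
      iAUCsurvROC = iauc(risk, NULL, outcome_test, "survROC"),
      iBSw = brier_curve(S_pred, outcome_test, grid, TRUE)$integrated,
      iBSunw = brier_curve(S_pred, outcome_test, grid, FALSE)$integrated,
      iSSw = schmid_curve(S_pred, outcome_test, grid, TRUE)$integrated,
      iSSunw = schmid_curve(S_pred, outcome_test, grid, FALSE)$integrated,
      SchemperV = schemper_henderson_curve(S_pred, outcome_test,
                                           grid)$integrated,
      iR2BSw = r2_curve_integrated(
        brier_curve(S_pred, outcome_test, grid, TRUE),
        brier_curve(S_null, outcome_test, grid, TRUE)),
      iRSSw = r2_curve_integrated(
        schmid_curve(S_pred, outcome_test, grid, TRUE),
        schmid_curve(S_null, outcome_test, grid, TRUE)),
      stop("unknown measure: ", m)), error = function(e) NA_real_)
    out[m] <- v
  }
  out
}
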