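#' Right-censored survival outcome
#'
#' Bundles observation times and event indicators for `n` subjects into a
#' validated container used throughout the package.
#'
#' @param time Positive observation times (event or censoring), one per
#'   subject, in a common unit.
#' @param status Event indicators: 1 = event observed, 0 = right-censored.
#' @return An object of class `surv_outcome` with elements `time`, `status`
#'   and `n`.
#' @examples
#' surv_outcome(c(2, 5, 3.5), c(1, 0, 1))
#' @export
surv_outcome <- function(time, status) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status))
    stop("time and status must have the same length")
  if (length(time) < 2L) stop("need at least 2 subjects")
  if (anyNA(time) || anyNA(status)) stop("missing values in outcome")
  if (any(time <= 0)) stop("all times must be > 0")
  if (!all(status %in% c(0, 1))) stop("status must be 0 or 1")
  structure(list(time = time, status = status, n = length(time)),
            class = "surv_outcome")
}

#' @export
print.surv_outcome <- function(x, ...) {
  cat(sprintf("surv_outcome: %d subjects, %d events (%.1f%% censored)\n",
              x$n, sum(x$status), 100 * mean(x$status == 0)))
  invisible(x)
}

as_surv_outcome <- function(x) {
  if (inherits(x, "surv_outcome")) return(x)
  surv_outcome(x$time, x$status)
}

# Risk-set bookkeeping shared by the partial likelihood, its derivatives and
# the Breslow baseline. Ties: events precede censoring, i.e. a subject
# censored at an event time is still at risk there (R_k = {j : t_j >= t_k}).
cox_event_layout <- function(outcome) {
  dt <- sort(unique(outcome$time[outcome$status == 1]))
  list(event_times = dt,
       d = vapply(dt, function(tk)
         sum(outcome$time == tk & outcome$status == 1), numeric(1)))
}

# log Breslow partial likelihood at linear predictor eta
log_pl_eta <- function(eta, outcome) {
  lay <- cox_event_layout(outcome)
  if (length(lay$event_times) == 0L) stop("no events")
  ll <- 0
  for (k in seq_along(lay$event_times)) {
    tk <- lay$event_times[k]
    at_risk <- outcome$time >= tk
    dead <- outcome$time == tk & outcome$status == 1
    ll <- ll + sum(eta[dead]) - lay$d[k] * log(sum(exp(eta[at_risk])))
  }
  ll
}

#' Cox log partial likelihood (Breslow ties)
#'
#' Pure evaluation of the log partial likelihood
#' \eqn{\sum_{k \in D} [\beta' x_k - d_k \log \sum_{j \in R_k} e^{\beta' x_j}]}
#' at a given coefficient vector; no fitting is performed.
#'
#' @param beta Coefficient vector (length = ncol(X); may be length 0).
#' @param X Design matrix (n x q); q = 0 allowed.
#' @param outcome A [surv_outcome()].
#' @return The log partial likelihood, a scalar.
#' @export
log_partial_likelihood <- function(beta, X, outcome) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  if (ncol(X) != length(beta)) stop("beta/X dimension mismatch")
  if (nrow(X) != outcome$n) stop("X/outcome dimension mismatch")
  eta <- if (length(beta)) drop(X %*% beta) else rep(0, outcome$n)
  log_pl_eta(eta, outcome)
}

cox_derivatives <- function(beta, X, outcome) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  q <- ncol(X)
  U <- numeric(q); H <- matrix(0, q, q); ll <- 0
  lay <- cox_event_layout(outcome)
  for (k in seq_along(lay$event_times)) {
    tk <- lay$event_times[k]
    at_risk <- which(outcome$time >= tk)
    dead <- which(outcome$time == tk & outcome$status == 1)
    wr <- w[at_risk]; sw <- sum(wr)
    Xr <- X[at_risk, , drop = FALSE]
    xbar <- drop(crossprod(Xr, wr)) / sw
    ll <- ll + sum(eta[dead]) - lay$d[k] * log(sw)
    U <- U + colSums(X[dead, , drop = FALSE]) - lay$d[k] * xbar
    Sxx <- crossprod(Xr * wr, Xr) / sw
    H <- H + lay$d[k] * (Sxx - tcrossprod(xbar))
  }
  list(ll = ll, U = U, H = H)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Breslow partial likelihood with
#' step-halving. With `q = 0` columns the null model is returned. Monotone
#' (separable) likelihoods are flagged, not silently accepted: the fit is
#' returned with `converged = FALSE` and `flagged = TRUE` when a
#' standardized coefficient exceeds 50 in absolute value.
#'
#' @param X Design matrix, n x q, no missing entries (missing handling lives
#'   upstream in the PLS layer).
#' @param outcome A [surv_outcome()]; at least one event required.
#' @param ties Tie rule; `"breslow"` (default) or `"efron"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `cox_fit`: `beta`, `log_pl`, `log_pl_null`,
#'   `converged`, `flagged`, `n_iter`, plus the data references needed by
#'   [breslow_cumhaz()].
#' @export
fit_cox <- function(X, outcome, ties = c("breslow", "efron"),
                    max_iter = 50L, tol = 1e-9) {
  ties <- match.arg(ties)
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  if (nrow(X) != outcome$n && ncol(X) > 0)
    stop("X/outcome dimension mismatch")
  if (sum(outcome$status) == 0) stop("no events")
  if (anyNA(X)) stop("missing entries in X; impute or use the PLS layer")
  q <- ncol(X)
  ll0 <- log_pl_eta(rep(0, outcome$n), outcome)
  if (q == 0L) {
    fit <- list(beta = numeric(0), log_pl = ll0, log_pl_null = ll0,
                converged = TRUE, flagged = FALSE, n_iter = 0L,
                ties = ties, X = matrix(0, outcome$n, 0), outcome = outcome)
    class(fit) <- "cox_fit"
    return(fit)
  }
  if (ties == "efron") {
    # delegated: Efron is optional and the Breslow baseline below is the one
    # the residual pipeline uses
    sf <- survival::coxph(survival::Surv(outcome$time, outcome$status) ~ X,
                          ties = "efron")
    beta <- unname(stats::coef(sf))
    eta <- drop(X %*% beta)
    fit <- list(beta = beta, log_pl = log_pl_eta(eta, outcome),
                log_pl_null = ll0, converged = TRUE, flagged = FALSE,
                n_iter = NA_integer_, ties = ties, X = X, outcome = outcome)
    class(fit) <- "cox_fit"
    return(fit)
  }
  beta <- numeric(q)
  ll <- ll0
  converged <- FALSE; flagged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dv <- cox_derivatives(beta, X, outcome)
    step <- tryCatch(solve(dv$H + diag(1e-10, q), dv$U),
                     error = function(e) dv$U / (max(diag(dv$H)) + 1e-10))
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      llc <- tryCatch(log_pl_eta(drop(X %*% cand), outcome),
                      error = function(e) -Inf)
      if (is.finite(llc) && llc >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    if (abs(llc - ll) < tol && it > 1L) { beta <- cand; ll <- llc
      converged <- TRUE; break }
    beta <- cand; ll <- llc
  }
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1
  if (any(abs(beta * sds) > 50)) { flagged <- TRUE; converged <- FALSE }
  if (converged && !flagged) {
    # monotone likelihood plateaus with a drifting Newton step: the log
    # partial likelihood change is < tol yet the increment stays large
    dv <- cox_derivatives(beta, X, outcome)
    step <- tryCatch(solve(dv$H + diag(1e-10, q), dv$U),
                     error = function(e) rep(0, q))
    if (max(abs(step * sds)) > 0.25) { flagged <- TRUE; converged <- FALSE }
  }
  if (!converged && !flagged && it >= max_iter) flagged <- TRUE
  fit <- list(beta = beta, log_pl = ll, log_pl_null = ll0,
              converged = converged, flagged = flagged, n_iter = it,
              ties = ties, X = X, outcome = outcome)
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d coefficients, logPL = %.4f (null %.4f), %s\n",
              length(x$beta), x$log_pl, x$log_pl_null,
              if (x$flagged) "FLAGGED" else if (x$converged) "converged"
              else "not converged"))
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' \eqn{\hat\Lambda_0(t) = \sum_{t_k \le t} d_k / \sum_{j \in R_k}
#' e^{\hat\beta' x_j}}. With `q = 0` this is the Nelson-Aalen estimator.
#'
#' @param fit A [fit_cox()] result.
#' @param X,outcome Optional overrides; default to the training data stored
#'   in `fit`.
#' @return A right-continuous non-decreasing step function with
#'   \eqn{\hat\Lambda_0(0) = 0}; attributes `times` and `hazard` expose the
#'   jump locations and cumulated values.
#' @export
breslow_cumhaz <- function(fit, X = fit$X, outcome = fit$outcome) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  eta <- if (length(fit$beta)) drop(X %*% fit$beta) else rep(0, outcome$n)
  w <- exp(eta)
  lay <- cox_event_layout(outcome)
  if (length(lay$event_times) == 0L) {
    f <- stats::stepfun(1, c(0, 0))
    attr(f, "times") <- numeric(0); attr(f, "hazard") <- numeric(0)
    return(f)
  }
  inc <- vapply(seq_along(lay$event_times), function(k)
    lay$d[k] / sum(w[outcome$time >= lay$event_times[k]]), numeric(1))
  H <- cumsum(inc)
  f <- stats::stepfun(lay$event_times, c(0, H), right = FALSE)
  attr(f, "times") <- lay$event_times
  attr(f, "hazard") <- H
  f
}

#' Martingale residuals of a Cox fit
#'
#' \eqn{\hat M_i = \delta_i - \hat\Lambda_0(t_i)\,e^{\hat\beta' x_i}}. With
#' the Breslow baseline the residuals sum to zero (estimating-equation
#' identity).
#'
#' @inheritParams breslow_cumhaz
#' @return A `residual_vector`: list with `values` and `kind = "martingale"`.
#' @export
martingale_residuals <- function(fit, X = fit$X, outcome = fit$outcome) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  eta <- if (length(fit$beta)) drop(X %*% fit$beta) else rep(0, outcome$n)
  L0 <- breslow_cumhaz(fit, X, outcome)
  m <- outcome$status - L0(outcome$time) * exp(eta)
  structure(list(values = m, kind = "martingale"), class = "residual_vector")
}

#' Deviance residuals from martingale residuals
#'
#' Variance-stabilizing, sign-preserving transform
#' \eqn{d_i = \mathrm{sign}(\hat M_i)\sqrt{2(-\hat M_i - \delta_i
#' \log((\delta_i - \hat M_i)/\delta_i))}} with the convention
#' \eqn{\delta_i \log(\cdot) = 0} when \eqn{\delta_i = 0} and
#' \eqn{\mathrm{sign}(0) = 0}.
#'
#' @param mart A martingale `residual_vector`.
#' @param status Event indicators aligned with the residuals.
#' @return A `residual_vector` with `kind = "deviance"`.
#' @export
deviance_residuals <- function(mart, status) {
  if (!inherits(mart, "residual_vector") || mart$kind != "martingale")
    stop("mart must be a martingale residual_vector")
  m <- mart$values
  status <- as.numeric(status)
  if (length(m) != length(status)) stop("length mismatch")
  if (any(status == 1 & m > 1 + 1e-12)) stop("martingale residual > 1 with an event: impossible input")
  arg <- -m
  ev <- status == 1
  arg[ev] <- -m[ev] - log((1 - m[ev]))  # delta = 1: log((delta - M)/delta)
  arg <- pmax(arg, 0)                    # guard roundoff at M ~ 0
  d <- sign(m) * sqrt(2 * arg)
  structure(list(values = d, kind = "deviance"), class = "residual_vector")
}

#' Null-model deviance residuals
#'
#' Composition of a covariate-free Cox fit (Nelson-Aalen baseline),
#' martingale residuals and the deviance transform. These residuals are the
#' continuous surrogate outcome consumed by the PLS stage of the PLSDR
#' families.
#'
#' @param outcome A [surv_outcome()] with at least one event.
#' @return A deviance `residual_vector`.
#' @export
null_deviance_residuals <- function(outcome) {
  outcome <- as_surv_outcome(outcome)
  fit <- fit_cox(matrix(0, outcome$n, 0), outcome)
  deviance_residuals(martingale_residuals(fit), outcome$status)
}
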