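with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Balanced cross-validation folds for censored outcomes
#'
#' Subjects are ordered status-major (status, then time), binned into `floor(n/K)` bins of
#' `K` adjacent subjects, and each fold draws one subject per bin without
#' replacement; the `n mod K` remainder is assigned one-per-fold. This
#' balances the folds both in response value and in censoring rate.
#'
#' @param outcome A [surv_outcome()].
#' @param K Number of folds (default 7).
#' @param seed Integer seed; the plan is a pure function of it.
#' @return A `fold_plan`: list of K disjoint index vectors covering 1..n,
#'   with attributes `K` and `seed`.
#' @export
balanced_folds <- function(outcome, K = 7L, seed = NULL) {
  outcome <- as_surv_outcome(outcome)
  n <- outcome$n
  if (K < 2) stop("K must be >= 2")
  if (K > n) stop("K exceeds n")
  with_seed(seed, {
    # status-major ordering makes the K-sized bins status-homogeneous, so
    # every fold is balanced in censor rate as well as in response value
    o <- order(outcome$status, outcome$time)
    nb <- n %/% K
    folds <- vector("list", K)
    for (b in seq_len(nb)) {
      members <- o[((b - 1) * K + 1):(b * K)]
      asg <- sample(K)
      for (k in seq_len(K)) folds[[k]] <- c(folds[[k]], members[asg == k])
    }
    rem <- if (nb * K < n) o[(nb * K + 1):n] else integer(0)
    if (length(rem)) {
      tofold <- sample(K, length(rem))
      for (i in seq_along(rem))
        folds[[tofold[i]]] <- c(folds[[tofold[i]]], rem[i])
    }
    structure(lapply(folds, sort), class = "fold_plan", K = K, seed = seed)
  })
}

#' Balanced train/test split
#'
#' Stratified by event status and binned observation time; falls back to a
#' simple random split (with a warning) when the strata degenerate.
#'
#' @param outcome A [surv_outcome()].
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @param time_bins Number of time bins per status class.
#' @return List with integer vectors `train` and `test`.
#' @export
balanced_split <- function(outcome, train_fraction = 0.7, seed = NULL,
                           time_bins = 4L) {
  outcome <- as_surv_outcome(outcome)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- outcome$n
  with_seed(seed, {
    strata <- tryCatch({
      s <- integer(n)
      nxt <- 1L
      for (st in unique(outcome$status)) {
        idx <- which(outcome$status == st)
        nb <- max(1L, min(time_bins, length(idx) %/% 4L))
        b <- cut(rank(outcome$time[idx], ties.method = "first"),
                 breaks = nb, labels = FALSE)
        s[idx] <- nxt + b - 1L
        nxt <- nxt + nb
      }
      if (any(table(s) < 2)) stop("degenerate")
      s
    }, error = function(e) NULL)
    n_train <- round(train_fraction * n)
    if (is.null(strata)) {
      warning("degenerate strata; falling back to simple random split")
      train <- sort(sample(n, n_train))
    } else {
      sizes <- table(strata)
      targ <- train_fraction * as.numeric(sizes)
      take <- floor(targ)
      extra <- n_train - sum(take)
      if (extra > 0) {
        ord <- order(targ - take, decreasing = TRUE)
        take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
      } else if (extra < 0) {
        ord <- order(targ - take)
        k <- 0L
        for (i in ord) {
          if (k == -extra) break
          if (take[i] > 0) { take[i] <- take[i] - 1L; k <- k + 1L }
        }
      }
      train <- integer(0)
      lev <- names(sizes)
      for (i in seq_along(lev)) {
        idx <- which(strata == as.integer(lev[i]))
        train <- c(train, sample(idx, min(take[i], length(idx))))
      }
      train <- sort(train)
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Fit one registered model family
#'
#' Dispatch shared by the cross-validation and benchmark layers.
#'
#' @param family One of `"plsdr"`, `"splsdr"`, `"gplsdr"`, `"sgplsdr"`,
#'   `"dkplsdr"`, `"dksplsdr"`, `"pls-cox"`, `"auto-pls-cox"`.
#' @param X,outcome Training data.
#' @param ncomp,eta,groups,kernel,alpha Hyperparameters; `kernel` defaults
#'   to gaussian for the DK families.
#' @return A `plsdr_model`.
#' @export
fit_family <- function(family, X, outcome, ncomp = 1L, eta = 0,
                       groups = NULL, kernel = NULL, alpha = 0.05) {
  if (family %in% c("dkplsdr", "dksplsdr") && is.null(kernel))
    kernel <- list(kind = "gaussian", bandwidth = NULL)
  switch(family,
    "plsdr" = fit_plsdr(X, outcome, ncomp, mode = "plain"),
    "splsdr" = fit_plsdr(X, outcome, ncomp, mode = "sparse", eta = eta),
    "gplsdr" = fit_plsdr(X, outcome, ncomp, mode = "group", eta = eta,
                         groups = groups),
    "sgplsdr" = fit_plsdr(X, outcome, ncomp, mode = "sparse-group",
                          eta = eta, groups = groups,
                          within_sparsity = eta),
    "dkplsdr" = fit_plsdr(X, outcome, ncomp, mode = "plain",
                          kernel = kernel),
    "dksplsdr" = fit_plsdr(X, outcome, ncomp, mode = "sparse", eta = eta,
                           kernel = kernel),
    "pls-cox" = if (ncomp == 0L) fit_plsdr(X, outcome, 0L)
                else fit_pls_cox(X, outcome, ncomp),
    "auto-pls-cox" = fit_auto_pls_cox(X, outcome, alpha = alpha),
    stop("unknown family: ", family))
}

criterion_result <- function(ncomp, eta, per_fold) {
  vals <- per_fold[is.finite(per_fold)]
  structure(list(ncomp = ncomp, eta = eta, per_fold = per_fold,
                 n_excluded = sum(!is.finite(per_fold)),
                 mean = if (length(vals)) mean(vals) else NA_real_),
            class = "criterion_result")
}

#' Naive cross-validated Cox partial likelihood (CVLL)
#'
#' Per fold j: fit the model on the data minus fold j and evaluate the Cox
#' log partial likelihood of the held-out subjects alone, at their
#' predicted linear predictors. Folds with no events are excluded with a
#' logged count.
#'
#' @param family Registered family name (see [fit_family()]).
#' @param hyper List with `ncomp` and optional `eta`.
#' @param X,outcome Full dataset.
#' @param folds A [balanced_folds()] plan.
#' @param ... Passed to [fit_family()].
#' @return A `criterion_result` (per-fold values + mean; larger = better).
#' @export
cvll <- function(family, hyper, X, outcome, folds, ...) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  per_fold <- vapply(folds, function(idx) {
    tr <- setdiff(seq_len(outcome$n), idx)
    out_f <- tryCatch(surv_outcome(outcome$time[idx], outcome$status[idx]),
                      error = function(e) NULL)
    if (is.null(out_f) || sum(out_f$status) == 0) return(NA_real_)
    eta_f <- tryCatch({
      m <- fit_family(family, X[tr, , drop = FALSE],
                      surv_outcome(outcome$time[tr], outcome$status[tr]),
                      ncomp = hyper$ncomp %||% 1L, eta = hyper$eta %||% 0,
                      ...)
      predict_risk(m, X[idx, , drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(eta_f)) return(NA_real_)
    log_pl_eta(eta_f, out_f)
  }, numeric(1))
  criterion_result(hyper$ncomp %||% NA, hyper$eta %||% 0, per_fold)
}

#' van Houwelingen cross-validated partial likelihood (vHCVLL)
#'
#' Per fold j: \eqn{l_{full}(\hat\beta_{(-j)}) - l_{(-j)}(\hat\beta_{(-j)})},
#' both evaluated through the linear predictors of the fold-j-excluded
#' model. Makes efficient use of the full-data risk sets; defined even for
#' folds without events. Larger = better.
#'
#' @inheritParams cvll
#' @return A `criterion_result`.
#' @export
vhcvll <- function(family, hyper, X, outcome, folds, ...) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  per_fold <- vapply(folds, function(idx) {
    if (length(idx) == 0) return(0)
    tr <- setdiff(seq_len(outcome$n), idx)
    out_tr <- surv_outcome(outcome$time[tr], outcome$status[tr])
    val <- tryCatch({
      m <- fit_family(family, X[tr, , drop = FALSE], out_tr,
                      ncomp = hyper$ncomp %||% 1L, eta = hyper$eta %||% 0,
                      ...)
      eta_full <- predict_risk(m, X)
      log_pl_eta(eta_full, outcome) - log_pl_eta(eta_full[tr], out_tr)
    }, error = function(e) NA_real_)
    val
  }, numeric(1))
  criterion_result(hyper$ncomp %||% NA, hyper$eta %||% 0, per_fold)
}

criterion_orientation <- function(criterion) {
  if (criterion %in% c("cvll", "vhcvll", "iAUCCD", "iAUCHC", "iAUCSH",
                       "iAUCUno", "iAUCHZ", "iAUCsurvROC")) "max"
  else if (criterion %in% c("iBSw", "iBSunw", "iSSw", "iSSunw")) "min"
  else stop("unknown criterion: ", criterion)
}

default_criterion <- function(family) {
  if (family %in% c("pls-cox", "auto-pls-cox")) "iAUCSH" else "iAUCsurvROC"
}

eval_heldout_criterion <- function(criterion, model, X_fold, out_fold) {
  risk <- predict_risk(model, X_fold)
  if (startsWith(criterion, "iAUC")) {
    method <- sub("^iAUC", "", criterion)
    if (method == "survROC") method <- "survROC"
    return(iauc(risk, NULL, out_fold, method))
  }
  grid <- default_grid(out_fold)
  if (!length(grid)) stop("no events in fold")
  S_pred <- predict_survival(model, X_fold,
                             pmin(grid, max(model$outcome$time)))
  switch(criterion,
    iBSw = brier_curve(S_pred, out_fold, grid, TRUE)$integrated,
    iBSunw = brier_curve(S_pred, out_fold, grid, FALSE)$integrated,
    iSSw = schmid_curve(S_pred, out_fold, grid, TRUE)$integrated,
    iSSunw = schmid_curve(S_pred, out_fold, grid, FALSE)$integrated)
}

#' Criterion-driven hyperparameter selection
#'
#' Fits every grid point on each training fold, evaluates the chosen
#' criterion on the held-out subjects (prediction-error criteria consume
#' predicted survival curves, AUC criteria the risk scores, likelihood
#' criteria the partial likelihood), and returns the grid point with the
#' best fold-mean. Ties are broken toward fewer components, then larger
#' `eta` (parsimony first).
#'
#' @param family Registered family name.
#' @param X,outcome Training data.
#' @param grid Data frame with columns `ncomp` and optionally `eta`.
#' @param criterion One of `"cvll"`, `"vhcvll"`, `"iAUCCD"`, `"iAUCHC"`,
#'   `"iAUCSH"`, `"iAUCUno"`, `"iAUCHZ"`, `"iAUCsurvROC"`, `"iBSw"`,
#'   `"iBSunw"`, `"iSSw"`, `"iSSunw"`; `NULL` selects the family default
#'   (iAUCSH for the PLS-Cox families, iAUCsurvROC otherwise).
#' @param folds A [balanced_folds()] plan.
#' @param ... Passed to [fit_family()].
#' @return List: `best` (row of `grid`), `criterion`, and `table` (grid +
#'   fold-mean column `value`).
#' @export
select_hyperparameters <- function(family, X, outcome, grid,
                                   criterion = NULL, folds, ...) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  if (is.null(criterion)) criterion <- default_criterion(family)
  if (nrow(grid) == 0) stop("empty grid")
  if (is.null(grid$eta)) grid$eta <- 0
  means <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hyper <- list(ncomp = grid$ncomp[g], eta = grid$eta[g])
    if (criterion %in% c("cvll", "vhcvll")) {
      cr <- if (criterion == "cvll") cvll(family, hyper, X, outcome, folds, ...)
            else vhcvll(family, hyper, X, outcome, folds, ...)
      means[g] <- cr$mean
    } else {
      vals <- vapply(folds, function(idx) {
        tr <- setdiff(seq_len(outcome$n), idx)
        tryCatch({
          out_tr <- surv_outcome(outcome$time[tr], outcome$status[tr])
          out_f <- surv_outcome(outcome$time[idx], outcome$status[idx])
          m <- fit_family(family, X[tr, , drop = FALSE], out_tr,
                          ncomp = hyper$ncomp, eta = hyper$eta, ...)
          eval_heldout_criterion(criterion, m, X[idx, , drop = FALSE], out_f)
        }, error = function(e) NA_real_)
      }, numeric(1))
      means[g] <- if (any(is.finite(vals))) mean(vals[is.finite(vals)])
                  else NA_real_
    }
  }
  if (!any(is.finite(means))) stop("all grid points undefined")
  orient <- criterion_orientation(criterion)
  score <- if (orient == "max") means else -means
  best_score <- max(score, na.rm = TRUE)
  cand <- which(is.finite(score) & score >= best_score - 1e-12)
  cand <- cand[order(grid$ncomp[cand], -grid$eta[cand])]
  best <- cand[1]
  list(best = grid[best, , drop = FALSE], criterion = criterion,
       table = cbind(grid, value = means))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
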