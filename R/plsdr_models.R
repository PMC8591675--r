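#' Fit a (DK)(s)(g)PLSDR survival model
#'
#' The deviance-residual PLS pipeline: (1) null-model deviance residuals of
#' the outcome; (2) PLS regression of those residuals on the predictors (or,
#' for the dual-kernel DK variants, on the Gram matrix, whose columns play
#' the role of predictors); (3) a final Cox fit of the outcome on the m
#' retained component scores.
#'
#' @param X Predictor matrix; NA entries allowed on the non-kernel path.
#' @param outcome A [surv_outcome()].
#' @param ncomp Number of PLS components (0 = null model).
#' @param mode `"plain"`, `"sparse"`, `"group"` or `"sparse-group"`.
#' @param eta Thresholding parameter for sparse/group modes.
#' @param groups A [group_structure()] for group modes.
#' @param within_sparsity Within-group threshold (sparse-group mode).
#' @param kernel `NULL` (primal fit on X) or a list
#'   `list(kind = "linear"|"gaussian", bandwidth = ...)` for the DK variants.
#' @return A `plsdr_model` with elements `family`, `residuals`, `pls`
#'   (a `pls_fit` or NULL), `final_cox`, `kernel`, and the training
#'   references needed for kernel prediction.
#' @export
fit_plsdr <- function(X, outcome, ncomp, mode = "plain", eta = 0,
                      groups = NULL, within_sparsity = 0, kernel = NULL) {
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  if (ncomp < 0) stop("ncomp must be >= 0")
  d <- null_deviance_residuals(outcome)
  fam <- paste0(if (!is.null(kernel)) "dk", switch(mode, plain = "",
                sparse = "s", group = "g", "sparse-group" = "sg"), "plsdr")
  kern_info <- NULL
  if (ncomp == 0L) {
    model <- list(family = fam, residuals = d, pls = NULL,
                  final_cox = fit_cox(matrix(0, outcome$n, 0), outcome),
                  kernel = kernel, X_train = NULL, outcome = outcome,
                  ncomp = 0L, mode = mode, eta = eta)
    class(model) <- "plsdr_model"
    return(model)
  }
  if (is.null(kernel)) {
    Z <- X
  } else {
    if (anyNA(X)) stop("kernel path requires complete data; mean-impute first")
    K <- gram_matrix(X, kind = kernel$kind,
                     bandwidth = kernel$bandwidth)
    # double-center the Gram matrix (standard kernel centering); the
    # centering stats are stored for cross-kernel prediction
    cm <- colMeans(K); gm <- mean(K)
    kern_info <- list(kind = kernel$kind, bandwidth = attr(K, "bandwidth"),
                      colmeans = cm, grandmean = gm)
    Z <- K - outer(rowMeans(K), rep(1, ncol(K))) -
      outer(rep(1, nrow(K)), cm) + gm
  }
  pf <- fit_pls(Z, d$values, ncomp, mode = mode, eta = eta, groups = groups,
                within_sparsity = within_sparsity)
  scores <- pf$scores
  cox <- fit_cox(scores, outcome)
  model <- list(family = fam, residuals = d, pls = pf, final_cox = cox,
                kernel = kern_info, X_train = if (!is.null(kernel)) X else NULL,
                outcome = outcome, ncomp = pf$ncomp, mode = mode, eta = eta)
  class(model) <- "plsdr_model"
  model
}

#' @export
print.plsdr_model <- function(x, ...) {
  cat(sprintf("plsdr_model [%s]: %d component(s), final Cox logPL %.4f\n",
              x$family, x$ncomp, x$final_cox$log_pl))
  invisible(x)
}

# deflate each column of X on the columns of T (OLS residuals),
# pairwise-complete for missing entries
deflate_on_components <- function(X, Tm) {
  if (is.null(Tm) || ncol(Tm) == 0L) return(X)
  for (a in seq_len(ncol(Tm))) {
    tt <- Tm[, a]
    sl <- colSums(X * tt, na.rm = TRUE) / sum(tt^2)
    X <- X - tcrossprod(tt, sl)
  }
  X
}

pls_cox_component <- function(Xd, Tm, outcome, alpha = NULL) {
  p <- ncol(Xd)
  w <- numeric(p)
  pval <- rep(1, p)
  for (j in seq_len(p)) {
    xj <- Xd[, j]
    xj[is.na(xj)] <- 0  # pairwise convention: missing contributes nothing
    D <- cbind(Tm, xj)
    ft <- tryCatch(fit_cox(D, outcome), error = function(e) NULL)
    if (is.null(ft)) next
    b <- ft$beta[length(ft$beta)]
    if (!is.finite(b)) b <- 0
    if (ft$flagged) b <- sign(b) * min(abs(b), 50 / max(stats::sd(xj), 1e-8))
    w[j] <- b
    if (!is.null(alpha)) {
      dv <- cox_derivatives(ft$beta, D, outcome)
      se <- tryCatch(sqrt(diag(solve(dv$H))[length(ft$beta)]),
                     error = function(e) NA_real_)
      pval[j] <- if (is.finite(se) && se > 0)
        2 * stats::pnorm(-abs(b / se)) else 1
    }
  }
  list(w = w, pval = pval)
}

#' Fit a PLS-Cox model
#'
#' Iterative generalized-linear-model PLS construction for censored
#' outcomes: the weight of predictor j in component h is the Cox
#' coefficient of its current residual part in a model containing the h-1
#' previous components; the component is the weighted sum of the residual
#' parts; a final Cox model is refit on all components.
#'
#' @param X Predictor matrix (NA allowed).
#' @param outcome A [surv_outcome()].
#' @param ncomp Number of components (>= 1).
#' @return A `plsdr_model` with `family = "pls-cox"`.
#' @export
fit_pls_cox <- function(X, outcome, ncomp) {
  outcome <- as_surv_outcome(outcome)
  if (ncomp < 1) stop("ncomp must be >= 1 for PLS-Cox")
  fit_pls_cox_engine(X, outcome, ncomp, alpha = NULL,
                     family = "pls-cox")
}

#' Fit an autoPLS-Cox model
#'
#' As [fit_pls_cox()], but within each component only predictors whose Wald
#' p-value (in the conditional Cox fit given the previous components) falls
#' below `alpha` contribute weight; component building stops as soon as no
#' predictor is significant. The achieved number of components is
#' data-driven.
#'
#' @inheritParams fit_pls_cox
#' @param alpha Wald significance level in (0, 1); default 0.05.
#' @param max_ncomp Safety cap on the number of components.
#' @return A `plsdr_model` with `family = "auto-pls-cox"`.
#' @export
fit_auto_pls_cox <- function(X, outcome, alpha = 0.05,
                             max_ncomp = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  outcome <- as_surv_outcome(outcome)
  X <- as.matrix(X)
  if (is.null(max_ncomp))
    max_ncomp <- min(outcome$n - 1L, ncol(X), 10L)
  fit_pls_cox_engine(X, outcome, max_ncomp, alpha = alpha,
                     family = "auto-pls-cox")
}

fit_pls_cox_engine <- function(X, outcome, ncomp, alpha, family) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xs <- center_scale(X)
  ctr <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  W <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  Xd <- Xs
  for (h in seq_len(ncomp)) {
    comp <- pls_cox_component(Xd, Tm, outcome, alpha = alpha)
    w <- comp$w
    if (!is.null(alpha)) {
      keep <- comp$pval < alpha
      if (!any(keep)) break
      w[!keep] <- 0
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) break
    w <- w / nw
    tt <- component_score(Xd, w)
    if (sum(tt^2) < 1e-12) break
    W <- cbind(W, w)
    Tm <- cbind(Tm, tt)
    Xd <- deflate_on_components(Xd, matrix(tt, ncol = 1))
  }
  m <- ncol(Tm)
  cox <- fit_cox(Tm, outcome)
  d <- null_deviance_residuals(outcome)
  model <- list(family = family, residuals = d,
                pls = list(ncomp = m, weights = W, scores = Tm,
                           center = ctr, scale = scl),
                final_cox = cox, kernel = NULL, X_train = X,
                outcome = outcome, ncomp = m, mode = "plain", eta = 0)
  class(model) <- c("pls_cox_model", "plsdr_model")
  model
}

# scores of new data under a pls-cox model: standardize, then project with
# the stored weights, deflating on the fly with training-slope recomputation
pls_cox_scores <- function(model, Xnew) {
  Xs_tr <- center_scale(model$X_train, center = model$pls$center,
                        scale = model$pls$scale)
  Xs_nw <- center_scale(as.matrix(Xnew), center = model$pls$center,
                        scale = model$pls$scale)
  m <- model$ncomp
  Tm_nw <- matrix(0, nrow(Xs_nw), m)
  Xd_tr <- Xs_tr; Xd_nw <- Xs_nw
  for (a in seq_len(m)) {
    w <- model$pls$weights[, a]
    tt_tr <- component_score(Xd_tr, w)
    Tm_nw[, a] <- component_score(Xd_nw, w)
    sl <- colSums(Xd_tr * tt_tr, na.rm = TRUE) / sum(tt_tr^2)
    Xd_tr <- Xd_tr - tcrossprod(tt_tr, sl)
    Xd_nw <- Xd_nw - tcrossprod(Tm_nw[, a], sl)
  }
  Tm_nw
}

model_scores <- function(model, Xnew) {
  if (model$ncomp == 0L) return(matrix(0, nrow(as.matrix(Xnew)), 0))
  if (inherits(model, "pls_cox_model")) return(pls_cox_scores(model, Xnew))
  if (!is.null(model$kernel)) {
    Knew <- gram_matrix(as.matrix(Xnew), kind = model$kernel$kind,
                        bandwidth = model$kernel$bandwidth,
                        Xref = model$X_train)
    Kc <- Knew - outer(rowMeans(Knew), rep(1, ncol(Knew))) -
      outer(rep(1, nrow(Knew)), model$kernel$colmeans) +
      model$kernel$grandmean
    return(predict_scores(model$pls, Kc))
  }
  predict_scores(model$pls, Xnew)
}

#' Linear risk predictor of a PLSDR-family model
#'
#' \eqn{\hat\beta' \cdot \mathrm{scores}(X_{new})} from the final Cox fit.
#' The risk score is translation-invariant downstream: all concordance and
#' AUC measures depend only on its ordering/differences.
#'
#' @param model A `plsdr_model`.
#' @param Xnew New predictor rows (defaults to the training data).
#' @return Numeric vector of linear predictors.
#' @export
predict_risk <- function(model, Xnew = NULL) {
  if (is.null(Xnew)) {
    if (model$ncomp == 0L) return(rep(0, model$outcome$n))
    return(drop(model$final_cox$X %*% model$final_cox$beta))
  }
  S <- model_scores(model, Xnew)
  if (ncol(S) == 0L) return(rep(0, nrow(S)))
  drop(S %*% model$final_cox$beta)
}

#' Predicted survival curves
#'
#' \eqn{\hat S(t \mid x) = \exp(-\hat\Lambda_0(t) e^{\mathrm{risk}(x)})}
#' using the Breslow baseline of the final Cox fit on the component scores.
#'
#' @param model A `plsdr_model`.
#' @param Xnew New predictor rows (defaults to training data).
#' @param times Non-negative evaluation times.
#' @return Matrix (rows = subjects of `Xnew`, columns = `times`) of
#'   survival probabilities, non-increasing along each row.
#' @export
predict_survival <- function(model, Xnew = NULL, times) {
  if (any(times < 0)) stop("negative times")
  risk <- predict_risk(model, Xnew)
  L0 <- breslow_cumhaz(model$final_cox)
  H <- L0(times)
  outer(exp(risk), H, function(r, h) exp(-h * r))
}

#' Serialize a PLSDR-family model to a flat JSON-compatible list
#'
#' All numeric fields needed for bit-reproducible prediction (centering,
#' scaling, directions, loadings, Cox coefficients, baseline-hazard steps)
#' in plain vectors/matrices.
#'
#' @param model A `plsdr_model`.
#' @return A named list of plain vectors and matrices.
#' @export
serialize_model <- function(model) {
  L0 <- breslow_cumhaz(model$final_cox)
  list(family = model$family, ncomp = model$ncomp, mode = model$mode,
       eta = model$eta,
       beta = model$final_cox$beta,
       baseline_times = attr(L0, "times"),
       baseline_cumhaz = attr(L0, "hazard"),
       center = if (!is.null(model$pls)) model$pls$center,
       scale = if (!is.null(model$pls)) model$pls$scale,
       directions = if (!is.null(model$pls$directions)) model$pls$directions
                    else model$pls$weights,
       x_loadings = model$pls$x_loadings,
       kernel = model$kernel,
       X_train = model$X_train)
}
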