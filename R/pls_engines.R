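#' Column-wise standardization with missing entries
#'
#' Centers and scales each column to mean 0 / variance 1 over its observed
#' entries; NA entries are preserved. Constant columns are an error (the PLS
#' weight step would be degenerate).
#'
#' @param X Numeric matrix, possibly with NA entries.
#' @param center,scale Optional pre-computed vectors (used to reproduce the
#'   training transform on new data).
#' @return The standardized matrix with attributes `center` and `scale`.
#' @export
center_scale <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(center)) {
    nobs <- colSums(!is.na(X))
    if (any(nobs == 0))
      stop("all-missing column(s): ", paste(which(nobs == 0), collapse = ", "))
    center <- colMeans(X, na.rm = TRUE)
  }
  Xc <- sweep(X, 2, center, "-")
  if (is.null(scale)) {
    scale <- apply(Xc, 2, stats::sd, na.rm = TRUE)
    if (any(!is.finite(scale) | scale == 0)) {
      bad <- which(!is.finite(scale) | scale == 0)
      stop("constant or under-observed column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  Xs <- sweep(Xc, 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

#' NIPALS weight vector
#'
#' Per-predictor regression slopes of each (standardized, possibly deflated)
#' column on the response, computed over pairwise-complete entries, then
#' normalized to unit Euclidean norm. On complete data this reduces exactly
#' to \eqn{w = X'y / \|X'y\|_2}.
#'
#' @param X Standardized predictor matrix (NA allowed).
#' @param y Centered response vector (no NA).
#' @return Unit-norm weight vector of length `ncol(X)`.
#' @export
nipals_weight <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X/y dimension mismatch")
  # pairwise-complete cross products with a common (complete-sample) scale:
  # reduces exactly to X'y on complete data and is invariant to masking
  # entries that are zero
  w <- colSums(X * y, na.rm = TRUE)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate direction: all slopes zero")
  w / nw
}

#' Soft-thresholded sparse direction
#'
#' Componentwise soft thresholding \eqn{(|Z_j| - \lambda)_+ \mathrm{sign}(Z_j)}
#' with \eqn{\lambda = \eta \max_j |Z_j|}, renormalized to unit norm. The
#' scale-free thresholding parameter \eqn{\eta \in [0, 1)} makes `eta = 0`
#' the identity and `eta` near 1 keep only the largest component.
#'
#' @param Z Unit-norm direction vector.
#' @param eta Thresholding parameter in [0, 1).
#' @return Sparse unit-norm direction.
#' @export
soft_threshold_direction <- function(Z, eta) {
  if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
  if (eta == 0) return(Z)
  lam <- eta * max(abs(Z))
  d <- pmax(abs(Z) - lam, 0) * sign(Z)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("degenerate direction after thresholding")
  d / nd
}

#' Group structure for group-sparse directions
#'
#' @param groups A list of disjoint integer index vectors (subsets of
#'   1..p); predictors not covered form implicit singleton groups.
#' @param p Number of predictors.
#' @return A `group_structure`: list of index vectors covering 1..p.
#' @export
group_structure <- function(groups, p) {
  if (length(groups) == 0) stop("empty group structure")
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop("groups must be disjoint")
  if (any(idx < 1 | idx > p)) stop("group index out of range")
  left <- setdiff(seq_len(p), idx)
  out <- c(groups, as.list(left))
  structure(out, class = "group_structure", p = p)
}

#' Read a group-structure file
#'
#' Two-column delimited text (predictor_name, group_label); predictor names
#' are matched against `colnames`.
#'
#' @param path File path.
#' @param colnames Predictor names of the design matrix, in column order.
#' @return A [group_structure()].
#' @export
read_group_structure <- function(path, colnames) {
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("predictor", "group"),
                          colClasses = "character")
  idx <- match(tb$predictor, colnames)
  if (anyNA(idx)) stop("unknown predictor name(s) in group file")
  group_structure(split(idx, tb$group), length(colnames))
}

#' Group-lasso-style thresholded direction
#'
#' Groupwise shrinkage \eqn{Z_g \leftarrow ((\|Z_g\|_2 - \lambda)_+ /
#' \|Z_g\|_2) Z_g} with \eqn{\lambda = \eta \max_g \|Z_g\|_2}; if
#' `within_sparsity > 0`, soft thresholding is additionally applied inside
#' each surviving group (sparse-group mode). The result is renormalized.
#'
#' @param Z Unit-norm direction vector.
#' @param groups A [group_structure()] covering `length(Z)`.
#' @param eta Group thresholding parameter in [0, 1).
#' @param within_sparsity Within-group soft threshold in [0, 1).
#' @return Group-sparse unit-norm direction.
#' @export
group_threshold_direction <- function(Z, groups, eta, within_sparsity = 0) {
  if (!inherits(groups, "group_structure")) stop("empty group structure")
  if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
  if (within_sparsity < 0 || within_sparsity >= 1)
    stop("within_sparsity must be in [0, 1)")
  norms <- vapply(groups, function(g) sqrt(sum(Z[g]^2)), numeric(1))
  lam <- eta * max(norms)
  d <- Z
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (norms[k] <= lam || norms[k] == 0) {
      d[g] <- 0
    } else {
      d[g] <- ((norms[k] - lam) / norms[k]) * Z[g]
      if (within_sparsity > 0 && length(g) > 0) {
        sub <- d[g]
        lam2 <- within_sparsity * max(abs(sub))
        d[g] <- pmax(abs(sub) - lam2, 0) * sign(sub)
      }
    }
  }
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("degenerate direction after group thresholding")
  d / nd
}

# Score of one component with NIPALS missing-data rescaling:
# t_i = (sum_{j obs} w_j x_ij) * (sum_j w_j^2) / (sum_{j obs} w_j^2)
component_score <- function(X, w) {
  obs <- !is.na(X)
  num <- as.numeric(ifelse(is.na(X), 0, X) %*% w)
  den <- as.numeric(obs %*% (w^2))
  tot <- sum(w^2)
  bad <- den < 1e-12
  den[bad] <- tot
  num * tot / den
}

#' Fit a PLS1 regression (plain, sparse, group, sparse-group)
#'
#' NIPALS-style univariate-response PLS: per component, a unit-norm weight
#' from pairwise-complete slopes, optional (group) soft thresholding of the
#' direction, scores with missing-data rescaling, loadings by regression on
#' the score, and deflation of X only (regression-mode PLS1; y is not
#' deflated).
#'
#' @param X Predictor matrix (NA allowed for plain/sparse modes).
#' @param y Continuous response vector.
#' @param ncomp Number of components.
#' @param mode One of `"plain"`, `"sparse"`, `"group"`, `"sparse-group"`.
#' @param eta Thresholding parameter in [0, 1) (sparse/group modes).
#' @param groups A [group_structure()] (group modes).
#' @param within_sparsity Within-group threshold for sparse-group mode.
#' @param standardize Standardize X internally (default TRUE).
#' @return A `pls_fit`: weights `W` (p x m), sparse directions `C`, scores
#'   `T`, x-loadings `P`, y-loadings `q`, centering/scaling vectors,
#'   `ncomp` achieved, `truncated` flag.
#' @export
fit_pls <- function(X, y, ncomp, mode = c("plain", "sparse", "group",
                                          "sparse-group"),
                    eta = 0, groups = NULL, within_sparsity = 0,
                    standardize = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1L, p)) stop("ncomp exceeds min(n-1, p)")
  if (mode %in% c("group", "sparse-group") && is.null(groups))
    stop("group modes require a group_structure")
  Xs <- if (standardize) center_scale(X) else
    structure(X, center = rep(0, p), scale = rep(1, p))
  ctr <- attr(Xs, "center"); scl <- attr(Xs, "scale")
  ybar <- mean(y)
  yc <- y - ybar
  W <- C <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  qv <- numeric(0)
  Xd <- Xs
  truncated <- FALSE
  for (a in seq_len(ncomp)) {
    w <- tryCatch(nipals_weight(Xd, yc), error = function(e) NULL)
    if (is.null(w)) { truncated <- TRUE; break }
    cdir <- switch(mode,
      "plain" = w,
      "sparse" = tryCatch(soft_threshold_direction(w, eta),
                          error = function(e) NULL),
      "group" = tryCatch(group_threshold_direction(w, groups, eta, 0),
                         error = function(e) NULL),
      "sparse-group" = tryCatch(
        group_threshold_direction(w, groups, eta, within_sparsity),
        error = function(e) NULL))
    if (is.null(cdir)) { truncated <- TRUE; break }
    tt <- component_score(Xd, cdir)
    stt <- sum(tt^2)
    if (stt < 1e-12) { truncated <- TRUE; break }
    # loadings: regression of each column on t, pairwise numerators over a
    # complete-sample denominator (zero-mask invariant)
    pl <- colSums(Xd * tt, na.rm = TRUE) / stt
    qa <- sum(tt * yc) / stt
    Xd <- Xd - tcrossprod(tt, pl)   # NA entries stay NA
    W <- cbind(W, w); C <- cbind(C, cdir); P <- cbind(P, pl)
    Tm <- cbind(Tm, tt); qv <- c(qv, qa)
  }
  structure(list(ncomp = ncol(Tm), weights = W, directions = C,
                 scores = Tm, x_loadings = P, y_loadings = qv,
                 center = ctr, scale = scl, y_center = ybar,
                 truncated = truncated, mode = mode, eta = eta,
                 groups = groups, within_sparsity = within_sparsity),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d component(s), mode %s%s\n", x$ncomp, x$mode,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Component scores for new data
#'
#' Applies the stored centering/scaling and the stored
#' direction/deflation chain of a [fit_pls()] model to new rows; missing
#' entries are handled by the NIPALS rescaling convention.
#'
#' @param fit A `pls_fit`.
#' @param Xnew Matrix with the same columns as the training data.
#' @return n_new x m score matrix.
#' @export
predict_scores <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(fit$center)) stop("column-count mismatch")
  Xd <- center_scale(Xnew, center = fit$center, scale = fit$scale)
  m <- fit$ncomp
  Tm <- matrix(0, nrow(Xnew), m)
  for (a in seq_len(m)) {
    tt <- component_score(Xd, fit$directions[, a])
    Tm[, a] <- tt
    Xd <- Xd - tcrossprod(tt, fit$x_loadings[, a])
  }
  Tm
}

#' Kernel Gram matrix
#'
#' Linear kernel \eqn{K = XX'} or gaussian kernel
#' \eqn{K_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}. The condensed n x n
#' matrix replaces the n x p design in the dual (DK) model variants.
#'
#' @param X Complete-data matrix (mean-impute first if needed).
#' @param kind `"linear"` or `"gaussian"`.
#' @param bandwidth Gaussian sigma; default = median pairwise distance of
#'   the rows of `X`.
#' @param Xref Optional reference rows: returns the cross-kernel
#'   k(X, Xref), an nrow(X) x nrow(Xref) matrix.
#' @return Symmetric PSD Gram matrix (or cross-kernel), with attribute
#'   `bandwidth` for the gaussian kind.
#' @export
gram_matrix <- function(X, kind = c("linear", "gaussian"), bandwidth = NULL,
                        Xref = NULL) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (anyNA(X) || (!is.null(Xref) && anyNA(Xref)))
    stop("missing entries: mean-impute before the kernel path")
  if (is.null(Xref)) Xref <- X
  Xref <- as.matrix(Xref)
  if (kind == "linear") {
    K <- tcrossprod(X, Xref)
  } else {
    d2 <- outer(rowSums(X^2), rowSums(Xref^2), "+") - 2 * tcrossprod(X, Xref)
    d2 <- pmax(d2, 0)
    if (is.null(bandwidth)) {
      dd <- sqrt(d2[upper.tri(d2, diag = FALSE)])
      bandwidth <- stats::median(dd[dd > 0])
      if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
    }
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    K <- exp(-d2 / (2 * bandwidth^2))
  }
  attr(K, "bandwidth") <- bandwidth
  K
}
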