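#' Eigengene expression simulator
#'
#' Module genes are noisy copies of a per-module standard-normal seed
#' vector: the k-th rank-correlated gene of a module of size `n_modgenes`
#' targets correlation \eqn{r_k = 1 - (k/n_{modgenes})(1 - r_{min})} with
#' its seed, achieved as \eqn{x_k = seed + a_k \varepsilon_k} with
#' \eqn{a_k = \sqrt{var(seed)/var(\varepsilon)}\sqrt{1/r_k^2 - 1}}.
#' Remaining genes are i.i.d. N(0,1) noise. Defaults: 4 modules of 25
#' genes, `r_min = 0.5`, so the first 100 genes are structured.
#'
#' @param n,p Numbers of samples and genes (default 100 x 1000).
#' @param n_modules,n_modgenes Module count and size.
#' @param r_min Target correlation of the last module gene with its seed.
#' @param seed Integer seed.
#' @return n x p matrix; attribute `structured` gives the structured gene
#'   indices.
#' @export
simulate_eigengene <- function(n = 100L, p = 1000L, n_modules = 4L,
                               n_modgenes = 25L, r_min = 0.5, seed = NULL) {
  if (r_min <= 0 || r_min >= 1) stop("r_min must be in (0, 1)")
  ns <- n_modules * n_modgenes
  if (ns > p) stop("modules exceed p")
  with_seed(seed, {
    X <- matrix(NA_real_, n, p)
    seeds <- matrix(NA_real_, n, n_modules)
    for (I in seq_len(n_modules)) {
      sd_vec <- stats::rnorm(n)
      seeds[, I] <- sd_vec
      vs <- stats::var(sd_vec)
      for (k in seq_len(n_modgenes)) {
        r <- 1 - (k / n_modgenes) * (1 - r_min)
        eps <- stats::rnorm(n)
        a <- sqrt(vs / stats::var(eps)) * sqrt(1 / r^2 - 1)
        X[, (I - 1) * n_modgenes + k] <- sd_vec + a * eps
      }
    }
    if (p > ns) X[, (ns + 1):p] <- stats::rnorm(n * (p - ns))
    attr(X, "structured") <- seq_len(ns)
    attr(X, "seeds") <- seeds
    X
  })
}

#' Cluster expression simulator
#'
#' Two sample classes with shifted means on the first 50 genes
#' (3 vs 4), all remaining genes centered at 3.5, unit-variance Gaussian
#' noise throughout.
#'
#' @param n,p Numbers of samples and genes; `p > 50` required.
#' @param seed Integer seed.
#' @return n x p matrix; attribute `structured` = 1..50.
#' @export
simulate_cluster <- function(n = 100L, p = 1000L, seed = NULL) {
  if (p <= 50) stop("p must exceed 50")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    half <- floor(n / 2)
    X[seq_len(half), 1:50] <- X[seq_len(half), 1:50] + 3
    X[(half + 1):n, 1:50] <- X[(half + 1):n, 1:50] + 4
    X[, 51:p] <- X[, 51:p] + 3.5
    attr(X, "structured") <- 1:50
    X
  })
}

#' Factorial (latent-group) expression simulator
#'
#' Structured genes follow a block compound-symmetry population
#' correlation (off-diagonal `rho` within each group, 0 across groups),
#' generated as \eqn{Z = F X} where F is the symmetric square root of the
#' block correlation matrix obtained from its eigendecomposition and X is
#' i.i.d. N(0,1). Defaults: 4 groups of 25 at rho = 0.7, so 70% of the
#' structured-block inertia lies in 4 principal directions.
#'
#' @param n,p Numbers of samples and genes.
#' @param n_groups,group_size Group layout of the structured genes.
#' @param rho Within-group correlation in (0, 1).
#' @param seed Integer seed.
#' @return n x p matrix; attributes `structured` and `groups` (list of
#'   index vectors).
#' @export
simulate_factorial <- function(n = 100L, p = 1000L, n_groups = 4L,
                               group_size = 25L, rho = 0.7, seed = NULL) {
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  ns <- n_groups * group_size
  if (ns > p) stop("groups exceed p")
  with_seed(seed, {
    # symmetric square root of one CS block: eigenvalues 1+(g-1)rho, 1-rho
    g <- group_size
    Rb <- matrix(rho, g, g); diag(Rb) <- 1
    eb <- eigen(Rb, symmetric = TRUE)
    Fb <- eb$vectors %*% (t(eb$vectors) * sqrt(pmax(eb$values, 0)))
    X <- matrix(stats::rnorm(n * p), n, p)
    for (k in seq_len(n_groups)) {
      idx <- ((k - 1) * g + 1):(k * g)
      X[, idx] <- X[, idx] %*% Fb
    }
    attr(X, "structured") <- seq_len(ns)
    attr(X, "groups") <- lapply(seq_len(n_groups),
                                function(k) ((k - 1) * g + 1):(k * g))
    X
  })
}

#' Attach exponential survival and calibrated censoring to expressions
#'
#' Event times \eqn{T_i \sim Exp(\lambda_T e^{\eta_i})} with
#' \eqn{\eta_i = 0} (no link), \eqn{\beta' x_{i,1:50}} (linear) or
#' \eqn{\beta' x + \gamma'(x^2 - 1)} on the same 50 genes (quadratic,
#' \eqn{\gamma = \beta/2}); independent exponential censoring whose rate is
#' calibrated so the expected censoring fraction equals `censor_target`
#' (closed form \eqn{\lambda_C = \lambda_T q/(1-q)} under the null,
#' bisection on the exact expectation given the linear predictors under a
#' link). Default \eqn{\beta_j = 1/\sqrt{50}} so that var(\eqn{\eta})
#' is about 1 for unit-variance genes.
#'
#' @param X Expression matrix (>= 50 columns when linked).
#' @param link `"none"`, `"linear"` or `"quadratic"`.
#' @param beta_scale Coefficient magnitude on the 50 survival-linked genes.
#' @param censor_target Target censoring probability in (0, 1).
#' @param lambda_T Baseline event rate (time unit arbitrary).
#' @param seed Integer seed.
#' @return A [surv_outcome()] with attributes `truth` (linked gene
#'   indices), `eta`, and `lambda_C`.
#' @export
attach_survival <- function(X, link = c("none", "linear", "quadratic"),
                            beta_scale = 1 / sqrt(50), censor_target = 0.4,
                            lambda_T = 1, seed = NULL) {
  link <- match.arg(link)
  X <- as.matrix(X)
  n <- nrow(X)
  if (censor_target <= 0 || censor_target >= 1)
    stop("censor_target must be in (0, 1)")
  if (link != "none" && ncol(X) < 50)
    stop("linked survival requires >= 50 predictors")
  truth <- if (link == "none") integer(0) else 1:50
  eta <- switch(link,
    none = rep(0, n),
    linear = drop(X[, 1:50, drop = FALSE] %*% rep(beta_scale, 50)),
    quadratic = {
      Xl <- X[, 1:50, drop = FALSE]
      drop(Xl %*% rep(beta_scale, 50)) +
        drop((Xl^2 - 1) %*% rep(beta_scale / 2, 50))
    })
  rates <- lambda_T * exp(eta)
  q <- censor_target
  cens_frac <- function(lc) mean(lc / (lc + rates))
  if (link == "none") {
    lambda_C <- lambda_T * q / (1 - q)
  } else {
    lo <- 1e-8; hi <- max(rates) * (1 / (1 - q)) * 100
    for (it in 1:200) {
      mid <- sqrt(lo * hi)
      if (cens_frac(mid) < q) lo <- mid else hi <- mid
      if (abs(cens_frac(mid) - q) < 1e-6) break
    }
    lambda_C <- sqrt(lo * hi)
    if (abs(cens_frac(lambda_C) - q) > 0.005)
      stop("censoring calibration failed")
  }
  with_seed(seed, {
    Tt <- stats::rexp(n, rate = rates)
    Ct <- stats::rexp(n, rate = lambda_C)
    out <- surv_outcome(pmin(Tt, Ct), as.numeric(Tt <= Ct))
    attr(out, "truth") <- truth
    attr(out, "eta") <- eta
    attr(out, "lambda_C") <- lambda_C
    out
  })
}

#' MCAR masking
#'
#' Masks each entry independently with probability `rate` (missing
#' completely at random: the pattern depends on neither observed nor
#' missing values). Columns that end up fully missing are redrawn up to 10
#' times.
#'
#' @param X Numeric matrix.
#' @param rate Masking probability in [0, 1).
#' @param seed Integer seed.
#' @return Matrix with NA entries.
#' @export
inject_mcar <- function(X, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(X)
  X <- as.matrix(X)
  with_seed(seed, {
    for (try in 1:10) {
      M <- matrix(stats::runif(length(X)) < rate, nrow(X), ncol(X))
      if (all(colSums(!M) > 0)) {
        X[M] <- NA
        return(X)
      }
    }
    stop("could not avoid a fully-masked column after 10 draws")
  })
}

#' Simulate a batch of gene-expression survival datasets
#'
#' Composes a scheme generator (eigengene, cluster or factorial) with the
#' calibrated exponential survival/censoring attachment at the study
#' defaults (n = 100 samples, p = 1000 genes, 40% censoring). Each dataset
#' is a pure function of `(scheme, link, seed, index)`.
#'
#' @param scheme `"eigengene"`, `"cluster"` or `"factorial"`.
#' @param link `"none"`, `"linear"` or `"quadratic"`.
#' @param n_datasets Number of datasets.
#' @param n,p Dataset dimensions.
#' @param seed Integer master seed.
#' @param mcar_rate Optional MCAR masking rate applied to X.
#' @return List of `sim_dataset` objects: `X`, `outcome`, `truth`,
#'   `scheme`, `link`, `seed`, and `groups` for the factorial scheme.
#' @export
simulate_study <- function(scheme = c("eigengene", "cluster", "factorial"),
                           link = c("none", "linear", "quadratic"),
                           n_datasets = 1L, n = 100L, p = 1000L,
                           seed = 1L, mcar_rate = 0) {
  scheme <- match.arg(scheme)
  link <- match.arg(link)
  lapply(seq_len(n_datasets), function(i) {
    s <- (seed * 1000L + i) %% .Machine$integer.max
    X <- switch(scheme,
      eigengene = simulate_eigengene(n, p, seed = s),
      cluster = simulate_cluster(n, p, seed = s),
      factorial = simulate_factorial(n, p, seed = s))
    outcome <- attach_survival(X, link = link, seed = s + 500000L)
    if (mcar_rate > 0) X <- inject_mcar(X, mcar_rate, seed = s + 900000L)
    structure(list(X = X, outcome = outcome,
                   truth = attr(outcome, "truth"),
                   groups = attr(X, "groups"),
                   scheme = scheme, link = link, seed = s),
              class = "sim_dataset")
  })
}
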