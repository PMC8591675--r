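# Independent oracles and small fixture builders used across the suite.
# These stay deliberately naive (grids, double loops) and never call the
# code paths they check.

# grid-search maximizer of the Breslow log partial likelihood
grid_cox_oracle <- function(X, outcome, lo = -3, hi = 3, step = 5e-4) {
  X <- as.matrix(X)
  grid <- seq(lo, hi, by = step)
  if (ncol(X) == 1L) {
    ll <- vapply(grid, function(b)
      log_partial_likelihood(b, X, outcome), numeric(1))
    return(grid[which.max(ll)])
  }
  stopifnot(ncol(X) == 2L)
  coarse <- seq(lo, hi, by = 0.05)
  best <- c(0, 0); bestll <- -Inf
  for (b1 in coarse) for (b2 in coarse) {
    ll <- log_partial_likelihood(c(b1, b2), X, outcome)
    if (ll > bestll) { bestll <- ll; best <- c(b1, b2) }
  }
  fine1 <- seq(best[1] - 0.05, best[1] + 0.05, by = 1e-3)
  fine2 <- seq(best[2] - 0.05, best[2] + 0.05, by = 1e-3)
  for (b1 in fine1) for (b2 in fine2) {
    ll <- log_partial_likelihood(c(b1, b2), X, outcome)
    if (ll > bestll) { bestll <- ll; best <- c(b1, b2) }
  }
  best
}

# double-loop cumulative/dynamic AUC with IPCW case weights and the
# 2*f*S density integration weight, built straight from survfit output
brute_survroc_iauc <- function(risk, outcome) {
  y <- outcome$time; d <- outcome$status
  Gfit <- survival::survfit(survival::Surv(y, 1 - d) ~ 1)
  Sfit <- survival::survfit(survival::Surv(y, d) ~ 1)
  stepval <- function(fit, t, left = FALSE) {
    i <- findInterval(t, fit$time, left.open = left)
    c(1, fit$surv)[i + 1L]
  }
  grid <- sort(unique(y[d == 1])); grid <- grid[grid < max(y)]
  aucs <- numeric(0); wts <- numeric(0)
  for (t in grid) {
    cases <- which(y <= t & d == 1); ctrls <- which(y > t)
    if (!length(cases) || !length(ctrls)) next
    num <- 0; den <- 0
    for (i in cases) for (j in ctrls) {
      w <- 1 / stepval(Gfit, y[i], left = TRUE)
      num <- num + w * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
      den <- den + w
    }
    aucs <- c(aucs, num / den)
    wts <- c(wts, 2 * (stepval(Sfit, t, left = TRUE) - stepval(Sfit, t)) *
               stepval(Sfit, t))
  }
  sum(wts * aucs) / sum(wts)
}

# pair-enumeration Harrell C (strict-tie-zero convention)
brute_harrell <- function(risk, outcome) {
  y <- outcome$time; d <- outcome$status
  num <- 0; den <- 0
  n <- length(y)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (y[i] < y[j] && d[i] == 1) {
      den <- den + 1; num <- num + (risk[i] > risk[j])
    } else if (y[j] < y[i] && d[j] == 1) {
      den <- den + 1; num <- num + (risk[j] > risk[i])
    }
  }
  num / den
}

# X'y-deflation reference PLS on complete standardized data
pls_oracle <- function(X, y, ncomp) {
  Xd <- scale(X); yc <- y - mean(y)
  Tm <- NULL
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    tt <- drop(Xd %*% w)
    pl <- drop(crossprod(Xd, tt)) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pl)
    Tm <- cbind(Tm, tt)
  }
  Tm
}

toy_exponential_outcome <- function(n, seed, censor = TRUE) {
  set.seed(seed)
  tt <- stats::rexp(n)
  cc <- if (censor) stats::rexp(n, 2 / 3) else rep(Inf, n)
  surv_outcome(pmin(tt, cc), as.numeric(tt <= cc))
}
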