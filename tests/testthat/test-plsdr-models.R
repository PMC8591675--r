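make_linked_data <- function(seed, n = 80, p = 150) {
  simulate_study("factorial", "linear", 1, n = n, p = p, seed = seed)[[1]]
}

test_that("ncomp = 0 short-circuits to the null model in every family", {
  sim <- make_linked_data(1, n = 50, p = 120)
  m <- fit_plsdr(sim$X, sim$outcome, 0)
  expect_equal(m$ncomp, 0L)
  expect_equal(predict_risk(m, sim$X), rep(0, 50))
  expect_equal(m$final_cox$log_pl, m$final_cox$log_pl_null)
  # all families coincide downstream at ncomp = 0
  mk <- fit_plsdr(sim$X, sim$outcome, 0, kernel = list(kind = "linear"))
  expect_equal(predict_survival(m, sim$X, c(0.1, 0.5)),
               predict_survival(mk, sim$X, c(0.1, 0.5)))
})

test_that("sparse mode with eta = 0 equals plain mode", {
  sim <- make_linked_data(2, n = 60, p = 120)
  m1 <- fit_plsdr(sim$X, sim$outcome, 2, mode = "plain")
  m2 <- fit_plsdr(sim$X, sim$outcome, 2, mode = "sparse", eta = 0)
  expect_equal(m1$pls$scores, m2$pls$scores, tolerance = 1e-10)
})

test_that("pipeline separability: residual stage + PLS = fused pipeline", {
  sim <- make_linked_data(3, n = 60, p = 120)
  m <- fit_plsdr(sim$X, sim$outcome, 2)
  d <- null_deviance_residuals(sim$outcome)
  pf <- fit_pls(sim$X, d$values, 2)
  expect_equal(m$pls$scores, pf$scores, tolerance = 1e-10)
})

test_that("sparse first direction concentrates on the linked genes", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_study("factorial", "linear", 1, n = 100, p = 1000,
                          seed = s)[[1]]
    m <- fit_plsdr(sim$X, sim$outcome, 1, mode = "sparse", eta = 0.5)
    w <- abs(m$pls$directions[, 1])
    if (sum(w[sim$truth]) / sum(w) >= 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("PLS-Cox on a single predictor equals the direct Cox fit", {
  set.seed(4)
  x <- rnorm(40)
  o <- surv_outcome(rexp(40, exp(0.8 * x)), rep(1, 40))
  m <- fit_pls_cox(matrix(x, ncol = 1), o, 1)
  direct <- fit_cox(matrix(x, ncol = 1), o)
  beta_orig <- m$final_cox$beta * m$pls$weights[1, 1] / m$pls$scale
  expect_equal(unname(beta_orig), direct$beta, tolerance = 1e-6)
  expect_equal(m$final_cox$log_pl, direct$log_pl, tolerance = 1e-8)
})

test_that("PLS-Cox gives duplicated columns equal weight", {
  set.seed(5)
  x <- rnorm(50)
  X <- cbind(x, x, rnorm(50))
  o <- surv_outcome(rexp(50, exp(0.6 * x)), rbinom(50, 1, 0.8) | c(1, 0))
  o <- surv_outcome(o$time, pmax(o$status, c(1, rep(0, 49))))
  m <- fit_pls_cox(X, o, 1)
  expect_equal(abs(m$pls$weights[1, 1]), abs(m$pls$weights[2, 1]),
               tolerance = 1e-8)
})

test_that("PLS-Cox null-link weights show no concentration", {
  set.seed(6)
  shares <- replicate(10, {
    X <- matrix(rnorm(60 * 8), 60, 8)
    o <- attach_survival(X, "none", seed = sample(1e6, 1))
    m <- fit_pls_cox(X, o, 1)
    w <- abs(m$pls$weights[, 1])
    max(w) / sum(w)
  })
  expect_lt(mean(shares), 3 / 8)
})

test_that("autoPLS-Cox stops under the null and nests in alpha", {
  set.seed(7)
  ncs <- replicate(10, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    o <- attach_survival(X, "none", seed = sample(1e6, 1))
    fit_auto_pls_cox(X, o)$ncomp
  })
  expect_gte(sum(ncs <= 1), 8)
  # achieved ncomp is non-increasing as alpha decreases
  set.seed(8)
  Xs <- matrix(rnorm(70 * 20), 70, 20)
  tt <- rexp(70, exp(drop(Xs[, 1:5] %*% rep(0.4, 5))))
  cc <- rexp(70, 2 / 3)
  sim <- list(X = Xs,
              outcome = surv_outcome(pmin(tt, cc), as.numeric(tt <= cc)))
  ncomps <- vapply(c(0.5, 0.2, 0.05, 0.01), function(a)
    fit_auto_pls_cox(sim$X, sim$outcome, alpha = a, max_ncomp = 4)$ncomp,
    integer(1))
  expect_true(all(diff(ncomps) <= 0))
  # alpha near 1 behaves like plain PLS-Cox with the same cap
  m1 <- fit_auto_pls_cox(sim$X, sim$outcome, alpha = 0.999, max_ncomp = 2)
  m2 <- fit_pls_cox(sim$X, sim$outcome, 2)
  expect_equal(m1$ncomp, m2$ncomp)
  expect_equal(abs(cor(predict_risk(m1, sim$X), predict_risk(m2, sim$X))),
               1, tolerance = 1e-6)
})

test_that("predict_risk contracts: refit identity and translation invariance", {
  sim <- make_linked_data(9, n = 60, p = 120)
  m <- fit_plsdr(sim$X, sim$outcome, 2)
  r <- predict_risk(m, sim$X)
  refit <- fit_cox(matrix(r, ncol = 1), sim$outcome)
  expect_equal(refit$log_pl, m$final_cox$log_pl, tolerance = 1e-8)
  expect_equal(harrell_c(r + 5, sim$outcome), harrell_c(r, sim$outcome))
  expect_error(predict_risk(m, sim$X[, 1:10]), "mismatch")
})

test_that("DK linear kernel spans the plain first-component direction", {
  # low-rank toy: the dual (Gram-column) and primal fits agree on the
  # leading component direction
  set.seed(10)
  n <- 60
  t1 <- rnorm(n); t2 <- rnorm(n)
  X <- tcrossprod(t1, rnorm(40)) + tcrossprod(t2, rnorm(40)) +
    0.1 * matrix(rnorm(n * 40), n, 40)
  tt <- rexp(n, exp(drop(scale(t1)))); cc <- rexp(n, 2 / 3)
  o <- surv_outcome(pmin(tt, cc), as.numeric(tt <= cc))
  mk <- fit_plsdr(X, o, 1, kernel = list(kind = "linear"))
  mp <- fit_plsdr(X, o, 1)
  expect_gt(abs(cor(mk$pls$scores[, 1], mp$pls$scores[, 1])), 0.99)
})

test_that("gaussian kernel at large bandwidth approaches the linear kernel", {
  sim <- make_linked_data(11, n = 50, p = 120)
  mg <- fit_plsdr(sim$X, sim$outcome, 1,
                  kernel = list(kind = "gaussian", bandwidth = 1e4))
  ml <- fit_plsdr(sim$X, sim$outcome, 1, kernel = list(kind = "linear"))
  ang <- acos(min(1, abs(cor(mg$pls$scores[, 1], ml$pls$scores[, 1])))) *
    180 / pi
  expect_lt(ang, 5)
})

test_that("predict_survival is a proper survival surface", {
  sim <- make_linked_data(12, n = 50, p = 120)
  m <- fit_plsdr(sim$X, sim$outcome, 2)
  tg <- c(0, sort(sim$outcome$time)[c(10, 25, 40)])
  S <- predict_survival(m, sim$X, tg)
  expect_true(all(S >= 0 & S <= 1))
  expect_equal(S[, 1], rep(1, 50))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 1e-12))))
  expect_error(predict_survival(m, sim$X, c(-1, 2)), "negative")
  # null model rows all equal the Nelson-Aalen-based null curve
  m0 <- fit_plsdr(sim$X, sim$outcome, 0)
  S0 <- predict_survival(m0, sim$X, tg)
  expect_equal(S0, matrix(S0[1, ], 50, 4, byrow = TRUE))
})

test_that("MCAR-masked fits return finite risks close to complete fits", {
  sim <- make_linked_data(13, n = 80, p = 200)
  Xm <- inject_mcar(sim$X, 0.1, seed = 99)
  mm <- fit_plsdr(Xm, sim$outcome, 2)
  rm_ <- predict_risk(mm, Xm)
  expect_true(all(is.finite(rm_)))
  mc <- fit_plsdr(sim$X, sim$outcome, 2)
  expect_lt(abs(gonen_heller_c(predict_risk(mc, sim$X)) -
                  gonen_heller_c(rm_)), 0.1)
})

test_that("serialize_model dumps enough for reproducible prediction", {
  sim <- make_linked_data(14, n = 50, p = 120)
  m <- fit_plsdr(sim$X, sim$outcome, 2, mode = "sparse", eta = 0.3)
  dump <- serialize_model(m)
  expect_equal(dump$ncomp, 2L)
  expect_length(dump$beta, 2L)
  # reconstruct survival prediction from the dump alone
  tg <- c(0.2, 0.8)
  Xs <- sweep(sweep(sim$X, 2, dump$center), 2, dump$scale, "/")
  Tm <- matrix(0, 50, dump$ncomp)
  for (a in seq_len(dump$ncomp)) {
    Tm[, a] <- Xs %*% dump$directions[, a]
    Xs <- Xs - tcrossprod(Tm[, a], dump$x_loadings[, a])
  }
  risk <- drop(Tm %*% dump$beta)
  H <- stats::stepfun(dump$baseline_times, c(0, dump$baseline_cumhaz))(tg)
  S_hand <- outer(exp(risk), H, function(r, h) exp(-h * r))
  expect_equal(S_hand, predict_survival(m, sim$X, tg), tolerance = 1e-10)
})
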