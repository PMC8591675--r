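test_that("km_censoring flips status and stays non-increasing", {
  o <- surv_outcome(c(1, 2, 3), c(1, 0, 1))
  G <- km_censoring(o)
  expect_equal(G$eval(1.9), 1)
  expect_equal(G$eval(2), 0.5)
  expect_true(all(diff(G$values) <= 1e-12))
  # no censoring: G identically 1
  G1 <- km_censoring(surv_outcome(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(G1$eval(c(0.5, 1, 5)), c(1, 1, 1))
})

test_that("brier and schmid curves match hand evaluation on toys", {
  o <- surv_outcome(c(1, 2), c(1, 1))
  S <- matrix(0.5, 2, 1)
  expect_equal(brier_curve(S, o, 1.5)$values, 0.25)
  expect_equal(schmid_curve(S, o, 1.5)$values, 0.5)
  expect_equal(schemper_henderson_curve(S, o, 1.5)$values, 0.5)
  # perfect oracle predictions, no censoring: zero everywhere
  o3 <- surv_outcome(c(1, 2, 3), c(1, 1, 1))
  grid <- c(0.5, 1.5, 2.5)
  S_oracle <- t(vapply(o3$time, function(ti) as.numeric(ti > grid),
                       numeric(3)))
  expect_equal(brier_curve(S_oracle, o3, grid)$values, rep(0, 3))
  expect_equal(schmid_curve(S_oracle, o3, grid)$values, rep(0, 3))
  # SS >= BS pointwise without censoring (|u| >= u^2 for |u| <= 1)
  set.seed(1)
  o4 <- surv_outcome(rexp(20), rep(1, 20))
  g4 <- sort(o4$time)[c(5, 10, 15)]
  S4 <- matrix(runif(60), 20, 3)
  expect_true(all(schmid_curve(S4, o4, g4)$values >=
                    brier_curve(S4, o4, g4)$values))
  # unweighted curves are bounded in [0, 1] and equal weighted ones
  # when there is no censoring
  expect_equal(brier_curve(S4, o4, g4, weighted = FALSE)$values,
               brier_curve(S4, o4, g4, weighted = TRUE)$values)
  o5 <- toy_exponential_outcome(30, 2)
  g5 <- sort(unique(o5$time[o5$status == 1]))
  S5 <- matrix(runif(30 * length(g5)), 30)
  bs_unw <- brier_curve(S5, o5, g5, weighted = FALSE)$values
  expect_true(all(bs_unw >= 0 & bs_unw <= 1))
})

test_that("integrate_curve follows the 1/max(t) trapezoid contract", {
  cc <- metric_curve(c(1, 2), c(0.3, 0.3), max_time = 4)
  expect_equal(integrate_curve(cc), 0.3)
  # two-point hand integral on [0,4]: flat 0.2 to t=1, line to 0.4 at t=3,
  # flat to 4 -> (0.2 + 0.6 + 0.4)/4
  c2 <- metric_curve(c(1, 3), c(0.2, 0.4), max_time = 4)
  expect_equal(integrate_curve(c2), (0.2 * 1 + 0.3 * 2 + 0.4 * 1) / 4)
  # linearity
  c3 <- metric_curve(c(1, 3), 5 * c(0.2, 0.4), max_time = 4)
  expect_equal(integrate_curve(c3), 5 * integrate_curve(c2))
})

test_that("r2_curve_integrated behaves at its anchors", {
  grid <- c(1, 2, 3)
  null_c <- metric_curve(grid, rep(0.2, 3), max_time = 3)
  expect_equal(r2_curve_integrated(null_c, null_c), 0)
  zero_c <- metric_curve(grid, rep(0, 3), max_time = 3)
  expect_equal(r2_curve_integrated(zero_c, null_c), 1)
  half_c <- metric_curve(grid, rep(0.1, 3), max_time = 3)
  expect_equal(r2_curve_integrated(half_c, null_c), 0.5)
  expect_error(r2_curve_integrated(half_c, zero_c), "null curve")
})

test_that("likelihood R-squared formulas and edge cases", {
  expect_equal(r2_likelihood(-10, -10, n = 50, kind = "nagelkerke"), 0)
  expect_equal(r2_likelihood(-10, -10, e = 30, kind = "oxs"), 0)
  expect_equal(r2_likelihood(-10, -7, n = 20, kind = "nagelkerke"),
               r2_likelihood(-10, -7, e = 20, kind = "oxs"))
  expect_equal(r2_likelihood(kind = "xo", J0 = 4, Jbeta = 4), 0)
  expect_error(r2_likelihood(-1, -1, e = 0, kind = "oxs"))
  # r2_xo on an informative score is positive, on a constant score zero
  set.seed(2)
  x <- rnorm(60)
  o <- surv_outcome(rexp(60, exp(x)), rep(1, 60))
  expect_gt(r2_xo(x, o), 0.2)
  expect_equal(r2_xo(rep(1, 60), o), 0)
})

test_that("harrell_c enumerates usable pairs", {
  o <- surv_outcome(c(1, 2, 3), c(1, 1, 0))
  expect_equal(harrell_c(c(3, 1, 2), o), 2 / 3)
  expect_equal(harrell_c(-(1:20), surv_outcome(1:20, rep(1, 20))), 1)
  # brute-force pair enumeration agreement under censoring
  for (s in 1:3) {
    oo <- toy_exponential_outcome(25, s + 10)
    r <- rnorm(25)
    expect_equal(harrell_c(r, oo), brute_harrell(r, oo))
  }
  expect_error(harrell_c(1:2, surv_outcome(c(1, 1), c(0, 0))))
})

test_that("gonen_heller_c matches hand values and invariances", {
  expect_equal(gonen_heller_c(c(0, 0, 0)), 0)
  expect_equal(gonen_heller_c(c(0, -1)), 1 / (1 + exp(-1)))
  set.seed(3)
  r <- rnorm(15)
  expect_equal(gonen_heller_c(r + 7), gonen_heller_c(r))
  X <- matrix(rnorm(30), 15, 2); b <- c(1, -2)
  expect_equal(gonen_heller_c(beta = b, X = X),
               gonen_heller_c(drop(X %*% b)))
  expect_gt(gonen_heller_c(seq(100, 10, by = -10)), 0.99)
})

test_that("iauc anchors: 0.5 under independence, 1 under perfect ranking", {
  methods <- c("CD", "HC", "SH", "Uno", "HZ", "survROC")
  # independence: average over replicates (single draws are noisy for the
  # uniformly integrated estimators)
  for (m in methods) {
    set.seed(21)
    v <- vapply(1:10, function(s) {
      big <- toy_exponential_outcome(400, 20 + s)
      iauc(rnorm(400), NULL, big, m)
    }, numeric(1))
    expect_lt(abs(mean(v) - 0.5), 0.05)
  }
  o <- surv_outcome(sort(rexp(50)), rep(1, 50))
  r_perf <- -o$time
  for (m in setdiff(methods, "HZ")) {
    expect_gt(iauc(r_perf, NULL, o, m), 0.95)
  }
  expect_gt(iauc(r_perf, NULL, o, "HZ"), 0.9)
  expect_error(iauc(1:3, NULL, surv_outcome(c(1, 2, 3), c(1, 0, 0)),
                    "survROC"), "event times")
})

test_that("survROC iauc equals the brute-force oracle on 10-subject toys", {
  for (s in 1:3) {
    set.seed(s)
    y <- rexp(10); d <- rbinom(10, 1, 0.7); d[which.max(y)] <- 0
    d[1] <- 1; d[2] <- 1
    oo <- surv_outcome(y, d)
    r <- rnorm(10)
    expect_equal(iauc(r, NULL, oo, "survROC"), brute_survroc_iauc(r, oo),
                 tolerance = 1e-8)
  }
})

test_that("iauc and concordance are rank-invariant in the risk score", {
  oo <- toy_exponential_outcome(60, 30)
  set.seed(31)
  r <- rnorm(60)
  mono <- function(x) exp(2 * x) + 1
  expect_equal(iauc(mono(r), NULL, oo, "survROC"),
               iauc(r, NULL, oo, "survROC"))
  expect_equal(harrell_c(mono(r), oo), harrell_c(r, oo))
  expect_equal(uno_c(mono(r), oo), uno_c(r, oo))
})

test_that("uno_c reduces to restricted harrell_c without censoring", {
  o <- surv_outcome(rexp(30), rep(1, 30))
  set.seed(32)
  r <- rnorm(30)
  tau <- sort(o$time)[20]
  # brute: harrell on pairs whose smaller time < tau
  y <- o$time
  num <- 0; den <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    lo <- which.min(c(y[i], y[j])); hi <- setdiff(c(i, j), c(i, j)[lo])
    if (min(y[i], y[j]) < tau) {
      den <- den + 1
      num <- num + (r[c(i, j)[lo]] > r[hi])
    }
  }
  expect_equal(uno_c(r, o, tau), num / den, tolerance = 1e-10)
  expect_gt(uno_c(-o$time, o, tau), 0.999)
})

test_that("performance_measures returns the reported panel", {
  sim <- simulate_study("factorial", "linear", 1, n = 80, p = 120,
                        seed = 40)[[1]]
  sp <- balanced_split(sim$outcome, 0.7, seed = 1)
  out_tr <- surv_outcome(sim$outcome$time[sp$train],
                         sim$outcome$status[sp$train])
  out_te <- surv_outcome(sim$outcome$time[sp$test],
                         sim$outcome$status[sp$test])
  m <- fit_plsdr(sim$X[sp$train, ], out_tr, 2)
  pm <- performance_measures(m, sim$X[sp$test, ], out_te)
  expect_named(pm, c("R2XO", "iRSSw", "GHCI", "iAUCCD", "iAUCsurvROC",
                     "iSSw"))
  expect_true(all(is.finite(pm)))
  expect_gt(pm["GHCI"], 0.5)
  # null model scores 0.5-ish AUC and 0 R2
  m0 <- fit_plsdr(sim$X[sp$train, ], out_tr, 0)
  pm0 <- performance_measures(m0, sim$X[sp$test, ], out_te,
                              measures = c("R2XO", "GHCI"))
  expect_equal(unname(pm0["R2XO"]), 0)
  expect_equal(unname(pm0["GHCI"]), 0)
})
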