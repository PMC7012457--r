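# Headshake time-series module: predictor hand evaluations, nesting
# identities, derived quantities, MCMC recovery, and LOO-CV selection.

test_that("decay predictor: hand evaluations and limits", {
  # a = 2, b = ln 2, c = -4, t = 1: logit = 2 * 1/2 - 4 = -3
  expect_equal(predict_p_decay(list(a = 2, b = log(2), c = -4), 1),
               1 / (1 + exp(3)))
  expect_equal(predict_p_decay(list(a = 2, b = 0.5, c = -4), 0),
               plogis(-2))  # onset: inv-logit(a + c)
  p0 <- predict_p_decay(list(a = 0, b = 0.3, c = -3), 0:10)
  expect_true(all(p0 == plogis(-3)))  # no-effect limit
  # monotone in t when a != 0
  pm <- predict_p_decay(list(a = 2, b = 0.3, c = -5), seq(0, 48, 0.5))
  expect_true(all(diff(pm) < 0))
})

test_that("day/night predictor: nesting, square-root case, ordering", {
  par <- list(a = 1.5, b = 0.2, c = -4, d = 1)
  tt <- 0:47
  isd <- rep(c(TRUE, FALSE), 24)
  expect_equal(predict_p_daynight(par, tt, isd),
               predict_p_decay(par, tt))  # d = 1 nests model 1
  par2 <- list(a = 0, b = 1, c = qlogis(0.25), d = 0.5)
  expect_equal(predict_p_daynight(par2, 0, TRUE), 0.5)  # 0.25^0.5
  par3 <- list(a = 1.5, b = 0.2, c = -4, d = 1.7)
  expect_true(all(predict_p_daynight(par3, tt, TRUE) <
                    predict_p_daynight(par3, tt, FALSE)))  # d > 1 damps
})

test_that("harmonic predictor: onset, baseline limit, hand evaluation", {
  par <- list(mu1 = 2, mu2 = -4, U11 = 0.7, U12 = 0.4, U21 = 0.2,
              U22 = 0.1, b = 0.3)
  expect_equal(predict_p_harmonic(par, 0), plogis(2 + 0.7))  # alpha1 = 1
  big_b <- modifyList(par, list(b = 50))
  tt <- 1:48
  expect_equal(predict_p_harmonic(big_b, tt),
               plogis(-4 + 0.2 * cos(2 * pi * tt / 24) +
                        0.1 * sin(2 * pi * tt / 24)))
  # all U = 0, mu1 = 2, mu2 = -4, b = ln 2, t = 1: logit = 1 - 2 = -1
  par0 <- list(mu1 = 2, mu2 = -4, U11 = 0, U12 = 0, U21 = 0, U22 = 0,
               b = log(2))
  expect_equal(predict_p_harmonic(par0, 1), plogis(-1))
  expect_equal(round(plogis(-1), 4), 0.2689)
})

test_that("harmonic model nests the decay model", {
  a <- 1.8; cc <- -5; b <- 0.25
  par3 <- list(mu1 = a + cc, mu2 = cc, U11 = 0, U12 = 0, U21 = 0, U22 = 0,
               b = b)
  tt <- seq(0, 100, 0.5)
  expect_equal(predict_p_harmonic(par3, tt),
               predict_p_decay(list(a = a, b = b, c = cc), tt))
})

test_that("half-life follows ln(2)/b", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.34657), 2, tolerance = 1e-4)
  expect_equal(half_life(0.1), 2 * half_life(0.2))
  expect_error(half_life(0), "positive")
  # decay term at t = half-life is exactly half its initial value
  b <- 0.37
  expect_equal(exp(-b * half_life(b)), 0.5)
})

test_that("treatment effect arithmetic from constructed draws", {
  mk_fit <- function(handling, recovery) {
    cc <- qlogis(recovery)
    a <- qlogis(handling) - cc
    structure(list(draws = cbind(a = rep(a, 50), c = rep(cc, 50),
                                 b = rep(0.2, 50)),
                   model_type = "decay", omega = 1 / 24),
              class = c("headshake_fit", "mcmc_fit"))
  }
  eff <- treatment_effect(mk_fit(0.058, 0.010))
  expect_equal(eff$summary$median[
    eff$summary$parameter == "treatment_effect_pct"], 480, tolerance = 1e-6)
  expect_equal(treatment_effect(mk_fit(0.02, 0.01))$draws$
                 treatment_effect_pct[1], 100, tolerance = 1e-9)
  expect_equal(treatment_effect(mk_fit(0.03, 0.03))$draws$
                 treatment_effect_pct[1], 0, tolerance = 1e-9)
  expect_equal(treatment_effect(mk_fit(0.058, 0.010))$draws$half_life[1],
               log(2) / 0.2)
})

test_that("harmonic treatment effect uses the baseline process", {
  fit <- structure(list(
    draws = cbind(mu1 = rep(-2, 20), U11 = rep(0.3, 20), U12 = rep(0, 20),
                  mu2 = rep(-5, 20), U21 = rep(0, 20), U22 = rep(0, 20),
                  b = rep(0.2, 20)),
    model_type = "harmonic", omega = 1 / 24),
    class = c("headshake_fit", "mcmc_fit"))
  eff <- treatment_effect(fit)  # flat baseline: cycle average = plogis(-5)
  expect_equal(eff$draws$handling_rate[1], plogis(-2 + 0.3))
  expect_equal(eff$draws$recovery_rate[1], plogis(-5), tolerance = 1e-9)
  onset <- treatment_effect(fit, recovery = "onset")
  expect_equal(onset$draws$recovery_rate[1], plogis(-5))
})

test_that("decay-model parameters are recovered from simulated series", {
  truth <- list(a = 2, b = 0.2, c = -5)
  ok <- 0
  for (s in 1:5) {
    ser <- make_series(predict_p_decay(truth, 0:199), seed = 500 + s)
    f <- fit_headshake_model(ser, "decay",
                             settings = fast_settings(s, n_iter = 4000))
    med <- setNames(f$summary$median, f$summary$parameter)
    ok <- ok + all(abs(med[c("a", "b", "c")] -
                         unlist(truth)) / abs(unlist(truth)) < 0.10)
  }
  expect_gte(ok, 4)
})

test_that("a null series leaves the treatment effect unidentified at zero", {
  ser <- make_series(rep(plogis(-5), 150), seed = 77)
  f <- fit_headshake_model(ser, "decay",
                           settings = fast_settings(3, n_iter = 4000))
  s <- f$summary
  expect_lt(s$q2.5[s$parameter == "a"], 0)
  expect_gt(s$q97.5[s$parameter == "a"], 0)
})

test_that("all-zero counts warn about the boundary", {
  ser <- data.frame(t = 0:49, y = 0, N = 1000, is_day = FALSE)
  expect_warning(fit_headshake_model(ser, "decay",
                                     settings = fast_settings(1,
                                                              n_iter = 500)),
                 "zero")
})

test_that("LOO-CV driver equals an independent per-fold refit loop", {
  p <- predict_p_decay(list(a = 1.5, b = 0.3, c = -5), 0:11)
  ser <- make_series(p, N = 5000, seed = 31)
  st <- fast_settings(9, n_iter = 1000)
  cv <- headshake_cv_select(ser, models = "decay", settings = st)
  brute <- vapply(seq_len(nrow(ser)), function(i) {
    s <- st
    s$seed <- derive_seed(st$seed, paste0("hs", "decay", "fold", i))
    f <- fit_headshake_model(ser[-i, ], "decay", settings = s)
    obs <- ser$y[i] / ser$N[i]
    (obs - predict_headshake_fit(f, ser$t[i], as.numeric(ser$is_day[i])))^2
  }, numeric(1))
  expect_equal(cv$details$decay$sse, sum(brute), tolerance = 1e-12)
})

test_that("a constant-probability series makes the decay model competitive", {
  ser <- make_series(rep(0.01, 30), N = 10000, seed = 41)
  fl <- with_seed(2, sort(sample.int(30, 6)))
  cv <- headshake_cv_select(ser, settings = fast_settings(4, n_iter = 1000),
                            folds = fl)
  sse <- setNames(cv$table$sse, cv$table$model)
  expect_lte(sse["decay"], 1.25 * min(sse))
})

test_that("day/night-generated series prefer the periodic models", {
  wins <- 0
  for (s in 1:10) {
    tt <- 0:47
    clock <- (9 + tt) %% 24
    isd <- clock >= 8 & clock < 17
    p <- predict_p_daynight(list(a = 2, b = 0.2, c = -6, d = 0.8), tt, isd)
    ser <- make_series(p, seed = 300 + s)
    fl <- with_seed(s, sort(sample.int(48, 6)))
    cv <- headshake_cv_select(ser,
                              settings = fast_settings(s, n_iter = 1200),
                              folds = fl)
    wins <- wins + (cv$winner %in% c("daynight", "harmonic"))
  }
  expect_gte(wins / 10, 0.7)
})
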