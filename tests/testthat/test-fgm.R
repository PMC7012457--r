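# FGM module: alignment/windowing, the four piecewise response shapes and
# their nesting identities, MCMC parameter recovery, and LOO-CV model
# selection against independent oracles.

test_that("align_and_window computes relative days and applies the window", {
  collars <- data.frame(individual_id = c("a", "b"),
                        collar_date = as.Date(c("2015-10-22", "2015-11-02")))
  samples <- data.frame(
    individual_id = c("a", "a", "a", "a", "a", "b"),
    group = "treatment",
    date = as.Date(c("2015-10-22", "2015-10-13", "2015-10-14", "2015-11-01",
                     "2015-11-02", "2015-11-02")),
    value = 40)
  out <- align_and_window(samples, collars)
  # collar date -> rel_day 0 retained; -9 dropped; -8 kept; +10 kept; +11
  # dropped; second individual aligned to its own date
  expect_equal(out$rel_day[out$individual_id == "a"], c(0, -8, 10))
  expect_equal(out$rel_day[out$individual_id == "b"], 0)

  ctrl <- data.frame(individual_id = "c", group = "control",
                     date = as.Date("2015-10-25"), value = 41)
  out2 <- align_and_window(rbind(samples, ctrl), collars)
  expect_equal(out2$rel_day[out2$individual_id == "c"], 3)  # earliest date

  unknown <- data.frame(individual_id = "zz", group = "treatment",
                        date = as.Date("2015-10-25"), value = 40)
  expect_error(align_and_window(unknown, collars), "zz")
})

test_that("predict_fgm_response reproduces the printed posterior identities", {
  handling <- list(beta0 = 43.35, beta1 = 6.59, k1 = 1, k2 = 5.03)
  expect_equal(predict_fgm_response("handling", handling, 3), 49.94)
  expect_equal(predict_fgm_response("handling", handling, -2), 43.35)
  expect_equal(predict_fgm_response("handling", handling, 7), 43.35)
  expect_equal(predict_fgm_response("none", list(beta0 = 43.95), 4), 43.95)
})

test_that("response shapes nest and are piecewise exactly as specified", {
  days <- -8:10
  # stress with beta1 = 0 equals none
  expect_equal(
    predict_fgm_response("stress", list(beta0 = 40, beta1 = 0), days),
    predict_fgm_response("none", list(beta0 = 40), days))
  # habituation with beta2 = 0 equals stress
  expect_equal(
    predict_fgm_response("habituation",
                         list(beta0 = 40, beta1 = 5, beta2 = 0), days),
    predict_fgm_response("stress", list(beta0 = 40, beta1 = 5), days))
  # handling returns exactly to baseline at day >= k2
  h <- predict_fgm_response("handling",
                            list(beta0 = 40, beta1 = 5, k2 = 5), days)
  expect_true(all(h[days >= 5] == 40))
  expect_true(all(h[days >= 1 & days < 5] == 45))
  # habituation slope may cross baseline (no floor)
  hab <- predict_fgm_response("habituation",
                              list(beta0 = 40, beta1 = 2, beta2 = -1), days)
  expect_lt(hab[days == 10], 40)
  expect_error(predict_fgm_response("handling", list(beta0 = 40), 1),
               "beta1")
})

test_that("constant data give back the constant under the none model", {
  d <- data.frame(rel_day = rep(-8:10, 2), value = 43.95)
  f <- fit_fgm_model(d, "none", settings = fast_settings(5))
  expect_lt(abs(f$summary$median[f$summary$parameter == "beta0"] - 43.95),
            0.5)
})

test_that("noiseless handling data are recovered to stated accuracy", {
  # half-day sampling grid so k2 is identified to a quarter-day interval
  days <- rep(seq(-8, 10, by = 0.5), 2)
  ok <- 0
  for (s in 1:10) {
    mu <- predict_fgm_response("handling",
                               list(beta0 = 43, beta1 = 7, k1 = 1, k2 = 5),
                               days)
    d <- data.frame(rel_day = days, value = mu)
    f <- fit_fgm_model(d, "handling", settings = fast_settings(s))
    med <- setNames(f$summary$median, f$summary$parameter)
    ok <- ok + (abs(med["beta0"] - 43) < 0.5 && abs(med["beta1"] - 7) < 0.5 &&
                  abs(med["k2"] - 5) <= 0.5)
  }
  expect_gte(ok, 9)
})

test_that("null data: the stress model's beta1 interval includes zero", {
  d <- simulate_fgm_dataset(fgm_sim_config("none", beta0 = 43.95,
                                           noise_sd = 8, seed = 3))
  f <- fit_fgm_model(d, "stress", settings = fast_settings(2, n_iter = 4000))
  s <- f$summary
  expect_lt(s$q2.5[s$parameter == "beta1"], 0)
  expect_gt(s$q97.5[s$parameter == "beta1"], 0)
})

test_that("k2 posterior respects its support constraint", {
  d <- simulate_fgm_dataset(fgm_sim_config(seed = 9))
  f <- fit_fgm_model(d, "handling", settings = fast_settings(4))
  expect_true(all(f$draws[, "k2"] > 1))
  expect_true(all(f$draws[, "k2"] <= max(d$rel_day)))
})

test_that("breakpoint models demand data on both sides of the lag", {
  d <- data.frame(rel_day = 2:9, value = 50)
  expect_error(fit_fgm_model(d, "handling", settings = fast_settings(1)),
               "day < k1")
})

test_that("noiseless none-model data make none the CV winner with SSE ~ 0", {
  d <- data.frame(rel_day = rep(seq(-8, 10, by = 2), 2), value = 44)
  cv <- fgm_cv_select(d, models = c("none", "stress"),
                      settings = fast_settings(3, n_iter = 1200))
  expect_equal(cv$winner, "none")
  expect_lt(cv$table$sse[cv$table$model == "none"], 0.1)
})

test_that("LOO-CV driver equals an independent per-fold refit loop", {
  d <- simulate_fgm_dataset(fgm_sim_config(samples_per_day = 1, seed = 13))
  d <- d[seq_len(12), ]
  st <- fast_settings(6, n_iter = 1200)
  cv <- fgm_cv_select(d, models = "none", settings = st)
  brute <- vapply(seq_len(nrow(d)), function(i) {
    s <- st
    s$seed <- derive_seed(st$seed, paste0("fgm", "none", "fold", i))
    f <- fit_fgm_model(d[-i, ], "none", settings = s)
    (d$value[i] - predict_fgm_fit(f, d$rel_day[i]))^2
  }, numeric(1))
  expect_equal(cv$details$none$sse, sum(brute), tolerance = 1e-12)

  # and the none-model SSE agrees with the closed-form leave-one-out mean
  # (broad prior: posterior mean ~ training mean)
  mform <- vapply(seq_len(nrow(d)), function(i)
    (d$value[i] - mean(d$value[-i]))^2, numeric(1))
  expect_equal(cv$details$none$sse, sum(mform), tolerance = 0.05 * sum(mform))
})

test_that("handling data at paper-like effect size select handling", {
  # reduced-size version of the selection property: the full criterion runs
  # in the acceptance suite
  wins <- 0
  for (s in 1:3) {
    d <- simulate_fgm_dataset(fgm_sim_config(seed = 600 + s))
    fl <- with_seed(s, sort(sample.int(nrow(d), 10)))
    cv <- fgm_cv_select(d, models = c("none", "handling"),
                        settings = fast_settings(s, n_iter = 1500),
                        folds = fl)
    wins <- wins + (cv$winner == "handling")
  }
  expect_gte(wins, 2)
})
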