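# Accelerometer module: feature extraction against brute-force oracles,
# classifier sanity, metric arithmetic, and hourly aggregation.

toy_stream <- function(n, seed = 1) {
  with_seed(seed, data.frame(time_s = (seq_len(n) - 1) / 8,
                             ax = rnorm(n), ay = rnorm(n), az = rnorm(n)))
}

test_that("static acceleration: constant, degenerate and sinusoid cases", {
  const <- data.frame(time_s = (0:99) / 8, ax = 0.7, ay = -0.2, az = 1)
  st <- static_acceleration(const)
  expect_equal(st$static_x, rep(0.7, 100))
  expect_equal(st$static_z, rep(1, 100))

  one <- data.frame(time_s = 0, ax = 0.5, ay = 0.1, az = -0.3)
  expect_equal(static_acceleration(one)$static_y, 0.1)

  # zero-mean 4 Hz sinusoid at 8 Hz sampling: the 2-s moving average
  # suppresses it almost completely in the interior
  tt <- (0:799) / 8
  s <- data.frame(time_s = tt, ax = sin(2 * pi * 4 * tt + 0.3), ay = 0,
                  az = 0)
  st2 <- static_acceleration(s)
  interior <- 20:780
  expect_true(all(abs(st2$static_x[interior]) < 0.02))

  expect_error(static_acceleration(const[0, ]), "empty")
})

test_that("dynamic acceleration is the exact residual", {
  raw <- toy_stream(300, 2)
  st <- static_acceleration(raw)
  dyn <- dynamic_acceleration(raw, st)
  expect_equal(dyn$dynamic_x + st$static_x, raw$ax)
  expect_equal(dyn$dynamic_y + st$static_y, raw$ay)
  expect_equal(dyn$dynamic_z + st$static_z, raw$az)
  expect_error(dynamic_acceleration(raw, st[1:10, ]), "mismatch")
})

test_that("vedba: Pythagorean values and symmetries", {
  d <- data.frame(x = c(0, 0.3), y = c(0, 0.4), z = c(0, 0))
  expect_equal(vedba(d), c(0, 0.5))
  r <- with_seed(3, data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50)))
  expect_equal(vedba(r), vedba(r[, c("z", "x", "y")]))
  flipped <- r
  flipped$y <- -flipped$y
  expect_equal(vedba(r), vedba(flipped))
})

test_that("running min/max agree exactly with a brute-force window scan", {
  s <- toy_stream(200, 7)
  mm <- running_minmax(s)
  n <- nrow(s)
  brute_min <- vapply(seq_len(n), function(i)
    min(s$ax[max(1, i - 7):min(n, i + 8)]), numeric(1))
  brute_max <- vapply(seq_len(n), function(i)
    max(s$ax[max(1, i - 7):min(n, i + 8)]), numeric(1))
  expect_identical(mm$runmin_x, brute_min)
  expect_identical(mm$runmax_x, brute_max)

  const <- data.frame(time_s = 0:20, ax = 2, ay = 2, az = 2)
  mmc <- running_minmax(const)
  expect_true(all(mmc$runmin_x == 2 & mmc$runmax_x == 2))

  inc <- data.frame(time_s = 0:99, ax = 1:100, ay = 0, az = 0)
  mmi <- running_minmax(inc)
  i <- 50  # interior: window is [i-7, i+8]
  expect_equal(mmi$runmin_x[i], inc$ax[i - 7])
  expect_equal(mmi$runmax_x[i], inc$ax[i + 8])
})

test_that("feature table has 13 predictors and honors its invariants", {
  s <- toy_stream(400, 4)
  ft <- build_features(s)
  expect_equal(ncol(ft), 13)
  expect_true(all(ft$vedba >= 0))
  expect_equal(ft$static_x + ft$dynamic_x, s$ax)
  expect_true(all(ft$runmin_x <= s$ax + 1e-12 & s$ax <= ft$runmax_x + 1e-12))
  # moving mean bounded by moving extrema
  expect_true(all(ft$runmin_y <= ft$static_y & ft$static_y <= ft$runmax_y))

  const <- data.frame(time_s = (0:49) / 8, ax = 1, ay = 0, az = 0)
  ftc <- build_features(const)
  expect_true(all(ftc$dynamic_x == 0) && all(ftc$vedba == 0))
})

test_that("classifier separates separable classes and is deterministic", {
  n <- 400
  X <- with_seed(5, rbind(
    data.frame(f1 = rnorm(n, 0), f2 = rnorm(n, 0)),
    data.frame(f1 = rnorm(n, 6), f2 = rnorm(n, 6))))
  y <- rep(c("a", "b"), each = n)
  tr <- c(1:300, 401:700)
  rf <- train_classifier(X[tr, ], y[tr], n_trees = 100, seed = 3)
  acc <- evaluate_classifier(predict(rf, X[-tr, ]), y[-tr])$overall_accuracy
  expect_gte(acc, 0.99)

  rf2 <- train_classifier(X[tr, ], y[tr], n_trees = 100, seed = 3)
  expect_identical(predict(rf, X), predict(rf2, X))
  rf3 <- train_classifier(X[tr, ], y[tr], n_trees = 100, seed = 4)
  expect_false(identical(rf$forest, rf3$forest))

  expect_error(train_classifier(X[1:10, ], rep("a", 10), seed = 1),
               "single class")
})

test_that("permuted labels drop held-out accuracy to chance", {
  # balanced two-class problem: chance = majority rate = 0.5
  n <- 400
  X <- with_seed(6, rbind(
    data.frame(f1 = rnorm(n, 0), f2 = rnorm(n, 0)),
    data.frame(f1 = rnorm(n, 6), f2 = rnorm(n, 6))))
  y <- rep(c("a", "b"), each = n)
  tr <- c(1:300, 401:700)
  yp <- with_seed(8, sample(y[tr]))
  rf <- train_classifier(X[tr, ], yp, n_trees = 100, seed = 3)
  acc <- evaluate_classifier(predict(rf, X[-tr, ]), y[-tr])$overall_accuracy
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("classifier metrics follow their formulas", {
  truth <- c(rep("pos", 9), "neg", rep("neg", 90))
  pred <- c(rep("pos", 9), "pos", rep("neg", 90))
  rep_ <- evaluate_classifier(pred, truth)
  pc <- rep_$per_class
  expect_equal(pc$precision[pc$behavior == "pos"], 0.9)
  expect_equal(pc$recall[pc$behavior == "pos"], 1.0)
  expect_equal(pc$accuracy[pc$behavior == "pos"], 0.99)
  expect_equal(rep_$overall_accuracy, 0.99)

  perfect <- evaluate_classifier(truth, truth)
  expect_true(all(perfect$per_class$precision == 1))
  expect_equal(perfect$overall_accuracy, 1)

  allpos <- evaluate_classifier(rep("pos", 100), truth)
  expect_equal(allpos$per_class$recall[allpos$per_class$behavior == "pos"],
               1)
  expect_equal(allpos$per_class$recall[allpos$per_class$behavior == "neg"],
               0)
  # confusion-matrix row sums equal class counts
  expect_equal(as.vector(rowSums(rep_$confusion)),
               as.vector(table(factor(truth))))
  expect_error(evaluate_classifier(character(0), character(0)), "empty")
})

test_that("hourly aggregation: counts, partial hours, day flag", {
  # 1.5 h at 8 Hz; headshake everywhere in the first 10 minutes
  n <- 1.5 * 3600 * 8
  lab <- rep("rest", n)
  lab[1:(600 * 8)] <- "headshake"
  s <- data.frame(time_s = (seq_len(n) - 1) / 8, label = lab)
  agg <- aggregate_hourly(s, start_clock_hour = 9)
  expect_equal(agg$N, c(28800, 14400))
  expect_equal(agg$y, c(4800, 0))
  expect_equal(sum(agg$y), sum(lab == "headshake"))
  expect_equal(sum(agg$N), n)
  expect_true(all(agg$is_day))  # 09:00 and 10:00 are pasture hours

  # night start: 20:00 and 21:00 are barn hours
  agg2 <- aggregate_hourly(s, start_clock_hour = 20)
  expect_false(any(agg2$is_day))

  all_hs <- data.frame(time_s = (0:99) / 8, label = "headshake")
  a3 <- aggregate_hourly(all_hs)
  expect_equal(a3$y, a3$N)
})
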