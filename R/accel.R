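# Accelerometer processing: static/dynamic decomposition with a 2-s centered
# moving window, running min/max, VeDBA, the 13-predictor feature table, a
# random-forest behavior classifier, and hourly binomial aggregation of
# classified headshaking.

ACCEL_BEHAVIORS <- c("rest", "feed", "locomote", "headshake")

check_stream <- function(stream) {
  stopifnot(all(c("ax", "ay", "az") %in% names(stream)))
  if (nrow(stream) == 0) stop_input("empty accelerometer stream")
  if (!all(is.finite(stream$ax)) || !all(is.finite(stream$ay)) ||
      !all(is.finite(stream$az)))
    stop_input("non-finite acceleration values")
  invisible(stream)
}

#' Static (gravitational) acceleration by centered moving average
#'
#' A centered moving window of `window_s` seconds (16 samples at 8 Hz, 7
#' back / 8 forward); windows shrink at the series edges.
#'
#' @param stream data.frame with `ax`, `ay`, `az`.
#' @param window_s window length in seconds (default 2).
#' @param rate_hz sampling rate (default 8).
#' @return data.frame `static_x`, `static_y`, `static_z`.
#' @export
static_acceleration <- function(stream, window_s = 2, rate_hz = 8) {
  check_stream(stream)
  w <- max(1L, round(window_s * rate_hz))
  data.frame(static_x = roll_stat_cpp(stream$ax, w, 0L),
             static_y = roll_stat_cpp(stream$ay, w, 0L),
             static_z = roll_stat_cpp(stream$az, w, 0L))
}

#' Dynamic (movement) acceleration
#'
#' Elementwise `raw - static`; the decomposition is exact by construction
#' (`raw = static + dynamic`).
#'
#' @param raw data.frame with `ax`, `ay`, `az`.
#' @param static data.frame from [static_acceleration()].
#' @return data.frame `dynamic_x`, `dynamic_y`, `dynamic_z`.
#' @export
dynamic_acceleration <- function(raw, static) {
  if (nrow(raw) != nrow(static)) stop_input("length mismatch")
  data.frame(dynamic_x = raw$ax - static$static_x,
             dynamic_y = raw$ay - static$static_y,
             dynamic_z = raw$az - static$static_z)
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' `sqrt(dx^2 + dy^2 + dz^2)` per record.
#'
#' @param dynamic data.frame from [dynamic_acceleration()] (or any three
#'   columns of dynamic components).
#' @return non-negative numeric vector.
#' @export
vedba <- function(dynamic) {
  m <- as.matrix(dynamic)
  if (ncol(m) != 3) stop_input("vedba needs exactly three axes")
  sqrt(rowSums(m^2))
}

#' Running minimum and maximum per axis
#'
#' Same centered, edge-shrunken window convention as
#' [static_acceleration()].
#'
#' @inheritParams static_acceleration
#' @return data.frame `runmin_x`, `runmin_y`, `runmin_z`, `runmax_x`,
#'   `runmax_y`, `runmax_z`.
#' @export
running_minmax <- function(stream, window_s = 2, rate_hz = 8) {
  check_stream(stream)
  w <- max(1L, round(window_s * rate_hz))
  data.frame(runmin_x = roll_stat_cpp(stream$ax, w, 1L),
             runmin_y = roll_stat_cpp(stream$ay, w, 1L),
             runmin_z = roll_stat_cpp(stream$az, w, 1L),
             runmax_x = roll_stat_cpp(stream$ax, w, 2L),
             runmax_y = roll_stat_cpp(stream$ay, w, 2L),
             runmax_z = roll_stat_cpp(stream$az, w, 2L))
}

#' Build the 13-predictor feature table
#'
#' Per record: static and dynamic acceleration on each axis, running min and
#' max on each axis, and VeDBA.
#'
#' @inheritParams static_acceleration
#' @return data.frame with 13 feature columns.
#' @export
build_features <- function(stream, window_s = 2, rate_hz = 8) {
  st <- static_acceleration(stream, window_s, rate_hz)
  dyn <- dynamic_acceleration(stream, st)
  mm <- running_minmax(stream, window_s, rate_hz)
  cbind(st, dyn, mm, data.frame(vedba = vedba(dyn)))
}

#' Train the random-forest behavior classifier
#'
#' CART random forest (Gini splits, bootstrap resampling, `mtry` features
#' per split, majority vote), deterministic under the seed.
#'
#' @param features data.frame/matrix of numeric predictors.
#' @param labels factor or character vector of behavior labels.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum records per terminal node (default 1).
#' @param max_depth maximum tree depth (default 30).
#' @param seed integer seed (mandatory).
#' @return object of class `collar_rf`.
#' @export
train_classifier <- function(features, labels, n_trees = 500, mtry = NULL,
                             min_node = 1, max_depth = 30, seed) {
  if (missing(seed)) stop_input("a seed is mandatory for classifier training")
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- factor(labels)
  if (nlevels(y) < 2) stop_input("training set has a single class")
  if (nrow(X) != length(y)) stop_input("features/labels length mismatch")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  forest <- with_seed(derive_seed(seed, "rf"), {
    rf_train_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                 as.integer(mtry), as.integer(min_node),
                 as.integer(max_depth))
  })
  structure(list(forest = forest, levels = levels(y),
                 features = colnames(X), n_trees = n_trees, mtry = mtry,
                 seed = seed),
            class = "collar_rf")
}

#' @param object a `collar_rf` classifier.
#' @param newdata feature table with the training columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @rdname train_classifier
#' @export
predict.collar_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  idx <- rf_predict_cpp(object$forest, X, length(object$levels))
  factor(object$levels[idx + 1], levels = object$levels)
}

#' Classifier performance report
#'
#' One-vs-rest metrics per behavior: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and per-class accuracy `(TP+TN)/total`; plus overall
#' accuracy (confusion-matrix trace over total) and the confusion matrix
#' (rows = truth, columns = predicted).
#'
#' @param predictions predicted labels.
#' @param truth true labels.
#' @return object of class `classifier_report`: `per_class` data.frame,
#'   `overall_accuracy`, `confusion`.
#' @export
evaluate_classifier <- function(predictions, truth) {
  if (length(predictions) == 0) stop_input("empty input")
  if (length(predictions) != length(truth)) stop_input("length mismatch")
  lev <- union(levels(factor(truth)), levels(factor(predictions)))
  truth <- factor(truth, levels = lev)
  predictions <- factor(predictions, levels = lev)
  cm <- table(truth = truth, predicted = predictions)
  n <- sum(cm)
  per <- lapply(lev, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    data.frame(behavior = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               accuracy = (tp + tn) / n)
  })
  structure(list(per_class = do.call(rbind, per),
                 overall_accuracy = sum(diag(cm)) / n,
                 confusion = cm),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Overall accuracy:", format(x$overall_accuracy, digits = 4), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Aggregate classified records into an hourly binomial headshake series
#'
#' Hours are half-open intervals `[t, t+1)` since collar fitting (t = 0 at
#' fitting); a partial trailing hour keeps its true record count. The day
#' flag comes from the clock hour (`[day_start, day_end)`, default
#' 08:00-17:00 pasture hours).
#'
#' @param stream data.frame with `time_s` (seconds since collaring) and a
#'   label column.
#' @param labels column name holding the (classified) behavior labels,
#'   default `"label"`.
#' @param start_clock_hour clock hour at collar fitting.
#' @param day_hours clock interval `[start, end)` counted as day.
#' @return data.frame `t` (hour index), `y` (headshake records), `N` (all
#'   records), `is_day`, `clock_hour`.
#' @export
aggregate_hourly <- function(stream, labels = "label", start_clock_hour = 9,
                             day_hours = c(8, 17)) {
  stopifnot("time_s" %in% names(stream), labels %in% names(stream))
  if (any(stream$time_s < 0))
    stop_input("records must be timestamped after collar fitting")
  dt <- data.table(hour = floor(stream$time_s / 3600),
                   hs = stream[[labels]] == "headshake")
  agg <- dt[, .(y = sum(hs), N = .N), keyby = hour]
  clock <- (start_clock_hour + agg$hour) %% 24
  data.frame(t = agg$hour, y = agg$y, N = agg$N,
             is_day = clock >= day_hours[1] & clock < day_hours[2],
             clock_hour = clock)
}
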