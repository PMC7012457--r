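# Fecal glucocorticoid metabolite (FGM) analysis: four hypothesized adrenal
# response shapes expressed as piecewise regressions on days relative to
# collar fitting, Bayesian fits, and model competition by leave-one-out SSE.
#
# Response shapes (k1 = fixed 1-day gut-passage lag; day 0 = collar fitting):
#   none        E[y] = b0
#   stress      E[y] = b0 + b1 * 1(day >= k1)
#   habituation E[y] = b0 + (b1 + b2 * (day - k1)) * 1(day >= k1)
#   handling    E[y] = b0 + b1 * 1(k1 <= day < k2), k2 estimated from data

FGM_MODELS <- c("none", "stress", "habituation", "handling")

#' Align FGM samples to collaring dates and apply the analysis window
#'
#' Computes the day of each sample relative to its individual's collaring date
#' (day 0 = fitting) and restricts to the window 8 days before through 10
#' days after. Control animals, which were never collared, are aligned to a
#' shared pseudo-collaring date (default: the earliest treatment collaring
#' date).
#'
#' @param samples data.frame with columns `individual_id`, `group`
#'   (`"treatment"`/`"control"`), `date` (Date or integer day), `value`
#'   (ng/g).
#' @param collar_dates data.frame with columns `individual_id`, `collar_date`
#'   for every treatment individual.
#' @param control_date pseudo-collaring date for control animals; default
#'   `min(collar_dates$collar_date)`.
#' @param window inclusive day window kept, default `c(-8, 10)`.
#' @return data.frame of `individual_id`, `group`, `rel_day`, `value`.
#' @export
align_and_window <- function(samples, collar_dates,
                             control_date = NULL, window = c(-8, 10)) {
  stopifnot(all(c("individual_id", "group", "date", "value") %in%
                  names(samples)))
  if (is.null(control_date)) control_date <- min(collar_dates$collar_date)
  idx <- match(samples$individual_id, collar_dates$individual_id)
  is_ctrl <- samples$group == "control"
  if (any(is.na(idx) & !is_ctrl)) {
    bad <- unique(samples$individual_id[is.na(idx) & !is_ctrl])
    stop_input("no collaring date for individual(s): %s",
               paste(bad, collapse = ", "))
  }
  origin <- collar_dates$collar_date[idx]
  origin[is_ctrl] <- control_date
  rel_day <- as.integer(round(as.numeric(samples$date) - as.numeric(origin)))
  keep <- rel_day >= window[1] & rel_day <= window[2]
  out <- data.frame(individual_id = samples$individual_id,
                    group = samples$group, rel_day = rel_day,
                    value = samples$value)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected FGM concentration under a hypothesized response shape
#'
#' @param model_type one of `"none"`, `"stress"`, `"habituation"`,
#'   `"handling"`.
#' @param params list with `beta0` (baseline ng/g), and as required by the
#'   shape: `beta1` (post-lag increment), `beta2` (post-lag slope per day,
#'   habituation), `k1` (lag day, default 1), `k2` (recovery day, handling).
#' @param day numeric vector of days relative to collaring.
#' @return expected concentrations (ng/g), same length as `day`.
#' @export
predict_fgm_response <- function(model_type, params, day) {
  model_type <- match.arg(model_type, FGM_MODELS)
  k1 <- params$k1 %||% 1
  need <- switch(model_type,
                 none = "beta0",
                 stress = c("beta0", "beta1"),
                 habituation = c("beta0", "beta1", "beta2"),
                 handling = c("beta0", "beta1", "k2"))
  miss <- setdiff(need, names(params)[!vapply(params, is.null, logical(1))])
  if (length(miss))
    stop_input("model '%s' needs parameter(s): %s", model_type,
               paste(miss, collapse = ", "))
  b0 <- params$beta0
  # indicator-style arithmetic so either `day` or the parameters may be
  # vectors (the latter is used for draw-wise posterior prediction)
  switch(model_type,
    none = b0 + 0 * day,
    stress = b0 + params$beta1 * (day >= k1),
    habituation = b0 + (params$beta1 + params$beta2 * (day - k1)) *
      (day >= k1),
    handling = b0 + params$beta1 * (day >= k1 & day < params$k2)
  )
}

#' Default priors for the FGM piecewise models
#'
#' Weakly informative: `beta0 ~ N(mean(y), 50)`, `beta1 ~ N(0, 25)`,
#' `beta2 ~ N(0, 10)`, `k2 ~ Uniform(k1, max(day))`, `sigma ~ half-N(25)`.
#'
#' @param data aligned FGM data (used to center the `beta0` prior and bound
#'   `k2`).
#' @param k1 lag day.
#' @return list of prior hyperparameters.
#' @export
fgm_priors <- function(data, k1 = 1) {
  list(beta0_mean = mean(data$value), beta0_sd = 50,
       beta1_sd = 25, beta2_sd = 10,
       k2_lower = k1, k2_upper = max(data$rel_day),
       sigma_sd = 25)
}

#' Fit one FGM response model by MCMC
#'
#' Gaussian likelihood on the ng/g scale with common residual SD; the
#' handling model's recovery breakpoint `k2` is sampled as a continuous
#' parameter on `(k1, max(rel_day)]`.
#'
#' @param data aligned FGM data (`rel_day`, `value`).
#' @param model_type response shape, see [predict_fgm_response()].
#' @param priors list from [fgm_priors()] (defaults derived from `data`).
#' @param settings [mcmc_settings()].
#' @param k1 fixed lag day (default 1).
#' @return object of class `fgm_fit`: the `mcmc_fit` plus `model_type`,
#'   `k1`, and a `summary` table on the natural scale.
#' @export
fit_fgm_model <- function(data, model_type, priors = NULL,
                          settings = mcmc_settings(), k1 = 1) {
  model_type <- match.arg(model_type, FGM_MODELS)
  if (nrow(data) < 4) stop_input("need at least 4 samples")
  if (model_type != "none" && !any(data$rel_day >= k1))
    stop_input("breakpoint model '%s' needs samples at day >= k1", model_type)
  if (model_type != "none" && !any(data$rel_day < k1))
    stop_input("breakpoint model '%s' needs samples at day < k1", model_type)
  if (is.null(priors)) priors <- fgm_priors(data, k1)
  y <- data$value
  day <- data$rel_day

  par_names <- switch(model_type,
                      none = c("beta0", "log_sigma"),
                      stress = c("beta0", "beta1", "log_sigma"),
                      habituation = c("beta0", "beta1", "beta2", "log_sigma"),
                      handling = c("beta0", "beta1", "k2", "log_sigma"))
  init <- c(beta0 = mean(y[day < k1]) %||% mean(y),
            beta1 = 0, beta2 = 0,
            k2 = (priors$k2_lower + priors$k2_upper) / 2,
            log_sigma = log(max(sd(y), 1e-3)))
  if (!is.finite(init["beta0"])) init["beta0"] <- mean(y)
  init <- init[par_names]

  # positional log posterior (hot path for the LOO-CV refits); the mean
  # structure is inlined but is identical to predict_fgm_response()
  n <- length(y)
  ind1 <- as.numeric(day >= k1)
  dk <- day - k1
  i_ls <- length(par_names)
  log_post <- function(theta) {
    ls <- theta[i_ls]
    sigma <- exp(ls)
    mu <- switch(model_type,
      none = theta[1],
      stress = theta[1] + theta[2] * ind1,
      habituation = theta[1] + (theta[2] + theta[3] * dk) * ind1,
      handling = {
        k2 <- theta[3]
        if (k2 <= priors$k2_lower || k2 > priors$k2_upper) return(-Inf)
        theta[1] + theta[2] * (ind1 * (day < k2))
      })
    ll <- -n * ls - 0.5 * sum((y - mu)^2) / sigma^2
    lp <- -0.5 * ((theta[1] - priors$beta0_mean) / priors$beta0_sd)^2 -
      0.5 * (sigma / priors$sigma_sd)^2 + ls
    if (model_type %in% c("stress", "habituation", "handling"))
      lp <- lp - 0.5 * (theta[2] / priors$beta1_sd)^2
    if (model_type == "habituation")
      lp <- lp - 0.5 * (theta[3] / priors$beta2_sd)^2
    # k2 prior is uniform on its support: constant, handled by the bound check
    ll + lp
  }

  fit <- sample_posterior(log_post, init, settings)
  draws <- fit$draws
  draws <- cbind(draws, sigma = exp(draws[, "log_sigma"]))
  fit$draws <- draws[, setdiff(colnames(draws), "log_sigma"), drop = FALSE]
  names(fit$rhat)[names(fit$rhat) == "log_sigma"] <- "sigma"
  fit$model_type <- model_type
  fit$k1 <- k1
  fit$summary <- summarize_fit(fit$draws)
  class(fit) <- c("fgm_fit", class(fit))
  fit
}

#' Posterior-mean FGM prediction from a fitted model
#'
#' @param fit an `fgm_fit`.
#' @param day numeric vector of days relative to collaring.
#' @return posterior mean of the expected response at each day.
#' @export
predict_fgm_fit <- function(fit, day) {
  d <- fit$draws
  cols <- colnames(d)
  vapply(day, function(dd) {
    mu <- predict_fgm_response(fit$model_type, list(
      beta0 = d[, "beta0"],
      beta1 = if ("beta1" %in% cols) d[, "beta1"],
      beta2 = if ("beta2" %in% cols) d[, "beta2"],
      k1 = fit$k1,
      k2 = if ("k2" %in% cols) d[, "k2"]
    ), dd)
    mean(mu)
  }, numeric(1))
}

#' Select among FGM response models by leave-one-out SSE
#'
#' For each candidate shape and each held-out sample the model is refit on
#' the remainder and the held-out concentration predicted by the posterior
#' mean; the winner minimizes the summed squared error.
#'
#' @param data aligned FGM data.
#' @param models candidate shapes (default all four).
#' @param settings [mcmc_settings()]; each refit derives its own seed from
#'   `settings$seed` and the fold index, so results are reproducible.
#' @param folds optional subset of rows to hold out (desk-scale option;
#'   flagged in the result).
#' @param k1 fixed lag day.
#' @return a `cv_result` (see [cv_select()]).
#' @export
fgm_cv_select <- function(data, models = FGM_MODELS,
                          settings = mcmc_settings(), folds = NULL, k1 = 1) {
  if (nrow(data) < 5) stop_input("need at least 5 samples for CV")
  fitters <- lapply(models, function(m) {
    list(
      fit = function(train, i) {
        s <- settings
        s$seed <- derive_seed(settings$seed, paste0("fgm", m, "fold", i))
        fit_fgm_model(train, m, settings = s, k1 = k1)
      },
      predict = function(fit, row) predict_fgm_fit(fit, row$rel_day)
    )
  })
  names(fitters) <- models
  cv_select(data, fitters, response = "value", folds = folds)
}

#' @export
print.fgm_fit <- function(x, ...) {
  cat("FGM piecewise model:", x$model_type, "(k1 =", x$k1, ")\n")
  NextMethod()
}
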