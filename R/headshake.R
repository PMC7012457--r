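# Binomial time-series models of post-collaring headshaking. Hourly counts
# y_t ~ Binomial(N_t, p_t) with three structures for p_t:
#   model 1 "decay":    logit(p_t) = a * exp(-b t) + c
#   model 2 "daynight": p_t = phi_t at night, phi_t^d by day,
#                       logit(phi_t) = a * exp(-b t) + c
#   model 3 "harmonic": logit(p_t) = sum_k alpha_kt (mu_k +
#                       U_k1 cos(2 pi w t) + U_k2 sin(2 pi w t)),
#                       alpha_1t = exp(-b t), alpha_2t = 1 - alpha_1t,
#                       w fixed at 1/24 cycles per hour.
# All three share the exponential decay e^(-bt), giving the treatment-effect
# half-life ln(2)/b.

HEADSHAKE_MODELS <- c("decay", "daynight", "harmonic")

#' Headshake probability, exponential-decay model (model 1)
#'
#' @param params list with `a` (initial logit-scale treatment effect), `b`
#'   (decay rate per hour, > 0 for a proper decay), `c` (baseline logit
#'   asymptote).
#' @param t hours since collar fitting (>= 0).
#' @return probability in (0, 1), vectorized over `t` or over parameter
#'   draws.
#' @export
predict_p_decay <- function(params, t) {
  inv_logit(params$a * exp(-params$b * t) + params$c)
}

#' Headshake probability, day/night switching model (model 2)
#'
#' The nighttime probability follows model 1; daytime hours amplify (d < 1)
#' or damp (d > 1) it through the power `phi^d`, which stays in (0, 1).
#'
#' @param params list with `a`, `b`, `c` as in [predict_p_decay()] plus `d`
#'   (daytime exponent, > 0).
#' @param t hours since collar fitting.
#' @param is_day logical (or 0/1) indicator per hour.
#' @return probability in (0, 1).
#' @export
predict_p_daynight <- function(params, t, is_day) {
  phi <- inv_logit(params$a * exp(-params$b * t) + params$c)
  ifelse_num <- as.numeric(is_day)
  phi^(1 + ifelse_num * (params$d - 1))
}

#' Headshake probability, harmonic-mixture model (model 3)
#'
#' Two harmonic processes (post-collaring and baseline) on the logit scale,
#' mixed with complementary weights `alpha_1t = exp(-b t)` and
#' `alpha_2t = 1 - alpha_1t`; at t = 0 the post-collaring process has weight
#' 1 and its contribution decays towards the baseline process.
#'
#' @param params list with `mu1`, `mu2` (process means, logit scale), `U11`,
#'   `U12`, `U21`, `U22` (harmonic coefficients), `b` (mixture decay rate per
#'   hour), optional `omega` (cycles per hour, default 1/24).
#' @param t hours since collar fitting.
#' @return probability in (0, 1).
#' @export
predict_p_harmonic <- function(params, t) {
  omega <- params$omega %||% (1 / 24)
  a1 <- exp(-params$b * t)
  cs <- cos(2 * pi * omega * t)
  sn <- sin(2 * pi * omega * t)
  lp <- a1 * (params$mu1 + params$U11 * cs + params$U12 * sn) +
    (1 - a1) * (params$mu2 + params$U21 * cs + params$U22 * sn)
  inv_logit(lp)
}

#' Half-life of the treatment effect
#'
#' Time for a logit-scale effect decaying as `exp(-b t)` to halve:
#' `ln(2) / b`.
#'
#' @param b decay rate per hour, must be > 0.
#' @return half-life in hours.
#' @export
half_life <- function(b) {
  if (any(b <= 0)) stop_input("half-life requires a positive decay rate")
  log(2) / b
}

#' Default priors for the headshake time-series models
#'
#' `a`, `c`, `mu_k ~ N(0, 5)`; `U_kj ~ N(0, 2)`; `b ~ half-N(1)` per hour;
#' `d ~ lognormal(0, 0.5)`. All overridable.
#'
#' @return list of prior hyperparameters.
#' @export
headshake_priors <- function() {
  list(mean_sd = 5, U_sd = 2, b_sd = 1, log_d_sd = 0.5)
}

#' Fit a binomial headshake time-series model by MCMC
#'
#' @param series data.frame with columns `t` (hours since collaring), `y`
#'   (headshake records in the hour), `N` (total records), `is_day` (logical,
#'   needed by the day/night model).
#' @param model_type `"decay"`, `"daynight"`, or `"harmonic"` (models 1-3).
#' @param priors list from [headshake_priors()].
#' @param settings [mcmc_settings()].
#' @param omega diel frequency in cycles per hour, fixed at 1/24.
#' @return object of class `headshake_fit`: `mcmc_fit` plus `model_type`,
#'   `omega`, natural-scale `summary` (b reported in place of its log).
#' @export
fit_headshake_model <- function(series, model_type = HEADSHAKE_MODELS,
                                priors = headshake_priors(),
                                settings = mcmc_settings(), omega = 1 / 24) {
  model_type <- match.arg(model_type)
  stopifnot(all(c("t", "y", "N") %in% names(series)))
  if (any(series$y > series$N) || any(series$y < 0))
    stop_input("need 0 <= y <= N for every hour")
  if (all(series$y == 0))
    warning("all hourly counts are zero; baseline parameters sit on the boundary")
  tt <- series$t
  y <- series$y
  N <- series$N
  is_day <- as.numeric(series$is_day %||% rep(0, length(tt)))
  rate <- (y + 0.5) / (N + 1)
  n_tail <- max(1, floor(length(tt) / 2))
  c_init <- qlogis(mean(rate[(length(rate) - n_tail + 1):length(rate)]))
  a_init <- qlogis(max(rate[seq_len(min(3, length(rate)))])) - c_init

  par_names <- switch(model_type,
                      decay = c("a", "log_b", "c"),
                      daynight = c("a", "log_b", "c", "log_d"),
                      harmonic = c("mu1", "U11", "U12", "mu2", "U21", "U22",
                                   "log_b"))
  init <- c(a = a_init, log_b = log(0.2), c = c_init, log_d = 0,
            mu1 = a_init + c_init, U11 = 0, U12 = 0, mu2 = c_init,
            U21 = 0, U22 = 0)[par_names]
  # single joint block: parameters are strongly correlated (a with c, the
  # harmonic means with b); the sampler's covariance adaptation handles it
  blocks <- list(seq_along(par_names))

  log_post <- function(theta) {
    th <- as.list(theta)
    names(th) <- par_names
    b <- exp(th$log_b)
    p <- switch(model_type,
      decay = predict_p_decay(list(a = th$a, b = b, c = th$c), tt),
      daynight = predict_p_daynight(list(a = th$a, b = b, c = th$c,
                                         d = exp(th$log_d)), tt, is_day),
      harmonic = predict_p_harmonic(list(mu1 = th$mu1, mu2 = th$mu2,
                                         U11 = th$U11, U12 = th$U12,
                                         U21 = th$U21, U22 = th$U22,
                                         b = b, omega = omega), tt))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(p) + (N - y) * log1p(-p))
    lp <- dnorm(b, 0, priors$b_sd, log = TRUE) + th$log_b  # half-normal + Jacobian
    for (nm in intersect(c("a", "c", "mu1", "mu2"), par_names))
      lp <- lp + dnorm(th[[nm]], 0, priors$mean_sd, log = TRUE)
    for (nm in intersect(c("U11", "U12", "U21", "U22"), par_names))
      lp <- lp + dnorm(th[[nm]], 0, priors$U_sd, log = TRUE)
    if ("log_d" %in% par_names)
      lp <- lp + dnorm(th$log_d, 0, priors$log_d_sd, log = TRUE)
    ll + lp
  }

  fit <- sample_posterior(log_post, init, settings, blocks = blocks)
  d <- fit$draws
  d <- cbind(d, b = exp(d[, "log_b"]))
  if ("log_d" %in% colnames(d)) d <- cbind(d, d = exp(d[, "log_d"]))
  d <- d[, setdiff(colnames(d), c("log_b", "log_d")), drop = FALSE]
  fit$draws <- d
  names(fit$rhat)[names(fit$rhat) == "log_b"] <- "b"
  names(fit$rhat)[names(fit$rhat) == "log_d"] <- "d"
  fit$model_type <- model_type
  fit$omega <- omega
  fit$summary <- summarize_fit(fit$draws)
  class(fit) <- c("headshake_fit", class(fit))
  fit
}

#' Posterior-mean headshake probability from a fitted time-series model
#'
#' @param fit a `headshake_fit`.
#' @param t hours since collaring.
#' @param is_day day indicator (day/night model only).
#' @return posterior mean probability per hour.
#' @export
predict_headshake_fit <- function(fit, t, is_day = NULL) {
  d <- fit$draws
  param_list <- function() as.list(as.data.frame(d))
  vapply(seq_along(t), function(i) {
    th <- param_list()
    p <- switch(fit$model_type,
      decay = predict_p_decay(th, t[i]),
      daynight = predict_p_daynight(th, t[i], is_day[i]),
      harmonic = predict_p_harmonic(c(th, omega = fit$omega), t[i]))
    mean(p)
  }, numeric(1))
}

#' Derived treatment-effect quantities from a fitted headshake model
#'
#' Computed per posterior draw, then summarized: `handling_rate` is the
#' predicted headshake probability at t = 0; `recovery_rate` is the baseline
#' probability with the treatment term removed (models 1-2: `plogis(c)`, the
#' nighttime scale; model 3: the baseline harmonic process alone, averaged
#' over one 24-h cycle by default or taken at the t = 0 phase); the percent
#' treatment effect is `(handling - recovery) / recovery * 100`. The
#' half-life `ln(2)/b` is included.
#'
#' @param fit a `headshake_fit`.
#' @param recovery `"cycle"` (default) or `"onset"` phase convention for the
#'   harmonic model's recovery rate.
#' @return object of class `derived_effects` with `draws` (data.frame of
#'   `half_life`, `handling_rate`, `recovery_rate`, `treatment_effect_pct`)
#'   and `summary`.
#' @export
treatment_effect <- function(fit, recovery = c("cycle", "onset")) {
  recovery <- match.arg(recovery)
  d <- as.data.frame(fit$draws)
  if (fit$model_type %in% c("decay", "daynight")) {
    handling <- inv_logit(d$a + d$c)
    recov <- inv_logit(d$c)
  } else {
    handling <- inv_logit(d$mu1 + d$U11)
    if (recovery == "onset") {
      recov <- inv_logit(d$mu2 + d$U21)
    } else {
      tg <- 0:23
      cs <- cos(2 * pi * fit$omega * tg)
      sn <- sin(2 * pi * fit$omega * tg)
      recov <- rowMeans(inv_logit(outer(d$mu2, rep(1, 24)) +
                                    outer(d$U21, cs) + outer(d$U22, sn)))
    }
  }
  if (any(recov <= 0)) stop_input("recovery rate of zero; effect undefined")
  draws <- data.frame(half_life = half_life(d$b),
                      handling_rate = handling,
                      recovery_rate = recov,
                      treatment_effect_pct = (handling - recov) / recov * 100)
  structure(list(draws = draws, summary = summarize_fit(draws),
                 model_type = fit$model_type, recovery = recovery),
            class = "derived_effects")
}

#' @export
print.derived_effects <- function(x, ...) {
  cat("Derived treatment effects (", x$model_type, " model):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select among headshake time-series models by leave-one-out SSE
#'
#' Residuals are scored on the proportion scale `y/N`, making models
#' comparable across hours with unequal record counts. Hold-outs may be
#' subsampled for desk-scale runs (flagged in the result).
#'
#' @param series hourly series as in [fit_headshake_model()].
#' @param models candidate models (default all three).
#' @param settings [mcmc_settings()]; per-fold seeds derive from it.
#' @param folds optional subset of hours to hold out.
#' @return a `cv_result`.
#' @export
headshake_cv_select <- function(series, models = HEADSHAKE_MODELS,
                                settings = mcmc_settings(), folds = NULL) {
  series <- as.data.frame(series)
  fitters <- lapply(models, function(m) {
    list(
      fit = function(train, i) {
        s <- settings
        s$seed <- derive_seed(settings$seed, paste0("hs", m, "fold", i))
        fit_headshake_model(train, m, settings = s)
      },
      predict = function(fit, row)
        predict_headshake_fit(fit, row$t, as.numeric(row$is_day %||% 0))
    )
  })
  names(fitters) <- models
  cv_select(series, fitters, response = function(d) d$y / d$N, folds = folds)
}
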