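# Ethogram analysis: Bayesian multinomial logistic regression of six-behavior
# scan-sample tallies across treatment periods (pre / treatment / post), with
# per-individual random effects, and the credible-interval significance rule
# (a period differs from baseline when its 95% CI excludes the pre-treatment
# posterior median).

BEHAVIOR_PERIODS <- c("pre", "treatment", "post")

#' Tally 15-second scan records into 10-minute behavior windows
#'
#' @param scans data.frame with columns `window_id`, `individual_id`,
#'   `period`, `code` (one row per 15-s scan).
#' @return data.frame of one row per window with `individual_id`, `period`,
#'   and the six behavior count columns.
#' @export
tally_scans <- function(scans) {
  stopifnot(all(c("window_id", "individual_id", "period", "code") %in%
                  names(scans)))
  if (nrow(scans) == 0) stop_input("no scan records supplied")
  bad <- !scans$code %in% BEHAVIOR_CODES
  if (any(bad))
    stop_input("unknown behavior code '%s' in window '%s'",
               scans$code[which(bad)[1]], scans$window_id[which(bad)[1]])
  dt <- as.data.table(scans)
  out <- dt[, {
    cnt <- as.list(as.integer(table(factor(code, levels = BEHAVIOR_CODES))))
    names(cnt) <- BEHAVIOR_CODES
    cnt
  }, by = .(window_id, individual_id, period)]
  setDF(out)
  out$window_id <- NULL
  out
}

#' Fit the multinomial ethogram model by MCMC
#'
#' Parameterization: per-period logits for the five non-reference behaviors
#' (reference = HU, the most common behavior) plus per-individual random
#' intercepts with a shared half-normal scale hyperparameter. The random
#' effect is per-behavior by default (a 5-vector per animal); a single
#' per-individual intercept is available via `random_effect = "intercept"`.
#' Counts are aggregated to (individual, period) cells before evaluating the
#' multinomial likelihood, which is equivalent up to a constant because
#' windows are exchangeable given period and individual.
#'
#' @param windows data.frame from [tally_scans()] or
#'   [simulate_behavior_dataset()].
#' @param settings [mcmc_settings()].
#' @param priors list: `beta_sd` (logit prior SD, default 2), `re_scale_sd`
#'   (half-normal SD of the random-effect scale, default 1).
#' @param random_effect `"behavior"` (default) or `"intercept"`.
#' @return object of class `behavior_fit`: the underlying `mcmc_fit`, plus
#'   `p_draws` (per-draw period-level probabilities for a typical individual,
#'   columns `p[<period>,<behavior>]`), `behaviors`, `periods`, `rhat`,
#'   `converged`.
#' @export
fit_behavior_model <- function(windows, settings = mcmc_settings(),
                               priors = list(beta_sd = 2, re_scale_sd = 1),
                               random_effect = c("behavior", "intercept")) {
  random_effect <- match.arg(random_effect)
  stopifnot(all(BEHAVIOR_CODES %in% names(windows)))
  inds <- sort(unique(windows$individual_id))
  if (length(inds) < 2) stop_input("need at least 2 individuals")
  if (!all(BEHAVIOR_PERIODS %in% windows$period))
    stop_input("need windows in every period (pre, treatment, post)")

  dt <- as.data.table(windows)
  cells <- dt[, lapply(.SD, sum), by = .(individual_id, period),
              .SDcols = BEHAVIOR_CODES]
  C <- as.matrix(cells[, ..BEHAVIOR_CODES])
  storage.mode(C) <- "double"
  period_idx <- match(cells$period, BEHAVIOR_PERIODS)
  ind_idx <- match(cells$individual_id, inds)
  n_ind <- length(inds)
  re_dim <- if (random_effect == "behavior") 5L else 1L

  beta_names <- as.vector(outer(BEHAVIOR_PERIODS, BEHAVIOR_CODES[-1],
                                function(p, b) paste0("beta[", p, ",", b, "]")))
  u_names <- as.vector(outer(seq_len(n_ind), seq_len(re_dim),
                             function(i, j) paste0("u[", i, ",", j, "]")))
  par_names <- c(beta_names, u_names, "log_sigma")
  init <- setNames(c(rep(0, length(beta_names) + length(u_names)),
                     log(0.5)), par_names)
  nb <- length(beta_names)

  # likelihood in C++ (hot path); random effects are centered across
  # individuals inside it, identifying the period logits as those of the
  # average individual (removes the beta/u ridge)
  nu <- n_ind * re_dim
  i_ls <- length(par_names)
  log_post <- function(theta) {
    sigma <- exp(theta[i_ls])
    ll <- behavior_ll_cpp(C, period_idx, ind_idx, theta[seq_len(nb)],
                          theta[nb + seq_len(nu)], n_ind, re_dim)
    lp <- -0.5 * sum(theta[seq_len(nb)]^2) / priors$beta_sd^2 -
      0.5 * sum(theta[nb + seq_len(nu)]^2) / sigma^2 - nu * theta[i_ls] -
      0.5 * (sigma / priors$re_scale_sd)^2 + theta[i_ls]
    ll + lp
  }

  blocks <- c(lapply(1:3, function(p) seq(p, nb, by = 3)),       # per period
              lapply(seq_len(n_ind),
                     function(i) nb + seq(i, n_ind * re_dim, by = n_ind)),
              list(length(par_names)))
  fit <- sample_posterior(log_post, init, settings, blocks = blocks)

  # typical-individual (random effects = 0) probabilities per draw
  nd <- nrow(fit$draws)
  p_draws <- matrix(NA_real_, nd, 18)
  colnames(p_draws) <- as.vector(outer(
    BEHAVIOR_PERIODS, BEHAVIOR_CODES,
    function(p, b) paste0("p[", p, ",", b, "]")))
  bdraws <- fit$draws[, beta_names, drop = FALSE]
  for (p in 1:3) {
    Lp <- cbind(0, bdraws[, seq(p, nb, by = 3), drop = FALSE])
    Pp <- exp(Lp - row_log_sum_exp(Lp))
    for (b in 1:6)
      p_draws[, paste0("p[", BEHAVIOR_PERIODS[p], ",", BEHAVIOR_CODES[b],
                       "]")] <- Pp[, b]
  }
  structure(list(fit = fit, p_draws = p_draws, behaviors = BEHAVIOR_CODES,
                 periods = BEHAVIOR_PERIODS, rhat = fit$rhat,
                 converged = fit$converged, random_effect = random_effect),
            class = "behavior_fit")
}

#' Period probability draws from a behavior fit
#'
#' @param bfit a `behavior_fit`.
#' @param period one of `pre`, `treatment`, `post`.
#' @param behavior one of the six codes.
#' @return numeric vector of posterior draws of the probability.
#' @export
behavior_prob_draws <- function(bfit, period, behavior) {
  bfit$p_draws[, paste0("p[", match.arg(period, BEHAVIOR_PERIODS), ",",
                        match.arg(behavior, BEHAVIOR_CODES), "]")]
}

#' Credible-interval significance table for the ethogram model
#'
#' For each behavior, the treatment and post-treatment probabilities are
#' flagged significant when their 95% credible interval excludes the
#' pre-treatment posterior median; overlap with the 50% interval is reported
#' separately (the open/closed circle distinction in the study's figures).
#'
#' @param bfit a `behavior_fit`.
#' @return data.frame with one row per behavior x period (treatment, post):
#'   `behavior`, `period`, `pre_median`, `median`, `l50`, `u50`, `l95`,
#'   `u95`, `overlap50`, `overlap95`, `significant` (= `!overlap95`).
#' @export
assess_significance <- function(bfit) {
  need <- as.vector(outer(BEHAVIOR_PERIODS, BEHAVIOR_CODES,
                          function(p, b) paste0("p[", p, ",", b, "]")))
  if (!all(need %in% colnames(bfit$p_draws)))
    stop_input("posterior draws missing for some period")
  rows <- list()
  for (b in BEHAVIOR_CODES) {
    pre_med <- median(behavior_prob_draws(bfit, "pre", b))
    for (pd in c("treatment", "post")) {
      dr <- behavior_prob_draws(bfit, pd, b)
      q <- quantile(dr, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        behavior = b, period = pd, pre_median = pre_med,
        median = median(dr), l50 = q[2], u50 = q[3], l95 = q[1], u95 = q[4],
        overlap50 = pre_med >= q[2] & pre_med <= q[3],
        overlap95 = pre_med >= q[1] & pre_med <= q[4])
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !out$overlap95
  rownames(out) <- NULL
  out
}

#' Descriptive Pearson correlations of window counts
#'
#' @param windows behavior windows.
#' @return 6 x 6 correlation matrix of the count columns.
#' @export
behavior_correlations <- function(windows) {
  stats::cor(as.matrix(windows[, BEHAVIOR_CODES]))
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat("Multinomial ethogram model (random effect:", x$random_effect, ")\n")
  cat("max split-Rhat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(utils::head(assess_significance(x)[, c("behavior", "period",
                                               "median", "l95", "u95",
                                               "significant")], 12),
        row.names = FALSE)
  invisible(x)
}
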