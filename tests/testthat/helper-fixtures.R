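# Shared fixture builders (all programmatic; no data files).

# hourly binomial series drawn from a given probability curve
make_series <- function(p, N = 28800, seed = 1, start_clock = 9,
                        day_hours = c(8, 17)) {
  tt <- seq_along(p) - 1
  clock <- (start_clock + tt) %% 24
  with_seed(seed, data.frame(
    t = tt, y = rbinom(length(p), N, p), N = N,
    is_day = clock >= day_hours[1] & clock < day_hours[2]))
}

# minimal behavior_fit stand-in for testing the significance rule in
# isolation (constructed draws, no MCMC)
fake_behavior_fit <- function(pre, treatment, post, behavior = "HDSK") {
  n <- max(length(pre), length(treatment), length(post))
  pre <- rep_len(pre, n)
  treatment <- rep_len(treatment, n)
  post <- rep_len(post, n)
  cols <- as.vector(outer(c("pre", "treatment", "post"),
                          c("HU", "HD", "LAY", "HDSK", "SCRATCH", "LOCO"),
                          function(p, b) paste0("p[", p, ",", b, "]")))
  p_draws <- matrix(0.1, n, 18, dimnames = list(NULL, cols))
  p_draws[, paste0("p[pre,", behavior, "]")] <- pre
  p_draws[, paste0("p[treatment,", behavior, "]")] <- treatment
  p_draws[, paste0("p[post,", behavior, "]")] <- post
  structure(list(p_draws = p_draws,
                 behaviors = c("HU", "HD", "LAY", "HDSK", "SCRATCH", "LOCO"),
                 periods = c("pre", "treatment", "post")),
            class = "behavior_fit")
}

fast_settings <- function(seed = 1, n_iter = 2000, thin = 4)
  mcmc_settings(n_iter = n_iter, thin = thin, seed = seed)
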