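# Deterministic fixture builders used across test files.

# Evenly spaced spike times within a half-open span (ms).
regular_train <- function(period_ms, span, offset = period_ms / 2) {
  seq(span[1] + offset, span[2] - 1e-9, by = period_ms)
}

# A session whose per-trial spike patterns are fixed functions of the trial
# class: rates given as inter-spike periods (ms) per unit and class.
# periods: list of c(L = period_L, R = period_R), one element per unit;
# NA period = no spikes.
manual_session <- function(n_LL = 25, n_RR = 25, n_LR = 0, n_RL = 0,
                           periods = list(c(L = 50, R = 100)),
                           span = c(-600, 2600), session_index = 1,
                           latency_ms = 350) {
  classes <- rep(c("L-L", "R-R", "L-R", "R-L"), c(n_LL, n_RR, n_LR, n_RL))
  cue <- ifelse(substr(classes, 1, 1) == "L", "left", "right")
  press <- ifelse(substr(classes, 3, 3) == "L", "left", "right")
  n <- length(classes)
  t_cue <- 1500 + (seq_len(n) - 1) * 12000
  trials <- data.frame(
    cue_side = cue, first_press_side = press,
    t_ready = t_cue, t_cue = t_cue, t_extend = t_cue + 2000,
    t_press = t_cue + 2000 + latency_ms,
    t_feedback = t_cue + 2000 + latency_ms + 1000,
    outcome = ifelse(cue == press, "success", "failure"),
    stringsAsFactors = FALSE
  )
  trains <- list()
  for (i in seq_along(periods)) {
    per <- periods[[i]]
    spikes <- lapply(seq_len(n), function(j) {
      p <- if (press[j] == "left") per[["L"]] else per[["R"]]
      if (is.na(p)) numeric(0) else t_cue[j] + regular_train(p, span)
    })
    trains[[sprintf("u%02d", i)]] <- unlist(spikes)
  }
  session(session_index, trials, trains)
}

# Shorthand generator for a single tuned session.
tuned_session <- function(d = 4, n_units = 4, trials_per_class = 50,
                          seed = 1, pattern_mode = "rate_offset",
                          accuracy = 0.7, error_tuning = "choice",
                          baseline = 10) {
  cfg <- generator_config(
    n_units = n_units, n_sessions = 2, trials_per_class = trials_per_class,
    baseline_rate = baseline, tuning_amplitude = d,
    pattern_mode = pattern_mode, error_tuning = error_tuning, seed = seed,
    behavior = make_learning_curve(2, accuracy, accuracy, 0.35, 0.35))
  simulate_session(cfg, 1)
}

# Brute-force spike count in [lo, hi).
count_between <- function(spikes, lo, hi) sum(spikes >= lo & spikes < hi)
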