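# Firing-rate estimation and ensemble rate statistics.

n_spikes_before <- function(spikes, t) {
  findInterval(t, spikes, left.open = TRUE)
}

#' Sliding-window firing rate of one spike train
#'
#' Boxcar firing-rate estimate: spike counts in a `bin_width` ms window
#' sliding in `step` ms increments through the interval, divided by the
#' window length. Windows are centered on the time grid
#' `start + step/2, start + 3*step/2, ...`, giving `1000/step` estimates
#' per second (50/s at the 20 ms default); each window is half-open,
#' `[t - bin_width/2, t + bin_width/2)`.
#'
#' @param spike_train Numeric vector of spike times, ms, nondecreasing.
#' @param interval Numeric `c(start, end)`, ms, half-open.
#' @param bin_width Window length, ms (> 0).
#' @param step Slide increment, ms (> 0).
#' @return Object of class `"rate_series"`: a data frame with columns
#'   `time` (window-center ms) and `rate` (Hz), with attributes
#'   `bin_width` and `step`.
#' @export
#' @examples
#' sr <- sliding_rate(c(100, 150, 900), c(0, 1000))
#' nrow(sr)  # 50 estimates in one second
sliding_rate <- function(spike_train, interval, bin_width = 100, step = 20) {
  if (bin_width <= 0 || step <= 0) stop("bin_width and step must be > 0")
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  n <- floor((interval[2] - interval[1]) / step + 1e-9)
  centers <- interval[1] + (seq_len(n) - 0.5) * step
  counts <- n_spikes_before(spike_train, centers + bin_width / 2) -
    n_spikes_before(spike_train, centers - bin_width / 2)
  out <- data.frame(time = centers, rate = counts / (bin_width / 1000))
  attr(out, "bin_width") <- bin_width
  attr(out, "step") <- step
  class(out) <- c("rate_series", "data.frame")
  out
}

# Window-mean firing rate of one unit in one trial: the average of all
# sliding-bin rates whose centers fall inside the (absolute) window.
window_mean_rate <- function(spike_train, bounds, bin_width = 100, step = 20) {
  mean(sliding_rate(spike_train, bounds, bin_width, step)$rate)
}

# Per-trial rate matrix (trials x bins) for one unit, aligned to an anchor.
aligned_rate_matrix <- function(spike_train, anchors, span,
                                bin_width = 100, step = 20) {
  rows <- lapply(anchors, function(a) {
    sliding_rate(spike_train - a, span, bin_width, step)$rate
  })
  do.call(rbind, rows)
}

#' Peri-event time histogram with per-bin class comparison
#'
#' Trial-averaged sliding firing rate of one unit, aligned to a task
#' event, computed per trial class. When exactly two classes are given,
#' each time bin is tested for a class difference with the two-sample
#' rank-sum (Wilcoxon) test across trials and flagged at `p < alpha`.
#'
#' @param session An `"ensemble_session"`.
#' @param unit Unit id (name in `session$spike_trains`).
#' @param classes Trial classes to average, e.g. `c("L-L", "R-R")`; each
#'   must have at least 2 trials.
#' @param anchor `"cue"` or `"press"`.
#' @param span `c(start, end)` ms around the anchor.
#' @param bin_width,step Sliding-window parameters, ms.
#' @param alpha Per-bin significance level for the rank-sum flags.
#' @return Object of class `"peth"`: list with `time` (bin centers, ms),
#'   `mean_rate` (matrix classes x bins), `n_trials`, and, for two
#'   classes, `p_value` and `significant` per bin.
#' @export
peth <- function(session, unit, classes = c("L-L", "R-R"),
                 anchor = c("cue", "press"), span = c(-500, 2000),
                 bin_width = 100, step = 20, alpha = 0.01) {
  anchor <- match.arg(anchor)
  train <- session$spike_trains[[unit]]
  if (is.null(train)) stop("unknown unit '", unit, "'")
  a_col <- if (anchor == "cue") "t_cue" else "t_press"
  mats <- lapply(classes, function(cl) {
    tr <- select_trials(session, cl)
    if (nrow(tr) < 2L) stop("class ", cl, " has fewer than 2 trials")
    aligned_rate_matrix(train, tr[[a_col]], span, bin_width, step)
  })
  names(mats) <- classes
  times <- sliding_rate(numeric(0), span, bin_width, step)$time
  means <- do.call(rbind, lapply(mats, colMeans))
  out <- list(time = times, mean_rate = means,
              n_trials = vapply(mats, nrow, integer(1L)),
              classes = classes, unit = unit, anchor = anchor)
  if (length(classes) == 2L) {
    p <- vapply(seq_along(times), function(j) {
      stats::wilcox.test(mats[[1L]][, j], mats[[2L]][, j], exact = FALSE)$p.value
    }, numeric(1L))
    p[is.na(p)] <- 1  # identical constant samples: no evidence of difference
    out$p_value <- p
    out$significant <- p < alpha
  }
  class(out) <- "peth"
  out
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("PETH of unit %s (%s-aligned), classes %s\n", x$unit, x$anchor,
              paste(x$classes, collapse = " vs ")))
  cat(sprintf("  %d bins spanning [%g, %g] ms\n", length(x$time),
              min(x$time), max(x$time)))
  if (!is.null(x$significant)) {
    cat(sprintf("  %d/%d bins with significant class difference\n",
                sum(x$significant), length(x$time)))
  }
  invisible(x)
}

#' @export
plot.peth <- function(x, ...) {
  graphics::matplot(x$time, t(x$mean_rate), type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "rate (Hz)", ...)
  graphics::legend("topleft", legend = x$classes, lty = 1,
                   col = seq_along(x$classes), bty = "n")
  if (!is.null(x$significant) && any(x$significant)) {
    graphics::points(x$time[x$significant],
                     rep(0, sum(x$significant)), pch = 15)
  }
  invisible(x)
}

#' Per-unit and ensemble rate summary of a session
#'
#' For every unit `i` computes the class mean window rates `M_L^i`,
#' `M_R^i` (average, over trials of the class, of the mean of all sliding
#' 100 ms/20 ms bin rates inside the window), the across-class mean
#' `M^i = (M_L^i + M_R^i)/2`, the signed class difference
#' `D^i = M_L^i - M_R^i`, and the across-trial standard deviations
#' `S_L^i`, `S_R^i` (sample, n-1). The ensemble summary averages over
#' units: `M(k) = mean(M^i)`, `D(k) = mean(|D^i|)`, `S_L(k) = mean(S_L^i)`,
#' `S_R(k) = mean(S_R^i)`.
#'
#' @param session An `"ensemble_session"` (correct-trial classes L-L and
#'   R-R are used).
#' @param window Analysis window name (see [window_catalog()]).
#' @param bin_width,step Sliding-window parameters, ms.
#' @return Object of class `"session_rate_summary"`: list with
#'   `per_unit` (data frame, one row per unit) and `ensemble`
#'   (named numeric `M`, `D`, `S_L`, `S_R`), plus the window and session
#'   index.
#' @export
unit_and_ensemble_summary <- function(session, window = "CO",
                                      bin_width = 100, step = 20) {
  trL <- select_trials(session, "L-L")
  trR <- select_trials(session, "R-R")
  units <- names(session$spike_trains)
  per_trial_rates <- function(train, trials) {
    vapply(seq_len(nrow(trials)), function(j) {
      window_mean_rate(train, window_bounds(window, trials[j, ]),
                       bin_width, step)
    }, numeric(1L))
  }
  rows <- lapply(units, function(u) {
    rL <- per_trial_rates(session$spike_trains[[u]], trL)
    rR <- per_trial_rates(session$spike_trains[[u]], trR)
    data.frame(unit = u,
               M_L = mean(rL), M_R = mean(rR),
               M = (mean(rL) + mean(rR)) / 2,
               D = mean(rL) - mean(rR),
               S_L = stats::sd(rL), S_R = stats::sd(rR),
               stringsAsFactors = FALSE)
  })
  per_unit <- do.call(rbind, rows)
  ens <- c(M = mean(per_unit$M), D = mean(abs(per_unit$D)),
           S_L = mean(per_unit$S_L), S_R = mean(per_unit$S_R))
  structure(list(per_unit = per_unit, ensemble = ens, window = window,
                 session_index = session$session_index),
            class = "session_rate_summary")
}

#' @export
print.session_rate_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Session %d rate summary, window %s\n",
              x$session_index, x$window))
  print(cbind(x$per_unit[1L],
              round(x$per_unit[-1L], digits)), row.names = FALSE)
  cat(sprintf("  ensemble: M=%.*f D=%.*f S_L=%.*f S_R=%.*f (Hz)\n",
              digits, x$ensemble["M"], digits, x$ensemble["D"],
              digits, x$ensemble["S_L"], digits, x$ensemble["S_R"]))
  invisible(x)
}

#' @export
as.data.frame.session_rate_summary <- function(x, ...) {
  ens <- data.frame(unit = "ensemble",
                    M_L = NA_real_, M_R = NA_real_,
                    M = unname(x$ensemble["M"]), D = unname(x$ensemble["D"]),
                    S_L = unname(x$ensemble["S_L"]),
                    S_R = unname(x$ensemble["S_R"]),
                    stringsAsFactors = FALSE)
  out <- rbind(x$per_unit, ens)
  out$session <- x$session_index
  out$window <- x$window
  out
}

#' Pooled time-resolved class rate difference
#'
#' Averages, over all unit-session records, the sliding-rate difference
#' between L-L and R-R trials, and tests each bin against zero with a
#' one-sample t-test across records. Used to locate the onset of
#' directional rate modulation relative to the cue.
#'
#' @param sessions List of `"ensemble_session"` objects.
#' @param span `c(start, end)` ms around cue onset.
#' @param bin_width,step Sliding-window parameters, ms.
#' @param alpha Per-bin significance level (one-sample t-test).
#' @return Object of class `"rate_difference"`: `time`, `mean_diff` (Hz),
#'   `p_value`, `significant`, `n_records`, and `onset_ms` (center of the
#'   first significant bin, `NA` if none).
#' @export
time_resolved_difference <- function(sessions, span = c(-500, 2000),
                                     bin_width = 100, step = 20,
                                     alpha = 0.001) {
  if (inherits(sessions, "ensemble_session")) sessions <- list(sessions)
  recs <- list()
  for (s in sessions) {
    trL <- select_trials(s, "L-L")
    trR <- select_trials(s, "R-R")
    for (u in names(s$spike_trains)) {
      mL <- colMeans(aligned_rate_matrix(s$spike_trains[[u]], trL$t_cue,
                                         span, bin_width, step))
      mR <- colMeans(aligned_rate_matrix(s$spike_trains[[u]], trR$t_cue,
                                         span, bin_width, step))
      recs[[length(recs) + 1L]] <- mL - mR
    }
  }
  if (length(recs) < 2L) stop("need at least 2 unit-session records")
  D <- do.call(rbind, recs)
  times <- sliding_rate(numeric(0), span, bin_width, step)$time
  p <- vapply(seq_along(times), function(j) {
    x <- D[, j]
    if (stats::sd(x) == 0) return(if (mean(x) == 0) 1 else 0)
    stats::t.test(x, mu = 0)$p.value
  }, numeric(1L))
  sig <- p < alpha
  structure(list(time = times, mean_diff = colMeans(D), p_value = p,
                 significant = sig, n_records = nrow(D),
                 onset_ms = if (any(sig)) times[which(sig)[1L]] else NA_real_),
            class = "rate_difference")
}

#' @export
print.rate_difference <- function(x, ...) {
  cat(sprintf("Pooled L-R rate difference over %d unit-session records\n",
              x$n_records))
  cat(sprintf("  first significant bin at %s ms; max |diff| %.3f Hz\n",
              format(x$onset_ms), max(abs(x$mean_diff))))
  invisible(x)
}

#' Z-score a session-wise measure
#'
#' Standardizes a per-session measure to zero mean and unit sample
#' standard deviation (n-1), so measures from different subjects can be
#' pooled before trend regression.
#'
#' @param values Numeric vector, length >= 2, nonzero spread.
#' @return Numeric vector of Z-scores.
#' @export
zscore_sessions <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to Z-score")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero spread: Z-score undefined")
  (values - mean(values)) / s
}
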