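#' Analysis window catalog
#'
#' Fixed catalog of the task's analysis windows, all half-open intervals
#' `[start, end)` in ms relative to their anchor event:
#'
#' * `BC`  -- baseline, `[-500, 0)` before cue onset;
#' * `CO`  -- cue-on analysis window, `[300, 1800)` after cue onset;
#' * `CO1`, `CO2`, `CO3` -- 500 ms cue-on sub-windows `[500, 1000)`,
#'   `[1000, 1500)`, `[1500, 2000)`;
#' * `LP`  -- lever-press window, `[-100, 400)` around the first response
#'   press.
#'
#' @return A data frame with columns `name`, `anchor` (`"cue"` or
#'   `"press"`), `start`, `end` (ms relative to the anchor).
#' @export
#' @examples
#' window_catalog()
window_catalog <- function() {
  data.frame(
    name   = c("BC", "CO", "CO1", "CO2", "CO3", "LP"),
    anchor = c("cue", "cue", "cue", "cue", "cue", "press"),
    start  = c(-500, 300, 500, 1000, 1500, -100),
    end    = c(0, 1800, 1000, 1500, 2000, 400),
    stringsAsFactors = FALSE
  )
}

window_spec <- function(window) {
  cat <- window_catalog()
  i <- match(window, cat$name)
  if (is.na(i)) {
    stop("unknown analysis window '", window, "'; known windows: ",
         paste(cat$name, collapse = ", "))
  }
  cat[i, ]
}

#' Absolute bounds of an analysis window for one trial
#'
#' Maps a named analysis window onto the session clock of a single trial,
#' using the trial's anchor timestamp (cue onset for `BC`/`CO`/`CO1-3`,
#' first response press for `LP`).
#'
#' @param window Window name, one of `window_catalog()$name`.
#' @param trial A one-row data frame (or list) with at least `t_cue` and,
#'   for `LP`, a finite `t_press` (ms on the session clock).
#' @return Numeric vector `c(start, end)`, the half-open absolute interval
#'   in ms.
#' @export
#' @examples
#' window_bounds("CO", list(t_cue = 1000))   # c(1300, 2800)
window_bounds <- function(window, trial) {
  spec <- window_spec(window)
  anchor <- if (spec$anchor == "cue") trial$t_cue else trial$t_press
  if (is.null(anchor) || length(anchor) != 1L || !is.finite(anchor)) {
    stop("trial lacks a finite '", if (spec$anchor == "cue") "t_cue" else "t_press",
         "' timestamp required to anchor window ", window)
  }
  c(anchor + spec$start, anchor + spec$end)
}

#' Derive the trial class from cue side and first press side
#'
#' Directional-choice trials are labelled by the cue side and the side of
#' the first response lever press: `L-L` and `R-R` are correct trials,
#' `L-R` and `R-L` are error trials (cue side named first). Lateral cue
#' positions `LL`/`L` and `RR`/`R` collapse to `left` and `right`;
#' center-cue trials are not directional-choice trials and are rejected.
#'
#' @param cue_side Cue position: `"left"`, `"right"`, or one of the raw
#'   panel codes `"LL"`, `"L"`, `"C"`, `"R"`, `"RR"`. Vectorised.
#' @param first_press_side `"left"` or `"right"`. Vectorised.
#' @return Character vector of trial classes in
#'   `c("L-L", "R-R", "L-R", "R-L")`.
#' @export
#' @examples
#' classify_trial("left", "left")    # "L-L"
#' classify_trial("right", "left")   # "R-L"
classify_trial <- function(cue_side, first_press_side) {
  cue <- collapse_side(cue_side, allow_center = TRUE)
  if (any(cue == "center")) {
    stop("center cue: not a directional-choice trial")
  }
  press <- collapse_side(first_press_side, allow_center = FALSE)
  paste0(ifelse(cue == "left", "L", "R"), "-",
         ifelse(press == "left", "L", "R"))
}

collapse_side <- function(side, allow_center = FALSE) {
  map <- c(LL = "left", L = "left", left = "left",
           RR = "right", R = "right", right = "right",
           C = "center", center = "center")
  out <- unname(map[as.character(side)])
  if (any(is.na(out))) {
    stop("unknown side value(s): ",
         paste(unique(side[is.na(out)]), collapse = ", "))
  }
  if (!allow_center && any(out == "center")) {
    stop("'center' is not a valid press side")
  }
  out
}

#' Construct a recording session object
#'
#' Bundles one recording day: the trials table, the per-unit spike trains
#' and the session index. The behavioral accuracy (successes over all
#' trials) and the inclusion flag (at least 20 L-L and 20 R-R trials) are
#' derived.
#'
#' @param session_index Positive integer session number within the subject.
#' @param trials Data frame with one row per trial and columns `cue_side`,
#'   `first_press_side`, `t_ready`, `t_cue`, `t_extend`, `t_press`,
#'   `t_feedback` (ms, session clock) and `outcome`
#'   (`"success"`/`"failure"`). A `trial_class` column is derived if
#'   absent.
#' @param spike_trains Named list of numeric vectors, one per unit, each a
#'   nondecreasing vector of spike times in ms on the session clock.
#'   Names are unit ids; units are kept in ascending id order.
#' @param subject Optional subject identifier.
#' @return An object of class `"ensemble_session"`.
#' @export
session <- function(session_index, trials, spike_trains, subject = "sim") {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1L)
  needed <- c("cue_side", "first_press_side", "t_ready", "t_cue",
              "t_extend", "t_press", "outcome")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trials table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(names(spike_trains)) || any(names(spike_trains) == "")) {
    stop("spike_trains must be a named list (unit ids as names)")
  }
  spike_trains <- spike_trains[order(names(spike_trains))]
  for (u in names(spike_trains)) {
    ts <- spike_trains[[u]]
    if (length(ts) && (any(!is.finite(ts)) || is.unsorted(ts))) {
      stop("spike train of unit '", u, "' must be finite and nondecreasing")
    }
  }
  if (is.null(trials$trial_class)) {
    trials$trial_class <- classify_trial(trials$cue_side, trials$first_press_side)
  }
  validate_trial_times(trials)
  obj <- list(
    session_index = as.integer(session_index),
    subject = subject,
    trials = trials,
    spike_trains = spike_trains,
    behavioral_accuracy = mean(trials$outcome == "success"),
    included = sum(trials$trial_class == "L-L") >= 20L &&
      sum(trials$trial_class == "R-R") >= 20L
  )
  class(obj) <- "ensemble_session"
  obj
}

validate_trial_times <- function(trials) {
  bad <- which(trials$t_cue != trials$t_ready)
  if (length(bad)) {
    stop("trial ", bad[1L], ": cue onset must coincide with the ready press")
  }
  bad <- which(abs(trials$t_extend - trials$t_cue - 2000) > 1e-9)
  if (length(bad)) {
    stop("trial ", bad[1L], ": lever extension must be 2000 ms after cue onset")
  }
  bad <- which(is.finite(trials$t_press) & trials$t_press < trials$t_extend)
  if (length(bad)) {
    stop("trial ", bad[1L], ": response press precedes lever extension")
  }
  invisible(trials)
}

#' @export
print.ensemble_session <- function(x, ...) {
  cls <- table(factor(x$trials$trial_class,
                      levels = c("L-L", "R-R", "L-R", "R-L")))
  cat("Recording session", x$session_index,
      sprintf("(subject %s)\n", x$subject))
  cat(sprintf("  %d trials: %s\n", nrow(x$trials),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  cat(sprintf("  %d units: %s\n", length(x$spike_trains),
              paste(names(x$spike_trains), collapse = ", ")))
  cat(sprintf("  behavioral accuracy %.3f; %s\n", x$behavioral_accuracy,
              if (x$included) "included" else "excluded (<20 trials in a class)"))
  invisible(x)
}

#' Filter sessions on the minimum-trial inclusion rule
#'
#' A session enters the analysis only if it contains at least 20 L-L and
#' at least 20 R-R (correct directional) trials.
#'
#' @param sessions List of `"ensemble_session"` objects.
#' @return The retained sessions, in the original order.
#' @export
filter_sessions <- function(sessions) {
  keep <- vapply(sessions, function(s) {
    sum(s$trials$trial_class == "L-L") >= 20L &&
      sum(s$trials$trial_class == "R-R") >= 20L
  }, logical(1L))
  sessions[keep]
}

#' Select trials of given classes from a session
#'
#' @param session An `"ensemble_session"`.
#' @param classes Character subset of `c("L-L","R-R","L-R","R-L")`.
#' @return The trials table rows of the requested classes in chronological
#'   (cue-time) order.
#' @export
select_trials <- function(session, classes) {
  stopifnot(all(classes %in% c("L-L", "R-R", "L-R", "R-L")))
  tr <- session$trials[session$trials$trial_class %in% classes, , drop = FALSE]
  tr[order(tr$t_cue), , drop = FALSE]
}
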