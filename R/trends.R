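# Session-trend statistics: Z-scored regression against normalized session
# number with CI-based slope sign calls, learning-stage summaries, behavior
# regressions, and slope-comparison (ANCOVA) tests.

#' Normalize session indices to [0, 1]
#'
#' Affine map sending the first session to 0 and the last to 1, so
#' learning trends are comparable across subjects with different session
#' counts.
#'
#' @param indices Numeric session indices, at least 2 distinct values.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' normalize_sessions(1:21)
normalize_sessions <- function(indices) {
  r <- range(indices)
  if (length(indices) < 2L || r[1] == r[2]) {
    stop("need at least 2 distinct session indices")
  }
  (indices - r[1]) / (r[2] - r[1])
}

#' Linear trend with confidence-interval slope sign call
#'
#' Ordinary least-squares regression of a session-wise measure on a
#' covariate (typically the normalized session number), with the slope's
#' confidence interval from its standard error and the t-distribution.
#' The sign of the trend is called from the interval: `"positive"` if the
#' lower bound exceeds 0, `"negative"` if the upper bound is below 0, and
#' `"zero"` otherwise.
#'
#' @param y Response values (length >= 3).
#' @param x Covariate, not constant.
#' @param level Confidence level (default 0.99).
#' @return Object of class `"trend_fit"`: `slope`, `intercept`, `ci`
#'   (`c(low, high)`), `ci_level`, `sign_call`, and the underlying
#'   `stats::lm` fit.
#' @export
#' @examples
#' slope_with_ci(c(1, 2, 3.1, 4), c(0, 1, 2, 3))
slope_with_ci <- function(y, x, level = 0.99) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  est <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, "x", level = level))
  ci <- as.numeric(ci)
  ci[is.nan(ci)] <- est[["x"]]  # zero-residual fit: zero-width interval
  sign_call <- if (ci[1] > 0) "positive" else if (ci[2] < 0) "negative" else "zero"
  structure(list(slope = unname(est[["x"]]),
                 intercept = unname(est[["(Intercept)"]]),
                 ci = ci, ci_level = level, sign_call = sign_call,
                 fit = fit, n = length(y)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Linear trend (n = %d): slope %.*f, %g%% CI [%.*f, %.*f] -> %s\n",
              x$n, digits, x$slope, 100 * x$ci_level,
              digits, x$ci[1], digits, x$ci[2], x$sign_call))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.trend_fit <- function(object, parm = "slope", level = NULL, ...) {
  if (!is.null(level) && level != object$ci_level) {
    return(as.numeric(stats::confint(object$fit, "x", level = level)))
  }
  object$ci
}

#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, data.frame(x = newdata), ...)
}

#' @export
residuals.trend_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.trend_fit <- function(object, ...) summary(object$fit, ...)

#' @export
plot.trend_fit <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$x, d$y, xlab = "x", ylab = "y", ...)
  graphics::abline(x$fit)
  invisible(x)
}

#' Learning-stage summary
#'
#' Splits a session-ordered measure into `n_stages` contiguous stages of
#' equal session counts (when the count is not divisible, the extra
#' sessions go to the last stage(s)), reports per-stage means and SDs, and
#' tests stage pairs with one-way ANOVA (for two groups this is the
#' two-sample t-test, F = t^2).
#'
#' @param values Session-ordered numeric vector (length >= `n_stages`).
#' @param n_stages Number of stages (default 3).
#' @return Object of class `"stage_summary"`: `stage` assignment, `mean`,
#'   `sd`, `n` per stage, and `p_value` (matrix of pairwise ANOVA
#'   p-values).
#' @export
stage_summary <- function(values, n_stages = 3L) {
  n <- length(values)
  if (n < n_stages) stop("fewer values than stages")
  base <- n %/% n_stages
  rem <- n - base * n_stages
  sizes <- c(rep(base, n_stages - rem), rep(base + 1L, rem))
  stage <- rep(seq_len(n_stages), times = sizes)
  means <- tapply(values, stage, mean)
  sds <- tapply(values, stage, stats::sd)
  p <- matrix(NA_real_, n_stages, n_stages)
  for (a in seq_len(n_stages - 1L)) {
    for (b in seq((a + 1L), n_stages)) {
      va <- values[stage == a]; vb <- values[stage == b]
      if (stats::sd(c(va, vb)) == 0) { p[a, b] <- p[b, a] <- 1; next }
      if (length(va) + length(vb) < 3L) next  # no residual df: p stays NA
      fit <- stats::lm(c(va, vb) ~ factor(rep(c(a, b), c(length(va), length(vb)))))
      p[a, b] <- p[b, a] <- suppressWarnings(stats::anova(fit)[["Pr(>F)"]][1L])
    }
  }
  structure(list(stage = stage, sizes = sizes,
                 mean = as.numeric(means), sd = as.numeric(sds),
                 p_value = p, n_stages = n_stages),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%d learning stages (sizes %s)\n", x$n_stages,
              paste(x$sizes, collapse = ", ")))
  cat("  means:", paste(round(x$mean, digits), collapse = ", "), "\n")
  cat("  SDs:  ", paste(round(x$sd, digits), collapse = ", "), "\n")
  if (x$n_stages >= 2L) {
    cat(sprintf("  1st vs last stage: ANOVA p = %.4g\n",
                x$p_value[1L, x$n_stages]))
  }
  invisible(x)
}

#' Per-subject regression of decoding accuracy on behavioral accuracy
#'
#' Regresses each subject's per-session decoding accuracy on the
#' fraction of correct-choice trials, and tests the subject slopes
#' against zero with a one-sample t-test.
#'
#' @param decoding_by_subject Named list of numeric vectors (per-session
#'   decoding accuracy), one per subject, each length >= 3.
#' @param behavior_by_subject Matching list of per-session behavioral
#'   accuracies.
#' @param level Confidence level for the per-subject slope CIs.
#' @return List with `per_subject` (list of [slope_with_ci()] fits),
#'   `slopes` (named numeric), and `slope_test` (one-sample t-test of the
#'   slopes against 0, or `NULL` with a message when fewer than 2
#'   subjects are available).
#' @export
accuracy_vs_behavior <- function(decoding_by_subject, behavior_by_subject,
                                 level = 0.99) {
  stopifnot(length(decoding_by_subject) == length(behavior_by_subject))
  subjects <- names(decoding_by_subject)
  if (is.null(subjects)) subjects <- paste0("s", seq_along(decoding_by_subject))
  fits <- Map(function(acc, beh) slope_with_ci(acc, beh, level),
              decoding_by_subject, behavior_by_subject)
  names(fits) <- subjects
  slopes <- vapply(fits, function(f) f$slope, numeric(1L))
  test <- NULL
  if (length(slopes) < 2L) {
    message("fewer than 2 subjects: across-subject slope test omitted")
  } else if (stats::sd(slopes) == 0) {
    message("subject slopes are identical: across-subject slope test omitted")
  } else {
    test <- stats::t.test(slopes, mu = 0)
  }
  list(per_subject = fits, slopes = slopes, slope_test = test)
}

#' Test for unequal regression slopes (ANCOVA interaction)
#'
#' Compares the slopes of two series measured on a common covariate via
#' the interaction term of the pooled linear model
#' `y ~ x * series`.
#'
#' @param series_a,series_b Numeric response vectors.
#' @param common_x Shared covariate (same length as each series).
#' @return List with `p_value` (interaction), `slopes` (per series) and
#'   the pooled `fit`.
#' @export
slope_comparison <- function(series_a, series_b, common_x) {
  stopifnot(length(series_a) == length(common_x),
            length(series_b) == length(common_x))
  if (length(common_x) < 3L || stats::sd(common_x) == 0) {
    stop("degenerate covariate")
  }
  y <- c(series_a, series_b)
  x <- c(common_x, common_x)
  g <- factor(rep(c("a", "b"), each = length(common_x)))
  fit <- stats::lm(y ~ x * g)
  an <- stats::anova(fit)
  p <- an[["Pr(>F)"]][rownames(an) == "x:g"]
  slopes <- c(a = unname(stats::coef(stats::lm(series_a ~ common_x))[2L]),
              b = unname(stats::coef(stats::lm(series_b ~ common_x))[2L]))
  list(p_value = p, slopes = slopes, fit = fit)
}

#' Behavioral summary of a learning experiment
#'
#' Per-session behavioral accuracy and response latency (first press
#' after lever extension), a first-vs-last-session accuracy comparison
#' (rank-sum over subjects when several are given, over single-trial
#' outcomes otherwise), a one-way ANOVA of per-trial latency over the
#' early sessions (1-4), and the latency trend from session 4 onwards
#' (slope in s/session with a 99% CI sign call).
#'
#' @param experiments One `"ensemble_experiment"` (or list of sessions),
#'   or a list of them (one per subject).
#' @param level Confidence level for the latency trend.
#' @return Object of class `"behavior_summary"`.
#' @export
behavior_summary <- function(experiments, level = 0.99) {
  if (inherits(experiments, "ensemble_experiment") ||
      (length(experiments) && inherits(experiments[[1L]], "ensemble_session"))) {
    experiments <- list(experiments)
  }
  acc <- lapply(experiments, function(ss) {
    vapply(ss, function(s) s$behavioral_accuracy, numeric(1L))
  })
  lat <- lapply(experiments, function(ss) {
    vapply(ss, function(s) {
      mean((s$trials$t_press - s$trials$t_extend) / 1000)
    }, numeric(1L))
  })
  n_sessions <- min(lengths(acc))
  acc_mat <- do.call(rbind, lapply(acc, function(a) a[seq_len(n_sessions)]))
  lat_mat <- do.call(rbind, lapply(lat, function(l) l[seq_len(n_sessions)]))

  if (length(experiments) >= 2L) {
    fl_test <- stats::wilcox.test(acc_mat[, 1L], acc_mat[, n_sessions],
                                  exact = FALSE)
  } else {
    s1 <- experiments[[1L]][[1L]]; sn <- experiments[[1L]][[n_sessions]]
    fl_test <- stats::wilcox.test(
      as.numeric(s1$trials$outcome == "success"),
      as.numeric(sn$trials$outcome == "success"), exact = FALSE)
  }

  early <- seq_len(min(4L, n_sessions))
  lat_trials <- list(); lat_session <- list()
  for (ss in experiments) {
    for (k in early) {
      l <- (ss[[k]]$trials$t_press - ss[[k]]$trials$t_extend) / 1000
      lat_trials[[length(lat_trials) + 1L]] <- l
      lat_session[[length(lat_session) + 1L]] <- rep(k, length(l))
    }
  }
  lat_anova <- stats::anova(stats::lm(unlist(lat_trials) ~
                                        factor(unlist(lat_session))))
  latency_anova_p <- lat_anova[["Pr(>F)"]][1L]

  late_trend <- NULL
  if (n_sessions >= 6L) {
    late <- 4L:n_sessions
    late_trend <- slope_with_ci(colMeans(lat_mat)[late], late, level)
  }
  structure(list(accuracy = acc_mat, latency = lat_mat,
                 mean_accuracy = colMeans(acc_mat),
                 mean_latency = colMeans(lat_mat),
                 first_vs_last = fl_test,
                 latency_anova_p = latency_anova_p,
                 latency_trend = late_trend,
                 n_subjects = length(experiments),
                 n_sessions = n_sessions),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("Behavior over %d sessions (%d subject%s)\n", x$n_sessions,
              x$n_subjects, if (x$n_subjects > 1L) "s" else ""))
  cat(sprintf("  accuracy: %.3f (session 1) -> %.3f (session %d); first-vs-last rank-sum p = %.3g\n",
              x$mean_accuracy[1L], x$mean_accuracy[x$n_sessions],
              x$n_sessions, x$first_vs_last$p.value))
  cat(sprintf("  latency: %.3f s -> %.3f s; sessions 1-4 ANOVA p = %.3g\n",
              x$mean_latency[1L], x$mean_latency[x$n_sessions],
              x$latency_anova_p))
  if (!is.null(x$latency_trend)) {
    cat(sprintf("  latency trend from session 4: slope %.4f s/session (%s)\n",
                x$latency_trend$slope, x$latency_trend$sign_call))
  }
  invisible(x)
}
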