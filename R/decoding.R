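# Spatiotemporal decoding of directional choice from spike-count vectors:
# resampled linear-classifier protocol with trial-averaged training samples,
# label-shuffle chance control, and the single-unit / bin-size / single-bin /
# ensemble-size analyses.

protocol_subseed <- function(seed, r) {
  as.integer((as.double(seed) * 613 + r) %% 2147483647)
}
shuffle_subseed <- function(seed, r) {
  as.integer((as.double(seed) * 613 + r + 1000003) %% 2147483647)
}

count_bins <- function(window_len, bin_size, truncate = FALSE) {
  n_bins <- floor(window_len / bin_size + 1e-9)
  if (n_bins < 1L) stop("bin_size larger than the window")
  if (!truncate && abs(n_bins * bin_size - window_len) > 1e-9) {
    stop("bin_size ", bin_size, " ms does not divide the ", window_len,
         " ms window; pass truncate = TRUE to drop the remainder")
  }
  as.integer(n_bins)
}

#' Spike-count vector of one trial
#'
#' Counts each unit's spikes in non-overlapping half-open `bin_size` ms
#' bins tiling the analysis window of the trial and concatenates the
#' per-unit count vectors unit-major (all bins of the first unit, then the
#' second, ...), in ascending unit-id order. This is the classifier's
#' single-trial sample; its dimension is `n_units * n_bins`.
#'
#' @param trial One trial row (see [window_bounds()]).
#' @param spike_trains Named list of spike-time vectors (ms).
#' @param window Analysis window name.
#' @param bin_size Bin length, ms; must divide the window length unless
#'   `truncate = TRUE`.
#' @param truncate Drop a trailing remainder instead of erroring?
#' @return Named numeric vector of spike counts.
#' @export
#' @examples
#' tr <- list(t_cue = 0)
#' spike_count_vector(tr, list(u1 = c(350, 400, 900)), "CO", 500)
spike_count_vector <- function(trial, spike_trains, window, bin_size,
                               truncate = FALSE) {
  bounds <- window_bounds(window, trial)
  counts_in_interval(trial, spike_trains, bounds, bin_size, truncate)
}

counts_in_interval <- function(trial, spike_trains, bounds, bin_size,
                               truncate = FALSE) {
  n_bins <- count_bins(bounds[2] - bounds[1], bin_size, truncate)
  edges <- bounds[1] + (0:n_bins) * bin_size
  units <- names(spike_trains)[order(names(spike_trains))]
  out <- unlist(lapply(units, function(u) {
    st <- spike_trains[[u]]
    diff(n_spikes_before(st, edges))
  }), use.names = FALSE)
  names(out) <- paste0(rep(units, each = n_bins), ".b", rep(seq_len(n_bins),
                                                            length(units)))
  out
}

# Feature matrix (trials x dim) and labels for the given classes.  Either a
# named catalog window or an explicit cue-anchored interval can be used.
session_features <- function(session, classes, window = "CO", bin_size = 500,
                             units = NULL, interval = NULL,
                             truncate = FALSE) {
  trains <- session$spike_trains
  if (!is.null(units)) {
    if (!all(units %in% names(trains))) stop("unknown unit id(s)")
    trains <- trains[sort(units)]
  }
  rows <- list(); labs <- character(0)
  for (cl in classes) {
    tr <- select_trials(session, cl)
    for (j in seq_len(nrow(tr))) {
      v <- if (is.null(interval)) {
        spike_count_vector(tr[j, ], trains, window, bin_size, truncate)
      } else {
        counts_in_interval(tr[j, ], trains, tr$t_cue[j] + interval, bin_size,
                           truncate)
      }
      rows[[length(rows) + 1L]] <- v
      labs <- c(labs, cl)
    }
  }
  list(x = do.call(rbind, rows), y = labs)
}

#' Linear decoder object
#'
#' A trained two-class linear classifier in explicit form: decision
#' function `df(x) = w . x + b`, with the convention that `df(x) >= 0`
#' assigns the positive class (the first of the two trial classes, e.g.
#' L-L) and `df(x) < 0` the negative class. For SVM-trained decoders the
#' support vectors `s_i` and weights `alpha_i` are retained so the kernel
#' form `sum_i alpha_i (s_i . x) + b` can be checked against the expanded
#' form.
#'
#' @param w Numeric weight vector.
#' @param b Numeric bias.
#' @param pos_class,neg_class Class labels for `df >= 0` / `df < 0`.
#' @param support_vectors,alpha Optional kernel-form parameters.
#' @param kind Training algorithm tag.
#' @return Object of class `"linear_decoder"`.
#' @export
linear_decoder <- function(w, b, pos_class = "L-L", neg_class = "R-R",
                           support_vectors = NULL, alpha = NULL,
                           kind = "manual") {
  structure(list(w = as.numeric(w), b = as.numeric(b),
                 pos_class = pos_class, neg_class = neg_class,
                 support_vectors = support_vectors, alpha = alpha,
                 kind = kind),
            class = "linear_decoder")
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("Linear decoder (%s): %d features, df >= 0 -> %s\n",
              x$kind, length(x$w), x$pos_class))
  invisible(x)
}

#' Apply a linear decoder
#'
#' Evaluates the decision function and the sign rule: `df(x) >= 0` is
#' classified as the positive class, otherwise as the negative class.
#'
#' @param decoder A `"linear_decoder"`.
#' @param x Numeric vector or matrix (rows = samples) matching the
#'   decoder's feature dimension.
#' @return List with `class` (character) and `df` (numeric) per sample.
#' @export
classify <- function(decoder, x) {
  stopifnot(inherits(decoder, "linear_decoder"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(decoder$w)) {
    stop("feature dimension ", ncol(x), " does not match decoder dimension ",
         length(decoder$w))
  }
  df <- drop(x %*% decoder$w) + decoder$b
  list(class = ifelse(df >= 0, decoder$pos_class, decoder$neg_class), df = df)
}

# Fit a linear SVM or LDA decoder; returns a linear_decoder with the sign
# convention df >= 0 -> pos_class.
train_decoder <- function(x, y, pos_class, neg_class,
                          kind = c("svm", "lda"), cost = 1) {
  kind <- match.arg(kind)
  fallback <- function() linear_decoder(rep(0, ncol(x)), 0, pos_class,
                                        neg_class, kind = kind)
  if (kind == "svm") {
    fit <- tryCatch(
      e1071::svm(x, factor(y, levels = c(pos_class, neg_class)),
                 kernel = "linear", cost = cost, scale = FALSE,
                 type = "C-classification"),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # e1071's decision values are positive for the first of fit$labels;
    # flip so df >= 0 always means pos_class
    first <- fit$levels[fit$labels[1L]]
    if (first != pos_class) {
      w <- -w; b <- -b
      alpha <- -drop(fit$coefs)
    } else {
      alpha <- drop(fit$coefs)
    }
    linear_decoder(w, b, pos_class, neg_class,
                   support_vectors = fit$SV, alpha = alpha, kind = "svm")
  } else {
    keep <- apply(x, 2L, stats::sd) > 0
    if (!any(keep)) return(fallback())
    fit <- tryCatch(
      suppressWarnings(MASS::lda(x[, keep, drop = FALSE], grouping = factor(y))),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback())
    sc <- fit$scaling[, 1L]
    mpos <- sum(fit$means[pos_class, ] * sc)
    mneg <- sum(fit$means[neg_class, ] * sc)
    if (mpos < mneg) { sc <- -sc; tmp <- mpos; mpos <- mneg; mneg <- tmp }
    w <- numeric(ncol(x)); w[keep] <- sc
    linear_decoder(w, -(mpos + mneg) / 2, pos_class, neg_class, kind = "lda")
  }
}

#' Trial-averaged training samples
#'
#' Builds the decoder's training set from the raw training vectors of each
#' class: every training sample is the arithmetic mean of `n_average`
#' same-class raw spike-count vectors drawn without replacement; its label
#' is inherited from the class.
#'
#' @param raw_by_class Named list (one element per class) of numeric
#'   matrices, rows = raw single-trial vectors.
#' @param n_average Number of raw vectors averaged per training sample.
#' @param count_per_class Training samples drawn per class; defaults to
#'   the raw training-set size of the class.
#' @return List `x` (matrix of training samples) and `y` (labels).
#' @export
make_training_samples <- function(raw_by_class, n_average = 5,
                                  count_per_class = NULL) {
  xs <- list(); ys <- character(0)
  for (cl in names(raw_by_class)) {
    raw <- raw_by_class[[cl]]
    n_raw <- nrow(raw)
    if (n_raw < n_average) {
      stop("class ", cl, " has only ", n_raw,
           " raw training vectors; need at least n_average = ", n_average)
    }
    n_out <- if (is.null(count_per_class)) n_raw else count_per_class
    for (s in seq_len(n_out)) {
      idx <- sample.int(n_raw, n_average)
      xs[[length(xs) + 1L]] <- colMeans(raw[idx, , drop = FALSE])
      ys <- c(ys, cl)
    }
  }
  list(x = do.call(rbind, xs), y = ys)
}

#' Resampled decoding protocol for one session
#'
#' The session-level decoding analysis: `n_repeats` independent
#' classifiers are trained and tested on the session's spike-count
#' vectors. In each repeat, `trials_per_class` trials are drawn from each
#' class (default: the minimum class count, for balance); a fraction
#' `test_fraction` of them (ceiling, per class) forms the test set and
#' the rest the raw training set; training samples are means of
#' `n_average` same-class raw vectors ([make_training_samples()]); a
#' linear SVM (or LDA) is fit and tested on the held-out single-trial
#' vectors. The session's accuracy is the unweighted mean over repeats of
#' the pooled test accuracy, and the class distance is the difference of
#' the class-mean decision-function values of test samples pooled over
#' repeats.
#'
#' Repeat `r` uses the subseed `(seed * 613 + r) mod (2^31 - 1)`; the
#' label shuffle of [shuffle_control()] draws from its own stream
#' (offset 1000003) so shuffled and unshuffled runs share their trial
#' draws.
#'
#' @param session An `"ensemble_session"`.
#' @param classes The two trial classes to discriminate.
#' @param window Analysis window name (ignored if `interval` given).
#' @param bin_size Bin length, ms.
#' @param classifier `"svm"` (linear kernel) or `"lda"`.
#' @param n_repeats Number of resampled classifiers.
#' @param test_fraction Held-out fraction per class.
#' @param n_average Raw vectors averaged per training sample.
#' @param trials_per_class Trials drawn per class and repeat; default
#'   `min(class counts)`.
#' @param cost SVM regularization constant.
#' @param units Optional subset of unit ids.
#' @param interval Optional explicit cue-anchored window `c(start, end)`
#'   ms overriding `window`.
#' @param truncate Allow a trailing partial bin to be dropped?
#' @param shuffle Permute training-sample labels before fitting (chance
#'   control)?
#' @param seed Protocol seed.
#' @return Object of class `"decoding_result"` with `mean_accuracy`,
#'   `class_distance`, per-repeat `accuracy`, pooled decision values
#'   `df_pos`/`df_neg`, and the protocol settings.
#' @export
decode_session <- function(session, classes = c("L-L", "R-R"),
                           window = "CO", bin_size = 500,
                           classifier = c("svm", "lda"),
                           n_repeats = 100, test_fraction = 0.2,
                           n_average = 5, trials_per_class = NULL,
                           cost = 1, units = NULL, interval = NULL,
                           truncate = FALSE, shuffle = FALSE, seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(length(classes) == 2L, n_repeats >= 1L, n_average >= 1L,
            test_fraction > 0, test_fraction < 1)
  feats <- session_features(session, classes, window, bin_size, units,
                            interval, truncate)
  pos <- classes[1L]; neg <- classes[2L]
  idx_pos <- which(feats$y == pos)
  idx_neg <- which(feats$y == neg)
  avail <- c(length(idx_pos), length(idx_neg))
  tpc <- if (is.null(trials_per_class)) min(avail) else as.integer(trials_per_class)
  if (tpc > min(avail)) {
    stop("trials_per_class = ", tpc, " exceeds available trials (",
         paste(avail, collapse = ", "), ")")
  }
  n_test <- ceiling(test_fraction * tpc)
  n_raw <- tpc - n_test
  if (n_raw < 1L) stop("split infeasible: empty raw training set")
  if (n_raw < n_average) {
    stop("raw training set per class (", n_raw,
         ") smaller than n_average (", n_average, ")")
  }

  acc <- numeric(n_repeats)
  df_pos <- list(); df_neg <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(protocol_subseed(seed, r))
    dpos <- sample(idx_pos, tpc)
    dneg <- sample(idx_neg, tpc)
    test_idx <- c(dpos[seq_len(n_test)], dneg[seq_len(n_test)])
    raw <- list(feats$x[dpos[-seq_len(n_test)], , drop = FALSE],
                feats$x[dneg[-seq_len(n_test)], , drop = FALSE])
    names(raw) <- classes
    train <- make_training_samples(raw, n_average)
    if (shuffle) {
      set.seed(shuffle_subseed(seed, r))
      train$y <- train$y[sample.int(length(train$y))]
    }
    dec <- train_decoder(train$x, train$y, pos, neg, classifier, cost)
    res <- classify(dec, feats$x[test_idx, , drop = FALSE])
    truth <- feats$y[test_idx]
    acc[r] <- mean(res$class == truth)
    df_pos[[r]] <- res$df[truth == pos]
    df_neg[[r]] <- res$df[truth == neg]
  }
  df_pos <- unlist(df_pos); df_neg <- unlist(df_neg)
  structure(list(
    mean_accuracy = mean(acc),
    class_distance = mean(df_pos) - mean(df_neg),
    accuracy = acc, df_pos = df_pos, df_neg = df_neg,
    classes = classes, window = window, bin_size = bin_size,
    classifier = classifier, n_repeats = n_repeats,
    trials_per_class = tpc, n_test = n_test, n_average = n_average,
    shuffled = shuffle, seed = seed,
    session_index = session$session_index
  ), class = "decoding_result")
}

#' Label-shuffle chance control
#'
#' Runs the full decoding protocol of [decode_session()] but randomly
#' permutes the class labels of the (trial-averaged) training samples
#' before each classifier is fit; test labels are untouched. Destroying
#' the label-feature association this way yields the empirical chance
#' level, ~50% for balanced two-class problems.
#'
#' @inheritParams decode_session
#' @param ... Passed to [decode_session()].
#' @return A `"decoding_result"` with `shuffled = TRUE`.
#' @export
shuffle_control <- function(session, ...) {
  decode_session(session, ..., shuffle = TRUE)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding %s vs %s (%s, window %s, %g ms bins%s)\n",
              x$classes[1L], x$classes[2L], toupper(x$classifier),
              x$window, x$bin_size,
              if (x$shuffled) ", training labels shuffled" else ""))
  cat(sprintf("  session %d: %d repeats, %d trials/class (%d test)\n",
              x$session_index, x$n_repeats, x$trials_per_class, x$n_test))
  cat(sprintf("  mean accuracy %.4f, class distance %.4f\n",
              x$mean_accuracy, x$class_distance))
  invisible(x)
}

#' @export
summary.decoding_result <- function(object, ...) {
  out <- list(
    mean_accuracy = object$mean_accuracy,
    sd_accuracy = stats::sd(object$accuracy),
    class_distance = object$class_distance,
    mean_df = c(stats::setNames(mean(object$df_pos), object$classes[1L]),
                stats::setNames(mean(object$df_neg), object$classes[2L])),
    n_repeats = object$n_repeats)
  class(out) <- "summary.decoding_result"
  out
}

#' @export
print.summary.decoding_result <- function(x, ...) {
  cat(sprintf("mean accuracy %.4f (sd %.4f over %d repeats)\n",
              x$mean_accuracy, x$sd_accuracy, x$n_repeats))
  cat(sprintf("class-mean df: %s = %.4f, %s = %.4f (distance %.4f)\n",
              names(x$mean_df)[1L], x$mean_df[1L],
              names(x$mean_df)[2L], x$mean_df[2L], x$class_distance))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, breaks = 20, ...) {
  rng <- range(x$df_pos, x$df_neg)
  h1 <- graphics::hist(x$df_pos, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(x$df_neg, breaks = breaks, plot = FALSE)
  graphics::plot(h1, col = grDevices::adjustcolor("red", 0.5),
                 xlim = rng, xlab = "decision function value",
                 main = "Test-sample decision values", ...)
  graphics::plot(h2, col = grDevices::adjustcolor("darkgreen", 0.5),
                 add = TRUE)
  graphics::legend("topright", fill = c("red", "darkgreen"),
                   legend = x$classes, bty = "n")
  invisible(x)
}

#' Single-unit decoding and best unit
#'
#' Runs the decoding protocol restricted to each unit's sub-vector in
#' turn and identifies the best single unit by mean accuracy.
#'
#' @inheritParams decode_session
#' @param ... Passed to [decode_session()].
#' @return List with `per_unit` (named list of `"decoding_result"`),
#'   `accuracy` (named numeric), and `best_unit`.
#' @export
single_unit_decoding <- function(session, ...) {
  units <- names(session$spike_trains)
  per_unit <- lapply(units, function(u) decode_session(session, units = u, ...))
  names(per_unit) <- units
  accs <- vapply(per_unit, function(r) r$mean_accuracy, numeric(1L))
  list(per_unit = per_unit, accuracy = accs,
       best_unit = units[which.max(accs)])
}

#' Decoding accuracy as a function of bin size
#'
#' Repeats the protocol on the CO window with different non-overlapping
#' bin sizes (divisors of the 1500 ms window).
#'
#' @inheritParams decode_session
#' @param sizes Bin sizes, ms.
#' @param ... Passed to [decode_session()].
#' @return Data frame with `bin_size` and `accuracy`.
#' @export
bin_size_sweep <- function(session, sizes = c(100, 150, 250, 300, 500, 750),
                           window = "CO", ...) {
  acc <- vapply(sizes, function(b) {
    decode_session(session, window = window, bin_size = b, ...)$mean_accuracy
  }, numeric(1L))
  data.frame(bin_size = sizes, accuracy = acc)
}

#' Decoding accuracy bin by bin through the cue-on period
#'
#' Tiles the 2 s cue-on period with non-overlapping `bin_width` ms bins
#' and runs the protocol on each single bin (feature dimension =
#' ensemble size), tracing how decodable the choice is over time.
#'
#' @inheritParams decode_session
#' @param bin_width Bin length, ms (must divide 2000).
#' @param ... Passed to [decode_session()].
#' @return Data frame with `start`, `end` (ms after cue) and `accuracy`.
#' @export
single_bin_time_course <- function(session, bin_width = 100, ...) {
  n_bins <- count_bins(CUE_ON_MS, bin_width)
  starts <- (seq_len(n_bins) - 1) * bin_width
  acc <- vapply(starts, function(s) {
    decode_session(session, interval = c(s, s + bin_width),
                   bin_size = bin_width, ...)$mean_accuracy
  }, numeric(1L))
  data.frame(start = starts, end = starts + bin_width, accuracy = acc)
}

#' Decoding accuracy vs ensemble size
#'
#' For each requested ensemble size, averages the protocol's accuracy
#' over random unit subsets drawn without replacement (a neuron-dropping
#' curve).
#'
#' @inheritParams decode_session
#' @param sizes Ensemble sizes to evaluate (each <= number of units).
#' @param n_draws Random subsets per size (a size equal to the full
#'   ensemble uses the single full subset).
#' @param subset_seed Seed for the subset draws.
#' @param ... Passed to [decode_session()].
#' @return Data frame with `size` and `accuracy`.
#' @export
ensemble_size_curve <- function(session, sizes = seq_along(session$spike_trains),
                                n_draws = 5, subset_seed = 1L, ...) {
  units <- names(session$spike_trains)
  if (any(sizes > length(units))) {
    stop("ensemble size exceeds the number of units (", length(units), ")")
  }
  acc <- vapply(seq_along(sizes), function(si) {
    m <- sizes[si]
    k_draws <- if (m == length(units)) 1L else n_draws
    set.seed(as.integer((as.double(subset_seed) * 131 + si) %% 2147483647))
    draws <- replicate(k_draws, sample(units, m), simplify = FALSE)
    mean(vapply(draws, function(u) {
      decode_session(session, units = u, ...)$mean_accuracy
    }, numeric(1L)))
  }, numeric(1L))
  data.frame(size = sizes, accuracy = acc)
}

#' Correct-vs-error trial decoding
#'
#' Decodes a correct class against the error class sharing its choice
#' side (`L-L` vs `R-L`: both left presses; `R-R` vs `L-R`: both right
#' presses). A session is eligible only if both classes have at least 20
#' trials; otherwise an ineligible marker is returned.
#'
#' @inheritParams decode_session
#' @param pair Character pair, `c("L-L", "R-L")` or `c("R-R", "L-R")`.
#' @param min_trials Eligibility threshold per class.
#' @param ... Passed to [decode_session()].
#' @return A `"decoding_result"`, or a list with `eligible = FALSE` and
#'   the class counts.
#' @export
error_trial_decoding <- function(session, pair = c("L-L", "R-L"),
                                 min_trials = 20L, ...) {
  stopifnot(length(pair) == 2L)
  counts <- vapply(pair, function(cl) sum(session$trials$trial_class == cl),
                   integer(1L))
  if (any(counts < min_trials)) {
    return(list(eligible = FALSE, counts = counts, pair = pair))
  }
  out <- decode_session(session, classes = pair, ...)
  out$eligible <- TRUE
  out
}
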