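# Plain-text session interchange: a directory bundle with manifest.json,
# trials.csv and spikes.csv.

SCHEMA_VERSION <- 1L

trial_columns <- c("cue_side", "first_press_side", "t_ready", "t_cue",
                   "t_extend", "t_press", "t_feedback", "outcome",
                   "trial_class")

#' Write a session bundle
#'
#' Serializes a session to a directory holding `manifest.json` (subject,
#' session index, unit ids, schema version), `trials.csv` (one row per
#' trial, chronological, integer ms timestamps) and `spikes.csv`
#' (`unit_id, timestamp_ms`, sorted by unit then time, sub-ms timestamps
#' kept to 3 decimals). Output is deterministic for a given session.
#'
#' @param session An `"ensemble_session"`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ensemble_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    subject = session$subject,
    session_index = session$session_index,
    unit_ids = names(session$spike_trains),
    behavioral_accuracy = session$behavioral_accuracy
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "manifest.json"))

  tr <- session$trials[order(session$trials$t_cue), trial_columns]
  for (col in c("t_ready", "t_cue", "t_extend", "t_press", "t_feedback")) {
    tr[[col]] <- sprintf("%d", as.integer(round(tr[[col]])))
  }
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)

  units <- names(session$spike_trains)
  sp <- data.frame(
    unit_id = rep(units, lengths(session$spike_trains)),
    timestamp_ms = sprintf("%.3f", unlist(lapply(session$spike_trains, sort),
                                          use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session bundle
#'
#' Inverse of [write_session()]: reads and validates a session directory.
#' Malformed trial rows, unsorted spike trains and schema mismatches are
#' reported with the offending row or unit.
#'
#' @param path Directory written by [write_session()].
#' @return An `"ensemble_session"`.
#' @export
read_session <- function(path) {
  man_file <- file.path(path, "manifest.json")
  if (!file.exists(man_file)) stop("no manifest.json under ", path)
  manifest <- jsonlite::fromJSON(man_file)
  if (!identical(as.integer(manifest$schema_version), SCHEMA_VERSION)) {
    stop("schema version mismatch: file has ", manifest$schema_version,
         ", reader expects ", SCHEMA_VERSION)
  }
  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(trial_columns, "trial_class"), names(tr))
  if (length(missing)) {
    stop("trials.csv lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("t_ready", "t_cue", "t_extend", "t_press", "t_feedback")) {
    v <- suppressWarnings(as.numeric(tr[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("trials.csv row ", bad[1L], ": non-numeric '", col, "' value '",
           tr[[col]][bad[1L]], "'")
    }
    tr[[col]] <- v
  }
  bad <- which(!tr$outcome %in% c("success", "failure"))
  if (length(bad)) {
    stop("trials.csv row ", bad[1L], ": invalid outcome '",
         tr$outcome[bad[1L]], "'")
  }

  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        stringsAsFactors = FALSE)
  if (!all(c("unit_id", "timestamp_ms") %in% names(sp))) {
    stop("spikes.csv must have columns unit_id, timestamp_ms")
  }
  ts <- suppressWarnings(as.numeric(sp$timestamp_ms))
  bad <- which(!is.finite(ts))
  if (nrow(sp) && length(bad)) {
    stop("spikes.csv row ", bad[1L], ": non-numeric timestamp '",
         sp$timestamp_ms[bad[1L]], "'")
  }
  unit_ids <- manifest$unit_ids
  trains <- stats::setNames(vector("list", length(unit_ids)), unit_ids)
  for (u in unit_ids) trains[[u]] <- numeric(0)
  if (nrow(sp)) {
    unknown <- setdiff(unique(sp$unit_id), unit_ids)
    if (length(unknown)) {
      stop("spikes.csv contains unit(s) absent from the manifest: ",
           paste(unknown, collapse = ", "))
    }
    for (u in unique(sp$unit_id)) {
      v <- ts[sp$unit_id == u]
      if (is.unsorted(v)) stop("spike train of unit '", u, "' is not sorted")
      trains[[u]] <- v
    }
  }
  session(manifest$session_index, tr, trains, subject = manifest$subject)
}
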