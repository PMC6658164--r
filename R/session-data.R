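#' @name session-data
#' @title Session data model
#'
#' @description
#' A \code{bandit_session} holds one mouse-session of ordered trials together
#' with its metadata; a \code{session_set} is an ordered collection of
#' sessions with a provenance note. Trial and block indices are 1-based and
#' ranges inclusive throughout the package.
NULL

LINE_LEVELS <- c("D1R", "D2R")
TREATMENT_LEVELS <- c("CNO", "DMSO", "eGFP-CNO")
TASK_LEVELS <- c("TAB", "reversal")
SIDE_LEVELS <- c("L", "R")

# Exact CSV column order (documented external interface).
SESSION_CSV_COLUMNS <- c("mouse_id", "line", "treatment", "task", "stage",
                         "day", "block_index", "trial_index", "choice",
                         "reward", "duration", "high_side", "p_left",
                         "p_right")

#' Construct a session
#'
#' @param mouse_id Character animal id.
#' @param line Mouse line, \code{"D1R"} or \code{"D2R"}.
#' @param treatment \code{"CNO"}, \code{"DMSO"} or \code{"eGFP-CNO"}.
#' @param task \code{"TAB"} or \code{"reversal"}.
#' @param stage Reversal-task training stage 1-5, or \code{NA} for TAB.
#' @param day Positive integer session day.
#' @param trials data.frame with columns \code{trial_index},
#'   \code{block_index}, \code{choice} ("L"/"R"), \code{reward} (0/1),
#'   \code{duration} (seconds > 0) and \code{high_side} ("L"/"R": the side
#'   whose reward probability is currently higher, or the currently rewarded
#'   side in the reversal task).
#' @param block_probs For TAB sessions, a data.frame with columns
#'   \code{block}, \code{p_left}, \code{p_right} (one row per block);
#'   \code{NULL} for reversal sessions.
#' @return A validated \code{bandit_session}. \code{mean_duration} is always
#'   recomputed from the trial durations.
#' @export
session <- function(mouse_id, line, treatment, task, stage = NA, day,
                    trials, block_probs = NULL) {
  s <- structure(list(mouse_id = as.character(mouse_id),
                      line = as.character(line),
                      treatment = as.character(treatment),
                      task = as.character(task),
                      stage = if (is.na(stage)) NA_integer_ else as.integer(stage),
                      day = as.integer(day),
                      block_probs = block_probs,
                      trials = trials,
                      mean_duration = mean(trials$duration)),
                 class = "bandit_session")
  validate_session(s)
  s
}

#' Validate a session
#'
#' Checks the structural invariants of a single session: known enum values,
#' contiguous 1-based trial indices, non-decreasing block indices, rewards in
#' \{0, 1\}, positive durations, and (for TAB) that \code{block_probs} covers
#' exactly the blocks present. \code{mean_duration} is recomputed.
#'
#' @param s A \code{bandit_session}.
#' @return \code{s}, invisibly. Errors name the offending session.
#' @export
validate_session <- function(s) {
  id <- paste0(s$mouse_id, "/", s$task,
               if (!is.na(s$stage)) paste0("/stage", s$stage) else "",
               "/day", s$day, "/", s$treatment)
  fail <- function(...) stop("session ", id, ": ", ..., call. = FALSE)
  if (!s$line %in% LINE_LEVELS) fail("unknown line '", s$line, "'")
  if (!s$treatment %in% TREATMENT_LEVELS) {
    fail("unknown treatment '", s$treatment, "'")
  }
  if (!s$task %in% TASK_LEVELS) fail("unknown task '", s$task, "'")
  if (s$task == "reversal" &&
      (is.na(s$stage) || !(s$stage %in% 1:5))) {
    fail("reversal sessions need stage in 1..5")
  }
  if (is.na(s$day) || s$day < 1L) fail("day must be a positive integer")
  tr <- s$trials
  if (!is.data.frame(tr) || nrow(tr) == 0L) fail("no trials")
  needed <- c("trial_index", "block_index", "choice", "reward", "duration",
              "high_side")
  miss <- setdiff(needed, names(tr))
  if (length(miss)) fail("missing trial column(s): ", paste(miss, collapse = ", "))
  if (!identical(as.integer(tr$trial_index), seq_len(nrow(tr)))) {
    fail("trial_index values must be contiguous 1..N")
  }
  if (is.unsorted(tr$block_index)) fail("block_index must be non-decreasing")
  if (any(tr$block_index < 1L)) fail("block_index must be >= 1")
  if (!all(tr$choice %in% SIDE_LEVELS)) fail("choice values must be 'L' or 'R'")
  if (!all(tr$high_side %in% SIDE_LEVELS)) {
    fail("high_side values must be 'L' or 'R'")
  }
  if (!all(tr$reward %in% c(0L, 1L))) fail("reward values must be 0 or 1")
  if (!all(is.finite(tr$duration)) || any(tr$duration <= 0)) {
    fail("durations must be positive")
  }
  if (!is.null(s$block_probs)) {
    bp <- s$block_probs
    if (!setequal(bp$block, unique(tr$block_index)) ||
        nrow(bp) != length(unique(tr$block_index))) {
      fail("block_probs must have one row per distinct block_index")
    }
    if (any(bp$p_left < 0 | bp$p_left > 1 | bp$p_right < 0 | bp$p_right > 1)) {
      fail("block probabilities must lie in [0, 1]")
    }
  } else if (s$task == "TAB") {
    fail("TAB sessions require block_probs")
  }
  s$mean_duration <- mean(tr$duration)
  invisible(s)
}

#' @export
print.bandit_session <- function(x, ...) {
  cat(sprintf("<session %s %s %s %s day %d: %d trials, %d block(s), mean duration %.2f s>\n",
              x$mouse_id, x$line, x$treatment,
              if (x$task == "reversal") paste0("reversal stage ", x$stage) else "TAB",
              x$day, nrow(x$trials), length(unique(x$trials$block_index)),
              x$mean_duration))
  invisible(x)
}

#' Construct a session set
#'
#' @param sessions List of [session()] objects.
#' @param provenance Free-text provenance note (file path or generator
#'   description).
#' @return A validated \code{session_set}.
#' @export
session_set <- function(sessions = list(), provenance = "") {
  x <- structure(list(sessions = sessions,
                      provenance = as.character(provenance)),
                 class = "session_set")
  validate_session_set(x)
  x
}

#' Validate a session set
#'
#' Validates each member session and checks that the
#' (mouse_id, task, stage, day, treatment) keys are unique.
#'
#' @param x A \code{session_set}.
#' @return \code{x}, invisibly.
#' @export
validate_session_set <- function(x) {
  stopifnot(inherits(x, "session_set"))
  for (s in x$sessions) validate_session(s)
  if (length(x$sessions)) {
    keys <- vapply(x$sessions, function(s) {
      paste(s$mouse_id, s$task, s$stage, s$day, s$treatment, sep = "|")
    }, character(1))
    if (anyDuplicated(keys)) {
      stop("duplicate session key(s): ",
           paste(unique(keys[duplicated(keys)]), collapse = "; "),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set: %d session(s), %d trials>\n",
              length(x$sessions),
              sum(vapply(x$sessions, function(s) nrow(s$trials), integer(1)))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.session_set <- function(x) length(x$sessions)

#' Flatten a session set to one row per trial
#'
#' Produces the documented flat layout (session metadata repeated per row,
#' columns in the fixed CSV order).
#'
#' @param x A [session_set()].
#' @param ... Unused.
#' @return A data.frame with columns \code{mouse_id, line, treatment, task,
#'   stage, day, block_index, trial_index, choice, reward, duration,
#'   high_side, p_left, p_right}.
#' @export
as.data.frame.session_set <- function(x, ...) {
  if (length(x$sessions) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)),
                                     length(SESSION_CSV_COLUMNS)),
                                 SESSION_CSV_COLUMNS))
    return(df)
  }
  parts <- lapply(x$sessions, function(s) {
    tr <- s$trials
    if (!is.null(s$block_probs)) {
      idx <- match(tr$block_index, s$block_probs$block)
      p_left <- s$block_probs$p_left[idx]
      p_right <- s$block_probs$p_right[idx]
    } else {
      # reversal task: deterministic reward on the currently rewarded side
      p_left <- as.numeric(tr$high_side == "L")
      p_right <- as.numeric(tr$high_side == "R")
    }
    data.frame(mouse_id = s$mouse_id, line = s$line, treatment = s$treatment,
               task = s$task, stage = s$stage, day = s$day,
               block_index = tr$block_index, trial_index = tr$trial_index,
               choice = tr$choice, reward = tr$reward,
               duration = tr$duration, high_side = tr$high_side,
               p_left = p_left, p_right = p_right)
  })
  do.call(rbind, parts)
}

# Rebuild a session_set from the flat trial table.
sessions_from_df <- function(df, provenance = "") {
  miss <- setdiff(SESSION_CSV_COLUMNS, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(session_set(list(), provenance))
  key <- paste(df$mouse_id, df$task, df$stage, df$day, df$treatment, sep = "|")
  # preserve first-appearance order
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  sessions <- lapply(groups, function(rows) {
    g <- df[rows, , drop = FALSE]
    trials <- data.frame(trial_index = as.integer(g$trial_index),
                         block_index = as.integer(g$block_index),
                         choice = as.character(g$choice),
                         reward = as.integer(g$reward),
                         duration = as.numeric(g$duration),
                         high_side = as.character(g$high_side))
    ord <- order(trials$trial_index)
    trials <- trials[ord, , drop = FALSE]
    g <- g[ord, , drop = FALSE]
    # line is session metadata but not part of the grouping key
    if (length(unique(g$line)) > 1L) {
      stop("session ", g$mouse_id[1], "/", g$task[1], "/day", g$day[1], "/",
           g$treatment[1], ": inconsistent line within session",
           call. = FALSE)
    }
    if (anyDuplicated(trials$trial_index)) {
      stop("session ", g$mouse_id[1], "/", g$task[1], "/day", g$day[1], "/",
           g$treatment[1], ": duplicated trial_index ",
           trials$trial_index[duplicated(trials$trial_index)][1],
           call. = FALSE)
    }
    rownames(trials) <- NULL
    block_probs <- NULL
    if (g$task[1] == "TAB") {
      bp <- unique(data.frame(block = trials$block_index,
                              p_left = as.numeric(g$p_left),
                              p_right = as.numeric(g$p_right)))
      rownames(bp) <- NULL
      block_probs <- bp
    }
    session(mouse_id = g$mouse_id[1], line = g$line[1],
            treatment = g$treatment[1], task = g$task[1],
            stage = if (is.na(g$stage[1])) NA else g$stage[1],
            day = g$day[1], trials = trials, block_probs = block_probs)
  })
  names(sessions) <- NULL
  session_set(sessions, provenance)
}

#' Read sessions from disk
#'
#' Reads the documented flat CSV layout (one row per trial) or the nested
#' JSON layout, validates every session, and recomputes derived fields.
#'
#' @param path File path.
#' @param format \code{"csv"} or \code{"json"}; defaults to the file
#'   extension.
#' @return A validated [session_set()] with \code{provenance = path}.
#' @export
read_sessions <- function(path, format = c("csv", "json")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- if (missing(format)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  } else {
    match.arg(format)
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(mouse_id = "character"))
    return(sessions_from_df(df, provenance = path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- raw$sessions
  n_sess <- if (is.data.frame(sl)) nrow(sl) else 0L
  sessions <- lapply(seq_len(n_sess), function(i) {
    trials <- as.data.frame(sl$trials[[i]])
    trials$trial_index <- as.integer(trials$trial_index)
    trials$block_index <- as.integer(trials$block_index)
    trials$reward <- as.integer(trials$reward)
    trials$duration <- as.numeric(trials$duration)
    bp <- sl$block_probs[[i]]
    block_probs <- if (is.null(bp) || length(bp) == 0L ||
                       (is.data.frame(bp) && nrow(bp) == 0L)) {
      NULL
    } else {
      data.frame(block = as.integer(bp$block), p_left = as.numeric(bp$p_left),
                 p_right = as.numeric(bp$p_right))
    }
    session(mouse_id = sl$mouse_id[i], line = sl$line[i],
            treatment = sl$treatment[i], task = sl$task[i],
            stage = sl$stage[i], day = sl$day[i],
            trials = trials, block_probs = block_probs)
  })
  session_set(sessions, provenance = path)
}

#' Write sessions to disk
#'
#' CSV emits the flat one-row-per-trial layout with a fixed column order;
#' JSON emits nested sessions. Both round-trip through [read_sessions()]
#' field-for-field.
#'
#' @param x A [session_set()].
#' @param path Output file path.
#' @param format \code{"csv"} or \code{"json"}; defaults to the file
#'   extension.
#' @return \code{path}, invisibly.
#' @export
write_sessions <- function(x, path, format = c("csv", "json")) {
  validate_session_set(x)
  format <- if (missing(format)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  } else {
    match.arg(format)
  }
  if (format == "csv") {
    df <- as.data.frame(x)
    write.csv(df[, SESSION_CSV_COLUMNS, drop = FALSE], path,
              row.names = FALSE)
  } else {
    payload <- list(
      provenance = x$provenance,
      sessions = lapply(x$sessions, function(s) {
        list(mouse_id = s$mouse_id, line = s$line, treatment = s$treatment,
             task = s$task, stage = s$stage, day = s$day,
             block_probs = s$block_probs, trials = s$trials)
      }))
    jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

# Mean trial duration of each session in a list.
session_mean_durations <- function(sessions) {
  vapply(sessions, `[[`, numeric(1), "mean_duration")
}
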