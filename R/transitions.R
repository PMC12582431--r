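#' Classify inter-keystroke transitions by text location and mode
#'
#' Pairs temporally consecutive keypresses and labels each pair with a
#' transition type following the typing-action taxonomy: `within-word`
#' (letter then letter), `post-word` (letter then space; always merged into
#' the `within-word` location), `pre-word` (space then letter, mid-sentence),
#' `pre-sentence` (space then letter where the character preceding the space
#' is sentence-terminating punctuation), and the editing types `word->edit`,
#' `pre-word->edit`, `pre-sentence->edit` (the following keypress initiates
#' deletion or cursor movement). Conventions the taxonomy leaves open are
#' resolved as follows and applied consistently by the session generator:
#'
#' * Any non-space typed character (including digits, punctuation and
#'   sentence terminators) counts as letter-like for preceding-context
#'   purposes; terminators play their special role only as the character
#'   before a space.
#' * Shifted capitals take two keypresses; the transition into the capital
#'   ends at the *shift* keypress, the transition out of it starts at the
#'   character keypress.
#' * A run of cursor moves that returns the cursor exactly to its prior
#'   position with no intervening text change (a scrolling strategy during
#'   lookback) is absorbed: the surrounding keypresses form a single
#'   non-editing transition at the appropriate location.
#' * Pairs that begin with an editing action, space-after-space pairs, and
#'   pairs involving only mouse movement are tagged `other` and excluded
#'   from analysis.
#'
#' @param events editor event data.frame for one session (see [replay()]).
#' @param timeline optional `document_timeline`; replayed from `events` when
#'   missing.
#' @return data.frame with one row per consecutive keypress pair:
#'   `transition_id`, `t_first`, `t_second`, `iki` (ms), `raw_type`,
#'   `location` (`pre-sentence`, `pre-word`, `within-word`, or `NA` for
#'   `other`), `mode` (`writing`/`editing`), and first/second event indices.
#'   Columns `participant`/`language` are carried through when present.
#' @export
classify_transitions <- function(events, timeline = NULL) {
  if (is.null(timeline)) timeline <- replay(events)
  n <- nrow(events)
  kp <- .keypress_stream(events, timeline)
  m <- nrow(kp)
  out <- data.frame(
    transition_id = integer(0), t_first = numeric(0), t_second = numeric(0),
    iki = numeric(0), raw_type = character(0), location = character(0),
    mode = character(0), first_event = integer(0), second_event = integer(0),
    stringsAsFactors = FALSE)
  if (m >= 2) {
    rows <- vector("list", m - 1L)
    for (i in seq_len(m - 1L)) {
      k1 <- kp[i, ]
      k2 <- kp[i + 1L, ]
      raw <- .pair_raw_type(k1, k2, timeline)
      loc <- .raw_location(raw)
      rows[[i]] <- data.frame(
        transition_id = i, t_first = k1$t_out, t_second = k2$t_in,
        iki = k2$t_in - k1$t_out, raw_type = raw, location = loc,
        mode = if (endsWith(raw, "->edit")) "editing" else
          if (raw == "other") NA_character_ else "writing",
        first_event = k1$event_idx, second_event = k2$event_idx,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  }
  for (col in c("participant", "language")) {
    if (col %in% names(events) && n > 0) {
      out[[col]] <- events[[col]][1]
    }
  }
  out
}

# Reduce the raw event stream to a keypress stream: merge shift+insert into a
# single keystroke timed at the shift, drop mouse moves and cursor-return
# excursions, and mark each keypress as a typed character or an edit action.
.keypress_stream <- function(events, timeline) {
  n <- nrow(events)
  keep <- rep(TRUE, n)
  t_in <- as.numeric(events$t_ms)   # time ending the incoming transition
  t_out <- as.numeric(events$t_ms)  # time starting the outgoing transition
  act <- events$action
  # shift followed by an insert: one keystroke; the incoming transition ends
  # at the shift keypress, the outgoing one starts at the character keypress
  for (i in seq_len(n)) {
    if (act[i] == "shift") {
      if (i < n && act[i + 1L] == "insert") {
        t_in[i + 1L] <- t_in[i]
      }
      keep[i] <- FALSE
    }
  }
  keep[act == "mouse_move"] <- FALSE
  # cursor-move runs that return to their starting position with no edit
  i <- 1L
  while (i <= n) {
    if (keep[i] && act[i] == "cursor_move") {
      j <- i
      while (j < n && act[j + 1L] %in% c("cursor_move", "mouse_move")) j <- j + 1L
      start_pos <- events$cursor_before[i]
      end_pos <- events$cursor_after[j]
      last_cm <- max(which(act[i:j] == "cursor_move")) + i - 1L
      if (!is.na(start_pos) && !is.na(end_pos) &&
          events$cursor_after[last_cm] == start_pos) {
        keep[i:j] <- FALSE
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx <- which(keep)
  kind <- ifelse(act[idx] == "insert", "char", "edit")
  data.frame(event_idx = idx, t_in = t_in[idx], t_out = t_out[idx],
             kind = kind,
             ch = ifelse(act[idx] == "insert", events$payload[idx], NA),
             stringsAsFactors = FALSE)
}

.char_before_space <- function(k1, timeline) {
  # character preceding the space typed by keypress k1, in the text state
  # immediately after k1 was applied
  txt <- timeline$text[k1$event_idx]
  pos <- timeline$cursor[k1$event_idx] - 1L  # 0-based index of the space
  if (pos < 1) return("")
  substr(txt, pos, pos)  # 1-based substr of char at 0-based pos-1
}

.pair_raw_type <- function(k1, k2, timeline) {
  if (k2$kind == "char") {
    if (k1$kind != "char") return("other")
    if (k1$ch == " ") {
      if (k2$ch == " ") return("other")
      prev <- .char_before_space(k1, timeline)
      if (prev %in% c(".", "?", "!")) return("pre-sentence")
      return("pre-word")
    }
    if (k2$ch == " ") return("post-word")
    return("within-word")
  }
  # k2 is an editing action
  if (k1$kind != "char") return("other")
  if (k1$ch == " ") {
    prev <- .char_before_space(k1, timeline)
    if (prev %in% c(".", "?", "!")) return("pre-sentence->edit")
    if (prev == "" || prev == " ") return("other")
    return("pre-word->edit")
  }
  "word->edit"
}

.raw_location <- function(raw) {
  switch(raw,
    "within-word" = ,
    "post-word" = ,
    "word->edit" = "within-word",
    "pre-word" = ,
    "pre-word->edit" = "pre-word",
    "pre-sentence" = ,
    "pre-sentence->edit" = "pre-sentence",
    NA_character_)
}

#' Production sequences: keystroke runs terminated by editing actions
#'
#' A production sequence is a run of typed characters delimited by editing
#' actions (deletions or cursor moves); its mean length indexes production
#' fluency. Sequence lengths partition the writing keystrokes of a session.
#'
#' @inheritParams classify_transitions
#' @return data.frame with one row per sequence: `sequence_id`, `length`
#'   (keystrokes), `terminated_by_edit` (the final run of a session is kept
#'   but flagged `FALSE`), plus `participant`/`language` when present.
#' @export
production_sequences <- function(events, timeline = NULL) {
  if (is.null(timeline)) timeline <- replay(events)
  kp <- .keypress_stream(events, timeline)
  is_char <- kp$kind == "char"
  out <- data.frame(sequence_id = integer(0), length = integer(0),
                    terminated_by_edit = logical(0))
  if (nrow(kp) > 0) {
    r <- rle(is_char)
    runs <- which(r$values)
    if (length(runs) > 0) {
      ends <- cumsum(r$lengths)
      out <- data.frame(
        sequence_id = seq_along(runs),
        length = r$lengths[runs],
        terminated_by_edit = ends[runs] < nrow(kp))
    }
  }
  for (col in c("participant", "language")) {
    if (col %in% names(events) && nrow(events) > 0) out[[col]] <- events[[col]][1]
  }
  out
}

#' Filter inter-keystroke intervals to the analysis window
#'
#' Removes transition durations at the tails: very short intervals
#' (typically two keys pressed at once) and very long ones (extended reading
#' or off-task activity). A transition is retained iff
#' `min_iki_ms < iki < max_iki_ms`.
#'
#' @param transitions data.frame from [classify_transitions()].
#' @param min_iki_ms lower cut (default 50 ms, removed inclusively).
#' @param max_iki_ms upper cut (default 30000 ms, removed inclusively).
#' @return list with `transitions` (retained rows) and `report`
#'   (per participant x language: counts and percentages excluded at each
#'   tail).
#' @export
filter_ikis <- function(transitions, min_iki_ms = 50, max_iki_ms = 30000) {
  low <- transitions$iki <= min_iki_ms
  high <- transitions$iki >= max_iki_ms
  keep <- !low & !high
  grp <- interaction(
    if ("participant" %in% names(transitions)) transitions$participant else "all",
    if ("language" %in% names(transitions)) transitions$language else "all",
    drop = TRUE)
  report <- do.call(rbind, lapply(split(seq_len(nrow(transitions)), grp), function(ix) {
    data.frame(group = as.character(grp[ix[1]]), n = length(ix),
               n_low = sum(low[ix]), n_high = sum(high[ix]),
               pct_low = 100 * mean(low[ix]), pct_high = 100 * mean(high[ix]))
  }))
  rownames(report) <- NULL
  list(transitions = transitions[keep, , drop = FALSE], report = report)
}

#' Cap per-cell observation counts by seeded random subsampling
#'
#' Within each participant x language x location x mode cell, cells with
#' more than `cap` transitions are reduced to exactly `cap` by uniform
#' sampling without replacement; smaller cells are untouched. Sampling is
#' deterministic given `seed`.
#'
#' @param transitions classified transitions data.frame.
#' @param cap maximum observations per cell (default 200).
#' @param seed integer seed for the subsampling RNG.
#' @return The subsampled transitions data.frame (original row order).
#' @export
subsample_cell <- function(transitions, cap = 200, seed = 1L) {
  if (!is.numeric(cap) || cap < 1) stop("cap must be >= 1")
  cols <- intersect(c("participant", "language", "location", "mode"),
                    names(transitions))
  grp <- interaction(transitions[cols], drop = TRUE)
  keep <- logical(nrow(transitions))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (ix in split(seq_len(nrow(transitions)), grp)) {
    if (length(ix) > cap) {
      keep[sample(ix, cap)] <- TRUE
    } else {
      keep[ix] <- TRUE
    }
  }
  transitions[keep, , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
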