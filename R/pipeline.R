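#' Process one session end to end
#'
#' Replays the event log, anchors the fixation stream against the evolving
#' text, classifies transitions, and detects lookback events on writing
#' transitions. This is the per-session path behind the analysis scripts.
#'
#' @param session a `writing_session` (or a list with `events` and
#'   `fixations` data.frames).
#' @param layout [layout_model()] used to anchor screen-coordinate
#'   fixations.
#' @param criteria lookback thresholds, see [lookback_criteria()].
#' @return list with `timeline`, `transitions` (with lookback columns on
#'   writing rows), `all_transitions` (including editing/other rows),
#'   `anchored_fixations`, `production` (production-sequence table), and
#'   `final_text`.
#' @export
process_session <- function(session, layout = layout_model(),
                            criteria = lookback_criteria()) {
  timeline <- replay(session$events)
  anchored <- anchor_fixations(session$fixations, timeline, layout)
  trans <- classify_transitions(session$events, timeline)
  lb <- lookback_events(trans, anchored, criteria)
  list(timeline = timeline,
       transitions = lb,
       all_transitions = trans,
       anchored_fixations = anchored,
       production = production_sequences(session$events, timeline),
       final_text = if (length(timeline$text) > 0) {
         timeline$text[length(timeline$text)]
       } else "")
}

#' Process a cohort of sessions into stacked analysis tables
#'
#' @param sessions list of `writing_session` objects (see
#'   [generate_cohort()]).
#' @inheritParams process_session
#' @return list of stacked data.frames: `transitions` (writing transitions
#'   with lookback columns), `all_transitions`, `production`, and `texts`
#'   (one row per session with the final text).
#' @export
cohort_tables <- function(sessions, layout = layout_model(),
                          criteria = lookback_criteria()) {
  res <- lapply(sessions, process_session, layout = layout,
                criteria = criteria)
  texts <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    data.frame(participant = sessions[[i]]$participant,
               language = sessions[[i]]$language,
               text = res[[i]]$final_text, stringsAsFactors = FALSE)
  }))
  list(transitions = do.call(rbind, lapply(res, `[[`, "transitions")),
       all_transitions = do.call(rbind, lapply(res, `[[`, "all_transitions")),
       production = do.call(rbind, lapply(res, `[[`, "production")),
       texts = texts)
}

#' Editing counts per participant, language and location
#'
#' Tabulates classified transitions into writing/editing counts per cell,
#' the input to the binomial editing model.
#'
#' @param transitions stacked classified transitions (all rows).
#' @return data.frame with `participant`, `language`, `location`,
#'   `successes` (editing transitions), `trials` (all classified
#'   transitions at that location).
#' @export
editing_counts <- function(transitions) {
  tr <- transitions[!is.na(transitions$location), , drop = FALSE]
  agg <- stats::aggregate(
    cbind(successes = tr$mode == "editing", trials = 1L),
    by = list(participant = tr$participant, language = tr$language,
              location = tr$location), FUN = sum)
  agg[order(agg$participant, agg$language, agg$location), ]
}

#' Lookback counts per participant, language and location
#'
#' @param transitions writing transitions with lookback columns (see
#'   [lookback_events()]).
#' @return data.frame with `successes` (lookback transitions) and `trials`
#'   (writing transitions) per cell.
#' @export
lookback_counts <- function(transitions) {
  tr <- transitions[!is.na(transitions$location), , drop = FALSE]
  agg <- stats::aggregate(
    cbind(successes = tr$lookback, trials = 1L),
    by = list(participant = tr$participant, language = tr$language,
              location = tr$location), FUN = sum)
  agg[order(agg$participant, agg$language, agg$location), ]
}
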