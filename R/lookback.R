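#' Default thresholds of the lookback definition
#'
#' A lookback event is a sequence of two or more fixations occurring between
#' the two keypresses of a writing transition where (a) fixations lie at a
#' median distance of at least `min_word_dist` words *and* at least
#' `min_char_dist` characters behind the point of inscription, (b) more than
#' `behind_frac` of fixations in the sequence fall within text preceding the
#' point of inscription, (c) the sequence does not start with a fixation on
#' the writing prompt, and (d) fewer than `prompt_frac` of fixations are on
#' the prompt. The thresholds are exposed for sensitivity analysis.
#'
#' @param min_word_dist minimum median word distance behind (default 1).
#' @param min_char_dist minimum median character distance behind (default 5).
#' @param behind_frac required fraction of behind fixations, exclusive
#'   (default 0.8).
#' @param prompt_frac maximum fraction of prompt fixations, exclusive
#'   (default 0.5).
#' @return list of thresholds.
#' @export
lookback_criteria <- function(min_word_dist = 1, min_char_dist = 5,
                              behind_frac = 0.8, prompt_frac = 0.5) {
  list(min_word_dist = min_word_dist, min_char_dist = min_char_dist,
       behind_frac = behind_frac, prompt_frac = prompt_frac)
}

#' Detect a lookback event within one transition window
#'
#' Evaluates the four lookback criteria (see [lookback_criteria()]) on the
#' maximal sequence of anchored fixations whose onsets fall in
#' `[t_first, t_second)` of the transition. Medians in criterion (a) are
#' taken over the signed distances of in-text fixations (prompt and
#' off-text fixations have no text distance but count in the denominators
#' of criteria (b) and (d)); "behind" means strictly before the point of
#' inscription.
#'
#' @param transition a single-row data.frame with `t_first`, `t_second`
#'   (and, for depth interpretation, `location`).
#' @param fixations anchored fixations for the session (see
#'   [anchor_fixations()]); an error is raised if anchoring columns are
#'   missing.
#' @param criteria thresholds from [lookback_criteria()].
#' @return A list of class `lookback_event` with the member fixations and
#'   metrics (`duration_ms`, `n_fixations`, `words_fixated`,
#'   `sentence_depth` — `NA` when the modal sentence is tied), or `NULL`
#'   when the window does not qualify.
#' @export
detect_lookback <- function(transition, fixations,
                            criteria = lookback_criteria()) {
  need <- c("t_start_ms", "duration_ms", "on_prompt", "in_text",
            "char_dist", "word_dist", "sentence_dist")
  miss <- setdiff(need, names(fixations))
  if (length(miss) > 0) {
    stop("fixations are not anchored (missing: ",
         paste(miss, collapse = ", "), "); run anchor_fixations() first")
  }
  win <- fixations[fixations$t_start_ms >= transition$t_first &
                     fixations$t_start_ms < transition$t_second, ,
                   drop = FALSE]
  win <- win[order(win$t_start_ms), , drop = FALSE]
  n <- nrow(win)
  if (n < 2) return(NULL)
  intext <- win$in_text & !win$on_prompt
  behind <- intext & !is.na(win$char_dist) & win$char_dist > 0
  # (a) median word and character distance behind
  if (!any(intext)) return(NULL)
  med_w <- stats::median(win$word_dist[intext])
  med_c <- stats::median(win$char_dist[intext])
  if (is.na(med_w) || is.na(med_c) ||
      med_w < criteria$min_word_dist || med_c < criteria$min_char_dist) {
    return(NULL)
  }
  # (b) share of fixations behind the point of inscription
  if (!(mean(behind) > criteria$behind_frac)) return(NULL)
  # (c) must not start on the prompt
  if (isTRUE(win$on_prompt[1])) return(NULL)
  # (d) prompt share
  if (!(mean(win$on_prompt) < criteria$prompt_frac)) return(NULL)

  structure(list(
    transition_id = transition$transition_id %||% NA_integer_,
    fixations = win,
    n_fixations = n,
    duration_ms = lookback_duration(win),
    words_fixated = words_fixated(win),
    sentence_depth = sentence_depth(win)
  ), class = "lookback_event")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total lookback duration
#'
#' The sum of the durations of all fixations in the lookback sequence.
#'
#' @param event a `lookback_event`, or a data.frame of member fixations.
#' @return duration in ms.
#' @export
lookback_duration <- function(event) {
  fx <- if (inherits(event, "lookback_event")) event$fixations else event
  sum(fx$duration_ms)
}

#' Number of words fixated during a lookback
#'
#' Counts word entries: every time gaze moves to (and fixates) a different
#' word counts, including re-entries to a previously fixated word;
#' consecutive fixations on the same word count once. Only in-text
#' fixations carry a word identity.
#'
#' @inheritParams lookback_duration
#' @return integer count (0 if no in-text fixations).
#' @export
words_fixated <- function(event) {
  fx <- if (inherits(event, "lookback_event")) event$fixations else event
  w <- fx$word_idx[fx$in_text & !fx$on_prompt & !is.na(fx$word_idx)]
  if (length(w) == 0) return(0L)
  length(rle(w)$lengths)
}

#' Depth of lookback in sentences
#'
#' The distance, in sentences, of the modal (most-fixated) sentence from the
#' sentence containing the point of inscription (same sentence = 0, previous
#' sentence = 1, ...). Sequences where two or more sentences tie for the
#' most fixations have no single modal value and return `NA` (excluded from
#' depth analysis). For transitions at sentence boundaries the minimum
#' attainable distance is 1.
#'
#' @inheritParams lookback_duration
#' @return sentence distance, or `NA` on a tie or when no fixation has a
#'   sentence assignment.
#' @export
sentence_depth <- function(event) {
  fx <- if (inherits(event, "lookback_event")) event$fixations else event
  sd_ <- fx$sentence_dist[fx$in_text & !fx$on_prompt & !is.na(fx$sentence_dist)]
  if (length(sd_) == 0) return(NA_real_)
  tab <- table(sd_)
  mx <- max(tab)
  modal <- names(tab)[tab == mx]
  if (length(modal) > 1) return(NA_real_)
  as.numeric(modal)
}

#' @export
print.lookback_event <- function(x, ...) {
  cat(sprintf(
    "<lookback_event> %d fixations, %.0f ms, %d words fixated, depth %s\n",
    x$n_fixations, x$duration_ms, x$words_fixated,
    ifelse(is.na(x$sentence_depth), "tied", x$sentence_depth)))
  invisible(x)
}

#' Detect lookback events for a table of transitions
#'
#' Applies [detect_lookback()] to every *writing* transition (editing
#' transitions trivially involve looking back to the edit site and are
#' excluded from lookback analysis).
#'
#' @param transitions classified transitions data.frame.
#' @param fixations anchored fixations for the same session.
#' @param criteria thresholds from [lookback_criteria()].
#' @return `transitions` restricted to writing rows, with columns `lookback`
#'   (logical), `lb_duration_ms`, `lb_n_fixations`, `lb_words_fixated`,
#'   `lb_sentence_depth` appended.
#' @export
lookback_events <- function(transitions, fixations,
                            criteria = lookback_criteria()) {
  tr <- transitions[!is.na(transitions$mode) & transitions$mode == "writing", ,
                    drop = FALSE]
  n <- nrow(tr)
  tr$lookback <- FALSE
  tr$lb_duration_ms <- NA_real_
  tr$lb_n_fixations <- NA_integer_
  tr$lb_words_fixated <- NA_integer_
  tr$lb_sentence_depth <- NA_real_
  if (n == 0) return(tr)
  for (i in seq_len(n)) {
    ev <- detect_lookback(tr[i, ], fixations, criteria)
    if (!is.null(ev)) {
      tr$lookback[i] <- TRUE
      tr$lb_duration_ms[i] <- ev$duration_ms
      tr$lb_n_fixations[i] <- ev$n_fixations
      tr$lb_words_fixated[i] <- ev$words_fixated
      tr$lb_sentence_depth[i] <- ev$sentence_depth
    }
  }
  tr
}
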