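#' Replay an editor event log into a time-indexed document model
#'
#' Applies editor events (character insertions, deletions, cursor moves) in
#' temporal order and records the document text, cursor position and point of
#' inscription after every event, so that the text state at any instant of the
#' session can be queried. The point of inscription is the 0-based index of
#' the last-typed (or last-deleted-before) character; it is updated by
#' text-modifying events only, so cursor excursions used for reading do not
#' move it.
#'
#' Character indices are 0-based; delete ranges are half-open `[start, end)`.
#'
#' @param events data.frame of editor events for a single session, with
#'   columns `t_ms`, `action` (one of `insert`, `backspace`, `delete_range`,
#'   `cursor_move`, `mouse_move`, `shift`), `payload`, `cursor_before`,
#'   `cursor_after`. Times must be non-decreasing.
#' @return An object of class `document_timeline`: a list with `t` (time of
#'   each event), `text` (document text after each event), `poi` (point of
#'   inscription after each event), `cursor`, and the original `events`.
#' @examples
#' ev <- data.frame(
#'   t_ms = c(0, 200, 400), action = "insert", payload = c("h", "i", "!"),
#'   cursor_before = 0:2, cursor_after = 1:3
#' )
#' tl <- replay(ev)
#' text_at(tl, 250)  # "hi"
#' @export
replay <- function(events) {
  stopifnot(is.data.frame(events))
  req <- c("t_ms", "action", "payload", "cursor_before", "cursor_after")
  miss <- setdiff(req, names(events))
  if (length(miss) > 0) {
    stop("event stream is missing columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(events)
  if (n > 0 && any(diff(events$t_ms) < 0)) {
    bad <- which(diff(events$t_ms) < 0)[1] + 1L
    stop("event timestamps out of order at event ", bad)
  }
  text <- character(n)
  poi <- integer(n)
  cursor <- integer(n)
  doc <- ""
  cur <- 0L
  p <- 0L
  for (i in seq_len(n)) {
    act <- events$action[i]
    pay <- events$payload[i]
    if (act == "insert") {
      at <- events$cursor_before[i]
      if (is.na(at)) at <- cur
      if (at < 0 || at > nchar(doc)) {
        stop("replay error at event ", i, ": insert position ", at,
             " outside document of length ", nchar(doc))
      }
      doc <- paste0(substr(doc, 1, at), pay,
                    substr(doc, at + 1, nchar(doc)))
      cur <- at + nchar(pay)
      p <- cur - 1L
    } else if (act == "backspace") {
      at <- events$cursor_before[i]
      if (is.na(at)) at <- cur
      if (at < 1 || at > nchar(doc)) {
        stop("replay error at event ", i, ": backspace at position ", at,
             " outside document of length ", nchar(doc))
      }
      doc <- paste0(substr(doc, 1, at - 1), substr(doc, at + 1, nchar(doc)))
      cur <- at - 1L
      p <- cur - 1L
    } else if (act == "delete_range") {
      rng <- as.integer(strsplit(pay, ":", fixed = TRUE)[[1]])
      if (length(rng) != 2 || anyNA(rng) || rng[1] < 0 || rng[2] < rng[1] ||
          rng[2] > nchar(doc)) {
        stop("replay error at event ", i, ": invalid delete range '", pay,
             "' for document of length ", nchar(doc))
      }
      doc <- paste0(substr(doc, 1, rng[1]), substr(doc, rng[2] + 1, nchar(doc)))
      cur <- rng[1]
      p <- cur - 1L
    } else if (act == "cursor_move") {
      tgt <- suppressWarnings(as.integer(pay))
      if (is.na(tgt)) tgt <- events$cursor_after[i]
      if (is.na(tgt) || tgt < 0 || tgt > nchar(doc)) {
        stop("replay error at event ", i, ": cursor target outside document")
      }
      cur <- tgt
    } else if (act %in% c("mouse_move", "shift")) {
      # no effect on document state
    } else {
      stop("replay error at event ", i, ": unknown action '", act, "'")
    }
    text[i] <- doc
    cursor[i] <- cur
    poi[i] <- max(0L, p)
  }
  structure(
    list(t = as.numeric(events$t_ms), text = text, poi = poi,
         cursor = cursor, events = events),
    class = "document_timeline"
  )
}

#' @export
print.document_timeline <- function(x, ...) {
  n <- length(x$t)
  cat("<document_timeline>", n, "events,",
      if (n > 0) sprintf("final text %d chars", nchar(x$text[n])) else "empty",
      "\n")
  invisible(x)
}

.snapshot_index <- function(timeline, t) {
  # index of last event with time <= t; 0 means before any event
  findInterval(t, timeline$t)
}

#' Query the document text at a given time
#'
#' @param timeline a `document_timeline` from [replay()].
#' @param t time in ms.
#' @return The document text as it existed at time `t` (text is a pure
#'   function of the events with time `<= t`).
#' @export
text_at <- function(timeline, t) {
  i <- .snapshot_index(timeline, t)
  ifelse(i == 0, "", timeline$text[pmax(i, 1L)])
}

#' Query the point of inscription at a given time
#'
#' @inheritParams text_at
#' @return 0-based character index of the last-typed character at time `t`.
#' @export
poi_at <- function(timeline, t) {
  i <- .snapshot_index(timeline, t)
  ifelse(i == 0, 0L, timeline$poi[pmax(i, 1L)])
}

#' Segment text into words, sentences and paragraphs
#'
#' Words are maximal non-whitespace runs. A sentence ends at a terminator
#' (`.`, `?`, `!`) that is followed by whitespace or end-of-text; the next
#' word starts the next sentence. Paragraphs are delimited by newline
#' characters. Indices are 0-based and stable under appending text.
#'
#' @param text a single string.
#' @return A list with `words` (data.frame: `word`, `start`, `end` half-open
#'   character range, `sentence`, `paragraph`), `n_words`, `n_sentences`,
#'   `n_paragraphs`, and `char_sentence`/`char_paragraph` (per-character
#'   0-based sentence/paragraph index, for anchoring arbitrary positions).
#' @examples
#' s <- segment("The dog barked. Then it ran away.")
#' s$n_words      # 7
#' s$n_sentences  # 2
#' @export
segment <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  nc <- nchar(text)
  if (nc == 0 || !grepl("\\S", text)) {
    empty <- data.frame(word = character(), start = integer(),
                        end = integer(), sentence = integer(),
                        paragraph = integer())
    return(list(words = empty, n_words = 0L, n_sentences = 0L,
                n_paragraphs = 0L,
                char_sentence = integer(nc), char_paragraph = integer(nc)))
  }
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  is_ws <- grepl("\\s", ch)
  is_term <- ch %in% c(".", "?", "!")
  # terminator position closing a sentence: followed by whitespace or EOT
  term_end <- is_term & c(is_ws[-1], TRUE)
  char_sentence <- c(0L, head(cumsum(term_end), -1L))
  char_paragraph <- c(0L, head(cumsum(ch == "\n"), -1L))
  m <- gregexpr("\\S+", text)[[1]]
  starts <- as.integer(m) - 1L           # 0-based
  lens <- attr(m, "match.length")
  words <- data.frame(
    word = regmatches(text, gregexpr("\\S+", text))[[1]],
    start = starts,
    end = starts + lens,
    sentence = char_sentence[starts + 1L],
    paragraph = char_paragraph[starts + 1L],
    stringsAsFactors = FALSE
  )
  list(words = words,
       n_words = nrow(words),
       n_sentences = length(unique(words$sentence)),
       n_paragraphs = length(unique(words$paragraph)),
       char_sentence = char_sentence,
       char_paragraph = char_paragraph)
}

#' Fixed-grid monospace layout model
#'
#' Maps linear 0-based character indices to nominal screen coordinates and
#' back, standing in for the editor's rendering. The text area starts at
#' (`x0_px`, `y0_px`); everything above `y0_px` is the writing-prompt region.
#' Lines wrap every `chars_per_line` characters.
#'
#' @param chars_per_line characters per display line.
#' @param px_per_char horizontal pixels per character cell.
#' @param px_per_line vertical pixels per line.
#' @param x0_px left edge of the text area.
#' @param y0_px top edge of the text area; the prompt occupies `y < y0_px`.
#' @return An object of class `layout_model`.
#' @export
layout_model <- function(chars_per_line = 80L, px_per_char = 12,
                         px_per_line = 30, x0_px = 0, y0_px = 120) {
  stopifnot(chars_per_line >= 1, px_per_char > 0, px_per_line > 0)
  structure(list(chars_per_line = as.integer(chars_per_line),
                 px_per_char = px_per_char, px_per_line = px_per_line,
                 x0_px = x0_px, y0_px = y0_px),
            class = "layout_model")
}

#' Convert character indices to screen coordinates (cell centres)
#' @param layout a [layout_model()].
#' @param idx 0-based character indices.
#' @return data.frame with `x_px`, `y_px`.
#' @export
char_to_xy <- function(layout, idx) {
  line <- idx %/% layout$chars_per_line
  col <- idx %% layout$chars_per_line
  data.frame(x_px = layout$x0_px + (col + 0.5) * layout$px_per_char,
             y_px = layout$y0_px + (line + 0.5) * layout$px_per_line)
}

#' Convert screen coordinates to a character index
#' @inheritParams char_to_xy
#' @param x_px,y_px screen coordinates.
#' @return 0-based character indices (`NA` for coordinates in the prompt
#'   region or left of the text area).
#' @export
xy_to_char <- function(layout, x_px, y_px) {
  col <- floor((x_px - layout$x0_px) / layout$px_per_char)
  line <- floor((y_px - layout$y0_px) / layout$px_per_line)
  idx <- line * layout$chars_per_line + col
  idx[y_px < layout$y0_px | col < 0 | col >= layout$chars_per_line] <- NA
  as.integer(idx)
}

#' Map fixations onto the text as it existed at fixation time
#'
#' Each fixation is located in the document state at its onset time
#' (`text_at(timeline, t_start_ms)`), assigned the word, sentence and
#' paragraph it falls in, and given distances behind the point of
#' inscription. Distances are signed: positive when the fixation is behind
#' (before) the point of inscription, negative when ahead. The character
#' distance is measured from the fixated character itself to the last-typed
#' character; the word distance counts word boundaries between the fixated
#' word and the word containing the point of inscription.
#'
#' Fixations that already carry a `char_idx` column are treated as
#' text-anchored and bypass the layout model; otherwise `x_px`/`y_px` are
#' converted through `layout`. Fixations whose onset precedes the first
#' event are skipped (counted in the `n_skipped` attribute).
#'
#' @param fixations data.frame with `t_start_ms`, `duration_ms`, and either
#'   `char_idx` (0-based, text-anchored) or `x_px`,`y_px`; an optional
#'   logical `on_prompt` forces prompt assignment.
#' @param timeline a `document_timeline`.
#' @param layout a [layout_model()]; required when fixations carry screen
#'   coordinates.
#' @return data.frame of anchored fixations: the input columns plus
#'   `on_prompt`, `in_text`, `ahead`, `char_idx`, `word_idx`,
#'   `sentence_idx`, `paragraph_idx`, `char_dist`, `word_dist`,
#'   `sentence_dist` (all distances signed, `NA` off-text/prompt), with
#'   attribute `n_skipped`.
#' @export
anchor_fixations <- function(fixations, timeline, layout = layout_model()) {
  stopifnot(is.data.frame(fixations))
  n0 <- nrow(fixations)
  if (n0 == 0) {
    out <- cbind(fixations,
                 data.frame(on_prompt = logical(0), in_text = logical(0),
                            ahead = logical(0), char_idx = integer(0),
                            word_idx = integer(0), sentence_idx = integer(0),
                            paragraph_idx = integer(0), char_dist = integer(0),
                            word_dist = integer(0), sentence_dist = integer(0)))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  t0 <- if (length(timeline$t) > 0) timeline$t[1] else Inf
  keep <- fixations$t_start_ms >= t0
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning(n_skipped, " fixation(s) before session start skipped")
  }
  fx <- fixations[keep, , drop = FALSE]
  n <- nrow(fx)
  anchored_input <- "char_idx" %in% names(fx) && !all(is.na(fx$char_idx))
  prompt_flag <- if ("on_prompt" %in% names(fx)) {
    as.logical(fx$on_prompt)
  } else {
    rep(FALSE, n)
  }
  if (anchored_input) {
    cidx <- as.integer(fx$char_idx)
  } else {
    if (!all(c("x_px", "y_px") %in% names(fx))) {
      stop("fixations need either char_idx or x_px/y_px coordinates")
    }
    cidx <- xy_to_char(layout, fx$x_px, fx$y_px)
    prompt_flag <- prompt_flag | (fx$y_px < layout$y0_px)
  }
  snap <- .snapshot_index(timeline, fx$t_start_ms)
  on_prompt <- prompt_flag
  in_text <- logical(n)
  ahead <- logical(n)
  word_idx <- rep(NA_integer_, n)
  sentence_idx <- rep(NA_integer_, n)
  paragraph_idx <- rep(NA_integer_, n)
  char_dist <- rep(NA_integer_, n)
  word_dist <- rep(NA_integer_, n)
  sentence_dist <- rep(NA_integer_, n)

  seg_cache <- new.env(parent = emptyenv())
  get_seg <- function(si) {
    key <- as.character(si)
    if (is.null(seg_cache[[key]])) {
      seg_cache[[key]] <- segment(timeline$text[si])
    }
    seg_cache[[key]]
  }
  for (i in seq_len(n)) {
    if (on_prompt[i]) next
    si <- snap[i]
    if (si == 0) next
    txt <- timeline$text[si]
    poi <- timeline$poi[si]
    ci <- cidx[i]
    if (is.na(ci) || ci < 0 || ci >= nchar(txt)) {
      ahead[i] <- !is.na(ci) && ci > poi
      next
    }
    in_text[i] <- TRUE
    seg <- get_seg(si)
    w <- seg$words
    # word containing the character, else the nearest word by edge distance
    wi <- which(ci >= w$start & ci < w$end)
    if (length(wi) == 0 && nrow(w) > 0) {
      edge <- pmin(abs(ci - w$start), abs(ci - (w$end - 1L)))
      wi <- which.min(edge)
    }
    # word containing (or immediately preceding) the point of inscription
    pw <- which(poi >= w$start & poi < w$end)
    if (length(pw) == 0 && nrow(w) > 0) {
      before <- which(w$end <= poi + 1L)
      pw <- if (length(before) > 0) max(before) else 1L
    }
    if (length(wi) > 0) {
      wi <- wi[1]
      word_idx[i] <- wi - 1L
      sentence_idx[i] <- w$sentence[wi]
      paragraph_idx[i] <- w$paragraph[wi]
      word_dist[i] <- (pw[1] - 1L) - (wi - 1L)
    }
    char_dist[i] <- poi - ci
    ahead[i] <- ci > poi
    poi_sent <- seg$char_sentence[min(poi, nchar(txt) - 1L) + 1L]
    if (!is.na(sentence_idx[i])) sentence_dist[i] <- poi_sent - sentence_idx[i]
  }
  out <- cbind(fx, data.frame(
    on_prompt = on_prompt, in_text = in_text, ahead = ahead,
    char_idx = cidx, word_idx = word_idx, sentence_idx = sentence_idx,
    paragraph_idx = paragraph_idx, char_dist = char_dist,
    word_dist = word_dist, sentence_dist = sentence_dist))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
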