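#' Configuration for synthetic writing sessions
#'
#' Bundles the generating parameters for the synthetic-session generator:
#' per-location two-component inter-keystroke-interval (IKI) distributions,
#' per-location editing probabilities, per-location lookback probability /
#' duration / extent, participant heterogeneity, and text-template
#' parameters, for two language conditions. Location cells are the rows
#' `pre-sentence`, `pre-word`, `within-word`; language columns are the
#' condition labels (default `L1`, `L2`). Defaults reproduce the study
#' conditions this package models: hesitations are rarer, shorter and less
#' often accompanied by lookback within words than before words, and most
#' frequent and most extensive at sentence boundaries, with every tendency
#' amplified in the second language.
#'
#' @param n_participants number of participants (default 39).
#' @param languages condition labels, length 2.
#' @param fluent_mean_ms mean of the fluent (finger-movement) IKI component
#'   in ms; shared across locations and languages.
#' @param fluent_sdlog,hesitation_sdlog lognormal sigma of the fluent and
#'   hesitation components.
#' @param hesitation_mean_ms 3 x 2 matrix (location x language) of
#'   hesitation-component means, ms.
#' @param mixing_proportion 3 x 2 matrix of hesitation probabilities.
#' @param edit_prob 3 x 2 matrix: probability that a transition at this
#'   location initiates an editing action.
#' @param lookback_prob 3 x 2 matrix: probability that a writing transition
#'   is accompanied by lookback.
#' @param lookback_dur_mean_ms 3 x 2 matrix of mean total lookback
#'   durations, ms.
#' @param words_fixated_mean 3 x 2 matrix of mean numbers of words fixated
#'   per lookback.
#' @param sentence_depth_mean 3 x 2 matrix of mean sentence distances of
#'   the most-fixated sentence.
#' @param participant_sd named list of participant random-effect SDs:
#'   `log_dur` (log-duration scale), `logit_mix`, `logit_edit`,
#'   `logit_lookback` (logit scales).
#' @param sentences_per_text,words_per_sentence,word_length_mean,
#'   closed_class_prob,lexicon_size named numeric vectors per language
#'   driving the text template.
#' @param distractor_fix_prob probability of a single near-inscription
#'   fixation on a non-lookback transition.
#' @param adversarial_prob probability of planting a multi-fixation
#'   sequence that *fails* one lookback criterion (exercises the detector's
#'   rejections).
#' @param cursor_return_prob probability of a cursor-away-and-return
#'   excursion (scrolling-style lookback support) on a writing transition.
#' @param shift_gap_ms delay between the shift and character keypresses of
#'   a capital.
#' @param layout a [layout_model()] used to place fixations on screen.
#' @param seed integer master seed; the same seed yields byte-identical
#'   sessions.
#' @return list of class `session_config`.
#' @export
session_config <- function(
    n_participants = 39L,
    languages = c("L1", "L2"),
    fluent_mean_ms = 153,
    fluent_sdlog = 0.25,
    hesitation_sdlog = 0.6,
    hesitation_mean_ms = cell_matrix(c(1366, 1912, 433, 703, 271, 370), languages),
    mixing_proportion = cell_matrix(c(.78, .94, .53, .88, .08, .20), languages),
    edit_prob = cell_matrix(c(.15, .24, .07, .13, .05, .07), languages),
    lookback_prob = cell_matrix(c(.342, .396, .041, .108, .003, .008), languages),
    lookback_dur_mean_ms = cell_matrix(c(1932, 2711, 1153, 1423, 795, 1004), languages),
    words_fixated_mean = cell_matrix(c(8.67, 11.26, 4.42, 4.59, 2.55, 2.6), languages),
    sentence_depth_mean = cell_matrix(c(1.45, 1.68, .54, .8, .46, .85), languages),
    participant_sd = list(log_dur = 0.15, logit_mix = 0.3,
                          logit_edit = 0.2, logit_lookback = 0.2),
    sentences_per_text = stats::setNames(c(34, 23), languages),
    words_per_sentence = stats::setNames(c(21, 14), languages),
    word_length_mean = stats::setNames(c(4.4, 4.8), languages),
    closed_class_prob = stats::setNames(c(0.38, 0.52), languages),
    lexicon_size = stats::setNames(c(150L, 100L), languages),
    distractor_fix_prob = 0.3,
    adversarial_prob = 0.05,
    cursor_return_prob = 0.01,
    shift_gap_ms = 90,
    layout = layout_model(),
    seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), languages = languages,
    fluent_mean_ms = fluent_mean_ms, fluent_sdlog = fluent_sdlog,
    hesitation_sdlog = hesitation_sdlog,
    hesitation_mean_ms = hesitation_mean_ms,
    mixing_proportion = mixing_proportion, edit_prob = edit_prob,
    lookback_prob = lookback_prob,
    lookback_dur_mean_ms = lookback_dur_mean_ms,
    words_fixated_mean = words_fixated_mean,
    sentence_depth_mean = sentence_depth_mean,
    participant_sd = participant_sd,
    sentences_per_text = sentences_per_text,
    words_per_sentence = words_per_sentence,
    word_length_mean = word_length_mean,
    closed_class_prob = closed_class_prob, lexicon_size = lexicon_size,
    distractor_fix_prob = distractor_fix_prob,
    adversarial_prob = adversarial_prob,
    cursor_return_prob = cursor_return_prob,
    shift_gap_ms = shift_gap_ms, layout = layout, seed = as.integer(seed))
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

#' Build a location x language cell matrix
#'
#' @param x numeric vector in row-major order (pre-sentence L1, L2,
#'   pre-word L1, L2, within-word L1, L2) or an existing 3 x 2 matrix.
#' @param languages column labels.
#' @return 3 x 2 matrix with dimnames.
#' @export
cell_matrix <- function(x, languages = c("L1", "L2")) {
  locs <- c("pre-sentence", "pre-word", "within-word")
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 3, ncol(x) == 2)
    dimnames(x) <- list(locs, languages)
    return(x)
  }
  stopifnot(length(x) %in% c(1, 6))
  matrix(x, nrow = 3, ncol = 2, byrow = TRUE,
         dimnames = list(locs, languages))
}

#' Validate a session configuration
#'
#' Checks that all probability cells lie in `[0, 1]` and all millisecond
#' quantities are positive; a violated cell is named in the error.
#'
#' @param cfg a `session_config` (or plain list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_session_config <- function(cfg) {
  check_prob <- function(m, nm) {
    bad <- which(m < 0 | m > 1 | is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("configuration error: ", nm, "[", rownames(m)[bad[1, 1]], ",",
           colnames(m)[bad[1, 2]], "] = ", m[bad[1, , drop = FALSE]],
           " is not a probability")
    }
  }
  check_pos <- function(m, nm) {
    bad <- which(m <= 0 | is.na(m), arr.ind = TRUE)
    if (length(bad) > 0) {
      bad <- matrix(bad, ncol = 2)
      stop("configuration error: ", nm, "[", rownames(m)[bad[1, 1]], ",",
           colnames(m)[bad[1, 2]], "] must be > 0")
    }
  }
  if (length(cfg$languages) != 2) stop("configuration error: need two languages")
  if (cfg$fluent_mean_ms <= 0) stop("configuration error: fluent_mean_ms must be > 0")
  check_prob(cfg$mixing_proportion, "mixing_proportion")
  check_prob(cfg$edit_prob, "edit_prob")
  check_prob(cfg$lookback_prob, "lookback_prob")
  check_pos(cfg$hesitation_mean_ms, "hesitation_mean_ms")
  check_pos(cfg$lookback_dur_mean_ms, "lookback_dur_mean_ms")
  check_pos(cfg$words_fixated_mean, "words_fixated_mean")
  invisible(cfg)
}

# deterministic sub-seed derivation (kept below .Machine$integer.max)
.derive_seed <- function(seed, a, b) {
  as.integer((abs(seed) %% 1e6) * 1009 + a * 131 + b * 17 + 7) %% 2147483647L
}

# synthetic lexicon for one language: open-class pseudo-words plus the
# shipped closed-class list; shared by all participants in a condition
.language_lexicon <- function(cfg, language) {
  li <- match(language, cfg$languages)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.derive_seed(cfg$seed, 0, li))
  closed <- closed_class_words(if (li == 1) "en" else "es")
  closed <- unique(closed[nchar(closed) >= 2 & nchar(closed) <= 6])
  nlex <- cfg$lexicon_size[[language]]
  consonants <- strsplit("bcdfghjklmnprstvz", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  target_len <- cfg$word_length_mean[[language]]
  open <- character(0)
  while (length(open) < nlex) {
    len <- max(3L, min(12L, stats::rpois(1, target_len + 0.8)))
    w <- paste(vapply(seq_len(ceiling(len / 2)), function(k) {
      paste0(sample(consonants, 1), sample(vowels, 1))
    }, ""), collapse = "")
    w <- substr(w, 1, len)
    if (!(w %in% closed)) open <- unique(c(open, w))
  }
  list(open = open, closed = closed)
}

# planned text for one session: list(text, plan data.frame, words registry)
.plan_text <- function(cfg, language) {
  n_sent <- max(2L, stats::rpois(1, cfg$sentences_per_text[[language]]))
  lex <- .language_lexicon(cfg, language)
  p_closed <- cfg$closed_class_prob[[language]]
  sent_words <- lapply(seq_len(n_sent), function(s) {
    nw <- max(3L, stats::rpois(1, cfg$words_per_sentence[[language]]))
    vapply(seq_len(nw), function(w) {
      if (stats::runif(1) < p_closed) sample(lex$closed, 1) else sample(lex$open, 1)
    }, "")
  })
  ch <- character(0); raw <- character(0); shift <- logical(0)
  word_start <- integer(0); word_sentence <- integer(0); word_text <- character(0)
  pos <- 0L
  for (s in seq_along(sent_words)) {
    ws <- sent_words[[s]]
    for (w in seq_along(ws)) {
      word <- ws[w]
      if (w == 1) word <- paste0(toupper(substr(word, 1, 1)),
                                 substr(word, 2, nchar(word)))
      chars <- strsplit(word, "")[[1]]
      raw_in <- c(if (w == 1 && s == 1) NA_character_
                  else if (w == 1) "pre-sentence" else "pre-word",
                  rep("within-word", length(chars) - 1L))
      ch <- c(ch, chars); raw <- c(raw, raw_in)
      shift <- c(shift, c(w == 1, rep(FALSE, length(chars) - 1L)))
      word_start <- c(word_start, pos)
      word_sentence <- c(word_sentence, s - 1L)
      word_text <- c(word_text, word)
      pos <- pos + length(chars)
      if (w == length(ws)) {
        ch <- c(ch, ".", " "); raw <- c(raw, "within-word", "post-word")
        shift <- c(shift, FALSE, FALSE)
        pos <- pos + 2L
      } else {
        ch <- c(ch, " "); raw <- c(raw, "post-word"); shift <- c(shift, FALSE)
        pos <- pos + 1L
      }
    }
  }
  list(text = paste(ch, collapse = ""),
       plan = data.frame(ch = ch, raw = raw, shift = shift,
                         stringsAsFactors = FALSE),
       words = data.frame(word = word_text, start = word_start,
                          end = word_start + nchar(word_text),
                          sentence = word_sentence, stringsAsFactors = FALSE),
       n_closed = sum(unlist(sent_words) %in% lex$closed),
       n_open = sum(!unlist(sent_words) %in% lex$closed))
}

# growing accumulator for row records
.acc_new <- function() new.env(parent = emptyenv())
.acc_add <- function(acc, row) {
  n <- (acc$n %||% 0L) + 1L
  acc$n <- n
  acc$rows[[n]] <- row
}
.acc_df <- function(acc) {
  if (is.null(acc$n) || acc$n == 0L) return(NULL)
  do.call(rbind, acc$rows[seq_len(acc$n)])
}

#' Generate one synthetic writing session
#'
#' Emits an editor event log, a fixation stream, and ground-truth labels
#' for a single participant x language session. The event stream replays
#' to a well-formed multi-sentence text; IKIs are drawn from the
#' two-component lognormal mixture for each location cell (with
#' participant random effects); editing episodes (backspace + retype) are
#' inserted with the per-location editing probability; lookback fixation
#' sequences satisfying all four detection criteria are planted behind the
#' point of inscription on a subset of writing transitions, and
#' non-qualifying fixation patterns (single fixations at the point of
#' inscription, prompt-heavy sequences) on others. Lookbacks are planted
#' together with hesitation-component IKIs — a lookback needs a window
#' long enough to hold its fixations — so transitions flagged `lookback`
#' in the ground truth always carry component 1.
#'
#' @param config a [session_config()].
#' @param participant participant number (1-based).
#' @param language one of `config$languages`.
#' @return list of class `writing_session` with `events` (editor event
#'   data.frame), `fixations` (fixation stream with screen coordinates),
#'   and `ground_truth`: `transitions` (per consecutive keypress pair:
#'   type, location, mode, mixture component, lookback flag and intended
#'   metrics), `fixation_anchors` (planted word/sentence indices), `text`
#'   (the final text), and lexicon tallies.
#' @export
generate_session <- function(config, participant, language) {
  validate_session_config(config)
  if (!(language %in% config$languages)) {
    stop("unknown language '", language, "'")
  }
  if (is.numeric(participant)) participant <- as.integer(participant)
  li <- match(language, config$languages)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  # participant effects are drawn from a participant-only seed so they are
  # shared between that participant's two sessions
  set.seed(.derive_seed(config$seed, participant, 0))
  psd <- config$participant_sd
  re <- list(log_dur = stats::rnorm(1, 0, psd$log_dur),
             mix = stats::rnorm(1, 0, psd$logit_mix),
             edit = stats::rnorm(1, 0, psd$logit_edit),
             look = stats::rnorm(1, 0, psd$logit_lookback))

  set.seed(.derive_seed(config$seed, participant, li))
  tp <- .plan_text(config, language)
  plan <- tp$plan
  words <- tp$words

  sdf <- config$fluent_sdlog
  sdh <- config$hesitation_sdlog
  mu_fluent <- log(config$fluent_mean_ms) - sdf^2 / 2 + re$log_dur
  mu_hes <- log(config$hesitation_mean_ms[, li]) - sdh^2 / 2 + re$log_dur
  theta <- stats::plogis(stats::qlogis(config$mixing_proportion[, li]) + re$mix)
  p_edit <- stats::plogis(stats::qlogis(config$edit_prob[, li]) + re$edit)
  p_look <- stats::plogis(stats::qlogis(pmin(pmax(config$lookback_prob[, li],
                                                  1e-6), 1 - 1e-6)) + re$look)

  draw_iki <- function(loc, z) {
    if (z == 1) stats::rlnorm(1, mu_hes[[loc]], sdh)
    else stats::rlnorm(1, mu_fluent, sdf)
  }

  events <- .acc_new(); fixs <- .acc_new(); gt <- .acc_new()
  pos <- 0L          # next insertion point (0-based)
  t_now <- 1000      # time of the most recent keypress (outgoing time)

  add_event <- function(t, action, payload, cb, ca) {
    .acc_add(events, data.frame(
      participant = participant, language = language,
      t_ms = as.integer(round(t)), action = action, payload = payload,
      cursor_before = cb, cursor_after = ca, stringsAsFactors = FALSE))
  }
  add_fix <- function(t, dur, char_idx, on_prompt, word_idx, sentence_idx) {
    .acc_add(fixs, data.frame(
      t_start_ms = as.integer(round(t)), duration_ms = as.integer(round(dur)),
      char_idx = char_idx, on_prompt = on_prompt, word_idx = word_idx,
      sentence_idx = sentence_idx, stringsAsFactors = FALSE))
  }
  add_gt <- function(t1, t2, raw, comp, lb = NULL) {
    loc <- .raw_location(raw)
    .acc_add(gt, data.frame(
      t_first = as.integer(round(t1)), t_second = as.integer(round(t2)),
      iki = as.integer(round(t2)) - as.integer(round(t1)),
      raw_type = raw, location = loc,
      mode = if (raw == "other") NA_character_
             else if (endsWith(raw, "->edit")) "editing" else "writing",
      component = comp,
      lookback = !is.null(lb),
      lb_duration_ms = if (is.null(lb)) NA_real_ else lb$duration,
      lb_n_fixations = if (is.null(lb)) NA_integer_ else lb$n_fix,
      lb_words_fixated = if (is.null(lb)) NA_integer_ else lb$words_fixated,
      lb_sentence_depth = if (is.null(lb)) NA_real_ else lb$depth,
      stringsAsFactors = FALSE))
  }

  # emit one planned character; returns the keypress "out" time
  emit_char <- function(t, ch, shifted) {
    if (shifted) {
      add_event(t, "shift", "", pos, pos)
      t_char <- t + config$shift_gap_ms
    } else {
      t_char <- t
    }
    add_event(t_char, "insert", ch, pos, pos + 1L)
    pos <<- pos + 1L
    t_char
  }

  # candidate fixation targets behind the point of inscription
  .candidates <- function(target_sentence, poi) {
    ok <- words$end <= poi & words$sentence == target_sentence &
      words$start <= poi - 5L
    which(ok)
  }

  poi_word_index <- function(poi) {
    before <- which(words$start <= poi)
    if (length(before) == 0) return(0L)
    max(before) - 1L
  }

  plan_lookback <- function(loc, poi, s_poi) {
    depth_mean <- config$sentence_depth_mean[loc, li]
    d <- if (loc == "pre-sentence") {
      1L + stats::rpois(1, max(0, depth_mean - 1))
    } else {
      stats::rpois(1, depth_mean)
    }
    d <- min(d, s_poi)
    if (loc == "pre-sentence" && d < 1L) return(NULL)
    ts <- s_poi - d
    cand <- .candidates(ts, poi)
    pw <- poi_word_index(poi)
    cand <- cand[cand - 1L < pw]           # word distance >= 1
    if (length(cand) == 0) return(NULL)
    v_target <- max(1L, stats::rpois(1, max(0.2, config$words_fixated_mean[loc, li] - 1)) + 1L)
    # visit sequence without consecutive repeats; re-entries allowed
    visits <- integer(0); last <- -1L
    for (k in seq_len(v_target)) {
      avail <- setdiff(cand, last)
      if (length(avail) == 0) break
      pick <- if (length(avail) == 1) avail else sample(avail, 1)
      visits <- c(visits, pick); last <- pick
    }
    if (length(visits) == 0) return(NULL)
    n_fix <- length(visits)
    if (n_fix == 1L) { visits <- c(visits, visits); n_fix <- 2L }
    total <- stats::rlnorm(1, log(config$lookback_dur_mean_ms[loc, li]) - 0.25^2 / 2, 0.25)
    share <- stats::rexp(n_fix) + 0.25
    dur <- round(pmax(60, total * share / sum(share)))
    fchar <- vapply(visits, function(w) {
      hi <- min(words$end[w] - 1L, poi - 5L)
      lo <- words$start[w]
      if (hi < lo) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
    }, integer(1))
    list(visits = visits, n_fix = n_fix, dur = dur, fchar = fchar,
         duration = sum(dur),
         words_fixated = length(rle(visits)$lengths),
         depth = {
           sd_ <- s_poi - words$sentence[visits]
           tab <- table(sd_); mx <- max(tab)
           if (sum(tab == mx) > 1) NA_real_ else as.numeric(names(tab)[tab == mx])
         })
  }

  place_fixations <- function(lb, t1, t2, s_poi) {
    gap <- 30
    t <- t1 + max(40, (t2 - t1 - lb$duration - lb$n_fix * gap) / 2)
    for (k in seq_len(lb$n_fix)) {
      w <- lb$visits[k]
      add_fix(t, lb$dur[k], lb$fchar[k], FALSE, w - 1L, words$sentence[w])
      t <- t + lb$dur[k] + gap
    }
  }

  n_plan <- nrow(plan)
  prev_kind <- NULL; prev_ch <- NULL; prev_before_space <- NULL
  # state describing the previous keypress for ground-truth pair labels
  pair_raw <- function(kind2, ch2) {
    if (is.null(prev_kind)) return(NA_character_)
    if (kind2 == "char") {
      if (prev_kind != "char") return("other")
      if (prev_ch == " ") {
        if (ch2 == " ") return("other")
        if (prev_before_space %in% c(".", "?", "!")) return("pre-sentence")
        return("pre-word")
      }
      if (ch2 == " ") return("post-word")
      return("within-word")
    }
    if (prev_kind != "char") return("other")
    if (prev_ch == " ") {
      if (prev_before_space %in% c(".", "?", "!")) return("pre-sentence->edit")
      return("pre-word->edit")
    }
    "word->edit"
  }
  note_keypress <- function(kind, ch) {
    prev_before_space <<- if (!is.null(ch) && ch == " " && pos >= 2L) {
      substr(tp$text, pos - 1L, pos - 1L)
    } else ""
    prev_kind <<- kind; prev_ch <<- ch
  }

  # first keystroke
  t_now <- emit_char(1000, plan$ch[1], plan$shift[1])
  note_keypress("char", plan$ch[1])

  for (i in 2:n_plan) {
    raw_in <- plan$raw[i]
    loc <- .raw_location(raw_in)
    poi <- pos - 1L
    s_here <- segment_sentence_index(tp$text, poi)

    # --- optional editing episode before this keystroke ---
    if (stats::runif(1) < p_edit[[loc]]) {
      z_e <- stats::rbinom(1, 1, theta[[loc]])
      iki_e <- max(60, draw_iki(loc, z_e))
      t_bsp <- t_now + iki_e
      edit_raw <- pair_raw("edit", NULL)
      add_event(t_bsp, "backspace", "", pos, pos - 1L)
      add_gt(t_now, t_bsp, edit_raw, z_e)
      deleted <- substr(tp$text, pos, pos)   # char at 0-based pos-1
      pos <- pos - 1L
      note_keypress("edit", NULL)
      # retype the deleted character
      t_re <- t_bsp + 150
      shifted <- deleted %in% LETTERS
      t_re_out <- emit_char(t_re, deleted, shifted)
      add_gt(t_bsp, t_re, "other", NA_integer_)
      note_keypress("char", deleted)
      t_now <- t_re_out
    }

    # --- the writing transition into this keystroke ---
    z <- stats::rbinom(1, 1, theta[[loc]])
    iki <- max(60, draw_iki(loc, z))
    lb <- NULL
    # lookbacks require a hesitation window long enough for their fixations,
    # so they are only planted on hesitation transitions
    if (theta[[loc]] > 0 && stats::runif(1) < p_look[[loc]]) {
      cand_lb <- plan_lookback(loc, poi, s_here)
      if (!is.null(cand_lb)) {
        lb <- cand_lb
        if (z == 0) { z <- 1L; iki <- max(60, draw_iki(loc, 1)) }
        iki <- max(iki, lb$duration + lb$n_fix * 30 + 200)
      }
    }
    excursion <- is.null(lb) && stats::runif(1) < config$cursor_return_prob &&
      pos > 10L
    if (excursion) iki <- max(iki, 500)
    t_next <- t_now + iki
    if (!is.null(lb)) {
      place_fixations(lb, t_now, t_next, s_here)
    } else if (stats::runif(1) < config$adversarial_prob && iki >= 600) {
      .plant_adversarial(add_fix, words, poi, t_now, t_next)
    } else if (stats::runif(1) < config$distractor_fix_prob && iki >= 300) {
      fc <- max(0L, poi - sample(0:3, 1))
      wi <- poi_word_index(fc)
      add_fix(t_now + iki * 0.3, min(iki - 150, 200), fc, FALSE,
              wi, words$sentence[wi + 1L])
    }
    if (excursion) {
      back <- sample.int(min(pos - 1L, 40L), 1)
      add_event(t_now + 0.3 * iki, "cursor_move", as.character(pos - back),
                pos, pos - back)
      add_event(t_now + 0.7 * iki, "cursor_move", as.character(pos),
                pos - back, pos)
    }
    t_out <- emit_char(t_next, plan$ch[i], plan$shift[i])
    add_gt(t_now, t_next, raw_in, z, lb)
    note_keypress("char", plan$ch[i])
    t_now <- t_out
  }

  ev <- .acc_df(events)
  fx <- .acc_df(fixs)
  gtd <- .acc_df(gt)
  # convert planted character anchors to screen coordinates
  if (!is.null(fx)) {
    xy <- char_to_xy(config$layout, ifelse(is.na(fx$char_idx), 0L, fx$char_idx))
    fx$x_px <- ifelse(fx$on_prompt, config$layout$x0_px + 50,
                      round(xy$x_px, 1))
    fx$y_px <- ifelse(fx$on_prompt, config$layout$y0_px / 2,
                      round(xy$y_px, 1))
    anchors <- fx[, c("t_start_ms", "char_idx", "on_prompt",
                      "word_idx", "sentence_idx")]
    fx <- data.frame(participant = participant, language = language,
                     t_start_ms = fx$t_start_ms,
                     duration_ms = fx$duration_ms,
                     x_px = fx$x_px, y_px = fx$y_px,
                     on_prompt = fx$on_prompt, stringsAsFactors = FALSE)
  } else {
    anchors <- NULL
    fx <- data.frame(participant = character(0), language = character(0),
                     t_start_ms = integer(0), duration_ms = integer(0),
                     x_px = numeric(0), y_px = numeric(0),
                     on_prompt = logical(0))
  }
  if (!is.null(gtd)) {
    gtd <- cbind(transition_id = seq_len(nrow(gtd)), gtd)
    gtd$participant <- participant
    gtd$language <- language
  }
  structure(list(events = ev, fixations = fx,
                 ground_truth = list(transitions = gtd,
                                     fixation_anchors = anchors,
                                     text = tp$text,
                                     n_closed = tp$n_closed,
                                     n_open = tp$n_open),
                 participant = participant, language = language),
            class = "writing_session")
}

# sentence index of the character at 0-based position poi, matching
# segment()'s convention (space after a terminator belongs to the next
# sentence); vector-free helper used during generation
segment_sentence_index <- function(text, poi) {
  if (poi <= 0) return(0L)
  pre <- substr(text, 1, poi)    # chars 0 .. poi-1
  n_term <- lengths(regmatches(pre, gregexpr("[.?!](?=\\s|$)", pre, perl = TRUE)))
  as.integer(n_term)
}

# multi-fixation sequences that must be rejected by the detector
.plant_adversarial <- function(add_fix, words, poi, t1, t2) {
  kind <- sample(c("near_pair", "prompt_start", "prompt_heavy"), 1)
  win <- t2 - t1
  t <- t1 + 0.15 * win
  near_char <- function() max(0L, poi - sample(0:4, 1))
  wi_of <- function(fc) {
    before <- which(words$start <= fc)
    if (length(before) == 0) 0L else max(before) - 1L
  }
  if (kind == "near_pair") {
    for (k in 1:2) {
      fc <- near_char()
      add_fix(t, 120, fc, FALSE, wi_of(fc), words$sentence[wi_of(fc) + 1L])
      t <- t + 170
    }
  } else if (kind == "prompt_start") {
    add_fix(t, 150, NA_integer_, TRUE, NA_integer_, NA_integer_)
    t <- t + 200
    for (k in 1:2) {
      fc <- near_char()
      add_fix(t, 120, fc, FALSE, wi_of(fc), words$sentence[wi_of(fc) + 1L])
      t <- t + 170
    }
  } else {
    for (k in 1:2) {
      add_fix(t, 130, NA_integer_, TRUE, NA_integer_, NA_integer_)
      t <- t + 180
    }
    for (k in 1:2) {
      fc <- near_char()
      add_fix(t, 120, fc, FALSE, wi_of(fc), words$sentence[wi_of(fc) + 1L])
      t <- t + 170
    }
  }
}

#' Generate a cohort of synthetic sessions
#'
#' @param config a [session_config()].
#' @param participants participant numbers (default all in `config`).
#' @return list of `writing_session` objects, one per
#'   participant x language.
#' @export
generate_cohort <- function(config, participants = seq_len(config$n_participants)) {
  out <- list()
  for (p in participants) {
    for (lg in config$languages) {
      out[[paste0("p", p, "_", lg)]] <- generate_session(config, p, lg)
    }
  }
  out
}

#' Simulate inter-keystroke intervals directly from the mixture
#'
#' Draws IKIs for a participants x languages x locations design from the
#' two-component lognormal mixture with participant random effects, without
#' building full sessions. This is the generating model that
#' [fit_iki_mixture()] estimates, used for parameter-recovery studies.
#'
#' @param n_participants,n_per_cell design size.
#' @param languages,locations cell labels (locations from `pre-sentence`,
#'   `pre-word`, `within-word`).
#' @param fluent_mean_ms,fluent_sdlog fluent component (shared across cells).
#' @param hesitation_mean_ms,mixing_proportion matrices or named values per
#'   location x language (see [cell_matrix()]).
#' @param hesitation_sdlog hesitation lognormal sigma.
#' @param participant_sd list with `log_dur` and `logit_mix` SDs.
#' @param seed RNG seed.
#' @return data.frame with `participant`, `language`, `location`,
#'   `mode = "writing"`, `iki` (ms) and the true `component` label.
#' @export
simulate_iki_cells <- function(n_participants = 30L, n_per_cell = 200L,
                               languages = c("L1", "L2"),
                               locations = "pre-word",
                               fluent_mean_ms = 153, fluent_sdlog = 0.25,
                               hesitation_mean_ms = cell_matrix(c(1366, 1912, 433, 703, 271, 370)),
                               mixing_proportion = cell_matrix(c(.78, .94, .53, .88, .08, .20)),
                               hesitation_sdlog = 0.6,
                               participant_sd = list(log_dur = 0.15, logit_mix = 0.3),
                               seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mu_f0 <- log(fluent_mean_ms) - fluent_sdlog^2 / 2
  rows <- list()
  for (p in seq_len(n_participants)) {
    u <- stats::rnorm(1, 0, participant_sd$log_dur)
    v <- stats::rnorm(1, 0, participant_sd$logit_mix)
    for (lg in languages) {
      for (loc in locations) {
        th <- stats::plogis(stats::qlogis(mixing_proportion[loc, lg]) + v)
        z <- stats::rbinom(n_per_cell, 1, th)
        mu_h <- log(hesitation_mean_ms[loc, lg]) - hesitation_sdlog^2 / 2
        iki <- ifelse(z == 1,
                      stats::rlnorm(n_per_cell, mu_h + u, hesitation_sdlog),
                      stats::rlnorm(n_per_cell, mu_f0 + u, fluent_sdlog))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, language = lg, location = loc, mode = "writing",
          iki = iki, component = z, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
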