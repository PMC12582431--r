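# Independent brute-force evaluation of the four lookback criteria,
# written directly from their definition and sharing no code with the
# detector. Returns TRUE iff the fixation window qualifies as a lookback.
brute_force_lookback <- function(window, min_word_dist = 1, min_char_dist = 5,
                                 behind_frac = 0.8, prompt_frac = 0.5) {
  w <- window[order(window$t_start_ms), , drop = FALSE]
  if (nrow(w) < 2) return(FALSE)
  # criterion (a): medians over in-text fixations' signed distances
  it <- which(w$in_text & !w$on_prompt)
  if (length(it) == 0) return(FALSE)
  wd <- sort(w$word_dist[it])
  cd <- sort(w$char_dist[it])
  med <- function(v) {
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  if (med(wd) < min_word_dist) return(FALSE)
  if (med(cd) < min_char_dist) return(FALSE)
  # criterion (b): more than behind_frac of all fixations strictly behind
  n_behind <- 0
  for (i in seq_len(nrow(w))) {
    if (w$in_text[i] && !w$on_prompt[i] && !is.na(w$char_dist[i]) &&
        w$char_dist[i] > 0) {
      n_behind <- n_behind + 1
    }
  }
  if (!(n_behind / nrow(w) > behind_frac)) return(FALSE)
  # criterion (c): must not start on the prompt
  if (w$on_prompt[1]) return(FALSE)
  # criterion (d): fewer than prompt_frac of fixations on the prompt
  if (!(sum(w$on_prompt) / nrow(w) < prompt_frac)) return(FALSE)
  TRUE
}

# random anchored-fixation window for oracle-equivalence testing
random_window <- function(t1 = 0, t2 = 1000) {
  n <- sample(1:8, 1)
  t <- sort(sample(seq(t1, t2 - 1), n))
  kind <- sample(c("behind", "near", "ahead", "prompt", "offtext"), n,
                 replace = TRUE, prob = c(.4, .2, .15, .15, .1))
  on_prompt <- kind == "prompt"
  in_text <- kind %in% c("behind", "near", "ahead")
  char_dist <- rep(NA_integer_, n)
  word_dist <- rep(NA_integer_, n)
  sent_dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (kind[i] == "behind") {
      char_dist[i] <- sample(1:60, 1)
      word_dist[i] <- sample(0:8, 1)
      sent_dist[i] <- sample(0:3, 1)
    } else if (kind[i] == "near") {
      char_dist[i] <- sample(0:6, 1)
      word_dist[i] <- sample(0:1, 1)
      sent_dist[i] <- 0L
    } else if (kind[i] == "ahead") {
      char_dist[i] <- -sample(1:20, 1)
      word_dist[i] <- -sample(0:3, 1)
      sent_dist[i] <- 0L
    }
  }
  data.frame(t_start_ms = t, duration_ms = sample(60:400, n, replace = TRUE),
             on_prompt = on_prompt, in_text = in_text,
             ahead = !is.na(char_dist) & char_dist < 0,
             word_idx = ifelse(in_text, sample(0:50, n, replace = TRUE), NA),
             sentence_idx = ifelse(in_text, sample(0:5, n, replace = TRUE), NA),
             char_dist = char_dist, word_dist = word_dist,
             sentence_dist = sent_dist)
}

# run-length word-entry count, independent of the package implementation
rle_word_entries <- function(word_seq) {
  if (length(word_seq) == 0) return(0L)
  entries <- 1L
  for (i in seq_along(word_seq)[-1]) {
    if (word_seq[i] != word_seq[i - 1]) entries <- entries + 1L
  }
  entries
}
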