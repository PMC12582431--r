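# Build an event stream from a compact keystroke notation:
#   "a".." "  typed character (capital letters are emitted as shift + insert)
#   "<bsp>"   backspace
#   "<L>"/"<R>" single-character cursor move left/right
#   "<move:k>" cursor move to absolute position k
# Times advance by `step` ms per keypress; shift precedes its character by
# `shift_gap`.
make_events <- function(keys, step = 300, shift_gap = 90, t0 = 1000,
                        participant = 1L, language = "L1") {
  rows <- list()
  doc_len <- 0L
  cur <- 0L
  t <- t0
  add <- function(t, action, payload, cb, ca) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = participant, language = language,
      t_ms = as.integer(t), action = action, payload = payload,
      cursor_before = cb, cursor_after = ca, stringsAsFactors = FALSE)
  }
  for (k in keys) {
    if (k == "<bsp>") {
      add(t, "backspace", "", cur, cur - 1L)
      cur <- cur - 1L
      doc_len <- doc_len - 1L
    } else if (k == "<L>") {
      add(t, "cursor_move", as.character(cur - 1L), cur, cur - 1L)
      cur <- cur - 1L
    } else if (k == "<R>") {
      add(t, "cursor_move", as.character(cur + 1L), cur, cur + 1L)
      cur <- cur + 1L
    } else if (grepl("^<move:", k)) {
      tgt <- as.integer(sub("^<move:(\\d+)>$", "\\1", k))
      add(t, "cursor_move", as.character(tgt), cur, tgt)
      cur <- tgt
    } else {
      if (grepl("^[A-Z]$", k)) {
        add(t, "shift", "", cur, cur)
        add(t + shift_gap, "insert", k, cur, cur + 1L)
      } else {
        add(t, "insert", k, cur, cur + 1L)
      }
      cur <- cur + 1L
      doc_len <- doc_len + 1L
    }
    t <- t + step
  }
  do.call(rbind, rows)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# The canonical example sentence pair, typed with a mid-word correction:
# "The dog barked. That[bsp][bsp]en it ran away."
table1_keys <- c("T", "h", "e", " ", "d", "o", "g", " ",
                 "b", "a", "r", "k", "e", "d", ".", " ",
                 "T", "h", "a", "t", "<bsp>", "<bsp>", "e", "n", " ",
                 "i", "t", " ", "r", "a", "n", " ",
                 "a", "w", "a", "y", ".")

small_config <- function(seed = 1, ...) {
  session_config(n_participants = 2,
                 sentences_per_text = c(L1 = 6, L2 = 5),
                 words_per_sentence = c(L1 = 8, L2 = 7),
                 seed = seed, ...)
}
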