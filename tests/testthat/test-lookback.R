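mk_window <- function(char_dist, word_dist = pmax(1, char_dist %/% 6),
                      on_prompt = rep(FALSE, length(char_dist)),
                      sentence_dist = rep(1L, length(char_dist)),
                      word_idx = seq_along(char_dist),
                      t0 = 100, dur = 200) {
  n <- length(char_dist)
  data.frame(t_start_ms = t0 + (seq_len(n) - 1) * 250,
             duration_ms = rep(dur, length.out = n),
             on_prompt = on_prompt,
             in_text = !on_prompt & !is.na(char_dist),
             ahead = !is.na(char_dist) & char_dist < 0,
             word_idx = word_idx, sentence_idx = 1L,
             char_dist = char_dist, word_dist = word_dist,
             sentence_dist = sentence_dist)
}
trans <- function(t1 = 0, t2 = 5000) {
  data.frame(transition_id = 1L, t_first = t1, t_second = t2,
             location = "pre-word", mode = "writing")
}

test_that("detector implements the four criteria", {
  # a single fixation behind the text never qualifies
  expect_null(detect_lookback(trans(), mk_window(20)))
  # five fixations, median word distance 3, char distance 12, none on prompt
  w <- mk_window(char_dist = c(12, 12, 13, 11, 12), word_dist = rep(3, 5))
  expect_s3_class(detect_lookback(trans(), w), "lookback_event")
  # 2 of 4 fixations on the prompt (50%) fails criterion (d)
  w2 <- mk_window(char_dist = c(12, 12, NA, NA), word_dist = c(3, 3, NA, NA),
                  on_prompt = c(FALSE, FALSE, TRUE, TRUE))
  expect_null(detect_lookback(trans(), w2))
  # starting on the prompt fails criterion (c) even with distant fixations
  w3 <- mk_window(char_dist = c(NA, 12, 13, 14, 12, 15),
                  word_dist = c(NA, 3, 3, 3, 3, 3),
                  on_prompt = c(TRUE, rep(FALSE, 5)))
  expect_null(detect_lookback(trans(), w3))
  # fixations at the point of inscription fail criterion (a)
  w4 <- mk_window(char_dist = c(0, 2, 3), word_dist = c(0, 0, 0))
  expect_null(detect_lookback(trans(), w4))
  # too many fixations ahead of the point of inscription fail criterion (b)
  w5 <- mk_window(char_dist = c(20, 22, -3, -5), word_dist = c(4, 4, -1, -1))
  expect_null(detect_lookback(trans(), w5))
  # unanchored input is an error
  expect_error(detect_lookback(trans(), data.frame(t_start_ms = 1:3)),
               "anchor")
})

test_that("detector agrees with the brute-force oracle on random windows", {
  set.seed(1234)
  tr <- trans(0, 1000)
  for (i in seq_len(1000)) {
    w <- random_window()
    got <- !is.null(detect_lookback(tr, w))
    want <- brute_force_lookback(w)
    if (got != want) {
      fail(sprintf("disagreement on window %d (detector %s, oracle %s)",
                   i, got, want))
      break
    }
  }
  succeed()
})

test_that("planted lookbacks are recovered with no false positives", {
  cfg <- small_config(
    seed = 77,
    lookback_prob = cell_matrix(c(.5, .5, .35, .35, .15, .15)))
  for (p in 1:2) {
    s <- generate_session(cfg, p, "L2")
    res <- process_session(s, layout = cfg$layout)
    gt <- s$ground_truth$transitions
    m <- merge(res$transitions,
               gt[c("t_first", "t_second", "lookback", "lb_duration_ms",
                    "lb_words_fixated", "lb_sentence_depth")],
               by = c("t_first", "t_second"), suffixes = c(".det", ".gt"))
    expect_gt(sum(m$lookback.gt), 10)
    expect_equal(sum(m$lookback.det & m$lookback.gt), sum(m$lookback.gt))
    expect_equal(sum(m$lookback.det & !m$lookback.gt), 0)
    hit <- m$lookback.det & m$lookback.gt
    expect_equal(m$lb_duration_ms.det[hit], m$lb_duration_ms.gt[hit])
    expect_equal(m$lb_words_fixated.det[hit], m$lb_words_fixated.gt[hit])
    expect_equal(m$lb_sentence_depth.det[hit], m$lb_sentence_depth.gt[hit])
  }
})

test_that("lookback duration is the sum of fixation durations", {
  w <- mk_window(char_dist = c(12, 13, 11), dur = c(200, 300, 250))
  ev <- detect_lookback(trans(), w)
  expect_equal(ev$duration_ms, 750)
  expect_equal(lookback_duration(mk_window(c(10, 11), dur = c(100, 100))), 200)
  # invariant under re-timing that preserves durations
  w2 <- w
  w2$t_start_ms <- w2$t_start_ms + 17
  expect_equal(lookback_duration(w2), 750)
})

test_that("words fixated counts word entries including re-entries", {
  w <- mk_window(char_dist = c(12, 13, 11), word_idx = c(3, 5, 3))
  expect_equal(words_fixated(w), 3)
  w2 <- mk_window(char_dist = c(12, 13, 11), word_idx = c(2, 2, 2))
  expect_equal(words_fixated(w2), 1)
  set.seed(9)
  for (i in 1:50) {
    ids <- sample(1:4, sample(2:10, 1), replace = TRUE)
    w3 <- mk_window(char_dist = rep(12, length(ids)), word_idx = ids)
    expect_equal(words_fixated(w3), rle_word_entries(ids))
  }
})

test_that("lookback depth is the modal sentence distance, ties excluded", {
  w <- mk_window(char_dist = rep(12, 4), sentence_dist = c(1, 1, 1, 2))
  expect_equal(sentence_depth(w), 1)
  w2 <- mk_window(char_dist = rep(12, 4), sentence_dist = c(1, 1, 2, 2))
  expect_true(is.na(sentence_depth(w2)))
  # pre-sentence transitions have all fixations at sentence distance >= 1
  cfg <- small_config(seed = 31,
                      lookback_prob = cell_matrix(c(.6, .6, .2, .2, .05, .05)))
  s <- generate_session(cfg, 1, "L1")
  res <- process_session(s, layout = cfg$layout)
  ps <- res$transitions[res$transitions$location == "pre-sentence" &
                          res$transitions$lookback, ]
  expect_gt(nrow(ps), 0)
  expect_true(all(ps$lb_sentence_depth >= 1, na.rm = TRUE))
})
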