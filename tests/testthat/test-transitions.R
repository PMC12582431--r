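test_that("the typing-action taxonomy labels the example sentence pair", {
  ev <- make_events(table1_keys)
  tr <- classify_transitions(ev)
  expect_identical(
    tr$raw_type,
    c("within-word", "within-word", "post-word",          # T^h^e^_
      "pre-word", "within-word", "within-word", "post-word",  # ^d^o^g_
      "pre-word", rep("within-word", 5),                  # ^b^a^r^k^e^d
      "within-word", "post-word",                          # d^. ^_
      "pre-sentence",                                      # _^T
      "within-word", "within-word", "within-word",         # T^h^a^t
      "word->edit", "other", "other",                      # t^[bsp][bsp]e
      "within-word", "post-word",                          # e^n^_
      "pre-word", "within-word", "post-word",              # ^i^t_
      "pre-word", "within-word", "within-word", "post-word", # ^r^a^n_
      "pre-word", "within-word", "within-word", "within-word", # ^a^w^a^y
      "within-word"))                                      # y^.
  # post-word is merged into the within-word location everywhere
  expect_true(all(tr$location[tr$raw_type == "post-word"] == "within-word"))
  expect_false("post-word" %in% tr$location)
  # editing mode iff the raw type ends in ->edit
  expect_identical(!is.na(tr$mode) & tr$mode == "editing",
                   grepl("->edit$", tr$raw_type))
})

test_that("capitals are timed to the shift keypress", {
  ev <- make_events(c(chars("a. "), "T", "h"), step = 400, shift_gap = 90)
  tr <- classify_transitions(ev)
  ps <- tr[tr$raw_type == "pre-sentence", ]
  expect_equal(nrow(ps), 1)
  # the space keypress and the shift keypress are 400 ms apart; the
  # character insert lands 90 ms later and must not stretch the IKI
  expect_equal(ps$iki, 400)
  # the outgoing within-word transition starts at the character keypress
  ww <- tr[tr$transition_id == ps$transition_id + 1, ]
  expect_equal(ww$iki, 400 - 90)
})

test_that("editing transitions are classified by preceding keypresses", {
  # pre-word edit: "The dug " then cursor moves back
  ev <- make_events(c(chars("The dug "), "<L>", "<L>"))
  tr <- classify_transitions(ev)
  expect_true("pre-word->edit" %in% tr$raw_type)
  # pre-sentence edit: "The dog barkid. " then cursor moves back
  ev2 <- make_events(c(chars("Barkid. "), "<L>", "<L>", "<L>", "<bsp>", "e"))
  tr2 <- classify_transitions(ev2)
  expect_true("pre-sentence->edit" %in% tr2$raw_type)
  # the subsequent edit-to-edit and edit-to-letter pairs are excluded
  expect_true(all(tr2$raw_type[(which(tr2$raw_type == "pre-sentence->edit") + 1):
                                 nrow(tr2)] == "other"))
})

test_that("a cursor excursion returning to its origin is absorbed", {
  ev <- make_events(c(chars("abc def gh"), "<move:3>", "<move:10>", "i"),
                    step = 300)
  tr <- classify_transitions(ev)
  # h ... i spans the two cursor moves: a single within-word transition
  last <- tr[nrow(tr), ]
  expect_equal(last$raw_type, "within-word")
  expect_equal(last$iki, 900)
  expect_false(any(tr$raw_type == "word->edit"))
  # but a cursor move that does not return is an edit
  ev2 <- make_events(c(chars("abc def gh"), "<move:3>", "i"))
  tr2 <- classify_transitions(ev2)
  expect_true("word->edit" %in% tr2$raw_type)
})

test_that("classified labels equal generator ground truth", {
  cfg <- small_config(seed = 21)
  for (lg in c("L1", "L2")) {
    s <- generate_session(cfg, 2, lg)
    tr <- classify_transitions(s$events)
    gt <- s$ground_truth$transitions
    expect_equal(nrow(tr), nrow(gt))
    m <- merge(tr, gt, by = c("t_first", "t_second"),
               suffixes = c(".cl", ".gt"))
    expect_equal(nrow(m), nrow(gt))
    expect_identical(m$raw_type.cl, m$raw_type.gt)
    expect_equal(m$iki.cl, m$iki.gt, ignore_attr = TRUE)
  }
})

test_that("production sequences partition keystrokes", {
  ev <- make_events(chars("abcdef"))
  ps <- production_sequences(ev)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$length, 6)

  ev2 <- make_events(c("a", "<bsp>", "a", "<bsp>", "a", "<bsp>"))
  ps2 <- production_sequences(ev2)
  expect_true(all(ps2$length == 1))
  expect_equal(nrow(ps2), 3)

  # planted edit positions: 3 keystrokes, edit, 2 keystrokes, edit, 4
  ev3 <- make_events(c(chars("abc"), "<bsp>", chars("de"), "<bsp>",
                       chars("fghi")))
  ps3 <- production_sequences(ev3)
  expect_equal(ps3$length, c(3, 2, 4))
  expect_equal(ps3$terminated_by_edit, c(TRUE, TRUE, FALSE))
})

test_that("IKI filter removes both tails and reports exclusions", {
  tr <- data.frame(participant = 1, language = "L1",
                   iki = c(40, 50, 51, 500, 29999, 30000, 31000),
                   location = "pre-word", mode = "writing")
  f <- filter_ikis(tr)
  expect_equal(f$transitions$iki, c(51, 500, 29999))
  expect_equal(f$report$n_low, 2)
  expect_equal(f$report$n_high, 2)
  expect_equal(f$report$pct_low, 100 * 2 / 7)
})

test_that("per-cell subsampling caps at 200 deterministically", {
  tr <- data.frame(participant = rep(1:2, c(350, 150)),
                   language = "L1", location = "pre-word", mode = "writing",
                   iki = seq_len(500))
  s1 <- subsample_cell(tr, cap = 200, seed = 99)
  s2 <- subsample_cell(tr, cap = 200, seed = 99)
  expect_identical(s1, s2)
  tab <- table(s1$participant)
  expect_equal(unname(tab[["1"]]), 200)
  expect_equal(unname(tab[["2"]]), 150)
  s3 <- subsample_cell(tr, cap = 200, seed = 100)
  expect_false(identical(rownames(s1), rownames(s3)))
  expect_error(subsample_cell(tr, cap = 0), "cap")
})

test_that("filtering then subsampling equals per-cell application", {
  set.seed(3)
  tr <- data.frame(
    participant = sample(1:3, 2000, replace = TRUE),
    language = sample(c("L1", "L2"), 2000, replace = TRUE),
    location = sample(c("pre-word", "within-word"), 2000, replace = TRUE),
    mode = "writing",
    iki = exp(rnorm(2000, log(300), 1.5)))
  whole <- subsample_cell(filter_ikis(tr)$transitions, cap = 50, seed = 7)
  cells <- split(tr, interaction(tr$participant, tr$language, tr$location))
  parts <- do.call(rbind, lapply(cells, function(cell) {
    subsample_cell(filter_ikis(cell)$transitions, cap = 50, seed = 7)
  }))
  counts_whole <- table(whole$participant, whole$language, whole$location)
  counts_parts <- table(parts$participant, parts$language, parts$location)
  expect_equal(counts_whole, counts_parts)
})
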