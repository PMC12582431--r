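test_that("configuration validation names the offending cell", {
  expect_error(
    session_config(mixing_proportion = cell_matrix(c(.78, .94, .53, 1.2, .08, .2))),
    "mixing_proportion\\[pre-word,L2\\]")
  expect_error(
    session_config(hesitation_mean_ms = cell_matrix(c(1366, 1912, -1, 703, 271, 370))),
    "hesitation_mean_ms\\[pre-word")
  expect_silent(validate_session_config(session_config()))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 404)
  s1 <- generate_session(cfg, 1, "L1")
  s2 <- generate_session(cfg, 1, "L1")
  expect_identical(s1$events, s2$events)
  expect_identical(s1$fixations, s2$fixations)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- generate_session(small_config(seed = 405), 1, "L1")
  expect_false(identical(s1$events, s3$events))
})

test_that("degenerate mixture: all IKIs fluent when theta is zero", {
  cfg <- small_config(
    seed = 6,
    mixing_proportion = cell_matrix(0),
    edit_prob = cell_matrix(0.02),
    cursor_return_prob = 0,
    participant_sd = list(log_dur = 0, logit_mix = 0, logit_edit = 0,
                          logit_lookback = 0))
  s <- generate_session(cfg, 1, "L1")
  gt <- s$ground_truth$transitions
  wr <- gt[!is.na(gt$mode) & gt$mode == "writing", ]
  expect_true(all(wr$component == 0))
  # empirical mean within 3 standard errors of the configured fluent mean
  mu <- cfg$fluent_mean_ms
  se <- sd(wr$iki) / sqrt(nrow(wr))
  expect_lt(abs(mean(wr$iki) - mu), 3 * se + 3)
})

test_that("no lookbacks are planted or detected when lookback_prob is zero", {
  cfg <- small_config(seed = 8, lookback_prob = cell_matrix(0),
                      adversarial_prob = 0.1)
  s <- generate_session(cfg, 1, "L2")
  expect_true(all(!s$ground_truth$transitions$lookback))
  res <- process_session(s, layout = cfg$layout)
  expect_equal(sum(res$transitions$lookback), 0)
})

test_that("empirical editing proportions converge to configured values", {
  cfg <- session_config(n_participants = 1,
                        sentences_per_text = c(L1 = 40, L2 = 40),
                        words_per_sentence = c(L1 = 12, L2 = 12),
                        participant_sd = list(log_dur = 0, logit_mix = 0,
                                              logit_edit = 0, logit_lookback = 0),
                        seed = 99)
  s <- generate_session(cfg, 1, "L1")
  gt <- s$ground_truth$transitions
  gt <- gt[!is.na(gt$location), ]
  for (loc in c("pre-word", "within-word")) {
    cell <- gt[gt$location == loc, ]
    n <- nrow(cell)
    expect_gt(n, 300)
    p_hat <- mean(cell$mode == "editing")
    p <- cfg$edit_prob[loc, "L1"]
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("event and fixation logs round-trip through files", {
  cfg <- small_config(seed = 15)
  s <- generate_session(cfg, 3, "L2")
  ep <- tempfile(fileext = ".tsv")
  fp <- tempfile(fileext = ".tsv")
  write_event_log(s$events, ep)
  ev <- read_event_log(ep)
  expect_equal(ev, s$events, ignore_attr = TRUE)
  # a second write of the re-read stream is byte-identical
  ep2 <- tempfile(fileext = ".tsv")
  write_event_log(ev, ep2)
  expect_identical(readBin(ep, "raw", file.size(ep)),
                   readBin(ep2, "raw", file.size(ep2)))
  write_fixation_log(s$fixations, fp)
  fx <- read_fixation_log(fp)
  expect_equal(fx, s$fixations, ignore_attr = TRUE)
  unlink(c(ep, ep2, fp))
})

test_that("an empty stream writes a header-only file", {
  ev0 <- data.frame(participant = character(0), language = character(0),
                    t_ms = integer(0), action = character(0),
                    payload = character(0), cursor_before = integer(0),
                    cursor_after = integer(0))
  p <- tempfile()
  write_event_log(ev0, p)
  expect_equal(length(readLines(p)), 1)
  expect_equal(nrow(read_event_log(p)), 0)
  unlink(p)
})

test_that("malformed logs are rejected with a line number", {
  cfg <- small_config(seed = 16)
  s <- generate_session(cfg, 1, "L1")
  p <- tempfile()
  write_event_log(s$events[1:5, ], p)
  lines <- readLines(p)
  lines[4] <- paste(lines[4], "extra", sep = "\t")
  writeLines(lines, p)
  expect_error(read_event_log(p), "line 4")
  # out-of-order timestamps
  ev <- s$events[1:5, ]
  ev$t_ms <- rev(ev$t_ms)
  write_event_log(ev, p)
  expect_error(read_event_log(p), "out of order")
  unlink(p)
})

test_that("direct IKI simulation hits the configured long-interval share", {
  # a cell configured as fluent 153 ms / hesitation 703 ms, theta = .88
  d <- simulate_iki_cells(
    n_participants = 10, n_per_cell = 200, languages = "L2",
    locations = "pre-word",
    participant_sd = list(log_dur = 0.1, logit_mix = 0.001), seed = 2)
  expect_gte(nrow(d), 1000)
  share <- mean(d$component)
  expect_lt(abs(share - 0.88), 3 * sqrt(.88 * .12 / nrow(d)))
  # and the component means are where they were configured to be
  expect_lt(abs(mean(d$iki[d$component == 1]) - 703) / 703, 0.1)
  expect_lt(abs(mean(d$iki[d$component == 0]) - 153) / 153, 0.1)
})
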