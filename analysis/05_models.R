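#!/usr/bin/env Rscript

# Step 5: Bayesian models.
#
# Fits the inferential models to the pipeline outputs of steps 2-4:
#  - the two-component lognormal mixture for IKIs (fluent component shared
#    across conditions, hesitation shift and mixing proportion per
#    language x location, by-participant random effects),
#  - binomial mixed models for editing probability and lookback
#    probability,
#  - a lognormal mixed model for lookback duration,
#  - negative-binomial mixed models for words fixated and lookback depth,
#  - the multivariate model of the six text measures.
# Writes summary tables (posterior means, 95% probability intervals,
# Savage-Dickey Bayes factors) under results/models/.

suppressPackageStartupMessages(library(scribeye))

seed <- 1L
ctrl <- sampler_control(chains = 2, adapt = 200, burn = 400, draws = 500,
                        seed = seed)
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)
langs <- c("L1", "L2")
save_tab <- function(x, name) {
  write.table(x, file.path("results/models", paste0(name, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

iki <- read.delim("results/transitions_iki_sample.tsv")
cat("== IKI mixture ==\n")
mix <- suppressWarnings(fit_iki_mixture(iki, control = ctrl, lang_levels = langs))
sm <- suppressWarnings(iki_mixture_summary(mix))
cat(sprintf("Fluent component mean: %.0f ms [%.0f, %.0f]\n",
            sm$fluent$estimate_ms, sm$fluent$q2.5, sm$fluent$q97.5))
print(sm$cells, row.names = FALSE)
print(sm$effects, row.names = FALSE)
save_tab(sm$cells, "iki_mixture_cells")
save_tab(sm$effects, "iki_mixture_effects")

all_tr <- read.delim("results/transitions_all.tsv")
cat("\n== Editing probability (binomial) ==\n")
fit_e <- suppressWarnings(fit_binomial(editing_counts(all_tr), control = ctrl,
                                       lang_levels = langs))
print(cell_estimates(fit_e), row.names = FALSE)
save_tab(cell_estimates(fit_e), "editing_cells")
save_tab(fixed_effects(fit_e), "editing_effects")

writing <- read.delim("results/transitions_writing.tsv")
cat("\n== Lookback probability (binomial) ==\n")
fit_p <- suppressWarnings(fit_binomial(lookback_counts(writing), control = ctrl,
                                       lang_levels = langs))
print(cell_estimates(fit_p), row.names = FALSE)
save_tab(cell_estimates(fit_p), "lookback_probability_cells")
save_tab(fixed_effects(fit_p), "lookback_probability_effects")

lb <- writing[writing$lookback, ]
cat("\n== Lookback duration (lognormal) ==\n")
fit_d <- suppressWarnings(fit_lognormal_lmm(
  data.frame(participant = lb$participant, language = lb$language,
             location = lb$location, y = lb$lb_duration_ms),
  control = ctrl, lang_levels = langs))
print(cell_estimates(fit_d), row.names = FALSE)
save_tab(cell_estimates(fit_d), "lookback_duration_cells")

cat("\n== Words fixated (negative binomial) ==\n")
fit_w <- suppressWarnings(fit_negbinomial(
  data.frame(participant = lb$participant, language = lb$language,
             location = lb$location, y = lb$lb_words_fixated),
  control = ctrl, lang_levels = langs))
print(cell_estimates(fit_w), row.names = FALSE)
save_tab(cell_estimates(fit_w), "words_fixated_cells")

cat("\n== Lookback depth (negative binomial; before-sentence separate) ==\n")
dep <- lb[!is.na(lb$lb_sentence_depth), ]
for (subset_name in c("pre_sentence", "word_level")) {
  d <- if (subset_name == "pre_sentence") {
    dep[dep$location == "pre-sentence", ]
  } else {
    dep[dep$location != "pre-sentence", ]
  }
  if (nrow(d) < 20) next
  df <- data.frame(participant = d$participant, language = d$language,
                   y = as.integer(d$lb_sentence_depth))
  if (subset_name == "word_level") df$location <- d$location
  fit_dep <- suppressWarnings(fit_negbinomial(df, control = ctrl,
                                              lang_levels = langs))
  cat(subset_name, ":\n")
  print(cell_estimates(fit_dep), row.names = FALSE)
  save_tab(cell_estimates(fit_dep), paste0("lookback_depth_", subset_name))
}

cat("\n== Text measures (multivariate) ==\n")
meas <- read.delim("results/text_measures.tsv")
fit_t <- suppressWarnings(fit_multivariate_text_model(
  meas, measures = c("word_count", "mean_word_length", "sentence_count",
                     "mean_sentence_length", "open_closed_ratio", "mtld"),
  control = ctrl, lang_levels = langs))
print(fit_t$effects, row.names = FALSE)
save_tab(fit_t$effects, "text_measure_effects")
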