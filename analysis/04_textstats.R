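#!/usr/bin/env Rscript

# Step 4: text characteristics of the final texts.
#
# Computes the six text measures per session: word count, mean word
# length, sentence count, mean sentence length, open/closed word-class
# ratio, and MTLD lexical diversity.

suppressPackageStartupMessages(library(scribeye))

texts <- read.delim("results/final_texts.tsv")
meas <- do.call(rbind, lapply(seq_len(nrow(texts)), function(i) {
  lang <- texts$language[i]
  cc <- closed_class_words(if (lang == "L1") "en" else "es")
  tm <- text_measures(texts$text[i], closed_class = cc)
  data.frame(participant = texts$participant[i], language = lang,
             word_count = tm$word_count,
             mean_word_length = tm$mean_word_length,
             sentence_count = tm$sentence_count,
             mean_sentence_length = tm$mean_sentence_length,
             open_closed_ratio = tm$open_closed_ratio,
             mtld = tm$mtld)
}))

write.table(meas, "results/text_measures.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Text measures, mean (SD) by language:\n")
for (v in names(meas)[-(1:2)]) {
  agg <- aggregate(meas[[v]], by = list(language = meas$language),
                   function(x) sprintf("%.2f (%.2f)", mean(x), sd(x)))
  cat(sprintf("%-22s L1 %s   L2 %s\n", v, agg$x[1], agg$x[2]))
}
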