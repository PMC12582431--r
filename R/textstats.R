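#' Closed-class (function) word lists
#'
#' Minimal English and Spanish function-word inventories shipped with the
#' package, used to compute the open/closed word-class ratio. The lists are
#' deliberately small and user-overridable: pass your own character vector
#' to [basic_measures()] for a different inventory.
#'
#' @param language `"en"` or `"es"`.
#' @return character vector of lower-case closed-class words.
#' @export
closed_class_words <- function(language = c("en", "es")) {
  language <- match.arg(language)
  path <- system.file("extdata", paste0("closed_class_", language, ".txt"),
                      package = "scribeye", mustWork = TRUE)
  tolower(trimws(readLines(path, encoding = "UTF-8")))
}

.clean_tokens <- function(text) {
  seg <- segment(text)
  toks <- tolower(seg$words$word)
  toks <- gsub("[^\\p{L}\\p{N}']", "", toks, perl = TRUE)
  toks[nzchar(toks)]
}

#' Text-characteristic measures of a final text
#'
#' Computes word count, mean word length (characters, punctuation
#' stripped), sentence count, mean sentence length (words), and the ratio
#' of open-class to closed-class words. Tokenization is identical to
#' [segment()]; tokens are case-folded and stripped of punctuation before
#' lexical measures.
#'
#' @param text a single string (a reconstructed final text).
#' @param closed_class character vector of closed-class words (see
#'   [closed_class_words()]).
#' @return list of class `text_measures` with `word_count`,
#'   `mean_word_length`, `sentence_count`, `mean_sentence_length`,
#'   `open_closed_ratio` (`NA` with `ratio_undefined = TRUE` when the text
#'   contains no closed-class token), and `ratio_undefined`.
#' @examples
#' basic_measures("The dog barked. Then it ran away.",
#'                closed_class = c("the", "then", "it"))
#' @export
basic_measures <- function(text, closed_class = character()) {
  seg <- segment(text)
  toks <- .clean_tokens(text)
  wc <- length(toks)
  if (wc == 0) {
    return(structure(list(word_count = 0L, mean_word_length = 0,
                          sentence_count = 0L, mean_sentence_length = 0,
                          open_closed_ratio = NA_real_,
                          ratio_undefined = TRUE),
                     class = "text_measures"))
  }
  n_closed <- sum(toks %in% tolower(closed_class))
  n_open <- wc - n_closed
  structure(list(
    word_count = wc,
    mean_word_length = mean(nchar(toks)),
    sentence_count = seg$n_sentences,
    mean_sentence_length = wc / max(1L, seg$n_sentences),
    open_closed_ratio = if (n_closed == 0) NA_real_ else n_open / n_closed,
    ratio_undefined = n_closed == 0
  ), class = "text_measures")
}

#' @export
print.text_measures <- function(x, ...) {
  cat(sprintf(
    "words %d (mean length %.2f), sentences %d (mean length %.2f), open/closed %s\n",
    x$word_count, x$mean_word_length, x$sentence_count,
    x$mean_sentence_length,
    if (isTRUE(x$ratio_undefined)) "undefined" else sprintf("%.2f", x$open_closed_ratio)))
  if (!is.null(x$mtld)) cat(sprintf("MTLD %.2f\n", x$mtld))
  invisible(x)
}

.mtld_one_direction <- function(tokens, threshold) {
  n <- length(tokens)
  factors <- 0
  seen <- character(0)
  ntok <- 0L
  ttr <- 1
  for (tok in tokens) {
    ntok <- ntok + 1L
    if (!(tok %in% seen)) seen <- c(seen, tok)
    ttr <- length(seen) / ntok
    if (ttr <= threshold) {
      factors <- factors + 1
      seen <- character(0)
      ntok <- 0L
      ttr <- 1
    }
  }
  if (ntok > 0L) factors <- factors + (1 - ttr) / (1 - threshold)
  if (factors == 0) return(NA_real_)
  n / factors
}

#' MTLD: measure of textual lexical diversity
#'
#' Sequential factor counting: walking through the token stream, a factor
#' completes whenever the running type-token ratio drops to or below
#' `ttr_threshold`, at which point the counter resets. A partial factor of
#' `(1 - TTR_end) / (1 - threshold)` is added for the remainder. The
#' directional value is `N / factors`; MTLD is the mean of the forward and
#' reverse passes. Texts whose TTR never reaches the threshold (e.g.
#' all-unique short texts) have zero factors in both passes and return `NA`
#' with attribute `undefined = TRUE`.
#'
#' @param tokens character vector of (cleaned) tokens, in text order.
#' @param ttr_threshold type-token-ratio threshold (default 0.72).
#' @return MTLD value, or `NA` when undefined.
#' @examples
#' mtld(c("a", "b", "a", "a", "b", "a"))  # 3
#' @export
mtld <- function(tokens, ttr_threshold = 0.72) {
  stopifnot(length(tokens) >= 1)
  fwd <- .mtld_one_direction(tokens, ttr_threshold)
  rev_ <- .mtld_one_direction(rev(tokens), ttr_threshold)
  if (is.na(fwd) && is.na(rev_)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  mean(c(fwd, rev_), na.rm = TRUE)
}

#' All six text measures, including MTLD
#'
#' Convenience wrapper combining [basic_measures()] and [mtld()].
#'
#' @inheritParams basic_measures
#' @param ttr_threshold passed to [mtld()].
#' @return `text_measures` list with an `mtld` element appended.
#' @export
text_measures <- function(text, closed_class = character(),
                          ttr_threshold = 0.72) {
  m <- basic_measures(text, closed_class)
  toks <- .clean_tokens(text)
  m$mtld <- if (length(toks) >= 1) as.numeric(mtld(toks, ttr_threshold)) else NA_real_
  m
}
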