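# Lexical richness and emotion-category rates from timed transcripts.
# Transcripts are data.frames with columns token, onset_s, offset_s and
# (after tagging) category; onset markers are the event anchors used by
# the event-locked fNIRS analysis and must survive every stage unchanged.

#' Honore's R lexical-richness statistic
#'
#' `R = 100 * ln(N) / (1 - V1/V)` where N is the token count, V the number
#' of distinct types and V1 the number of hapax legomena (types occurring
#' exactly once). Natural log. When every type is a hapax (V1 = V) the
#' statistic is undefined and `NA` is returned with a warning.
#'
#' @param tokens Character vector of tokens (N >= 2).
#' @return Numeric statistic, or `NA` when undefined.
#' @examples
#' honore_r(c("a", "b", "a", "c"))  # 415.8883
#' @export
honore_r <- function(tokens) {
  stopifnot(is.character(tokens) || is.factor(tokens))
  tokens <- as.character(tokens)
  n <- length(tokens)
  if (n < 2) stop("honore_r requires at least 2 tokens")
  tab <- table(tokens)
  v <- length(tab)
  v1 <- sum(tab == 1)
  if (v1 == v) {
    warning("all types are hapax legomena; Honore's R undefined")
    return(NA_real_)
  }
  100 * log(n) / (1 - v1 / v)
}

#' Read a word -> category lexicon
#'
#' @param path TSV with columns `word`, `category`.
#' @return Named character vector mapping word to category.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "category") %in% names(df)))
  if (anyDuplicated(df$word)) stop("lexicon words must be unique")
  structure(df$category, names = df$word)
}

#' Tag transcript tokens by lexicon lookup
#'
#' Words absent from the lexicon default to `"neutral"`. Onset and offset
#' markers are passed through untouched.
#'
#' @param transcript data.frame with columns token, onset_s, offset_s.
#' @param lexicon Named character vector (word -> category) as returned by
#'   [read_lexicon()] or [default_lexicon()].
#' @return The transcript with a `category` column.
#' @export
tag_tokens_lexicon <- function(transcript, lexicon) {
  stopifnot(nrow(transcript) > 0,
            all(c("token", "onset_s", "offset_s") %in% names(transcript)))
  cat <- unname(lexicon[transcript$token])
  cat[is.na(cat)] <- "neutral"
  transcript$category <- cat
  transcript
}

#' Emotion/fact vocabulary rates
#'
#' Percent of tokens labelled negative, positive and factual.
#'
#' @param transcript Labelled transcript (column `category`).
#' @return Named numeric vector `neg_pct`, `pos_pct`, `factual_pct`.
#' @export
emotion_rates <- function(transcript) {
  if (nrow(transcript) == 0) stop("empty transcript")
  if (is.null(transcript$category)) stop("transcript is not labelled")
  n <- nrow(transcript)
  c(neg_pct = 100 * sum(transcript$category == "negative") / n,
    pos_pct = 100 * sum(transcript$category == "positive") / n,
    factual_pct = 100 * sum(transcript$category == "factual") / n)
}

#' Per-subject language feature row
#'
#' @param transcript Labelled transcript.
#' @return One-row data.frame with token count, Honore's R and the
#'   emotion rates.
#' @export
language_features <- function(transcript) {
  r <- emotion_rates(transcript)
  hr <- suppressWarnings(honore_r(transcript$token))
  data.frame(n_tokens = nrow(transcript), honore_r = hr,
             neg_pct = r[["neg_pct"]], pos_pct = r[["pos_pct"]],
             factual_pct = r[["factual_pct"]])
}

#' Read / write timed transcripts
#'
#' Plain TSV with columns token, onset_s, offset_s and optionally
#' category.
#'
#' @param path File path.
#' @param transcript Transcript data.frame (for writing).
#' @return `read_transcript` returns the data.frame.
#' @export
read_transcript <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("token", "onset_s", "offset_s") %in% names(df)))
  if (any(diff(df$onset_s) <= 0)) stop("transcript onsets must be strictly increasing")
  df
}

#' @rdname read_transcript
#' @export
write_transcript <- function(transcript, path) {
  utils::write.table(transcript, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
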