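#' Word sequence: the stimulus clock
#'
#' An ordered set of stimulus words with presentation onsets/offsets (in
#' seconds, relative to the start of the scan) and a sentence grouping.
#' Word timing doubles as the clock against which word-rate signals are
#' resampled to scanner (TR) rate.
#'
#' @param words character vector of tokens.
#' @param onsets numeric vector of word onset times (seconds), strictly
#'   increasing.
#' @param offsets numeric vector of word offset times; `offsets[k] >=
#'   onsets[k]` and `offsets[k] <= onsets[k + 1]`.
#' @param sentence_ids non-negative integers, non-decreasing; words sharing
#'   an id form one contiguous sentence.
#' @return An object of class `word_sequence` (a list with the four fields).
#' @export
word_sequence <- function(words, onsets, offsets, sentence_ids) {
  w <- length(words)
  if (length(onsets) != w || length(offsets) != w || length(sentence_ids) != w)
    stop_invalid("word_sequence fields must have equal length (got %d/%d/%d/%d)",
                 w, length(onsets), length(offsets), length(sentence_ids))
  if (w > 0) {
    if (any(diff(onsets) <= 0))
      stop_invalid("onsets must be strictly increasing (first violation at word %d)",
                   which(diff(onsets) <= 0)[1] + 1L)
    if (any(offsets < onsets))
      stop_invalid("offsets must be >= onsets (first violation at word %d)",
                   which(offsets < onsets)[1])
    if (w > 1 && any(offsets[-w] > onsets[-1] + 1e-9))
      stop_invalid("offset of word %d overlaps the next onset",
                   which(offsets[-w] > onsets[-1] + 1e-9)[1])
    if (any(sentence_ids < 0) || any(diff(sentence_ids) < 0))
      stop_invalid("sentence_ids must be non-negative and non-decreasing")
  }
  structure(list(words = as.character(words), onsets = as.numeric(onsets),
                 offsets = as.numeric(offsets),
                 sentence_ids = as.integer(sentence_ids)),
            class = "word_sequence")
}

#' @export
length.word_sequence <- function(x) length(x$words)

#' @export
print.word_sequence <- function(x, ...) {
  cat(sprintf("<word_sequence> %d words, %d sentences, %.1f-%.1f s\n",
              length(x), length(unique(x$sentence_ids)),
              if (length(x)) min(x$onsets) else NA, if (length(x)) max(x$offsets) else NA))
  invisible(x)
}

#' Word anchor times
#'
#' The time point each word is anchored to for resampling: the midpoint of
#' its onset and offset.
#'
#' @param seq a [word_sequence()].
#' @return numeric vector of times in seconds.
#' @export
word_times <- function(seq) (seq$onsets + seq$offsets) / 2

#' Run layout
#'
#' Describes how scanner volumes are organized into runs: per-run lengths in
#' TRs, the TR duration, the number of TRs trimmed from each run edge, and
#' how many times the held-out test run was presented.
#'
#' @param run_lengths integer vector, length in TRs of each run.
#' @param tr repetition time in seconds (default 2.0045).
#' @param trim TRs discarded at each run edge before modeling (default 10).
#' @param test_repeats number of presentations of the test run (default 2).
#' @return An object of class `run_layout`.
#' @export
run_layout <- function(run_lengths, tr = 2.0045, trim = 10L, test_repeats = 2L) {
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths <= 2L * trim))
    stop_invalid("every run must be longer than 2 * trim = %d TRs (run %d has %d)",
                 2L * trim, which(run_lengths <= 2L * trim)[1],
                 run_lengths[which(run_lengths <= 2L * trim)[1]])
  if (tr <= 0) stop_invalid("TR must be positive")
  if (trim < 0) stop_invalid("trim must be non-negative")
  structure(list(run_lengths = run_lengths, tr = tr, trim = as.integer(trim),
                 test_repeats = as.integer(test_repeats)),
            class = "run_layout")
}

#' @export
print.run_layout <- function(x, ...) {
  cat(sprintf("<run_layout> %d runs (%s TRs), TR = %.4f s, trim = %d, test repeats = %d\n",
              length(x$run_lengths), paste(x$run_lengths, collapse = ", "),
              x$tr, x$trim, x$test_repeats))
  invisible(x)
}

# Row index of the first TR of each run within the concatenated matrix.
run_starts <- function(run_lengths) cumsum(c(1L, run_lengths[-length(run_lengths)]))

#' Generate a word sequence with naturalistic irregular timing
#'
#' Inter-word intervals are drawn log-normal with the requested mean and
#' coefficient of variation (`jitter`), emulating the positive, irregular
#' word presentation rate of spoken narration. Word durations are set to
#' 80% of the gap to the next word so that offsets never overlap the next
#' onset. Sentence lengths are drawn shifted-Poisson with the requested
#' mean, producing contiguous sentence ids.
#'
#' @param n_words number of words (>= 0).
#' @param mean_interval mean inter-word interval in seconds (> 0).
#' @param jitter coefficient of variation of the intervals, in `[0, 1)`;
#'   0 gives exactly arithmetic onsets.
#' @param sentence_len_mean mean sentence length in words.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param start_time onset of the first word in seconds (default 10, the
#'   silent lead-in of each scan).
#' @return A [word_sequence()].
#' @export
generate_word_sequence <- function(n_words, mean_interval = 0.4, jitter = 0.3,
                                   sentence_len_mean = 12, seed = NULL,
                                   start_time = 10) {
  if (n_words < 0) stop_invalid("n_words must be >= 0")
  if (mean_interval <= 0) stop_invalid("mean_interval must be positive")
  if (jitter < 0 || jitter >= 1) stop_invalid("jitter must lie in [0, 1)")
  if (n_words == 0)
    return(word_sequence(character(0), numeric(0), numeric(0), integer(0)))
  with_seed_or_current(seed, {
    if (jitter == 0) {
      gaps <- rep(mean_interval, n_words)
    } else {
      sdlog <- sqrt(log(1 + jitter^2))
      gaps <- exp(rnorm(n_words, log(mean_interval) - sdlog^2 / 2, sdlog))
    }
    onsets <- start_time + cumsum(c(0, gaps[-n_words]))
    offsets <- onsets + 0.8 * gaps
    sent_len <- integer(0)
    while (sum(sent_len) < n_words)
      sent_len <- c(sent_len, 1L + rpois(32L, max(sentence_len_mean - 1, 0)))
    sentence_ids <- rep(seq_along(sent_len), sent_len)[seq_len(n_words)]
    syll <- c("ba", "do", "ki", "lu", "mer", "na", "po", "ra", "se", "ti",
              "va", "wo", "zen", "fa", "gri", "hu")
    words <- paste0(syll[sample.int(16L, n_words, replace = TRUE)],
                    syll[sample.int(16L, n_words, replace = TRUE)])
    word_sequence(words, onsets, offsets, sentence_ids)
  })
}

#' Read word timing from a TSV file
#'
#' Expects a tab-separated file with header columns `word`, `onset`,
#' `offset`, `sentence_id`. Validation failures report the offending row.
#'
#' @param path file path.
#' @return A [word_sequence()].
#' @export
read_word_timing <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("word", "onset", "offset", "sentence_id")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop_invalid("word timing file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", "))
  if (nrow(tab) > 1 && any(diff(tab$onset) <= 0))
    stop_invalid("onsets are not strictly increasing at row %d of %s",
                 which(diff(tab$onset) <= 0)[1] + 1L, path)
  word_sequence(tab$word, tab$onset, tab$offset, tab$sentence_id)
}

#' Write word timing to a TSV file
#'
#' @param seq a [word_sequence()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_word_timing <- function(seq, path) {
  tab <- data.frame(word = seq$words, onset = seq$onsets, offset = seq$offsets,
                    sentence_id = seq$sentence_ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
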