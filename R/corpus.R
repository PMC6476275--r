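# Corpus processing: cleaning, vocabulary, windowed co-occurrence counts and
# the smoothed non-negative PMI weighting that defines the base space.

#' Clean raw text into tokenized sentences
#'
#' Lowercases the input, detects sentence boundaries, strips punctuation and
#' splits on whitespace. Punctuation is removed except apostrophes and
#' hyphens, which are part of surface word forms; every removed character is
#' replaced by a space, so a token glued together by punctuation (e.g. an
#' em-dash) splits into two tokens. Sentence boundaries are detected before
#' punctuation stripping, at `.`, `!` or `?` followed by whitespace or end of
#' input; the boundary characters are configurable.
#'
#' @param text character vector of raw text; each element is treated as an
#'   independent document (one-document-per-line corpora work unchanged).
#' @param sentence_chars characters treated as sentence terminators
#'   (a regex character-class body, default `".!?"`).
#' @return a list of character vectors, one per non-empty sentence, each a
#'   sequence of lowercase tokens containing only letters, digits,
#'   apostrophes and hyphens.
#' @examples
#' clean_corpus("The fox's den—cold! A b. C d.")
#' @export
clean_corpus <- function(text, sentence_chars = ".!?") {
  if (!is.character(text)) stop("`text` must be a character vector")
  if (length(text) == 0L) return(list())
  bad <- which(!validUTF8(text))
  if (length(bad)) {
    off <- .first_invalid_utf8_offset(text[bad[1L]])
    stop(sprintf("input is not valid UTF-8: element %d, byte offset %d",
                 bad[1L], off))
  }
  text <- tolower(text)
  boundary <- sprintf("[%s]+(\\s+|$)", gsub("([][\\^-])", "\\\\\\1", sentence_chars))
  sentences <- unlist(strsplit(text, boundary, perl = TRUE), use.names = FALSE)
  # keep apostrophes (ASCII and typographic) and hyphens inside tokens
  sentences <- gsub("[^[:alnum:]'’-]+", " ", sentences, perl = TRUE)
  toks <- strsplit(trimws(sentences), "\\s+", perl = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  toks[lengths(toks) > 0L]
}

# Locate the first invalid byte in a string R already holds but whose bytes
# do not form valid UTF-8 (1-based offset).
.first_invalid_utf8_offset <- function(s) {
  b <- as.integer(charToRaw(s))
  i <- 1L
  n <- length(b)
  while (i <= n) {
    lead <- b[i]
    need <- if (lead < 0x80) 0L
      else if (lead >= 0xC2 && lead <= 0xDF) 1L
      else if (lead >= 0xE0 && lead <= 0xEF) 2L
      else if (lead >= 0xF0 && lead <= 0xF4) 3L
      else return(i)
    if (need > 0L) {
      if (i + need > n) return(i)
      cont <- b[(i + 1L):(i + need)]
      if (any(cont < 0x80 | cont > 0xBF)) return(i)
    }
    i <- i + 1L + need
  }
  n + 1L
}

#' Read and clean a plain-text corpus file
#'
#' @param path path to a UTF-8 text file; each line is a document.
#' @inheritParams clean_corpus
#' @return list of tokenized sentences, as [clean_corpus()].
#' @export
read_corpus <- function(path, sentence_chars = ".!?") {
  if (!file.exists(path)) stop(sprintf("corpus file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    stop(sprintf("corpus file %s is not valid UTF-8: byte offset %d",
                 path, .first_invalid_utf8_offset(txt)))
  }
  clean_corpus(strsplit(txt, "\n", fixed = TRUE)[[1L]],
               sentence_chars = sentence_chars)
}

#' Build a frequency-ranked vocabulary
#'
#' Retains the `size_limit` most frequent word types. Frequency ties are
#' broken lexicographically (ascending) so builds are reproducible.
#'
#' @param sentences list of token vectors from [clean_corpus()].
#' @param size_limit maximum vocabulary size (the paper-scale default is
#'   200000; desk-scale corpora use far less).
#' @return data.frame with columns `word` and `freq`, ordered by frequency
#'   descending then word ascending.
#' @export
build_vocabulary <- function(sentences, size_limit = 200000L) {
  stopifnot(size_limit >= 1L)
  tokens <- unlist(sentences, use.names = FALSE)
  if (length(tokens) == 0L) stop("empty corpus: no tokens to build a vocabulary from")
  tab <- table(tokens)
  words <- names(tab)
  freq <- as.integer(tab)
  ord <- order(-freq, words, method = "radix")
  keep <- ord[seq_len(min(size_limit, length(ord)))]
  data.frame(word = words[keep], freq = freq[keep], stringsAsFactors = FALSE)
}

#' Count windowed co-occurrences
#'
#' For each occurrence of a vocabulary word at position i within a sentence,
#' increments f(w, c) for every token c at positions i-window ... i+window
#' (excluding i itself), never crossing sentence boundaries. Context types
#' are all corpus types, not only vocabulary words; a word within the window
#' of another occurrence of itself does count.
#'
#' @param sentences list of token vectors.
#' @param vocab vocabulary data.frame from [build_vocabulary()].
#' @param window half-width of the symmetric window (default 2, i.e. 2 x 2).
#' @param min_context_count drop context columns whose total corpus frequency
#'   is below this (default 1 = keep all).
#' @return an object of class `cooc_table`: a list with the sparse `counts`
#'   matrix (rows = vocabulary words by rank, columns = context types,
#'   lexicographic), `vocab_freq` f(w), `context_freq` f(c), `total_W` (the
#'   summed vocabulary token count W) and `window`.
#' @export
count_cooccurrences <- function(sentences, vocab, window = 2L,
                                min_context_count = 1L) {
  stopifnot(window >= 1L)
  tokens <- unlist(sentences, use.names = FALSE)
  sid <- rep.int(seq_along(sentences), lengths(sentences))
  ctx_freq_tab <- table(tokens)
  ctx_types <- sort(names(ctx_freq_tab), method = "radix")
  ctx_freq <- as.integer(ctx_freq_tab[ctx_types])
  names(ctx_freq) <- ctx_types
  if (min_context_count > 1L) {
    keep <- ctx_freq >= min_context_count
    ctx_types <- ctx_types[keep]
    ctx_freq <- ctx_freq[keep]
  }

  wi <- match(tokens, vocab$word)      # vocab rank of each token (NA if OOV)
  ci <- match(tokens, ctx_types)       # context column of each token
  n <- length(tokens)
  ii <- integer(0)
  jj <- integer(0)
  if (n >= 2L) {
    for (d in seq_len(window)) {
      left <- seq_len(n - d)
      ok <- sid[left] == sid[left + d]
      l <- left[ok]
      r <- l + d
      # centre on the left token, context on the right, and vice versa
      a <- !is.na(wi[l]) & !is.na(ci[r])
      b <- !is.na(wi[r]) & !is.na(ci[l])
      ii <- c(ii, wi[l][a], wi[r][b])
      jj <- c(jj, ci[r][a], ci[l][b])
    }
  }
  counts <- Matrix::sparseMatrix(
    i = ii, j = jj, x = rep.int(1, length(ii)),
    dims = c(nrow(vocab), length(ctx_types)),
    dimnames = list(vocab$word, ctx_types))
  structure(list(counts = counts,
                 vocab_freq = stats::setNames(vocab$freq, vocab$word),
                 context_freq = ctx_freq,
                 total_W = sum(vocab$freq),
                 window = as.integer(window)),
            class = "cooc_table")
}

#' Smoothed non-negative PMI weighting
#'
#' The weighting applied to every observed co-occurrence count:
#' \deqn{PMI(w,c) = \log_2\left(\frac{f(w,c)\,W}{f(w)\,(f(c)+a)} + 1\right)}
#' The smoothing constant `a` penalizes very rare context words (which would
#' otherwise dominate dimension selection), and the +1 inside the logarithm
#' makes every value non-negative, with 0 exactly when f(w,c) = 0.
#'
#' @param fwc co-occurrence count f(w, c).
#' @param fw vocabulary-word frequency f(w), > 0.
#' @param fc context-word frequency f(c).
#' @param W total vocabulary token count, > 0.
#' @param a smoothing constant, >= 0 (default 10000).
#' @return PMI value(s), vectorized over the count arguments.
#' @examples
#' smoothed_pmi(0, 100, 100, 10000)        # never co-occur -> 0
#' smoothed_pmi(50, 100, 100, 10000, a = 0)
#' @export
smoothed_pmi <- function(fwc, fw, fc, W, a = 10000) {
  if (any(fw <= 0)) stop("invalid table: f(w) must be positive")
  if (any(W <= 0)) stop("invalid table: W must be positive")
  if (any(a < 0)) stop("smoothing constant `a` must be non-negative")
  log2(fwc * W / (fw * (fc + a)) + 1)
}

#' PMI configuration
#'
#' @param smoothing_a smoothing constant, >= 0 (default 10000, roughly the
#'   mean context-word frequency at the scale the weighting was designed for).
#' @return list of class `pmi_config`.
#' @export
pmi_config <- function(smoothing_a = 10000) {
  stopifnot(is.numeric(smoothing_a), length(smoothing_a) == 1L, smoothing_a >= 0)
  structure(list(smoothing_a = smoothing_a, log_base = 2), class = "pmi_config")
}

#' Compute the smoothed PMI matrix
#'
#' Applies [smoothed_pmi()] to every stored co-occurrence count. Cells with
#' f(w,c) = 0 are exactly 0 and are not stored.
#'
#' @param table a `cooc_table` from [count_cooccurrences()].
#' @param cfg a [pmi_config()].
#' @return object of class `pmi_matrix`: list with sparse non-negative `pmi`
#'   (same dimnames as the count matrix) plus the marginals and parameters
#'   needed to reproduce it.
#' @export
compute_pmi <- function(table, cfg = pmi_config()) {
  stopifnot(inherits(table, "cooc_table"), inherits(cfg, "pmi_config"))
  if (table$total_W <= 0) stop("invalid table: W must be positive")
  if (any(table$vocab_freq <= 0)) stop("invalid table: all f(w) must be positive")
  m <- methods::as(methods::as(table$counts, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::summary(m)  # triplets of stored counts
  vals <- smoothed_pmi(fwc = tr$x,
                       fw = table$vocab_freq[tr$i],
                       fc = table$context_freq[tr$j],
                       W = table$total_W,
                       a = cfg$smoothing_a)
  pmi <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = vals,
                              dims = dim(m), dimnames = dimnames(m))
  structure(list(pmi = pmi,
                 vocab_freq = table$vocab_freq,
                 context_freq = table$context_freq,
                 total_W = table$total_W,
                 window = table$window,
                 smoothing_a = cfg$smoothing_a),
            class = "pmi_matrix")
}

#' Build a PMI matrix straight from cleaned sentences
#'
#' Convenience wrapper chaining [build_vocabulary()],
#' [count_cooccurrences()] and [compute_pmi()].
#'
#' @inheritParams build_vocabulary
#' @inheritParams count_cooccurrences
#' @param smoothing_a smoothing constant for [smoothed_pmi()].
#' @return a `pmi_matrix`.
#' @export
build_pmi_matrix <- function(sentences, size_limit = 200000L, window = 2L,
                             smoothing_a = 10000, min_context_count = 1L) {
  vocab <- build_vocabulary(sentences, size_limit)
  tab <- count_cooccurrences(sentences, vocab, window, min_context_count)
  compute_pmi(tab, pmi_config(smoothing_a))
}

#' @export
print.pmi_matrix <- function(x, ...) {
  cat(sprintf("pmi_matrix: %d vocabulary words x %d context types, %d stored values\n",
              nrow(x$pmi), ncol(x$pmi), length(x$pmi@x)))
  cat(sprintf("  W = %d, window = %d, smoothing a = %g\n",
              x$total_W, x$window, x$smoothing_a))
  invisible(x)
}
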