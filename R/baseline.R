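# Static-embedding baseline: read externally trained word vectors in the
# word2vec text format, score each dyad by cosine similarity, and run the
# same correlation / one-vs-rest classification protocol on that single
# predictor.

#' Load word embeddings in word2vec text format
#'
#' Expects a header line `count dim` followed by `word v1 ... vd` lines.
#' Malformed lines, dimension mismatches, header/count discrepancies and
#' duplicate words are format errors naming the offending line.
#'
#' @param path path to the text-format embedding file.
#' @return numeric matrix (rows = words, `dim` columns).
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop(sprintf("embedding file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("embedding file is empty")
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("embedding header must be two integers: `count dim` (line 1)")
  }
  count <- as.integer(header[1L])
  d <- as.integer(header[2L])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count) {
    stop(sprintf("embedding header declares %d vectors but file has %d data lines",
                 count, length(body)))
  }
  words <- character(count)
  mat <- matrix(NA_real_, nrow = count, ncol = d)
  for (i in seq_len(count)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop(sprintf("line %d: expected %d values after the word, found %d",
                   i + 1L, d, length(parts) - 1L))
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) stop(sprintf("line %d: non-numeric vector component", i + 1L))
    words[i] <- parts[1L]
    mat[i, ] <- vals
  }
  if (anyDuplicated(words)) {
    stop(sprintf("duplicate word(s) in embedding file: %s",
                 paste(unique(words[duplicated(words)]), collapse = ", ")))
  }
  rownames(mat) <- words
  mat
}

#' Write word embeddings in word2vec text format
#'
#' @param emb numeric matrix with words as rownames.
#' @param path output path.
#' @param digits significant digits to write (default 8; round-trips to
#'   within 1e-6 on typical magnitudes).
#' @export
write_embeddings <- function(emb, path, digits = 8L) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)))
  lines <- c(sprintf("%d %d", nrow(emb), ncol(emb)),
             vapply(seq_len(nrow(emb)), function(i) {
               paste(c(rownames(emb)[i],
                       formatC(emb[i, ], digits = digits, format = "g")),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Cosine similarity of each dyad's word vectors
#'
#' @param emb embedding matrix from [load_embeddings()].
#' @param dyads a `dyad_dataset`.
#' @param strict if TRUE, dyads with an out-of-vocabulary word are an error;
#'   otherwise they get `NA` with a message giving the count (drop them
#'   before evaluation).
#' @return numeric vector of cosines, length nrow(dyads); `NA` for dropped
#'   dyads, `NaN` where a vector is all-zero.
#' @export
dyad_cosines <- function(emb, dyads, strict = FALSE) {
  cosine <- function(v, w) {
    nv <- sqrt(sum(v^2))
    nw <- sqrt(sum(w^2))
    if (nv == 0 || nw == 0) return(NaN)
    sum(v * w) / (nv * nw)
  }
  out <- rep(NA_real_, nrow(dyads))
  missing_words <- character(0)
  for (i in seq_len(nrow(dyads))) {
    v <- dyads$verb[i]
    n <- dyads$noun[i]
    if (!(v %in% rownames(emb)) || !(n %in% rownames(emb))) {
      missing_words <- c(missing_words,
                         setdiff(c(v, n), rownames(emb)))
      next
    }
    out[i] <- cosine(emb[v, ], emb[n, ])
  }
  if (length(missing_words)) {
    msg <- sprintf("%d dyad(s) dropped: word(s) not in embedding vocabulary (%s)",
                   sum(is.na(out)),
                   paste(unique(missing_words), collapse = ", "))
    if (strict) stop(msg)
    message(msg)
  }
  out
}

#' Evaluate the cosine baseline
#'
#' The single-predictor analogue of the full protocol: Pearson correlation
#' of the dyad cosine with each of the three ratings, plus leave-one-out
#' one-vs-rest logistic accuracy on the class labels with cosine as the
#' sole (standardized) feature. A strict special case of the multi-feature
#' machinery with p = 1.
#'
#' @param cosines numeric vector from [dyad_cosines()]; `NA` entries (and
#'   their dyads) are excluded.
#' @param dyads a `dyad_dataset`.
#' @return list with `correlations` (named: metaphoricity, meaningfulness,
#'   familiarity), `class_cv` (a `cv_result`) and `n_used`.
#' @export
baseline_evaluate <- function(cosines, dyads) {
  stopifnot(length(cosines) == nrow(dyads))
  keep <- is.finite(cosines)
  if (!any(keep)) stop("no finite cosines to evaluate")
  d <- dyads[keep, , drop = FALSE]
  Fm <- matrix(cosines[keep], ncol = 1, dimnames = list(NULL, "cosine"))
  Fs <- standardize_features(Fm)
  cors <- vapply(c("metaphoricity", "meaningfulness", "familiarity"),
                 function(t) stats::cor(Fm[, 1], d[[t]]), numeric(1))
  cv <- loo_logistic_ovr_cv(Fs, d$class, technique = "w2v")
  list(correlations = cors, class_cv = cv, n_used = sum(keep))
}
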