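# Dyad-contextual subspace projection: select k salient co-occurrence
# dimensions for a verb-object pair, project word vectors, and construct the
# generic mean / maximum / central vectors with unit-normalized counterparts.

#' Combine a pair of PMI values under a selection technique
#'
#' The per-dimension combination rule behind the `mean` and `geom`
#' techniques: arithmetic mean (p1 + p2) / 2, or geometric mean
#' sqrt(p1 * p2). The geometric mean is non-zero only where both inputs are,
#' and favours dimensions valued highly by both words over dimensions
#' dominated by one: it combines (5, 5) to 5 but (9, 1) to only 3.
#'
#' @param p1,p2 non-negative PMI values (vectorized).
#' @param technique `"mean"` or `"geom"`.
#' @return combined score(s), non-negative.
#' @examples
#' combine_pmi(5, 5, "geom")  # 5
#' combine_pmi(9, 1, "geom")  # 3
#' combine_pmi(9, 1, "mean")  # 5
#' @export
combine_pmi <- function(p1, p2, technique = c("mean", "geom")) {
  technique <- match.arg(technique)
  if (any(p1 < 0) || any(p2 < 0)) stop("PMI values must be non-negative")
  switch(technique,
         mean = (p1 + p2) / 2,
         geom = sqrt(p1 * p2))
}

#' A dyad subspace query
#'
#' @param word1 the verb (first input word).
#' @param word2 the object noun (second input word).
#' @param technique dimension-selection technique: `"indy"` (interleave each
#'   word's independently top-ranked dimensions), `"mean"` (top arithmetic
#'   mean) or `"geom"` (top geometric mean).
#' @param k subspace dimensionality (default 200).
#' @return list of class `dyad_query`.
#' @export
dyad_query <- function(word1, word2, technique = c("indy", "mean", "geom"),
                       k = 200L) {
  technique <- match.arg(technique)
  stopifnot(is.character(word1), is.character(word2),
            length(word1) == 1L, length(word2) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  structure(list(word1 = word1, word2 = word2, technique = technique, k = k),
            class = "dyad_query")
}

.check_in_vocab <- function(pmi, word) {
  if (!word %in% rownames(pmi$pmi)) {
    stop(sprintf("word '%s' is not in the matrix vocabulary", word))
  }
}

# Dense named PMI row for one vocabulary word.
.pmi_row <- function(pmi, word) {
  .check_in_vocab(pmi, word)
  v <- as.numeric(pmi$pmi[word, ])
  names(v) <- colnames(pmi$pmi)
  v
}

#' Score every candidate dimension for a word pair
#'
#' @param pmi a `pmi_matrix`.
#' @param w1,w2 vocabulary words.
#' @param technique `"mean"` or `"geom"` (the `indy` technique ranks each
#'   word separately and has no joint score).
#' @return data.frame with columns `context` and `score`, restricted to
#'   dimensions with non-zero score, ordered score-descending with
#'   lexicographic tie-break.
#' @export
score_dimensions <- function(pmi, w1, w2, technique = c("mean", "geom")) {
  technique <- match.arg(technique)
  r1 <- .pmi_row(pmi, w1)
  r2 <- .pmi_row(pmi, w2)
  s <- combine_pmi(r1, r2, technique)
  keep <- s > 0
  out <- data.frame(context = names(s)[keep], score = unname(s[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$context, method = "radix"), , drop = FALSE]
}

# Contexts of one word ordered by its own PMI descending, ties lexicographic.
.ranked_contexts <- function(row) {
  nz <- row[row > 0]
  names(nz)[order(-nz, names(nz), method = "radix")]
}

#' Select the k dimensions of a dyad's contextual subspace
#'
#' `mean` and `geom` take the top k context types by combined score
#' ([combine_pmi()]), descending, ties broken lexicographically. `indy`
#' alternately takes each word's next-highest-PMI context type, starting
#' with `word1`, skipping types already selected, until k dimensions are
#' collected; when one word's candidates run out the remainder come from the
#' other word's list.
#'
#' When `geom` has fewer than k positive-product candidates, all of them are
#' taken and the remaining slots are filled by arithmetic-mean ranking, with
#' a warning (at corpus scale, k = 200 avoids this; desk-scale corpora may
#' not). Fewer total candidates than k yields a shorter subspace with a
#' warning.
#'
#' @param pmi a `pmi_matrix`.
#' @param query a [dyad_query()].
#' @return character vector of selected context types, in selection order.
#' @export
select_dimensions <- function(pmi, query) {
  stopifnot(inherits(query, "dyad_query"))
  r1 <- .pmi_row(pmi, query$word1)
  r2 <- .pmi_row(pmi, query$word2)
  k <- query$k
  dims <- switch(query$technique,
    mean = {
      sc <- score_dimensions(pmi, query$word1, query$word2, "mean")
      sc$context[seq_len(min(k, nrow(sc)))]
    },
    geom = {
      sc <- score_dimensions(pmi, query$word1, query$word2, "geom")
      if (nrow(sc) == 0L) {
        stop(sprintf(
          "degenerate subspace: '%s' and '%s' share no non-zero PMI dimension",
          query$word1, query$word2))
      }
      d <- sc$context[seq_len(min(k, nrow(sc)))]
      if (length(d) < k) {
        warning(sprintf(
          "geom: only %d positive-product dimensions; filling %d by arithmetic-mean ranking",
          length(d), k - length(d)))
        mn <- score_dimensions(pmi, query$word1, query$word2, "mean")
        fill <- setdiff(mn$context, d)
        d <- c(d, fill[seq_len(min(k - length(d), length(fill)))])
      }
      d
    },
    indy = {
      l1 <- .ranked_contexts(r1)
      l2 <- .ranked_contexts(r2)
      .interleave_indy(l1, l2, k)
    })
  if (length(dims) < k) {
    warning(sprintf("only %d candidate dimensions available for k = %d",
                    length(dims), k))
  }
  dims
}

# Alternate between the two ranked lists, starting with the first, skipping
# already-selected types; fill from the survivor once one list is exhausted.
.interleave_indy <- function(l1, l2, k) {
  out <- character(0)
  i1 <- 1L
  i2 <- 1L
  turn1 <- TRUE
  while (length(out) < k && (i1 <= length(l1) || i2 <= length(l2))) {
    if (turn1 && i1 > length(l1)) turn1 <- FALSE
    if (!turn1 && i2 > length(l2)) turn1 <- TRUE
    if (turn1) {
      while (i1 <= length(l1) && l1[i1] %in% out) i1 <- i1 + 1L
      if (i1 <= length(l1)) {
        out <- c(out, l1[i1])
        i1 <- i1 + 1L
      }
    } else {
      while (i2 <= length(l2) && l2[i2] %in% out) i2 <- i2 + 1L
      if (i2 <= length(l2)) {
        out <- c(out, l2[i2])
        i2 <- i2 + 1L
      }
    }
    turn1 <- !turn1
  }
  out
}

#' Project a word into a set of dimensions
#'
#' The coordinate on each dimension is simply the word's value in the full
#' base space: PMI(word, dims_j), zero where the pair never co-occurs.
#'
#' @param pmi a `pmi_matrix`.
#' @param dims character vector of context types.
#' @param word a vocabulary word.
#' @return named numeric vector of length `length(dims)`.
#' @export
project_word <- function(pmi, dims, word) {
  row <- .pmi_row(pmi, word)
  unknown <- setdiff(dims, names(row))
  if (length(unknown)) {
    stop(sprintf("unknown context dimension(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  row[dims]
}

#' Generic vectors of a subspace
#'
#' The mean-vector M has, on each dimension, the mean PMI over the
#' vocabulary words with a non-zero value there (0 if none); the
#' maximum-vector X has the highest value of any vocabulary word; the
#' central-vector C is uniform, every element the mean of M's elements.
#'
#' @param pmi a `pmi_matrix`.
#' @param dims character vector of context types.
#' @return list with numeric vectors `M`, `X`, `C` of length `length(dims)`.
#' @export
generic_vectors <- function(pmi, dims) {
  if (length(dims) == 0L) stop("dims must be non-empty")
  sub <- pmi$pmi[, dims, drop = FALSE]
  M <- numeric(length(dims))
  X <- numeric(length(dims))
  for (j in seq_along(dims)) {
    col <- sub[, j]
    nz <- col[col > 0]
    if (length(nz)) {
      M[j] <- mean(nz)
      X[j] <- max(nz)
    }
  }
  names(M) <- dims
  names(X) <- dims
  C <- rep(mean(M), length(dims))
  names(C) <- dims
  list(M = M, X = X, C = C)
}

#' Rescale a vector to unit Euclidean norm
#'
#' @param v numeric vector.
#' @param strict if TRUE a zero vector is an error; otherwise it is returned
#'   unchanged and flagged with attribute `degenerate = TRUE` so downstream
#'   features involving it can be marked undefined.
#' @return unit vector (or the flagged zero vector).
#' @export
unit_normalize <- function(v, strict = FALSE) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    if (strict) stop("cannot normalize a zero vector")
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  v / nrm
}

#' Build a dyad's contextual subspace
#'
#' Selects dimensions, projects both words, computes the generic vectors and
#' all unit-normalized counterparts.
#'
#' @param pmi a `pmi_matrix`.
#' @param word1,word2 the verb and object noun.
#' @inheritParams dyad_query
#' @param strict if TRUE, zero vectors (words with no mass on the selected
#'   dimensions) raise an error instead of being flagged degenerate.
#' @return object of class `subspace`: dims plus vectors `V`, `N`, `M`, `X`,
#'   `C` and normalized `Vn`, `Nn`, `Mn`, `Xn`, `Cn`.
#' @export
build_subspace <- function(pmi, word1, word2,
                           technique = c("indy", "mean", "geom"), k = 200L,
                           strict = FALSE) {
  technique <- match.arg(technique)
  q <- dyad_query(word1, word2, technique, k)
  dims <- select_dimensions(pmi, q)
  V <- project_word(pmi, dims, word1)
  N <- project_word(pmi, dims, word2)
  g <- generic_vectors(pmi, dims)
  new_subspace(dims, V, N, g$M, g$X, g$C,
               word1 = word1, word2 = word2, technique = technique,
               strict = strict)
}

#' Assemble a subspace from explicit vectors
#'
#' Lower-level constructor used by [build_subspace()] and by tests or
#' simulations that supply coordinates directly.
#'
#' @param dims dimension labels.
#' @param V,N,M,X,C numeric vectors of length `length(dims)`.
#' @param word1,word2,technique optional metadata.
#' @param strict passed to [unit_normalize()].
#' @return object of class `subspace`.
#' @export
new_subspace <- function(dims, V, N, M, X, C, word1 = NA_character_,
                         word2 = NA_character_, technique = NA_character_,
                         strict = FALSE) {
  k <- length(dims)
  vecs <- list(V = V, N = N, M = M, X = X, C = C)
  for (nm in names(vecs)) {
    if (length(vecs[[nm]]) != k) {
      stop(sprintf("vector %s has length %d, expected %d",
                   nm, length(vecs[[nm]]), k))
    }
  }
  if (anyDuplicated(dims)) stop("subspace dimensions must be distinct")
  structure(c(list(dims = dims), vecs,
              list(Vn = unit_normalize(V, strict),
                   Nn = unit_normalize(N, strict),
                   Mn = unit_normalize(M, strict),
                   Xn = unit_normalize(X, strict),
                   Cn = unit_normalize(C, strict),
                   word1 = word1, word2 = word2, technique = technique,
                   k = k)),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("subspace: %s '%s' ~ '%s', k = %d\n",
              x$technique, x$word1, x$word2, x$k))
  cat(sprintf("  |V| = %.4g, |N| = %.4g, |M| = %.4g, |X| = %.4g, |C| = %.4g\n",
              sqrt(sum(x$V^2)), sqrt(sum(x$N^2)), sqrt(sum(x$M^2)),
              sqrt(sum(x$X^2)), sqrt(sum(x$C^2))))
  invisible(x)
}

#' Serialize a subspace to JSON
#'
#' @param s a `subspace`.
#' @param path output path.
#' @export
write_subspace <- function(s, path) {
  stopifnot(inherits(s, "subspace"))
  payload <- list(word1 = s$word1, word2 = s$word2, technique = s$technique,
                  k = s$k, dims = s$dims)
  for (nm in c("V", "N", "M", "X", "C", "Vn", "Nn", "Mn", "Xn", "Cn")) {
    payload[[nm]] <- unname(s[[nm]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subspace written by [write_subspace()]
#'
#' @param path JSON path.
#' @return a `subspace`.
#' @export
read_subspace <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- new_subspace(p$dims, p$V, p$N, p$M, p$X, p$C,
                    word1 = p$word1, word2 = p$word2, technique = p$technique)
  s
}
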