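# Persistence for PMI matrices: MatrixMarket coordinate file plus row/column
# label TSVs and a JSON metadata sidecar.

#' Write a PMI matrix to a directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `rows.tsv` and
#' `cols.tsv` (`word<TAB>frequency`) and `meta.json` (W, window, smoothing).
#' Values are written with 17 significant digits so a write/read round-trip
#' reproduces every stored double bit-exactly.
#'
#' @param pmi a `pmi_matrix`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pmi_matrix <- function(pmi, dir) {
  stopifnot(inherits(pmi, "pmi_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- Matrix::summary(pmi$pmi)
  ord <- order(tr$j, tr$i)
  lines <- c("%%MatrixMarket matrix coordinate real general",
             sprintf("%d %d %d", nrow(pmi$pmi), ncol(pmi$pmi), length(tr$i)),
             sprintf("%d %d %s", tr$i[ord], tr$j[ord],
                     formatC(tr$x[ord], digits = 17, format = "g")))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(word = rownames(pmi$pmi), freq = unname(pmi$vocab_freq)),
    file.path(dir, "rows.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(word = colnames(pmi$pmi), freq = unname(pmi$context_freq)),
    file.path(dir, "cols.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(total_W = pmi$total_W, window = pmi$window,
         smoothing_a = pmi$smoothing_a),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a PMI matrix written by [write_pmi_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `rows.tsv`, `cols.tsv`,
#'   `meta.json`.
#' @return a `pmi_matrix`.
#' @export
read_pmi_matrix <- function(dir) {
  for (f in c("matrix.mtx", "rows.tsv", "cols.tsv", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("PMI matrix directory %s is missing %s", dir, f))
    }
  }
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rows <- utils::read.table(file.path(dir, "rows.tsv"), sep = "\t",
                            quote = "", comment.char = "",
                            col.names = c("word", "freq"),
                            colClasses = c("character", "integer"))
  cols <- utils::read.table(file.path(dir, "cols.tsv"), sep = "\t",
                            quote = "", comment.char = "",
                            col.names = c("word", "freq"),
                            colClasses = c("character", "integer"))
  if (nrow(rows) != nrow(m) || nrow(cols) != ncol(m)) {
    stop("row/column label files do not match the matrix dimensions")
  }
  dimnames(m) <- list(rows$word, cols$word)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(pmi = m,
                 vocab_freq = stats::setNames(rows$freq, rows$word),
                 context_freq = stats::setNames(cols$freq, cols$word),
                 total_W = meta$total_W,
                 window = meta$window,
                 smoothing_a = meta$smoothing_a),
            class = "pmi_matrix")
}

#' Read a rated-dyad table
#'
#' @param path CSV with header `verb,noun,class,metaphoricity,meaningfulness,
#'   familiarity`; class labels must be `literal`, `conventional` or `novel`,
#'   ratings within \[1, 7\], (verb, noun) pairs unique.
#' @return data.frame of class `dyad_dataset`.
#' @export
read_dyads <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_dyad_dataset(d)
}

#' Validate a rated-dyad data.frame
#'
#' @param d data.frame with the columns described in [read_dyads()].
#' @return the validated data.frame with class `dyad_dataset` prepended.
#' @export
as_dyad_dataset <- function(d) {
  need <- c("verb", "noun", "class", "metaphoricity", "meaningfulness",
            "familiarity")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop(sprintf("dyad table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(d$class %in% c("literal", "conventional", "novel"))) {
    stop("dyad class labels must be literal, conventional or novel")
  }
  ratings <- as.matrix(d[, c("metaphoricity", "meaningfulness", "familiarity")])
  if (any(!is.finite(ratings)) || any(ratings < 1) || any(ratings > 7)) {
    stop("ratings must be finite and within [1, 7]")
  }
  if (anyDuplicated(paste(d$verb, d$noun, sep = "\r"))) {
    stop("(verb, noun) pairs must be unique")
  }
  class(d) <- unique(c("dyad_dataset", class(d)))
  d
}

#' Write a rated-dyad table to CSV
#'
#' @param d a `dyad_dataset`.
#' @param path output CSV path.
#' @export
write_dyads <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
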