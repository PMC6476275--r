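# Deterministic synthetic data: a hand-countable micro-corpus, a
# topic-structured corpus generator, and a rated-dyad generator emulating
# the shape of the human judgement dataset (three balanced classes, 1-7
# ratings, metaphoricity negatively correlated with meaningfulness and
# familiarity).

#' A fixed micro-corpus with hand-countable statistics
#'
#' Twelve short sentences over a ~20-type vocabulary, small enough that
#' co-occurrence counts and PMI values can be tabulated by hand. Returns
#' identical bytes on every call.
#'
#' @return a single character string of raw text.
#' @export
micro_corpus <- function() {
  paste(
    "the cat sat on the mat.",
    "the dog sat on the rug.",
    "a cat saw a dog.",
    "the dog saw the cat.",
    "a bird sang on the mat.",
    "the bird saw the cat sit.",
    "the cat and the dog ran.",
    "a dog ran to the rug.",
    "the bird sat on the rug.",
    "a cat ran to the mat.",
    "the dog and the bird sat.",
    "a bird and a cat sang.",
    sep = " ")
}

#' Specification of a topic-structured synthetic corpus
#'
#' Sentences are drawn from one of `n_topics` topics; each topic has its own
#' word inventory plus `bridge_words` words shared with every other topic,
#' so planted word pairs have controllably overlapping co-occurrence
#' profiles: within-topic pairs share many non-zero PMI dimensions,
#' cross-topic pairs share only the bridges (none, when `bridge_words = 0`).
#'
#' @param n_topics number of topics (>= 1).
#' @param words_per_topic topic-exclusive word types per topic (>= 1).
#' @param bridge_words word types shared by each topic pair (>= 0).
#' @param n_sentences sentences to generate (>= 1).
#' @param sentence_length inclusive `c(min, max)` token range.
#' @param seed RNG seed fixing the output exactly.
#' @return list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_topics = 3L, words_per_topic = 12L,
                        bridge_words = 2L, n_sentences = 400L,
                        sentence_length = c(4L, 8L), seed = 42L) {
  spec <- list(n_topics = as.integer(n_topics),
               words_per_topic = as.integer(words_per_topic),
               bridge_words = as.integer(bridge_words),
               n_sentences = as.integer(n_sentences),
               sentence_length = as.integer(sentence_length),
               seed = as.integer(seed))
  if (spec$n_topics < 1L || spec$words_per_topic < 1L || spec$n_sentences < 1L) {
    stop("invalid corpus spec: n_topics, words_per_topic and n_sentences must be >= 1")
  }
  if (spec$bridge_words < 0L) stop("invalid corpus spec: bridge_words must be >= 0")
  if (length(spec$sentence_length) != 2L ||
      spec$sentence_length[1L] < 1L ||
      spec$sentence_length[2L] < spec$sentence_length[1L]) {
    stop("invalid corpus spec: sentence_length must be c(min, max) with 1 <= min <= max")
  }
  structure(spec, class = "corpus_spec")
}

# topic-exclusive and bridge word inventories for a spec
.topic_inventories <- function(spec) {
  topics <- lapply(seq_len(spec$n_topics), function(t) {
    sprintf("t%dw%02d", t, seq_len(spec$words_per_topic))
  })
  bridges <- list()
  if (spec$n_topics >= 2L && spec$bridge_words > 0L) {
    for (t1 in seq_len(spec$n_topics - 1L)) {
      for (t2 in (t1 + 1L):spec$n_topics) {
        bridges[[paste(t1, t2)]] <- sprintf("br%d%dw%02d", t1, t2,
                                            seq_len(spec$bridge_words))
      }
    }
  }
  list(topics = topics, bridges = bridges)
}

#' Generate a topic-structured synthetic corpus
#'
#' @param spec a [corpus_spec()].
#' @return list of tokenized sentences (the same shape [clean_corpus()]
#'   produces); identical for identical specs.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  inv <- .topic_inventories(spec)
  pools <- lapply(seq_len(spec$n_topics), function(t) {
    incident <- unlist(inv$bridges[grepl(sprintf("(^| )%d( |$)", t),
                                         names(inv$bridges))],
                       use.names = FALSE)
    c(inv$topics[[t]], incident)
  })
  .with_seed(spec$seed, {
    lapply(seq_len(spec$n_sentences), function(i) {
      t <- sample.int(spec$n_topics, 1L)
      len <- sample(seq(spec$sentence_length[1L], spec$sentence_length[2L]), 1L)
      sample(pools[[t]], len, replace = TRUE)
    })
  })
}

#' Specification of synthetic dyad ratings
#'
#' Metaphoricity is a linear combination of named geometric features plus
#' Gaussian noise, clipped to the rating range; meaningfulness and
#' familiarity are driven by the same latent signal with negative slopes,
#' reproducing the negative correlation with metaphoricity seen in human
#' judgements. Class labels (literal / conventional / novel) are assigned
#' by latent tertiles, so the three classes are balanced by construction.
#' The default slopes and intercepts are calibrated once to the published
#' per-class rating means of the judgement study this emulates
#' (metaphoricity 2.74 / 3.98 / 5.00, meaningfulness 5.99 / 5.17 / 4.09,
#' familiarity 3.85 / 2.97 / 2.15 on the 1-7 scale).
#'
#' @param coefficients named numeric vector of weights over canonical
#'   feature names ([geometry_feature_names()]) defining the latent signal.
#' @param noise_sd rating noise SD (default 0.5, about the published
#'   per-class SE scaled to item level).
#' @param clip inclusive rating range (default `c(1, 7)`).
#' @param seed RNG seed.
#' @return list of class `rating_spec`.
#' @export
rating_spec <- function(coefficients = c(dist_VpNp = 1, mean_VpMp_NpMp = 0.7,
                                         frac_VX_NX = 0.4),
                        noise_sd = 0.5, clip = c(1, 7), seed = 7L) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("coefficients must be named by canonical feature names")
  }
  unknown <- setdiff(names(coefficients), geometry_feature_names())
  if (length(unknown)) {
    stop(sprintf("unknown feature name(s) in coefficients: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(clip) != 2L || clip[2L] <= clip[1L]) stop("clip must be c(lo, hi), lo < hi")
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 clip = clip, seed = as.integer(seed),
                 # intercept / slope per rating on the standardized latent
                 calibration = list(
                   metaphoricity = c(intercept = 3.91, slope = 1.04),
                   meaningfulness = c(intercept = 5.04, slope = -0.87),
                   familiarity = c(intercept = 3.00, slope = -0.78))),
            class = "rating_spec")
}

#' Generate a rated-dyad dataset from computed features
#'
#' @param spec a [rating_spec()].
#' @param features n x 48 feature matrix for the planted dyads (canonical
#'   column names); `NaN` cells are treated as 0 signal.
#' @param verbs,nouns character vectors naming the dyads (unique pairs).
#' @return a `dyad_dataset` data.frame with columns verb, noun, class,
#'   metaphoricity, meaningfulness, familiarity.
#' @export
generate_dyad_dataset <- function(spec, features, verbs, nouns) {
  stopifnot(inherits(spec, "rating_spec"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(verbs) != n || length(nouns) != n) {
    stop("verbs and nouns must match the feature matrix rows")
  }
  if (n < 3L) stop("too few dyads: need at least 3 for three classes")
  used <- names(spec$coefficients)
  missing_f <- setdiff(used, colnames(features))
  if (length(missing_f)) {
    stop(sprintf("feature matrix is missing coefficient feature(s): %s",
                 paste(missing_f, collapse = ", ")))
  }
  Fm <- features[, used, drop = FALSE]
  Fm[is.nan(Fm)] <- 0
  latent <- drop(Fm %*% spec$coefficients)
  s <- stats::sd(latent)
  z <- if (s > 0) (latent - mean(latent)) / s else latent * 0
  clip <- function(x) pmin(spec$clip[2L], pmax(spec$clip[1L], x))
  cal <- spec$calibration
  ratings <- .with_seed(spec$seed, {
    lapply(cal, function(cs) {
      clip(cs[["intercept"]] + cs[["slope"]] * z +
             stats::rnorm(n, sd = spec$noise_sd))
    })
  })
  # balanced classes from latent tertiles: low latent -> literal
  ord <- order(z, paste(verbs, nouns), method = "radix")
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  cls <- character(n)
  cls[ord] <- rep(c("literal", "conventional", "novel"), times = sizes)
  as_dyad_dataset(data.frame(
    verb = verbs, noun = nouns, class = cls,
    metaphoricity = ratings$metaphoricity,
    meaningfulness = ratings$meaningfulness,
    familiarity = ratings$familiarity,
    stringsAsFactors = FALSE))
}

#' Synthesize a complete desk-scale study
#'
#' Generates a topic-structured corpus, builds its PMI matrix, plants a set
#' of dyads (pairs of vocabulary words), extracts their geometric features
#' under one technique and generates ratings from those features. The
#' ratings are by construction functions of the model's own feature space:
#' this exercises the recovery machinery end to end, it does not test the
#' empirical claim that real judgements follow subspace geometry.
#'
#' The default smoothing follows the design rationale of the PMI weighting:
#' `smoothing_a = NULL` sets a to the mean context-word frequency of the
#' generated corpus, the same relationship the corpus-scale default of
#' 10000 has to its corpus.
#'
#' @param corpus a [corpus_spec()].
#' @param ratings a [rating_spec()].
#' @param n_dyads number of planted dyads (default 228, three balanced
#'   classes of 76).
#' @param technique subspace technique used to generate the features.
#' @param k subspace dimensionality (desk-scale default 20).
#' @param vocab_size vocabulary limit.
#' @param window co-occurrence half-window.
#' @param smoothing_a PMI smoothing constant, or `NULL` for the mean
#'   context frequency.
#' @return list with `sentences`, `pmi`, `verbs`, `nouns`, `features`
#'   (n x 48) and `dyads` (a `dyad_dataset`).
#' @export
synthesize_study <- function(corpus = corpus_spec(), ratings = rating_spec(),
                             n_dyads = 228L, technique = "indy", k = 20L,
                             vocab_size = 5000L, window = 2L,
                             smoothing_a = NULL) {
  sentences <- generate_corpus(corpus)
  vocab <- build_vocabulary(sentences, vocab_size)
  tab <- count_cooccurrences(sentences, vocab, window)
  if (is.null(smoothing_a)) smoothing_a <- mean(tab$context_freq)
  pmi <- compute_pmi(tab, pmi_config(smoothing_a))
  words <- rownames(pmi$pmi)
  if (length(words) < 2L) stop("corpus too small to plant dyads")
  pairs <- .with_seed(corpus$seed + 1L, {
    max_pairs <- length(words) * (length(words) - 1L)
    if (n_dyads > max_pairs) stop("too few vocabulary words for the requested dyad count")
    idx <- sample.int(max_pairs, n_dyads)
    v <- (idx - 1L) %/% (length(words) - 1L) + 1L
    u <- (idx - 1L) %% (length(words) - 1L) + 1L
    u <- ifelse(u >= v, u + 1L, u)
    list(verbs = words[v], nouns = words[u])
  })
  features <- dyad_feature_matrix(pmi, pairs$verbs, pairs$nouns,
                                  technique = technique, k = k)
  dyads <- generate_dyad_dataset(ratings, features, pairs$verbs, pairs$nouns)
  list(sentences = sentences, pmi = pmi, verbs = pairs$verbs,
       nouns = pairs$nouns, features = features, dyads = dyads)
}
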