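# Orchestration of the full experiment from one configuration: build or
# load a PMI matrix, run every requested technique over a rated-dyad table,
# extract features, evaluate full-feature / single-feature / VIF-selected
# models, optionally the static-embedding baseline, and write a report
# bundle (CSV tables + JSON manifest + log).

#' Experiment configuration
#'
#' Either `corpus` (a text file path, or a list of tokenized sentences) or
#' `matrix_dir` (a directory written by [write_pmi_matrix()]) must be
#' supplied.
#'
#' @param dyads path to a dyad CSV ([read_dyads()]) or a `dyad_dataset`.
#' @param corpus corpus path or sentence list (ignored when `matrix_dir`
#'   given).
#' @param matrix_dir directory holding a persisted PMI matrix.
#' @param techniques subset of `c("indy", "mean", "geom")`.
#' @param k subspace dimensionality.
#' @param vocab_size vocabulary limit when building from a corpus.
#' @param window co-occurrence half-window.
#' @param smoothing_a PMI smoothing constant; `NULL` = mean context
#'   frequency of the corpus at hand.
#' @param fac VIF threshold.
#' @param max_features VIF selection cap.
#' @param n_perm permutations for significance tests.
#' @param seed RNG seed for every stochastic step.
#' @param embeddings optional word2vec-text embedding path (enables the
#'   cosine baseline).
#' @param out_dir report output directory.
#' @param strict strict (error) vs permissive (flag-and-continue) handling
#'   of degenerate geometry.
#' @return list of class `run_config`.
#' @export
run_config <- function(dyads, corpus = NULL, matrix_dir = NULL,
                       techniques = c("indy", "mean", "geom"), k = 200L,
                       vocab_size = 200000L, window = 2L, smoothing_a = NULL,
                       fac = 2, max_features = 5L, n_perm = 10000L,
                       seed = 1L, embeddings = NULL, out_dir = "report",
                       strict = FALSE) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  if (is.null(corpus) && is.null(matrix_dir)) {
    stop("config needs either `corpus` or `matrix_dir`")
  }
  for (p in c(if (is.character(corpus)) corpus, matrix_dir,
              if (is.character(dyads)) dyads, embeddings)) {
    if (!is.null(p) && !file.exists(p)) stop(sprintf("path does not exist: %s", p))
  }
  structure(list(dyads = dyads, corpus = corpus, matrix_dir = matrix_dir,
                 techniques = techniques, k = as.integer(k),
                 vocab_size = as.integer(vocab_size),
                 window = as.integer(window), smoothing_a = smoothing_a,
                 fac = fac, max_features = as.integer(max_features),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 embeddings = embeddings, out_dir = out_dir,
                 strict = isTRUE(strict)),
            class = "run_config")
}

#' Read a YAML experiment configuration
#'
#' Flat key-value file with the fields of [run_config()].
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full experiment
#'
#' For every technique and every target (the three graded ratings plus the
#' class labels): full-feature leave-one-out evaluation, the ranked
#' single-feature table, and the VIF-selected model with its all-in
#' coefficients; plus the cosine baseline when embeddings are configured.
#' Writes `summary.csv`, per-(technique, target) single-feature and VIF
#' CSVs, `manifest.json` and `run.log` under `cfg$out_dir`; reruns with the
#' same configuration produce byte-identical bundles.
#'
#' Dyads with an out-of-vocabulary word are excluded with a logged list.
#' For class-target feature ranking and VIF selection the class labels are
#' encoded ordinally (literal = 1, conventional = 2, novel = 3, the
#' metaphoricity ordering).
#'
#' @param cfg a [run_config()].
#' @return the report, invisibly: list with `summary` (data.frame),
#'   per-technique details, `baseline` (or NULL), `log` and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, code) {
    withCallingHandlers(
      tryCatch(code, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note("[%s] warning: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  pmi <- stage("matrix", {
    if (!is.null(cfg$matrix_dir)) {
      read_pmi_matrix(cfg$matrix_dir)
    } else {
      sentences <- if (is.character(cfg$corpus)) read_corpus(cfg$corpus) else cfg$corpus
      vocab <- build_vocabulary(sentences, cfg$vocab_size)
      tab <- count_cooccurrences(sentences, vocab, cfg$window)
      a <- if (is.null(cfg$smoothing_a)) mean(tab$context_freq) else cfg$smoothing_a
      compute_pmi(tab, pmi_config(a))
    }
  })
  note("matrix: %d x %d, W = %d", nrow(pmi$pmi), ncol(pmi$pmi), pmi$total_W)

  dyads <- stage("dyads", {
    if (is.character(cfg$dyads)) read_dyads(cfg$dyads) else as_dyad_dataset(cfg$dyads)
  })
  in_vocab <- dyads$verb %in% rownames(pmi$pmi) & dyads$noun %in% rownames(pmi$pmi)
  if (any(!in_vocab)) {
    note("dyads: excluded %d out-of-vocabulary dyad(s): %s", sum(!in_vocab),
         paste(paste(dyads$verb[!in_vocab], dyads$noun[!in_vocab]),
               collapse = "; "))
    dyads <- dyads[in_vocab, , drop = FALSE]
  }
  if (nrow(dyads) < 6L) stop("too few in-vocabulary dyads to evaluate")
  note("dyads: evaluating %d dyads", nrow(dyads))

  rating_targets <- c("metaphoricity", "meaningfulness", "familiarity")
  class_ord <- c(literal = 1, conventional = 2, novel = 3)
  summary_rows <- list()
  details <- list()
  for (tech in cfg$techniques) {
    feats <- stage(paste0("features-", tech), {
      dyad_feature_matrix(pmi, dyads$verb, dyads$noun, technique = tech,
                          k = cfg$k, strict = cfg$strict)
    })
    Fs <- stage(paste0("standardize-", tech), standardize_features(feats))
    tech_detail <- list(features = feats)
    for (target in c(rating_targets, "class")) {
      nm <- paste(tech, target, sep = "/")
      if (target == "class") {
        y <- unname(class_ord[dyads$class])
        full <- stage(nm, loo_logistic_ovr_cv(Fs, dyads$class, technique = tech))
        full_score <- full$accuracy
      } else {
        y <- dyads[[target]]
        full <- stage(nm, loo_linear_cv(Fs, y, target = target, technique = tech))
        full_score <- full$r
      }
      ranking <- stage(nm, rank_single_features(Fs, y))
      sel <- stage(nm, vif_select(ranking, Fs, fac = cfg$fac,
                                  max_features = cfg$max_features))
      Fsel <- Fs[, sel$selected, drop = FALSE]
      if (target == "class") {
        vifcv <- stage(nm, loo_logistic_ovr_cv(Fsel, dyads$class, technique = tech))
        vif_score <- vifcv$accuracy
      } else {
        vifcv <- stage(nm, loo_linear_cv(Fsel, y, target = target, technique = tech))
        vif_score <- vifcv$r
      }
      # all-in OLS coefficients of the selected features (Table-7 layout)
      beta <- stage(nm, .ols_coef(cbind(1, Fsel), y))
      coefs <- stats::setNames(beta[-1L], sel$selected)
      summary_rows[[nm]] <- data.frame(
        technique = tech, target = target,
        measure = if (target == "class") "accuracy" else "pearson_r",
        full_features = full_score, vif_selected = vif_score,
        n_selected = length(sel$selected), stringsAsFactors = FALSE)
      tech_detail[[target]] <- list(full = full, ranking = ranking,
                                    selection = sel, vif_cv = vifcv,
                                    coefficients = coefs)
      note("%s: full = %.4f, vif(%d) = %.4f", nm, full_score,
           length(sel$selected), vif_score)
    }
    details[[tech]] <- tech_detail
  }

  baseline <- NULL
  if (!is.null(cfg$embeddings)) {
    baseline <- stage("baseline", {
      emb <- load_embeddings(cfg$embeddings)
      cosines <- suppressMessages(dyad_cosines(emb, dyads, strict = cfg$strict))
      baseline_evaluate(cosines, dyads)
    })
    note("baseline: class accuracy = %.4f over %d dyads",
         baseline$class_cv$accuracy, baseline$n_used)
  }

  summary_df <- do.call(rbind, unname(summary_rows))
  manifest <- list(
    package = "metaphorspace",
    version = as.character(utils::packageVersion("metaphorspace")),
    config = cfg[setdiff(names(cfg), c("dyads", "corpus", "out_dir"))],
    dyads_source = if (is.character(cfg$dyads)) cfg$dyads else "<in-memory>",
    corpus_source = if (is.character(cfg$corpus)) cfg$corpus
      else if (!is.null(cfg$corpus)) "<in-memory>" else NULL,
    n_dyads = nrow(dyads),
    feature_names = geometry_feature_names())
  manifest$config_hash <- .config_hash(manifest$config)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  for (tech in names(details)) {
    for (target in c(rating_targets, "class")) {
      det <- details[[tech]][[target]]
      utils::write.csv(det$ranking,
                       file.path(cfg$out_dir,
                                 sprintf("single_feature_%s_%s.csv", tech, target)),
                       row.names = FALSE, quote = FALSE)
      vif_tab <- data.frame(feature = det$selection$selected,
                            coefficient = unname(det$coefficients))
      utils::write.csv(vif_tab,
                       file.path(cfg$out_dir,
                                 sprintf("vif_%s_%s.csv", tech, target)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(baseline)) {
    utils::write.csv(
      data.frame(target = c(rating_targets, "class"),
                 value = c(unname(baseline$correlations),
                           baseline$class_cv$accuracy)),
      file.path(cfg$out_dir, "baseline.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(summary = summary_df, details = details, baseline = baseline,
                 log = log_lines, manifest = manifest))
}

# md5 of the canonical JSON encoding of the configuration
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
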