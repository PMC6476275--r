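# Mapping geometric features to human judgements: standardization,
# leave-one-out linear and one-vs-rest logistic evaluation, single-feature
# Pearson ranking, VIF-constrained feature selection, and significance
# machinery (Fisher r-to-z, permutation tests).

# L2 penalty used when a logistic fit separates or fails to converge.
.RIDGE_LAMBDA <- 1e-2

#' Standardize a feature matrix
#'
#' Column-wise z-scores (sample SD, n - 1 denominator), computed once on the
#' full dataset before cross-validation. Constant columns are set to zero
#' with a warning. `NaN` cells (features undefined for a degenerate
#' subspace) are imputed as 0 -- the column mean -- after standardization,
#' with a warning giving the count.
#'
#' @param F numeric matrix (rows = dyads, columns = named features).
#' @return matrix with attribute `standardized = TRUE`.
#' @export
standardize_features <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) < 2L) stop("insufficient data: need at least 2 rows to standardize")
  n_nan <- sum(is.nan(F))
  out <- F
  constant <- logical(ncol(F))
  for (j in seq_len(ncol(F))) {
    col <- F[, j]
    ok <- !is.nan(col)
    mu <- mean(col[ok])
    sdv <- stats::sd(col[ok])
    if (!is.finite(sdv) || sdv == 0) {
      out[, j] <- 0
      constant[j] <- TRUE
    } else {
      out[, j] <- (col - mu) / sdv
      out[is.nan(col), j] <- 0
    }
  }
  if (any(constant)) {
    warning(sprintf("constant feature column(s) set to zero: %s",
                    paste(colnames(F)[constant], collapse = ", ")))
  }
  if (n_nan > 0) {
    warning(sprintf("%d undefined feature value(s) imputed to the column mean", n_nan))
  }
  attr(out, "standardized") <- TRUE
  out
}

# OLS coefficients for design X (with intercept column already prepended);
# rank-deficient designs fall back to the minimum-norm pseudoinverse
# solution.
.ols_coef <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank == ncol(X)) {
    return(qr.coef(qr_x, y))
  }
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Leave-one-out cross-validated linear regression
#'
#' For each row i an ordinary-least-squares model with intercept is fit on
#' the other n - 1 rows and predicts row i; the summary is the Pearson
#' correlation between the n held-out predictions and the true ratings.
#' Singular designs use the minimum-norm pseudoinverse solution (one
#' warning).
#'
#' @param F standardized feature matrix.
#' @param y numeric target ratings, length nrow(F).
#' @param target optional target name carried into the result.
#' @param technique optional technique name carried into the result.
#' @return list of class `cv_result` with `predictions`, `r`, `target`,
#'   `technique`, `kind = "linear"`.
#' @export
loo_linear_cv <- function(F, y, target = NA_character_,
                          technique = NA_character_) {
  F <- as.matrix(F)
  n <- nrow(F)
  stopifnot(length(y) == n)
  if (n <= ncol(F) + 1L) {
    warning("n <= p + 1: leave-one-out OLS is under-determined; using minimum-norm fits")
  }
  X <- cbind(1, F)
  singular_seen <- FALSE
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    if (!singular_seen && qr(Xi)$rank < ncol(Xi)) singular_seen <- TRUE
    beta <- suppressWarnings(.ols_coef(Xi, y[-i]))
    preds[i] <- drop(X[i, ] %*% beta)
  }
  if (singular_seen) warning("singular design in at least one fold; minimum-norm solution used")
  structure(list(predictions = preds,
                 r = stats::cor(preds, y),
                 target = target, technique = technique, kind = "linear"),
            class = "cv_result")
}

# Logistic fit returning a prediction function; plain ML via glm.fit, with a
# fixed small-L2 IRLS fallback on separation or non-convergence.
.fit_logistic <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  seps <- any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (fit$converged && !seps && all(is.finite(fit$coefficients))) {
    return(list(beta = fit$coefficients, regularized = FALSE))
  }
  list(beta = .ridge_logistic(X, y, .RIDGE_LAMBDA), regularized = TRUE)
}

# IRLS for L2-penalized logistic regression (intercept unpenalized).
.ridge_logistic <- function(X, y, lambda, max_iter = 100L, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(rep(lambda, p))
  pen[1, 1] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Leave-one-out one-vs-rest logistic classification
#'
#' For each held-out row, one binary logistic model per class is fit on the
#' remaining rows; the predicted class is the one whose model assigns the
#' highest probability (ties broken lexicographically on the class name).
#' On separation or non-convergence a fixed small L2 penalty is applied,
#' with one warning. The summary is held-out accuracy.
#'
#' @param F standardized feature matrix.
#' @param classes character or factor class labels, length nrow(F).
#' @param technique optional technique name carried into the result.
#' @return list of class `cv_result` with `predictions` (character),
#'   `accuracy`, `technique`, `kind = "logistic"`.
#' @export
loo_logistic_ovr_cv <- function(F, classes, technique = NA_character_) {
  F <- as.matrix(F)
  n <- nrow(F)
  classes <- as.character(classes)
  stopifnot(length(classes) == n)
  levs <- sort(unique(classes))
  if (length(levs) < 2L) stop("need at least 2 classes present")
  X <- cbind(1, F)
  preds <- character(n)
  regularized <- FALSE
  for (i in seq_len(n)) {
    scores <- vapply(levs, function(cl) {
      yb <- as.numeric(classes[-i] == cl)
      fit <- .fit_logistic(X[-i, , drop = FALSE], yb)
      if (fit$regularized) regularized <<- TRUE
      eta <- drop(X[i, ] %*% fit$beta)
      1 / (1 + exp(-eta))
    }, numeric(1))
    # which.max takes the first maximum; levs is sorted, so ties resolve
    # lexicographically
    preds[i] <- levs[which.max(scores)]
  }
  if (regularized) {
    warning(sprintf("separation or non-convergence in at least one logistic fit; L2 penalty %g applied",
                    .RIDGE_LAMBDA))
  }
  structure(list(predictions = preds,
                 accuracy = mean(preds == classes),
                 technique = technique, kind = "logistic"),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  if (x$kind == "linear") {
    cat(sprintf("cv_result (linear%s): LOO Pearson r = %.4f over %d items\n",
                if (is.na(x$target)) "" else paste0(", ", x$target),
                x$r, length(x$predictions)))
  } else {
    cat(sprintf("cv_result (logistic): LOO accuracy = %.4f over %d items\n",
                x$accuracy, length(x$predictions)))
  }
  invisible(x)
}

#' Rank features by absolute Pearson correlation with a target
#'
#' @param F feature matrix (standardized or raw; r is scale-invariant).
#' @param y numeric target.
#' @return data.frame with columns `feature`, `r`, ordered by |r|
#'   descending with lexicographic tie-break; zero-variance features get
#'   r = 0 with a warning.
#' @export
rank_single_features <- function(F, y) {
  F <- as.matrix(F)
  stopifnot(length(y) == nrow(F))
  sds <- apply(F, 2, stats::sd)
  rs <- numeric(ncol(F))
  if (any(sds == 0)) {
    warning(sprintf("zero-variance feature(s) assigned r = 0: %s",
                    paste(colnames(F)[sds == 0], collapse = ", ")))
  }
  ok <- sds > 0
  rs[ok] <- suppressWarnings(as.numeric(stats::cor(F[, ok, drop = FALSE], y)))
  out <- data.frame(feature = colnames(F), r = rs, stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$feature, method = "radix"), , drop = FALSE]
}

#' VIF-constrained feature selection
#'
#' Seeds the selection with the top-|r| feature, then walks down the
#' ranking: each candidate is regressed (OLS with intercept) on the
#' already-selected set and appended only if its variance inflation factor
#' 1 / (1 - R^2) stays below `fac`. Selection stops at `max_features` or at
#' the end of the ranking.
#'
#' @param ranking data.frame from [rank_single_features()].
#' @param F feature matrix the ranking was computed on.
#' @param fac VIF threshold (default 2, a stringent collinearity bound).
#' @param max_features maximum number of selected features (default 5).
#' @return list of class `vif_selection`: `selected` (ordered names),
#'   `trace` (per-candidate feature, r, R^2, VIF, accepted flag), `fac`.
#' @export
vif_select <- function(ranking, F, fac = 2, max_features = 5L) {
  stopifnot(nrow(ranking) >= 1L)
  F <- as.matrix(F)
  selected <- ranking$feature[1L]
  trace <- data.frame(feature = ranking$feature[1L], r = ranking$r[1L],
                      r2 = NA_real_, vif = NA_real_, accepted = TRUE,
                      stringsAsFactors = FALSE)
  for (idx in seq_len(nrow(ranking))[-1L]) {
    if (length(selected) >= max_features) break
    cand <- ranking$feature[idx]
    X <- cbind(1, F[, selected, drop = FALSE])
    yc <- F[, cand]
    beta <- .ols_coef(X, yc)
    res <- yc - drop(X %*% beta)
    tss <- sum((yc - mean(yc))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(res^2) / tss
    vif <- if (r2 >= 1) Inf else 1 / (1 - r2)
    accept <- vif < fac
    trace <- rbind(trace, data.frame(feature = cand, r = ranking$r[idx],
                                     r2 = r2, vif = vif, accepted = accept,
                                     stringsAsFactors = FALSE))
    if (accept) selected <- c(selected, cand)
  }
  structure(list(selected = selected, trace = trace, fac = fac),
            class = "vif_selection")
}

#' @export
print.vif_selection <- function(x, ...) {
  cat(sprintf("vif_selection: %d feature(s) at fac = %g\n  %s\n",
              length(x$selected), x$fac, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Fisher r-to-z test for the difference of two correlations
#'
#' Independent-samples form: z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided normal p-value.
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 sample sizes, > 3.
#' @return list with `z` and `p`.
#' @export
fisher_r_to_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1: the Fisher transform is infinite at |r| = 1")
  }
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# evaluation metrics shared by the permutation machinery
.metric_fun <- function(metric) {
  switch(metric,
    pearson = function(pred, truth) stats::cor(pred, truth),
    accuracy = function(pred, truth) mean(pred == truth),
    macro_f1 = function(pred, truth) {
      levs <- sort(unique(truth))
      f1 <- vapply(levs, function(cl) {
        tp <- sum(pred == cl & truth == cl)
        fp <- sum(pred == cl & truth != cl)
        fn <- sum(pred != cl & truth == cl)
        if (tp == 0) return(0)
        prec <- tp / (tp + fp)
        rec <- tp / (tp + fn)
        2 * prec * rec / (prec + rec)
      }, numeric(1))
      mean(f1)
    },
    stop(sprintf("unknown metric '%s'", metric)))
}

# Run code with a locally-seeded RNG without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation test for a prediction metric
#'
#' With one prediction set, tests the metric against the label-shuffling
#' null: labels are permuted `n_perm` times and
#' p = (1 + #\{permuted metric >= observed\}) / (n_perm + 1).
#' With two prediction sets, tests the paired difference metric(a) -
#' metric(b) by randomly swapping the two predictions per item, with the
#' analogous one-sided p. `exhaustive = TRUE` enumerates every permutation
#' (all n! label orders, or all 2^n swap patterns) and reports the exact
#' proportion of permutations at or above the observed value.
#'
#' @param predictions_a predictions to evaluate.
#' @param truth true labels or ratings.
#' @param metric `"pearson"`, `"accuracy"` or `"macro_f1"`.
#' @param predictions_b optional second prediction set for a paired
#'   comparison.
#' @param n_perm number of sampled permutations (default 10000).
#' @param seed RNG seed; required so results are reproducible.
#' @param exhaustive enumerate all permutations exactly (small n only).
#' @return list with `p`, `observed`, `n_perm`.
#' @export
permutation_test <- function(predictions_a, truth,
                             metric = c("pearson", "accuracy", "macro_f1"),
                             predictions_b = NULL, n_perm = 10000L, seed,
                             exhaustive = FALSE) {
  metric <- match.arg(metric)
  mfun <- .metric_fun(metric)
  n <- length(truth)
  if (length(predictions_a) != n ||
      (!is.null(predictions_b) && length(predictions_b) != n)) {
    stop("predictions and truth must have equal length")
  }
  if (!exhaustive && missing(seed)) stop("a seed is required for sampled permutations")
  if (is.null(predictions_b)) {
    observed <- mfun(predictions_a, truth)
    if (exhaustive) {
      perms <- .all_permutations(n)
      stats_perm <- apply(perms, 1, function(ix) mfun(predictions_a, truth[ix]))
      return(list(p = mean(stats_perm >= observed - 1e-12),
                  observed = observed, n_perm = nrow(perms)))
    }
    stats_perm <- .with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) mfun(predictions_a, truth[sample.int(n)]), numeric(1))
    })
  } else {
    observed <- mfun(predictions_a, truth) - mfun(predictions_b, truth)
    diff_for <- function(swap) {
      a <- ifelse(swap, predictions_b, predictions_a)
      b <- ifelse(swap, predictions_a, predictions_b)
      mfun(a, truth) - mfun(b, truth)
    }
    if (exhaustive) {
      grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
      stats_perm <- apply(grid, 1, diff_for)
      return(list(p = mean(stats_perm >= observed - 1e-12),
                  observed = observed, n_perm = nrow(grid)))
    }
    stats_perm <- .with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) diff_for(stats::runif(n) < 0.5), numeric(1))
    })
  }
  list(p = (1 + sum(stats_perm >= observed - 1e-12)) / (n_perm + 1),
       observed = observed, n_perm = n_perm)
}

# All permutations of 1..n as a matrix (n! rows); n is expected to be tiny.
.all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration is limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      # insert n at position pos of a permutation of 1..n-1
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}
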