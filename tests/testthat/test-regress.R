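test_that("standardization yields exact column z-scores and zeroes constants", {
  expect_equal(unname(standardize_features(cbind(x = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  expect_warning(out <- standardize_features(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "constant")
  expect_equal(unname(out[, "b"]), c(0, 0, 0))
  set.seed(41)
  Fm <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  Z <- standardize_features(Fm)
  expect_equal(unname(colMeans(Z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 5), tolerance = 1e-9)
  expect_error(standardize_features(Fm[1, , drop = FALSE]), "insufficient")
})

test_that("leave-one-out linear predictions match hand-solved two-point fits", {
  Fm <- cbind(x = c(0, 1, 2))
  y <- c(0, 1, 4)
  cv <- loo_linear_cv(Fm, y)
  # hold out each row, fit the line through the other two points by hand
  expect_equal(cv$predictions, c(-2, 2, 2))
  expect_equal(cv$r, cor(c(-2, 2, 2), y))
})

test_that("leave-one-out linear predictions match the hat-matrix closed form", {
  set.seed(42)
  Fm <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(60)
  cv <- loo_linear_cv(Fm, y)
  expect_equal(cv$predictions, oracle_loo_hat(Fm, y), tolerance = 1e-9)
})

test_that("noiseless linear targets are recovered perfectly; pure noise is not", {
  set.seed(43)
  Fm <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- drop(Fm %*% c(1, -2, 0.5, 0, 3, -1)) + 2
  expect_equal(loo_linear_cv(Fm, y)$r, 1, tolerance = 1e-9)
  y_noise <- rnorm(200)
  expect_lt(abs(loo_linear_cv(Fm, y_noise)$r), 0.2)
})

test_that("linear LOO is invariant to row order", {
  set.seed(44)
  Fm <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(Fm %*% c(1, 2, 3)) + rnorm(40, sd = 0.3)
  cv1 <- loo_linear_cv(Fm, y)
  perm <- sample.int(40)
  cv2 <- loo_linear_cv(Fm[perm, ], y[perm])
  expect_equal(cv2$predictions, cv1$predictions[perm], tolerance = 1e-9)
  expect_equal(cv2$r, cv1$r, tolerance = 1e-12)
})

test_that("rank-deficient designs warn and fall back to minimum-norm fits", {
  set.seed(45)
  x <- rnorm(20)
  Fm <- cbind(a = x, b = x)  # duplicated column
  y <- x + rnorm(20, sd = 0.1)
  expect_warning(cv <- loo_linear_cv(Fm, y), "singular|minimum-norm")
  expect_true(all(is.finite(cv$predictions)))
  expect_gt(cv$r, 0.9)
})

test_that("one-vs-rest logistic separates separable classes and fails shuffled labels", {
  set.seed(46)
  n <- 30
  cls <- rep(c("literal", "conventional", "novel"), each = n)
  Fm <- cbind(f1 = c(rnorm(n, -6), rnorm(n, 0), rnorm(n, 6)),
              f2 = rnorm(3 * n))
  Fs <- standardize_features(Fm)
  cv <- suppressWarnings(loo_logistic_ovr_cv(Fs, cls))
  expect_gt(cv$accuracy, 0.95)
  expect_true(all(cv$predictions %in% cls))
  # shuffled labels: accuracy near chance (permutation null band)
  shuffled <- sample(cls)
  cv0 <- suppressWarnings(loo_logistic_ovr_cv(Fs, shuffled))
  expect_lt(cv0$accuracy, 0.5)
  expect_error(loo_logistic_ovr_cv(Fs, rep("one", 3 * n)), "2 classes")
})

test_that("perfect separation triggers the penalized fallback with a warning", {
  cls <- rep(c("a", "b"), each = 10)
  Fm <- cbind(f = c(seq(-2, -1, length.out = 10), seq(1, 2, length.out = 10)))
  expect_warning(cv <- loo_logistic_ovr_cv(standardize_features(Fm), cls),
                 "penalty")
  expect_gt(cv$accuracy, 0.9)
})

test_that("single-feature ranking orders by |r| with deterministic ties", {
  set.seed(47)
  y <- rnorm(50)
  Fm <- cbind(zzz_same = y, aaa_anti = -y, weak = y + rnorm(50, sd = 3))
  rk <- rank_single_features(Fm, y)
  expect_equal(rk$r[rk$feature == "zzz_same"], 1, tolerance = 1e-12)
  expect_equal(rk$r[rk$feature == "aaa_anti"], -1, tolerance = 1e-12)
  # |r| ties at 1: lexicographic tie-break puts aaa_anti first
  expect_identical(rk$feature[1:2], c("aaa_anti", "zzz_same"))
  expect_identical(rk$feature[3], "weak")
  # each r matches the direct covariance formula
  for (j in seq_len(ncol(Fm))) {
    r_direct <- sum((Fm[, j] - mean(Fm[, j])) * (y - mean(y))) /
      sqrt(sum((Fm[, j] - mean(Fm[, j]))^2) * sum((y - mean(y))^2))
    expect_equal(rk$r[rk$feature == colnames(Fm)[j]], r_direct,
                 tolerance = 1e-12)
  }
  expect_warning(rank_single_features(cbind(const = rep(1, 50), ok = y), y),
                 "zero-variance")
})

test_that("VIF selection rejects collinear candidates and accepts orthogonal ones", {
  set.seed(48)
  n <- 64
  x1 <- as.numeric(scale(rnorm(n)))
  e_raw <- rnorm(n)
  e <- as.numeric(scale(residuals(lm(e_raw ~ x1))))
  # planted coefficient of determination against x1
  plant <- function(r2) as.numeric(scale(sqrt(r2) * x1 + sqrt(1 - r2) * e))
  y <- x1 + 0.5 * plant(0.6) + rnorm(n, sd = 0.1)
  Fm <- cbind(top = x1, dup = x1, r2_06 = plant(0.6), r2_04 = plant(0.4),
              orth = e)
  ranking <- data.frame(feature = c("top", "dup", "r2_06", "r2_04", "orth"),
                        r = c(0.9, 0.9, 0.5, 0.4, 0.3))
  sel <- vif_select(ranking, Fm, fac = 2, max_features = 5)
  tr <- sel$trace
  expect_false(tr$accepted[tr$feature == "dup"])       # R^2 = 1, VIF infinite
  expect_equal(tr$r2[tr$feature == "dup"], 1, tolerance = 1e-9)
  expect_false(tr$accepted[tr$feature == "r2_06"])     # 1/(1-0.6) = 2.5 >= 2
  expect_equal(tr$r2[tr$feature == "r2_06"], 0.6, tolerance = 1e-9)
  expect_true(tr$accepted[tr$feature == "r2_04"])      # 1/(1-0.4) < 2
  expect_identical(sel$selected[1], "top")
  # mutually orthogonal standardized features are all accepted
  Q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5)))
  Fo <- apply(Q, 2, function(c) as.numeric(scale(c)))
  colnames(Fo) <- paste0("q", 1:5)
  rk <- data.frame(feature = colnames(Fo), r = seq(0.5, 0.1, by = -0.1))
  sel_o <- vif_select(rk, Fo, fac = 2, max_features = 5)
  expect_length(sel_o$selected, 5)
  # post-hoc internal collinearity: every selected feature has VIF < fac
  for (f in sel_o$selected) {
    others <- setdiff(sel_o$selected, f)
    r2 <- summary(lm(Fo[, f] ~ Fo[, others]))$r.squared
    expect_lt(1 / (1 - r2), 2)
  }
})

test_that("VIF selection stops at max_features", {
  set.seed(49)
  Fm <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("f", 1:8)))
  rk <- rank_single_features(Fm, rnorm(50))
  sel <- vif_select(rk, Fm, fac = 10, max_features = 3)
  expect_length(sel$selected, 3)
})

test_that("Fisher r-to-z test matches the closed form and its symmetries", {
  expect_equal(fisher_r_to_z_test(0.4, 100, 0.4, 50)$z, 0)
  expect_equal(fisher_r_to_z_test(0.4, 100, 0.4, 50)$p, 1)
  a <- fisher_r_to_z_test(0.5, 228, 0.3, 228)
  b <- fisher_r_to_z_test(-0.5, 228, -0.3, 228)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # independent closed-form evaluation
  z_direct <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 225 + 1 / 225)
  expect_equal(a$z, z_direct, tolerance = 1e-12)
  expect_equal(a$p, 2 * (1 - pnorm(abs(z_direct))), tolerance = 1e-12)
  expect_error(fisher_r_to_z_test(1, 10, 0.5, 10), "infinite")
  expect_error(fisher_r_to_z_test(0.2, 3, 0.5, 10), "exceed 3")
})

test_that("permutation p-values match exhaustive enumeration on 6 items", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  res <- permutation_test(pred, truth, metric = "accuracy", exhaustive = TRUE)
  perms <- oracle_all_perms(6)
  obs <- mean(pred == truth)
  stats <- apply(perms, 1, function(ix) mean(pred == truth[ix]))
  expect_equal(res$p, mean(stats >= obs - 1e-12), tolerance = 1e-12)
  expect_equal(res$observed, obs)
  expect_equal(res$n_perm, 720)
  # pearson metric under exhaustive enumeration as well
  y <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.4)
  p2 <- c(1.0, 3.0, 2.5, 4.8, 4.0, 1.1)
  res2 <- permutation_test(p2, y, metric = "pearson", exhaustive = TRUE)
  stats2 <- apply(perms, 1, function(ix) cor(p2, y[ix]))
  expect_equal(res2$p, mean(stats2 >= cor(p2, y) - 1e-12), tolerance = 1e-12)
})

test_that("sampled permutation tests are deterministic under a fixed seed", {
  set.seed(50)
  truth <- rnorm(30)
  pred <- truth + rnorm(30)
  r1 <- permutation_test(pred, truth, metric = "pearson", n_perm = 500, seed = 9)
  r2 <- permutation_test(pred, truth, metric = "pearson", n_perm = 500, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  # identical prediction sets in paired mode: observed difference 0, p ~ 1
  res <- permutation_test(pred, truth, metric = "pearson",
                          predictions_b = pred, n_perm = 200, seed = 4)
  expect_equal(res$observed, 0)
  expect_gt(res$p, 0.5)
  expect_error(permutation_test(pred, truth[1:10], seed = 1), "equal length")
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(51)
  ps <- replicate(200, {
    y <- rnorm(12)
    pred <- rnorm(12)
    permutation_test(pred, y, metric = "pearson", n_perm = 99,
                     seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
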