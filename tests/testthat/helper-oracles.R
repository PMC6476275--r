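# Independent oracles used across the suite. These deliberately take
# different computational routes from the package internals: dense O(n^2)
# scans, law-of-cosines / Heron formulas on pairwise distances, hat-matrix
# leave-one-out identities, and brute-force permutation enumeration.

# Dense brute-force within-sentence pair scan: counts[w, c] for vocabulary
# word w and any corpus type c within `window` positions.
oracle_cooc_counts <- function(sentences, vocab_words, window) {
  types <- sort(unique(unlist(sentences)))
  m <- matrix(0L, nrow = length(vocab_words), ncol = length(types),
              dimnames = list(vocab_words, types))
  for (s in sentences) {
    for (i in seq_along(s)) {
      if (!(s[i] %in% vocab_words)) next
      for (j in seq_along(s)) {
        if (j != i && abs(j - i) <= window) {
          m[s[i], s[j]] <- m[s[i], s[j]] + 1L
        }
      }
    }
  }
  m
}

# Scalar re-statement of the smoothed PMI weighting.
oracle_pmi <- function(fwc, fw, fc, W, a) {
  log(fwc * W / (fw * (fc + a)) + 1) / log(2)
}

# Angle at vertex B via the law of cosines on the three pairwise distances.
oracle_angle_loc <- function(A, B, Cc) {
  ab <- sqrt(sum((A - B)^2))
  cb <- sqrt(sum((Cc - B)^2))
  ac <- sqrt(sum((A - Cc)^2))
  acos(max(-1, min(1, (ab^2 + cb^2 - ac^2) / (2 * ab * cb))))
}

# Triangle area via Heron's formula on the pairwise distances.
oracle_area_heron <- function(A, B, Cc) {
  a <- sqrt(sum((B - Cc)^2))
  b <- sqrt(sum((A - Cc)^2))
  c <- sqrt(sum((A - B)^2))
  s <- (a + b + c) / 2
  sqrt(max(0, s * (s - a) * (s - b) * (s - c)))
}

# Leave-one-out OLS predictions through the hat-matrix identity
# yhat(-i) = y_i - e_i / (1 - h_ii), a closed form independent of the
# package's refit-per-fold loop.
oracle_loo_hat <- function(F, y) {
  X <- cbind(1, as.matrix(F))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  e <- y - H %*% y
  as.numeric(y - e / (1 - diag(H)))
}

# All permutations of 1..n by filtering the full n^n grid (independent of
# any package-internal enumeration); n is tiny.
oracle_all_perms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# A random subspace with positive coordinates; X element-wise dominates the
# other vectors, C is uniform at the mean of M, mirroring how generic
# vectors arise.
random_subspace <- function(k = 4) {
  V <- runif(k, 0.1, 5)
  N <- runif(k, 0.1, 5)
  M <- runif(k, 0.1, 5)
  X <- pmax(V, N, M) + runif(k, 0, 2)
  C <- rep(mean(M), k)
  new_subspace(paste0("d", seq_len(k)), V, N, M, X, C)
}

# Tiny shared corpus for cross-module tests.
fixture_sentences <- function() clean_corpus(micro_corpus())

fixture_pmi <- function(a = 10) {
  build_pmi_matrix(fixture_sentences(), size_limit = 50, smoothing_a = a)
}
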