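test_that("vertex angles match hand values and the law-of-cosines oracle", {
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)), pi / 2)
  expect_equal(angle_at_vertex(c(2, 2), c(1, 1), c(2, 2)), 0)
  expect_error(angle_at_vertex(c(1, 1), c(1, 1), c(0, 0), strict = TRUE),
               "zero-length")
  expect_true(is.nan(angle_at_vertex(c(1, 1), c(1, 1), c(0, 0))))
  set.seed(31)
  for (i in 1:200) {
    A <- rnorm(5); B <- rnorm(5); Cc <- rnorm(5)
    expect_equal(angle_at_vertex(A, B, Cc), oracle_angle_loc(A, B, Cc),
                 tolerance = 1e-9)
  }
})

test_that("triangle areas match hand values and Heron's formula", {
  expect_equal(triangle_area(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  expect_equal(triangle_area(c(0, 0), c(1, 1), c(2, 2)), 0)
  set.seed(32)
  for (i in 1:200) {
    A <- rnorm(4); B <- rnorm(4); Cc <- rnorm(4)
    expect_equal(triangle_area(A, B, Cc), oracle_area_heron(A, B, Cc),
                 tolerance = 1e-9)
  }
})

test_that("the feature vector has exactly the 48 canonical entries", {
  expect_length(geometry_feature_names(), 48)
  s <- random_subspace(5)
  f <- extract_features(s)
  expect_length(f, 48)
  expect_identical(names(f), geometry_feature_names())
  # invariant ranges on a clean subspace
  ratios <- f[grepl("^ratio_", names(f))]
  expect_true(all(ratios > 0 & ratios <= 1))
  angles <- f[grepl("^angle_", names(f))]
  expect_true(all(angles >= 0 & angles <= pi))
  expect_true(all(f[grepl("^area_", names(f))] >= 0))
  expect_true(all(f[grepl("^(norm|dist)_", names(f))] >= 0))
})

test_that("every feature of a hand-built integer subspace matches an independent scalar computation", {
  V <- c(3, 0, 4); N <- c(1, 2, 2); M <- c(2, 1, 3); X <- c(4, 2, 5)
  C <- rep(2, 3)
  s <- new_subspace(c("d1", "d2", "d3"), V, N, M, X, C)
  f <- extract_features(s)
  d <- function(a, b) sqrt(sum((a - b)^2))
  nrm <- function(a) sqrt(sum(a^2))
  un <- function(a) a / nrm(a)
  Vp <- un(V); Np <- un(N); Mp <- un(M); Xp <- un(X); Cp <- un(C)
  O <- c(0, 0, 0)
  expected <- c(
    norm_V = 5, norm_N = 3, dist_VN = d(V, N), norm_M = nrm(M),
    norm_X = nrm(X), norm_C = sqrt(12), dist_VpNp = d(Vp, Np),
    mean_VM_NM = (d(V, M) + d(N, M)) / 2,
    mean_VX_NX = (d(V, X) + d(N, X)) / 2,
    mean_VC_NC = (d(V, C) + d(N, C)) / 2,
    mean_VpMp_NpMp = (d(Vp, Mp) + d(Np, Mp)) / 2,
    mean_VpXp_NpXp = (d(Vp, Xp) + d(Np, Xp)) / 2,
    mean_VpCp_NpCp = (d(Vp, Cp) + d(Np, Cp)) / 2,
    ratio_VM_NM = min(d(V, M), d(N, M)) / max(d(V, M), d(N, M)),
    ratio_VX_NX = min(d(V, X), d(N, X)) / max(d(V, X), d(N, X)),
    ratio_VC_NC = min(d(V, C), d(N, C)) / max(d(V, C), d(N, C)),
    ratio_VpMp_NpMp = min(d(Vp, Mp), d(Np, Mp)) / max(d(Vp, Mp), d(Np, Mp)),
    ratio_VpXp_NpXp = min(d(Vp, Xp), d(Np, Xp)) / max(d(Vp, Xp), d(Np, Xp)),
    ratio_VpCp_NpCp = min(d(Vp, Cp), d(Np, Cp)) / max(d(Vp, Cp), d(Np, Cp)),
    frac_V_N = 5 / 3,
    frac_VM_NM = d(V, M) / d(N, M),
    frac_VX_NX = d(V, X) / d(N, X),
    frac_VC_NC = d(V, C) / d(N, C),
    frac_meanVN_M = 4 / nrm(M),
    frac_meanVN_X = 4 / nrm(X),
    frac_meanVN_C = 4 / sqrt(12),
    frac_C_M = sqrt(12) / nrm(M),
    frac_C_X = sqrt(12) / nrm(X),
    frac_M_X = nrm(M) / nrm(X),
    frac_VpMp_NpMp = d(Vp, Mp) / d(Np, Mp),
    frac_VpXp_NpXp = d(Vp, Xp) / d(Np, Xp),
    frac_VpCp_NpCp = d(Vp, Cp) / d(Np, Cp),
    angle_VON = oracle_angle_loc(V, O, N),
    angle_VMN = oracle_angle_loc(V, M, N),
    angle_VXN = oracle_angle_loc(V, X, N),
    angle_VCN = oracle_angle_loc(V, C, N),
    angle_MOC = oracle_angle_loc(M, O, C),
    angle_MOX = oracle_angle_loc(M, O, X),
    angle_COX = oracle_angle_loc(C, O, X),
    angle_VpMpNp = oracle_angle_loc(Vp, Mp, Np),
    angle_VpXpNp = oracle_angle_loc(Vp, Xp, Np),
    angle_VpCpNp = oracle_angle_loc(Vp, Cp, Np),
    area_VMN = oracle_area_heron(V, M, N),
    area_VXM = oracle_area_heron(V, X, M),
    area_VCM = oracle_area_heron(V, C, M),
    area_VpMpNp = oracle_area_heron(Vp, Mp, Np),
    area_VpXpMp = oracle_area_heron(Vp, Xp, Mp),
    area_VpCpMp = oracle_area_heron(Vp, Cp, Mp))
  expect_equal(f, expected[names(f)], tolerance = 1e-9)
})

test_that("coincident word vectors collapse the pair features", {
  V <- c(2, 1, 3)
  s <- new_subspace(c("a", "b", "c"), V, V, c(1, 1, 1), c(3, 2, 4), rep(1, 3))
  f <- extract_features(s)
  expect_equal(unname(f["dist_VN"]), 0)
  expect_equal(unname(f["angle_VON"]), 0)
  expect_equal(unname(f[c("ratio_VM_NM", "ratio_VX_NX", "ratio_VC_NC")]),
               c(1, 1, 1))
  expect_equal(unname(f["area_VMN"]), 0)
})

test_that("swapping V and N: pair features fixed, directed fractions invert, anchored features exchange", {
  set.seed(33)
  directed <- c("frac_V_N", "frac_VM_NM", "frac_VX_NX", "frac_VC_NC",
                "frac_VpMp_NpMp", "frac_VpXp_NpXp", "frac_VpCp_NpCp")
  # the word norms and the V-anchored areas are the features that are not
  # symmetric in (V, N): the norms exchange with each other, and the areas
  # become their (unlisted) N-anchored counterparts
  anchored <- c("norm_V", "norm_N", "area_VXM", "area_VCM",
                "area_VpXpMp", "area_VpCpMp")
  for (i in 1:50) {
    s <- random_subspace(4)
    swapped <- new_subspace(s$dims, s$N, s$V, s$M, s$X, s$C)
    f1 <- extract_features(s)
    f2 <- extract_features(swapped)
    sym <- setdiff(names(f1), c(directed, anchored))
    expect_equal(f1[sym], f2[sym], tolerance = 1e-9)
    expect_equal(unname(f2[directed]), unname(1 / f1[directed]),
                 tolerance = 1e-9)
    expect_equal(unname(f2["norm_V"]), unname(f1["norm_N"]), tolerance = 1e-12)
    expect_equal(unname(f2["norm_N"]), unname(f1["norm_V"]), tolerance = 1e-12)
    expect_equal(unname(f2["area_VXM"]),
                 triangle_area(s$N, s$X, s$M), tolerance = 1e-9)
    expect_equal(unname(f2["area_VCM"]),
                 triangle_area(s$N, s$C, s$M), tolerance = 1e-9)
  }
})

test_that("scaling the subspace scales distances linearly, areas quadratically and fixes the rest", {
  set.seed(34)
  for (i in 1:50) {
    s <- random_subspace(4)
    lam <- runif(1, 0.2, 5)
    scaled <- new_subspace(s$dims, lam * s$V, lam * s$N, lam * s$M,
                           lam * s$X, lam * s$C)
    f1 <- extract_features(s)
    f2 <- extract_features(scaled)
    full_dist <- c("norm_V", "norm_N", "dist_VN", "norm_M", "norm_X",
                   "norm_C", "mean_VM_NM", "mean_VX_NX", "mean_VC_NC")
    full_area <- c("area_VMN", "area_VXM", "area_VCM")
    invariant <- setdiff(names(f1), c(full_dist, full_area))
    expect_equal(unname(f2[full_dist]), unname(lam * f1[full_dist]),
                 tolerance = 1e-9)
    expect_equal(unname(f2[full_area]), unname(lam^2 * f1[full_area]),
                 tolerance = 1e-9)
    expect_equal(f1[invariant], f2[invariant], tolerance = 1e-9)
  }
})

test_that("normalized chord equals 2 sin(angle/2) exactly", {
  set.seed(35)
  for (i in 1:100) {
    s <- random_subspace(5)
    f <- extract_features(s)
    expect_equal(unname(f["dist_VpNp"]),
                 2 * sin(f[["angle_VON"]] / 2), tolerance = 1e-12)
  }
})

test_that("normalized-vertex angles agree with angle_at_vertex on the normalized vectors", {
  s <- random_subspace(6)
  f <- extract_features(s)
  expect_equal(unname(f["angle_VpMpNp"]),
               angle_at_vertex(s$Vn, s$Mn, s$Nn), tolerance = 1e-12)
  expect_equal(unname(f["angle_VpXpNp"]),
               angle_at_vertex(s$Vn, s$Xn, s$Nn), tolerance = 1e-12)
})

test_that("degenerate vectors flag features as undefined in permissive mode and error in strict", {
  s <- new_subspace(c("a", "b"), c(0, 0), c(1, 2), c(1, 1), c(1, 2), rep(1, 2))
  f <- extract_features(s)
  expect_true(is.nan(f[["dist_VpNp"]]))
  expect_true(is.nan(f[["angle_VON"]]))   # zero-length ray at the origin
  expect_false(is.nan(f[["norm_N"]]))
  expect_error(extract_features(s, strict = TRUE), "degenerate")
})

test_that("batch feature matrices carry canonical columns per dyad", {
  pmi <- fixture_pmi()
  fm <- dyad_feature_matrix(pmi, c("cat", "bird"), c("dog", "mat"),
                            technique = "indy", k = 5)
  expect_identical(dim(fm), c(2L, 48L))
  expect_identical(colnames(fm), geometry_feature_names())
  s <- build_subspace(pmi, "cat", "dog", "indy", k = 5)
  expect_equal(fm[1, ], extract_features(s), tolerance = 1e-12)
})
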