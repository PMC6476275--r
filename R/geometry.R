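# The 48-measure statistical geometry of a contextual subspace: distances,
# means and ratios of distance pairs, directed fractions, angles at the
# origin and at generic-vector vertices, and triangle areas, each taken on
# the full vectors and (for a subset) on their unit-normalized counterparts.

.euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Angle at a vertex between two rays
#'
#' The angle at vertex `B` subtended by points `A` and `Cc`: the arccosine
#' of the cosine between rays B->A and B->Cc, clamped to \[-1, 1\] to absorb
#' floating-point overshoot. Valid in any dimension.
#'
#' @param A,B,Cc numeric vectors of equal length; `B` is the vertex.
#' @param strict if TRUE a zero-length ray is an error; otherwise `NaN`.
#' @return angle in radians, within \[0, pi\].
#' @examples
#' angle_at_vertex(c(1, 0), c(0, 0), c(0, 1))  # pi / 2
#' @export
angle_at_vertex <- function(A, B, Cc, strict = FALSE) {
  a <- A - B
  b <- Cc - B
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    if (strict) stop("degenerate angle: zero-length ray at vertex")
    return(NaN)
  }
  if (all(a == b)) return(0)  # coincident rays, exactly
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

#' Area of the triangle spanned by three points
#'
#' Computed as half the Gram-determinant square root,
#' 0.5 * sqrt(|a|^2 |b|^2 - (a.b)^2) with a = B - A and b = Cc - A, which is
#' valid in any dimension; collinear points give 0.
#'
#' @param A,B,Cc numeric vectors of equal length.
#' @return non-negative area.
#' @examples
#' triangle_area(c(0, 0), c(1, 0), c(0, 1))  # 0.5
#' @export
triangle_area <- function(A, B, Cc) {
  a <- B - A
  b <- Cc - A
  g <- sum(a^2) * sum(b^2) - sum(a * b)^2
  0.5 * sqrt(max(0, g))
}

# min/max ratio of a distance pair: both zero -> 1 (coincident geometry),
# exactly one zero -> 0.
.ratio_minmax <- function(d1, d2) {
  if (d1 == 0 && d2 == 0) return(1)
  min(d1, d2) / max(d1, d2)
}

# directed fraction num/den; zero denominator is undefined (NaN) in
# permissive mode, an error in strict mode.
.fraction <- function(num, den, strict = FALSE) {
  if (den == 0) {
    if (strict) stop("undefined fraction: zero denominator")
    return(NaN)
  }
  num / den
}

#' Canonical names of the 48 geometric features
#'
#' Naming convention: `V`, `N` are the projected verb and noun vectors, `M`,
#' `X`, `C` the mean, maximum and central generic vectors, `O` the origin; a
#' `p` suffix (prime) marks the unit-normalized counterpart. `norm_*` are
#' vector norms, `dist_*` point-to-point distances, `mean_*` means of a
#' distance pair, `ratio_*` min/max ratios of a pair, `frac_*` directed
#' fractions, `angle_*` angles (radians) at the named middle vertex and
#' `area_*` triangle areas.
#'
#' @return character vector of length 48 in canonical order.
#' @export
geometry_feature_names <- function() {
  c(
    # distances (7)
    "norm_V", "norm_N", "dist_VN", "norm_M", "norm_X", "norm_C", "dist_VpNp",
    # means (6)
    "mean_VM_NM", "mean_VX_NX", "mean_VC_NC",
    "mean_VpMp_NpMp", "mean_VpXp_NpXp", "mean_VpCp_NpCp",
    # ratios (6)
    "ratio_VM_NM", "ratio_VX_NX", "ratio_VC_NC",
    "ratio_VpMp_NpMp", "ratio_VpXp_NpXp", "ratio_VpCp_NpCp",
    # fractions (13)
    "frac_V_N", "frac_VM_NM", "frac_VX_NX", "frac_VC_NC",
    "frac_meanVN_M", "frac_meanVN_X", "frac_meanVN_C",
    "frac_C_M", "frac_C_X", "frac_M_X",
    "frac_VpMp_NpMp", "frac_VpXp_NpXp", "frac_VpCp_NpCp",
    # angles (10)
    "angle_VON", "angle_VMN", "angle_VXN", "angle_VCN",
    "angle_MOC", "angle_MOX", "angle_COX",
    "angle_VpMpNp", "angle_VpXpNp", "angle_VpCpNp",
    # areas (6)
    "area_VMN", "area_VXM", "area_VCM",
    "area_VpMpNp", "area_VpXpMp", "area_VpCpMp"
  )
}

#' Extract the 48 geometric features of a subspace
#'
#' Distances and norms are Euclidean; the origin O is the zero vector.
#' Ratios take the lower of a distance pair over the higher, so no vector is
#' presumed as numerator; fractions keep the stated directed orientation.
#' Features involving a degenerate (zero) vector's normalized counterpart,
#' an undefined angle or a zero-denominator fraction are `NaN` in permissive
#' mode; `strict = TRUE` raises an error instead.
#'
#' @param s a `subspace`.
#' @param strict error on degenerate geometry instead of flagging `NaN`.
#' @return named numeric vector of length 48 in canonical order.
#' @export
extract_features <- function(s, strict = FALSE) {
  stopifnot(inherits(s, "subspace"))
  V <- as.numeric(s$V); N <- as.numeric(s$N)
  M <- as.numeric(s$M); X <- as.numeric(s$X); C <- as.numeric(s$C)
  O <- numeric(s$k)
  deg <- function(v) isTRUE(attr(v, "degenerate"))
  if (strict && (deg(s$Vn) || deg(s$Nn) || deg(s$Mn) || deg(s$Xn) || deg(s$Cn))) {
    stop("degenerate subspace: a zero vector cannot be normalized in strict mode")
  }
  nan_if <- function(value, any_deg) if (any_deg) NaN else value
  dVp <- deg(s$Vn); dNp <- deg(s$Nn); dMp <- deg(s$Mn)
  dXp <- deg(s$Xn); dCp <- deg(s$Cn)
  Vp <- as.numeric(s$Vn); Np <- as.numeric(s$Nn)
  Mp <- as.numeric(s$Mn); Xp <- as.numeric(s$Xn); Cp <- as.numeric(s$Cn)

  d <- list(
    VN = .euclid(V, N),
    VM = .euclid(V, M), NM = .euclid(N, M),
    VX = .euclid(V, X), NX = .euclid(N, X),
    VC = .euclid(V, C), NC = .euclid(N, C),
    VpNp = .euclid(Vp, Np),
    VpMp = .euclid(Vp, Mp), NpMp = .euclid(Np, Mp),
    VpXp = .euclid(Vp, Xp), NpXp = .euclid(Np, Xp),
    VpCp = .euclid(Vp, Cp), NpCp = .euclid(Np, Cp))
  nV <- sqrt(sum(V^2)); nN <- sqrt(sum(N^2)); nM <- sqrt(sum(M^2))
  nX <- sqrt(sum(X^2)); nC <- sqrt(sum(C^2))

  ang <- function(A, B, Cc) angle_at_vertex(A, B, Cc, strict = strict)
  out <- c(
    norm_V = nV, norm_N = nN, dist_VN = d$VN,
    norm_M = nM, norm_X = nX, norm_C = nC,
    dist_VpNp = nan_if(d$VpNp, dVp || dNp),
    mean_VM_NM = (d$VM + d$NM) / 2,
    mean_VX_NX = (d$VX + d$NX) / 2,
    mean_VC_NC = (d$VC + d$NC) / 2,
    mean_VpMp_NpMp = nan_if((d$VpMp + d$NpMp) / 2, dVp || dNp || dMp),
    mean_VpXp_NpXp = nan_if((d$VpXp + d$NpXp) / 2, dVp || dNp || dXp),
    mean_VpCp_NpCp = nan_if((d$VpCp + d$NpCp) / 2, dVp || dNp || dCp),
    ratio_VM_NM = .ratio_minmax(d$VM, d$NM),
    ratio_VX_NX = .ratio_minmax(d$VX, d$NX),
    ratio_VC_NC = .ratio_minmax(d$VC, d$NC),
    ratio_VpMp_NpMp = nan_if(.ratio_minmax(d$VpMp, d$NpMp), dVp || dNp || dMp),
    ratio_VpXp_NpXp = nan_if(.ratio_minmax(d$VpXp, d$NpXp), dVp || dNp || dXp),
    ratio_VpCp_NpCp = nan_if(.ratio_minmax(d$VpCp, d$NpCp), dVp || dNp || dCp),
    frac_V_N = .fraction(nV, nN, strict),
    frac_VM_NM = .fraction(d$VM, d$NM, strict),
    frac_VX_NX = .fraction(d$VX, d$NX, strict),
    frac_VC_NC = .fraction(d$VC, d$NC, strict),
    frac_meanVN_M = .fraction((nV + nN) / 2, nM, strict),
    frac_meanVN_X = .fraction((nV + nN) / 2, nX, strict),
    frac_meanVN_C = .fraction((nV + nN) / 2, nC, strict),
    frac_C_M = .fraction(nC, nM, strict),
    frac_C_X = .fraction(nC, nX, strict),
    frac_M_X = .fraction(nM, nX, strict),
    frac_VpMp_NpMp = if (dVp || dNp || dMp) NaN else .fraction(d$VpMp, d$NpMp, strict),
    frac_VpXp_NpXp = if (dVp || dNp || dXp) NaN else .fraction(d$VpXp, d$NpXp, strict),
    frac_VpCp_NpCp = if (dVp || dNp || dCp) NaN else .fraction(d$VpCp, d$NpCp, strict),
    angle_VON = ang(V, O, N),
    angle_VMN = ang(V, M, N),
    angle_VXN = ang(V, X, N),
    angle_VCN = ang(V, C, N),
    angle_MOC = ang(M, O, C),
    angle_MOX = ang(M, O, X),
    angle_COX = ang(C, O, X),
    angle_VpMpNp = nan_if(ang(Vp, Mp, Np), dVp || dNp || dMp),
    angle_VpXpNp = nan_if(ang(Vp, Xp, Np), dVp || dNp || dXp),
    angle_VpCpNp = nan_if(ang(Vp, Cp, Np), dVp || dNp || dCp),
    area_VMN = triangle_area(V, M, N),
    area_VXM = triangle_area(V, X, M),
    area_VCM = triangle_area(V, C, M),
    area_VpMpNp = nan_if(triangle_area(Vp, Mp, Np), dVp || dNp || dMp),
    area_VpXpMp = nan_if(triangle_area(Vp, Xp, Mp), dVp || dNp || dXp),
    area_VpCpMp = nan_if(triangle_area(Vp, Cp, Mp), dVp || dNp || dCp)
  )
  stopifnot(identical(names(out), geometry_feature_names()))
  out
}

#' Feature matrix for a table of dyads
#'
#' Builds one subspace per dyad and stacks the 48 features into an n x 48
#' matrix with canonical column names.
#'
#' @param pmi a `pmi_matrix`.
#' @param verbs,nouns character vectors of equal length.
#' @inheritParams build_subspace
#' @return numeric matrix, rows named `verb noun`.
#' @export
dyad_feature_matrix <- function(pmi, verbs, nouns,
                                technique = c("indy", "mean", "geom"),
                                k = 200L, strict = FALSE) {
  technique <- match.arg(technique)
  stopifnot(length(verbs) == length(nouns))
  feats <- matrix(NA_real_, nrow = length(verbs),
                  ncol = length(geometry_feature_names()),
                  dimnames = list(paste(verbs, nouns),
                                  geometry_feature_names()))
  for (i in seq_along(verbs)) {
    s <- build_subspace(pmi, verbs[i], nouns[i], technique, k, strict)
    feats[i, ] <- extract_features(s, strict)
  }
  feats
}
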