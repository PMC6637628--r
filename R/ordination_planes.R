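#' Bray-Curtis dissimilarity matrix
#'
#' Computes `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample
#' pairs of an abundance profile (via \pkg{vegan}). A pair of all-zero
#' samples, for which the ratio is 0/0, is defined to have distance 0.
#'
#' @param profile samples x species nonnegative abundance matrix.
#' @return symmetric numeric matrix of dissimilarities in `[0, 1]` with
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(profile) {
  check_profile(profile)
  if (nrow(profile) < 2L) stop_gp("need at least 2 samples")
  d <- as.matrix(suppressWarnings(vegan::vegdist(profile, method = "bray")))
  zero <- rowSums(profile) == 0
  if (any(zero)) d[zero, zero] <- 0   # 0/0 pairs: identical empty communities
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-0.5 * D^2` and eigendecomposes it. Axes whose eigenvalue
#' is at most `1e-8 *` the largest eigenvalue (including all negative axes)
#' are dropped; coordinates are eigenvectors scaled by the square root of
#' their eigenvalue, so Euclidean distances in the embedding approximate the
#' input dissimilarities. If fewer than `k` positive axes survive, `k` is
#' reduced with a warning.
#'
#' @param dist symmetric dissimilarity matrix with zero diagonal.
#' @param k number of coordinates to retain (default 3, the number used for
#'   plane fitting).
#' @return object of class `pcoa_embedding`: list with `coordinates`
#'   (samples x k), `eigenvalues` (all, descending) and `sample_ids`.
#' @export
pcoa_embed <- function(dist, k = 3) {
  dist <- as.matrix(dist)
  if (any(!is.finite(dist))) stop_gp("distance matrix contains non-finite values")
  if (max(abs(dist - t(dist))) > 1e-8) stop_gp("distance matrix is not symmetric")
  if (k < 1) stop_gp("k must be >= 1")
  n <- nrow(dist)
  cs <- suppressWarnings(stats::cmdscale(dist, k = n - 1, eig = TRUE))
  ev <- cs$eig
  keep <- which(ev > 1e-8 * max(ev))
  if (length(keep) < k) {
    warning(sprintf("only %d positive principal coordinates available; k reduced from %d",
                    length(keep), k))
    k <- length(keep)
  }
  coords <- cs$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  rownames(coords) <- rownames(dist)
  structure(list(coordinates = coords,
                 eigenvalues = sort(ev, decreasing = TRUE),
                 sample_ids = rownames(dist)),
            class = "pcoa_embedding")
}

#' Fit a 2-D plane to 3-D points by total least squares
#'
#' Orthogonal (total) least squares: the plane passes through the centroid
#' of the points and its normal is the right singular vector of the centered
#' point matrix with the smallest singular value, which minimizes the sum of
#' squared orthogonal residuals. The normal's sign is canonicalized so its
#' first nonzero component is positive, making the fit deterministic.
#'
#' @param points numeric matrix with >= 3 rows and 3 columns.
#' @return object of class `plane_model`: list with `centroid` and unit
#'   `normal` (3-vectors) and `rss`, the orthogonal residual sum of squares.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_gp("points must have exactly 3 columns")
  if (nrow(points) < 3L)
    stop_gp("plane fitting needs >= 3 points, got %d", nrow(points))
  if (any(!is.finite(points))) stop_gp("points contain non-finite values")
  centroid <- colMeans(points)
  centered <- sweep(points, 2, centroid, "-")
  sv <- svd(centered)
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300))
    stop_gp("points are collinear (rank < 2); plane is not identified")
  normal <- sv$v[, 3]
  nz <- which(abs(normal) > 1e-12)[1]
  if (normal[nz] < 0) normal <- -normal
  structure(list(centroid = centroid,
                 normal = normal / sqrt(sum(normal^2)),
                 rss = sv$d[3]^2),
            class = "plane_model")
}

#' Euclidean distance from a point to a fitted plane
#'
#' `|(point - centroid) . normal|`, the orthogonal distance in the units of
#' the principal-coordinate space.
#'
#' @param point numeric 3-vector.
#' @param plane a `plane_model`.
#' @return nonnegative scalar.
#' @export
distance_to_plane <- function(point, plane) {
  if (!inherits(plane, "plane_model")) stop_gp("plane must be a plane_model")
  point <- as.numeric(point)
  if (length(point) != 3L || any(!is.finite(point)))
    stop_gp("point must be a finite 3-vector")
  abs(sum((point - plane$centroid) * plane$normal))
}

#' Per-timepoint healthy/disease plane distances for every sample
#'
#' One joint PCoA embedding is assumed (all groups and timepoints in a
#' shared coordinate space). At each timepoint the healthy plane (HP) is
#' fitted to the healthy group's samples and the disease plane (DP) to the
#' disease group's samples, in the first three principal coordinates; every
#' sample at that timepoint then receives its orthogonal distance to both
#' planes. This is the quantitative backbone of trajectory ("dysbiosis
#' score") plots: treated animals moving back toward health approach HP and
#' leave DP.
#'
#' @param embedding a `pcoa_embedding` with k >= 3.
#' @param meta sample metadata covering all embedded samples.
#' @param healthy_group,disease_group group labels defining HP and DP.
#' @return data.frame (`sample_id`, `group`, `timepoint`, `dist_hp`,
#'   `dist_dp`) with the fitted planes in attribute `"planes"`.
#' @export
plane_distance_series <- function(embedding, meta,
                                  healthy_group = "normal",
                                  disease_group = "model") {
  if (!inherits(embedding, "pcoa_embedding"))
    stop_gp("embedding must be a pcoa_embedding")
  coords <- embedding$coordinates
  if (ncol(coords) < 3L) stop_gp("embedding must retain >= 3 coordinates")
  coords <- coords[, 1:3, drop = FALSE]
  check_metadata(meta)
  meta <- meta[match(rownames(coords), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop_gp("embedding contains samples absent from metadata")
  for (g in c(healthy_group, disease_group))
    if (!g %in% meta$group) stop_gp("group '%s' not present in metadata", g)

  tps <- unique(meta$timepoint)
  planes <- list()
  out <- vector("list", length(tps))
  for (i in seq_along(tps)) {
    tp <- tps[i]
    at_tp <- meta$timepoint == tp
    hp_pts <- coords[at_tp & meta$group == healthy_group, , drop = FALSE]
    dp_pts <- coords[at_tp & meta$group == disease_group, , drop = FALSE]
    if (nrow(hp_pts) < 3L || nrow(dp_pts) < 3L)
      stop_gp("timepoint %s has fewer than 3 plane-defining samples", tp)
    hp <- fit_plane(hp_pts)
    dp <- fit_plane(dp_pts)
    planes[[as.character(tp)]] <- list(hp = hp, dp = dp)
    pts <- coords[at_tp, , drop = FALSE]
    out[[i]] <- data.frame(
      sample_id = rownames(pts),
      group = meta$group[at_tp],
      timepoint = tp,
      dist_hp = apply(pts, 1, distance_to_plane, plane = hp),
      dist_dp = apply(pts, 1, distance_to_plane, plane = dp),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[match(rownames(coords), res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "planes") <- planes
  res
}

#' Paired t test on matched HP/DP distances
#'
#' Standard paired t test on the per-sample differences `hp - dp`. Two
#' degenerate inputs are handled explicitly rather than erroring: if all
#' differences are zero the result is `t = 0, p = 1`; if the differences
#' are a nonzero constant the mean difference is certain given the data and
#' `p = 0` is reported with `degenerate = TRUE`.
#'
#' @param hp_distances,dp_distances equal-length paired distance vectors.
#' @return list with `t`, `p.value`, `n`, `df`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_t <- function(hp_distances, dp_distances) {
  if (length(hp_distances) != length(dp_distances))
    stop_gp("paired vectors differ in length")
  d <- hp_distances - dp_distances
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2L) stop_gp("paired t test needs n >= 2, got %d", n)
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p.value = 1, n = n, df = n - 1L,
                  mean_difference = 0, degenerate = FALSE))
    return(list(t = sign(mean(d)) * Inf, p.value = 0, n = n, df = n - 1L,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p.value = tt$p.value, n = n,
       df = unname(tt$parameter), mean_difference = mean(d),
       degenerate = FALSE)
}

#' Arthritis score vs plane-distance correlations
#'
#' Semi-partial Spearman correlation of the arthritis score with the
#' distance to HP and with the distance to DP, adjusted for body weight and
#' group (dummy-coded). Covariates are regressed out of the distance
#' variable; see [semipartial_spearman()]. Groups whose score does not vary
#' (unimmunized controls, which are fixed at zero) are excluded: they carry
#' no score information and their tied ranks only dilute the estimate. In a
#' cohort where dysbiosis drives disease the HP-distance correlation is
#' expected positive and the DP-distance correlation negative.
#'
#' @param series output of [plane_distance_series()].
#' @param meta metadata with `arthritis_score` and `weight`.
#' @return list with elements `hp` and `dp`, each a `correlation_result`.
#' @export
score_plane_correlation <- function(series, meta) {
  check_metadata(meta)
  if (!"arthritis_score" %in% names(meta))
    stop_gp("metadata lacks arthritis_score")
  m <- meta[match(series$sample_id, meta$sample_id), , drop = FALSE]
  varies <- vapply(split(m$arthritis_score, m$group),
                   function(v) length(unique(v)) > 1, logical(1))
  keep <- m$group %in% names(varies)[varies]
  if (!any(keep)) keep <- rep(TRUE, nrow(m))  # constant score: degenerate
  m <- m[keep, , drop = FALSE]
  ser <- series[keep, , drop = FALSE]
  covar <- data.frame(weight = m$weight, group = m$group)
  list(hp = semipartial_spearman(ser$dist_hp, m$arthritis_score, covar),
       dp = semipartial_spearman(ser$dist_dp, m$arthritis_score, covar))
}
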