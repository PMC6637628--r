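test_that("bray_curtis matches the direct formula and its metric properties", {
  # (0.5, 0.5) vs (0.25, 0.75): sum|d| / sum(x+y) = 0.5 / 2 = 0.25
  m <- rbind(a = c(0.5, 0.5), b = c(0.25, 0.75))
  colnames(m) <- c("s__x", "s__y")
  expect_equal(bray_curtis(m)["a", "b"], 0.25)

  # identical samples -> 0; disjoint supports -> 1
  m2 <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  colnames(m2) <- c("s__x", "s__y")
  d2 <- bray_curtis(m2)
  expect_equal(d2["a", "c"], 0)
  expect_equal(d2["a", "b"], 1)

  # direct-formula oracle on random compositions + symmetry and bounds
  set.seed(42)
  r <- matrix(rexp(8 * 6), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:6)))
  r <- r / rowSums(r) * 100
  d <- bray_curtis(r)
  bc_direct <- function(x, y) sum(abs(x - y)) / sum(x + y)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(d[i, j], bc_direct(r[i, ], r[j, ]), tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(r[1, , drop = FALSE]), "2 samples")
})

test_that("bray_curtis defines all-zero sample pairs as zero", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  colnames(m) <- c("s__x", "s__y")
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
})

test_that("pcoa reconstructs Euclidean configurations", {
  set.seed(7)
  pts <- matrix(rnorm(10 * 3), 10, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  emb <- pcoa_embed(d, k = 3)
  drec <- as.matrix(dist(emb$coordinates))
  expect_equal(unname(drec), unname(d), tolerance = 1e-8)
  # eigenvalues descending; coincident samples embed at the same point
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  d2 <- as.matrix(dist(pts[c(1, 1:9), ]))
  emb2 <- suppressWarnings(pcoa_embed(d2, k = 3))
  expect_equal(emb2$coordinates[1, ], emb2$coordinates[2, ], tolerance = 1e-8)
  expect_error(pcoa_embed(d[, 1:9], k = 3))
})

test_that("pcoa reduces k with a warning when rank is insufficient", {
  pts <- cbind(rnorm(6), rnorm(6))            # planar configuration
  d <- as.matrix(dist(pts))
  expect_warning(emb <- pcoa_embed(d, k = 3), "reduced")
  expect_equal(ncol(emb$coordinates), 2L)
})

test_that("fit_plane is exact on coplanar points and rotation-equivariant", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(9), 3)))
  pts <- cbind(rnorm(7), rnorm(7), 0) %*% t(basis) +
    matrix(c(1, 2, 3), 7, 3, byrow = TRUE)
  pl <- fit_plane(pts)
  expect_lt(pl$rss, 1e-20)
  resid <- sweep(pts, 2, pl$centroid, "-") %*% pl$normal
  expect_lt(max(abs(resid)), 1e-10)
  expect_equal(sum(pl$normal^2), 1, tolerance = 1e-12)

  # rigid rotation of the input rotates centroid and normal identically
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  pl2 <- fit_plane(pts %*% t(R))
  expect_equal(pl2$centroid, as.numeric(R %*% pl$centroid), tolerance = 1e-8)
  n2 <- as.numeric(R %*% pl$normal)
  nz <- which(abs(n2) > 1e-12)[1]
  if (n2[nz] < 0) n2 <- -n2      # account for sign canonicalization
  expect_equal(pl2$normal, n2, tolerance = 1e-8)
})

test_that("fit_plane solves the symmetric 4-point configuration", {
  delta <- 0.01
  pts <- rbind(c(1, 0, delta), c(-1, 0, delta),
               c(0, 1, -delta), c(0, -1, -delta))
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-10)  # plane z = 0
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-12)
  # SVD oracle: residual sum equals the smallest squared singular value
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  expect_equal(pl$rss, sv$d[3]^2, tolerance = 1e-12)
})

test_that("fit_plane minimizes orthogonal residuals locally", {
  set.seed(3)
  pts <- matrix(rnorm(21), 7, 3)
  pl <- fit_plane(pts)
  rss <- function(nrm) {
    nrm <- nrm / sqrt(sum(nrm^2))
    sum((sweep(pts, 2, colMeans(pts), "-") %*% nrm)^2)
  }
  base <- rss(pl$normal)
  for (i in 1:20) {
    pert <- pl$normal + rnorm(3, sd = 0.05)
    expect_gte(rss(pert), base - 1e-10)
  }
  expect_error(fit_plane(pts[1:2, ]), ">= 3 points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_plane(line), "collinear")
})

test_that("distance_to_plane is the orthogonal distance and isometric", {
  pl <- fit_plane(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)))
  expect_equal(distance_to_plane(pl$centroid, pl), 0)
  expect_equal(distance_to_plane(pl$centroid + pl$normal, pl), 1)
  expect_error(distance_to_plane(c(1, NA, 0), pl), "finite")

  set.seed(5)
  pts <- matrix(rnorm(15), 5, 3)
  pl <- fit_plane(pts)
  x <- rnorm(3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  plR <- fit_plane(pts %*% t(R))
  expect_equal(distance_to_plane(as.numeric(R %*% x), plR),
               distance_to_plane(x, pl), tolerance = 1e-8)
})

test_that("plane_distance_series fits both planes per timepoint", {
  sim <- small_cohort(seed = 2)
  emb <- pcoa_embed(bray_curtis(sim$profile), 3)
  ser <- plane_distance_series(emb, sim$metadata)
  expect_setequal(ser$sample_id, rownames(sim$profile))
  expect_true(all(ser$dist_hp >= 0 & ser$dist_dp >= 0))
  planes <- attr(ser, "planes")
  expect_setequal(names(planes), unique(sim$metadata$timepoint))

  # invariant to sample ordering
  perm <- sample(nrow(sim$profile))
  emb2 <- pcoa_embed(bray_curtis(sim$profile[perm, ]), 3)
  ser2 <- plane_distance_series(emb2, sim$metadata)
  ser2 <- ser2[match(ser$sample_id, ser2$sample_id), ]
  expect_equal(ser2$dist_hp, ser$dist_hp, tolerance = 1e-8)
  expect_equal(ser2$dist_dp, ser$dist_dp, tolerance = 1e-8)

  # disease group identical to healthy group: HP = DP exactly
  ser3 <- plane_distance_series(emb, sim$metadata,
                                healthy_group = "normal",
                                disease_group = "normal")
  expect_equal(ser3$dist_hp, ser3$dist_dp)

  # too few plane-defining samples is an error naming the timepoint
  drop <- sim$metadata$sample_id[sim$metadata$group == "normal" &
                                   sim$metadata$timepoint == "TP3"][1:5]
  meta_cut <- sim$metadata[!sim$metadata$sample_id %in% drop, ]
  emb_cut <- pcoa_embed(bray_curtis(
    sim$profile[meta_cut$sample_id, ]), 3)
  expect_error(plane_distance_series(emb_cut, meta_cut), "TP3")
})

test_that("treated rats converge to the healthy plane under full reversion", {
  sim <- simulate_cohort(sim_config(seed = 4, n_species = 60,
                                    n_drift_species = 20,
                                    reversion_fraction = 1,
                                    response_sd = 0))
  emb <- pcoa_embed(bray_curtis(sim$profile), 3)
  ser <- plane_distance_series(emb, sim$metadata)
  final_tp <- "TP5"
  treated <- ser$group %in% c("mtx", "lcasei") & ser$timepoint == final_tp
  expect_lt(mean(ser$dist_hp[treated]), mean(ser$dist_dp[treated]))
})

test_that("paired_t matches closed forms and flags degeneracies", {
  # alternating +1/-1 differences: mean 0 -> t = 0, p = 1
  r <- paired_t(c(2, 1, 2, 1), c(1, 2, 1, 2))
  expect_equal(r$t, 0)
  expect_equal(r$p.value, 1)

  # differences (1,2,3): t = 2/(1/sqrt(3)), p from t distribution, df = 2
  r2 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$p.value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
  expect_equal(r2$p.value, 0.0742, tolerance = 1e-3)

  # identical vectors -> t = 0, p = 1; constant nonzero shift -> degenerate
  r3 <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$t, 0)
  expect_equal(r3$p.value, 1)
  r4 <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(r4$degenerate)
  expect_equal(r4$p.value, 0)
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("score-plane correlation recovers planted signs", {
  sim <- small_cohort(seed = 11)
  emb <- pcoa_embed(bray_curtis(sim$profile), 3)
  ser <- plane_distance_series(emb, sim$metadata)
  sc <- score_plane_correlation(ser, sim$metadata)
  expect_gt(sc$hp$estimate, 0)

  # constant score: flagged degenerate, no exception
  meta0 <- sim$metadata
  meta0$arthritis_score <- 3
  sc0 <- score_plane_correlation(ser, meta0)
  expect_true(sc0$hp$degenerate)

  # shuffled scores: mean correlation over permutations near zero
  set.seed(99)
  perm_cc <- replicate(30, {
    mp <- sim$metadata
    mp$arthritis_score <- sample(mp$arthritis_score)
    score_plane_correlation(ser, mp)$hp$estimate
  })
  expect_lt(abs(mean(perm_cc)), 0.1)
})
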