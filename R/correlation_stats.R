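#' Tukey-fence outlier removal for a paired sample
#'
#' A pair is dropped when its x or its y value lies outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of that variable (quartiles by the default
#' type-7 rule). With fewer than `min_n` pairs no removal is attempted,
#' since quartile fences are meaningless at very small n.
#'
#' @param x,y equal-length numeric vectors.
#' @param min_n minimum n for the fence rule to apply; default 8.
#' @return integer vector of kept indices.
#' @export
remove_outliers <- function(x, y, min_n = 8) {
  if (length(x) != length(y)) stop_gp("x and y differ in length")
  n <- length(x)
  if (n < min_n) return(seq_len(n))
  inside <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr
  }
  which(inside(x) & inside(y))
}

# rank-transform a covariate data.frame: numeric columns by midrank,
# character/factor columns dummy-coded against the first level
rank_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.vector(covariates) && !is.list(covariates))
    covariates <- data.frame(cov1 = covariates)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop_gp("covariates have wrong length")
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- rank(v)
    } else {
      lev <- unique(as.character(v))
      for (l in lev[-1]) cols[[paste0(nm, "_", l)]] <- as.numeric(v == l)
    }
  }
  do.call(cbind, cols)
}

#' Semi-partial (part) Spearman correlation
#'
#' Rank-based part correlation: x, y and the covariates are rank-transformed
#' (average ranks for ties; categorical covariates dummy-coded), the
#' covariate ranks are regressed out of one variable's ranks by least
#' squares, and the residuals are Pearson-correlated with the other
#' variable's ranks. By default the adjustment is applied to `x` only (the
#' "part" correlation of the microbiome variable with the outcome). The
#' p value uses the t approximation with `df = n - k - 2`, k the number of
#' covariate columns after coding.
#'
#' @param x,y equal-length numeric vectors.
#' @param covariates data.frame/matrix of covariates (or NULL for plain
#'   Spearman).
#' @param adjust which variable the covariates are removed from: `"x"`
#'   (default) or `"y"`.
#' @return object of class `correlation_result`: list with `estimate`,
#'   `p.value`, `n_used`, `df`, `n_covariates`, `degenerate`.
#' @export
semipartial_spearman <- function(x, y, covariates = NULL,
                                 adjust = c("x", "y")) {
  adjust <- match.arg(adjust)
  if (length(x) != length(y)) stop_gp("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  Z <- rank_covariates(covariates, n)
  # drop constant covariate columns: they adjust nothing
  if (!is.null(Z)) {
    Z <- Z[, apply(Z, 2, function(v) length(unique(v)) > 1), drop = FALSE]
    if (ncol(Z) == 0L) Z <- NULL
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n < k + 3L) stop_gp("need n >= %d observations, got %d", k + 3L, n)

  rx <- rank(x); ry <- rank(y)
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0) {
    return(structure(list(estimate = NA_real_, p.value = NA_real_,
                          n_used = n, df = NA_integer_, n_covariates = k,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  if (k > 0L) {
    Zc <- cbind(1, Z)
    q <- qr(Zc)
    if (q$rank < ncol(Zc)) stop_gp("covariates are rank-deficient after coding")
    if (adjust == "x") rx <- stats::residuals(stats::lm.fit(Zc, rx))
    else ry <- stats::residuals(stats::lm.fit(Zc, ry))
  }
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0) {
    return(structure(list(estimate = NA_real_, p.value = NA_real_,
                          n_used = n, df = NA_integer_, n_covariates = k,
                          degenerate = TRUE),
                     class = "correlation_result"))
  }
  cc <- stats::cor(rx, ry)
  df <- n - k - 2L
  p <- if (df > 0 && abs(cc) < 1) {
    tval <- cc * sqrt(df / (1 - cc^2))
    2 * stats::pt(-abs(tval), df)
  } else if (abs(cc) >= 1) 0 else NA_real_
  structure(list(estimate = cc, p.value = p, n_used = n, df = df,
                 n_covariates = k, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) {
    cat("semi-partial Spearman: degenerate (zero-variance input), n =",
        x$n_used, "\n")
  } else {
    cat(sprintf("semi-partial Spearman: cc = %.3f, p = %.4g, n = %d, covariate columns = %d\n",
                x$estimate, x$p.value, x$n_used, x$n_covariates))
  }
  invisible(x)
}

#' Correlate species abundances with metadata targets
#'
#' One covariate-adjusted semi-partial Spearman correlation per
#' (species, target) pair, the screening used for taxa vs plane distances
#' or serum cytokines. Outlier pairs are removed per pair by the Tukey
#' fence rule before adjustment. No multiple-testing correction is applied
#' by default; Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' @param profile samples x species abundance matrix.
#' @param meta metadata; must contain the target and covariate columns.
#' @param species character vector of species to test (must be profile
#'   columns).
#' @param targets character vector of metadata column names (cytokines,
#'   `dist_hp`, ...).
#' @param covariates character vector of metadata columns to adjust for;
#'   default `c("weight", "group", "arthritis_score")`.
#' @param outlier_rule `"tukey"` (default) or `"none"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per (species, target): `estimate`,
#'   `p.value`, `n_used`, `n_removed_outliers`, `degenerate`.
#' @export
correlate_panel <- function(profile, meta, species, targets,
                            covariates = c("weight", "group",
                                           "arthritis_score"),
                            outlier_rule = c("tukey", "none"),
                            p_adjust = c("none", "BH")) {
  check_profile(profile)
  outlier_rule <- match.arg(outlier_rule)
  p_adjust <- match.arg(p_adjust)
  meta <- align_meta(meta, profile)
  bad <- setdiff(species, colnames(profile))
  if (length(bad))
    stop_gp("species not in profile: %s", paste(bad, collapse = ", "))
  bad <- setdiff(c(targets, covariates), names(meta))
  if (length(bad))
    stop_gp("unknown metadata column(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (sp in species) {
    for (tg in targets) {
      x <- profile[, sp]
      y <- meta[[tg]]
      keep <- if (outlier_rule == "tukey") remove_outliers(x, y) else
        seq_along(x)
      res <- semipartial_spearman(x[keep], y[keep],
                                  meta[keep, covariates, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, target = tg, estimate = res$estimate,
        p.value = res$p.value, n_used = res$n_used,
        n_removed_outliers = length(x) - length(keep),
        degenerate = res$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p.adjusted <- stats::p.adjust(out$p.value, "BH")
  rownames(out) <- NULL
  out
}
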