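#' Non-negative elastic-net regression (single fit)
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\|y - \beta_0 - X\beta\|^2 +
#'       \lambda\big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big)}
#' subject to \eqn{\beta \ge 0} (the constraint can be lifted with
#' `nonneg = FALSE`), by cyclic coordinate descent with projected
#' soft-thresholding and an unpenalized intercept. Convergence is declared
#' when the largest coefficient change in a sweep falls below `tol`.
#'
#' @param X samples x species matrix of column-standardized predictors
#'   (z-scores; see [log_zscore()]).
#' @param y numeric response (arthritis scores).
#' @param lambda penalty weight, >= 0.
#' @param alpha L1/L2 mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param nonneg constrain coefficients to be nonnegative (default TRUE).
#' @param tol convergence tolerance on the max coefficient change.
#' @param maxit maximum coordinate-descent sweeps.
#' @param trace record the objective value after every sweep.
#' @return object of class `enet_model`: list with named `beta`,
#'   `intercept`, `lambda`, `alpha`, `nonneg`, `converged`, `sweeps`, and
#'   `objective` trace when requested.
#' @export
fit_elastic_net_nn <- function(X, y, lambda, alpha = 0.5, nonneg = TRUE,
                               tol = 1e-7, maxit = 1e5, trace = FALSE) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop_gp("X and y must be finite")
  if (nrow(X) != length(y)) stop_gp("nrow(X) != length(y)")
  if (!is.numeric(lambda) || lambda < 0) stop_gp("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop_gp("alpha must be in [0, 1]")
  fit <- enet_cd_path(X, as.numeric(y), as.numeric(lambda), alpha, nonneg,
                      tol, as.integer(maxit), trace)
  if (!fit$converged[1])
    warning(sprintf("coordinate descent did not converge in %d sweeps", maxit))
  beta <- fit$beta[, 1]
  names(beta) <- colnames(X)
  structure(list(beta = beta, intercept = fit$intercept[1],
                 lambda = lambda, alpha = alpha, nonneg = nonneg,
                 converged = fit$converged[1], sweeps = fit$sweeps[1],
                 objective = fit$objective),
            class = "enet_model")
}

# decreasing log-spaced lambda grid from lambda_max (smallest lambda giving
# an all-zero beta, from the KKT conditions) down `decades` decades
lambda_grid <- function(X, y, alpha, nlambda = 100, decades = 4,
                        nonneg = TRUE) {
  n <- nrow(X)
  g <- crossprod(X, y - mean(y)) / n
  top <- if (nonneg) max(g) else max(abs(g))
  lmax <- top / max(alpha, 1e-3)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

# fit a full warm-started path; returns p x nlambda coefficient matrix
enet_path <- function(X, y, lambdas, alpha, nonneg = TRUE, tol = 1e-7,
                      maxit = 1e5) {
  enet_cd_path(X, as.numeric(y), as.numeric(lambdas), alpha, nonneg,
               tol, as.integer(maxit), FALSE)
}

#' Repeated cross-validated consensus selection of arthritis-correlated taxa
#'
#' The stability-selection scheme: `repeats` times, samples are shuffled
#' into `folds` folds; for every fold the remaining training portion gets
#' its own penalty `lambda` chosen by an inner cross-validation over a
#' log-spaced grid (`nlambda` values spanning `decades` decades down from
#' the smallest all-zero-coefficient lambda), and one non-negative
#' elastic-net model is fitted on that training portion at the chosen
#' lambda. This yields `folds * repeats` models (50 under the defaults).
#' Models with fewer than `min_nonzero` nonzero coefficients are discarded,
#' and a species enters the consensus set iff it has a nonzero coefficient
#' in strictly more than `consensus_threshold` of the retained models.
#'
#' @param X samples x species z-score matrix (see [log_zscore()]).
#' @param y arthritis scores, one per row of X.
#' @param folds,repeats outer CV geometry; defaults 5 and 10.
#' @param alpha elastic-net mixing; default 0.5.
#' @param min_nonzero minimum nonzero coefficients for a model to be
#'   retained; default 5.
#' @param consensus_threshold strict model-count cutoff for consensus
#'   membership; default 25 (i.e. selected when present in >= 26 of 50).
#' @param seed integer seed controlling all shuffling.
#' @param inner_folds folds of the inner lambda-selection CV; default 5.
#' @param nlambda,decades lambda grid geometry.
#' @param lambda_rule inner-CV penalty choice: `"1se"` (default; the
#'   largest lambda within one standard error of the minimum CV error,
#'   which resists the over-selection of the raw minimum) or `"min"`.
#' @return object of class `selection_result`: list with `models` (retained
#'   `enet_model`s), `inclusion_counts` (per species), `selected_species`,
#'   `total_models_fit`, `n_retained`, and the call parameters.
#' @export
repeated_cv_select <- function(X, y, folds = 5, repeats = 10, alpha = 0.5,
                               min_nonzero = 5, consensus_threshold = 25,
                               seed = 1, inner_folds = 5, nlambda = 100,
                               decades = 4, lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2) stop_gp("folds must be >= 2")
  if (folds > n) stop_gp("folds (%d) exceeds sample count (%d)", folds, n)
  if (length(y) != n) stop_gp("length(y) != nrow(X)")
  species <- colnames(X)
  if (is.null(species)) species <- paste0("V", seq_len(ncol(X)))

  set.seed(as.integer(seed))
  models <- list()
  total <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      lam <- choose_lambda_cv(Xtr, ytr, alpha, inner_folds, nlambda, decades,
                              lambda_rule)
      m <- fit_elastic_net_nn(Xtr, ytr, lam, alpha)
      m$fold <- f
      m$repeat_index <- r
      total <- total + 1L
      models[[total]] <- m
    }
  }
  nz <- vapply(models, function(m) sum(m$beta != 0), integer(1))
  retained <- models[nz >= min_nonzero]
  counts <- integer(length(species))
  names(counts) <- species
  for (m in retained) counts <- counts + (m$beta != 0)
  selected <- names(counts)[counts > consensus_threshold]
  structure(list(models = retained,
                 inclusion_counts = counts,
                 selected_species = selected,
                 total_models_fit = total,
                 n_retained = length(retained),
                 folds = folds, repeats = repeats, alpha = alpha,
                 min_nonzero = min_nonzero,
                 consensus_threshold = consensus_threshold,
                 seed = seed),
            class = "selection_result")
}

# inner CV over the lambda grid. "1se": largest lambda whose mean CV error
# is within one standard error of the minimum (guards against the
# over-selection of the CV-minimum); "min": the CV-minimum itself.
choose_lambda_cv <- function(X, y, alpha, inner_folds, nlambda, decades,
                             rule = "1se") {
  n <- nrow(X)
  k <- min(inner_folds, n)
  lambdas <- lambda_grid(X, y, alpha, nlambda, decades)
  fold_id <- sample(rep_len(seq_len(k), n))
  err <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- enet_path(X[tr, , drop = FALSE], y[tr], lambdas, alpha)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta +
      rep(fit$intercept, each = sum(!tr))
    err[f, ] <- colMeans((pred - y[!tr])^2)
  }
  mean_err <- colMeans(err)
  if (rule == "min") return(lambdas[which.min(mean_err)])
  imin <- which.min(mean_err)
  se <- stats::sd(err[, imin]) / sqrt(k)
  lambdas[which(mean_err <= mean_err[imin] + se)[1]]
}

#' Tabulate a selection result
#'
#' One row per species with a nonzero coefficient in any retained model:
#' inclusion count, mean nonzero coefficient, and association sign, sorted
#' by count descending with lexicographic tie-break so the order is
#' deterministic.
#'
#' @param result a `selection_result`.
#' @param selected_only keep only consensus species (default FALSE).
#' @return data.frame (`species`, `inclusion_count`, `mean_beta`, `sign`,
#'   `selected`).
#' @export
selection_report <- function(result, selected_only = FALSE) {
  if (!inherits(result, "selection_result"))
    stop_gp("result must be a selection_result")
  counts <- result$inclusion_counts
  species <- names(counts)
  bsum <- numeric(length(counts))
  names(bsum) <- species
  for (m in result$models) bsum <- bsum + m$beta
  keep <- counts > 0
  df <- data.frame(species = species[keep],
                   inclusion_count = unname(counts[keep]),
                   mean_beta = unname(bsum[keep] / pmax(counts[keep], 1)),
                   stringsAsFactors = FALSE)
  df$sign <- sign(df$mean_beta)
  df$selected <- df$species %in% result$selected_species
  if (selected_only) df <- df[df$selected, , drop = FALSE]
  df <- df[order(-df$inclusion_count, df$species), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Consensus selection: %d/%d models retained (>= %d nonzero), %d species selected (> %d models)\n",
              x$n_retained, x$total_models_fit, x$min_nonzero,
              length(x$selected_species), x$consensus_threshold))
  if (length(x$selected_species))
    cat(" ", paste(x$selected_species, collapse = ", "), "\n")
  invisible(x)
}
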