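#' Read a KO relative-abundance table
#'
#' Plain TSV with KO identifiers in the first column (`ko_id`) and one
#' column per sample; returned as a samples x KO matrix.
#'
#' @param path path to the KO TSV.
#' @return numeric matrix, samples x KOs.
#' @export
read_ko_profile <- function(path) {
  if (!file.exists(path)) stop_gp("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_gp("KO profile %s is empty or has no sample columns", path)
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  if (!is.numeric(m)) stop_gp("non-numeric values in %s", path)
  dimnames(m) <- list(colnames(raw)[-1], as.character(raw[[1]]))
  check_profile(m, "KO profile")
}

#' Read a KO-to-module map
#'
#' Two-column TSV (`module_id`, `ko_id`), one row per membership.
#'
#' @param path path to the map TSV.
#' @return named list: module id -> character vector of member KO ids.
#' @export
read_module_map <- function(path) {
  if (!file.exists(path)) stop_gp("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_gp("module map %s is empty", path)
  split(as.character(raw[[2]]), as.character(raw[[1]]))
}

#' Aggregate KO abundances to KEGG modules
#'
#' Module abundance is the mean (optionally the sum) over the module's
#' member KOs that are present in the profile. Modules with no present
#' member are dropped with a warning.
#'
#' @param ko samples x KOs abundance matrix.
#' @param map named list module id -> KO ids.
#' @param stat `"mean"` (default, insensitive to module size) or `"sum"`.
#' @return samples x modules matrix.
#' @export
module_abundance <- function(ko, map, stat = c("mean", "sum")) {
  check_profile(ko, "KO profile")
  stat <- match.arg(stat)
  if (length(map) == 0L) stop_gp("module map is empty")
  if (any(lengths(map) == 0L)) stop_gp("module map has empty member sets")
  cols <- lapply(map, intersect, y = colnames(ko))
  dropped <- names(map)[lengths(cols) == 0L]
  if (length(dropped))
    warning(sprintf("module(s) with no KOs in the profile dropped: %s",
                    paste(dropped, collapse = ", ")))
  cols <- cols[lengths(cols) > 0L]
  if (length(cols) == 0L) stop_gp("no module has any KO in the profile")
  agg <- vapply(cols, function(kk) {
    v <- rowSums(ko[, kk, drop = FALSE])
    if (stat == "mean") v / length(kk) else v
  }, numeric(nrow(ko)))
  agg <- matrix(agg, nrow = nrow(ko),
                dimnames = list(rownames(ko), names(cols)))
  agg
}

#' Wilcoxon rank-sum test with the classic W statistic
#'
#' `W` is the sum of the pooled-sample ranks of the first group (average
#' ranks for ties). The two-sided p value is exact by complete enumeration
#' of rank assignments when `n1 + n2 <= 12` and there are no ties, and a
#' normal approximation with tie and continuity corrections otherwise.
#' Direction is the sign of (mean rank of a) - (mean rank of b).
#'
#' @param a,b numeric vectors for the two groups.
#' @return object of class `ranksum_result`: list with `W`, `p.value`,
#'   `direction`, `n1`, `n2`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop_gp("both groups must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  direction <- sign(mean(r[seq_len(n1)]) - mean(r[-seq_len(n1)]))
  N <- n1 + n2
  ties <- anyDuplicated(pooled) > 0L
  if (N <= 12L && !ties) {
    # exact null distribution of W: every n1-subset of ranks equally likely
    sums <- colSums(matrix(seq_len(N)[utils::combn(N, n1)], nrow = n1))
    p <- min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal_approx"
  }
  structure(list(W = W, p.value = p, direction = direction,
                 n1 = n1, n2 = n2, method = method),
            class = "ranksum_result")
}

#' Rank-sum tests over all KOs between two groups at one timepoint
#'
#' Applies [wilcoxon_rank_sum()] KO-by-KO to the samples of two groups at a
#' given timepoint (the final, day-30 timepoint in the study design).
#'
#' @param ko samples x KOs abundance matrix.
#' @param meta metadata with `group` and `timepoint`.
#' @param group_a,group_b groups to compare (`W` is group_a's rank sum).
#' @param timepoint timepoint label; default `"TP5"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame (`ko`, `W`, `p.value`, `direction`, `n1`, `n2`).
#' @export
ko_differential <- function(ko, meta, group_a, group_b, timepoint = "TP5",
                            p_adjust = c("none", "BH")) {
  check_profile(ko, "KO profile")
  p_adjust <- match.arg(p_adjust)
  meta <- align_meta(meta, ko)
  ia <- meta$group == group_a & meta$timepoint == timepoint
  ib <- meta$group == group_b & meta$timepoint == timepoint
  if (!any(ia) || !any(ib))
    stop_gp("no samples for one of the groups at %s", timepoint)
  res <- lapply(colnames(ko), function(k) {
    r <- wilcoxon_rank_sum(ko[ia, k], ko[ib, k])
    data.frame(ko = k, W = r$W, p.value = r$p.value,
               direction = r$direction, n1 = r$n1, n2 = r$n2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") out$p.adjusted <- stats::p.adjust(out$p.value, "BH")
  rownames(out) <- NULL
  out
}

#' Module log2 fold change between two timepoints, per group
#'
#' Per group and module: `log2((mean at tp_to + eps) / (mean at tp_from +
#' eps))` over that group's samples, with the table-wide pseudocount. With
#' `complete_only = TRUE` only modules quantified in every group are
#' reported, matching heatmap displays that drop modules missing from any
#' group.
#'
#' @param modules samples x modules matrix (see [module_abundance()]).
#' @param meta metadata with `group` and `timepoint`.
#' @param tp_from,tp_to contrast timepoints; defaults `"TP1"` and `"TP5"`.
#' @param groups groups to report; default all non-reference groups present.
#' @param complete_only keep only modules nonzero in every reported group
#'   at either timepoint (default TRUE).
#' @return data.frame (`module`, `group`, `log2_fc`).
#' @export
module_log2fc <- function(modules, meta, tp_from = "TP1", tp_to = "TP5",
                          groups = NULL, complete_only = TRUE) {
  check_profile(modules, "module table")
  meta <- align_meta(meta, modules)
  for (tp in c(tp_from, tp_to))
    if (!tp %in% meta$timepoint) stop_gp("timepoint '%s' not in metadata", tp)
  if (is.null(groups)) groups <- unique(meta$group)
  eps <- pseudocount(modules)
  if (is.na(eps)) stop_gp("module table has no nonzero values")
  rows <- list()
  present <- matrix(TRUE, length(groups), ncol(modules),
                    dimnames = list(groups, colnames(modules)))
  for (g in groups) {
    m_from <- modules[meta$group == g & meta$timepoint == tp_from, ,
                      drop = FALSE]
    m_to <- modules[meta$group == g & meta$timepoint == tp_to, ,
                    drop = FALSE]
    if (nrow(m_from) == 0L || nrow(m_to) == 0L)
      stop_gp("group '%s' lacks samples at the contrast timepoints", g)
    present[g, ] <- colSums(m_from) + colSums(m_to) > 0
    rows[[g]] <- data.frame(
      module = colnames(modules), group = g,
      log2_fc = log2((colMeans(m_to) + eps) / (colMeans(m_from) + eps)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (complete_only) {
    keep <- colnames(modules)[colSums(present) == length(groups)]
    out <- out[out$module %in% keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
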