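#' Normalize abundances to the reference-group mean at each timepoint
#'
#' Each sample's abundance of each species is divided by the mean abundance
#' of that species among the reference (normal) group's rats at the same
#' timepoint, with the table-wide pseudocount added to numerator and
#' denominator so all-zero references stay finite:
#' `value = (a + eps) / (mean_ref + eps)`.
#'
#' @param profile samples x species abundance matrix.
#' @param meta metadata with `group` and `timepoint`.
#' @param reference_group label of the reference group; default `"normal"`.
#' @param stat reference statistic: `"mean"` (default) or `"median"`.
#' @return samples x species matrix of normalized ratios (pseudocount kept
#'   in attribute `"eps"`).
#' @export
normalize_to_reference <- function(profile, meta, reference_group = "normal",
                                   stat = c("mean", "median")) {
  check_profile(profile)
  stat <- match.arg(stat)
  meta <- align_meta(meta, profile)
  if (!reference_group %in% meta$group)
    stop_gp("reference group '%s' not in metadata", reference_group)
  eps <- pseudocount(profile)
  if (is.na(eps)) stop_gp("profile has no nonzero abundances")
  tps <- unique(meta$timepoint)
  out <- profile
  for (tp in tps) {
    ref <- profile[meta$group == reference_group & meta$timepoint == tp, ,
                   drop = FALSE]
    if (nrow(ref) == 0L)
      stop_gp("reference group '%s' has no samples at timepoint %s",
              reference_group, tp)
    refstat <- if (stat == "mean") colMeans(ref) else
      apply(ref, 2, stats::median)
    rows <- meta$timepoint == tp
    out[rows, ] <- sweep(profile[rows, , drop = FALSE] + eps, 2,
                         refstat + eps, "/")
  }
  attr(out, "eps") <- eps
  out
}

#' Per-rat log10 fold change against the baseline timepoint
#'
#' For each rat and species, `log10` of the ratio of the normalized value at
#' each later timepoint to the rat's own value at baseline (TP1). Pairing is
#' within rat, so the statistic tracks each animal's own trajectory.
#'
#' @param normtab normalized table from [normalize_to_reference()].
#' @param meta metadata with `rat_id` and `timepoint`.
#' @param baseline baseline timepoint label; default `"TP1"`.
#' @return long data.frame (`rat_id`, `group`, `species`, `timepoint`,
#'   `log10_fc`), baseline rows excluded.
#' @export
log10_fc_vs_baseline <- function(normtab, meta, baseline = "TP1") {
  meta <- align_meta(meta, normtab)
  if (!baseline %in% meta$timepoint)
    stop_gp("baseline timepoint '%s' not in metadata", baseline)
  rats <- unique(meta$rat_id)
  has_base <- rats %in% meta$rat_id[meta$timepoint == baseline]
  if (!all(has_base))
    stop_gp("rat(s) missing the %s baseline sample: %s", baseline,
            paste(rats[!has_base], collapse = ", "))
  base_row <- match(paste(meta$rat_id, baseline),
                    paste(meta$rat_id, meta$timepoint))
  keep <- which(meta$timepoint != baseline)
  species <- colnames(normtab)
  fc <- log10(normtab[keep, , drop = FALSE] /
                normtab[base_row[keep], , drop = FALSE])
  data.frame(
    rat_id = rep(meta$rat_id[keep], times = length(species)),
    group = rep(meta$group[keep], times = length(species)),
    species = rep(species, each = length(keep)),
    timepoint = rep(meta$timepoint[keep], times = length(species)),
    log10_fc = as.vector(fc),
    stringsAsFactors = FALSE)
}

#' Fold-change significance cutoff on the log10 scale
#'
#' @param threshold_fold fold-change threshold (default 16).
#' @return `log10(threshold_fold)`; 16-fold corresponds to 1.20 at two
#'   decimals.
#' @export
fc_cutoff <- function(threshold_fold = 16) {
  if (threshold_fold <= 1) stop_gp("threshold_fold must be > 1")
  log10(threshold_fold)
}

#' Call significant fold changes by the consistent-majority rule
#'
#' Per (species, group, timepoint contrast): a rat "passes" when its
#' absolute log10 fold change strictly exceeds `log10(threshold_fold)`
#' (1.20 for 16-fold); the change is "consistent" when all passing rats
#' share one sign; the call is significant iff the passing fraction
#' strictly exceeds `rat_fraction` and the passes are consistent. The
#' reported direction is the shared sign.
#'
#' @param fc long fold-change table from [log10_fc_vs_baseline()].
#' @param threshold_fold fold-change threshold; default 16.
#' @param rat_fraction strict minimum fraction of passing rats; default 0.8.
#' @return data.frame (`species`, `group`, `timepoint`, `n_rats`,
#'   `fraction_passing`, `direction`, `significant`).
#' @export
call_significant <- function(fc, threshold_fold = 16, rat_fraction = 0.8) {
  need <- c("rat_id", "group", "species", "timepoint", "log10_fc")
  miss <- setdiff(need, names(fc))
  if (length(miss))
    stop_gp("fold-change table missing column(s): %s",
            paste(miss, collapse = ", "))
  if (rat_fraction < 0 || rat_fraction > 1)
    stop_gp("rat_fraction must be in [0, 1]")
  cut <- fc_cutoff(threshold_fold)
  key <- interaction(fc$species, fc$group, fc$timepoint, drop = TRUE,
                     lex.order = TRUE)
  res <- lapply(split(fc, key), function(d) {
    pass <- abs(d$log10_fc) > cut
    frac <- mean(pass)
    signs <- unique(sign(d$log10_fc[pass]))
    consistent <- length(signs) == 1L
    data.frame(species = d$species[1], group = d$group[1],
               timepoint = d$timepoint[1], n_rats = nrow(d),
               fraction_passing = frac,
               direction = if (consistent && frac > rat_fraction) signs else 0,
               significant = consistent && frac > rat_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
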