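#' Read a species relative-abundance profile
#'
#' Reads a MetaPhlAn-style TSV (clade names in the first column, one column
#' per sample, percent-scale relative abundances) and keeps only rows whose
#' clade name terminates at the species level, i.e. contains an `s__` field
#' and no `t__` (strain) field. The table is returned transposed into the
#' package's working orientation: a numeric matrix with samples as rows and
#' species as columns.
#'
#' @param path path to a tab-delimited UTF-8 file whose first column is
#'   `clade_name` and whose remaining columns are sample ids.
#' @return numeric matrix, samples x species, percent scale.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop_gp("file not found: %s", path)
  if (length(readLines(path, n = 1L)) == 0L)
    stop_gp("profile file %s is empty", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop_gp("profile file %s is empty or has no sample columns", path)
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids))
    stop_gp("duplicate sample columns in %s: %s", path,
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  clade <- as.character(raw[[1]])
  keep <- grepl("s__", clade, fixed = TRUE) & !grepl("t__", clade, fixed = TRUE)
  if (!any(keep))
    stop_gp("no species-level rows (s__ without t__) in %s", path)
  vals <- raw[keep, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad))
      stop_gp("non-numeric value in %s, column '%s', data row %d",
              path, sample_ids[j], bad[1])
    vals[[j]] <- v
  }
  m <- t(as.matrix(vals))
  dimnames(m) <- list(sample_ids, clade[keep])
  check_profile(m)
}

#' Write a species profile to MetaPhlAn-style TSV
#'
#' Inverse of [read_profile()]: species back in rows under a `clade_name`
#' first column. Values are written with full precision so a write/read
#' round trip reproduces the matrix.
#'
#' @param profile samples x species matrix.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  check_profile(profile)
  df <- data.frame(clade_name = colnames(profile),
                   t(profile), check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write per-sample metadata
#'
#' Metadata is a plain TSV with one row per sample and named header columns.
#' Required: `sample_id`, `rat_id`, `group`, `timepoint`; typical further
#' columns are `weight` (g), `arthritis_score`, and serum cytokine
#' concentrations (`IL17`, `IL1b`, `TNFa`, `IL6`, `IFNg`, `IL2`).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_gp("file not found: %s", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(meta) == 0L) stop_gp("metadata file %s is empty", path)
  check_metadata(meta)
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  check_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove rare species by per-rat prevalence
#'
#' A rat "presents" a species if the species has abundance > 0 in at least
#' one of that rat's samples (any timepoint). Species presenting in fewer
#' than `min_fraction` of the rats are removed; samples are untouched. The
#' per-rat (not per-sample) count is used because longitudinal samples of
#' one animal are not independent observations of carriage.
#'
#' @param profile samples x species abundance matrix.
#' @param meta metadata with `sample_id` and `rat_id`.
#' @param min_fraction minimum fraction of rats presenting the species,
#'   in `[0, 1]`; default 0.05.
#' @return the profile restricted to retained species.
#' @export
filter_prevalence <- function(profile, meta, min_fraction = 0.05) {
  check_profile(profile)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop_gp("min_fraction must be a single value in [0, 1]")
  meta <- align_meta(meta, profile)
  rats <- unique(meta$rat_id)
  present <- rowsum((profile > 0) + 0, group = meta$rat_id) > 0
  frac <- colSums(present) / length(rats)
  profile[, frac >= min_fraction, drop = FALSE]
}

#' Log-transform and z-score a profile
#'
#' Applies `log10(v + eps)` with `eps` = half the smallest nonzero value of
#' the table (see [pseudocount()]), then centers and scales each species to
#' zero mean and unit population (n-denominator) standard deviation across
#' samples. Species with zero variance on the log scale map to all-zero
#' columns rather than NaN.
#'
#' @param profile samples x species abundance matrix.
#' @return samples x species matrix of z-scores, with the pseudocount kept
#'   in attribute `"eps"`.
#' @export
log_zscore <- function(profile) {
  if (length(profile) == 0L) stop_gp("profile is empty")
  check_profile(profile)
  eps <- pseudocount(profile)
  if (is.na(eps)) stop_gp("profile has no nonzero abundances")
  lg <- log10(profile + eps)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, pop_sd)
  z <- sweep(lg, 2, mu, "-")
  nz <- sd > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd[nz], "/")
  z[, !nz] <- 0
  attr(z, "eps") <- eps
  z
}
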