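#' Pseudocount for zero-safe ratios and logs
#'
#' Half the smallest nonzero value of a nonnegative table. Used as the shared
#' additive pseudocount for log transforms, reference normalization and fold
#' changes, so that the offset scales with the data rather than being an
#' arbitrary constant.
#'
#' @param x numeric matrix or vector with nonnegative values.
#' @return A positive scalar, or `NA` if `x` has no nonzero entries.
#' @export
pseudocount <- function(x) {
  v <- x[is.finite(x) & x > 0]
  if (length(v) == 0L) return(NA_real_)
  min(v) / 2
}

# population (n-denominator) standard deviation
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

stop_gp <- function(...) stop(sprintf(...), call. = FALSE)

# shared checks for the samples x species abundance matrix
check_profile <- function(profile, arg = "profile") {
  if (!is.matrix(profile) || !is.numeric(profile))
    stop_gp("%s must be a numeric matrix (samples x species)", arg)
  if (is.null(rownames(profile)) || is.null(colnames(profile)))
    stop_gp("%s must have sample rownames and species colnames", arg)
  if (anyDuplicated(rownames(profile)))
    stop_gp("%s has duplicated sample ids", arg)
  if (anyDuplicated(colnames(profile)))
    stop_gp("%s has duplicated species ids", arg)
  if (any(!is.finite(profile)))
    stop_gp("%s contains non-finite values", arg)
  if (any(profile < 0))
    stop_gp("%s contains negative abundances", arg)
  invisible(profile)
}

check_metadata <- function(meta, profile = NULL) {
  need <- c("sample_id", "rat_id", "group", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop_gp("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_gp("metadata has duplicated sample_id values")
  if (anyDuplicated(meta[, c("rat_id", "timepoint")]))
    stop_gp("metadata has duplicated (rat_id, timepoint) pairs")
  if (!is.null(profile)) {
    missing_meta <- setdiff(rownames(profile), meta$sample_id)
    if (length(missing_meta))
      stop_gp("profile samples missing from metadata: %s",
              paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  invisible(meta)
}

# metadata rows aligned to the profile's sample order
align_meta <- function(meta, profile) {
  check_metadata(meta, profile)
  meta[match(rownames(profile), meta$sample_id), , drop = FALSE]
}
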