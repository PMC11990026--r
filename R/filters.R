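# Quality-based call filtering

#' Filter calls by quality score and read depth
#'
#' A call is kept iff its QUAL is at least `min_qual` (when set) and its
#' depth is present and at least `min_depth` (when set).  Calls lacking a
#' DP annotation fail a configured `min_depth`: an unknown depth cannot
#' certify the threshold.  Leaving both thresholds `NULL` is the
#' identity.
#'
#' @param calls A call tibble.
#' @param min_qual Optional minimum QUAL (non-negative).
#' @param min_depth Optional minimum read depth (non-negative integer).
#' @return A list with `calls` (the retained rows, order preserved) and
#'   `removed_count`.
#' @examples
#' calls <- simulate_cohort(simulation_config(seed = 1, n_samples = 3))$calls
#' apply_filters(calls, min_qual = 100)$removed_count
#' @export
apply_filters <- function(calls, min_qual = NULL, min_depth = NULL) {
  assert_calls(calls)
  if (!is.null(min_qual) && (!is.numeric(min_qual) || min_qual < 0)) {
    stop("`min_qual` must be a non-negative number", call. = FALSE)
  }
  if (!is.null(min_depth) && (!is.numeric(min_depth) || min_depth < 0)) {
    stop("`min_depth` must be a non-negative number", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(min_qual)) {
    keep <- keep & !is.na(calls$qual) & calls$qual >= min_qual
  }
  if (!is.null(min_depth)) {
    keep <- keep & !is.na(calls$depth) & calls$depth >= min_depth
  }
  list(
    calls = calls[keep, , drop = FALSE],
    removed_count = sum(!keep)
  )
}
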