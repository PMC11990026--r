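# Cross-platform merging and four-state concordance classification

#' Classify one (sample, site) platform pair
#'
#' The four-state concordance scheme: both platforms report the site with
#' the same (unordered) genotype -> `AGREE`; both report it with
#' different genotypes -> `DISCREPANT`; only one platform reports it ->
#' `ILLUMINA_ONLY` / `ONT_ONLY`.  Phase order is ignored: `0|1`, `1|0`
#' and `0/1` compare equal, since haplotype labels within a phase set are
#' arbitrary.
#'
#' @param illumina_call,ont_call One-row call tibbles (or `NULL` when the
#'   platform did not report the site).  When both are present they must
#'   share the same site key.
#' @return One of `"AGREE"`, `"DISCREPANT"`, `"ILLUMINA_ONLY"`,
#'   `"ONT_ONLY"`.
#' @examples
#' ilm <- normalize_site("chr1", 10, "A", "G")
#' classify_pair(illumina_call = NULL,
#'               ont_call = tibble::tibble(a1 = 0L, a2 = 1L))
#' @export
classify_pair <- function(illumina_call = NULL, ont_call = NULL) {
  has_ilm <- !is.null(illumina_call) && nrow(illumina_call) > 0
  has_ont <- !is.null(ont_call) && nrow(ont_call) > 0
  if (!has_ilm && !has_ont) {
    stop("at least one platform call is required", call. = FALSE)
  }
  if (has_ilm && has_ont &&
      all(c("contig", "pos", "ref", "alt") %in% names(illumina_call)) &&
      all(c("contig", "pos", "ref", "alt") %in% names(ont_call))) {
    k1 <- site_key(illumina_call$contig, illumina_call$pos,
                   illumina_call$ref, illumina_call$alt)
    k2 <- site_key(ont_call$contig, ont_call$pos,
                   ont_call$ref, ont_call$alt)
    if (!identical(k1, k2)) {
      stop("calls to classify must share the same site", call. = FALSE)
    }
  }
  if (!has_ont) return("ILLUMINA_ONLY")
  if (!has_ilm) return("ONT_ONLY")
  same <- genotypes_equal(
    illumina_call$a1, illumina_call$a2, ont_call$a1, ont_call$a2
  )
  if (same) "AGREE" else "DISCREPANT"
}

# unordered genotype equality, vectorized
genotypes_equal <- function(x1, x2, y1, y2) {
  pmin(x1, x2) == pmin(y1, y2) & pmax(x1, x2) == pmax(y1, y2)
}

#' Merge two platforms' call sets into concordance records
#'
#' Builds one record per (sample, site) present in either platform's
#' calls and classifies it with the [classify_pair()] semantics.  A site
#' absent from one platform's VCF counts as "not reported" (platform-only
#' category), never as homozygous reference: bcftools-style variant VCFs
#' omit non-variant sites.  Calls with a missing genotype (`./.`) are
#' likewise dropped as unreported (a message discloses the count).
#' Records are sorted by (contig, pos, sample).
#'
#' @param illumina_calls,ont_calls Call tibbles from the respective
#'   platforms (the `platform` columns are checked).
#' @return A tibble with columns `sample_id`, `contig`, `pos`, `ref`,
#'   `alt`, `category` (factor over the four states) and the per-platform
#'   payloads `illumina_a1/_a2/_phased/_phase_set/_qual/_depth` and
#'   `ont_*` equivalents.
#' @examples
#' cfg <- simulation_config(seed = 7, n_samples = 5)
#' cohort <- simulate_cohort(cfg)
#' rec <- merge_cohorts(
#'   dplyr::filter(cohort$calls, platform == "ILLUMINA"),
#'   dplyr::filter(cohort$calls, platform == "ONT")
#' )
#' table(rec$category)
#' @export
merge_cohorts <- function(illumina_calls, ont_calls) {
  assert_calls(illumina_calls, "illumina_calls")
  assert_calls(ont_calls, "ont_calls")
  if (nrow(illumina_calls) > 0 &&
      any(illumina_calls$platform != "ILLUMINA")) {
    stop("`illumina_calls` contains non-ILLUMINA platform rows",
         call. = FALSE)
  }
  if (nrow(ont_calls) > 0 && any(ont_calls$platform != "ONT")) {
    stop("`ont_calls` contains non-ONT platform rows", call. = FALSE)
  }

  prep <- function(calls, prefix) {
    n_missing <- sum(is.na(calls$a1) | is.na(calls$a2))
    if (n_missing > 0) {
      message(sprintf(
        "dropping %d %s call(s) with missing genotype", n_missing, prefix
      ))
    }
    calls <- calls[!(is.na(calls$a1) | is.na(calls$a2)), , drop = FALSE]
    key <- paste(calls$sample_id,
                 site_key(calls$contig, calls$pos, calls$ref, calls$alt))
    dup <- duplicated(key)
    if (any(dup)) {
      stop(sprintf(
        "duplicate (sample, site) in %s calls: %s", prefix, key[dup][1]
      ), call. = FALSE)
    }
    out <- calls[, c("sample_id", "contig", "pos", "ref", "alt",
                     "a1", "a2", "phased", "phase_set", "qual", "depth")]
    nm <- names(out)
    nm[6:11] <- paste0(prefix, "_", nm[6:11])
    stats::setNames(out, nm)
  }

  ilm <- prep(illumina_calls, "illumina")
  ont <- prep(ont_calls, "ont")
  merged <- dplyr::full_join(
    ilm, ont, by = c("sample_id", "contig", "pos", "ref", "alt")
  )
  has_ilm <- !is.na(merged$illumina_a1)
  has_ont <- !is.na(merged$ont_a1)
  category <- dplyr::case_when(
    has_ilm & has_ont & genotypes_equal(
      merged$illumina_a1, merged$illumina_a2,
      merged$ont_a1, merged$ont_a2
    ) ~ "AGREE",
    has_ilm & has_ont ~ "DISCREPANT",
    has_ilm ~ "ILLUMINA_ONLY",
    TRUE ~ "ONT_ONLY"
  )
  merged$category <- factor(category, levels = CONCORDANCE_LEVELS)
  merged <- merged[order(merged$contig, merged$pos, merged$sample_id), ]
  cols <- c("sample_id", "contig", "pos", "ref", "alt", "category")
  tibble::as_tibble(merged[, c(cols, setdiff(names(merged), cols))])
}

#' Summarize concordance categories
#'
#' Counts and frequencies of the four categories, overall or grouped by
#' variant position or by sample.  Frequencies are relative to the
#' records in each group (for `"overall"`, all records), so every group's
#' frequencies sum to 1.
#'
#' @param records Output of [merge_cohorts()].
#' @param scope `"overall"`, `"per_position"` or `"per_sample"`.
#' @return A tibble with the grouping columns (none for overall), then
#'   `category`, `n` and `frequency`; all four categories are present in
#'   every group (zero-filled).
#' @export
summarize_concordance <- function(records,
                                  scope = c("overall", "per_position",
                                            "per_sample")) {
  scope <- match.arg(scope)
  if (nrow(records) == 0) {
    return(tibble::tibble(category = factor(character(),
                                            levels = CONCORDANCE_LEVELS),
                          n = integer(), frequency = double()))
  }
  group_cols <- switch(scope,
    overall = character(),
    per_position = c("contig", "pos", "ref", "alt"),
    per_sample = "sample_id"
  )
  if (length(group_cols) == 0) {
    counts <- records |>
      dplyr::count(.data$category, .drop = FALSE)
    counts$frequency <- counts$n / sum(counts$n)
    return(tibble::as_tibble(counts))
  }
  records |>
    dplyr::count(dplyr::across(dplyr::all_of(group_cols)),
                 .data$category) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(group_cols)),
      category = factor(CONCORDANCE_LEVELS, levels = CONCORDANCE_LEVELS),
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
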