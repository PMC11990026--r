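# Per-site genotype counts, Hardy-Weinberg and reference-frequency tests

#' Tally genotype classes per variant site
#'
#' Counts homozygous-reference, heterozygous and homozygous-alternate
#' genotypes per site across a cohort's calls for one platform.  Two
#' denominator modes are supported:
#' \describe{
#'   \item{`"amplicon_complete"`}{every amplicon covers every site, so a
#'     sample without a call at a site is a homozygous-reference
#'     genotype; `n_total` equals the cohort size (`n_samples`
#'     required).}
#'   \item{`"called_only"`}{only samples with a (non-missing) genotype at
#'     the site enter the tally.}
#' }
#' Calls with missing genotype (`./.`) are excluded from the explicit
#' classes in both modes (under `amplicon_complete` the fixed cohort size
#' imputes them as hom-ref).
#'
#' @param calls A call tibble; restrict to one platform via `platform`
#'   (or pre-filter).
#' @param platform Optional platform to select (`"ONT"`/`"ILLUMINA"`).
#' @param mode Denominator mode, see above.
#' @param n_samples Cohort size, required for `"amplicon_complete"`.
#' @return A tibble with one row per site: `contig`, `pos`, `ref`, `alt`,
#'   `n_hom_ref`, `n_het`, `n_hom_alt`, `n_total`.
#' @export
count_genotypes <- function(calls, platform = NULL,
                            mode = c("amplicon_complete", "called_only"),
                            n_samples = NULL) {
  assert_calls(calls)
  mode <- match.arg(mode)
  if (!is.null(platform)) {
    platform <- match_platform(platform)
    calls <- calls[calls$platform == platform, , drop = FALSE]
  }
  if (mode == "amplicon_complete") {
    if (is.null(n_samples)) {
      stop("`n_samples` is required in amplicon_complete mode",
           call. = FALSE)
    }
    n_samples <- as.integer(n_samples)
  }
  key <- paste(calls$sample_id,
               site_key(calls$contig, calls$pos, calls$ref, calls$alt))
  dup <- duplicated(key)
  if (any(dup)) {
    first <- key[dup][1]
    stop(sprintf("duplicate genotype for %s", first), call. = FALSE)
  }
  counts <- calls |>
    dplyr::group_by(.data$contig, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_hom_ref = sum(is_hom_ref(.data$a1, .data$a2)),
      n_het = sum(is_het(.data$a1, .data$a2)),
      n_hom_alt = sum(is_hom_alt(.data$a1, .data$a2)),
      .groups = "drop"
    )
  if (mode == "amplicon_complete") {
    called <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
    if (any(called > n_samples)) {
      stop("more called genotypes at a site than `n_samples`",
           call. = FALSE)
    }
    counts$n_hom_ref <- counts$n_hom_ref + (n_samples - called)
  }
  counts$n_total <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  counts
}

#' Hardy-Weinberg equilibrium test per site
#'
#' For each site the alt allele frequency `p = (2 n_AA + n_RA) / (2 n)`
#' is estimated and the observed genotype counts are compared with the
#' Hardy-Weinberg expectations `n (1-p)^2`, `2 n p (1-p)`, `n p^2` by a
#' 1-df chi-square goodness-of-fit statistic, without continuity
#' correction.  Monomorphic sites (`p` of 0 or 1) are flagged and get
#' `NA` statistics.  Raw p-values are reported; no multiple-testing
#' correction is applied across sites.
#'
#' @param counts Output of [count_genotypes()] (or any tibble with
#'   `n_hom_ref`, `n_het`, `n_hom_alt` columns); `n_total` > 0 required.
#' @return The input with columns `allele_freq_alt`, `chi_square`, `df`,
#'   `p_value` and `status` (`"OK"` / `"MONOMORPHIC"`) appended.
#' @examples
#' hwe_test(tibble::tibble(n_hom_ref = 30, n_het = 30, n_hom_alt = 40))
#' @export
hwe_test <- function(counts) {
  need <- c("n_hom_ref", "n_het", "n_hom_alt")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have n_hom_ref, n_het, n_hom_alt columns",
         call. = FALSE)
  }
  n <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  if (any(n <= 0)) {
    stop("every site needs at least one genotype (n_total > 0)",
         call. = FALSE)
  }
  p <- (2 * counts$n_hom_alt + counts$n_het) / (2 * n)
  mono <- p == 0 | p == 1
  e_rr <- n * (1 - p)^2
  e_ra <- 2 * n * p * (1 - p)
  e_aa <- n * p^2
  chi <- (counts$n_hom_ref - e_rr)^2 / e_rr +
    (counts$n_het - e_ra)^2 / e_ra +
    (counts$n_hom_alt - e_aa)^2 / e_aa
  chi[mono] <- NA_real_
  pval <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out <- counts
  out$allele_freq_alt <- p
  out$chi_square <- chi
  out$df <- 1L
  out$p_value <- pval
  out$status <- ifelse(mono, "MONOMORPHIC", "OK")
  out
}

#' Compare observed allele frequencies with an external reference
#'
#' A 1-df chi-square test of the observed allele counts (alt =
#' `2 n_AA + n_RA` out of `2 n` alleles) against expected counts
#' `2 n f` and `2 n (1 - f)` for a user-supplied reference alt-allele
#' frequency `f` (e.g. from a population frequency database such as
#' ALFA).  Deviation with `p_value < alpha` is flagged significant.
#'
#' @param counts Genotype counts as from [count_genotypes()].
#' @param expected_alt_freq Reference alt allele frequency, strictly
#'   between 0 and 1; scalar or one value per site.
#' @param alpha Significance threshold (default 0.05).
#' @return The input with `observed_alt_freq`, `expected_alt_freq`,
#'   `ref_chi_square`, `ref_p_value` and `significant` appended.
#' @export
compare_to_reference <- function(counts, expected_alt_freq, alpha = 0.05) {
  need <- c("n_hom_ref", "n_het", "n_hom_alt")
  if (!all(need %in% names(counts))) {
    stop("`counts` must have n_hom_ref, n_het, n_hom_alt columns",
         call. = FALSE)
  }
  if (any(expected_alt_freq <= 0 | expected_alt_freq >= 1)) {
    stop("`expected_alt_freq` must be strictly between 0 and 1",
         call. = FALSE)
  }
  n <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  alleles <- 2 * n
  obs_alt <- 2 * counts$n_hom_alt + counts$n_het
  obs_ref <- alleles - obs_alt
  e_alt <- alleles * expected_alt_freq
  e_ref <- alleles * (1 - expected_alt_freq)
  chi <- (obs_alt - e_alt)^2 / e_alt + (obs_ref - e_ref)^2 / e_ref
  pval <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  out <- counts
  out$observed_alt_freq <- obs_alt / alleles
  out$expected_alt_freq <- expected_alt_freq
  out$ref_chi_square <- chi
  out$ref_p_value <- pval
  out$significant <- pval < alpha
  out
}

#' Per-site statistics table for one platform
#'
#' Convenience wrapper: genotype counts, HWE statistics and (optionally)
#' reference-frequency comparison for every site in a cohort call set,
#' ready for TSV export.
#'
#' @inheritParams count_genotypes
#' @param reference Optional tibble with `contig`, `pos`, `ref`, `alt`,
#'   `expected_alt_freq` columns (sites without a reference frequency get
#'   `NA` comparison columns).
#' @param alpha Significance threshold for the reference comparison.
#' @return One row per site with counts and statistics.
#' @export
site_statistics <- function(calls, platform = NULL,
                            mode = c("amplicon_complete", "called_only"),
                            n_samples = NULL, reference = NULL,
                            alpha = 0.05) {
  counts <- count_genotypes(calls, platform = platform, mode = mode,
                            n_samples = n_samples)
  res <- hwe_test(counts)
  if (!is.null(reference)) {
    res <- dplyr::left_join(
      res, reference,
      by = c("contig", "pos", "ref", "alt")
    )
    has_ref <- !is.na(res$expected_alt_freq)
    if (any(has_ref)) {
      cmp <- compare_to_reference(
        res[has_ref, c("n_hom_ref", "n_het", "n_hom_alt")],
        res$expected_alt_freq[has_ref], alpha = alpha
      )
      res$observed_alt_freq <- NA_real_
      res$ref_chi_square <- NA_real_
      res$ref_p_value <- NA_real_
      res$significant <- NA
      res$observed_alt_freq[has_ref] <- cmp$observed_alt_freq
      res$ref_chi_square[has_ref] <- cmp$ref_chi_square
      res$ref_p_value[has_ref] <- cmp$ref_p_value
      res$significant[has_ref] <- cmp$significant
    }
  }
  res
}
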