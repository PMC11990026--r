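# Phase-block assembly, percent-phased, haplotype rendering and
# cohort haplotype/diplotype frequency tables

#' Assemble phase blocks for one sample and platform
#'
#' Groups phased heterozygous calls by their PS tag into phase blocks:
#' within a block `hap_a` takes the first allele of each ordered genotype
#' and `hap_b` the second.  Homozygous calls carry no phase information
#' and are appended to every block with identical alleles on both
#' haplotypes.  Unphased heterozygous calls cannot be placed and are
#' excluded; their count is attached as attribute `n_unphased_het`.
#' When phased calls carry no PS tag they are accepted only if they form
#' a single block (its `phase_set` is then the smallest site position);
#' missing PS alongside other blocks is a validation error.
#'
#' @param calls Call tibble for exactly one sample and platform.
#' @param windows Optional `interval_set` restriction applied first.
#' @return A list of `phase_block` objects (`sample_id`, `platform`,
#'   `phase_set`, `sites` tibble, integer vectors `hap_a`, `hap_b`,
#'   sites sorted by position), with attribute `n_unphased_het`.
#' @export
build_phase_blocks <- function(calls, windows = NULL) {
  assert_calls(calls)
  if (!is.null(windows)) calls <- filter_by_region(calls, windows)
  if (nrow(calls) > 0) {
    if (length(unique(calls$sample_id)) > 1 ||
        length(unique(calls$platform)) > 1) {
      stop("`calls` must contain exactly one sample and platform",
           call. = FALSE)
    }
  }
  calls <- calls[!(is.na(calls$a1) | is.na(calls$a2)), , drop = FALSE]
  het <- is_het(calls$a1, calls$a2)
  hom <- !het
  phased_het <- het & calls$phased
  n_unphased_het <- sum(het & !calls$phased)

  ph <- calls[phased_het, , drop = FALSE]
  ps <- ph$phase_set
  if (any(is.na(ps))) {
    if (length(unique(ps[!is.na(ps)])) > 0) {
      bad <- ph[is.na(ps), ][1, ]
      stop(sprintf(
        "phased call at %s:%d lacks a PS tag but other phase sets exist",
        bad$contig, bad$pos
      ), call. = FALSE)
    }
    ps <- rep(if (nrow(ph) > 0) min(ph$pos) else NA_integer_, nrow(ph))
  }

  homs <- calls[hom, , drop = FALSE]
  make_block <- function(block_calls, phase_set) {
    all_calls <- dplyr::bind_rows(block_calls, homs)
    all_calls <- all_calls[order(all_calls$pos), , drop = FALSE]
    structure(
      list(
        sample_id = if (nrow(calls) > 0) calls$sample_id[1] else NA_character_,
        platform = if (nrow(calls) > 0) calls$platform[1] else NA_character_,
        phase_set = phase_set,
        sites = all_calls[, c("contig", "pos", "ref", "alt")],
        hap_a = all_calls$a1,
        hap_b = all_calls$a2
      ),
      class = "phase_block"
    )
  }

  blocks <- list()
  if (nrow(ph) > 0) {
    for (set_id in sort(unique(ps))) {
      blocks[[length(blocks) + 1]] <-
        make_block(ph[ps == set_id, , drop = FALSE], as.integer(set_id))
    }
  } else if (nrow(homs) > 0) {
    # fully homozygous (or nothing phased): a single trivial block
    blocks[[1]] <- make_block(homs[0, , drop = FALSE], NA_integer_)
  }
  attr(blocks, "n_unphased_het") <- n_unphased_het
  blocks
}

#' @export
print.phase_block <- function(x, ...) {
  cat(sprintf(
    "<phase_block> %s/%s PS=%s: %d site(s)\n  hap_a: %s\n  hap_b: %s\n",
    x$sample_id, x$platform, x$phase_set, nrow(x$sites),
    paste(x$hap_a, collapse = ""), paste(x$hap_b, collapse = "")
  ))
  invisible(x)
}

#' Percentage of heterozygous calls that are phased
#'
#' `100 * phased het / total het` over the supplied (region-restricted)
#' calls.  Homozygous genotypes carry no phase information and are not
#' counted in the denominator; `denominator = "all"` switches to the
#' all-variants convention.  With an empty denominator the statistic is
#' vacuously 100 and the result carries attribute `vacuous = TRUE`.
#'
#' @param calls Call tibble (any number of samples; one platform/region
#'   slice is the meaningful unit).
#' @param denominator `"heterozygous"` (default) or `"all"`.
#' @return Percentage in `[0, 100]`, with attribute `vacuous`.
#' @export
percent_phased <- function(calls, denominator = c("heterozygous", "all")) {
  assert_calls(calls)
  denominator <- match.arg(denominator)
  called <- !(is.na(calls$a1) | is.na(calls$a2))
  het <- is_het(calls$a1, calls$a2)
  in_denom <- if (denominator == "heterozygous") het else called
  n <- sum(in_denom)
  if (n == 0) {
    return(structure(100, vacuous = TRUE))
  }
  structure(100 * sum(in_denom & calls$phased) / n, vacuous = FALSE)
}

#' Render a phase block as a pair of haplotype sequences
#'
#' Applies each haplotype's alternate alleles to the reference sequence
#' of the region, editing from the highest coordinate down so earlier
#' coordinates stay valid under indels.  Substitutions and simple indels
#' (VCF-style, shared leading base) are supported.
#'
#' @param reference Reference sequence for the region: a character
#'   string or [Biostrings::DNAString].
#' @param block A `phase_block`.
#' @param region_start 1-based genomic position of the first reference
#'   base (default 1).
#' @return Named character vector `c(hap_a = , hap_b = )`.
#' @export
haplotype_sequence <- function(reference, block, region_start = 1L) {
  stopifnot(inherits(block, "phase_block"))
  refseq <- toupper(as.character(reference))
  region_start <- as.integer(region_start)
  apply_hap <- function(alleles) {
    seq <- refseq
    ord <- order(block$sites$pos, decreasing = TRUE)
    for (i in ord) {
      pos <- block$sites$pos[i]
      ref <- block$sites$ref[i]
      alt <- block$sites$alt[i]
      idx <- pos - region_start + 1L
      if (idx < 1L || idx + nchar(ref) - 1L > nchar(seq)) {
        stop(sprintf(
          "site %s:%d lies outside the supplied reference",
          block$sites$contig[i], pos
        ), call. = FALSE)
      }
      seen <- substr(seq, idx, idx + nchar(ref) - 1L)
      if (seen != ref) {
        stop(sprintf(
          "reference mismatch at %s:%d: VCF ref '%s' vs sequence '%s'",
          block$sites$contig[i], pos, ref, seen
        ), call. = FALSE)
      }
      if (alleles[i] == 1L) {
        seq <- paste0(
          substr(seq, 1L, idx - 1L), alt,
          substr(seq, idx + nchar(ref), nchar(seq))
        )
      }
    }
    seq
  }
  c(hap_a = apply_hap(block$hap_a), hap_b = apply_hap(block$hap_b))
}

# compact haplotype label: carried alt alleles as pos:ref>alt joined by
# "+", or "ref" when no alt allele is carried.  Sites absent from a
# sample's calls count as reference (amplicon-complete coverage).
hap_label <- function(sites, alleles) {
  carried <- alleles == 1L
  if (!any(carried)) return("ref")
  paste(sprintf("%d:%s>%s", sites$pos[carried], sites$ref[carried],
                sites$alt[carried]), collapse = "+")
}

#' Derive per-sample diplotypes for a region
#'
#' For each sample the phase blocks are assembled and, when all
#' heterozygous sites fall into a single block, the two haplotypes are
#' rendered as compact labels (carried alt alleles, `"ref"` when none).
#' Samples whose heterozygous sites split across more than one phase
#' block, or with unphased heterozygous calls, are flagged incomplete
#' and carry the haplotypes of their largest block only: concatenating
#' blocks would assert phase the data does not support.
#'
#' @param calls Call tibble for one platform (all samples).
#' @param region_id Label for the analyzed region.
#' @param windows Optional `interval_set` restriction.
#' @return A tibble with `sample_id`, `region_id`, `hap_a`, `hap_b`,
#'   `complete`, `n_blocks`, `n_unphased_het`.
#' @export
build_diplotypes <- function(calls, region_id = "region", windows = NULL) {
  assert_calls(calls)
  if (!is.null(windows)) calls <- filter_by_region(calls, windows)
  if (nrow(calls) > 0 && length(unique(calls$platform)) > 1) {
    stop("`calls` must come from a single platform", call. = FALSE)
  }
  per_sample <- split(calls, calls$sample_id)
  rows <- lapply(per_sample, function(sc) {
    blocks <- build_phase_blocks(sc)
    n_unphased <- attr(blocks, "n_unphased_het")
    n_het_blocks <- sum(vapply(
      blocks, function(b) any(b$hap_a != b$hap_b), logical(1)
    ))
    complete <- n_het_blocks <= 1 && n_unphased == 0
    if (length(blocks) == 0) {
      block <- NULL
      hap_a <- hap_b <- "ref"
    } else {
      sizes <- vapply(blocks, function(b) nrow(b$sites), integer(1))
      block <- blocks[[which.max(sizes)]]
      hap_a <- hap_label(block$sites, block$hap_a)
      hap_b <- hap_label(block$sites, block$hap_b)
    }
    tibble::tibble(
      sample_id = sc$sample_id[1], region_id = region_id,
      hap_a = hap_a, hap_b = hap_b,
      complete = complete, n_blocks = length(blocks),
      n_unphased_het = n_unphased
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort haplotype or diplotype frequency table
#'
#' Counts haplotypes (each complete sample contributes its two) or
#' unordered diplotype pairs (one per sample) across a cohort and lists
#' them by descending count, ties broken lexicographically.  Incomplete
#' diplotypes are excluded; the excluded count is attached as attribute
#' `n_excluded` and disclosed in a message.
#'
#' @param diplotypes Output of [build_diplotypes()] (shared `region_id`).
#' @param level `"haplotype"` or `"diplotype"`.
#' @return A tibble `region_id`, `haplotype` (or `diplotype`), `count`,
#'   `frequency` sorted by descending count; frequencies sum to 1.
#' @export
cohort_haplotype_frequencies <- function(diplotypes,
                                         level = c("haplotype",
                                                   "diplotype")) {
  level <- match.arg(level)
  if (length(unique(diplotypes$region_id)) > 1) {
    stop("`diplotypes` must share one region_id", call. = FALSE)
  }
  n_excluded <- sum(!diplotypes$complete)
  if (n_excluded > 0) {
    message(sprintf(
      "excluding %d incomplete diplotype(s) from the frequency table",
      n_excluded
    ))
  }
  dip <- diplotypes[diplotypes$complete, , drop = FALSE]
  region <- if (nrow(diplotypes) > 0) diplotypes$region_id[1] else NA_character_
  if (level == "haplotype") {
    items <- c(dip$hap_a, dip$hap_b)
    label_col <- "haplotype"
  } else {
    items <- ifelse(
      dip$hap_a <= dip$hap_b,
      paste(dip$hap_a, dip$hap_b, sep = " / "),
      paste(dip$hap_b, dip$hap_a, sep = " / ")
    )
    label_col <- "diplotype"
  }
  if (length(items) == 0) {
    out <- tibble::tibble(region_id = character(), label = character(),
                          count = integer(), frequency = double())
    names(out)[2] <- label_col
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  tab <- table(items)
  out <- tibble::tibble(
    region_id = region,
    label = names(tab),
    count = as.integer(tab),
    frequency = as.integer(tab) / length(items)
  )
  out <- out[order(-out$count, out$label), , drop = FALSE]
  names(out)[2] <- label_col
  attr(out, "n_excluded") <- n_excluded
  out
}
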