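# VCF input: phased, per-sample or multi-sample variant calls

# INFO metrics carried through when the source VCF annotates them
# (bcftools call output: bias z-scores, MQ0 fraction, mean mapping quality)
INFO_METRICS <- c("SCBZ", "RPBZ", "MQBZ", "MQSBZ", "BQBZ", "MQ0F", "MQ")

#' Read phased variant calls from a VCF file
#'
#' Reads a VCF (plain or gzip/bgzip) produced by a bcftools-call +
#' WhatsHap-phase pathway and returns one row per (sample, site, alt
#' allele).  Multi-allelic records are split into biallelic calls: within
#' a split record any genotype allele index other than the split alt's
#' original index is recoded to 0, preserving per-alt presence/absence.
#' Phase information is preserved: a `|`-separated GT yields
#' `phased = TRUE` and the PS tag (when present) populates `phase_set`.
#' Records with genotype `./.` (or any `.` allele) are returned with
#' missing genotype (`a1 = a2 = NA`).
#'
#' Per-sample read depth is taken from FORMAT/DP when present, falling
#' back to INFO/DP.  INFO metrics `r paste(INFO_METRICS, collapse = ", ")`
#' are carried through as extra numeric columns when the file defines
#' them.
#'
#' @param path Path to a VCF file with a GT FORMAT field and at least one
#'   sample column.
#' @param platform Which sequencing platform produced the calls:
#'   `"ONT"` or `"ILLUMINA"` (case-insensitive).
#' @param sample_override Optional sample name replacing the (single)
#'   sample column name in the file; an error for multi-sample files.
#' @return A call tibble (see [ampliphase]) ordered as in the file.
#' @examples
#' vcf <- system.file("extdata", "example_ont.vcf", package = "ampliphase")
#' read_phased_vcf(vcf, platform = "ONT")
#' @export
read_phased_vcf <- function(path, platform, sample_override = NULL) {
  platform <- match_platform(platform)
  if (!file.exists(path)) {
    stop(sprintf("cannot read VCF: no such file '%s'", path), call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) {
    # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt_raw <- vcf@gt
  if (!is.null(gt_raw) && !is.matrix(gt_raw)) {
    gt_raw <- matrix(gt_raw, nrow = 1, dimnames = list(NULL, names(gt_raw)))
  }
  if (is.null(gt_raw) || ncol(gt_raw) < 2) {
    stop(sprintf("VCF '%s' has no sample columns", path), call. = FALSE)
  }
  sample_names <- colnames(gt_raw)[-1]
  if (!is.null(sample_override)) {
    if (length(sample_names) != 1) {
      stop("`sample_override` requires a single-sample VCF", call. = FALSE)
    }
    sample_names <- sample_override
  }
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(empty_calls())
  }

  fmt <- gt_raw[, "FORMAT"]
  has_gt <- vapply(
    strsplit(fmt, ":", fixed = TRUE),
    function(x) "GT" %in% x, logical(1)
  )
  if (any(!has_gt)) {
    bad <- which(!has_gt)[1]
    stop(sprintf(
      "record %s:%s lacks a GT FORMAT field",
      fix[bad, "CHROM"], fix[bad, "POS"]
    ), call. = FALSE)
  }

  extract_fmt <- function(element, as_num = FALSE) {
    out <- tryCatch(
      vcfR::extract.gt(vcf, element = element, as.numeric = as_num),
      error = function(e) NULL
    )
    if (!is.null(out) && !is.matrix(out)) out <- matrix(out, nrow = n_rec)
    out
  }
  gt_mat <- extract_fmt("GT")
  ps_mat <- extract_fmt("PS", as_num = TRUE)
  dp_mat <- extract_fmt("DP", as_num = TRUE)
  dp_info <- tryCatch(
    suppressWarnings(vcfR::extract.info(vcf, element = "DP", as.numeric = TRUE)),
    error = function(e) NULL
  )

  info_extra <- list()
  for (m in INFO_METRICS) {
    v <- tryCatch(
      suppressWarnings(vcfR::extract.info(vcf, element = m, as.numeric = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(v) && any(!is.na(v))) info_extra[[m]] <- v
  }

  qual <- unname(suppressWarnings(as.numeric(fix[, "QUAL"])))
  pos <- unname(as.integer(fix[, "POS"]))
  contig <- unname(fix[, "CHROM"])
  ref <- unname(toupper(fix[, "REF"]))
  alt_field <- unname(toupper(fix[, "ALT"]))
  alts <- strsplit(alt_field, ",", fixed = TRUE)

  rows <- vector("list", n_rec * length(sample_names))
  k <- 0L
  for (s in seq_along(sample_names)) {
    gt_col <- gt_mat[, s]
    for (i in seq_len(n_rec)) {
      gt <- gt_col[i]
      phased <- FALSE
      alleles <- c(NA_integer_, NA_integer_)
      if (!is.na(gt)) {
        phased <- grepl("|", gt, fixed = TRUE)
        parts <- strsplit(gt, "[/|]")[[1]]
        if (length(parts) != 2) {
          stop(sprintf(
            "unsupported ploidy in GT '%s' at %s:%d (diploid calls required)",
            gt, contig[i], pos[i]
          ), call. = FALSE)
        }
        if (any(parts == ".")) {
          phased <- FALSE
        } else {
          alleles <- as.integer(parts)
        }
      }
      rec_alts <- alts[[i]]
      for (j in seq_along(rec_alts)) {
        if (rec_alts[j] %in% c(".", "")) next
        a <- alleles
        if (!is.na(a[1])) {
          # recode against this alt: carrying index j -> 1, anything else -> 0
          a <- ifelse(a == j, 1L, 0L)
        }
        dp <- NA_real_
        if (!is.null(dp_mat) && !is.na(dp_mat[i, s])) {
          dp <- dp_mat[i, s]
        } else if (!is.null(dp_info) && !is.na(dp_info[i])) {
          dp <- dp_info[i]
        }
        ps <- if (!is.null(ps_mat)) ps_mat[i, s] else NA_real_
        k <- k + 1L
        rows[[k]] <- list(
          sample_id = sample_names[s], platform = platform,
          contig = contig[i], pos = pos[i],
          ref = ref[i], alt = rec_alts[j],
          a1 = a[1], a2 = a[2],
          phased = phased,
          phase_set = if (is.na(ps)) NA_integer_ else as.integer(ps),
          qual = qual[i],
          depth = if (is.na(dp)) NA_integer_ else as.integer(dp),
          rec = i
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(k)])
  for (m in names(info_extra)) out[[m]] <- info_extra[[m]][out$rec]
  out$rec <- NULL
  out
}

#' Normalize a site into a cross-platform merge key
#'
#' Builds the shared identity used to align calls from the two platforms:
#' contig, 1-based position and uppercased REF/ALT alleles.  No indel
#' re-alignment is attempted; input is assumed left-aligned by the
#' upstream caller.
#'
#' @param contig Contig / chromosome name.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt Reference and alternate allele strings (non-empty,
#'   distinct after case folding).
#' @return A one-row tibble with columns `contig`, `pos`, `ref`, `alt`
#'   and the canonical string `key`.
#' @examples
#' normalize_site("chr19", 100, "a", "g")
#' @export
normalize_site <- function(contig, pos, ref, alt) {
  if (any(is.na(c(contig, pos, ref, alt)))) {
    stop("site fields must be non-missing", call. = FALSE)
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (!nzchar(ref) || !nzchar(alt)) {
    stop("ref and alt alleles must be non-empty strings", call. = FALSE)
  }
  if (identical(ref, alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  if (is.na(pos) || pos < 1L) {
    stop("pos must be a positive 1-based coordinate", call. = FALSE)
  }
  tibble::tibble(
    contig = as.character(contig), pos = pos, ref = ref, alt = alt,
    key = site_key(contig, pos, ref, alt)
  )
}
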