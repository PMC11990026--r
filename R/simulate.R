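# Synthetic two-platform cohort generator with known truth
#
# Operates at the call level: truth diplotypes are drawn per sample and
# site under Hardy-Weinberg proportions, then corrupted per platform
# with genotype-error, missed-call and phasing rates and QUAL/DP values
# drawn from normal distributions, emulating the variant-only phased
# VCFs a bcftools + WhatsHap pathway produces.

#' Per-platform corruption and annotation parameters
#'
#' @param genotype_error_rate Probability that an emitted genotype is
#'   perturbed (heterozygous <-> homozygous-alternate swap).
#' @param missed_call_rate Probability that a non-hom-ref truth genotype
#'   is dropped from the platform's call set.
#' @param phased_rate Probability that an emitted heterozygous call is
#'   phased (truth allele order, shared PS per region).
#' @param qual_mean,qual_sd Normal QUAL distribution (floored at 0,
#'   rounded to 1 decimal as callers print it).
#' @param depth_mean,depth_sd Normal DP distribution (floored at 1,
#'   rounded to integer).
#' @return A `platform_params` list.
#' @export
platform_params <- function(genotype_error_rate = 0,
                            missed_call_rate = 0,
                            phased_rate = 1,
                            qual_mean = 165.5, qual_sd = 52.7,
                            depth_mean = 690.5, depth_sd = 175.4) {
  rates <- c(genotype_error_rate, missed_call_rate, phased_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      genotype_error_rate = genotype_error_rate,
      missed_call_rate = missed_call_rate,
      phased_rate = phased_rate,
      qual_mean = qual_mean, qual_sd = qual_sd,
      depth_mean = depth_mean, depth_sd = depth_sd
    ),
    class = "platform_params"
  )
}

#' Default variant site panel for the simulator
#'
#' Ten SNV sites spread across an 11 kb amplicon-sized region (about one
#' naturally occurring SNV per kilobase) with a spread of plausible
#' population alt-allele frequencies.
#'
#' @param contig Contig name.
#' @return Tibble with `contig`, `pos`, `ref`, `alt`, `alt_freq`.
#' @export
default_sites <- function(contig = "chr19") {
  tibble::tibble(
    contig = contig,
    pos = as.integer(seq(750L, by = 1000L, length.out = 10L)),
    ref = rep(c("A", "C", "G", "T", "A"), 2),
    alt = rep(c("G", "T", "A", "C", "T"), 2),
    alt_freq = c(0.30, 0.10, 0.05, 0.45, 0.20,
                 0.02, 0.15, 0.35, 0.08, 0.25)
  )
}

#' Full parameterization of a synthetic two-platform cohort
#'
#' Defaults emulate the study conditions the package targets: a 400-donor
#' amplicon cohort, 10 SNV sites on an 11 kb region, ONT QUAL/DP of
#' roughly 165 +- 53 / 690 +- 175 and Illumina 223 +- 1 / 880 +- 157,
#' ONT phasing 99.7% of heterozygous calls vs 91.9% for Illumina, and
#' small genotype-error / missed-call rates on the ~1% discordance
#' scale.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_samples Cohort size.
#' @param contig,region_start,region_end Simulated amplicon region.
#' @param sites Site panel tibble (`contig`, `pos`, `ref`, `alt`,
#'   `alt_freq` in (0,1)), sorted by position, unique.
#' @param ont,illumina [platform_params()] for each platform.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 400L,
                              contig = "chr19",
                              region_start = 1L,
                              region_end = 11000L,
                              sites = default_sites(contig),
                              ont = platform_params(
                                genotype_error_rate = 0.01,
                                missed_call_rate = 0.005,
                                phased_rate = 0.997,
                                qual_mean = 165.5, qual_sd = 52.7,
                                depth_mean = 690.5, depth_sd = 175.4
                              ),
                              illumina = platform_params(
                                genotype_error_rate = 0.002,
                                missed_call_rate = 0.005,
                                phased_rate = 0.919,
                                qual_mean = 222.6, qual_sd = 1.2,
                                depth_mean = 880, depth_sd = 156.8
                              )) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("pos", "ref", "alt", "alt_freq") %in% names(sites)))
  if (!"contig" %in% names(sites)) sites$contig <- contig
  if (is.unsorted(sites$pos, strictly = TRUE)) {
    stop("`sites` must be sorted by position and unique", call. = FALSE)
  }
  if (any(sites$alt_freq <= 0 | sites$alt_freq >= 1)) {
    stop("site alt_freq values must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_samples = as.integer(n_samples),
      contig = contig, region_start = as.integer(region_start),
      region_end = as.integer(region_end),
      sites = sites, ont = ont, illumina = illumina
    ),
    class = "simulation_config"
  )
}

#' Draw a truth cohort under Hardy-Weinberg proportions
#'
#' For each sample and site the two haplotype alleles are independent
#' Bernoulli(`alt_freq`) draws, so genotype frequencies follow HWE and
#' the phase (`a1` = haplotype A) is known by construction.
#'
#' @param config A [simulation_config()].
#' @return Tibble with `sample_id`, `contig`, `pos`, `ref`, `alt`,
#'   `a1`, `a2` for every sample x site; deterministic given
#'   `config$seed`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  s <- nrow(config$sites)
  samples <- sprintf("S%04d", seq_len(n))
  a1 <- stats::rbinom(n * s, 1L, rep(config$sites$alt_freq, each = n))
  a2 <- stats::rbinom(n * s, 1L, rep(config$sites$alt_freq, each = n))
  tibble::tibble(
    sample_id = rep(samples, times = s),
    contig = rep(config$sites$contig, each = n),
    pos = rep(config$sites$pos, each = n),
    ref = rep(config$sites$ref, each = n),
    alt = rep(config$sites$alt, each = n),
    a1 = as.integer(a1), a2 = as.integer(a2)
  ) |>
    dplyr::arrange(.data$sample_id, .data$pos)
}

#' Corrupt a truth cohort into one platform's call set
#'
#' Variant-only VCF semantics: homozygous-reference truth genotypes are
#' never emitted.  Each remaining genotype is dropped with probability
#' `missed_call_rate`; emitted genotypes are perturbed (het <->
#' hom-alt swap) with probability `genotype_error_rate`; each emitted
#' heterozygote is phased with probability `phased_rate`, keeping the
#' truth allele order and sharing one PS (the region's first site
#' position) per contig.  QUAL and DP are drawn from the configured
#' normal distributions.
#'
#' @param truth Output of [simulate_truth()].
#' @param params [platform_params()] for the platform.
#' @param platform `"ONT"` or `"ILLUMINA"`.
#' @param seed Integer seed for the corruption draws.
#' @return A call tibble.
#' @export
corrupt_for_platform <- function(truth, params, platform, seed) {
  stopifnot(inherits(params, "platform_params"))
  platform <- match_platform(platform)
  set.seed(seed)

  calls <- truth[truth$a1 + truth$a2 > 0, , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) {
    return(empty_calls())
  }
  keep <- stats::runif(n) >= params$missed_call_rate
  calls <- calls[keep, , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) {
    return(empty_calls())
  }

  flip <- stats::runif(n) < params$genotype_error_rate
  het <- calls$a1 != calls$a2
  # het -> hom-alt; hom-alt -> het with random allele order
  new_a1 <- calls$a1
  new_a2 <- calls$a2
  new_a1[flip & het] <- 1L
  new_a2[flip & het] <- 1L
  to_het <- flip & !het
  if (any(to_het)) {
    first_alt <- stats::runif(sum(to_het)) < 0.5
    new_a1[to_het] <- ifelse(first_alt, 1L, 0L)
    new_a2[to_het] <- ifelse(first_alt, 0L, 1L)
  }
  calls$a1 <- new_a1
  calls$a2 <- new_a2

  het <- calls$a1 != calls$a2
  phased <- het & stats::runif(n) < params$phased_rate
  ps0 <- min(truth$pos)
  calls$phased <- phased
  calls$phase_set <- ifelse(phased, ps0, NA_integer_)
  # unphased heterozygotes lose their order: canonical 0/1
  calls$a1[het & !phased] <- 0L
  calls$a2[het & !phased] <- 1L

  calls$platform <- platform
  calls$qual <- round(pmax(0, stats::rnorm(n, params$qual_mean,
                                           params$qual_sd)), 1)
  calls$depth <- as.integer(pmax(1, round(stats::rnorm(
    n, params$depth_mean, params$depth_sd
  ))))
  calls <- calls[order(calls$sample_id, calls$pos), , drop = FALSE]
  calls[, names(empty_calls())]
}

#' Simulate a full paired-platform cohort
#'
#' Draws the truth cohort and both platforms' corrupted call sets.
#' Sub-seeds for the two corruption passes are derived deterministically
#' from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `truth` and `calls` (both platforms, bound).
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 42, n_samples = 20))
#' dplyr::count(cohort$calls, platform)
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  ont <- corrupt_for_platform(truth, config$ont, "ONT",
                              seed = config$seed + 1L)
  ilm <- corrupt_for_platform(truth, config$illumina, "ILLUMINA",
                              seed = config$seed + 2L)
  list(truth = truth, calls = dplyr::bind_rows(ont, ilm))
}

#' Truth haplotype and diplotype distributions of a cohort
#'
#' Tabulates the simulated truth haplotypes (two per sample) and
#' unordered diplotype pairs with the same labels used by
#' [cohort_haplotype_frequencies()], for recovery comparisons.
#'
#' @param truth Output of [simulate_truth()].
#' @param region_id Region label for the tables.
#' @return List of tibbles `haplotype` and `diplotype`.
#' @export
truth_haplotype_frequencies <- function(truth, region_id = "region") {
  per_sample <- split(truth, truth$sample_id)
  labels <- lapply(per_sample, function(tt) {
    tt <- tt[order(tt$pos), ]
    sites <- tt[, c("contig", "pos", "ref", "alt")]
    c(hap_label(sites, tt$a1), hap_label(sites, tt$a2))
  })
  hap <- unlist(labels)
  dip <- vapply(labels, function(h) {
    paste(sort(h), collapse = " / ")
  }, character(1))
  as_table <- function(x, label_col) {
    tab <- table(x)
    out <- tibble::tibble(
      region_id = region_id, label = names(tab),
      count = as.integer(tab),
      frequency = as.integer(tab) / length(x)
    )
    out <- out[order(-out$count, out$label), , drop = FALSE]
    names(out)[2] <- label_col
    out
  }
  list(
    haplotype = as_table(hap, "haplotype"),
    diplotype = as_table(dip, "diplotype")
  )
}

#' Write one sample's calls as a phased VCF fixture
#'
#' Emits a minimal but valid VCF 4.2 file (GT:PS:DP FORMAT, QUAL column)
#' that [read_phased_vcf()] round-trips field-identically.
#'
#' @param calls Call tibble for exactly one sample and platform.
#' @param path Output path (`.vcf`).
#' @param contig_length Optional contig length for the header.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(calls, path, contig_length = NULL) {
  assert_calls(calls)
  if (nrow(calls) > 0 &&
      (length(unique(calls$sample_id)) > 1 ||
       length(unique(calls$platform)) > 1)) {
    stop("`calls` must contain exactly one sample and platform",
         call. = FALSE)
  }
  sample_id <- if (nrow(calls) > 0) calls$sample_id[1] else "SAMPLE"
  contigs <- unique(calls$contig)
  contig_lines <- if (length(contigs) > 0) {
    if (!is.null(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", contigs, contig_length)
    } else {
      sprintf("##contig=<ID=%s>", contigs)
    }
  } else {
    character()
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ampliphase-synthetic-cohort",
    contig_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=PS,Number=1,Type=Integer,",
           "Description=\"Phase set identifier\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character()
  if (nrow(calls) > 0) {
    calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
    gt <- format_gt(calls$a1, calls$a2, calls$phased)
    gt[gt == "."] <- "./."
    ps <- ifelse(is.na(calls$phase_set), ".",
                 as.character(calls$phase_set))
    dp <- ifelse(is.na(calls$depth), ".", as.character(calls$depth))
    qual <- ifelse(is.na(calls$qual), ".",
                   format(calls$qual, trim = TRUE, scientific = FALSE))
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
                  qual, ".", ".", "GT:PS:DP",
                  paste(gt, ps, dp, sep = ":"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated cohort to per-sample VCFs plus a truth table
#'
#' Materializes a simulated study on disk: one VCF per sample and
#' platform under `dir/<platform>/<sample>.vcf`, the truth genotypes as
#' `truth.tsv`, and the configuration as `config.yaml`-style TSV
#' provenance (`config.tsv`).
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort and the written paths.
#' @export
write_cohort_fixtures <- function(config, dir) {
  cohort <- simulate_cohort(config)
  paths <- character()
  for (pf in PLATFORMS) {
    pf_dir <- file.path(dir, tolower(pf))
    dir.create(pf_dir, recursive = TRUE, showWarnings = FALSE)
    pf_calls <- cohort$calls[cohort$calls$platform == pf, , drop = FALSE]
    for (sid in unique(pf_calls$sample_id)) {
      p <- file.path(pf_dir, paste0(sid, ".vcf"))
      write_phased_vcf(pf_calls[pf_calls$sample_id == sid, , drop = FALSE], p)
      paths <- c(paths, p)
    }
  }
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(cohort$truth, truth_path)
  cfg_path <- file.path(dir, "config.tsv")
  cfg_flat <- tibble::tibble(
    key = c(
      "seed", "n_samples", "contig", "region_start", "region_end",
      paste0("ont_", names(config$ont)),
      paste0("illumina_", names(config$illumina))
    ),
    value = as.character(c(
      config$seed, config$n_samples, config$contig,
      config$region_start, config$region_end,
      unlist(config$ont), unlist(config$illumina)
    ))
  )
  readr::write_tsv(cfg_flat, cfg_path)
  invisible(list(cohort = cohort,
                 paths = c(paths, truth_path, cfg_path)))
}
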