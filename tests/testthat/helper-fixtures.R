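# shared fixture builders: every fixture is constructed in code

# one call-table row from compact arguments
make_call <- function(sample_id = "S1", platform = "ONT",
                      contig = "chr19", pos = 100L, ref = "A", alt = "G",
                      gt = "0/1", phase_set = NA_integer_,
                      qual = 100, depth = 500L) {
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  a <- suppressWarnings(as.integer(parts))
  tibble::tibble(
    sample_id = sample_id, platform = platform,
    contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
    a1 = a[1], a2 = a[2], phased = phased,
    phase_set = as.integer(phase_set),
    qual = as.numeric(qual), depth = as.integer(depth)
  )
}

make_calls <- function(...) dplyr::bind_rows(...)

# random single-platform call set over random sites
random_calls <- function(n, seed, platform = "ONT", n_samples = 5,
                         contig = "chr19") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pos <- sort(sample(seq_len(5000), n))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gt_pool <- c("0/1", "0|1", "1|0", "1/1")
  gts <- sample(gt_pool, n, replace = TRUE)
  calls <- lapply(seq_len(n), function(i) {
    make_call(
      sample_id = sprintf("S%02d", sample(n_samples, 1)),
      platform = platform, contig = contig, pos = pos[i],
      ref = ref[i], alt = alt[i], gt = gts[i],
      phase_set = if (grepl("|", gts[i], fixed = TRUE)) 1L else NA_integer_,
      qual = round(runif(1, 0, 250), 1),
      depth = sample(100:1000, 1)
    )
  })
  out <- dplyr::bind_rows(calls)
  out[!duplicated(paste(out$sample_id, out$pos)), ]
}

# the toy gene model used throughout the region tests
toy_gene_model <- function() {
  new_gene_model(
    gene_id = "TOY1", contig = "chr19", strand = "+",
    gene_span = c(1001L, 4000L),
    exons = rbind(c(1001L, 1200L), c(1901L, 2100L), c(3801L, 4000L)),
    cds = rbind(c(1051L, 1200L), c(1901L, 2100L), c(3801L, 3950L))
  )
}

# base-by-base enumeration oracle for target windows, independent of the
# interval arithmetic in build_target_windows
windows_oracle <- function(model, kind, intronic_flank = 50,
                           noncoding_flank = 200, genome_max = 10000) {
  member <- rep(FALSE, genome_max)
  mark <- function(lo, hi) {
    lo <- max(1, lo)
    member[lo:hi] <<- TRUE
  }
  if (kind == "CDS") {
    for (i in seq_len(nrow(model$cds))) {
      mark(model$cds[i, 1] - intronic_flank, model$cds[i, 2] + intronic_flank)
    }
  } else if (kind == "EXONS_PLUS") {
    first_start <- min(model$exons[, 1])
    last_end <- max(model$exons[, 2])
    for (i in seq_len(nrow(model$exons))) {
      lo <- model$exons[i, 1]
      hi <- model$exons[i, 2]
      lo_f <- if (lo == first_start) noncoding_flank else intronic_flank
      hi_f <- if (hi == last_end) noncoding_flank else intronic_flank
      mark(lo - lo_f, hi + hi_f)
    }
  } else {
    mark(model$gene_span[1] - noncoding_flank,
         model$gene_span[2] + noncoding_flank)
  }
  which(member)
}

# positions covered by an interval_set, by direct expansion
expand_windows <- function(windows) {
  if (nrow(windows$intervals) == 0) return(integer())
  sort(unique(unlist(apply(windows$intervals, 1, function(r) r[1]:r[2]))))
}

# independent HWE chi-square oracle: textbook formula plus the
# closed-form df=1 survival function P(X > x) = 2 * (1 - Phi(sqrt(x)))
hwe_oracle <- function(rr, ra, aa) {
  n <- rr + ra + aa
  p <- (2 * aa + ra) / (2 * n)
  if (p == 0 || p == 1) return(list(chi = NA_real_, p = NA_real_, f = p))
  e <- c(n * (1 - p)^2, 2 * n * p * (1 - p), n * p^2)
  chi <- sum((c(rr, ra, aa) - e)^2 / e)
  list(chi = chi, p = 2 * stats::pnorm(-sqrt(chi)), f = p)
}

# write VCF text lines to a temp file
write_vcf_text <- function(records, samples = "S1",
                           format_defs = c("GT", "PS", "DP")) {
  defs <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    PS = "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"ps\">",
    DP = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">"
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr19>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    unname(defs[format_defs]),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
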