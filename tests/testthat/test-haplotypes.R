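test_that("phase blocks transpose ordered genotypes into haplotypes", {
  calls <- make_calls(
    make_call(pos = 100L, gt = "0|1", phase_set = 100L),
    make_call(pos = 200L, ref = "C", alt = "T", gt = "1|0",
              phase_set = 100L)
  )
  blocks <- build_phase_blocks(calls)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$phase_set, 100L)
  expect_equal(blocks[[1]]$hap_a, c(0L, 1L))
  expect_equal(blocks[[1]]$hap_b, c(1L, 0L))

  # homozygous sites join every block on both haplotypes
  with_hom <- dplyr::bind_rows(
    calls, make_call(pos = 150L, ref = "G", alt = "A", gt = "1/1")
  )
  blocks <- build_phase_blocks(with_hom)
  expect_equal(blocks[[1]]$sites$pos, c(100L, 150L, 200L))
  expect_equal(blocks[[1]]$hap_a, c(0L, 1L, 1L))
  expect_equal(blocks[[1]]$hap_b, c(1L, 1L, 0L))
})

test_that("a phased call without PS is rejected when other blocks exist", {
  calls <- make_calls(
    make_call(pos = 100L, gt = "0|1", phase_set = 100L),
    make_call(pos = 200L, ref = "C", alt = "T", gt = "1|0",
              phase_set = NA)
  )
  expect_error(build_phase_blocks(calls), "PS")
  # alone, PS-less phased calls form a single block keyed by position
  solo <- make_call(pos = 300L, gt = "0|1", phase_set = NA)
  blocks <- build_phase_blocks(solo)
  expect_equal(blocks[[1]]$phase_set, 300L)
})

test_that("random cohorts group into blocks exactly by phase set", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    ps_ids <- sample(c(1000L, 2000L), n, replace = TRUE)
    calls <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_call(pos = 100L * i, gt = sample(c("0|1", "1|0"), 1),
                phase_set = ps_ids[i])
    }))
    blocks <- build_phase_blocks(calls)
    expect_equal(length(blocks), length(unique(ps_ids)))
    for (b in blocks) {
      expected_pos <- sort(calls$pos[ps_ids == b$phase_set])
      expect_equal(b$sites$pos, expected_pos)
      # transposition: column j of (hap_a, hap_b) is the ordered GT
      idx <- match(b$sites$pos, calls$pos)
      expect_equal(b$hap_a, calls$a1[idx])
      expect_equal(b$hap_b, calls$a2[idx])
    }
  }
})

test_that("percent phased counts heterozygous calls only", {
  calls <- make_calls(
    make_call(pos = 100L, gt = "0|1", phase_set = 1L),
    make_call(pos = 200L, gt = "0|1", phase_set = 1L),
    make_call(pos = 300L, gt = "1|0", phase_set = 1L),
    make_call(pos = 400L, gt = "0/1"),
    make_call(pos = 500L, gt = "1/1")
  )
  pp <- percent_phased(calls)
  expect_equal(as.numeric(pp), 75)
  expect_false(attr(pp, "vacuous"))
  # the hom call enters the all-variants denominator
  expect_equal(as.numeric(percent_phased(calls, denominator = "all")), 60)

  homs <- make_call(pos = 100L, gt = "1/1")
  vac <- percent_phased(homs)
  expect_equal(as.numeric(vac), 100)
  expect_true(attr(vac, "vacuous"))
})

test_that("cohort-mean percent phased recovers the phasing probability", {
  sites <- tibble::tibble(
    contig = "chr19", pos = seq(100L, by = 100L, length.out = 30L),
    ref = "A", alt = "G", alt_freq = rep(0.5, 30)
  )
  cfg <- simulation_config(
    seed = 81, n_samples = 400, sites = sites,
    ont = platform_params(phased_rate = 0.9),
    illumina = platform_params()
  )
  cohort <- simulate_cohort(cfg)
  ont <- cohort$calls[cohort$calls$platform == "ONT", ]
  pp <- as.numeric(percent_phased(ont))
  n_het <- sum(ont$a1 != ont$a2)
  se <- 100 * sqrt(0.9 * 0.1 / n_het)
  expect_lt(abs(pp - 90), 3 * se)
})

test_that("haplotype sequences apply alleles against the reference", {
  block <- structure(list(
    sample_id = "S1", platform = "ONT", phase_set = 1L,
    sites = tibble::tibble(contig = "chr1", pos = 2L, ref = "C",
                           alt = "T"),
    hap_a = 1L, hap_b = 0L
  ), class = "phase_block")
  expect_equal(unname(haplotype_sequence("ACGT", block)),
               c("ATGT", "ACGT"))

  empty <- structure(list(
    sample_id = "S1", platform = "ONT", phase_set = 1L,
    sites = tibble::tibble(contig = character(), pos = integer(),
                           ref = character(), alt = character()),
    hap_a = integer(), hap_b = integer()
  ), class = "phase_block")
  expect_equal(unname(haplotype_sequence("ACGT", empty)), c("ACGT", "ACGT"))

  bad <- block
  bad$sites$ref <- "G"
  expect_error(haplotype_sequence("ACGT", bad), "mismatch")
})

test_that("random substitution sets equal a per-base editor oracle", {
  set.seed(91)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:50) {
    len <- sample(20:60, 1)
    refseq <- paste(sample(bases, len, replace = TRUE), collapse = "")
    n_var <- sample(1:5, 1)
    pos <- sort(sample(len, n_var))
    ref_al <- vapply(pos, function(p) substr(refseq, p, p), character(1))
    alt_al <- vapply(ref_al, function(r) sample(setdiff(bases, r), 1),
                     character(1))
    hap_a <- sample(0:1, n_var, replace = TRUE)
    hap_b <- 1L - hap_a
    block <- structure(list(
      sample_id = "S1", platform = "ONT", phase_set = 1L,
      sites = tibble::tibble(contig = "c", pos = pos, ref = ref_al,
                             alt = alt_al),
      hap_a = hap_a, hap_b = hap_b
    ), class = "phase_block")
    got <- haplotype_sequence(refseq, block)
    edit <- function(alleles) {
      chars <- strsplit(refseq, "")[[1]]
      chars[pos[alleles == 1L]] <- alt_al[alleles == 1L]
      paste(chars, collapse = "")
    }
    expect_equal(unname(got), c(edit(hap_a), edit(hap_b)))
  }
})

test_that("indel alleles shift later edits correctly", {
  block <- structure(list(
    sample_id = "S1", platform = "ONT", phase_set = 1L,
    sites = tibble::tibble(
      contig = c("c", "c"), pos = c(2L, 5L),
      ref = c("CG", "A"), alt = c("C", "T")
    ),
    hap_a = c(1L, 1L), hap_b = c(0L, 0L)
  ), class = "phase_block")
  # ref ACGTA: deletion of G at 3 (rendered as CG>C) plus A>T at 5
  expect_equal(unname(haplotype_sequence("ACGTA", block)),
               c("ACTT", "ACGTA"))
})

test_that("haplotype and diplotype tables count as expected by hand", {
  # three samples: H1/H2, H1/H1, H1/H2 over one het site
  calls <- make_calls(
    make_call(sample_id = "A", pos = 100L, gt = "0|1", phase_set = 1L),
    make_call(sample_id = "C", pos = 100L, gt = "0|1", phase_set = 1L)
  )
  # sample B carries hom-alt: haplotypes identical
  calls <- dplyr::bind_rows(
    calls, make_call(sample_id = "B", pos = 100L, gt = "1/1")
  )
  dip <- build_diplotypes(calls)
  expect_true(all(dip$complete))
  hap <- cohort_haplotype_frequencies(dip, "haplotype")
  expect_equal(hap$count, c(4L, 2L))
  expect_equal(hap$frequency, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(hap$frequency), 1)
  dt <- cohort_haplotype_frequencies(dip, "diplotype")
  expect_equal(sum(dt$count), 3)
  expect_equal(max(dt$count), 2)

  # a single het sample yields its two haplotypes at 0.5 each
  solo <- build_diplotypes(
    make_call(sample_id = "A", pos = 100L, gt = "0|1", phase_set = 1L)
  )
  hap1 <- cohort_haplotype_frequencies(solo, "haplotype")
  expect_equal(hap1$frequency, c(0.5, 0.5))
})

test_that("split phase blocks mark diplotypes incomplete and are excluded", {
  calls <- make_calls(
    make_call(sample_id = "A", pos = 100L, gt = "0|1", phase_set = 100L),
    make_call(sample_id = "A", pos = 200L, gt = "0|1", phase_set = 200L),
    make_call(sample_id = "B", pos = 100L, gt = "0|1", phase_set = 100L)
  )
  dip <- build_diplotypes(calls)
  expect_equal(dip$complete[dip$sample_id == "A"], FALSE)
  expect_equal(dip$complete[dip$sample_id == "B"], TRUE)
  expect_message(
    tab <- cohort_haplotype_frequencies(dip, "haplotype"),
    "incomplete"
  )
  expect_equal(attr(tab, "n_excluded"), 1)
  expect_equal(sum(tab$frequency), 1)
})

test_that("random diplotype multisets are counted exactly", {
  set.seed(101)
  haps <- c("ref", "100:A>G", "100:A>G+200:C>T")
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    a <- sample(haps, n, replace = TRUE)
    b <- sample(haps, n, replace = TRUE)
    dip <- tibble::tibble(
      sample_id = sprintf("S%02d", seq_len(n)), region_id = "r",
      hap_a = a, hap_b = b, complete = TRUE, n_blocks = 1L,
      n_unphased_het = 0L
    )
    tab <- cohort_haplotype_frequencies(dip, "haplotype")
    ref_tab <- table(c(a, b))
    for (h in names(ref_tab)) {
      expect_equal(tab$count[tab$haplotype == h],
                   as.integer(ref_tab[[h]]))
    }
    expect_equal(sum(tab$frequency), 1)
    expect_false(is.unsorted(rev(tab$count)))
  }
})
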