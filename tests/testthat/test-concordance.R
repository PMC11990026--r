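test_that("pair classification follows the four-state semantics", {
  ilm <- function(gt) make_call(platform = "ILLUMINA", gt = gt)
  ont <- function(gt) make_call(platform = "ONT", gt = gt)
  expect_equal(classify_pair(ilm("0/1"), ont("0/1")), "AGREE")
  expect_equal(classify_pair(ilm("0/1"), ont("1/1")), "DISCREPANT")
  expect_equal(classify_pair(NULL, ont("0/1")), "ONT_ONLY")
  expect_equal(classify_pair(ilm("0/1"), NULL), "ILLUMINA_ONLY")
  # phase order is ignored
  expect_equal(classify_pair(ilm("0|1"), ont("1|0")), "AGREE")
  expect_error(classify_pair(NULL, NULL), "at least one")
  expect_error(
    classify_pair(ilm("0/1"), make_call(platform = "ONT", pos = 999L)),
    "same site"
  )
})

test_that("merge matches an exhaustive pairing oracle on random cohorts", {
  set.seed(55)
  gts <- c("0/1", "0|1", "1|0", "1/1")
  make_cohort <- function(platform) {
    rows <- list()
    for (s in sprintf("S%02d", 1:20)) {
      for (pos in seq(100L, by = 100L, length.out = 30L)) {
        if (runif(1) < 0.4) next  # platform did not report this site
        rows[[length(rows) + 1]] <- make_call(
          sample_id = s, platform = platform, pos = pos,
          ref = "A", alt = "G", gt = sample(gts, 1)
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  ilm <- make_cohort("ILLUMINA")
  ont <- make_cohort("ONT")
  rec <- merge_cohorts(ilm, ont)

  # oracle: loop over the (sample, site) union, classify by hand
  keys_i <- paste(ilm$sample_id, ilm$pos)
  keys_o <- paste(ont$sample_id, ont$pos)
  union_keys <- union(keys_i, keys_o)
  expected <- vapply(union_keys, function(k) {
    i <- match(k, keys_i)
    o <- match(k, keys_o)
    if (is.na(o)) return("ILLUMINA_ONLY")
    if (is.na(i)) return("ONT_ONLY")
    gi <- sort(c(ilm$a1[i], ilm$a2[i]))
    go <- sort(c(ont$a1[o], ont$a2[o]))
    if (all(gi == go)) "AGREE" else "DISCREPANT"
  }, character(1))
  expect_equal(nrow(rec), length(union_keys))  # conservation
  rec_keys <- paste(rec$sample_id, rec$pos)
  expect_setequal(rec_keys, union_keys)
  expect_equal(as.character(rec$category),
               unname(expected[rec_keys]))
  # sorted by (contig, pos, sample)
  expect_false(is.unsorted(rec$pos))
})

test_that("swapping platforms mirrors the platform-only categories", {
  cfg <- simulation_config(seed = 9, n_samples = 25)
  cohort <- simulate_cohort(cfg)
  ilm <- cohort$calls[cohort$calls$platform == "ILLUMINA", ]
  ont <- cohort$calls[cohort$calls$platform == "ONT", ]
  rec <- merge_cohorts(ilm, ont)
  ilm_as_ont <- dplyr::mutate(ilm, platform = "ONT")
  ont_as_ilm <- dplyr::mutate(ont, platform = "ILLUMINA")
  rec_swapped <- merge_cohorts(ont_as_ilm, ilm_as_ont)
  tab <- table(rec$category)
  tab_sw <- table(rec_swapped$category)
  expect_equal(tab[["AGREE"]], tab_sw[["AGREE"]])
  expect_equal(tab[["DISCREPANT"]], tab_sw[["DISCREPANT"]])
  expect_equal(tab[["ILLUMINA_ONLY"]], tab_sw[["ONT_ONLY"]])
  expect_equal(tab[["ONT_ONLY"]], tab_sw[["ILLUMINA_ONLY"]])
})

test_that("merging a cohort with itself yields pure agreement", {
  cfg <- simulation_config(seed = 11, n_samples = 30)
  truth <- simulate_truth(cfg)
  clean <- platform_params()  # zero corruption
  ont <- corrupt_for_platform(truth, clean, "ONT", seed = 12)
  ilm <- dplyr::mutate(ont, platform = "ILLUMINA")
  rec <- merge_cohorts(ilm, ont)
  expect_true(all(rec$category == "AGREE"))
})

test_that("duplicate (sample, site) rows within a platform are rejected", {
  a <- make_call(platform = "ILLUMINA")
  expect_error(merge_cohorts(dplyr::bind_rows(a, a), make_call()),
               "duplicate")
})

test_that("summaries count and normalize per scope", {
  rows <- c(rep("AGREE", 98), "DISCREPANT", "ONT_ONLY")
  rec <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
    tibble::tibble(
      sample_id = sprintf("S%03d", i), contig = "chr19",
      pos = 100L + (i %% 5L), ref = "A", alt = "G",
      category = factor(rows[i], levels = levels(factor(
        c("AGREE", "DISCREPANT", "ILLUMINA_ONLY", "ONT_ONLY")
      )))
    )
  }))
  ov <- summarize_concordance(rec, "overall")
  expect_equal(ov$frequency[ov$category == "AGREE"], 0.98)
  expect_equal(ov$frequency[ov$category == "DISCREPANT"], 0.01)
  expect_equal(ov$frequency[ov$category == "ILLUMINA_ONLY"], 0)
  expect_equal(ov$frequency[ov$category == "ONT_ONLY"], 0.01)
  expect_equal(sum(ov$frequency), 1)

  # per-position counts equal a brute-force group-by
  pp <- summarize_concordance(rec, "per_position")
  for (p in unique(rec$pos)) {
    for (cat in levels(rec$category)) {
      expect_equal(
        pp$n[pp$pos == p & pp$category == cat],
        sum(rec$pos == p & rec$category == cat)
      )
    }
  }
  per_sample <- summarize_concordance(rec, "per_sample")
  expect_true(all(abs(tapply(per_sample$frequency,
                             per_sample$sample_id, sum) - 1) < 1e-9))
})
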