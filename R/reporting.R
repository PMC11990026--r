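# Concordance reports and quality-metric summaries

#' Summarize quality metrics per platform
#'
#' Mean, sample standard deviation (n-1 denominator), Tukey boxplot
#' hinges and 1.5 x IQR whiskers for each requested numeric metric,
#' split by platform.  Values missing for a call are skipped; their
#' count is disclosed in `n_missing`.  Metrics absent from every call
#' produce a warning and no summary row.
#'
#' @param calls A call tibble.
#' @param metrics Character vector of numeric columns to summarize
#'   (e.g. `"qual"`, `"depth"`, or INFO metrics such as `"MQ"`).
#' @return A tibble with one row per (platform, metric): `n`,
#'   `n_missing`, `mean`, `sd`, `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
summarize_quality_metrics <- function(calls,
                                      metrics = c("qual", "depth")) {
  assert_calls(calls)
  rows <- list()
  for (metric in metrics) {
    if (!metric %in% names(calls) ||
        all(is.na(as.numeric(calls[[metric]])))) {
      warning(sprintf("metric '%s' is absent from all calls", metric),
              call. = FALSE)
      next
    }
    for (pf in unique(calls$platform)) {
      x <- as.numeric(calls[[metric]][calls$platform == pf])
      n_missing <- sum(is.na(x))
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      fn <- stats::fivenum(x)  # Tukey hinges
      q1 <- fn[2]; med <- fn[3]; q3 <- fn[4]
      iqr <- q3 - q1
      inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
      rows[[length(rows) + 1]] <- tibble::tibble(
        platform = pf, metric = metric,
        n = length(x), n_missing = n_missing,
        mean = mean(x), sd = stats::sd(x),
        q1 = q1, median = med, q3 = q3,
        whisker_low = min(inside), whisker_high = max(inside)
      )
    }
  }
  dplyr::bind_rows(rows)
}

# flat per-record view shared by the tsv and html renderers
report_table <- function(records, colormap) {
  tibble::tibble(
    sample = records$sample_id,
    contig = records$contig,
    pos = records$pos,
    ref = records$ref,
    alt = records$alt,
    category = as.character(records$category),
    color = unname(colormap[as.character(records$category)]),
    illumina_gt = format_gt(records$illumina_a1, records$illumina_a2,
                            records$illumina_phased %in% TRUE),
    illumina_qual = records$illumina_qual,
    illumina_dp = records$illumina_depth,
    ont_gt = format_gt(records$ont_a1, records$ont_a2,
                       records$ont_phased %in% TRUE),
    ont_qual = records$ont_qual,
    ont_dp = records$ont_depth
  )
}

#' Render a color-coded concordance report
#'
#' Writes the merged two-platform table with one row per (sample, site):
#' concordance category and color, and both platforms' genotype, QUAL
#' and DP (`.` for missing).  For `format = "tsv"` the per-position and
#' per-sample frequency summaries are written to sibling files
#' (`<path basename>_per_position.tsv`, `_per_sample.tsv`); for
#' `format = "html"` a single document carries all three tables with
#' category-colored rows.
#'
#' @param records Output of [merge_cohorts()].
#' @param path Output file path.
#' @param format `"tsv"` or `"html"`.
#' @param colormap Named category -> color vector,
#'   [default_colormap()] by default.
#' @param summaries Write/embed the per-position and per-sample
#'   frequency summaries (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
render_concordance_report <- function(records, path,
                                      format = c("tsv", "html"),
                                      colormap = default_colormap(),
                                      summaries = TRUE) {
  format <- match.arg(format)
  if (!all(CONCORDANCE_LEVELS %in% names(colormap))) {
    stop("`colormap` must name all four concordance categories",
         call. = FALSE)
  }
  tab <- report_table(records, colormap)
  per_pos <- if (summaries) summarize_concordance(records, "per_position")
  per_sample <- if (summaries) summarize_concordance(records, "per_sample")

  if (format == "tsv") {
    readr::write_tsv(tab, path, na = ".")
    written <- path
    if (summaries) {
      stem <- sub("\\.tsv$", "", path)
      pp <- paste0(stem, "_per_position.tsv")
      ps <- paste0(stem, "_per_sample.tsv")
      readr::write_tsv(per_pos, pp, na = ".")
      readr::write_tsv(per_sample, ps, na = ".")
      written <- c(written, pp, ps)
    }
    return(invisible(written))
  }

  html_table <- function(df, row_colors = NULL) {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    header <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                    collapse = ""), "</tr>")
    body <- vapply(seq_len(nrow(df)), function(i) {
      cells <- vapply(df[i, ], function(v) {
        if (is.na(v)) "." else esc(format(v, trim = TRUE))
      }, character(1))
      style <- if (!is.null(row_colors)) {
        sprintf(" style=\"background-color:%s\"", row_colors[i])
      } else ""
      paste0("<tr", style, ">",
             paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
    }, character(1))
    paste0("<table border=\"1\" cellspacing=\"0\">", header,
           paste(body, collapse = "\n"), "</table>")
  }

  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Cross-platform concordance report</title></head><body>",
    "<h1>Cross-platform concordance report</h1>",
    sprintf("<p>%d (sample, site) records.</p>", nrow(tab)),
    html_table(tab, row_colors = tab$color)
  )
  if (summaries) {
    parts <- c(
      parts,
      "<h2>Per-position category frequencies</h2>",
      html_table(as.data.frame(per_pos)),
      "<h2>Per-sample category frequencies</h2>",
      html_table(as.data.frame(per_sample))
    )
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, path)
  invisible(path)
}
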