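# Gene models and target windows (CDS / exons-plus / complete gene)

#' Read a gene model from GFF3 or BED12
#'
#' Extracts one gene's exon and CDS structure in genomic coordinates.
#' GFF3 input must contain a `gene` feature whose `ID`, `Name` or
#' `gene_id` attribute equals `gene_id`, with `exon` and (optionally)
#' `CDS` features inside its span.  BED12 input must contain a line whose
#' name column equals `gene_id`; exons come from the block structure and
#' the CDS from the thick region intersected with the blocks.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @param gene_id Identifier of the gene to extract.
#' @return A `gene_model` object: list with `gene_id`, `contig`, `strand`,
#'   `gene_span` (length-2 integer), `exons` and `cds` (two-column
#'   start/end matrices, 1-based inclusive, sorted).
#' @export
read_gene_model <- function(path, gene_id) {
  if (!file.exists(path)) {
    stop(sprintf("no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(path)
    attr_col <- function(col) {
      m <- S4Vectors::mcols(gr)
      if (col %in% names(m)) as.character(m[[col]])
      else rep(NA_character_, length(gr))
    }
    is_gene <- tolower(as.character(gr$type)) == "gene"
    match_gene <- is_gene & (
      attr_col("ID") %in% gene_id |
        attr_col("Name") %in% gene_id |
        attr_col("gene_id") %in% gene_id
    )
    match_gene[is.na(match_gene)] <- FALSE
    if (!any(match_gene, na.rm = TRUE)) {
      stop(sprintf("gene '%s' not found in '%s'", gene_id, path), call. = FALSE)
    }
    gene <- gr[which(match_gene)[1]]
    within_gene <- as.character(GenomicRanges::seqnames(gr)) ==
      as.character(GenomicRanges::seqnames(gene)) &
      GenomicRanges::start(gr) >= GenomicRanges::start(gene) &
      GenomicRanges::end(gr) <= GenomicRanges::end(gene)
    exons <- gr[tolower(as.character(gr$type)) == "exon" & within_gene]
    cds <- gr[tolower(as.character(gr$type)) == "cds" & within_gene]
    if (length(exons) == 0) {
      stop(sprintf("gene '%s' has no exon features", gene_id), call. = FALSE)
    }
    exon_mat <- ranges_to_mat(GenomicRanges::ranges(exons))
    cds_mat <- ranges_to_mat(GenomicRanges::ranges(cds))
    new_gene_model(
      gene_id = gene_id,
      contig = as.character(GenomicRanges::seqnames(gene)),
      strand = as.character(GenomicRanges::strand(gene)),
      gene_span = c(GenomicRanges::start(gene), GenomicRanges::end(gene)),
      exons = exon_mat, cds = cds_mat
    )
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    hit <- which(gr$name == gene_id)
    if (length(hit) == 0) {
      stop(sprintf("gene '%s' not found in '%s'", gene_id, path), call. = FALSE)
    }
    gene <- gr[hit[1]]
    blocks <- rtracklayer::blocks(gene)[[1]]
    exon_mat <- ranges_to_mat(GenomicRanges::ranges(blocks))
    thick <- gene$thick
    cds_ir <- IRanges::intersect(
      GenomicRanges::ranges(blocks),
      thick
    )
    new_gene_model(
      gene_id = gene_id,
      contig = as.character(GenomicRanges::seqnames(gene)),
      strand = as.character(GenomicRanges::strand(gene)),
      gene_span = c(GenomicRanges::start(gene), GenomicRanges::end(gene)),
      exons = exon_mat, cds = ranges_to_mat(cds_ir)
    )
  } else {
    stop(sprintf("unsupported gene model format '.%s'", ext), call. = FALSE)
  }
}

ranges_to_mat <- function(ir) {
  ir <- IRanges::reduce(ir)
  m <- cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  m[order(m[, "start"]), , drop = FALSE]
}

#' Construct a gene model directly
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param gene_span Length-2 integer vector, 1-based inclusive.
#' @param exons,cds Two-column start/end matrices (1-based inclusive);
#'   exons must be sorted, non-overlapping and inside `gene_span`, and
#'   every CDS interval must lie within the exon union.
#' @return A `gene_model` object.
#' @export
new_gene_model <- function(gene_id, contig, strand = "+", gene_span,
                           exons, cds = NULL) {
  exons <- as_interval_mat(exons)
  cds <- if (is.null(cds) || nrow(as_interval_mat(cds)) == 0) {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  } else {
    as_interval_mat(cds)
  }
  gene_span <- as.integer(gene_span)
  if (any(exons[, "start"] > exons[, "end"])) {
    stop("exon intervals must satisfy start <= end", call. = FALSE)
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] <= exons[-nrow(exons), "end"])) {
    stop("exons must be sorted and non-overlapping", call. = FALSE)
  }
  if (min(exons[, "start"]) < gene_span[1] ||
      max(exons[, "end"]) > gene_span[2]) {
    stop("exons must lie within the gene span", call. = FALSE)
  }
  if (nrow(cds) > 0) {
    exon_ir <- IRanges::IRanges(exons[, "start"], exons[, "end"])
    cds_ir <- IRanges::IRanges(cds[, "start"], cds[, "end"])
    uncovered <- IRanges::setdiff(cds_ir, exon_ir)
    if (length(uncovered) > 0) {
      stop("CDS intervals must be contained in the exon union", call. = FALSE)
    }
  }
  structure(
    list(
      gene_id = gene_id, contig = contig, strand = strand,
      gene_span = gene_span, exons = exons, cds = cds
    ),
    class = "gene_model"
  )
}

as_interval_mat <- function(x) {
  if (is.null(x)) return(matrix(integer(), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(x), ncol = 2)
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s  %s:%d-%d (%s)  %d exon(s), %d CDS interval(s)\n",
    x$gene_id, x$contig, x$gene_span[1], x$gene_span[2], x$strand,
    nrow(x$exons), nrow(x$cds)
  ))
  invisible(x)
}

#' Build a target window set from a gene model
#'
#' Three nested target definitions derived from one transcript model:
#' \describe{
#'   \item{`CDS`}{each CDS interval extended by `intronic_flank` on both
#'     ends, capturing splice-site variants.}
#'   \item{`EXONS_PLUS`}{each exon extended by `intronic_flank` at the
#'     intron-facing boundaries; the two gene-terminal boundaries are
#'     instead extended by `noncoding_flank` into the 5' and 3'
#'     noncoding regions.}
#'   \item{`COMPLETE_GENE`}{the full gene span extended by
#'     `noncoding_flank` on both ends.}
#' }
#' The result is merged, clipped at position 1 and returned as an
#' `interval_set`.
#'
#' @param model A [gene_model][new_gene_model].
#' @param kind One of `"CDS"`, `"EXONS_PLUS"`, `"COMPLETE_GENE"`.
#' @param intronic_flank Flank (bp) added at intron-facing boundaries;
#'   default 50.
#' @param noncoding_flank Flank (bp) added at the gene termini; default
#'   200.
#' @return An `interval_set`: list with `contig` and a merged two-column
#'   start/end matrix `intervals`.
#' @examples
#' gm <- new_gene_model("G", "chr1", "+", c(1001, 4000),
#'   exons = rbind(c(1001, 1200), c(1901, 2100), c(3801, 4000)),
#'   cds   = rbind(c(1051, 1200), c(1901, 2100), c(3801, 3950))
#' )
#' build_target_windows(gm, "CDS")
#' @export
build_target_windows <- function(model, kind = c("CDS", "EXONS_PLUS",
                                                 "COMPLETE_GENE"),
                                 intronic_flank = 50L,
                                 noncoding_flank = 200L) {
  stopifnot(inherits(model, "gene_model"))
  kind <- match.arg(kind)
  intronic_flank <- as.integer(intronic_flank)
  noncoding_flank <- as.integer(noncoding_flank)
  if (intronic_flank < 0 || noncoding_flank < 0) {
    stop("flanks must be non-negative", call. = FALSE)
  }
  if (kind == "CDS") {
    if (nrow(model$cds) == 0) {
      stop(sprintf("gene '%s' has no CDS intervals", model$gene_id),
           call. = FALSE)
    }
    iv <- cbind(
      model$cds[, "start"] - intronic_flank,
      model$cds[, "end"] + intronic_flank
    )
  } else if (kind == "EXONS_PLUS") {
    ex <- model$exons
    starts <- ex[, "start"] - intronic_flank
    ends <- ex[, "end"] + intronic_flank
    # gene-terminal boundaries get the noncoding flank instead
    terminal_start <- which.min(ex[, "start"])
    terminal_end <- which.max(ex[, "end"])
    starts[terminal_start] <- ex[terminal_start, "start"] - noncoding_flank
    ends[terminal_end] <- ex[terminal_end, "end"] + noncoding_flank
    iv <- cbind(starts, ends)
  } else {
    iv <- matrix(c(
      model$gene_span[1] - noncoding_flank,
      model$gene_span[2] + noncoding_flank
    ), ncol = 2)
  }
  new_interval_set(model$contig, iv)
}

#' Construct an interval set
#'
#' Intervals are 1-based inclusive; overlapping or adjacent intervals are
#' merged and everything is clipped at position 1.
#'
#' @param contig Contig name shared by all intervals.
#' @param intervals Two-column start/end matrix (or something coercible).
#' @return An `interval_set` object.
#' @export
new_interval_set <- function(contig, intervals) {
  m <- as_interval_mat(intervals)
  m[, "start"] <- pmax(m[, "start"], 1L)
  if (nrow(m) > 0) {
    ir <- IRanges::reduce(IRanges::IRanges(m[, "start"], m[, "end"]))
    m <- cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  }
  structure(list(contig = contig, intervals = m), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf(
    "<interval_set> %s: %d interval(s), %d bp\n",
    x$contig, nrow(x$intervals), total_length(x)
  ))
  if (nrow(x$intervals) > 0) {
    cat(paste(sprintf("  [%d, %d]", x$intervals[, "start"],
                      x$intervals[, "end"]), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Total length of an interval set in bp
#' @param x An `interval_set`.
#' @return Integer number of bases covered.
#' @export
total_length <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x$intervals) == 0) return(0L)
  sum(x$intervals[, "end"] - x$intervals[, "start"] + 1L)
}

#' Test positions for membership in an interval set
#' @param pos Integer vector of 1-based positions.
#' @param windows An `interval_set`.
#' @return Logical vector.
#' @export
in_windows <- function(pos, windows) {
  stopifnot(inherits(windows, "interval_set"))
  if (nrow(windows$intervals) == 0) return(rep(FALSE, length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(pos, pos),
    IRanges::IRanges(windows$intervals[, "start"], windows$intervals[, "end"])
  )
  seq_along(pos) %in% S4Vectors::queryHits(hits)
}

#' Restrict a call set to target windows
#'
#' Keeps calls whose position falls inside any window on the window set's
#' contig; input order is preserved.  If no call shares the window
#' contig a warning is raised and an empty call set returned.
#'
#' @param calls A call tibble.
#' @param windows An `interval_set`.
#' @return The retained calls.
#' @export
filter_by_region <- function(calls, windows) {
  assert_calls(calls)
  stopifnot(inherits(windows, "interval_set"))
  if (nrow(calls) == 0) return(calls)
  on_contig <- calls$contig == windows$contig
  if (!any(on_contig)) {
    warning(sprintf(
      "no calls on window contig '%s'; returning an empty call set",
      windows$contig
    ), call. = FALSE)
    return(calls[0, , drop = FALSE])
  }
  keep <- on_contig & in_windows(calls$pos, windows)
  calls[keep, , drop = FALSE]
}

#' Export an interval set as BED6
#'
#' Written 0-based half-open per the BED convention.
#'
#' @param windows An `interval_set`.
#' @param path Output path.
#' @param name Feature name column value.
#' @return Invisibly, `path`.
#' @export
write_windows_bed <- function(windows, path, name = "target") {
  stopifnot(inherits(windows, "interval_set"))
  df <- data.frame(
    chrom = windows$contig,
    start = windows$intervals[, "start"] - 1L,
    end = windows$intervals[, "end"],
    name = name, score = 0L, strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
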