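# internal helpers shared across modules

match_platform <- function(platform) {
  platform <- toupper(as.character(platform))
  match.arg(platform, PLATFORMS)
}

# canonical string identity of a site; equal keys merge across platforms
site_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, toupper(ref), toupper(alt), sep = ":")
}

# empty call tibble with the canonical column set
empty_calls <- function() {
  tibble::tibble(
    sample_id = character(), platform = character(),
    contig = character(), pos = integer(),
    ref = character(), alt = character(),
    a1 = integer(), a2 = integer(),
    phased = logical(), phase_set = integer(),
    qual = double(), depth = integer()
  )
}

assert_calls <- function(calls, arg = "calls") {
  need <- names(empty_calls())
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0) {
    stop(sprintf(
      "`%s` is not a call table: missing column(s) %s",
      arg, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(calls)
}

is_het <- function(a1, a2) !is.na(a1) & !is.na(a2) & a1 != a2
is_hom_alt <- function(a1, a2) !is.na(a1) & !is.na(a2) & a1 == 1L & a2 == 1L
is_hom_ref <- function(a1, a2) !is.na(a1) & !is.na(a2) & a1 == 0L & a2 == 0L

# "0|1" / "0/1" / "." rendering of a genotype pair
format_gt <- function(a1, a2, phased) {
  out <- ifelse(
    is.na(a1) | is.na(a2), ".",
    paste0(a1, ifelse(phased, "|", "/"), a2)
  )
  out
}
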