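# Step 1: quality / length / abundance filtering of adapter-trimmed reads and
# collapsing to unique sequences.

#' Read adapter-trimmed small RNA-seq reads from FASTQ
#'
#' Expects Phred+33 qualities; gzip-compressed files are handled
#' transparently. An empty file yields an empty tibble with a warning.
#'
#' @param path Path to a FASTQ (or FASTQ.gz) file.
#' @return A tibble with character columns `sequence` and `quality`.
#' @export
read_small_rna_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  if (length(x) == 0L) {
    warn(sprintf("no reads in FASTQ file '%s'", path))
    return(tibble::tibble(sequence = character(0), quality = character(0)))
  }
  tibble::tibble(
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}

#' Per-read quality gate
#'
#' A read passes only if its Phred+33 score is at or above `min_q` at every
#' position ("drops below" fails, so a position exactly at the threshold
#' passes). Quality characters below `'!'` raise a malformed-FASTQ error.
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @param min_q Minimum per-position Phred score (default 28, conservative so
#'   downstream mismatch/deletion calls reflect biology, not sequencer error).
#' @return Logical vector, one element per read.
#' @export
#' @examples
#' passes_quality(c("JJJJJ", "JJ&JJ", "====="))
passes_quality <- function(quality, min_q = 28L) {
  vapply(quality, function(q) all(phred33_scores(q) >= min_q), logical(1),
         USE.NAMES = FALSE)
}

#' Filter raw reads and collapse to unique sequences
#'
#' Raw reads are discarded if any position falls below the quality threshold,
#' if their length lies outside `[min_len, max_len]`, or if they contain `N`
#' (ambiguous bases cannot participate in exact matching). Survivors are
#' collapsed by exact sequence, and unique sequences seen fewer than
#' `min_count` times are dropped — low-count sequences are dominated by
#' degradation noise rather than true tDR signal. Filtering order: quality,
#' then length, then N, then the abundance threshold, so a unique sequence's
#' count reflects only trustworthy copies.
#'
#' @param reads Tibble with columns `sequence` and `quality` (quality may be
#'   omitted, in which case the quality gate is skipped).
#' @param min_q Minimum per-position Phred score (default 28).
#' @param min_len,max_len Inclusive read-length window (defaults 14 and 40).
#' @param min_count Minimum copies a unique sequence must reach (default 100,
#'   inclusive).
#' @param min_count_frac Optional fraction of total input reads to use as the
#'   abundance threshold instead of `min_count` (useful when libraries differ
#'   greatly in depth).
#' @return A tibble of unique reads (`sequence`, `count`) sorted by
#'   descending count (ties broken by sequence), with a `filter_summary`
#'   attribute; see [filter_summary()].
#' @export
collapse_and_filter <- function(reads, min_q = 28L, min_len = 14L,
                                max_len = 40L, min_count = 100L,
                                min_count_frac = NULL) {
  n_input <- nrow(reads)
  if (n_input == 0L) {
    warn("collapse_and_filter: empty input")
  }
  if (!is.null(min_count_frac)) {
    min_count <- max(1L, as.integer(ceiling(min_count_frac * n_input)))
  }
  seqs <- reads$sequence
  ok_q <- if ("quality" %in% names(reads) && n_input > 0L) {
    passes_quality(reads$quality, min_q)
  } else {
    rep(TRUE, n_input)
  }
  len <- nchar(seqs)
  ok_len <- len >= min_len & len <= max_len
  has_n <- grepl("N", seqs, fixed = TRUE)

  fail_quality <- sum(!ok_q)
  fail_length <- sum(ok_q & !ok_len)
  fail_n <- sum(ok_q & ok_len & has_n)
  if (fail_n > 0L) {
    inform(sprintf("discarded %d read(s) containing N", fail_n))
  }
  keep <- ok_q & ok_len & !has_n

  collapsed <- tibble::tibble(sequence = seqs[keep]) |>
    dplyr::count(.data$sequence, name = "count")
  fail_count <- sum(collapsed$count[collapsed$count < min_count])
  out <- collapsed |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)

  attr(out, "filter_summary") <- tibble::tibble(
    n_input = n_input,
    fail_quality = fail_quality,
    fail_length = fail_length,
    fail_n = fail_n,
    fail_count = fail_count,
    n_kept = sum(out$count),
    n_unique = nrow(out),
    min_count_used = as.integer(min_count)
  )
  out
}

#' Retrieve the read-filtering ledger
#'
#' @param unique_reads The result of [collapse_and_filter()].
#' @return A one-row tibble whose discard columns plus `n_kept` sum to
#'   `n_input`.
#' @export
filter_summary <- function(unique_reads) {
  s <- attr(unique_reads, "filter_summary")
  if (is.null(s)) abort("no filter summary attached; was this produced by collapse_and_filter()?")
  s
}
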