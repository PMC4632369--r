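# Step 2: hierarchical error-tolerant alignment of unique reads to the
# mature and pre-tRNA family libraries.
#
# The "error types" (mismatches, single-base deletions, a contiguous 3-base
# deletion) proxy reverse-transcriptase misincorporation and pausing over
# chemically modified tRNA positions; a deletion is a reference base absent
# from the read. Insertions are not modeled. Alignment is end-to-end (no
# clipping) and sense-strand only.

#' The error-type stage hierarchy
#'
#' Reads are tried against stages in this order and assigned to the first
#' stage at which they align to at least one family: exact match to mature
#' tRNAs, exact match to pre-tRNAs, then one mismatch, one deletion, two
#' mismatches, two deletions, and a contiguous three-base deletion, all
#' against mature tRNAs only (pre-tRNAs are assumed not to carry extensive
#' modifications).
#'
#' @return A tibble with columns `stage`, `kind` (reference library
#'   searched), `n_mm`, `n_del` and `contiguous`.
#' @export
tdr_stages <- function() {
  tibble::tibble(
    stage = c("EXACT_MATURE", "EXACT_PRE", "MM1", "DEL1", "MM2", "DEL2", "DEL3"),
    kind = c("mature", "pre", "mature", "mature", "mature", "mature", "mature"),
    n_mm = c(0L, 0L, 1L, 0L, 2L, 0L, 0L),
    n_del = c(0L, 0L, 0L, 1L, 0L, 2L, 3L),
    contiguous = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' @rdname tdr_stages
#' @export
tdr_stage_order <- function() tdr_stages()$stage

# --- window scanners (read and reference as character vectors) -------------

# Best window allowing <= max_mm substitutions: fewest mismatches, then
# leftmost start. Returns list(start, mm_pos (window-local)) or NULL.
scan_mismatch <- function(rch, refch, max_mm) {
  L <- length(rch)
  nwin <- length(refch) - L + 1L
  if (nwin < 1L) return(NULL)
  idx <- outer(seq_len(nwin) - 1L, seq_len(L), "+")
  neq <- matrix(refch[idx], nrow = nwin) != matrix(rch, nrow = nwin, ncol = L, byrow = TRUE)
  counts <- rowSums(neq)
  ok <- counts <= max_mm
  if (!any(ok)) return(NULL)
  best <- which(ok & counts == min(counts[ok]))[1]
  list(start = best, mm_pos = which(neq[best, ]))
}

# Leftmost deletion combination (window-local positions) turning window wch
# into read rch by deleting exactly e reference bases; NULL if impossible.
del_positions <- function(rch, wch, e) {
  if (e == 0L) {
    if (length(rch) == length(wch) && all(rch == wch)) return(integer(0))
    return(NULL)
  }
  L <- length(rch); W <- length(wch)
  cmp <- if (L > 0L) rch != wch[seq_len(L)] else logical(0)
  p <- if (any(cmp)) which.max(cmp) else L + 1L
  for (j in seq_len(min(p, W))) {
    r2 <- if (j <= L) rch[j:L] else character(0)
    w2 <- if (j < W) wch[(j + 1L):W] else character(0)
    rest <- del_positions(r2, w2, e - 1L)
    if (!is.null(rest)) return(c(j, rest + j))
  }
  NULL
}

# Window with a contiguous 3-base deletion at local positions j..j+2.
del3_positions <- function(rch, wch) {
  L <- length(rch); W <- length(wch)  # W = L + 3
  for (j in seq_len(W - 2L)) {
    pre_ok <- j == 1L || all(rch[seq_len(j - 1L)] == wch[seq_len(j - 1L)])
    suf_ok <- j > L || all(rch[j:L] == wch[(j + 3L):W])
    if (pre_ok && suf_ok) return(j:(j + 2L))
  }
  NULL
}

# Best window for a deletion stage: fewest deletions first (0..n_del), then
# leftmost start. Contiguity is enforced only for the 3-deletion pattern.
scan_deletion <- function(rch, refch, n_del, contiguous) {
  L <- length(rch)
  for (e in 0:n_del) {
    span <- L + e
    nwin <- length(refch) - span + 1L
    if (nwin < 1L) next
    for (s in seq_len(nwin)) {
      wch <- refch[s:(s + span - 1L)]
      pos <- if (contiguous && e == 3L) {
        del3_positions(rch, wch)
      } else {
        del_positions(rch, wch, e)
      }
      if (!is.null(pos)) return(list(start = s, del_pos = pos))
    }
  }
  NULL
}

#' Find the best placement of a read on one family at a given stage
#'
#' Scans every end-to-end window of the family sequence under the stage's
#' error budget (at most `n_mm` substitutions or `n_del` deleted reference
#' bases; the three-deletion stage requires the deleted bases to be
#' contiguous). Within a family only the best window is kept: fewest total
#' errors, then leftmost start. Error positions are reported in reference
#' coordinates.
#'
#' @param read_seq A single read sequence (14-40 nt).
#' @param family One row of a family tibble (the reference kind must match
#'   the stage: the exact-pre stage targets pre families, all others mature).
#' @param stage One of [tdr_stage_order()].
#' @return A tibble with zero or one row: `family`, `ref_start`, `ref_span`,
#'   `n_mm`, `n_del`, `mismatch_positions` and `deletion_positions` (list
#'   columns of 1-based reference positions).
#' @export
#' @examples
#' fam <- tibble::tibble(name = "toy", kind = "mature",
#'                       sequence = "ACGTACGTACGT", body_start = 1, body_end = 12)
#' find_placements("GTACG", fam, "EXACT_MATURE")
find_placements <- function(read_seq, family, stage) {
  stages <- tdr_stages()
  st <- stages[stages$stage == stage, ]
  if (nrow(st) != 1L) abort(sprintf("unknown stage '%s'", stage))
  if (family$kind[1] != st$kind) {
    abort(sprintf("stage %s targets %s families, got kind '%s'",
                  stage, st$kind, family$kind[1]))
  }
  rch <- seq_chars(read_seq)
  refch <- seq_chars(family$sequence[1])
  empty <- tibble::tibble(
    family = character(0), ref_start = integer(0), ref_span = integer(0),
    n_mm = integer(0), n_del = integer(0),
    mismatch_positions = list(), deletion_positions = list()
  )
  if (st$n_del > 0L) {
    hit <- scan_deletion(rch, refch, st$n_del, st$contiguous)
    if (is.null(hit)) return(empty)
    tibble::tibble(
      family = family$name[1],
      ref_start = hit$start,
      ref_span = length(rch) + length(hit$del_pos),
      n_mm = 0L, n_del = length(hit$del_pos),
      mismatch_positions = list(integer(0)),
      deletion_positions = list(hit$del_pos + hit$start - 1L)
    )
  } else {
    hit <- scan_mismatch(rch, refch, st$n_mm)
    if (is.null(hit)) return(empty)
    tibble::tibble(
      family = family$name[1],
      ref_start = hit$start,
      ref_span = length(rch),
      n_mm = length(hit$mm_pos), n_del = 0L,
      mismatch_positions = list(hit$mm_pos + hit$start - 1L),
      deletion_positions = list(integer(0))
    )
  }
}

# All placements of one read at one stage across a library (0+ rows).
scan_library <- function(read_seq, library, stage) {
  hits <- lapply(seq_len(nrow(library)), function(i) {
    find_placements(read_seq, library[i, ], stage)
  })
  dplyr::bind_rows(hits)
}

#' Run the error-type hierarchy over a set of unique reads
#'
#' Each read is tested against the stages in order and assigned to the first
#' stage at which it places in at least one family; a read placing in
#' several families at that stage receives one placement per family (each
#' later counted with the read's full count — no fractional splitting).
#' Reads exhausting every stage are recorded with stage `"UNMAPPED"`.
#'
#' @param unique_reads Tibble with columns `sequence` and `count`, e.g. from
#'   [collapse_and_filter()].
#' @param mature_lib,pre_lib Family tibbles from [build_mature_library()]
#'   and [build_pre_library()] (either may be empty).
#' @param stages Stage order; reorderable, e.g. to prioritise one deletion
#'   over one mismatch (default [tdr_stage_order()]).
#' @return An assignment tibble: `sequence`, `count`, `stage`, `family`,
#'   `ref_start`, `ref_span`, `n_mm`, `n_del`, `mismatch_positions`,
#'   `deletion_positions`. Unmapped reads carry `NA` placement fields.
#' @export
run_hierarchy <- function(unique_reads, mature_lib, pre_lib = NULL,
                          stages = tdr_stage_order()) {
  stage_tab <- tdr_stages()
  bad <- setdiff(stages, stage_tab$stage)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  libs <- list(
    mature = mature_lib %||% tibble::tibble(),
    pre = pre_lib %||% tibble::tibble()
  )
  out <- lapply(seq_len(nrow(unique_reads)), function(i) {
    seqv <- unique_reads$sequence[i]
    cnt <- unique_reads$count[i]
    for (stg in stages) {
      kind <- stage_tab$kind[stage_tab$stage == stg]
      lib <- libs[[kind]]
      if (is.null(lib) || nrow(lib) == 0L) next
      hits <- scan_library(seqv, lib, stg)
      if (nrow(hits) > 0L) {
        return(dplyr::mutate(hits, sequence = seqv, count = cnt, stage = stg,
                             .before = 1))
      }
    }
    tibble::tibble(
      sequence = seqv, count = cnt, stage = "UNMAPPED",
      family = NA_character_, ref_start = NA_integer_, ref_span = NA_integer_,
      n_mm = NA_integer_, n_del = NA_integer_,
      mismatch_positions = list(integer(0)), deletion_positions = list(integer(0))
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(
      sequence = character(0), count = integer(0), stage = character(0),
      family = character(0), ref_start = integer(0), ref_span = integer(0),
      n_mm = integer(0), n_del = integer(0),
      mismatch_positions = list(), deletion_positions = list()
    )
  }
  res
}

#' Keep only mapped assignment rows
#'
#' @param assignments Result of [run_hierarchy()].
#' @return The assignment tibble without `"UNMAPPED"` rows.
#' @export
mapped_assignments <- function(assignments) {
  dplyr::filter(assignments, .data$stage != "UNMAPPED")
}
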