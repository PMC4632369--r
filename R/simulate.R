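# Synthetic reference and read generation with truth tables. The simulator
# emulates the study conditions the pipeline is built for: short (14-40 nt)
# sense-strand reads drawn from declared spans of mature or pre-tRNA family
# sequences, optionally carrying one declared error pattern (substitutions
# or skipped reference bases) that mimics reverse-transcriptase errors over
# modified positions.

SIM_AMINO_ACIDS <- c("Ala", "Gly", "Glu", "Val", "Asp", "Lys", "His", "Arg",
                     "Pro", "Ser", "Leu", "Thr", "Cys", "Met", "Phe", "Trp",
                     "Tyr", "Gln", "Asn", "Ile")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Declare a synthetic sample
#'
#' A `sim_spec` fixes everything about a synthetic reference and read set:
#' the number of tRNA families, their body lengths, gene multiplicities
#' (identical copies, to exercise family aggregation), optional intron
#' lengths, the declared tDRs (span, copy count, error pattern) and the
#' background noise. The seed fully determines the output.
#'
#' @param n_families Number of distinct tRNA families.
#' @param body_len Length range (inclusive) for gene bodies, sampled
#'   uniformly; the default 70-76 nt matches typical human tRNA genes.
#' @param multiplicity Genes per family with identical sequence (recycled).
#' @param intron_len Intron length per family, 0 for none (recycled).
#' @param tdrs Declared tDRs: a tibble with columns `family` (family index),
#'   `kind` (`"mature"`/`"pre"`), `start`, `end` (1-based span on that
#'   family's sequence), `count`, `error` (one of `none`, `mm1`, `del1`,
#'   `mm2`, `del2`, `del3`) and `error_pos` (reference position of the first
#'   error; `NA` for `none`). Two-position patterns use `error_pos` and
#'   `error_pos + 2`; `del3` deletes `error_pos..error_pos+2`.
#' @param noise_reads Number of background singleton reads (random
#'   sequences, count 1 each).
#' @param seed Integer seed.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(n_families = 3, body_len = c(70, 76), multiplicity = 1,
                     intron_len = 0, tdrs = NULL, noise_reads = 0, seed = 1) {
  if (is.null(tdrs)) {
    tdrs <- tibble::tibble(
      family = integer(0), kind = character(0), start = integer(0),
      end = integer(0), count = integer(0), error = character(0),
      error_pos = integer(0)
    )
  }
  spec <- list(
    n_families = as.integer(n_families),
    body_len = as.integer(body_len),
    multiplicity = rep_len(as.integer(multiplicity), n_families),
    intron_len = rep_len(as.integer(intron_len), n_families),
    tdrs = tdrs,
    noise_reads = as.integer(noise_reads),
    seed = as.integer(seed)
  )
  if (spec$n_families < 1L) abort("n_families must be >= 1")
  if (nrow(tdrs) > 0L) {
    if (any(!tdrs$family %in% seq_len(spec$n_families))) abort("tdr declaration references an unknown family index")
    if (any(!tdrs$kind %in% c("mature", "pre"))) abort("tdr kind must be 'mature' or 'pre'")
    if (any(!tdrs$error %in% c("none", "mm1", "del1", "mm2", "del2", "del3"))) {
      abort("unknown error pattern in tdr declarations")
    }
    if (any(tdrs$error != "none" & tdrs$kind == "pre")) {
      abort("error patterns are only modeled on mature tRNAs (pre alignment is exact-only)")
    }
    if (any(tdrs$start < 1L | tdrs$start > tdrs$end)) abort("invalid tdr span")
  }
  structure(spec, class = "sim_spec")
}

#' Generate a synthetic tRNA gene table
#'
#' Random gene bodies with 40-nt flanks and optional introns, guaranteed
#' pairwise-distinct mature sequences across families; a family with
#' multiplicity m yields m genes with identical sequence (copy indices
#' 1..m), so the mature family aggregates to `Z = m`.
#'
#' @param spec A [sim_spec()].
#' @param fasta,meta_tsv Optional output paths; when given, the gene table
#'   is also written in the [read_trna_genes()] input format.
#' @return A validated gene tibble.
#' @export
sim_reference <- function(spec, fasta = NULL, meta_tsv = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  seen_mature <- character(0)
  fams <- lapply(seq_len(spec$n_families), function(i) {
    repeat {
      blen <- spec$body_len[1] + sample.int(spec$body_len[2] - spec$body_len[1] + 1L, 1) - 1L
      body <- random_dna(blen)
      introns <- NA_character_
      if (spec$intron_len[i] > 0L) {
        # canonical tRNA introns sit just 3' of the anticodon; fix the start
        ist <- min(38L, blen - spec$intron_len[i])
        body <- paste0(substr(body, 1, ist - 1), random_dna(spec$intron_len[i]),
                       substr(body, ist, blen))
        introns <- sprintf("%d-%d", ist, ist + spec$intron_len[i] - 1L)
      }
      mat <- paste0(excise_introns(body, introns), "CCA")
      if (!mat %in% seen_mature) {
        seen_mature <<- c(seen_mature, mat)
        break
      }
    }
    aa <- SIM_AMINO_ACIDS[(i - 1L) %% length(SIM_AMINO_ACIDS) + 1L]
    ac <- random_dna(3)
    m <- spec$multiplicity[i]
    tibble::tibble(
      gene_id = sprintf("sim%02d_copy%d", i, seq_len(m)),
      amino_acid = aa, anticodon = ac,
      family_index = i, copy_index = seq_len(m),
      body_sequence = body, introns = introns,
      flank5 = random_dna(FLANK_LEN), flank3 = random_dna(FLANK_LEN)
    )
  })
  genes <- validate_trna_genes(dplyr::bind_rows(fams))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(genes$body_sequence, genes$gene_id)),
      fasta
    )
  }
  if (!is.null(meta_tsv)) {
    readr::write_tsv(dplyr::select(genes, -"body_sequence"), meta_tsv)
  }
  genes
}

rotate_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]

# Apply one declared error pattern to a span sequence extracted from
# positions start..end of the reference. Positions are reference coords.
apply_error_pattern <- function(span_seq, start, end, error, error_pos) {
  loc <- function(p) p - start + 1L
  n <- nchar(span_seq)
  ch <- seq_chars(span_seq)
  pos <- switch(error,
    none = integer(0),
    mm1 = error_pos,
    del1 = error_pos,
    mm2 = c(error_pos, error_pos + 2L),
    del2 = c(error_pos, error_pos + 2L),
    del3 = error_pos:(error_pos + 2L)
  )
  if (error == "none") return(span_seq)
  if (anyNA(pos)) abort("error_pos is required for error patterns")
  if (startsWith(error, "del")) {
    # an end-of-span deletion is indistinguishable from a shorter exact read
    if (min(pos) <= start || max(pos) >= end) {
      abort(sprintf("deletion positions %s must lie strictly inside the span %d-%d",
                    paste(pos, collapse = ","), start, end))
    }
    return(paste(ch[-loc(pos)], collapse = ""))
  }
  if (min(pos) < start || max(pos) > end) {
    abort(sprintf("mismatch positions %s outside the span %d-%d",
                  paste(pos, collapse = ","), start, end))
  }
  for (p in pos) ch[loc(p)] <- rotate_base(ch[loc(p)])
  paste(ch, collapse = "")
}

error_to_stage <- function(error, kind) {
  dplyr::case_when(
    error == "none" & kind == "mature" ~ "EXACT_MATURE",
    error == "none" & kind == "pre" ~ "EXACT_PRE",
    error == "mm1" ~ "MM1",
    error == "del1" ~ "DEL1",
    error == "mm2" ~ "MM2",
    error == "del2" ~ "DEL2",
    error == "del3" ~ "DEL3"
  )
}

#' Simulate reads from a synthetic reference
#'
#' Emits the declared reads (uniform quality Q40) plus background noise
#' singletons, together with a truth table giving, per declaration, the
#' emitted sequence, the expected assignment stage and family, and — per
#' family — the expected read count, maximum coverage and relative
#' abundance derived from the declared spans and counts alone.
#'
#' Declarations that cannot realise their stage are rejected: deletions at
#' span edges (indistinguishable from shorter exact reads), spans outside
#' the reference, and error reads that still match some family exactly.
#'
#' @param genes A gene tibble from [sim_reference()] (same spec).
#' @param spec The same [sim_spec()].
#' @param fastq Optional path; when given the reads are written as FASTQ
#'   (gzip if the path ends in `.gz`).
#' @return A list with `reads` (sequence, quality, count), `truth`
#'   (per-declaration) and `truth_families` (per-family expectations).
#' @export
sim_reads <- function(genes, spec, fastq = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  mature <- build_mature_library(genes)
  pre <- build_pre_library(genes)
  lib <- dplyr::bind_rows(mature, pre)
  fam_name <- function(idx, kind) {
    parsed <- parse_family_name(lib$name)
    hit <- lib$name[parsed$family_index == idx & lib$kind == kind]
    if (length(hit) != 1L) abort(sprintf("family index %d (%s) not found uniquely", idx, kind))
    hit
  }
  decl <- spec$tdrs
  truth <- NULL
  if (nrow(decl) > 0L) {
    rows <- lapply(seq_len(nrow(decl)), function(k) {
      d <- decl[k, ]
      fname <- fam_name(d$family, d$kind)
      fseq <- lib$sequence[lib$name == fname]
      if (d$end > nchar(fseq)) {
        abort(sprintf("declared span %d-%d exceeds %s (length %d)",
                      d$start, d$end, fname, nchar(fseq)))
      }
      span_seq <- substr(fseq, d$start, d$end)
      read_seq <- apply_error_pattern(span_seq, d$start, d$end, d$error, d$error_pos)
      if (d$error != "none" &&
          any(vapply(lib$sequence, function(s) grepl(read_seq, s, fixed = TRUE),
                     logical(1)))) {
        abort(sprintf(
          "infeasible declaration %d: the %s read still matches a reference exactly",
          k, d$error))
      }
      dplyr::mutate(d, family_name = fname, sequence = read_seq,
                    expected_stage = error_to_stage(d$error, d$kind))
    })
    truth <- dplyr::bind_rows(rows)
  }
  set.seed(spec$seed + 1L)
  noise <- if (spec$noise_reads > 0L) {
    noise_seq <- vapply(seq_len(spec$noise_reads),
                        function(i) random_dna(sample(14:40, 1)), character(1))
    tibble::tibble(
      sequence = noise_seq,
      quality = strrep("I", nchar(noise_seq)),
      count = 1L
    )
  } else {
    tibble::tibble(sequence = character(0), quality = character(0), count = integer(0))
  }
  reads <- dplyr::bind_rows(
    if (!is.null(truth)) {
      tibble::tibble(sequence = truth$sequence,
                     quality = strrep("I", nchar(truth$sequence)),
                     count = as.integer(truth$count))
    },
    noise
  )
  truth_families <- if (!is.null(truth)) sim_truth_families(truth, lib) else NULL
  if (!is.null(fastq)) write_fastq(reads, fastq)
  list(reads = reads, truth = truth, truth_families = truth_families)
}

# Closed-form per-family expectations from the declarations alone: coverage
# at p is the declared-count-weighted fraction of spans containing p.
sim_truth_families <- function(truth, lib) {
  total_mapped <- sum(truth$count)
  truth |>
    dplyr::group_split(.data$family_name) |>
    lapply(function(rows) {
      len <- nchar(lib$sequence[lib$name == rows$family_name[1]])
      cov <- numeric(len)
      for (k in seq_len(nrow(rows))) {
        cov[rows$start[k]:rows$end[k]] <- cov[rows$start[k]:rows$end[k]] + rows$count[k]
      }
      fam_total <- sum(rows$count)
      tibble::tibble(
        family = rows$family_name[1],
        expected_count = fam_total,
        expected_max_coverage = max(cov) / fam_total,
        expected_relative_abundance =
          fam_total / total_mapped * max(cov) / fam_total * 100
      )
    }) |>
    dplyr::bind_rows()
}

#' Write reads to FASTQ
#'
#' Each unique read row is emitted `count` times; a `.gz` suffix triggers
#' gzip compression.
#'
#' @param reads Tibble with `sequence`, `quality` and optionally `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads)
  counts <- if ("count" %in% names(reads)) reads$count else rep(1L, n)
  idx <- rep(seq_len(n), counts)
  seqs <- reads$sequence[idx]
  quals <- reads$quality[idx]
  lines <- as.vector(rbind(
    sprintf("@read_%d", seq_along(idx)), seqs, rep("+", length(idx)), quals
  ))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
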