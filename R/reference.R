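# Reference construction: mature and pre-tRNA family libraries from annotated
# tRNA genes. All coordinates are 1-based closed intervals.

FLANK_LEN <- 40L

#' Read a tRNA gene table (FASTA body sequences + metadata sidecar)
#'
#' The reference input mirrors a gtRNAdb-style export: a multi-FASTA of
#' full-length tRNA gene body sequences (headers = gene_id, introns still
#' present) plus a tab-separated sidecar with per-gene metadata:
#' `gene_id`, `amino_acid`, `anticodon`, `family_index`, `copy_index`,
#' `introns` (1-based closed intervals as `"start-end;start-end"`, empty for
#' none) and 40-nt genomic flanks `flank5` / `flank3`.
#'
#' @param fasta Path to the multi-FASTA of gene body sequences.
#' @param meta_tsv Path to the metadata TSV described above.
#' @return A validated gene tibble (one row per tRNA gene).
#' @seealso [build_mature_library()], [build_pre_library()]
#' @export
read_trna_genes <- function(fasta, meta_tsv) {
  bodies <- Biostrings::readDNAStringSet(fasta)
  meta <- readr::read_tsv(meta_tsv, show_col_types = FALSE,
                          col_types = readr::cols(
                            gene_id = "c", amino_acid = "c", anticodon = "c",
                            family_index = "i", copy_index = "i",
                            introns = "c", flank5 = "c", flank3 = "c"
                          ))
  ids <- sub("\\s.*$", "", names(bodies))
  missing <- setdiff(meta$gene_id, ids)
  if (length(missing)) {
    abort(paste0("genes in metadata but not in FASTA: ",
                 paste(missing, collapse = ", ")))
  }
  genes <- meta |>
    dplyr::mutate(body_sequence = unname(as.character(bodies))[match(.data$gene_id, ids)])
  validate_trna_genes(genes)
}

#' Validate a tRNA gene tibble
#'
#' Checks the gene-table invariants: DNA alphabet (A/C/G/T/N), 40-nt flanks,
#' intron intervals non-overlapping and inside the gene body, unique gene ids.
#'
#' @param genes A gene tibble as returned by [read_trna_genes()] or
#'   [sim_reference()].
#' @return The input, invisibly usable, with introns normalised to character.
#' @export
validate_trna_genes <- function(genes) {
  required <- c("gene_id", "amino_acid", "anticodon", "family_index",
                "copy_index", "body_sequence", "flank5", "flank3")
  miss <- setdiff(required, names(genes))
  if (length(miss)) abort(paste0("gene table missing columns: ", paste(miss, collapse = ", ")))
  if (!"introns" %in% names(genes)) genes$introns <- NA_character_
  if (anyDuplicated(genes$gene_id)) abort("duplicate gene_id in gene table")
  bad <- !is_dna(genes$body_sequence) | !is_dna(genes$flank5) | !is_dna(genes$flank3)
  if (any(bad)) {
    abort(paste0("non-ACGTN sequence for gene(s): ",
                 paste(genes$gene_id[bad], collapse = ", ")))
  }
  flank_bad <- nchar(genes$flank5) != FLANK_LEN | nchar(genes$flank3) != FLANK_LEN
  if (any(flank_bad)) {
    abort(paste0("flanks must be exactly ", FLANK_LEN, " nt; offending gene(s): ",
                 paste(genes$gene_id[flank_bad], collapse = ", ")))
  }
  for (i in seq_len(nrow(genes))) {
    iv <- parse_intervals(genes$introns[i])
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[, 1] > iv[, 2]) || iv[1, 1] < 1L ||
        max(iv[, 2]) > nchar(genes$body_sequence[i]) ||
        (nrow(iv) > 1L && any(iv[-1, 1] <= iv[-nrow(iv), 2]))) {
      abort(sprintf("invalid intron intervals for gene %s", genes$gene_id[i]))
    }
  }
  if (anyDuplicated(genes[, c("amino_acid", "anticodon", "family_index", "copy_index")])) {
    abort("duplicate (amino_acid, anticodon, family_index, copy_index) among genes")
  }
  genes
}

# Excise 1-based closed intron intervals from a body sequence.
excise_introns <- function(body, introns) {
  iv <- parse_intervals(introns)
  if (nrow(iv) == 0L) return(body)
  keep <- rep(TRUE, nchar(body))
  for (i in seq_len(nrow(iv))) keep[iv[i, 1]:iv[i, 2]] <- FALSE
  paste(seq_chars(body)[keep], collapse = "")
}

wxy_key <- function(genes) {
  paste(genes$amino_acid, genes$anticodon, genes$family_index, sep = "-")
}

#' Build the mature tRNA family library
#'
#' The mature sequence of each gene is its body with predicted introns
#' excised and a non-templated 3' terminal `CCA` appended. Genes with an
#' identical mature sequence and identical amino acid / anticodon / family
#' identifier are aggregated into one family named `W-X-Y-Z`, where `Z` is
#' the number of member genes. Identical sequences arising under *different*
#' `W-X-Y` metadata are kept as distinct families (with a warning), so the
#' printed naming scheme is preserved.
#'
#' @param genes A validated gene tibble.
#' @return A family tibble (kind `"mature"`) with columns `name`, `kind`,
#'   `sequence`, `body_start`, `body_end`, `n_members`, `member_gene_ids`
#'   (list column).
#' @export
#' @examples
#' g <- sim_reference(sim_spec(n_families = 2, seed = 7))
#' build_mature_library(g)
build_mature_library <- function(genes) {
  genes <- validate_trna_genes(genes)
  mature <- vapply(seq_len(nrow(genes)), function(i) {
    paste0(excise_introns(genes$body_sequence[i], genes$introns[i]), "CCA")
  }, character(1))
  g <- genes |>
    dplyr::mutate(mature_seq = mature, wxy = wxy_key(genes))
  # a W-X-Y group whose members disagree on the mature sequence would mint
  # clashing W-X-Y-Z names whenever two of its sequence groups have equal size
  fam <- g |>
    dplyr::group_by(.data$wxy, .data$mature_seq) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      member_gene_ids = list(sort(.data$gene_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(name = paste0(.data$wxy, "-", .data$n_members))
  if (anyDuplicated(fam$name)) {
    dup <- fam$name[duplicated(fam$name)]
    offenders <- unlist(fam$member_gene_ids[fam$name %in% dup])
    abort(paste0(
      "conflicting metadata: genes ", paste(offenders, collapse = ", "),
      " would produce duplicate family name(s) ", paste(unique(dup), collapse = ", ")
    ))
  }
  shared <- fam |>
    dplyr::group_by(.data$mature_seq) |>
    dplyr::filter(dplyr::n() > 1L)
  if (nrow(shared) > 0L) {
    warn(paste0(
      "identical mature sequence under different W-X-Y metadata kept as ",
      "distinct families: ", paste(unique(shared$name), collapse = ", ")
    ))
  }
  fam |>
    dplyr::transmute(
      name = .data$name, kind = "mature", sequence = .data$mature_seq,
      body_start = 1L, body_end = nchar(.data$mature_seq),
      n_members = .data$n_members, member_gene_ids = .data$member_gene_ids
    ) |>
    dplyr::arrange(.data$name)
}

#' Build the pre-tRNA family library
#'
#' The pre-tRNA sequence of a gene is the unspliced genomic transcript:
#' 40 nt of 5' flank, the full gene body (introns retained), and 40 nt of
#' 3' flank. Genes from the same `W-X-Y` mature family with an identical
#' pre-tRNA sequence are grouped into a family named `pre-W-X-Y-Z.n`, where
#' `n` is the group size and `Z` the largest copy index among members.
#'
#' @inheritParams build_mature_library
#' @return A family tibble (kind `"pre"`); `body_start` is always 41 and
#'   `body_end` is `nchar(sequence) - 40`.
#' @export
build_pre_library <- function(genes) {
  genes <- validate_trna_genes(genes)
  g <- genes |>
    dplyr::mutate(
      pre_seq = paste0(.data$flank5, .data$body_sequence, .data$flank3),
      wxy = wxy_key(genes)
    )
  g |>
    dplyr::group_by(.data$wxy, .data$pre_seq) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      max_z = max(.data$copy_index),
      member_gene_ids = list(sort(.data$gene_id)),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      name = paste0("pre-", .data$wxy, "-", .data$max_z, ".", .data$n_members),
      kind = "pre", sequence = .data$pre_seq,
      body_start = FLANK_LEN + 1L,
      body_end = nchar(.data$pre_seq) - FLANK_LEN,
      n_members = .data$n_members, member_gene_ids = .data$member_gene_ids
    ) |>
    dplyr::arrange(.data$name)
}

#' Generalized cloverleaf loop bounds
#'
#' Loop windows drive the positional suffixes of mature-tRNA-derived tDR
#' names. The D-loop and anticodon-loop windows are positions from the 5'
#' end; the T-loop window is given in negative coordinates from the 3' end
#' (-1 = last base) because the variable loop makes its 5'-anchored position
#' unstable. Given per-gene secondary-structure annotations, each bound is
#' the statistical mode across genes (ties resolve to the smallest value,
#' with a warning); with no annotations the generalized human defaults are
#' returned: D 13-22, anticodon 31-39, T -23..-15.
#'
#' @param structures Optional tibble with columns `d_start`, `d_end`,
#'   `a_start`, `a_end`, `t_start`, `t_end` (one row per gene; `t_*`
#'   negative, from the 3' end).
#' @return A `loop_bounds` list with elements `d_start`, `d_end`, `a_start`,
#'   `a_end`, `t_start`, `t_end`.
#' @export
#' @examples
#' generalized_loop_bounds()
generalized_loop_bounds <- function(structures = NULL) {
  if (is.null(structures) || nrow(structures) == 0L) {
    return(loop_bounds())
  }
  need <- c("d_start", "d_end", "a_start", "a_end", "t_start", "t_end")
  miss <- setdiff(need, names(structures))
  if (length(miss)) abort(paste0("structure table missing columns: ", paste(miss, collapse = ", ")))
  vals <- lapply(setNames(need, need), function(col) {
    as.integer(stat_mode(structures[[col]], what = col))
  })
  do.call(loop_bounds, vals)
}

#' @rdname generalized_loop_bounds
#' @param d_start,d_end,a_start,a_end,t_start,t_end Loop window bounds
#'   (1-based from the 5' end for D and anticodon; negative from the 3' end
#'   for T).
#' @export
loop_bounds <- function(d_start = 13L, d_end = 22L, a_start = 31L, a_end = 39L,
                        t_start = -23L, t_end = -15L) {
  b <- list(d_start = d_start, d_end = d_end, a_start = a_start, a_end = a_end,
            t_start = t_start, t_end = t_end)
  if (b$d_start > b$d_end || b$a_start > b$a_end || b$t_start > b$t_end) {
    abort("loop bounds must satisfy start <= end (negative T coordinates included)")
  }
  if (b$t_start >= 0 || b$t_end >= 0) abort("T-loop bounds must be negative (from the 3' end)")
  structure(b, class = "loop_bounds")
}

#' Write a family library to FASTA (+ optional membership TSV)
#'
#' @param library A family tibble from [build_mature_library()] or
#'   [build_pre_library()].
#' @param fasta Output FASTA path (headers = family names).
#' @param members_tsv Optional path for a two-column family/gene_id table.
#' @return `fasta`, invisibly.
#' @export
write_trna_library <- function(library, fasta, members_tsv = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(library$sequence, library$name))
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(members_tsv)) {
    library |>
      dplyr::select("name", "member_gene_ids") |>
      tidyr::unnest_longer("member_gene_ids", values_to = "gene_id") |>
      readr::write_tsv(members_tsv)
  }
  invisible(fasta)
}

#' Read a family library back from FASTA
#'
#' Family metadata (kind, body coordinates, member counts) are recovered from
#' the family names, so a library written by [write_trna_library()] round-trips.
#'
#' @param fasta Path to a library FASTA whose headers are family names.
#' @return A family tibble.
#' @export
read_trna_library <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  parsed <- parse_family_name(nm)
  tibble::tibble(
    name = nm,
    kind = parsed$kind,
    sequence = unname(as.character(seqs)),
    body_start = ifelse(parsed$kind == "pre", FLANK_LEN + 1L, 1L),
    body_end = ifelse(parsed$kind == "pre",
                      nchar(as.character(seqs)) - FLANK_LEN,
                      nchar(as.character(seqs))),
    n_members = ifelse(parsed$kind == "pre", parsed$n_pre, parsed$copy_count),
    member_gene_ids = replicate(length(nm), character(0), simplify = FALSE)
  )
}
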