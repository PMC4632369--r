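# Fixture builders used across test files. Everything is generated in code;
# seeds are fixed by the callers.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_gene <- function(gene_id = "g1", amino_acid = "Gly", anticodon = "GCC",
                      family_index = 1L, copy_index = 1L,
                      body_sequence = NULL, body_len = 72L,
                      introns = NA_character_,
                      flank5 = NULL, flank3 = NULL) {
  tibble::tibble(
    gene_id = gene_id, amino_acid = amino_acid, anticodon = anticodon,
    family_index = as.integer(family_index), copy_index = as.integer(copy_index),
    body_sequence = body_sequence %||% rand_dna(body_len),
    introns = introns,
    flank5 = flank5 %||% rand_dna(40),
    flank3 = flank3 %||% rand_dna(40)
  )
}

make_family <- function(name = "Toy-AAA-1-1", kind = "mature", sequence,
                        body_start = NULL, body_end = NULL) {
  tibble::tibble(
    name = name, kind = kind, sequence = sequence,
    body_start = body_start %||% if (kind == "pre") 41L else 1L,
    body_end = body_end %||% if (kind == "pre") nchar(sequence) - 40L else nchar(sequence),
    n_members = 1L, member_gene_ids = list(character(0))
  )
}

# Coverage profile from weighted spans; spans is a list of c(start, end, count).
make_profile <- function(spans, len = 76L, family = "Toy-AAA-1-1",
                         kind = "mature", body_start = 1L, body_end = len) {
  cov <- numeric(len)
  for (s in spans) cov[s[1]:s[2]] <- cov[s[1]:s[2]] + s[3]
  region <- rep("body", len)
  if (kind == "pre") {
    if (body_start > 1L) region[seq_len(body_start - 1L)] <- "leader"
    if (body_end < len) region[(body_end + 1L):len] <- "trailer"
  }
  tibble::tibble(
    family = family, kind = kind, position = seq_len(len),
    ref_base = strsplit(rand_dna(len), "")[[1]], region = region,
    coverage = cov / sum(vapply(spans, `[`, numeric(1), 3)),
    frac_mismatch = 0, frac_del = 0, frac_del3 = 0
  )
}

# Raw-read tibble: each row of (sequence, count) expanded with uniform Q40.
expand_reads <- function(reads) {
  counts <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  idx <- rep(seq_len(nrow(reads)), counts)
  tibble::tibble(
    sequence = reads$sequence[idx],
    quality = strrep("I", nchar(reads$sequence[idx]))
  )
}

# A one-row assignment tibble, defaulting to an error-free placement.
make_assignment <- function(sequence, count, stage, family, ref_start,
                            ref_span = nchar(sequence),
                            mismatch_positions = integer(0),
                            deletion_positions = integer(0)) {
  tibble::tibble(
    sequence = sequence, count = as.integer(count), stage = stage,
    family = family, ref_start = as.integer(ref_start),
    ref_span = as.integer(ref_span),
    n_mm = length(mismatch_positions), n_del = length(deletion_positions),
    mismatch_positions = list(as.integer(mismatch_positions)),
    deletion_positions = list(as.integer(deletion_positions))
  )
}
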