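# Independent brute-force alignment oracle: enumerates every window and
# every error pattern per stage, with no code shared with the package's
# scanner. Used to validate run_hierarchy() on generated cases.

oracle_stage_defs <- function() {
  list(
    EXACT_MATURE = list(kind = "mature", type = "mm", budget = 0L),
    EXACT_PRE    = list(kind = "pre",    type = "mm", budget = 0L),
    MM1          = list(kind = "mature", type = "mm", budget = 1L),
    DEL1         = list(kind = "mature", type = "del", budget = 1L),
    MM2          = list(kind = "mature", type = "mm", budget = 2L),
    DEL2         = list(kind = "mature", type = "del", budget = 2L),
    DEL3         = list(kind = "mature", type = "del3", budget = 3L)
  )
}

# Best window of one family at one stage by exhaustive enumeration:
# list(ref_start, ref_span, n_err) or NULL. Fewest errors, then leftmost.
oracle_scan_family <- function(rch, refch, def) {
  L <- length(rch)
  if (def$type == "mm") {
    best <- NULL
    nwin <- length(refch) - L + 1L
    if (nwin < 1L) return(NULL)
    for (s in seq_len(nwin)) {
      ne <- sum(refch[s:(s + L - 1L)] != rch)
      if (ne <= def$budget && (is.null(best) || ne < best$n_err)) {
        best <- list(ref_start = s, ref_span = L, n_err = ne)
        if (ne == 0L) break
      }
    }
    return(best)
  }
  if (def$type == "del") {
    for (e in 0:def$budget) {
      span <- L + e
      nwin <- length(refch) - span + 1L
      if (nwin < 1L) next
      combos <- if (e == 0L) list(integer(0)) else
        asplit(utils::combn(span, e), 2)
      for (s in seq_len(nwin)) {
        w <- refch[s:(s + span - 1L)]
        for (dd in combos) {
          kept <- if (length(dd)) w[-dd] else w
          if (length(kept) == L && all(kept == rch)) {
            return(list(ref_start = s, ref_span = span, n_err = e))
          }
        }
      }
    }
    return(NULL)
  }
  # del3: contiguous triple (or fewer scattered deletions, tried first so
  # "at most the budget" holds for the standalone scan as well)
  for (e in 0:2) {
    span <- L + e
    nwin <- length(refch) - span + 1L
    if (nwin < 1L) next
    combos <- if (e == 0L) list(integer(0)) else asplit(utils::combn(span, e), 2)
    for (s in seq_len(nwin)) {
      w <- refch[s:(s + span - 1L)]
      for (dd in combos) {
        kept <- if (length(dd)) w[-dd] else w
        if (length(kept) == L && all(kept == rch)) {
          return(list(ref_start = s, ref_span = span, n_err = e))
        }
      }
    }
  }
  span <- L + 3L
  nwin <- length(refch) - span + 1L
  if (nwin >= 1L) {
    for (s in seq_len(nwin)) {
      w <- refch[s:(s + span - 1L)]
      for (j in seq_len(span - 2L)) {
        if (all(w[-(j:(j + 2L))] == rch)) {
          return(list(ref_start = s, ref_span = span, n_err = 3L))
        }
      }
    }
  }
  NULL
}

# Full hierarchy for one read: list(stage, placements data.frame) with one
# row per family placed at the winning stage; stage "UNMAPPED" when none.
oracle_assign_read <- function(read_seq, mature_lib, pre_lib) {
  rch <- strsplit(read_seq, "")[[1]]
  libs <- list(mature = mature_lib, pre = pre_lib)
  for (stg in names(oracle_stage_defs())) {
    def <- oracle_stage_defs()[[stg]]
    lib <- libs[[def$kind]]
    if (is.null(lib) || nrow(lib) == 0L) next
    hits <- list()
    for (i in seq_len(nrow(lib))) {
      refch <- strsplit(lib$sequence[i], "")[[1]]
      h <- oracle_scan_family(rch, refch, def)
      if (!is.null(h)) {
        hits[[length(hits) + 1L]] <- data.frame(
          family = lib$name[i], ref_start = h$ref_start, ref_span = h$ref_span,
          n_err = h$n_err
        )
      }
    }
    if (length(hits)) {
      return(list(stage = stg, placements = do.call(rbind, hits)))
    }
  }
  list(stage = "UNMAPPED", placements = NULL)
}

# A mixed read set exercising every stage: spans drawn from the libraries
# with injected substitutions/deletions, plus pure-random reads.
oracle_read_set <- function(n, mature_lib, pre_lib, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    mode <- sample(c("mature", "pre", "random"), 1, prob = c(0.55, 0.2, 0.25))
    if (mode == "random") {
      out[i] <- rand_dna(sample(14:30, 1))
      next
    }
    lib <- if (mode == "mature") mature_lib else pre_lib
    fam <- lib[sample(nrow(lib), 1), ]
    len <- sample(14:30, 1)
    start <- sample(nchar(fam$sequence) - len + 1L, 1)
    ch <- strsplit(substr(fam$sequence, start, start + len - 1L), "")[[1]]
    if (mode == "mature") {
      err <- sample(c("none", "mm1", "mm2", "del1", "del2", "del3"), 1)
      np <- switch(err, none = 0L, mm1 = 1L, del1 = 1L, mm2 = 2L, del2 = 2L, del3 = 3L)
      if (np > 0L && length(ch) > np + 2L) {
        if (err %in% c("mm1", "mm2")) {
          pos <- sample(seq_along(ch), np)
          for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
        } else if (err == "del3") {
          j <- sample(2:(length(ch) - 3L), 1)
          ch <- ch[-(j:(j + 2L))]
        } else {
          pos <- sample(2:(length(ch) - 1L), np)
          ch <- ch[-pos]
        }
      }
    }
    out[i] <- paste(ch, collapse = "")
  }
  out <- out[nchar(out) >= 14]
  tibble::tibble(sequence = unique(out)) |>
    dplyr::mutate(count = 100L + seq_along(sequence))
}

# Compare run_hierarchy with the oracle read by read; returns a character
# vector of human-readable disagreements (empty when fully concordant).
oracle_disagreements <- function(unique_reads, mature_lib, pre_lib) {
  got <- run_hierarchy(unique_reads, mature_lib, pre_lib)
  bad <- character(0)
  for (i in seq_len(nrow(unique_reads))) {
    rs <- unique_reads$sequence[i]
    exp <- oracle_assign_read(rs, mature_lib, pre_lib)
    rows <- got[got$sequence == rs, ]
    if (!all(rows$stage == exp$stage)) {
      bad <- c(bad, sprintf("%s: stage %s != oracle %s", rs,
                            paste(unique(rows$stage), collapse = ","), exp$stage))
      next
    }
    if (exp$stage == "UNMAPPED") next
    o <- exp$placements[order(exp$placements$family), ]
    g <- rows[order(rows$family), ]
    if (!identical(g$family, o$family) ||
        !identical(as.integer(g$ref_start), as.integer(o$ref_start)) ||
        !identical(as.integer(g$ref_span), as.integer(o$ref_span)) ||
        !identical(as.integer(g$n_mm + g$n_del), as.integer(o$n_err))) {
      bad <- c(bad, sprintf("%s: placements differ at stage %s", rs, exp$stage))
    }
  }
  bad
}
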