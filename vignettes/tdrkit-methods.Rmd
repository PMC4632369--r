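---
title: "tdrkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tdrkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdrkit)
```

## What the package models

tRNA-derived RNAs (tDRs) are small RNAs processed from mature tRNAs or from
unspliced pre-tRNA transcripts. `tdrkit` treats a small RNA-seq sample as a
mixture of short (14–40 nt) sense-strand fragments of a known set of tRNA
sequences, observed through a reverse-transcription step that converts
chemical modifications on mature tRNAs into sequencing "errors": base
misincorporations (mismatches) and skipped template bases (deletions).
Three modelling commitments follow:

* reads are aligned to **tRNA family sequences, not the genome** — multi-copy
  genes, spliced reads and the non-templated 3' `CCA` make genome alignment
  both ambiguous and lossy for this RNA class;
* alignment tolerance is **structured, not free**: a read is assigned to the
  first stage of a fixed hierarchy (exact to mature, exact to pre, then 1
  mismatch, 1 deletion, 2 mismatches, 2 deletions, one contiguous 3-base
  deletion, all against mature tRNAs) rather than to a best-scoring
  alignment. The stage is itself a measurement — the "error type" — that
  proxies modification positions;
* each tRNA family is summarised by its **dominant (primary) tDR** rather
  than by an attempt to deconvolve every co-occurring species.

## Reference libraries

A tRNA gene enters the package as its annotated body sequence plus
metadata (amino acid, anticodon, family identifier, copy index, intron
intervals, and exactly 40 nt of genomic flank on each side — the input
format mirrors a gtRNAdb-style export so real references and synthetic
fixtures are built through the same code path).

* **Mature families**: introns excised, `CCA` appended; genes with an
  identical mature sequence *and* identical amino-acid/anticodon/identifier
  metadata aggregate into one family `W-X-Y-Z` with `Z` the number of
  copies. Identical sequences under *different* metadata are deliberately
  kept as separate families (with a warning): merging them would destroy
  the printed naming scheme, and the ambiguity is the annotation's, not
  ours. Metadata that would mint two families with the same name is a hard
  error naming the offending genes.
* **Pre families**: flank + unspliced body + flank (a pre-tRNA is the
  unprocessed transcript, so introns are retained); genes from one mature
  family with an identical pre sequence group into `pre-W-X-Y-Z.n`, with
  `Z` the largest member copy index and `n` the group size.

All coordinates in the package are 1-based closed intervals, matching how
positions are spoken about in the field ("position +1", "positions 13–22").

## The alignment hierarchy

A "deletion" is a reference base absent from the read (the polymerase
skipped it); read insertions are not modelled at any stage. Alignment is
end-to-end — tDRs have well-defined termini, so clipping would blur exactly
the signal the tool measures — and sense-strand only, as small RNA-seq
library protocols are stranded.

Numerical/tie-break choices, all deterministic:

* within a family, if several windows qualify at a stage, the one with the
  fewest total errors wins, then the leftmost start;
* when several deletion-position combinations explain the same window, the
  lexicographically smallest (leftmost) combination is recorded;
* the two-deletion stage accepts any two deleted positions, adjacent or
  not; a contiguous triple is only reachable at the final stage because the
  earlier stages run first;
* across families there is deliberately **no** tie-breaking: a read placed
  in k families at its stage counts fully toward each (see Quantification);
* the mismatch/deletion stages stop at mature tRNAs; reads failing the full
  hierarchy are reported as unmapped rather than being chased into
  pre-tRNAs, on the assumption that only mature tRNAs carry extensive
  modifications.

The stage order is a parameter (`stages =` / `--stage-order`), so a user
with a biological reason to prioritise one deletion over one mismatch can
reorder without touching code.

## Filtering parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_qual` | 28 | Phred | a single low-quality base can fake a mismatch/deletion call, so the whole read must clear a conservative floor ("drops below 28" — a position exactly at 28 passes) |
| `min_len`, `max_len` | 14, 40 | nt | below 14 nt reads multi-map by chance, especially with error budgets; above 40 nt is outside the tDR size grammar. The keep-range [14, 40] is consistent with the tRNA-half definition capping at 40 nt; both bounds are configurable |
| `min_count` | 100 | reads | unique sequences seen fewer than 100 times are dominated by degradation noise; the bound is inclusive, and `min_count_frac` converts it to a fraction of total input for libraries of very different depth |

Quality filtering runs before collapsing, so a unique sequence's count
reflects only trustworthy copies. Reads containing `N` are discarded (they
cannot participate in exact matching) and tallied separately in the run
ledger, which conserves reads exactly:
input = quality + length + N + abundance + mapped + unmapped.

## Coverage, naming and the dominance threshold

Coverage at a position is the count-weighted fraction of a family's reads
whose alignment window spans it; deleted reference positions count as
spanned (the read derives from across them). The primary tDR length is the
number of positions with coverage strictly above 50 %; 28–40 nt is a `tRH`,
15–27 nt a `tRF`.

Location suffixes use the generalized cloverleaf windows — D-loop 13–22 and
anticodon loop 31–39 from the 5' end, T-loop −23..−15 from the 3' end
(−1 = last base; the variable loop makes a 5'-anchored T-window unstable).
Given per-gene structure annotations the windows are the per-bound modes
(ties resolve to the smallest candidate, warned, erring toward a wider
annotation window). The 3' rule tests position −7 rather than −1 because of
the tapering signal at tDR 3' ends; with the `CCA` appended, −7 sits just
inside the tRNA body. Suffix letters concatenate in the fixed order
`5' D T A 3'` — the unique simple order consistent with the composite
suffixes `DA` and `DTA` that dominant anticodon-spanning halves produce.
Two open corners are resolved explicitly: body-only pre-tDR coverage emits
a bare `B`, and near-full-length coverage may legitimately emit `5'3'`
(kept, with a warning, rather than suppressed). Suffixes use ASCII quotes
(`5'`), keeping names safe in file paths and TSVs.

A primary tDR is named only when some position's coverage strictly exceeds
2/3. Below that, dominance is too close to call (52 % vs 48 % can be a
mapping-efficiency artifact), so the family is reported `undefined` with
its statistics retained — including when a dominant span falls outside both
size windows.

## Quantification

```
relative_abundance = (family reads / all tRNA-mapped reads)
                     x highest coverage proportion x 100
```

Counting is deliberately non-fractional: a read mapping to k families adds
its full count to each family (fractional splitting would under-quantify
tDRs from multi-copy genes), while the denominator counts every mapped
read once, which keeps relative abundance in [0, 100]. Multiplying by the
maximum coverage makes the quantity a ceiling on the fraction of reads
belonging to the primary tDR — reads not spanning the best-covered
position cannot be part of it. Reports keep full precision; printed tables
round to one decimal. Post-hoc aggregation to isodecoder or amino-acid
level sums counts and takes the member maximum coverage (a documented
choice; no formula exists for an aggregated coverage, and the maximum
preserves the ceiling interpretation).

## Visualization

Coverage maps show the top 50 families (configurable) in descending
relative abundance, dot area scaling linearly with coverage. Mature maps
color by nucleotide and overlay an error-type glyph where an error class
exceeds 5 % of the reads spanning a position; when two classes tie for
display, the more frequent one is drawn. Pre maps color by
leader/body/trailer and carry no overlays, since pre alignment is
exact-only. Colors and glyph shapes live in `tdr_map_style()`, not in the
plotting code.

## The simulator, and what passing tests do not show

`sim_spec()`/`sim_reference()`/`sim_reads()` generate random gene bodies of
70–76 nt (typical human tRNA gene lengths) with 40-nt flanks, optional
introns placed at the canonical position 3' of the anticodon, declared tDR
spans with declared error patterns (substitutions rotate the base
deterministically; deletions must sit strictly inside the span, because an
edge deletion is indistinguishable from a shorter exact read), uniform Q40
qualities, and singleton background noise. Declarations that cannot realise
their stage — spans beyond the reference, edge deletions, error reads that
still match some family exactly — are rejected rather than silently
emitted. The seed fully determines every byte of output.

This emulates the *combinatorial* structure of the problem (family
aggregation, stage dispatch, the naming grammar, multi-mapping), not the
*chemistry* of real data: real tRNAs are structured rather than random
sequence (so real multi-mapping is far heavier), modifications cluster at
specific positions, qualities vary, and adapter-trimming artifacts exist.
Passing the recovery suites therefore validates the algorithmic contracts,
not tissue-level biology.

Validation problem sizes, chosen to exercise every code path at desk
scale: the alignment hierarchy is checked read-by-read against an
independent brute-force enumerator (all windows × all error patterns per
stage) on 500+ mixed reads over three families; end-to-end recovery runs
one noiseless simulation per cell of {alignment stage} × {tRH, tRF} ×
{location suffix} (68 feasible cells); the naming grammar is additionally
unit-tested at every rule boundary (28/27, 14/41, 0.66/0.69).

## Known limitations

* No modelling of read insertions, soft clipping, or error budgets beyond
  the three-base deletion; reads needing more tolerance are "unmapped".
* Reverse-transcriptase *aborts* (which under-represent some tDRs) are an
  experimental problem and are not corrected for.
* Mismatch/deletion stages never target pre-tRNAs; heavily modified
  pre-tDRs, if they exist, would go uncounted.
* One primary tDR per family: co-dominant species below the 2/3 threshold
  are reported `undefined` by design.
* No cross-sample statistics (correlation, clustering, differential
  abundance); the per-sample reports are the interface to such analyses.
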