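# End-to-end pipeline: preprocess -> hierarchical alignment -> coverage &
# naming -> quantification, bundled into a result object with broom-style
# tidy()/glance() methods.

#' Run the full tDR mapping pipeline
#'
#' Executes read filtering/collapsing, the error-type alignment hierarchy,
#' per-family coverage profiling, primary-tDR naming and relative-abundance
#' quantification. References can be given either as a gene table (both
#' libraries are built) or as prebuilt family tibbles.
#'
#' @param fastq Path to an adapter-trimmed FASTQ file (alternatively supply
#'   `reads`).
#' @param reads A tibble with `sequence`/`quality` columns (alternative to
#'   `fastq`).
#' @param genes A gene tibble (see [read_trna_genes()], [sim_reference()]);
#'   ignored when both libraries are supplied.
#' @param mature_lib,pre_lib Prebuilt family tibbles.
#' @param loop_structures Optional per-gene loop annotation tibble for
#'   [generalized_loop_bounds()]; defaults to the generalized human windows.
#' @param min_qual,min_len,max_len,min_count,min_count_frac Filter settings,
#'   passed to [collapse_and_filter()].
#' @param stages Stage order for [run_hierarchy()].
#' @return A `tdr_result` object: a list with `unique_reads`, `assignments`,
#'   `profiles`, `report`, `summary` (the read-conservation ledger),
#'   `bounds`, `mature_lib`, `pre_lib` and `params`. Methods: [print()],
#'   [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' spec <- sim_spec(
#'   n_families = 1, seed = 11,
#'   tdrs = tibble::tibble(family = 1, kind = "mature", start = 1, end = 32,
#'                         count = 500, error = "none", error_pos = NA)
#' )
#' genes <- sim_reference(spec)
#' sim <- sim_reads(genes, spec)
#' res <- tdr_pipeline(reads = sim$reads |> tidyr::uncount(count) |>
#'                       dplyr::select(sequence, quality),
#'                     genes = genes)
#' tidy(res)
tdr_pipeline <- function(fastq = NULL, reads = NULL, genes = NULL,
                         mature_lib = NULL, pre_lib = NULL,
                         loop_structures = NULL,
                         min_qual = 28L, min_len = 14L, max_len = 40L,
                         min_count = 100L, min_count_frac = NULL,
                         stages = tdr_stage_order()) {
  if (is.null(reads)) {
    if (is.null(fastq)) abort("supply either `fastq` or `reads`")
    reads <- read_small_rna_fastq(fastq)
  }
  if (is.null(mature_lib) || is.null(pre_lib)) {
    if (is.null(genes)) abort("supply `genes` or both prebuilt libraries")
    genes <- validate_trna_genes(genes)
    if (is.null(mature_lib)) mature_lib <- build_mature_library(genes)
    if (is.null(pre_lib)) pre_lib <- build_pre_library(genes)
  }
  bounds <- generalized_loop_bounds(loop_structures)

  unique_reads <- collapse_and_filter(
    reads, min_q = min_qual, min_len = min_len, max_len = max_len,
    min_count = min_count, min_count_frac = min_count_frac
  )
  fs <- filter_summary(unique_reads)

  assignments <- run_hierarchy(unique_reads, mature_lib, pre_lib, stages = stages)
  placed <- mapped_assignments(assignments)
  lib <- dplyr::bind_rows(mature_lib, pre_lib)

  if (nrow(placed) > 0L) {
    profiles <- compute_coverage(assignments, lib)
    report <- family_report(assignments, profiles, lib, bounds)
  } else {
    profiles <- tibble::tibble(
      family = character(0), kind = character(0), position = integer(0),
      ref_base = character(0), region = character(0), coverage = numeric(0),
      frac_mismatch = numeric(0), frac_del = numeric(0), frac_del3 = numeric(0)
    )
    report <- tibble::tibble(
      family = character(0), kind = character(0), read_count = integer(0),
      max_coverage = numeric(0), relative_abundance = numeric(0),
      size_class = character(0), location_suffix = character(0),
      full_name = character(0), primary_length = integer(0)
    )
    attr(report, "total_mapped") <- 0L
  }

  n_mapped <- total_mapped_reads(assignments)
  n_unmapped <- sum(assignments$count[assignments$stage == "UNMAPPED"])
  summary <- dplyr::mutate(fs,
    n_mapped = n_mapped, n_unmapped = n_unmapped,
    n_families_mature = sum(report$kind == "mature"),
    n_families_pre = sum(report$kind == "pre")
  )

  structure(
    list(
      unique_reads = unique_reads, assignments = assignments,
      profiles = profiles, report = report, summary = summary,
      bounds = bounds, mature_lib = mature_lib, pre_lib = pre_lib,
      params = list(min_qual = min_qual, min_len = min_len, max_len = max_len,
                    min_count = min_count, min_count_frac = min_count_frac,
                    stages = stages)
    ),
    class = "tdr_result"
  )
}

#' @export
print.tdr_result <- function(x, ...) {
  s <- x$summary
  cat("<tdr_result>\n")
  cat(sprintf("  reads: %d in; %d discarded (quality %d, length %d, N %d, abundance %d)\n",
              s$n_input, s$n_input - s$n_kept, s$fail_quality, s$fail_length,
              s$fail_n, s$fail_count))
  cat(sprintf("  kept: %d reads in %d unique sequences; mapped %d, unmapped %d\n",
              s$n_kept, s$n_unique, s$n_mapped, s$n_unmapped))
  cat(sprintf("  families with signal: %d mature, %d pre\n",
              s$n_families_mature, s$n_families_pre))
  if (nrow(x$report) > 0L) {
    cat("  top families (relative abundance, %):\n")
    top <- head(x$report, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-28s %6.1f  %s\n", top$family[i],
                  round(top$relative_abundance[i], 1), top$full_name[i]))
    }
  }
  invisible(x)
}

#' Tidy the per-family report of a pipeline result
#'
#' @param x A `tdr_result`.
#' @param ... Unused.
#' @return The family report tibble (one row per tRNA family).
#' @export
tidy.tdr_result <- function(x, ...) x$report

#' One-row summary of a pipeline run
#'
#' @param x A `tdr_result`.
#' @param ... Unused.
#' @return The read-conservation ledger tibble (one row): input, per-filter
#'   discards, mapped/unmapped counts and family tallies.
#' @export
glance.tdr_result <- function(x, ...) x$summary

#' Write the pipeline's report tables
#'
#' Emits `<prefix>_mature_report.tsv`, `<prefix>_pre_report.tsv` (one family
#' per row, relative abundance printed at full precision), a per-position
#' `<prefix>_profiles.tsv` and `<prefix>_summary.tsv`. Any partial outputs
#' are removed if writing fails midway.
#'
#' @param result A `tdr_result`.
#' @param out_prefix Path prefix for the output files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_tdr_reports <- function(result, out_prefix) {
  paths <- paste0(out_prefix, c("_mature_report.tsv", "_pre_report.tsv",
                                "_profiles.tsv", "_summary.tsv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))
  readr::write_tsv(dplyr::filter(result$report, .data$kind == "mature"), paths[1])
  readr::write_tsv(dplyr::filter(result$report, .data$kind == "pre"), paths[2])
  readr::write_tsv(result$profiles, paths[3])
  readr::write_tsv(result$summary, paths[4])
  ok <- TRUE
  invisible(paths)
}
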