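# Step 4: relative abundance, multi-mapping counts, error-type proportions,
# and the per-sample family report.

#' Relative abundance of a family's primary tDR
#'
#' `((family_reads / total_mapped) * max_coverage) * 100`: the fraction of
#' all tRNA-mapped reads that both map to the family and span its
#' best-covered position — a ceiling on the fraction of reads belonging to
#' the primary tDR. Tables print one decimal; full precision is returned.
#'
#' @param family_reads Reads mapped to the family (each multi-mapping read
#'   counted in full).
#' @param total_mapped Reads mapped to any tRNA (each read counted once).
#' @param max_coverage The family's highest positional coverage proportion.
#' @return The relative abundance in percent.
#' @export
#' @examples
#' round(relative_abundance(45347, 679288, 0.69), 1)
relative_abundance <- function(family_reads, total_mapped, max_coverage) {
  if (any(total_mapped == 0)) abort("total_mapped must be > 0")
  if (any(max_coverage < 0 | max_coverage > 1)) abort("max_coverage must lie in [0, 1]")
  (family_reads / total_mapped) * max_coverage * 100
}

#' Per-family read counts under full multi-mapping
#'
#' Every instance a read maps to a family it is counted once with its full
#' copy number — no fractional splitting, so tDRs from multi-copy tRNA genes
#' are not under-quantified. The denominator (`total_mapped`, attached as an
#' attribute) counts each mapped read once regardless of how many families
#' it hit, which keeps relative abundances at or below 100 %.
#'
#' @param assignments Assignment tibble from [run_hierarchy()].
#' @return A tibble (`family`, `read_count`) sorted by descending count with
#'   attribute `total_mapped`; see also [total_mapped_reads()].
#' @export
count_family_reads <- function(assignments) {
  placed <- mapped_assignments(assignments)
  counts <- placed |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(read_count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$read_count), .data$family)
  attr(counts, "total_mapped") <- total_mapped_reads(assignments)
  counts
}

#' @rdname count_family_reads
#' @export
total_mapped_reads <- function(assignments) {
  placed <- mapped_assignments(assignments)
  placed |>
    dplyr::distinct(.data$sequence, .data$count) |>
    dplyr::pull(.data$count) |>
    sum()
}

#' Error-type stage proportions
#'
#' The fraction of mapped read counts assigned at each stage of the error
#' hierarchy (unmapped reads excluded). With `by = "all"` each read counts
#' once; with `by = "family"` proportions are computed within each family
#' over that family's placements.
#'
#' @param assignments Assignment tibble from [run_hierarchy()].
#' @param by `"all"` for sample-wide proportions or `"family"`.
#' @return A tibble with columns (`family`,) `stage`, `count`, `proportion`.
#' @export
stage_proportions <- function(assignments, by = c("all", "family")) {
  by <- match.arg(by)
  placed <- mapped_assignments(assignments)
  if (by == "all") {
    placed |>
      dplyr::distinct(.data$sequence, .data$count, .data$stage) |>
      dplyr::group_by(.data$stage) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::mutate(proportion = .data$count / sum(.data$count))
  } else {
    placed |>
      dplyr::group_by(.data$family, .data$stage) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
      dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
  }
}

#' Per-sample family report
#'
#' Joins counts, coverage maxima, primary-tDR names and relative abundances
#' into the sample-level table, ordered by descending relative abundance
#' (ties broken by family name).
#'
#' @param assignments Assignment tibble from [run_hierarchy()].
#' @param profiles Coverage profiles from [compute_coverage()].
#' @param library Family tibble covering all placed families.
#' @param bounds A [loop_bounds()] object.
#' @return A tibble: `family`, `kind`, `read_count`, `max_coverage`,
#'   `relative_abundance`, `size_class`, `location_suffix`, `full_name`,
#'   `primary_length`, with attribute `total_mapped`.
#' @export
family_report <- function(assignments, profiles, library,
                          bounds = loop_bounds()) {
  counts <- count_family_reads(assignments)
  total <- attr(counts, "total_mapped")
  primaries <- profiles |>
    dplyr::group_split(.data$family) |>
    lapply(function(pr) {
      fam <- library[library$name == pr$family[1], ]
      name_primary(fam, pr, bounds)
    }) |>
    dplyr::bind_rows()
  report <- counts |>
    dplyr::left_join(primaries, by = "family") |>
    dplyr::left_join(dplyr::select(library, "name", "kind"),
                     by = c(family = "name")) |>
    dplyr::mutate(
      relative_abundance = relative_abundance(.data$read_count, total,
                                              .data$max_coverage)
    ) |>
    dplyr::select("family", "kind", "read_count", "max_coverage",
                  "relative_abundance", "size_class", "location_suffix",
                  "full_name", "primary_length") |>
    dplyr::arrange(dplyr::desc(.data$relative_abundance), .data$family)
  attr(report, "total_mapped") <- total
  report
}

#' Aggregate a family report to isodecoder or amino-acid level
#'
#' Post-hoc aggregation of families into super-families sharing the
#' anticodon (isodecoder) or the amino acid, parsed from the family names.
#' Read counts are summed; the aggregated maximum coverage is the maximum
#' over members, and relative abundance is recomputed at that level.
#'
#' @param report A [family_report()] tibble (its `total_mapped` attribute is
#'   used for the denominator).
#' @param level `"family"` (identity), `"anticodon"` or `"amino_acid"`.
#' @return An aggregated tibble sorted by descending relative abundance.
#' @export
aggregate_report <- function(report, level = c("family", "anticodon", "amino_acid")) {
  level <- match.arg(level)
  if (level == "family") return(report)
  total <- attr(report, "total_mapped")
  if (is.null(total)) abort("report lacks a total_mapped attribute; use family_report()")
  parsed <- parse_family_name(report$family)
  key <- switch(level,
    anticodon = paste(parsed$amino_acid, parsed$anticodon, sep = "-"),
    amino_acid = parsed$amino_acid
  )
  out <- report |>
    dplyr::mutate(group = key) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      read_count = sum(.data$read_count),
      max_coverage = max(.data$max_coverage),
      n_families = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_abundance = relative_abundance(.data$read_count, total,
                                              .data$max_coverage)
    ) |>
    dplyr::arrange(dplyr::desc(.data$relative_abundance), .data$group)
  attr(out, "total_mapped") <- total
  out
}
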