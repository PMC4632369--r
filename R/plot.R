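# Step 5: coverage-map visualization. One row per family (most abundant on
# top), one dot per reference position sized by coverage; mature maps color
# dots by nucleotide and overlay error-type glyphs, pre maps color by
# leader/body/trailer region (pre alignment is exact-only, so no overlays).

#' Style table for coverage maps
#'
#' Colors and glyph shapes are configuration, not hard-coded aesthetics:
#' override any element to restyle the maps. Dot area scales linearly with
#' coverage.
#'
#' @param nucleotide_colors Named colors for A/C/G/T.
#' @param region_colors Named colors for leader/body/trailer.
#' @param error_shapes Named plotting shapes for the mismatch, single-base
#'   deletion and three-base deletion overlays.
#' @param max_size Dot size at 100 % coverage.
#' @return A named list consumed by [plot_coverage_map()].
#' @export
tdr_map_style <- function(nucleotide_colors = c(A = "#33A02C", C = "#1F78B4",
                                                G = "#FF7F00", T = "#E31A1C"),
                          region_colors = c(leader = "#E31A1C",
                                            body = "#FF7F00",
                                            trailer = "#FFD92F"),
                          error_shapes = c(mismatch = 4L, del = 2L, del3 = 0L),
                          max_size = 4) {
  list(nucleotide_colors = nucleotide_colors, region_colors = region_colors,
       error_shapes = error_shapes, max_size = max_size)
}

# Pick, per position, the dominant error class above the overlay threshold
# (ties go to the more frequent class; exact ties to mismatch > del > del3).
dominant_errors <- function(profiles, min_frac) {
  profiles |>
    tidyr::pivot_longer(c("frac_mismatch", "frac_del", "frac_del3"),
                        names_to = "error_class", values_to = "frac") |>
    dplyr::mutate(error_class = sub("^frac_", "", .data$error_class)) |>
    dplyr::filter(.data$frac > min_frac) |>
    dplyr::mutate(error_class = factor(.data$error_class,
                                       levels = c("mismatch", "del", "del3"))) |>
    dplyr::group_by(.data$family, .data$position) |>
    dplyr::arrange(dplyr::desc(.data$frac), .data$error_class, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Per-sample tDR coverage map
#'
#' One row per family, restricted to the `top_n` most abundant, in
#' descending relative abundance (abundance printed in the axis label).
#' Mature maps color positions by nucleotide and overlay an error-type
#' glyph wherever an error class exceeds `error_overlay_min` of the reads
#' spanning that position; pre maps color by pre-tRNA region instead.
#'
#' @param report A [family_report()] tibble (or `tidy()` of a result).
#' @param profiles Matching [compute_coverage()] tibble.
#' @param kind `"mature"` or `"pre"`.
#' @param top_n Families shown (default 50).
#' @param error_overlay_min Minimum error fraction for an overlay glyph
#'   (default 0.05).
#' @param style A [tdr_map_style()] list.
#' @return A ggplot object (warning and `NULL` when the report has no
#'   families of the requested kind).
#' @export
plot_coverage_map <- function(report, profiles, kind = c("mature", "pre"),
                              top_n = 50, error_overlay_min = 0.05,
                              style = tdr_map_style()) {
  kind <- match.arg(kind)
  stopifnot(top_n >= 1, error_overlay_min >= 0, error_overlay_min <= 1)
  rep_k <- report |>
    dplyr::filter(.data$kind == !!kind) |>
    dplyr::arrange(dplyr::desc(.data$relative_abundance), .data$family) |>
    head(top_n)
  if (nrow(rep_k) == 0L) {
    warn(sprintf("no %s families in report: nothing to plot", kind))
    return(NULL)
  }
  lab <- sprintf("%s (%.1f%%)", rep_k$family, rep_k$relative_abundance)
  prof <- profiles |>
    dplyr::filter(.data$family %in% rep_k$family, .data$coverage > 0) |>
    dplyr::mutate(row = factor(.data$family, levels = rev(rep_k$family),
                               labels = rev(lab)))
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$row)) +
    ggplot2::scale_size_area(max_size = style$max_size, limits = c(0, 1),
                             name = "coverage") +
    ggplot2::labs(x = "position in tRNA", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
  if (kind == "mature") {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(size = .data$coverage,
                                       colour = .data$ref_base)) +
      ggplot2::scale_colour_manual(values = style$nucleotide_colors,
                                   name = "nucleotide")
    err <- dominant_errors(
      dplyr::semi_join(prof, rep_k, by = "family"), error_overlay_min
    ) |>
      dplyr::mutate(row = factor(.data$family, levels = rev(rep_k$family),
                                 labels = rev(lab)))
    if (nrow(err) > 0L) {
      p <- p + ggplot2::geom_point(
        data = err,
        ggplot2::aes(x = .data$position, y = .data$row,
                     shape = .data$error_class),
        size = style$max_size * 0.8, stroke = 0.9, colour = "black"
      ) +
        ggplot2::scale_shape_manual(
          values = style$error_shapes,
          labels = c(mismatch = "mismatch", del = "1-2 base deletion",
                     del3 = "3-base deletion"),
          name = "error type", drop = TRUE
        )
    }
  } else {
    p <- p +
      ggplot2::geom_point(ggplot2::aes(size = .data$coverage,
                                       colour = .data$region)) +
      ggplot2::scale_colour_manual(values = style$region_colors,
                                   name = "region")
  }
  p
}

#' @rdname plot_coverage_map
#' @param object A `tdr_result`.
#' @param ... Passed to [plot_coverage_map()].
#' @export
autoplot.tdr_result <- function(object, kind = "mature", ...) {
  plot_coverage_map(object$report, object$profiles, kind = kind, ...)
}

#' Write coverage maps to image files
#'
#' Writes `<prefix>_mature_map.<ext>` and `<prefix>_pre_map.<ext>` for the
#' library kinds present in the report; a kind with no families is skipped
#' with a warning and no file.
#'
#' @param result A `tdr_result`.
#' @param out_prefix Output path prefix.
#' @param format `"pdf"`, `"svg"` or `"png"`.
#' @param width,height Device size in inches.
#' @inheritParams plot_coverage_map
#' @return Paths written, invisibly.
#' @export
write_coverage_maps <- function(result, out_prefix, format = c("pdf", "svg", "png"),
                                top_n = 50, error_overlay_min = 0.05,
                                width = 10, height = 8,
                                style = tdr_map_style()) {
  format <- match.arg(format)
  written <- character(0)
  for (k in c("mature", "pre")) {
    p <- plot_coverage_map(result$report, result$profiles, kind = k,
                           top_n = top_n,
                           error_overlay_min = error_overlay_min, style = style)
    if (is.null(p)) next
    path <- sprintf("%s_%s_map.%s", out_prefix, k, format)
    ggplot2::ggsave(path, p, width = width, height = height)
    written <- c(written, path)
  }
  invisible(written)
}
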