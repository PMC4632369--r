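# Step 3: per-family positional coverage profiles and the positional naming
# grammar for the primary (dominant) tDR of each family.

#' Per-position coverage and error-class profiles
#'
#' For each family with at least one placed read, coverage at a position is
#' the count-weighted fraction of the family's reads whose alignment window
#' spans that position (deleted reference positions included — the read
#' physically derives from across them). Error fractions at a position are
#' computed among the reads spanning it: substitutions feed `frac_mismatch`,
#' deletions from the one/two-deletion stages feed `frac_del`, and the
#' contiguous three-base deletion feeds `frac_del3`.
#'
#' @param assignments Assignment tibble from [run_hierarchy()] (unmapped
#'   rows are ignored).
#' @param library Family tibble covering every family present in
#'   `assignments`; both kinds may be passed together (e.g.
#'   `dplyr::bind_rows(mature_lib, pre_lib)`).
#' @return A long tibble: `family`, `kind`, `position`, `ref_base`, `region`
#'   (`leader`/`body`/`trailer`; mature positions are all `body`),
#'   `coverage`, `frac_mismatch`, `frac_del`, `frac_del3`.
#' @export
compute_coverage <- function(assignments, library) {
  placed <- mapped_assignments(assignments)
  if (nrow(placed) == 0L) abort("no placed reads: coverage profiles exist only for families with >= 1 placement")
  missing <- setdiff(unique(placed$family), library$name)
  if (length(missing)) {
    abort(paste0("families missing from library: ", paste(missing, collapse = ", ")))
  }
  profiles <- placed |>
    dplyr::group_split(.data$family) |>
    lapply(function(rows) {
      fam <- library[library$name == rows$family[1], ]
      len <- nchar(fam$sequence[1])
      cov_n <- numeric(len); mm_n <- numeric(len)
      del_n <- numeric(len); del3_n <- numeric(len)
      for (k in seq_len(nrow(rows))) {
        span <- rows$ref_start[k]:(rows$ref_start[k] + rows$ref_span[k] - 1L)
        cov_n[span] <- cov_n[span] + rows$count[k]
        mp <- rows$mismatch_positions[[k]]
        if (length(mp)) mm_n[mp] <- mm_n[mp] + rows$count[k]
        dp <- rows$deletion_positions[[k]]
        if (length(dp)) {
          if (identical(rows$stage[k], "DEL3")) {
            del3_n[dp] <- del3_n[dp] + rows$count[k]
          } else {
            del_n[dp] <- del_n[dp] + rows$count[k]
          }
        }
      }
      total <- sum(rows$count)
      region <- rep("body", len)
      if (fam$kind[1] == "pre") {
        if (fam$body_start[1] > 1L) region[seq_len(fam$body_start[1] - 1L)] <- "leader"
        if (fam$body_end[1] < len) region[(fam$body_end[1] + 1L):len] <- "trailer"
      }
      tibble::tibble(
        family = fam$name[1], kind = fam$kind[1],
        position = seq_len(len),
        ref_base = seq_chars(fam$sequence[1]),
        region = region,
        coverage = cov_n / total,
        frac_mismatch = ifelse(cov_n > 0, mm_n / cov_n, 0),
        frac_del = ifelse(cov_n > 0, del_n / cov_n, 0),
        frac_del3 = ifelse(cov_n > 0, del3_n / cov_n, 0)
      )
    })
  dplyr::bind_rows(profiles)
}

#' Length of the primary tDR
#'
#' The number of positions whose coverage strictly exceeds 50 %.
#'
#' @param profile Coverage profile rows for one family (from
#'   [compute_coverage()]).
#' @return An integer length.
#' @export
primary_length <- function(profile) {
  if (length(unique(profile$family)) > 1L) abort("profile must cover a single family")
  sum(profile$coverage > 0.5)
}

#' Size class of a primary tDR
#'
#' A dominant span of 28-40 nt is a tRNA-half (`tRH`); 15-27 nt is a
#' tRNA-fragment (`tRF`); anything else (including 14 and 41) is
#' `undefined`.
#'
#' @param primary_length Integer length(s) from [primary_length()].
#' @return Character vector of `"tRH"`, `"tRF"` or `"undefined"`.
#' @export
#' @examples
#' classify_size(c(14, 15, 27, 28, 40, 41))
classify_size <- function(primary_length) {
  dplyr::case_when(
    primary_length >= 28 & primary_length <= 40 ~ "tRH",
    primary_length >= 15 & primary_length <= 27 ~ "tRF",
    TRUE ~ "undefined"
  )
}

# Resolve a (possibly negative) loop coordinate: -k is the k-th base from
# the 3' end, so -1 maps to the last base.
resolve_pos <- function(pos, len) ifelse(pos < 0, len + 1L + pos, pos)

#' Location suffix for a mature-tRNA-derived tDR
#'
#' Applies the positional rules against the generalized cloverleaf:
#' \itemize{
#'   \item `5'` if coverage > 50 % at position +1;
#'   \item `3'` if coverage > 50 % at position -7 (seven bases from the 3'
#'     end, chosen over -1 because of 3'-tapering signal);
#'   \item `D` if coverage > 50 % anywhere in the D-loop window and not at
#'     position 1;
#'   \item `A` if coverage > 50 % anywhere in the anticodon-loop window and
#'     not at position 1 or position -7;
#'   \item `T` if coverage > 50 % anywhere in the T-loop window and not at
#'     position -7.
#' }
#' Applicable letters are concatenated in the fixed order `5'`, `D`, `T`,
#' `A`, `3'` (the order that reproduces the printed `DTA` and `DA` forms).
#' Near-full-length coverage can legitimately fire both `5'` and `3'`; the
#' combined suffix is emitted with a warning.
#'
#' @param profile Coverage profile rows for one mature family.
#' @param bounds A [loop_bounds()] object.
#' @return The suffix string (possibly empty).
#' @export
mature_suffix <- function(profile, bounds = loop_bounds()) {
  if (!all(profile$kind == "mature")) abort("mature_suffix expects a mature-family profile")
  cov <- profile$coverage[order(profile$position)]
  len <- length(cov)
  t_win <- resolve_pos(bounds$t_start, len):resolve_pos(bounds$t_end, len)
  if (len < max(bounds$a_end, bounds$d_end) || min(t_win) < 1L || len < 8L) {
    abort("profile shorter than the loop coordinate windows require")
  }
  at <- function(p) cov[p] > 0.5
  hit5 <- at(1L)
  hit3 <- at(resolve_pos(-7L, len))
  hitD <- any(at(bounds$d_start:bounds$d_end)) && !hit5
  hitA <- any(at(bounds$a_start:bounds$a_end)) && !hit5 && !hit3
  hitT <- any(at(t_win)) && !hit3
  if (hit5 && hit3) {
    warn("coverage >50% at both position +1 and position -7; emitting combined 5'3' suffix")
  }
  paste0(
    if (hit5) "5'" else "", if (hitD) "D" else "", if (hitT) "T" else "",
    if (hitA) "A" else "", if (hit3) "3'" else ""
  )
}

#' Location suffix for a pre-tRNA-derived tDR
#'
#' `0` if any leader position (5' of the tRNA body) exceeds 50 % coverage,
#' `1` if any trailer position does (the `tRF-1` series), and `B` appended
#' (after the `0`/`1`, or alone) if any body position does.
#'
#' @param profile Coverage profile rows for one pre family.
#' @param body_start,body_end 1-based body coordinates on the pre-tRNA
#'   sequence; taken from the profile's `region` column when omitted.
#' @return The suffix string (possibly empty).
#' @export
pre_suffix <- function(profile, body_start = NULL, body_end = NULL) {
  if (!all(profile$kind == "pre")) abort("pre_suffix expects a pre-family profile")
  profile <- profile[order(profile$position), ]
  cov <- profile$coverage
  len <- length(cov)
  if (is.null(body_start)) body_start <- min(profile$position[profile$region == "body"])
  if (is.null(body_end)) body_end <- max(profile$position[profile$region == "body"])
  leader <- if (body_start > 1L) any(cov[seq_len(body_start - 1L)] > 0.5) else FALSE
  trailer <- if (body_end < len) any(cov[(body_end + 1L):len] > 0.5) else FALSE
  body <- any(cov[body_start:body_end] > 0.5)
  paste0(if (leader) "0" else "", if (trailer) "1" else "", if (body) "B" else "")
}

#' Name the primary tDR of a family
#'
#' A primary tDR is named only when it is clearly dominant: at least one
#' position must have coverage above 2/3 (strictly). Otherwise — and also
#' when the dominant span falls outside both size-class windows — the name
#' is `"undefined"` (the positional statistics are still reported). The
#' full name is `family-sizeclass-suffix` (pre families already carry the
#' `pre-` prefix in the family name).
#'
#' @param family One row of a family tibble.
#' @param profile Coverage profile rows for that family.
#' @param bounds A [loop_bounds()] object (used for mature families).
#' @return A one-row tibble: `family`, `size_class`, `location_suffix`,
#'   `full_name`, `primary_length`, `max_coverage`.
#' @export
name_primary <- function(family, profile, bounds = loop_bounds()) {
  fam_name <- family$name[1]
  max_cov <- max(profile$coverage)
  plen <- primary_length(profile)
  if (max_cov <= 2 / 3) {
    return(tibble::tibble(
      family = fam_name, size_class = "undefined",
      location_suffix = NA_character_, full_name = "undefined",
      primary_length = plen, max_coverage = max_cov
    ))
  }
  size <- classify_size(plen)
  suffix <- if (family$kind[1] == "pre") {
    pre_suffix(profile, family$body_start[1], family$body_end[1])
  } else {
    mature_suffix(profile, bounds)
  }
  tibble::tibble(
    family = fam_name,
    size_class = size,
    location_suffix = suffix,
    full_name = if (size == "undefined") "undefined" else
      paste(fam_name, size, suffix, sep = "-"),
    primary_length = plen,
    max_coverage = max_cov
  )
}
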