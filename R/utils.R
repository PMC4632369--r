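# Internal helpers shared across modules.

# Statistical mode; multimodal ties resolve to the smallest candidate (a wider
# loop window errs toward annotation rather than omission) with a warning.
stat_mode <- function(x, what = "value") {
  stopifnot(length(x) > 0)
  tab <- table(x)
  top <- as.numeric(names(tab)[tab == max(tab)])
  if (length(top) > 1L) {
    warn(sprintf(
      "multimodal %s: candidates %s; using the smallest (%s)",
      what, paste(top, collapse = ", "), min(top)
    ))
  }
  min(top)
}

# Phred+33 decoding for one quality string; characters below '!' are not
# legal Phred+33 and indicate a malformed FASTQ.
phred33_scores <- function(quality) {
  raw <- as.integer(charToRaw(quality))
  if (any(raw < 33L)) {
    abort("malformed FASTQ: quality character below '!' (not Phred+33)")
  }
  raw - 33L
}

# "6-10;20-25" -> 2-column matrix of closed 1-based intervals; NA/"" -> none.
parse_intervals <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se)) {
      abort(sprintf("cannot parse interval '%s' (expected 'start-end')", p))
    }
    se
  }))
  colnames(m) <- c("start", "end")
  m
}

format_intervals <- function(m) {
  if (nrow(m) == 0L) return(NA_character_)
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ";")
}

is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGTN]*$", x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Parse a tRNA family name into its components
#'
#' Family names follow the `W-X-Y-Z` scheme (amino acid, anticodon, family
#' identifier, number of identical gene copies); pre-tRNA families carry a
#' `pre-` prefix and a `.n` suffix counting genes with the identical
#' unspliced sequence. The amino-acid part may itself contain hyphens
#' (e.g. `nmt-tRNA-Lys`), so names are parsed from the right.
#'
#' @param name Character vector of family names.
#' @return A tibble with columns `name`, `kind` (`"mature"` or `"pre"`),
#'   `amino_acid`, `anticodon`, `family_index`, `copy_count` and `n_pre`
#'   (NA for mature families).
#' @export
#' @examples
#' parse_family_name(c("Asp-GTC-2-11", "pre-Gly-TCC-2-5.4"))
parse_family_name <- function(name) {
  res <- lapply(name, function(nm) {
    kind <- if (startsWith(nm, "pre-")) "pre" else "mature"
    core <- if (kind == "pre") sub("^pre-", "", nm) else nm
    n_pre <- NA_integer_
    if (kind == "pre") {
      if (!grepl("\\.\\d+$", core)) {
        abort(sprintf("cannot parse pre-tRNA family name '%s' (missing '.n')", nm))
      }
      n_pre <- as.integer(sub("^.*\\.", "", core))
      core <- sub("\\.\\d+$", "", core)
    }
    parts <- strsplit(core, "-", fixed = TRUE)[[1]]
    if (length(parts) < 4L) {
      abort(sprintf("cannot parse family name '%s' (expected W-X-Y-Z)", nm))
    }
    k <- length(parts)
    tibble::tibble(
      name = nm, kind = kind,
      amino_acid = paste(parts[seq_len(k - 3L)], collapse = "-"),
      anticodon = parts[k - 2L],
      family_index = as.integer(parts[k - 1L]),
      copy_count = as.integer(parts[k]),
      n_pre = n_pre
    )
  })
  dplyr::bind_rows(res)
}
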