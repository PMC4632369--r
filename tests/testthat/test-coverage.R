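test_that("coverage is the count-weighted fraction of reads spanning each position", {
  set.seed(40)
  fam <- make_family(sequence = rand_dna(80))
  asn <- dplyr::bind_rows(
    make_assignment(strrep("A", 30), 150, "EXACT_MATURE", fam$name, 1),
    make_assignment(strrep("C", 31), 50, "EXACT_MATURE", fam$name, 40)
  )
  prof <- compute_coverage(asn, fam)
  cov <- prof$coverage
  expect_equal(cov[5], 0.75)
  expect_equal(cov[50], 0.25)
  expect_equal(cov[35], 0)

  solo <- compute_coverage(asn[1, ], fam)
  expect_equal(unique(solo$coverage[1:30]), 1)
  expect_equal(unique(solo$coverage[31:80]), 0)
  expect_true(all(prof$coverage >= 0 & prof$coverage <= 1))
})

test_that("error fractions are computed among reads spanning the position", {
  set.seed(41)
  fam <- make_family(sequence = rand_dna(60))
  asn <- dplyr::bind_rows(
    make_assignment(strrep("A", 20), 100, "EXACT_MATURE", fam$name, 1),
    make_assignment(strrep("G", 19), 25, "DEL1", fam$name, 1, ref_span = 20,
                    deletion_positions = 8L)
  )
  prof <- compute_coverage(asn, fam)
  expect_equal(prof$frac_del[prof$position == 8], 25 / 125)
  expect_equal(prof$frac_del[prof$position == 9], 0)

  # DEL3 deletions land in their own class, mismatches in theirs
  asn2 <- dplyr::bind_rows(
    make_assignment(strrep("A", 20), 80, "EXACT_MATURE", fam$name, 1),
    make_assignment(strrep("T", 17), 20, "DEL3", fam$name, 1, ref_span = 20,
                    deletion_positions = 6:8),
    make_assignment(strrep("C", 20), 100, "MM1", fam$name, 1,
                    mismatch_positions = 3L)
  )
  prof2 <- compute_coverage(asn2, fam)
  expect_equal(prof2$frac_del3[prof2$position == 7], 20 / 200)
  expect_equal(prof2$frac_mismatch[prof2$position == 3], 100 / 200)
  expect_equal(prof2$frac_del[prof2$position == 7], 0)

  expect_error(compute_coverage(asn[0, ], fam), "no placed reads")
})

test_that("primary length counts positions with strictly >50% coverage", {
  uni <- make_profile(list(c(1, 30, 1)), len = 76)
  expect_equal(primary_length(uni), 30L)

  # two equal populations: flat 0.5 everywhere they do not overlap
  half <- make_profile(list(c(1, 30, 100), c(15, 44, 100)), len = 76)
  expect_equal(primary_length(half), 16L)
  expect_equal(sum(half$coverage == 0.5), (14 + 14))

  flat <- make_profile(list(c(1, 76, 1), c(1, 76, 1)), len = 76)
  flat$coverage <- rep(0.5, 76)
  expect_equal(primary_length(flat), 0L)
})

test_that("size classes split at the documented boundaries", {
  expect_equal(classify_size(c(14, 15, 27, 28, 40, 41)),
               c("undefined", "tRF", "tRF", "tRH", "tRH", "undefined"))
})

test_that("primary length is monotone under pointwise coverage increase", {
  set.seed(42)
  for (i in 1:20) {
    base <- make_profile(list(c(sample(1:30, 1), sample(40:76, 1), 100),
                              c(1, 76, sample(10:90, 1))), len = 76)
    bumped <- base
    bumped$coverage <- pmin(1, base$coverage + runif(76, 0, 0.3))
    expect_gte(primary_length(bumped), primary_length(base))
  }
})

test_that("mature suffixes follow the positional rules and fixed order", {
  suffix_of <- function(start, end, len = 76) {
    mature_suffix(make_profile(list(c(start, end, 1)), len = len))
  }
  # 5' wins at position 1 and suppresses D and A
  expect_equal(suffix_of(1, 32), "5'")
  # D + A without 5'/3'/T
  expect_equal(suffix_of(14, 44), "DA")
  # D + T + A: -23..-15 on a 76-mer is 54..62
  expect_equal(suffix_of(14, 60), "DTA")
  # D alone
  expect_equal(suffix_of(2, 28), "D")
  # A alone
  expect_equal(suffix_of(25, 52), "A")
  # T alone (avoiding the anticodon window and position -7 = 70)
  expect_equal(suffix_of(42, 68), "T")
  # 3' at position -7 suppresses T and A
  expect_equal(suffix_of(45, 76), "3'")
  # near-full-length coverage fires both ends, with a warning
  # 5' and 3' suppress every loop letter, leaving the combined ends
  expect_warning(s <- suffix_of(1, 76), "5'3'")
  expect_equal(s, "5'3'")
})

test_that("mature suffix exclusion rules never co-emit forbidden pairs", {
  set.seed(43)
  for (i in 1:60) {
    st <- sample(1:60, 1); en <- min(76, st + sample(14:40, 1) - 1)
    prof <- make_profile(list(c(st, en, 1)), len = 76)
    s <- suppressWarnings(mature_suffix(prof))
    has <- function(p) grepl(p, s, fixed = TRUE)
    if (has("D")) expect_false(has("5'"))
    if (has("A")) expect_false(has("5'") || has("3'"))
    if (has("T")) expect_false(has("3'"))
  }
})

test_that("profiles shorter than the loop windows are rejected", {
  short <- make_profile(list(c(1, 20, 1)), len = 30)
  expect_error(mature_suffix(short), "shorter")
})

test_that("pre suffixes mark leader, trailer and body in order 0, 1, B", {
  pre_of <- function(start, end) {
    pre_suffix(make_profile(list(c(start, end, 1)), len = 156, kind = "pre",
                            body_start = 41, body_end = 116))
  }
  expect_equal(pre_of(120, 140), "1")    # trailer only
  expect_equal(pre_of(31, 50), "0B")     # leader into body
  expect_equal(pre_of(50, 70), "B")      # body only
  expect_equal(pre_of(10, 30), "0")      # leader only
  expect_equal(pre_of(100, 130), "1B")   # body into trailer
  expect_equal(pre_of(30, 130), "01B")   # spans everything
})

test_that("primary tDRs are only named above the 2/3 dominance threshold", {
  fam <- make_family(name = "Glu-CTC-1-7", sequence = strrep("ACGT", 19))
  amb <- make_profile(list(c(1, 32, 60), c(40, 70, 40)), len = 76,
                      family = "Glu-CTC-1-7")
  res <- name_primary(fam, amb)
  expect_equal(res$full_name, "undefined")
  expect_equal(res$size_class, "undefined")
  expect_equal(res$max_coverage, 0.6)

  named <- make_profile(list(c(1, 32, 69), c(40, 70, 31)), len = 76,
                        family = "Glu-CTC-1-7")
  res2 <- name_primary(fam, named)
  expect_equal(res2$max_coverage, 0.69)
  expect_equal(res2$full_name, "Glu-CTC-1-7-tRH-5'")
  expect_equal(res2$primary_length, 32L)

  # dominant but outside both size windows -> undefined with stats retained
  tiny <- make_profile(list(c(1, 10, 9), c(1, 76, 1)), len = 76,
                       family = "Glu-CTC-1-7")
  res3 <- name_primary(fam, tiny)
  expect_equal(res3$full_name, "undefined")
  expect_equal(res3$primary_length, 10L)
  expect_gt(res3$max_coverage, 2 / 3)
})

test_that("pre families compose full names from their family name", {
  fam <- make_family(name = "pre-Arg-CTC-2-1.1", kind = "pre",
                     sequence = strrep("ACGT", 39), body_start = 41,
                     body_end = 116)
  prof <- make_profile(list(c(120, 139, 1)), len = 156, kind = "pre",
                       family = "pre-Arg-CTC-2-1.1",
                       body_start = 41, body_end = 116)
  res <- name_primary(fam, prof)
  expect_equal(res$full_name, "pre-Arg-CTC-2-1.1-tRF-1")
})
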