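toy_family <- function(seq = "ACGTACGTACGT", kind = "mature",
                       name = "Toy-AAA-1-1") {
  make_family(name = name, kind = kind, sequence = seq)
}

test_that("find_placements handles exact, mismatch and deletion windows", {
  fam <- toy_family()

  exact <- find_placements("GTACG", fam, "EXACT_MATURE")
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$ref_start, 3L)
  expect_equal(exact$ref_span, 5L)
  expect_equal(exact$n_mm + exact$n_del, 0L)

  mm <- find_placements("GTTCG", fam, "MM1")
  expect_equal(mm$ref_start, 3L)
  expect_equal(mm$mismatch_positions[[1]], 5L)

  del <- find_placements("GTAGT", fam, "DEL1")
  expect_equal(del$ref_start, 3L)
  expect_equal(del$ref_span, 6L)
  expect_equal(del$deletion_positions[[1]], 6L)

  # ref_span always equals read length + number of deletions
  expect_equal(del$ref_span, nchar("GTAGT") + del$n_del)

  # no placement -> empty tibble, not an error
  expect_equal(nrow(find_placements("TTTTTTTT", fam, "EXACT_MATURE")), 0L)

  # stage/kind mismatch is caught
  expect_error(find_placements("GTACG", fam, "EXACT_PRE"), "pre families")
})

test_that("DEL3 requires the three deleted bases to be contiguous", {
  fam <- toy_family("AACCGGTTAACCGGTT")
  # read = window 1..16 minus positions 5,6,7 (contiguous "GGT")
  read <- "AACCTAACCGGTT"
  hit <- find_placements(read, fam, "DEL3")
  expect_equal(hit$n_del, 3L)
  expect_equal(diff(hit$deletion_positions[[1]]), c(1L, 1L))
  # read formed by three scattered deletions of a window is not a DEL3 hit
  ref2 <- "ACGTACGTACGTACGTAC"
  scattered <- paste(strsplit(ref2, "")[[1]][-c(3, 8, 13)], collapse = "")
  fam2 <- toy_family(ref2)
  expect_equal(nrow(find_placements(scattered, fam2, "DEL3")), 0L)
})

test_that("the hierarchy assigns each read to its first matching stage", {
  set.seed(20)
  body <- rand_dna(72)
  gene <- make_gene("h1", "Gly", "GCC", 1, 1, body_sequence = body)
  mat <- build_mature_library(gene)
  pre <- build_pre_library(gene)

  exact_read <- substr(mat$sequence, 5, 28)          # in body: matches both libs
  leader_read <- substr(pre$sequence, 10, 30)        # flank-only: pre exact
  ur <- tibble::tibble(sequence = c(exact_read, leader_read), count = c(100L, 100L))
  asn <- run_hierarchy(ur, mat, pre)
  expect_equal(asn$stage[asn$sequence == exact_read], "EXACT_MATURE")
  expect_equal(asn$stage[asn$sequence == leader_read], "EXACT_PRE")
})

test_that("MM1 precedes DEL1: the deletion-only family gets no placement", {
  # family A holds the read at Hamming distance 1; family B holds it at one
  # deletion; the read must land at MM1 with a placement in A only
  read <- "ACGTTGCAGGTCAT"
  chars <- strsplit(read, "")[[1]]
  mmw <- chars; mmw[7] <- "T"                       # A-window: 1 mismatch
  delw <- append(chars, "G", after = 6)             # B-window: 1 extra ref base
  famA <- toy_family(paste0("TT", paste(mmw, collapse = ""), "TT"), name = "A-AAA-1-1")
  famB <- toy_family(paste0("GG", paste(delw, collapse = ""), "GG"), name = "B-AAA-1-1")
  asn <- run_hierarchy(tibble::tibble(sequence = read, count = 100L),
                       dplyr::bind_rows(famA, famB), NULL)
  expect_equal(asn$stage, "MM1")
  expect_equal(asn$family, "A-AAA-1-1")
})

test_that("every mapped read has exactly one stage and unmapped reads are recorded", {
  set.seed(21)
  spec <- sim_spec(n_families = 2, seed = 22,
                   tdrs = tibble::tibble(
                     family = c(1, 2), kind = "mature", start = c(1, 10),
                     end = c(30, 29), count = c(200, 150),
                     error = c("none", "mm1"), error_pos = c(NA, 20)))
  genes <- sim_reference(spec)
  sim <- sim_reads(genes, spec)
  ur <- dplyr::bind_rows(
    dplyr::select(sim$reads, sequence, count),
    tibble::tibble(sequence = "TTTTTTTTTTTTTTTTTTTT", count = 120L)
  )
  asn <- run_hierarchy(ur, build_mature_library(genes), build_pre_library(genes))
  per_read <- asn |> dplyr::distinct(sequence, stage) |> dplyr::count(sequence)
  expect_true(all(per_read$n == 1L))
  expect_true("UNMAPPED" %in% asn$stage)
})

test_that("assignments are invariant under read order", {
  set.seed(23)
  spec <- sim_spec(n_families = 2, seed = 24,
                   tdrs = tibble::tibble(
                     family = c(1, 1, 2), kind = "mature",
                     start = c(1, 4, 8), end = c(28, 24, 30),
                     count = c(100, 120, 140),
                     error = c("none", "del1", "mm2"), error_pos = c(NA, 12, 15)))
  genes <- sim_reference(spec)
  sim <- sim_reads(genes, spec)
  ur <- dplyr::select(sim$reads, sequence, count)
  mat <- build_mature_library(genes); pre <- build_pre_library(genes)
  a1 <- run_hierarchy(ur, mat, pre) |> dplyr::arrange(sequence, family)
  a2 <- run_hierarchy(ur[rev(seq_len(nrow(ur))), ], mat, pre) |>
    dplyr::arrange(sequence, family)
  expect_equal(a1, a2)
})

test_that("adding later stages never decreases the number of mapped reads", {
  set.seed(25)
  spec <- sim_spec(n_families = 2, seed = 26,
                   tdrs = tibble::tibble(
                     family = c(1, 1, 2, 2), kind = "mature",
                     start = c(1, 5, 3, 12), end = c(28, 26, 30, 34),
                     count = 100,
                     error = c("none", "mm1", "del2", "del3"),
                     error_pos = c(NA, 10, 10, 20)))
  genes <- sim_reference(spec)
  sim <- sim_reads(genes, spec)
  ur <- dplyr::select(sim$reads, sequence, count)
  mat <- build_mature_library(genes); pre <- build_pre_library(genes)
  order_full <- tdr_stage_order()
  mapped_n <- function(stages) {
    asn <- run_hierarchy(ur, mat, pre, stages = stages)
    total_mapped_reads(asn)
  }
  counts <- vapply(seq_along(order_full),
                   function(k) mapped_n(order_full[1:k]), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], sum(ur$count))
})

test_that("the hierarchy agrees with the brute-force oracle on generated cases", {
  set.seed(30)
  genes <- dplyr::bind_rows(
    make_gene("o1", "Gly", "GCC", 1, 1, body_len = 40),
    make_gene("o2", "Glu", "CTC", 2, 1, body_len = 40)
  )
  mat <- build_mature_library(genes)
  pre <- build_pre_library(genes)
  reads <- oracle_read_set(120, mat, pre, seed = 31)
  expect_equal(oracle_disagreements(reads, mat, pre), character(0))
})
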