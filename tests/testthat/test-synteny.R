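mk_aln <- function(q_start, q_end, t_start, t_end, strand = "+",
                   query = "q1", target = "chr1") {
  tibble::tibble(query = query, q_len = 1e7, q_start = q_start, q_end = q_end,
                 strand = strand, target = target, t_len = 1e8,
                 t_start = t_start, t_end = t_end,
                 matches = q_end - q_start + 1,
                 aln_len = q_end - q_start + 1, mapq = 60)
}

mk_block <- function(id, query, target, t_start, t_end, q_start, q_end,
                     strand = "+") {
  tibble::tibble(block_id = id, query = query, q_start = q_start,
                 q_end = q_end, target = target, t_start = t_start,
                 t_end = t_end, strand = strand, n_records = 1L,
                 aligned_bases = q_end - q_start + 1)
}

test_that("collinear records chain into one block; mixed targets never merge", {
  a <- dplyr::bind_rows(
    mk_aln(1, 5000, 100, 5099, target = "chr4"),
    mk_aln(6000, 11000, 6100, 11100, target = "chr4"),
    mk_aln(12000, 17000, 12100, 17100, target = "chr4"))
  b <- chain_blocks(a, max_join_gap = 1e5, min_block = 100)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_records, 3)
  expect_equal(b$aligned_bases, sum(a$matches))

  alt <- dplyr::bind_rows(
    mk_aln(1, 5000, 100, 5099, target = "chr4"),
    mk_aln(6000, 11000, 6100, 11100, target = "chr8"),
    mk_aln(12000, 17000, 12100, 17100, target = "chr4"),
    mk_aln(18000, 23000, 18100, 23100, target = "chr8"))
  b2 <- chain_blocks(alt, max_join_gap = 1e5, min_block = 100)
  expect_gte(nrow(b2), 2)
  expect_true(all(purrr::map_lgl(seq_len(nrow(b2)), function(i) {
    length(unique(b2$target[i])) == 1
  })))
})

test_that("gaps beyond max_join_gap split chains", {
  a <- dplyr::bind_rows(
    mk_aln(1, 5000, 100, 5099),
    mk_aln(200000, 205000, 200100, 205099))
  b <- chain_blocks(a, max_join_gap = 5e4, min_block = 100)
  expect_equal(nrow(b), 2)
})

test_that("chaining score equals the exhaustive best-chain oracle", {
  set.seed(50)
  for (i in 1:20) {
    rec <- random_chain_group(sample(4:9, 1), max_gap = 1000)
    b <- chain_blocks(rec, max_join_gap = 1000, min_block = 1)
    oracle <- best_chain_oracle(rec, max_join_gap = 1000)
    expect_equal(max(b$aligned_bases), oracle, info = paste("case", i))
  }
})

test_that("PAF round trip converts between 0-based and 1-based coordinates", {
  a <- mk_aln(101, 200, 1001, 1100)
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(a, f)
  raw <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(raw[3]), 100) # 0-based start on disk
  r <- read_paf(f)
  expect_equal(r$q_start, a$q_start)
  expect_equal(r$t_end, a$t_end)
})

test_that("join classification follows chromosome-majority and U rules", {
  joins <- tibble::tibble(
    output_scaffold = "o1", n_members = 2L,
    members = list(tibble::tibble(input_scaffold = c("m1", "m2"),
                                  orientation = "+", out_start = c(1L, 2000L),
                                  out_end = c(1500L, 3500L))),
    gap_between = list(tibble::tibble()))
  same_blocks <- dplyr::bind_rows(
    mk_block(1, "m1", "chr4", 1, 1000, 1, 1000),
    mk_block(2, "m2", "chr4", 5000, 6000, 1, 1000))
  expect_equal(classify_joins(joins, same_blocks)$verdict, "same")

  diff_blocks <- dplyr::bind_rows(
    mk_block(1, "m1", "chr4", 1, 1000, 1, 1000),
    mk_block(2, "m2", "chr8", 5000, 6000, 1, 1000))
  expect_equal(classify_joins(joins, diff_blocks)$verdict, "different")

  u_blocks <- dplyr::bind_rows(
    mk_block(1, "m1", "chr4", 1, 1000, 1, 1000),
    mk_block(2, "m2", "U", 5000, 6000, 1, 1000))
  expect_equal(classify_joins(joins, u_blocks)$verdict, "unknown")

  # no blocks at all for one member -> unassigned -> unknown
  expect_equal(classify_joins(joins, same_blocks[1, ])$verdict, "unknown")

  # order/strand invariance: reversing members does not change the verdict
  joins_rev <- joins
  joins_rev$members[[1]] <- joins$members[[1]][2:1, ]
  joins_rev$members[[1]]$orientation <- c("-", "-")
  expect_equal(classify_joins(joins_rev, diff_blocks)$verdict, "different")
})

test_that("majority fraction controls chromosome assignment", {
  blocks <- dplyr::bind_rows(
    mk_block(1, "m1", "chr4", 1, 600, 1, 600),
    mk_block(2, "m1", "chr8", 1000, 1400, 700, 1100))
  joins <- tibble::tibble(
    output_scaffold = "o1", n_members = 2L,
    members = list(tibble::tibble(input_scaffold = c("m1", "m2"),
                                  orientation = "+", out_start = c(1L, 5000L),
                                  out_end = c(1200L, 6000L))),
    gap_between = list(tibble::tibble()))
  blocks2 <- dplyr::bind_rows(blocks, mk_block(3, "m2", "chr4", 1, 500, 1, 500))
  # m1: 600 of 1000 bases on chr4 -> chr4 at the default 0.5 threshold
  expect_equal(classify_joins(joins, blocks2)$verdict, "same")
  # at a 0.7 threshold m1 is unassigned
  expect_equal(classify_joins(joins, blocks2, majority_fraction = 0.7)$verdict,
               "unknown")
})

test_that("validation rates and stratum differences use two-decimal percentages", {
  v <- tibble::tibble(
    output_scaffold = sprintf("o%02d", 1:14),
    verdict = c(rep("same", 11), rep("different", 3)),
    members = purrr::map(1:14, ~ tibble::tibble(input_scaffold = c("x", "y"))))
  supported <- sprintf("o%02d", c(1:10, 12))
  r <- validation_rates(v, support = supported)
  expect_equal(r$same_rate_all, 78.57)
  expect_equal(r$same_rate_supported, 90.91)
  expect_equal(r$supported_minus_all, 12.34)

  v2 <- tibble::tibble(
    output_scaffold = sprintf("d%02d", 1:48),
    verdict = c(rep("same", 45), rep("different", 3)),
    members = purrr::map(1:48, ~ tibble::tibble(input_scaffold = c("x", "y"))))
  supported2 <- sprintf("d%02d", c(1:33, 46, 47))
  r2 <- validation_rates(v2, support = supported2)
  expect_equal(r2$same_rate_all, 93.75)
  expect_equal(r2$same_rate_supported, 94.29)
  expect_equal(r2$supported_minus_all, 0.54)

  all_same <- dplyr::mutate(v, verdict = "same")
  r3 <- validation_rates(all_same, support = supported)
  expect_equal(r3$same_rate_all, 100)
  expect_equal(r3$supported_minus_all, 0)
})

test_that("breakpoints are the reference intervals between flanking blocks", {
  blocks <- dplyr::bind_rows(
    mk_block(1, "scf005", "chr4", 1e6, 39021787, 1, 38021788),
    mk_block(2, "scf005", "chr8", 34003973, 40000000, 38030000, 44026027),
    mk_block(3, "scf002", "chr4", 39021892, 45000000, 1, 5978109),
    mk_block(4, "scf015", "chr8", 30000000, 33996307, 1, 3996308))
  bp <- find_breakpoints(blocks)
  b4 <- bp[bp$chromosome == "chr4", ]
  expect_equal(b4$start, 39021788)
  expect_equal(b4$end, 39021891)
  expect_equal(b4$length, 104)
  b8 <- bp[bp$chromosome == "chr8", ]
  expect_equal(b8$start, 33996308)
  expect_equal(b8$end, 34003972)
  expect_equal(b8$length, 7665)
  expect_true(all(bp$length == bp$end - bp$start + 1))
  expect_true(all(bp$length >= 1))
})

test_that("collinear same-chromosome blocks yield no breakpoint", {
  blocks <- dplyr::bind_rows(
    mk_block(1, "q", "chr1", 1, 1000, 1, 1000),
    mk_block(2, "q", "chr1", 1500, 2500, 1100, 2100))
  expect_equal(nrow(find_breakpoints(blocks)), 0)
})
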