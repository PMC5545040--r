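test_that("nxx reproduces worked examples and the adjusted variant", {
  expect_equal(nxx(c(10, 10, 10), 50), 10)
  expect_equal(nxx(c(8, 5, 4, 3), 50), 5)
  expect_equal(nxx(c(8, 5, 4, 3), 50, genome_size = 26), 5)
  expect_equal(nxx(c(8, 5, 4, 3), 50, genome_size = 28), 4)
  # unreachable coverage gives 0 (adjusted N50 of a too-small assembly)
  expect_equal(nxx(c(5, 5), 50, genome_size = 1000), 0)
  expect_error(nxx(numeric(0)))
  expect_error(nxx(c(5, -1)))
})

test_that("nxx agrees with the brute-force oracle across x and genome sizes", {
  set.seed(42)
  for (i in 1:100) {
    l <- sample(1:5000, sample(1:50, 1), replace = TRUE)
    x <- sample(c(10, 50, 90), 1)
    expect_equal(nxx(l, x), nxx_oracle(l, x))
    gs <- round(sum(l) * runif(1, 0.5, 2))
    expect_equal(nxx(l, x, genome_size = gs), nxx_oracle(l, x, gs))
  }
})

test_that("nxx is monotone in genome size and in x", {
  set.seed(43)
  for (i in 1:20) {
    l <- sample(1:5000, 30, replace = TRUE)
    expect_gte(nxx(l, 50, genome_size = sum(l)), nxx(l, 50, genome_size = 2 * sum(l)))
    expect_gte(nxx(l, 10), nxx(l, 50))
    expect_gte(nxx(l, 50), nxx(l, 90))
  }
})

test_that("gap_stats summarises counts, extremes, mean and N50", {
  g <- tibble::tibble(length = rep(100, 116))
  s <- gap_stats(g)
  expect_equal(s$total_gap_length, 11600)
  expect_equal(s$mean_gap, 100)
  expect_equal(s$gap_n50, 100)
  g2 <- tibble::tibble(length = c(500, 647836))
  expect_equal(gap_stats(g2)$max_gap, 647836)
  e <- gap_stats(tibble::tibble(length = numeric(0)))
  expect_equal(e$n_gaps, 0)
  expect_equal(e$total_gap_length, 0)
  expect_true(is.na(e$mean_gap))
})

test_that("assembly_stats satisfies its internal identities", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  st <- assembly_stats(sc$assembly)
  expect_equal(st$scaffold_length, st$contig_length + st$total_gap_length)
  expect_gte(st$scaffold_n10, st$scaffold_n50)
  expect_gte(st$scaffold_n50, st$scaffold_n90)
  expect_gte(st$max_scaffold, st$scaffold_n10)
  # adjusted N50 with the true total equals the classical N50
  st2 <- assembly_stats(sc$assembly, adjust_size = st$scaffold_length)
  expect_equal(st2$adjusted_scaffold_n50, st$scaffold_n50)
})

test_that("percent rounding is half-away-from-zero at two decimals", {
  expect_equal(pct(415, 522), 79.50)
  expect_equal(pct_change(3768504, 5925378), 57.23)
  expect_equal(round_half_away(0.005, 2), 0.01)
  expect_equal(round_half_away(-0.005, 2), -0.01)
})

test_that("gapfill_delta counts exactly the planted filled gaps", {
  set.seed(77)
  mk <- function(n_gaps, fill_idx) {
    ctgs <- replicate(n_gaps + 1, random_dna(round(runif(1, 1500, 4000))))
    gaps <- pmax(100L, as.integer(round(rlnorm(n_gaps, log(300), 0.4))))
    before <- ctgs[1]; after <- ctgs[1]
    for (i in seq_len(n_gaps)) {
      before <- paste0(before, strrep("N", gaps[i]), ctgs[i + 1])
      mid <- if (i %in% fill_idx) random_dna(gaps[i] + sample(-50:50, 1))
             else strrep("N", gaps[i])
      after <- paste0(after, mid, ctgs[i + 1])
    }
    list(before = before, after = after)
  }
  planted <- 0L
  parts <- lapply(1:5, function(s) {
    k <- sample(0:4, 1)
    planted <<- planted + k
    mk(4, sample(4, k))
  })
  before <- tibble::tibble(scaffold = paste0("s", 1:5),
                           sequence = sapply(parts, `[[`, "before"))
  after <- tibble::tibble(scaffold = paste0("s", 1:5),
                          sequence = sapply(parts, `[[`, "after"))
  d <- gapfill_delta(before, after)
  expect_equal(d$gaps_filled, planted)
  expect_equal(d$n_gaps_before, 20)
  expect_equal(d$pct_filled, pct(planted, 20))
})

test_that("gapfill_delta on identical assemblies reports nothing filled", {
  a <- assembly(s1 = paste0(random_dna(1000), strrep("N", 200),
                            random_dna(1000)))
  d <- gapfill_delta(a, a)
  expect_equal(d$gaps_filled, 0)
  expect_equal(d$pct_filled, 0)
  expect_error(gapfill_delta(a, assembly(zz = "ACGT")), "missing")
})

test_that("scaffold_reduction reports the count delta", {
  b <- tibble::tibble(scaffold = paste0("s", 1:12),
                      sequence = replicate(12, random_dna(30)))
  a <- b[1:9, ]
  r <- scaffold_reduction(b, a)
  expect_equal(r$reduction, 3)
})
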