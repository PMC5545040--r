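test_that("flank enrichment handles degenerate and error inputs", {
  set.seed(70)
  a <- assembly(s1 = random_dna(20000))
  events <- tibble::tibble(scaffold = "s1", start = 10000L, end = 10099L)
  # no repeat annotation at all
  expect_error(flank_repeat_enrichment(a, events, softmask = FALSE),
               "repeat annotation")
  # no events
  rep_tbl <- tibble::tibble(scaffold = "s1", start = 1L, end = 20000L)
  expect_error(flank_repeat_enrichment(a, events[0, ], repeats = rep_tbl),
               "no events")
  # repeats covering everything: ratio 1, p near 1
  fe <- flank_repeat_enrichment(a, events, repeats = rep_tbl, flank = 2000,
                                n_perm = 99, seed = 1, softmask = FALSE)
  expect_equal(fe$summary$enrichment_ratio, 1)
  expect_gt(fe$summary$p_value, 0.5)
})

test_that("flanks are truncated at scaffold ends and exclude gap bases", {
  set.seed(71)
  a <- assembly(s1 = paste0(random_dna(3000), strrep("N", 500),
                            random_dna(3000)))
  rep_tbl <- tibble::tibble(scaffold = "s1", start = 1L, end = 1000L)
  events <- tibble::tibble(scaffold = "s1", start = 3001L, end = 3500L)
  fe <- flank_repeat_enrichment(a, events, repeats = rep_tbl, flank = 5000,
                                n_perm = 49, seed = 2, softmask = FALSE)
  # left flank truncated to [1,3000]: 1000 repeat of 3000 sequence bases;
  # right flank [3501,6500] has none; gap bases never counted
  expect_equal(fe$summary$flank_repeat_fraction, 1000 / 6000)
})

test_that("softmask runs count as repeat annotation", {
  set.seed(72)
  up <- random_dna(8000)
  masked <- paste0(substr(up, 1, 2000), tolower(substr(up, 2001, 4000)),
                   substr(up, 4001, 8000))
  a <- tibble::tibble(scaffold = "s1", sequence = masked)
  events <- tibble::tibble(scaffold = "s1", start = 3000L, end = 3001L)
  fe <- flank_repeat_enrichment(a, events, flank = 500, n_perm = 49, seed = 3)
  expect_equal(fe$summary$flank_repeat_fraction, 1) # flank inside masked run
  expect_equal(fe$summary$background_repeat_fraction, 0.25)
})

test_that("permutation p-values are reproducible bit-exactly under a seed", {
  set.seed(73)
  a <- assembly(s1 = random_dna(50000))
  starts <- seq(1L, 45000L, by = 5000L)
  rep_tbl <- tibble::tibble(scaffold = "s1", start = starts,
                            end = starts + 999L)
  events <- tibble::tibble(scaffold = "s1",
                           start = c(2000L, 12000L, 30000L),
                           end = c(2099L, 12099L, 30099L))
  f1 <- flank_repeat_enrichment(a, events, repeats = rep_tbl, flank = 1000,
                                n_perm = 199, seed = 99, softmask = FALSE)
  f2 <- flank_repeat_enrichment(a, events, repeats = rep_tbl, flank = 1000,
                                n_perm = 199, seed = 99, softmask = FALSE)
  expect_identical(f1$summary$p_value, f2$summary$p_value)
  expect_identical(f1$null, f2$null)
})

test_that("tidy, glance and autoplot expose the enrichment report", {
  set.seed(74)
  a <- assembly(s1 = random_dna(30000))
  rep_tbl <- tibble::tibble(scaffold = "s1", start = 1L, end = 10000L)
  events <- tibble::tibble(scaffold = "s1", start = c(5000L, 20000L),
                           end = c(5099L, 20099L))
  fe <- flank_repeat_enrichment(a, events, repeats = rep_tbl, flank = 1000,
                                n_perm = 49, seed = 4, softmask = FALSE)
  td <- tidy(fe)
  expect_equal(nrow(td), 2)
  expect_true("flank_repeat_fraction" %in% names(td))
  gl <- glance(fe)
  expect_equal(gl$n_events, 2)
  expect_true(gl$p_value > 0 && gl$p_value <= 1)
  expect_s3_class(autoplot(fe), "ggplot")
})

test_that("gaps planted inside long repeats give strong enrichment", {
  set.seed(75)
  cfg <- sim_config(genome_size = 3e6, n_chromosomes = 2, mean_contig = 6e4,
                    repeat_unit = 12000L, repeat_weight = 50,
                    drop_prob = 0.5, drop_len_mean = 2e3,
                    drop_len_sdlog = 0.5,
                    inversion = list(offset = 5e4, length = 3e4),
                    novel_donor = 2e4, novel_acceptor = 1e4,
                    n_chimeras = 0, seed = 75)
  ref <- simulate_reference(cfg)
  acc <- simulate_accession(ref, cfg)
  frag <- fragment_assembly(acc, cfg)
  sc <- simulate_scaffolding(frag, technology_profile("proximity"))
  gaps <- detect_gaps(sc$assembly, origin = "proximity")
  rep_lift <- scaffeval:::lift_gap_repeats(sc, acc)
  fe <- flank_repeat_enrichment(sc$assembly, gaps, repeats = rep_lift,
                                flank = 5000, n_perm = 999, seed = 75,
                                softmask = FALSE)
  expect_gt(fe$summary$enrichment_ratio, 1)
  expect_lte(fe$summary$p_value, 0.01)
})
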