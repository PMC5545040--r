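test_that("placements recover simple concatenation joins and orientation", {
  set.seed(9)
  s1 <- random_dna(3000); s2 <- random_dna(2500)
  input <- assembly(s1 = s1, s2 = s2)
  out_fwd <- assembly(o1 = paste0(s1, strrep("N", 100), s2))
  pl <- place_inputs(input, out_fwd)
  expect_equal(sort(pl$input_scaffold), c("s1", "s2"))
  expect_equal(unique(pl$output_scaffold), "o1")
  expect_equal(pl$strand, c("+", "+"))

  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  out_rev <- assembly(o1 = paste0(s1, strrep("N", 100), rc(s2)))
  pl2 <- place_inputs(input, out_rev)
  expect_equal(pl2$strand[pl2$input_scaffold == "s2"], "-")
})

test_that("unrelated assemblies raise an error", {
  set.seed(10)
  expect_error(place_inputs(assembly(a = random_dna(2000)),
                            assembly(b = random_dna(2000))),
               "unrelated")
})

test_that("joins and breaks are called exactly on a simulated round", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("proximity"))
  pl <- place_inputs(sim$frag$assembly, sc$assembly)
  gaps <- detect_gaps(sc$assembly, origin = "proximity")
  joins <- call_joins(pl, gaps)

  expect_setequal(called_pairs(joins), truth_pairs(sc$truth$joins))

  br <- call_breaks(pl, detect_gaps(sim$frag$assembly))
  expect_equal(nrow(br), nrow(sc$truth$breaks))
  m <- match(br$input_scaffold, sc$truth$breaks$input_scaffold)
  expect_false(anyNA(m))
  expect_true(all(abs(br$position - sc$truth$breaks$position[m]) <= 64))
})

test_that("join events order members by output coordinate with one gap per junction", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  pl <- place_inputs(sim$frag$assembly, sc$assembly)
  gaps <- detect_gaps(sc$assembly, origin = "opticalmap")
  joins <- call_joins(pl, gaps)
  expect_true(all(joins$n_members >= 2))
  for (i in seq_len(nrow(joins))) {
    mem <- joins$members[[i]]
    expect_true(all(diff(mem$out_start) > 0))
    expect_equal(nrow(joins$gap_between[[i]]), nrow(mem) - 1)
  }
  js <- join_summary(joins)
  expect_equal(js$scaffolds_per_join, js$n_inputs_joined / js$n_join_events)
})

test_that("pass-through assemblies produce no joins and no breaks", {
  sim <- small_sim()
  base <- sim$frag$assembly
  pl <- place_inputs(base, base)
  expect_equal(nrow(call_joins(pl, NULL)), 0)
  expect_equal(nrow(call_breaks(pl)), 0)
  # conservation: every placement is an identity span
  expect_true(all(pl$input_scaffold == pl$output_scaffold))
})

test_that("join/break calls are invariant to renaming and reordering inputs", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  base <- sim$frag$assembly
  pl <- place_inputs(base, sc$assembly)
  joins <- call_joins(pl, NULL)

  perm <- sample(nrow(base))
  renamed <- base[perm, ]
  map <- setNames(sprintf("x%04d", seq_len(nrow(base))), renamed$scaffold)
  renamed$scaffold <- unname(map[renamed$scaffold])
  pl2 <- place_inputs(renamed, sc$assembly)
  joins2 <- call_joins(pl2, NULL)
  back <- setNames(names(map), map)
  pairs2 <- called_pairs(joins2)
  pairs2_orig <- vapply(strsplit(pairs2, " "), function(p) {
    q <- sort(unname(back[p])); paste(q[1], q[2])
  }, character(1))
  expect_setequal(pairs2_orig, called_pairs(joins))
})

test_that("size classes match a direct filter of joined scaffold lengths", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("proximity"))
  pl <- place_inputs(sim$frag$assembly, sc$assembly)
  joins <- call_joins(pl, NULL)
  cls <- join_size_classes(joins, sim$frag$assembly,
                           cutoffs = c(1e5, 1e6))
  joined <- unique(unlist(purrr::map(joins$members, "input_scaffold")))
  lens <- nchar(sim$frag$assembly$sequence)[match(joined, sim$frag$assembly$scaffold)]
  expect_equal(cls$n[cls$class == "all"], length(joined))
  expect_equal(cls$n[cls$class == "lt_100000"], sum(lens < 1e5))
  expect_equal(cls$n[cls$class == "ge_100000_cum"], sum(lens >= 1e5))
  expect_equal(cls$n[cls$class == "ge_1000000_cum"], sum(lens >= 1e6))
  expect_equal(cls$min_scaffold[cls$class == "all"], min(lens))
})

test_that("empty join set yields zero-filled size classes", {
  joins <- call_joins(tibble::tibble(
    input_scaffold = "a", in_start = 1L, in_end = 10L,
    output_scaffold = "a", out_start = 1L, out_end = 10L,
    strand = "+", n_anchors = 3L), NULL)
  cls <- join_size_classes(joins, assembly(a = random_dna(100)))
  expect_true(all(cls$n == 0))
})

test_that("join-set comparison finds shared unordered adjacent pairs", {
  mk_joins <- function(pairs) {
    tibble::tibble(
      output_scaffold = paste0("o", seq_along(pairs)),
      n_members = 2L,
      members = purrr::map(pairs, ~ tibble::tibble(
        input_scaffold = .x, orientation = "+",
        out_start = c(1L, 1000L), out_end = c(900L, 1900L))),
      gap_between = purrr::map(pairs, ~ tibble::tibble())
    )
  }
  a <- mk_joins(list(c("s1", "s2"), c("s3", "s4")))
  b <- mk_joins(list(c("s2", "s1"), c("s5", "s6")))
  cmp <- compare_join_sets(a, b)
  sm <- attr(cmp, "summary")
  expect_equal(sm$n_shared_pairs, 1)
  expect_equal(sm$n_unique_a, 1)
  expect_equal(sm$n_unique_b, 1)
  shared <- cmp[cmp$shared, ]
  expect_equal(c(shared$input_1, shared$input_2), c("s1", "s2"))

  # identical sets: no unique joins
  cmp2 <- compare_join_sets(a, a)
  expect_equal(attr(cmp2, "summary")$n_unique_a, 0)
  expect_equal(attr(cmp2, "summary")$n_unique_b, 0)

  # symmetry up to swapping the unique sides
  cmp_ba <- compare_join_sets(b, a)
  expect_equal(attr(cmp_ba, "summary")$n_unique_a,
               attr(cmp, "summary")$n_unique_b)
  expect_equal(attr(cmp_ba, "summary")$n_shared_pairs, sm$n_shared_pairs)
})

test_that("shared input-scaffold count matches co-membership of both join sets", {
  sim <- small_sim()
  sc1 <- simulate_scaffolding(sim$frag, technology_profile("proximity"))
  sc2 <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  pl1 <- place_inputs(sim$frag$assembly, sc1$assembly)
  pl2 <- place_inputs(sim$frag$assembly, sc2$assembly)
  j1 <- call_joins(pl1, NULL); j2 <- call_joins(pl2, NULL)
  cmp <- compare_join_sets(j1, j2)
  m1 <- unique(unlist(purrr::map(j1$members, "input_scaffold")))
  m2 <- unique(unlist(purrr::map(j2$members, "input_scaffold")))
  expect_equal(attr(cmp, "summary")$n_shared_inputs,
               length(intersect(m1, m2)))
})
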