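test_that("reference simulation hits the configured repeat fraction", {
  cfg <- sim_config(genome_size = 1e7, n_chromosomes = 2, seed = 5)
  set.seed(5)
  ref <- simulate_reference(cfg)
  frac <- sum(ref$repeats$end - ref$repeats$start + 1) /
    sum(nchar(ref$genome$sequence))
  expect_lt(abs(frac - 0.25), 0.02)

  cfg0 <- sim_config(genome_size = 1e6, n_chromosomes = 2,
                     repeat_fraction = 0, seed = 6)
  set.seed(6)
  ref0 <- simulate_reference(cfg0)
  expect_equal(nrow(ref0$repeats), 0)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_config()
  set.seed(cfg$seed); r1 <- simulate_reference(cfg)
  set.seed(cfg$seed); r2 <- simulate_reference(cfg)
  expect_identical(r1$genome$sequence, r2$genome$sequence)
  expect_identical(r1$repeats, r2$repeats)
})

test_that("zero-divergence accession without rearrangement equals the reference", {
  cfg <- sim_config(genome_size = 1e6, n_chromosomes = 2, snp_rate = 0,
                    indel_rate = 0, translocation = NULL, seed = 7)
  set.seed(7)
  ref <- simulate_reference(cfg)
  acc <- simulate_accession(ref, cfg)
  expect_identical(unname(acc$genome$sequence), unname(ref$genome$sequence))
  expect_equal(nrow(acc$breakpoints), 0)
  expect_equal(nrow(acc$novel), 0)
})

test_that("accession truth tables are consistent with the emitted sequence", {
  sim <- small_sim()
  acc <- sim$acc
  # segment map tiles every accession chromosome
  for (ch in acc$genome$scaffold) {
    m <- acc$segment_map[acc$segment_map$acc_chrom == ch, ]
    expect_equal(min(m$acc_start), 1)
    expect_equal(max(m$acc_end), nchar(acc$genome$sequence[
      match(ch, acc$genome$scaffold)]))
    expect_true(all(m$acc_start[-1] == head(m$acc_end, -1) + 1))
  }
  # 4 planted breakpoints: 1 donor translocation + acceptor translocation +
  # two inversion edges
  expect_equal(nrow(acc$breakpoints), 4)
  expect_equal(sum(acc$breakpoints$kind == "translocation"), 2)
  # novel truth segments really are non-reference sequence
  expect_equal(nrow(acc$novel), 2)
  expect_equal(sum(acc$novel$length),
               sim$cfg$novel_donor + sim$cfg$novel_acceptor)
})

test_that("fragmentation provenance tiles the accession", {
  sim <- small_sim()
  prov <- sim$frag$provenance
  for (ch in unique(prov$acc_chrom)) {
    p <- prov[prov$acc_chrom == ch, ]
    p <- p[order(p$acc_start), ]
    expect_equal(p$acc_start[1], 1)
    expect_true(all(p$acc_start[-1] == head(p$acc_end, -1) + 1))
    expect_equal(max(p$acc_end), nchar(sim$acc$genome$sequence[
      match(ch, sim$acc$genome$scaffold)]))
  }
  # kept pieces reconstruct contig sequences (orientation-aware)
  seqs <- setNames(sim$frag$assembly$sequence, sim$frag$assembly$scaffold)
  kept <- prov[prov$kept & !is.na(prov$contig), ]
  one <- kept[sample.int(nrow(kept), 1), ]
  acc_seq <- substr(sim$acc$genome$sequence[
    match(one$acc_chrom, sim$acc$genome$scaffold)], one$acc_start, one$acc_end)
  stored <- substr(seqs[[one$contig]], one$contig_start, one$contig_end)
  if (one$strand == "-") {
    acc_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(acc_seq)))
  }
  expect_identical(stored, acc_seq)
})

test_that("unbiased breakage gives uniform cut positions", {
  cfg <- sim_config(genome_size = 5e6, n_chromosomes = 1, repeat_fraction = 0,
                    translocation = list(donor = 1L, acceptor = 1L,
                                         donor_frac = 0.5,
                                         acceptor_frac = 0.5),
                    mean_contig = 1e4, repeat_weight = 1, drop_prob = 0,
                    n_chimeras = 0, seed = 8)
  set.seed(8)
  ref <- simulate_reference(cfg)
  frag <- fragment_assembly(list(genome = ref$genome, repeats = ref$repeats),
                            cfg)
  len <- nchar(ref$genome$sequence)
  expect_equal(len, 5e6)
  cuts <- frag$provenance$acc_end
  cuts <- cuts[cuts < max(cuts)]
  ks <- suppressWarnings(stats::ks.test(cuts / len, "punif"))
  expect_gt(ks$p.value, 0.01)
  # piece count within Poisson-style bounds around genome_size / mean_contig
  n <- nrow(frag$provenance)
  expect_gt(n, 500 - 4 * sqrt(500))
  expect_lt(n, 500 + 4 * sqrt(500))
})

test_that("technology gap dialects are respected", {
  sim <- small_sim()
  sc_fix <- simulate_scaffolding(sim$frag, technology_profile("proximity"))
  if (nrow(sc_fix$truth$gaps) > 0) {
    expect_true(all(sc_fix$truth$gaps$length == 100))
  }
  sc_sized <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  if (nrow(sc_sized$truth$gaps) > 0) {
    expect_true(all(sc_sized$truth$gaps$length >= 500))
  }
  # emitted gaps agree with detect_gaps on the emitted sequence
  g <- detect_gaps(sc_sized$assembly)
  expect_equal(nrow(g), nrow(sc_sized$truth$gaps))
  expect_setequal(g$length, sc_sized$truth$gaps$length)
})

test_that("scaffolding only adds gap characters when chimeras are logged, not broken", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag, technology_profile("opticalmap"))
  base_contig_bases <- sum(nchar(sim$frag$assembly$sequence))
  out_contig_bases <- sum(detect_contigs(sc$assembly, min_contig = 1)$length)
  expect_equal(out_contig_bases, base_contig_bases)
  expect_equal(nrow(sc$truth$chimera_log), nrow(sim$frag$chimeras))
})

test_that("min_joinable excludes short scaffolds from joins", {
  sim <- small_sim()
  sc <- simulate_scaffolding(sim$frag,
                             technology_profile("opticalmap",
                                                min_joinable = 2e5))
  joined <- unique(sc$truth$joins$member)
  lens <- nchar(sim$frag$assembly$sequence)[
    match(sub("_p[12]$", "", joined), sim$frag$assembly$scaffold)]
  expect_true(all(lens >= 2e5 | grepl("_p", joined)))
})
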