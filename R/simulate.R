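# Ground-truth simulator: reference genome with interspersed and tandem
# repeats, a diverged accession carrying a reciprocal chromosome-arm
# translocation (plus an inversion and novel insertions near the junctions),
# a fragmented base assembly with repeat-biased breakage and planted
# chimeras, and scaffolded derivatives under configurable technology
# profiles. All functions draw from the current RNG stream; seed once (or via
# `run_pipeline()`) for byte-identical outputs.

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome (50 Mb over 4 chromosomes) with a
#' quarter of the genome repetitive, accession divergence of about 1% SNPs,
#' one reciprocal arm translocation with novel insertions at the junctions
#' and an inversion on the acceptor arm, and fragmentation into ~500 kb
#' contigs with breakage biased into repeats.
#'
#' @param genome_size total reference size in nt.
#' @param n_chromosomes number of chromosomes.
#' @param repeat_fraction target fraction of repetitive sequence.
#' @param repeat_unit interspersed repeat consensus length (nt).
#' @param repeat_divergence per-copy substitution rate of repeat copies.
#' @param tandem_unit,tandem_copies tandem array unit length and copy number.
#' @param tandem_share fraction of repeat insertions that are tandem arrays.
#' @param snp_rate,indel_rate accession divergence rates per nt.
#' @param translocation list: `donor`, `acceptor` chromosome indices and
#'   `donor_frac`, `acceptor_frac` arm positions (fractions of length).
#' @param inversion list: `offset`, `length` (nt) of the inversion planted on
#'   the acceptor arm downstream of the junction.
#' @param novel_donor,novel_acceptor lengths (nt) of the novel insertions
#'   placed at the two translocation junctions.
#' @param mean_contig mean fragment size (nt) of the base assembly.
#' @param repeat_weight relative breakage weight inside repeats (1 =
#'   unbiased).
#' @param drop_prob probability that a break loses sequence (an unassembled
#'   region) around the cut.
#' @param drop_len_mean median length (nt) of lost sequence at a dropping
#'   break.
#' @param drop_len_sdlog sdlog of the log-normal lost-sequence length; a
#'   broad value leaves some spans beyond a technology's `max_span`.
#' @param frag_min_keep fragments shorter than this are not assembled
#'   (dropped).
#' @param n_chimeras number of chimeric contigs planted in the base
#'   assembly.
#' @param flip_prob probability a base contig is stored reverse-complemented.
#' @param gene_spacing spacing (nt) of toy gene models.
#' @param seed integer seed recorded in the config (used by
#'   [run_pipeline()]).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 5e7, n_chromosomes = 4L,
                       repeat_fraction = 0.25, repeat_unit = 3000L,
                       repeat_divergence = 0.05, tandem_unit = 50L,
                       tandem_copies = 40L, tandem_share = 0.2,
                       snp_rate = 0.01, indel_rate = 5e-4,
                       translocation = list(donor = 1L, acceptor = 2L,
                                            donor_frac = 0.55,
                                            acceptor_frac = 0.55),
                       inversion = list(offset = 2e5, length = 1.5e5),
                       novel_donor = 1.25e5, novel_acceptor = 4.6e4,
                       mean_contig = 5e5, repeat_weight = 5,
                       drop_prob = 0.5, drop_len_mean = 5e4,
                       drop_len_sdlog = 1.3,
                       frag_min_keep = 1000L, n_chimeras = 8L,
                       flip_prob = 0.5, gene_spacing = 2e4, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$repeat_fraction >= 0, cfg$repeat_fraction < 1,
            cfg$snp_rate >= 0, cfg$snp_rate <= 1,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            cfg$genome_size > 0, cfg$mean_contig > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Technology profile for simulated scaffolding
#'
#' Two presets capture the contrast between an optical-map-like technology
#' (cannot use short scaffolds, spans very large gaps, emits sized gap
#' estimates with a 500 nt floor, only logs suspected chimeras) and a
#' proximity-ligation-like technology (joins scaffolds down to a few kb over
#' spans up to the input DNA length, emits fixed 100-N gaps, and breaks
#' chimeras automatically).
#'
#' @param name `"opticalmap"` or `"proximity"`, or any label when the other
#'   parameters are given explicitly.
#' @param min_joinable minimum scaffold length (nt) the technology can join.
#' @param max_span maximum bridgeable distance (nt).
#' @param gap_convention `"sized"` (estimated gap length with multiplicative
#'   error) or `"fixed_100N"`.
#' @param gap_size_error sdlog of the multiplicative gap-size error.
#' @param min_gap_emitted floor (nt) on emitted sized gaps.
#' @param chimera_break `"breaks"` (splits planted chimeras) or
#'   `"logs_only"` (reports them, leaves sequence intact).
#' @param join_error_rate fraction of spurious joins added.
#' @return a list of class `tech_profile`.
#' @export
technology_profile <- function(name = c("opticalmap", "proximity"),
                               min_joinable = NULL, max_span = NULL,
                               gap_convention = NULL, gap_size_error = NULL,
                               min_gap_emitted = NULL, chimera_break = NULL,
                               join_error_rate = 0) {
  preset <- switch(match.arg(name),
    opticalmap = list(min_joinable = 1e5, max_span = 6.5e5,
                      gap_convention = "sized", gap_size_error = 0.1,
                      min_gap_emitted = 500L, chimera_break = "logs_only"),
    proximity = list(min_joinable = 4500, max_span = 1e5,
                     gap_convention = "fixed_100N", gap_size_error = 0,
                     min_gap_emitted = 100L, chimera_break = "breaks")
  )
  p <- list(
    name = match.arg(name),
    min_joinable = min_joinable %||% preset$min_joinable,
    max_span = max_span %||% preset$max_span,
    gap_convention = gap_convention %||% preset$gap_convention,
    gap_size_error = gap_size_error %||% preset$gap_size_error,
    min_gap_emitted = min_gap_emitted %||% preset$min_gap_emitted,
    chimera_break = chimera_break %||% preset$chimera_break,
    join_error_rate = join_error_rate
  )
  stopifnot(p$min_joinable > 0, p$gap_convention %in% c("sized", "fixed_100N"),
            p$chimera_break %in% c("breaks", "logs_only"))
  class(p) <- "tech_profile"
  p
}

substitute_bases <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  r <- charToRaw(seq)
  idx <- sample.int(n, k)
  cur <- match(r[idx], DNA_RAW)
  cur[is.na(cur)] <- 1L
  r[idx] <- DNA_RAW[((cur - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
  rawToChar(r)
}

apply_indels <- function(seq, rate, max_len = 6L) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sort(sample.int(n - max_len, k))
  pos <- pos[c(TRUE, diff(pos) > max_len)]
  pieces <- character(0)
  prev <- 1L
  for (p in pos) {
    len <- sample.int(max_len, 1)
    if (runif(1) < 0.5) { # deletion
      pieces <- c(pieces, substr(seq, prev, p - 1L))
      prev <- p + len
    } else {             # insertion
      pieces <- c(pieces, substr(seq, prev, p), random_dna(len))
      prev <- p + 1L
    }
  }
  pieces <- c(pieces, substr(seq, prev, n))
  paste0(pieces, collapse = "")
}

#' Simulate a reference genome
#'
#' Chromosomes are built as alternating unique blocks and repeat insertions
#' (diverged interspersed copies and tandem arrays) hitting the configured
#' repeat fraction in expectation, with toy gene models at uniform spacing.
#'
#' @param config a [sim_config()].
#' @return list: `genome` (assembly tibble, chromosomes named `chr1`...),
#'   `repeats` (tibble `scaffold`, `start`, `end`, `family`), `genes` (GFF3
#'   style tibble with `gene` and `CDS` rows).
#' @export
simulate_reference <- function(config = sim_config()) {
  rf <- config$repeat_fraction
  chr_len <- round(config$genome_size / config$n_chromosomes)
  inter_cons <- random_dna(config$repeat_unit)
  tandem_cons <- random_dna(config$tandem_unit)
  mean_rep <- (1 - config$tandem_share) * config$repeat_unit +
    config$tandem_share * config$tandem_unit * config$tandem_copies
  mean_unique <- if (rf > 0) mean_rep * (1 - rf) / rf else chr_len

  chroms <- character(config$n_chromosomes)
  rep_rows <- list()
  gene_rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    pieces <- character(0)
    pos <- 0L
    while (pos < chr_len) {
      u <- if (rf == 0) chr_len - pos
           else as.integer(round(runif(1, 0.5, 1.5) * mean_unique))
      u <- min(u, chr_len - pos)
      if (u > 0) { pieces <- c(pieces, random_dna(u)); pos <- pos + u }
      if (pos >= chr_len || rf == 0) break
      if (runif(1) < config$tandem_share) {
        arr <- strrep(tandem_cons, config$tandem_copies)
        fam <- "tandem"
      } else {
        arr <- substitute_bases(inter_cons, config$repeat_divergence)
        fam <- "interspersed"
      }
      arr <- substr(arr, 1, chr_len - pos)
      if (nchar(arr) == 0) break
      rep_rows[[length(rep_rows) + 1L]] <-
        tibble(scaffold = chrom, start = pos + 1L,
               end = pos + nchar(arr), family = fam)
      pieces <- c(pieces, arr)
      pos <- pos + nchar(arr)
    }
    chroms[ci] <- paste0(pieces, collapse = "")
    # toy genes: uniform spacing, 1-5 CDS each
    gstarts <- seq(5000L, nchar(chroms[ci]) - 5000L, by = config$gene_spacing)
    for (gi in seq_along(gstarts)) {
      gid <- sprintf("%s.g%04d", chrom, gi)
      glen <- 3000L
      ncds <- sample.int(5L, 1)
      cds_st <- sort(sample.int(glen - 500L, ncds)) + gstarts[gi]
      cds_en <- cds_st + sample(150:450, ncds, replace = TRUE)
      cds_en <- pmin(cds_en, gstarts[gi] + glen)
      # drop overlapping CDS
      keep <- c(TRUE, cds_st[-1] > cds_en[-ncds])[seq_len(ncds)]
      gene_rows[[length(gene_rows) + 1L]] <- bind_rows(
        tibble(scaffold = chrom, type = "gene", start = gstarts[gi],
               end = gstarts[gi] + glen, strand = "+", ID = gid,
               Parent = NA_character_),
        tibble(scaffold = chrom, type = "CDS", start = cds_st[keep],
               end = cds_en[keep], strand = "+", ID = NA_character_,
               Parent = gid)
      )
    }
  }
  list(
    genome = tibble(scaffold = sprintf("chr%d", seq_len(config$n_chromosomes)),
                    sequence = chroms),
    repeats = if (length(rep_rows)) bind_rows(rep_rows) else
      tibble(scaffold = character(), start = integer(), end = integer(),
             family = character()),
    genes = bind_rows(gene_rows)
  )
}

# linear lift of a reference interval into a (possibly shrunken/stretched)
# accession segment; approximate under indels, exact without them
lift_linear <- function(pos, from_start, from_end, to_start, to_end,
                        reverse = FALSE) {
  if (from_end == from_start) return(to_start)
  f <- (pos - from_start) / (from_end - from_start)
  if (reverse) f <- 1 - f
  as.integer(round(to_start + f * (to_end - to_start)))
}

#' Simulate a diverged accession from a reference
#'
#' Applies a reciprocal arm translocation between the configured donor and
#' acceptor chromosomes, inserts novel sequence at both junctions, plants an
#' inversion on the acceptor-derived arm, and diverges all syntenic sequence
#' by the configured SNP and indel rates. The returned segment map records,
#' for every accession segment, its reference origin (or novel status), from
#' which perfect alignments, repeat liftover and all truth tables derive.
#'
#' @param reference output of [simulate_reference()].
#' @param config a [sim_config()].
#' @return list: `genome` (accession assembly, chromosomes named `acc_*`),
#'   `segment_map` (tibble `acc_chrom`, `acc_start`, `acc_end`, `ref_chrom`,
#'   `ref_start`, `ref_end`, `strand`, `class`), `breakpoints` (truth tibble
#'   `chromosome`, `position`, `kind` in reference coordinates), `novel`
#'   (truth tibble of novel segments in accession coordinates), `repeats`
#'   (lifted repeat annotation in accession coordinates), `genes` (lifted +
#'   novel-segment toy genes, with `novel` flag).
#' @export
simulate_accession <- function(reference, config = sim_config()) {
  ref <- reference$genome
  tr <- config$translocation
  if (is.null(tr)) {
    # no rearrangement: per-chromosome divergence only
    seg_def <- list()
    for (k in seq_len(nrow(ref))) {
      seg_def[[sprintf("acc_%d", k)]] <- tibble(
        ref_chrom = ref$scaffold[k], ref_start = 1L,
        ref_end = nchar(ref$sequence[k]), strand = "+",
        class = "syntenic", novel_len = NA)
    }
    return(build_accession(reference, config, seg_def,
                           breakpoints = tibble(chromosome = character(),
                                                position = integer(),
                                                kind = character())))
  }
  donor <- ref$scaffold[tr$donor]
  acceptor <- ref$scaffold[tr$acceptor]
  d_len <- nchar(ref$sequence[tr$donor])
  a_len <- nchar(ref$sequence[tr$acceptor])
  d_pos <- as.integer(round(tr$donor_frac * d_len))
  a_pos <- as.integer(round(tr$acceptor_frac * a_len))
  i1 <- a_pos + as.integer(config$inversion$offset)
  i2 <- i1 + as.integer(config$inversion$length) - 1L
  stopifnot(i2 < a_len)

  seg_def <- list()
  seg_def[["acc_1"]] <- tibble(
    ref_chrom = c(donor, NA, acceptor, acceptor, acceptor),
    ref_start = c(1L, NA, a_pos + 1L, i1, i2 + 1L),
    ref_end   = c(d_pos, NA, i1 - 1L, i2, a_len),
    strand    = c("+", NA, "+", "-", "+"),
    class     = c("syntenic", "novel", "syntenic", "syntenic", "syntenic"),
    novel_len = c(NA, config$novel_donor, NA, NA, NA)
  )
  seg_def[["acc_2"]] <- tibble(
    ref_chrom = c(acceptor, NA, donor),
    ref_start = c(1L, NA, d_pos + 1L),
    ref_end   = c(a_pos, NA, d_len),
    strand    = c("+", NA, "+"),
    class     = c("syntenic", "novel", "syntenic"),
    novel_len = c(NA, config$novel_acceptor, NA)
  )
  others <- setdiff(seq_len(nrow(ref)), c(tr$donor, tr$acceptor))
  for (k in seq_along(others)) {
    seg_def[[sprintf("acc_%d", k + 2L)]] <- tibble(
      ref_chrom = ref$scaffold[others[k]], ref_start = 1L,
      ref_end = nchar(ref$sequence[others[k]]), strand = "+",
      class = "syntenic", novel_len = NA)
  }

  build_accession(reference, config, seg_def, breakpoints = tibble(
    chromosome = c(donor, acceptor, acceptor, acceptor),
    position = c(d_pos, a_pos, i1 - 1L, i2),
    kind = c("translocation", "translocation", "inversion", "inversion")
  ))
}

# realise an accession genome from a segment definition list and derive all
# truth tables (segment map, novel segments, lifted repeats and genes)
build_accession <- function(reference, config, seg_def, breakpoints) {
  ref <- reference$genome
  acc_seqs <- character(0)
  map_rows <- list()
  for (acc in names(seg_def)) {
    defs <- seg_def[[acc]]
    pieces <- character(nrow(defs))
    acc_pos <- 0L
    for (i in seq_len(nrow(defs))) {
      d <- defs[i, ]
      if (d$class == "novel") {
        s <- random_dna(d$novel_len)
      } else {
        s <- substr(ref$sequence[match(d$ref_chrom, ref$scaffold)],
                    d$ref_start, d$ref_end)
        if (d$strand == "-") s <- revcomp(s)
        s <- substitute_bases(s, config$snp_rate)
        if (config$indel_rate > 0) s <- apply_indels(s, config$indel_rate)
      }
      pieces[i] <- s
      map_rows[[length(map_rows) + 1L]] <- tibble(
        acc_chrom = acc, acc_start = acc_pos + 1L,
        acc_end = acc_pos + nchar(s),
        ref_chrom = d$ref_chrom, ref_start = d$ref_start,
        ref_end = d$ref_end, strand = d$strand, class = d$class)
      acc_pos <- acc_pos + nchar(s)
    }
    acc_seqs[acc] <- paste0(pieces, collapse = "")
  }
  segment_map <- bind_rows(map_rows)

  novel <- segment_map |> filter(.data$class == "novel") |>
    mutate(length = .data$acc_end - .data$acc_start + 1L) |>
    select(scaffold = "acc_chrom", start = "acc_start", end = "acc_end",
           "length")

  # repeat liftover (linear within segments; approximate under indels)
  acc_repeats <- purrr::pmap_dfr(segment_map, function(acc_chrom, acc_start,
                                                       acc_end, ref_chrom,
                                                       ref_start, ref_end,
                                                       strand, class) {
    if (class != "syntenic") return(NULL)
    r <- filter(reference$repeats, .data$scaffold == ref_chrom,
                .data$end >= ref_start, .data$start <= ref_end)
    if (nrow(r) == 0) return(NULL)
    s1 <- pmax(r$start, ref_start); e1 <- pmin(r$end, ref_end)
    a <- lift_linear(s1, ref_start, ref_end,
                     if (strand == "+") acc_start else acc_end,
                     if (strand == "+") acc_end else acc_start)
    b <- lift_linear(e1, ref_start, ref_end,
                     if (strand == "+") acc_start else acc_end,
                     if (strand == "+") acc_end else acc_start)
    tibble(scaffold = acc_chrom, start = pmin(a, b), end = pmax(a, b),
           family = r$family)
  })
  acc_repeats <- if (nrow(acc_repeats) > 0) {
    arrange(acc_repeats, .data$scaffold, .data$start)
  } else {
    tibble(scaffold = character(), start = integer(), end = integer(),
           family = character())
  }

  # lifted genes + toy genes inside novel insertions
  acc_genes <- purrr::pmap_dfr(segment_map, function(acc_chrom, acc_start,
                                                     acc_end, ref_chrom,
                                                     ref_start, ref_end,
                                                     strand, class) {
    if (class != "syntenic" || strand != "+") return(NULL)
    g <- filter(reference$genes, .data$scaffold == ref_chrom,
                .data$start >= ref_start, .data$end <= ref_end)
    if (nrow(g) == 0) return(NULL)
    mutate(g, scaffold = acc_chrom,
           start = lift_linear(.data$start, ref_start, ref_end, acc_start, acc_end),
           end = lift_linear(.data$end, ref_start, ref_end, acc_start, acc_end),
           novel = FALSE)
  })
  nov_genes <- purrr::pmap_dfr(novel, function(scaffold, start, end, length) {
    if (length < 6000L) return(NULL)
    gstarts <- seq(start + 1000L, end - 4000L, by = 10000L)
    purrr::map_dfr(seq_along(gstarts), function(gi) {
      gid <- sprintf("%s.nov%03d_%d", scaffold, gi, start)
      bind_rows(
        tibble(scaffold = scaffold, type = "gene", start = gstarts[gi],
               end = gstarts[gi] + 3000L, strand = "+", ID = gid,
               Parent = NA_character_, novel = TRUE),
        tibble(scaffold = scaffold, type = "CDS", start = gstarts[gi] + 100L,
               end = gstarts[gi] + 1000L, strand = "+", ID = NA_character_,
               Parent = gid, novel = TRUE)
      )
    })
  })

  list(
    genome = tibble(scaffold = names(acc_seqs), sequence = unname(acc_seqs)),
    segment_map = segment_map,
    breakpoints = breakpoints,
    novel = novel,
    repeats = acc_repeats,
    genes = bind_rows(acc_genes, nov_genes)
  )
}

#' Fragment an accession into a base assembly
#'
#' Cuts each accession chromosome into fragments whose breakpoints fall
#' inside repeats with elevated probability (`repeat_weight`); some breaks
#' additionally lose surrounding sequence (unassembled regions), and
#' fragments below `frag_min_keep` are dropped. A configurable number of
#' chimeric contigs is planted by concatenating fragments from different
#' chromosomes. Kept fragments are stored in random orientation and order.
#'
#' @param accession output of [simulate_accession()] (or a list with
#'   `genome` and optionally `repeats`).
#' @param config a [sim_config()].
#' @param n_pieces optional exact number of fragments per chromosome
#'   (overrides `mean_contig`; cuts still drawn randomly).
#' @return list: `assembly` (base assembly tibble, contigs `ctg****`),
#'   `provenance` (tibble `contig`, `contig_start`, `contig_end`,
#'   `acc_chrom`, `acc_start`, `acc_end`, `strand`, `kept`; rows with
#'   `kept = FALSE` have `contig = NA` and tile the accession together with
#'   the kept rows), `chimeras` (tibble `contig`, `junction`).
#' @export
fragment_assembly <- function(accession, config = sim_config(),
                              n_pieces = NULL) {
  genome <- accession$genome
  repeats <- accession$repeats %||% tibble(scaffold = character(),
                                           start = integer(), end = integer())
  w <- config$repeat_weight
  pieces <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$scaffold[ci]
    len <- nchar(genome$sequence[ci])
    n_cut <- if (!is.null(n_pieces)) n_pieces - 1L
             else max(0L, as.integer(round(len / config$mean_contig)) - 1L)
    rp <- filter(repeats, .data$scaffold == chrom, .data$end <= len - 1L)
    rep_ir <- IRanges::reduce(iranges_of(rp))
    rep_tot <- sum(IRanges::width(rep_ir))
    R <- rep_tot / len
    cuts <- integer(0)
    if (n_cut > 0) {
      p_rep <- if (w == 1 || rep_tot == 0) NA else (w * R) / (w * R + (1 - R))
      draw <- function(n) {
        if (is.na(p_rep)) return(sample.int(len - 1L, min(n, len - 1L)))
        in_rep <- runif(n) < p_rep
        out <- integer(n)
        if (any(in_rep)) {
          # uniform position within repeat space
          u <- sample.int(rep_tot, sum(in_rep), replace = TRUE)
          cw <- cumsum(IRanges::width(rep_ir))
          iv <- findInterval(u - 1L, c(0L, cw[-length(cw)]))
          iv <- pmax(1L, pmin(iv, length(rep_ir)))
          out[in_rep] <- IRanges::start(rep_ir)[iv] +
            (u - c(0L, cw)[iv] - 1L)
        }
        if (any(!in_rep)) {
          non <- IRanges::setdiff(IRanges::IRanges(1L, len - 1L), rep_ir)
          nw <- IRanges::width(non)
          u <- sample.int(sum(nw), sum(!in_rep), replace = TRUE)
          cw <- cumsum(nw)
          iv <- findInterval(u - 1L, c(0L, cw[-length(cw)]))
          iv <- pmax(1L, pmin(iv, length(non)))
          out[!in_rep] <- IRanges::start(non)[iv] + (u - c(0L, cw)[iv] - 1L)
        }
        pmin(pmax(out, 1L), len - 1L)
      }
      cuts <- sort(unique(draw(n_cut)))
    }
    bounds <- c(0L, cuts, len)
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i] + 1L; e <- bounds[i + 1L]
      drop_left <- 0L; drop_right <- 0L
      sdl <- config$drop_len_sdlog %||% 1.3
      if (i > 1L && runif(1) < config$drop_prob) {
        drop_left <- as.integer(round(stats::rlnorm(1, log(config$drop_len_mean / 2), sdl)))
      }
      if (i < length(bounds) - 1L && runif(1) < config$drop_prob) {
        drop_right <- as.integer(round(stats::rlnorm(1, log(config$drop_len_mean / 2), sdl)))
      }
      s2 <- min(s + drop_left, e); e2 <- max(e - drop_right, s2)
      if (drop_left > 0 && s2 > s) {
        pieces[[length(pieces) + 1L]] <- tibble(
          acc_chrom = chrom, acc_start = s, acc_end = s2 - 1L, kept = FALSE)
      }
      keep <- (e2 - s2 + 1L) >= config$frag_min_keep
      pieces[[length(pieces) + 1L]] <- tibble(
        acc_chrom = chrom, acc_start = s2, acc_end = e2, kept = keep)
      if (drop_right > 0 && e2 < e) {
        pieces[[length(pieces) + 1L]] <- tibble(
          acc_chrom = chrom, acc_start = e2 + 1L, acc_end = e, kept = FALSE)
      }
    }
  }
  prov <- bind_rows(pieces) |>
    mutate(piece_id = row_number(),
           length = .data$acc_end - .data$acc_start + 1L)

  kept <- filter(prov, .data$kept)
  # plant chimeras: pair pieces from different chromosomes
  n_chim <- min(config$n_chimeras, floor(nrow(kept) / 4))
  chim_pairs <- list()
  if (n_chim > 0 && dplyr::n_distinct(kept$acc_chrom) > 1) {
    cand <- sample(kept$piece_id)
    used <- integer(0)
    for (pid in cand) {
      if (length(chim_pairs) >= n_chim) break
      if (pid %in% used) next
      chrom_p <- kept$acc_chrom[kept$piece_id == pid]
      mate <- setdiff(kept$piece_id[kept$acc_chrom != chrom_p], used)
      if (length(mate) == 0) next
      m <- mate[sample.int(length(mate), 1)]
      chim_pairs[[length(chim_pairs) + 1L]] <- c(pid, m)
      used <- c(used, pid, m)
    }
  }
  chim_ids <- unlist(chim_pairs)

  seqs <- setNames(genome$sequence, genome$scaffold)
  singles <- filter(kept, !.data$piece_id %in% chim_ids)
  n_contigs <- nrow(singles) + length(chim_pairs)
  ord <- sample.int(n_contigs)
  names_pool <- sprintf("ctg%04d", seq_len(n_contigs))

  contigs <- character(0)
  prov_rows <- list()
  chim_rows <- list()
  ni <- 0L
  emit_piece <- function(row, contig, at) {
    flip <- runif(1) < config$flip_prob
    s <- substr(seqs[[row$acc_chrom]], row$acc_start, row$acc_end)
    if (flip) s <- revcomp(s)
    list(seq = s,
         prov = tibble(contig = contig, contig_start = at,
                       contig_end = at + nchar(s) - 1L,
                       acc_chrom = row$acc_chrom, acc_start = row$acc_start,
                       acc_end = row$acc_end,
                       strand = if (flip) "-" else "+", kept = TRUE))
  }
  for (i in seq_len(nrow(singles))) {
    ni <- ni + 1L
    nm <- names_pool[ord[ni]]
    ep <- emit_piece(singles[i, ], nm, 1L)
    contigs[nm] <- ep$seq
    prov_rows[[length(prov_rows) + 1L]] <- ep$prov
  }
  for (pr in chim_pairs) {
    ni <- ni + 1L
    nm <- names_pool[ord[ni]]
    r1 <- kept[kept$piece_id == pr[1], ]
    r2 <- kept[kept$piece_id == pr[2], ]
    e1 <- emit_piece(r1, nm, 1L)
    e2 <- emit_piece(r2, nm, nchar(e1$seq) + 1L)
    contigs[nm] <- paste0(e1$seq, e2$seq)
    prov_rows[[length(prov_rows) + 1L]] <- bind_rows(e1$prov, e2$prov)
    chim_rows[[length(chim_rows) + 1L]] <-
      tibble(contig = nm, junction = nchar(e1$seq))
  }
  provenance <- bind_rows(
    bind_rows(prov_rows),
    filter(prov, !.data$kept) |>
      mutate(contig = NA_character_, contig_start = NA_integer_,
             contig_end = NA_integer_, strand = NA_character_) |>
      select("contig", "contig_start", "contig_end", "acc_chrom",
             "acc_start", "acc_end", "strand", "kept")
  ) |> arrange(.data$acc_chrom, .data$acc_start)

  list(
    assembly = tibble(scaffold = names(contigs), sequence = unname(contigs)),
    provenance = provenance,
    chimeras = if (length(chim_rows)) bind_rows(chim_rows) else
      tibble(contig = character(), junction = integer())
  )
}

#' Simulate one round of scaffolding
#'
#' Joins base contigs that are truly adjacent on the accession when the
#' intervening distance is within the technology's `max_span` and both
#' members meet `min_joinable`; emits gaps according to the technology's gap
#' convention; and handles planted chimeras per profile (`"breaks"` splits
#' them first, `"logs_only"` reports them and excludes them from joins).
#'
#' @param base output of [fragment_assembly()] (or a compatible list with
#'   `assembly`, `provenance`, `chimeras`).
#' @param profile a [technology_profile()].
#' @return list: `assembly` (scaffolded tibble), `truth` with `joins`
#'   (tibble `output_scaffold`, `member`, `orientation`, `ord`, `gap_after`),
#'   `breaks` (executed chimera splits), `chimera_log`, `gaps` (emitted gap
#'   records with `origin = profile$name`), and `provenance` updated to the
#'   split contigs.
#' @export
simulate_scaffolding <- function(base, profile) {
  prov <- filter(base$provenance, .data$kept)
  chim <- base$chimeras
  seqs <- setNames(base$assembly$sequence, base$assembly$scaffold)

  breaks_done <- tibble(input_scaffold = character(), position = integer())
  if (nrow(chim) > 0 && profile$chimera_break == "breaks") {
    for (i in seq_len(nrow(chim))) {
      ctg <- chim$contig[i]
      j <- chim$junction[i]
      full <- seqs[[ctg]]
      parts <- c(substr(full, 1L, j), substr(full, j + 1L, nchar(full)))
      new_names <- sprintf("%s_p%d", ctg, 1:2)
      seqs <- seqs[names(seqs) != ctg]
      seqs[new_names] <- parts
      pr <- prov$contig == ctg
      stopifnot(sum(pr) == 2L)
      idx <- which(pr)[order(prov$contig_start[pr])]
      prov$contig[idx] <- new_names
      len2 <- prov$contig_end[idx[2]] - prov$contig_start[idx[2]] + 1L
      prov$contig_start[idx] <- 1L
      prov$contig_end[idx] <- c(j, len2)
      breaks_done <- bind_rows(breaks_done,
                               tibble(input_scaffold = ctg, position = j))
    }
    chim_excluded <- character(0)
  } else {
    chim_excluded <- chim$contig
  }

  # chain truly-adjacent contigs along the accession
  ordered <- prov |> arrange(.data$acc_chrom, .data$acc_start)
  lens <- setNames(nchar(seqs), names(seqs))
  ordered$len <- lens[ordered$contig]
  n <- nrow(ordered)
  link <- logical(max(0L, n - 1L))
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      a <- ordered[i, ]; b <- ordered[i + 1L, ]
      if (a$acc_chrom != b$acc_chrom) next
      if (a$contig %in% chim_excluded || b$contig %in% chim_excluded) next
      if (a$contig == b$contig) next # chimera kept intact (logs_only)
      gapd <- b$acc_start - a$acc_end - 1L
      if (gapd > profile$max_span) next
      if (a$len < profile$min_joinable || b$len < profile$min_joinable) next
      link[i] <- TRUE
    }
  }
  chain_id <- cumsum(c(TRUE, !link))

  out_seqs <- character(0)
  join_rows <- list()
  gap_rows <- list()
  si <- 0L
  for (cid in unique(chain_id)) {
    rows <- ordered[chain_id == cid, , drop = FALSE]
    rows <- distinct(rows, .data$contig, .keep_all = TRUE)
    if (nrow(rows) == 1L) {
      nm <- rows$contig[1]
      out_seqs[nm] <- seqs[[nm]]
      next
    }
    si <- si + 1L
    nm <- sprintf("scaf%04d", si)
    piece_seqs <- character(nrow(rows))
    pos <- 0L
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      s <- seqs[[r$contig]]
      ori <- r$strand
      if (ori == "-") s <- revcomp(s) # orient to accession forward
      piece_seqs[i] <- s
      gap_after <- NA_integer_
      if (i < nrow(rows)) {
        gapd <- rows$acc_start[i + 1L] - r$acc_end - 1L
        gap_after <- if (profile$gap_convention == "fixed_100N") 100L else {
          max(as.integer(round(gapd * exp(rnorm(1, 0, profile$gap_size_error)))),
              profile$min_gap_emitted)
        }
        gap_rows[[length(gap_rows) + 1L]] <- tibble(
          scaffold = nm, start = pos + nchar(s) + 1L,
          end = pos + nchar(s) + gap_after, length = gap_after,
          origin = profile$name)
      }
      join_rows[[length(join_rows) + 1L]] <- tibble(
        output_scaffold = nm, member = r$contig, orientation = r$strand,
        ord = i, gap_after = gap_after)
      pos <- pos + nchar(s) + (if (!is.na(gap_after)) gap_after else 0L)
    }
    gaps_vec <- purrr::map_chr(join_rows[(length(join_rows) - nrow(rows) + 1):length(join_rows)],
                               ~ if (is.na(.x$gap_after)) "" else strrep("N", .x$gap_after))
    out_seqs[nm] <- paste0(piece_seqs, c(gaps_vec[-length(gaps_vec)], ""),
                           collapse = "")
  }

  list(
    assembly = tibble(scaffold = names(out_seqs), sequence = unname(out_seqs)),
    truth = list(
      joins = if (length(join_rows)) bind_rows(join_rows) else
        tibble(output_scaffold = character(), member = character(),
               orientation = character(), ord = integer(),
               gap_after = integer()),
      breaks = breaks_done,
      chimera_log = if (profile$chimera_break == "logs_only") chim else
        chim[0, ],
      gaps = if (length(gap_rows)) bind_rows(gap_rows) else
        tibble(scaffold = character(), start = integer(), end = integer(),
               length = integer(), origin = character())
    ),
    provenance = prov
  )
}

#' Derive perfect alignments from simulation truth
#'
#' Emits PAF-style alignment records (1-based inclusive, as from
#' [read_paf()]) for syntenic sequence, either per accession chromosome
#' (`provenance = NULL`) or per base contig, splitting long segments into
#' chunks to emulate fragmented whole-genome alignments. Coordinates are
#' mapped linearly within segments (exact in the absence of indels).
#'
#' @param accession output of [simulate_accession()].
#' @param reference output of [simulate_reference()] (for target lengths).
#' @param provenance optional provenance tibble from [fragment_assembly()];
#'   when given, queries are base contigs.
#' @param chunk alignment record length (nt); default 5e4.
#' @param identity match fraction recorded in the `matches` column.
#' @param edge_trim nt left unaligned at each segment edge, emulating the
#'   fraying of alignments near rearrangement junctions; default 100.
#' @return alignment tibble compatible with [chain_blocks()].
#' @export
simulate_alignments <- function(accession, reference, provenance = NULL,
                                chunk = 5e4, identity = 0.99,
                                edge_trim = 100L) {
  segmap <- accession$segment_map
  ref_lens <- setNames(nchar(reference$genome$sequence),
                       reference$genome$scaffold)
  acc_lens <- setNames(nchar(accession$genome$sequence),
                       accession$genome$scaffold)

  emit_segment <- function(query, q_len, q_lo, q_hi, seg, local_strand) {
    # overlap of [q_lo, q_hi] (accession coords) with segment `seg`;
    # segment edges fray by edge_trim
    lo <- max(q_lo, seg$acc_start + edge_trim)
    hi <- min(q_hi, seg$acc_end - edge_trim)
    if (lo > hi || seg$class != "syntenic") return(NULL)
    starts <- seq(lo, hi, by = chunk)
    purrr::map_dfr(starts, function(s) {
      e <- min(s + chunk - 1L, hi)
      t1 <- lift_linear(s, seg$acc_start, seg$acc_end, seg$ref_start,
                        seg$ref_end, reverse = seg$strand == "-")
      t2 <- lift_linear(e, seg$acc_start, seg$acc_end, seg$ref_start,
                        seg$ref_end, reverse = seg$strand == "-")
      strand <- if ((seg$strand == "-") != (local_strand == "-")) "-" else "+"
      q1 <- s - q_lo + 1L; q2 <- e - q_lo + 1L
      if (local_strand == "-") { # query stored reverse-complemented
        q1 <- q_len - (e - q_lo); q2 <- q_len - (s - q_lo)
      }
      tibble(query = query, q_len = q_len, q_start = q1, q_end = q2,
             strand = strand, target = seg$ref_chrom,
             t_len = unname(ref_lens[seg$ref_chrom]),
             t_start = min(t1, t2), t_end = max(t1, t2),
             matches = as.integer(round((e - s + 1L) * identity)),
             aln_len = e - s + 1L, mapq = 60L)
    })
  }

  if (is.null(provenance)) {
    purrr::map_dfr(seq_len(nrow(segmap)), function(i) {
      seg <- segmap[i, ]
      emit_segment(seg$acc_chrom, unname(acc_lens[seg$acc_chrom]),
                   1L, unname(acc_lens[seg$acc_chrom]), seg, "+")
    })
  } else {
    pr <- filter(provenance, .data$kept)
    purrr::map_dfr(seq_len(nrow(pr)), function(i) {
      p <- pr[i, ]
      segs <- filter(segmap, .data$acc_chrom == p$acc_chrom,
                     .data$acc_end >= p$acc_start,
                     .data$acc_start <= p$acc_end)
      if (nrow(segs) == 0) return(NULL)
      q_len <- p$acc_end - p$acc_start + 1L
      purrr::map_dfr(seq_len(nrow(segs)), function(j) {
        out <- emit_segment(p$contig, q_len, p$acc_start, p$acc_end,
                            segs[j, ], p$strand)
        if (is.null(out)) return(NULL)
        # emit_segment's q coords are relative to [p$acc_start, p$acc_end]
        out
      })
    })
  }
}
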