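# Novel-sequence extraction: subtract aligned intervals from the gap-removed
# assembly, then reclassify segments that are too short, tandem-repetitive,
# or low-complexity so they are not reported as novel.

#' DUST-style low-complexity score per window
#'
#' Triplet-composition score over sliding windows:
#' `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` where `c_t` counts each
#' distinct triplet in the window. A uniform random window scores about 0.5,
#' a homopolymer 31, a dinucleotide run about 15.
#'
#' @param seq character scalar (A/C/G/T/N; case-insensitive).
#' @param window window width in nt (default 64).
#' @param step window step (default 32).
#' @return numeric vector of window scores (length 1 for short sequences).
#' @export
dust_score <- function(seq, window = 64L, step = 32L) {
  s <- toupper(seq)
  n <- nchar(s)
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- code[strsplit(s, "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- 0L
  if (n < 3L) return(0)
  trip <- v[1:(n - 2L)] * 16L + v[2:(n - 1L)] * 4L + v[3:n] + 1L
  win <- min(window, n)
  starts <- seq(1L, max(1L, n - win + 1L), by = step)
  vapply(starts, function(st) {
    tt <- trip[st:min(st + win - 3L, length(trip))]
    ct <- tabulate(tt, 64L)
    sum(ct * (ct - 1) / 2) / max(1L, length(tt) - 1L)
  }, numeric(1))
}

is_low_complexity <- function(seq, threshold = 4, min_frac = 0.5) {
  sc <- dust_score(seq)
  mean(sc >= threshold) >= min_frac
}

# Tandem periodicity via k-mer start spacing: a k-mer with >= min_copies
# occurrences at a constant period (2..max_period) marks a tandem array.
# Period-1 spacing (homopolymers) is deliberately excluded; those are the
# low-complexity filter's job.
is_tandem <- function(seq, k = 5L, min_copies = 5L, max_period = 100L,
                      min_frac = 0.5) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < k * min_copies) return(FALSE)
  starts <- 1:(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  tab <- table(kmers)
  cand <- names(tab)[tab >= min_copies]
  covered <- IRanges::IRanges()
  for (km in cand) {
    pos <- starts[kmers == km]
    d <- diff(pos)
    ok <- d >= 2L & d <= max_period
    if (!any(ok)) next
    r <- rle(paste0(ok, "_", d))
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    good <- which(startsWith(r$values, "TRUE") & r$lengths >= min_copies - 1L)
    for (g in good) {
      covered <- c(covered,
                   IRanges::IRanges(pos[run_start[g]],
                                    pos[run_end[g] + 1L] + k - 1L))
    }
  }
  if (length(covered) == 0) return(FALSE)
  sum(IRanges::width(IRanges::reduce(covered))) / n >= min_frac
}

#' Extract novel (unaligned) sequence segments
#'
#' Subtracts all aligned intervals from the gap-removed (contig) space of the
#' assembly and classifies each unaligned segment: shorter than `min_segment`
#' -> `short_removed`; tandem-periodic -> `tandem_removed`; DUST-style
#' low-complexity -> `low_complexity_removed`; otherwise `novel`. Aligned
#' bases, novel bases, removed bases and gap bases partition the assembly.
#'
#' @param assembly assembly tibble.
#' @param alignments tibble with `query`, `q_start`, `q_end` columns —
#'   either raw alignment records ([read_paf()]) or synteny blocks
#'   ([chain_blocks()]); all given intervals count as aligned.
#' @param min_segment minimum segment length (nt) to be considered; default
#'   100.
#' @param min_contig,min_gap gap-scan parameters.
#' @return tibble of segments (`scaffold`, `start`, `end`, `length`,
#'   `class`), with attribute `"totals"`: a tibble of nt and percent per
#'   category (including `aligned` and `gap`) on the scale of total assembly
#'   bases.
#' @export
novel_sequence <- function(assembly, alignments, min_segment = 100L,
                           min_contig = 200L, min_gap = 1L) {
  assert_assembly(assembly)
  sc <- scan_assembly(assembly, min_contig, min_gap)
  total <- sum(as.numeric(nchar(assembly$sequence)))
  gap_bases <- sum(as.numeric(sc$gaps$length))
  aln <- tibble(scaffold = alignments$query,
                start = alignments$q_start, end = alignments$q_end)
  aln_ir <- split_iranges(aln)
  ctg_ir <- split_iranges(sc$contigs)

  segs <- purrr::imap_dfr(ctg_ir, function(cir, scaf) {
    a <- aln_ir[[scaf]] %||% IRanges::IRanges()
    un <- IRanges::setdiff(cir, IRanges::reduce(a))
    if (length(un) == 0) return(NULL)
    mutate(tbl_of_iranges(un), scaffold = scaf, .before = 1)
  })
  if (nrow(segs) == 0) {
    segs <- tibble(scaffold = character(), start = integer(), end = integer(),
                   length = integer(), class = character())
  } else {
    segs$length <- segs$end - segs$start + 1L
    seq_by <- setNames(assembly$sequence, assembly$scaffold)
    segs$class <- purrr::pmap_chr(segs, function(scaffold, start, end, length) {
      if (length < min_segment) return("short_removed")
      s <- substr(seq_by[[scaffold]], start, end)
      if (is_tandem(s)) return("tandem_removed")
      if (is_low_complexity(s)) return("low_complexity_removed")
      "novel"
    })
  }
  aligned_bases <- overlap_bases(aln, sc$contigs)
  by_class <- segs |> group_by(.data$class) |>
    summarise(nt = sum(as.numeric(.data$length)), .groups = "drop")
  get <- function(cl) sum(by_class$nt[by_class$class == cl])
  totals <- tibble(
    category = c("total", "aligned", "novel", "low_complexity_removed",
                 "tandem_removed", "short_removed", "gap"),
    nt = c(total, aligned_bases, get("novel"), get("low_complexity_removed"),
           get("tandem_removed"), get("short_removed"), gap_bases)
  )
  totals$pct <- pct(totals$nt, total)
  attr(segs, "totals") <- totals
  segs
}

read_gff_tbl <- function(gff) {
  if (is.character(gff) && length(gff) == 1) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      g <- as.data.frame(rtracklayer::import(gff))
      tibble(scaffold = as.character(g$seqnames), type = as.character(g$type),
             start = g$start, end = g$end, strand = as.character(g$strand),
             ID = if ("ID" %in% names(g)) as.character(g$ID) else NA_character_,
             Parent = if ("Parent" %in% names(g)) {
               vapply(g$Parent, function(p)
                 if (length(p)) as.character(p)[1] else NA_character_,
                 character(1))
             } else NA_character_)
    } else {
      lines <- readLines(gff)
      lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
      f <- strsplit(lines, "\t", fixed = TRUE)
      tibble(scaffold = purrr::map_chr(f, 1), type = purrr::map_chr(f, 3),
             start = as.integer(purrr::map_chr(f, 4)),
             end = as.integer(purrr::map_chr(f, 5)),
             strand = purrr::map_chr(f, 7),
             ID = stringr::str_match(purrr::map_chr(f, 9), "ID=([^;]+)")[, 2],
             Parent = stringr::str_match(purrr::map_chr(f, 9), "Parent=([^;]+)")[, 2])
    }
  } else {
    as_tibble(gff)
  }
}

#' Accession-specific genes from novel segments
#'
#' A gene qualifies when the summed overlap of its CDS with novel segments
#' exceeds half of its total CDS length (strictly greater than 50%).
#'
#' @param novel_segments tibble from [novel_sequence()] (only rows with
#'   `class == "novel"` are used).
#' @param gff gene models: a GFF3 path or a tibble with columns `scaffold`,
#'   `type`, `start`, `end`, `ID`, `Parent` (CDS rows grouped by `Parent`).
#' @return tibble per gene: `gene`, `cds_length`, `novel_overlap`,
#'   `fraction`, `novel` (logical, the >50% rule).
#' @export
novel_genes <- function(novel_segments, gff) {
  g <- read_gff_tbl(gff)
  cds <- filter(g, .data$type == "CDS") |>
    mutate(gene = dplyr::coalesce(.data$Parent, .data$ID))
  nov <- filter(novel_segments, .data$class == "novel")
  nov_ir <- split_iranges(nov)
  per_gene <- cds |> group_by(.data$gene) |>
    summarise(scaffold = .data$scaffold[1],
              cds_length = sum(.data$end - .data$start + 1),
              rows = list(dplyr::pick("start", "end")),
              .groups = "drop")
  per_gene$novel_overlap <- purrr::pmap_dbl(per_gene, function(gene, scaffold,
                                                               cds_length, rows) {
    ir <- nov_ir[[scaffold]]
    if (is.null(ir)) return(0)
    sum(IRanges::width(IRanges::intersect(IRanges::reduce(iranges_of(rows)),
                                          IRanges::reduce(ir))))
  })
  per_gene |>
    mutate(fraction = .data$novel_overlap / .data$cds_length,
           novel = .data$fraction > 0.5) |>
    select("gene", "scaffold", "cds_length", "novel_overlap", "fraction",
           "novel")
}
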