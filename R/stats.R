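# Continuity and gap statistics: Nxx (with the genome-size-adjusted variant),
# whole-assembly summary, gap summaries, and before/after gap-filling deltas.

#' Nxx length statistic
#'
#' The smallest length L such that sequences of length >= L together cover at
#' least `x` percent of `genome_size`. With `genome_size = NULL` (the default)
#' the denominator is the sum of `lengths`, giving the classical N50/N90/N10.
#' Supplying a fixed genome size gives the "adjusted" variant that makes N50s
#' comparable across assemblies of different total length; if the assembly
#' covers less than `x`% of that size the statistic is 0.
#'
#' @param lengths positive sequence lengths (nt).
#' @param x percent threshold in (0, 100]; default 50.
#' @param genome_size denominator (nt); `NULL` means `sum(lengths)`.
#' @return a single length in nt (0 when unreachable).
#' @examples
#' nxx(c(8, 5, 4, 3))               # 5
#' nxx(c(8, 5, 4, 3), genome_size = 28)  # 4
#' @export
nxx <- function(lengths, x = 50, genome_size = NULL) {
  if (length(lengths) == 0) stop("`lengths` must be nonempty", call. = FALSE)
  if (any(lengths <= 0)) stop("`lengths` must be positive", call. = FALSE)
  stopifnot(x > 0, x <= 100)
  genome_size <- genome_size %||% sum(as.numeric(lengths))
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  need <- x / 100 * genome_size
  cum <- cumsum(ls)
  i <- which(cum >= need)
  if (length(i) == 0) return(0)
  ls[i[1]]
}

#' Summary statistics for a gap set
#'
#' Count, minimum, maximum, arithmetic mean (rounded to the nearest nt), gap
#' N50 and total gap length. An empty gap set returns count and total of 0
#' with `NA` for the undefined statistics.
#'
#' @param gaps gap tibble from [detect_gaps()] (needs a `length` column).
#' @return a one-row tibble: `n_gaps`, `min_gap`, `max_gap`, `mean_gap`,
#'   `gap_n50`, `total_gap_length`.
#' @export
gap_stats <- function(gaps) {
  if (is.null(gaps) || nrow(gaps) == 0) {
    return(tibble(n_gaps = 0L, min_gap = NA_real_, max_gap = NA_real_,
                  mean_gap = NA_real_, gap_n50 = NA_real_,
                  total_gap_length = 0))
  }
  l <- as.numeric(gaps$length)
  tibble(
    n_gaps = length(l),
    min_gap = min(l),
    max_gap = max(l),
    mean_gap = round_half_away(mean(l)),
    gap_n50 = nxx(l, 50),
    total_gap_length = sum(l)
  )
}

#' Continuity statistics for an assembly
#'
#' Scaffold- and contig-level counts, lengths, N50/N90/N10, the genome-size
#' adjusted N50, and the gap summary of [gap_stats()], all in one row.
#'
#' @param assembly assembly tibble.
#' @param min_contig minimum island size passed to the gap scan; default 200.
#' @param min_gap minimum N-run length counting as a gap; default 1.
#' @param adjust_size genome size (nt) used for the adjusted N50 column;
#'   default 4e8.
#' @param keep_short keep free-standing scaffolds shorter than `min_contig` in
#'   the statistics (default TRUE).
#' @return a one-row tibble of class `scaffeval_stats`.
#' @export
assembly_stats <- function(assembly, min_contig = 200L, min_gap = 1L,
                           adjust_size = 4e8, keep_short = TRUE) {
  assert_assembly(assembly)
  if (!keep_short) {
    assembly <- filter(assembly, nchar(.data$sequence) >= min_contig)
  }
  sl <- as.numeric(nchar(assembly$sequence))
  sc <- scan_assembly(assembly, min_contig, min_gap)
  cl <- as.numeric(sc$contigs$length)
  gs <- gap_stats(sc$gaps)
  out <- tibble(
    n_scaffolds = nrow(assembly),
    n_contigs = nrow(sc$contigs),
    scaffold_length = sum(sl),
    contig_length = sum(cl),
    scaffold_n50 = nxx(sl, 50),
    contig_n50 = if (length(cl)) nxx(cl, 50) else NA_real_,
    adjusted_scaffold_n50 = nxx(sl, 50, genome_size = adjust_size),
    adjusted_contig_n50 = if (length(cl)) nxx(cl, 50, genome_size = adjust_size) else NA_real_,
    scaffold_n90 = nxx(sl, 90),
    scaffold_n10 = nxx(sl, 10),
    max_scaffold = max(sl),
    min_scaffold = min(sl)
  )
  out <- dplyr::bind_cols(out, gs)
  class(out) <- c("scaffeval_stats", class(out))
  out
}

#' Gap-filling delta between two versions of an assembly
#'
#' Compares an assembly before and after gap filling. Scaffold names must
#' match. Each before-gap is lifted into after coordinates by locating the
#' flanking contigs (which gap filling leaves intact) and counts as filled if
#' no gap overlaps the lifted interval.
#'
#' @param before,after assembly tibbles with identical scaffold names.
#' @param min_contig,min_gap gap-scan parameters (see [detect_gaps()]).
#' @return a one-row tibble: `n_gaps_before`, `n_gaps_after`, `gaps_filled`,
#'   `pct_filled`, `gap_n50_before`, `gap_n50_after`,
#'   `total_gap_reduction_pct`, `contig_n50_before`, `contig_n50_after`,
#'   `contig_n50_change_pct`.
#' @export
gapfill_delta <- function(before, after, min_contig = 200L, min_gap = 1L) {
  assert_assembly(before, "before")
  assert_assembly(after, "after")
  missing <- setdiff(before$scaffold, after$scaffold)
  if (length(missing) > 0) {
    stop("scaffold(s) missing from `after`: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sb <- scan_assembly(before, min_contig, min_gap)
  sa <- scan_assembly(after, min_contig, min_gap)
  after_seq <- setNames(toupper(after$sequence), after$scaffold)
  after_gap_ir <- split_iranges(sa$gaps)

  filled <- 0L
  for (scaf in unique(sb$gaps$scaffold)) {
    ctg <- filter(sb$contigs, .data$scaffold == scaf) |> arrange(.data$start)
    gp <- filter(sb$gaps, .data$scaffold == scaf) |> arrange(.data$start)
    bseq <- toupper(before$sequence[match(scaf, before$scaffold)])
    subj <- Biostrings::DNAString(after_seq[[scaf]])
    # locate each before-contig in after, left to right
    pos <- integer(nrow(ctg)) # after-coordinate of contig start
    prev_end <- 0L
    ok <- TRUE
    for (i in seq_len(nrow(ctg))) {
      # anchor on the contig prefix (long patterns are unnecessary: gap
      # filling leaves contig sequence intact)
      full_len <- ctg$end[i] - ctg$start[i] + 1L
      pat_len <- min(full_len, 10000L)
      pat <- substr(bseq, ctg$start[i], ctg$start[i] + pat_len - 1L)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
      st <- Biostrings::start(m)
      st <- st[st > prev_end]
      if (length(st) == 0) { ok <- FALSE; break }
      pos[i] <- st[1]
      prev_end <- st[1] + full_len - 1L
    }
    if (!ok) next # conservatively: none of this scaffold's gaps counted filled
    gir <- after_gap_ir[[scaf]] %||% IRanges::IRanges()
    for (j in seq_len(nrow(gp))) {
      # lifted interval: between the contigs flanking this gap (scaffold
      # boundary when the gap is terminal)
      i_left <- which(ctg$end < gp$start[j])
      i_right <- which(ctg$start > gp$end[j])
      lift_s <- if (length(i_left)) {
        i_left <- max(i_left)
        pos[i_left] + (ctg$end[i_left] - ctg$start[i_left])
      } else 1L
      lift_e <- if (length(i_right)) pos[min(i_right)]
                else nchar(after_seq[[scaf]])
      hit <- IRanges::countOverlaps(IRanges::IRanges(lift_s, lift_e), gir)
      if (hit == 0) filled <- filled + 1L
    }
  }
  gsb <- gap_stats(sb$gaps)
  gsa <- gap_stats(sa$gaps)
  c50b <- nxx(as.numeric(sb$contigs$length), 50)
  c50a <- nxx(as.numeric(sa$contigs$length), 50)
  tibble(
    n_gaps_before = gsb$n_gaps,
    n_gaps_after = gsa$n_gaps,
    gaps_filled = filled,
    pct_filled = if (gsb$n_gaps > 0) pct(filled, gsb$n_gaps) else 0,
    gap_n50_before = gsb$gap_n50,
    gap_n50_after = gsa$gap_n50,
    total_gap_reduction_pct = if (gsb$total_gap_length > 0)
      pct(gsb$total_gap_length - gsa$total_gap_length, gsb$total_gap_length) else 0,
    contig_n50_before = c50b,
    contig_n50_after = c50a,
    contig_n50_change_pct = pct_change(c50b, c50a)
  )
}

#' Scaffold-count reduction between two assemblies
#'
#' @param before,after assembly tibbles or `scaffeval_stats` rows.
#' @return a one-row tibble with scaffold counts and the reduction.
#' @export
scaffold_reduction <- function(before, after) {
  nb <- if (inherits(before, "scaffeval_stats")) before$n_scaffolds else nrow(before)
  na_ <- if (inherits(after, "scaffeval_stats")) after$n_scaffolds else nrow(after)
  tibble(n_before = nb, n_after = na_, reduction = nb - na_)
}
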