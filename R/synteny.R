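# Synteny-block construction against a reference, chromosome-agreement
# validation of scaffolding joins, and rearrangement breakpoint pinpointing.
# Alignments are consumed as tabular records (PAF columns 1-12); the package
# never runs an aligner itself, keeping this module deterministic.

#' Read pairwise alignments from a PAF file
#'
#' Reads the first 12 PAF columns and converts the 0-based half-open
#' coordinates to the 1-based inclusive convention used throughout the
#' package.
#'
#' @param path PAF file.
#' @return tibble: `query`, `q_len`, `q_start`, `q_end`, `strand`, `target`,
#'   `t_len`, `t_start`, `t_end`, `matches`, `aln_len`, `mapq`.
#' @export
read_paf <- function(path) {
  cols <- c("query", "q_len", "q_start", "q_end", "strand", "target",
            "t_len", "t_start", "t_end", "matches", "aln_len", "mapq")
  df <- readr::read_tsv(path, col_names = FALSE, col_select = 1:12,
                        show_col_types = FALSE, progress = FALSE)
  names(df) <- cols
  mutate(df, q_start = .data$q_start + 1L, t_start = .data$t_start + 1L)
}

#' Write alignment records as PAF
#'
#' @param aln alignment tibble in the internal 1-based inclusive convention.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  out <- aln |>
    mutate(q_start = .data$q_start - 1L, t_start = .data$t_start - 1L)
  readr::write_tsv(out[, c("query", "q_len", "q_start", "q_end", "strand",
                           "target", "t_len", "t_start", "t_end", "matches",
                           "aln_len", "mapq")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# coverage index over disjoint sorted intervals: O(log n) width queries
make_cov <- function(ir) {
  ir <- IRanges::reduce(ir)
  list(s = IRanges::start(ir), e = IRanges::end(ir),
       cw = cumsum(IRanges::width(ir)))
}
cov_width <- function(cov, lo, hi) {
  if (length(cov$s) == 0 || hi < lo) return(0)
  upto <- function(p) {
    j <- findInterval(p, cov$s)
    if (j == 0) return(0)
    cov$cw[j] - max(0, cov$e[j] - p)
  }
  upto(hi) - upto(lo - 1)
}

# Best collinear chain for one (query, target, strand) group, by aligned
# bases; quadratic DP, repeated extraction until no records remain. A chain
# never bridges a query gap that is mostly covered by other alignments of
# the same query (other targets/strands): that is the "fixing" step that
# keeps rearranged segments as separate blocks.
chain_group <- function(rec, max_join_gap, other_cov = NULL) {
  rec <- rec[order(rec$q_start, rec$q_end), , drop = FALSE]
  chains <- list()
  remaining <- rec
  while (nrow(remaining) > 0) {
    n <- nrow(remaining)
    score <- as.numeric(remaining$matches)
    prev <- rep(NA_integer_, n)
    if (n > 1) {
      for (i in 2:n) {
        for (j in 1:(i - 1)) {
          if (remaining$q_start[i] <= remaining$q_end[j]) next
          qgap <- remaining$q_start[i] - remaining$q_end[j] - 1L
          if (qgap > max_join_gap) next
          if (!is.null(other_cov) && qgap > 0) {
            cw <- cov_width(other_cov, remaining$q_end[j] + 1L,
                            remaining$q_start[i] - 1L)
            if (cw > 0.5 * qgap) next
          }
          if (remaining$strand[1] == "+") {
            if (remaining$t_start[i] <= remaining$t_end[j]) next
            tgap <- remaining$t_start[i] - remaining$t_end[j] - 1L
          } else {
            if (remaining$t_end[i] >= remaining$t_start[j]) next
            tgap <- remaining$t_start[j] - remaining$t_end[i] - 1L
          }
          if (tgap > max_join_gap) next
          cand <- score[j] + remaining$matches[i]
          if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
        }
      }
    }
    best <- which.max(score)
    idx <- best
    while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
    chains[[length(chains) + 1L]] <- remaining[idx, , drop = FALSE]
    remaining <- remaining[-idx, , drop = FALSE]
  }
  chains
}

#' Chain alignment records into synteny blocks
#'
#' Greedy best-first collinear chaining per (query, target, strand): the
#' highest-scoring chain (by aligned bases) under the `max_join_gap`
#' constraint is extracted, then the next, until all records are assigned.
#' Blocks spanning less than `min_block` nt on the query are dropped, and
#' overlapping query coverage is resolved by keeping the block with the most
#' aligned bases (lower-scoring blocks overlapping a kept block on the query
#' are discarded), so blocks are single-coverage on the query.
#'
#' @param alignments alignment tibble (see [read_paf()]).
#' @param max_join_gap maximum gap (nt, on query and on target) bridged
#'   within one block; default 1e5.
#' @param min_block minimum query span of a reported block; default 1e3.
#' @return tibble of blocks: `block_id`, `query`, `q_start`, `q_end`,
#'   `target`, `t_start`, `t_end`, `strand`, `n_records`, `aligned_bases`.
#' @export
chain_blocks <- function(alignments, max_join_gap = 1e5, min_block = 1e3) {
  if (nrow(alignments) == 0) {
    return(tibble(block_id = integer(), query = character(),
                  q_start = integer(), q_end = integer(), target = character(),
                  t_start = integer(), t_end = integer(), strand = character(),
                  n_records = integer(), aligned_bases = numeric()))
  }
  key <- paste(alignments$query, alignments$target, alignments$strand,
               sep = "\r")
  groups <- split(alignments, key)
  blocks <- purrr::map_dfr(groups, function(g) {
    # gap coverage by any alignment of this query (other groups and skipped
    # records alike) vetoes bridging in the DP
    same_q <- alignments[alignments$query == g$query[1], , drop = FALSE]
    other_cov <- make_cov(IRanges::IRanges(same_q$q_start, same_q$q_end))
    purrr::map_dfr(chain_group(g, max_join_gap, other_cov), function(ch) {
      tibble(query = ch$query[1],
             q_start = min(ch$q_start), q_end = max(ch$q_end),
             target = ch$target[1],
             t_start = min(ch$t_start), t_end = max(ch$t_end),
             strand = ch$strand[1], n_records = nrow(ch),
             aligned_bases = sum(as.numeric(ch$matches)))
    })
  })
  blocks <- filter(blocks, .data$q_end - .data$q_start + 1L >= min_block)
  # single coverage on the query: best aligned_bases wins; blocks mostly
  # covered by better blocks are dropped, small overlaps are trimmed away
  blocks <- blocks |> arrange(dplyr::desc(.data$aligned_bases))
  kept <- logical(nrow(blocks))
  cov <- list()
  for (i in seq_len(nrow(blocks))) {
    q <- blocks$query[i]
    prior <- cov[[q]] %||% IRanges::IRanges()
    ir <- IRanges::setdiff(IRanges::IRanges(blocks$q_start[i], blocks$q_end[i]),
                           prior)
    w0 <- blocks$q_end[i] - blocks$q_start[i] + 1L
    if (length(ir) == 0 || sum(IRanges::width(ir)) < 0.5 * w0) next
    ir <- ir[which.max(IRanges::width(ir))] # largest uncovered piece
    frac <- IRanges::width(ir) / w0
    # trim the target interval proportionally (strand-aware)
    cut_l <- (IRanges::start(ir) - blocks$q_start[i]) / w0
    cut_r <- (blocks$q_end[i] - IRanges::end(ir)) / w0
    tw <- blocks$t_end[i] - blocks$t_start[i] + 1L
    if (blocks$strand[i] == "+") {
      blocks$t_start[i] <- blocks$t_start[i] + round(cut_l * tw)
      blocks$t_end[i] <- blocks$t_end[i] - round(cut_r * tw)
    } else {
      blocks$t_start[i] <- blocks$t_start[i] + round(cut_r * tw)
      blocks$t_end[i] <- blocks$t_end[i] - round(cut_l * tw)
    }
    blocks$q_start[i] <- IRanges::start(ir)
    blocks$q_end[i] <- IRanges::end(ir)
    blocks$aligned_bases[i] <- blocks$aligned_bases[i] * frac
    kept[i] <- TRUE
    cov[[q]] <- IRanges::reduce(c(prior, ir))
  }
  blocks[kept, ] |>
    arrange(.data$query, .data$q_start) |>
    mutate(block_id = row_number(), .before = 1)
}

member_chromosome <- function(member_scaffold, blocks, majority_fraction,
                              intervals = NULL) {
  b <- filter(blocks, .data$query == member_scaffold)
  if (nrow(b) == 0) return("unassigned")
  w <- rep(1, nrow(b))
  if (!is.null(intervals) && nrow(intervals) > 0 &&
      !anyNA(intervals$in_start)) {
    # weight each block by its overlap with the member's placed interval
    # (matters when only part of an input scaffold went into this join)
    iv <- IRanges::reduce(IRanges::IRanges(intervals$in_start,
                                           intervals$in_end))
    ov <- vapply(seq_len(nrow(b)), function(i) {
      sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(b$q_start[i], b$q_end[i]), iv)))
    }, numeric(1))
    w <- ov / (b$q_end - b$q_start + 1)
    if (all(w == 0)) return("unassigned")
  }
  by_chr <- tibble(target = b$target, bases = b$aligned_bases * w) |>
    group_by(.data$target) |>
    summarise(bases = sum(.data$bases), .groups = "drop")
  if (sum(by_chr$bases) == 0) return("unassigned")
  share <- by_chr$bases / sum(by_chr$bases)
  i <- which.max(share)
  if (share[i] > majority_fraction) by_chr$target[i] else "unassigned"
}

#' Validate joins by reference-chromosome agreement
#'
#' Assigns each join member the reference chromosome holding more than
#' `majority_fraction` of its synteny-aligned bases (else `"unassigned"`).
#' A join's verdict is `same` when all members share one assigned chromosome,
#' `different` when two assigned members disagree, and `unknown` when any
#' member is `"unassigned"` or maps to the unplaced pseudo-chromosome `"U"`.
#' The verdict is invariant to member order and strand.
#'
#' @param joins tibble from [call_joins()].
#' @param blocks synteny blocks from [chain_blocks()] whose `query` labels are
#'   input-scaffold names.
#' @param majority_fraction dominance threshold for chromosome assignment;
#'   default 0.5.
#' @return `joins` with added `member_chromosomes` (list of character) and
#'   `verdict` columns.
#' @export
classify_joins <- function(joins, blocks, majority_fraction = 0.5) {
  joins$member_chromosomes <- purrr::map(joins$members, function(mem) {
    vapply(unique(mem$input_scaffold), function(ms) {
      iv <- if (all(c("in_start", "in_end") %in% names(mem))) {
        mem[mem$input_scaffold == ms, c("in_start", "in_end")]
      } else NULL
      member_chromosome(ms, blocks, majority_fraction, intervals = iv)
    }, character(1))
  })
  joins$verdict <- purrr::map_chr(joins$member_chromosomes, function(ch) {
    if (any(ch %in% c("unassigned", "U"))) return("unknown")
    if (dplyr::n_distinct(ch) == 1L) "same" else "different"
  })
  joins
}

#' Same-chromosome rates of validated joins
#'
#' The same-chromosome rate is `same / (same + different)` as a two-decimal
#' percentage; joins with verdict `unknown` are excluded from the
#' denominator. With a support set the rate is also computed within the
#' supported and unsupported strata, together with the difference between each
#' stratum and the overall rate (differences of the rounded percentages,
#' matching how such increases are quoted).
#'
#' @param validations tibble from [classify_joins()].
#' @param support optional: either a comparison tibble from
#'   [compare_join_sets()] (a join is supported when one of its adjacent pairs
#'   is shared) or a character vector of supported `output_scaffold` labels.
#' @return a one-row tibble of counts, rates and differences.
#' @export
validation_rates <- function(validations, support = NULL) {
  rate <- function(v) {
    s <- sum(v$verdict == "same"); d <- sum(v$verdict == "different")
    if (s + d == 0) return(tibble(n_same = s, n_different = d,
                                  n_unknown = sum(v$verdict == "unknown"),
                                  same_rate = NA_real_))
    tibble(n_same = s, n_different = d, n_unknown = sum(v$verdict == "unknown"),
           same_rate = pct(s, s + d))
  }
  overall <- rate(validations)
  out <- rename(overall, n_same_all = "n_same", n_different_all = "n_different",
                n_unknown_all = "n_unknown", same_rate_all = "same_rate")
  if (!is.null(support)) {
    supported_ids <- if (is.character(support)) support else {
      shared <- filter(support, .data$shared)
      keys <- paste(shared$input_1, shared$input_2)
      validations$output_scaffold[purrr::map_lgl(validations$members, function(mem) {
        m <- mem$input_scaffold
        if (length(m) < 2) return(FALSE)
        any(paste(pmin(m[-length(m)], m[-1]), pmax(m[-length(m)], m[-1])) %in% keys)
      })]
    }
    sup <- rate(filter(validations, .data$output_scaffold %in% supported_ids))
    uns <- rate(filter(validations, !.data$output_scaffold %in% supported_ids))
    out <- dplyr::bind_cols(
      out,
      rename(sup, n_same_supported = "n_same",
             n_different_supported = "n_different",
             n_unknown_supported = "n_unknown",
             same_rate_supported = "same_rate"),
      tibble(same_rate_unsupported = uns$same_rate,
             supported_minus_all = round_half_away(
               sup$same_rate - overall$same_rate, 2))
    )
  }
  out
}

#' Pinpoint rearrangement breakpoints from synteny blocks
#'
#' Walks each query scaffold's blocks in query order; a transition is an
#' adjacent block pair mapping to different chromosomes, opposite strands, or
#' non-collinear target positions (target overlap, direction inconsistent
#' with the strand, or a target gap above `max_colinear_gap`). For each
#' transition side the breakpoint is the reference interval between the
#' flanking block and the nearest block beyond it on the same chromosome:
#' `(end of upstream block + 1, start of downstream block - 1)`, 1-based
#' inclusive, reported only when non-empty and bounded on both sides.
#'
#' @param blocks tibble from [chain_blocks()].
#' @param max_colinear_gap target-side gap (nt) beyond which same-chromosome
#'   adjacent blocks count as a transition; default 1e5.
#' @return tibble: `chromosome`, `start`, `end`, `length`, `left_block`,
#'   `right_block`, `query` (the transition's query scaffold).
#' @export
find_breakpoints <- function(blocks, max_colinear_gap = 1e5) {
  empty <- tibble(chromosome = character(), start = integer(),
                  end = integer(), length = integer(), left_block = integer(),
                  right_block = integer(), query = character())
  if (nrow(blocks) < 2) return(empty)
  by_chr <- split(blocks, blocks$target)

  # nearest block boundaries beyond a position on one chromosome
  interval_after <- function(chr, pos, query) {
    b <- by_chr[[chr]]
    b <- b[b$t_start > pos, , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    i <- which.min(b$t_start)
    list(start = pos + 1L, end = b$t_start[i] - 1L, other = b$block_id[i])
  }
  interval_before <- function(chr, pos, query) {
    b <- by_chr[[chr]]
    b <- b[b$t_end < pos, , drop = FALSE]
    if (nrow(b) == 0) return(NULL)
    i <- which.max(b$t_end)
    list(start = b$t_end[i] + 1L, end = pos - 1L, other = b$block_id[i])
  }

  res <- list()
  add <- function(chr, iv, flank_id, side, query) {
    if (is.null(iv) || iv$end < iv$start) return(invisible())
    res[[length(res) + 1L]] <<- tibble(
      chromosome = chr, start = iv$start, end = iv$end,
      length = iv$end - iv$start + 1L,
      left_block = if (side == "after") flank_id else iv$other,
      right_block = if (side == "after") iv$other else flank_id,
      query = query)
  }

  for (q in unique(blocks$query)) {
    b <- blocks |> filter(.data$query == q) |> arrange(.data$q_start)
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1L)) {
      up <- b[i, ]; dn <- b[i + 1L, ]
      transition <- up$target != dn$target || up$strand != dn$strand
      if (!transition) {
        if (up$strand == "+") {
          tgap <- dn$t_start - up$t_end - 1L
          transition <- tgap < 0 || tgap > max_colinear_gap
        } else {
          tgap <- up$t_start - dn$t_end - 1L
          transition <- tgap < 0 || tgap > max_colinear_gap
        }
      }
      if (!transition) next
      # upstream side: reference boundary at the high-query end of `up`
      if (up$strand == "+") {
        add(up$target, interval_after(up$target, up$t_end), up$block_id,
            "after", q)
      } else {
        add(up$target, interval_before(up$target, up$t_start), up$block_id,
            "before", q)
      }
      # downstream side: reference boundary at the low-query end of `dn`
      if (dn$strand == "+") {
        add(dn$target, interval_before(dn$target, dn$t_start), dn$block_id,
            "before", q)
      } else {
        add(dn$target, interval_after(dn$target, dn$t_end), dn$block_id,
            "after", q)
      }
    }
  }
  if (length(res) == 0) return(empty)
  bind_rows(res) |>
    distinct(.data$chromosome, .data$start, .data$end, .keep_all = TRUE) |>
    arrange(.data$chromosome, .data$start)
}
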