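# Scaffold lineage between an input assembly and a scaffolded output.
# Scaffolding reorders, joins and breaks scaffolds but never edits sequence
# inside contigs, so exact unique k-mer anchors place every contig
# deterministically; anchors hitting more than one output locus (repeats) are
# discarded and contigs without enough unique anchors are reported as
# ambiguous rather than guessed at.

sample_anchor_starts <- function(len, k, n_min, spacing = 2000L, n_max = 32L) {
  if (len < k) return(integer(0))
  n <- max(n_min, min(n_max, ceiling(len / spacing)))
  n <- min(n, len - k + 1L)
  unique(as.integer(round(seq(1L, len - k + 1L, length.out = n))))
}

# Extend an exact diagonal match outwards within contig bounds.
# in_seq/out_seq are uppercase character scalars; returns extended in-coords.
extend_match <- function(in_seq, out_seq, in_lo, in_hi, bound_lo, bound_hi,
                         strand, diag, out_len) {
  # map input coord p -> output coord: '+': p + diag ; '-': diag - p
  step <- 4096L
  # right extension
  repeat {
    if (in_hi >= bound_hi) break
    n <- min(step, bound_hi - in_hi)
    a <- charToRaw(substr(in_seq, in_hi + 1L, in_hi + n))
    if (strand == "+") {
      o_lo <- in_hi + 1L + diag; o_hi <- in_hi + n + diag
      if (o_lo < 1L || o_hi > out_len) { n2 <- max(0L, out_len - diag - in_hi); if (n2 <= 0L) break; n <- min(n, n2); a <- a[seq_len(n)]; o_hi <- in_hi + n + diag }
      b <- charToRaw(substr(out_seq, in_hi + 1L + diag, in_hi + n + diag))
    } else {
      o_hi <- diag - (in_hi + 1L); o_lo <- diag - (in_hi + n)
      if (o_lo < 1L) { n2 <- diag - 1L - in_hi; if (n2 <= 0L) break; n <- min(n, n2); a <- a[seq_len(n)]; o_lo <- diag - (in_hi + n) }
      if (o_hi < 1L) break
      b <- charToRaw(revcomp(substr(out_seq, o_lo, diag - (in_hi + 1L))))
    }
    if (length(b) != length(a)) break
    mm <- first_mismatch(a, b)
    if (mm == 0L) { in_hi <- in_hi + n; if (n < step) next } else { in_hi <- in_hi + mm - 1L; break }
    if (in_hi >= bound_hi) break
  }
  # left extension
  repeat {
    if (in_lo <= bound_lo) break
    n <- min(step, in_lo - bound_lo)
    a <- charToRaw(substr(in_seq, in_lo - n, in_lo - 1L))
    if (strand == "+") {
      o_lo <- in_lo - n + diag
      if (o_lo < 1L) { n2 <- in_lo - 1L + diag; if (n2 <= 0L) break; n <- min(n, n2); a <- charToRaw(substr(in_seq, in_lo - n, in_lo - 1L)) }
      b <- charToRaw(substr(out_seq, in_lo - n + diag, in_lo - 1L + diag))
    } else {
      o_hi <- diag - (in_lo - n)
      if (o_hi > out_len) { n2 <- diag - in_lo - out_len; n2 <- in_lo - (diag - out_len); if (n2 <= 0L) break; n <- min(n, n2); a <- charToRaw(substr(in_seq, in_lo - n, in_lo - 1L)) }
      b <- charToRaw(revcomp(substr(out_seq, diag - (in_lo - 1L), diag - (in_lo - n))))
    }
    if (length(b) != length(a)) break
    mm <- first_mismatch(rev(a), rev(b))
    if (mm == 0L) { in_lo <- in_lo - n; if (n < step) next } else { in_lo <- in_lo - mm + 1L; break }
    if (in_lo <= bound_lo) break
  }
  c(in_lo, in_hi)
}

#' Place input contigs onto a scaffolded output assembly
#'
#' Places every contig of `input` onto `output` by unique exact k-mer
#' anchoring: anchors are sampled along each contig, matched (both strands)
#' against the output, and anchors with more than one output hit are
#' discarded. Anchor clusters on a common diagonal with at least
#' `min_anchor_count` unique anchors seed a placement that is then extended
#' base-by-base to the maximal exact match, so placement boundaries are exact
#' up to the immediate neighbourhood of a break. Contigs whose anchors support
#' conflicting loci are flagged ambiguous and excluded (see the
#' `"ambiguous"` attribute); adjacent placements of the same
#' (input, output, strand) pair are merged into spans.
#'
#' @param input,output assembly tibbles; `output` must derive from `input` by
#'   joining/breaking/reordering with contig sequence unmodified.
#' @param anchor_k anchor k-mer length (default 64).
#' @param min_anchor_count minimum unique anchors supporting a placement
#'   (default 3).
#' @return tibble of placements: `input_scaffold`, `in_start`, `in_end`,
#'   `output_scaffold`, `out_start`, `out_end`, `strand`, `n_anchors`.
#'   Attribute `"ambiguous"`: tibble of excluded contigs with a reason.
#' @export
place_inputs <- function(input, output, anchor_k = 64L, min_anchor_count = 3L) {
  assert_assembly(input, "input")
  assert_assembly(output, "output")
  in_up <- setNames(toupper(input$sequence), input$scaffold)
  out_up <- setNames(toupper(output$sequence), output$scaffold)
  contigs <- detect_contigs(input, min_contig = 1L, min_gap = 1L) |>
    mutate(contig_id = row_number())

  # --- anchors -------------------------------------------------------------
  # match a table of (contig_id, scaffold, a_start) anchors against the
  # output on both strands, keep genome-wide unique hits, add the diagonal
  match_anchors <- function(anch) {
    anch$seq <- unname(substr(in_up[anch$scaffold], anch$a_start,
                              anch$a_start + anchor_k - 1L))
    anch <- filter(anch, !stringr::str_detect(.data$seq, "[^ACGT]"))
    if (nrow(anch) == 0) return(NULL)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(anch$seq))
    hits <- purrr::imap_dfr(out_up, function(oseq, oname) {
      subj <- Biostrings::DNAString(oseq)
      olen <- nchar(oseq)
      mf <- Biostrings::matchPDict(pd, subj)
      sf <- Biostrings::startIndex(mf)
      mr <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      sr <- Biostrings::startIndex(mr)
      fw <- tibble(anchor = rep(seq_along(sf), lengths(sf)),
                   out_start = unlist(sf) %||% integer(0),
                   strand = "+")
      rv0 <- unlist(sr) %||% integer(0)
      rv <- tibble(anchor = rep(seq_along(sr), lengths(sr)),
                   out_start = olen - (rv0 + anchor_k - 1L) + 1L,
                   strand = "-")
      bind_rows(fw, rv) |> mutate(output_scaffold = oname)
    })
    if (nrow(hits) == 0) return(NULL)
    cnt <- table(hits$anchor)
    uniq <- as.integer(names(cnt)[cnt == 1L])
    hits <- filter(hits, .data$anchor %in% uniq)
    if (nrow(hits) == 0) return(NULL)
    dplyr::bind_cols(anch[hits$anchor, ],
                     select(hits, "out_start", "strand", "output_scaffold")) |>
      mutate(diag = ifelse(.data$strand == "+",
                           .data$out_start - .data$a_start,
                           .data$out_start + anchor_k - 1L + .data$a_start))
  }
  cluster_anchors <- function(anch2, min_count) {
    anch2 |>
      group_by(.data$contig_id, .data$scaffold, .data$output_scaffold,
               .data$strand, .data$diag) |>
      summarise(n_anchors = n(), a_lo = min(.data$a_start),
                a_hi = max(.data$a_start) + anchor_k - 1L, .groups = "drop") |>
      filter(.data$n_anchors >= min_count)
  }

  anch <- purrr::pmap_dfr(contigs, function(scaffold, start, end, length, contig_id) {
    st <- sample_anchor_starts(length, anchor_k, min_anchor_count)
    if (length(st) == 0) return(NULL)
    tibble(contig_id = contig_id, scaffold = scaffold,
           a_start = start + st - 1L)
  })
  if (nrow(anch) == 0) stop("assemblies appear unrelated", call. = FALSE)
  anch2 <- match_anchors(anch)
  if (is.null(anch2)) stop("assemblies appear unrelated", call. = FALSE)
  clust <- cluster_anchors(anch2, min_anchor_count)

  # --- refinement pass: re-anchor uncovered contig regions densely --------
  # a contig tail not covered by any cluster (e.g. the short half of a
  # chimera falling between sparse anchors) gets anchors every anchor_k nt
  refine <- purrr::pmap_dfr(contigs, function(scaffold, start, end, length,
                                              contig_id) {
    cl <- clust[clust$contig_id == contig_id, , drop = FALSE]
    covered <- IRanges::reduce(IRanges::IRanges(
      pmax(cl$a_lo - anchor_k, start), pmin(cl$a_hi + anchor_k, end)))
    un <- IRanges::setdiff(IRanges::IRanges(start, end), covered)
    un <- un[IRanges::width(un) >= 3L * anchor_k]
    if (length(un) == 0) return(NULL)
    purrr::map_dfr(seq_along(un), function(i) {
      st <- seq(IRanges::start(un)[i],
                IRanges::end(un)[i] - anchor_k + 1L, by = anchor_k)
      if (length(st) > 200) st <- st[seq(1, length(st), length.out = 200)]
      tibble(contig_id = contig_id, scaffold = scaffold,
             a_start = as.integer(st))
    })
  })
  if (nrow(refine) > 0) {
    anch_r <- match_anchors(refine)
    if (!is.null(anch_r)) {
      clust <- cluster_anchors(bind_rows(anch2, anch_r), min_anchor_count)
    }
  }

  ambiguous <- contigs |>
    filter(!.data$contig_id %in% clust$contig_id) |>
    mutate(reason = ifelse(.data$length < anchor_k, "too_short", "no_unique_anchors")) |>
    select("scaffold", "start", "end", "length", "reason")

  if (nrow(clust) == 0) stop("assemblies appear unrelated", call. = FALSE)

  # --- extend clusters to maximal exact matches ----------------------------
  placements <- purrr::pmap_dfr(clust, function(contig_id, scaffold,
                                                output_scaffold, strand, diag,
                                                n_anchors, a_lo, a_hi) {
    ctg <- contigs[contig_id, ]
    ext <- extend_match(in_up[[scaffold]], out_up[[output_scaffold]],
                        a_lo, a_hi, ctg$start, ctg$end, strand, diag,
                        nchar(out_up[[output_scaffold]]))
    in_s <- ext[1]; in_e <- ext[2]
    if (strand == "+") {
      o_s <- in_s + diag; o_e <- in_e + diag
    } else {
      o_s <- diag - in_e; o_e <- diag - in_s
    }
    tibble(contig_id = contig_id, input_scaffold = scaffold,
           in_start = in_s, in_end = in_e, output_scaffold = output_scaffold,
           out_start = o_s, out_end = o_e, strand = strand, diag = diag,
           n_anchors = n_anchors)
  })

  # resolve per-contig overlaps: nested clusters dropped, large overlaps ->
  # contig flagged ambiguous, small (break-neighbourhood) overlaps trimmed
  resolved <- list(); amb_extra <- list()
  for (cid in unique(placements$contig_id)) {
    p <- placements |> filter(.data$contig_id == cid) |> arrange(.data$in_start, .data$in_end)
    keep <- rep(TRUE, nrow(p))
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(p))) {
        if (i != j && keep[i] && keep[j] &&
            p$in_start[j] <= p$in_start[i] && p$in_end[j] >= p$in_end[i] &&
            (p$in_start[j] < p$in_start[i] || p$in_end[j] > p$in_end[i])) {
          keep[i] <- FALSE
        }
      }
    }
    p <- p[keep, ]
    bad <- FALSE
    if (nrow(p) > 1) {
      for (i in seq_len(nrow(p) - 1L)) {
        ov <- p$in_end[i] - p$in_start[i + 1L] + 1L
        if (ov > 2L * anchor_k) { bad <- TRUE; break }
        if (ov > 0L) {
          half <- ov %/% 2L
          p$in_end[i] <- p$in_end[i] - (ov - half)
          p$in_start[i + 1L] <- p$in_start[i + 1L] + half
        }
      }
    }
    if (bad) {
      ctg <- contigs[cid, ]
      amb_extra[[length(amb_extra) + 1L]] <-
        tibble(scaffold = ctg$scaffold, start = ctg$start, end = ctg$end,
               length = ctg$length, reason = "conflicting_placements")
    } else {
      resolved[[length(resolved) + 1L]] <- p
    }
  }
  placements <- bind_rows(resolved)
  if (nrow(placements) == 0) stop("assemblies appear unrelated", call. = FALSE)
  # recompute output coords after any trimming (the diagonal is invariant)
  placements <- placements |>
    mutate(out_start = ifelse(.data$strand == "+",
                              .data$in_start + .data$diag,
                              .data$diag - .data$in_end),
           out_end = ifelse(.data$strand == "+",
                            .data$in_end + .data$diag,
                            .data$diag - .data$in_start)) |>
    select(-"diag")

  # --- merge adjacent same-pair placements ---------------------------------
  placements <- placements |>
    arrange(.data$input_scaffold, .data$in_start) |>
    group_by(.data$input_scaffold) |>
    mutate(new_run = cumsum(
      row_number() == 1L |
        .data$output_scaffold != lag(.data$output_scaffold, default = "") |
        .data$strand != lag(.data$strand, default = "")
    )) |>
    ungroup() |>
    group_by(.data$input_scaffold, .data$new_run, .data$output_scaffold,
             .data$strand) |>
    summarise(in_start = min(.data$in_start), in_end = max(.data$in_end),
              out_start = min(.data$out_start), out_end = max(.data$out_end),
              n_anchors = sum(.data$n_anchors), .groups = "drop") |>
    select("input_scaffold", "in_start", "in_end", "output_scaffold",
           "out_start", "out_end", "strand", "n_anchors") |>
    arrange(.data$input_scaffold, .data$in_start)

  attr(placements, "ambiguous") <- bind_rows(ambiguous, bind_rows(amb_extra))
  placements
}

#' Call join events from placements
#'
#' One join event per output scaffold that carries two or more distinct input
#' scaffolds. Members are ordered by output coordinate; gaps of the output
#' assembly falling between consecutive members are attached.
#'
#' @param placements placement tibble from [place_inputs()].
#' @param output_gaps gap tibble of the output assembly ([detect_gaps()]),
#'   or `NULL`.
#' @return tibble with one row per join: `output_scaffold`, `n_members`,
#'   `members` (list of tibbles `input_scaffold`, `orientation`),
#'   `gap_between` (list of gap tibbles, one gap per junction where present).
#' @export
call_joins <- function(placements, output_gaps = NULL) {
  ord <- placements |> arrange(.data$output_scaffold, .data$out_start)
  joins <- ord |>
    group_by(.data$output_scaffold) |>
    filter(.data$input_scaffold != lag(.data$input_scaffold, default = "")) |>
    ungroup() |>
    select("output_scaffold", "input_scaffold", orientation = "strand",
           "out_start", "out_end", "in_start", "in_end") |>
    tidyr::nest(members = !"output_scaffold") |>
    mutate(n_members = purrr::map_int(.data$members,
                                      ~ dplyr::n_distinct(.x$input_scaffold))) |>
    filter(.data$n_members >= 2L)
  if (nrow(joins) == 0) {
    return(tibble(output_scaffold = character(), n_members = integer(),
                  members = list(), gap_between = list()))
  }
  joins$gap_between <- purrr::map2(joins$output_scaffold, joins$members,
    function(os, mem) {
      if (is.null(output_gaps) || nrow(output_gaps) == 0) {
        return(tibble(start = integer(), end = integer(), length = integer()))
      }
      g <- filter(output_gaps, .data$scaffold == os)
      purrr::map_dfr(seq_len(nrow(mem) - 1L), function(i) {
        filter(g, .data$start > mem$out_end[i], .data$end < mem$out_start[i + 1L])
      })
    })
  select(joins, "output_scaffold", "n_members", "members", "gap_between")
}

#' Summary statistics of a join set
#'
#' The number of input scaffolds joined, the number of resulting output
#' scaffolds, and scaffolds-per-join means both per join event and per output
#' scaffold (the two readings of "average scaffolds per join").
#'
#' @param joins tibble from [call_joins()].
#' @return a one-row tibble.
#' @export
join_summary <- function(joins) {
  members <- purrr::map_dfr(joins$members, ~.x)
  n_inputs <- dplyr::n_distinct(members$input_scaffold)
  tibble(
    n_inputs_joined = n_inputs,
    n_join_events = nrow(joins),
    scaffolds_per_join = if (nrow(joins) > 0) n_inputs / nrow(joins) else NA_real_,
    mean_members_per_output = if (nrow(joins) > 0) mean(joins$n_members) else NA_real_
  )
}

#' Call break events from placements
#'
#' One break event row per transition where an input scaffold continues on a
#' different output scaffold. The break position is the input coordinate of
#' the last base placed before the transition. When `input_gaps` is supplied,
#' the distance from each break to the nearest input gap is reported.
#'
#' @param placements placement tibble from [place_inputs()].
#' @param input_gaps optional gap tibble for the input assembly.
#' @return tibble: `input_scaffold`, `position`, `left_output`,
#'   `right_output`, and `dist_to_gap` when `input_gaps` is given.
#' @export
call_breaks <- function(placements, input_gaps = NULL) {
  br <- placements |>
    arrange(.data$input_scaffold, .data$in_start) |>
    group_by(.data$input_scaffold) |>
    mutate(next_out = lead(.data$output_scaffold),
           next_start = lead(.data$in_start)) |>
    ungroup() |>
    filter(!is.na(.data$next_out), .data$next_out != .data$output_scaffold) |>
    mutate(position = .data$in_end,
           left_output = .data$output_scaffold,
           right_output = .data$next_out) |>
    select("input_scaffold", "position", "left_output", "right_output")
  if (!is.null(input_gaps) && nrow(br) > 0) {
    br$dist_to_gap <- purrr::map2_dbl(br$input_scaffold, br$position,
      function(s, p) {
        g <- filter(input_gaps, .data$scaffold == s)
        if (nrow(g) == 0) return(NA_real_)
        min(pmax(0, pmax(g$start - p, p - g$end)))
      })
  }
  br
}

#' Size-class breakdown of joined input scaffolds
#'
#' Splits the input scaffolds participating in joins into size classes at the
#' given cutoffs and reports per-class counts together with min/max/N50/N90
#' and total length of the joined scaffolds. The first row (`all`) covers
#' every joined scaffold.
#'
#' @param joins tibble from [call_joins()].
#' @param input input assembly tibble (source of scaffold lengths).
#' @param cutoffs ascending class boundaries in nt; default `c(1e5, 1e6)`
#'   (sub-100 kb, 100 kb-1 Mb, >= 1 Mb), plus cumulative `ge_` classes.
#' @return tibble with one row per class.
#' @export
join_size_classes <- function(joins, input, cutoffs = c(1e5, 1e6)) {
  members <- purrr::map_dfr(joins$members, ~.x)
  member_names <- if (nrow(members) > 0) unique(members$input_scaffold)
                  else character(0)
  lens <- scaffold_lengths(input)
  joined <- lens |> filter(.data$scaffold %in% member_names)
  classify <- function(df, label) {
    if (nrow(df) == 0) {
      return(tibble(class = label, n = 0L, min_scaffold = NA_real_,
                    max_scaffold = NA_real_, scaffold_n50 = NA_real_,
                    scaffold_n90 = NA_real_, total_length = 0))
    }
    l <- as.numeric(df$length)
    tibble(class = label, n = nrow(df), min_scaffold = min(l),
           max_scaffold = max(l), scaffold_n50 = nxx(l, 50),
           scaffold_n90 = nxx(l, 90), total_length = sum(l))
  }
  cuts <- sort(cutoffs)
  bounds <- c(0, cuts, Inf)
  bands <- purrr::map_dfr(seq_len(length(bounds) - 1L), function(i) {
    lab <- if (i == 1) sprintf("lt_%s", format(bounds[2], scientific = FALSE))
           else if (is.infinite(bounds[i + 1])) sprintf("ge_%s", format(bounds[i], scientific = FALSE))
           else sprintf("%s_to_%s", format(bounds[i], scientific = FALSE),
                        format(bounds[i + 1], scientific = FALSE))
    classify(filter(joined, .data$length >= bounds[i],
                    .data$length < bounds[i + 1]), lab)
  })
  cum <- purrr::map_dfr(cuts, function(ct) {
    classify(filter(joined, .data$length >= ct),
             sprintf("ge_%s_cum", format(ct, scientific = FALSE)))
  })
  bind_rows(classify(joined, "all"), bands, cum)
}

join_pairs <- function(joins) {
  purrr::map2_dfr(joins$output_scaffold, joins$members, function(os, mem) {
    m <- mem$input_scaffold
    if (length(m) < 2) return(NULL)
    tibble(output_scaffold = os,
           input_1 = pmin(m[-length(m)], m[-1]),
           input_2 = pmax(m[-length(m)], m[-1]))
  }) |> distinct(.data$input_1, .data$input_2, .keep_all = TRUE)
}

#' Compare the join sets of two technologies
#'
#' A shared join is an unordered, directly adjacent pair of input scaffolds
#' joined in both sets (any orientation). Also reports the input scaffolds
#' scaffolded by both technologies (co-membership, the published "scaffolded
#' by both" count).
#'
#' @param joins_a,joins_b join tibbles from [call_joins()].
#' @return tibble of adjacent pairs with logical columns `in_a`, `in_b`,
#'   `shared`; attributes `"shared_inputs"` (character vector of input
#'   scaffolds joined by both) and `"summary"` (one-row count tibble).
#' @export
compare_join_sets <- function(joins_a, joins_b) {
  pa <- join_pairs(joins_a)
  pb <- join_pairs(joins_b)
  all_pairs <- dplyr::full_join(
    mutate(pa, in_a = TRUE), mutate(pb, in_b = TRUE),
    by = c("input_1", "input_2")
  ) |>
    mutate(in_a = !is.na(.data$in_a), in_b = !is.na(.data$in_b),
           shared = .data$in_a & .data$in_b) |>
    select("input_1", "input_2", "in_a", "in_b", "shared")
  mem_a <- unique(unlist(purrr::map(joins_a$members, "input_scaffold")))
  mem_b <- unique(unlist(purrr::map(joins_b$members, "input_scaffold")))
  shared_inputs <- intersect(mem_a, mem_b)
  attr(all_pairs, "shared_inputs") <- shared_inputs
  attr(all_pairs, "summary") <- tibble(
    n_pairs_a = sum(all_pairs$in_a), n_pairs_b = sum(all_pairs$in_b),
    n_shared_pairs = sum(all_pairs$shared),
    n_unique_a = sum(all_pairs$in_a & !all_pairs$shared),
    n_unique_b = sum(all_pairs$in_b & !all_pairs$shared),
    n_shared_inputs = length(shared_inputs)
  )
  all_pairs
}
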