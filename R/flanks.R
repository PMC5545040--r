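# Repeat enrichment in fixed-width flanks around scaffolding events (gaps or
# breaks), against a permutation null of random positions in contig space.

# Global (concatenated) coordinate bookkeeping so multi-scaffold interval
# arithmetic reduces to one IRanges universe per run.
global_offsets <- function(assembly) {
  len <- nchar(assembly$sequence)
  setNames(cumsum(c(0, as.numeric(len[-length(len)]))), assembly$scaffold)
}

to_global <- function(df, offsets) {
  IRanges::IRanges(start = df$start + offsets[df$scaffold],
                   end = df$end + offsets[df$scaffold])
}

# lowercase (softmask) runs as a tibble(scaffold, start, end)
softmask_runs <- function(assembly) {
  purrr::map2_dfr(assembly$scaffold, assembly$sequence, function(s, seq) {
    m <- gregexpr("[acgtumrwsykvhdb]+", seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    tibble(scaffold = s, start = as.integer(m),
           end = as.integer(m) + attr(m, "match.length") - 1L)
  })
}

#' Repeat enrichment in event flanks
#'
#' Measures the repeat fraction of the sequence flanking scaffolding events
#' (captured gaps or break positions) against the genome-wide background, with
#' a one-sided permutation test: the same number of events (with the same
#' widths) is re-drawn uniformly over contig space `n_perm` times and the
#' pooled flank repeat fraction recomputed;
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' Flanks are up to `flank` nt on each side of an event, truncated at scaffold
#' ends and excluding gap (N) bases. The repeat annotation is the union of
#' `repeats` intervals and softmasked (lowercase) runs when `softmask = TRUE`;
#' at least one source must be available.
#'
#' @param assembly assembly tibble.
#' @param events tibble with `scaffold` and either `start`/`end` or
#'   `position` columns.
#' @param repeats optional repeat intervals: tibble (`scaffold`, `start`,
#'   `end`, 1-based inclusive) or a BED path (0-based half-open, converted on
#'   read).
#' @param flank flank width in nt on each side; default 1e4.
#' @param n_perm number of permutations; default 1000.
#' @param seed integer seed for the permutation RNG (set it for
#'   reproducibility).
#' @param softmask also count lowercase runs as repeat; default TRUE.
#' @return an object of class `flank_enrichment`: list with `summary`
#'   (one-row tibble: observed and background fractions, enrichment ratio,
#'   p-value, n_events, n_perm, seed), `per_event` (per-event flank repeat
#'   fractions) and `null` (the permutation null fractions). Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
flank_repeat_enrichment <- function(assembly, events, repeats = NULL,
                                    flank = 1e4, n_perm = 1000L, seed = NULL,
                                    softmask = TRUE) {
  assert_assembly(assembly)
  if (is.null(events) || nrow(events) == 0) stop("no events", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.character(repeats) && length(repeats) == 1) repeats <- read_bed(repeats)
  rep_tbl <- repeats %||% tibble(scaffold = character(), start = integer(),
                                 end = integer())
  if (softmask) rep_tbl <- bind_rows(rep_tbl, softmask_runs(assembly))
  if (nrow(rep_tbl) == 0) {
    stop("no repeat annotation: supply `repeats` or softmasked sequence",
         call. = FALSE)
  }
  if (!"start" %in% names(events) && "position" %in% names(events)) {
    events <- mutate(events, start = .data$position, end = .data$position)
  }
  if (!"end" %in% names(events)) events <- mutate(events, end = .data$start)

  off <- global_offsets(assembly)
  lens <- setNames(nchar(assembly$sequence), assembly$scaffold)
  sc <- scan_assembly(assembly, min_contig = 1L, min_gap = 1L)
  ctg_g <- IRanges::reduce(to_global(sc$contigs, off))
  rep_g <- IRanges::reduce(IRanges::intersect(to_global(rep_tbl, off), ctg_g))
  background <- sum(IRanges::width(rep_g)) / sum(IRanges::width(ctg_g))

  flanks_of <- function(scaf, start, end) {
    ls <- pmax(1, start - flank); le <- pmax(1, start - 1)
    rs <- pmin(lens[scaf], end + 1); re <- pmin(lens[scaf], end + flank)
    keep_l <- le >= ls & start > 1
    keep_r <- re >= rs & end < lens[scaf]
    gl <- IRanges::IRanges(ls[keep_l] + off[scaf[keep_l]],
                           le[keep_l] + off[scaf[keep_l]])
    gr <- IRanges::IRanges(rs[keep_r] + off[scaf[keep_r]],
                           re[keep_r] + off[scaf[keep_r]])
    list(left = gl, right = gr, idx_l = which(keep_l), idx_r = which(keep_r))
  }
  frac_in <- function(ir) {
    ir <- IRanges::intersect(IRanges::reduce(ir), ctg_g)
    w <- sum(IRanges::width(ir))
    if (w == 0) return(NA_real_)
    sum(IRanges::width(IRanges::intersect(ir, rep_g))) / w
  }

  fl <- flanks_of(events$scaffold, events$start, events$end)
  observed <- frac_in(c(fl$left, fl$right))

  # per-event fractions
  per_event <- events
  per_event$flank_repeat_fraction <- vapply(seq_len(nrow(events)), function(i) {
    f <- flanks_of(events$scaffold[i], events$start[i], events$end[i])
    frac_in(c(f$left, f$right))
  }, numeric(1))

  # permutation null: widths preserved, positions uniform over contig space
  widths <- events$end - events$start + 1L
  ctg <- sc$contigs
  probs <- as.numeric(ctg$length) / sum(as.numeric(ctg$length))
  null <- vapply(seq_len(n_perm), function(p) {
    ci <- sample.int(nrow(ctg), length(widths), replace = TRUE, prob = probs)
    offs <- floor(runif(length(widths)) * pmax(1, ctg$length[ci] - widths + 1))
    st <- ctg$start[ci] + as.integer(offs)
    en <- pmin(st + widths - 1L, ctg$end[ci])
    f <- flanks_of(ctg$scaffold[ci], st, en)
    frac_in(c(f$left, f$right))
  }, numeric(1))
  pval <- (1 + sum(null >= observed, na.rm = TRUE)) / (1 + n_perm)

  out <- list(
    summary = tibble(
      n_events = nrow(events),
      flank_repeat_fraction = observed,
      background_repeat_fraction = background,
      enrichment_ratio = observed / background,
      p_value = pval,
      n_perm = n_perm,
      seed = seed %||% NA_integer_,
      flank = flank
    ),
    per_event = per_event,
    null = null
  )
  class(out) <- "flank_enrichment"
  out
}

#' @export
print.flank_enrichment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Flank repeat enrichment: %d events, flank %s nt\n",
                     "  flank fraction %.4f vs background %.4f ",
                     "(ratio %.2f), permutation p = %.4g (%d perms)\n"),
              s$n_events, format(s$flank, scientific = FALSE),
              s$flank_repeat_fraction, s$background_repeat_fraction,
              s$enrichment_ratio, s$p_value, s$n_perm))
  invisible(x)
}

#' @rdname flank_repeat_enrichment
#' @param x a `flank_enrichment` object.
#' @param ... unused.
#' @export
tidy.flank_enrichment <- function(x, ...) as_tibble(x$per_event)

#' @rdname flank_repeat_enrichment
#' @export
glance.flank_enrichment <- function(x, ...) x$summary

#' @rdname flank_repeat_enrichment
#' @param object a `flank_enrichment` object.
#' @export
autoplot.flank_enrichment <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$summary$flank_repeat_fraction,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "null flank repeat fraction", y = "permutations",
                  title = sprintf("Observed %.3f, p = %.3g",
                                  object$summary$flank_repeat_fraction,
                                  object$summary$p_value)) +
    ggplot2::theme_minimal()
}

#' Read intervals from a BED file
#'
#' Converts BED's 0-based half-open coordinates to 1-based inclusive.
#'
#' @param path BED file (first three columns used).
#' @return tibble: `scaffold`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  out <- tibble(scaffold = as.character(df[[1]]),
                start = as.integer(df[[2]]) + 1L,
                end = as.integer(df[[3]]))
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write intervals to a BED file
#'
#' @param df tibble with `scaffold`, `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$scaffold, df$start - 1L, df$end)
  if ("name" %in% names(df)) out$name <- df$name
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
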