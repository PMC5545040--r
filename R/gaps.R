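# Captured-gap and contig accounting. A gap is a maximal run of N of at least
# `min_gap` nt; short non-N islands trapped between two gaps (optical-map
# pipelines leave restriction-site fragments inside their sized gaps) are
# merged into a single gap so that each join contributes one gap. Terminal
# contigs are never merged: the island rule targets sequence *between* gaps.

scan_scaffold <- function(seq, min_contig = 200L, min_gap = 1L) {
  len <- nchar(seq)
  m <- gregexpr("[Nn]+", seq, perl = TRUE)[[1]]
  gaps <- tibble(start = integer(), end = integer())
  if (m[1] != -1L) {
    st <- as.integer(m)
    en <- st + attr(m, "match.length") - 1L
    keep <- (en - st + 1L) >= min_gap
    st <- st[keep]; en <- en[keep]
    if (length(st) > 0) {
      # left-to-right merge of sub-min_contig islands between gap seeds
      out_s <- integer(0); out_e <- integer(0)
      cur_s <- st[1]; cur_e <- en[1]
      for (i in seq_along(st)[-1]) {
        island <- st[i] - cur_e - 1L
        if (island < min_contig) {
          cur_e <- en[i]
        } else {
          out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
          cur_s <- st[i]; cur_e <- en[i]
        }
      }
      gaps <- tibble(start = c(out_s, cur_s), end = c(out_e, cur_e))
    }
  }
  contigs <- tbl_of_iranges(IRanges::setdiff(
    IRanges::IRanges(1L, len), iranges_of(gaps)
  ))
  list(gaps = gaps, contigs = contigs)
}

scan_assembly <- function(assembly, min_contig = 200L, min_gap = 1L) {
  assert_assembly(assembly)
  res <- purrr::map(assembly$sequence, scan_scaffold,
                    min_contig = min_contig, min_gap = min_gap)
  gaps <- purrr::map2_dfr(assembly$scaffold, res, function(s, r) {
    if (nrow(r$gaps) == 0) return(NULL)
    mutate(r$gaps, scaffold = s, .before = 1)
  })
  contigs <- purrr::map2_dfr(assembly$scaffold, res, function(s, r) {
    if (nrow(r$contigs) == 0) return(NULL)
    mutate(r$contigs, scaffold = s, .before = 1)
  })
  empty <- tibble(scaffold = character(), start = integer(), end = integer())
  if (nrow(gaps) == 0) gaps <- empty
  if (nrow(contigs) == 0) contigs <- empty
  list(gaps = mutate(gaps, length = .data$end - .data$start + 1L),
       contigs = mutate(contigs, length = .data$end - .data$start + 1L))
}

#' Detect captured gaps in an assembly
#'
#' Finds maximal N runs of at least `min_gap` nt in every scaffold. Non-N
#' islands shorter than `min_contig` that lie between two gaps are merged with
#' their neighbours into a single gap, so one scaffolding join yields one gap
#' even when the scaffolder fills the gap with short sequence fragments.
#' Detection ignores case (softmasked `n` counts as gap).
#'
#' @param assembly assembly tibble (`scaffold`, `sequence`).
#' @param min_contig minimum island size (nt) for sequence between two gaps to
#'   count as a contig rather than being merged into the gap; default 200.
#' @param min_gap minimum N-run length (nt) that counts as a gap; default 1.
#' @param origin technology label recorded in the `origin` column
#'   (default `"unknown"`).
#' @return tibble with columns `scaffold`, `start`, `end`, `length`, `origin`
#'   (1-based inclusive coordinates, sorted and non-overlapping per scaffold).
#' @seealso [detect_contigs()] for the complementary contig set.
#' @examples
#' a <- assembly(s1 = paste0(strrep("A", 300), strrep("N", 50),
#'                           strrep("G", 30), strrep("N", 50), strrep("T", 300)))
#' detect_gaps(a)  # one merged gap of 130 nt
#' @export
detect_gaps <- function(assembly, min_contig = 200L, min_gap = 1L,
                        origin = "unknown") {
  stopifnot(min_contig >= 1, min_gap >= 1)
  mutate(scan_assembly(assembly, min_contig, min_gap)$gaps, origin = origin)
}

#' Derive contig records from an assembly
#'
#' Contigs are the maximal runs of a scaffold not classified as gap content by
#' the same rules as [detect_gaps()]; contigs and gaps tile each scaffold
#' exactly.
#'
#' @inheritParams detect_gaps
#' @return tibble with columns `scaffold`, `start`, `end`, `length`.
#' @export
detect_contigs <- function(assembly, min_contig = 200L, min_gap = 1L) {
  stopifnot(min_contig >= 1, min_gap >= 1)
  scan_assembly(assembly, min_contig, min_gap)$contigs
}

#' Write an assembly as AGP v2.1
#'
#' Emits one W line per contig and one N line per gap; the gap line's evidence
#' column carries the gap's `origin` label. Bases of sub-`min_contig` islands
#' that were merged into gaps are preserved in `# island` comment lines so the
#' AGP plus the component FASTA reconstructs the scaffold FASTA byte for byte.
#'
#' @param assembly assembly tibble.
#' @param gaps gap tibble from [detect_gaps()].
#' @param path output AGP path.
#' @param fasta_path optional path; when given, component (contig) sequences
#'   are also written there as FASTA.
#' @return `path`, invisibly.
#' @export
write_agp <- function(assembly, gaps, path, fasta_path = NULL) {
  assert_assembly(assembly)
  lines <- c("##agp-version\t2.1")
  comp_names <- character(0)
  comp_seqs <- character(0)
  for (i in seq_len(nrow(assembly))) {
    scaf <- assembly$scaffold[i]
    seq <- assembly$sequence[i]
    len <- nchar(seq)
    g <- filter(gaps, .data$scaffold == scaf) |> arrange(.data$start)
    if (nrow(g) > 0 && (any(g$start < 1) || any(g$end > len) ||
                        any(g$end - g$start + 1 != g$length))) {
      stop("gap coordinates inconsistent with scaffold ", scaf, call. = FALSE)
    }
    contigs <- tbl_of_iranges(IRanges::setdiff(IRanges::IRanges(1L, len),
                                               iranges_of(g)))
    parts <- bind_rows(
      mutate(contigs, type = "W"),
      if (nrow(g) > 0) mutate(select(g, "start", "end"), type = "N",
                              origin = g$origin)
    ) |> arrange(.data$start)
    ctg_i <- 0L
    for (j in seq_len(nrow(parts))) {
      p <- parts[j, ]
      if (p$type == "W") {
        ctg_i <- ctg_i + 1L
        cid <- sprintf("%s_ctg%03d", scaf, ctg_i)
        comp_names <- c(comp_names, cid)
        comp_seqs <- c(comp_seqs, substr(seq, p$start, p$end))
        lines <- c(lines, paste(scaf, p$start, p$end, j, "W", cid, 1L,
                                p$end - p$start + 1L, "+", sep = "\t"))
      } else {
        sub <- substr(seq, p$start, p$end)
        isl <- gregexpr("[^Nn]+", sub, perl = TRUE)[[1]]
        if (isl[1] != -1L) {
          for (k in seq_along(isl)) {
            is0 <- as.integer(isl[k])
            iw <- attr(isl, "match.length")[k]
            lines <- c(lines, sprintf("# island\t%s\t%d\t%d\t%s", scaf,
                                      p$start + is0 - 1L,
                                      p$start + is0 + iw - 2L,
                                      substr(sub, is0, is0 + iw - 1L)))
          }
        }
        lines <- c(lines, paste(scaf, p$start, p$end, j, "N",
                                p$end - p$start + 1L, "scaffold", "yes",
                                p$origin, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  if (!is.null(fasta_path)) {
    write_fasta(tibble(scaffold = comp_names, sequence = comp_seqs), fasta_path)
  }
  invisible(path)
}

#' Reconstruct an assembly from AGP plus component sequences
#'
#' Inverse of [write_agp()]: rebuilds scaffold sequences from W lines (looked
#' up in `components`), N lines (emitted as N runs) and `# island` comments
#' (restoring merged-island bases inside gaps).
#'
#' @param path AGP file written by [write_agp()].
#' @param components named character vector of component sequences, or a path
#'   to the component FASTA.
#' @return an assembly tibble.
#' @export
read_agp <- function(path, components) {
  if (is.character(components) && length(components) == 1 &&
      file.exists(components)) {
    fa <- read_fasta(components)
    components <- setNames(fa$sequence, fa$scaffold)
  }
  lines <- readLines(path)
  islands <- lines[startsWith(lines, "# island")]
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  scafs <- list()
  for (p in parts) {
    scaf <- p[1]
    if (!scaf %in% names(scafs)) scafs[[scaf]] <- character(0)
    piece <- if (p[5] == "W") {
      comp <- components[[p[6]]]
      if (is.null(comp)) stop("missing component ", p[6], call. = FALSE)
      substr(comp, as.integer(p[7]), as.integer(p[8]))
    } else {
      strrep("N", as.integer(p[6]))
    }
    exp_len <- as.integer(p[3]) - as.integer(p[2]) + 1L
    if (nchar(piece) != exp_len) {
      stop("AGP coordinate inconsistency at ", scaf, ":", p[2], call. = FALSE)
    }
    scafs[[scaf]] <- c(scafs[[scaf]], piece)
  }
  out <- tibble(scaffold = names(scafs),
                sequence = unname(purrr::map_chr(scafs, paste0, collapse = "")))
  # restore merged-island bases
  if (length(islands) > 0) {
    fields <- strsplit(islands, "\t", fixed = TRUE)
    for (f in fields) {
      i <- match(f[2], out$scaffold)
      s <- as.integer(f[3]); e <- as.integer(f[4])
      substr(out$sequence[i], s, e) <- f[5]
    }
  }
  out
}
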