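# End-to-end orchestration: simulate -> scaffold with each technology ->
# statistics -> join/break lineage -> cross-technology comparison -> synteny
# validation -> breakpoints -> novel sequence -> flank enrichment.

#' Run the full simulation and evaluation pipeline
#'
#' Generates a reference and accession, fragments the accession into a base
#' assembly, scaffolds it with each technology profile, and runs every
#' evaluation stage of the package, returning all reports in one bundle.
#' Deterministic given `config$seed` and the profiles.
#'
#' @param config a [sim_config()]; `config$seed` seeds all randomness.
#' @param technologies named list of [technology_profile()]s; default one
#'   proximity-ligation-like and one optical-map-like profile.
#' @param flank flank width (nt) for the repeat-enrichment stage.
#' @param n_perm permutations for the repeat-enrichment stage.
#' @return a named list of class `scaffeval_bundle`: `config`, `stats`
#'   (Table-style continuity statistics, one row per assembly), per
#'   technology `joins`, `breaks`, `join_summary`, `size_classes`,
#'   `validation`, `flanks`, plus `comparison`, `comparison_summary`,
#'   `breakpoints`, `novel_totals`, `novel_genes`, and `truth` (the
#'   simulation ground truth).
#' @export
run_pipeline <- function(config = sim_config(),
                         technologies = list(
                           proximity = technology_profile("proximity"),
                           opticalmap = technology_profile("opticalmap")),
                         flank = 1e4, n_perm = 200L) {
  set.seed(config$seed)
  ref <- simulate_reference(config)
  acc <- simulate_accession(ref, config)
  frag <- fragment_assembly(acc, config)
  base <- frag$assembly

  stats <- mutate(assembly_stats(base), assembly = "base", .before = 1)
  per_tech <- list()
  joins_by_tech <- list()
  scaffolded <- list()
  for (tn in names(technologies)) {
    prof <- technologies[[tn]]
    sc <- simulate_scaffolding(frag, prof)
    out <- sc$assembly
    scaffolded[[tn]] <- sc
    gaps <- detect_gaps(out, origin = prof$name)
    stats <- bind_rows(stats,
                       mutate(assembly_stats(out), assembly = tn, .before = 1))
    placements <- place_inputs(base, out)
    joins <- call_joins(placements, gaps)
    joins_by_tech[[tn]] <- joins
    breaks <- call_breaks(placements, detect_gaps(base))
    fl <- tryCatch(
      flank_repeat_enrichment(out, gaps, repeats = lift_gap_repeats(sc, acc),
                              flank = flank, n_perm = n_perm,
                              seed = config$seed, softmask = FALSE),
      error = function(e) NULL)
    per_tech[[tn]] <- list(
      gaps = gaps, placements = placements, joins = joins, breaks = breaks,
      join_summary = join_summary(joins),
      size_classes = join_size_classes(joins, base),
      gap_stats = gap_stats(gaps),
      flanks = fl,
      truth = sc$truth
    )
  }

  comparison <- if (length(technologies) >= 2) {
    compare_join_sets(joins_by_tech[[1]], joins_by_tech[[2]])
  } else NULL

  # synteny validation of joins (queries = base contigs)
  aln_ctg <- simulate_alignments(acc, ref, provenance = frag$provenance)
  blocks_ctg <- chain_blocks(aln_ctg)
  for (tn in names(technologies)) {
    val <- classify_joins(joins_by_tech[[tn]], blocks_ctg)
    per_tech[[tn]]$validation <- val
    per_tech[[tn]]$validation_rates <-
      validation_rates(val, support = comparison)
  }

  # whole-accession synteny: breakpoints + novel sequence
  aln_acc <- simulate_alignments(acc, ref)
  blocks_acc <- chain_blocks(aln_acc)
  bp <- find_breakpoints(blocks_acc)
  nov <- novel_sequence(acc$genome, aln_acc)
  ng <- novel_genes(nov, acc$genes)

  out <- list(
    config = config,
    stats = stats,
    per_tech = per_tech,
    comparison = comparison,
    comparison_summary = if (!is.null(comparison)) attr(comparison, "summary"),
    blocks = blocks_acc,
    breakpoints = bp,
    novel_segments = nov,
    novel_totals = attr(nov, "totals"),
    novel_genes = ng,
    truth = list(reference = ref[c("repeats", "genes")],
                 accession = acc[c("segment_map", "breakpoints", "novel")],
                 provenance = frag$provenance, chimeras = frag$chimeras),
    assemblies = c(list(base = base),
                   purrr::map(scaffolded, "assembly"))
  )
  class(out) <- "scaffeval_bundle"
  out
}

# accession repeat annotation lifted onto an output assembly's scaffolds via
# the join truth and provenance (used for the pipeline's flank stage);
# repeats straddling a piece boundary are clipped, not dropped
lift_gap_repeats <- function(sc, acc) {
  prov <- sc$provenance
  joins <- sc$truth$joins
  empty <- tibble(scaffold = character(), start = integer(), end = integer())

  clip_repeats <- function(acc_chrom, acc_start, acc_end) {
    r <- filter(acc$repeats, .data$scaffold == acc_chrom,
                .data$end >= acc_start, .data$start <= acc_end)
    if (nrow(r) == 0) return(NULL)
    tibble(start = pmax(r$start, acc_start) - acc_start + 1L,
           end = pmin(r$end, acc_end) - acc_start + 1L) # piece-local (+)
  }

  rows <- list()
  joined_members <- unique(joins$member)
  # joined scaffolds: pieces laid out accession-forward at cumulative offsets
  for (os in unique(joins$output_scaffold)) {
    mem <- filter(joins, .data$output_scaffold == os) |> arrange(.data$ord)
    pos <- 0L
    for (i in seq_len(nrow(mem))) {
      p <- filter(prov, .data$contig == mem$member[i])
      seg_len <- p$acc_end[1] - p$acc_start[1] + 1L
      r <- clip_repeats(p$acc_chrom[1], p$acc_start[1], p$acc_end[1])
      if (!is.null(r)) {
        rows[[length(rows) + 1L]] <- mutate(r, scaffold = os,
                                            start = .data$start + pos,
                                            end = .data$end + pos)
      }
      pos <- pos + seg_len + (if (!is.na(mem$gap_after[i])) mem$gap_after[i] else 0L)
    }
  }
  # pass-through scaffolds keep their stored orientation
  passthrough <- filter(prov, !.data$contig %in% joined_members)
  for (i in seq_len(nrow(passthrough))) {
    p <- passthrough[i, ]
    if (!p$contig %in% sc$assembly$scaffold) next
    r <- clip_repeats(p$acc_chrom, p$acc_start, p$acc_end)
    if (is.null(r)) next
    len <- p$acc_end - p$acc_start + 1L
    if (p$strand == "-") {
      r <- tibble(start = len - r$end + 1L, end = len - r$start + 1L)
    }
    rows[[length(rows) + 1L]] <- mutate(r, scaffold = p$contig,
                                        start = .data$start + p$contig_start - 1L,
                                        end = .data$end + p$contig_start - 1L)
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> select("scaffold", "start", "end") |>
    arrange(.data$scaffold, .data$start)
}

#' @export
print.scaffeval_bundle <- function(x, ...) {
  cat("scaffeval pipeline bundle (seed ", x$config$seed, ")\n", sep = "")
  cat("assemblies: ", paste(x$stats$assembly, collapse = ", "), "\n", sep = "")
  print(select(x$stats, "assembly", "n_scaffolds", "n_contigs",
               "scaffold_length", "scaffold_n50", "n_gaps",
               "total_gap_length"))
  for (tn in names(x$per_tech)) {
    js <- x$per_tech[[tn]]$join_summary
    cat(sprintf("%s: %d inputs joined into %d scaffolds (%.2f per join)\n",
                tn, js$n_inputs_joined, js$n_join_events,
                js$scaffolds_per_join))
  }
  if (!is.null(x$comparison_summary)) {
    cat(sprintf("shared adjacent joins: %d; inputs scaffolded by both: %d\n",
                x$comparison_summary$n_shared_pairs,
                x$comparison_summary$n_shared_inputs))
  }
  cat(sprintf("breakpoints found: %d; novel sequence: %s nt (%.2f%%)\n",
              nrow(x$breakpoints),
              format(x$novel_totals$nt[x$novel_totals$category == "novel"],
                     big.mark = ","),
              x$novel_totals$pct[x$novel_totals$category == "novel"]))
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Writes every tabular report as TSV (with a `# scaffeval seed=<seed>`
#' header line) and/or a single JSON mirror of the whole bundle.
#'
#' @param bundle a `scaffeval_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"`, `"json"` or both.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- sprintf("# scaffeval seed=%d", bundle$config$seed)
  tables <- list(stats = bundle$stats,
                 comparison_summary = bundle$comparison_summary,
                 breakpoints = bundle$breakpoints,
                 novel_totals = bundle$novel_totals,
                 novel_genes = bundle$novel_genes)
  for (tn in names(bundle$per_tech)) {
    pt <- bundle$per_tech[[tn]]
    tables[[paste0(tn, "_join_summary")]] <- pt$join_summary
    tables[[paste0(tn, "_size_classes")]] <- pt$size_classes
    tables[[paste0(tn, "_gap_stats")]] <- pt$gap_stats
    tables[[paste0(tn, "_breaks")]] <- pt$breaks
    tables[[paste0(tn, "_validation_rates")]] <- pt$validation_rates
    if (!is.null(pt$flanks)) {
      tables[[paste0(tn, "_flank_enrichment")]] <- glance(pt$flanks)
    }
  }
  tables <- purrr::compact(tables)
  if ("tsv" %in% format) {
    for (nm in names(tables)) {
      path <- file.path(dir, paste0(nm, ".tsv"))
      writeLines(seed_line, path)
      suppressWarnings(readr::write_tsv(tables[[nm]], path, append = TRUE,
                                        col_names = TRUE, progress = FALSE))
    }
  }
  if ("json" %in% format) {
    jsonlite::write_json(c(list(seed = bundle$config$seed), tables),
                         file.path(dir, "bundle.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(dir)
}
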