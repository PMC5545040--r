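# broom-style methods for the package's composite result objects.

#' @rdname assembly_stats
#' @param x a `scaffeval_stats` row.
#' @param ... unused.
#' @export
tidy.scaffeval_stats <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), cols = dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @rdname run_pipeline
#' @param x a `scaffeval_bundle`.
#' @export
glance.scaffeval_bundle <- function(x, ...) {
  base_n50 <- x$stats$scaffold_n50[x$stats$assembly == "base"]
  out <- tibble(
    seed = x$config$seed,
    genome_size = x$config$genome_size,
    n_assemblies = nrow(x$stats),
    base_scaffold_n50 = base_n50,
    best_scaffold_n50 = max(x$stats$scaffold_n50),
    n_breakpoints = nrow(x$breakpoints),
    novel_pct = x$novel_totals$pct[x$novel_totals$category == "novel"]
  )
  for (tn in names(x$per_tech)) {
    js <- x$per_tech[[tn]]$join_summary
    out[[paste0(tn, "_inputs_joined")]] <- js$n_inputs_joined
    out[[paste0(tn, "_join_events")]] <- js$n_join_events
  }
  out
}

#' @rdname run_pipeline
#' @export
tidy.scaffeval_bundle <- function(x, ...) {
  x$stats
}
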