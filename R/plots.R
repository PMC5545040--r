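# ggplot2 views of the main result types.

#' Cumulative length (Nx) curve
#'
#' Plots cumulative assembly length against the sorted scaffold lengths; the
#' x-position where the curve crosses 50% of the total is the N50.
#'
#' @param assemblies a named list of assembly tibbles, or a single assembly.
#' @return a ggplot object.
#' @export
plot_nx_curve <- function(assemblies) {
  if (is.data.frame(assemblies)) assemblies <- list(assembly = assemblies)
  df <- purrr::imap_dfr(assemblies, function(a, nm) {
    l <- sort(as.numeric(nchar(a$sequence)), decreasing = TRUE)
    tibble(assembly = nm, frac = cumsum(l) / sum(l), length = l)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac * 100, y = .data$length,
                                   colour = .data$assembly)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cumulative assembly fraction (%)",
                  y = "scaffold length (nt)") +
    ggplot2::theme_minimal()
}

#' Gap size distribution
#'
#' @param gaps gap tibble from [detect_gaps()]; facets by `origin` when more
#'   than one technology is present.
#' @return a ggplot object.
#' @export
plot_gap_sizes <- function(gaps) {
  p <- ggplot2::ggplot(gaps, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gap length (nt)", y = "captured gaps") +
    ggplot2::theme_minimal()
  if ("origin" %in% names(gaps) && dplyr::n_distinct(gaps$origin) > 1) {
    p <- p + ggplot2::facet_wrap(~origin)
  }
  p
}

#' Synteny dot plot of blocks against the reference
#'
#' @param blocks tibble from [chain_blocks()].
#' @return a ggplot object (query position vs target position, faceted by
#'   query and coloured by target chromosome).
#' @export
plot_synteny <- function(blocks) {
  ggplot2::ggplot(blocks) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$q_start, xend = .data$q_end,
      y = ifelse(.data$strand == "+", .data$t_start, .data$t_end),
      yend = ifelse(.data$strand == "+", .data$t_end, .data$t_start),
      colour = .data$target), linewidth = 1) +
    ggplot2::facet_wrap(~query, scales = "free") +
    ggplot2::labs(x = "query position (nt)", y = "reference position (nt)",
                  colour = "chromosome") +
    ggplot2::theme_minimal()
}

#' Joined-scaffold size-class bar chart
#'
#' @param size_classes tibble from [join_size_classes()] (band rows only are
#'   shown, not cumulative classes).
#' @return a ggplot object.
#' @export
plot_join_size_classes <- function(size_classes) {
  df <- filter(size_classes, !grepl("_cum$", .data$class),
               .data$class != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "input scaffold size class", y = "joined scaffolds") +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object a `scaffeval_bundle`.
#' @param ... unused.
#' @export
autoplot.scaffeval_bundle <- function(object, ...) {
  plot_nx_curve(object$assemblies)
}
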