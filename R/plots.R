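#' Plot detection calls as a coverage chart
#'
#' One bar per module/replicon call, height = coverage percentage, filled
#' by presence; the cutoff used for the calls can be drawn as a reference
#' line.
#'
#' @param object A `gcm_calls` tibble from [scan_genome()].
#' @param cutoff Optional cutoff percentage to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.gcm_calls <- function(object, cutoff = NULL, ...) {
  df <- as_tibble(object) |>
    mutate(call = paste0(.data$gcm_id, "\n",
                         ifelse(is.na(.data$replicon_id), "-", .data$replicon_id),
                         ":", ifelse(is.na(.data$start_rank), "-", .data$start_rank)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$call, y = .data$coverage_percent,
                                        fill = .data$present)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "module Pfam coverage (%)", fill = "present") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Plot a pathway graph with optional module annotation
#'
#' A force-directed layout of the compound/reaction graph; when a scan
#' result is supplied, compounds belonging to a detected module are
#' colored by module and shaped by presence.
#'
#' @param object A `pathway_graph`.
#' @param scan Optional `pathway_scan` result.
#' @param seed Layout seed (default 1).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pathway_graph <- function(object, scan = NULL, seed = 1L, ...) {
  ig <- pathway_igraph(object, drop_external = FALSE)
  rs <- local_rng(seed)
  on.exit(rs(), add = TRUE)
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble(compound_id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2])
  ends <- igraph::as_edgelist(ig)
  edges <- tibble(
    x = nodes$x[match(ends[, 1], nodes$compound_id)],
    y = nodes$y[match(ends[, 1], nodes$compound_id)],
    xend = nodes$x[match(ends[, 2], nodes$compound_id)],
    yend = nodes$y[match(ends[, 2], nodes$compound_id)]
  )
  ann <- annotate_nodes(object,
                        if (!is.null(scan)) scan$calls else NULL,
                        if (!is.null(scan)) scan$modules else NULL)
  nodes <- left_join(nodes, ann, by = "compound_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$module_id,
                                     shape = .data$present), size = 4) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$compound_id),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(color = "module", shape = "present") +
    ggplot2::theme_void()
}
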