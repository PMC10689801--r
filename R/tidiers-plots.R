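#' Broom-style methods and plots
#'
#' `tidy()` returns the per-gene result tibble of a fitted object;
#' `glance()` a one-row model summary; `autoplot()` the standard diagnostic
#' plot (volcano for DA fits, forest for meta fits).
#'
#' @name tidiers
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.bfl_da <- function(x, ...) x$results

#' @export
glance.bfl_da <- function(x, ...) {
  r <- x$results
  tibble(location = x$location,
         n_genes = nrow(r),
         n_excluded = length(x$excluded),
         n_significant = sum(r$padj < 0.05, na.rm = TRUE),
         median_dispersion = median(x$dispersions),
         df = x$df)
}

#' @export
tidy.bfl_meta <- function(x, ...) x$results

#' @export
glance.bfl_meta <- function(x, ...) {
  r <- x$results
  tibble(n_genes = nrow(r),
         n_significant = sum(r$p < 0.05, na.rm = TRUE),
         median_tau2 = median(r$tau2),
         alpha = x$alpha)
}

#' @export
print.bfl_da <- function(x, ...) {
  cat(sprintf("<bfl_da> %s: %d genes (%d excluded), %d with padj < 0.05\n",
              x$location, nrow(x$results), length(x$excluded),
              sum(x$results$padj < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.bfl_meta <- function(x, ...) {
  cat(sprintf("<bfl_meta> %d genes pooled, %d with p < 0.05\n",
              nrow(x$results), sum(x$results$p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidiers
#' @param object a `bfl_da` or `bfl_meta` object.
#' @param ... unused.
#' @export
autoplot.bfl_da <- function(object, ...) {
  r <- filter(object$results, is.finite(.data$log2fc), is.finite(.data$padj))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$padj, 1e-300)),
                                  colour = .data$padj < 0.05)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
                                 name = "padj < 0.05") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  title = sprintf("Differential abundance: %s", object$location)) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @export
autoplot.bfl_meta <- function(object, ...) {
  r <- object$results |>
    filter(is.finite(.data$pooled_log2fc)) |>
    arrange(.data$pooled_log2fc) |>
    mutate(gene_id = factor(.data$gene_id, levels = .data$gene_id))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$pooled_log2fc, y = .data$gene_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p < 0.05), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
                                 name = "p < 0.05") +
    ggplot2::labs(x = "pooled log2 fold change (95% CI)", y = NULL,
                  title = "Random-effects meta-analysis") +
    ggplot2::theme_minimal()
}

#' Plot the virus-host pair network
#'
#' Bipartite layout of virus and host population nodes with pair edges.
#'
#' @param pairs pair tibble ([integrate_pairs()] output).
#' @param virus_pops,host_pops optional population tibbles passed to
#'   [pair_network_components()].
#' @return a ggplot object.
#' @export
plot_pair_network <- function(pairs, virus_pops = NULL, host_pops = NULL) {
  comp <- pair_network_components(pairs, virus_pops, host_pops)
  memb <- comp$membership
  if (nrow(memb) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty pair network"))
  }
  pop_of <- function(ids, pops, prefix) {
    if (is.null(pops) || nrow(pops) == 0L) return(paste0(prefix, ids))
    m <- pops$population_id[match(ids, pops$member_id)]
    paste0(prefix, dplyr::coalesce(m, ids))
  }
  edges <- tibble(from = pop_of(pairs$virus_unit_id, virus_pops, "V:"),
                  to = pop_of(pairs$host_bin_id, host_pops, "H:")) |>
    distinct()
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(node_id = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L]) |>
    mutate(entity = if_else(startsWith(.data$node_id, "V:"), "virus", "host"))
  seg <- edges |>
    left_join(nodes, by = c(from = "node_id")) |>
    left_join(nodes, by = c(to = "node_id"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$x_to, yend = .data$y_to),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$entity, shape = .data$entity),
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(virus = "firebrick", host = "steelblue")) +
    ggplot2::labs(title = sprintf("Virus-host pair network (%d groups, %d with >1 population)",
                                  comp$n_groups, comp$n_multi)) +
    ggplot2::theme_void()
}
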