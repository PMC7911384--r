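#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal geom_segment geom_text geom_errorbar
#'   geom_jitter scale_size_area position_nudge
#' @export
ggplot2::autoplot

#' Plot a terminal damage profile
#'
#' Mismatch frequency against offset from each read end: a genuine
#' ancient library shows C->T (5') and G->A (3') frequencies elevated at
#' offset 0 and decaying into the read.
#'
#' @param object A `damage_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot damage_profile
#' @export
autoplot.damage_profile <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$freq), ]
  ggplot(df, aes(x = .data$offset, y = .data$freq, colour = .data$class)) +
    geom_line() +
    geom_point(size = 1.5) +
    facet_wrap(~end) +
    labs(x = "offset from read end (bp)", y = "mismatch frequency",
         colour = NULL, title = "terminal deamination profile") +
    theme_minimal()
}

#' Plot per-reference mapping evidence
#'
#' Normalized mapped-read percentages (bars) and mapping evenness
#' (points) per candidate reference — the two mapping-based lines of
#' evidence side by side.
#'
#' @param object A `coverage_summary` (after [normalized_counts()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coverage_summary
#' @export
autoplot.coverage_summary <- function(object, ...) {
  df <- as_tibble(object)
  if (!"normalized_pct" %in% names(df)) df <- normalized_counts(df)
  df <- tidyr::pivot_longer(
    dplyr::select(df, "ref_id", "normalized_pct", "evenness"),
    c("normalized_pct", "evenness"),
    names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$ref_id, y = .data$value)) +
    geom_col(fill = "grey70") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "mapping evidence per reference") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a median-joining haplotype network
#'
#' Nodes are placed with a deterministic Kamada-Kawai layout; node area
#' scales with haplotype frequency, inferred median vectors are drawn as
#' small black points, and edges are annotated with their mutation
#' counts.
#'
#' @param object A `haplo_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot haplo_network
#' @export
autoplot.haplo_network <- function(object, ...) {
  lay <- igraph::layout_with_kk(object$graph)
  nodes <- dplyr::mutate(object$nodes, x = lay[, 1], y = lay[, 2])
  edges <- object$edges %>%
    left_join(dplyr::select(nodes, "id", "x", "y"), by = c(from = "id")) %>%
    left_join(dplyr::select(nodes, "id", "x", "y"), by = c(to = "id"),
              suffix = c("", "_to"))
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = edges,
                 aes(xend = .data$x_to, yend = .data$y_to),
                 colour = "grey60") +
    geom_text(data = edges,
              aes(x = (.data$x + .data$x_to) / 2,
                  y = (.data$y + .data$y_to) / 2,
                  label = paste0("(", .data$weight, ")")),
              size = 3, colour = "grey40") +
    geom_point(aes(size = pmax(.data$n, 0.3),
                   colour = .data$is_median)) +
    geom_text(data = nodes[!nodes$is_median, ],
              aes(label = .data$id), size = 3,
              position = position_nudge(y = 0.12)) +
    scale_size_area(max_size = 10, guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::theme_void() +
    labs(title = "median-joining haplotype network")
}

#' Plot within-group pairwise differences
#'
#' One jittered point per sequence pair, with the group mean and
#' standard deviation overlaid — the usual within-species diversity
#' comparison.
#'
#' @param object A `pairwise_diffs` built with group labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pairwise_diffs
#' @export
autoplot.pairwise_diffs <- function(object, ...) {
  if (is.null(object$group_stats)) {
    abort("pairwise_diffs was built without group labels")
  }
  within <- object$pairs[!is.na(object$pairs$group_a) &
                           object$pairs$group_a == object$pairs$group_b, ]
  gs <- object$group_stats[!is.na(object$group_stats$mean), ]
  ggplot(within, aes(x = .data$group_a, y = .data$n_diff)) +
    geom_jitter(width = 0.15, alpha = 0.5, colour = "grey40") +
    geom_point(data = gs, aes(x = .data$group, y = .data$mean),
               colour = "red", size = 3) +
    geom_errorbar(data = gs,
                  aes(x = .data$group, y = .data$mean,
                      ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd),
                  colour = "red", width = 0.1) +
    labs(x = NULL, y = "pairwise differences (absolute)",
         title = "within-group diversity") +
    theme_minimal()
}
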