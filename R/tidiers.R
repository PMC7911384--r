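#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the evidence table of a species call
#'
#' @param x A `species_call`.
#' @param ... Unused.
#' @return The per-reference evidence tibble (`ref_id`, `n_mapped`,
#'   `normalized_pct`, `evenness`, ...).
#' @method tidy species_call
#' @export
tidy.species_call <- function(x, ...) as_tibble(x$evidence)

#' One-row summary of a species call
#'
#' @param x A `species_call`.
#' @param ... Unused.
#' @return A one-row tibble with the verdict and the three lines of
#'   evidence.
#' @method glance species_call
#' @export
glance.species_call <- function(x, ...) {
  tibble(sample_id = x$sample_id, verdict = x$verdict,
         species = x$species, top_by_count = x$top_by_count,
         top_by_evenness = x$top_by_evenness,
         phylo_assignment = x$phylo_assignment,
         n_notes = length(x$notes))
}

#' @method tidy damage_fit
#' @export
tidy.damage_fit <- function(x, ...) {
  tibble(term = c("d", "r"), estimate = c(x$d, x$r))
}

#' @method glance damage_fit
#' @export
glance.damage_fit <- function(x, ...) {
  tibble(d = x$d, r = x$r, end = x$end, method = x$method,
         n_offsets = x$n_offsets)
}

#' @method glance consensus_seq
#' @export
glance.consensus_seq <- function(x, ...) {
  tibble(ref_id = x$ref_id, length = nchar(x$seq),
         called_frac = x$called_frac, min_depth = x$min_depth,
         threshold = x$threshold)
}

#' @method tidy haplo_network
#' @export
tidy.haplo_network <- function(x, ...) as_tibble(x$edges)

#' @method glance haplo_network
#' @export
glance.haplo_network <- function(x, ...) {
  tibble(n_sampled = sum(!x$nodes$is_median),
         n_median = sum(x$nodes$is_median),
         n_edges = nrow(x$edges), length = x$length,
         epsilon = x$epsilon)
}

#' @method tidy pairwise_diffs
#' @export
tidy.pairwise_diffs <- function(x, ...) as_tibble(x$pairs)

#' @method tidy truth_score
#' @export
tidy.truth_score <- function(x, ...) as_tibble(x$confusion)

#' @method glance truth_score
#' @export
glance.truth_score <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n)
}

#' @method tidy length_summary
#' @export
tidy.length_summary <- function(x, ...) as_tibble(x$histogram)

#' @method glance length_summary
#' @export
glance.length_summary <- function(x, ...) {
  tibble(n = x$n, mean = x$mean, sd = x$sd, no_data = x$no_data)
}
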