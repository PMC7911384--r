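#' Per-reference coverage, breadth and mapping evenness
#'
#' Summarises filtered, deduplicated alignments per reference. Mean
#' coverage is `C = S / L` (total aligned bases over reference length)
#' and mean read depth is `D = S / B`, computed over covered positions
#' only, matching the convention of standard depth extractors that omit
#' zero-depth positions. The mapping evenness is the ratio `C / D`: a
#' value near 1 means reads tile the reference uniformly, a low value
#' means mapping is confined to conserved pockets — the behaviour
#' expected when reads are mapped to an increasingly divergent
#' reference. With `D` over covered positions the ratio is algebraically
#' identical to the breadth fraction `B / L`, which is also reported and
#' asserted.
#'
#' Depth is accumulated with circular wrap-around, so origin-spanning
#' reads contribute to positions on both sides of the origin.
#'
#' @param alignments A `mito_alignments` tibble (ideally after
#'   [filter_mapq()] and [dedup_alignments()]).
#' @param panel A `mito_panel`; every panel reference gets a summary row
#'   (zero rows of evidence yield `n_mapped = 0` and evenness 0 by
#'   convention).
#' @return A tibble of class `coverage_summary` with columns `ref_id`,
#'   `L`, `n_mapped`, `S` (aligned bases), `B` (positions with depth >=
#'   1), `C` (mean coverage), `D` (mean read depth over covered
#'   positions), `evenness`, `breadth_frac`.
#' @export
coverage_summary <- function(alignments, panel) {
  if (!is.data.frame(panel)) panel <- dplyr::bind_rows(panel)
  rows <- purrr::map(seq_len(nrow(panel)), function(i) {
    rid <- panel$ref_id[i]
    L <- nchar(panel$seq[i])
    aln <- alignments[alignments$ref_id == rid, , drop = FALSE]
    n <- nrow(aln)
    if (!n) {
      return(tibble(ref_id = rid, L = L, n_mapped = 0L, S = 0, B = 0L,
                    C = 0, D = NA_real_, evenness = 0, breadth_frac = 0))
    }
    depth <- depth_vector(aln, L)
    S <- sum(as.numeric(aln$aligned_len))
    B <- sum(depth > 0L)
    C <- S / L
    D <- S / B
    tibble(ref_id = rid, L = L, n_mapped = n, S = S, B = B,
           C = C, D = D, evenness = C / D, breadth_frac = B / L)
  })
  out <- bind_rows(rows)
  class(out) <- c("coverage_summary", class(out))
  out
}

# Per-position depth with circular wrap (1-based positions 1..L).
depth_vector <- function(alignments, L) {
  if (!nrow(alignments)) return(integer(L))
  lens <- alignments$aligned_len
  pos <- (rep(alignments$start, lens) + sequence(lens) - 1L) %% L + 1L
  tabulate(pos, nbins = L)
}

#' Normalize per-reference mapped-read counts to the best reference
#'
#' Expresses each reference's post-filter read count as a percentage of
#' the highest count in the panel, so the best-supported reference reads
#' exactly 100 and all others scale relative to it.
#'
#' @param summaries A `coverage_summary` tibble (or any tibble with
#'   `ref_id` and `n_mapped`).
#' @return The input with a `normalized_pct` column. If every count is
#'   zero all percentages are 0 and the result carries attribute
#'   `all_zero = TRUE`.
#' @export
normalized_counts <- function(summaries) {
  if (!nrow(summaries)) abort("need at least one coverage summary")
  top <- max(summaries$n_mapped)
  out <- mutate(summaries,
                normalized_pct = if (top == 0) 0 else 100 * .data$n_mapped / top)
  attr(out, "all_zero") <- top == 0
  class(out) <- unique(c("coverage_summary", class(out)))
  out
}

#' Combine mapping evidence and phylogenetic placement into a species call
#'
#' Formalises a three-lines-of-evidence species identification: (1) the
#' reference attracting the most mapped reads, (2) the reference with the
#' highest mapping evenness, and (3) the clade the sample joins in a
#' phylogenetic placement (optional). The verdict is `"concordant"` only
#' when all available lines name the same non-outgroup reference;
#' otherwise `"ambiguous"`.
#'
#' References flagged `is_outgroup` (e.g. a human contaminant control)
#' can never be the verdict species, but if such a reference attracts the
#' most reads a `"low endogenous content"` note is attached.
#'
#' @param evidence A `coverage_summary` tibble covering every candidate
#'   reference (a `normalized_pct` column is added if missing).
#' @param panel The `mito_panel` (for outgroup flags).
#' @param phylo_assignment Optional `ref_id` from phylogenetic placement
#'   (see [clade_of()]), or `NA`/`NULL` if unavailable.
#' @param sample_id Sample label carried into the report.
#' @return An object of class `species_call`: a list with `sample_id`,
#'   `evidence` (tibble), `top_by_count`, `top_by_evenness`,
#'   `phylo_assignment`, `verdict`, `species` (the called reference or
#'   `NA`), and `notes`.
#' @export
call_species <- function(evidence, panel, phylo_assignment = NULL,
                         sample_id = "sample") {
  if (!nrow(evidence)) abort("empty evidence table")
  if (!"normalized_pct" %in% names(evidence)) {
    evidence <- normalized_counts(evidence)
  }
  ev <- dplyr::left_join(as_tibble(evidence),
                         dplyr::select(as_tibble(panel), "ref_id", "is_outgroup"),
                         by = "ref_id")
  ev$is_outgroup[is.na(ev$is_outgroup)] <- FALSE
  notes <- character(0)

  if (all(ev$n_mapped == 0)) {
    out <- list(sample_id = sample_id, evidence = ev,
                top_by_count = NA_character_,
                top_by_evenness = NA_character_,
                phylo_assignment = phylo_assignment %||% NA_character_,
                verdict = "no_data", species = NA_character_,
                notes = "no reads mapped to any reference")
    class(out) <- "species_call"
    return(out)
  }

  top_count_raw <- ev$ref_id[which.max(ev$n_mapped)]
  if (ev$is_outgroup[match(top_count_raw, ev$ref_id)]) {
    notes <- c(notes, "low endogenous content: a contaminant-control reference attracts the most reads")
  }
  cand <- ev[!ev$is_outgroup, , drop = FALSE]
  if (!nrow(cand) || all(cand$n_mapped == 0)) {
    out <- list(sample_id = sample_id, evidence = ev,
                top_by_count = top_count_raw,
                top_by_evenness = NA_character_,
                phylo_assignment = phylo_assignment %||% NA_character_,
                verdict = "ambiguous", species = NA_character_,
                notes = c(notes, "no candidate (non-outgroup) reference attracted reads"))
    class(out) <- "species_call"
    return(out)
  }
  top_by_count <- cand$ref_id[which.max(cand$n_mapped)]
  top_by_evenness <- cand$ref_id[which.max(cand$evenness)]

  phylo <- phylo_assignment %||% NA_character_
  lines <- c(top_by_count, top_by_evenness)
  if (!is.na(phylo)) lines <- c(lines, phylo)
  out_flag <- ev$is_outgroup[match(lines, ev$ref_id)]
  concordant <- length(unique(lines)) == 1 && !any(out_flag, na.rm = TRUE)

  out <- list(
    sample_id = sample_id, evidence = ev,
    top_by_count = top_by_count, top_by_evenness = top_by_evenness,
    phylo_assignment = phylo,
    verdict = if (concordant) "concordant" else "ambiguous",
    species = if (concordant) top_by_count else NA_character_,
    notes = if (length(notes)) notes else character(0)
  )
  class(out) <- "species_call"
  out
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("Species call for %s: %s", x$sample_id, x$verdict))
  if (!is.na(x$species)) cat(sprintf(" (%s)", x$species))
  cat("\n  lines of evidence: count ->", x$top_by_count,
      "| evenness ->", x$top_by_evenness,
      "| phylogeny ->", ifelse(is.na(x$phylo_assignment), "n/a",
                               x$phylo_assignment), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  print(dplyr::select(x$evidence, "ref_id", "n_mapped", "normalized_pct",
                      "evenness"))
  invisible(x)
}
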