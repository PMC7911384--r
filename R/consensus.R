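#' Call a consensus sequence from a read pileup
#'
#' Reference-coordinate consensus over filtered, deduplicated
#' alignments. At each reference position the covering read bases are
#' tallied; positions with depth below `min_depth` are called `N`, and
#' otherwise the unique plurality base is called only if its frequency
#' among covering reads reaches `threshold` (ties at the top, or no base
#' reaching the threshold, also yield `N` — the conservative choice).
#' The threshold comparison is inclusive (`>=`).
#'
#' Insertions relative to the reference are not called; pileup positions
#' wrap circularly, so origin-spanning reads contribute on both sides of
#' the origin.
#'
#' `trim_terminal` excludes that many bases from each end of every read
#' before the pileup — an optional damage-aware mode that removes the
#' read termini where deamination concentrates.
#'
#' @param alignments A `mito_alignments` tibble for one reference.
#' @param panel The `mito_panel` (or a single entry).
#' @param ref_id Reference to call against.
#' @param min_depth Minimum read depth to call a base (default 3).
#' @param threshold Minimum plurality-base frequency (default 0.5).
#' @param trim_terminal Bases to clip from each read end in the pileup.
#' @return An object of class `consensus_seq`: list with `ref_id`, `seq`
#'   (single string over A/C/G/T/N of reference length), `depth`
#'   (integer vector), `called_frac`, `min_depth`, `threshold`.
#' @export
call_consensus <- function(alignments, panel, ref_id, min_depth = 3,
                           threshold = 0.5, trim_terminal = 0) {
  entry <- panel_entry(panel, ref_id)
  L <- nchar(entry$seq)
  aln <- alignments[alignments$ref_id == ref_id, , drop = FALSE]

  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(DNA_BASES, NULL))
  if (nrow(aln)) {
    lens <- aln$aligned_len
    flat <- unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE)
    off <- sequence(lens) - 1L
    pos0 <- (rep(aln$start, lens) + off) %% L  # 0-based wrapped
    if (trim_terminal > 0) {
      keep <- off >= trim_terminal & off < rep(lens, lens) - trim_terminal
      flat <- flat[keep]; pos0 <- pos0[keep]
    }
    code <- match(flat, DNA_BASES)
    ok <- !is.na(code)
    if (any(ok)) {
      counts[] <- tabulate((pos0[ok]) * 4L + code[ok], nbins = 4L * L)
    }
  }
  depth <- colSums(counts)
  top <- apply(counts, 2, max)
  n_at_top <- colSums(counts == rep(top, each = 4)) * (top > 0)
  top_base <- DNA_BASES[max.col(t(counts), ties.method = "first")]
  freq <- ifelse(depth > 0, top / depth, 0)
  call <- ifelse(depth >= min_depth & n_at_top == 1 & freq >= threshold,
                 top_base, "N")

  out <- list(ref_id = ref_id, seq = paste(call, collapse = ""),
              depth = as.integer(depth),
              called_frac = mean(call != "N"),
              min_depth = min_depth, threshold = threshold)
  class(out) <- "consensus_seq"
  out
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("consensus on %s: %d bp, %.1f%% called (min_depth %d, threshold %.2f)\n",
              x$ref_id, nchar(x$seq), 100 * x$called_frac, x$min_depth,
              x$threshold))
  invisible(x)
}

#' Tidy a consensus into a per-position tibble
#'
#' @param x A `consensus_seq`.
#' @param ... Unused.
#' @return A tibble with `pos` (1-based), `depth`, `call`.
#' @method tidy consensus_seq
#' @export
tidy.consensus_seq <- function(x, ...) {
  tibble(pos = seq_len(nchar(x$seq)), depth = x$depth,
         call = strsplit(x$seq, "")[[1]])
}

#' Write a consensus sequence to FASTA (and optionally a per-position TSV)
#'
#' @param consensus A `consensus_seq`.
#' @param fasta FASTA output path.
#' @param tsv Optional per-position TSV path (`pos`, `depth`, `call`).
#' @param id Sequence name in the FASTA header.
#' @return The FASTA path, invisibly.
#' @export
write_consensus <- function(consensus, fasta, tsv = NULL,
                            id = paste0("consensus_", consensus$ref_id)) {
  write_fasta(setNames(consensus$seq, id), fasta)
  if (!is.null(tsv)) readr::write_tsv(generics::tidy(consensus), tsv)
  invisible(fasta)
}
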