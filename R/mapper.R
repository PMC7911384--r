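#' Mapper configuration
#'
#' Thresholds for the desk-scale seed-and-verify read mapper. Defaults
#' follow common ancient-DNA practice: reads shorter than 30 bp are
#' discarded and placements with mapping quality below 30 are filtered.
#'
#' @param k Seed (k-mer) length used to find candidate placements. Every
#'   read k-mer is looked up, so any placement whose mismatches are at
#'   least `k` apart somewhere along the read is guaranteed to be found;
#'   with the defaults that covers all placements with up to
#'   `floor(read_len / k) - 1` mismatches.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction of a
#'   placement (mismatches / aligned length). The default 0.1 leaves room
#'   for deamination damage on top of true divergence.
#' @param mapq_min Mapping-quality filter threshold.
#' @param min_read_len Minimum read length; shorter reads are discarded.
#' @return A list of class `map_config`.
#' @export
map_config <- function(k = 10, max_mismatch_frac = 0.1, mapq_min = 30,
                       min_read_len = 30) {
  stopifnot(k >= 1, k <= min_read_len, k <= 31,
            max_mismatch_frac >= 0, max_mismatch_frac <= 0.5)
  structure(list(k = k, max_mismatch_frac = max_mismatch_frac,
                 mapq_min = mapq_min, min_read_len = min_read_len),
            class = "map_config")
}

#' Map reads against every reference of a panel
#'
#' Aligns each read independently against each panel reference (ungapped,
#' both strands, circularity-aware), as in competitive per-reference
#' mapping: each reference gets its own alignment set, and downstream
#' evidence (read counts, evenness) is compared across references.
#'
#' The best placement minimises mismatches over all seeded candidate
#' positions on both strands; placements with a mismatch fraction above
#' `cfg$max_mismatch_frac` are rejected. The mapping-quality proxy
#' reflects placement uniqueness: 60 when no competing placement comes
#' within 3 mismatches of the best, `25 * delta` for a margin `delta` of
#' 1 or 2, and 0 for exact ties (e.g. repeats).
#'
#' @param reads A tibble with columns `read_id` and `seq` (e.g. from
#'   [sim_reads()] or [read_fastq()]).
#' @param panel A `mito_panel` tibble, or a single entry of one.
#' @param cfg A [map_config()].
#' @return A tibble of class `mito_alignments` with one row per mapped
#'   (read, reference) pair: `read_id`, `ref_id`, `start` (0-based),
#'   `end` (exclusive; may exceed the reference length for
#'   origin-spanning placements), `strand`, `n_mismatch`, `mapq`,
#'   `aligned_len`, and `seq` (the read in reference orientation).
#'   Reads discarded as too short are recorded in the `"filtered"`
#'   attribute with reason `"too_short"`.
#' @export
map_reads <- function(reads, panel, cfg = map_config()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  if (!is.data.frame(panel)) panel <- dplyr::bind_rows(panel)

  too_short <- nchar(reads$seq) < cfg$min_read_len
  filtered <- tibble(read_id = reads$read_id[too_short], reason = "too_short")
  reads <- reads[!too_short, , drop = FALSE]

  out <- purrr::map(seq_len(nrow(panel)), function(i) {
    ref <- panel$seq[i]
    if (!nrow(reads)) return(NULL)
    hits <- cpp_map_reads(reads$seq, ref, isTRUE(panel$circular[i]),
                          as.integer(cfg$k), cfg$max_mismatch_frac)
    keep <- hits$mapped
    if (!any(keep)) return(NULL)
    seq_fwd <- reads$seq[keep]
    minus <- hits$strand[keep] == "-"
    seq_fwd[minus] <- revcomp(seq_fwd[minus])
    tibble(
      read_id = reads$read_id[keep],
      ref_id = panel$ref_id[i],
      start = hits$start[keep],
      end = hits$start[keep] + hits$aligned_len[keep],
      strand = hits$strand[keep],
      n_mismatch = hits$n_mismatch[keep],
      mapq = hits$mapq[keep],
      aligned_len = hits$aligned_len[keep],
      seq = seq_fwd
    )
  })
  aln <- bind_rows(out)
  if (!nrow(aln)) {
    aln <- tibble(read_id = character(0), ref_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), n_mismatch = integer(0),
                  mapq = integer(0), aligned_len = integer(0),
                  seq = character(0))
  }
  attr(aln, "filtered") <- filtered
  class(aln) <- c("mito_alignments", class(aln))
  aln
}

#' Filter alignments on mapping quality
#'
#' Retains records with `mapq >= mapq_min` (a record with mapq exactly at
#' the threshold is kept).
#'
#' @param alignments A `mito_alignments` tibble.
#' @param mapq_min Threshold, or a [map_config()] whose `mapq_min` is used.
#' @return The filtered tibble.
#' @export
filter_mapq <- function(alignments, mapq_min = 30) {
  if (inherits(mapq_min, "map_config")) mapq_min <- mapq_min$mapq_min
  out <- alignments[alignments$mapq >= mapq_min, , drop = FALSE]
  class(out) <- unique(c("mito_alignments", class(out)))
  out
}

#' Remove PCR/optical duplicates from alignments
#'
#' Keeps at most one record per (reference, start, end, strand)
#' coordinate triple. The retained record is the one with the highest
#' mapping quality; ties break on the lexicographically smallest read id,
#' making the operation deterministic and idempotent.
#'
#' @param alignments A `mito_alignments` tibble (one or more references).
#' @return The deduplicated tibble.
#' @export
dedup_alignments <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  out <- alignments %>%
    group_by(.data$ref_id, .data$start, .data$end, .data$strand) %>%
    arrange(desc(.data$mapq), .data$read_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$ref_id, .data$start, .data$end, .data$strand)
  class(out) <- unique(c("mito_alignments", class(out)))
  out
}

#' Positions of a k-mer in a (possibly circular) reference
#'
#' Lookup utility mirroring the mapper's seed index: the reference is
#' extended by its first `max_read_len - 1` bases when circular, so
#' origin-spanning seed placements are found; returned start positions
#' are 0-based on the unextended reference.
#'
#' @param ref_seq Reference sequence (single string).
#' @param kmer The k-mer to look up (forward strand).
#' @param circular Whether the reference is circular.
#' @param max_read_len Extension window for circular references.
#' @return Integer vector of 0-based start positions.
#' @export
seed_positions <- function(ref_seq, kmer, circular = TRUE, max_read_len = 75) {
  k <- nchar(kmer)
  L <- nchar(ref_seq)
  if (k > L) abort("k-mer longer than the reference")
  ext <- if (circular) paste0(ref_seq, substr(ref_seq, 1, max_read_len - 1)) else ref_seq
  starts <- seq_len(nchar(ext) - k + 1) - 1L
  hit <- substring(ext, starts + 1, starts + k) == kmer
  sort(unique(starts[hit][starts[hit] < L]))
}

# ---------------------------------------------------------------------------
# SAM interchange (text SAM; 1-based POS, NM tag for mismatches)
# ---------------------------------------------------------------------------

#' Write alignments for one reference to a SAM file
#'
#' Emits valid single-reference SAM with an `@SQ` header line, 1-based
#' `POS`, ungapped CIGAR, and the mismatch count as an `NM` tag.
#' Origin-spanning placements are written at their (unwrapped) start with
#' a full-length match CIGAR against the circularly extended reference
#' coordinate, which round-trips through [read_sam()].
#'
#' @param alignments A `mito_alignments` tibble restricted to `ref_id`.
#' @param panel The reference panel (for lengths).
#' @param ref_id Reference to export.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, panel, ref_id, path) {
  entry <- panel_entry(panel, ref_id)
  aln <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_id, nchar(entry$seq)),
           "@PG\tID:paleomito\tPN:paleomito")
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  seq_out <- aln$seq  # stored in reference orientation, as SAM requires
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                 aln$read_id, flag, ref_id, aln$start + 1L, aln$mapq,
                 aln$aligned_len, seq_out, strrep("F", aln$aligned_len),
                 aln$n_mismatch)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file into an alignments tibble
#'
#' Ingests externally produced SAM (e.g. from another aligner) so the
#' downstream statistics can run on any mapping. Only the core columns
#' and the `NM` tag are used; unmapped records (flag 0x4) are skipped and
#' the aligned length is taken from the CIGAR's consumed reference
#' length.
#'
#' @param path SAM file path.
#' @param ref_id Optional reference filter.
#' @return A `mito_alignments` tibble.
#' @export
read_sam <- function(path, ref_id = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- tibble(read_id = character(0), ref_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), n_mismatch = integer(0),
                  mapq = integer(0), aligned_len = integer(0),
                  seq = character(0))
    class(out) <- c("mito_alignments", class(out))
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L
  f <- f[keep]; flag <- flag[keep]
  cigar_ref_len <- function(cig) {
    if (cig == "*") return(NA_integer_)
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  out <- tibble(
    read_id = vapply(f, `[`, character(1), 1),
    ref_id = vapply(f, `[`, character(1), 3),
    start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    aligned_len = vapply(f, function(x) cigar_ref_len(x[6]), integer(1)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    n_mismatch = nm,
    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
    seq = vapply(f, `[`, character(1), 10)
  ) %>%
    mutate(end = .data$start + .data$aligned_len) %>%
    select("read_id", "ref_id", "start", "end", "strand", "n_mismatch",
           "mapq", "aligned_len", "seq")
  if (!is.null(ref_id)) out <- out[out$ref_id == ref_id, , drop = FALSE]
  class(out) <- c("mito_alignments", class(out))
  out
}
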