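#' Simulate single-end ancient-style reads from a reference panel
#'
#' Draws short fragments uniformly from circular reference sequences
#' (fragments may span the origin), applies a cytosine-deamination damage
#' model, uniform sequencing error, PCR duplicates, and contaminant reads
#' from the panel's outgroup/contaminant-control entries. Every read
#' carries a lossless truth tag in its identifier (see Details), so
#' downstream accuracy can be scored without external bookkeeping.
#'
#' Fragment lengths are lognormal (moment-matched to `frag_len_mean` /
#' `frag_len_sd`), truncated to `[min_len, max_len]` and rounded — the
#' right-skewed length profile typical of degraded DNA, capped at the
#' 75 bp single-end read length of the emulated sequencing runs.
#'
#' Damage model: at 5' offset `i` (0-based), a fragment base `C` is read
#' as `T` with probability `d5 * decay_r^i`; mirrored from the 3' end,
#' `G` is read as `A` with probability `d3 * decay_r^j`. Damage is
#' applied to the read in sequencing orientation (after strand flip) and
#' before sequencing error, matching the physical order of events
#' (post-mortem deamination, then library amplification and sequencing).
#' Duplicates are exact coordinate copies of an already-damaged fragment,
#' re-exposed to independent sequencing error (PCR copies share the
#' template's deamination but not the sequencer's errors).
#'
#' Truth-tag grammar (reserved delimiter `|`):
#' `sim|<serial>|<source_ref>|<start0>|<strand>|<len>|<D or .>|<C or .>`
#' where `start0` is the 0-based fragment start on the source reference,
#' `D` marks a PCR duplicate and `C` a contaminant read.
#'
#' @param panel A `mito_panel` tibble (see [sim_panel()]).
#' @param n_reads Total number of reads to emit.
#' @param source_mix Named numeric vector of source fractions over
#'   non-contaminant references; must sum to 1 (within 1e-9). Default:
#'   everything from the first non-outgroup reference.
#' @param frag_len_mean,frag_len_sd Fragment-length mean/sd in bases.
#' @param min_len,max_len Truncation bounds on fragment length.
#' @param d5,d3 Terminal deamination probabilities (C->T at 5', G->A at 3').
#' @param decay_r Per-position geometric decay of the damage probability,
#'   in (0, 1].
#' @param seq_error Per-base uniform sequencing-error probability.
#' @param dup_rate Fraction of emitted reads that are coordinate
#'   duplicates of another emitted read.
#' @param contam_fraction Fraction of reads drawn (uniformly) from
#'   references flagged `is_outgroup` in the panel.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A tibble of class `sim_reads` with columns `read_id`, `seq`,
#'   `qual` (fixed Q37 Sanger qualities) and the truth columns
#'   `source_ref`, `start` (0-based), `strand`, `frag_len`,
#'   `is_duplicate`, `is_contaminant`.
#' @export
sim_reads <- function(panel, n_reads, source_mix = NULL,
                      frag_len_mean = 55, frag_len_sd = 15,
                      min_len = 30, max_len = 75,
                      d5 = 0.2, d3 = 0.2, decay_r = 0.5,
                      seq_error = 0.005, dup_rate = 0, contam_fraction = 0,
                      seed = 1) {
  stopifnot(nrow(panel) >= 1, min_len >= 1, min_len <= max_len)
  probs <- c(d5 = d5, d3 = d3, seq_error = seq_error, dup_rate = dup_rate,
             contam_fraction = contam_fraction)
  if (any(probs < 0) || any(probs > 1)) abort("probabilities must lie in [0, 1]")
  stopifnot(decay_r > 0, decay_r <= 1)

  endo <- panel$ref_id[!panel$is_outgroup]
  contam_refs <- panel$ref_id[panel$is_outgroup]
  if (is.null(source_mix)) {
    if (!length(endo)) abort("panel has no non-outgroup reference to draw from")
    source_mix <- setNames(1, endo[1])
  }
  if (abs(sum(source_mix) - 1) > 1e-9) abort("source fractions must sum to 1")
  if (!all(names(source_mix) %in% panel$ref_id)) {
    abort("source_mix names must be panel reference ids")
  }
  if (contam_fraction > 0 && !length(contam_refs)) {
    abort("contam_fraction > 0 but no panel reference is flagged is_outgroup")
  }

  empty <- tibble(read_id = character(0), seq = character(0),
                  qual = character(0), source_ref = character(0),
                  start = integer(0), strand = character(0),
                  frag_len = integer(0), is_duplicate = logical(0),
                  is_contaminant = logical(0))
  class(empty) <- c("sim_reads", class(empty))
  if (n_reads == 0) return(empty)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  n_dup <- round(dup_rate * n_reads)
  n_orig <- n_reads - n_dup
  if (n_orig < 1) abort("dup_rate too high: no original reads left")

  # --- originals: source, coordinates, fragment -----------------------------
  is_contam <- runif(n_orig) < contam_fraction
  src <- character(n_orig)
  if (any(!is_contam)) {
    src[!is_contam] <- sample(names(source_mix), sum(!is_contam),
                              replace = TRUE, prob = source_mix)
  }
  if (any(is_contam)) {
    src[is_contam] <- sample(contam_refs, sum(is_contam), replace = TRUE)
  }
  lens <- .rlnorm_trunc(n_orig, frag_len_mean, frag_len_sd, min_len, max_len)
  ref_len <- setNames(nchar(panel$seq), panel$ref_id)
  L <- ref_len[src]
  if (any(lens > L)) abort("fragment length exceeds reference length")
  starts <- floor(runif(n_orig) * L)  # 0-based, uniform on the circle
  strand <- ifelse(runif(n_orig) < 0.5, "+", "-")

  # extract fragments from the circularly doubled reference
  frags <- character(n_orig)
  for (rid in unique(src)) {
    i <- which(src == rid)
    s <- panel$seq[match(rid, panel$ref_id)]
    doubled <- paste0(s, substr(s, 1, max(lens[i])))
    frags[i] <- substring(doubled, starts[i] + 1, starts[i] + lens[i])
  }
  minus <- strand == "-"
  frags[minus] <- revcomp(frags[minus])  # sequencing orientation

  frags <- .apply_damage(frags, lens, d5, d3, decay_r)

  # --- duplicates: coordinate + damaged-template copies ---------------------
  if (n_dup > 0) {
    pick <- sample.int(n_orig, n_dup, replace = TRUE)
    src <- c(src, src[pick]); starts <- c(starts, starts[pick])
    strand <- c(strand, strand[pick]); lens <- c(lens, lens[pick])
    frags <- c(frags, frags[pick])
    is_contam <- c(is_contam, is_contam[pick])
  }
  is_dup <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))

  frags <- .apply_seq_error(frags, lens, seq_error)

  read_id <- sprintf("sim|%d|%s|%d|%s|%d|%s|%s",
                     seq_len(n_reads), src, starts, strand, lens,
                     ifelse(is_dup, "D", "."), ifelse(is_contam, "C", "."))
  out <- tibble(
    read_id = read_id, seq = frags,
    qual = strrep("F", lens),  # Sanger Q37
    source_ref = src, start = as.integer(starts), strand = strand,
    frag_len = as.integer(lens), is_duplicate = is_dup,
    is_contaminant = is_contam
  )
  class(out) <- c("sim_reads", class(out))
  out
}

# Truncated (by rejection) moment-matched lognormal, rounded to integers.
.rlnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(as.integer(pmin(pmax(round(mean), lo), hi)), n))
  meanlog <- log(mean^2 / sqrt(mean^2 + sd^2))
  sdlog <- sqrt(log(1 + sd^2 / mean^2))
  out <- integer(0)
  guard <- 0
  while (length(out) < n && guard < 1000) {
    x <- as.integer(round(rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)))
    x <- x[x >= lo & x <= hi]
    out <- c(out, x)
    guard <- guard + 1
  }
  if (length(out) < n) abort("fragment-length truncation window rejects almost all draws")
  out[seq_len(n)]
}

# Deamination on reads in sequencing orientation: C->T from the 5' end,
# G->A from the 3' end, each with geometrically decaying probability.
.apply_damage <- function(reads, lens, d5, d3, decay_r) {
  if ((d5 == 0 && d3 == 0) || !length(reads)) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  off5 <- sequence(lens) - 1L
  off3 <- rep(lens, lens) - 1L - off5
  p5 <- d5 * decay_r^off5
  p3 <- d3 * decay_r^off3
  hit5 <- flat == "C" & runif(length(flat)) < p5
  hit3 <- flat == "G" & runif(length(flat)) < p3
  flat[hit5] <- "T"
  flat[hit3] <- "A"
  .reassemble(flat, lens)
}

.apply_seq_error <- function(reads, lens, seq_error) {
  if (seq_error == 0 || !length(reads)) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  err <- which(runif(length(flat)) < seq_error)
  if (length(err)) {
    # uniform substitution to one of the three other bases
    shift <- sample.int(3, length(err), replace = TRUE)
    idx <- match(flat[err], DNA_BASES)
    flat[err] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  .reassemble(flat, lens)
}

.reassemble <- function(flat, lens) {
  grp <- rep(seq_along(lens), lens)
  unname(vapply(split(flat, grp), paste, character(1), collapse = ""))
}

#' Write simulated reads to FASTQ / truth table to TSV
#'
#' @param reads A `sim_reads` tibble (or any tibble with `read_id`,
#'   `seq`, `qual`).
#' @param fastq,truth File paths (`truth` optional).
#' @return The FASTQ path, invisibly.
#' @export
write_fastq <- function(reads, fastq, truth = NULL) {
  lines <- if (nrow(reads)) {
    as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                    rep("+", nrow(reads)), reads$qual))
  } else {
    character(0)
  }
  writeLines(lines, fastq)
  if (!is.null(truth)) {
    readr::write_tsv(
      dplyr::select(as_tibble(reads), "read_id", "source_ref", "start",
                    "strand", "frag_len", "is_duplicate", "is_contaminant"),
      truth)
  }
  invisible(fastq)
}

#' Read a FASTQ file into a reads tibble
#'
#' Plain-text four-line FASTQ; if read identifiers follow the simulator's
#' truth-tag grammar the truth columns are recovered as well.
#'
#' @param path FASTQ file path.
#' @return A tibble with `read_id`, `seq`, `qual` (and truth columns when
#'   recoverable).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(tibble(read_id = character(0), seq = character(0),
                  qual = character(0)))
  }
  if (length(lines) %% 4 != 0) abort("malformed FASTQ: line count not a multiple of 4")
  m <- matrix(lines, nrow = 4)
  out <- tibble(read_id = sub("^@", "", sub("\\s.*$", "", m[1, ])),
                seq = toupper(m[2, ]), qual = m[4, ])
  truth <- parse_truth_tags(out$read_id)
  if (!is.null(truth)) out <- dplyr::bind_cols(out, truth)
  out
}

#' Recover truth tags from simulated read identifiers
#'
#' @param read_id Character vector of read identifiers.
#' @return A tibble with `source_ref`, `start`, `strand`, `frag_len`,
#'   `is_duplicate`, `is_contaminant`, or `NULL` if the ids do not follow
#'   the simulator's grammar.
#' @export
parse_truth_tags <- function(read_id) {
  parts <- strsplit(read_id, "|", fixed = TRUE)
  if (!length(parts) || any(lengths(parts) != 8) ||
      any(vapply(parts, `[`, character(1), 1) != "sim")) {
    return(NULL)
  }
  m <- do.call(rbind, parts)
  tibble(
    source_ref = m[, 3], start = as.integer(m[, 4]), strand = m[, 5],
    frag_len = as.integer(m[, 6]), is_duplicate = m[, 7] == "D",
    is_contaminant = m[, 8] == "C"
  )
}

#' Score species calls against simulation truth
#'
#' @param calls A tibble with columns `id` and `called_ref` (one row per
#'   replicate or sample).
#' @param truth A tibble with columns `id` and `true_ref`.
#' @return A list of class `truth_score`: `accuracy`, `n`, and a
#'   `confusion` tibble of (true_ref, called_ref, n) counts.
#' @export
score_against_truth <- function(calls, truth) {
  if (!nrow(calls)) abort("no calls to score")
  if (!setequal(calls$id, truth$id) || anyDuplicated(calls$id)) {
    abort("call ids do not match truth ids")
  }
  j <- dplyr::inner_join(calls, truth, by = "id")
  confusion <- j %>%
    dplyr::count(.data$true_ref, .data$called_ref, name = "n") %>%
    arrange(.data$true_ref, .data$called_ref)
  structure(list(accuracy = mean(j$called_ref == j$true_ref),
                 n = nrow(j), confusion = confusion),
            class = "truth_score")
}

#' @export
print.truth_score <- function(x, ...) {
  cat(sprintf("species-call accuracy: %.3f over %d replicates\n",
              x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}
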