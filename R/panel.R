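#' Simulate a panel of candidate mitochondrial reference genomes
#'
#' Generates a set of circular, mitogenome-scale reference sequences at a
#' controlled pairwise divergence, emulating a panel of candidate species
#' mitogenomes (e.g. several canids plus a human contaminant control).
#' Evolution is substitution-only (no indels), so every sequence has the
#' same length and reference coordinates are directly comparable; this
#' keeps downstream coordinate bookkeeping exact.
#'
#' Sequences radiate from a single random root ("star" topology): each
#' reference mutates the root independently at a per-site rate chosen so
#' that the expected pairwise divergence between any two references equals
#' `divergence` (the rate accounts for the chance that two lineages hit
#' the same site). A synthetic control-region interval is annotated at the
#' 3' end of each reference, emulating the rapidly evolving non-coding
#' segment of real mitogenomes.
#'
#' @param n_refs Number of references in the panel.
#' @param ref_length Length of every reference, in bases.
#' @param divergence Target expected pairwise divergence
#'   (substitutions/site) between any two references. Either a scalar, or
#'   a vector of length `n_refs` of per-reference root divergences (the
#'   expected pairwise divergence between refs i and j is then roughly
#'   `div[i] + div[j]`). Must be below 0.75 (saturation).
#' @param seed Integer seed; fully determines the panel.
#' @param ref_ids Optional character vector of reference names.
#' @param outgroup Indices (or names) of references flagged as
#'   outgroup/contaminant-control entries: they are never eligible as a
#'   species verdict and serve as the phylogenetic outgroup and as the
#'   source of contaminant reads in simulation. Default: the last
#'   reference.
#' @param cr_frac Fraction of the reference length annotated as the
#'   synthetic control region (placed at the 3' end).
#'
#' @return A tibble of class `mito_panel` with one row per reference and
#'   columns `ref_id`, `seq`, `circular`, `cr_start`, `cr_end` (1-based
#'   inclusive), `is_outgroup`, plus a `mutations` list-column logging the
#'   substitutions applied to the shared root (`pos`, `from`, `to`) —
#'   the ground truth used by oracle-style tests.
#' @export
sim_panel <- function(n_refs = 5, ref_length = 16500, divergence = 0.08,
                      seed = 1, ref_ids = NULL, outgroup = n_refs,
                      cr_frac = 0.07) {
  stopifnot(n_refs >= 1, ref_length > 0)
  if (any(divergence < 0) || any(divergence >= 0.75)) {
    abort("divergence must lie in [0, 0.75): beyond that substitutions saturate")
  }
  if (length(divergence) == 1) {
    # per-branch rate a solving 2a - (4/3)a^2 = divergence
    d <- divergence
    a <- (2 - sqrt(4 - 16 * d / 3)) / (8 / 3)
    rate <- rep(a, n_refs)
  } else {
    stopifnot(length(divergence) == n_refs)
    rate <- divergence
  }
  ref_ids <- ref_ids %||% sprintf("ref%02d", seq_len(n_refs))
  stopifnot(!anyDuplicated(ref_ids))
  if (is.character(outgroup)) outgroup <- match(outgroup, ref_ids)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  root <- sample(DNA_BASES, ref_length, replace = TRUE)

  rows <- purrr::map(seq_len(n_refs), function(i) {
    s <- root
    hit <- which(runif(ref_length) < rate[i])
    log <- tibble(pos = integer(0), from = character(0), to = character(0))
    if (length(hit)) {
      # substitute to one of the three other bases, uniformly
      to <- vapply(s[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
      log <- tibble(pos = hit, from = s[hit], to = to)
      s[hit] <- to
    }
    tibble(
      ref_id = ref_ids[i],
      seq = paste(s, collapse = ""),
      circular = TRUE,
      cr_start = as.integer(ref_length - max(1, round(cr_frac * ref_length)) + 1),
      cr_end = as.integer(ref_length),
      is_outgroup = i %in% outgroup,
      mutations = list(log)
    )
  })
  panel <- bind_rows(rows)
  class(panel) <- c("mito_panel", class(panel))
  attr(panel, "root_seq") <- paste(root, collapse = "")
  panel
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a reference panel as multi-FASTA plus annotation TSV
#'
#' The annotation TSV has columns `ref_id`, `cr_start`, `cr_end` (1-based
#' inclusive control-region interval), `is_outgroup`, `circular`.
#'
#' @param panel A `mito_panel` tibble (see [sim_panel()]).
#' @param fasta,annotations File paths.
#' @return `read_panel()` returns a `mito_panel` tibble (without a
#'   mutation log); `write_panel()` returns the paths invisibly.
#' @export
write_panel <- function(panel, fasta, annotations) {
  writeLines(paste0(">", panel$ref_id, "\n", panel$seq), fasta)
  ann <- panel %>%
    as_tibble() %>%
    select("ref_id", "cr_start", "cr_end", "is_outgroup", "circular")
  readr::write_tsv(ann, annotations)
  invisible(c(fasta = fasta, annotations = annotations))
}

#' @rdname write_panel
#' @export
read_panel <- function(fasta, annotations = NULL) {
  seqs <- read_fasta(fasta)
  panel <- tibble(
    ref_id = names(seqs), seq = unname(seqs), circular = TRUE,
    cr_start = NA_integer_, cr_end = NA_integer_, is_outgroup = FALSE
  )
  if (!is.null(annotations)) {
    ann <- readr::read_tsv(annotations, show_col_types = FALSE)
    stopifnot(all(panel$ref_id %in% ann$ref_id))
    ann <- ann[match(panel$ref_id, ann$ref_id), ]
    panel$cr_start <- as.integer(ann$cr_start)
    panel$cr_end <- as.integer(ann$cr_end)
    panel$is_outgroup <- as.logical(ann$is_outgroup)
    if ("circular" %in% names(ann)) panel$circular <- as.logical(ann$circular)
  }
  class(panel) <- c("mito_panel", class(panel))
  panel
}

# FASTA I/O through Biostrings (named character vectors in and out).
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  s <- toupper(as.character(x))
  setNames(unname(s), sub("\\s.*$", "", names(x)))
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

# Look up a single panel entry as a list(ref_id, seq, circular, ...).
panel_entry <- function(panel, ref_id) {
  i <- match(ref_id, panel$ref_id)
  if (is.na(i)) abort(paste0("reference '", ref_id, "' not in panel"))
  as.list(panel[i, setdiff(names(panel), "mutations")])
}
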