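#' Multiple sequence alignment container
#'
#' A light rectangular alignment: a character matrix over
#' `{A,C,G,T,N,-}` with unique row ids and a `column_map` giving, for
#' each column, the 1-based coordinate on the anchor reference it derives
#' from (preserved through column filtering).
#'
#' @param ids Character vector of sequence ids (unique).
#' @param mat Character matrix, rows in the order of `ids`.
#' @param column_map Integer vector, one anchor coordinate per column.
#' @return An object of class `mito_msa`.
#' @export
mito_msa <- function(ids, mat, column_map = seq_len(ncol(mat))) {
  stopifnot(is.matrix(mat), length(ids) == nrow(mat),
            !anyDuplicated(ids), length(column_map) == ncol(mat))
  structure(list(ids = ids, mat = mat,
                 column_map = as.integer(column_map)),
            class = "mito_msa")
}

#' @export
print.mito_msa <- function(x, ...) {
  cat(sprintf("mito_msa: %d sequences x %d columns\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' @method as_tibble mito_msa
#' @export
as_tibble.mito_msa <- function(x, ...) {
  tibble(seq_id = x$ids,
         seq = apply(x$mat, 1, paste, collapse = ""))
}

msa_strings <- function(msa) {
  setNames(apply(msa$mat, 1, paste, collapse = ""), msa$ids)
}

#' Build a reference-anchored multiple alignment
#'
#' Aligns every input sequence pairwise to a single anchor reference
#' (banded global alignment: match 1, mismatch -1, gap open -5, gap
#' extend -1, band half-width `band`) and stacks the results on the
#' anchor's coordinates. Insertions relative to the anchor are dropped —
#' they would become gap-containing columns and be removed by
#' [strip_columns()] anyway — so every column corresponds to one anchor
#' position. For sets of mitogenomes at >= 90% identity this
#' anchor-stacked alignment is nearly identical to a full progressive
#' MSA after gap-column removal, while remaining exactly testable.
#' Externally produced alignments can be imported with
#' [read_alignment()] to bypass this step.
#'
#' @param sequences Named character vector of sequences (or a tibble with
#'   `seq_id` and `seq` columns).
#' @param anchor The anchor: a single panel entry (list with `ref_id`
#'   and `seq`) or a single named sequence.
#' @param band Band half-width for the alignment.
#' @param include_anchor Include the anchor itself as the first row.
#' @param min_score_frac Sanity floor: a sequence whose alignment score
#'   is below `min_score_frac * anchor_length` is rejected as
#'   unalignable.
#' @return A `mito_msa` whose columns are the anchor positions 1..L.
#' @export
anchor_msa <- function(sequences, anchor, band = 200,
                       include_anchor = TRUE, min_score_frac = 0) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$seq, sequences$seq_id)
  }
  if (is.list(anchor)) {
    anchor_id <- anchor$ref_id
    anchor_seq <- anchor$seq
  } else {
    anchor_id <- names(anchor) %||% "anchor"
    anchor_seq <- unname(anchor)
  }
  L <- nchar(anchor_seq)
  stopifnot(length(sequences) >= 1, !is.null(names(sequences)))

  rows <- purrr::map(names(sequences), function(id) {
    s <- toupper(sequences[[id]])
    al <- cpp_banded_align(s, anchor_seq, as.integer(band),
                           1, -1, -5, -1)
    if (al$score < min_score_frac * L) {
      abort(paste0("sequence '", id, "' is unalignable to the anchor ",
                   "(score ", round(al$score), " below floor)"))
    }
    a <- strsplit(al$a, "", fixed = TRUE)[[1]]
    b <- strsplit(al$b, "", fixed = TRUE)[[1]]
    a[b != "-"]  # project onto anchor columns; drop insertions
  })
  mat <- do.call(rbind, rows)
  ids <- names(sequences)
  if (include_anchor && !(anchor_id %in% ids)) {
    mat <- rbind(strsplit(toupper(anchor_seq), "")[[1]], mat)
    ids <- c(anchor_id, ids)
  }
  rownames(mat) <- NULL
  mito_msa(ids, mat, seq_len(L))
}

#' Remove gap/uncalled columns (and optionally the control region)
#'
#' Keeps exactly the columns where every sequence has a called base
#' (A/C/G/T — no `-` and no `N`), restricting all downstream statistics
#' to positions covered by all samples. With `remove_cr = TRUE`, columns
#' whose anchor coordinate falls inside the control-region interval are
#' removed as well. Idempotent.
#'
#' @param msa A `mito_msa`.
#' @param remove_cr Remove control-region columns?
#' @param cr_interval Length-2 integer vector (1-based inclusive anchor
#'   coordinates); required when `remove_cr = TRUE`.
#' @return The filtered `mito_msa`; attribute `empty` is `TRUE` if no
#'   column survives.
#' @export
strip_columns <- function(msa, remove_cr = FALSE, cr_interval = NULL) {
  keep <- colSums(!matrix(msa$mat %in% DNA_BASES, nrow = nrow(msa$mat))) == 0
  if (remove_cr) {
    if (is.null(cr_interval) || length(cr_interval) != 2 ||
        any(is.na(cr_interval))) {
      abort("remove_cr = TRUE needs a valid cr_interval (start, end)")
    }
    keep <- keep & !(msa$column_map >= cr_interval[1] &
                     msa$column_map <= cr_interval[2])
  }
  out <- mito_msa(msa$ids, msa$mat[, keep, drop = FALSE],
                  msa$column_map[keep])
  attr(out, "empty") <- !any(keep)
  if (!any(keep)) warn("all alignment columns were removed")
  out
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable when it holds at least two distinct states, and
#' parsimony-informative when at least two states each occur in at least
#' two sequences.
#'
#' @param msa A gap/N-free `mito_msa` (run [strip_columns()] first).
#' @return A one-row tibble: `n_columns`, `n_variable`,
#'   `n_parsimony_informative`.
#' @export
classify_sites <- function(msa) {
  m <- msa$mat
  if (!ncol(m) || !nrow(m)) abort("empty alignment")
  counts <- vapply(DNA_BASES, function(b) colSums(m == b),
                   numeric(ncol(m)))
  counts <- matrix(counts, ncol = 4)  # columns x bases
  n_states <- rowSums(counts > 0)
  tibble(n_columns = ncol(m),
         n_variable = sum(n_states >= 2),
         n_parsimony_informative = sum(rowSums(counts >= 2) >= 2 &
                                         n_states >= 2))
}

#' Pairwise absolute sequence differences, with per-group diversity
#'
#' Hamming distances (absolute counts of differing columns) between all
#' sequence pairs of a gap/N-free alignment, plus mean and standard
#' deviation of the within-group pairwise differences for each group
#' with at least two members — the standard way to compare genetic
#' diversity across species groups.
#'
#' @param msa A gap/N-free `mito_msa`.
#' @param groups Optional named character vector mapping `seq_id` to a
#'   group label (e.g. species).
#' @return An object of class `pairwise_diffs`: list with `diffs` (the
#'   symmetric count matrix), `pairs` (long tibble: `id_a`, `id_b`,
#'   `n_diff`, `group_a`, `group_b`), and `group_stats` (tibble `group`,
#'   `n_seqs`, `n_pairs`, `mean`, `sd`; groups of size < 2 are flagged
#'   with `NA` stats).
#' @export
pairwise_diffs <- function(msa, groups = NULL) {
  m <- msa$mat
  n <- nrow(m)
  if (n < 2) abort("need at least two sequences")
  d <- matrix(0L, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  pr <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- tibble(id_a = msa$ids[pr[, 1]], id_b = msa$ids[pr[, 2]],
                  n_diff = d[pr])
  group_stats <- NULL
  if (!is.null(groups)) {
    ga <- unname(groups[pairs$id_a]); gb <- unname(groups[pairs$id_b])
    pairs$group_a <- ga; pairs$group_b <- gb
    gsz <- table(factor(unname(groups[msa$ids])))
    within <- pairs[!is.na(ga) & !is.na(gb) & ga == gb, , drop = FALSE]
    group_stats <- within %>%
      group_by(group = .data$group_a) %>%
      summarise(n_pairs = n(), mean = mean(.data$n_diff),
                sd = sd(.data$n_diff), .groups = "drop")
    singletons <- setdiff(names(gsz)[gsz < 2], group_stats$group)
    if (length(singletons)) {
      group_stats <- bind_rows(group_stats,
                               tibble(group = singletons, n_pairs = 0L,
                                      mean = NA_real_, sd = NA_real_))
    }
    group_stats$n_seqs <- as.integer(gsz[group_stats$group])
    group_stats <- group_stats %>%
      select("group", "n_seqs", "n_pairs", "mean", "sd") %>%
      arrange(.data$group)
  }
  structure(list(diffs = d, pairs = pairs, group_stats = group_stats),
            class = "pairwise_diffs")
}

#' @export
print.pairwise_diffs <- function(x, ...) {
  cat(sprintf("pairwise differences over %d sequences\n", nrow(x$diffs)))
  if (!is.null(x$group_stats)) print(x$group_stats)
  invisible(x)
}

#' Percent identity between two sequences
#'
#' Aligns the pair (banded global alignment, same scoring as
#' [anchor_msa()]) and reports `100 * matches / aligned columns`,
#' excluding columns where either sequence has a gap.
#'
#' @param a,b DNA sequences (single strings).
#' @param band Band half-width.
#' @return Percent identity (0-100).
#' @export
sequence_identity <- function(a, b, band = 200) {
  al <- cpp_banded_align(toupper(a), toupper(b), as.integer(band),
                         1, -1, -5, -1)
  x <- strsplit(al$a, "", fixed = TRUE)[[1]]
  y <- strsplit(al$b, "", fixed = TRUE)[[1]]
  keep <- x != "-" & y != "-"
  if (!any(keep)) abort("no aligned columns: sequences unalignable")
  100 * sum(x[keep] == y[keep]) / sum(keep)
}

#' Read an aligned FASTA or NEXUS file as a `mito_msa`
#'
#' @param path File path.
#' @param format `"fasta"` or `"nexus"` (default: guessed from the
#'   extension).
#' @return A `mito_msa` (columns mapped 1..width).
#' @export
read_alignment <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "fasta")
  if (format == "nexus") {
    x <- ape::read.nexus.data(path)
    seqs <- vapply(x, function(s) paste(toupper(s), collapse = ""),
                   character(1))
  } else {
    seqs <- read_fasta(path)
  }
  wid <- unique(nchar(seqs))
  if (length(wid) != 1) abort("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  mito_msa(names(seqs), mat)
}

#' Write a `mito_msa` to aligned FASTA
#'
#' @param msa A `mito_msa`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(msa_strings(msa), path)
}
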