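#' Terminal deamination damage profile
#'
#' Computes the classic ancient-DNA authenticity signal from alignments:
#' the per-offset frequency of C->T mismatches from the 5' read end and
#' of G->A mismatches from the 3' end. For each read the aligned
#' reference segment is extracted (with circular wrap), reverse-strand
#' reads are complement-flipped back into sequencing orientation, and at
#' read offset `i` the profile counts reads whose reference base is `C`
#' (resp. `G`) and whose read base is `T` (resp. `A`), divided by the
#' number of reads whose reference base is `C` (resp. `G`) at that
#' offset. Genuine ancient libraries show elevated frequencies at the
#' termini decaying into the read; contaminating modern DNA does not.
#'
#' @param alignments A `mito_alignments` tibble for one reference.
#' @param panel The `mito_panel` (or a single entry).
#' @param ref_id Reference the alignments are on.
#' @param w Window: number of terminal offsets profiled from each end.
#'   Beyond ~15 positions the deamination signal is negligible for <=
#'   75 bp reads.
#' @return A tibble of class `damage_profile` with columns `end`
#'   (`"5p"`/`"3p"`), `offset` (0-based from that end), `class`
#'   (`"C>T"`/`"G>A"`), `n_obs` (denominator), `n_mut`, `freq` (`NA`
#'   where `n_obs` is 0). Attribute `no_data` is `TRUE` for an empty
#'   alignment set.
#' @export
damage_profile <- function(alignments, panel, ref_id, w = 15) {
  entry <- panel_entry(panel, ref_id)
  L <- nchar(entry$seq)
  aln <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  out5 <- tibble(end = "5p", offset = 0:(w - 1), class = "C>T",
                 n_obs = 0L, n_mut = 0L)
  out3 <- tibble(end = "3p", offset = 0:(w - 1), class = "G>A",
                 n_obs = 0L, n_mut = 0L)
  if (nrow(aln)) {
    doubled <- paste0(entry$seq, substr(entry$seq, 1, max(aln$aligned_len)))
    ref_seg <- substring(doubled, aln$start + 1, aln$start + aln$aligned_len)
    # into sequencing orientation
    minus <- aln$strand == "-"
    read_seq <- aln$seq
    read_seq[minus] <- revcomp(read_seq[minus])
    ref_seg[minus] <- revcomp(ref_seg[minus])

    lens <- aln$aligned_len
    tally <- function(off_from, ref_base, read_base) {
      n_obs <- integer(w); n_mut <- integer(w)
      for (i in seq_len(w)) {
        off <- i - 1L
        has <- lens > off
        if (!any(has)) break
        p <- if (off_from == 5) rep(off + 1L, sum(has)) else lens[has] - off
        rb <- substring(ref_seg[has], p, p)
        qb <- substring(read_seq[has], p, p)
        n_obs[i] <- sum(rb == ref_base)
        n_mut[i] <- sum(rb == ref_base & qb == read_base)
      }
      list(n_obs = n_obs, n_mut = n_mut)
    }
    t5 <- tally(5, "C", "T")
    t3 <- tally(3, "G", "A")
    out5$n_obs <- t5$n_obs; out5$n_mut <- t5$n_mut
    out3$n_obs <- t3$n_obs; out3$n_mut <- t3$n_mut
  }
  out <- bind_rows(out5, out3) %>%
    mutate(freq = ifelse(.data$n_obs > 0, .data$n_mut / .data$n_obs, NA_real_))
  attr(out, "no_data") <- nrow(aln) == 0
  class(out) <- c("damage_profile", class(out))
  out
}

#' Fit a geometric decay model to a damage profile
#'
#' Models the 5' C->T frequency at offset `i` as `d * r^i` and estimates
#' `(d, r)` by weighted nonlinear least squares (weights = per-offset
#' observation counts), recovering the simulator's damage parameters
#' from mapped data. Falls back to a log-linear regression if the
#' nonlinear fit does not converge.
#'
#' @param profile A `damage_profile`.
#' @param end Which end to fit (`"5p"` or `"3p"`).
#' @return An object of class `damage_fit` with elements `d` (terminal
#'   frequency), `r` (per-position decay), `method`, `n_offsets`.
#' @export
fit_damage <- function(profile, end = "5p") {
  df <- profile[profile$end == end & profile$n_obs > 0 & !is.na(profile$freq), ]
  if (nrow(df) < 2) abort("not enough informative offsets to fit a decay model")
  fit <- tryCatch({
    m <- stats::nls(freq ~ d * r^offset, data = df,
                    start = list(d = max(df$freq[1], 1e-3), r = 0.5),
                    weights = df$n_obs,
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
    p <- stats::coef(m)
    list(d = unname(p["d"]), r = unname(p["r"]), method = "nls")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    pos <- df[df$freq > 0, ]
    m <- stats::lm(log(freq) ~ offset, data = pos, weights = pos$n_obs)
    co <- stats::coef(m)
    fit <- list(d = exp(unname(co[1])), r = exp(unname(co[2])),
                method = "log-linear")
  }
  structure(c(fit, list(end = end, n_offsets = nrow(df))),
            class = "damage_fit")
}

#' @export
print.damage_fit <- function(x, ...) {
  cat(sprintf("geometric damage fit (%s, %s): d = %.3f, r = %.3f\n",
              x$end, x$method, x$d, x$r))
  invisible(x)
}

#' Fragment-length summary of aligned reads
#'
#' @param alignments A `mito_alignments` tibble.
#' @return A list of class `length_summary`: `n`, `mean`, `sd`, and a
#'   `histogram` tibble (`length`, `n`). `no_data` is `TRUE` when empty.
#' @export
length_summary <- function(alignments) {
  n <- nrow(alignments)
  if (!n) {
    return(structure(list(n = 0L, mean = NA_real_, sd = NA_real_,
                          histogram = tibble(length = integer(0), n = integer(0)),
                          no_data = TRUE),
                     class = "length_summary"))
  }
  len <- alignments$aligned_len
  structure(list(n = n, mean = mean(len), sd = sd(len),
                 histogram = dplyr::count(tibble(length = len), .data$length),
                 no_data = FALSE),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  if (x$no_data) cat("length summary: no data\n")
  else cat(sprintf("length summary: n = %d, mean = %.1f, sd = %.2f\n",
                   x$n, x$mean, x$sd))
  invisible(x)
}

#' Write a damage profile to TSV
#'
#' @param profile A `damage_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_damage_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
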