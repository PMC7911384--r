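# Shared fixtures and independent oracles, built in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# a one-row panel around a given sequence (no annotation frills)
panel_from_seq <- function(seq, ref_id = "ref", circular = TRUE,
                           is_outgroup = FALSE) {
  p <- tibble::tibble(ref_id = ref_id, seq = seq, circular = circular,
                      cr_start = NA_integer_, cr_end = NA_integer_,
                      is_outgroup = is_outgroup)
  class(p) <- c("mito_panel", class(p))
  p
}

# hand-built alignment records (reads given in reference orientation)
aln_tbl <- function(ref_id, start, seq, strand = "+", mapq = 60,
                    read_id = NULL) {
  n <- max(length(start), length(seq))
  start <- rep_len(start, n); seq <- rep_len(seq, n)
  strand <- rep_len(strand, n); mapq <- rep_len(mapq, n)
  out <- tibble::tibble(
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    ref_id = ref_id, start = as.integer(start),
    end = as.integer(start + nchar(seq)), strand = strand,
    n_mismatch = 0L, mapq = as.integer(mapq),
    aligned_len = nchar(seq), seq = seq
  )
  class(out) <- c("mito_alignments", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random gap-free alignment matrix as a mito_msa
rand_msa <- function(n_seq, n_col) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n_seq * n_col, TRUE),
                nrow = n_seq)
  mito_msa(sprintf("s%d", seq_len(n_seq)), mat)
}

# brute-force site classification: per-column state tally
oracle_classify <- function(mat) {
  variable <- 0L; pi <- 0L
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) >= 2) variable <- variable + 1L
    if (sum(tab >= 2) >= 2) pi <- pi + 1L
  }
  c(variable = variable, pi = pi)
}

# brute-force per-position depth/breadth from an alignment set
oracle_breadth <- function(aln, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(aln))) {
    pos <- (aln$start[i] + seq_len(aln$aligned_len[i]) - 1L) %% L + 1L
    depth[pos] <- depth[pos] + 1L
  }
  sum(depth > 0)
}

# evolve sequences down an ape tree, substitution-only; branch lengths are
# expected substitutions per site (low-divergence regime)
evolve_on_tree <- function(tree, n_sites, seed = 1) {
  set.seed(seed)
  root_seq <- sample(c("A", "C", "G", "T"), n_sites, TRUE)
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1
  seqs[[root]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    from <- ord$edge[k, 1]; to <- ord$edge[k, 2]
    s <- seqs[[from]]
    hit <- which(runif(n_sites) < ord$edge.length[k])
    if (length(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       character(1))
    }
    seqs[[to]] <- s
  }
  mat <- do.call(rbind, seqs[seq_len(n_tip)])
  mito_msa(tree$tip.label, mat)
}
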