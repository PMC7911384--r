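#' Pairwise distance matrix from an alignment
#'
#' Computes evolutionary distances between all sequences of a gap/N-free
#' alignment under the p-distance, Jukes-Cantor (JC69) or Kimura
#' two-parameter (K80) model, via the standard distance machinery of the
#' \pkg{ape} package.
#'
#' @param msa A gap/N-free `mito_msa`.
#' @param model `"p"`, `"JC69"` or `"K80"`.
#' @return A `dist` object with a `model` attribute.
#' @export
distance_matrix <- function(msa, model = c("K80", "JC69", "p")) {
  model <- match.arg(model)
  bin <- msa_as_dnabin(msa)
  ape_model <- c(p = "raw", JC69 = "JC69", K80 = "K80")[[model]]
  d <- ape::dist.dna(bin, model = ape_model, pairwise.deletion = FALSE)
  if (any(!is.finite(d))) {
    m <- as.matrix(d)
    bad <- which(!is.finite(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    abort(paste0("distance saturated under ", model, " for pair ",
                 rownames(m)[bad[1]], " / ", colnames(m)[bad[2]]))
  }
  attr(d, "model") <- model
  d
}

msa_as_dnabin <- function(msa) {
  m <- tolower(msa$mat)
  rownames(m) <- msa$ids
  ape::as.DNAbin(m)
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining on a distance matrix (exact on additive
#' matrices). Negative branch-length estimates — a known artefact of NJ
#' on noisy distances — are clamped to zero; the number of clamped
#' branches is recorded in attribute `n_clamped`.
#'
#' @param dm A `dist` object (>= 3 taxa), e.g. from [distance_matrix()].
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (attr(dm, "Size") < 3) abort("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(dm)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    inform(sprintf("clamped %d negative branch length(s) to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilds the tree from each resample, and
#' maps bipartition frequencies (as percentages) onto the full-data
#' tree's internal nodes.
#'
#' @param msa A gap/N-free `mito_msa`.
#' @param model Distance model (see [distance_matrix()]).
#' @param n_reps Number of bootstrap replicates (0 = no supports).
#' @param seed Integer seed for the resampling.
#' @return A `phylo` tree; `node.label` holds the supports (the root
#'   node's label is empty). With `n_reps = 0`, attribute
#'   `no_support = TRUE`.
#' @export
bootstrap_support <- function(msa, model = "K80", n_reps = 100, seed = 1) {
  tree <- nj_tree(distance_matrix(msa, model))
  if (n_reps == 0) {
    attr(tree, "no_support") <- TRUE
    return(tree)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nc <- ncol(msa$mat)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    sub <- mito_msa(msa$ids, msa$mat[, cols, drop = FALSE])
    boots[[b]] <- suppressMessages(nj_tree(distance_matrix(sub, model)))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- round(100 * counts / n_reps)
  tree$node.label[1] <- ""  # root of the unrooted representation
  tree
}

#' Root a tree on an outgroup taxon
#'
#' Places the root on the outgroup's pendant edge. Rooting an
#' already-rooted tree on the same outgroup is a no-op.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Leaf label to root on.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    abort(paste0("outgroup '", outgroup, "' is not a leaf of the tree"))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Phylogenetic assignment of a query sequence
#'
#' Formalises "where does the sample fall in the tree": the query's
#' assignment is the candidate reference that is its closest leaf
#' (patristic distance) within the smallest well-supported clade
#' (bootstrap >= `min_support`) containing the query and at least one
#' candidate, or `NA` when no such clade exists. Trees without support
#' values are treated as fully supported.
#'
#' @param tree A `phylo` tree (rooted; see [root_with_outgroup()]).
#' @param taxon The query leaf label.
#' @param candidates Character vector of candidate reference labels.
#' @param min_support Minimum bootstrap percentage for a clade to count.
#' @return A single `ref_id` from `candidates`, or `NA_character_`.
#' @export
clade_of <- function(tree, taxon, candidates, min_support = 50) {
  if (!taxon %in% tree$tip.label) abort(paste0("taxon '", taxon, "' not in tree"))
  candidates <- intersect(candidates, tree$tip.label)
  if (!length(candidates)) return(NA_character_)
  n_tip <- length(tree$tip.label)
  tip <- match(taxon, tree$tip.label)
  # internal nodes on the path from the query to the root, smallest clade first
  anc <- ape::nodepath(tree, from = tip, to = n_tip + 1)
  anc <- anc[anc > n_tip]
  supports <- tree$node.label
  coph <- ape::cophenetic.phylo(tree)
  for (node in anc) {
    if (!is.null(supports)) {
      lab <- supports[node - n_tip]
      sup <- suppressWarnings(as.numeric(lab))
      is_root <- node == n_tip + 1
      if (!is_root && !is.na(lab) && nzchar(lab) && !is.na(sup) &&
          sup < min_support) {
        next
      }
    }
    leaves <- tree$tip.label[.clade_tips(tree, node)]
    hits <- intersect(setdiff(leaves, taxon), candidates)
    if (length(hits)) {
      return(hits[which.min(coph[taxon, hits])])
    }
  }
  NA_character_
}

.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  out <- integer(0)
  todo <- node
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n_tip])
    todo <- c(todo, kids[kids > n_tip])
  }
  out
}

#' Write a tree to newick (supports as internal node labels)
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a distance matrix in PHYLIP format
#'
#' @param dm A `dist` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phylip_dist <- function(dm, path) {
  m <- as.matrix(dm)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(rownames(m)[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
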