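#' Collapse aligned sequences into haplotypes
#'
#' Merges identical rows of a gap/N-free alignment into haplotypes,
#' counting how many input sequences each collapses.
#'
#' @param msa A gap/N-free `mito_msa`.
#' @return A tibble of class `haplotypes` with `hap_id` (`H1`, `H2`, ...
#'   in order of first appearance), `seq`, `n` (frequency), and a
#'   `members` list-column of collapsed sequence ids.
#' @export
collapse_haplotypes <- function(msa) {
  if (!nrow(msa$mat)) abort("empty alignment")
  s <- msa_strings(msa)
  first <- !duplicated(s)
  key <- match(s, s[first])
  out <- tibble(
    hap_id = sprintf("H%d", seq_len(sum(first))),
    seq = unname(s[first]),
    n = as.integer(tabulate(key, nbins = sum(first))),
    members = unname(split(msa$ids, key))
  )
  class(out) <- c("haplotypes", class(out))
  out
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction: (1) pairwise Hamming
#' distances between haplotype state vectors; (2) the epsilon-relaxed
#' minimum-spanning network (an edge is kept when its length is within
#' `epsilon` of the bottleneck — the largest edge on the minimum
#' spanning tree path — between its endpoints; at `epsilon = 0` this is
#' the union of all minimum spanning trees); (3) for each triplet of
#' mutually connected nodes, the median vector (per-column majority of
#' the three states, ties resolved toward the first node in a fixed
#' ordering) is added as an inferred node if doing so strictly shortens
#' the network; (4) median vectors that end with degree < 3 are pruned;
#' steps 2-4 repeat to a fixed point. Node ordering is fixed by input
#' order, so the result is independent of row permutations of the input.
#'
#' Inferred median nodes approximate unsampled intermediate haplotypes;
#' sampled haplotypes always remain nodes and stay connected.
#'
#' @param haplotypes A `haplotypes` tibble from [collapse_haplotypes()]
#'   (at least 2 haplotypes).
#' @param epsilon Relaxation parameter (0 = strict, the usual default).
#' @param max_iter Safety cap on median-joining sweeps.
#' @return An object of class `haplo_network`: list with `nodes`
#'   (tibble: `id`, `seq`, `n`, `is_median`), `edges` (tibble: `from`,
#'   `to`, `weight`), `epsilon`, `length` (sum of edge weights), and
#'   `graph` (an igraph object).
#' @export
build_mj_network <- function(haplotypes, epsilon = 0, max_iter = 50) {
  if (nrow(haplotypes) < 2) abort("need at least two haplotypes")
  # canonical (content-based) node ordering, so tie-breaks - and hence the
  # final edge set - do not depend on input row order
  ord <- order(haplotypes$seq)
  haplotypes <- haplotypes[ord, , drop = FALSE]
  states <- do.call(rbind, strsplit(haplotypes$seq, "", fixed = TRUE))
  n_samp <- nrow(states)

  ham <- function(a, b) sum(a != b)
  all_dist <- function(S) {
    n <- nrow(S)
    d <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- ham(S[i, ], S[j, ])
    }
    d
  }

  # epsilon-relaxed MSN over node set with distance matrix d
  msn_edges <- function(d, eps) {
    n <- nrow(d)
    g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                                  weighted = TRUE)
    mst <- igraph::mst(g_full, algorithm = "prim")
    # bottleneck (minimax edge) between every pair, via MST paths
    bottle <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      paths <- igraph::shortest_paths(mst, from = i, to = (i + 1):n,
                                      output = "epath", weights = NA)
      for (k in seq_along(paths$epath)) {
        w <- igraph::E(mst)$weight[as.integer(paths$epath[[k]])]
        bottle[i, i + k] <- bottle[i + k, i] <- max(w)
      }
    }
    idx <- which(upper.tri(d) & d <= bottle + eps & d > 0, arr.ind = TRUE)
    tibble(from = idx[, 1], to = idx[, 2],
           weight = d[idx])
  }

  net_length <- function(S, eps) sum(msn_edges(all_dist(S), eps)$weight)

  majority3 <- function(a, b, c) {
    out <- a
    bc <- b == c
    out[bc] <- b[bc]  # two agreeing states win; all-distinct keeps a
    out
  }

  S <- states
  is_median <- rep(FALSE, n_samp)
  changed <- FALSE
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # (re)build network, prune obsolete medians (degree < 3)
    repeat {
      d <- all_dist(S)
      ed <- msn_edges(d, epsilon)
      deg <- tabulate(c(ed$from, ed$to), nbins = nrow(S))
      drop <- which(is_median & deg < 3)
      if (!length(drop)) break
      S <- S[-drop, , drop = FALSE]
      is_median <- is_median[-drop]
    }
    cur_len <- sum(ed$weight)

    # connected triplets, in deterministic order
    g <- igraph::graph_from_data_frame(ed[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(nrow(S))))
    tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
    if (ncol(tri)) {
      tri <- matrix(apply(tri, 2, sort), nrow = 3)
      tri <- tri[, order(tri[1, ], tri[2, ], tri[3, ]), drop = FALSE]
      for (t in seq_len(ncol(tri))) {
        u <- tri[1, t]; v <- tri[2, t]; w <- tri[3, t]
        med <- majority3(S[u, ], S[v, ], S[w, ])
        dup <- any(apply(S, 1, function(r) all(r == med)))
        if (dup) next
        S2 <- rbind(S, med)
        if (net_length(S2, epsilon) < cur_len) {
          S <- S2
          is_median <- c(is_median, TRUE)
          changed <- TRUE
          break  # restart the sweep with the new node set
        }
      }
    }
    if (!changed) break
  }
  if (changed) warn("median joining hit the iteration cap before converging")

  # final prune + edges
  repeat {
    d <- all_dist(S)
    ed <- msn_edges(d, epsilon)
    deg <- tabulate(c(ed$from, ed$to), nbins = nrow(S))
    drop <- which(is_median & deg < 3)
    if (!length(drop)) break
    S <- S[-drop, , drop = FALSE]
    is_median <- is_median[-drop]
  }

  seqs <- apply(S, 1, paste, collapse = "")
  samp_idx <- which(!is_median)
  ids <- character(nrow(S))
  ids[samp_idx] <- haplotypes$hap_id[seq_along(samp_idx)]
  if (any(is_median)) {
    ids[is_median] <- sprintf("mv%d", seq_len(sum(is_median)))
  }
  nodes <- tibble(id = ids, seq = unname(seqs),
                  n = ifelse(is_median, 0L,
                             haplotypes$n[match(ids, haplotypes$hap_id)]),
                  is_median = is_median)
  edges <- tibble(from = ids[ed$from], to = ids[ed$to], weight = ed$weight)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                 length = sum(edges$weight), graph = g),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("median-joining network: %d sampled + %d inferred nodes, %d edges, total length %d\n",
              sum(!x$nodes$is_median), sum(x$nodes$is_median),
              nrow(x$edges), x$length))
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes the edge list as TSV (`from`, `to`, `weight`) and/or the graph
#' as GraphML.
#'
#' @param network A `haplo_network`.
#' @param tsv,graphml Output paths (either may be `NULL`).
#' @return The written paths, invisibly.
#' @export
write_network <- function(network, tsv = NULL, graphml = NULL) {
  if (!is.null(tsv)) readr::write_tsv(network$edges, tsv)
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
  }
  invisible(c(tsv = tsv, graphml = graphml))
}
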