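test_that("distances follow closed-form model corrections", {
  msa <- mito_msa(c("a", "b"), rbind(strsplit(strrep("A", 100), "")[[1]],
                                     strsplit(strrep("A", 100), "")[[1]]))
  for (m in c("p", "JC69", "K80")) {
    expect_equal(as.numeric(distance_matrix(msa, m)), 0)
  }
  # 2 differences over 100 columns (transversions)
  m2 <- msa$mat
  m2[2, 1:2] <- "C"  # A->C transversion
  msa2 <- mito_msa(c("a", "b"), m2)
  expect_equal(as.numeric(distance_matrix(msa2, "p")), 0.02)
  expect_equal(as.numeric(distance_matrix(msa2, "JC69")),
               -0.75 * log(1 - 0.08 / 3), tolerance = 1e-10)
})

test_that("p-distances equal the differing-column-count oracle", {
  set.seed(101)
  for (i in 1:20) {
    msa <- rand_msa(sample(3:6, 1), 80)
    d <- as.matrix(distance_matrix(msa, "p"))
    a <- sample(nrow(msa$mat), 1); b <- sample(nrow(msa$mat), 1)
    expect_equal(d[a, b], sum(msa$mat[a, ] != msa$mat[b, ]) / 80)
  }
})

test_that("saturated pairs are rejected with the pair named", {
  mat <- rbind(strsplit(strrep("A", 100), "")[[1]],
               strsplit(strrep("C", 100), "")[[1]])
  msa <- mito_msa(c("a", "b"), mat)
  expect_error(distance_matrix(msa, "JC69"), "a / b|saturat")
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 3,
                2, 0, 4,
                3, 4, 0), 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(as.dist(d))
  # a = (d_AB + d_AC - d_BC)/2 = 0.5; b = 1.5; c = 2.5
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.5, 1.5, 2.5))
})

test_that("NJ recovers additive matrices exactly", {
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  # four-point condition: AB|CD with internal branch 1
  sums <- c(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"],
            d["A", "D"] + d["B", "C"])
  expect_equal(sort(sums), c(7, 9, 9))
  tr <- nj_tree(as.dist(d))
  # the split AB|CD is present; path-length matrix reproduces the input
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]],
               d)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
  # random additive matrices from random trees: exact recovery
  set.seed(102)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    dm <- as.dist(ape::cophenetic.phylo(gen))
    rec <- nj_tree(dm)
    expect_equal(as.matrix(ape::cophenetic.phylo(rec))[attr(dm, "Labels"),
                                                       attr(dm, "Labels")],
                 as.matrix(dm), tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(rec)), 0)
  }
  expect_error(nj_tree(as.dist(matrix(0, 2, 2))), "3 taxa")
})

test_that("NJ recovers the topology of sequences evolved on a known tree", {
  set.seed(103)
  gen <- ape::rtree(8, br = function(k) runif(k, 0.01, 0.05))
  msa <- evolve_on_tree(gen, n_sites = 20000, seed = 104)
  tr <- nj_tree(distance_matrix(msa, "JC69"))
  expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(tr)), 0)
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # alignment whose every column supports the split ab|cd
  n_col <- 60
  mat <- rbind(rep("A", n_col), rep("A", n_col), rep("C", n_col),
               rep("C", n_col))
  # add a few noise-free distinguishing columns within pairs
  mat[2, 1:10] <- "G"; mat[4, 1:10] <- "T"
  msa <- mito_msa(c("a", "b", "c", "d"), mat)
  t1 <- bootstrap_support(msa, model = "p", n_reps = 50, seed = 7)
  t2 <- bootstrap_support(msa, model = "p", n_reps = 50, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  # n_reps = 0: no supports, flagged
  t0 <- bootstrap_support(msa, model = "p", n_reps = 0)
  expect_null(t0$node.label)
  expect_true(attr(t0, "no_support"))
})

test_that("bootstrap supports do not depend on taxon order", {
  set.seed(105)
  gen <- ape::rtree(6, br = function(k) runif(k, 0.02, 0.08))
  msa <- evolve_on_tree(gen, 500, seed = 106)
  perm <- sample(6)
  msa_p <- mito_msa(msa$ids[perm], msa$mat[perm, ])
  t1 <- bootstrap_support(msa, model = "p", n_reps = 30, seed = 9)
  t2 <- bootstrap_support(msa_p, model = "p", n_reps = 30, seed = 9)
  key <- function(tr) {
    n_tip <- length(tr$tip.label)
    parts <- ape::prop.part(tr)
    labs <- lapply(parts, function(p) sort(tr$tip.label[p]))
    sup <- tr$node.label
    out <- setNames(sup[seq_along(labs)],
                    vapply(labs, paste, character(1), collapse = ","))
    out[order(names(out))]
  }
  expect_identical(key(t1), key(t2))
})

test_that("outgroup rooting is idempotent and guards its input", {
  set.seed(107)
  gen <- ape::rtree(5)
  r1 <- root_with_outgroup(ape::unroot(gen), "t1")
  expect_true(ape::is.rooted(r1))
  r2 <- root_with_outgroup(r1, "t1")
  expect_equal(phangorn::RF.dist(r1, r2, rooted = TRUE), 0)
  expect_error(root_with_outgroup(gen, "nope"), "not a leaf")
})

test_that("queries are assigned to the clade of their source reference", {
  p <- sim_panel(n_refs = 5, ref_length = 4000, divergence = 0.08, seed = 108)
  # evolve a query a small distance from ref02
  q <- strsplit(p$seq[2], "")[[1]]
  set.seed(109)
  at <- sample(4000, 40)
  q[at] <- vapply(q[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  msa <- mito_msa(c(p$ref_id, "query"),
                  rbind(do.call(rbind, strsplit(p$seq, "")), q))
  tree <- bootstrap_support(msa, model = "K80", n_reps = 50, seed = 110)
  tree <- root_with_outgroup(tree, "ref05")
  hit <- clade_of(tree, "query", candidates = p$ref_id[1:4])
  expect_equal(hit, "ref02")
  expect_error(clade_of(tree, "ghost", p$ref_id), "not in tree")
})

test_that("trees and distance matrices export to standard formats", {
  set.seed(111)
  gen <- ape::rtree(4)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_tree(gen, nwk)
  expect_equal(phangorn::RF.dist(ape::read.tree(nwk), gen), 0)
  msa <- rand_msa(3, 50)
  phy <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(distance_matrix(msa, "p"), phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
})
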