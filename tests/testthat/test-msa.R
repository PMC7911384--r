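test_that("identical sequences stack without gaps", {
  set.seed(81)
  anchor <- list(ref_id = "anchor", seq = rand_dna(400))
  msa <- anchor_msa(setNames(c(anchor$seq, anchor$seq), c("a", "b")), anchor)
  expect_equal(ncol(msa$mat), 400)
  expect_true(all(msa$mat != "-"))
  expect_equal(msa$ids, c("anchor", "a", "b"))
  expect_equal(unname(paleomito:::msa_strings(msa)[["a"]]), anchor$seq)
})

test_that("a deletion appears as gaps at the deleted anchor positions", {
  set.seed(82)
  anchor <- list(ref_id = "anchor", seq = rand_dna(300))
  del <- paste0(substr(anchor$seq, 1, 150), substr(anchor$seq, 154, 300))
  msa <- anchor_msa(c(q = del), anchor)
  row <- msa$mat[msa$ids == "q", ]
  expect_equal(sum(row == "-"), 3)
  expect_equal(ncol(msa$mat), 300)
  # surviving columns carry the anchor's bases
  keep <- row != "-"
  expect_identical(row[keep],
                   strsplit(anchor$seq, "")[[1]][keep])
})

test_that("insertions relative to the anchor are dropped", {
  set.seed(83)
  anchor <- list(ref_id = "anchor", seq = rand_dna(300))
  ins <- paste0(substr(anchor$seq, 1, 100), "TTTTT",
                substr(anchor$seq, 101, 300))
  msa <- anchor_msa(c(q = ins), anchor)
  expect_equal(ncol(msa$mat), 300)
  expect_identical(unname(paleomito:::msa_strings(msa)[["q"]]), anchor$seq)
})

test_that("pairwise differences from the MSA equal the mutation-log counts", {
  p <- sim_panel(n_refs = 5, ref_length = 2000,
                 divergence = c(0.01, 0.02, 0.03, 0.04, 0.01), seed = 84)
  anchor <- list(ref_id = "anchor", seq = attr(p, "root_seq"))
  msa <- anchor_msa(setNames(p$seq, p$ref_id), anchor, include_anchor = FALSE)
  pd <- pairwise_diffs(msa)
  root <- strsplit(attr(p, "root_seq"), "")[[1]]
  for (i in 1:4) for (j in (i + 1):5) {
    li <- p$mutations[[i]]; lj <- p$mutations[[j]]
    pos <- union(li$pos, lj$pos)
    si <- root[pos]; si[match(li$pos, pos)] <- li$to
    sj <- root[pos]; sj[match(lj$pos, pos)] <- lj$to
    expect_equal(unname(pd$diffs[i, j]), sum(si != sj))
  }
})

test_that("column stripping removes gap, N and control-region columns", {
  mat <- rbind(strsplit("ACGTACGTAC", "")[[1]],
               strsplit("ACGTACGTAC", "")[[1]])
  mat[2, 7] <- "N"
  msa <- mito_msa(c("a", "b"), mat)
  out <- strip_columns(msa)
  expect_equal(ncol(out$mat), 9)
  expect_false(7 %in% out$column_map)
  # idempotent
  expect_identical(strip_columns(out)$mat, out$mat)
  # no-op when nothing to strip
  clean <- mito_msa(c("a", "b"), mat[, -7, drop = FALSE], setdiff(1:10, 7))
  expect_identical(strip_columns(clean)$mat, clean$mat)
  # control-region removal uses anchor coordinates
  cr <- strip_columns(msa, remove_cr = TRUE, cr_interval = c(1, 4))
  expect_true(all(cr$column_map > 4))
  expect_error(strip_columns(msa, remove_cr = TRUE), "cr_interval")
  # stripping everything flags the result
  allN <- mito_msa("a", matrix("N", 1, 3))
  expect_warning(empty <- strip_columns(allN), "removed")
  expect_true(attr(empty, "empty"))
})

test_that("site classification matches hand-enumerable columns", {
  mat <- rbind(c("A", "A", "A"),
               c("A", "A", "A"),
               c("A", "C", "C"),
               c("A", "C", "T"))
  # col1: invariant; col2: variable + informative; col3: variable + informative
  # (two states with >= 2 each in col2; col3 has A:2,C:1,T:1 -> not informative)
  msa <- mito_msa(sprintf("s%d", 1:4), mat)
  cs <- classify_sites(msa)
  expect_equal(cs$n_columns, 3L)
  expect_equal(cs$n_variable, 2L)
  expect_equal(cs$n_parsimony_informative, 1L)
  # (A,A,A,C) variable but not informative; (A,A,C,C) both
  one <- classify_sites(mito_msa(sprintf("s%d", 1:4),
                                 matrix(c("A", "A", "A", "C"), 4)))
  expect_equal(one$n_variable, 1L)
  expect_equal(one$n_parsimony_informative, 0L)
  expect_error(classify_sites(mito_msa("a", matrix(character(0), 1, 0))),
               "empty")
})

test_that("site classification matches the brute-force oracle on random alignments", {
  set.seed(85)
  for (i in 1:250) {
    msa <- rand_msa(sample(2:8, 1), sample(1:30, 1))
    want <- oracle_classify(msa$mat)
    got <- classify_sites(msa)
    expect_equal(got$n_variable, unname(want["variable"]))
    expect_equal(got$n_parsimony_informative, unname(want["pi"]))
    expect_lte(got$n_parsimony_informative, got$n_variable)
  }
})

test_that("pairwise differences are Hamming counts, invariant to row order", {
  msa <- mito_msa(c("a", "b"), rbind(strsplit("AAAA", "")[[1]],
                                     strsplit("AATT", "")[[1]]))
  pd <- pairwise_diffs(msa)
  expect_equal(unname(pd$diffs["a", "b"]), 2L)
  expect_equal(unname(diag(pd$diffs)), c(0L, 0L))
  set.seed(86)
  big <- rand_msa(6, 40)
  pd1 <- pairwise_diffs(big)
  perm <- sample(6)
  shuffled <- mito_msa(big$ids[perm], big$mat[perm, ])
  pd2 <- pairwise_diffs(shuffled)
  expect_equal(pd2$diffs[big$ids, big$ids], pd1$diffs)
})

test_that("within-group diversity matches the star-tree expectation", {
  # star tree: every member carries ~m private mutations, so within-group
  # pairs differ at ~2m sites (minus rare coincident hits)
  m_rate <- 0.01  # per-site, 2000 sites -> m = 20
  p <- sim_panel(n_refs = 6, ref_length = 2000,
                 divergence = rep(m_rate, 6), seed = 87)
  msa <- mito_msa(p$ref_id, do.call(rbind, strsplit(p$seq, "")))
  groups <- setNames(rep("grp", 6), p$ref_id)
  pd <- pairwise_diffs(msa, groups)
  expect_equal(pd$group_stats$n_pairs, 15L)
  # mutation-log oracle: mean pairwise difference ~ twice the realized
  # per-branch mutation count (coincident hits make it slightly smaller)
  m_bar <- mean(vapply(p$mutations, nrow, integer(1)))
  expect_lt(abs(pd$group_stats$mean - 2 * m_bar), 3)
  # groups of size < 2 get flagged NA stats
  groups2 <- setNames(c(rep("big", 5), "lone"), p$ref_id)
  pd2 <- pairwise_diffs(msa, groups2)
  lone <- pd2$group_stats[pd2$group_stats$group == "lone", ]
  expect_true(is.na(lone$mean))
  expect_equal(lone$n_seqs, 1L)
})

test_that("sequence identity reflects alignment-level divergence", {
  expect_equal(sequence_identity("ACGTACGT", "ACGTACGT"), 100)
  p <- sim_panel(n_refs = 2, ref_length = 8000, divergence = 0.08, seed = 88)
  expect_lt(abs(sequence_identity(p$seq[1], p$seq[2]) - 92), 1)
})

test_that("alignments round-trip through FASTA and NEXUS import works", {
  set.seed(89)
  msa <- rand_msa(4, 60)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_alignment(msa, fa)
  back <- read_alignment(fa)
  expect_identical(back$mat, msa$mat)
  expect_identical(back$ids, msa$ids)
  # NEXUS via ape round-trip
  nex <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus.data(setNames(lapply(seq_len(4), function(i) msa$mat[i, ]),
                                 msa$ids),
                        nex, interleaved = FALSE)
  nback <- read_alignment(nex)
  expect_identical(nback$mat, msa$mat)
})
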