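test_that("seed lookup finds wrapped k-mer positions on a circular reference", {
  # "ACGTACGT", k = 4: TACG occurs at 3 and (wrapped) at 7
  expect_equal(seed_positions("ACGTACGT", "TACG", circular = TRUE,
                              max_read_len = 8), c(3L, 7L))
  expect_equal(seed_positions("ACGTACGT", "TACG", circular = FALSE), 3L)
  # k = L: one hit per rotation origin present in the extension window
  expect_equal(seed_positions("ACGT", "ACGT", circular = TRUE,
                              max_read_len = 4), 0L)
  expect_error(seed_positions("ACG", "ACGT"), "longer")
})

test_that("seed index agrees with an exhaustive substring scan", {
  set.seed(21)
  ref <- rand_dna(2000)
  ext <- paste0(ref, substr(ref, 1, 74))
  for (i in 1:100) {
    pos <- sample(2000, 1)
    kmer <- substr(ext, pos, pos + 11)
    got <- seed_positions(ref, kmer, circular = TRUE, max_read_len = 75)
    want <- integer(0)
    for (s in seq_len(2000)) {
      if (substr(ext, s, s + 11) == kmer) want <- c(want, s - 1L)
    }
    expect_equal(got, want)
  }
})

test_that("a planted exact substring maps uniquely with mapq 60", {
  set.seed(3)
  ref <- rand_dna(16000)
  panel <- panel_from_seq(ref)
  read <- substr(ref, 101, 140)  # 0-based start 100
  aln <- map_reads(tibble::tibble(read_id = "q", seq = read), panel)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 100L)
  expect_equal(aln$strand, "+")
  expect_equal(aln$n_mismatch, 0L)
  expect_equal(aln$mapq, 60L)
})

test_that("origin-spanning reads map through the circular junction", {
  set.seed(4)
  ref <- rand_dna(1000)
  panel <- panel_from_seq(ref, circular = TRUE)
  read <- paste0(substr(ref, 991, 1000), substr(ref, 1, 10))
  cfg <- map_config(min_read_len = 20, k = 10)
  aln <- map_reads(tibble::tibble(read_id = "junction", seq = read), panel, cfg)
  expect_equal(aln$start, 990L)
  expect_equal(aln$end, 1010L)  # exceeds L before modular wrap
  expect_equal(aln$n_mismatch, 0L)
  # linear mode must not produce the wrapped placement
  panel_lin <- panel_from_seq(ref, circular = FALSE)
  expect_equal(nrow(map_reads(tibble::tibble(read_id = "junction", seq = read),
                              panel_lin, cfg)), 0)
})

test_that("mapping the reverse complement gives the mirrored placement", {
  set.seed(5)
  ref <- rand_dna(5000)
  panel <- panel_from_seq(ref)
  fwd <- substr(ref, 2001, 2050)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(fwd, "")[[1]])), collapse = "")
  a1 <- map_reads(tibble::tibble(read_id = "f", seq = fwd), panel)
  a2 <- map_reads(tibble::tibble(read_id = "r", seq = rc), panel)
  expect_equal(a1$start, a2$start)
  expect_equal(a1$strand, "+")
  expect_equal(a2$strand, "-")
  expect_equal(a2$seq, fwd)  # stored in reference orientation
})

test_that("best placements agree with the exhaustive all-positions scan", {
  set.seed(6)
  ref <- rand_dna(3000)
  panel <- panel_from_seq(ref)
  n <- 300
  starts <- sample(0:2999, n, replace = TRUE)
  lens <- sample(35:70, n, replace = TRUE)
  ext <- paste0(ref, substr(ref, 1, 74))
  reads <- substring(ext, starts + 1, starts + lens)
  # plant up to 3 mismatches
  n_mm <- sample(0:3, n, replace = TRUE)
  for (i in seq_len(n)) {
    if (n_mm[i] == 0) next
    ch <- strsplit(reads[i], "")[[1]]
    at <- sample(lens[i], n_mm[i])
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  aln <- map_reads(tibble::tibble(read_id = sprintf("r%03d", 1:n), seq = reads),
                   panel)
  expect_equal(nrow(aln), n)
  for (i in seq_len(n)) {
    scan <- paleomito:::cpp_scan_read(reads[i], ref, TRUE)
    best <- which.min(scan$n_mismatch)
    rec <- aln[aln$read_id == sprintf("r%03d", i), ]
    expect_equal(rec$n_mismatch, min(scan$n_mismatch))
    # the found placement is among the scan's minimal ones
    mins <- which(scan$n_mismatch == min(scan$n_mismatch))
    keys <- paste(scan$start[mins], scan$strand[mins])
    expect_true(paste(rec$start, rec$strand) %in% keys)
  }
})

test_that("simulated undamaged reads map back to their truth coordinates", {
  p <- sim_panel(n_refs = 4, ref_length = 8000, divergence = 0.08, seed = 31)
  r <- sim_reads(p, 2000, source_mix = c(ref02 = 1), d5 = 0, d3 = 0,
                 seq_error = 0, seed = 32)
  aln <- map_reads(r, p[p$ref_id == "ref02", ])
  hit <- dplyr::inner_join(aln, as_tibble(r)[, c("read_id", "start", "strand")],
                           by = "read_id", suffix = c("", "_true"))
  ok <- hit$start == hit$start_true & hit$strand == hit$strand_true
  expect_gte(mean(ok), 0.99)
  expect_gte(nrow(hit) / nrow(r), 0.99)
})

test_that("reads below the length threshold are filtered with a reason", {
  panel <- panel_from_seq(rand_dna(500))
  reads <- tibble::tibble(read_id = c("short", "ok"),
                          seq = c(strrep("A", 20), substr(panel$seq, 51, 100)))
  aln <- map_reads(reads, panel)
  expect_false("short" %in% aln$read_id)
  expect_equal(attr(aln, "filtered")$read_id, "short")
  expect_equal(attr(aln, "filtered")$reason, "too_short")
})

test_that("mapq filter keeps exactly the records at or above threshold", {
  a <- aln_tbl("ref", start = c(1, 2, 3), seq = strrep("A", 40),
               mapq = c(29, 30, 60))
  expect_equal(filter_mapq(a, 30)$mapq, c(30L, 60L))
  expect_equal(nrow(filter_mapq(a[0, ], 30)), 0)
})

test_that("reads from an exact repeat are ties with mapq 0", {
  set.seed(8)
  unit <- rand_dna(60)
  ref <- paste0(unit, rand_dna(400), unit, rand_dna(400))
  panel <- panel_from_seq(ref, circular = FALSE)
  read <- substr(unit, 11, 50)
  aln <- map_reads(tibble::tibble(read_id = "rep", seq = read), panel)
  expect_equal(aln$mapq, 0L)
  expect_equal(nrow(filter_mapq(aln, 30)), 0)
})

test_that("duplicate removal keeps one record per coordinate and is idempotent", {
  a <- aln_tbl("ref", start = c(10, 10, 10, 5), seq = strrep("C", 40),
               mapq = c(40, 60, 60, 60),
               read_id = c("c", "b", "a", "d"))
  d <- dedup_alignments(a)
  expect_equal(nrow(d), 2)
  # highest mapq wins; among equals the smallest read id
  expect_equal(sort(d$read_id), c("a", "d"))
  expect_identical(dedup_alignments(d), d)
  # different end -> both survive
  b <- aln_tbl("ref", start = c(10, 10), seq = c(strrep("C", 40), strrep("C", 50)))
  expect_equal(nrow(dedup_alignments(b)), 2)
})

test_that("duplicate removal matches a coordinate-grouping oracle", {
  set.seed(9)
  n <- 400
  a <- aln_tbl("ref",
               start = sample(1:50, n, TRUE),
               seq = strrep("G", 40)[rep(1, n)],
               strand = sample(c("+", "-"), n, TRUE),
               mapq = sample(c(0, 25, 50, 60), n, TRUE),
               read_id = sprintf("r%04d", sample(n)))
  a$aligned_len <- sample(c(35L, 40L), n, TRUE)
  a$end <- a$start + a$aligned_len
  d <- dedup_alignments(a)
  key <- paste(a$start, a$end, a$strand)
  expect_equal(nrow(d), length(unique(key)))
  for (k in unique(key)) {
    g <- a[key == k, ]
    g <- g[order(-g$mapq, g$read_id), ]
    expect_true(g$read_id[1] %in% d$read_id)
  }
})

test_that("alignments round-trip through SAM", {
  set.seed(10)
  p <- sim_panel(n_refs = 2, ref_length = 2000, divergence = 0.05, seed = 12)
  r <- sim_reads(p, 150, source_mix = c(ref01 = 1), seed = 13)
  aln <- dedup_alignments(filter_mapq(map_reads(r, p), 30))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, p, "ref01", sam)
  back <- read_sam(sam)
  a1 <- aln[aln$ref_id == "ref01", ]
  expect_equal(nrow(back), nrow(a1))
  expect_equal(back$start, a1$start)
  expect_equal(back$strand, a1$strand)
  expect_equal(back$n_mismatch, a1$n_mismatch)
  expect_equal(back$mapq, a1$mapq)
  expect_equal(back$seq, a1$seq)
  # header sanity
  hdr <- readLines(sam, n = 2)
  expect_match(hdr[2], "^@SQ\tSN:ref01\tLN:2000$")
})
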