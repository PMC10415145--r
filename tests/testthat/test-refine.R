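# Consensus building and jump-alignment breakpoint refinement.

test_that("jump alignment handles exact concatenations and spliced inserts", {
  cfg <- fx_cfg()
  ref1 <- "TTTTACGTTTTT"; ref2 <- "GGGGCATGAAAA"
  q <- paste0("ACGTTTTT", "GGGGCATG")
  r <- jump_sw_align(q, ref1, ref2, cfg)
  expect_equal(r$score, 2 * 16)
  expect_true(r$jumped)
  expect_equal(r$inserted_seq, "")
  expect_equal(r$r1_end, 12L)      # layer 1 consumes ref1 to its end
  expect_equal(r$r2_start, 0L)

  q2 <- paste0("ACGTTTTT", "AAACCC", "GGGGCATG")
  r2 <- jump_sw_align(q2, ref1, ref2, cfg)
  expect_equal(r2$inserted_seq, "AAACCC")
  expect_equal(r2$score, 2 * 16)
})

test_that("jump alignment equals the exhaustive split-point oracle on random instances", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (t in 1:60) {
    q <- paste(sample(bases, sample(5:30, 1), TRUE), collapse = "")
    r1 <- paste(sample(bases, sample(8:50, 1), TRUE), collapse = "")
    r2 <- paste(sample(bases, sample(8:50, 1), TRUE), collapse = "")
    for (pen in list(c(0, 0), c(-3, -1))) {
      cfg <- sv_config(jump_penalty = pen[1], per_inserted_base = pen[2])
      expect_equal(jump_sw_align(q, r1, r2, cfg)$score,
                   oracle_jump_score(q, r1, r2, jp = pen[1], pb = pen[2]),
                   info = paste(q, r1, r2, pen[1], pen[2]))
    }
  }
})

test_that("jump score is never below a plain local alignment against either region", {
  set.seed(77)
  cfg <- fx_cfg()
  bases <- c("A", "C", "G", "T")
  for (t in 1:40) {
    q <- paste(sample(bases, sample(10:40, 1), TRUE), collapse = "")
    r1 <- paste(sample(bases, sample(10:60, 1), TRUE), collapse = "")
    r2 <- paste(sample(bases, sample(10:60, 1), TRUE), collapse = "")
    res <- jump_sw_align(q, r1, r2, cfg)
    expect_gte(res$score, svlr:::sw_score(q, r1, cfg))
    expect_gte(res$score, svlr:::sw_score(q, r2, cfg))
  }
})

test_that("micro-homology ties resolve to maximal breakpoint-1 attribution", {
  cfg <- fx_cfg()
  # junction with 4 bp homology "ACGT" shared by the end of ref1 and the
  # start of ref2: the optimal split is ambiguous over 5 positions
  core <- "ACGT"
  ref1 <- paste0("TTGCAATTGGCC", core)
  ref2 <- paste0(core, "GGATCCAATTGG")
  q <- paste0("TTGCAATTGGCC", core, "GGATCCAATTGG")
  r <- jump_sw_align(q, ref1, ref2, cfg)
  expect_equal(r$q_end1, 16L)      # homology attributed to side 1
  expect_equal(r$r1_end, 16L)
  expect_equal(r$r2_start, 4L)
})

test_that("majority-vote consensus recovers the truth from noisy copies", {
  cfg <- fx_cfg()
  set.seed(5)
  truth <- rand_seq(400)
  ident <- data.frame(read_id = paste0("r", 1:5), seq = truth,
                      j1 = 200L, j2 = 200L, stringsAsFactors = FALSE)
  expect_equal(build_consensus(ident, cfg)$seq, truth)

  noisy <- vapply(1:5, function(i) svlr:::weave_errors(truth, 0.05)$seq, "")
  segs <- data.frame(read_id = paste0("r", 1:5), seq = noisy,
                     j1 = 200L, j2 = 200L, stringsAsFactors = FALSE)
  cons <- build_consensus(segs, cfg)
  expect_gte(seq_identity(cons$seq, truth), 0.99)
  expect_equal(cons$flag, "ok")

  # a mixture of two different junction haplotypes is flagged discordant
  other <- rand_seq(400)
  mix <- data.frame(read_id = paste0("m", 1:6),
                    seq = c(noisy[1:3],
                            vapply(1:3, function(i)
                              svlr:::weave_errors(other, 0.05)$seq, "")),
                    j1 = 200L, j2 = 200L, stringsAsFactors = FALSE)
  expect_equal(build_consensus(mix, cfg)$flag, "discordant")
})

test_that("single segments pass through unpolished", {
  cfg <- fx_cfg()
  seg <- data.frame(read_id = "r1", seq = rand_seq(300), j1 = 150L,
                    j2 = 150L, stringsAsFactors = FALSE)
  cons <- build_consensus(seg, cfg)
  expect_equal(cons$flag, "unpolished")
  expect_equal(cons$seq, seg$seq)
})

test_that("junction segments extract strand-symmetrically", {
  cfg <- fx_cfg()
  genome <- fx_genome()
  # a clean deletion read on both strands must give identical segments
  del_start <- 50000L; del_end <- 51000L
  left <- svlr:::genome_slice(genome, "chr1", del_start - 400L, del_start)
  right <- svlr:::genome_slice(genome, "chr1", del_end, del_end + 400L)
  read_fwd <- paste0(left, right)
  aln_f <- aln_row("rf", "chr1", del_start - 400L, "+", "400M1000D400M",
                   read_fwd)
  aln_r <- aln_row("rr", "chr1", del_start - 400L, "-", "400M1000D400M",
                   read_fwd)   # minus-strand read: stored SEQ is ref-forward
  for (aln in list(aln_f, aln_r)) {
    sig <- parse_sv_signals(aln, min_indel_size = 50L)
    cl <- list(signals = sig, chrom1 = "chr1", dir1 = "+", chrom2 = "chr1",
               dir2 = "-", bp1_lo = sig$pos1, bp1_hi = sig$pos1,
               bp2_lo = sig$pos2, bp2_hi = sig$pos2,
               read_ids = sig$read_id)
    seg <- extract_junction_segments(cl, aln, cfg)
    expect_equal(seg$seq, paste0(substr(left, 101, 400),
                                 substr(right, 1, 300)))
    expect_equal(seg$j1, 300L)
  }
})

test_that("refinement recovers exact breakpoints of a constructed deletion and inversion", {
  cfg <- fx_cfg()
  genome <- fx_genome()
  mk_reads <- function(events, n = 5L, seed = 9L) {
    blocks <- svlr:::make_haplotype_blocks(genome, events)
    simulate_reads(list(h1 = blocks), genome, depth = 12, error_rate = 0.08,
                   seed = seed, sample = "tumor")$alignments
  }
  run_refine <- function(aln) {
    sig <- parse_sv_signals(aln, min_indel_size = cfg$parse_indel_size,
                            known_chroms = names(genome))
    cls <- cluster_signals(sig, cfg$cluster_margin, min_reads = 3L)
    lapply(cls, refine_candidate, reference = genome, aln = aln, cfg = cfg)
  }
  del <- list(list(event_id = 1L, type = "DEL", class = "DEL", chrom = "chr1",
                   pos = 60000L, end = 60500L, size = 500L, insert_seq = "",
                   tsd = 0L))
  recs <- run_refine(mk_reads(del))
  recs <- Filter(function(r) is.null(r$failure), recs)
  expect_true(any(vapply(recs, function(r)
    r$svtype == "DEL" && r$pos1 == 59999L && r$pos2 == 60500L, TRUE)))

  inv <- list(list(event_id = 1L, type = "INV", class = "INV", chrom = "chr2",
                   pos = 80000L, end = 81000L, size = 1000L, insert_seq = "",
                   tsd = 0L))
  recs2 <- run_refine(mk_reads(inv, seed = 10L))
  recs2 <- Filter(function(r) is.null(r$failure), recs2)
  expect_true(length(recs2) >= 1L)
  hit <- vapply(recs2, function(r) {
    r$svtype == "INV" &&
      ((abs(r$pos1 - 79999L) <= 1 && abs(r$pos2 - 80999L) <= 1) ||
       (abs(r$pos1 - 80000L) <= 1 && abs(r$pos2 - 81000L) <= 1))
  }, TRUE)
  expect_true(any(hit))
})
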