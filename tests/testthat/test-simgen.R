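# Synthetic-data generator: reproducibility, alignment-record correctness,
# and truth bookkeeping.

test_that("genome generation is byte-identical under a seed and differs across seeds", {
  g1 <- make_genome(length = 5e4, n_chroms = 2, seed = 7)$seqs
  g2 <- make_genome(length = 5e4, n_chroms = 2, seed = 7)$seqs
  g3 <- make_genome(length = 5e4, n_chroms = 2, seed = 8)$seqs
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
})

test_that("embedded features appear at the requested loci", {
  feats <- data.frame(chrom = "chr1", pos = c(10000L, 20000L),
                      what = c("telomere", "simple_repeat"),
                      len = c(600L, 400L))
  gen <- make_genome(length = 5e4, n_chroms = 1, seed = 7, features = feats)
  expect_equal(substr(gen$seqs[["chr1"]], 10001L, 10012L),
               strrep("TTAGGG", 2))
  expect_equal(gen$features$label, c("telomere", "simple_repeat"))
  expect_equal(gen$features$start, c(10000L, 20000L))
})

test_that("injected deletions respect the requested spec and record truth", {
  gen <- make_genome(length = 2e5, n_chroms = 2, seed = 3)
  inj <- inject_svs(gen$seqs, list(list(type = "DEL", n = 5L,
                                        size = c(200, 2000))), seed = 5)
  expect_equal(nrow(inj$events), 5L)
  expect_true(all(inj$events$size >= 200 & inj$events$size <= 2000))
  expect_true(all(inj$events$type == "DEL"))
  # derived chromosome shrinks by the deleted total
  expect_equal(sum(nchar(inj$seqs)),
               sum(nchar(gen$seqs)) - sum(inj$events$size))
  # reproducible
  inj2 <- inject_svs(gen$seqs, list(list(type = "DEL", n = 5L,
                                         size = c(200, 2000))), seed = 5)
  expect_identical(inj$seqs, inj2$seqs)

  # an MEI request records its engineered TSD in the truth set
  mei <- inject_svs(gen$seqs, list(list(type = "MEI", n = 1L, class = "L1",
                                        tsd = 12L, polya = 25L)), seed = 6)
  expect_equal(mei$events$tsd, 12L)
  jn <- mei$junctions
  expect_equal(jn$pos1 - jn$pos2 + 1L, 12L)
})

test_that("error-free reads spanning a deletion carry one exact D operation", {
  genome <- fx_genome()
  ev <- list(list(event_id = 1L, type = "DEL", class = "DEL", chrom = "chr1",
                  pos = 60000L, end = 60700L, size = 700L, insert_seq = "",
                  tsd = 0L))
  blocks <- svlr:::make_haplotype_blocks(genome, ev)
  sim <- simulate_reads(list(h1 = blocks), genome, depth = 8,
                        error_rate = 0, seed = 13, sample = "tumor")
  aln <- sim$alignments
  span <- aln[aln$chrom == "chr1" & aln$start < 59500L & aln$end > 61200L, ]
  expect_gt(nrow(span), 0L)
  expect_true(all(grepl("(^|[0-9]M)700D", span$cigar)))
  expect_false(any(span$is_supplementary))
  # error-free: sequence equals the reference allele
  r <- span[1, ]
  ops <- svlr:::parse_cigar(r$cigar)
  expect_equal(svlr:::cigar_ref_len(ops), r$end - r$start)
})

test_that("reads spanning a translocation split into consistent primary + supplementary", {
  genome <- fx_genome()
  ev <- list(list(event_id = 1L, type = "TRA", class = "TRA", chrom = "chr1",
                  pos = 100000L, end = 100000L, size = 0L, insert_seq = "",
                  tsd = 0L, chrom2 = "chr2", pos2 = 50000L))
  blocks <- svlr:::make_haplotype_blocks(genome, ev)
  sim <- simulate_reads(list(h1 = blocks), genome, depth = 10,
                        error_rate = 0.05, seed = 17, sample = "tumor")
  aln <- sim$alignments
  multi <- split(aln, aln$read_id)
  multi <- multi[vapply(multi, nrow, 0L) == 2L]
  expect_gt(length(multi), 0L)
  pair <- multi[[1]]
  expect_equal(sum(pair$is_supplementary), 1L)
  expect_true(all(nzchar(pair$sa)))
  # SA tags reference each other's position
  expect_match(pair$sa[1], sprintf("%s,%d", pair$chrom[2], pair$start[2] + 1L))
  # the caller's parser recovers the junction from these records
  sig <- parse_sv_signals(aln, min_indel_size = 50L,
                          known_chroms = names(genome))
  tra <- sig[sig$chrom1 != sig$chrom2, ]
  expect_gt(nrow(tra), 0L)
  expect_true(all(abs(tra$pos1 - 100000L) <= 1 | abs(tra$pos1 - 50000L) <= 1))
})

test_that("alignment records satisfy the CIGAR/sequence invariants", {
  genome <- fx_genome()
  ds_blocks <- svlr:::make_haplotype_blocks(genome, list())
  sim <- simulate_reads(list(h1 = ds_blocks), genome, depth = 4,
                        error_rate = 0.1, seed = 23, sample = "tumor")
  aln <- sim$alignments
  expect_gt(nrow(aln), 0L)
  for (i in seq_len(min(nrow(aln), 50L))) {
    ops <- svlr:::parse_cigar(aln$cigar[i])
    expect_equal(svlr:::cigar_ref_len(ops), aln$end[i] - aln$start[i])
    expect_equal(svlr:::cigar_query_len(ops), nchar(aln$seq[i]))
    s_idx <- which(ops$op == "S")
    expect_true(all(s_idx %in% c(1L, length(ops$op))))
  }
})

test_that("read counts track the requested depth", {
  genome <- fx_genome()
  blocks <- svlr:::make_haplotype_blocks(genome, list())
  sim <- simulate_reads(list(h1 = blocks, h2 = blocks), genome, depth = 30,
                        error_rate = 0, seed = 29, sample = "tumor")
  prim <- sim$alignments[!sim$alignments$is_supplementary, ]
  bases <- sum(nchar(prim$seq))
  expect_lt(abs(bases / sum(nchar(genome)) - 30) / 30, 0.1)
})

test_that("breakpoint deviations are measured up to junction equivalence", {
  set.seed(61)
  A <- rand_seq(200); B <- rand_seq(300); C <- rand_seq(200)
  H <- "ACGTT"   # 5 bp homology flanking both deletion edges
  ref <- list(chr1 = paste0(A, H, B, H, C))
  p1 <- nchar(A) + nchar(H) - 1L          # last retained base, right edge of H
  p2 <- nchar(A) + nchar(H) + nchar(B) + nchar(H)  # first retained base of C
  jn <- data.frame(event_id = 1L, class = "DEL", chrom1 = "chr1", pos1 = p1,
                   dir1 = "+", chrom2 = "chr1", pos2 = p2, dir2 = "-",
                   insert_len = 0L, insert_seq = "", stringsAsFactors = FALSE)
  # a call shifted left through the homology describes the same allele
  calls <- data.frame(chr1 = "chr1", pos1 = p1 - 3L, dir1 = "+",
                      chr2 = "chr1", pos2 = p2 - 3L, dir2 = "-",
                      inserted_seq = "", stringsAsFactors = FALSE)
  expect_equal(match_calls(calls, jn, reference = ref)$bp_dev, 0L)
  expect_equal(match_calls(calls, jn)$bp_dev, 3L)   # without the reference
  # a shift beyond the homology is a genuine deviation
  calls2 <- calls; calls2$pos1 <- p1 - 7L; calls2$pos2 <- p2 - 7L
  expect_equal(match_calls(calls2, jn, reference = ref)$bp_dev, 7L)
  # insertion-edge homology: the insert tail equals the two reference
  # bases left of the junction, so a caller that attributes those bases
  # to the reference (layer 2 resuming two bases earlier, a TSD-like
  # overlap) describes the same allele
  A2 <- paste0(rand_seq(198), "AC")        # reference ends ...AC at pos 199
  refI <- list(chr1 = paste0(A2, C))
  X <- paste0(rand_seq(120), "AC")         # insert tail matches ref[198..200)
  jnI <- data.frame(event_id = 1L, class = "INS", chrom1 = "chr1",
                    pos1 = 199L, dir1 = "+", chrom2 = "chr1", pos2 = 200L,
                    dir2 = "-", insert_len = nchar(X), insert_seq = X,
                    stringsAsFactors = FALSE)
  callI <- data.frame(chr1 = "chr1", pos1 = 199L, dir1 = "+",
                      chr2 = "chr1", pos2 = 198L, dir2 = "-",
                      inserted_seq = substr(X, 1L, nchar(X) - 2L),
                      stringsAsFactors = FALSE)
  expect_equal(match_calls(callI, jnI, reference = refI)$bp_dev, 0L)
})

test_that("simulation is deterministic given the seed", {
  genome <- fx_genome()
  blocks <- svlr:::make_haplotype_blocks(genome, list())
  a <- simulate_reads(list(h1 = blocks), genome, depth = 3,
                      error_rate = 0.1, seed = 31, sample = "s")
  b <- simulate_reads(list(h1 = blocks), genome, depth = 3,
                      error_rate = 0.1, seed = 31, sample = "s")
  expect_identical(a$alignments, b$alignments)
})
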