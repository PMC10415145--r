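# Junction signal extraction from CIGARs and split alignments, clustering,
# and control subtraction.

test_that("CIGAR deletion and insertion operations become oriented signals", {
  seq <- rand_seq(150)
  aln <- aln_row("r1", "chr1", 1000L, "+", "50M200D50M", substr(seq, 1, 100))
  sig <- parse_sv_signals(aln, min_indel_size = 50L)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$pos1, 1049L); expect_equal(sig$dir1, "+")
  expect_equal(sig$pos2, 1250L); expect_equal(sig$dir2, "-")
  expect_equal(sig$insert_len, 0L)

  aln2 <- aln_row("r2", "chr1", 1000L, "+", "50M150I50M", substr(seq, 1, 150))
  sig2 <- parse_sv_signals(aln2, min_indel_size = 50L)
  expect_equal(sig2$insert_len, 150L)
  expect_equal(sig2$pos1 + 1L, sig2$pos2)

  # below threshold: no signal
  aln3 <- aln_row("r3", "chr1", 1000L, "+", "50M40D50M", substr(seq, 1, 100))
  expect_equal(nrow(parse_sv_signals(aln3, min_indel_size = 50L)), 0L)
})

test_that("split-alignment strand/clip combinations map to the consistent direction pairs", {
  # read of 200 bases: first 100 align to chr1, last 100 to chr5, in the
  # four strand combinations of the chr5 segment and read orientation.
  # Hand-drawn junctions give: A(+ end-clipped) -> dir1 '+';
  # B(+ start-clipped) -> '-'; B(-) -> '+'; A(-) -> '-'.
  seq <- rand_seq(200)
  combos <- list(
    list(sA = "+", sB = "+", d = c("+", "-")),
    list(sA = "+", sB = "-", d = c("+", "+")),
    list(sA = "-", sB = "+", d = c("-", "-")),
    list(sA = "-", sB = "-", d = c("-", "+")))
  for (cb in combos) {
    seqA <- if (cb$sA == "+") seq else revcomp(seq)
    seqB <- if (cb$sB == "+") seq else revcomp(seq)
    cigA <- if (cb$sA == "+") "100M100S" else "100S100M"
    cigB <- if (cb$sB == "+") "100S100M" else "100M100S"
    aln <- rbind(
      aln_row("r", "chr1", 1000L, cb$sA, cigA, seqA),
      aln_row("r", "chr5", 5000L, cb$sB, cigB, seqB, supp = TRUE))
    sig <- parse_sv_signals(aln, min_indel_size = 50L)
    expect_equal(nrow(sig), 1L, info = paste(cb$sA, cb$sB))
    # chr1 < chr5 so breakpoint 1 is always the chr1 side
    expect_equal(sig$dir1, cb$d[1], info = paste(cb$sA, cb$sB))
    expect_equal(sig$dir2, cb$d[2], info = paste(cb$sA, cb$sB))
    expect_equal(sig$pos1, if (cb$d[1] == "+") 1099L else 1000L)
    expect_equal(sig$pos2, if (cb$d[2] == "+") 5099L else 5000L)
  }
})

test_that("unknown-chromosome split segments are skipped and counted", {
  aln2 <- rbind(
    aln_row("q", "chr1", 1000L, "+", "100M100S", rand_seq(200)),
    aln_row("q", "chrUn", 5000L, "+", "100S100M", rand_seq(200), supp = TRUE))
  sig2 <- parse_sv_signals(aln2, min_indel_size = 50L,
                           known_chroms = c("chr1", "chr5"))
  expect_equal(nrow(sig2), 0L)
  expect_equal(attr(sig2, "n_skipped"), 1L)
})

test_that("clustering joins same-junction signals and separates direction pairs", {
  base <- data.frame(read_id = paste0("r", 1:3), chrom1 = "chr1",
                     pos1 = c(1000L, 1010L, 1020L), dir1 = "+",
                     chrom2 = "chr1", pos2 = 5000L, dir2 = "-",
                     insert_len = 0L, source = "split_alignment",
                     q1 = 0L, q2 = 0L, frame = "original", swapped = FALSE,
                     rec = 1L, sample = "tumor", stringsAsFactors = FALSE)
  cl <- cluster_signals(base, margin = 200L, min_reads = 3L)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$read_ids, 3L)

  flip <- base
  flip$dir1 <- "-"; flip$dir2 <- "+"
  both <- rbind(base, flip)
  both$read_id <- paste0("r", 1:6)
  cl2 <- cluster_signals(both, margin = 200L, min_reads = 3L)
  expect_length(cl2, 2L)

  # chained signals merge transitively even past one margin
  chain <- base[rep(1, 4), ]
  chain$read_id <- paste0("c", 1:4)
  chain$pos1 <- c(0L, 150L, 300L, 450L)
  cl3 <- cluster_signals(chain, margin = 200L, min_reads = 3L)
  expect_length(cl3, 1L)
  expect_length(cl3[[1]]$read_ids, 4L)
})

test_that("clustering matches a brute-force single-linkage oracle and is order-invariant", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 30L
    sig <- data.frame(read_id = paste0("r", 1:n), chrom1 = "chr1",
                      pos1 = sort(sample.int(5000L, n)), dir1 = "+",
                      chrom2 = "chr2", pos2 = sample.int(2000L, n),
                      dir2 = "-", insert_len = 0L, source = "split_alignment",
                      q1 = 0L, q2 = 0L, frame = "original", swapped = FALSE,
                      rec = 1L, sample = "tumor", stringsAsFactors = FALSE)
    cl <- cluster_signals(sig, margin = 150L, min_reads = 1L)
    comp <- oracle_single_linkage(sig$pos1, sig$pos2, 150L)
    expect_equal(length(cl), length(unique(comp)))
    got_sizes <- sort(vapply(cl, function(c) length(c$read_ids), 0L))
    want_sizes <- sort(unname(as.integer(table(comp))))
    expect_equal(got_sizes, want_sizes)
    # permutation invariance
    perm <- sample.int(n)
    cl_p <- cluster_signals(sig[perm, ], margin = 150L, min_reads = 1L)
    key <- function(cls) sort(vapply(cls, function(c)
      paste(sort(c$signals$read_id), collapse = ","), ""))
    expect_equal(key(cl_p), key(cl))
  }
})

test_that("control and panel matches remove clusters; distant control evidence does not", {
  sig <- data.frame(read_id = paste0("r", 1:3), chrom1 = "chr1",
                    pos1 = c(1000L, 1010L, 1020L), dir1 = "+",
                    chrom2 = "chr1", pos2 = 5000L, dir2 = "-",
                    insert_len = 0L, source = "split_alignment",
                    q1 = 0L, q2 = 0L, frame = "original", swapped = FALSE,
                    rec = 1L, sample = "tumor", stringsAsFactors = FALSE)
  cl <- cluster_signals(sig, margin = 200L, min_reads = 3L)
  ctl1 <- sig[1, ]; ctl1$read_id <- "ctl"; ctl1$sample <- "control"
  expect_length(filter_by_control(cl, ctl1, margin = 200L), 0L)
  ctl2 <- ctl1; ctl2$pos1 <- 1500L; ctl2$pos2 <- 5500L   # 500 bp away
  expect_length(filter_by_control(cl, ctl2, margin = 200L), 1L)
  # panel-only match also removes
  expect_length(filter_by_control(cl, sig[0, ], panel_signals = ctl1,
                                  margin = 200L), 0L)
  # opposite directions never match
  ctl3 <- ctl1; ctl3$dir1 <- "-"; ctl3$dir2 <- "+"
  expect_length(filter_by_control(cl, ctl3, margin = 200L), 1L)
})

test_that("distinct supporting reads are counted once per cluster", {
  sig <- data.frame(read_id = c("a", "a", "b", "c"), chrom1 = "chr1",
                    pos1 = c(1000L, 1001L, 1010L, 1020L), dir1 = "+",
                    chrom2 = "chr1", pos2 = 5000L, dir2 = "-",
                    insert_len = 0L, source = "split_alignment",
                    q1 = 0L, q2 = 0L, frame = "original", swapped = FALSE,
                    rec = 1L, sample = "tumor", stringsAsFactors = FALSE)
  cl <- cluster_signals(sig, margin = 200L, min_reads = 3L)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$read_ids), c("a", "b", "c"))
  tab <- clusters_to_table(cl)
  expect_equal(tab$n_reads, 3L)
})
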