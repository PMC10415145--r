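# Single-breakend module: soft-clip parsing, clustering, contig polishing,
# validation and classification.

test_that("soft clips become junction-outward breakend signals", {
  genome <- fx_genome()
  aligned <- svlr:::genome_slice(genome, "chr1", 5000L, 5100L)
  clip <- rand_seq(600)
  r_right <- aln_row("r1", "chr1", 5000L, "+", "100M600S",
                     paste0(aligned, clip))
  sig <- parse_softclips(r_right, min_clip = 500L)
  expect_equal(sig$pos, 5099L)
  expect_equal(sig$dir, "+")
  expect_equal(sig$clip_seq, clip)            # junction-proximal first

  r_left <- aln_row("r2", "chr1", 5000L, "+", "600S100M",
                    paste0(clip, aligned))
  sig2 <- parse_softclips(r_left, min_clip = 500L)
  expect_equal(sig2$pos, 5000L)
  expect_equal(sig2$dir, "-")
  expect_equal(sig2$clip_seq, revcomp(clip))

  # below threshold, SA-explained, or supplementary: no signal
  short <- aln_row("r3", "chr1", 5000L, "+", "100S100M", rand_seq(200))
  expect_equal(nrow(parse_softclips(short, min_clip = 500L)), 0L)
  with_sa <- r_right; with_sa$sa <- "chr2,100,+,600M100S,60,0;"
  expect_equal(nrow(parse_softclips(with_sa, min_clip = 500L)), 0L)
})

test_that("breakend clustering separates directions and control matches remove", {
  sig <- data.frame(read_id = paste0("r", 1:3), chrom = "chr1",
                    pos = c(1000L, 1010L, 1020L), dir = "+",
                    clip_side = "right", clip_len = 600L,
                    clip_seq = rand_seq(600), inner_seq = rand_seq(100),
                    sample = "tumor", stringsAsFactors = FALSE)
  cl <- cluster_breakends(sig, margin = 50L, min_reads = 3L)
  expect_length(cl, 1L)
  opp <- sig; opp$dir <- "-"; opp$read_id <- paste0("q", 1:3)
  cl2 <- cluster_breakends(rbind(sig, opp), margin = 50L, min_reads = 3L)
  expect_length(cl2, 2L)

  ctl <- sig[1, ]; ctl$sample <- "control"
  expect_length(filter_breakends_by_control(cl, ctl, margin = 200L), 0L)
  ctl$pos <- 2000L
  expect_length(filter_breakends_by_control(cl, ctl, margin = 200L), 1L)
})

test_that("breakend contigs polish to the clipped truth", {
  cfg <- fx_cfg()
  set.seed(8)
  truth <- rand_seq(1500)
  inner <- rand_seq(100)
  sig <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(read_id = paste0("r", i), chrom = "chr1", pos = 1000L,
               dir = "+", clip_side = "right", clip_len = 1500L,
               clip_seq = svlr:::weave_errors(truth, 0.05)$seq,
               inner_seq = inner, sample = "tumor", stringsAsFactors = FALSE)
  }))
  cl <- list(signals = sig, chrom = "chr1", dir = "+", pos_lo = 1000L,
             pos_hi = 1000L, read_ids = sig$read_id)
  cons <- build_breakend_contig(cl, cfg)
  expect_gte(seq_identity(cons$seq, paste0(inner, truth)), 0.99)

  two <- cl; two$signals <- sig[1:2, ]; two$read_ids <- sig$read_id[1:2]
  expect_equal(build_breakend_contig(two, cfg)$n_inputs, 2L)
})

test_that("constructed contigs receive their classification categories", {
  cfg <- fx_cfg()
  genome <- fx_genome()
  lib <- fx_library()
  hor <- fx_hor()
  mkrec <- function(contig) data.frame(
    chrom = "chr1", pos = 100000L, dir = "+", contig = contig,
    tumor_support = 5L, control_support = 0L,
    classification = "Unclassified", stringsAsFactors = FALSE)
  sat <- strrep(paste(hor$chrX$monomers[hor$chrX$order], collapse = ""), 2)
  telo <- strrep("TTAGGG", 400)
  l1 <- lib[["L1HS#LINE/L1"]]
  chim <- paste0(substr(l1, nchar(l1) - 1020L, nchar(l1) - 21L),
                 svlr:::genome_slice(genome, "chr2", 150000L, 152000L))
  hbv <- paste0(substr(lib[["HBV#Virus"]], 1, 1500),
                svlr:::genome_slice(genome, "chr1", 180000L, 180500L))
  cases <- list(Satellite = sat, Telomere = telo, L1Mediated = chim,
                VirusMediated = hbv)
  for (want in names(cases)) {
    got <- classify_breakend(mkrec(cases[[want]]), genome, lib, cfg = cfg)
    expect_equal(got$classification, want, info = want)
  }
})

test_that("a uniquely aligning contig is rescued into a validated canonical record", {
  cfg <- fx_cfg()
  genome <- fx_genome()
  lib <- fx_library()
  # tumor haplotype: chr1 truncated at 100 kb, continuing into chr2:50 kb -
  # exactly what a rescued translocation should reconstruct
  ev <- list(list(event_id = 1L, type = "SBND", class = "SBND_tra",
                  chrom = "chr1", pos = 100000L, end = 100000L,
                  size = 4000L, tsd = 0L,
                  insert_seq = svlr:::genome_slice(genome, "chr2", 50000L,
                                                   54000L)))
  blocks <- svlr:::make_haplotype_blocks(genome, ev)
  ref_blocks <- svlr:::make_haplotype_blocks(genome, list())
  tum <- simulate_reads(list(h1 = blocks, h2 = ref_blocks), genome,
                        depth = 24, error_rate = 0.08, seed = 41,
                        sample = "tumor")$alignments
  ctl <- simulate_reads(list(h1 = ref_blocks, h2 = ref_blocks), genome,
                        depth = 24, error_rate = 0.08, seed = 42,
                        sample = "control")$alignments
  res <- call_breakend_svs(tum, ctl, genome, lib, cfg = cfg)
  expect_gte(nrow(res$breakends), 1L)
  expect_true("RescuedCanonical" %in% res$breakends$classification)
  expect_false(is.null(res$rescued))
  rc <- res$rescued[1, ]
  expect_equal(rc$chr1, "chr1")
  expect_lte(abs(rc$pos1 - 100000L), 2L)
  expect_equal(rc$chr2, "chr2")
  expect_lte(abs(rc$pos2 - 50000L), 2L)
  # the rescued record passed the full canonical validation thresholds
  expect_gte(rc$tumor_support, cfg$min_tumor_support)
  expect_equal(rc$control_support, 0L)
  # a tumor==control run yields nothing
  res0 <- call_breakend_svs(ctl, ctl, genome, lib, cfg = cfg)
  expect_equal(nrow(res0$breakends), 0L)
})

test_that("breakends duplicating a canonical record are dropped", {
  cfg <- fx_cfg()
  genome <- fx_genome()
  lib <- fx_library()
  rec <- data.frame(chrom = "chr1", pos = 100000L, dir = "+",
                    contig = svlr:::genome_slice(genome, "chr2", 50000L,
                                                 52500L),
                    tumor_support = 5L, control_support = 0L,
                    classification = "Unclassified", stringsAsFactors = FALSE)
  canon <- data.frame(chr1 = "chr1", pos1 = 100050L, chr2 = "chr1",
                      pos2 = 130000L, stringsAsFactors = FALSE)
  expect_null(classify_breakend(rec, genome, lib, canonical_records = canon,
                                cfg = cfg))
})

test_that("RepeatMasker .out files parse into annotation intervals", {
  out <- c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)  strand  repeat class begin end (left) ID",
    "",
    " 1234   5.0  0.1  0.2   contig1    1  984  (2000)   +  L1HS   LINE/L1   4000 4984 (1016)  1",
    "  800  12.0  1.0  0.0   contig1  985 1500   (500)   C  AluY   SINE/Alu   1  300   (0)  2")
  tf <- tempfile(fileext = ".out")
  writeLines(out, tf)
  ann <- read_repeatmasker_out(tf)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$start, c(0L, 984L))     # 1-based begin -> 0-based
  expect_equal(ann$end, c(984L, 1500L))
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(ann$label, c("L1HS", "AluY"))
  expect_equal(ann$identity, c(0.95, 0.88))
  # usable as a classification provider: a contig annotated mostly as
  # satellite classifies without any built-in alignment
  cfg <- fx_cfg()
  genome <- fx_genome()
  rec <- data.frame(chrom = "chr1", pos = 1000L, dir = "+",
                    contig = rand_seq(1600), tumor_support = 5L,
                    control_support = 0L, classification = "Unclassified",
                    stringsAsFactors = FALSE)
  sat_ann <- data.frame(start = 0L, end = 1200L, label = "ALR",
                        class = "Satellite/centr", identity = 0.9,
                        strand = "+", stringsAsFactors = FALSE)
  got <- classify_breakend(rec, genome, fx_library(),
                           annotation = sat_ann, cfg = cfg)
  expect_equal(got$classification, "Satellite")
})
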