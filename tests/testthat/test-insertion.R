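# Inserted-sequence classification and MEI structure extraction.

ins_fixtures <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      feats <- data.frame(chrom = "chr1", pos = 50000L, what = "l1_source",
                          len = NA)
      gen <- make_genome(length = 2e5, n_chroms = 2, seed = 11,
                         features = feats)
      env$fx <- list(ref = gen$seqs,
                     sources = svlr:::l1_sources_from_features(gen$features),
                     lib = make_classification_library(),
                     tx = make_transcripts(3))
    }
    env$fx
  }
})

test_that("the constructed insertion panel classifies with structure recovered", {
  cfg <- fx_cfg()
  f <- ins_fixtures()
  l1 <- f$lib[["L1HS#LINE/L1"]]
  alu <- f$lib[["AluY#SINE/Alu"]]

  # solo LINE1 with twin-priming 5' inversion and a polyA tail
  st <- 2500L; b <- st + 800L
  ins1 <- paste0(revcomp(substr(l1, st, b)),
                 substr(l1, b + 150L, nchar(l1) - 20L), strrep("A", 25))
  r1 <- classify_insertion(ins1, f$lib, transcripts = f$tx,
                           reference = f$ref, sources = f$sources, cfg = cfg)
  expect_equal(r1$insertion_class, "SoloLINE1")
  expect_true(r1$has_5prime_inversion)
  expect_equal(r1$polya$side, "3p")
  expect_gte(r1$polya$length, 25L)
  # antisense then sense segments, in query order
  segs <- r1$inversion$segments[order(r1$inversion$segments$q_start), ]
  expect_equal(segs$strand, c("-", "+"))

  # sense-only truncated LINE1: no inversion
  ins2 <- paste0(substr(l1, 3000L, nchar(l1) - 20L), strrep("A", 30))
  r2 <- classify_insertion(ins2, f$lib, reference = f$ref, cfg = cfg)
  expect_equal(r2$insertion_class, "SoloLINE1")
  expect_false(r2$has_5prime_inversion)

  # solo Alu
  ins3 <- paste0(substr(alu, 1L, 280L), strrep("A", 22))
  expect_equal(classify_insertion(ins3, f$lib, reference = f$ref,
                                  cfg = cfg)$insertion_class, "SoloAlu")

  # partnered transduction: LINE1 3' end + source-downstream tag + polyA
  tag <- svlr:::genome_slice(f$ref, "chr1", f$sources$end[1],
                             f$sources$end[1] + 1200L)
  ins4 <- paste0(substr(l1, nchar(l1) - 820L, nchar(l1) - 20L), tag,
                 strrep("A", 25))
  r4 <- classify_insertion(ins4, f$lib, reference = f$ref,
                           sources = f$sources, cfg = cfg)
  expect_equal(r4$insertion_class, "PartneredTransduction")
  expect_equal(r4$transduction_source$id, f$sources$id[1])

  # orphan transduction: downstream tag only
  ins5 <- paste0(tag, strrep("A", 25))
  r5 <- classify_insertion(ins5, f$lib, reference = f$ref,
                           sources = f$sources, cfg = cfg)
  expect_equal(r5$insertion_class, "OrphanTransduction")

  # processed pseudogene: spliced transcript copy spanning exon junctions
  r6 <- classify_insertion(f$tx$seqs[[2]], f$lib, transcripts = f$tx,
                           reference = f$ref, cfg = cfg)
  expect_equal(r6$insertion_class, "ProcessedPseudogene")
  expect_equal(r6$transcript_id, "TX02")

  # tandem duplication: copy of the insertion-site flank
  site <- list(chrom = "chr2", pos = 100000L)
  ins7 <- svlr:::genome_slice(f$ref, "chr2", 99500L, 100000L)
  r7 <- classify_insertion(ins7, f$lib, reference = f$ref,
                           sources = f$sources, site = site, cfg = cfg)
  expect_equal(r7$insertion_class, "TandemDup")

  # uninformative sequence
  r8 <- classify_insertion(rand_seq(400), f$lib, reference = f$ref,
                           cfg = cfg)
  expect_equal(r8$insertion_class, "Other")
})

test_that("5' inversion detection follows twin-priming geometry", {
  cfg <- fx_cfg()
  l1 <- ins_fixtures()$lib[["L1HS#LINE/L1"]]
  # constructed twin-priming insert: revcomp(L1[a..b]) + L1[b'..end]
  a <- 2000L; b <- 2900L; b2 <- 3100L
  tw <- detect_5prime_inversion(
    paste0(revcomp(substr(l1, a, b)), substr(l1, b2, 5800L)), l1, cfg)
  expect_true(tw$inverted)
  expect_equal(tw$orientation, "twin")
  expect_gt(tw$internal_loss, 0L)
  # fully antisense insert: orientation recorded, no inversion call
  anti <- detect_5prime_inversion(revcomp(substr(l1, 3000L, 5000L)), l1, cfg)
  expect_false(anti$inverted)
  expect_equal(anti$orientation, "antisense")
  sense <- detect_5prime_inversion(substr(l1, 3000L, 5000L), l1, cfg)
  expect_false(sense$inverted)
  expect_equal(sense$orientation, "sense")
})

test_that("polyA detection equals the brute-force substring oracle", {
  cfg <- fx_cfg()
  expect_null(detect_polya(paste0(rand_seq(50), strrep("A", 9)), cfg = cfg))
  expect_equal(detect_polya(paste0(strrep("C", 30), "AAAAAGAAAAA"),
                            cfg = cfg)$length, 11L)
  expect_equal(detect_polya(paste0("GG", strrep("A", 25)),
                            cfg = cfg)$length, 25L)
  # antisense orientation scans the 5' end for T runs
  expect_equal(detect_polya(paste0(strrep("T", 15), rand_seq(60)),
                            orientation = "antisense", cfg = cfg)$side, "5p")
  set.seed(99)
  for (i in 1:40) {
    s <- paste(sample(c("A", "A", "A", "C", "G", "T"),
                      sample(20:100, 1), TRUE), collapse = "")
    got <- detect_polya(s, cfg = cfg)
    want <- oracle_polya(s)
    if (is.null(want)) expect_null(got, info = s)
    else expect_equal(got$length, want, info = s)
  }
})

test_that("target-site duplications come from overlapping breakpoints", {
  cfg <- fx_cfg()
  ref <- fx_genome()
  tsd <- detect_tsd(list(chrom1 = "chr1", pos1 = 1000L, pos2 = 989L), ref,
                    cfg)
  expect_equal(tsd$length, 12L)
  expect_equal(tsd$seq, svlr:::genome_slice(ref, "chr1", 989L, 1001L))
  # blunt junction and out-of-range overlaps give nothing
  expect_null(detect_tsd(list(chrom1 = "chr1", pos1 = 1000L, pos2 = 1001L),
                         ref, cfg))
  expect_null(detect_tsd(list(chrom1 = "chr1", pos1 = 1000L, pos2 = 998L),
                         ref, cfg))    # 3 bp < min_tsd
  expect_null(detect_tsd(list(chrom1 = "chr1", pos1 = 1000L, pos2 = 900L),
                         ref, cfg))    # 101 bp > max_tsd
})

test_that("transduction events group by source with nested sources flagged", {
  f <- ins_fixtures()
  src <- rbind(f$sources,
               data.frame(chrom = "chr2", start = 80000L, end = 86000L,
                          strand = "+", id = "somL1_1",
                          provenance = "somatic", stringsAsFactors = FALSE))
  ann <- data.frame(
    insertion_class = c("OrphanTransduction", "PartneredTransduction",
                        "OrphanTransduction", "SoloLINE1"),
    source_id = c(src$id[1], src$id[1], "somL1_1", NA),
    stringsAsFactors = FALSE)
  grp <- infer_transduction_sources(ann, src)
  expect_equal(nrow(grp), 2L)
  expect_equal(grp$n_events[grp$source_id == src$id[1]], 2L)
  expect_true(grp$nested[grp$source_id == "somL1_1"])
  expect_false(grp$nested[grp$source_id == src$id[1]])
})

test_that("inserts far beyond the source window are not attributed", {
  cfg <- fx_cfg()
  f <- ins_fixtures()
  far_tag <- svlr:::genome_slice(f$ref, "chr1",
                                 f$sources$end[1] + 50000L,
                                 f$sources$end[1] + 51200L)
  r <- classify_insertion(paste0(far_tag, strrep("A", 25)), f$lib,
                          reference = f$ref, sources = f$sources, cfg = cfg)
  expect_equal(r$insertion_class, "Other")
})
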