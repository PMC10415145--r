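# Classification of full-length inserted sequences: processed pseudogenes,
# solo mobile elements (LINE1 / Alu / SVA), partnered and orphan 3'
# transductions with source-element inference, tandem duplications; plus
# structural features - 5' inversion (twin priming), target-site
# duplication, polyA tail.

#' Classify an inserted sequence
#'
#' Decision order: (1) a transcript covering at least `insert_coverage` of
#' the insert and spanning at least `min_exon_junctions` exon junctions
#' gives `ProcessedPseudogene`; (2) a single mobile-element family covering
#' at least `insert_coverage` (polyA tail excluded from the denominator)
#' gives `SoloLINE1` / `SoloAlu` / `SoloSVA`; (3) otherwise the largest
#' unannotated block is placed on the reference: a unique hit adjacent to
#' the insertion site is a `TandemDup`; a hit downstream of a LINE1 source
#' element (within `source_window`, strand-aware) is a
#' `PartneredTransduction` when LINE1 sequence is also present in the
#' insert, else `OrphanTransduction`; (4) anything else is `Other`.
#'
#' @param inserted_seq character scalar (>= 100 bp expected).
#' @param repeat_library named consensus library (`name#class`).
#' @param transcripts optional [make_transcripts()]-shaped list (`seqs`,
#'   `exon_ends`).
#' @param reference optional named character genome (needed for tandem /
#'   transduction calls).
#' @param sources optional LINE1 source element table (`chrom`, `start`,
#'   `end`, `strand`, `id`, optional `provenance`).
#' @param site optional insertion site `list(chrom=, pos=)` enabling the
#'   tandem-duplication adjacency test.
#' @param cfg an [sv_config()].
#' @return list with `insertion_class`, `repeat_segments` (annotation
#'   intervals), `has_5prime_inversion`, `inversion`, `polya` (list or
#'   NULL), `transduction_source` (source row or NULL), `residue_hit`
#'   (genome placement of the non-repeat part, or NULL) and `transcript_id`
#'   for pseudogenes.
#' @export
classify_insertion <- function(inserted_seq, repeat_library,
                               transcripts = NULL, reference = NULL,
                               sources = NULL, site = NULL,
                               cfg = sv_config()) {
  n <- nchar(inserted_seq)
  out <- list(insertion_class = "Other", repeat_segments = NULL,
              has_5prime_inversion = FALSE, inversion = NULL, polya = NULL,
              transduction_source = NULL, residue_hit = NULL,
              transcript_id = NA_character_)

  # (1) processed pseudogene
  if (!is.null(transcripts)) {
    for (ti in seq_along(transcripts$seqs)) {
      tx <- transcripts$seqs[[ti]]
      al <- sw_align(inserted_seq, tx, cfg)
      al_rc <- sw_align(revcomp(inserted_seq), tx, cfg)
      if (al_rc$score > al$score) al <- al_rc
      cov <- (al$q_end - al$q_start) / n
      ends <- transcripts$exon_ends[[ti]]
      junctions <- ends[-length(ends)]
      spanned <- sum(junctions > al$r_start + 20L & junctions < al$r_end - 20L)
      if (cov >= cfg$insert_coverage && spanned >= cfg$min_exon_junctions) {
        out$insertion_class <- "ProcessedPseudogene"
        out$transcript_id <- names(transcripts$seqs)[ti]
        out$polya <- detect_polya(inserted_seq, cfg = cfg)
        return(out)
      }
    }
  }

  ann <- annotate_repeats(inserted_seq, repeat_library, cfg = cfg)
  out$repeat_segments <- ann
  out$polya <- detect_polya(inserted_seq, cfg = cfg)
  eff_len <- n - (if (!is.null(out$polya) && out$polya$side == "3p")
    out$polya$length else 0L)
  eff_len <- max(eff_len, 1L)

  # (2) solo mobile elements
  fams <- list(SoloLINE1 = "LINE/L1|^L1", SoloAlu = "SINE/Alu|^Alu",
               SoloSVA = "SVA")
  l1pat <- fams$SoloLINE1
  for (cl in names(fams)) {
    if (class_coverage(ann, eff_len, fams[[cl]]) >= cfg$insert_coverage) {
      out$insertion_class <- cl
      if (cl == "SoloLINE1") {
        cons <- l1_consensus_of(repeat_library)
        if (!is.null(cons)) {
          inv <- detect_5prime_inversion(inserted_seq, cons, cfg)
          out$has_5prime_inversion <- inv$inverted
          out$inversion <- inv
        }
      }
      return(out)
    }
  }

  # (3) realign the non-repeat residue to the reference
  if (!is.null(reference)) {
    residue <- mask_annotated(inserted_seq, ann, out$polya)
    block <- longest_clean_block(residue)
    if (!is.null(block) && block$len >= cfg$min_span) {
      hit <- locate_sequence(substr(inserted_seq, block$start + 1L,
                                    block$start + block$len),
                             reference, cfg = cfg)
      if (!is.null(hit) && hit$unique && hit$coverage >= 0.5) {
        out$residue_hit <- hit
        if (!is.null(site) && hit$chrom == site$chrom &&
            min(abs(c(hit$r_start, hit$r_end) - site$pos)) <=
              cfg$tandem_adjacency) {
          out$insertion_class <- "TandemDup"
          return(out)
        }
        if (!is.null(sources) && nrow(sources)) {
          for (si in seq_len(nrow(sources))) {
            src <- sources[si, ]
            down <- if (src$strand == "+")
              hit$chrom == src$chrom && hit$r_start >= src$end - 50L &&
                hit$r_start <= src$end + cfg$source_window
            else
              hit$chrom == src$chrom && hit$r_end <= src$start + 50L &&
                hit$r_end >= src$start - cfg$source_window
            if (isTRUE(down)) {
              has_l1 <- any((grepl(l1pat, ann$class) |
                             grepl(l1pat, ann$label)) &
                            (ann$end - ann$start) >= 100L)
              out$insertion_class <- if (has_l1) "PartneredTransduction"
                                     else "OrphanTransduction"
              out$transduction_source <- src
              if (has_l1) {
                cons <- l1_consensus_of(repeat_library)
                if (!is.null(cons)) {
                  inv <- detect_5prime_inversion(inserted_seq, cons, cfg)
                  out$has_5prime_inversion <- inv$inverted
                  out$inversion <- inv
                }
              }
              return(out)
            }
          }
        }
      }
    }
  }
  out
}

#' @noRd
l1_consensus_of <- function(repeat_library) {
  idx <- grep("LINE/L1|^L1", names(repeat_library))
  if (!length(idx)) return(NULL)
  repeat_library[[idx[1]]]
}

# Replace annotated repeat intervals and the polyA tail with N.
#' @noRd
mask_annotated <- function(seq, ann, polya = NULL) {
  n <- nchar(seq)
  if (!is.null(ann) && nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      len <- ann$end[i] - ann$start[i]
      substr(seq, ann$start[i] + 1L, ann$end[i]) <- strrep("N", len)
    }
  }
  if (!is.null(polya) && polya$side == "3p")
    substr(seq, n - polya$length + 1L, n) <- strrep("N", polya$length)
  seq
}

#' @noRd
longest_clean_block <- function(seq) {
  m <- gregexpr("[^N]+", seq)[[1]]
  if (m[1] == -1) return(NULL)
  lens <- attr(m, "match.length")
  i <- which.max(lens)
  list(start = m[i] - 1L, len = lens[i])
}

#' Detect a 5' inversion (twin priming) against an element consensus
#'
#' The insert is aligned to the consensus in both orientations. An
#' inversion is reported when the insert decomposes into a 5' segment
#' matching the antisense consensus followed by a 3' segment matching
#' sense, with the antisense consensus interval upstream-adjacent to (or
#' overlapping) the sense segment's start - the geometry twin priming
#' produces. A purely antisense insert is not an inversion (the whole
#' element is simply on the other strand); its orientation is recorded.
#'
#' @param inserted_seq character scalar.
#' @param element_consensus consensus sequence (sense orientation).
#' @param cfg an [sv_config()].
#' @return list with `inverted`, `segments` (query/consensus intervals and
#'   strands), `internal_loss` (consensus bases lost between the segments,
#'   0 when overlapping) and `orientation` (`"sense"`, `"antisense"`,
#'   `"twin"` or `"none"`).
#' @export
detect_5prime_inversion <- function(inserted_seq, element_consensus,
                                    cfg = sv_config()) {
  min_seg <- 100L
  tol <- 50L
  L <- nchar(element_consensus)
  sense <- sw_align(inserted_seq, element_consensus, cfg)
  anti <- sw_align(inserted_seq, revcomp(element_consensus), cfg)
  has_sense <- sense$score >= min_seg * cfg$match * 0.6 &&
    (sense$q_end - sense$q_start) >= min_seg
  has_anti <- anti$score >= min_seg * cfg$match * 0.6 &&
    (anti$q_end - anti$q_start) >= min_seg
  segments <- data.frame(q_start = integer(), q_end = integer(),
                         c_start = integer(), c_end = integer(),
                         strand = character(), stringsAsFactors = FALSE)
  if (has_sense)
    segments <- rbind(segments, data.frame(
      q_start = sense$q_start, q_end = sense$q_end,
      c_start = sense$r_start, c_end = sense$r_end, strand = "+",
      stringsAsFactors = FALSE))
  if (has_anti)
    segments <- rbind(segments, data.frame(
      q_start = anti$q_start, q_end = anti$q_end,
      c_start = L - anti$r_end, c_end = L - anti$r_start, strand = "-",
      stringsAsFactors = FALSE))
  if (!has_sense && !has_anti)
    return(list(inverted = FALSE, segments = segments, internal_loss = 0L,
                orientation = "none"))
  if (has_sense && !has_anti)
    return(list(inverted = FALSE, segments = segments, internal_loss = 0L,
                orientation = "sense"))
  if (!has_sense && has_anti)
    return(list(inverted = FALSE, segments = segments, internal_loss = 0L,
                orientation = "antisense"))
  # both present: 5' antisense + 3' sense, query-adjacent, antisense
  # consensus span starting upstream of (or overlapping) the sense start
  q_adjacent <- anti$q_end <= sense$q_start + tol &&
    sense$q_start - anti$q_end <= tol
  a_start <- L - anti$r_end
  twin <- q_adjacent && anti$q_end <= sense$q_start + tol &&
    a_start <= sense$r_start + tol
  loss <- max(0L, sense$r_start - (L - anti$r_start))
  list(inverted = twin, segments = segments,
       internal_loss = if (twin) loss else 0L,
       orientation = if (twin) "twin" else "mixed")
}

#' Detect a polyA tail
#'
#' Scans the 3' terminal window for the longest run with A-fraction at
#' least `polya_min_frac` and length at least `polya_min_len` (the 5'
#' window and T-runs when `orientation = "antisense"`). The scan
#' enumerates all substrings of the window that begin and end with the
#' tail base, so interrupted tails such as `AAAAAGAAAAA` qualify while a
#' too-short pure run cannot borrow flanking characters to reach the
#' length threshold.
#'
#' @param seq character scalar.
#' @param orientation `"sense"` (A at 3') or `"antisense"` (T at 5').
#' @param cfg an [sv_config()] (`polya_window`, `polya_min_len`,
#'   `polya_min_frac`).
#' @return list with `length` and `side` (`"3p"` / `"5p"`), or `NULL`.
#' @export
detect_polya <- function(seq, orientation = "sense", cfg = sv_config()) {
  n <- nchar(seq)
  w <- min(cfg$polya_window, n)
  if (w < cfg$polya_min_len) return(NULL)
  if (orientation == "sense") {
    window <- substr(seq, n - w + 1L, n); base <- "A"; side <- "3p"
  } else {
    window <- substr(seq, 1L, w); base <- "T"; side <- "5p"
  }
  chars <- strsplit(window, "")[[1]]
  isb <- as.integer(chars == base)
  cum <- c(0L, cumsum(isb))
  best <- 0L
  # a qualifying run must begin and end with the tail base, so a too-short
  # pure run cannot borrow flanking off-base characters to reach min_len
  for (i in which(isb == 1L)) for (j in which(isb == 1L)) {
    if (j < i) next
    len <- j - i + 1L
    if (len < cfg$polya_min_len || len <= best) next
    if ((cum[j + 1L] - cum[i]) / len >= cfg$polya_min_frac) best <- len
  }
  if (best == 0L) return(NULL)
  list(length = best, side = side)
}

#' Detect a target-site duplication at an insertion junction
#'
#' At an insertion with a target-site duplication the two refined
#' breakpoints overlap on the reference: breakpoint 2 (the first retained
#' base of the right side) lies at or before breakpoint 1 (the last
#' retained base of the left side), and the duplicated site is the
#' reference between them, of length `pos1 - pos2 + 1`. A blunt insertion
#' has `pos2 == pos1 + 1` and reports no TSD.
#'
#' @param sv canonical insertion record (list or one-row data.frame with
#'   `chrom1`/`chr1`, `pos1`, `pos2`).
#' @param reference named character genome.
#' @param cfg an [sv_config()] (`min_tsd`, `max_tsd`).
#' @return list with `length` and `seq`, or `NULL`.
#' @export
detect_tsd <- function(sv, reference, cfg = sv_config()) {
  chrom <- if (!is.null(sv$chrom1)) sv$chrom1 else sv$chr1
  len <- sv$pos1 - sv$pos2 + 1L
  if (is.na(len) || len < cfg$min_tsd || len > cfg$max_tsd) return(NULL)
  list(length = len,
       seq = genome_slice(reference, chrom, sv$pos2, sv$pos1 + 1L))
}

#' Group transduction events by their source element
#'
#' @param annotations list of [classify_insertion()] results (or a
#'   data.frame with `insertion_class` and `source_id`).
#' @param sources source element table with `id` and `provenance`;
#'   somatically-created sources (provenance `"somatic"`) mark their events
#'   as nested transductions.
#' @return data.frame with one row per source: `source_id`, `n_events`,
#'   `nested`.
#' @export
infer_transduction_sources <- function(annotations, sources) {
  ids <- if (is.data.frame(annotations)) {
    annotations$source_id[annotations$insertion_class %in%
                          c("PartneredTransduction", "OrphanTransduction")]
  } else {
    unlist(lapply(annotations, function(a) {
      if (a$insertion_class %in% c("PartneredTransduction",
                                   "OrphanTransduction") &&
          !is.null(a$transduction_source)) a$transduction_source$id
      else NULL
    }))
  }
  if (!length(ids)) {
    return(data.frame(source_id = character(), n_events = integer(),
                      nested = logical(), stringsAsFactors = FALSE))
  }
  tab <- table(ids)
  prov <- setNames(
    if ("provenance" %in% names(sources)) sources$provenance
    else rep("reference", nrow(sources)), sources$id)
  data.frame(source_id = names(tab), n_events = as.integer(tab),
             nested = unname(prov[names(tab)] == "somatic"),
             stringsAsFactors = FALSE, row.names = NULL)
}
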