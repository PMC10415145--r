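# Stage 4 of the canonical SV caller: rebuild the putative SV allele
# sequence, re-genotype every read near the breakpoints in tumor and control
# against SV-allele vs reference-allele segments, and apply the final size
# and simple-repeat filters.

#' Build the putative SV segment and its reference counterparts
#'
#' The SV segment concatenates `validate_flank` bases of reference
#' approaching breakpoint 1 (per its direction), the inserted sequence, and
#' `validate_flank` bases leaving breakpoint 2 (reverse-complemented when
#' the direction demands). The two reference segments are contiguous
#' reference spanning each breakpoint +/- the flank.
#'
#' @param sv refined candidate (list with `chrom1`, `pos1`, `dir1`, ...).
#' @param reference named character genome.
#' @param cfg an [sv_config()].
#' @return list with `sv_segment`, `ref_segment1`, `ref_segment2`, junction
#'   offsets `j1`/`j2` within the SV segment (the inserted bases occupy
#'   `[j1, j2)`), and `truncated` flag when a breakpoint sits within a flank
#'   of a chromosome end.
#' @export
build_segment_pair <- function(sv, reference, cfg = sv_config()) {
  fl <- cfg$validate_flank
  side1 <- if (sv$dir1 == "+")
    genome_slice(reference, sv$chrom1, sv$pos1 + 1L - fl, sv$pos1 + 1L)
  else revcomp(genome_slice(reference, sv$chrom1, sv$pos1, sv$pos1 + fl))
  side2 <- if (sv$dir2 == "-")
    genome_slice(reference, sv$chrom2, sv$pos2, sv$pos2 + fl)
  else revcomp(genome_slice(reference, sv$chrom2, sv$pos2 + 1L - fl, sv$pos2 + 1L))
  ins <- sv$inserted_seq
  truncated <- nchar(side1) < fl || nchar(side2) < fl
  list(sv_segment = paste0(side1, ins, side2),
       ref_segment1 = genome_slice(reference, sv$chrom1,
                                   sv$pos1 + 1L - fl, sv$pos1 + 1L + fl),
       ref_segment2 = genome_slice(reference, sv$chrom2,
                                   sv$pos2 - fl, sv$pos2 + fl),
       j1 = nchar(side1), j2 = nchar(side1) + nchar(ins),
       truncated = truncated)
}

#' Classify one read against the SV and reference alleles
#'
#' The read (or its window around the junction) is locally aligned, in both
#' orientations, against the SV segment and both reference segments. Scores
#' are normalized by twice the shorter of read and segment. The read is a
#' variant read iff the SV-segment score exceeds the best reference score by
#' `validate_delta` and the alignment spans at least `min_span` bases on
#' both sides of the junction; the reverse condition gives a reference read;
#' anything else is ambiguous and counts for neither allele.
#'
#' @param read_seq character scalar.
#' @param pair segment pair from [build_segment_pair()].
#' @param cfg an [sv_config()].
#' @return `"variant"`, `"reference"` or `"ambiguous"`.
#' @export
classify_read <- function(read_seq, pair, cfg = sv_config()) {
  nr <- nchar(read_seq)
  if (nr < cfg$min_span) return("ambiguous")
  norm <- function(score, ns) score / (2 * min(nr, ns))
  # forward orientation first; fall back to the reverse complement only
  # when the forward scores are uninformative (read windows are extracted
  # in stored SEQ orientation, which matches the segment frame for the
  # breakpoint side the record aligned to)
  score3 <- function(rs) {
    c(sv = sw_align(rs, pair$sv_segment, cfg)$score,
      r1 = sw_score(rs, pair$ref_segment1, cfg),
      r2 = sw_score(rs, pair$ref_segment2, cfg))
  }
  al_sv <- sw_align(read_seq, pair$sv_segment, cfg)
  s_fwd <- c(sv = al_sv$score,
             r1 = sw_score(read_seq, pair$ref_segment1, cfg),
             r2 = sw_score(read_seq, pair$ref_segment2, cfg))
  n_sv <- nchar(pair$sv_segment)
  n_r1 <- nchar(pair$ref_segment1); n_r2 <- nchar(pair$ref_segment2)
  best_norm <- max(norm(s_fwd["sv"], n_sv), norm(s_fwd["r1"], n_r1),
                   norm(s_fwd["r2"], n_r2))
  if (best_norm < 0.5) {
    rc <- revcomp(read_seq)
    al_rc <- sw_align(rc, pair$sv_segment, cfg)
    s_rc <- c(sv = al_rc$score,
              r1 = sw_score(rc, pair$ref_segment1, cfg),
              r2 = sw_score(rc, pair$ref_segment2, cfg))
    if (max(s_rc) > max(s_fwd)) { s_fwd <- s_rc; al_sv <- al_rc }
  }
  s_sv <- norm(s_fwd["sv"], n_sv)
  s_ref <- max(norm(s_fwd["r1"], n_r1), norm(s_fwd["r2"], n_r2))
  spans <- al_sv$r_start <= pair$j1 - cfg$min_span &&
    al_sv$r_end >= pair$j2 + cfg$min_span
  if (s_sv >= s_ref + cfg$validate_delta && spans) "variant"
  else if (s_ref >= s_sv + cfg$validate_delta) "reference"
  else "ambiguous"
}

# Collect, per distinct read, a window of read sequence around either
# breakpoint of `sv`. The window is wide enough to span the junction plus
# the validation flank and the inserted sequence.
#' @noRd
collect_read_windows <- function(sv, aln, cfg) {
  if (is.null(aln) || !nrow(aln)) return(character())
  W <- cfg$validate_flank + nchar(sv$inserted_seq) + 200L
  hits <- list()
  for (side in 1:2) {
    chrom <- if (side == 1L) sv$chrom1 else sv$chrom2
    pos <- if (side == 1L) sv$pos1 else sv$pos2
    idx <- which(aln$chrom == chrom &
                 aln$start < pos + cfg$validate_flank &
                 aln$end > pos - cfg$validate_flank)
    for (i in idx) {
      id <- aln$read_id[i]
      if (!is.null(hits[[id]])) next
      qoff <- query_offset_at(aln$start[i], aln$cigar[i], pos)
      if (is.na(qoff)) next
      seq <- aln$seq[i]
      win <- substr(seq, max(1L, qoff - W + 1L),
                    min(nchar(seq), qoff + W))
      if (nzchar(win)) hits[[id]] <- win
    }
  }
  unlist(hits)
}

#' Validate a refined candidate against tumor and control reads
#'
#' Reads overlapping either breakpoint window in each sample are classified
#' with [classify_read()]. The candidate is kept iff the tumor has at least
#' `min_tumor_support` variant reads and the control has at most
#' `max_control_support` (default: none).
#'
#' @param sv refined candidate list.
#' @param tumor_aln,control_aln alignment data.frames.
#' @param reference named character genome.
#' @param cfg an [sv_config()].
#' @return on success a one-row canonical SV data.frame (`chr1`, `pos1`,
#'   `dir1`, `chr2`, `pos2`, `dir2`, `inserted_seq`, `svtype`,
#'   `tumor_support`, `control_support`, `vaf`, `homlen`, `read_ids`);
#'   otherwise a list with `failure` and the observed counts. A candidate
#'   with no overlapping control reads is kept but flagged
#'   `control_uncovered`.
#' @export
validate_candidate <- function(sv, tumor_aln, control_aln, reference,
                               cfg = sv_config()) {
  pair <- build_segment_pair(sv, reference, cfg)
  tw <- collect_read_windows(sv, tumor_aln, cfg)
  cw <- collect_read_windows(sv, control_aln, cfg)
  tcls <- vapply(tw, classify_read, "", pair = pair, cfg = cfg)
  ccls <- vapply(cw, classify_read, "", pair = pair, cfg = cfg)
  t_var <- sum(tcls == "variant"); t_ref <- sum(tcls == "reference")
  c_var <- sum(ccls == "variant")
  if (t_var < cfg$min_tumor_support)
    return(list(failure = "insufficient_tumor_support",
                tumor_support = t_var, control_support = c_var))
  if (c_var > cfg$max_control_support)
    return(list(failure = "control_support",
                tumor_support = t_var, control_support = c_var))
  flag <- if (!length(cw)) "control_uncovered" else ""
  out <- data.frame(
    chr1 = sv$chrom1, pos1 = sv$pos1, dir1 = sv$dir1,
    chr2 = sv$chrom2, pos2 = sv$pos2, dir2 = sv$dir2,
    inserted_seq = sv$inserted_seq, svtype = sv$svtype,
    tumor_support = t_var, control_support = c_var,
    vaf = if (t_var + t_ref > 0) t_var / (t_var + t_ref) else NA_real_,
    homlen = if (!is.null(sv$homlen)) sv$homlen else NA_integer_,
    read_ids = paste(sort(names(tw)[tcls == "variant"]), collapse = ","),
    flag = flag,
    stringsAsFactors = FALSE)
  out
}

#' Final size and simple-repeat filters
#'
#' Deletions and insertions smaller than `min_indel_size` are removed, as
#' are deletions and insertions confined within a single simple-repeat
#' interval (both breakpoints inside the same interval, padded by
#' `simple_repeat_pad`).
#'
#' @param records canonical SV data.frame.
#' @param simple_repeats `GRanges` of simple-repeat intervals (or `NULL`).
#' @param cfg an [sv_config()].
#' @return the filtered data.frame.
#' @export
final_filters <- function(records, simple_repeats = NULL, cfg = sv_config()) {
  if (!nrow(records)) return(records)
  size <- ifelse(records$svtype == "DEL",
                 abs(records$pos2 - records$pos1) - 1L,
                 nchar(records$inserted_seq))
  keep <- !(records$svtype %in% c("DEL", "INS")) | size >= cfg$min_indel_size
  if (!is.null(simple_repeats) && length(simple_repeats)) {
    pad <- cfg$simple_repeat_pad
    gr <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(simple_repeats),
      ranges = IRanges::IRanges(
        start = pmax(1L, GenomicRanges::start(simple_repeats) - pad),
        end = GenomicRanges::end(simple_repeats) + pad))
    for (i in which(keep & records$svtype %in% c("DEL", "INS"))) {
      b1 <- GenomicRanges::GRanges(records$chr1[i],
                                   IRanges::IRanges(records$pos1[i] + 1L,
                                                    records$pos1[i] + 1L))
      b2 <- GenomicRanges::GRanges(records$chr2[i],
                                   IRanges::IRanges(records$pos2[i] + 1L,
                                                    records$pos2[i] + 1L))
      h1 <- GenomicRanges::findOverlaps(b1, gr)
      h2 <- GenomicRanges::findOverlaps(b2, gr)
      if (length(h1) && length(h2) &&
          length(intersect(S4Vectors::subjectHits(h1),
                           S4Vectors::subjectHits(h2))))
        keep[i] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
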