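# Single-breakend SV module: tumor-specific breakpoints whose partner
# sequence cannot be aligned, detected from long soft clips, polished into a
# beyond-breakpoint contig, validated against tumor/control reads, and
# classified (satellite / simple repeat / telomere / LINE1- or Alu-mediated
# / virus / rescued canonical).

#' Extract long soft-clip breakend signals
#'
#' One signal per alignment record carrying a soft clip of at least
#' `min_clip` bases that is not explained by a split alignment (no SA tag).
#' Clip sequences are normalized junction-outward: position 0 of `clip_seq`
#' is the base adjacent to the junction (left clips are
#' reverse-complemented).
#'
#' @param aln alignment data.frame.
#' @param min_clip minimal clip length.
#' @return data.frame with `read_id`, `chrom`, `pos`, `dir`, `clip_side`,
#'   `clip_len`, `clip_seq`, `inner_seq` (up to 100 aligned bases adjacent
#'   to the junction, junction-distal first), `sample`.
#' @export
parse_softclips <- function(aln, min_clip = 500L) {
  out <- list()
  inner <- 100L
  for (i in seq_len(nrow(aln))) {
    if (aln$is_supplementary[i] || nzchar(aln$sa[i])) next
    ops <- parse_cigar(aln$cigar[i])
    if (is.null(ops)) next
    cl <- cigar_clips(ops)
    L <- nchar(aln$seq[i])
    if (cl[["right"]] >= min_clip) {
      qs <- L - cl[["right"]]
      out[[length(out) + 1L]] <- data.frame(
        read_id = aln$read_id[i], chrom = aln$chrom[i],
        pos = aln$end[i] - 1L, dir = "+", clip_side = "right",
        clip_len = cl[["right"]],
        clip_seq = substr(aln$seq[i], qs + 1L, L),
        inner_seq = substr(aln$seq[i], max(1L, qs - inner + 1L), qs),
        sample = aln$sample[i], stringsAsFactors = FALSE)
    }
    if (cl[["left"]] >= min_clip) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = aln$read_id[i], chrom = aln$chrom[i],
        pos = aln$start[i], dir = "-", clip_side = "left",
        clip_len = cl[["left"]],
        clip_seq = revcomp(substr(aln$seq[i], 1L, cl[["left"]])),
        inner_seq = revcomp(substr(aln$seq[i], cl[["left"]] + 1L,
                                   min(L, cl[["left"]] + inner))),
        sample = aln$sample[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), dir = character(),
                      clip_side = character(), clip_len = integer(),
                      clip_seq = character(), inner_seq = character(),
                      sample = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster breakend signals
#'
#' Single-linkage clustering of soft-clip signals sharing chromosome and
#' direction within `margin`.
#'
#' @param signals data.frame from [parse_softclips()].
#' @param margin clustering distance in bp.
#' @param min_reads minimal distinct supporting reads.
#' @return list of clusters (member `signals`, `chrom`, `dir`, `pos_lo`,
#'   `pos_hi`, `read_ids`).
#' @export
cluster_breakends <- function(signals, margin = 50L, min_reads = 3L) {
  if (!nrow(signals)) return(list())
  out <- list()
  for (grp in split(seq_len(nrow(signals)),
                    paste(signals$chrom, signals$dir))) {
    pos <- signals$pos[grp]
    ord <- order(pos)
    brk <- c(0L, which(diff(pos[ord]) > margin), length(grp))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- grp[ord[(brk[b] + 1L):brk[b + 1L]]]
      sub <- signals[idx, , drop = FALSE]
      ids <- unique(sub$read_id)
      if (length(ids) < min_reads) next
      out[[length(out) + 1L]] <- list(
        signals = sub, chrom = sub$chrom[1], dir = sub$dir[1],
        pos_lo = min(sub$pos), pos_hi = max(sub$pos), read_ids = ids)
    }
  }
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "chrom"),
                 vapply(out, `[[`, 0L, "pos_lo"))
    out <- out[ord]
  }
  out
}

#' Remove breakend clusters with control support
#'
#' @param clusters list from [cluster_breakends()].
#' @param control_signals control soft-clip signals (parse with the
#'   permissive `control_min_clip`).
#' @param margin match margin in bp.
#' @return retained clusters.
#' @export
filter_breakends_by_control <- function(clusters, control_signals,
                                        margin = 200L) {
  if (is.null(control_signals) || !nrow(control_signals)) return(clusters)
  Filter(function(cl) {
    !any(control_signals$chrom == cl$chrom &
         control_signals$dir == cl$dir &
         control_signals$pos >= cl$pos_lo - margin &
         control_signals$pos <= cl$pos_hi + margin)
  }, clusters)
}

#' Polish the beyond-breakpoint contig of a breakend cluster
#'
#' Consensus inputs are the soft-clipped parts prefixed by up to 100
#' aligned bases inside the breakpoint; polishing reuses the canonical
#' consensus machinery (two majority-vote rounds against a centroid).
#'
#' @param cluster one cluster from [cluster_breakends()].
#' @param cfg an [sv_config()].
#' @return list as [build_consensus()], with `j1` the junction offset
#'   (boundary between inner margin and clip), trimmed to
#'   `bnd_inner_margin + max_contig` bases.
#' @export
build_breakend_contig <- function(cluster, cfg = sv_config()) {
  sig <- cluster$signals
  segs <- data.frame(
    read_id = sig$read_id,
    seq = paste0(sig$inner_seq, substr(sig$clip_seq, 1L, cfg$max_contig)),
    j1 = nchar(sig$inner_seq), j2 = nchar(sig$inner_seq),
    stringsAsFactors = FALSE)
  segs <- segs[!duplicated(segs$read_id), , drop = FALSE]
  cons <- build_consensus(segs, cfg)
  lim <- cfg$bnd_inner_margin + cfg$max_contig
  if (nchar(cons$seq) > lim) cons$seq <- substr(cons$seq, 1L, lim)
  cons
}

#' Refine and validate a single-breakend candidate
#'
#' A plain local alignment of the contig's inner portion against the
#' reference window fixes the breakpoint at single-base resolution; the
#' putative segment (reference flank + beyond-breakpoint contig) is then
#' used to classify nearby tumor and control reads, keeping candidates with
#' at least `min_tumor_support` tumor variant reads and none in the
#' control.
#'
#' @param cluster breakend cluster.
#' @param contig [build_breakend_contig()] output.
#' @param reference named character genome.
#' @param tumor_aln,control_aln alignment data.frames.
#' @param cfg an [sv_config()].
#' @return a one-row data.frame (`chrom`, `pos`, `dir`, `contig`,
#'   `tumor_support`, `control_support`, `classification` =
#'   `"Unclassified"`) or a list with `failure`.
#' @export
refine_and_validate_breakend <- function(cluster, contig, reference,
                                         tumor_aln, control_aln,
                                         cfg = sv_config()) {
  pad <- cfg$flank
  clen <- nchar(reference[[cluster$chrom]])
  wa <- max(0L, cluster$pos_lo - pad)
  wb <- min(clen, cluster$pos_hi + 1L + pad)
  win <- genome_slice(reference, cluster$chrom, wa, wb)
  if (cluster$dir == "-") win <- revcomp(win)
  al <- sw_align(contig$seq, win, cfg)
  if (al$score < cfg$match * cfg$min_span)
    return(list(failure = "no_reference_anchor"))
  pos <- if (cluster$dir == "+") wa + al$r_end - 1L else wb - al$r_end
  beyond <- substr(contig$seq, al$q_end + 1L, nchar(contig$seq))
  if (nchar(beyond) < cfg$min_span)
    return(list(failure = "short_contig"))

  fl <- cfg$validate_flank
  side1 <- if (cluster$dir == "+")
    genome_slice(reference, cluster$chrom, pos + 1L - fl, pos + 1L)
  else revcomp(genome_slice(reference, cluster$chrom, pos, pos + fl))
  pair <- list(
    sv_segment = paste0(side1, substr(beyond, 1L, 400L)),
    ref_segment1 = genome_slice(reference, cluster$chrom, pos - fl, pos + fl),
    ref_segment2 = genome_slice(reference, cluster$chrom, pos - fl, pos + fl),
    j1 = nchar(side1), j2 = nchar(side1))
  sv_like <- list(chrom1 = cluster$chrom, pos1 = pos, dir1 = cluster$dir,
                  chrom2 = cluster$chrom, pos2 = pos, dir2 = cluster$dir,
                  inserted_seq = "")
  tw <- collect_read_windows(sv_like, tumor_aln, cfg)
  cw <- collect_read_windows(sv_like, control_aln, cfg)
  tcls <- vapply(tw, classify_read, "", pair = pair, cfg = cfg)
  ccls <- vapply(cw, classify_read, "", pair = pair, cfg = cfg)
  t_var <- sum(tcls == "variant"); c_var <- sum(ccls == "variant")
  if (t_var < cfg$min_tumor_support)
    return(list(failure = "insufficient_tumor_support",
                tumor_support = t_var, control_support = c_var))
  if (c_var > cfg$max_control_support)
    return(list(failure = "control_support",
                tumor_support = t_var, control_support = c_var))
  data.frame(chrom = cluster$chrom, pos = pos, dir = cluster$dir,
             contig = beyond, tumor_support = t_var,
             control_support = c_var, classification = "Unclassified",
             stringsAsFactors = FALSE)
}

#' Classify a validated single-breakend record
#'
#' Decision order: (1) a breakpoint shared with an existing canonical
#' record (within `bnd_dup_margin`) is a duplicate and returns `NULL`;
#' (2) a contig aligning uniquely to the reference over at least
#' `rescue_coverage` of its length is rescued into a canonical SV (the
#' implied second breakpoint is validated through the canonical machinery
#' when alignments are supplied); (3) contigs mostly covered by satellite /
#' simple-repeat / telomere annotation take those classes; (4) a LINE1 (or
#' Alu) match at the contig start followed by a unique distant locus gives
#' `L1Mediated` / `AluMediated`; (5) a virus match of at least
#' `element_min_match` gives `VirusMediated`; (6) otherwise `Unclassified`.
#'
#' @param record one-row data.frame from [refine_and_validate_breakend()].
#' @param reference named character genome.
#' @param repeat_library named character consensus library (RepeatMasker
#'   `name#class` naming; virus entries use class `Virus`).
#' @param canonical_records canonical SV data.frame (may be empty).
#' @param tumor_aln,control_aln optional alignments enabling full canonical
#'   validation of rescued records.
#' @param annotation optional precomputed annotation intervals for the
#'   contig (e.g. from [read_repeatmasker_out()]); when `NULL` the built-in
#'   aligner annotates against `repeat_library`.
#' @param cfg an [sv_config()].
#' @return `NULL` for duplicates; otherwise a list with `classification`,
#'   `evidence` (annotation intervals), `placement` (genome hit or NULL)
#'   and, for rescued records, `rescued` (a canonical SV row).
#' @export
classify_breakend <- function(record, reference, repeat_library,
                              canonical_records = NULL,
                              tumor_aln = NULL, control_aln = NULL,
                              annotation = NULL, cfg = sv_config()) {
  if (!is.null(canonical_records) && nrow(canonical_records)) {
    near <- (canonical_records$chr1 == record$chrom &
             abs(canonical_records$pos1 - record$pos) <= cfg$bnd_dup_margin) |
            (canonical_records$chr2 == record$chrom &
             abs(canonical_records$pos2 - record$pos) <= cfg$bnd_dup_margin)
    if (any(near)) return(NULL)
  }
  contig <- record$contig
  n <- nchar(contig)

  loc <- locate_sequence(contig, reference, cfg = cfg)
  if (!is.null(loc) && loc$unique && loc$coverage >= cfg$rescue_coverage) {
    res <- list(classification = "RescuedCanonical", evidence = NULL,
                placement = loc)
    sv <- rescued_candidate(record, loc, contig)
    if (!is.null(tumor_aln)) {
      val <- validate_candidate(sv, tumor_aln, control_aln, reference, cfg)
      if (is.null(val$failure)) res$rescued <- val
      else { res$classification <- "Unclassified"; res$failure <- val$failure }
    } else {
      res$rescued <- as.data.frame(
        c(list(chr1 = sv$chrom1, pos1 = sv$pos1, dir1 = sv$dir1,
               chr2 = sv$chrom2, pos2 = sv$pos2, dir2 = sv$dir2,
               inserted_seq = sv$inserted_seq, svtype = sv$svtype,
               tumor_support = record$tumor_support,
               control_support = record$control_support,
               vaf = NA_real_)), stringsAsFactors = FALSE)
    }
    if (res$classification == "RescuedCanonical") return(res)
  }

  ann <- if (is.null(annotation))
    annotate_repeats(contig, repeat_library, cfg = cfg) else annotation
  sat_cov <- class_coverage(ann, n, "Satellite")
  simple_cov <- class_coverage(ann, n, "Simple_repeat")
  telo_cov <- telomere_coverage(contig)
  if (sat_cov >= cfg$repeat_coverage)
    return(list(classification = "Satellite", evidence = ann, placement = loc))
  if (simple_cov >= cfg$repeat_coverage)
    return(list(classification = "SimpleRepeat", evidence = ann,
                placement = loc))
  if (telo_cov >= cfg$repeat_coverage)
    return(list(classification = "Telomere", evidence = ann, placement = loc))

  for (fam in c("L1", "Alu")) {
    pat <- if (fam == "L1") "LINE/L1|^L1" else "SINE/Alu|^Alu"
    hits <- ann[(grepl(pat, ann$class) | grepl(pat, ann$label)) &
                (ann$end - ann$start) >= cfg$element_min_match &
                ann$start <= 100L, , drop = FALSE]
    if (nrow(hits)) {
      tail_start <- max(hits$end)
      remainder <- substr(contig, tail_start + 1L, n)
      if (nchar(remainder) >= cfg$element_min_match) {
        rloc <- locate_sequence(remainder, reference, cfg = cfg)
        if (!is.null(rloc) && rloc$unique && rloc$coverage >= 0.5) {
          distant <- rloc$chrom != record$chrom ||
            abs(rloc$r_start - record$pos) > cfg$distant_min
          if (distant)
            return(list(
              classification = if (fam == "L1") "L1Mediated" else "AluMediated",
              evidence = ann, placement = rloc))
        }
      }
    }
  }

  vir <- ann[grepl("Virus", ann$class) &
             (ann$end - ann$start) >= cfg$element_min_match, , drop = FALSE]
  if (nrow(vir))
    return(list(classification = "VirusMediated", evidence = ann,
                placement = loc))
  list(classification = "Unclassified", evidence = ann, placement = loc)
}

# Canonical candidate implied by a uniquely-placed breakend contig: the
# partner breakpoint enters the located locus at its junction-proximal end.
#' @noRd
rescued_candidate <- function(record, loc, contig) {
  if (loc$strand == "+") {
    bp2 <- list(chrom = loc$chrom, pos = loc$r_start, dir = "-")
  } else {
    bp2 <- list(chrom = loc$chrom, pos = loc$r_end - 1L, dir = "+")
  }
  ins <- substr(contig, 1L, loc$q_start)
  sv <- list(chrom1 = record$chrom, pos1 = record$pos, dir1 = record$dir,
             chrom2 = bp2$chrom, pos2 = bp2$pos, dir2 = bp2$dir,
             inserted_seq = ins, homlen = NA_integer_)
  sv$svtype <- svtype_of(sv$chrom1, sv$pos1, sv$dir1, sv$chrom2, sv$pos2,
                         sv$dir2, nchar(ins))
  sv
}

#' Read RepeatMasker annotation (.out) for a single query sequence
#'
#' Parses the standard fixed-column `.out` layout and returns annotation
#' intervals in the shape [annotate_repeats()] produces, usable as the
#' `annotation` provider of [classify_breakend()].
#'
#' @param path `.out` file.
#' @param query optional query name filter (column 5).
#' @return data.frame with `start`, `end` (0-based half-open query coords),
#'   `label`, `class`, `identity`, `strand`.
#' @export
read_repeatmasker_out <- function(path, query = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[-seq_len(min(3L, length(lines)))]   # header block
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(start = integer(), end = integer(), label = character(),
                      class = character(), identity = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(lines, "\\s+")
  get <- function(i) vapply(toks, `[`, "", i)
  out <- data.frame(
    qname = get(5L),
    start = as.integer(get(6L)) - 1L,
    end = as.integer(get(7L)),
    strand = ifelse(get(9L) == "C", "-", "+"),
    label = get(10L),
    class = get(11L),
    identity = 1 - as.numeric(get(2L)) / 100,
    stringsAsFactors = FALSE)
  if (!is.null(query)) out <- out[out$qname == query, , drop = FALSE]
  out$qname <- NULL
  rownames(out) <- NULL
  out[, c("start", "end", "label", "class", "identity", "strand")]
}

#' Call single-breakend SVs from paired alignments
#'
#' Full single-breakend workflow: soft-clip parsing in tumor and control,
#' clustering, control subtraction, contig polishing, refinement +
#' validation, duplicate removal against canonical records, and
#' classification (with canonical rescue).
#'
#' @param tumor_aln,control_aln alignment data.frames.
#' @param reference named character genome.
#' @param repeat_library consensus library (see [classify_breakend()]).
#' @param canonical_records canonical SV data.frame for duplicate removal
#'   and rescue merging (may be empty).
#' @param cfg an [sv_config()].
#' @return list with `breakends` (classified records), `rescued` (canonical
#'   SV rows recovered from breakend contigs) and `evidence` (per-record
#'   annotation list).
#' @export
call_breakend_svs <- function(tumor_aln, control_aln, reference,
                              repeat_library, canonical_records = NULL,
                              cfg = sv_config()) {
  tsig <- parse_softclips(tumor_aln, min_clip = cfg$min_clip)
  csig <- parse_softclips(control_aln, min_clip = cfg$control_min_clip)
  clusters <- cluster_breakends(tsig, margin = cfg$bnd_cluster_margin,
                                min_reads = cfg$min_tumor_read_pre)
  clusters <- filter_breakends_by_control(clusters, csig,
                                          margin = cfg$control_margin)
  recs <- list(); rescued <- list(); evid <- list()
  for (cl in clusters) {
    contig <- build_breakend_contig(cl, cfg)
    if (contig$flag == "discordant") next
    rec <- refine_and_validate_breakend(cl, contig, reference, tumor_aln,
                                        control_aln, cfg)
    if (!is.null(rec$failure)) next
    cls <- classify_breakend(rec, reference, repeat_library,
                             canonical_records, tumor_aln, control_aln,
                             cfg = cfg)
    if (is.null(cls)) next   # duplicate of a canonical record
    rec$classification <- cls$classification
    if (!is.null(cls$rescued)) rescued[[length(rescued) + 1L]] <- cls$rescued
    recs[[length(recs) + 1L]] <- rec
    evid[[length(evid) + 1L]] <- cls$evidence
  }
  breakends <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), pos = integer(), dir = character(),
               contig = character(), tumor_support = integer(),
               control_support = integer(), classification = character(),
               stringsAsFactors = FALSE)
  rownames(breakends) <- NULL
  rs <- if (length(rescued)) do.call(rbind, lapply(rescued, function(r)
    r[, intersect(names(r), names(empty_sv_records())), drop = FALSE])) else
    NULL
  list(breakends = breakends, rescued = rs, evidence = evid)
}
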