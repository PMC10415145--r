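# Stage 3 of the canonical SV caller: error-correct the junction-spanning
# read portions into a consensus, then align the consensus to the two
# candidate reference regions with the jump-enabled Smith-Waterman to obtain
# single-base breakpoints and the inserted sequence.

#' Extract junction-spanning read segments for a cluster
#'
#' For every supporting read, takes the read subsequence from `flank` bases
#' before the junction to `flank` after (clipped at read ends), oriented to a
#' common frame: the segment traverses the breakpoint-1 side approaching the
#' junction in the direction given by `dir1`.
#'
#' @param cluster one cluster from [cluster_signals()].
#' @param aln the alignment data.frame the signals came from.
#' @param cfg an [sv_config()]; uses `flank` and `min_flank`.
#' @return data.frame with `seq` and the junction offsets `j1`, `j2` within
#'   each segment (0-based; the inserted bases sit in `[j1, j2)`). Reads with
#'   less than `min_flank` sequence on either side are excluded.
#' @export
extract_junction_segments <- function(cluster, aln, cfg = sv_config()) {
  sig <- cluster$signals
  out <- vector("list", nrow(sig))
  for (i in seq_len(nrow(sig))) {
    s <- sig[i, ]
    rec <- s$rec
    seq <- aln$seq[rec]
    if (is.na(seq) || !nzchar(seq)) next
    if (s$frame == "original" && aln$strand[rec] == "-") seq <- revcomp(seq)
    L <- nchar(seq)
    a <- max(0L, s$q1 - cfg$flank)
    b <- min(L, s$q2 + cfg$flank)
    if (s$q1 - a < cfg$min_flank || b - s$q2 < cfg$min_flank) next
    win <- substr(seq, a + 1L, b)
    j1 <- s$q1 - a; j2 <- s$q2 - a
    if (isTRUE(s$swapped)) {
      win <- revcomp(win)
      w <- b - a
      tmp <- w - s$q2 + a   # new j1 = len - old j2
      j2 <- w - j1
      j1 <- tmp
    }
    out[[i]] <- data.frame(read_id = s$read_id, seq = win, j1 = j1, j2 = j2,
                           stringsAsFactors = FALSE)
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(read_id = character(), seq = character(),
                      j1 = integer(), j2 = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # one segment per read (a read can emit several identical-junction signals)
  res <- res[!duplicated(res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Error-corrected consensus of junction segments
#'
#' A centroid segment (highest summed pairwise alignment score among a
#' deterministic subset) is chosen; all segments are aligned to it with a
#' banded ends-free alignment and a per-column majority vote (gaps included;
#' insertion slots voted as strings) produces the polished sequence. Two
#' rounds are run, the second against the first round's output.
#'
#' @param segments data.frame from [extract_junction_segments()].
#' @param cfg an [sv_config()].
#' @return list with `seq`, `j1` (junction offset carried through the vote),
#'   `n_inputs`, `mean_identity` (segments vs centroid, final round) and
#'   `flag` (`"ok"`, `"unpolished"` for a single segment, `"discordant"`
#'   when mean identity falls below `consensus_discord_identity`).
#' @export
build_consensus <- function(segments, cfg = sv_config()) {
  k <- nrow(segments)
  if (k == 0L) stop("no segments")
  if (k == 1L) {
    return(list(seq = segments$seq[1], j1 = segments$j1[1], n_inputs = 1L,
                mean_identity = NA_real_, flag = "unpolished"))
  }
  if (k > cfg$consensus_max_reads) {
    ord <- order(nchar(segments$seq), decreasing = TRUE)
    segments <- segments[sort(ord[seq_len(cfg$consensus_max_reads)]), ,
                         drop = FALSE]
    k <- nrow(segments)
  }
  seqs <- segments$seq
  j1s <- segments$j1

  band_for <- function(len) as.integer(150L + 0.15 * len)

  # centroid: maximal summed pairwise score over a deterministic subset
  cand <- unique(as.integer(round(seq(1L, k, length.out = min(k, 8L)))))
  if (length(cand) > 1L) {
    scores <- numeric(length(cand))
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
      if (b <= a) next
      i <- cand[a]; j <- cand[b]
      al <- nw_align(seqs[i], seqs[j], cfg,
                     band_offset = j1s[j] - j1s[i],
                     band_width = band_for(max(nchar(seqs[i]), nchar(seqs[j]))))
      sc <- if (is.na(al$score)) 0 else al$score
      scores[a] <- scores[a] + sc
      scores[b] <- scores[b] + sc
    }
    centroid_i <- cand[which.max(scores)]
  } else centroid_i <- cand[1]

  centroid <- seqs[centroid_i]
  jc <- j1s[centroid_i]
  mean_id <- NA_real_
  for (round in seq_len(cfg$consensus_rounds)) {
    res <- vote_round(centroid, jc, seqs, j1s, centroid_i, cfg, band_for)
    centroid <- res$seq
    jc <- res$j1
    mean_id <- res$mean_identity
    centroid_i <- 0L  # later rounds: centroid is synthetic, all segs align
  }
  flag <- if (!is.na(mean_id) && mean_id < cfg$consensus_discord_identity)
    "discordant" else "ok"
  list(seq = centroid, j1 = jc, n_inputs = k, mean_identity = mean_id,
       flag = flag)
}

# One majority-vote polishing round of `seqs` against `centroid`.
#' @noRd
vote_round <- function(centroid, jc, seqs, j1s, centroid_i, cfg, band_for) {
  L <- nchar(centroid)
  cchars <- strsplit(centroid, "")[[1]]
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, `-` = 5L)
  votes <- matrix(0, nrow = 5L, ncol = L)
  ccode <- code[cchars]; ccode[is.na(ccode)] <- 5L
  # centroid votes for itself with a half-weight tie-break bonus
  votes[cbind(ccode, seq_len(L))] <- votes[cbind(ccode, seq_len(L))] + 1.5
  ins <- list()   # slot (0..L, as character) -> character vector of strings
  ins_cov <- rep(1L, L + 1L)  # number of sequences spanning each slot
  ids <- numeric(0)
  for (i in seq_along(seqs)) {
    if (i == centroid_i) next
    al <- nw_align(seqs[i], centroid, cfg,
                   band_offset = jc - j1s[i],
                   band_width = band_for(max(nchar(seqs[i]), L)))
    if (is.na(al$score) || !nzchar(al$r_aln)) next
    ids <- c(ids, al$identity)
    qa <- strsplit(al$q_aln, "")[[1]]
    ra <- strsplit(al$r_aln, "")[[1]]
    isref <- ra != "-"
    rpos <- cumsum(isref) + al$r_start    # 1-based centroid pos of ref cols
    if (any(isref)) {
      p <- rpos[isref]
      v <- code[qa[isref]]; v[is.na(v)] <- 5L
      idx <- cbind(v, p)
      for (r in seq_len(nrow(idx))) votes[idx[r, 1L], idx[r, 2L]] <-
          votes[idx[r, 1L], idx[r, 2L]] + 1
      ins_cov[(min(p)):(max(p) + 1L)] <- ins_cov[(min(p)):(max(p) + 1L)] + 1L
    }
    if (any(!isref)) {
      gap <- which(!isref)
      runs <- split(gap, cumsum(c(1L, diff(gap) != 1L)))
      for (run in runs) {
        slot <- as.character(rpos[run[1]])   # insert after this centroid pos
        str <- paste(qa[run], collapse = "")
        ins[[slot]] <- c(ins[[slot]], str)
      }
    }
  }
  win <- max.col(t(votes), ties.method = "first")
  keep <- win != 5L
  out_chars <- character(L + 1L)           # slot s outputs ins + base
  names(win) <- NULL
  letters4 <- c("A", "C", "G", "T", "")
  base_out <- ifelse(keep, letters4[win], "")
  ins_out <- character(L + 1L)
  if (length(ins)) {
    # alignment ambiguity can place the same inserted base at neighbouring
    # slots in different segments; pool votes over adjacent slots so a
    # split vote still reaches the majority
    slots <- as.integer(names(ins))
    support <- lengths(ins)
    used <- logical(L + 2L)
    for (k in order(support, decreasing = TRUE)) {
      s <- slots[k]
      nb <- slots[abs(slots - s) <= 1L]
      if (any(used[nb + 1L])) next
      pooled <- unlist(ins[as.character(nb)], use.names = FALSE)
      if (length(pooled) > ins_cov[s + 1L] / 2) {
        tab <- sort(table(pooled), decreasing = TRUE)
        ins_out[s + 1L] <- names(tab)[1]
        used[nb + 1L] <- TRUE
      }
    }
  }
  # emitted length before centroid position jc (0-based junction offset)
  emit <- nchar(ins_out) + c(0L, nchar(base_out))
  # emit[s+1] = insertion at slot s + base at centroid pos s (base s emitted
  # after slot s-1's insert); slot 0's insert precedes everything
  pieces <- paste0(ins_out, c(base_out, ""))
  seq_out <- paste(pieces, collapse = "")
  j1_new <- nchar(ins_out[1L])
  if (jc > 0L) j1_new <- nchar(paste(pieces[seq_len(jc)], collapse = "")) +
      nchar(ins_out[jc + 1L])
  list(seq = seq_out, j1 = j1_new,
       mean_identity = if (length(ids)) mean(ids) else NA_real_)
}

#' Refine a candidate cluster to single-base breakpoints
#'
#' Builds the consensus of the junction segments and aligns it with
#' [jump_sw_align()] against the two reference windows (each breakpoint
#' range padded by the extraction flank plus `refine_window`), oriented
#' according to the junction directions. Window-local coordinates are
#' converted back to genome coordinates; ties from junction micro-homology
#' are broken towards maximal attribution to breakpoint 1, and the
#' micro-homology length is reported.
#'
#' @param cluster a cluster that survived control filtering.
#' @param reference named character genome.
#' @param aln tumor alignment data.frame.
#' @param cfg an [sv_config()].
#' @return on success, a list with `chrom1`, `pos1`, `dir1`, `chrom2`,
#'   `pos2`, `dir2`, `inserted_seq`, `svtype`, `homlen`, `consensus`,
#'   `read_ids`; on failure, a list with `failure` giving the reason.
#' @export
refine_candidate <- function(cluster, reference, aln, cfg = sv_config()) {
  segs <- extract_junction_segments(cluster, aln, cfg)
  if (nrow(segs) < 1L) return(list(failure = "no_segments"))
  cons <- build_consensus(segs, cfg)
  if (cons$flag == "discordant") return(list(failure = "discordant_segments"))

  pad <- cfg$flank + cfg$refine_window
  w1a <- max(0L, cluster$bp1_lo - pad)
  w1b <- min(nchar(reference[[cluster$chrom1]]), cluster$bp1_hi + 1L + pad)
  w2a <- max(0L, cluster$bp2_lo - pad)
  w2b <- min(nchar(reference[[cluster$chrom2]]), cluster$bp2_hi + 1L + pad)
  ref1 <- genome_slice(reference, cluster$chrom1, w1a, w1b)
  ref2 <- genome_slice(reference, cluster$chrom2, w2a, w2b)
  if (cluster$dir1 == "-") ref1 <- revcomp(ref1)
  if (cluster$dir2 == "+") ref2 <- revcomp(ref2)

  res <- jump_sw_align(cons$seq, ref1, ref2, cfg)
  if (is.na(res$jump_score)) return(list(failure = "no_jump_alignment"))
  span1 <- res$q_end1 - res$q_start1
  span2 <- res$q_end2 - res$q_start2
  if (span1 < cfg$min_span || span2 < cfg$min_span)
    return(list(failure = "short_junction_span"))
  aligned <- span1 + span2
  if (res$jump_score < cfg$min_jump_identity * cfg$match * aligned)
    return(list(failure = "low_consensus_score"))

  pos1 <- if (cluster$dir1 == "+") w1a + res$r1_end - 1L else w1b - res$r1_end
  pos2 <- if (cluster$dir2 == "-") w2a + res$r2_start else w2b - 1L - res$r2_start
  inserted <- substr(cons$seq, res$q_end1 + 1L, res$q_start2)

  # micro-homology: bases entering the junction that also match ref2 just
  # before the resumption point (attributable to either side). For a
  # non-empty insert the comparison starts from the insert's tail -
  # comparing the reference flank would degenerate for blunt insertions,
  # where the bases left of both junction sides are identical by
  # construction.
  hom <- 0L
  qh <- res$q_start2
  while (qh - hom > 0L && res$r2_start - hom > 0L &&
         substr(cons$seq, qh - hom, qh - hom) ==
         substr(ref2, res$r2_start - hom, res$r2_start - hom) &&
         hom < 200L) hom <- hom + 1L
  if (nzchar(inserted)) hom <- min(hom, nchar(inserted))

  rec <- list(chrom1 = cluster$chrom1, pos1 = pos1, dir1 = cluster$dir1,
              chrom2 = cluster$chrom2, pos2 = pos2, dir2 = cluster$dir2,
              inserted_seq = inserted, homlen = hom,
              consensus = cons$seq, read_ids = cluster$read_ids)
  rec$svtype <- svtype_of(rec$chrom1, rec$pos1, rec$dir1,
                          rec$chrom2, rec$pos2, rec$dir2, nchar(inserted))
  # canonical side order for junctions that are not insertion-like
  if (rec$svtype != "INS" &&
      (rec$chrom1 > rec$chrom2 ||
       (rec$chrom1 == rec$chrom2 && rec$pos1 > rec$pos2))) {
    rec2 <- rec
    rec2$chrom1 <- rec$chrom2; rec2$pos1 <- rec$pos2; rec2$dir1 <- rec$dir2
    rec2$chrom2 <- rec$chrom1; rec2$pos2 <- rec$pos1; rec2$dir2 <- rec$dir1
    rec2$inserted_seq <- if (nzchar(inserted)) revcomp(inserted) else ""
    rec <- rec2
  }
  rec
}

#' SV class from breakpoint geometry
#'
#' Directions `(+,-)` are a colinear adjacency: a deletion when the skipped
#' reference exceeds the inserted sequence, otherwise an insertion.
#' `(-,+)` is a duplication-type adjacency, equal directions an inversion
#' junction, and differing chromosomes a translocation.
#'
#' @param chrom1,pos1,dir1,chrom2,pos2,dir2 breakpoint pair.
#' @param insert_len length of the inserted sequence.
#' @return one of `"DEL"`, `"INS"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @export
svtype_of <- function(chrom1, pos1, dir1, chrom2, pos2, dir2, insert_len = 0L) {
  if (chrom1 != chrom2) return("TRA")
  d <- paste0(dir1, dir2)
  if (d %in% c("++", "--")) return("INV")
  if (d == "-+") return("DUP")
  lo <- min(pos1, pos2); hi <- max(pos1, pos2)
  gap <- if (dir1 == "+") pos2 - pos1 - 1L else pos1 - pos2 - 1L
  if (insert_len > gap) "INS" else "DEL"
}
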