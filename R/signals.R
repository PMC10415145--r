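# Stage 1-2 of the canonical SV caller: per-read junction signals from CIGAR
# indels and split alignments, single-linkage clustering, and subtraction of
# control / panel-of-normals evidence.
#
# Breakpoint direction convention (shared package-wide): at a breakpoint
# (chrom, pos, dir), dir "+" means the SV adjacency retains the reference up
# to and including pos and leaves it moving right; dir "-" means pos is the
# first retained base and the adjacency leaves moving left.

#' @noRd
empty_signals <- function() {
  data.frame(read_id = character(), chrom1 = character(), pos1 = integer(),
             dir1 = character(), chrom2 = character(), pos2 = integer(),
             dir2 = character(), insert_len = integer(), source = character(),
             q1 = integer(), q2 = integer(), frame = character(),
             swapped = logical(), rec = integer(), sample = character(),
             stringsAsFactors = FALSE)
}

#' Extract per-read SV junction signals
#'
#' One signal per deletion/insertion CIGAR operation at or above
#' `min_indel_size`, and one per adjacent pair of split-alignment segments of
#' the same read (junction orientation derived from segment strands and clip
#' structure). `q1`/`q2` are query offsets bracketing the junction, in the
#' frame named by `frame` ("stored" = the generating record's SEQ
#' orientation; "original" = the sequenced read's orientation).
#'
#' @param aln alignment data.frame from one sample ([read_alignments()]).
#' @param min_indel_size smallest CIGAR indel that becomes a signal.
#' @param known_chroms optional character vector; split segments on other
#'   chromosomes are skipped and counted in `attr(, "n_skipped")`.
#' @return signal data.frame, one row per (read, junction), deduplicated.
#' @export
parse_sv_signals <- function(aln, min_indel_size = 50L, known_chroms = NULL) {
  if (!nrow(aln)) return(empty_signals())
  aln$.row <- seq_len(nrow(aln))
  sigs <- vector("list", 64L); ns <- 0L
  add <- function(df) { ns <<- ns + 1L; sigs[[ns]] <<- df }
  n_skipped <- 0L

  # --- CIGAR indel signals ------------------------------------------------
  for (i in seq_len(nrow(aln))) {
    ops <- parse_cigar(aln$cigar[i])
    if (is.null(ops)) next
    big <- which(ops$op %in% c("I", "D") & ops$len >= min_indel_size)
    if (!length(big)) next
    rlen <- cumsum(ifelse(ops$op %in% c("M", "=", "X", "D", "N"), ops$len, 0L))
    qlen <- cumsum(ifelse(ops$op %in% c("M", "=", "X", "I", "S"), ops$len, 0L))
    for (k in big) {
      rpos <- aln$start[i] + (if (k > 1L) rlen[k - 1L] else 0L)
      qpos <- if (k > 1L) qlen[k - 1L] else 0L
      if (ops$op[k] == "D") {
        add(data.frame(read_id = aln$read_id[i], chrom1 = aln$chrom[i],
                       pos1 = rpos - 1L, dir1 = "+", chrom2 = aln$chrom[i],
                       pos2 = rpos + ops$len[k], dir2 = "-", insert_len = 0L,
                       source = "cigar_indel", q1 = qpos, q2 = qpos,
                       frame = "stored", swapped = FALSE, rec = i,
                       sample = aln$sample[i], stringsAsFactors = FALSE))
      } else {
        add(data.frame(read_id = aln$read_id[i], chrom1 = aln$chrom[i],
                       pos1 = rpos - 1L, dir1 = "+", chrom2 = aln$chrom[i],
                       pos2 = rpos, dir2 = "-", insert_len = ops$len[k],
                       source = "cigar_indel", q1 = qpos, q2 = qpos + ops$len[k],
                       frame = "stored", swapped = FALSE, rec = i,
                       sample = aln$sample[i], stringsAsFactors = FALSE))
      }
    }
  }

  # --- split-alignment signals -------------------------------------------
  multi <- split(seq_len(nrow(aln)), aln$read_id)
  multi <- multi[lengths(multi) > 1L]
  for (rows in multi) {
    segs <- lapply(rows, function(i) {
      ops <- parse_cigar(aln$cigar[i])
      if (is.null(ops)) return(NULL)
      cl <- cigar_clips(ops)
      qlen <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
      L <- cl[["left"]] + qlen + cl[["right"]]
      qs <- if (aln$strand[i] == "+") cl[["left"]] else cl[["right"]]
      list(i = i, chrom = aln$chrom[i], start = aln$start[i],
           end = aln$end[i], strand = aln$strand[i],
           qs = qs, qe = qs + qlen, L = L,
           primary = !aln$is_supplementary[i])
    })
    segs <- Filter(Negate(is.null), segs)
    if (length(segs) < 2L) next
    if (!is.null(known_chroms)) {
      drop <- vapply(segs, function(s) !(s$chrom %in% known_chroms), TRUE)
      n_skipped <- n_skipped + sum(drop)
      segs <- segs[!drop]
      if (length(segs) < 2L) next
    }
    segs <- segs[order(vapply(segs, `[[`, 0L, "qs"))]
    prim <- which(vapply(segs, `[[`, TRUE, "primary"))[1]
    if (is.na(prim)) prim <- 1L
    for (k in seq_len(length(segs) - 1L)) {
      A <- segs[[k]]; B <- segs[[k + 1L]]
      bpA <- if (A$strand == "+") list(chrom = A$chrom, pos = A$end - 1L, dir = "+")
             else list(chrom = A$chrom, pos = A$start, dir = "-")
      bpB <- if (B$strand == "+") list(chrom = B$chrom, pos = B$start, dir = "-")
             else list(chrom = B$chrom, pos = B$end - 1L, dir = "+")
      swapped <- bpA$chrom > bpB$chrom ||
        (bpA$chrom == bpB$chrom && bpA$pos > bpB$pos)
      bp1 <- if (swapped) bpB else bpA
      bp2 <- if (swapped) bpA else bpB
      add(data.frame(read_id = aln$read_id[A$i], chrom1 = bp1$chrom,
                     pos1 = bp1$pos, dir1 = bp1$dir, chrom2 = bp2$chrom,
                     pos2 = bp2$pos, dir2 = bp2$dir,
                     insert_len = max(0L, B$qs - A$qe),
                     source = "split_alignment", q1 = A$qe, q2 = B$qs,
                     frame = "original", swapped = swapped,
                     rec = segs[[prim]]$i, sample = aln$sample[A$i],
                     stringsAsFactors = FALSE))
    }
  }

  out <- if (ns) do.call(rbind, sigs[seq_len(ns)]) else empty_signals()
  key <- paste(out$read_id, out$chrom1, out$pos1, out$dir1,
               out$chrom2, out$pos2, out$dir2, out$source)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Cluster junction signals into SV candidates
#'
#' Two signals join one cluster iff they share the chromosome pair and
#' direction pair and both breakpoints are within `margin` of each other;
#' linkage is transitive (single linkage), so chained signals merge.
#'
#' @param signals tumor signal data.frame from [parse_sv_signals()].
#' @param margin clustering distance in bp.
#' @param min_reads clusters with fewer distinct supporting reads are
#'   discarded early.
#' @return list of clusters; each is a list with the member `signals`,
#'   breakpoint ranges `bp1_lo/bp1_hi/bp2_lo/bp2_hi` (positions, inclusive),
#'   `chrom1/dir1/chrom2/dir2`, `insert_med` and distinct `read_ids`.
#' @export
cluster_signals <- function(signals, margin = 200L, min_reads = 3L) {
  if (!nrow(signals)) return(list())
  key <- paste(signals$chrom1, signals$dir1, signals$chrom2, signals$dir2)
  out <- list()
  for (grp in split(seq_len(nrow(signals)), key)) {
    n <- length(grp)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    p1 <- signals$pos1[grp]; p2 <- signals$pos2[grp]
    ord <- order(p1)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (b <= a) next
      i <- ord[a]; j <- ord[b]
      if (p1[j] - p1[i] > margin) break
      if (abs(p2[i] - p2[j]) <= margin) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    for (members in split(seq_len(n), roots)) {
      sub <- signals[grp[members], , drop = FALSE]
      ids <- unique(sub$read_id)
      if (length(ids) < min_reads) next
      out[[length(out) + 1L]] <- list(
        signals = sub,
        chrom1 = sub$chrom1[1], dir1 = sub$dir1[1],
        chrom2 = sub$chrom2[1], dir2 = sub$dir2[1],
        bp1_lo = min(sub$pos1), bp1_hi = max(sub$pos1),
        bp2_lo = min(sub$pos2), bp2_hi = max(sub$pos2),
        insert_med = as.integer(round(median(sub$insert_len))),
        read_ids = ids)
    }
  }
  # deterministic order: by genomic position of breakpoint 1
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "chrom1"),
                 vapply(out, `[[`, 0L, "bp1_lo"),
                 vapply(out, `[[`, "", "chrom2"),
                 vapply(out, `[[`, 0L, "bp2_lo"))
    out <- out[ord]
  }
  out
}

#' Remove clusters with apparent support in the control or panel
#'
#' A cluster is removed iff any control or panel signal shares the
#' chromosome/direction pair and falls within `margin` of both breakpoint
#' ranges. Control signals should be parsed with a permissive size threshold
#' (see `control_parse_indel_size` in [sv_config()]): a germline SV narrowly
#' missing the tumor-side threshold in the control must still subtract.
#'
#' @param clusters list from [cluster_signals()].
#' @param control_signals,panel_signals signal data.frames (panel may be
#'   `NULL`).
#' @param margin match margin in bp.
#' @return the retained clusters, each annotated with `control_matches`.
#' @export
filter_by_control <- function(clusters, control_signals, panel_signals = NULL,
                              margin = 200L) {
  ctl <- control_signals
  if (!is.null(panel_signals) && nrow(panel_signals))
    ctl <- rbind(ctl, panel_signals)
  if (is.null(ctl) || !nrow(ctl)) {
    return(lapply(clusters, function(cl) { cl$control_matches <- 0L; cl }))
  }
  ckey <- paste(ctl$chrom1, ctl$dir1, ctl$chrom2, ctl$dir2)
  kept <- list()
  for (cl in clusters) {
    k <- paste(cl$chrom1, cl$dir1, cl$chrom2, cl$dir2)
    idx <- which(ckey == k)
    hit <- idx[ctl$pos1[idx] >= cl$bp1_lo - margin &
               ctl$pos1[idx] <= cl$bp1_hi + margin &
               ctl$pos2[idx] >= cl$bp2_lo - margin &
               ctl$pos2[idx] <= cl$bp2_hi + margin]
    cl$control_matches <- length(hit)
    if (!length(hit)) kept[[length(kept) + 1L]] <- cl
  }
  kept
}

#' Candidate clusters as a summary table
#'
#' Tabular view of [cluster_signals()] output, the staged intermediate a
#' debugging run can write to TSV.
#'
#' @param clusters list of clusters.
#' @return data.frame with one row per cluster.
#' @export
clusters_to_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(chrom1 = character(), bp1_lo = integer(),
                      bp1_hi = integer(), dir1 = character(),
                      chrom2 = character(), bp2_lo = integer(),
                      bp2_hi = integer(), dir2 = character(),
                      insert_med = integer(), n_reads = integer(),
                      read_ids = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    chrom1 = vapply(clusters, `[[`, "", "chrom1"),
    bp1_lo = vapply(clusters, `[[`, 0L, "bp1_lo"),
    bp1_hi = vapply(clusters, `[[`, 0L, "bp1_hi"),
    dir1 = vapply(clusters, `[[`, "", "dir1"),
    chrom2 = vapply(clusters, `[[`, "", "chrom2"),
    bp2_lo = vapply(clusters, `[[`, 0L, "bp2_lo"),
    bp2_hi = vapply(clusters, `[[`, 0L, "bp2_hi"),
    dir2 = vapply(clusters, `[[`, "", "dir2"),
    insert_med = vapply(clusters, `[[`, 0L, "insert_med"),
    n_reads = vapply(clusters, function(cl) length(cl$read_ids), 0L),
    read_ids = vapply(clusters, function(cl)
      paste(sort(cl$read_ids), collapse = ","), ""),
    stringsAsFactors = FALSE)
}
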