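# End-to-end canonical SV calling: parsing -> clustering -> control
# subtraction -> refinement -> validation -> final filters.

#' Call somatic canonical SVs from paired alignments
#'
#' Runs the four-stage canonical caller. Tumor junction signals are parsed
#' at the permissive internal threshold, clustered, and subtracted against
#' control (and optional panel-of-normals) signals parsed at an even more
#' permissive threshold. Each surviving cluster is refined to single-base
#' breakpoints and an error-corrected inserted sequence, then every read
#' near the breakpoints in both samples is re-genotyped against the putative
#' SV segment; candidates with at least `min_tumor_support` tumor variant
#' reads and no control variant reads survive, subject to the final size and
#' simple-repeat filters.
#'
#' @param tumor_aln,control_aln alignment data.frames
#'   ([read_alignments()] or [simulate_reads()]).
#' @param reference named character genome.
#' @param panel_aln optional list of panel-of-normals alignment data.frames.
#' @param simple_repeats optional `GRanges` of simple-repeat intervals.
#' @param cfg an [sv_config()].
#' @param verbose print stage progress.
#' @return list with `svs` (canonical SV data.frame) and `audit`
#'   (per-candidate fate: refined/validated or the rejection reason).
#' @export
call_somatic_svs <- function(tumor_aln, control_aln, reference,
                             panel_aln = NULL, simple_repeats = NULL,
                             cfg = sv_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tsig <- parse_sv_signals(tumor_aln, min_indel_size = cfg$parse_indel_size,
                           known_chroms = names(reference))
  csig <- parse_sv_signals(control_aln,
                           min_indel_size = cfg$control_parse_indel_size,
                           known_chroms = names(reference))
  psig <- NULL
  if (!is.null(panel_aln)) {
    psig <- do.call(rbind, lapply(panel_aln, parse_sv_signals,
                                  min_indel_size = cfg$control_parse_indel_size,
                                  known_chroms = names(reference)))
  }
  say("signals: %d tumor, %d control", nrow(tsig), nrow(csig))
  clusters <- cluster_signals(tsig, margin = cfg$cluster_margin,
                              min_reads = cfg$min_tumor_read_pre)
  say("clusters: %d", length(clusters))
  clusters <- filter_by_control(clusters, csig, psig,
                                margin = cfg$control_margin)
  say("after control subtraction: %d", length(clusters))

  records <- list(); audit <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ref_rec <- refine_candidate(cl, reference, tumor_aln, cfg)
    loc <- sprintf("%s:%d-%s:%d %s%s", cl$chrom1, cl$bp1_lo, cl$chrom2,
                   cl$bp2_lo, cl$dir1, cl$dir2)
    if (!is.null(ref_rec$failure)) {
      audit[[length(audit) + 1L]] <- data.frame(
        candidate = loc, stage = "refine", outcome = ref_rec$failure,
        stringsAsFactors = FALSE)
      next
    }
    val <- validate_candidate(ref_rec, tumor_aln, control_aln, reference, cfg)
    if (!is.null(val$failure)) {
      audit[[length(audit) + 1L]] <- data.frame(
        candidate = loc, stage = "validate", outcome = val$failure,
        stringsAsFactors = FALSE)
      next
    }
    records[[length(records) + 1L]] <- val
    audit[[length(audit) + 1L]] <- data.frame(
      candidate = loc, stage = "validate", outcome = "kept",
      stringsAsFactors = FALSE)
  }
  svs <- if (length(records)) do.call(rbind, records) else empty_sv_records()
  # a junction can be discovered from both sides (e.g. both inversion
  # junctions feed one adjacency); collapse exact duplicates
  if (nrow(svs)) {
    key <- paste(svs$chr1, svs$pos1, svs$dir1, svs$chr2, svs$pos2, svs$dir2)
    svs <- svs[!duplicated(key), , drop = FALSE]
  }
  svs <- final_filters(svs, simple_repeats, cfg)
  rownames(svs) <- NULL
  say("final: %d SVs", nrow(svs))
  list(svs = svs,
       audit = if (length(audit)) do.call(rbind, audit) else
         data.frame(candidate = character(), stage = character(),
                    outcome = character(), stringsAsFactors = FALSE))
}
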