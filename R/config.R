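#' Pipeline configuration
#'
#' All tunable thresholds of the caller in one place. Values can be
#' overridden by name; unknown names are an error, so typos do not silently
#' fall back to defaults.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Defaults (units are base pairs unless noted):
#' \describe{
#'   \item{min_indel_size}{100 - smallest deletion/insertion reported.}
#'   \item{parse_indel_size}{50 - internal CIGAR indel signal threshold;
#'     parsing below the reporting size lets consensus refinement recover
#'     true sizes near the boundary.}
#'   \item{control_parse_indel_size}{25 - permissive signal threshold for the
#'     matched control / panel, so germline SVs narrowly missing the tumor
#'     threshold in the control still subtract.}
#'   \item{cluster_margin}{200 - single-linkage clustering distance.}
#'   \item{control_margin}{200 - breakpoint match margin for control
#'     subtraction.}
#'   \item{min_tumor_read_pre}{3 - distinct tumor reads required for a
#'     cluster to survive the pre-filter.}
#'   \item{flank}{300 - read bases extracted on each side of a junction.}
#'   \item{min_flank}{50 - smallest usable flank for an extracted segment.}
#'   \item{consensus_rounds}{2 - polishing iterations.}
#'   \item{consensus_max_reads}{20 - cap on segments entering the consensus.}
#'   \item{consensus_discord_identity}{0.8 - mean identity to the centroid
#'     below which a candidate is flagged as a discordant mixture.}
#'   \item{match, mismatch, gap_open, gap_extend}{2, -4, -4, -2 - alignment
#'     scores; a gap of length k costs gap_open + k * gap_extend.}
#'   \item{jump_penalty, per_inserted_base}{0, 0 - cost of the one-time jump
#'     and per-base cost of unaligned (inserted) query between the layers.}
#'   \item{refine_window}{200 - padding added beyond the extraction flank
#'     around each breakpoint range when building reference windows.}
#'   \item{min_jump_identity}{0.6 - jump alignment must reach this fraction
#'     of the maximal score over its aligned (non-inserted) query length.}
#'   \item{min_span}{50 - aligned bases required on each side of a junction.}
#'   \item{validate_flank}{300 - flank length of the putative SV segment.}
#'   \item{validate_delta}{0.05 - normalized score margin separating variant
#'     from reference reads; in-between reads are ambiguous.}
#'   \item{min_tumor_support, max_control_support}{3, 0 - final keep rule.}
#'   \item{simple_repeat_pad}{10 - padding when testing confinement of a
#'     deletion/insertion within one simple-repeat interval.}
#'   \item{min_clip}{500 - soft-clip length starting a breakend signal.}
#'   \item{control_min_clip}{250 - permissive clip threshold for control.}
#'   \item{bnd_cluster_margin}{50 - breakend clustering distance.}
#'   \item{bnd_inner_margin}{100 - aligned bases kept inside the breakpoint
#'     when building the breakend contig.}
#'   \item{max_contig}{5000 - breakend contig length cap.}
#'   \item{bnd_dup_margin}{200 - breakend dropped when this close to an
#'     already-called canonical breakpoint.}
#'   \item{rescue_coverage}{0.8 - contig fraction that must align uniquely to
#'     the reference to rescue a canonical SV.}
#'   \item{repeat_coverage}{0.6 - contig fraction annotated as satellite /
#'     simple repeat / telomere for those classes.}
#'   \item{element_min_match}{200 - LINE1/Alu/virus match length for
#'     mediated-rearrangement and virus classes.}
#'   \item{distant_min}{10000 - minimal distance for "distant locus" in
#'     mediated-rearrangement classification.}
#'   \item{insert_coverage}{0.8 - mobile-element or transcript coverage for
#'     solo MEI / processed pseudogene classes.}
#'   \item{min_exon_junctions}{2 - spliced junctions a pseudogene alignment
#'     must span.}
#'   \item{source_window}{10000 - transduction source attribution window
#'     downstream of a LINE1 source element.}
#'   \item{tandem_adjacency}{1000 - residue hit within this distance of the
#'     insertion site means tandem duplication.}
#'   \item{polya_window, polya_min_len, polya_min_frac}{30, 10, 0.8 - polyA
#'     tail scan parameters.}
#'   \item{min_tsd, max_tsd}{5, 50 - reported target-site duplication range.}
#'   \item{hor_min_identity}{50 - percent identity below which a monomer
#'     block is a gap.}
#'   \item{hor_min_call}{0.3 - best HOR score needed before an
#'     interchromosomal assignment is made.}
#' }
#'
#' @return a named list of settings (class `svlr_config`).
#' @export
#' @examples
#' cfg <- sv_config(cluster_margin = 100)
#' cfg$cluster_margin
sv_config <- function(...) {
  cfg <- list(
    min_indel_size = 100L,
    parse_indel_size = 50L,
    control_parse_indel_size = 25L,
    cluster_margin = 200L,
    control_margin = 200L,
    min_tumor_read_pre = 3L,
    flank = 300L,
    min_flank = 50L,
    consensus_rounds = 2L,
    consensus_max_reads = 20L,
    consensus_discord_identity = 0.8,
    match = 2, mismatch = -4, gap_open = -4, gap_extend = -2,
    jump_penalty = 0, per_inserted_base = 0,
    refine_window = 200L,
    min_jump_identity = 0.6,
    min_span = 50L,
    validate_flank = 300L,
    validate_delta = 0.05,
    min_tumor_support = 3L,
    max_control_support = 0L,
    simple_repeat_pad = 10L,
    min_clip = 500L,
    control_min_clip = 250L,
    bnd_cluster_margin = 50L,
    bnd_inner_margin = 100L,
    max_contig = 5000L,
    bnd_dup_margin = 200L,
    rescue_coverage = 0.8,
    repeat_coverage = 0.6,
    element_min_match = 200L,
    distant_min = 10000L,
    insert_coverage = 0.8,
    min_exon_junctions = 2L,
    source_window = 10000L,
    tandem_adjacency = 1000L,
    polya_window = 30L, polya_min_len = 10L, polya_min_frac = 0.8,
    min_tsd = 5L, max_tsd = 50L,
    hor_min_identity = 50,
    hor_min_call = 0.3
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "svlr_config")
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are coerced
#' to the type of the corresponding [sv_config()] default.
#'
#' @param path file path.
#' @return an `svlr_config` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(sv_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  defaults <- sv_config()
  over <- lapply(seq_along(keys), function(i) {
    d <- defaults[[keys[i]]]
    if (is.null(d)) stop("unknown config key: ", keys[i])
    if (is.integer(d)) as.integer(vals[i])
    else if (is.numeric(d)) as.numeric(vals[i])
    else vals[i]
  })
  names(over) <- keys
  do.call(sv_config, over)
}
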