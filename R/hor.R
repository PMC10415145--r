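# Centromeric higher-order repeat (HOR) analysis: decomposition of
# satellite-classified breakend contigs into alpha-satellite monomers and
# the per-chromosome HOR match score. A monomer block contributes
# (end - start) * identity / 100 when its predecessor relationship is
# consistent with the chromosome's canonical monomer order; the sum divided
# by the contig length is the HOR match score.

#' Decompose a contig into satellite monomer blocks
#'
#' The contig is tiled left to right: at each boundary every monomer is fit
#' with an end-free global alignment (the monomer may be truncated at the
#' contig end) and the best-scoring monomer claims the block. Stretches
#' where no monomer reaches `hor_min_identity` percent identity become gap
#' blocks. Both contig orientations are tried; the better one is reported.
#'
#' @param contig character scalar.
#' @param monomers named character vector of monomer consensi.
#' @param cfg an [sv_config()].
#' @return data.frame of blocks with `monomer` (`NA` for gaps), `start`,
#'   `end` (0-based half-open, in the reported orientation), `identity`
#'   (percent); `attr(,"orientation")` gives the orientation used.
#' @export
decompose_monomers <- function(contig, monomers, cfg = sv_config()) {
  empty <- data.frame(monomer = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE)
  mlen <- nchar(monomers)
  if (nchar(contig) < min(mlen)) {
    attr(empty, "orientation") <- "+"
    return(empty)
  }
  best <- NULL; best_score <- -Inf; best_orient <- "+"
  for (orient in c("+", "-")) {
    s <- if (orient == "+") contig else revcomp(contig)
    blocks <- tile_monomers(s, monomers, cfg)
    sc <- sum((blocks$end - blocks$start) * blocks$identity / 100,
              na.rm = TRUE)
    if (sc > best_score) { best <- blocks; best_score <- sc; best_orient <- orient }
  }
  attr(best, "orientation") <- best_orient
  best
}

#' @noRd
tile_monomers <- function(s, monomers, cfg) {
  n <- nchar(s)
  mlen <- nchar(monomers)
  maxm <- max(mlen); minm <- min(mlen)
  step <- 25L
  out <- list()
  i <- 0L
  gap_start <- NA_integer_
  while (n - i >= max(30L, as.integer(0.4 * minm))) {
    win <- substr(s, i + 1L, min(n, i + maxm + 40L))
    bestm <- NULL
    for (mi in seq_along(monomers)) {
      al <- nw_align(monomers[[mi]], win, cfg,
                     free_begin_q = FALSE, free_begin_r = FALSE,
                     free_end_q = TRUE, free_end_r = TRUE)
      if (is.na(al$score)) next
      if (is.null(bestm) || al$score > bestm$score) {
        bestm <- list(score = al$score, id = names(monomers)[mi],
                      consumed = al$r_end, identity = al$identity * 100)
      }
    }
    ok <- !is.null(bestm) && bestm$identity >= cfg$hor_min_identity &&
      bestm$consumed >= max(30L, as.integer(0.4 * minm))
    if (ok) {
      if (!is.na(gap_start)) {
        out[[length(out) + 1L]] <- data.frame(
          monomer = NA_character_, start = gap_start, end = i, identity = 0,
          stringsAsFactors = FALSE)
        gap_start <- NA_integer_
      }
      out[[length(out) + 1L]] <- data.frame(
        monomer = bestm$id, start = i, end = i + bestm$consumed,
        identity = bestm$identity, stringsAsFactors = FALSE)
      i <- i + bestm$consumed
    } else {
      if (is.na(gap_start)) gap_start <- i
      i <- i + step
    }
  }
  if (!is.na(gap_start) || i < n) {
    gs <- if (is.na(gap_start)) i else gap_start
    if (n > gs)
      out[[length(out) + 1L]] <- data.frame(
        monomer = NA_character_, start = gs, end = n, identity = 0,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(monomer = character(), start = integer(),
                      end = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Higher-order repeat match score
#'
#' For each monomer block whose predecessor relationship is consistent with
#' the canonical cyclic monomer order (the first block is always
#' consistent; gap blocks contribute nothing and break adjacency),
#' `(end - start) * identity / 100` is added; the sum divided by the contig
#' length is the score.
#'
#' @param matches block data.frame from [decompose_monomers()].
#' @param hor_order character vector giving the canonical monomer order
#'   (cyclic).
#' @param contig_len contig length in bp.
#' @return score in `[0, 1]`.
#' @export
hor_match_score <- function(matches, hor_order, contig_len) {
  if (!nrow(matches) || contig_len <= 0L) return(0)
  succ <- setNames(c(hor_order[-1L], hor_order[1L]), hor_order)
  total <- 0
  prev <- NULL          # monomer id of the immediately preceding block
  first <- TRUE
  for (i in seq_len(nrow(matches))) {
    m <- matches$monomer[i]
    if (is.na(m)) { prev <- NULL; next }   # gap breaks adjacency
    consistent <- first ||
      (!is.null(prev) && !is.na(succ[prev]) && succ[[prev]] == m)
    if (consistent)
      total <- total + (matches$end[i] - matches$start[i]) *
        matches$identity[i] / 100
    prev <- if (m %in% names(succ)) m else NULL
    first <- FALSE
  }
  total / contig_len
}

#' Per-chromosome HOR profile of a breakend contig
#'
#' The contig is decomposed against every chromosome's monomer set and
#' scored against that chromosome's canonical HOR; the best-scoring
#' chromosome is reported, with an interchromosomal flag when it differs
#' from the breakend's own chromosome.
#'
#' @param contig character scalar (the beyond-breakpoint contig).
#' @param bp_chrom chromosome of the breakend.
#' @param catalog [make_hor_catalog()]-shaped list: per chromosome,
#'   `monomers` and `order`.
#' @param cfg an [sv_config()].
#' @return list with `scores` (named numeric), `best_chrom` (NA when no
#'   score reaches `hor_min_call`), and `interchromosomal`.
#' @export
hor_profile <- function(contig, bp_chrom, catalog, cfg = sv_config()) {
  scores <- vapply(names(catalog), function(ch) {
    dec <- decompose_monomers(contig, catalog[[ch]]$monomers, cfg)
    hor_match_score(dec, catalog[[ch]]$order, nchar(contig))
  }, 0)
  best <- names(scores)[which.max(scores)]
  callable <- max(scores) >= cfg$hor_min_call
  list(scores = scores,
       best_chrom = if (callable) best else NA_character_,
       interchromosomal = callable && !is.na(bp_chrom) && best != bp_chrom)
}
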