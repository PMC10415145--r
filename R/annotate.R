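# Sequence annotation shared by the single-breakend and insertion
# classifiers: local-alignment annotation of a contig against a repeat /
# virus / transcript library, and seed-and-extend placement of a contig on
# the reference genome with a uniqueness call.

#' Annotate a sequence against a consensus library
#'
#' Every library entry is aligned locally (both orientations) against the
#' sequence; matches are masked and realignment repeats until scores drop,
#' so tandem arrays yield one interval per unit. Library names follow the
#' RepeatMasker `name#class` convention; the class is split out.
#'
#' @param seq character scalar to annotate.
#' @param library named character vector of consensus sequences.
#' @param min_match smallest reported match length in bp.
#' @param min_identity smallest reported match identity (0-1).
#' @param max_hits_per_entry safety cap on matches per library entry.
#' @param cfg an [sv_config()] (alignment scores).
#' @return data.frame with `start`, `end` (0-based half-open on `seq`),
#'   `label`, `class`, `identity`, `strand`, sorted by `start`.
#' @export
annotate_repeats <- function(seq, library, min_match = 50L,
                             min_identity = 0.7, max_hits_per_entry = 60L,
                             cfg = sv_config()) {
  out <- list()
  n <- nchar(seq)
  min_score <- min_match * cfg$match * 0.5
  for (nm in names(library)) {
    entry <- library[[nm]]
    label <- sub("#.*", "", nm)
    class <- if (grepl("#", nm)) sub(".*#", "", nm) else ""
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") entry else revcomp(entry)
      masked <- seq
      for (it in seq_len(max_hits_per_entry)) {
        al <- sw_align(masked, probe, cfg)
        if (al$score < min_score) break
        len <- al$q_end - al$q_start
        # identity of the matched stretch via a bounded global realignment
        sub_q <- substr(masked, al$q_start + 1L, al$q_end)
        sub_r <- substr(probe, al$r_start + 1L, al$r_end)
        gl <- nw_align(sub_q, sub_r, cfg, free_begin_q = FALSE,
                       free_begin_r = FALSE, free_end_q = FALSE,
                       free_end_r = FALSE)
        idt <- gl$identity
        if (len >= min_match && idt >= min_identity) {
          out[[length(out) + 1L]] <- data.frame(
            start = al$q_start, end = al$q_end, label = label,
            class = class, identity = idt, strand = strand,
            stringsAsFactors = FALSE)
        }
        masked <- paste0(substr(masked, 1L, al$q_start),
                         strrep("N", len),
                         substr(masked, al$q_end + 1L, n))
        if (len < min_match) break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), label = character(),
                      class = character(), identity = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Fraction of `seq_len` covered by annotation intervals whose class matches
# `pattern` (regular expression).
#' @noRd
class_coverage <- function(ann, seq_len, pattern) {
  hit <- ann[grepl(pattern, ann$class) | grepl(pattern, ann$label), ,
             drop = FALSE]
  if (!nrow(hit) || seq_len == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(hit$start + 1L, hit$end))
  sum(IRanges::width(ir)) / seq_len
}

# Coverage of the telomeric hexamer repeat, either strand, as the fraction
# of positions inside TTAGGG/CCCTAA matches.
#' @noRd
telomere_coverage <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(0)
  s <- Biostrings::DNAString(seq)
  cov <- IRanges::IRanges()
  for (motif in c("TTAGGG", "CCCTAA")) {
    m <- Biostrings::matchPattern(motif, s)
    if (length(m)) cov <- c(cov, IRanges::IRanges(Biostrings::start(m),
                                                  Biostrings::end(m)))
  }
  if (!length(cov)) return(0)
  sum(IRanges::width(IRanges::reduce(cov))) / n
}

#' Place a sequence on the reference genome by seed-and-extend
#'
#' Sampled k-mers of the query are located exactly on each chromosome
#' strand (via Biostrings), clustered by alignment diagonal, and the best
#' cluster's window is refined with a local alignment. The placement is
#' `unique` when the runner-up diagonal cluster (beyond `sep` of the best)
#' collects fewer than half the seed hits of the best.
#'
#' @param query character scalar.
#' @param reference named character genome.
#' @param k seed length.
#' @param stride distance between sampled seeds.
#' @param sep minimal distance between distinct candidate loci.
#' @param cfg an [sv_config()].
#' @return `NULL` when nothing seeds; otherwise a list with `chrom`,
#'   `strand`, `r_start`, `r_end` (genome, 0-based half-open), `q_start`,
#'   `q_end`, `score`, `coverage` (aligned fraction of the query),
#'   `unique`, `n_seed_best`, `n_seed_second`.
#' @export
locate_sequence <- function(query, reference, k = 17L, stride = 29L,
                            sep = 2000L, cfg = sv_config()) {
  n <- nchar(query)
  if (n < k) return(NULL)
  starts <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    seeds <- vapply(starts, function(p) substr(qs, p, p + k - 1L), "")
    keep <- !grepl("N", seeds, fixed = TRUE)
    if (!any(keep)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[keep]))
    qpos <- starts[keep]
    for (chrom in names(reference)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(reference[[chrom]]))
      for (si in seq_along(m)) {
        sp <- Biostrings::start(m[[si]])
        if (!length(sp)) next
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, diag = sp - qpos[si],
          qpos = qpos[si], rpos = sp, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  h$bin <- paste(h$chrom, h$strand, round(h$diag / (sep / 2)))
  tab <- sort(table(h$bin), decreasing = TRUE)
  best_bin <- names(tab)[1]
  n_best <- as.integer(tab[1])
  # runner-up must be a genuinely different locus
  n_second <- 0L
  bh <- h[h$bin == best_bin, , drop = FALSE]
  bdiag <- median(bh$diag)
  for (b in names(tab)[-1]) {
    rh <- h[h$bin == b, , drop = FALSE]
    if (rh$chrom[1] != bh$chrom[1] || rh$strand[1] != bh$strand[1] ||
        abs(median(rh$diag) - bdiag) > sep) {
      n_second <- as.integer(tab[b]); break
    }
  }
  chrom <- bh$chrom[1]; strand <- bh$strand[1]
  clen <- nchar(reference[[chrom]])
  wa <- max(0L, as.integer(min(bh$rpos) - min(bh$qpos) - 200L))
  wb <- min(clen, as.integer(max(bh$rpos) + k + (n - max(bh$qpos)) + 200L))
  window <- genome_slice(reference, chrom, wa, wb)
  qs <- if (strand == "+") query else revcomp(query)
  al <- sw_align(qs, window, cfg)
  qa <- al$q_start; qb <- al$q_end
  if (strand == "-") { tmp <- n - qb; qb <- n - qa; qa <- tmp }
  list(chrom = chrom, strand = strand,
       r_start = wa + al$r_start, r_end = wa + al$r_end,
       q_start = qa, q_end = qb,
       score = al$score, coverage = (al$q_end - al$q_start) / n,
       unique = n_second < n_best / 2,
       n_seed_best = n_best, n_seed_second = n_second)
}
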