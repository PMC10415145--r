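# Shared low-level helpers: sequence arithmetic, CIGAR parsing, seeded RNG.

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' @keywords internal
#' @noRd
rand_dna <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 0-based half-open slice of a chromosome from a named character genome,
# clamped to the sequence ends.
#' @noRd
genome_slice <- function(genome, chrom, start0, end0) {
  s <- genome[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  n <- nchar(s)
  a <- max(0L, as.integer(start0))
  b <- min(n, as.integer(end0))
  if (b <= a) return("")
  substr(s, a + 1L, b)
}

# ---------------------------------------------------------------------------
# CIGAR handling. Parsed form: list(op = character, len = integer).
# ---------------------------------------------------------------------------

#' @noRd
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) return(NULL)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) return(NULL)  # malformed remainder
  n <- nchar(toks)
  list(op = substr(toks, n, n), len = as.integer(substr(toks, 1L, n - 1L)))
}

#' @noRd
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])

#' @noRd
cigar_query_len <- function(ops, clipped = TRUE) {
  keep <- c("M", "=", "X", "I", if (clipped) c("S", "H"))
  sum(ops$len[ops$op %in% keep])
}

#' @noRd
cigar_clips <- function(ops) {
  n <- length(ops$op)
  left <- if (ops$op[1] %in% c("S", "H")) ops$len[1] else 0L
  right <- if (n > 1L && ops$op[n] %in% c("S", "H")) ops$len[n] else 0L
  c(left = left, right = right)
}

#' @noRd
unparse_cigar <- function(op, len) paste0(len, op, collapse = "")

# Merge adjacent identical ops and drop zero-length ones.
#' @noRd
merge_cigar_ops <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return(list(op = character(), len = integer()))
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  list(op = op[!duplicated(grp)],
       len = as.integer(rowsum(as.numeric(len), grp)[, 1L]))
}

# Query offset (0-based, stored-SEQ frame) of the first query base aligned
# at or after reference position `pos` (0-based). Walks the CIGAR. When
# `pos` lies at or beyond the aligned end, the offset of the first base
# after the last aligned one is returned (trailing clips are not counted),
# so a breakpoint at the alignment edge maps to the clip boundary.
#' @noRd
query_offset_at <- function(start0, cigar, pos) {
  ops <- parse_cigar(cigar)
  if (is.null(ops)) return(NA_integer_)
  r <- start0; q <- 0L
  consumed_ref <- FALSE
  for (i in seq_along(ops$op)) {
    o <- ops$op[i]; l <- ops$len[i]
    if (o == "S") {
      if (consumed_ref) return(q)   # trailing clip: stop at aligned end
      q <- q + l
    } else if (o == "I") {
      q <- q + l
    } else if (o %in% c("M", "=", "X")) {
      if (pos < r + l) return(q + max(0L, pos - r))
      q <- q + l; r <- r + l; consumed_ref <- TRUE
    } else if (o %in% c("D", "N")) {
      if (pos < r + l) return(q)
      r <- r + l; consumed_ref <- TRUE
    }
  }
  q
}

# ---------------------------------------------------------------------------
# Thin R wrappers over the compiled aligners, applying a config's scores.
# ---------------------------------------------------------------------------

#' @noRd
sw_align <- function(query, ref, cfg = sv_config()) {
  cpp_sw(query, ref, cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend)
}

# score-only local alignment (no start coordinates; cheaper)
#' @noRd
sw_score <- function(query, ref, cfg = sv_config()) {
  cpp_sw_score(query, ref, cfg$match, cfg$mismatch, cfg$gap_open,
               cfg$gap_extend)$score
}

#' @noRd
nw_align <- function(query, ref, cfg = sv_config(),
                     free_begin_q = TRUE, free_begin_r = TRUE,
                     free_end_q = TRUE, free_end_r = TRUE,
                     band_offset = 0L, band_width = -1L) {
  cpp_nw(query, ref, cfg$match, cfg$mismatch, cfg$gap_open, cfg$gap_extend,
         free_begin_q, free_begin_r, free_end_q, free_end_r,
         as.integer(band_offset), as.integer(band_width))
}

#' Smith-Waterman alignment with a one-time jump between two regions
#'
#' Aligns `query` locally against `ref1`, permitting a single jump into
#' `ref2`: the alignment may leave `ref1` at any query position and resume in
#' `ref2` at any later query position; the skipped query bases are the
#' inserted sequence at the junction. The reported score is never below a
#' plain local alignment against either region alone.
#'
#' @param query,ref1,ref2 character scalars (DNA).
#' @param cfg an [sv_config()]; uses `match`, `mismatch`, `gap_open`,
#'   `gap_extend`, `jump_penalty`, `per_inserted_base`.
#' @return list with `score`, `jumped`, `jump_score`, query/reference
#'   coordinates of the two aligned pieces (0-based half-open), and
#'   `inserted_seq`, the query bases between the layers.
#' @export
jump_sw_align <- function(query, ref1, ref2, cfg = sv_config()) {
  res <- cpp_jump_align(query, ref1, ref2, cfg$match, cfg$mismatch,
                        cfg$gap_open, cfg$gap_extend,
                        cfg$jump_penalty, cfg$per_inserted_base)
  res$inserted_seq <- if (isTRUE(res$jumped) || !is.na(res$jump_score)) {
    substr(query, res$q_end1 + 1L, res$q_start2)
  } else ""
  res
}
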