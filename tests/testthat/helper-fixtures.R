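# Shared fixtures and independent oracles, built in code at test time.

fx <- new.env()

fx_cfg <- function() sv_config()

fx_genome <- function() {
  if (is.null(fx$genome))
    fx$genome <- make_genome(length = 2e5, n_chroms = 2, seed = 11)$seqs
  fx$genome
}

fx_library <- function() {
  if (is.null(fx$lib)) fx$lib <- make_classification_library()
  fx$lib
}

fx_hor <- function() {
  if (is.null(fx$hor)) fx$hor <- make_hor_catalog()
  fx$hor
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# one alignment record as the pipeline's data.frame row
aln_row <- function(read_id, chrom, start, strand, cigar, seq,
                    sa = "", supp = FALSE, sample = "tumor") {
  ops <- svlr:::parse_cigar(cigar)
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(start) + svlr:::cigar_ref_len(ops),
             strand = strand, cigar = cigar, seq = seq, sa = sa,
             is_supplementary = supp, sample = sample,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Independent oracle for the jump alignment: plain-R affine local DP plus
# exhaustive enumeration over all (layer-1 end, layer-2 start) row pairs.
# ---------------------------------------------------------------------------

oracle_local_M <- function(q, r, ma, mi, go, ge) {
  qn <- strsplit(q, "")[[1]]; rn <- strsplit(r, "")[[1]]
  n <- length(qn); m <- length(rn)
  M <- matrix(-Inf, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (qn[i - 1] == rn[j - 1]) ma else mi
    M[i, j] <- s + max(M[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1], 0)
    E[i, j] <- max(M[i, j - 1] + go + ge, E[i, j - 1] + ge)
    F[i, j] <- max(M[i - 1, j] + go + ge, F[i - 1, j] + ge)
  }
  M[-1, -1, drop = FALSE]
}

oracle_jump_score <- function(q, r1, r2, ma = 2, mi = -4, go = -4, ge = -2,
                              jp = 0, pb = 0) {
  n <- nchar(q)
  M1 <- oracle_local_M(q, r1, ma, mi, go, ge)
  M2 <- oracle_local_M(q, r2, ma, mi, go, ge)
  best1 <- max(M1, 0); best2 <- max(M2, 0)
  e1 <- apply(M1, 1, max)
  strrev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  Mr <- oracle_local_M(strrev(q), strrev(r2), ma, mi, go, ge)
  s2 <- rev(apply(Mr, 1, max))     # s2[i]: layer-2 alignment starts at row i
  bj <- -Inf
  if (n >= 2) {
    for (ip in 1:(n - 1)) {
      if (e1[ip] <= 0) next
      for (i in (ip + 1):n)
        bj <- max(bj, e1[ip] + jp + pb * (i - ip - 1) + s2[i])
    }
  }
  max(best1, best2, bj)
}

# brute-force single-linkage clustering oracle over signal rows
oracle_single_linkage <- function(pos1, pos2, margin) {
  n <- length(pos1)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          abs(pos1[i] - pos1[j]) <= margin &&
          abs(pos2[i] - pos2[j]) <= margin) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# brute-force polyA oracle: all substrings of the terminal window that
# begin and end with the base
oracle_polya <- function(seq, base = "A", window = 30L, min_len = 10L,
                         min_frac = 0.8) {
  n <- nchar(seq)
  w <- min(window, n)
  tail_s <- substr(seq, n - w + 1L, n)
  ch <- strsplit(tail_s, "")[[1]]
  best <- 0L
  for (i in seq_len(w)) for (j in i:w) {
    if (ch[i] != base || ch[j] != base) next
    len <- j - i + 1L
    frac <- mean(ch[i:j] == base)
    if (len >= min_len && frac >= min_frac && len > best) best <- len
  }
  if (best == 0L) NULL else best
}

# alignment identity of two sequences (ends-free), for consensus accuracy
seq_identity <- function(a, b) {
  svlr:::nw_align(a, b, sv_config(), free_begin_q = TRUE, free_begin_r = TRUE,
                  free_end_q = TRUE, free_end_r = TRUE)$identity
}
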