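# Readers and writers for the on-disk formats. Internal coordinates are
# 0-based half-open everywhere; 1-based appears only at the SAM/VCF boundary.

#' Read long-read alignments from SAM/BAM
#'
#' Secondary alignments are dropped at ingest; supplementary alignments are
#' retained (they carry the split-read evidence) and flagged. A SAM input is
#' converted to a temporary BAM via Rsamtools.
#'
#' @param path SAM or BAM file.
#' @param region optional `GRanges` of length 1 restricting the fetch (the
#'   file must be indexed, which the SAM conversion performs).
#' @param sample sample label stored on every record, e.g. `"tumor"`,
#'   `"control"` or `"panel"`.
#' @return a data.frame with one row per alignment record: `read_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `cigar`, `seq`
#'   (stored SEQ orientation), `sa` (SA tag or `""`), `is_supplementary`,
#'   `sample`. Records with malformed CIGARs are skipped; the count of
#'   skipped records is in `attr(, "n_skipped")`.
#' @export
read_alignments <- function(path, region = NULL, sample = "tumor") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!is.null(region) && !file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
      tag = "SA", flag = flag)
  } else {
    Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
      tag = "SA", flag = flag, which = region)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  fields <- c("qname", "flag", "rname", "pos", "strand", "cigar", "seq")
  dat <- lapply(fields, function(f) do.call(c, lapply(res, function(x) x[[f]])))
  names(dat) <- fields
  n <- length(dat$qname)
  sa <- do.call(c, lapply(res, function(x) {
    s <- x$tag$SA
    if (is.null(s)) rep(NA_character_, length(x$qname)) else s
  }))
  if (is.null(sa) || !length(sa)) sa <- rep(NA_character_, n)
  if (n == 0L) {
    warning("no mapped alignments in ", path)
    out <- empty_alignments(sample)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  cigars <- as.character(dat$cigar)
  ref_lens <- vapply(cigars, function(cg) {
    ops <- parse_cigar(cg)
    if (is.null(ops)) NA_integer_ else cigar_ref_len(ops)
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(ref_lens)
  n_skipped <- sum(!keep)
  start0 <- as.integer(dat$pos) - 1L
  out <- data.frame(
    read_id = as.character(dat$qname),
    chrom = as.character(dat$rname),
    start = start0,
    end = start0 + ref_lens,
    strand = as.character(dat$strand),
    cigar = cigars,
    seq = as.character(dat$seq),
    sa = ifelse(is.na(sa), "", as.character(sa)),
    is_supplementary = bitwAnd(as.integer(dat$flag), 2048L) > 0L,
    sample = sample,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @noRd
empty_alignments <- function(sample = "tumor") {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), cigar = character(),
             seq = character(), sa = character(),
             is_supplementary = logical(), sample = character(),
             stringsAsFactors = FALSE)
}

#' Write alignment records as SAM
#'
#' @param aln alignment data.frame (see [read_alignments()]).
#' @param path output SAM path.
#' @param seqlens named integer vector of chromosome lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqlens) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  if (nrow(aln)) {
    ord <- order(match(aln$chrom, names(seqlens)), aln$start)
    aln <- aln[ord, , drop = FALSE]
    flag <- ifelse(aln$strand == "-", 16L, 0L) +
      ifelse(aln$is_supplementary, 2048L, 0L)
    opt <- ifelse(nzchar(aln$sa), paste0("\tSA:Z:", aln$sa), "")
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*%s",
                    aln$read_id, flag, aln$chrom, aln$start + 1L, aln$cigar,
                    aln$seq, opt)
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate sequence names in ", path)
  setNames(as.character(x), nm)
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED file as a GRanges (0-based half-open input)
#'
#' Only the first three columns (plus an optional name column) are used.
#'
#' @param path BED file.
#' @return `GRanges`; BED's 0-based half-open intervals become the 1-based
#'   closed convention GRanges uses, covering the same bases.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(GenomicRanges::GRanges())
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (!nrow(tab)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tab[[1]]),
    ranges = IRanges::IRanges(start = as.integer(tab[[2]]) + 1L,
                              end = as.integer(tab[[3]])))
  if (ncol(tab) >= 4L) gr$name <- as.character(tab[[4]])
  gr
}

# ---------------------------------------------------------------------------
# Result tables. The TSV is the authoritative round-trip format; the VCF
# (4.2, breakend notation) is for interoperability.
# ---------------------------------------------------------------------------

#' @noRd
sv_record_columns <- c("chr1", "pos1", "dir1", "chr2", "pos2", "dir2",
                       "inserted_seq", "svtype", "tumor_support",
                       "control_support", "vaf")

#' @noRd
empty_sv_records <- function() {
  data.frame(chr1 = character(), pos1 = integer(), dir1 = character(),
             chr2 = character(), pos2 = integer(), dir2 = character(),
             inserted_seq = character(), svtype = character(),
             tumor_support = integer(), control_support = integer(),
             vaf = numeric(), homlen = integer(), read_ids = character(),
             stringsAsFactors = FALSE)
}

#' Write canonical SV records as TSV and VCF
#'
#' The TSV keeps the internal 0-based breakpoint positions; the VCF emits
#' 1-based positions with paired breakend (BND) records whose ALT strings
#' encode both junction directions and carry the inserted sequence.
#'
#' @param records canonical SV data.frame (as returned by the caller).
#' @param out_prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.vcf`.
#' @param reference optional named character genome used for VCF REF bases
#'   and contig header lines ("N" and no contig lines when absent).
#' @return named character vector of the two paths, invisibly.
#' @export
write_results <- function(records, out_prefix, reference = NULL) {
  tsv <- paste0(out_prefix, ".tsv")
  vcf <- paste0(out_prefix, ".vcf")
  cols <- c(sv_record_columns, intersect(c("homlen", "read_ids"),
                                         names(records)))
  tab <- if (nrow(records)) records[, cols, drop = FALSE] else
    empty_sv_records()[, cols, drop = FALSE]
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_vcf_bnd(records, vcf, reference)
  invisible(c(tsv = tsv, vcf = vcf))
}

#' Read back a canonical SV TSV written by [write_results()]
#' @param path the `.tsv` file.
#' @return data.frame with the same columns and types.
#' @export
read_results <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (!nrow(tab)) return(empty_sv_records()[, names(tab), drop = FALSE])
  for (col in c("pos1", "pos2", "tumor_support", "control_support", "homlen"))
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  if ("vaf" %in% names(tab)) tab$vaf <- as.numeric(tab$vaf)
  tab
}

#' @noRd
write_vcf_bnd <- function(records, path, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svlr",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Mate breakend id">',
           '##INFO=<ID=SVINSSEQ,Number=1,Type=String,Description="Inserted sequence at the junction">',
           '##INFO=<ID=TUMOR_SUPPORT,Number=1,Type=Integer,Description="Tumor variant supporting reads">',
           '##INFO=<ID=CONTROL_SUPPORT,Number=1,Type=Integer,Description="Control variant supporting reads">')
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(reference),
                          nchar(reference)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character()
  if (nrow(records)) {
    ref_base <- function(chrom, pos0) {
      if (is.null(reference)) return("N")
      b <- genome_slice(reference, chrom, pos0, pos0 + 1L)
      if (nzchar(b)) b else "N"
    }
    for (i in seq_len(nrow(records))) {
      r <- records[i, ]
      id1 <- sprintf("svlr_%d_1", i); id2 <- sprintf("svlr_%d_2", i)
      b1 <- ref_base(r$chr1, r$pos1); b2 <- ref_base(r$chr2, r$pos2)
      ins <- r$inserted_seq
      # breakend ALT: dir '+' keeps sequence left of pos (t then bracket);
      # dir '-' keeps sequence right of pos (bracket then t). The partner's
      # dir picks the bracket orientation.
      alt1 <- bnd_alt(b1, ins, r$dir1, r$chr2, r$pos2 + 1L, r$dir2)
      alt2 <- bnd_alt(b2, if (nzchar(ins)) revcomp_if(ins, r$dir1, r$dir2) else "",
                      r$dir2, r$chr1, r$pos1 + 1L, r$dir1)
      info1 <- sprintf("SVTYPE=BND;MATEID=%s;TUMOR_SUPPORT=%d;CONTROL_SUPPORT=%d%s",
                       id2, r$tumor_support, r$control_support,
                       if (nzchar(ins)) paste0(";SVINSSEQ=", ins) else "")
      info2 <- sub(sprintf("MATEID=%s", id2), sprintf("MATEID=%s", id1), info1,
                   fixed = TRUE)
      body <- c(body,
                sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                        r$chr1, r$pos1 + 1L, id1, b1, alt1, info1),
                sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                        r$chr2, r$pos2 + 1L, id2, b2, alt2, info2))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ALT string for one breakend. `t` is REF base plus inserted sequence in the
# orientation leaving this breakend.
#' @noRd
bnd_alt <- function(base, ins, dir_here, chr_mate, pos_mate_1based, dir_mate) {
  mate <- sprintf("%s:%d", chr_mate, pos_mate_1based)
  brk <- if (dir_mate == "-") sprintf("[%s[", mate) else sprintf("]%s]", mate)
  t <- paste0(base, ins)
  if (dir_here == "+") paste0(t, brk) else paste0(brk, t)
}

# inserted sequence as seen from breakend 2: reverse-complemented unless the
# two directions describe a colinear (+,-) junction.
#' @noRd
revcomp_if <- function(ins, dir1, dir2) {
  if (dir1 == "+" && dir2 == "-") ins else revcomp(ins)
}
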