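# Synthetic-data generator: toy genomes with embedded repeat features,
# injected germline and somatic SVs represented as haplotype block
# structures, and noisy long reads emitted directly as alignment records
# with correct CIGAR / SA-tag / soft-clip structure - no external aligner.

#' Synthetic repeat / virus consensus library
#'
#' Deterministically generated consensus sequences standing in for a repeat
#' library: a LINE1-like element (6 kb), an Alu-like element (300 bp), an
#' SVA-like fragment, a hepatitis-B-virus-like fragment and two
#' simple-repeat consensi. Names follow the `name#class` convention of
#' RepeatMasker libraries. These are synthetic sequences (fixed internal
#' seed), not biological consensi; real analyses should supply their own
#' library FASTA.
#'
#' @return named character vector of sequences.
#' @export
make_repeat_library <- function() {
  with_seed(104729L, {
    lib <- c(
      "L1HS#LINE/L1" = paste0(rand_dna(5980), strrep("A", 20)),
      "AluY#SINE/Alu" = paste0(rand_dna(280), strrep("A", 20)),
      "SVA#Retroposon/SVA" = rand_dna(1200),
      "HBV#Virus" = rand_dna(3200),
      "SR1#Simple_repeat" = strrep("TAGA", 50),
      "SR2#Simple_repeat" = strrep("ATTCC", 40))
    lib
  })
}

#' Classification library: repeat/virus consensi plus satellite monomers
#'
#' The [make_repeat_library()] entries extended with the alpha-satellite
#' monomers of [make_hor_catalog()] (class `Satellite/centr`), the library
#' the single-breakend classifier expects.
#'
#' @return named character vector of sequences.
#' @export
make_classification_library <- function() {
  lib <- make_repeat_library()
  hor <- make_hor_catalog()
  for (ch in names(hor)) {
    mono <- hor[[ch]]$monomers
    names(mono) <- sprintf("alpha_%s_%s#Satellite/centr", ch, names(mono))
    lib <- c(lib, mono)
  }
  lib
}

#' Synthetic centromere monomer and higher-order-repeat catalog
#'
#' Alpha-satellite-like monomers (~171 bp) and a canonical monomer order per
#' chromosome. Monomer sets differ between chromosomes, mimicking the
#' chromosome specificity of centromeric higher-order repeats. Synthetic
#' (fixed internal seed).
#'
#' @param chroms chromosome labels to build catalogs for.
#' @param n_monomers monomers per chromosome.
#' @param monomer_len monomer length in bp.
#' @return named list; per chromosome a list with `monomers` (named
#'   character vector, names `A`, `B`, ...) and `order` (the canonical HOR
#'   as a character vector of monomer names).
#' @export
make_hor_catalog <- function(chroms = c("chr11", "chr13", "chrX"),
                             n_monomers = 12L, monomer_len = 171L) {
  with_seed(104731L, {
    out <- lapply(seq_along(chroms), function(i) {
      mono <- setNames(vapply(seq_len(n_monomers),
                              function(k) rand_dna(monomer_len), ""),
                       LETTERS[seq_len(n_monomers)])
      list(monomers = mono, order = LETTERS[seq_len(n_monomers)])
    })
    names(out) <- chroms
    out
  })
}

#' Synthetic transcript set with known exon structure
#'
#' Random multi-exon transcripts; exon boundary positions within each
#' spliced transcript are recorded so processed-pseudogene classification
#' can require alignments spanning exon junctions.
#'
#' @param n number of transcripts.
#' @param seed RNG seed.
#' @return list with `seqs` (named character) and `exon_ends` (named list of
#'   cumulative exon end positions within each transcript, last = length).
#' @export
make_transcripts <- function(n = 3L, seed = 104733L) {
  with_seed(seed, {
    seqs <- character(n); ends <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample(4:7, 1)
      exons <- vapply(seq_len(k), function(j) rand_dna(sample(150:500, 1)), "")
      seqs[i] <- paste(exons, collapse = "")
      ends[[i]] <- cumsum(nchar(exons))
    }
    names(seqs) <- names(ends) <- sprintf("TX%02d", seq_len(n))
    list(seqs = seqs, exon_ends = ends)
  })
}

#' Generate a random toy genome with optional embedded features
#'
#' @param length chromosome length in bp.
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param gc GC content.
#' @param seed RNG seed; generation is byte-identical for a given seed.
#' @param features optional data.frame with columns `chrom`, `pos` (0-based)
#'   and `what` (`"simple_repeat"`, `"satellite:<chrom>"` to embed a HOR
#'   array from [make_hor_catalog()], `"telomere"`, or `"l1_source"` to
#'   embed a full-length LINE1 copy followed by unique downstream sequence),
#'   plus optional `len`. Features overwrite the random sequence in place,
#'   keeping coordinates stable.
#' @return list with `seqs` (named character genome) and `features`
#'   (data.frame `chrom`, `start`, `end`, `label`, `strand`).
#' @export
make_genome <- function(length = 1e6, n_chroms = 2L, gc = 0.41, seed = 1L,
                        features = NULL) {
  set.seed(seed)
  seqs <- setNames(vapply(seq_len(n_chroms), function(i)
    rand_dna(length, gc), ""), paste0("chr", seq_len(n_chroms)))
  feat <- data.frame(chrom = character(), start = integer(), end = integer(),
                     label = character(), strand = character(),
                     stringsAsFactors = FALSE)
  if (!is.null(features) && nrow(features)) {
    lib <- make_repeat_library()
    hor <- make_hor_catalog()
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      what <- f$what
      len <- if (!is.null(features$len) && !is.na(f$len)) f$len else NA
      if (what == "simple_repeat") {
        unit <- "TAGA"
        if (is.na(len)) len <- 800L
        s <- substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
        lab <- "simple_repeat"
      } else if (startsWith(what, "satellite:")) {
        ch <- sub("satellite:", "", what)
        cat_ <- hor[[ch]]
        arr <- strrep(paste(cat_$monomers[cat_$order], collapse = ""), 3L)
        if (is.na(len)) len <- nchar(arr)
        s <- substr(arr, 1L, len)
        lab <- paste0("satellite_", ch)
      } else if (what == "telomere") {
        if (is.na(len)) len <- 1200L
        s <- substr(strrep("TTAGGG", ceiling(len / 6)), 1L, len)
        lab <- "telomere"
      } else if (what == "l1_source") {
        s <- lib[["L1HS#LINE/L1"]]
        lab <- "L1_source"
      } else stop("unknown feature: ", what)
      pos <- f$pos
      chrom <- f$chrom
      stopifnot(pos + nchar(s) <= nchar(seqs[[chrom]]))
      substr(seqs[[chrom]], pos + 1L, pos + nchar(s)) <- s
      feat <- rbind(feat, data.frame(chrom = chrom, start = pos,
                                     end = pos + nchar(s), label = lab,
                                     strand = "+", stringsAsFactors = FALSE))
    }
  }
  list(seqs = seqs, features = feat)
}

# ---------------------------------------------------------------------------
# SV injection. Events live in reference coordinates; a haplotype is an
# ordered list of blocks per derived chromosome:
#   kind "ref": (chrom, start, end, strand) slice of the reference
#   kind "ins": (seq, clip_only) novel sequence; clip_only blocks are
#               unalignable (single-breakend partners) and emit soft clips.
# ---------------------------------------------------------------------------

#' @noRd
ref_block <- function(chrom, start, end, strand = "+") {
  data.frame(kind = "ref", chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, seq = "",
             clip_only = FALSE, stringsAsFactors = FALSE)
}

#' @noRd
ins_block <- function(seq, clip_only = FALSE) {
  data.frame(kind = "ins", chrom = NA_character_, start = NA_integer_,
             end = NA_integer_, strand = "+", seq = seq,
             clip_only = clip_only, stringsAsFactors = FALSE)
}

#' Inject structural variants into a genome
#'
#' Samples non-overlapping events (minimum 1 kb apart, away from `avoid`
#' intervals and chromosome ends), builds the derived haplotype as block
#' structures, and returns the truth set: the event table, the expected
#' junction list in reference coordinates, and the mutated sequences.
#'
#' @param genome output of [make_genome()] (or a named character vector).
#' @param svspec a list of requests, each a list with `type` (`"DEL"`,
#'   `"INS"`, `"DUP"`, `"INV"`, `"TRA"`, `"SBND"`, `"MEI"`), `n`, and for
#'   sized types `size = c(min, max)`. `MEI` requests take `class`
#'   (`"L1"`, `"Alu"`, `"TD_PARTNERED"`, `"TD_ORPHAN"`, `"PPG"`,
#'   `"TANDEM"`), optional `tsd`, `polya`, `inv5`. `SBND` requests take
#'   `foreign` (`"satellite:<chrom>"`, `"telomere"`, `"virus"`,
#'   `"l1_chimera"`) and optional `len`.
#' @param seed RNG seed.
#' @param avoid optional data.frame (`chrom`, `start`, `end`) of intervals
#'   to stay clear of (e.g. a previous event set).
#' @param sources optional LINE1 source element table (`chrom`, `start`,
#'   `end`, `strand`, `id`) for transduction requests.
#' @param transcripts optional [make_transcripts()] output for `PPG`.
#' @return list with `events` (one row per event, insert structure fields
#'   included), `junctions` (reference-coordinate breakpoint pairs, several
#'   per event for inversions and translocations), `blocks` (derived
#'   chromosome block lists) and `seqs` (materialized derived chromosomes).
#' @export
inject_svs <- function(genome, svspec, seed = 1L, avoid = NULL,
                       sources = NULL, transcripts = NULL) {
  if (is.list(genome) && !is.null(genome$seqs)) genome <- genome$seqs
  set.seed(seed)
  lib <- make_repeat_library()
  hor <- make_hor_catalog()
  chroms <- names(genome)
  clen <- setNames(nchar(genome), chroms)

  occupied <- if (!is.null(avoid) && nrow(avoid)) {
    data.frame(chrom = avoid$chrom, start = avoid$start, end = avoid$end,
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  gap <- 1000L
  edge <- 12000L
  place <- function(span) {
    for (try in seq_len(2000L)) {
      ch <- sample(chroms, 1L)
      pos <- as.integer(floor(runif(1, edge, clen[[ch]] - edge - span)))
      ok <- !any(occupied$chrom == ch &
                 occupied$start < pos + span + gap &
                 occupied$end > pos - gap)
      if (ok) {
        occupied[nrow(occupied) + 1L, ] <<- list(ch, pos, pos + span)
        return(list(chrom = ch, pos = pos))
      }
    }
    stop("could not place event of span ", span)
  }

  events <- list()
  eid <- 0L
  add_event <- function(...) {
    eid <<- eid + 1L
    ev <- list(event_id = eid, ...)
    events[[eid]] <<- ev
    ev
  }

  for (req in svspec) {
    n <- req$n
    for (k in seq_len(n)) {
      type <- req$type
      if (type %in% c("DEL", "DUP", "INV")) {
        size <- as.integer(round(runif(1, req$size[1], req$size[2])))
        loc <- place(size)
        add_event(type = type, chrom = loc$chrom, pos = loc$pos,
                  end = loc$pos + size, size = size, insert_seq = "",
                  tsd = 0L, class = type)
      } else if (type == "INS") {
        size <- as.integer(round(runif(1, req$size[1], req$size[2])))
        loc <- place(1L)
        add_event(type = "INS", chrom = loc$chrom, pos = loc$pos,
                  end = loc$pos, size = size, insert_seq = rand_dna(size),
                  tsd = if (is.null(req$tsd)) 0L else req$tsd, class = "INS")
      } else if (type == "TRA") {
        locA <- place(1L); locB <- place(1L)
        while (locB$chrom == locA$chrom) locB <- place(1L)
        add_event(type = "TRA", chrom = locA$chrom, pos = locA$pos,
                  end = locA$pos, size = 0L, insert_seq = "", tsd = 0L,
                  chrom2 = locB$chrom, pos2 = locB$pos, class = "TRA")
      } else if (type == "SBND") {
        len <- if (is.null(req$len)) 3000L else req$len
        foreign <- req$foreign
        s <- if (startsWith(foreign, "satellite:")) {
          ch <- sub("satellite:", "", foreign)
          arr <- strrep(paste(hor[[ch]]$monomers[hor[[ch]]$order],
                              collapse = ""), 4L)
          substr(arr, 1L, len)
        } else if (foreign == "telomere") {
          substr(strrep("TTAGGG", ceiling(len / 6)), 1L, len)
        } else if (foreign == "virus") {
          substr(lib[["HBV#Virus"]], 1L, len)
        } else if (foreign == "l1_chimera") {
          l1 <- lib[["L1HS#LINE/L1"]]
          part <- substr(l1, nchar(l1) - 999L, nchar(l1))
          ch <- sample(chroms, 1L)
          far <- as.integer(floor(runif(1, edge, clen[[ch]] - edge - 2000L)))
          paste0(part, genome_slice(genome, ch, far, far + len - 1000L))
        } else stop("unknown foreign class: ", foreign)
        loc <- place(1L)
        add_event(type = "SBND", chrom = loc$chrom, pos = loc$pos,
                  end = loc$pos, size = nchar(s), insert_seq = s, tsd = 0L,
                  class = paste0("SBND_", sub(":.*", "", foreign)))
      } else if (type == "MEI") {
        cls <- req$class
        tsd <- if (is.null(req$tsd)) 12L else req$tsd
        polya <- if (is.null(req$polya)) 25L else req$polya
        l1 <- lib[["L1HS#LINE/L1"]]
        core <- NULL; inv5 <- isTRUE(req$inv5)
        src_id <- NA_character_
        if (cls == "L1") {
          st <- sample(1500:3500, 1)
          sense <- substr(l1, st, nchar(l1) - 20L)
          core <- if (inv5) {
            # twin priming: antisense 5' segment + sense 3' segment with a
            # small internal loss of consensus sequence
            b <- st + 800L
            paste0(revcomp(substr(l1, st, b)), substr(l1, b + 150L,
                                                      nchar(l1) - 20L))
          } else sense
        } else if (cls == "Alu") {
          core <- substr(lib[["AluY#SINE/Alu"]], 1L, 280L)
        } else if (cls %in% c("TD_PARTNERED", "TD_ORPHAN")) {
          if (is.null(sources) || !nrow(sources))
            stop("transduction request needs `sources`")
          si <- sample(nrow(sources), 1L)
          src <- sources[si, ]
          src_id <- src$id
          tag_len <- sample(800:2000, 1)
          tag <- genome_slice(genome, src$chrom, src$end, src$end + tag_len)
          core <- if (cls == "TD_PARTNERED")
            paste0(substr(l1, nchar(l1) - 820L, nchar(l1) - 20L), tag)
          else tag
        } else if (cls == "PPG") {
          if (is.null(transcripts)) stop("PPG request needs `transcripts`")
          ti <- sample(length(transcripts$seqs), 1L)
          core <- transcripts$seqs[[ti]]
          src_id <- names(transcripts$seqs)[ti]
        } else if (cls == "TANDEM") {
          size <- if (is.null(req$size)) 500L else
            as.integer(round(runif(1, req$size[1], req$size[2])))
          loc <- place(size)
          ins <- genome_slice(genome, loc$chrom, loc$pos - size, loc$pos)
          add_event(type = "INS", chrom = loc$chrom, pos = loc$pos,
                    end = loc$pos, size = size, insert_seq = ins, tsd = 0L,
                    class = "MEI_TANDEM", polya = 0L, inv5 = FALSE,
                    source_id = NA_character_)
          next
        } else stop("unknown MEI class: ", cls)
        ins <- paste0(core, strrep("A", polya))
        loc <- place(1L)
        add_event(type = "INS", chrom = loc$chrom, pos = loc$pos,
                  end = loc$pos, size = nchar(ins), insert_seq = ins,
                  tsd = tsd, class = paste0("MEI_", cls), polya = polya,
                  inv5 = inv5, source_id = src_id)
      } else stop("unknown SV type: ", type)
    }
  }

  # ---- truth junctions ---------------------------------------------------
  jn <- list()
  add_j <- function(ev, c1, p1, d1, c2, p2, d2, ins_len = 0L,
                    ins_seq = "") {
    jn[[length(jn) + 1L]] <<- data.frame(
      event_id = ev$event_id, class = ev$class,
      chrom1 = c1, pos1 = as.integer(p1), dir1 = d1,
      chrom2 = c2, pos2 = as.integer(p2), dir2 = d2,
      insert_len = as.integer(ins_len), insert_seq = ins_seq,
      stringsAsFactors = FALSE)
  }
  for (ev in events) {
    if (ev$type == "DEL") add_j(ev, ev$chrom, ev$pos - 1L, "+",
                                ev$chrom, ev$end, "-")
    else if (ev$type == "INS") add_j(ev, ev$chrom, ev$pos - 1L, "+",
                                     ev$chrom, ev$pos - ev$tsd, "-",
                                     nchar(ev$insert_seq), ev$insert_seq)
    else if (ev$type == "DUP") add_j(ev, ev$chrom, ev$pos, "-",
                                     ev$chrom, ev$end - 1L, "+")
    else if (ev$type == "INV") {
      add_j(ev, ev$chrom, ev$pos - 1L, "+", ev$chrom, ev$end - 1L, "+")
      add_j(ev, ev$chrom, ev$pos, "-", ev$chrom, ev$end, "-")
    } else if (ev$type == "TRA") {
      add_j(ev, ev$chrom, ev$pos, "+", ev$chrom2, ev$pos2, "-")
    } else if (ev$type == "SBND") {
      add_j(ev, ev$chrom, ev$pos, "+", NA_character_, NA_integer_, NA_character_,
            nchar(ev$insert_seq))
    }
  }
  junctions <- if (length(jn)) do.call(rbind, jn) else
    data.frame(event_id = integer(), class = character(), chrom1 = character(),
               pos1 = integer(), dir1 = character(), chrom2 = character(),
               pos2 = integer(), dir2 = character(), insert_len = integer(),
               insert_seq = character(), stringsAsFactors = FALSE)

  # ---- derived haplotype blocks -----------------------------------------
  blocks <- make_haplotype_blocks(genome, events)
  seqs <- materialize_blocks(genome, blocks)

  ev_df <- do.call(rbind, lapply(events, function(ev) {
    data.frame(event_id = ev$event_id, type = ev$type, class = ev$class,
               chrom = ev$chrom, pos = ev$pos, end = ev$end, size = ev$size,
               tsd = ev$tsd,
               chrom2 = if (!is.null(ev$chrom2)) ev$chrom2 else NA_character_,
               pos2 = if (!is.null(ev$pos2)) ev$pos2 else NA_integer_,
               polya = if (!is.null(ev$polya)) ev$polya else NA_integer_,
               inv5 = if (!is.null(ev$inv5)) ev$inv5 else NA,
               source_id = if (!is.null(ev$source_id)) ev$source_id
                           else NA_character_,
               insert_seq = ev$insert_seq, stringsAsFactors = FALSE)
  }))

  list(events = ev_df, junctions = junctions, blocks = blocks, seqs = seqs)
}

# Build per-chromosome block lists from the event table. Intra-chromosomal
# events are applied left to right; translocations exchange chromosome tails
# reciprocally afterwards.
#' @noRd
make_haplotype_blocks <- function(genome, events) {
  chroms <- names(genome)
  blocks <- lapply(chroms, function(ch) ref_block(ch, 0L, nchar(genome[[ch]])))
  names(blocks) <- chroms
  intra <- Filter(function(ev) ev$type %in% c("DEL", "INS", "DUP", "INV", "SBND"),
                  events)
  for (ch in chroms) {
    evs <- Filter(function(ev) ev$chrom == ch, intra)
    if (!length(evs)) next
    evs <- evs[order(vapply(evs, `[[`, 0L, "pos"))]
    cur <- 0L
    out <- list()
    terminated <- FALSE
    for (ev in evs) {
      if (terminated) break
      if (ev$type == "DEL") {
        out[[length(out) + 1L]] <- ref_block(ch, cur, ev$pos)
        cur <- ev$end
      } else if (ev$type == "INS") {
        out[[length(out) + 1L]] <- ref_block(ch, cur, ev$pos)
        out[[length(out) + 1L]] <- ins_block(ev$insert_seq)
        cur <- ev$pos - ev$tsd
      } else if (ev$type == "DUP") {
        out[[length(out) + 1L]] <- ref_block(ch, cur, ev$end)
        out[[length(out) + 1L]] <- ref_block(ch, ev$pos, ev$end)
        cur <- ev$end
      } else if (ev$type == "INV") {
        out[[length(out) + 1L]] <- ref_block(ch, cur, ev$pos)
        out[[length(out) + 1L]] <- ref_block(ch, ev$pos, ev$end, "-")
        cur <- ev$end
      } else if (ev$type == "SBND") {
        out[[length(out) + 1L]] <- ref_block(ch, cur, ev$pos + 1L)
        out[[length(out) + 1L]] <- ins_block(ev$insert_seq, clip_only = TRUE)
        terminated <- TRUE
      }
    }
    if (!terminated)
      out[[length(out) + 1L]] <- ref_block(ch, cur, nchar(genome[[ch]]))
    blocks[[ch]] <- do.call(rbind, out)
  }
  # translocations: each junction lives on its own derived fusion segment
  # (a rearranged chromosome piece), leaving the original chromosomes of
  # this haplotype intact so coverage elsewhere stays balanced
  tras <- Filter(function(ev) ev$type == "TRA", events)
  W <- 25000L
  for (ev in tras) {
    lenA <- nchar(genome[[ev$chrom]]); lenB <- nchar(genome[[ev$chrom2]])
    fus <- rbind(
      ref_block(ev$chrom, max(0L, ev$pos - W), min(lenA, ev$pos + 1L)),
      ref_block(ev$chrom2, max(0L, ev$pos2), min(lenB, ev$pos2 + W)))
    blocks[[sprintf("fusion_%d", ev$event_id)]] <- fus
  }
  blocks
}

#' @noRd
block_lengths <- function(blocks) {
  ifelse(blocks$kind == "ref", blocks$end - blocks$start, nchar(blocks$seq))
}

#' @noRd
materialize_blocks <- function(genome, blocks) {
  vapply(blocks, function(b) {
    parts <- vapply(seq_len(nrow(b)), function(i) {
      if (b$kind[i] == "ins") return(b$seq[i])
      s <- genome_slice(genome, b$chrom[i], b$start[i], b$end[i])
      if (b$strand[i] == "-") revcomp(s) else s
    }, "")
    paste(parts, collapse = "")
  }, "")
}

# ---------------------------------------------------------------------------
# Read simulation.
# ---------------------------------------------------------------------------

# Inject sequencing errors into one fragment. Error composition follows a
# 40:30:30 substitution:insertion:deletion split of the total rate. Returns
# the mutated fragment and merged M/I/D CIGAR ops relative to the input.
#' @noRd
weave_errors <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0)
    return(list(seq = seq, op = if (n) "M" else character(),
                len = if (n) n else integer()))
  k <- rbinom(1L, n, rate)
  if (k == 0L)
    return(list(seq = seq, op = "M", len = n))
  pos <- sort(sample.int(n, k))
  typ <- sample(c("S", "I", "D"), k, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  pS <- pos[typ == "S"]
  if (length(pS)) {
    cur <- match(chars[pS], bases)
    cur[is.na(cur)] <- 1L
    chars[pS] <- bases[((cur - 1L + sample.int(3L, length(pS),
                                               replace = TRUE)) %% 4L) + 1L]
  }
  w <- rep(1L, n)
  pD <- pos[typ == "D"]; pI <- pos[typ == "I"]
  w[pD] <- 0L
  w[pI] <- 2L
  out <- rep.int(chars, w)
  if (length(pI)) {
    at <- cumsum(w)[pI]
    out[at] <- bases[sample.int(4L, length(pI), replace = TRUE)]
  }
  ev <- pos[typ != "S"]; et <- typ[typ != "S"]
  if (!length(ev)) return(list(seq = paste(out, collapse = ""), op = "M", len = n))
  prev <- c(0L, ev[-length(ev)])
  mlen <- ev - prev - as.integer(et == "D")
  ops <- as.vector(rbind(rep("M", length(ev)), et))
  lens <- as.vector(rbind(mlen, rep(1L, length(ev))))
  ops <- c(ops, "M"); lens <- c(lens, n - ev[length(ev)])
  m <- merge_cigar_ops(ops, as.integer(lens))
  list(seq = paste(out, collapse = ""), op = m$op, len = m$len)
}

#' Simulate noisy long reads from haplotype block structures
#'
#' Reads are drawn uniformly from each derived chromosome of each haplotype
#' at `depth / length(haplotypes)` coverage, mutated at `error_rate`
#' (40:30:30 substitution:insertion:deletion), and converted directly into
#' alignment records reflecting their true origin: contained deletions and
#' insertions become D/I CIGAR operations, strand flips, chromosome changes
#' and back-jumps split the read into primary + supplementary records with
#' mutually consistent SA tags, and unalignable (clip-only) blocks become
#' soft clips.
#'
#' @param haplotypes list of block lists (one element per haplotype, each as
#'   returned in `$blocks` by [inject_svs()]).
#' @param genome reference named character vector.
#' @param depth total target coverage across haplotypes.
#' @param error_rate per-base error rate.
#' @param seed RNG seed.
#' @param sample sample label for the records.
#' @param read_shape,read_scale gamma read-length parameters (mean =
#'   shape * scale).
#' @param read_min minimum read length.
#' @return list with `alignments` (data.frame compatible with
#'   [read_alignments()]) and `origins` (per-read truth: haplotype, derived
#'   chromosome, span, orientation).
#' @export
simulate_reads <- function(haplotypes, genome, depth = 30, error_rate = 0.1,
                           seed = 1L, sample = "tumor",
                           read_shape = 4, read_scale = 2000,
                           read_min = 500L) {
  set.seed(seed)
  mean_len <- read_shape * read_scale
  acc <- list(); orig <- list()
  ridx <- 0L
  for (h in seq_along(haplotypes)) {
    blocks <- haplotypes[[h]]
    for (ch in names(blocks)) {
      b <- blocks[[ch]]
      lens <- block_lengths(b)
      dstart <- cumsum(c(0L, lens))[seq_len(nrow(b))]
      L <- sum(lens)
      if (L < read_min) next
      n_reads <- rpois(1L, L * (depth / length(haplotypes)) / mean_len)
      if (n_reads == 0L) next
      starts <- as.integer(floor(runif(n_reads, 0, max(1L, L - read_min))))
      rl <- pmax(read_min, as.integer(round(rgamma(n_reads, read_shape,
                                                   scale = read_scale))))
      o_strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
      for (ri in seq_len(n_reads)) {
        ridx <- ridx + 1L
        rid <- sprintf("%s_%s_h%d_%06d", sample, ch, h, ridx)
        rs <- starts[ri]; re <- min(L, rs + rl[ri])
        recs <- build_read_records(b, dstart, rs, re, genome, error_rate,
                                   rid, o_strand[ri], sample)
        if (!is.null(recs)) {
          acc[[length(acc) + 1L]] <- recs
          orig[[length(orig) + 1L]] <- data.frame(
            read_id = rid, haplotype = h, derived_chrom = ch,
            dstart = rs, dend = re, o_strand = o_strand[ri],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  alignments <- if (length(acc)) do.call(rbind, acc) else empty_alignments(sample)
  rownames(alignments) <- NULL
  origins <- if (length(orig)) do.call(rbind, orig) else
    data.frame(read_id = character(), haplotype = integer(),
               derived_chrom = character(), dstart = integer(),
               dend = integer(), o_strand = character(),
               stringsAsFactors = FALSE)
  list(alignments = alignments, origins = origins)
}

# Construct the alignment records of one read spanning derived interval
# [rs, re) of a block list. Returns NULL when the read has no alignable part.
#' @noRd
build_read_records <- function(b, dstart, rs, re, genome, error_rate,
                               read_id, o_strand, sample) {
  lens <- block_lengths(b)
  first <- findInterval(rs, dstart)
  pieces <- list()
  i <- first
  while (i <= nrow(b) && dstart[i] < re) {
    a <- max(0L, rs - dstart[i])
    z <- min(lens[i], re - dstart[i])
    if (z > a) {
      if (b$kind[i] == "ref") {
        if (b$strand[i] == "+") {
          pieces[[length(pieces) + 1L]] <- list(
            kind = "ref", chrom = b$chrom[i], start = b$start[i] + a,
            end = b$start[i] + z, strand = "+",
            seq = genome_slice(genome, b$chrom[i], b$start[i] + a,
                               b$start[i] + z))
        } else {
          pieces[[length(pieces) + 1L]] <- list(
            kind = "ref", chrom = b$chrom[i], start = b$end[i] - z,
            end = b$end[i] - a, strand = "-",
            seq = revcomp(genome_slice(genome, b$chrom[i], b$end[i] - z,
                                       b$end[i] - a)))
        }
      } else {
        pieces[[length(pieces) + 1L]] <- list(
          kind = "ins", seq = substr(b$seq[i], a + 1L, z),
          clip_only = b$clip_only[i])
      }
    }
    i <- i + 1L
  }
  if (!length(pieces)) return(NULL)

  # resolve small reference overlaps (target-site duplications): absorb the
  # overlapping start of the next ref piece into the preceding insertion
  k <- 1L
  repeat {
    refs <- which(vapply(pieces, function(p) p$kind == "ref", TRUE))
    if (k > length(refs) - 1L) break
    i1 <- refs[k]; i2 <- refs[k + 1L]
    p1 <- pieces[[i1]]; p2 <- pieces[[i2]]
    if (p1$chrom == p2$chrom && p1$strand == "+" && p2$strand == "+") {
      ov <- p1$end - p2$start
      if (ov > 0L && ov <= 100L && p2$end > p1$end) {
        extra <- genome_slice(genome, p2$chrom, p2$start, p1$end)
        if (i2 - i1 >= 2L && pieces[[i1 + 1L]]$kind == "ins") {
          pieces[[i1 + 1L]]$seq <- paste0(pieces[[i1 + 1L]]$seq, extra)
        } else {
          pieces <- append(pieces, list(list(kind = "ins", seq = extra,
                                             clip_only = FALSE)), after = i1)
          i2 <- i2 + 1L
        }
        pieces[[i2]]$start <- pieces[[i2]]$start + ov
        pieces[[i2]]$seq <- substr(pieces[[i2]]$seq, ov + 1L,
                                   nchar(pieces[[i2]]$seq))
      }
    }
    k <- k + 1L
  }

  # weave errors, assemble the read, group pieces into colinear runs
  qpos <- 0L
  runs <- list(); run <- NULL
  read_parts <- character(length(pieces))
  flush <- function() {
    if (!is.null(run) && length(run$items)) runs[[length(runs) + 1L]] <<- run
    run <<- NULL
  }
  for (pi in seq_along(pieces)) {
    p <- pieces[[pi]]
    if (p$kind == "ins") {
      mut <- weave_errors(p$seq, error_rate)
      read_parts[pi] <- mut$seq
      ql <- nchar(mut$seq)
      if (isTRUE(p$clip_only) || is.null(run)) {
        flush()   # clip-only or leading insertion: not part of any run
      } else {
        run$pending_ins <- run$pending_ins + ql
      }
      qpos <- qpos + ql
      next
    }
    mut <- weave_errors(p$seq, error_rate)
    read_parts[pi] <- mut$seq
    ql <- nchar(mut$seq)
    joined <- FALSE
    if (!is.null(run)) {
      lastp <- run$last
      colinear <- lastp$chrom == p$chrom && lastp$strand == p$strand &&
        ((p$strand == "+" && p$start >= lastp$end) ||
         (p$strand == "-" && p$end <= lastp$start))
      if (colinear) {
        gapd <- if (p$strand == "+") p$start - lastp$end else lastp$start - p$end
        if (run$pending_ins > 0L)
          run$items[[length(run$items) + 1L]] <- list(op = "I",
                                                      len = run$pending_ins)
        if (gapd > 0L)
          run$items[[length(run$items) + 1L]] <- list(op = "D", len = gapd)
        run$items[[length(run$items) + 1L]] <- list(ops = mut$op,
                                                    lens = mut$len)
        run$last <- p
        run$qb <- qpos + ql
        run$rmin <- min(run$rmin, p$start); run$rmax <- max(run$rmax, p$end)
        run$pending_ins <- 0L
        joined <- TRUE
      }
    }
    if (!joined) {
      flush()
      run <- list(chrom = p$chrom, strand = p$strand, qa = qpos,
                  qb = qpos + ql, rmin = p$start, rmax = p$end, last = p,
                  pending_ins = 0L,
                  items = list(list(ops = mut$op, lens = mut$len)))
    }
    qpos <- qpos + ql
  }
  flush()
  if (!length(runs)) return(NULL)
  read_fwd <- paste(read_parts, collapse = "")
  Lr <- nchar(read_fwd)

  # assemble records
  recs <- lapply(runs, function(run) {
    op <- character(); len <- integer()
    for (it in run$items) {
      if (!is.null(it$op)) { op <- c(op, it$op); len <- c(len, it$len) }
      else { op <- c(op, it$ops); len <- c(len, it$lens) }
    }
    m <- merge_cigar_ops(op, len)
    op <- m$op; len <- m$len
    if (run$strand == "-") { op <- rev(op); len <- rev(len) }
    clipL <- if (run$strand == "+") run$qa else Lr - run$qb
    clipR <- if (run$strand == "+") Lr - run$qb else run$qa
    if (clipL > 0L) { op <- c("S", op); len <- c(clipL, len) }
    if (clipR > 0L) { op <- c(op, "S"); len <- c(len, clipR) }
    seq_stored <- if (run$strand == "+") read_fwd else revcomp(read_fwd)
    list(chrom = run$chrom, start = run$rmin, end = run$rmax,
         strand_block = run$strand, cigar = unparse_cigar(op, len),
         seq = seq_stored, qspan = run$qb - run$qa)
  })
  prim <- which.max(vapply(recs, `[[`, 0L, "qspan"))
  strand_char <- vapply(recs, function(r)
    if (r$strand_block == o_strand) "+" else "-", "")
  sa_of <- function(k) {
    if (length(recs) == 1L) return("")
    others <- setdiff(seq_along(recs), k)
    paste0(vapply(others, function(j)
      sprintf("%s,%d,%s,%s,60,0;", recs[[j]]$chrom, recs[[j]]$start + 1L,
              strand_char[j], recs[[j]]$cigar), ""), collapse = "")
  }
  do.call(rbind, lapply(seq_along(recs), function(k) {
    r <- recs[[k]]
    data.frame(read_id = read_id, chrom = r$chrom, start = r$start,
               end = r$end, strand = strand_char[k], cigar = r$cigar,
               seq = r$seq, sa = sa_of(k), is_supplementary = k != prim,
               sample = sample, stringsAsFactors = FALSE)
  }))
}

#' Write simulated alignments as a SAM file
#'
#' @param sim output of [simulate_reads()].
#' @param genome reference named character vector (for header lengths).
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
emit_alignments <- function(sim, genome, path) {
  write_sam(sim$alignments, path, setNames(nchar(genome), names(genome)))
}

# ---------------------------------------------------------------------------
# Whole-dataset convenience wrapper and truth matching.
# ---------------------------------------------------------------------------

#' Simulate a complete tumor/control dataset with known truth
#'
#' Builds a two-chromosome genome, injects germline SVs shared by both
#' samples and somatic SVs private to one tumor haplotype, and simulates
#' reads for both samples.
#'
#' @param seed master RNG seed; every stage derives from it.
#' @param genome_len,n_chroms genome shape.
#' @param depth per-sample coverage.
#' @param error_rate per-base read error rate.
#' @param somatic_spec,germline_spec [inject_svs()] request lists.
#' @param with_features embed simple-repeat and LINE1-source features.
#' @return list with `reference`, `features`, `simple_repeats` (GRanges),
#'   `truth` (somatic events + junctions), `germline`, `tumor`, `control`
#'   (each `$alignments` + `$origins`), and `sources`.
#' @export
simulate_dataset <- function(seed = 1L, genome_len = 1e6, n_chroms = 2L,
                             depth = 30, error_rate = 0.1,
                             somatic_spec = list(
                               list(type = "DEL", n = 10L, size = c(150, 5000)),
                               list(type = "INS", n = 10L, size = c(150, 5000)),
                               list(type = "INV", n = 10L, size = c(150, 5000)),
                               list(type = "TRA", n = 10L)),
                             germline_spec = list(
                               list(type = "DEL", n = 5L, size = c(150, 3000)),
                               list(type = "INS", n = 5L, size = c(150, 3000))),
                             with_features = TRUE) {
  feats <- NULL
  if (with_features && genome_len >= 50000) {
    feats <- data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      pos = as.integer(genome_len * c(0.301, 0.651, 0.471)),
      what = c("simple_repeat", "l1_source", "simple_repeat"),
      len = c(800L, NA, 800L), stringsAsFactors = FALSE)
    feats <- feats[feats$chrom %in% paste0("chr", seq_len(n_chroms)), ,
                   drop = FALSE]
  }
  gen <- make_genome(length = genome_len, n_chroms = n_chroms, seed = seed,
                     features = feats)
  avoid <- gen$features[, c("chrom", "start", "end")]
  germ <- inject_svs(gen$seqs, germline_spec, seed = seed + 11L, avoid = avoid)
  avoid2 <- rbind(avoid, data.frame(chrom = germ$events$chrom,
                                    start = pmin(germ$events$pos,
                                                 germ$events$end) - 1L,
                                    end = pmax(germ$events$pos,
                                               germ$events$end) + 1L))
  som_events <- rbind_spec_events(gen$seqs, germ$events, somatic_spec,
                                  seed + 23L, avoid2)
  tumor_blocks_h1 <- make_haplotype_blocks(gen$seqs, som_events$all_events)
  ref_blocks <- make_haplotype_blocks(gen$seqs, list())
  germ_blocks <- germ$blocks

  tumor <- simulate_reads(list(h1 = tumor_blocks_h1, h2 = germ_blocks),
                          gen$seqs, depth = depth, error_rate = error_rate,
                          seed = seed + 101L, sample = "tumor")
  control <- simulate_reads(list(h1 = germ_blocks, h2 = ref_blocks),
                            gen$seqs, depth = depth, error_rate = error_rate,
                            seed = seed + 211L, sample = "control")

  sr <- gen$features[gen$features$label == "simple_repeat", , drop = FALSE]
  simple_repeats <- if (nrow(sr)) GenomicRanges::GRanges(
    sr$chrom, IRanges::IRanges(sr$start + 1L, sr$end)) else
    GenomicRanges::GRanges()
  sources <- l1_sources_from_features(gen$features)

  list(reference = gen$seqs, features = gen$features,
       simple_repeats = simple_repeats,
       truth = list(events = som_events$somatic$events,
                    junctions = som_events$somatic$junctions),
       germline = germ, tumor = tumor, control = control, sources = sources)
}

# Somatic events injected on top of germline: the tumor haplotype carries
# both event sets (all in reference coordinates, mutually avoiding).
#' @noRd
rbind_spec_events <- function(genome, germline_events, somatic_spec, seed,
                              avoid) {
  som <- inject_svs(genome, somatic_spec, seed = seed, avoid = avoid)
  ge <- germline_events
  all_ev <- c(
    lapply(seq_len(nrow(ge)), function(i) as.list(ge[i, ])),
    lapply(seq_len(nrow(som$events)), function(i) as.list(som$events[i, ])))
  list(somatic = som, all_events = all_ev)
}

#' @noRd
l1_sources_from_features <- function(features) {
  src <- features[features$label == "L1_source", , drop = FALSE]
  if (!nrow(src)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), id = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = src$chrom, start = src$start, end = src$end,
             strand = src$strand,
             id = sprintf("L1src_%s_%d", src$chrom, src$start),
             provenance = "reference", stringsAsFactors = FALSE)
}

#' Match called SVs against a truth junction set
#'
#' A call matches a truth junction when chromosomes and directions agree
#' (in either breakpoint order) and both positions are within `margin`.
#' When `reference` is supplied, the per-call breakpoint deviation is
#' measured up to junction equivalence: micro-homology at a junction (and
#' insert-edge homology at insertions) makes several representations
#' describe the same derived sequence. Equivalence is decided by
#' rebuilding the local derived allele from both representations (their
#' inserted sequences included) and testing sequence identity; an
#' equivalent call has deviation 0.
#'
#' @param calls canonical SV data.frame.
#' @param junctions truth junction data.frame from [inject_svs()].
#' @param margin matching distance in bp.
#' @param reference optional named character genome enabling
#'   homology-aware deviations.
#' @return list with per-call `matched_event` (NA when unmatched), per-call
#'   breakpoint deviation `bp_dev` (max of the two distances), `recall`
#'   (fraction of truth events with at least one matched junction),
#'   `precision` (fraction of calls matching truth), and
#'   `frac_within_2bp` among matched calls.
#' @export
match_calls <- function(calls, junctions, margin = 200L, reference = NULL) {
  n <- nrow(calls)
  matched <- rep(NA_integer_, n)
  dev <- rep(NA_integer_, n)
  jn <- junctions[!is.na(junctions$chrom2), , drop = FALSE]
  truth_ins <- if ("insert_seq" %in% names(jn)) jn$insert_seq
               else character(nrow(jn))
  call_ins <- if (!is.null(calls$inserted_seq)) calls$inserted_seq
              else character(n)
  jdist <- function(i, c1, p1, d1, c2, p2, d2, tins) {
    if (calls$chr1[i] != c1 || calls$chr2[i] != c2 ||
        calls$dir1[i] != d1 || calls$dir2[i] != d2) return(Inf)
    d0 <- max(abs(calls$pos1[i] - p1), abs(calls$pos2[i] - p2))
    if (is.null(reference) || d0 == 0 || d0 > margin) return(d0)
    # rebuild the derived allele around the junction from both
    # representations; a call whose (trimmed) window occurs in the truth
    # window describes the same sequence and deviates only in
    # representation
    w <- 80L + d0
    tw <- junction_window(reference, c1, p1, d1, c2, p2, d2, tins, w)
    cw <- junction_window(reference, calls$chr1[i], calls$pos1[i],
                          calls$dir1[i], calls$chr2[i], calls$pos2[i],
                          calls$dir2[i], call_ins[i], w)
    cw <- substr(cw, d0 + 1L, nchar(cw) - d0)
    if (nzchar(cw) && grepl(cw, tw, fixed = TRUE)) return(0)
    d0
  }
  for (i in seq_len(n)) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_len(nrow(jn))) {
      ti <- if (is.na(truth_ins[j])) "" else truth_ins[j]
      d <- min(jdist(i, jn$chrom1[j], jn$pos1[j], jn$dir1[j],
                     jn$chrom2[j], jn$pos2[j], jn$dir2[j], ti),
               jdist(i, jn$chrom2[j], jn$pos2[j], jn$dir2[j],
                     jn$chrom1[j], jn$pos1[j], jn$dir1[j],
                     if (nzchar(ti)) revcomp(ti) else ""))
      if (d <= margin && d < bestd) { bestd <- d; best <- j }
    }
    if (!is.na(best)) {
      matched[i] <- jn$event_id[best]
      dev[i] <- as.integer(bestd)
    }
  }
  truth_events <- unique(jn$event_id)
  recalled <- unique(matched[!is.na(matched)])
  list(matched_event = matched, bp_dev = dev,
       recall = if (length(truth_events))
         length(intersect(recalled, truth_events)) / length(truth_events)
       else NA_real_,
       precision = if (n) mean(!is.na(matched)) else NA_real_,
       frac_within_2bp = if (any(!is.na(dev)))
         mean(dev[!is.na(dev)] <= 2L) else NA_real_)
}
# Local derived-allele sequence around a junction: `w` reference bases
# approaching breakpoint 1 (per its direction), the inserted sequence, and
# `w` reference bases leaving breakpoint 2. Two representations of the
# same rearrangement produce windows that are substrings of one another.
#' @noRd
junction_window <- function(reference, c1, p1, d1, c2, p2, d2, ins, w) {
  side1 <- if (d1 == "+") genome_slice(reference, c1, p1 + 1L - w, p1 + 1L)
           else revcomp(genome_slice(reference, c1, p1, p1 + w))
  side2 <- if (d2 == "-") genome_slice(reference, c2, p2, p2 + w)
           else revcomp(genome_slice(reference, c2, p2 + 1L - w, p2 + 1L))
  paste0(side1, if (is.null(ins) || is.na(ins)) "" else ins, side2)
}
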