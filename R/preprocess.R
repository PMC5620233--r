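#' Construct an aligned amplicon read pair
#'
#' Both mates are stored in reference orientation (sequence as aligned to
#' the forward reference strand, qualities in the same order), with 1-based
#' alignment start positions; `strand` records which strand each mate was
#' sequenced from. Alignments are assumed ungapped, which holds for the
#' short amplicon products this pipeline handles.
#'
#' @param chrom chromosome both mates align to.
#' @param seq1,seq2 mate sequences (A/C/G/T strings, reference orientation).
#' @param qual1,qual2 integer Phred qualities per base.
#' @param start1,start2 1-based alignment starts.
#' @param strand1,strand2 `"+"` or `"-"`.
#' @param name read-pair name.
#' @return a `read_pair` object.
#' @export
read_pair <- function(chrom, seq1, qual1, start1, strand1 = "+",
                      seq2 = NULL, qual2 = NULL, start2 = NULL,
                      strand2 = "-", name = "pair") {
  m1 <- .mate(chrom, seq1, qual1, start1, strand1)
  m2 <- if (is.null(seq2)) NULL else .mate(chrom, seq2, qual2, start2, strand2)
  structure(list(chrom = chrom, name = name, mate1 = m1, mate2 = m2),
            class = "read_pair")
}

.mate <- function(chrom, seq, qual, start, strand) {
  seq <- toupper(seq)
  qual <- as.integer(qual)
  if (nchar(seq) != length(qual)) {
    stop("sequence length and quality length differ")
  }
  if (any(qual < 0L) || any(qual > 93L)) stop("Phred qualities out of range")
  stopifnot(strand %in% c("+", "-"))
  list(chrom = chrom, seq = seq, qual = qual,
       start = as.integer(start), strand = strand)
}

#' @export
print.read_pair <- function(x, ...) {
  fmt <- function(m, lab) {
    if (is.null(m)) return()
    cat(sprintf("  %s %s:%d%s %dbp Q[%d-%d]\n", lab, m$chrom, m$start,
                m$strand, nchar(m$seq), min(m$qual), max(m$qual)))
  }
  cat("<read_pair>", x$name, "\n")
  fmt(x$mate1, "mate1"); fmt(x$mate2, "mate2")
  invisible(x)
}

#' Trim a 5' primer prefix off one read
#'
#' Compares the read's 5' prefix (in sequencing orientation) with every
#' primer designed for the read's chromosome by Hamming distance; if the
#' mismatch fraction is at most `max_mismatch_frac` for any primer, the
#' longest such matching prefix is hard-trimmed (bases and qualities
#' removed). At most one trim is applied. For forward-strand reads the
#' alignment start advances by the trimmed length; for reverse-strand reads
#' the trimmed bases are the 3' end in reference orientation, so the start
#' is unchanged. A read shorter than every primer is returned untouched.
#'
#' @param read a mate as built by [read_pair()] (`$mate1`/`$mate2`), i.e. a
#'   list with `chrom`, `seq`, `qual`, `start`, `strand`.
#' @param primers data frame `chrom`, `primer`.
#' @param max_mismatch_frac maximum allowed mismatch fraction (default 0.20).
#' @return the read with the primer removed (and a `trimmed` attribute
#'   giving the trimmed length).
#' @export
trim_primer <- function(read, primers, max_mismatch_frac = 0.20) {
  cand <- primers$primer[primers$chrom == read$chrom]
  cand <- toupper(cand[nchar(cand) <= nchar(read$seq)])
  best <- 0L
  if (length(cand) > 0L) {
    # sequencing-orientation 5' prefix: for "-" mates this is the reverse
    # complement of the reference-orientation 3' suffix
    n <- nchar(read$seq)
    seq_orient <- if (read$strand == "-") revcomp(read$seq) else read$seq
    for (p in cand) {
      L <- nchar(p)
      if (L <= best) next
      mism <- sum(strsplit(substr(seq_orient, 1L, L), "")[[1L]] !=
                  strsplit(p, "")[[1L]])
      if (mism / L <= max_mismatch_frac) best <- L
    }
    if (best > 0L) {
      if (read$strand == "-") {
        keep <- n - best
        read$seq <- substr(read$seq, 1L, keep)
        read$qual <- read$qual[seq_len(keep)]
        # reference start unchanged: bases removed from the reference 3' end
      } else {
        read$seq <- substr(read$seq, best + 1L, n)
        read$qual <- read$qual[(best + 1L):n]
        read$start <- read$start + best
      }
    }
  }
  attr(read, "trimmed") <- best
  read
}

#' Trim primers off both mates of a pair
#'
#' @param pair a [read_pair()].
#' @inheritParams trim_primer
#' @return the pair with both mates primer-trimmed.
#' @export
trim_read_pair <- function(pair, primers, max_mismatch_frac = 0.20) {
  stopifnot(inherits(pair, "read_pair"))
  pair$mate1 <- trim_primer(pair$mate1, primers, max_mismatch_frac)
  if (!is.null(pair$mate2)) {
    pair$mate2 <- trim_primer(pair$mate2, primers, max_mismatch_frac)
  }
  pair
}

#' Overlap-aware base-quality refinement for overlapping mates
#'
#' Short amplicons sequenced with reads longer than half the product length
#' give mates that overlap on the reference; the two observations of each
#' overlapped base are combined. Where the mates agree, both bases get
#' quality `min(q1 + q2, 60)`; where they disagree, the base from the
#' higher-quality mate keeps `max(q_high - q_low, 2)` and the other mate's
#' base quality is set to 2 (on a quality tie, mate 1 is deemed the keeper
#' and both drop to 2). Non-overlapping positions are unchanged. Bases are
#' never edited, only qualities. All output qualities are clamped to
#' [2, 60].
#'
#' @param pair a [read_pair()] whose mates align to the same chromosome.
#' @return the pair with refined qualities.
#' @export
refine_overlap_qualities <- function(pair) {
  stopifnot(inherits(pair, "read_pair"))
  if (is.null(pair$mate2)) return(pair)
  m1 <- pair$mate1; m2 <- pair$mate2
  if (m1$chrom != m2$chrom) {
    stop("mates aligned to different chromosomes: ", m1$chrom, " vs ",
         m2$chrom)
  }
  end1 <- m1$start + nchar(m1$seq) - 1L
  end2 <- m2$start + nchar(m2$seq) - 1L
  lo <- max(m1$start, m2$start)
  hi <- min(end1, end2)
  clamp <- function(q) pmin(pmax(q, 2L), 60L)
  if (lo <= hi) {
    i1 <- (lo - m1$start + 1L):(hi - m1$start + 1L)
    i2 <- (lo - m2$start + 1L):(hi - m2$start + 1L)
    b1 <- strsplit(m1$seq, "")[[1L]][i1]
    b2 <- strsplit(m2$seq, "")[[1L]][i2]
    q1 <- m1$qual[i1]; q2 <- m2$qual[i2]
    agree <- b1 == b2
    nq1 <- q1; nq2 <- q2
    nq1[agree] <- pmin(q1[agree] + q2[agree], 60L)
    nq2[agree] <- nq1[agree]
    dis <- !agree
    one_wins <- dis & q1 >= q2           # mate-1 keeps on ties
    two_wins <- dis & q2 > q1
    nq1[one_wins] <- pmax(q1[one_wins] - q2[one_wins], 2L)
    nq2[one_wins] <- 2L
    nq2[two_wins] <- pmax(q2[two_wins] - q1[two_wins], 2L)
    nq1[two_wins] <- 2L
    m1$qual[i1] <- nq1
    m2$qual[i2] <- nq2
  }
  m1$qual <- clamp(m1$qual)
  m2$qual <- clamp(m2$qual)
  pair$mate1 <- m1
  pair$mate2 <- m2
  pair
}

#' Preprocess aligned read pairs: primer trim, then overlap refinement
#'
#' @param pairs list of [read_pair()] objects.
#' @param primers data frame `chrom`, `primer`, or `NULL` to skip trimming.
#' @param max_mismatch_frac primer mismatch allowance.
#' @return list of processed pairs.
#' @export
preprocess_pairs <- function(pairs, primers = NULL,
                             max_mismatch_frac = 0.20) {
  lapply(pairs, function(p) {
    if (!is.null(primers)) p <- trim_read_pair(p, primers, max_mismatch_frac)
    refine_overlap_qualities(p)
  })
}

# ---- FASTQ / SAM -----------------------------------------------------------

#' Write read pairs as a FASTQ file pair
#'
#' Mate 2 is reverse-complemented back to sequencing orientation on write.
#'
#' @param pairs list of [read_pair()] objects.
#' @param r1_path,r2_path output FASTQ paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  get <- function(mate, rc) {
    seqs <- vapply(pairs, function(p) p[[mate]]$seq, character(1))
    quals <- lapply(pairs, function(p) p[[mate]]$qual)
    if (rc) {
      seqs <- revcomp(seqs)
      quals <- lapply(quals, rev)
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- vapply(pairs, `[[`, character(1), "name")
    q <- Biostrings::PhredQuality(vapply(quals, function(qq)
      rawToChar(as.raw(qq + 33L)), character(1)))
    list(x = x, q = q)
  }
  r1 <- get("mate1", rc = FALSE)
  rc2 <- vapply(pairs, function(p) p$mate2$strand == "-", logical(1))
  stopifnot(all(rc2) || !any(rc2))
  r2 <- get("mate2", rc = all(rc2))
  Biostrings::writeXStringSet(r1$x, r1_path, format = "fastq",
                              qualities = r1$q)
  Biostrings::writeXStringSet(r2$x, r2_path, format = "fastq",
                              qualities = r2$q)
  invisible(r1_path)
}

# SAM flags for a proper pair with mate 2 on the reverse strand
.FLAG1 <- 99L   # paired, proper, mate reverse, first in pair
.FLAG2 <- 147L  # paired, proper, reverse, second in pair

#' Write aligned read pairs as coordinate-sorted SAM text
#'
#' Minimal SAM: the 11 mandatory columns, ungapped CIGAR, MAPQ 60.
#'
#' @param pairs list of [read_pair()] objects.
#' @param path output `.sam` path.
#' @export
write_sam_pairs <- function(pairs, path) {
  recs <- list()
  maxend <- list()
  for (p in pairs) {
    for (m in list(c("mate1", .FLAG1), c("mate2", .FLAG2))) {
      mate <- p[[m[1L]]]
      if (is.null(mate)) next
      other <- p[[if (m[1L] == "mate1") "mate2" else "mate1"]]
      tlen <- if (is.null(other)) 0L else {
        span <- max(mate$start + nchar(mate$seq),
                    other$start + nchar(other$seq)) -
                min(mate$start, other$start)
        if (mate$start <= other$start) span else -span
      }
      recs[[length(recs) + 1L]] <- data.frame(
        qname = p$name, flag = as.integer(m[2L]), rname = mate$chrom,
        pos = mate$start, mapq = 60L,
        cigar = paste0(nchar(mate$seq), "M"),
        rnext = "=", pnext = if (is.null(other)) 0L else other$start,
        tlen = tlen, seq = mate$seq,
        qual = rawToChar(as.raw(mate$qual + 33L)))
      end <- mate$start + nchar(mate$seq) - 1L
      maxend[[mate$chrom]] <- max(end, maxend[[mate$chrom]] %||% 0L)
    }
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$rname, df$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in sort(names(maxend))) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, maxend[[ch]] + 1000L), con)
  }
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                     df$qname, df$flag, df$rname, df$pos, df$mapq, df$cigar,
                     df$rnext, df$pnext, df$tlen, df$seq, df$qual), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read aligned pairs back from minimal SAM text
#'
#' Supports the dialect written by [write_sam_pairs()] (ungapped alignments,
#' paired records sharing a QNAME).
#'
#' @param path `.sam` path.
#' @return list of [read_pair()] objects.
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad) > 0L) {
    stop("malformed SAM record at line ", bad[1L])
  }
  recs <- data.frame(qname = vapply(f, `[[`, "", 1L),
                     flag = as.integer(vapply(f, `[[`, "", 2L)),
                     rname = vapply(f, `[[`, "", 3L),
                     pos = as.integer(vapply(f, `[[`, "", 4L)),
                     seq = vapply(f, `[[`, "", 10L),
                     qual = vapply(f, `[[`, "", 11L))
  out <- list()
  for (qn in unique(recs$qname)) {
    r <- recs[recs$qname == qn, , drop = FALSE]
    first <- r[bitwAnd(r$flag, 64L) > 0L, , drop = FALSE]
    second <- r[bitwAnd(r$flag, 128L) > 0L, , drop = FALSE]
    if (nrow(first) == 0L) { first <- r[1L, ]; second <- r[0L, ] }
    dq <- function(x) as.integer(charToRaw(x)) - 33L
    strand <- function(flag) if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    out[[length(out) + 1L]] <- read_pair(
      chrom = first$rname[1L], name = qn,
      seq1 = first$seq[1L], qual1 = dq(first$qual[1L]),
      start1 = first$pos[1L], strand1 = strand(first$flag[1L]),
      seq2 = if (nrow(second) > 0L) second$seq[1L] else NULL,
      qual2 = if (nrow(second) > 0L) dq(second$qual[1L]) else NULL,
      start2 = if (nrow(second) > 0L) second$pos[1L] else NULL,
      strand2 = if (nrow(second) > 0L) strand(second$flag[1L]) else "-")
  }
  out
}
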