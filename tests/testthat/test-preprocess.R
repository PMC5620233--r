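mk_read <- function(seq, qual = rep(30L, nchar(seq)), start = 100L,
                    strand = "+", chrom = "chr1") {
  list(chrom = chrom, seq = seq, qual = as.integer(qual),
       start = as.integer(start), strand = strand)
}

mutate_prefix <- function(seq, n) {
  # flip the first n bases to a different base
  ch <- strsplit(seq, "")[[1L]]
  for (i in seq_len(n)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1L]
  paste(ch, collapse = "")
}

test_that("primer trimming honors the 20% mismatch allowance boundary", {
  set.seed(4)
  primer <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
  primers <- data.frame(chrom = "chr1", primer = primer)
  rest <- paste(sample(c("A", "C", "G", "T"), 79, replace = TRUE),
                collapse = "")

  # exact 21-bp primer prefix: trimmed, start advanced
  r <- trim_primer(mk_read(paste0(primer, rest)), primers)
  expect_equal(attr(r, "trimmed"), 21L)
  expect_equal(nchar(r$seq), 79L)
  expect_equal(r$start, 121L)
  expect_length(r$qual, 79L)

  # 4 mismatches of 21 (0.190 <= 0.20): still trimmed
  r4 <- trim_primer(mk_read(paste0(mutate_prefix(primer, 4), rest)), primers)
  expect_equal(attr(r4, "trimmed"), 21L)

  # 5 mismatches of 21 (0.238 > 0.20): untouched
  r5 <- trim_primer(mk_read(paste0(mutate_prefix(primer, 5), rest)), primers)
  expect_equal(attr(r5, "trimmed"), 0L)
  expect_equal(nchar(r5$seq), 100L)
  expect_equal(r5$start, 100L)

  # primers on another chromosome never match; short reads are a no-op
  r6 <- trim_primer(mk_read(paste0(primer, rest), chrom = "chr9"), primers)
  expect_equal(attr(r6, "trimmed"), 0L)
  short <- trim_primer(mk_read(substr(primer, 1, 10)), primers)
  expect_equal(attr(short, "trimmed"), 0L)
})

test_that("reverse-strand mates are trimmed at their sequencing 5' end", {
  set.seed(5)
  primer <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  primers <- data.frame(chrom = "chr1", primer = primer)
  core <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  # reference-orientation read ending in revcomp(primer): its sequencing
  # 5' prefix is the primer
  seq <- paste0(core, ctcwga:::revcomp(primer))
  r <- trim_primer(mk_read(seq, start = 500L, strand = "-"), primers)
  expect_equal(attr(r, "trimmed"), 20L)
  expect_equal(r$seq, core)
  expect_equal(r$start, 500L)  # POS unchanged for reverse-strand trims
})

test_that("overlap refinement applies the agreement/disagreement rules", {
  # two 4-bp mates fully overlapping; position-wise: agree, agree,
  # disagree (30 vs 20), disagree tie (25 vs 25)
  p <- read_pair("chr1",
                 seq1 = "ACGT", qual1 = c(30L, 45L, 30L, 25L), start1 = 10L,
                 strand1 = "+",
                 seq2 = "ACTG", qual2 = c(30L, 30L, 20L, 25L), start2 = 10L,
                 strand2 = "-")
  r <- refine_overlap_qualities(p)
  expect_equal(r$mate1$qual, c(60L, 60L, 10L, 2L))  # 30+30, 45+30 capped,
                                                    # 30-20, tie -> 2
  expect_equal(r$mate2$qual, c(60L, 60L, 2L, 2L))
  # bases are never edited
  expect_equal(r$mate1$seq, "ACGT")
  expect_equal(r$mate2$seq, "ACTG")

  # disagreement where mate2 is higher quality
  p2 <- read_pair("chr1", seq1 = "A", qual1 = 11L, start1 = 1L,
                  seq2 = "C", qual2 = 38L, start2 = 1L)
  r2 <- refine_overlap_qualities(p2)
  expect_equal(r2$mate1$qual, 2L)
  expect_equal(r2$mate2$qual, 27L)
})

test_that("non-overlapping pairs pass through unchanged and chromosome
           mismatches are structural errors", {
  p <- read_pair("chr1", seq1 = "ACGT", qual1 = rep(30L, 4), start1 = 1L,
                 seq2 = "ACGT", qual2 = rep(30L, 4), start2 = 100L)
  r <- refine_overlap_qualities(p)
  expect_equal(r$mate1$qual, rep(30L, 4))
  expect_equal(r$mate2$qual, rep(30L, 4))

  bad <- read_pair("chr1", seq1 = "A", qual1 = 30L, start1 = 1L)
  bad$mate2 <- list(chrom = "chr2", seq = "A", qual = 30L, start = 1L,
                    strand = "-")
  expect_error(refine_overlap_qualities(bad), "different chromosomes")
})

test_that("quality monotonicity and saturation on random overlapping pairs", {
  set.seed(11)
  primer <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
  pairs <- simulate_amplicon_read_pairs(25L, 158L, 150L, primer,
                                        error_rate = 0.02)
  for (p in pairs) {
    r <- refine_overlap_qualities(p)
    lo <- max(p$mate1$start, p$mate2$start)
    hi <- min(p$mate1$start, p$mate2$start) + 149L
    i1 <- (lo - p$mate1$start + 1L):(hi - p$mate1$start + 1L)
    i2 <- (lo - p$mate2$start + 1L):(hi - p$mate2$start + 1L)
    agree <- strsplit(p$mate1$seq, "")[[1]][i1] ==
             strsplit(p$mate2$seq, "")[[1]][i2]
    # agreement never lowers, disagreement never raises
    expect_true(all(r$mate1$qual[i1][agree] >= p$mate1$qual[i1][agree]))
    expect_true(all(r$mate1$qual[i1][!agree] <= p$mate1$qual[i1][!agree]))
    expect_true(all(r$mate2$qual[i2][!agree] <= p$mate2$qual[i2][!agree]))
    # refinement is not idempotent, but positions at cap or floor after one
    # application stay fixed under a second
    rr <- refine_overlap_qualities(r)
    fixed <- r$mate1$qual[i1] %in% c(2L, 60L)
    expect_equal(rr$mate1$qual[i1][fixed], r$mate1$qual[i1][fixed])
    fixed2 <- r$mate2$qual[i2] %in% c(2L, 60L)
    expect_equal(rr$mate2$qual[i2][fixed2], r$mate2$qual[i2][fixed2])
    expect_true(all(r$mate1$qual >= 2L & r$mate1$qual <= 60L))
  }
})

test_that("primer trimming and overlap refinement commute when the primer
           lies outside the overlap", {
  set.seed(13)
  primer <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
  primers <- data.frame(chrom = "chr1", primer = primer)
  # amplicon 250 bp, reads 150 bp: overlap is 50 bp in the middle, far from
  # both 21-bp primer ends
  pairs <- simulate_amplicon_read_pairs(10L, 250L, 150L, primer,
                                        error_rate = 0.01)
  for (p in pairs) {
    a <- refine_overlap_qualities(trim_read_pair(p, primers))
    b <- trim_read_pair(refine_overlap_qualities(p), primers)
    expect_equal(a$mate1[c("seq", "qual", "start")],
                 b$mate1[c("seq", "qual", "start")])
    expect_equal(a$mate2[c("seq", "qual", "start")],
                 b$mate2[c("seq", "qual", "start")])
  }
})

test_that("FASTQ and SAM round-trips preserve read pairs", {
  set.seed(17)
  primer <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                  collapse = "")
  pairs <- simulate_amplicon_read_pairs(4L, 158L, 150L, primer,
                                        error_rate = 0.01, chrom = "chr7",
                                        start = 5000L)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_pairs(pairs, sam)
  back <- read_sam_pairs(sam)
  expect_length(back, 4L)
  ord <- match(vapply(pairs, `[[`, "", "name"),
               vapply(back, `[[`, "", "name"))
  for (i in seq_along(pairs)) {
    b <- back[[ord[i]]]
    expect_equal(b$mate1$seq, pairs[[i]]$mate1$seq)
    expect_equal(b$mate1$qual, pairs[[i]]$mate1$qual)
    expect_equal(b$mate2$start, pairs[[i]]$mate2$start)
    expect_equal(b$mate2$qual, pairs[[i]]$mate2$qual)
  }

  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs, r1, r2)
  # Biostrings warns about dropped metadata columns on FASTQ input
  x1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1))
  expect_length(x1, 4L)
  expect_equal(as.character(x1[[1]]), pairs[[1]]$mate1$seq)
  x2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2))
  expect_equal(as.character(x2[[1]]),
               ctcwga:::revcomp(pairs[[1]]$mate2$seq))
})
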