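norm_set <- function(...) make_vs(..., role = "NORMAL")
amp_set <- function(...) make_vs(..., role = "AMPLIFIED_NORMAL")

test_that("amplification-error calling is the key set difference", {
  amp <- amp_set(c("chr1", "chr2"), c(10L, 20L), c("A", "C"), c("G", "T"),
                 sample_id = "AN", patient_id = "P1")
  una <- norm_set("chr1", 10L, "A", "G", sample_id = "N", patient_id = "P1")
  e <- call_amplification_errors(amp, una)
  expect_equal(nrow(e), 1L)
  expect_equal(e$chrom, "chr2")

  same <- call_amplification_errors(amp, amp_set(
    c("chr1", "chr2"), c(10L, 20L), c("A", "C"), c("G", "T"),
    sample_id = "N2", patient_id = "P1"))
  expect_equal(nrow(same), 0L)

  empty <- amp_set(character(0), integer(0), character(0), character(0),
                   sample_id = "AN0", patient_id = "P1")
  expect_equal(nrow(call_amplification_errors(empty, una)), 0L)

  other <- norm_set("chr1", 10L, "A", "G", sample_id = "N", patient_id = "P9")
  expect_error(call_amplification_errors(amp, other), "pairing error")
})

test_that("blacklist membership follows the min_recurrence rule", {
  mk_err <- function(i, chrom, pos, ref, alt, alt_count = 2L) {
    e <- amp_set(chrom, pos, ref, alt, depth = 400L, alt_count = alt_count,
                 sample_id = paste0("AN", i), patient_id = paste0("P", i))
    call_amplification_errors(e, norm_set(character(0), integer(0),
                                          character(0), character(0),
                                          sample_id = paste0("N", i),
                                          patient_id = paste0("P", i)))
  }
  sets <- c(
    lapply(1:2, function(i) mk_err(i, c("chr1", "chr2"), c(10L, 20L),
                                   c("A", "C"), c("G", "T"))),
    lapply(3:14, function(i) mk_err(i, "chr1", 10L, "A", "G")))
  expect_error(build_blacklist(sets[1]), "insufficient controls")
  b <- build_blacklist(sets)
  # chr1:10:A>G in all 14 sets, chr2:20:C>T in 2 sets: both blacklisted
  expect_equal(sort(b$n_samples), c(2L, 14L))
  b3 <- build_blacklist(sets, min_recurrence = 3L)
  expect_equal(b3$n_samples, 14L)
})

test_that("blacklist entry medians are the order statistics of the
           per-sample VAFs", {
  mk_err <- function(i, alt_count) {
    e <- amp_set("chr1", 10L, "A", "G", depth = 1000L,
                 alt_count = alt_count, sample_id = paste0("AN", i),
                 patient_id = paste0("P", i))
    call_amplification_errors(e, norm_set(character(0), integer(0),
                                          character(0), character(0),
                                          sample_id = paste0("N", i),
                                          patient_id = paste0("P", i)))
  }
  counts <- c(4L, 5L, 6L, 7L, 8L)
  sets <- lapply(seq_along(counts), function(i) mk_err(i, counts[i]))
  b <- build_blacklist(sets)
  expect_equal(b$n_samples, 5L)
  expect_equal(b$vaf_median, 0.006)  # middle order statistic of 4..8/1000
})

test_that("blacklist construction equals brute-force incidence counting on
           random toy cohorts", {
  set.seed(21)
  for (trial in 1:20) {
    n_samples <- sample(2:5, 1L)
    sets <- lapply(seq_len(n_samples), function(i) {
      n <- sample(0:20, 1L)
      pos <- sample(1:30, n, replace = FALSE)
      e <- amp_set(rep("chr1", n), pos * 10L, rep("A", n),
                   sample(c("C", "G", "T"), n, replace = TRUE),
                   depth = 400L,
                   alt_count = sample(2:8, max(n, 1L),
                                      replace = TRUE)[seq_len(n)],
                   sample_id = paste0("AN", i),
                   patient_id = paste0("P", i))
      call_amplification_errors(e, norm_set(character(0), integer(0),
                                            character(0), character(0),
                                            sample_id = paste0("N", i),
                                            patient_id = paste0("P", i)))
    })
    min_rec <- sample(2:3, 1L)
    b <- build_blacklist(sets, min_recurrence = min_rec)
    # brute force over all (key, sample) incidence pairs
    inc <- unique(do.call(rbind, lapply(seq_along(sets), function(i) {
      s <- sets[[i]]
      if (nrow(s) == 0L) return(NULL)
      data.frame(key = paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"),
                 sample = i)
    })))
    expected_keys <- if (is.null(inc)) character(0) else {
      tab <- table(inc$key)
      sort(names(tab)[tab >= min_rec])
    }
    got_keys <- sort(paste(b$chrom, b$pos, b$ref, b$alt, sep = ":"))
    expect_equal(got_keys, expected_keys)
    # monotonicity: raising min_recurrence never adds entries
    b_up <- build_blacklist(sets, min_recurrence = min_rec + 1L)
    expect_true(all(paste(b_up$chrom, b_up$pos, b_up$ref, b_up$alt) %in%
                    paste(b$chrom, b$pos, b$ref, b$alt)))
  }
})

test_that("error-VAF summary partitions every observation exactly once", {
  co <- generate_cohort(cohort_config(n_patients = 6L,
                                      n_amplified_normals = 6L,
                                      n_genes = 6L, total_length = 30000L,
                                      n_recurrent_hotspots = 50L,
                                      random_errors_per_amplified_normal = 40,
                                      seed = 31L))
  sets <- lapply(co$patients, function(p)
    call_amplification_errors(p$samples$amplified_normal, p$samples$normal))
  b <- build_blacklist(sets)
  s <- summarize_error_vafs(sets, b)
  expect_equal(s$n_recurrent + s$n_nonrecurrent, s$n_total)
  expect_equal(s$n_total, sum(vapply(sets, nrow, integer(1))))
  expect_true(s$recurrent_vaf_median > 0 && s$nonrecurrent_vaf_median > 0)

  one <- summarize_error_vafs(sets[1], make_blacklist())
  expect_true(is.na(one$recurrent_vaf_median))  # empty partition is NA
  expect_equal(one$nonrecurrent_vaf_median, median(sets[[1]]$vaf))
})

test_that("single error observation is its own partition median", {
  e <- call_amplification_errors(
    amp_set("chr1", 10L, "A", "G", depth = 500L, alt_count = 9L,
            sample_id = "AN", patient_id = "P1"),
    norm_set(character(0), integer(0), character(0), character(0),
             sample_id = "N", patient_id = "P1"))
  s <- summarize_error_vafs(list(e), make_blacklist())
  expect_equal(s$nonrecurrent_vaf_median, 9 / 500)
  expect_true(is.na(s$recurrent_vaf_median))
})

test_that("false-positive match rate reproduces the printed worked example", {
  # 1,915 threshold-passing artifact variants, 4 matching the paired tumor
  set.seed(41)
  n <- 1915L
  pos <- seq_len(n) * 10L
  err <- amp_set(rep("chr1", n), pos, rep("A", n), rep("G", n),
                 depth = 400L, alt_count = 8L,   # VAF 2% > 1%
                 sample_id = "AN1", patient_id = "P1")
  e <- call_amplification_errors(err, norm_set(character(0), integer(0),
                                               character(0), character(0),
                                               sample_id = "N1",
                                               patient_id = "P1"))
  tumor <- make_vs(rep("chr1", 4), pos[c(3L, 500L, 1200L, 1915L)],
                   rep("A", 4), rep("G", 4), depth = 400L, alt_count = 200L,
                   sample_id = "T1", patient_id = "P1", role = "TUMOR")
  fp <- estimate_fp_match_rate(list(e), make_blacklist(), list(tumor))
  expect_equal(fp$n_total, 1915L)
  expect_equal(fp$n_match, 4L)
  expect_equal(fp$rate_percent, 0.2)
  expect_equal(expected_chance_matches(fp$rate_percent, 1000), 2)

  # no matches: rate 0.0
  no_match_tumor <- make_vs("chr2", 5L, "C", "T", sample_id = "T1",
                            patient_id = "P1", role = "TUMOR")
  fp0 <- estimate_fp_match_rate(list(e), make_blacklist(),
                                list(no_match_tumor))
  expect_equal(fp0$rate_percent, 0)

  # VAF exactly at the threshold is excluded (strict >): rate undefined
  at_thr <- call_amplification_errors(
    amp_set("chr1", 10L, "A", "G", depth = 400L, alt_count = 4L,
            sample_id = "AN1", patient_id = "P1"),
    norm_set(character(0), integer(0), character(0), character(0),
             sample_id = "N1", patient_id = "P1"))
  expect_equal(at_thr$vaf, 0.01)
  expect_error(estimate_fp_match_rate(list(at_thr), make_blacklist(),
                                      list(tumor)),
               "undefined rate")
})
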