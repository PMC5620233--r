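test_that("blacklist removal and the strict AF threshold behave at the
           boundary and commute", {
  b <- make_blacklist("chr1", 100L, "A", "G")
  s <- make_vs(c("chr1", "chr1", "chr1"), c(100L, 200L, 300L),
               c("A", "C", "G"), c("G", "T", "A"),
               depth = c(1000L, 1000L, 10000L),
               alt_count = c(50L, 10L, 101L),   # VAF 5%, exactly 1%, 1.01%
               sample_id = "C1", patient_id = "P1", role = "CTC_WGA",
               replicate_index = 1L)
  nb <- remove_blacklisted(s, b)
  expect_equal(nrow(nb), 2L)               # blacklisted key dropped
  expect_false("100" %in% as.character(nb$pos))
  thr <- apply_af_threshold(nb, 0.01)
  expect_equal(thr$pos, 300L)              # 1% removed (strict), 1.01% kept

  expect_equal(nrow(remove_blacklisted(s, make_blacklist())), 3L)
  expect_equal(nrow(apply_af_threshold(s, 0)), 3L)  # only vaf == 0 removed

  a <- apply_af_threshold(remove_blacklisted(s, b), 0.01)
  c <- remove_blacklisted(apply_af_threshold(s, 0.01), b)
  expect_equal(as.data.frame(a), as.data.frame(c))
})

test_that("tumor-matched calls are the key intersection with CTC VAFs", {
  ctc <- make_vs(c("chr1", "chr2"), c(10L, 20L), c("A", "C"), c("G", "T"),
                 depth = 400L, alt_count = c(20L, 30L),
                 sample_id = "C1", patient_id = "P1", role = "CTC_WGA",
                 replicate_index = 1L)
  tumor <- make_vs(c("chr2", "chr3"), c(20L, 9L), c("C", "G"), c("T", "A"),
                   depth = 300L, alt_count = 150L,
                   sample_id = "T1", patient_id = "P1", role = "TUMOR")
  m <- tumor_matched_calls(ctc, tumor)
  expect_equal(nrow(m), 1L)
  expect_equal(m$chrom, "chr2")
  expect_equal(m$vaf, 30 / 400)            # CTC VAF, not tumor VAF

  expect_equal(nrow(tumor_matched_calls(
    ctc, make_vs(character(0), integer(0), character(0), character(0),
                 sample_id = "T1", patient_id = "P1", role = "TUMOR"))), 0L)
  expect_equal(as.data.frame(tumor_matched_calls(ctc, make_vs(
    c("chr1", "chr2"), c(10L, 20L), c("A", "C"), c("G", "T"),
    depth = 400L, alt_count = c(20L, 30L), sample_id = "T1",
    patient_id = "P1", role = "TUMOR"))), as.data.frame(ctc))
  other <- make_vs("chr2", 20L, "C", "T", sample_id = "T9",
                   patient_id = "P9", role = "TUMOR")
  expect_error(tumor_matched_calls(ctc, other), "pairing error")
})

test_that("replicate-concordant private calls require both replicates and
           exclude blacklist and tumor keys", {
  mk_rep <- function(i, pos) {
    make_vs(rep("chr1", length(pos)), pos, rep("A", length(pos)),
            rep("G", length(pos)), depth = 400L, alt_count = 32L,
            sample_id = paste0("C", i), patient_id = "P1", role = "CTC_WGA",
            replicate_index = i)
  }
  rep1 <- mk_rep(1L, c(100L, 200L, 300L, 400L))
  rep2 <- mk_rep(2L, c(100L, 300L, 400L, 500L))
  tumor <- make_vs("chr1", 400L, "A", "G", depth = 300L, alt_count = 150L,
                   sample_id = "T1", patient_id = "P1", role = "TUMOR")
  b <- make_blacklist("chr1", 300L, "A", "G")
  priv <- replicate_concordant_private(rep1, rep2, tumor, b)
  # 100: in both reps, clean -> kept; 200: rep1 only; 300: blacklisted;
  # 400: tumor-matched; 500: rep2 only
  expect_equal(priv$pos, 100L)
  expect_equal(priv$vaf, 0.08)             # mean of the replicate VAFs
  expect_equal(priv$vaf_rep1, priv$vaf_rep2)
  expect_error(replicate_concordant_private(rep1, rep1, tumor, b),
               "pairing error")
})

test_that("the filter funnel is monotone on every synthetic run", {
  co <- generate_cohort(cohort_config(n_patients = 8L,
                                      n_amplified_normals = 4L,
                                      n_genes = 8L, total_length = 40000L,
                                      random_errors_per_ctc = 60,
                                      seed = 77L))
  sets <- lapply(co$patients[1:4], function(p)
    call_amplification_errors(p$samples$amplified_normal, p$samples$normal))
  b <- build_blacklist(sets)
  for (p in co$patients) {
    for (s in p$samples$ctc) {
      r <- filter_ctc_sample(s, b, p$samples$tumor)
      tr <- r$trace
      expect_lte(tr[["after_blacklist"]], tr[["input"]])
      expect_lte(tr[["after_af_threshold"]], tr[["after_blacklist"]])
      expect_lte(tr[["tumor_matched"]], tr[["after_af_threshold"]])
      expect_equal(tr[["tumor_matched"]], nrow(r$calls))
    }
  }
})

test_that("tumor-matched calls on synthetic cohorts recover truth up to
           rare chance matches", {
  co <- generate_cohort(cohort_config(n_patients = 10L,
                                      n_amplified_normals = 4L,
                                      n_genes = 5L, total_length = 20000L,
                                      ctc_positive_fraction = 1,
                                      subclone_prob = 0, seed = 101L))
  sets <- lapply(co$patients[1:4], function(p)
    call_amplification_errors(p$samples$amplified_normal, p$samples$normal))
  b <- build_blacklist(sets)
  n_chance <- 0L; n_calls <- 0L
  for (p in co$patients) {
    truth_keys <- variant_keys(p$tumor_truth)
    for (s in p$samples$ctc) {
      r <- filter_ctc_sample(s, b, p$samples$tumor)
      k <- paste(r$calls$chrom, r$calls$pos, r$calls$ref,
                 r$calls$alt, sep = ":")
      n_calls <- n_calls + length(k)
      n_chance <- n_chance + sum(!(k %in% truth_keys))
    }
  }
  expect_gt(n_calls, 0L)
  # chance-match probability per error variant is bounded by
  # n_tumor_mutations / (3 * panel length); with ~150 retained errors per
  # sample the expected chance matches stay well below 1 per sample
  expect_lt(n_chance / n_calls, 0.05)
})

test_that("cohort detection summary counts patients and averages retained
           variants", {
  mk_res <- function(counts, matched) {
    lapply(seq_along(counts), function(i) {
      list(trace = c(input = counts[i] + 5, after_blacklist = counts[i] + 2,
                     after_af_threshold = counts[i],
                     tumor_matched = matched[i]))
    })
  }
  res <- list(mk_res(c(80, 88), c(3, 0)),    # detected
              mk_res(c(10, 20), c(0, 0)),    # not detected
              mk_res(c(50, 50), c(0, 1)))    # detected
  s <- cohort_detection_summary(res)
  expect_equal(s$n_detected, 2L)
  expect_equal(s$n_total, 3L)
  expect_equal(s$percent, 67)
  expect_equal(s$mean_variants_per_ctc_sample, mean(c(80, 88, 10, 20,
                                                      50, 50)))
  expect_error(cohort_detection_summary(list()), "zero patients")
  # the printed study proportion: 29 of 48 rounds to 60%
  res29 <- c(replicate(29, mk_res(5, 1), simplify = FALSE),
             replicate(19, mk_res(5, 0), simplify = FALSE))
  expect_equal(cohort_detection_summary(res29)$percent, 60)
})
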