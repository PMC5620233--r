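# Fixture builders shared across the suite; everything is generated in code.

# quick variant_set from parallel vectors
make_vs <- function(chrom, pos, ref, alt, depth = 100L, alt_count = 10L,
                    sample_id = "S1", patient_id = "P1", role = "TUMOR",
                    replicate_index = NA_integer_) {
  n <- length(chrom)
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         depth = rep_len(depth, n),
                         alt_count = rep_len(alt_count, n)),
              sample_id = sample_id, patient_id = patient_id, role = role,
              replicate_index = replicate_index)
}

empty_hotspots <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0))
}

# blacklist with given keys (vaf_median/n_samples are placeholders)
make_blacklist <- function(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0)) {
  s1 <- make_vs(chrom, pos, ref, alt, sample_id = "B1", patient_id = "PB",
                role = "AMPLIFIED_NORMAL")
  s2 <- make_vs(chrom, pos, ref, alt, sample_id = "B2", patient_id = "PB",
                role = "AMPLIFIED_NORMAL")
  empty_norm <- make_vs(character(0), integer(0), character(0), character(0),
                        sample_id = "BN", patient_id = "PB", role = "NORMAL")
  e1 <- call_amplification_errors(s1, empty_norm)
  e2 <- call_amplification_errors(s2, empty_norm)
  build_blacklist(list(e1, e2), min_recurrence = 2L)
}

# random valid minimal variant (used to build padded representations)
random_minimal_variant <- function() {
  bases <- c("A", "C", "G", "T")
  kind <- sample(c("snv", "ins", "del"), 1L)
  pos <- sample(50:500, 1L)
  if (kind == "snv") {
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
  } else {
    anchor <- sample(bases, 1L)
    tail <- paste(sample(bases, sample(1:4, 1L), replace = TRUE),
                  collapse = "")
    if (kind == "ins") { ref <- anchor; alt <- paste0(anchor, tail) }
    else { ref <- paste0(anchor, tail); alt <- anchor }
  }
  list(chrom = "chr1", pos = pos, ref = ref, alt = alt)
}

# pad a minimal variant with a shared prefix/suffix (a redundant but valid
# representation of the same mutation)
pad_variant <- function(v, n_prefix = sample(0:3, 1L),
                        n_suffix = sample(0:3, 1L)) {
  bases <- c("A", "C", "G", "T")
  pre <- paste(sample(bases, n_prefix, replace = TRUE), collapse = "")
  suf <- paste(sample(bases, n_suffix, replace = TRUE), collapse = "")
  list(chrom = v$chrom, pos = v$pos - n_prefix,
       ref = paste0(pre, v$ref, suf), alt = paste0(pre, v$alt, suf))
}

# independent trimming oracle: enumerate every (suffix, prefix) trim depth
# that leaves equal flanks and both alleles non-empty; apply the deepest
# suffix trim then the deepest prefix trim (keeping one anchor base each)
oracle_normalize <- function(pos, ref, alt) {
  rc <- strsplit(ref, "")[[1L]]
  ac <- strsplit(alt, "")[[1L]]
  max_s <- 0L
  for (s in seq_len(min(length(rc), length(ac)) - 1L)) {
    rs <- rc[(length(rc) - s + 1L):length(rc)]
    as <- ac[(length(ac) - s + 1L):length(ac)]
    if (identical(rs, as)) max_s <- s
  }
  if (max_s > 0L) {
    rc <- rc[seq_len(length(rc) - max_s)]
    ac <- ac[seq_len(length(ac) - max_s)]
  }
  max_p <- 0L
  for (p in seq_len(min(length(rc), length(ac)) - 1L)) {
    if (identical(rc[seq_len(p)], ac[seq_len(p)])) max_p <- p
  }
  if (max_p > 0L) {
    rc <- rc[(max_p + 1L):length(rc)]
    ac <- ac[(max_p + 1L):length(ac)]
    pos <- pos + max_p
  }
  list(pos = pos, ref = paste(rc, collapse = ""),
       alt = paste(ac, collapse = ""))
}

# exhaustive-permutation two-sided Mann-Whitney p: enumerate every
# assignment of ranks to the first group
oracle_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  idx <- utils::combn(n + m, n)
  r <- rank(vals)
  us <- apply(idx, 2L, function(i) sum(r[i]) - n * (n + 1) / 2)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_min <- min(u_obs, n * m - u_obs)
  min(1, 2 * mean(us <= u_min))
}

# small calibration cohort for the null association test
calibration_config <- function(seed, slope = 0) {
  cohort_config(n_patients = 30L, n_genes = 5L, total_length = 5000L,
                n_amplified_normals = 2L, n_recurrent_hotspots = 20L,
                random_errors_per_amplified_normal = 5,
                random_errors_per_ctc = 5, tumor_mutations_mean = 6,
                ctc_positive_fraction = 1, n_wga_replicates = 1L,
                subclone_prob = 0, cea_slope = slope, cea_intercept = 0,
                cea_missing_prob = 0, seed = seed)
}

# pooled tumor-matched call rows (with alleles) across a cohort
pooled_calls_variants <- function(cohort, min_vaf = 0.01) {
  out <- lapply(cohort$patients, function(p) {
    s <- tumor_matched_calls(apply_af_threshold(p$samples$ctc[[1L]],
                                                min_vaf),
                             p$samples$tumor)
    if (nrow(s) == 0L) return(NULL)
    as.data.frame(s)
  })
  do.call(rbind, out)
}

# pooled tumor-matched calls of a cohort without blacklist removal
# (association fixtures do not need the error model)
pooled_calls <- function(cohort, min_vaf = 0.01) {
  out <- lapply(cohort$patients, function(p) {
    s <- tumor_matched_calls(apply_af_threshold(p$samples$ctc[[1L]],
                                                min_vaf),
                             p$samples$tumor)
    if (nrow(s) == 0L) return(NULL)
    data.frame(patient_id = p$patient_id, vaf = s$vaf)
  })
  do.call(rbind, out)
}
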