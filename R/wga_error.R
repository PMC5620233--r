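#' Call amplification errors from a matched amplified/unamplified pair
#'
#' Variant calls present in a WGA-amplified normal sample but absent from
#' the same patient's unamplified normal are, by construction, errors
#' introduced by the amplification. The comparison is a set difference on
#' normalized variant keys; VAFs are carried from the amplified sample.
#'
#' @param amplified `AMPLIFIED_NORMAL` [variant_set()].
#' @param unamplified `NORMAL` [variant_set()] from the same patient.
#' @return an `error_call_set`: the amplified-only variants as a
#'   [variant_set()]-like data frame with attribute `patient_id`.
#' @export
call_amplification_errors <- function(amplified, unamplified) {
  stopifnot(inherits(amplified, "variant_set"),
            inherits(unamplified, "variant_set"))
  if (!identical(attr(amplified, "patient_id"),
                 attr(unamplified, "patient_id"))) {
    stop("pairing error: amplified sample is from patient ",
         attr(amplified, "patient_id"), ", unamplified from ",
         attr(unamplified, "patient_id"))
  }
  keep <- !(set_keys(amplified) %in% set_keys(unamplified))
  out <- subset_variant_set(amplified, keep)
  class(out) <- c("error_call_set", class(out))
  out
}

#' Build the recurrent WGA-error blacklist
#'
#' A variant key enters the blacklist iff it is observed in at least
#' `min_recurrence` distinct amplified-normal error sets. Each entry records
#' how many samples carried it and the median VAF across those occurrences.
#'
#' @param error_sets list of error sets from [call_amplification_errors()]
#'   (at least 2: recurrence is undefined with a single control).
#' @param min_recurrence minimum number of distinct samples (default 2).
#' @return a `wga_blacklist`: data frame `chrom`, `pos`, `ref`, `alt`,
#'   `n_samples`, `vaf_median`, keyed by normalized variant.
#' @export
build_blacklist <- function(error_sets, min_recurrence = 2L) {
  if (length(error_sets) < 2L) {
    stop("insufficient controls: need >= 2 amplified-normal error sets, got ",
         length(error_sets))
  }
  min_recurrence <- as.integer(min_recurrence)
  stopifnot(min_recurrence >= 1L)
  obs <- do.call(rbind, lapply(seq_along(error_sets), function(i) {
    s <- error_sets[[i]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(key = set_keys(s), chrom = s$chrom, pos = s$pos,
               ref = s$ref, alt = s$alt, vaf = s$vaf, sample = i)
  }))
  if (is.null(obs) || nrow(obs) == 0L) {
    return(.as_blacklist(data.frame(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    n_samples = integer(0),
                                    vaf_median = numeric(0)),
                         min_recurrence))
  }
  n_samp <- tapply(obs$sample, obs$key, function(s) length(unique(s)))
  keys <- names(n_samp)[n_samp >= min_recurrence]
  if (length(keys) == 0L) {
    return(.as_blacklist(data.frame(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    n_samples = integer(0),
                                    vaf_median = numeric(0)),
                         min_recurrence))
  }
  sel <- obs[obs$key %in% keys, , drop = FALSE]
  agg <- do.call(rbind, lapply(split(sel, sel$key), function(g) {
    data.frame(chrom = g$chrom[1L], pos = g$pos[1L], ref = g$ref[1L],
               alt = g$alt[1L], n_samples = length(unique(g$sample)),
               vaf_median = median(g$vaf))
  }))
  agg <- agg[order(agg$chrom, agg$pos, agg$ref, agg$alt), , drop = FALSE]
  rownames(agg) <- NULL
  .as_blacklist(agg, min_recurrence)
}

.as_blacklist <- function(df, min_recurrence) {
  df$pos <- as.integer(df$pos)
  df$n_samples <- as.integer(df$n_samples)
  structure(df, min_recurrence = as.integer(min_recurrence),
            class = c("wga_blacklist", "data.frame"))
}

blacklist_keys <- function(b) {
  if (nrow(b) == 0L) return(character(0))
  paste(b$chrom, b$pos, b$ref, b$alt, sep = ":")
}

#' @export
print.wga_blacklist <- function(x, ...) {
  cat(sprintf(paste0("<wga_blacklist> %d recurrent WGA-error variants ",
                     "(seen in >= %d samples); median VAF %s\n"),
              nrow(x), attr(x, "min_recurrence"),
              if (nrow(x) > 0L)
                sprintf("%.4f", median(x$vaf_median)) else "-"))
  invisible(x)
}

#' Summarize error VAFs by recurrence class
#'
#' Partitions every error observation (across all error sets) into
#' recurrent (key present in the blacklist) vs non-recurrent, and reports
#' the median VAF and size of each partition. An empty partition's median is
#' `NA`, never zero.
#'
#' @param error_sets list of error sets (see
#'   [call_amplification_errors()]).
#' @param blacklist a [build_blacklist()] result built from the same sets.
#' @return list with `recurrent_vaf_median`, `nonrecurrent_vaf_median`
#'   (fractions), `n_recurrent`, `n_nonrecurrent`, `n_total`.
#' @export
summarize_error_vafs <- function(error_sets, blacklist) {
  stopifnot(inherits(blacklist, "wga_blacklist"))
  bkeys <- blacklist_keys(blacklist)
  vafs <- unlist(lapply(error_sets, function(s) s$vaf), use.names = FALSE)
  keys <- unlist(lapply(error_sets, set_keys), use.names = FALSE)
  rec <- keys %in% bkeys
  list(recurrent_vaf_median = if (any(rec)) median(vafs[rec]) else NA_real_,
       nonrecurrent_vaf_median = if (any(!rec)) median(vafs[!rec])
                                 else NA_real_,
       n_recurrent = sum(rec),
       n_nonrecurrent = sum(!rec),
       n_total = length(keys))
}

#' Estimate the false-positive tumor-match rate from amplified normals
#'
#' Amplified-normal error variants that survive the blacklist and the
#' strict `> min_vaf` allele-frequency threshold are pure WGA artifacts;
#' the fraction of them that nonetheless match a somatic variant in the
#' same patient's tumor estimates how often an artifact would be
#' misclassified as a tumor-derived mutation.
#'
#' @param error_sets list of error sets, one per amplified-normal sample.
#' @param blacklist a [build_blacklist()] result.
#' @param tumor_sets list of `TUMOR` [variant_set()]s covering the same
#'   patients.
#' @param min_vaf strict lower VAF bound (default 0.01, i.e. keep > 1%).
#' @return list with `n_match`, `n_total` (post-blacklist, post-threshold),
#'   `n_total_incl_blacklisted` (pre-blacklist threshold-passing count) and
#'   `rate_percent` (one decimal).
#' @export
estimate_fp_match_rate <- function(error_sets, blacklist, tumor_sets,
                                   min_vaf = 0.01) {
  stopifnot(inherits(blacklist, "wga_blacklist"))
  tumor_by_patient <- list()
  for (t in tumor_sets) {
    tumor_by_patient[[attr(t, "patient_id")]] <- set_keys(t)
  }
  bkeys <- blacklist_keys(blacklist)
  n_match <- 0L; n_total <- 0L; n_pre <- 0L
  for (s in error_sets) {
    pid <- attr(s, "patient_id")
    if (is.null(tumor_by_patient[[pid]])) {
      stop("pairing error: no tumor sample for patient ", pid)
    }
    keys <- set_keys(s)
    pass_vaf <- s$vaf > min_vaf
    n_pre <- n_pre + sum(pass_vaf)
    keep <- pass_vaf & !(keys %in% bkeys)
    n_total <- n_total + sum(keep)
    n_match <- n_match + sum(keys[keep] %in% tumor_by_patient[[pid]])
  }
  if (n_total == 0L) {
    stop("undefined rate: no error variants pass the blacklist and the VAF ",
         "threshold")
  }
  list(n_match = n_match, n_total = n_total,
       n_total_incl_blacklisted = n_pre,
       rate_percent = round(100 * n_match / n_total, 1))
}

#' Expected chance tumor-matches among a batch of calls
#'
#' Given a false-positive match rate (percent), the expected number of calls
#' in a batch of `n_calls` that would match a tumor mutation by chance.
#'
#' @param rate_percent false-positive match rate in percent (e.g. from
#'   [estimate_fp_match_rate()]).
#' @param n_calls batch size (default 1000).
#' @return expected count.
#' @export
expected_chance_matches <- function(rate_percent, n_calls = 1000) {
  stopifnot(rate_percent >= 0, n_calls >= 0)
  rate_percent / 100 * n_calls
}
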