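#' Remove blacklisted recurrent WGA errors from a sample
#'
#' @param s a [variant_set()].
#' @param blacklist a [build_blacklist()] result.
#' @return the set without variants whose normalized key is blacklisted.
#' @export
remove_blacklisted <- function(s, blacklist) {
  stopifnot(inherits(s, "variant_set"), inherits(blacklist, "wga_blacklist"))
  subset_variant_set(s, !(set_keys(s) %in% blacklist_keys(blacklist)))
}

#' Keep variants with allele frequency strictly above a threshold
#'
#' The threshold is strict: a variant at exactly `min_vaf` is removed
#' (keep "> 1%", not ">= 1%").
#'
#' @param s a [variant_set()].
#' @param min_vaf threshold in `[0, 1)`; default 0.01.
#' @return the thresholded set.
#' @export
apply_af_threshold <- function(s, min_vaf = 0.01) {
  stopifnot(inherits(s, "variant_set"), min_vaf >= 0, min_vaf < 1)
  if (nrow(s) > 0L && any(s$vaf < 0)) stop("data error: negative vaf")
  subset_variant_set(s, s$vaf > min_vaf)
}

#' Tumor-matched CTC calls
#'
#' Intersection of a CTC sample with the matched primary tumor, by
#' normalized variant key; depths and VAFs are reported from the CTC
#' sample. Only variants also seen in the tumor are considered genuine,
#' which trades sensitivity to CTC-private subclones for robustness against
#' residual WGA artifacts.
#'
#' @param ctc `CTC_WGA` [variant_set()].
#' @param tumor `TUMOR` [variant_set()] from the same patient.
#' @return the tumor-matched subset of `ctc`.
#' @export
tumor_matched_calls <- function(ctc, tumor) {
  stopifnot(inherits(ctc, "variant_set"), inherits(tumor, "variant_set"))
  if (!identical(attr(ctc, "patient_id"), attr(tumor, "patient_id"))) {
    stop("pairing error: CTC sample is from patient ",
         attr(ctc, "patient_id"), ", tumor from ", attr(tumor, "patient_id"))
  }
  subset_variant_set(ctc, set_keys(ctc) %in% set_keys(tumor))
}

#' Replicate-concordant CTC-private calls
#'
#' Candidate disseminated-subclone mutations: variants present in BOTH
#' independent WGA replicates of one CTC capture, absent from the
#' recurrent-error blacklist, and NOT matching any variant of the same
#' patient's tumor. Reported VAF is the mean of the two replicate VAFs;
#' depth and alt_count are taken from replicate 1.
#'
#' @param rep1,rep2 AF-thresholded `CTC_WGA` [variant_set()]s, independent
#'   WGA replicates of the same capture.
#' @param tumor matched `TUMOR` [variant_set()].
#' @param blacklist a [build_blacklist()] result.
#' @return a data frame of private calls (`chrom`, `pos`, `ref`, `alt`,
#'   `vaf` = mean replicate VAF, `vaf_rep1`, `vaf_rep2`).
#' @export
replicate_concordant_private <- function(rep1, rep2, tumor, blacklist) {
  stopifnot(inherits(rep1, "variant_set"), inherits(rep2, "variant_set"))
  pid <- attr(rep1, "patient_id")
  if (!identical(pid, attr(rep2, "patient_id")) ||
      !identical(pid, attr(tumor, "patient_id"))) {
    stop("pairing error: replicates and tumor must share one patient")
  }
  if (identical(attr(rep1, "sample_id"), attr(rep2, "sample_id")) &&
      identical(attr(rep1, "replicate_index"),
                attr(rep2, "replicate_index"))) {
    stop("pairing error: two distinct WGA replicates are required")
  }
  k1 <- set_keys(rep1); k2 <- set_keys(rep2)
  shared <- intersect(k1, k2)
  shared <- setdiff(shared, blacklist_keys(blacklist))
  shared <- setdiff(shared, set_keys(tumor))
  out <- as.data.frame(rep1)[match(shared, k1),
                             c("chrom", "pos", "ref", "alt", "depth",
                               "alt_count"), drop = FALSE]
  out$vaf_rep1 <- rep1$vaf[match(shared, k1)]
  out$vaf_rep2 <- rep2$vaf[match(shared, k2)]
  out$vaf <- (out$vaf_rep1 + out$vaf_rep2) / 2
  rownames(out) <- NULL
  out
}

#' Run the full filter cascade on one CTC sample
#'
#' Stage order: blacklist removal, then the strict allele-frequency
#' threshold, then tumor-matched intersection. Returns the calls plus an
#' auditable per-stage funnel count (`filter_trace`).
#'
#' @param ctc `CTC_WGA` [variant_set()].
#' @param blacklist a [build_blacklist()] result.
#' @param tumor matched `TUMOR` [variant_set()].
#' @param min_vaf strict VAF threshold (default 0.01).
#' @return list with `calls` (tumor-matched [variant_set()]), `retained`
#'   (post-threshold, pre-matching set) and `trace` (named counts: `input`,
#'   `after_blacklist`, `after_af_threshold`, `tumor_matched`).
#' @export
filter_ctc_sample <- function(ctc, blacklist, tumor, min_vaf = 0.01) {
  s1 <- remove_blacklisted(ctc, blacklist)
  s2 <- apply_af_threshold(s1, min_vaf)
  calls <- tumor_matched_calls(s2, tumor)
  trace <- c(input = nrow(ctc), after_blacklist = nrow(s1),
             after_af_threshold = nrow(s2), tumor_matched = nrow(calls))
  stopifnot(trace["after_blacklist"] <= trace["input"],
            trace["after_af_threshold"] <= trace["after_blacklist"],
            trace["tumor_matched"] <= trace["after_af_threshold"])
  list(calls = calls, retained = s2, trace = trace)
}

#' Cohort-level detection summary
#'
#' A patient counts as detected iff at least one tumor-matched call was
#' made in any of their CTC samples. The mean retained-variant count is the
#' post-blacklist, post-threshold, pre-matching mean over all CTC samples.
#'
#' @param patient_results list (one element per patient) of lists of
#'   [filter_ctc_sample()] results (one per CTC sample).
#' @return list with `n_detected`, `n_total`, `percent` (nearest integer),
#'   `mean_variants_per_ctc_sample`.
#' @export
cohort_detection_summary <- function(patient_results) {
  if (length(patient_results) == 0L) stop("zero patients")
  detected <- vapply(patient_results, function(res) {
    any(vapply(res, function(r) r$trace[["tumor_matched"]] > 0L, logical(1)))
  }, logical(1))
  retained <- unlist(lapply(patient_results, function(res) {
    vapply(res, function(r) r$trace[["after_af_threshold"]], numeric(1))
  }), use.names = FALSE)
  list(n_detected = sum(detected),
       n_total = length(patient_results),
       percent = round(100 * sum(detected) / length(patient_results)),
       mean_variants_per_ctc_sample = mean(retained))
}
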