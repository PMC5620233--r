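VALID_ROLES <- c("TUMOR", "NORMAL", "AMPLIFIED_NORMAL", "CTC_WGA")
BASES <- c("A", "C", "G", "T")

#' Normalize variants to their minimal left-most representation
#'
#' Trims shared allele bases so that differently written but equivalent
#' variant records (this matters for indels) collapse to one canonical key:
#' the common suffix is trimmed first, then the common prefix, advancing the
#' position past each trimmed prefix base; one anchor base is always retained
#' for indels. The operation is idempotent.
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (non-empty A/C/G/T strings). Extra columns are carried through.
#' @return the data frame with `pos`, `ref`, `alt` normalized and a
#'   `vclass` column (`SNV`, `INS`, `DEL`, or `MNV`).
#' @examples
#' normalize_variants(data.frame(chrom = "chr5", pos = 100,
#'                               ref = "TTC", alt = "TC"))
#' @export
normalize_variants <- function(variants) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (nrow(variants) == 0L) {
    variants$vclass <- character(0)
    return(variants)
  }
  ref <- toupper(as.character(variants$ref))
  alt <- toupper(as.character(variants$alt))
  pos <- as.integer(variants$pos)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("invalid variant: ref/alt must be non-empty A/C/G/T strings (row ",
         which(bad)[1L], ")")
  }
  if (any(pos < 1L)) stop("invalid variant: pos must be >= 1")
  if (any(ref == alt)) {
    stop("invalid variant: ref equals alt (row ", which(ref == alt)[1L], ")")
  }
  needs <- nchar(ref) > 1L | nchar(alt) > 1L
  for (i in which(needs)) {
    v <- .normalize_one(pos[i], ref[i], alt[i])
    pos[i] <- v$pos; ref[i] <- v$ref; alt[i] <- v$alt
  }
  variants$pos <- pos
  variants$ref <- ref
  variants$alt <- alt
  variants$vclass <- variant_class(ref, alt)
  variants
}

# minimal left-most representation of one allele pair
.normalize_one <- function(pos, ref, alt) {
  # trim common suffix, keeping at least one base on each allele
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, advancing pos; indels keep the last shared base as anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop("invalid variant: ref equals alt after trimming")
  list(pos = pos, ref = ref, alt = alt)
}

#' Variant class from allele lengths
#'
#' @param ref,alt character vectors of normalized alleles.
#' @return `"SNV"`, `"INS"`, `"DEL"`, or `"MNV"` per element.
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS",
                ifelse(nchar(ref) > nchar(alt), "DEL", "MNV")))
}

#' Canonical variant keys
#'
#' `chrom:pos:ref:alt` strings computed after normalization; two variant
#' records denote the same mutation iff their keys are equal.
#'
#' @param variants data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param normalized set `TRUE` to skip re-normalization.
#' @return character vector of keys.
#' @export
variant_keys <- function(variants, normalized = FALSE) {
  if (!normalized) variants <- normalize_variants(variants)
  if (nrow(variants) == 0L) return(character(0))
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Do two variant records denote the same mutation?
#'
#' Matching is exact on the normalized `(chrom, pos, ref, alt)` key; there is
#' no position-window fuzziness. Both arguments are single-row data frames
#' (or 1-row slices of variant sets).
#'
#' @param a,b single variants as 1-row data frames with `chrom`, `pos`,
#'   `ref`, `alt`.
#' @return logical scalar.
#' @examples
#' a <- data.frame(chrom = "chr5", pos = 100, ref = "TTC", alt = "TC")
#' b <- data.frame(chrom = "chr5", pos = 100, ref = "TT", alt = "T")
#' variants_match(a, b)  # TRUE: same deletion, written differently
#' @export
variants_match <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  variant_keys(a) == variant_keys(b)
}

#' Construct a per-sample variant set
#'
#' The central container: all variants called in one sample, normalized,
#' unique by canonical key, with read-count support. `vaf` is always
#' `alt_count / depth`; if a `vaf` column is supplied it is checked against
#' the counts and recomputed.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth` (>= 1), `alt_count` (0..depth). A `vaf` column is optional.
#' @param sample_id,patient_id identifiers.
#' @param role one of `"TUMOR"`, `"NORMAL"`, `"AMPLIFIED_NORMAL"`,
#'   `"CTC_WGA"`.
#' @param replicate_index WGA replicate number, `CTC_WGA` samples only.
#' @return a `variant_set`: a data frame sorted by (chrom, pos, ref, alt)
#'   with attributes `sample_id`, `patient_id`, `role`, `replicate_index`.
#' @export
variant_set <- function(variants, sample_id, patient_id,
                        role = c("TUMOR", "NORMAL", "AMPLIFIED_NORMAL",
                                 "CTC_WGA"),
                        replicate_index = NA_integer_) {
  role <- match.arg(role)
  if (role != "CTC_WGA" && !is.na(replicate_index)) {
    stop("replicate_index is only meaningful for CTC_WGA samples")
  }
  if (role == "CTC_WGA" && is.na(replicate_index)) replicate_index <- 1L
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")
  if (!all(need %in% names(variants))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  }
  v <- normalize_variants(as.data.frame(variants))
  v$depth <- as.integer(v$depth)
  v$alt_count <- as.integer(v$alt_count)
  if (nrow(v) > 0L) {
    if (any(v$depth < 1L)) stop("depth must be >= 1")
    if (any(v$alt_count < 0L) || any(v$alt_count > v$depth)) {
      stop("alt_count must lie in [0, depth] (row ",
           which(v$alt_count < 0L | v$alt_count > v$depth)[1L], ")")
    }
    vaf <- v$alt_count / v$depth
    if (!is.null(variants$vaf) &&
        any(abs(variants$vaf - vaf) > 1e-6, na.rm = TRUE)) {
      stop("supplied vaf inconsistent with alt_count/depth")
    }
    v$vaf <- vaf
    key <- variant_keys(v, normalized = TRUE)
    if (anyDuplicated(key)) {
      stop("duplicate normalized variant key: ", key[duplicated(key)][1L])
    }
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
    rownames(v) <- NULL
  } else {
    v$vaf <- numeric(0)
  }
  v <- v[, c("chrom", "pos", "ref", "alt", "depth", "alt_count", "vaf",
             "vclass",
             setdiff(names(v), c("chrom", "pos", "ref", "alt", "depth",
                                 "alt_count", "vaf", "vclass")))]
  structure(v,
            sample_id = as.character(sample_id),
            patient_id = as.character(patient_id),
            role = role,
            replicate_index = as.integer(replicate_index),
            class = c("variant_set", "data.frame"))
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> sample %s (patient %s, role %s%s): %d variants\n",
              attr(x, "sample_id"), attr(x, "patient_id"), attr(x, "role"),
              if (!is.na(attr(x, "replicate_index")) &&
                  attr(x, "role") == "CTC_WGA")
                paste0(", replicate ", attr(x, "replicate_index")) else "",
              nrow(x)))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x), 10L), ...)
    if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  }
  invisible(x)
}

# rebuild a variant_set from a row subset, keeping sample metadata
subset_variant_set <- function(x, idx) {
  v <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(v) <- NULL
  structure(v,
            sample_id = attr(x, "sample_id"),
            patient_id = attr(x, "patient_id"),
            role = attr(x, "role"),
            replicate_index = attr(x, "replicate_index"),
            class = c("variant_set", "data.frame"))
}

set_keys <- function(x) variant_keys(as.data.frame(x), normalized = TRUE)

same_variant_set <- function(a, b) {
  identical(set_keys(a), set_keys(b)) &&
    identical(a$depth, b$depth) && identical(a$alt_count, b$alt_count)
}
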