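SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
SPECTRUM_CLASSES_12 <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                         "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Compute the substitution spectrum of a variant set
#'
#' Each SNV is assigned its pyrimidine-reference substitution class:
#' purine-reference changes are complemented onto the opposite strand
#' (G>A becomes C>T, and so on), collapsing the 12 raw change types onto
#' the field's six classes C>A, C>G, C>T, T>A, T>C, T>G. Non-SNVs are
#' ignored but counted. With `collapse = FALSE` the 12 raw classes are
#' reported instead.
#'
#' @param variants data frame (or [variant_set()]) with `ref` and `alt`.
#' @param collapse collapse to the six pyrimidine-reference classes
#'   (default) or keep the 12 raw classes.
#' @return a `spectrum_profile`: list with `frequencies` (named, summing to
#'   1), `counts`, `n_snvs`, `n_non_snv`, `collapsed`.
#' @export
compute_spectrum <- function(variants, collapse = TRUE) {
  v <- as.data.frame(variants)
  stopifnot(all(c("ref", "alt") %in% names(v)))
  is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  n_snvs <- sum(is_snv)
  if (n_snvs == 0L) {
    stop("undefined spectrum: no SNVs in input (",
         nrow(v) - n_snvs, " non-SNV variants ignored)")
  }
  ref <- toupper(v$ref[is_snv])
  alt <- toupper(v$alt[is_snv])
  if (collapse) {
    pur <- ref %in% c("A", "G")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref[pur] <- comp[ref[pur]]
    alt[pur] <- comp[alt[pur]]
    classes <- SPECTRUM_CLASSES
  } else {
    classes <- SPECTRUM_CLASSES_12
  }
  cls <- factor(paste0(ref, ">", alt), levels = classes)
  counts <- table(cls)
  structure(list(frequencies = as.numeric(counts) / n_snvs,
                 counts = as.integer(counts),
                 classes = classes,
                 n_snvs = n_snvs,
                 n_non_snv = nrow(v) - n_snvs,
                 collapsed = collapse),
            class = "spectrum_profile")
}

#' Dominant substitution class of a spectrum
#'
#' Argmax over class frequencies; ties break toward the first class in the
#' fixed order (C>A, C>G, C>T, T>A, T>C, T>G).
#'
#' @param p a `spectrum_profile` from [compute_spectrum()].
#' @return class label, e.g. `"C>T"`.
#' @export
dominant_class <- function(p) {
  stopifnot(inherits(p, "spectrum_profile"), p$n_snvs > 0L)
  p$classes[which.max(p$frequencies)]
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile> %d SNVs (%d non-SNV ignored), %s classes\n",
              x$n_snvs, x$n_non_snv, if (x$collapsed) "6" else "12"))
  df <- data.frame(class = x$classes, count = x$counts,
                   frequency = round(x$frequencies, 4))
  print.data.frame(df, row.names = FALSE)
  cat("dominant:", dominant_class(x), "\n")
  invisible(x)
}

#' @export
plot.spectrum_profile <- function(x, ...) {
  graphics::barplot(x$frequencies, names.arg = x$classes,
                    ylab = "frequency of SNVs", las = 2,
                    main = sprintf("Substitution spectrum (n = %d SNVs)",
                                   x$n_snvs), ...)
  invisible(x)
}

#' Serialize a spectrum profile
#'
#' @param p a `spectrum_profile`.
#' @param path output path; `.json` for JSON, anything else TSV.
#' @export
write_spectrum <- function(p, path) {
  stopifnot(inherits(p, "spectrum_profile"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(frequencies = as.list(setNames(p$frequencies,
                                                             p$classes)),
                              n_snvs = p$n_snvs, n_non_snv = p$n_non_snv,
                              collapsed = p$collapsed),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(class = p$classes, count = p$counts,
                           frequency = p$frequencies),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
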