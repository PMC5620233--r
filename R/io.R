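TSV_HEADER <- c("chrom", "pos", "ref", "alt", "depth", "alt_count")

#' Read a per-sample variant table (TSV or minimal VCF)
#'
#' The TSV dialect is tab-separated with header
#' `chrom pos ref alt depth alt_count` (1-based positions). Files ending in
#' `.vcf` are parsed as minimal VCF 4.2 with `DP` and `AD` FORMAT fields;
#' multi-allelic records are split into one row per alternate allele.
#' All variants are normalized on read and duplicate normalized keys are
#' rejected.
#'
#' @param path file path.
#' @param sample_id,patient_id,role,replicate_index sample metadata (see
#'   [variant_set()]); `sample_id` defaults to the file stem.
#' @return a [variant_set()].
#' @export
read_variant_table <- function(path, sample_id = NULL, patient_id = "NA",
                               role = "TUMOR", replicate_index = NA_integer_) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  }
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    v <- .read_vcf_minimal(path)
  } else {
    v <- .read_tsv_variants(path)
  }
  out <- tryCatch(
    variant_set(v, sample_id = sample_id, patient_id = patient_id,
                role = role, replicate_index = replicate_index),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  out
}

.read_tsv_variants <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("parse error in ", path, ": empty file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, TSV_HEADER)) {
    stop("parse error in ", path, " line 1: expected header '",
         paste(TSV_HEADER, collapse = "\t"), "'")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stop("parse error in ", path, " line ", which(nf != 6L)[1L] + 1L,
         ": expected 6 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  depth <- suppressWarnings(as.integer(m[, 5L]))
  altc <- suppressWarnings(as.integer(m[, 6L]))
  bad <- is.na(pos) | is.na(depth) | is.na(altc)
  if (any(bad)) {
    stop("parse error in ", path, " line ", which(bad)[1L] + 1L,
         ": non-integer pos/depth/alt_count")
  }
  bad <- altc > depth | altc < 0L | depth < 1L
  if (any(bad)) {
    stop("parse error in ", path, " line ", which(bad)[1L] + 1L,
         ": alt_count must lie in [0, depth] and depth >= 1")
  }
  data.frame(chrom = m[, 1L], pos = pos, ref = m[, 3L], alt = m[, 4L],
             depth = depth, alt_count = altc)
}

#' Write a per-sample variant table
#'
#' Writes the TSV dialect of [read_variant_table()], or minimal VCF 4.2
#' (with `DP`/`AD` in FORMAT) when `path` ends in `.vcf`. `write` then
#' `read` is the identity on normalized sets.
#'
#' @param x a [variant_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  stopifnot(inherits(x, "variant_set"))
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    .write_vcf_minimal(x, path)
  } else {
    df <- as.data.frame(x)[, TSV_HEADER, drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.write_vcf_minimal <- function(x, path) {
  sid <- attr(x, "sample_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)),
    con)
  if (nrow(x) > 0L) {
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t0/1:%d:%d,%d",
                    x$chrom, x$pos, x$ref, x$alt, x$depth,
                    x$depth - x$alt_count, x$alt_count)
    writeLines(rows, con)
  }
}

.read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF gives a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0)))
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1L]))
  ad <- vcfR::extract.gt(v, "AD")[, 1L]
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    ads <- suppressWarnings(as.integer(strsplit(ad[i], ",",
                                                fixed = TRUE)[[1L]]))
    if (length(ads) != length(alts) + 1L) {
      stop("parse error in ", path, ": AD has ", length(ads),
           " values for ", length(alts), " alt allele(s) at ",
           fix$CHROM[i], ":", fix$POS[i])
    }
    out[[i]] <- data.frame(chrom = fix$CHROM[i],
                           pos = as.integer(fix$POS[i]),
                           ref = fix$REF[i], alt = alts,
                           depth = dp[i], alt_count = ads[-1L])
  }
  do.call(rbind, out)
}

#' Read and write the amplicon panel definition
#'
#' Panel target regions travel as BED (0-based half-open intervals; the BED
#' name column holds the gene label) and primers as a two-column TSV
#' (`chrom`, `primer`).
#'
#' @param bed_path BED file of target regions.
#' @param primers_path primer TSV; `NULL` for a panel without primers.
#' @return an `amplicon_panel`: list with `regions` (data frame `chrom`,
#'   `start`, `end`, `gene`, 0-based half-open) and `primers` (data frame
#'   `chrom`, `primer`).
#' @export
read_panel <- function(bed_path, primers_path = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to BED 0-based
    end = GenomicRanges::end(gr),
    gene = if (!is.null(gr$name)) as.character(gr$name)
           else paste0("region", seq_along(gr)))
  primers <- if (is.null(primers_path)) {
    data.frame(chrom = character(0), primer = character(0))
  } else {
    read.delim(primers_path, colClasses = "character")
  }
  amplicon_panel(regions, primers)
}

#' @rdname read_panel
#' @param panel an `amplicon_panel`.
#' @export
write_panel <- function(panel, bed_path, primers_path = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  r <- panel$regions
  gr <- GenomicRanges::GRanges(r$chrom,
                               IRanges::IRanges(r$start + 1L, r$end),
                               name = r$gene)
  rtracklayer::export(gr, bed_path, format = "BED")
  if (!is.null(primers_path)) {
    write.table(panel$primers, primers_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(bed_path)
}

#' Read and write clinical records
#'
#' CSV with columns `patient_id`, `age` (years), `dukes` (A-D or empty),
#' `cea` (ng/ml or empty), `msi` (`MSI`/`MSS` or empty). Missing values are
#' `NA` on read.
#'
#' @param path CSV path.
#' @return data frame of clinical records.
#' @export
read_clinical <- function(path) {
  cl <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  need <- c("patient_id", "age", "dukes", "cea", "msi")
  if (!all(need %in% names(cl))) {
    stop("clinical file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.na(cl$cea) & cl$cea < 0)) stop("cea must be >= 0")
  cl
}

#' @rdname read_clinical
#' @param clinical data frame of clinical records.
#' @export
write_clinical <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialize a recurrent-error blacklist
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `n_samples`, `vaf_median`.
#'
#' @param blacklist a `wga_blacklist` (see [build_blacklist()]).
#' @param path output path.
#' @export
write_blacklist <- function(blacklist, path) {
  stopifnot(inherits(blacklist, "wga_blacklist"))
  write.table(as.data.frame(blacklist), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_blacklist
#' @param min_recurrence recurrence floor recorded on the object.
#' @export
read_blacklist <- function(path, min_recurrence = 2L) {
  df <- read.delim(path, colClasses = c(chrom = "character",
                                        ref = "character",
                                        alt = "character"))
  need <- c("chrom", "pos", "ref", "alt", "n_samples", "vaf_median")
  if (!all(need %in% names(df))) {
    stop("blacklist file must have columns: ", paste(need, collapse = ", "))
  }
  .as_blacklist(df, min_recurrence)
}
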