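# The 39 genes of a colorectal-cancer amplicon panel: frequently mutated or
# druggable genes (WNT, RAS/ERBB and P53 pathway members among them).
PANEL_GENES_39 <- c(
  "APC", "KRAS", "TP53", "ERBB2", "ERBB3", "FBXW7", "TCF7L2", "ATM",
  "PIK3CA", "SMAD4", "BRAF", "NRAS", "CTNNB1", "AMER1", "SOX9", "ARID1A",
  "ACVR2A", "TGFBR2", "MSH2", "MSH6", "MLH1", "POLE", "PTEN", "EGFR",
  "KIT", "PDGFRA", "ALK", "MET", "RET", "NOTCH1", "CDC27", "CASP8",
  "DNAH5", "EDNRB", "GNAS", "KDR", "MAP2K1", "AKT1", "CDKN2A")

#' Construct an amplicon panel
#'
#' @param regions data frame `chrom`, `start`, `end` (0-based half-open),
#'   `gene`. Regions must not overlap within a chromosome.
#' @param primers data frame `chrom`, `primer` (nucleotide strings).
#' @return an `amplicon_panel` list with `regions`, `primers`, and
#'   `total_length` (sum of interval lengths).
#' @export
amplicon_panel <- function(regions,
                           primers = data.frame(chrom = character(0),
                                                primer = character(0))) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$end <= regions$start)) stop("panel regions must be non-empty")
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("panel regions overlap on ", ch)
    }
  }
  stopifnot(all(c("chrom", "primer") %in% names(primers)))
  structure(list(regions = regions,
                 primers = primers,
                 total_length = sum(regions$end - regions$start)),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf(paste0("<amplicon_panel> %d genes, %d regions, %d bp targeted,",
                     " %d primers\n"),
              length(unique(x$regions$gene)), nrow(x$regions),
              x$total_length, nrow(x$primers)))
  invisible(x)
}

#' Build a synthetic amplicon panel
#'
#' Lays `n_genes` non-overlapping target regions of roughly equal size
#' (total `total_length` bp) across chromosomes chr1..chr22, one region per
#' gene, and draws one random primer sequence per gene. Gene labels default
#' to a 39-gene colorectal-cancer panel; extra genes get synthetic labels.
#' Deterministic given the current RNG state.
#'
#' @param n_genes number of genes (one region each).
#' @param total_length total targeted length in bp.
#' @param primer_length primer length in bp.
#' @return an [amplicon_panel()].
#' @export
make_panel <- function(n_genes = 39L, total_length = 110000L,
                       primer_length = 21L) {
  stopifnot(n_genes >= 1L, total_length >= n_genes)
  genes <- if (n_genes <= length(PANEL_GENES_39)) {
    PANEL_GENES_39[seq_len(n_genes)]
  } else {
    c(PANEL_GENES_39, paste0("GENE", seq_len(n_genes - length(PANEL_GENES_39))))
  }
  len <- rep(total_length %/% n_genes, n_genes)
  len[seq_len(total_length %% n_genes)] <- len[1L] + 1L
  chroms <- paste0("chr", ((seq_len(n_genes) - 1L) %% 22L) + 1L)
  slot <- (seq_len(n_genes) - 1L) %/% 22L
  start <- as.integer(1e6 + slot * 1e5)
  regions <- data.frame(chrom = chroms, start = start,
                        end = start + len, gene = genes)
  primers <- data.frame(
    chrom = chroms,
    primer = vapply(seq_len(n_genes), function(i)
      paste(sample(BASES, primer_length, replace = TRUE), collapse = ""),
      character(1)))
  amplicon_panel(regions, primers)
}

# Map offsets 1..total_length into (chrom, pos) on the panel; the reference
# base at a position is a fixed function of the position so that independent
# draws of the same locus agree on the reference allele.
panel_locus <- function(panel, offset) {
  r <- panel$regions
  lens <- r$end - r$start
  cum <- cumsum(lens)
  i <- findInterval(offset - 1L, c(0L, cum), rightmost.closed = FALSE)
  within <- offset - c(0L, cum)[i]            # 1-based offset inside region
  data.frame(chrom = r$chrom[i],
             pos = r$start[i] + within,       # 1-based genomic position
             gene = r$gene[i])
}

panel_ref_base <- function(pos) BASES[(pos %% 4L) + 1L]

# gene label for 1-based positions; NA when off-target
panel_gene_at <- function(panel, chrom, pos) {
  r <- panel$regions
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(r))) {
    hit <- chrom == r$chrom[i] & pos > r$start[i] & pos <= r$end[i]
    out[hit] <- r$gene[i]
  }
  out
}
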