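#' Per-gene alteration tabulation
#'
#' A sample is "altered" in a gene if at least one of its calls overlaps
#' that gene's target regions; the table reports, per gene, the number and
#' percentage (one decimal) of samples altered. Calls outside every panel
#' region are counted under `off_target` with a warning.
#'
#' @param calls_by_sample named list: per sample, a data frame of calls
#'   with `chrom` and `pos`.
#' @param panel an [amplicon_panel()].
#' @param n_samples denominator; defaults to `length(calls_by_sample)`.
#' @return list with `table` (data frame `gene`, `n_samples_altered`,
#'   `percent`, all panel genes included) and `off_target` count.
#' @export
gene_alteration_table <- function(calls_by_sample, panel,
                                  n_samples = length(calls_by_sample)) {
  stopifnot(inherits(panel, "amplicon_panel"), n_samples >= 1L)
  genes <- unique(panel$regions$gene)
  altered <- matrix(FALSE, nrow = length(genes),
                    ncol = length(calls_by_sample),
                    dimnames = list(genes, NULL))
  off_target <- 0L
  for (j in seq_along(calls_by_sample)) {
    calls <- as.data.frame(calls_by_sample[[j]])
    if (nrow(calls) == 0L) next
    g <- panel_gene_at(panel, calls$chrom, calls$pos)
    n_off <- sum(is.na(g))
    if (n_off > 0L) {
      off_target <- off_target + n_off
      warning(n_off, " call(s) outside all panel regions (off-target)")
    }
    altered[unique(g[!is.na(g)]), j] <- TRUE
  }
  n_alt <- rowSums(altered)
  tab <- data.frame(gene = genes,
                    n_samples_altered = as.integer(n_alt),
                    percent = round(100 * n_alt / n_samples, 1))
  tab <- tab[order(-tab$n_samples_altered, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, off_target = off_target, n_samples = n_samples)
}

#' Run the end-to-end CTC mutation pipeline
#'
#' Stages: cohort acquisition (synthetic generation, or reading a sample
#' manifest of variant tables), amplification-error calling and blacklist
#' construction from the amplified-normal controls, error-VAF summary and
#' false-positive match-rate estimation, the per-CTC-sample filter cascade
#' (blacklist removal, strict AF threshold, tumor-matched intersection),
#' replicate-concordant private calling where two WGA replicates exist,
#' mutation spectrum of the pooled tumor-matched calls, clinical
#' associations, and the per-gene alteration table. Deterministic given the
#' config seed; all randomness flows from it.
#'
#' @param config a [cohort_config()] (synthetic mode), or the path to a
#'   YAML/JSON config file. A file config either holds the synthetic
#'   parameters under `cohort:` or, for file mode, `manifest:`, `clinical:`,
#'   `panel_bed:` and optionally `primers:` paths (relative to the config
#'   file) plus `min_vaf` and `min_recurrence`.
#' @param output_dir if non-NULL, all intermediates (blacklist, per-sample
#'   calls, traces, report JSON) are written under this directory.
#' @param min_vaf strict AF threshold (default 0.01).
#' @param min_recurrence blacklist recurrence floor (default 2).
#' @return a `ctc_pipeline_report` list: `detection`, `fp_match`,
#'   `error_summary`, `spectrum`, `associations`, `gene_table`, `traces`,
#'   `private_calls`, `calls`, `config`, `seed`, `version`.
#' @export
run_pipeline <- function(config, output_dir = NULL, min_vaf = 0.01,
                         min_recurrence = 2L) {
  stage <- "configuration"
  tryCatch({
    acquired <- .acquire_cohort(config)
    cohort <- acquired$cohort
    if (!is.null(acquired$min_vaf)) min_vaf <- acquired$min_vaf
    if (!is.null(acquired$min_recurrence)) {
      min_recurrence <- acquired$min_recurrence
    }

    stage <- "blacklist"
    amp <- Filter(Negate(is.null),
                  lapply(cohort$patients,
                         function(p) p$samples$amplified_normal))
    if (length(amp) < 2L) {
      stop("insufficient controls: need >= 2 amplified-normal samples")
    }
    error_sets <- lapply(amp, function(a) {
      pid <- attr(a, "patient_id")
      norm <- .patient_by_id(cohort, pid)$samples$normal
      call_amplification_errors(a, norm)
    })
    blacklist <- build_blacklist(error_sets, min_recurrence)
    error_summary <- summarize_error_vafs(error_sets, blacklist)

    stage <- "false-positive match rate"
    tumors <- lapply(cohort$patients, function(p) p$samples$tumor)
    amp_pids <- vapply(amp, attr, "", "patient_id")
    fp <- tryCatch(
      estimate_fp_match_rate(error_sets, blacklist,
                             tumors[vapply(tumors, attr, "",
                                           "patient_id") %in% amp_pids],
                             min_vaf),
      error = function(e) list(n_match = NA_integer_, n_total = 0L,
                               rate_percent = NA_real_,
                               note = conditionMessage(e)))

    stage <- "filter cascade"
    traces <- list()
    all_calls <- list()
    calls_by_sample <- list()
    private_calls <- list()
    patient_results <- vector("list", length(cohort$patients))
    for (i in seq_along(cohort$patients)) {
      p <- cohort$patients[[i]]
      res <- lapply(p$samples$ctc, function(s)
        filter_ctc_sample(s, blacklist, p$samples$tumor, min_vaf))
      patient_results[[i]] <- res
      for (r in res) {
        sid <- attr(r$calls, "sample_id")
        calls_by_sample[[sid]] <- as.data.frame(r$calls)
        traces[[sid]] <- r$trace
        if (nrow(r$calls) > 0L) {
          cc <- as.data.frame(r$calls)
          cc$patient_id <- p$patient_id
          cc$sample_id <- sid
          all_calls[[length(all_calls) + 1L]] <- cc
        }
      }
      if (length(res) >= 2L) {
        priv <- replicate_concordant_private(res[[1L]]$retained,
                                             res[[2L]]$retained,
                                             p$samples$tumor, blacklist)
        if (nrow(priv) > 0L) {
          priv$patient_id <- p$patient_id
          private_calls[[length(private_calls) + 1L]] <- priv
        }
      }
    }
    calls <- if (length(all_calls) > 0L) do.call(rbind, all_calls) else
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), vaf = numeric(0),
                 patient_id = character(0), sample_id = character(0))
    private <- if (length(private_calls) > 0L) {
      do.call(rbind, private_calls)
    } else NULL

    stage <- "summaries"
    detection <- cohort_detection_summary(patient_results)
    spectrum <- tryCatch(compute_spectrum(calls),
                         error = function(e) NULL)
    associations <- lapply(c("CEA", "DUKES", "MSI", "AGE"), function(v) {
      tryCatch(associate_af_with_clinical(calls, cohort$clinical, v),
               error = function(e) list(variable = v, p = NA_real_,
                                        note = conditionMessage(e)))
    })
    names(associations) <- c("CEA", "DUKES", "MSI", "AGE")
    genes <- suppressWarnings(
      gene_alteration_table(calls_by_sample, cohort$panel))

    report <- structure(
      list(detection = detection, fp_match = fp,
           error_summary = error_summary, blacklist = blacklist,
           spectrum = spectrum, associations = associations,
           gene_table = genes, traces = traces,
           private_calls = private, calls = calls,
           config = cohort$config, seed = cohort$config$seed,
           version = as.character(utils::packageVersion("ctcwga"))),
      class = "ctc_pipeline_report")

    if (!is.null(output_dir)) .write_report_files(report, cohort, output_dir)
    report
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}

.patient_by_id <- function(cohort, pid) {
  for (p in cohort$patients) if (p$patient_id == pid) return(p)
  stop("missing manifest entries: no samples for patient ", pid)
}

# build a ctc_cohort either by synthetic generation or from a file manifest
.acquire_cohort <- function(config) {
  if (inherits(config, "ctc_cohort")) return(list(cohort = config))
  if (inherits(config, "cohort_config")) {
    return(list(cohort = generate_cohort(config)))
  }
  if (is.character(config) && length(config) == 1L) {
    cfgdir <- dirname(config)
    cfg <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
           else jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(cfg$manifest)) {
      rel <- function(p) if (is.null(p)) NULL else file.path(cfgdir, p)
      return(c(list(cohort = read_cohort_files(rel(cfg$manifest),
                                               rel(cfg$clinical),
                                               rel(cfg$panel_bed),
                                               rel(cfg$primers))),
               cfg[intersect(names(cfg), c("min_vaf", "min_recurrence"))]))
    }
    cohort_args <- if (!is.null(cfg$cohort)) cfg$cohort else cfg
    cohort_args <- cohort_args[intersect(names(cohort_args),
                                         names(formals(cohort_config)))]
    return(c(list(cohort = generate_cohort(do.call(cohort_config,
                                                   cohort_args))),
             cfg[intersect(names(cfg), c("min_vaf", "min_recurrence"))]))
  }
  if (is.list(config)) {
    return(list(cohort = generate_cohort(do.call(cohort_config, config))))
  }
  stop("config must be a cohort_config, a ctc_cohort, or a config file path")
}

#' Read a cohort from a sample manifest (file mode)
#'
#' The manifest is a CSV with columns `sample_id`, `patient_id`, `role`,
#' `replicate_index`, `path` (variant-table paths relative to the
#' manifest). [write_cohort()] produces this layout.
#'
#' @param manifest_path manifest CSV.
#' @param clinical_path clinical CSV.
#' @param panel_bed_path panel BED.
#' @param primers_path primers TSV (optional).
#' @return a `ctc_cohort` (without latent truth: `tumor_truth` is `NULL`).
#' @export
read_cohort_files <- function(manifest_path, clinical_path, panel_bed_path,
                              primers_path = NULL) {
  mf <- read.csv(manifest_path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("sample_id", "patient_id", "role", "path")
  if (!all(need %in% names(mf))) {
    stop("missing manifest entries: manifest needs columns ",
         paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  panel <- read_panel(panel_bed_path, primers_path)
  clinical <- read_clinical(clinical_path)
  patients <- list()
  for (pid in unique(mf$patient_id)) {
    rows <- mf[mf$patient_id == pid, , drop = FALSE]
    samp <- list(tumor = NULL, normal = NULL, amplified_normal = NULL,
                 ctc = list())
    for (k in seq_len(nrow(rows))) {
      s <- read_variant_table(file.path(base, rows$path[k]),
                              sample_id = rows$sample_id[k],
                              patient_id = pid, role = rows$role[k],
                              replicate_index =
                                if (rows$role[k] == "CTC_WGA") {
                                  as.integer(rows$replicate_index[k])
                                } else NA_integer_)
      switch(rows$role[k],
             TUMOR = { samp$tumor <- s },
             NORMAL = { samp$normal <- s },
             AMPLIFIED_NORMAL = { samp$amplified_normal <- s },
             CTC_WGA = { samp$ctc[[length(samp$ctc) + 1L]] <- s })
    }
    if (is.null(samp$tumor)) {
      stop("missing manifest entries: no TUMOR sample for patient ", pid)
    }
    if (is.null(samp$normal)) {
      stop("missing manifest entries: no NORMAL sample for patient ", pid)
    }
    patients[[length(patients) + 1L]] <-
      list(patient_id = pid, tumor_truth = NULL, samples = samp,
           clinical = clinical[clinical$patient_id == pid, , drop = FALSE],
           latent = NULL)
  }
  structure(list(patients = patients, panel = panel, hotspots = NULL,
                 clinical = clinical,
                 config = list(seed = NA_integer_, mode = "files")),
            class = "ctc_cohort")
}

.write_report_files <- function(report, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_blacklist(report$blacklist, file.path(dir, "blacklist.tsv"))
  write.table(report$calls, file.path(dir, "tumor_matched_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$private_calls)) {
    write.table(report$private_calls,
                file.path(dir, "replicate_concordant_private.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$spectrum)) {
    write_spectrum(report$spectrum, file.path(dir, "spectrum.tsv"))
  }
  write.table(report$gene_table$table,
              file.path(dir, "gene_alteration_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$traces, file.path(dir, "filter_traces.json"),
                       auto_unbox = FALSE)
  summary <- list(
    detection = report$detection,
    fp_match = report$fp_match,
    error_summary = report$error_summary,
    associations = lapply(report$associations, function(a)
      list(variable = a$variable, test = a$test, p = a$p,
           statistic = a$statistic)),
    seed = report$seed, version = report$version)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(cohort$config) && is.null(cohort$config$mode)) {
    jsonlite::write_json(unclass(cohort$config),
                         file.path(dir, "config_echo.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @export
print.ctc_pipeline_report <- function(x, ...) {
  cat("<ctc_pipeline_report> seed", x$seed, "- ctcwga", x$version, "\n")
  d <- x$detection
  cat(sprintf("  detection: tumor-matched mutations in %d/%d patients (%d%%)\n",
              d$n_detected, d$n_total, d$percent))
  cat(sprintf("  mean retained variants per CTC sample: %.1f\n",
              d$mean_variants_per_ctc_sample))
  es <- x$error_summary
  cat(sprintf(paste0("  WGA errors: %d observations; recurrent median VAF ",
                     "%.2f%%, non-recurrent %.2f%%\n"),
              es$n_total, 100 * es$recurrent_vaf_median,
              100 * es$nonrecurrent_vaf_median))
  fp <- x$fp_match
  if (!is.na(fp$rate_percent)) {
    cat(sprintf("  false-positive tumor-match rate: %d/%d = %.1f%%\n",
                fp$n_match, fp$n_total, fp$rate_percent))
  }
  if (!is.null(x$spectrum)) {
    cat(sprintf("  spectrum: dominant class %s (%.2f of %d SNVs)\n",
                dominant_class(x$spectrum),
                max(x$spectrum$frequencies), x$spectrum$n_snvs))
  }
  for (a in x$associations) {
    if (!is.na(a$p)) {
      cat(sprintf("  association %s: %s p = %.4g\n", a$variable, a$test,
                  a$p))
    } else {
      cat(sprintf("  association %s: not testable (%s)\n", a$variable,
                  a$note))
    }
  }
  top <- utils::head(x$gene_table$table[x$gene_table$table$percent > 0, ], 5)
  if (nrow(top) > 0L) {
    cat("  most altered genes:",
        paste(sprintf("%s %.1f%%", top$gene, top$percent), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.ctc_pipeline_report <- function(object, ...) print(object, ...)
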