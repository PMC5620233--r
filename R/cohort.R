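#' Synthetic cohort configuration
#'
#' All parameters of the synthetic-cohort generator, grouped the way the
#' generating process is layered. Defaults reproduce a cohort at the scale of
#' the colorectal CTC study the pipeline is designed for: 48 patients, a
#' 39-gene ~110 kb amplicon panel, 14 amplified-normal WGA controls, a WGA
#' error process mixing recurrent hotspot errors (median VAF 0.5%) with
#' random non-recurrent errors (median VAF 1%), tumor DNA spiked into CTC
#' samples of 60% of patients at latent tumor fractions of 0.05-0.40, ~400x
#' coverage, and CEA serum levels positively linked to tumor fraction.
#'
#' @param n_patients cohort size.
#' @param n_genes,total_length,primer_length panel layout (see
#'   [make_panel()]).
#' @param n_amplified_normals patients that additionally contribute a
#'   WGA-amplified normal control.
#' @param n_recurrent_hotspots size of the cohort-global recurrent-error
#'   locus set.
#' @param hotspot_occurrence_prob per-sample probability that a given
#'   hotspot error occurs in a WGA sample.
#' @param recurrent_vaf_median,random_vaf_median median VAF (fraction) of
#'   recurrent and random WGA errors.
#' @param random_errors_per_amplified_normal,random_errors_per_ctc Poisson
#'   means of the per-sample random (non-recurrent) error counts.
#' @param vaf_dispersion lognormal sigma of the error VAF distributions.
#' @param tumor_mutations_mean Poisson mean somatic mutations per tumor,
#'   placed uniformly in the panel.
#' @param clonal_fraction fraction of tumor cells carrying each mutation
#'   (1 = fully clonal).
#' @param het_vaf true allele fraction of a clonal heterozygous mutation in
#'   pure tumor (0.5).
#' @param indel_fraction fraction of tumor mutations that are small indels.
#' @param ctc_positive_fraction fraction of patients whose CTC samples carry
#'   tumor DNA; the generator makes this an exact count,
#'   `round(fraction * n_patients)`.
#' @param tumor_fraction_range uniform range of the latent tumor DNA
#'   fraction in CTC-positive samples.
#' @param n_wga_replicates independent WGA replicates per CTC capture.
#' @param subclone_prob probability that a CTC-positive patient carries an
#'   extra CTC-private subclonal mutation (seen in both replicates, absent
#'   from the tumor); exercises replicate-concordant private calling.
#' @param coverage_mean,coverage_dispersion negative-binomial per-locus
#'   depth: mean and dispersion (variance = mu + dispersion * mu^2).
#' @param cea_intercept,cea_slope logistic link for P(CEA >= 5 ng/ml) as a
#'   function of latent tumor fraction.
#' @param cea_missing_prob probability a patient's CEA value is missing.
#' @param msi_prob probability of MSI (vs MSS) tumor status.
#' @param ct_mass probability mass of the C>T class among tumor SNVs; the
#'   remaining five strand-collapsed classes share the rest equally.
#' @param seed integer seed; the entire cohort is a deterministic function
#'   of the configuration including the seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 48L,
                          n_genes = 39L,
                          total_length = 110000L,
                          primer_length = 21L,
                          n_amplified_normals = 14L,
                          n_recurrent_hotspots = 400L,
                          hotspot_occurrence_prob = 0.5,
                          recurrent_vaf_median = 0.005,
                          random_errors_per_amplified_normal = 275,
                          random_errors_per_ctc = 150,
                          random_vaf_median = 0.010,
                          vaf_dispersion = 0.8,
                          tumor_mutations_mean = 12,
                          clonal_fraction = 1.0,
                          het_vaf = 0.5,
                          indel_fraction = 0.10,
                          ctc_positive_fraction = 0.60,
                          tumor_fraction_range = c(0.05, 0.40),
                          n_wga_replicates = 2L,
                          subclone_prob = 0.2,
                          coverage_mean = 400,
                          coverage_dispersion = 0.2,
                          cea_intercept = -2,
                          cea_slope = 12,
                          cea_missing_prob = 0.5,
                          msi_prob = 0.15,
                          ct_mass = 0.45,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              total_length = as.integer(total_length),
              primer_length = as.integer(primer_length),
              n_amplified_normals = as.integer(n_amplified_normals),
              n_recurrent_hotspots = as.integer(n_recurrent_hotspots),
              hotspot_occurrence_prob = hotspot_occurrence_prob,
              recurrent_vaf_median = recurrent_vaf_median,
              random_errors_per_amplified_normal =
                random_errors_per_amplified_normal,
              random_errors_per_ctc = random_errors_per_ctc,
              random_vaf_median = random_vaf_median,
              vaf_dispersion = vaf_dispersion,
              tumor_mutations_mean = tumor_mutations_mean,
              clonal_fraction = clonal_fraction,
              het_vaf = het_vaf,
              indel_fraction = indel_fraction,
              ctc_positive_fraction = ctc_positive_fraction,
              tumor_fraction_range = tumor_fraction_range,
              n_wga_replicates = as.integer(n_wga_replicates),
              subclone_prob = subclone_prob,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              cea_intercept = cea_intercept,
              cea_slope = cea_slope,
              cea_missing_prob = cea_missing_prob,
              msi_prob = msi_prob,
              ct_mass = ct_mass,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      stop("invalid configuration field '", field, "': must be in [0, 1]")
    }
  }
  chk_pos <- function(field, strict = TRUE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || (strict && any(v <= 0)) ||
        (!strict && any(v < 0))) {
      stop("invalid configuration field '", field, "': must be positive")
    }
  }
  for (f in c("hotspot_occurrence_prob", "ctc_positive_fraction",
              "cea_missing_prob", "msi_prob", "ct_mass", "indel_fraction",
              "clonal_fraction", "recurrent_vaf_median", "random_vaf_median",
              "het_vaf")) chk_prob(f)
  for (f in c("n_patients", "n_genes", "total_length", "vaf_dispersion",
              "coverage_mean", "coverage_dispersion", "n_wga_replicates")) {
    chk_pos(f)
  }
  for (f in c("random_errors_per_amplified_normal", "random_errors_per_ctc",
              "tumor_mutations_mean", "n_recurrent_hotspots",
              "n_amplified_normals", "subclone_prob")) chk_pos(f, strict = FALSE)
  tfr <- cfg$tumor_fraction_range
  if (length(tfr) != 2L || any(tfr < 0) || any(tfr > 1) || tfr[1] > tfr[2]) {
    stop("invalid configuration field 'tumor_fraction_range'")
  }
  if (cfg$n_amplified_normals > cfg$n_patients) {
    stop("invalid configuration field 'n_amplified_normals': exceeds n_patients")
  }
  invisible(cfg)
}

# run expr with a local RNG seeded at `seed`, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# independent substream seeds below 2^31, derived from a root seed
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + stream * 12345) %% 2147483647
}

rdepth <- function(n, cfg) {
  pmax(1L, rnbinom(n, mu = cfg$coverage_mean,
                   size = 1 / cfg$coverage_dispersion))
}

# lognormal parameterized by its median; right-skewed, positive, capped at 1
rvaf_lnorm <- function(n, median, sigma) {
  pmin(rlnorm(n, meanlog = log(median), sdlog = sigma), 1)
}

# draw n variant loci uniformly on the panel; SNV alt alleles follow
# `class_probs` over the six strand-collapsed classes when given (the locus
# is redrawn until its reference base can realize the drawn class, keeping
# loci uniform within the compatible half of the panel), otherwise uniform
# over the three non-reference bases
draw_panel_variants <- function(n, panel, class_probs = NULL,
                                indel_fraction = 0) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0)))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  loc <- panel_locus(panel, sample.int(panel$total_length, n, replace = TRUE))
  loc$ref <- panel_ref_base(loc$pos)
  is_indel <- runif(n) < indel_fraction
  alt <- character(n)
  for (i in seq_len(n)) {
    if (is_indel[i]) {
      ins <- runif(1) < 0.5
      tail <- paste(sample(BASES, sample(1:3, 1), replace = TRUE),
                    collapse = "")
      if (ins) {
        alt[i] <- paste0(loc$ref[i], tail)
      } else {
        # deletion: ref extends past the anchor base
        loc$ref[i] <- paste0(loc$ref[i], tail)
        alt[i] <- substr(loc$ref[i], 1L, 1L)
      }
    } else if (is.null(class_probs)) {
      alt[i] <- sample(setdiff(BASES, loc$ref[i]), 1L)
    } else {
      cls <- sample(names(class_probs), 1L, prob = class_probs)
      from <- substr(cls, 1L, 1L)      # pyrimidine reference base (C or T)
      to <- substr(cls, 3L, 3L)
      while (!(loc$ref[i] %in% c(from, comp[[from]]))) {
        li <- panel_locus(panel, sample.int(panel$total_length, 1L))
        li$ref <- panel_ref_base(li$pos)
        loc[i, c("chrom", "pos", "gene", "ref")] <-
          li[, c("chrom", "pos", "gene", "ref")]
      }
      alt[i] <- if (loc$ref[i] == from) to else comp[[to]]
    }
  }
  loc$alt <- alt
  loc[, c("chrom", "pos", "ref", "alt", "gene")]
}

default_class_probs <- function(ct_mass) {
  p <- rep((1 - ct_mass) / 5, 6)
  names(p) <- SPECTRUM_CLASSES
  p["C>T"] <- ct_mass
  p
}

#' Simulate one WGA-amplified sample's variant calls
#'
#' Emits the three sources of variation in a whole-genome-amplified sample:
#' (a) each cohort-global recurrent hotspot error occurs independently with
#' `hotspot_occurrence_prob`, at a VAF drawn lognormal around the recurrent
#' median; (b) a Poisson number of random non-recurrent errors at uniform
#' panel loci, lognormal around the random median; (c) for `CTC_WGA`
#' samples, each tumor-truth variant is observed at
#' `Binomial(depth, tumor_fraction * true_vaf) / depth`. Depth is drawn per
#' locus from the negative-binomial coverage model; error `alt_count` is
#' `round(vaf * depth)` and the VAF is re-derived from counts. Variants whose
#' `alt_count` rounds to zero are not callable and are dropped.
#'
#' @param truth data frame of tumor-truth variants (`chrom`, `pos`, `ref`,
#'   `alt`, `true_vaf`), or `NULL`.
#' @param role `"AMPLIFIED_NORMAL"` or `"CTC_WGA"`.
#' @param config a [cohort_config()].
#' @param panel an [amplicon_panel()].
#' @param hotspots data frame of cohort-global hotspot loci (`chrom`,
#'   `pos`, `ref`, `alt`).
#' @param tumor_fraction latent tumor DNA fraction of the sample.
#' @param sample_id,patient_id,replicate_index sample metadata.
#' @return a [variant_set()].
#' @export
simulate_wga_sample <- function(truth, role, config, panel, hotspots,
                                tumor_fraction = 0,
                                sample_id = "S1", patient_id = "P1",
                                replicate_index = NA_integer_) {
  stopifnot(role %in% c("AMPLIFIED_NORMAL", "CTC_WGA"))
  cfg <- config
  parts <- list()

  # (a) recurrent hotspot errors
  if (nrow(hotspots) > 0L && cfg$hotspot_occurrence_prob > 0) {
    occ <- runif(nrow(hotspots)) < cfg$hotspot_occurrence_prob
    if (any(occ)) {
      h <- hotspots[occ, , drop = FALSE]
      h$depth <- rdepth(nrow(h), cfg)
      vaf <- rvaf_lnorm(nrow(h), cfg$recurrent_vaf_median, cfg$vaf_dispersion)
      h$alt_count <- as.integer(round(vaf * h$depth))
      parts$hotspot <- h[h$alt_count >= 1L,
                         c("chrom", "pos", "ref", "alt", "depth", "alt_count")]
    }
  }

  # (b) random non-recurrent errors
  mu <- if (role == "AMPLIFIED_NORMAL") cfg$random_errors_per_amplified_normal
        else cfg$random_errors_per_ctc
  n_rand <- if (mu > 0) rpois(1L, mu) else 0L
  if (n_rand > 0L) {
    r <- draw_panel_variants(n_rand, panel)
    r$depth <- rdepth(nrow(r), cfg)
    vaf <- rvaf_lnorm(nrow(r), cfg$random_vaf_median, cfg$vaf_dispersion)
    r$alt_count <- as.integer(round(vaf * r$depth))
    parts$random <- r[r$alt_count >= 1L,
                      c("chrom", "pos", "ref", "alt", "depth", "alt_count")]
  }

  # (c) tumor-derived variants carried into the CTC sample
  if (role == "CTC_WGA" && !is.null(truth) && nrow(truth) > 0L &&
      tumor_fraction > 0) {
    t <- truth
    t$depth <- rdepth(nrow(t), cfg)
    p <- pmin(tumor_fraction * t$true_vaf, 1)
    t$alt_count <- rbinom(nrow(t), t$depth, p)
    parts$truth <- t[t$alt_count >= 1L,
                     c("chrom", "pos", "ref", "alt", "depth", "alt_count")]
  }

  v <- do.call(rbind, c(list(data.frame(chrom = character(0), pos = integer(0),
                                        ref = character(0),
                                        alt = character(0),
                                        depth = integer(0),
                                        alt_count = integer(0))),
                        rev(unname(parts))))  # truth first: wins collisions
  if (nrow(v) > 0L) {
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    v <- v[!duplicated(key), , drop = FALSE]
  }
  variant_set(v, sample_id = sample_id, patient_id = patient_id, role = role,
              replicate_index = replicate_index)
}

#' Generate a full synthetic CTC study cohort
#'
#' Deterministic given the configuration (including its seed). Every patient
#' gets a tumor sample, an (empty-of-somatic-calls) unamplified normal, and
#' `n_wga_replicates` CTC-WGA samples; the first `n_amplified_normals`
#' patients additionally get a WGA-amplified normal control. A single
#' cohort-global hotspot locus set drives recurrent errors in every WGA
#' sample. CTC-positive patients (an exact `round(fraction * n)` count)
#' carry tumor DNA at a latent uniform tumor fraction; their replicates
#' share tumor-derived variants but have independent WGA errors. Clinical
#' records (age, Dukes' stage, CEA, MSI) are generated with CEA linked to
#' the latent tumor fraction through a logistic model.
#'
#' @param config a [cohort_config()].
#' @return a `ctc_cohort`: list with `patients` (each a `SimulatedPatient`
#'   list: `patient_id`, `tumor_truth`, `samples`, `clinical`, `latent`),
#'   `panel`, `hotspots`, `clinical` (cohort table), and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  .validate_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    panel <- make_panel(cfg$n_genes, cfg$total_length, cfg$primer_length)

    # cohort-global recurrent hotspot set (unique keys)
    hotspots <- draw_panel_variants(cfg$n_recurrent_hotspots, panel)
    hotspots <- hotspots[!duplicated(paste(hotspots$chrom, hotspots$pos,
                                           hotspots$alt)),
                         c("chrom", "pos", "ref", "alt"), drop = FALSE]

    n <- cfg$n_patients
    pid <- sprintf("P%02d", seq_len(n))
    n_pos <- round(cfg$ctc_positive_fraction * n)
    positive <- logical(n)
    positive[sample.int(n, n_pos)] <- TRUE
    tf <- ifelse(positive,
                 runif(n, cfg$tumor_fraction_range[1],
                       cfg$tumor_fraction_range[2]), 0)
    amp_idx <- seq_len(cfg$n_amplified_normals)
    class_probs <- default_class_probs(cfg$ct_mass)

    patients <- vector("list", n)
    for (i in seq_len(n)) {
      n_mut <- rpois(1L, cfg$tumor_mutations_mean)
      truth <- draw_panel_variants(n_mut, panel, class_probs = class_probs,
                                   indel_fraction = cfg$indel_fraction)
      truth <- truth[!duplicated(paste(truth$chrom, truth$pos, truth$alt)), ,
                     drop = FALSE]
      truth$true_vaf <- rep(cfg$het_vaf * cfg$clonal_fraction, nrow(truth))

      # tumor sample: truth observed at full cellularity
      td <- truth
      if (nrow(td) > 0L) {
        td$depth <- rdepth(nrow(td), cfg)
        td$alt_count <- rbinom(nrow(td), td$depth, td$true_vaf)
        td <- td[td$alt_count >= 1L, , drop = FALSE]
      } else {
        td$depth <- integer(0); td$alt_count <- integer(0)
      }
      tumor <- variant_set(td[, c("chrom", "pos", "ref", "alt", "depth",
                                  "alt_count")],
                           sample_id = paste0(pid[i], "_T"),
                           patient_id = pid[i], role = "TUMOR")
      normal <- variant_set(td[0L, c("chrom", "pos", "ref", "alt", "depth",
                                     "alt_count")],
                            sample_id = paste0(pid[i], "_N"),
                            patient_id = pid[i], role = "NORMAL")
      amplified <- if (i %in% amp_idx) {
        simulate_wga_sample(NULL, "AMPLIFIED_NORMAL", cfg, panel, hotspots,
                            sample_id = paste0(pid[i], "_AN"),
                            patient_id = pid[i])
      } else NULL

      # optional CTC-private subclonal mutation, shared by both replicates
      ctc_truth <- truth
      if (positive[i] && runif(1) < cfg$subclone_prob) {
        sub <- draw_panel_variants(1L, panel, class_probs = class_probs)
        sub$true_vaf <- cfg$het_vaf
        ctc_truth <- rbind(ctc_truth,
                           sub[, c("chrom", "pos", "ref", "alt", "gene",
                                   "true_vaf")])
      }
      ctc <- lapply(seq_len(cfg$n_wga_replicates), function(r) {
        simulate_wga_sample(ctc_truth, "CTC_WGA", cfg, panel, hotspots,
                            tumor_fraction = tf[i],
                            sample_id = sprintf("%s_CTC%d", pid[i], r),
                            patient_id = pid[i], replicate_index = r)
      })

      cea_high <- runif(1) < plogis(cfg$cea_intercept + cfg$cea_slope * tf[i])
      cea <- if (runif(1) < cfg$cea_missing_prob) NA_real_
             else if (cea_high) 5 + rexp(1, rate = 1 / 8)
             else runif(1, 0.5, 4.9)
      clinical <- data.frame(
        patient_id = pid[i],
        age = as.integer(pmin(pmax(round(rnorm(1, 65, 10)), 30), 92)),
        dukes = sample(c("A", "B", "C", "D"), 1L,
                       prob = c(0.15, 0.30, 0.35, 0.20)),
        cea = cea,
        msi = sample(c("MSI", "MSS"), 1L,
                     prob = c(cfg$msi_prob, 1 - cfg$msi_prob)))

      patients[[i]] <- list(patient_id = pid[i],
                            tumor_truth = truth,
                            samples = list(tumor = tumor, normal = normal,
                                           amplified_normal = amplified,
                                           ctc = ctc),
                            clinical = clinical,
                            latent = list(tumor_fraction = tf[i],
                                          ctc_positive = positive[i]))
    }
    structure(list(patients = patients,
                   panel = panel,
                   hotspots = hotspots,
                   clinical = do.call(rbind, lapply(patients,
                                                    `[[`, "clinical")),
                   config = cfg),
              class = "ctc_cohort")
  })
}

#' @export
print.ctc_cohort <- function(x, ...) {
  n_amp <- sum(vapply(x$patients,
                      function(p) !is.null(p$samples$amplified_normal),
                      logical(1)))
  n_pos <- sum(vapply(x$patients, function(p) p$latent$ctc_positive,
                      logical(1)))
  cat(sprintf(paste0("<ctc_cohort> %d patients (%d CTC-positive), ",
                     "%d amplified normals, %d CTC-WGA replicates each, ",
                     "%d-gene %d bp panel, seed %d\n"),
              length(x$patients), n_pos, n_amp,
              x$config$n_wga_replicates, x$config$n_genes,
              x$panel$total_length, x$config$seed))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' One TSV variant table per sample, a sample manifest CSV, the panel BED
#' and primers TSV, the clinical CSV, and a JSON config echo — the file-mode
#' inputs of [run_pipeline()].
#'
#' @param cohort a `ctc_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(s) {
    if (is.null(s)) return()
    f <- file.path(dir, paste0(attr(s, "sample_id"), ".tsv"))
    write_variant_table(s, f)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      sample_id = attr(s, "sample_id"), patient_id = attr(s, "patient_id"),
      role = attr(s, "role"),
      replicate_index = attr(s, "replicate_index"),
      path = basename(f))
  }
  for (p in cohort$patients) {
    emit(p$samples$tumor); emit(p$samples$normal)
    emit(p$samples$amplified_normal)
    for (s in p$samples$ctc) emit(s)
  }
  mf <- do.call(rbind, manifest)
  write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE, na = "")
  write_panel(cohort$panel, file.path(dir, "panel.bed"),
              file.path(dir, "primers.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Simulate overlapping amplicon read pairs
#'
#' Fixture generator for the read-preprocessing stage. Builds one amplicon
#' whose 5' end (and, reverse-complemented, its 3' end) is the primer, then
#' draws read pairs whose mates overlap by `2 * read_length -
#' amplicon_length` reference bases. Sequencing errors are injected per base
#' at `error_rate`, with reduced base quality at error positions. Mates are
#' stored in reference orientation (mate 2 flagged `strand = "-"`).
#'
#' @param n_pairs number of read pairs.
#' @param amplicon_length amplicon length, bp; must satisfy
#'   `read_length <= amplicon_length <= 2 * read_length` so mates overlap.
#' @param read_length read length, bp.
#' @param primer primer nucleotide string (its length must fit the amplicon
#'   twice).
#' @param error_rate per-base substitution error probability.
#' @param chrom,start reference placement of the amplicon.
#' @param base_quality Phred quality of error-free bases; error bases get
#'   qualities drawn in 11..25.
#' @return list of `read_pair` objects (see [read_pair()]).
#' @export
simulate_amplicon_read_pairs <- function(n_pairs, amplicon_length,
                                         read_length, primer,
                                         error_rate = 0.001,
                                         chrom = "chr1", start = 1000L,
                                         base_quality = 37L) {
  if (amplicon_length > 2L * read_length) {
    stop("no overlap: amplicon (", amplicon_length,
         " bp) longer than 2 * read_length (", 2L * read_length, " bp)")
  }
  if (read_length > amplicon_length) {
    stop("read_length exceeds amplicon_length")
  }
  primer <- toupper(primer)
  lp <- nchar(primer)
  if (2L * lp > amplicon_length) stop("primer too long for amplicon")
  core <- paste(sample(BASES, amplicon_length - 2L * lp, replace = TRUE),
                collapse = "")
  amplicon <- paste0(primer, core, revcomp(primer))
  amp <- strsplit(amplicon, "")[[1L]]
  s2 <- start + amplicon_length - read_length
  lapply(seq_len(n_pairs), function(i) {
    mk <- function(seq_chars) {
      q <- rep(as.integer(base_quality), read_length)
      err <- runif(read_length) < error_rate
      if (any(err)) {
        seq_chars[err] <- vapply(seq_chars[err], function(b)
          sample(setdiff(BASES, b), 1L), character(1))
        q[err] <- sample(11:25, sum(err), replace = TRUE)
      }
      list(seq = paste(seq_chars, collapse = ""), qual = q)
    }
    m1 <- mk(amp[seq_len(read_length)])
    m2 <- mk(amp[(amplicon_length - read_length + 1L):amplicon_length])
    read_pair(chrom = chrom,
              seq1 = m1$seq, qual1 = m1$qual, start1 = start, strand1 = "+",
              seq2 = m2$seq, qual2 = m2$qual, start2 = s2, strand2 = "-",
              name = sprintf("pair%04d", i))
  })
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}
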