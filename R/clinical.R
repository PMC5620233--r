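#' Mann-Whitney U rank-sum test
#'
#' U is computed from midrank sums (`U = sum over (x, y) pairs of
#' [x > y] + [x == y]/2`, reported for the first group). For small samples
#' (`min(n, m) <= 8`) with no ties the two-sided p-value comes from the
#' exact null distribution of U; otherwise from the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction. If every
#' value in both groups is identical the test is degenerate and p = 1.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `U` (first group), `p` (two-sided), `n`, `m`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) stop("NA values in input")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  N <- n + m
  if (!has_ties && min(n, m) <= 8L) {
    # exact: two-sided p doubles the smaller tail of the symmetric U null
    u_min <- min(U, n * m - U)
    p <- min(1, 2 * pwilcox(u_min, n, m))
    method <- "exact"
  } else {
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      return(list(U = U, p = 1, n = n, m = m, method = "degenerate"))
    }
    mu <- n * m / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, n = n, m = m, method = method)
}

#' Associate CTC mutation allele frequencies with a clinical variable
#'
#' The analysis unit is the tumor-matched CTC variant allele frequency.
#' By default AFs are pooled across each patient's calls (`mode =
#' "pooled"`); `mode = "patient"` summarizes each patient to their median
#' AF first, which makes observations independent across patients. Patients
#' with a missing clinical value are excluded. CEA is dichotomized at
#' 5 ng/ml (abnormal `>= 5`); two-group variables (CEA, MSI) use the
#' Mann-Whitney rank-sum test, Dukes' stage (up to four groups) uses
#' Kruskal-Wallis, and age uses Spearman rank correlation.
#'
#' @param calls data frame of tumor-matched calls with columns
#'   `patient_id` and `vaf` (e.g. pooled from [filter_ctc_sample()]).
#' @param clinical clinical records (see [read_clinical()]).
#' @param variable one of `"CEA"`, `"DUKES"`, `"MSI"`, `"AGE"`.
#' @param mode `"pooled"` (per-variant observations) or `"patient"`
#'   (per-patient median AF).
#' @param cea_cutoff dichotomization cutoff in ng/ml (default 5).
#' @return a `ctc_assoc`: list with `variable`, `mode`, `test`,
#'   `statistic`, `p`, `group_sizes`, `direction`, `group_medians`.
#' @export
associate_af_with_clinical <- function(calls, clinical,
                                       variable = c("CEA", "DUKES", "MSI",
                                                    "AGE"),
                                       mode = c("pooled", "patient"),
                                       cea_cutoff = 5) {
  variable <- match.arg(variable)
  mode <- match.arg(mode)
  stopifnot(all(c("patient_id", "vaf") %in% names(calls)))
  obs <- data.frame(patient_id = as.character(calls$patient_id),
                    vaf = calls$vaf)
  if (mode == "patient") {
    med <- tapply(obs$vaf, obs$patient_id, median)
    obs <- data.frame(patient_id = names(med), vaf = as.numeric(med))
  }
  cl <- clinical
  cl$patient_id <- as.character(cl$patient_id)
  obs <- merge(obs, cl, by = "patient_id")
  value <- switch(variable,
                  CEA = obs$cea, DUKES = obs$dukes, MSI = obs$msi,
                  AGE = obs$age)
  keep <- !is.na(value)
  obs <- obs[keep, , drop = FALSE]
  value <- value[keep]
  if (nrow(obs) == 0L) stop("no observations left after exclusions")

  if (variable == "AGE") {
    ct <- suppressWarnings(cor.test(obs$vaf, value, method = "spearman",
                                    exact = FALSE))
    res <- list(test = "spearman", statistic = unname(ct$estimate),
                p = ct$p.value, group_sizes = c(n = nrow(obs)),
                direction = if (ct$estimate >= 0) "AF increases with age"
                            else "AF decreases with age",
                group_medians = NULL)
  } else {
    group <- switch(variable,
                    CEA = ifelse(value >= cea_cutoff,
                                 sprintf(">=%g ng/ml", cea_cutoff),
                                 sprintf("<%g ng/ml", cea_cutoff)),
                    DUKES = as.character(value),
                    MSI = as.character(value))
    group <- factor(group)
    sizes <- table(group)
    sizes <- sizes[sizes > 0L]
    if (length(sizes) < 2L) {
      stop("fewer than 2 non-empty groups for ", variable,
           " after exclusions")
    }
    medians <- tapply(obs$vaf, group, median)
    if (length(sizes) == 2L) {
      g <- levels(droplevels(group))
      mw <- mann_whitney_u(obs$vaf[group == g[2L]],
                           obs$vaf[group == g[1L]])
      hi <- g[which.max(medians)]
      res <- list(test = "mann-whitney", statistic = mw$U, p = mw$p,
                  group_sizes = as.integer(sizes),
                  direction = paste0("higher AF in ", hi),
                  group_medians = as.numeric(medians))
      names(res$group_sizes) <- names(sizes)
      names(res$group_medians) <- names(medians)
    } else {
      kw <- kruskal.test(obs$vaf, group)
      res <- list(test = "kruskal-wallis",
                  statistic = unname(kw$statistic), p = kw$p.value,
                  group_sizes = as.integer(sizes),
                  direction = paste0("highest AF in ",
                                     names(medians)[which.max(medians)]),
                  group_medians = as.numeric(medians))
      names(res$group_sizes) <- names(sizes)
      names(res$group_medians) <- names(medians)
    }
  }
  structure(c(list(variable = variable, mode = mode), res),
            class = "ctc_assoc")
}

#' @export
print.ctc_assoc <- function(x, ...) {
  cat(sprintf("<ctc_assoc> %s vs CTC mutation AF (%s, %s mode)\n",
              x$variable, x$test, x$mode))
  cat(sprintf("  statistic = %.4g, p = %.4g; %s\n", x$statistic, x$p,
              x$direction))
  if (!is.null(x$group_medians)) {
    cat("  group medians:",
        paste(sprintf("%s %.4f (n=%d)", names(x$group_medians),
                      x$group_medians, x$group_sizes), collapse = ", "),
        "\n")
  }
  invisible(x)
}
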