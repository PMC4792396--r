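#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: the statistic is the maximum absolute deviation
#' from the sample mean in sample-SD units, G = max|x - mean(x)| / sd(x).
#' The critical value at significance `alpha` is
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}} \sqrt{\frac{t^2}{n-2+t^2}}}
#' with t the upper alpha/(2n) quantile of the t distribution on n - 2
#' degrees of freedom. The most extreme value is declared an outlier when
#' G exceeds the critical value.
#'
#' @param values Numeric vector, n >= 3. NAs are not allowed.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `grubbs_test`: list with `statistic`,
#'   `critical_value`, `outlier_index`, `is_outlier`, `value` (the extreme
#'   value), `direction` (+1 above the mean, -1 below), `n`, `alpha`.
#' @examples
#' grubbs_test(c(1, 1, 1, 1, 10))
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite with no NA")
  n <- length(values)
  if (n < 3) stop("Grubbs test requires at least 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  if (s == 0) {
    warning("zero variance: no outlier detectable")
    res <- list(statistic = 0, critical_value = crit, outlier_index = NA_integer_,
                is_outlier = FALSE, value = NA_real_, direction = 0L,
                n = n, alpha = alpha)
    class(res) <- "grubbs_test"
    return(res)
  }
  dev <- abs(values - m)
  idx <- which.max(dev)
  G <- dev[idx] / s
  res <- list(statistic = G, critical_value = crit, outlier_index = idx,
              is_outlier = G > crit, value = values[idx],
              direction = if (values[idx] >= m) 1L else -1L,
              n = n, alpha = alpha)
  class(res) <- "grubbs_test"
  res
}

#' @export
print.grubbs_test <- function(x, ...) {
  cat(sprintf("Grubbs test (n = %d, alpha = %g): G = %.4f, critical = %.4f\n",
              x$n, x$alpha, x$statistic, x$critical_value))
  if (x$is_outlier)
    cat(sprintf("  outlier: value %.4g at position %d (%s the mean)\n",
                x$value, x$outlier_index,
                if (x$direction > 0) "above" else "below"))
  else cat("  no outlier\n")
  invisible(x)
}

#' Sample-level quality filtering
#'
#' Applies the two sample-exclusion rules used before mtCN estimation,
#' independently of each other:
#' \enumerate{
#'   \item `LOW_MT_BASES`: bases aligned to the mitochondrial contig are
#'     at most `min_mt_fraction` of the total mitochondrial length;
#'   \item `HIGH_AUTOSOMAL_SD`: within its tissue, the sample's
#'     log10(SD of autosomal coverage / mean autosomal coverage) is flagged
#'     by a Grubbs test. Only samples *above* the tissue mean are excluded:
#'     unusually uniform coverage is not a quality defect.
#' }
#' The Grubbs step needs at least 3 samples per tissue and is applied once
#' (single pass); tissues with fewer samples skip it with a warning while
#' the threshold rule still applies.
#'
#' @param tables A stacked coverage data.frame (rows = sample x contig), as
#'   from [bind_coverage_tables()].
#' @param index A [reference_index()].
#' @param min_mt_fraction Mitochondrial aligned-base threshold as a fraction
#'   of mitochondrial length (default 0.60).
#' @param alpha Grubbs significance level (default 0.05).
#' @return A `qc_report`: list with `excluded_samples` (data.frame
#'   `sample_id`, `tissue`, `reason`, `statistic`, `threshold`) and the
#'   parameters used. Each excluded sample carries exactly one primary
#'   reason (`LOW_MT_BASES` takes precedence).
#' @export
filter_samples <- function(tables, index, min_mt_fraction = 0.60,
                           alpha = 0.05) {
  mito_len <- index$chrom_lengths[[index$mito_name]]
  key <- paste(tables$sample_id, tables$tissue)
  per_sample <- lapply(split(tables, key), function(t) {
    auto <- t[t$chrom %in% index$autosome_names, ]
    data.frame(sample_id = t$sample_id[1], tissue = t$tissue[1],
               mt_bases = t$aligned_bases[t$chrom == index$mito_name][1],
               auto_mean = mean(auto$coverage),
               auto_sd = stats::sd(auto$coverage),
               stringsAsFactors = FALSE)
  })
  ps <- do.call(rbind, per_sample)
  rownames(ps) <- NULL
  excl <- list()

  ## rule 1: minimum mitochondrial representation
  low <- ps$mt_bases <= min_mt_fraction * mito_len
  if (any(low))
    excl[[length(excl) + 1L]] <- data.frame(
      sample_id = ps$sample_id[low], tissue = ps$tissue[low],
      reason = "LOW_MT_BASES",
      statistic = ps$mt_bases[low] / mito_len,
      threshold = min_mt_fraction, stringsAsFactors = FALSE)

  ## rule 2: Grubbs on log10 normalized autosomal-coverage SD, per tissue
  for (tis in unique(ps$tissue)) {
    sub <- ps[ps$tissue == tis, ]
    if (nrow(sub) < 3) {
      warning("tissue '", tis, "' has fewer than 3 samples; ",
              "Grubbs step skipped")
      next
    }
    x <- log10(sub$auto_sd / sub$auto_mean)
    if (!all(is.finite(x))) {
      ## a sample with exactly zero autosomal dispersion cannot be a
      ## high-dispersion outlier; its -Inf would poison the test
      warning("tissue '", tis, "': non-finite log-normalized SD; ",
              "Grubbs step skipped")
      next
    }
    g <- grubbs_test(x, alpha = alpha)
    if (g$is_outlier && g$direction > 0) {
      i <- g$outlier_index
      excl[[length(excl) + 1L]] <- data.frame(
        sample_id = sub$sample_id[i], tissue = tis,
        reason = "HIGH_AUTOSOMAL_SD",
        statistic = g$statistic, threshold = g$critical_value,
        stringsAsFactors = FALSE)
    }
  }
  ex <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(), tissue = character(),
               reason = character(), statistic = numeric(),
               threshold = numeric(), stringsAsFactors = FALSE)
  ## one primary reason per sample: threshold rule wins
  ex <- ex[order(match(ex$reason, c("LOW_MT_BASES", "HIGH_AUTOSOMAL_SD"))), ]
  ex <- ex[!duplicated(paste(ex$sample_id, ex$tissue)), ]
  rownames(ex) <- NULL
  structure(list(excluded_samples = ex, min_mt_fraction = min_mt_fraction,
                 alpha = alpha),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$excluded_samples), "sample(s) excluded\n")
  if (nrow(x$excluded_samples)) print(x$excluded_samples)
  invisible(x)
}

#' Chromosome-level exclusion by coverage variability
#'
#' Within each tissue, the SD of each autosome's coverage across the
#' retained samples is normalized by the tissue's mean autosomal coverage,
#' and a Grubbs test is applied to the per-chromosome normalized SDs.
#' Flagging is iterative by default: the flagged chromosome is removed and
#' the test repeated until no outlier remains (or fewer than 3 chromosomes
#' are left). Only chromosomes with SD above the mean are flagged — inflated,
#' not deflated, variance is the defect. A chromosome is globally excluded
#' when it is flagged in at least `tissue_fraction` of the tissues.
#'
#' @param tables Stacked coverage data.frame of the retained samples.
#' @param index A [reference_index()].
#' @param alpha Grubbs significance level (default 0.05).
#' @param tissue_fraction Fraction of tissues in which a chromosome must be
#'   flagged to be excluded (default 0.50, compared with `>=`).
#' @param iterate Iterate the per-tissue Grubbs test (default TRUE); set
#'   FALSE for a single pass.
#' @return Character vector of excluded contig names, with attribute
#'   `votes`: a data.frame (`chrom`, `n_flagged`, `n_tissues`).
#' @export
select_excluded_chromosomes <- function(tables, index, alpha = 0.05,
                                        tissue_fraction = 0.50,
                                        iterate = TRUE) {
  tissues <- unique(tables$tissue)
  if (length(tissues) < 2)
    warning("fewer than 2 tissues: the tissue vote is degenerate")
  flagged <- list()
  for (tis in tissues) {
    sub <- tables[tables$tissue == tis, ]
    auto <- sub[sub$chrom %in% index$autosome_names, ]
    wide <- tapply(auto$coverage,
                   list(auto$chrom, paste(auto$sample_id, auto$tissue)),
                   identity)
    chrom_sd <- apply(wide, 1, stats::sd)
    sample_means <- colMeans(wide)
    norm_sd <- chrom_sd / mean(sample_means)
    remaining <- names(norm_sd)
    hits <- character()
    repeat {
      if (length(remaining) < 3) break
      g <- grubbs_test(norm_sd[remaining], alpha = alpha)
      if (!g$is_outlier || g$direction <= 0) break
      hit <- remaining[g$outlier_index]
      hits <- c(hits, hit)
      remaining <- setdiff(remaining, hit)
      if (!iterate) break
    }
    flagged[[tis]] <- hits
  }
  hits <- unlist(flagged, use.names = FALSE)
  if (length(hits) == 0) {
    excluded <- character()
    attr(excluded, "votes") <- data.frame(chrom = character(),
                                          n_flagged = integer(),
                                          n_tissues = integer(),
                                          stringsAsFactors = FALSE)
    return(excluded)
  }
  votes <- table(hits)
  vote_df <- data.frame(chrom = names(votes),
                        n_flagged = as.integer(votes),
                        n_tissues = length(tissues),
                        stringsAsFactors = FALSE)
  excluded <- vote_df$chrom[vote_df$n_flagged / length(tissues) >= tissue_fraction]
  attr(excluded, "votes") <- vote_df
  excluded
}
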