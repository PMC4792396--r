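#' Coverage-based mtCN estimation
#'
#' Estimates mitochondrial copy number per diploid cell from a coverage
#' table as
#' \deqn{mtCN = 2 \times \frac{mtDNA\ coverage}{mean\ autosomal\ coverage}}
#' where the mean runs over the index's autosomes minus any excluded
#' chromosomes. The factor 2 converts the haploid coverage ratio to copies
#' per diploid cell. The estimator is invariant to rescaling all aligned
#' bases by a constant (sequencing depth cancels).
#'
#' @param tables A `coverage_table` (one sample) or a stacked coverage
#'   data.frame (several samples).
#' @param index A [reference_index()].
#' @param excluded Contigs excluded from the autosomal mean (e.g. from
#'   [select_excluded_chromosomes()]).
#' @param method Label stored in the output: `"shotgun"`, `"capture"` or
#'   another tag. Capture-enriched data are processed identically, but the
#'   enrichment step is non-linear, so capture estimates are meaningful only
#'   relative to one another; they are tagged by this label so downstream
#'   consumers can treat them as relative.
#' @return data.frame with one row per sample: `sample_id`, `tissue`,
#'   `method`, `mtcn`, `chrom_norm_sd` (SD of autosomal coverage divided by
#'   its mean — the per-sample chromosomal reproducibility figure),
#'   `qc_pass`.
#' @export
mtcn_from_coverage <- function(tables, index, excluded = character(),
                               method = "shotgun") {
  key <- paste(tables$sample_id, tables$tissue)
  rows <- lapply(split(as.data.frame(tables), key), function(t) {
    auto_mean <- mean_autosomal_coverage(t, index, excluded)
    if (auto_mean <= 0) stop("zero autosomal coverage for sample ",
                             t$sample_id[1])
    auto <- setdiff(index$autosome_names, excluded)
    cov_auto <- t$coverage[match(auto, t$chrom)]
    mito_cov <- t$coverage[t$chrom == index$mito_name][1]
    mtcn <- 2 * mito_cov / auto_mean
    data.frame(sample_id = t$sample_id[1], tissue = t$tissue[1],
               method = method, mtcn = mtcn,
               chrom_norm_sd = stats::sd(cov_auto) / auto_mean,
               qc_pass = mito_cov > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$qc_pass))
    warning("samples with zero mitochondrial coverage: mtcn = 0, qc_pass = FALSE")
  out
}

#' ddPCR-based mtCN estimation
#'
#' Per replicate, mtCN is twice the dilution-corrected ratio of
#' mitochondrial to nuclear target copies,
#' \deqn{mtCN = 2 \times \frac{mt\ counts \times mt\ dilution}
#'                            {n\ counts \times n\ dilution}}
#' and the per-sample estimate is the arithmetic mean over replicates, with
#' the replicate SD and the SD normalized by the sample mean reported
#' alongside. Dilution factors restore scale when the two targets are
#' measured in separate reactions at different template amounts (the
#' high-mtCN workflow); in a multiplexed reaction both factors are 1.
#'
#' @param replicates data.frame with columns `sample_id`, `tissue`,
#'   `replicate_id`, `mt_counts`, `n_counts` and optional `mt_dilution`,
#'   `n_dilution` (default 1).
#' @return data.frame with one row per sample: `sample_id`, `tissue`,
#'   `method` (`"ddpcr"`), `mtcn`, `replicate_sd` (NA for a single
#'   replicate), `normalized_sd`, `n_replicates`, `qc_pass`.
#' @examples
#' mtcn_from_ddpcr(data.frame(sample_id = "S1", tissue = "BL",
#'                            replicate_id = 1, mt_counts = 1300,
#'                            n_counts = 10))
#' @export
mtcn_from_ddpcr <- function(replicates) {
  req <- c("sample_id", "tissue", "replicate_id", "mt_counts", "n_counts")
  if (!all(req %in% names(replicates)))
    stop("replicates must have columns: ", paste(req, collapse = ", "))
  if (is.null(replicates$mt_dilution)) replicates$mt_dilution <- 1
  if (is.null(replicates$n_dilution)) replicates$n_dilution <- 1
  if (any(replicates$mt_dilution <= 0) || any(replicates$n_dilution <= 0))
    stop("dilution factors must be > 0")
  if (any(replicates$mt_counts < 0) || any(replicates$n_counts < 0))
    stop("droplet-derived counts must be >= 0")
  key <- paste(replicates$sample_id, replicates$tissue)
  rows <- lapply(split(replicates, key), function(r) {
    bad <- r$n_counts == 0
    if (any(bad)) {
      warning("dropping ", sum(bad), " replicate(s) with zero nuclear counts",
              " for sample ", r$sample_id[1])
      r <- r[!bad, , drop = FALSE]
    }
    if (nrow(r) == 0)
      stop("all replicates dropped for sample ", replicates$sample_id[1])
    est <- 2 * (r$mt_counts * r$mt_dilution) / (r$n_counts * r$n_dilution)
    m <- mean(est)
    s <- if (length(est) > 1) stats::sd(est) else NA_real_
    data.frame(sample_id = r$sample_id[1], tissue = r$tissue[1],
               method = "ddpcr", mtcn = m, replicate_sd = s,
               normalized_sd = s / m, n_replicates = length(est),
               qc_pass = m > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Poisson correction of raw droplet counts
#'
#' Converts positive-droplet counts to target copies the way the instrument
#' does: with k of n droplets positive, the estimated number of template
#' molecules in the reaction is \eqn{-n \log(1 - k/n)}. Provided as an
#' optional pre-step for datasets that record raw positives; the estimators
#' otherwise consume instrument-corrected counts directly.
#'
#' @param positives Number of positive droplets.
#' @param droplets Total droplets in the reaction.
#' @return Estimated copies per reaction.
#' @export
ddpcr_poisson_correct <- function(positives, droplets) {
  if (any(positives > droplets)) stop("positives cannot exceed droplets")
  frac <- positives / droplets
  if (any(frac > 0.99))
    warning("more than 99% of droplets positive: reaction saturated, ",
            "counts unreliable")
  frac <- pmin(frac, 1 - 1 / droplets)  # avoid log(0) at full saturation
  -droplets * log(1 - frac)
}

#' Reproducibility summaries per tissue and method
#'
#' Mirrors the per-tissue reproducibility bookkeeping of multi-method mtCN
#' comparisons: per tissue and method, the mean mtCN, the mean normalized
#' chromosomal SD (per sample: SD of autosomal coverage divided by its mean
#' autosomal coverage, then averaged over samples), and the replicate SD in
#' both conventions — normalized per sample then averaged
#' (`sd_replicates_sample`), and averaged first then normalized by the
#' tissue's mean mtCN (`sd_replicates_tissue`).
#'
#' @param estimates data.frame of estimates from [mtcn_from_coverage()]
#'   and/or [mtcn_from_ddpcr()] (rows from several methods may be stacked).
#' @return data.frame with one row per tissue x method: `tissue`, `method`,
#'   `n`, `mean_mtcn`, `sd_chromosomes`, `sd_replicates_sample`,
#'   `sd_replicates_tissue`. Columns that do not apply to a method are NA;
#'   single-sample groups report NA SDs.
#' @export
reproducibility_summary <- function(estimates) {
  key <- paste(estimates$tissue, estimates$method)
  rows <- lapply(split(estimates, key), function(e) {
    n <- nrow(e)
    rep_sd <- if ("replicate_sd" %in% names(e)) e$replicate_sd else NULL
    data.frame(
      tissue = e$tissue[1], method = e$method[1], n = n,
      mean_mtcn = mean(e$mtcn),
      sd_chromosomes = if ("chrom_norm_sd" %in% names(e))
        mean(e$chrom_norm_sd) else NA_real_,
      sd_replicates_sample = if (!is.null(rep_sd))
        mean(rep_sd / e$mtcn, na.rm = TRUE) else NA_real_,
      sd_replicates_tissue = if (!is.null(rep_sd))
        mean(rep_sd, na.rm = TRUE) / mean(e$mtcn) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$tissue), ]
}
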