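#' Pipeline run configuration
#'
#' Collects the thresholds of every stage with their standard defaults:
#' minimum read length 50 bp, mate-distance filter 3 SD, poly-N mask
#' threshold 5, minimum mitochondrial fraction 0.60, Grubbs alpha 0.05,
#' tissue vote fraction 0.50, minimum MAF carriers 10, BH alpha 0.05.
#'
#' @param seed Integer seed recorded in output headers.
#' @param min_read_len,max_pair_sd,n_run_threshold,min_mt_fraction
#'   Coverage/QC thresholds (see the stage functions).
#' @param grubbs_alpha,tissue_fraction Chromosome/sample exclusion knobs.
#' @param min_carriers,bh_alpha Association knobs.
#' @param alpha_normality,max_exclusions Normality-gate knobs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, min_read_len = 50, max_pair_sd = 3,
                       n_run_threshold = 5, min_mt_fraction = 0.60,
                       grubbs_alpha = 0.05, tissue_fraction = 0.50,
                       min_carriers = 10, bh_alpha = 0.05,
                       alpha_normality = 0.05, max_exclusions = 2) {
  structure(list(seed = as.integer(seed), min_read_len = min_read_len,
                 max_pair_sd = max_pair_sd, n_run_threshold = n_run_threshold,
                 min_mt_fraction = min_mt_fraction,
                 grubbs_alpha = grubbs_alpha,
                 tissue_fraction = tissue_fraction,
                 min_carriers = min_carriers, bh_alpha = bh_alpha,
                 alpha_normality = alpha_normality,
                 max_exclusions = max_exclusions),
            class = "run_config")
}

tsv_header <- function(config) {
  c(sprintf("# mitocn %s", as.character(utils::packageVersion("mitocn"))),
    sprintf("# seed=%d", config$seed),
    sprintf("# params: %s",
            paste(sprintf("%s=%g", setdiff(names(config), "seed"),
                          unlist(config[setdiff(names(config), "seed")])),
                  collapse = " ")))
}

#' Write a data.frame as TSV with a '#' provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param config A [run_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, config = run_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a '#'-headed TSV
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a pre-tabulated coverage table
#'
#' Alternative input that bypasses BAM parsing: a TSV with columns
#' `sample_id`, `tissue`, `chrom`, `aligned_bases`. Coverage is recomputed
#' against the supplied index.
#'
#' @param path TSV path.
#' @param index A [reference_index()].
#' @return Stacked coverage data.frame.
#' @export
read_coverage_tsv <- function(path, index) {
  d <- read_tsv(path)
  req <- c("sample_id", "tissue", "chrom", "aligned_bases")
  if (!all(req %in% names(d)))
    stop("coverage TSV needs columns: ", paste(req, collapse = ", "))
  d$mappable_bases <- as.numeric(index$mappable_bases[d$chrom])
  if (anyNA(d$mappable_bases))
    stop("coverage TSV contains contigs absent from the index")
  d$coverage <- d$aligned_bases / d$mappable_bases
  d
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in order — coverage QC (sample then chromosome
#' exclusion), mtCN estimation, and the association battery — writing each
#' stage's table as a '#'-headed TSV plus a JSON manifest linking the
#' artifacts and recording every exclusion.
#'
#' @param coverage Stacked coverage data.frame (e.g. from
#'   [bind_coverage_tables()] or [read_coverage_tsv()]).
#' @param index A [reference_index()].
#' @param metadata Individual metadata data.frame (`individual_id`, `age`,
#'   `sex`, `haplogroup`).
#' @param heteroplasmy Optional heteroplasmy table.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param method Estimate label (default `"shotgun"`).
#' @return List with `estimates`, `summary`, `battery`, `qc`,
#'   `excluded_chromosomes`, `manifest` (path).
#' @export
run_pipeline <- function(coverage, index, metadata, heteroplasmy = NULL,
                         out_dir = tempfile("mitocn_run"),
                         config = run_config(), method = "shotgun") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(out_dir, name)

  qc <- filter_samples(coverage, index,
                       min_mt_fraction = config$min_mt_fraction,
                       alpha = config$grubbs_alpha)
  bad <- paste(qc$excluded_samples$sample_id, qc$excluded_samples$tissue)
  retained <- coverage[!paste(coverage$sample_id, coverage$tissue) %in% bad, ]
  if (nrow(retained) == 0) stop("all samples excluded by QC")

  excl_chr <- select_excluded_chromosomes(
    retained, index, alpha = config$grubbs_alpha,
    tissue_fraction = config$tissue_fraction)

  estimates <- mtcn_from_coverage(retained, index, excluded = excl_chr,
                                  method = method)
  summary_tab <- reproducibility_summary(estimates)

  cohort <- build_cohort(estimates, metadata, heteroplasmy)
  battery <- association_battery(cohort, heteroplasmy, method = method,
                                 min_carriers = config$min_carriers,
                                 alpha_normality = config$alpha_normality,
                                 max_exclusions = config$max_exclusions)

  write_tsv(qc$excluded_samples, art("qc_excluded_samples.tsv"), config)
  write_tsv(estimates, art("mtcn_estimates.tsv"), config)
  write_tsv(summary_tab, art("reproducibility_summary.tsv"), config)
  write_tsv(battery$results, art("association_results.tsv"), config)
  if (!is.null(battery$pairs))
    write_tsv(battery$pairs, art("tissue_pairs.tsv"), config)
  write_tsv(battery$exclusions, art("normality_exclusions.tsv"), config)

  manifest <- art("manifest.json")
  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("mitocn")),
         seed = config$seed,
         config = unclass(config),
         artifacts = list(
           qc_excluded_samples = "qc_excluded_samples.tsv",
           mtcn_estimates = "mtcn_estimates.tsv",
           reproducibility_summary = "reproducibility_summary.tsv",
           association_results = "association_results.tsv",
           tissue_pairs = if (!is.null(battery$pairs)) "tissue_pairs.tsv",
           normality_exclusions = "normality_exclusions.tsv"),
         excluded_samples = qc$excluded_samples,
         excluded_chromosomes = as.character(excl_chr)),
    manifest, auto_unbox = TRUE, digits = NA)

  list(estimates = estimates, summary = summary_tab, battery = battery,
       qc = qc, excluded_chromosomes = excl_chr, manifest = manifest)
}
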