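#' NUMT catalogue from intervals
#'
#' Builds the catalogue of nuclear insertions of mitochondrial DNA (NUMTs)
#' used by the misalignment model. Intervals are 0-based half-open
#' (BED convention); overlapping intervals are merged before lengths are
#' computed, so that placements are never double-counted.
#'
#' @param x A BED file path, a `GRanges`, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return An object of class `numt_catalog`: list with `intervals`
#'   (a merged `GRanges`), `lengths` (interval widths, bp) and `N`
#'   (maximum NUMT length; 0 for an empty catalogue).
#' @export
numt_catalog <- function(x) {
  if (is.character(x)) {
    gr <- rtracklayer::import(x, format = "BED")
  } else if (methods::is(x, "GRanges")) {
    gr <- x
  } else if (is.data.frame(x)) {
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stop("data.frame input needs columns chrom, start, end")
    if (any(x$end <= x$start)) stop("intervals must satisfy end > start")
    gr <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(start = x$start + 1L, end = x$end))
  } else stop("unsupported catalogue input")
  gr <- GenomicRanges::reduce(gr)
  lens <- GenomicRanges::width(gr)
  structure(list(intervals = gr, lengths = as.numeric(lens),
                 N = if (length(lens)) max(lens) else 0),
            class = "numt_catalog")
}

#' @export
print.numt_catalog <- function(x, ...) {
  cat("numt_catalog:", length(x$lengths), "merged intervals; max length",
      x$N, "bp; total", sum(x$lengths), "bp\n")
  invisible(x)
}

#' Count fully-contained fragment placements within NUMTs
#'
#' For a fragment of a given insert size, counts the start positions at
#' which the fragment would lie entirely inside some NUMT: the sum over
#' NUMTs of length j >= insert of (j - insert + 1). Only such placements
#' can produce a read with no flanking nuclear sequence, i.e. one that can
#' be misattributed to the mitochondrial genome.
#'
#' @param catalog A [numt_catalog()].
#' @param insert_size Fragment insert size in bp (>= 1).
#' @return Integer count (0 for an empty catalogue or an insert longer than
#'   every NUMT).
#' @examples
#' cat2 <- numt_catalog(data.frame(chrom = "chr1", start = c(0, 100),
#'                                 end = c(10, 105)))
#' placements_within_numts(cat2, 4)  # 7 + 2 = 9
#' @export
placements_within_numts <- function(catalog, insert_size) {
  stopifnot(inherits(catalog, "numt_catalog"))
  if (insert_size < 1) stop("insert_size must be >= 1")
  sum(pmax(catalog$lengths - insert_size + 1, 0))
}

#' Probability that a NUMT-derived fragment is misattributed to mtDNA
#'
#' Estimates the chance that a sequenced fragment originating in the nuclear
#' genome lies fully within a NUMT — and so carries no distinguishing
#' nuclear flank and can be falsely aligned to the mitochondrial genome.
#' For each observed insert size i the fraction of the mappable genome's
#' (l - i + 1) possible placements that fall entirely inside a NUMT is
#' computed, and these per-size probabilities are averaged with the
#' empirical insert-size frequencies as weights:
#' \deqn{p = \sum_i w_i \frac{\sum_{j \ge i} (j - i + 1)}{l - i + 1}}
#' Average autosomal coverage does not enter the probability — it converts
#' it into an expected per-run count of misattributed fragments, reported
#' alongside.
#'
#' @param catalog A [numt_catalog()].
#' @param inserts Insert-size distribution: a data.frame with columns
#'   `size`, `count` (as from [insert_size_histogram()]) or a numeric
#'   vector of observed insert sizes.
#' @param mappable_l Length of the mappable genome in bp.
#' @param coverage_c Average autosomal coverage of the run (optional;
#'   carried in the report).
#' @param mode `"empirical"` (default) weights insert sizes by their
#'   observed frequency; `"printed"` is a compatibility mode that sums the
#'   unweighted ratio over all insert sizes 1..M and is **not** a
#'   probability (it can exceed 1).
#' @return An object of class `misalignment_risk`: list with `probability`,
#'   `placements_by_insert` (data.frame `size`, `count`, `placements`,
#'   `p_size`), `expected_misattributed` (probability times total fragment
#'   count), `mode`, `inputs` (list with `coverage_c`, `mappable_l`,
#'   `total_fragments`).
#' @export
misalignment_probability <- function(catalog, inserts, mappable_l,
                                     coverage_c = NA_real_,
                                     mode = c("empirical", "printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "numt_catalog"))
  if (mappable_l <= 0) stop("mappable_l must be > 0")
  if (is.numeric(inserts) && is.null(dim(inserts))) {
    h <- table(inserts)
    inserts <- data.frame(size = as.integer(names(h)), count = as.integer(h))
  }
  if (!all(c("size", "count") %in% names(inserts)) || nrow(inserts) == 0)
    stop("inserts must be a non-empty histogram (size, count) or a vector")
  inserts <- inserts[inserts$count > 0, , drop = FALSE]
  if (any(inserts$size >= mappable_l))
    stop("insert sizes must be smaller than the mappable genome")

  sizes <- if (mode == "printed") seq_len(max(inserts$size)) else inserts$size
  plc <- vapply(sizes, function(i) placements_within_numts(catalog, i),
                numeric(1))
  per_size <- plc / (mappable_l - sizes + 1)
  if (mode == "empirical") {
    w <- inserts$count / sum(inserts$count)
    p <- sum(w * per_size)
    tab <- data.frame(size = sizes, count = inserts$count,
                      placements = plc, p_size = per_size)
  } else {
    p <- sum(per_size)
    cnt <- integer(length(sizes))
    cnt[match(inserts$size, sizes)] <- inserts$count
    tab <- data.frame(size = sizes, count = cnt,
                      placements = plc, p_size = per_size)
  }
  if (all(plc == 0))
    message("all observed inserts are longer than every NUMT: p = 0")
  total <- sum(inserts$count)
  structure(list(probability = p,
                 placements_by_insert = tab,
                 expected_misattributed = p * total,
                 mode = mode,
                 inputs = list(coverage_c = coverage_c,
                               mappable_l = mappable_l,
                               total_fragments = total)),
            class = "misalignment_risk")
}

#' @export
print.misalignment_risk <- function(x, ...) {
  cat(sprintf("NUMT misalignment risk (%s mode): p = %.3g (%.4f%%)\n",
              x$mode, x$probability, 100 * x$probability))
  cat(sprintf("  expected misattributed fragments: %.2f of %d\n",
              x$expected_misattributed, x$inputs$total_fragments))
  invisible(x)
}

#' Write a misalignment-risk report as JSON
#'
#' @param risk A `misalignment_risk` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_misalignment_report <- function(risk, path) {
  jsonlite::write_json(
    list(probability = risk$probability,
         expected_misattributed_fragments = risk$expected_misattributed,
         mode = risk$mode,
         inputs_digest = risk$inputs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
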