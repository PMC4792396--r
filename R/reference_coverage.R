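#' Construct a reference index
#'
#' Low-level constructor for the per-contig bookkeeping used by the coverage
#' and QC stages: contig names, lengths, mappable-base counts (bases left
#' after masking long poly-N runs) and the identity of the mitochondrial
#' contig. Sex chromosomes and any other designated contigs are kept out of
#' the autosome set, so that the mtCN denominator only ever averages
#' autosomal coverage.
#'
#' @param chrom_names Character vector of contig identifiers.
#' @param chrom_lengths Integer vector of contig lengths (bp), parallel to
#'   `chrom_names`.
#' @param mappable_bases Integer vector of mappable bases per contig.
#'   Defaults to `chrom_lengths` (no masking).
#' @param mito_name Identifier of the mitochondrial contig; must be one of
#'   `chrom_names`.
#' @param sex_chroms Contigs excluded from the autosome set in addition to
#'   the mitochondrial contig (default: common X/Y spellings).
#' @return An object of class `reference_index`: a list with elements
#'   `chrom_names`, `chrom_lengths`, `mappable_bases` (both named),
#'   `mito_name` and `autosome_names`.
#' @seealso [build_reference_index()] to derive the index from a FASTA file.
#' @export
reference_index <- function(chrom_names, chrom_lengths,
                            mappable_bases = chrom_lengths,
                            mito_name,
                            sex_chroms = c("chrX", "chrY", "X", "Y")) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names))
    stop("duplicated contig names in reference")
  if (length(chrom_lengths) != length(chrom_names) ||
      length(mappable_bases) != length(chrom_names))
    stop("chrom_lengths and mappable_bases must parallel chrom_names")
  if (!mito_name %in% chrom_names)
    stop("mitochondrial contig '", mito_name, "' not present in reference")
  if (any(chrom_lengths <= 0))
    stop("all contig lengths must be > 0")
  if (any(mappable_bases < 0) || any(mappable_bases > chrom_lengths))
    stop("mappable_bases must lie in [0, chrom_length] for every contig")
  chrom_lengths <- setNames(as.numeric(chrom_lengths), chrom_names)
  mappable_bases <- setNames(as.numeric(mappable_bases), chrom_names)
  autosome_names <- setdiff(chrom_names, c(mito_name, sex_chroms))
  if (length(autosome_names) == 0)
    stop("reference contains no autosomes")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = chrom_lengths,
         mappable_bases = mappable_bases,
         mito_name = mito_name,
         autosome_names = autosome_names),
    class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("reference_index:", length(x$chrom_names), "contigs; mitochondrial =",
      x$mito_name, "\n")
  cat("  autosomes:", length(x$autosome_names),
      "| total mappable:", format(sum(x$mappable_bases), big.mark = ","),
      "bp\n")
  invisible(x)
}

#' Build a reference index from a FASTA file
#'
#' Reads a (multi-)FASTA reference and computes, per contig, the number of
#' mappable bases: the contig length minus the total length of poly-N runs
#' strictly longer than `n_run_threshold` (case-insensitive). With the
#' default threshold of 5, a run of exactly 5 Ns is retained while runs of 6
#' or more are masked. Mappable-base counts are the denominator of
#' per-chromosome coverage and the effective genome length used by the NUMT
#' misalignment model.
#'
#' @param fasta Path to a FASTA file.
#' @param mito_name Name of the mitochondrial contig (first whitespace-token
#'   of its FASTA header).
#' @param n_run_threshold N-runs strictly longer than this are masked
#'   (default 5).
#' @param sex_chroms Passed to [reference_index()].
#' @return A [reference_index()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", strrep("A", 40), ">chrM", strrep("C", 30)), fa)
#' idx <- build_reference_index(fa, mito_name = "chrM")
#' idx$mappable_bases
#' @export
build_reference_index <- function(fasta, mito_name = "chrM",
                                  n_run_threshold = 5,
                                  sex_chroms = c("chrX", "chrY", "X", "Y")) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0) stop("no sequences in FASTA: ", fasta)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- nm
  lens <- Biostrings::width(seqs)
  if (any(lens == 0)) stop("empty contig in FASTA: ",
                           paste(nm[lens == 0], collapse = ", "))
  if (!mito_name %in% nm)
    stop("mitochondrial contig '", mito_name, "' not found in ", fasta)
  pat <- sprintf("[Nn]{%d,}", n_run_threshold + 1L)
  masked <- vapply(seq_along(seqs), function(i) {
    m <- gregexpr(pat, as.character(seqs[[i]]))[[1]]
    if (m[1] == -1L) 0L else sum(attr(m, "match.length"))
  }, integer(1))
  reference_index(nm, lens, lens - masked, mito_name, sex_chroms)
}

## Shared tally core: takes a fragment data.frame (chrom, insert_size,
## optional proper), applies the two-pass insert-distance filter and sums
## insert lengths per contig of the index.
tally_core <- function(frag, index, max_pair_sd, sample_id, tissue,
                       single_end = FALSE) {
  if (!is.null(frag$proper)) frag <- frag[as.logical(frag$proper), , drop = FALSE]
  frag <- frag[!is.na(frag$chrom) & !is.na(frag$insert_size), , drop = FALSE]
  unknown <- !frag$chrom %in% index$chrom_names
  if (any(unknown)) {
    warning(sum(unknown), " fragments on contigs absent from the index were dropped")
    frag <- frag[!unknown, , drop = FALSE]
  }
  if (nrow(frag) == 0) stop("no fragments to tally")
  if (any(frag$insert_size < 1)) stop("insert sizes must be >= 1")
  ## pass 1: estimate the insert-size distribution from all same-contig pairs
  mu <- mean(frag$insert_size)
  s <- stats::sd(frag$insert_size)
  ## pass 2: distance filter |insert - mean| <= max_pair_sd * SD
  if (!single_end && !is.na(s) && s > 0) {
    keep <- abs(frag$insert_size - mu) <= max_pair_sd * s
    frag <- frag[keep, , drop = FALSE]
  }
  if (nrow(frag) == 0) stop("no fragments passed the insert-size distance filter")
  ab <- tapply(frag$insert_size, factor(frag$chrom, levels = index$chrom_names),
               sum, default = 0)
  ab <- setNames(as.numeric(ab), index$chrom_names)
  tab <- data.frame(
    sample_id = sample_id,
    tissue = tissue,
    chrom = index$chrom_names,
    aligned_bases = ab,
    mappable_bases = as.numeric(index$mappable_bases),
    coverage = ab / as.numeric(index$mappable_bases),
    stringsAsFactors = FALSE, row.names = NULL)
  h <- table(frag$insert_size)
  attr(tab, "insert_hist") <- data.frame(size = as.integer(names(h)),
                                         count = as.integer(h))
  attr(tab, "insert_mean") <- mu
  attr(tab, "insert_sd") <- s
  attr(tab, "n_fragments") <- nrow(frag)
  attr(tab, "single_end") <- single_end
  class(tab) <- c("coverage_table", "data.frame")
  tab
}

#' Tally paired-end fragments into a per-chromosome coverage table
#'
#' Converts alignments into per-contig aligned-base totals: each counted
#' fragment contributes its insert size (the span between outer mate ends,
#' which equals the merged-read length when mates overlap) once to its
#' contig. Only pairs with both mates on the same contig are counted, and a
#' two-pass filter removes pairs whose insert size deviates from the mean by
#' more than `max_pair_sd` standard deviations: the insert-size distribution
#' is first estimated from all same-contig pairs, then the distance filter
#' is applied. Coverage is aligned bases divided by the contig's mappable
#' bases.
#'
#' @param alignments Either a path to a BAM/SAM file, or a data.frame of
#'   pre-extracted fragments with columns `chrom`, `insert_size` and
#'   optionally `proper` (rows with `proper = FALSE` are cross-contig or
#'   otherwise invalid pairs and are discarded before the distance filter).
#' @param index A [reference_index()].
#' @param min_read_len Alignment records shorter than this are ignored
#'   (default 50 bp); applies to the BAM path only, tabular fragments are
#'   assumed pre-filtered.
#' @param max_pair_sd Mate-distance filter width in insert-size SD units
#'   (default 3).
#' @param sample_id,tissue Labels stored in the output.
#' @return A `coverage_table`: a data.frame with one row per contig of the
#'   index (`sample_id`, `tissue`, `chrom`, `aligned_bases`,
#'   `mappable_bases`, `coverage`) and attributes `insert_hist` (data.frame
#'   `size`, `count`), `insert_mean`, `insert_sd`, `n_fragments`,
#'   `single_end`.
#' @details If the input contains no paired records at all, a warning is
#'   emitted and single reads are counted by their read length, with the
#'   `single_end` attribute set.
#' @export
tally_fragments <- function(alignments, index, min_read_len = 50,
                            max_pair_sd = 3, sample_id = "sample",
                            tissue = NA_character_) {
  if (is.character(alignments)) {
    frag <- read_bam_fragments(alignments, min_read_len = min_read_len)
    return(tally_core(frag$fragments, index, max_pair_sd, sample_id, tissue,
                      single_end = frag$single_end))
  }
  if (!is.data.frame(alignments) ||
      !all(c("chrom", "insert_size") %in% names(alignments)))
    stop("alignments must be a BAM/SAM path or a data.frame with columns ",
         "'chrom' and 'insert_size'")
  tally_core(alignments, index, max_pair_sd, sample_id, tissue)
}

## Extract same-contig pair fragments from a BAM (or SAM, converted on the
## fly). Each pair is represented once, by its leftmost mate (TLEN > 0);
## TLEN is the fragment span, i.e. the merged length for overlapping mates.
read_bam_fragments <- function(path, min_read_len = 50) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "qwidth", "mrnm", "isize")))[[1]]
  mapped <- !is.na(b$pos) & bitwAnd(b$flag, 4L) == 0L
  long_enough <- !is.na(b$qwidth) & b$qwidth >= min_read_len
  paired <- bitwAnd(b$flag, 1L) > 0L
  same_contig <- !is.na(b$mrnm) & as.character(b$mrnm) == as.character(b$rname)
  rep_mate <- mapped & long_enough & paired & same_contig &
    !is.na(b$isize) & b$isize > 0L
  if (any(rep_mate)) {
    frag <- data.frame(chrom = as.character(b$rname)[rep_mate],
                       insert_size = as.integer(b$isize)[rep_mate],
                       stringsAsFactors = FALSE)
    return(list(fragments = frag, single_end = FALSE))
  }
  single <- mapped & long_enough & !paired
  if (!any(single))
    stop("no same-contig pairs and no usable single-end reads in ", path)
  warning("no paired records found; counting single reads by read length")
  frag <- data.frame(chrom = as.character(b$rname)[single],
                     insert_size = as.integer(b$qwidth)[single],
                     stringsAsFactors = FALSE)
  list(fragments = frag, single_end = TRUE)
}

#' Mean autosomal coverage of one sample
#'
#' Arithmetic mean of per-chromosome coverage over the index's autosomes,
#' minus any excluded contigs. This is the denominator of the coverage-based
#' mtCN estimator.
#'
#' @param table A `coverage_table` for a single sample.
#' @param index A [reference_index()].
#' @param excluded Contig names to leave out of the average (e.g. flagged by
#'   [select_excluded_chromosomes()]).
#' @return A single number.
#' @export
mean_autosomal_coverage <- function(table, index, excluded = character()) {
  if (length(unique(paste(table$sample_id, table$tissue))) > 1)
    stop("mean_autosomal_coverage expects a single-sample coverage table")
  auto <- setdiff(index$autosome_names, excluded)
  if (length(auto) == 0) stop("all autosomes excluded")
  cov <- table$coverage[match(auto, table$chrom)]
  if (anyNA(cov)) stop("coverage table lacks rows for some autosomes")
  mean(cov)
}

#' Insert-size histogram of a coverage table
#'
#' @param table A `coverage_table` produced by [tally_fragments()].
#' @return A data.frame with columns `size` and `count`.
#' @export
insert_size_histogram <- function(table) {
  h <- attr(table, "insert_hist")
  if (is.null(h)) stop("table carries no insert-size histogram")
  h
}

#' Stack per-sample coverage tables
#'
#' @param tables A list of `coverage_table` objects.
#' @return One data.frame with all rows; per-sample attributes are dropped.
#' @export
bind_coverage_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)))
  rownames(out) <- NULL
  out
}
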