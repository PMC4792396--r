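#' Simulation configuration with study-scale defaults
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' emulate a multi-tissue autopsy cohort: per-tissue mtCN scales of 257
#' (blood), 2873 (skeletal muscle) and 7023 (liver) copies per diploid
#' cell, log-normal inter-individual spread (SD 0.15 on log10), ages
#' uniform on 0-96 years, a negative age trend on SM mtCN that is stronger
#' in males (-0.004 vs -0.0015 log10 units/year), a positive age trend in
#' LIV (+0.002), heteroplasmic sites 408 and 16327 whose minor allele
#' frequency rises with age (bounded by the observed ceilings 0.282 and
#' 0.20 and a 0.02 detection floor) and is negatively coupled to SM mtCN,
#' and one 100-fold extreme-mtCN SM sample per 150 individuals. With
#' `effects = "null"` every planted effect is zeroed (flat age trends, no
#' MAF accumulation, no outliers) for type-I-error checks.
#'
#' @param seed Integer seed; every generator reseeds from it, so identical
#'   configs give byte-identical outputs.
#' @param effects `"default"` (planted effects above) or `"null"`.
#' @param cohort_n Individuals in the cohort (default 150).
#' @param tissues Tissue labels simulated (default BL, SM, LIV).
#' @param mtcn_scale Named per-tissue true mtCN scales.
#' @param log_mtcn_sd Inter-individual SD of log10 mtCN (default 0.15).
#' @param age_range Uniform age range in years (default 0-96).
#' @param male_fraction P(male) (default 85/152).
#' @param beta_age Named list of per-tissue `c(m=, f=)` age slopes on log10
#'   mtCN per year.
#' @param maf_sites data.frame describing heteroplasmic sites: `site`,
#'   `tissue`, `slope` (natural-scale MAF per year), `ceiling`, `coupling`
#'   (log10 mtCN shift per unit MAF; negative = copy-number loss).
#' @param maf_logit_sd Biological MAF noise SD on the logit scale.
#' @param maf_floor Detection floor: MAF below it is recorded as absent.
#' @param het_base,het_age_slope Poisson mean of the heteroplasmic-site
#'   count: `het_base + het_age_slope * age`.
#' @param outlier_rate,outlier_fold,outlier_tissue Extreme-mtCN samples:
#'   `round(cohort_n * outlier_rate)` individuals (deterministic count, so
#'   the default config always contains exactly one) get their mtCN in
#'   `outlier_tissue` multiplied by `outlier_fold`.
#' @param haplogroup_probs Named sampling probabilities for haplogroups.
#' @param autosome_lengths,mito_length,mito_name Toy reference geometry.
#' @param n_run_spec data.frame of planted poly-N runs (`chrom`, `start`
#'   0-based, `length`), or NULL.
#' @param numt_spec data.frame of planted NUMTs (`length`, `chrom`), or
#'   NULL.
#' @param depth Mean autosomal coverage of simulated runs (default 0.5).
#' @param insert_mean,insert_sd,read_len Fragment geometry (bp).
#' @param numt_fragment_rate Fraction of extra fragments originating inside
#'   NUMTs (default 0).
#' @param droplets,ddpcr_cells_mt,ddpcr_cells_n,ddpcr_pipette_cv ddPCR
#'   model: droplets per reaction, diploid-cell equivalents of template in
#'   the mt and nuclear reactions, and the lognormal CV of template
#'   pipetting per replicate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       effects = c("default", "null"),
                       cohort_n = 150L,
                       tissues = c("BL", "SM", "LIV"),
                       mtcn_scale = c(BL = 257, SM = 2873, LIV = 7023),
                       log_mtcn_sd = 0.15,
                       age_range = c(0, 96),
                       male_fraction = 85 / 152,
                       beta_age = list(BL = c(m = 0, f = 0),
                                       SM = c(m = -0.004, f = -0.0015),
                                       LIV = c(m = 0.002, f = 0.002)),
                       maf_sites = data.frame(
                         site = c(408L, 16327L),
                         tissue = c("SM", "SM"),
                         slope = c(0.0015, 0.0010),
                         ceiling = c(0.282, 0.20),
                         coupling = c(-1.5, -1.5)),
                       maf_logit_sd = 0.5,
                       maf_floor = 0.02,
                       het_base = 2, het_age_slope = 0.05,
                       outlier_rate = 1 / 150, outlier_fold = 100,
                       outlier_tissue = "SM",
                       haplogroup_probs = c(H = 0.45, J = 0.09, U = 0.15,
                                            other = 0.31),
                       autosome_lengths = c(chr1 = 5e5, chr2 = 5e5,
                                            chr3 = 5e5),
                       mito_length = 16569L, mito_name = "chrM",
                       n_run_spec = NULL,
                       numt_spec = data.frame(length = c(500L, 300L),
                                              chrom = c("chr1", "chr2")),
                       depth = 0.5,
                       insert_mean = 150, insert_sd = 15, read_len = 95,
                       numt_fragment_rate = 0,
                       droplets = 20000L,
                       ddpcr_cells_mt = c(BL = 151.5, SM = 3.03, LIV = 1.5),
                       ddpcr_cells_n = c(BL = 151.5, SM = 1515, LIV = 1515),
                       ddpcr_pipette_cv = 0.03) {
  effects <- match.arg(effects)
  if (effects == "null") {
    beta_age <- lapply(beta_age, function(b) b * 0)
    maf_sites$slope <- 0
    maf_sites$coupling <- 0
    het_age_slope <- 0
    outlier_rate <- 0
  }
  if (cohort_n < 10) stop("cohort_n must be >= 10")
  if (!all(tissues %in% names(mtcn_scale)))
    stop("mtcn_scale must name every tissue")
  cfg <- list(seed = as.integer(seed), effects = effects,
              cohort_n = as.integer(cohort_n), tissues = tissues,
              mtcn_scale = mtcn_scale, log_mtcn_sd = log_mtcn_sd,
              age_range = age_range, male_fraction = male_fraction,
              beta_age = beta_age, maf_sites = maf_sites,
              maf_logit_sd = maf_logit_sd, maf_floor = maf_floor,
              het_base = het_base, het_age_slope = het_age_slope,
              outlier_rate = outlier_rate, outlier_fold = outlier_fold,
              outlier_tissue = outlier_tissue,
              haplogroup_probs = haplogroup_probs,
              autosome_lengths = autosome_lengths,
              mito_length = as.integer(mito_length), mito_name = mito_name,
              n_run_spec = n_run_spec, numt_spec = numt_spec,
              depth = depth, insert_mean = insert_mean,
              insert_sd = insert_sd, read_len = read_len,
              numt_fragment_rate = numt_fragment_rate,
              droplets = as.integer(droplets),
              ddpcr_cells_mt = ddpcr_cells_mt,
              ddpcr_cells_n = ddpcr_cells_n,
              ddpcr_pipette_cv = ddpcr_pipette_cv)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy reference genome with planted NUMTs and N-runs
#'
#' Generates random-sequence autosomes plus a mitochondrial contig, plants
#' the configured poly-N runs, and inserts NUMTs as verbatim copies of
#' mitochondrial subsequences at recorded (0-based half-open) coordinates.
#' Overlapping placements are re-drawn up to a retry cap. The FASTA and a
#' BED of the NUMT intervals are written to `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (default a fresh tempdir subdirectory).
#' @return List with `fasta`, `bed` (paths), `index` (the
#'   [reference_index()] built from the FASTA), `numts` (data.frame
#'   `chrom`, `start`, `end`, `mito_start`, `length`) and `config`.
#' @export
simulate_reference <- function(config, dir = tempfile("simref")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lens <- config$autosome_lengths
  seqs <- lapply(lens, random_dna)
  mito <- random_dna(config$mito_length)

  ## plant N-runs
  if (!is.null(config$n_run_spec) && nrow(config$n_run_spec)) {
    for (i in seq_len(nrow(config$n_run_spec))) {
      r <- config$n_run_spec[i, ]
      s <- seqs[[r$chrom]]
      substr(s, r$start + 1L, r$start + r$length) <-
        strrep("N", r$length)
      seqs[[r$chrom]] <- s
    }
  }

  ## plant NUMTs: verbatim mito subsequences
  numts <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mito_start = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  if (!is.null(config$numt_spec) && nrow(config$numt_spec)) {
    for (i in seq_len(nrow(config$numt_spec))) {
      len <- config$numt_spec$length[i]
      chrom <- config$numt_spec$chrom[i]
      if (!chrom %in% names(lens))
        stop("NUMT host chromosome '", chrom, "' not in the reference")
      if (len > lens[[chrom]]) stop("NUMT longer than host chromosome")
      if (len > config$mito_length) stop("NUMT longer than mito genome")
      placed <- FALSE
      for (try in 1:100) {
        start <- sample.int(lens[[chrom]] - len + 1L, 1L) - 1L
        same <- numts[numts$chrom == chrom, ]
        if (nrow(same) == 0 ||
            all(start + len <= same$start | start >= same$end)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place NUMT without overlap after 100 tries")
      mstart <- sample.int(config$mito_length - len + 1L, 1L) - 1L
      piece <- substr(mito, mstart + 1L, mstart + len)
      s <- seqs[[chrom]]
      substr(s, start + 1L, start + len) <- piece
      seqs[[chrom]] <- s
      numts <- rbind(numts, data.frame(
        chrom = chrom, start = start, end = start + len,
        mito_start = mstart, length = len, stringsAsFactors = FALSE))
    }
  }

  fasta <- file.path(dir, "reference.fa")
  ss <- Biostrings::DNAStringSet(c(unlist(seqs), setNames(mito, config$mito_name)))
  names(ss) <- c(names(lens), config$mito_name)
  Biostrings::writeXStringSet(ss, fasta)

  bed <- file.path(dir, "numts.bed")
  if (nrow(numts)) {
    gr <- GenomicRanges::GRanges(
      numts$chrom,
      IRanges::IRanges(start = numts$start + 1L, end = numts$end),
      name = sprintf("NUMT%02d", seq_len(nrow(numts))))
    rtracklayer::export(gr, bed, format = "BED")
  } else {
    writeLines(character(), bed)
  }
  idx <- build_reference_index(fasta, mito_name = config$mito_name)
  list(fasta = fasta, bed = bed, index = idx, numts = numts,
       config = config)
}

#' Simulate aligned paired-end fragments at a known true mtCN
#'
#' Draws fragments so that expected autosomal coverage equals `depth` and
#' expected mitochondrial coverage equals `depth * true_mtcn / 2` —
#' inverting the coverage-based estimator, so the estimator applied to the
#' output should recover `true_mtcn` up to sampling noise. Per-contig
#' fragment counts are Poisson; insert sizes are drawn from a normal
#' truncated below at the read length (and above at the contig length);
#' start positions are uniform. Optionally, a fraction of extra fragments
#' originate inside planted NUMT intervals and are labelled as such.
#'
#' @param config A [sim_config()].
#' @param true_mtcn True copies per diploid cell.
#' @param index A [reference_index()]; defaults to an unmasked index built
#'   from the config's geometry (no FASTA needed).
#' @param numts NUMT data.frame from [simulate_reference()] (only needed if
#'   `config$numt_fragment_rate > 0`).
#' @param sample_id,tissue Labels carried in the output.
#' @return data.frame of fragments: `chrom`, `start` (0-based),
#'   `insert_size`, `origin` (`"mito"`, `"autosome"` or `"numt"`),
#'   `proper`.
#' @export
simulate_fragments <- function(config, true_mtcn, index = NULL,
                               numts = NULL, sample_id = "S1",
                               tissue = "BL") {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth <= 0) stop("depth must be > 0")
  set.seed(config$seed)
  if (is.null(index)) {
    lens <- c(config$autosome_lengths,
              setNames(config$mito_length, config$mito_name))
    index <- reference_index(names(lens), lens, mito_name = config$mito_name)
  }
  cov_target <- setNames(rep(config$depth, length(index$chrom_names)),
                         index$chrom_names)
  cov_target[index$mito_name] <- config$depth * true_mtcn / 2
  draw_on <- function(chrom, n, origin, lo = 0L, hi = NULL) {
    if (n == 0) return(NULL)
    clen <- index$chrom_lengths[[chrom]]
    if (is.null(hi)) hi <- clen
    ins <- round(rnorm(n, config$insert_mean, config$insert_sd))
    ins <- pmin(pmax(ins, config$read_len), hi - lo)
    start <- lo + floor(runif(n, 0, hi - lo - ins + 1))
    data.frame(chrom = chrom, start = start, insert_size = as.integer(ins),
               origin = origin, proper = TRUE, stringsAsFactors = FALSE)
  }
  parts <- lapply(index$chrom_names, function(ch) {
    lambda <- cov_target[[ch]] * index$mappable_bases[[ch]] / config$insert_mean
    n <- rpois(1, lambda)
    draw_on(ch, n, if (ch == index$mito_name) "mito" else "autosome")
  })
  if (config$numt_fragment_rate > 0 && !is.null(numts) && nrow(numts)) {
    n_total <- sum(vapply(parts, function(p) if (is.null(p)) 0L else nrow(p),
                          integer(1)))
    n_numt <- rpois(1, config$numt_fragment_rate * n_total)
    if (n_numt > 0) {
      pick <- sample.int(nrow(numts), n_numt, replace = TRUE,
                         prob = numts$length)
      parts <- c(parts, lapply(seq_len(n_numt), function(k) {
        r <- numts[pick[k], ]
        draw_on(r$chrom, 1L, "numt", lo = r$start, hi = r$end)
      }))
    }
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  attr(out, "tissue") <- tissue
  attr(out, "true_mtcn") <- true_mtcn
  out
}

#' Write simulated fragments as a SAM file
#'
#' Emits each fragment as a properly-paired read pair (flags 99/147, TLEN =
#' +/- insert size, placeholder sequence) with an @SQ header per contig.
#' Useful for exercising the BAM-reading path end to end; reads shorter
#' than the insert overlap and their span still equals the insert size.
#'
#' @param fragments data.frame from [simulate_fragments()].
#' @param index A [reference_index()].
#' @param path Output SAM path.
#' @param read_len Read length written into the records.
#' @return `path`, invisibly.
#' @export
write_fragments_sam <- function(fragments, index, path, read_len = 95) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", index$chrom_names,
                   as.integer(index$chrom_lengths)))
  n <- nrow(fragments)
  rl <- pmin(read_len, fragments$insert_size)
  pos1 <- fragments$start + 1L
  pos2 <- fragments$start + fragments$insert_size - rl + 1L
  qname <- sprintf("frag%07d", seq_len(n))
  seq1 <- strrep("A", rl)
  cig <- sprintf("%dM", rl)
  r1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*", qname,
                fragments$chrom, pos1, cig, pos2, fragments$insert_size,
                seq1)
  r2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*", qname,
                fragments$chrom, pos2, cig, pos1, -fragments$insert_size,
                seq1)
  writeLines(c(hdr, rbind(r1, r2)), path)
  invisible(path)
}

#' Simulate ddPCR droplet measurements at a known true mtCN
#'
#' Models the droplet partitioning of a ddPCR reaction: the expected number
#' of template molecules is `cells_mt * true_mtcn` for the mitochondrial
#' target and `2 * cells_n` for the single-copy nuclear target (2 copies
#' per diploid cell); template pipetting noise is lognormal per replicate;
#' each reaction's positive-droplet count is Binomial with per-droplet
#' occupancy `1 - exp(-lambda / droplets)`; and counts are back-converted
#' to copies with the instrument's Poisson correction
#' ([ddpcr_poisson_correct()]). Dilution factors are reported as the ratio
#' of nuclear to mitochondrial template, so the estimator recovers absolute
#' mtCN for separate-reaction workflows.
#'
#' @param config A [sim_config()].
#' @param true_mtcn True copies per diploid cell.
#' @param replicates Number of replicates (default 3).
#' @param tissue Tissue label; selects `ddpcr_cells_mt[tissue]` and
#'   `ddpcr_cells_n[tissue]` from the config. Equal cell inputs correspond
#'   to a multiplexed reaction (shared pipetting noise), unequal inputs to
#'   separate reactions.
#' @param sample_id Sample label.
#' @return data.frame of replicate measurements with the columns expected
#'   by [mtcn_from_ddpcr()], plus `multiplexed`.
#' @export
simulate_ddpcr <- function(config, true_mtcn, replicates = 3,
                           tissue = "BL", sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  set.seed(config$seed)
  cells_mt <- config$ddpcr_cells_mt[[tissue]]
  cells_n <- config$ddpcr_cells_n[[tissue]]
  multiplexed <- isTRUE(all.equal(cells_mt, cells_n))
  nd <- config$droplets
  if (nd < 2) warning("degenerate droplet count: reaction saturates")
  cv <- config$ddpcr_pipette_cv
  sdlog <- sqrt(log(1 + cv^2))
  one_target <- function(lambda) {
    occupancy <- 1 - exp(-lambda / nd)
    pos <- rbinom(1, nd, min(occupancy, 1))
    if (pos >= nd) pos <- nd - 1L  # saturation guard
    ddpcr_poisson_correct(pos, nd)
  }
  rows <- lapply(seq_len(replicates), function(r) {
    noise_mt <- exp(rnorm(1, -sdlog^2 / 2, sdlog))
    noise_n <- if (multiplexed) noise_mt else exp(rnorm(1, -sdlog^2 / 2, sdlog))
    lam_mt <- cells_mt * true_mtcn * noise_mt
    lam_n <- 2 * cells_n * noise_n
    if (1 - exp(-lam_mt / nd) > 0.99 || 1 - exp(-lam_n / nd) > 0.99)
      warning("replicate ", r, ": >99% positive droplets (saturation)")
    data.frame(sample_id = sample_id, tissue = tissue, replicate_id = r,
               mt_counts = one_target(lam_mt),
               n_counts = one_target(lam_n),
               mt_dilution = cells_n / cells_mt, n_dilution = 1,
               multiplexed = multiplexed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a multi-tissue cohort with planted covariate effects
#'
#' Generates one row per individual x tissue with true mtCN drawn from the
#' planted effect model:
#' `log10 mtCN = log10(scale[tissue]) + beta_age[tissue, sex] * age +
#'  coupling * MAF(site) + noise`,
#' with ages uniform, log-normal inter-individual noise, site MAFs that
#' rise with age (logit-scale truncated noise, detection floor and
#' per-site ceiling) and are recorded only for carriers (MAF >= floor),
#' Poisson heteroplasmy counts whose mean grows with age, and a
#' deterministic number of extreme-mtCN outlier samples
#' (`round(cohort_n * outlier_rate)`) whose mtCN in the outlier tissue is
#' multiplied by `outlier_fold`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (data.frame `individual_id`, `tissue`,
#'   `method`, `mtcn`, `age`, `sex`, `haplogroup`, `het_count`),
#'   `heteroplasmy` (data.frame `individual_id`, `tissue`, `site`, `maf`,
#'   `minor_allele`; carriers only) and `truth` (list of every planted
#'   parameter, the per-sample true MAFs and the outlier individuals).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$cohort_n
  ids <- sprintf("IND%03d", seq_len(n))
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < config$male_fraction, "m", "f")
  hap <- sample(names(config$haplogroup_probs), n, replace = TRUE,
                prob = config$haplogroup_probs)

  ## site MAFs (true, pre-censoring) per individual
  ms <- config$maf_sites
  true_maf <- matrix(0, nrow = n, ncol = nrow(ms),
                     dimnames = list(ids, as.character(ms$site)))
  for (j in seq_len(nrow(ms))) {
    mu_nat <- pmin(pmax(ms$slope[j] * age, 1e-4), ms$ceiling[j] - 1e-4)
    z <- qlogis(mu_nat) + rnorm(n, 0, config$maf_logit_sd)
    true_maf[, j] <- pmin(plogis(z), ms$ceiling[j])
  }

  n_out <- round(n * config$outlier_rate)
  outlier_ids <- if (n_out > 0) sample(ids, n_out) else character()

  cohort <- list()
  het <- list()
  for (tis in config$tissues) {
    b <- config$beta_age[[tis]]
    logm <- log10(config$mtcn_scale[[tis]]) +
      ifelse(sex == "m", b[["m"]], b[["f"]]) * age +
      rnorm(n, 0, config$log_mtcn_sd)
    for (j in which(ms$tissue == tis))
      logm <- logm + ms$coupling[j] * true_maf[, j]
    if (tis == config$outlier_tissue && length(outlier_ids))
      logm[ids %in% outlier_ids] <-
        logm[ids %in% outlier_ids] + log10(config$outlier_fold)
    het_count <- rpois(n, config$het_base + config$het_age_slope * age)
    cohort[[tis]] <- data.frame(
      individual_id = ids, tissue = tis, method = "shotgun",
      mtcn = 10^logm, age = age, sex = sex, haplogroup = hap,
      het_count = het_count, stringsAsFactors = FALSE)
    for (j in which(ms$tissue == tis)) {
      carrier <- true_maf[, j] >= config$maf_floor
      if (any(carrier))
        het[[paste(tis, j)]] <- data.frame(
          individual_id = ids[carrier], tissue = tis,
          site = ms$site[j], maf = round(true_maf[carrier, j], 4),
          minor_allele = if (ms$site[j] == 408L) "A" else "T",
          stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, cohort)
  rownames(cohort) <- NULL
  het <- if (length(het)) do.call(rbind, het) else
    data.frame(individual_id = character(), tissue = character(),
               site = integer(), maf = numeric(),
               minor_allele = character(), stringsAsFactors = FALSE)
  rownames(het) <- NULL
  list(cohort = cohort, heteroplasmy = het,
       truth = list(config = config, age = setNames(age, ids),
                    sex = setNames(sex, ids), true_maf = true_maf,
                    outlier_ids = outlier_ids,
                    beta_age = config$beta_age,
                    maf_sites = config$maf_sites))
}
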