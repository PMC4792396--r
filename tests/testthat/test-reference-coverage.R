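test_that("mappable bases mask poly-N runs strictly longer than the threshold", {
  fa <- write_fasta(c(
    chr1 = paste0(strrep("A", 45), strrep("N", 10), strrep("G", 45)),  # run of 10
    chr2 = paste0(strrep("A", 50), strrep("N", 5), strrep("G", 45)),   # run of exactly 5
    chr3 = "ACGT",
    chrM = strrep("C", 30)))
  idx <- build_reference_index(fa, mito_name = "chrM")
  expect_equal(unname(idx$mappable_bases["chr1"]), 90)
  expect_equal(unname(idx$mappable_bases["chr2"]), 100)  # not "> 5"
  expect_equal(unname(idx$mappable_bases["chr3"]), 4)
  expect_equal(idx$autosome_names, c("chr1", "chr2", "chr3"))
})

test_that("N-run masking is case-insensitive and agrees with a brute-force scan", {
  set.seed(11)
  for (k in 1:15) {
    n <- sample(50:200, 1)
    ch <- sample(c("A", "C", "G", "T", "N", "n"), n, replace = TRUE,
                 prob = c(.2, .2, .2, .2, .1, .1))
    s <- paste(ch, collapse = "")
    fa <- write_fasta(c(c1 = s, chrM = "ACGTACGT"))
    idx <- build_reference_index(fa, mito_name = "chrM")
    expect_equal(unname(idx$mappable_bases["c1"]), mappable_oracle(s),
                 info = paste("case", k))
  }
})

test_that("index construction rejects bad inputs", {
  fa <- write_fasta(c(chr1 = "ACGT"))
  expect_error(build_reference_index(fa, mito_name = "chrM"), "not found")
  expect_error(reference_index("chrM", 100, mito_name = "chrM"),
               "no autosomes")
  expect_error(reference_index(c("chr1", "chrM"), c(0, 100),
                               mito_name = "chrM"), "> 0")
  expect_error(reference_index(c("chr1", "chrM"), c(50, 100),
                               mappable_bases = c(60, 100),
                               mito_name = "chrM"), "mappable")
})

test_that("fragment tallying sums insert sizes per contig", {
  idx <- make_index(n_auto = 1, auto_len = 100, mito_len = 100)
  fr <- data.frame(chrom = "chr1", insert_size = c(50, 30))
  tab <- tally_fragments(fr, idx)
  expect_equal(tab$aligned_bases[tab$chrom == "chr1"], 80)
  expect_equal(tab$coverage[tab$chrom == "chr1"], 0.8)
  expect_equal(tab$aligned_bases[tab$chrom == "chrM"], 0)
  h <- insert_size_histogram(tab)
  expect_equal(sum(h$count), 2)
})

test_that("cross-contig pairs contribute nothing", {
  idx <- make_index(n_auto = 2, auto_len = 100)
  fr <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   insert_size = c(40, 45, 60),
                   proper = c(TRUE, TRUE, FALSE))
  tab <- tally_fragments(fr, idx)
  expect_equal(tab$aligned_bases[tab$chrom == "chr2"], 0)
  expect_equal(tab$aligned_bases[tab$chrom == "chr1"], 85)
})

test_that("distance filter removes inserts beyond max_pair_sd SDs, two-pass", {
  idx <- make_index(n_auto = 1, auto_len = 1e6)
  set.seed(5)
  ins <- round(rnorm(2000, 150, 10))
  fr <- data.frame(chrom = "chr1", insert_size = c(ins, 5000))
  tab <- tally_fragments(fr, idx, max_pair_sd = 3)
  # oracle: mean/SD from the full first pass, then filter
  mu <- mean(fr$insert_size); s <- sd(fr$insert_size)
  kept <- fr$insert_size[abs(fr$insert_size - mu) <= 3 * s]
  expect_equal(sum(tab$aligned_bases), sum(kept))
  expect_false(5000 %in% insert_size_histogram(tab)$size)
})

test_that("aligned bases are conserved: totals equal the sum of counted inserts", {
  cfg <- sim_config(seed = 21, autosome_lengths = c(chr1 = 2e4, chr2 = 2e4))
  idx <- reference_index(c("chr1", "chr2", "chrM"), c(2e4, 2e4, 16569),
                         mito_name = "chrM")
  fr <- simulate_fragments(cfg, true_mtcn = 10, index = idx)
  tab <- tally_fragments(fr, idx)
  mu <- mean(fr$insert_size); s <- sd(fr$insert_size)
  kept <- abs(fr$insert_size - mu) <= 3 * s
  expect_equal(sum(tab$aligned_bases), sum(fr$insert_size[kept]))
  expect_equal(attr(tab, "n_fragments"), sum(kept))
})

test_that("coverage recovers simulated depth within 3 sampling SDs", {
  cfg <- sim_config(seed = 31, depth = 1,
                    autosome_lengths = c(chr1 = 3e5, chr2 = 3e5))
  idx <- reference_index(c("chr1", "chr2", "chrM"), c(3e5, 3e5, 16569),
                         mito_name = "chrM")
  fr <- simulate_fragments(cfg, true_mtcn = 2, index = idx)
  tab <- tally_fragments(fr, idx)
  for (ch in idx$chrom_names) {
    n_frag <- sum(fr$chrom == ch)
    cov <- tab$coverage[tab$chrom == ch]
    expect_lt(abs(cov - 1), 3 / sqrt(n_frag) + 0.01)
  }
})

test_that("BAM path matches the tabular path and keeps merged lengths once", {
  cfg <- sim_config(seed = 41, autosome_lengths = c(chr1 = 5e4))
  idx <- reference_index(c("chr1", "chrM"), c(5e4, 16569), mito_name = "chrM")
  fr <- simulate_fragments(cfg, true_mtcn = 4, index = idx)
  sam <- tempfile(fileext = ".sam")
  write_fragments_sam(fr, idx, sam)
  tab_sam <- tally_fragments(sam, idx)
  tab_df <- tally_fragments(fr, idx)
  expect_equal(tab_sam$aligned_bases, tab_df$aligned_bases)

  # a 95-bp fragment with fully-overlapping 95-bp mates contributes 95, not 190
  idx2 <- make_index(n_auto = 1, auto_len = 1000, mito_len = 200)
  fr2 <- data.frame(chrom = "chr1", start = c(10L, 200L),
                    insert_size = c(95L, 95L), proper = TRUE)
  sam2 <- tempfile(fileext = ".sam")
  write_fragments_sam(fr2, idx2, sam2, read_len = 95)
  tab2 <- tally_fragments(sam2, idx2)
  expect_equal(tab2$aligned_bases[tab2$chrom == "chr1"], 190)
})

test_that("unpaired-only input warns and counts reads by length", {
  idx <- make_index(n_auto = 1, auto_len = 1000, mito_len = 200)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", idx$chrom_names,
                       as.integer(idx$chrom_lengths)),
               sprintf("r%d\t0\tchr1\t%d\t60\t60M\t*\t0\t0\t%s\t*",
                       1:3, c(1, 100, 200), strrep("A", 60))), sam)
  expect_warning(tab <- tally_fragments(sam, idx), "single reads")
  expect_true(attr(tab, "single_end"))
  expect_equal(tab$aligned_bases[tab$chrom == "chr1"], 180)
})

test_that("short reads are dropped by the BAM read-length filter", {
  idx <- make_index(n_auto = 1, auto_len = 1000, mito_len = 200)
  sam <- tempfile(fileext = ".sam")
  # one pair with 95-bp reads, one with 30-bp reads (below the 50-bp floor)
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", idx$chrom_names,
                       as.integer(idx$chrom_lengths)),
               sprintf("a\t99\tchr1\t1\t60\t95M\t=\t106\t200\t%s\t*", strrep("A", 95)),
               sprintf("a\t147\tchr1\t106\t60\t95M\t=\t1\t-200\t%s\t*", strrep("A", 95)),
               sprintf("b\t99\tchr1\t301\t60\t30M\t=\t471\t200\t%s\t*", strrep("A", 30)),
               sprintf("b\t147\tchr1\t471\t60\t30M\t=\t301\t-200\t%s\t*", strrep("A", 30))),
             sam)
  tab <- tally_fragments(sam, idx, min_read_len = 50)
  expect_equal(tab$aligned_bases[tab$chrom == "chr1"], 200)
})

test_that("mean autosomal coverage averages non-excluded autosomes", {
  idx <- make_index(n_auto = 3, auto_len = 100, mito_len = 50)
  tab <- make_cov_table(idx, c(chr1 = 1, chr2 = 2, chr3 = 3, chrM = 9))
  expect_equal(mean_autosomal_coverage(tab, idx), 2)
  expect_equal(mean_autosomal_coverage(tab, idx, excluded = "chr3"), 1.5)
  expect_equal(mean_autosomal_coverage(tab, idx,
                                       excluded = c("chr1", "chr2")), 3)
  expect_error(mean_autosomal_coverage(tab, idx,
                                       excluded = paste0("chr", 1:3)),
               "all autosomes excluded")
})

test_that("zero passing fragments is an error", {
  idx <- make_index()
  expect_error(tally_fragments(data.frame(chrom = "chr9", insert_size = 5)[0, ],
                               idx), "no fragments")
  expect_warning(
    expect_error(tally_fragments(data.frame(chrom = "chr9", insert_size = 5),
                                 idx), "no fragments"),
    "absent from the index")
})
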