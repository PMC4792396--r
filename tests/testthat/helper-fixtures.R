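# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# small reference index without a FASTA
make_index <- function(n_auto = 3, auto_len = 1000, mito_len = 100,
                       mito = "chrM") {
  nm <- c(paste0("chr", seq_len(n_auto)), mito)
  reference_index(nm, c(rep(auto_len, n_auto), mito_len), mito_name = mito)
}

# coverage table for one sample from a named per-contig coverage vector
make_cov_table <- function(index, coverage, sample_id = "S1", tissue = "T1") {
  cov <- coverage[index$chrom_names]
  data.frame(sample_id = sample_id, tissue = tissue,
             chrom = index$chrom_names,
             aligned_bases = as.numeric(cov * index$mappable_bases),
             mappable_bases = as.numeric(index$mappable_bases),
             coverage = as.numeric(cov),
             stringsAsFactors = FALSE)
}

# stacked tables for many samples: `cov_list` is a named list
# sample_id -> list(tissue =, coverage = named vector)
make_cov_stack <- function(index, cov_list) {
  do.call(rbind, lapply(names(cov_list), function(s)
    make_cov_table(index, cov_list[[s]]$coverage, sample_id = s,
                   tissue = cov_list[[s]]$tissue)))
}

# write a FASTA from a named character vector of sequences
write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

# brute-force mappable-base oracle: character scan with rle
mappable_oracle <- function(seq, threshold = 5) {
  ch <- strsplit(toupper(seq), "")[[1]]
  r <- rle(ch == "N")
  nchar(seq) - sum(r$lengths[r$values & r$lengths > threshold])
}

# brute-force step-up BH oracle, independent of p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
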