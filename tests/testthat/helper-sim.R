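# Small planted worlds shared across test files.

tiny_config <- function(seed = 11, ...) {
  defaults <- list(genome_length = 30000L, n_up = 8L, n_down = 8L,
                   n_flat = 10L, library_depth = 20000L,
                   n_structural = c(rRNA = 3L, tRNA = 5L, snRNA = 2L,
                                    snoRNA = 2L, miRNA = 3L),
                   n_background_tx = 20L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Random genome hits with a mix of planted duplex pairs and unpaired decoys.
random_hit_set <- function(n_hits, genome_length = 50000L) {
  n_pairs <- n_hits %/% 4L
  lens <- sample(20:24, n_hits, replace = TRUE)
  starts <- sample.int(genome_length - 30L, n_hits, replace = TRUE) + 3L
  strand <- sample(c("+", "-"), n_hits, replace = TRUE)
  hits <- data.frame(tag = sprintf("t%04d", seq_len(n_hits)), chrom = "chr1",
                     start = starts, end = starts + lens, strand = strand,
                     stringsAsFactors = FALSE)
  if (n_pairs > 0L) {
    ix <- sample(which(hits$strand == "+"), min(n_pairs, sum(hits$strand == "+")))
    partners <- data.frame(tag = paste0(hits$tag[ix], "m"), chrom = "chr1",
                           start = hits$start[ix] - 2L,
                           end = hits$end[ix] - 2L, strand = "-",
                           stringsAsFactors = FALSE)
    hits <- rbind(hits, partners)
  }
  hits
}

random_guide <- function(len = 21L) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
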