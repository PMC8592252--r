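make_test_genome <- function(len = 10000L, seed = 31) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  stats::setNames(g, "chr1")
}

test_that("planted substrings are found on both strands", {
  genome <- make_test_genome()
  idx <- build_index(genome)
  q <- substring(genome[[1]], 101, 121)  # genome[100:121) 0-based
  hits <- map_exact(q, idx)
  plus <- hits[hits$strand == "+", ]
  expect_true(nrow(plus) >= 1L)
  expect_true(any(plus$start == 100L & plus$end == 121L))
  # strand symmetry: the reverse complement hits the same interval on minus
  hits_rc <- map_exact(revcomp(q), idx)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_true(any(minus$start == 100L & minus$end == 121L))
})

test_that("mapping a tag and its reverse complement swaps strands only", {
  genome <- make_test_genome(seed = 33)
  idx <- build_index(genome)
  set.seed(34)
  for (rep in 1:10) {
    s <- sample.int(nchar(genome[[1]]) - 24L, 1)
    tag <- substring(genome[[1]], s, s + 20L)
    h1 <- map_exact(tag, idx)
    h2 <- map_exact(revcomp(tag), idx)
    flip <- c("+" = "-", "-" = "+")
    h2$strand <- unname(flip[h2$strand])
    h2 <- h2[order(h2$chrom, h2$start, h2$strand), ]
    h1$tag <- NULL; h2$tag <- NULL
    rownames(h1) <- rownames(h2) <- NULL
    expect_equal(h1[order(h1$chrom, h1$start, h1$strand), ], h2)
  }
})

test_that("exact mapper equals the naive full-scan oracle on random tags", {
  genome <- make_test_genome(len = 20000L, seed = 35)
  idx <- build_index(genome)
  set.seed(36)
  # mix of planted (present) and random (mostly absent) tags
  planted <- vapply(1:100, function(i) {
    s <- sample.int(19950, 1)
    substring(genome[[1]], s, s + sample(19:23, 1))
  }, character(1))
  rand <- vapply(1:100, function(i) random_guide(sample(20:24, 1)), character(1))
  tags <- unique(c(planted, rand, revcomp(planted[1:20])))
  res <- map_tags(tags, idx, max_hits = 1000L)
  oracle <- oracle_map(tags, genome)
  key <- function(df) sort(paste(df$tag, df$chrom, df$start, df$end, df$strand))
  expect_identical(key(res$hits), key(oracle))
  # partition: mapped + unmapped = all tags, disjoint
  expect_setequal(c(unique(res$hits$tag), res$unmapped), tags)
  expect_length(intersect(unique(res$hits$tag), res$unmapped), 0L)
})

test_that("multi-mapping cap drops and logs pathological tags", {
  rep_unit <- "ACGTACGTACGTACGTACGTA"  # 21 nt
  genome <- stats::setNames(strrep("ACGT", 200), "chr1")
  idx <- build_index(genome)
  res <- map_tags(rep_unit, idx, max_hits = 5L)
  expect_equal(nrow(res$hits), 0L)
  expect_equal(res$capped, rep_unit)
})

test_that("duplicate chromosome names are rejected", {
  expect_error(build_index(c(chr1 = "ACGT", chr1 = "ACGT")), "duplicate")
})

test_that("structural subtraction removes whole tags by any 1-bp overlap", {
  hits <- data.frame(
    tag = c("inside", "adjacent", "onebp", "clear"),
    chrom = "chr1",
    start = c(150L, 200L, 180L, 500L),
    end = c(171L, 221L, 201L, 521L),
    strand = "+", stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", start = c(100L, 190L), end = c(200L, 191L),
                    strand = "+", class = c("rRNA", "tRNA"),
                    id = c("r1", "t1"), stringsAsFactors = FALSE)
  res <- subtract_annotated(hits, ann)
  # fully inside rRNA -> removed, tallied rRNA
  expect_true("inside" %in% res$removed$tag)
  expect_equal(res$removed$class[res$removed$tag == "inside"], "rRNA")
  # adjacency (start == annotation end) is zero overlap -> kept
  expect_true("adjacent" %in% res$kept$tag)
  # 1-bp overlap -> removed; precedence rRNA > tRNA for the tally
  expect_true("onebp" %in% res$removed$tag)
  expect_equal(res$removed$class[res$removed$tag == "onebp"], "rRNA")
  expect_true("clear" %in% res$kept$tag)
  expect_equal(unname(res$tally["rRNA"]), 2L)
  # partition: kept tags + removed tags = mapped tags
  expect_setequal(c(unique(res$kept$tag), res$removed$tag), hits$tag)
})

test_that("1-bp overlaps agree with an interval-intersection oracle", {
  set.seed(37)
  for (rep in 1:20) {
    s <- sample.int(1000, 1)
    hits <- data.frame(tag = "t", chrom = "chr1", start = s, end = s + 21L,
                       strand = "+", stringsAsFactors = FALSE)
    a <- sample.int(1000, 1)
    ann <- data.frame(chrom = "chr1", start = a, end = a + 50L, strand = "+",
                      class = "tRNA", id = "x", stringsAsFactors = FALSE)
    res <- subtract_annotated(hits, ann)
    overlap <- max(0L, min(s + 21L, a + 50L) - max(s, a))
    expect_equal(nrow(res$removed) == 1L, overlap >= 1L)
  }
})

test_that("annotation on unknown chromosomes warns and is ignored", {
  hits <- data.frame(tag = "t", chrom = "chr1", start = 10L, end = 31L,
                     strand = "+", stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chrX", start = 0L, end = 1000L, strand = "+",
                    class = "rRNA", id = "r", stringsAsFactors = FALSE)
  expect_warning(res <- subtract_annotated(hits, ann, chrom_names = "chr1"),
                 "ignoring")
  expect_equal(nrow(res$kept), 1L)
})

test_that("GFF3 round trip preserves structural annotation coordinates", {
  cfg <- tiny_config(seed = 41)
  g <- make_genome(cfg)
  path <- tempfile(fileext = ".gff3")
  sirnapipe:::write_annotation_gff3(g$annotation, path)
  back <- read_structural_annotation(path)
  expect_equal(back$start, g$annotation$start)
  expect_equal(back$end, g$annotation$end)
  expect_equal(back$class, g$annotation$class)
})
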