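intervals_overlap_test <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

test_that("genome generation is seeded-deterministic and places loci without overlap", {
  cfg <- sim_config(genome_length = 50000L, seed = 7,
                    n_structural = c(rRNA = 10L),
                    n_up = 2L, n_down = 2L, n_flat = 2L)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$annotation, g2$annotation)

  ann <- g1$annotation
  expect_equal(nrow(ann), 10L)
  for (i in seq_len(nrow(ann) - 1L)) {
    for (j in (i + 1L):nrow(ann)) {
      expect_false(intervals_overlap_test(ann$start[i], ann$end[i],
                                          ann$start[j], ann$end[j]))
    }
  }
})

test_that("zero structural loci yields an empty but valid annotation", {
  cfg <- sim_config(n_structural = c(rRNA = 0L), n_up = 1L, n_down = 1L,
                    n_flat = 1L, seed = 3)
  g <- make_genome(cfg)
  expect_equal(nrow(g$annotation), 0L)
  path <- tempfile(fileext = ".gff3")
  sirnapipe:::write_annotation_gff3(g$annotation, path)
  lines <- readLines(path)
  expect_true(grepl("^##gff-version 3", lines[1]))
  expect_equal(sum(!grepl("^#", lines)), 0L)
})

test_that("planted loci satisfy the duplex geometry and status invariants", {
  cfg <- tiny_config(seed = 5)
  g <- make_genome(cfg)
  truth <- plant_sirna_loci(g, cfg)
  expect_equal(nrow(truth), 26L)
  # 2-nt shift geometry on both ends
  expect_true(all(truth$plus_start - truth$minus_start == 2L))
  expect_true(all(truth$plus_end - truth$minus_end == 2L))
  expect_true(all(truth$guide_length >= 20L & truth$guide_length <= 24L))
  # minus-strand read is the reverse complement of the genome over its interval
  gseq <- g$genome[[1]]
  for (i in sample(nrow(truth), 5L)) {
    expect_identical(truth$minus_seq[i],
                     revcomp(substring(gseq, truth$minus_start[i] + 1L,
                                       truth$minus_end[i])))
  }
  # fold-change classes
  folds <- as.matrix(truth[, c("fold_1h", "fold_6h", "fold_12h")])
  expect_true(all(folds[truth$status_1h == "up", ] >= 2))
  expect_true(all(folds[truth$status_1h == "down", ] <= 0.5))
  flat <- folds[truth$status_1h == "flat", ]
  expect_true(all(flat >= 0.8 & flat <= 1.25))
  # log2 separation: planted up/down effects exceed the DE threshold
  expect_true(all(abs(log2(folds[truth$status_1h != "flat", ])) >= 1))
  expect_true(all(abs(log2(flat)) < 1))
})

test_that("noise-free reads all map to planted or structural loci", {
  cfg <- tiny_config(seed = 9, junk_fraction = 0, lowq_fraction = 0,
                     library_depth = 5000L)
  g <- make_genome(cfg)
  truth <- plant_sirna_loci(g, cfg)
  sim <- simulate_reads(truth, g, cfg)
  tr <- trim_adapter(sim$reads[["0h"]]$seq, cfg$adapter)
  inserts <- unique(tr$insert[tr$status == "ok"])
  hits <- oracle_map(inserts, g$genome)
  expect_setequal(inserts, unique(hits$tag))
})

test_that("simulated FASTQ output is deterministic and depth 0 is valid-empty", {
  cfg <- tiny_config(seed = 2, library_depth = 2000L)
  d1 <- file.path(tempdir(), "simdet1")
  d2 <- file.path(tempdir(), "simdet2")
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  cfg0 <- tiny_config(seed = 2, library_depth = 0L)
  g <- make_genome(cfg0)
  truth <- plant_sirna_loci(g, cfg0)
  sim <- simulate_reads(truth, g, cfg0)
  expect_equal(nrow(sim$reads[["0h"]]), 0L)
  fq <- tempfile(fileext = ".fastq")
  sirnapipe:::write_fastq(sim$reads[["0h"]], fq)
  expect_true(file.exists(fq))
  expect_equal(file.size(fq), 0)
})

test_that("planted transcriptome, GO map and Ct table encode the truth", {
  cfg <- tiny_config(seed = 13, ct_noise_sd = 0)
  g <- make_genome(cfg)
  truth <- plant_sirna_loci(g, cfg)
  tg <- make_transcriptome_and_go(truth, cfg)

  # perfect-complement planted sites score 0 under both schemes
  for (i in sample(nrow(truth), 4L)) {
    site <- substr(tg$transcripts[[truth$target_id[i]]],
                   tg$sites$start[i] + 1L, tg$sites$end[i])
    expect_identical(site, revcomp(truth$guide_seq[i]))
    expect_equal(score_site_scheme_a(truth$guide_seq[i], site), 0)
    expect_equal(score_site_scheme_b(truth$guide_seq[i], site), 0)
  }

  # designated term is enriched for the planted DE-target gene set
  de_targets <- truth$target_id[truth$status_1h != "flat"]
  gm <- tg$go_map
  N <- length(unique(gm$gene_id))
  K <- sum(gm$go_id == "GO:0009408")
  p <- oracle_hyper_tail(length(de_targets), length(de_targets), K, N)
  expect_lt(p, 0.05)

  # noiseless Ct encodes the planted log2 fold changes exactly
  rel <- delta_delta_ct(tg$qpcr)
  for (tp in c("1h", "6h", "12h")) {
    tnum <- as.numeric(sub("h", "", tp))
    sub_rel <- rel[rel$timepoint == tnum, ]
    planted <- log2(truth[[paste0("fold_", tp)]][
      match(sub_rel$sirna_id, truth$locus_id)])
    expect_equal(sub_rel$log2fc, planted, tolerance = 1e-9)
  }
})
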