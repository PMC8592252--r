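#' Simulation configuration for a planted siRNA experiment
#'
#' Builds the configuration object for the synthetic-data generator. The
#' generator emulates a four-library (0/1/6/12 h heat stress) small RNA-seq
#' experiment on a toy genome: annotated structural-RNA loci, planted siRNA
#' duplex loci (20-24 nt guides, plus/minus read pairs with the 2-nt 3'
#' overhang Dicer signature), adapter-ligated reads with quality strings,
#' junk (unalignable) contamination and a low-quality read fraction.
#'
#' Defaults describe the reference planted world: a 100-kb genome carrying
#' 200 siRNA loci (60 upregulated at >= 4-fold, 60 downregulated at <=
#' 0.25-fold, 80 flat) sequenced at 200,000 reads per library.
#'
#' @param genome_length genome size in bp (>= 10,000).
#' @param n_up,n_down,n_flat planted locus counts per differential class.
#' @param fold_up,fold_down expected heat/control fold change for up/down loci.
#' @param n_structural named integer vector of structural locus counts for
#'   classes rRNA, tRNA, snRNA, snoRNA, miRNA.
#' @param library_depth reads per library (length 1 or 4).
#' @param adapter 3' adapter sequence ligated to every insert (default:
#'   Illumina TruSeq small-RNA 3' adapter).
#' @param junk_fraction proportion of reads that are random, unalignable inserts.
#' @param lowq_fraction proportion of reads given sub-threshold (mean Phred
#'   < 20) quality strings.
#' @param read_length sequencer read length; insert + adapter is truncated here.
#' @param sirna_share,structural_share split of the alignable read mass
#'   between planted siRNA loci and structural loci (must sum to 1).
#' @param guide_fraction fraction of a locus's reads from the guide strand.
#' @param tx_length transcript length for planted target transcripts.
#' @param n_background_tx untargeted background transcripts.
#' @param n_qpcr loci on the synthetic qPCR panel.
#' @param ct_noise_sd Gaussian sd (cycles) on simulated Ct values.
#' @param seed RNG seed; a fixed seed gives byte-identical output files.
#' @return a list of class `sirna_sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_up = 60L, n_down = 60L, n_flat = 80L,
                       fold_up = 4, fold_down = 0.25,
                       n_structural = c(rRNA = 8L, tRNA = 20L, snRNA = 6L,
                                        snoRNA = 6L, miRNA = 10L),
                       library_depth = 200000L,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       junk_fraction = 0.05,
                       lowq_fraction = 0.02,
                       read_length = 50L,
                       sirna_share = 0.7,
                       structural_share = 0.3,
                       guide_fraction = 0.75,
                       tx_length = 300L,
                       n_background_tx = 100L,
                       n_qpcr = 18L,
                       ct_noise_sd = 0.15,
                       seed = 1L) {
  stopifnot(genome_length >= 10000L,
            n_up >= 0L, n_down >= 0L, n_flat >= 0L,
            fold_up >= 2, fold_down <= 0.5, fold_down > 0,
            all(library_depth >= 0),
            nchar(adapter) >= 6L,
            junk_fraction >= 0, junk_fraction <= 1,
            lowq_fraction >= 0, lowq_fraction <= 1,
            abs(sirna_share + structural_share - 1) < 1e-9,
            guide_fraction > 0, guide_fraction < 1)
  stopifnot_dna(adapter, allow_n = FALSE)
  ns <- c(rRNA = 0L, tRNA = 0L, snRNA = 0L, snoRNA = 0L, miRNA = 0L)
  ns[names(n_structural)] <- as.integer(n_structural)
  depth <- as.integer(rep_len(library_depth, 4L))
  cfg <- list(genome_length = as.integer(genome_length),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              n_flat = as.integer(n_flat),
              fold_up = fold_up, fold_down = fold_down,
              n_structural = ns,
              library_depth = depth,
              adapter = adapter,
              junk_fraction = junk_fraction,
              lowq_fraction = lowq_fraction,
              read_length = as.integer(read_length),
              sirna_share = sirna_share,
              structural_share = structural_share,
              guide_fraction = guide_fraction,
              tx_length = as.integer(tx_length),
              n_background_tx = as.integer(n_background_tx),
              n_qpcr = as.integer(n_qpcr),
              ct_noise_sd = ct_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sirna_sim_config"
  cfg
}

# Reference lengths (bp) of simulated structural loci, per class.
STRUCTURAL_LENGTHS <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L,
                        snoRNA = 90L, miRNA = 90L)

# Rejection-sample `n` non-overlapping intervals of length `len` that also
# avoid `occupied` (data.frame with start/end, 0-based half-open), keeping a
# `gap` bp margin. Bounded retries; placement error on failure.
place_intervals <- function(n, len, genome_length, occupied, gap = 5L,
                            max_tries = 20000L) {
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  starts <- integer(0)
  occ_s <- occupied$start
  occ_e <- occupied$end
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("placement error: could not place ", n, " loci of length ", len,
           " without overlap after ", max_tries, " tries", call. = FALSE)
    }
    s <- sample.int(genome_length - len - gap, 1L) + 1L  # keep off the edges
    e <- s + len
    if (any(intervals_overlap(s - gap, e + gap, occ_s, occ_e))) next
    occ_s <- c(occ_s, s)
    occ_e <- c(occ_e, e)
    starts <- c(starts, s)
  }
  data.frame(start = as.integer(starts), end = as.integer(starts + len))
}

#' Generate a random genome with annotated structural-RNA loci
#'
#' @param config a [sim_config()] object.
#' @return list with `genome` (named character vector, one chromosome) and
#'   `annotation` (data.frame: chrom, start, end (0-based half-open), strand,
#'   class, id) with feature classes rRNA/tRNA/snRNA/snoRNA/miRNA.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sirna_sim_config"))
  set.seed(config$seed)
  genome <- random_dna(config$genome_length)
  names(genome) <- "chr1"
  occupied <- data.frame(start = integer(0), end = integer(0))
  ann <- list()
  for (cls in names(config$n_structural)) {
    n <- config$n_structural[[cls]]
    if (n == 0L) next
    len <- STRUCTURAL_LENGTHS[[cls]]
    placed <- place_intervals(n, len, config$genome_length, occupied)
    occupied <- rbind(occupied, placed)
    ann[[cls]] <- data.frame(chrom = "chr1", start = placed$start,
                             end = placed$end, strand = "+", class = cls,
                             id = sprintf("%s_%03d", cls, seq_len(n)))
  }
  ann <- if (length(ann)) do.call(rbind, ann) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), class = character(0), id = character(0))
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  list(genome = genome, annotation = ann)
}

# Temporal fold-change profiles per class; every value respects the class
# constraint (up >= 2x at every timepoint, down <= 0.5x, flat in [0.9, 1.1]).
sample_fold_profiles <- function(status, fold_up, fold_down) {
  up_shapes <- list(c(1, 1.25, 1.5), c(1.5, 1.25, 1), c(1, 1, 1))
  down_shapes <- list(c(1, 1, 1), c(1, 1.5, 2), c(2, 1.5, 1))
  t(vapply(status, function(st) {
    switch(st,
      up = fold_up * up_shapes[[sample.int(3L, 1L)]],
      down = fold_down / down_shapes[[sample.int(3L, 1L)]],
      flat = stats::runif(3L, 0.9, 1.1))
  }, numeric(3L)))
}

#' Plant siRNA duplex loci on a simulated genome
#'
#' Each locus is a plus-strand guide-length interval paired with a
#' minus-strand interval shifted left by exactly 2 bp, so that the two reads
#' form a duplex with 2-nt 3' overhangs on both ends -- every planted locus
#' satisfies the duplex-calling geometry by construction. Guide lengths are
#' drawn from 20-24 nt with 21 nt the modal class, 24 nt next.
#'
#' @param genome_obj output of [make_genome()].
#' @param config a [sim_config()] object.
#' @return truth table data.frame, one row per locus: coordinates of both
#'   strands, guide sequence/strand/length, baseline abundance weight,
#'   per-timepoint fold changes and status labels, and a planted target
#'   transcript id.
#' @export
plant_sirna_loci <- function(genome_obj, config) {
  set.seed(config$seed + 1L)
  n <- config$n_up + config$n_down + config$n_flat
  lens <- sample(20:24, n, replace = TRUE,
                 prob = c(0.10, 0.35, 0.17, 0.13, 0.25))
  occupied <- genome_obj$annotation[, c("start", "end")]
  starts <- integer(n)
  for (i in seq_len(n)) {
    # extend footprint 2 bp left for the minus-strand partner
    placed <- place_intervals(1L, lens[i] + 2L, config$genome_length,
                              occupied, gap = 10L)
    starts[i] <- placed$start + 2L
    occupied <- rbind(occupied, placed)
  }
  status <- sample(rep(c("up", "down", "flat"),
                       c(config$n_up, config$n_down, config$n_flat)))
  folds <- sample_fold_profiles(status, config$fold_up, config$fold_down)
  guide_strand <- sample(c("+", "-"), n, replace = TRUE)
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

  genome <- genome_obj$genome[[1L]]
  plus_seq <- substring(genome, starts + 1L, starts + lens)
  minus_seq <- revcomp(substring(genome, starts - 1L, starts + lens - 2L))
  guide_seq <- ifelse(guide_strand == "+", plus_seq, minus_seq)

  truth <- data.frame(
    locus_id = sprintf("locus_%04d", seq_len(n)),
    chrom = "chr1",
    plus_start = as.integer(starts), plus_end = as.integer(starts + lens),
    minus_start = as.integer(starts - 2L), minus_end = as.integer(starts + lens - 2L),
    guide_length = as.integer(lens),
    guide_strand = guide_strand,
    plus_seq = plus_seq, minus_seq = minus_seq, guide_seq = guide_seq,
    baseline = baseline,
    status_1h = ifelse(status == "flat", "flat", status),
    status_6h = ifelse(status == "flat", "flat", status),
    status_12h = ifelse(status == "flat", "flat", status),
    fold_1h = folds[, 1L], fold_6h = folds[, 2L], fold_12h = folds[, 3L],
    target_id = sprintf("tx_locus_%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$plus_start), , drop = FALSE]
  rownames(truth) <- NULL
  truth
}

# Expected per-library read counts for every planted locus strand and every
# structural tag, under the configured mass split. Returns a list with the
# expectation matrices; the total alignable mass per library is the TPM
# denominator used for planted TPMs.
expected_counts <- function(truth, struct_tags, config) {
  depth <- config$library_depth
  alignable <- (1 - config$junk_fraction) * depth
  folds <- cbind(1, truth$fold_1h, truth$fold_6h, truth$fold_12h)
  w <- truth$baseline / sum(truth$baseline)
  e_locus <- outer(w, alignable * config$sirna_share) * folds
  e_guide <- e_locus * config$guide_fraction
  e_pass <- e_locus * (1 - config$guide_fraction)
  e_plus <- ifelse(truth$guide_strand == "+", 1, 0) * e_guide +
    ifelse(truth$guide_strand == "+", 0, 1) * e_pass
  e_minus <- e_locus - e_plus
  if (nrow(struct_tags)) {
    v <- struct_tags$weight / sum(struct_tags$weight)
    e_struct <- outer(v, alignable * config$structural_share)
  } else {
    e_struct <- matrix(0, 0L, 4L)
  }
  list(e_locus = e_locus, e_plus = e_plus, e_minus = e_minus,
       e_struct = e_struct,
       total = colSums(e_locus) + colSums(e_struct))
}

# One representative expressed tag per structural locus (21-mer at offset 3).
structural_tags <- function(genome_obj) {
  ann <- genome_obj$annotation
  if (!nrow(ann)) {
    return(data.frame(seq = character(0), weight = numeric(0)))
  }
  genome <- genome_obj$genome[[1L]]
  seqs <- substring(genome, ann$start + 4L, ann$start + 24L)
  data.frame(seq = seqs, class = ann$class, weight = stats::rlnorm(nrow(ann), 0, 0.5),
             stringsAsFactors = FALSE)
}

#' Simulate adapter-ligated FASTQ reads for the four libraries
#'
#' Per-locus read counts are Poisson around the planted expectations; each
#' read is its insert followed by the 3' adapter, truncated to the read
#' length, with Phred+33 quality strings. A configured fraction of reads is
#' junk (random unalignable inserts) and a fraction carries sub-threshold
#' quality (mean Phred < 20).
#'
#' @param truth output of [plant_sirna_loci()].
#' @param genome_obj output of [make_genome()].
#' @param config a [sim_config()] object.
#' @return list: `reads` (per-library data.frames with id/seq/qual), `truth`
#'   (the truth table augmented with expected counts and expected TPMs) and
#'   `library_expected_mapped` (expected alignable reads per library).
#' @export
simulate_reads <- function(truth, genome_obj, config) {
  stopifnot(nrow(truth) >= 1L)
  set.seed(config$seed + 2L)
  stags <- structural_tags(genome_obj)
  ec <- expected_counts(truth, stags, config)

  tpm <- sweep(ec$e_locus, 2L, ec$total, "/") * 1e6
  colnames(tpm) <- paste0("tpm_", LIB_LABELS)
  ecount <- ec$e_locus
  colnames(ecount) <- paste0("expected_", count_cols())
  truth_aug <- cbind(truth, as.data.frame(ecount), as.data.frame(tpm))

  tag_seqs <- c(truth$plus_seq, truth$minus_seq, stags$seq)
  reads <- vector("list", 4L)
  names(reads) <- LIB_LABELS
  for (lib in seq_len(4L)) {
    e <- c(ec$e_plus[, lib], ec$e_minus[, lib], ec$e_struct[, lib])
    counts <- stats::rpois(length(e), e)
    n_junk <- stats::rpois(1L, config$junk_fraction * config$library_depth[lib])
    junk <- random_dna(sample(18:28, n_junk, replace = TRUE))
    inserts <- c(rep(tag_seqs, counts), junk)
    n <- length(inserts)
    if (n == 0L) {
      reads[[lib]] <- data.frame(id = character(0), seq = character(0),
                                 qual = character(0))
      next
    }
    inserts <- inserts[sample.int(n)]
    seqs <- substr(paste0(inserts, config$adapter), 1L, config$read_length)
    qual <- strrep("I", nchar(seqs))
    n_lowq <- round(config$lowq_fraction * n)
    if (n_lowq > 0L) {
      ix <- sample.int(n, n_lowq)
      qual[ix] <- strrep("#", nchar(seqs[ix]))
    }
    reads[[lib]] <- data.frame(
      id = sprintf("read_%s_%07d", LIB_LABELS[lib], seq_len(n)),
      seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
  list(reads = reads, truth = truth_aug,
       library_expected_mapped = unname(ec$total))
}

#' Build the planted transcriptome, GO map and qPCR Ct table
#'
#' Every planted locus gets one target transcript carrying a perfect
#' reverse-complement binding site for its guide (penalty 0 under both
#' scoring schemes, hence a consensus site). A designated GO term
#' (GO:0009408, "response to heat") annotates all targets of non-flat loci
#' plus 5 percent of the remaining genes, so the planted target set is
#' enriched for it by construction. The Ct table encodes 2^-ddCt values
#' consistent with the planted fold changes plus Gaussian noise.
#'
#' @param truth truth table from [plant_sirna_loci()] (or the augmented one).
#' @param config a [sim_config()] object.
#' @return list: `transcripts` (named character), `sites` (data.frame of
#'   planted site intervals, 0-based half-open), `go_map` (gene_id, go_id,
#'   namespace), `qpcr` (sirna_id, timepoint, replicate, ct_target,
#'   ct_reference).
#' @export
make_transcriptome_and_go <- function(truth, config) {
  set.seed(config$seed + 3L)
  n <- nrow(truth)
  site_seq <- revcomp(truth$guide_seq)
  pos <- vapply(nchar(site_seq), function(L) {
    sample.int(config$tx_length - L - 20L, 1L) + 10L  # 1-based site start
  }, integer(1L))
  left <- random_dna(pos - 1L)
  right_len <- config$tx_length - (pos - 1L) - nchar(site_seq)
  right <- random_dna(right_len)
  tx <- paste0(left, site_seq, right)
  bg <- random_dna(rep(config$tx_length, config$n_background_tx))
  transcripts <- c(tx, bg)
  names(transcripts) <- c(truth$target_id,
                          sprintf("tx_bg_%04d", seq_len(config$n_background_tx)))
  sites <- data.frame(sirna_id = truth$locus_id, transcript_id = truth$target_id,
                      start = pos - 1L, end = pos - 1L + nchar(site_seq))

  genes <- names(transcripts)
  de_targets <- truth$target_id[truth$status_1h != "flat"]
  other <- setdiff(genes, de_targets)
  extra <- sample(other, max(1L, round(0.05 * length(other))))
  go <- data.frame(gene_id = c(de_targets, extra),
                   go_id = "GO:0009408", namespace = "biological_process",
                   stringsAsFactors = FALSE)
  namespaces <- c("biological_process", "molecular_function", "cellular_component")
  for (i in seq_len(15L)) {
    members <- sample(genes, max(2L, round(0.10 * length(genes))))
    go <- rbind(go, data.frame(gene_id = members,
                               go_id = sprintf("GO:%07d", 1000000L + i),
                               namespace = namespaces[(i %% 3L) + 1L]))
  }
  go <- go[order(go$go_id, go$gene_id), , drop = FALSE]
  rownames(go) <- NULL

  # qPCR panel: stratified over up/down/flat loci
  per <- config$n_qpcr %/% 3L
  pick <- function(st, k) {
    ids <- truth$locus_id[truth$status_1h == st]
    sample(ids, min(k, length(ids)))
  }
  panel <- c(pick("up", per), pick("down", per),
             pick("flat", config$n_qpcr - 2L * per))
  ti <- match(panel, truth$locus_id)
  folds <- cbind(1, truth$fold_1h[ti], truth$fold_6h[ti], truth$fold_12h[ti])
  ct0 <- 25 - log2(truth$baseline[ti])
  rows <- list()
  tp_num <- c(0L, 1L, 6L, 12L)
  for (j in seq_along(panel)) {
    for (t in seq_len(4L)) {
      ct_t <- ct0[j] - log2(folds[j, t]) +
        stats::rnorm(3L, 0, config$ct_noise_sd)
      ct_r <- 15 + stats::rnorm(3L, 0, config$ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sirna_id = panel[j], timepoint = tp_num[t], replicate = 1:3,
        ct_target = ct_t, ct_reference = ct_r)
    }
  }
  qpcr <- do.call(rbind, rows)
  rownames(qpcr) <- NULL
  list(transcripts = transcripts, sites = sites, go_map = go, qpcr = qpcr)
}

write_fastq <- function(df, path) {
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(df$seq), Biostrings::PhredQuality(df$qual))
  names(x) <- df$id
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

write_annotation_gff3 <- function(ann, path) {
  if (nrow(ann) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- ann$class
  S4Vectors::mcols(gr)$ID <- ann$id
  S4Vectors::mcols(gr)$source <- "sirnapipe_sim"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate a complete planted experiment and write all input files
#'
#' Runs [make_genome()], [plant_sirna_loci()], [simulate_reads()] and
#' [make_transcriptome_and_go()] and writes: `genome.fa`, `annotation.gff3`,
#' `reads_0h.fastq` .. `reads_12h.fastq`, `transcripts.fa`, `go_map.tsv`,
#' `qpcr_ct.csv` and the truth table `truth.tsv`. With a fixed seed the
#' outputs are byte-identical across runs.
#'
#' @param config a [sim_config()] object.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with all in-memory objects plus `paths`.
#' @export
simulate_experiment <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- make_genome(config)
  truth <- plant_sirna_loci(g, config)
  sim <- simulate_reads(truth, g, config)
  tg <- make_transcriptome_and_go(sim$truth, config)

  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    reads = file.path(outdir, paste0("reads_", LIB_LABELS, ".fastq")),
    transcripts = file.path(outdir, "transcripts.fa"),
    go_map = file.path(outdir, "go_map.tsv"),
    qpcr = file.path(outdir, "qpcr_ct.csv"),
    truth = file.path(outdir, "truth.tsv"))
  write_genome_fasta(g$genome, paths$genome)
  write_annotation_gff3(g$annotation, paths$annotation)
  for (i in seq_len(4L)) write_fastq(sim$reads[[i]], paths$reads[i])
  write_genome_fasta(tg$transcripts, paths$transcripts)
  data.table::fwrite(tg$go_map, paths$go_map, sep = "\t")
  data.table::fwrite(tg$qpcr, paths$qpcr)
  data.table::fwrite(sim$truth, paths$truth, sep = "\t")
  invisible(list(genome = g, truth = sim$truth, reads = sim$reads,
                 transcripts = tg$transcripts, sites = tg$sites,
                 go_map = tg$go_map, qpcr = tg$qpcr, paths = paths))
}
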