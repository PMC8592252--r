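#' Run the complete siRNA discovery and heat-stress DE pipeline
#'
#' End-to-end driver: preprocess FASTQ libraries, map tags by exact match,
#' subtract structural-RNA tags, call siRNA duplexes, run TPM-based DE
#' against the 0 h control, compute the three-timepoint intersection
#' report, cluster the common DE set with fuzzy c-means, scan transcripts
#' for consensus target sites of the common DE guides, run GO enrichment on
#' the consensus target genes and (when a Ct table is available)
#' cross-validate against qPCR. All outputs are written as plain-text
#' tables into `out_dir`; a fixed configuration yields byte-identical
#' outputs across runs.
#'
#' @param input_dir directory containing `genome.fa`, `annotation.gff3`,
#'   `reads_0h.fastq` .. `reads_12h.fastq` and optionally `transcripts.fa`,
#'   `go_map.tsv`, `qpcr_ct.csv`, `truth.tsv` (layout of
#'   [simulate_experiment()]). Individual paths can be overridden via
#'   `paths`.
#' @param out_dir output directory (created if missing).
#' @param adapter 3' adapter used in preprocessing.
#' @param params named list overriding defaults: min_overlap, min_len,
#'   max_len, min_mean_phred, max_hits, min_reads, abundance_mode, len_min,
#'   len_max, relaxed, floor, alpha, lfc, pseudocount, test, clusters,
#'   fuzzifier, cluster_seed, restarts, cutoff_a, cutoff_b, allow_bulge,
#'   go_method.
#' @param paths optional named list of explicit input paths (genome,
#'   annotation, reads, transcripts, go_map, qpcr, truth).
#' @return invisibly, a list with every stage's in-memory result and the
#'   output file paths.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         params = list(), paths = NULL) {
  p <- utils::modifyList(list(
    min_overlap = 6L, min_len = 18L, max_len = 30L, min_mean_phred = 20,
    max_hits = 20L, min_reads = 5L, abundance_mode = "all",
    len_min = 20L, len_max = 24L, relaxed = FALSE,
    floor = 30, alpha = 0.05, lfc = 1, pseudocount = 0.01, test = "binomial",
    clusters = 4L, fuzzifier = 2, cluster_seed = 1L, restarts = 3L,
    cutoff_a = 4, cutoff_b = 2.5, allow_bulge = TRUE,
    go_method = "BH"), params)
  dflt <- list(genome = file.path(input_dir, "genome.fa"),
               annotation = file.path(input_dir, "annotation.gff3"),
               reads = file.path(input_dir, paste0("reads_", LIB_LABELS, ".fastq")),
               transcripts = file.path(input_dir, "transcripts.fa"),
               go_map = file.path(input_dir, "go_map.tsv"),
               qpcr = file.path(input_dir, "qpcr_ct.csv"),
               truth = file.path(input_dir, "truth.tsv"))
  pth <- utils::modifyList(dflt, paths %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
  }

  ## preprocess
  pre <- preprocess_fastq(pth$reads, adapter, p$min_overlap, p$min_len,
                          p$max_len, p$min_mean_phred)
  wt(pre$tags, "tags.tsv")
  wt(pre$stats, "cleanup_stats.tsv")

  ## map + structural subtraction
  index <- build_index(pth$genome)
  mapped <- map_tags(pre$tags$sequence, index, max_hits = p$max_hits)
  ann <- read_structural_annotation(pth$annotation)
  sub <- subtract_annotated(mapped$hits, ann, chrom_names = names(index$seqs))
  hit_counts <- pre$tags$total[match(mapped$hits$tag, pre$tags$sequence)]
  bed <- data.frame(chrom = mapped$hits$chrom, start = mapped$hits$start,
                    end = mapped$hits$end, name = mapped$hits$tag,
                    score = hit_counts, strand = mapped$hits$strand)
  wt(bed, "hits.bed")
  wt(data.frame(class = names(sub$tally), removed_tags = as.integer(sub$tally)),
     "subtraction_tally.tsv")

  ## library sizes: cleaned mapped reads per library (before subtraction)
  mapped_tags <- unique(mapped$hits$tag)
  mi <- match(mapped_tags, pre$tags$sequence)
  library_sizes <- colSums(pre$tags[mi, count_cols(), drop = FALSE])

  ## siRNA calling
  catalogue <- call_sirnas(sub$kept, pre$tags, min_reads = p$min_reads,
                           mode = p$abundance_mode, len_min = p$len_min,
                           len_max = p$len_max, relaxed = p$relaxed)
  wt(catalogue, "sirna_catalogue.tsv")
  stats_lfb <- length_first_base_stats(catalogue)
  wt(data.frame(length = rownames(stats_lfb), stats_lfb, check.names = FALSE),
     "length_first_base.tsv")

  ## differential expression
  de <- de_analysis(catalogue, library_sizes, floor = p$floor,
                    alpha = p$alpha, lfc = p$lfc,
                    pseudocount = p$pseudocount, method = p$test)
  wt(de, "de_table.tsv")
  isect <- intersection_report(de)
  wt(isect, "intersections.tsv")

  ## fuzzy c-means on the common DE set
  common <- common_de_ids(de, "all")
  clus <- NULL
  if (length(common) >= p$clusters) {
    prof <- as.matrix(de[match(common, de$sirna_id),
                         paste0("log2_ratio_", COMPARISONS)])
    rownames(prof) <- common
    z <- standardize_profiles(prof)
    clus <- fuzzy_cmeans(z, c = p$clusters, m = p$fuzzifier,
                         seed = p$cluster_seed, restarts = p$restarts)
    memb <- data.frame(sirna_id = rownames(z),
                       round(clus$membership, 10L))
    names(memb)[-1L] <- paste0("cluster_", seq_len(p$clusters))
    memb$label <- clus$labels
    wt(memb, "cluster_membership.tsv")
    wt(cluster_summary(clus), "cluster_summary.tsv")
  } else {
    wt(data.frame(sirna_id = character(0)), "cluster_membership.tsv")
    wt(data.frame(cluster = integer(0)), "cluster_summary.tsv")
  }

  ## target prediction for the common DE guides
  targets <- NULL
  go <- NULL
  if (file.exists(pth$transcripts) && length(common)) {
    guides <- catalogue[match(common, catalogue$sirna_id),
                        c("sirna_id", "guide_seq")]
    targets <- scan_transcripts(guides, pth$transcripts,
                                cutoff_a = p$cutoff_a, cutoff_b = p$cutoff_b,
                                allow_bulge = p$allow_bulge)
    wt(targets, "target_hits.tsv")
    if (file.exists(pth$go_map)) {
      go_map <- as.data.frame(data.table::fread(pth$go_map))
      consensus_genes <- unique(targets$transcript_id[targets$consensus])
      consensus_genes <- intersect(consensus_genes, go_map$gene_id)
      go <- enrich(consensus_genes, go_map, method = p$go_method)
      wt(go, "go_enrichment.tsv")
    }
  }

  ## qPCR cross-validation (panel ids mapped through the truth table when
  ## the input is the synthetic world)
  qv <- NULL
  if (file.exists(pth$qpcr)) {
    ct <- as.data.frame(data.table::fread(pth$qpcr))
    id_map <- NULL
    if (file.exists(pth$truth)) {
      truth <- as.data.frame(data.table::fread(pth$truth))
      mt <- match_truth_ids(catalogue, truth)
      id_map <- data.frame(panel_id = mt$locus_id, sirna_id = mt$sirna_id)
    }
    qv <- tryCatch(qpcr_validate(ct, de, id_map = id_map),
                   error = function(e) {
                     warning("qPCR validation skipped: ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(qv)) {
      wt(qv$rel_expr, "qpcr_relative_expression.tsv")
      wt(qv$pairs, "qpcr_pairs.tsv")
      jsonlite::write_json(qv$agreement,
                           file.path(out_dir, "qpcr_agreement.json"),
                           auto_unbox = TRUE, digits = 10)
    }
  }

  invisible(list(preprocess = pre, mapped = mapped, subtracted = sub,
                 library_sizes = library_sizes, catalogue = catalogue,
                 length_first_base = stats_lfb, de = de,
                 intersections = isect, clustering = clus,
                 targets = targets, go = go, qpcr = qv, out_dir = out_dir))
}
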