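#' Build an exact-match genome index
#'
#' @param genome a genome FASTA path, a named character vector, or a
#'   [Biostrings::DNAStringSet].
#' @return an object of class `sirna_genome_index` supporting exact
#'   full-length lookup of tags on both strands.
#' @export
build_index <- function(genome) {
  seqs <- if (inherits(genome, "DNAStringSet")) {
    genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    Biostrings::readDNAStringSet(genome)
  } else {
    Biostrings::DNAStringSet(genome)
  }
  if (length(seqs) == 0L) stop("genome is empty", call. = FALSE)
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("genome chromosomes must be named", call. = FALSE)
  }
  names(seqs) <- sub("\\s.*$", "", nm)  # FASTA ids up to first whitespace
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome names in genome", call. = FALSE)
  }
  structure(list(seqs = seqs), class = "sirna_genome_index")
}

# Exact full-length hits of `sequences` on both strands of every chromosome.
# Minus-strand semantics: a tag hits (chrom, s, e, -) when its reverse
# complement equals genome[s, e) on the plus strand.
match_tags_one_strand <- function(sequences, index, strand_label) {
  widths <- nchar(sequences)
  out <- list()
  for (w in sort(unique(widths))) {
    ix <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[ix]))
    for (ch in names(index$seqs)) {
      m <- Biostrings::matchPDict(pd, index$seqs[[ch]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      ir <- unlist(m)
      out[[length(out) + 1L]] <- data.frame(
        tag = rep(sequences[ix], cnt),
        chrom = ch,
        start = IRanges::start(ir) - 1L,
        end = IRanges::end(ir),
        strand = strand_label,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0))
}

#' Map tags to the genome by exact full-length match
#'
#' Finds all and only the exact full-length occurrences of each tag on both
#' strands. Tags with zero hits are flagged unmapped; tags with more hits
#' than `max_hits` (pathological repeats) are dropped and logged.
#'
#' @param sequences character vector of tag sequences (no N).
#' @param index a [build_index()] object.
#' @param max_hits multi-mapping cap; tags exceeding it are dropped.
#' @return list: `hits` (data.frame tag/chrom/start/end/strand, 0-based
#'   half-open, sorted by chrom, start, strand, tag), `unmapped` and
#'   `capped` (character vectors of tag sequences).
#' @export
map_tags <- function(sequences, index, max_hits = 20L) {
  stopifnot(inherits(index, "sirna_genome_index"))
  sequences <- unique(sequences)
  has_n <- grepl("N", sequences, fixed = TRUE)
  clean <- sequences[!has_n]
  hits <- rbind(match_tags_one_strand(clean, index, "+"),
                match_tags_one_strand(revcomp(clean), index, "-"))
  if (nrow(hits)) {
    # minus-strand rows carry the reverse complement; restore the tag
    mi <- hits$strand == "-"
    hits$tag[mi] <- revcomp(hits$tag[mi])
    nh <- table(hits$tag)
    capped <- names(nh)[nh > max_hits]
    hits <- hits[!(hits$tag %in% capped), , drop = FALSE]
    hits <- hits[order(hits$chrom, hits$start, hits$strand, hits$tag), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  } else {
    capped <- character(0)
  }
  mapped <- unique(hits$tag)
  unmapped <- setdiff(sequences, c(mapped, capped))
  list(hits = hits, unmapped = unmapped, capped = capped)
}

#' Exact-match lookup of a single tag
#'
#' @param tag_sequence one tag sequence.
#' @param index a [build_index()] object.
#' @return data.frame of hits (possibly empty), as in [map_tags()].
#' @export
map_exact <- function(tag_sequence, index) {
  stopifnot(length(tag_sequence) == 1L)
  map_tags(tag_sequence, index, max_hits = .Machine$integer.max)$hits
}

STRUCTURAL_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA")

#' Read a structural-RNA annotation from GFF3
#'
#' Keeps features whose type matches (case-insensitively) one of rRNA, tRNA,
#' snRNA, snoRNA, miRNA and converts GFF3 1-based inclusive coordinates to
#' the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return data.frame: chrom, start, end, strand, class, id.
#' @export
read_structural_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  cls <- STRUCTURAL_CLASSES[match(tolower(type), tolower(STRUCTURAL_CLASSES))]
  keep <- !is.na(cls)
  gr <- gr[keep]
  id <- S4Vectors::mcols(gr)$ID
  if (is.null(id)) id <- sprintf("feature_%04d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             class = cls[keep], id = as.character(id),
             stringsAsFactors = FALSE)
}

#' Subtract tags attributable to annotated structural RNAs
#'
#' A tag is removed entirely (all of its hits) if any of its hits overlaps
#' any annotated structural interval by at least 1 bp, irrespective of
#' strand. The removed-class tally uses the precedence rRNA > tRNA > snRNA >
#' snoRNA > miRNA when a tag overlaps multiple classes.
#'
#' @param hits data.frame of genome hits (see [map_tags()]).
#' @param annotation data.frame from [read_structural_annotation()].
#' @param chrom_names optional genome chromosome names; annotation rows on
#'   other chromosomes are ignored with a warning.
#' @return list: `kept` (hits of surviving tags), `removed` (data.frame tag,
#'   class) and `tally` (named integer, removed tag counts per class).
#' @export
subtract_annotated <- function(hits, annotation, chrom_names = NULL) {
  tally <- stats::setNames(integer(length(STRUCTURAL_CLASSES)),
                           STRUCTURAL_CLASSES)
  empty_removed <- data.frame(tag = character(0), class = character(0))
  if (!is.null(chrom_names)) {
    bad <- !(annotation$chrom %in% chrom_names)
    if (any(bad)) {
      warning("ignoring ", sum(bad),
              " annotation interval(s) on chromosomes absent from the genome")
      annotation <- annotation[!bad, , drop = FALSE]
    }
  }
  if (nrow(hits) == 0L || nrow(annotation) == 0L) {
    return(list(kept = hits, removed = empty_removed, tally = tally))
  }
  gh <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  ga <- GenomicRanges::GRanges(annotation$chrom,
                               IRanges::IRanges(annotation$start + 1L,
                                                annotation$end))
  ov <- GenomicRanges::findOverlaps(gh, ga)
  if (length(ov) == 0L) {
    return(list(kept = hits, removed = empty_removed, tally = tally))
  }
  tag_hit <- hits$tag[S4Vectors::queryHits(ov)]
  cls_hit <- annotation$class[S4Vectors::subjectHits(ov)]
  prec <- match(cls_hit, STRUCTURAL_CLASSES)
  best <- tapply(prec, tag_hit, min)
  removed <- data.frame(tag = names(best),
                        class = STRUCTURAL_CLASSES[as.integer(best)],
                        stringsAsFactors = FALSE)
  removed <- removed[order(removed$tag), , drop = FALSE]
  rownames(removed) <- NULL
  tb <- table(factor(removed$class, levels = STRUCTURAL_CLASSES))
  tally[] <- as.integer(tb)
  kept <- hits[!(hits$tag %in% removed$tag), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed, tally = tally)
}
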