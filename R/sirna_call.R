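#' Find siRNA duplexes from mapped hits
#'
#' Pairs plus-strand with minus-strand hits on the same chromosome that show
#' the canonical Dicer signature: each strand's 3' end extends exactly 2 nt
#' past the partner's 5' end, i.e. the minus interval equals the plus
#' interval shifted left by 2 (which forces equal strand lengths). A relaxed
#' geometry (each overhang independently 1-3 nt, unequal lengths possible)
#' is available but off by default.
#'
#' @param hits data.frame of genome hits (tag/chrom/start/end/strand,
#'   0-based half-open), typically the `kept` hits after structural
#'   subtraction.
#' @param relaxed if TRUE, accept overhangs of 1-3 nt on either end
#'   independently.
#' @return data.frame, one row per duplex: chrom, plus_tag, plus_start,
#'   plus_end, minus_tag, minus_start, minus_end; deduplicated and ordered
#'   by (chrom, plus_start, plus_end, minus_start).
#' @export
find_duplexes <- function(hits, relaxed = FALSE) {
  empty <- data.frame(chrom = character(0), plus_tag = character(0),
                      plus_start = integer(0), plus_end = integer(0),
                      minus_tag = character(0), minus_start = integer(0),
                      minus_end = integer(0))
  if (nrow(hits) == 0L) return(empty)
  plus <- hits[hits$strand == "+", , drop = FALSE]
  minus <- hits[hits$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  key_m <- paste(minus$chrom, minus$start, minus$end)
  offsets <- if (relaxed) expand.grid(d1 = 1:3, d2 = 1:3) else
    data.frame(d1 = 2L, d2 = 2L)
  out <- list()
  for (r in seq_len(nrow(offsets))) {
    key_p <- paste(plus$chrom, plus$start - offsets$d1[r],
                   plus$end - offsets$d2[r])
    mi <- match(key_p, key_m)
    sel <- !is.na(mi)
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = plus$chrom[sel],
      plus_tag = plus$tag[sel],
      plus_start = plus$start[sel], plus_end = plus$end[sel],
      minus_tag = minus$tag[mi[sel]],
      minus_start = minus$start[mi[sel]], minus_end = minus$end[mi[sel]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  dup <- do.call(rbind, out)
  dup <- dup[!duplicated(dup[, c("chrom", "plus_start", "plus_end",
                                 "minus_start", "minus_end")]), , drop = FALSE]
  dup <- dup[order(dup$chrom, dup$plus_start, dup$plus_end, dup$minus_start), ,
             drop = FALSE]
  rownames(dup) <- NULL
  dup
}

#' Per-library abundance criterion for siRNA duplexes
#'
#' Keep a duplex iff its raw count is strictly greater than `min_reads`
#' ("more than five reads") in every library (mode `all`, default) or in at
#' least one library (mode `any`).
#'
#' @param counts numeric matrix or data.frame, one row per duplex, one
#'   column per library.
#' @param min_reads strictly-greater threshold (count 6 passes, 5 fails).
#' @param mode `"all"` or `"any"`.
#' @return logical keep vector.
#' @export
abundance_filter <- function(counts, min_reads = 5L, mode = c("all", "any")) {
  mode <- match.arg(mode)
  m <- as.matrix(counts)
  if (nrow(m) == 0L) return(logical(0))
  pass <- m > min_reads
  if (mode == "all") apply(pass, 1L, all) else apply(pass, 1L, any)
}

#' Call siRNA duplexes from mapped, annotation-subtracted hits
#'
#' Applies [find_duplexes()], restricts guides to the 20-24 nt window,
#' attaches per-library counts (guide + passenger strands summed), applies
#' the abundance criterion and assigns reproducible serial identifiers
#' (`novel_sirNNNNN`) after sorting by genomic position.
#'
#' The guide strand is the strand with the larger total count across
#' libraries, ties broken toward the plus strand.
#'
#' @param hits kept hits (see [subtract_annotated()]).
#' @param tags collapsed tag table from [preprocess_fastq()] (or
#'   [collapse_tags()]).
#' @param min_reads,mode abundance criterion; see [abundance_filter()].
#' @param len_min,len_max inclusive guide-length window.
#' @param relaxed duplex geometry option; see [find_duplexes()].
#' @return the siRNA catalogue: data.frame with sirna_id, coordinates of
#'   both strands, guide strand/sequence/length, 5' first base and raw
#'   per-library counts.
#' @export
call_sirnas <- function(hits, tags, min_reads = 5L, mode = "all",
                        len_min = 20L, len_max = 24L, relaxed = FALSE) {
  dup <- find_duplexes(hits, relaxed = relaxed)
  ccols <- grep("^count_", names(tags), value = TRUE)
  if (nrow(dup) == 0L) {
    out <- data.frame(sirna_id = character(0), chrom = character(0),
                      plus_start = integer(0), plus_end = integer(0),
                      minus_start = integer(0), minus_end = integer(0),
                      guide_strand = character(0), guide_seq = character(0),
                      guide_length = integer(0), first_base = character(0))
    for (cc in ccols) out[[cc]] <- integer(0)
    return(out)
  }
  glen_p <- dup$plus_end - dup$plus_start
  glen_m <- dup$minus_end - dup$minus_start
  keep_len <- glen_p >= len_min & glen_p <= len_max &
    glen_m >= len_min & glen_m <= len_max
  dup <- dup[keep_len, , drop = FALSE]
  if (nrow(dup) == 0L) return(call_sirnas(hits[0, ], tags))
  cp <- as.matrix(tags[match(dup$plus_tag, tags$sequence), ccols, drop = FALSE])
  cm <- as.matrix(tags[match(dup$minus_tag, tags$sequence), ccols, drop = FALSE])
  cp[is.na(cp)] <- 0L
  cm[is.na(cm)] <- 0L
  tot <- cp + cm
  guide_plus <- rowSums(cp) >= rowSums(cm)
  guide_seq <- ifelse(guide_plus, dup$plus_tag, dup$minus_tag)
  keep <- abundance_filter(tot, min_reads = min_reads, mode = mode)
  dup <- dup[keep, , drop = FALSE]
  tot <- tot[keep, , drop = FALSE]
  guide_plus <- guide_plus[keep]
  guide_seq <- guide_seq[keep]
  out <- data.frame(
    sirna_id = sprintf("novel_sir%05d", seq_len(nrow(dup))),
    chrom = dup$chrom,
    plus_start = dup$plus_start, plus_end = dup$plus_end,
    minus_start = dup$minus_start, minus_end = dup$minus_end,
    guide_strand = ifelse(guide_plus, "+", "-"),
    guide_seq = guide_seq,
    guide_length = nchar(guide_seq),
    first_base = substr(guide_seq, 1L, 1L),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tot))
  rownames(out) <- NULL
  out
}

#' Length x first-base statistics of called siRNAs
#'
#' @param catalogue siRNA catalogue from [call_sirnas()].
#' @param lengths guide lengths tabulated (rows).
#' @return integer matrix, rows = lengths, columns = A/C/G/T counts of the
#'   guide 5' first base.
#' @export
length_first_base_stats <- function(catalogue, lengths = 20:24) {
  bases <- c("A", "C", "G", "T")
  tab <- table(factor(catalogue$guide_length, levels = lengths),
               factor(catalogue$first_base, levels = bases))
  m <- matrix(as.integer(tab), nrow = length(lengths),
              dimnames = list(length = as.character(lengths), first_base = bases))
  m
}
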