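#' Trim the 3' adapter from reads
#'
#' Returns the insert preceding the leftmost adapter match. A match is either
#' the full adapter anywhere in the read or a 3'-terminal prefix of the
#' adapter of length >= `min_overlap`. Reads with no adapter evidence are
#' rejected as `no_adapter` (an insert shorter than the read length must
#' expose the adapter); reads whose insert is empty are rejected as
#' `empty_insert`.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum 3'-terminal adapter prefix length (>= 6).
#' @param keep_untrimmed if TRUE, reads without adapter evidence are kept
#'   whole instead of rejected (for chemistries where inserts can fill the
#'   read).
#' @return list with `insert` (character, `NA` where rejected) and `status`
#'   (one of `ok`, `no_adapter`, `empty_insert` per read).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L,
                         keep_untrimmed = FALSE) {
  stopifnot(nchar(adapter) >= 1L, min_overlap >= 6L)
  stopifnot_dna(adapter, allow_n = FALSE)
  stopifnot_dna(reads, allow_n = TRUE)
  n <- length(reads)
  insert <- rep(NA_character_, n)
  status <- rep("no_adapter", n)
  # leftmost full-adapter occurrence
  pos <- regexpr(adapter, reads, fixed = TRUE)
  hit <- pos > 0L
  insert[hit] <- substr(reads[hit], 1L, pos[hit] - 1L)
  status[hit] <- "ok"
  # 3'-terminal partial adapter: longest prefix wins (leftmost cut)
  alen <- nchar(adapter)
  todo <- !hit
  if (any(todo) && alen > min_overlap) {
    nch <- nchar(reads)
    for (k in seq.int(min_overlap, alen - 1L)) {
      pref <- substr(adapter, 1L, k)
      m <- todo & nch >= k & endsWith(reads, pref)
      insert[m] <- substr(reads[m], 1L, nch[m] - k)
      status[m] <- "ok"
    }
  }
  if (keep_untrimmed) {
    keep <- status == "no_adapter"
    insert[keep] <- reads[keep]
    status[keep] <- "ok"
  }
  empty <- status == "ok" & !nzchar(insert)
  insert[empty] <- NA_character_
  status[empty] <- "empty_insert"
  list(insert = insert, status = status)
}

#' Whole-read mean-quality filter
#'
#' Keeps a read iff its mean Phred score is at or above the threshold
#' (boundary inclusive).
#'
#' @param quality character vector of Phred+33 quality strings.
#' @param min_mean_phred keep threshold on the per-read mean Phred score.
#' @param sequence optional matching sequences; a length mismatch with
#'   `quality` raises an input-format error.
#' @return logical keep vector with attribute `mean_phred`.
#' @export
quality_filter <- function(quality, min_mean_phred = 20, sequence = NULL) {
  if (!is.null(sequence) && any(nchar(sequence) != nchar(quality))) {
    stop("quality/sequence length mismatch", call. = FALSE)
  }
  if (length(quality) == 0L) return(logical(0))
  q <- Biostrings::PhredQuality(quality)
  means <- BiocGenerics::mean(methods::as(q, "IntegerList"))
  keep <- !is.na(means) & means >= min_mean_phred
  attr(keep, "mean_phred") <- means
  keep
}

#' Insert length filter
#'
#' @param sequence character vector of inserts.
#' @param min_len,max_len inclusive length window (defaults 18-30, the
#'   candidate window; the stricter 20-24 window is applied at siRNA
#'   calling).
#' @return logical keep vector.
#' @export
length_filter <- function(sequence, min_len = 18L, max_len = 30L) {
  stopifnot(min_len <= max_len)
  nch <- nchar(sequence)
  nch >= min_len & nch <= max_len
}

#' Collapse cleaned reads to unique tags with per-library counts
#'
#' @param reads_by_library list of character vectors of cleaned reads, one
#'   per library (names used as count column suffixes; defaults to
#'   `0h/1h/6h/12h`).
#' @return data.frame: `sequence`, one `count_<lib>` column per library and
#'   `total`, sorted by total count descending with ties broken
#'   lexicographically by sequence.
#' @export
collapse_tags <- function(reads_by_library) {
  stopifnot(is.list(reads_by_library))
  labs <- names(reads_by_library) %||% LIB_LABELS[seq_along(reads_by_library)]
  if (is.null(names(reads_by_library)) && length(reads_by_library) > 4L) {
    labs <- paste0("lib", seq_along(reads_by_library))
  }
  u <- sort(unique(unlist(reads_by_library, use.names = FALSE)))
  if (length(u) == 0L) {
    counts <- matrix(integer(0), 0L, length(reads_by_library))
  } else {
    counts <- vapply(reads_by_library, function(v) {
      tabulate(match(v, u), nbins = length(u))
    }, integer(length(u)))
    if (length(u) == 1L) counts <- matrix(counts, nrow = 1L)
  }
  colnames(counts) <- paste0("count_", labs)
  out <- data.frame(sequence = u, counts, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out$total <- as.integer(rowSums(counts))
  out <- out[order(-out$total, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

read_fastq_file <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(list(seq = character(0), qual = character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Clean FASTQ libraries and collapse to unique tags
#'
#' Runs the full cleanup stage per library -- mean-quality filter, 3'
#' adapter trim, removal of N-containing inserts, insert length filter --
#' and collapses the survivors to unique tags with per-library counts.
#'
#' @param fastq_paths character vector of FASTQ paths in library order
#'   (0, 1, 6, 12 h).
#' @param adapter 3' adapter sequence.
#' @param min_overlap,min_len,max_len,min_mean_phred filter parameters; see
#'   [trim_adapter()], [length_filter()], [quality_filter()].
#' @param keep_untrimmed see [trim_adapter()].
#' @return list: `tags` (see [collapse_tags()]) and `stats`, a per-library
#'   cleanup-statistics data.frame (reads surviving each filter).
#' @export
preprocess_fastq <- function(fastq_paths, adapter,
                             min_overlap = 6L, min_len = 18L, max_len = 30L,
                             min_mean_phred = 20, keep_untrimmed = FALSE) {
  labs <- names(fastq_paths) %||% LIB_LABELS[seq_along(fastq_paths)]
  cleaned <- vector("list", length(fastq_paths))
  names(cleaned) <- labs
  stats <- list()
  for (i in seq_along(fastq_paths)) {
    fq <- read_fastq_file(fastq_paths[i])
    n_raw <- length(fq$seq)
    keep_q <- quality_filter(fq$qual, min_mean_phred, sequence = fq$seq)
    seqs <- fq$seq[keep_q]
    tr <- trim_adapter(seqs, adapter, min_overlap, keep_untrimmed)
    ok <- tr$status == "ok"
    ins <- tr$insert[ok]
    no_n <- !grepl("N", ins, fixed = TRUE)
    ins <- ins[no_n]
    keep_l <- length_filter(ins, min_len, max_len)
    cleaned[[i]] <- ins[keep_l]
    stats[[i]] <- data.frame(
      library = labs[i], raw = n_raw,
      after_quality = length(seqs),
      no_adapter = sum(tr$status == "no_adapter"),
      empty_insert = sum(tr$status == "empty_insert"),
      after_adapter = sum(ok),
      n_containing = sum(!no_n),
      surviving = length(cleaned[[i]]))
  }
  list(tags = collapse_tags(cleaned), stats = do.call(rbind, stats))
}
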