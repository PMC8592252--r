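#' Transcripts-per-million normalisation
#'
#' `tpm[i, j] = raw[i, j] / library_size[j] * 1e6`. When the library sizes
#' are the column sums, every TPM column sums to one million.
#'
#' @param raw_counts numeric matrix (rows = siRNAs, columns = libraries).
#' @param library_sizes totals per library (all > 0); by convention the
#'   total cleaned mapped reads per library.
#' @return TPM matrix of the same shape.
#' @export
tpm_normalize <- function(raw_counts, library_sizes) {
  m <- as.matrix(raw_counts)
  stopifnot(length(library_sizes) == ncol(m))
  if (any(library_sizes <= 0)) stop("zero or negative library size", call. = FALSE)
  sweep(m, 2L, library_sizes, "/") * 1e6
}

#' Expression floor on normalised counts
#'
#' Excludes records whose TPM is strictly below `min_tpm` in every library;
#' a record at exactly `min_tpm` anywhere is kept (boundary inclusive-keep).
#'
#' @param tpm TPM matrix.
#' @param min_tpm floor (default 30, on the normalised scale).
#' @return logical keep vector.
#' @export
expression_floor <- function(tpm, min_tpm = 30) {
  m <- as.matrix(tpm)
  if (nrow(m) == 0L) return(logical(0))
  apply(m, 1L, max) >= min_tpm
}

de_test_one <- function(k_t, k_c, size_t, size_c, method) {
  if (method == "fisher") {
    return(stats::fisher.test(matrix(c(k_t, size_t - k_t,
                                       k_c, size_c - k_c), 2L))$p.value)
  }
  k <- k_t + k_c
  if (k == 0L) return(1)
  p0 <- size_t / (size_t + size_c)
  pr <- stats::dbinom(0:k, k, p0)
  p_obs <- pr[k_t + 1L]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Exact test for differential counts between two pooled libraries
#'
#' Default is the exact conditional binomial test for replicate-free pooled
#' libraries: conditional on the total `k = k_t + k_c`, `k_t ~ Binomial(k,
#' size_t / (size_t + size_c))` under the null of equal proportions; the
#' two-sided p-value sums the probabilities of all outcomes at most as
#' probable as the observed one. Both counts zero gives p = 1 by
#' convention. Fisher's exact test on the 2x2 (count, size - count) table is
#' available as an alternative.
#'
#' @param k_t,k_c counts in treatment and control (vectorised).
#' @param size_t,size_c library sizes (> 0).
#' @param method `"binomial"` (default) or `"fisher"`.
#' @return numeric vector of two-sided p-values.
#' @export
de_test <- function(k_t, k_c, size_t, size_c,
                    method = c("binomial", "fisher")) {
  method <- match.arg(method)
  stopifnot(all(k_t >= 0), all(k_c >= 0), all(size_t > 0), all(size_c > 0))
  n <- max(length(k_t), length(k_c))
  k_t <- rep_len(k_t, n); k_c <- rep_len(k_c, n)
  size_t <- rep_len(size_t, n); size_c <- rep_len(size_c, n)
  vapply(seq_len(n), function(i) {
    de_test_one(k_t[i], k_c[i], size_t[i], size_c[i], method)
  }, numeric(1L))
}

#' DE status from effect size and p-value
#'
#' `up` iff log2 ratio >= `lfc` and p < `alpha`; `down` iff log2 ratio <=
#' -`lfc` and p < `alpha`; otherwise `ns`. Thresholds follow the DE-siRNA
#' rule |log2 ratio| >= 1, p < 0.05.
#'
#' @param log2_ratio,p_value numeric vectors.
#' @param alpha strict p-value threshold.
#' @param lfc inclusive log2-ratio threshold.
#' @return character vector in `{up, down, ns}`.
#' @export
call_de <- function(log2_ratio, p_value, alpha = 0.05, lfc = 1) {
  status <- rep("ns", length(log2_ratio))
  sig <- p_value < alpha
  status[sig & log2_ratio >= lfc] <- "up"
  status[sig & log2_ratio <= -lfc] <- "down"
  status
}

#' Full differential-expression analysis of an siRNA catalogue
#'
#' Normalises raw counts to TPM, applies the expression floor, tests each
#' heat timepoint (1, 6, 12 h) against the 0 h control with [de_test()] on
#' the raw pooled counts, computes log2 TPM ratios with a pseudocount, and
#' assigns up/down/ns statuses.
#'
#' @param catalogue siRNA catalogue from [call_sirnas()].
#' @param library_sizes cleaned mapped reads per library (length 4, order
#'   0/1/6/12 h).
#' @param floor TPM expression floor (see [expression_floor()]).
#' @param alpha,lfc DE thresholds (see [call_de()]).
#' @param pseudocount TPM pseudocount in the log2 ratio (default 0.01).
#' @param method test choice (see [de_test()]).
#' @param adjust if TRUE, Benjamini-Hochberg-adjust p-values within each
#'   comparison before calling status (off by default: statuses use raw p).
#' @return data.frame: sirna_id, raw counts, tpm_*, and per comparison
#'   log2_ratio_*, p_* and status_*.
#' @export
de_analysis <- function(catalogue, library_sizes, floor = 30,
                        alpha = 0.05, lfc = 1, pseudocount = 0.01,
                        method = "binomial", adjust = FALSE) {
  ccols <- count_cols()
  raw <- as.matrix(catalogue[, ccols, drop = FALSE])
  tpm <- tpm_normalize(raw, library_sizes)
  keep <- expression_floor(tpm, floor)
  cat2 <- catalogue[keep, , drop = FALSE]
  raw <- raw[keep, , drop = FALSE]
  tpm <- tpm[keep, , drop = FALSE]
  out <- data.frame(sirna_id = cat2$sirna_id, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(raw))
  tpm_df <- as.data.frame(tpm)
  names(tpm_df) <- paste0("tpm_", LIB_LABELS)
  out <- cbind(out, tpm_df)
  for (j in seq_along(COMPARISONS)) {
    lib <- j + 1L
    p <- de_test(raw[, lib], raw[, 1L], library_sizes[lib], library_sizes[1L],
                 method = method)
    if (adjust) p <- stats::p.adjust(p, method = "BH")
    l2r <- log2((tpm[, lib] + pseudocount) / (tpm[, 1L] + pseudocount))
    out[[paste0("log2_ratio_", COMPARISONS[j])]] <- l2r
    out[[paste0("p_", COMPARISONS[j])]] <- p
    out[[paste0("status_", COMPARISONS[j])]] <- call_de(l2r, p, alpha, lfc)
  }
  rownames(out) <- NULL
  out
}

#' Exclusive three-set intersection regions (UpSet structure)
#'
#' Computes the 7 exclusive regions of the three-set Venn over the DE id
#' sets at 1, 6 and 12 h, plus the per-set totals. Region names are binary
#' membership signatures in set order (e.g. `111` = common to all three).
#'
#' @param ids_1h,ids_6h,ids_12h character id vectors.
#' @return list with `regions` (named integer, 7 exclusive regions) and
#'   `totals` (named integer, the 3 set sizes).
#' @export
set_intersections <- function(ids_1h, ids_6h, ids_12h) {
  sets <- list(ids_1h, ids_6h, ids_12h)
  u <- unique(unlist(sets))
  sig <- paste0(as.integer(u %in% sets[[1L]]),
                as.integer(u %in% sets[[2L]]),
                as.integer(u %in% sets[[3L]]))
  levels <- c("100", "010", "001", "110", "101", "011", "111")
  regions <- stats::setNames(as.integer(table(factor(sig, levels = levels))),
                             levels)
  totals <- stats::setNames(vapply(sets, function(s) length(unique(s)),
                                   integer(1L)),
                            paste0("total_", COMPARISONS))
  list(regions = regions, totals = totals)
}

#' Intersection report over all/up/down DE directions
#'
#' @param de_table output of [de_analysis()].
#' @return data.frame, one row per direction (all/up/down) with the 7
#'   exclusive region sizes and 3 set totals as columns.
#' @export
intersection_report <- function(de_table) {
  pick <- function(comp, dir) {
    st <- de_table[[paste0("status_", comp)]]
    if (dir == "all") de_table$sirna_id[st != "ns"] else
      de_table$sirna_id[st == dir]
  }
  rows <- lapply(c("all", "up", "down"), function(dir) {
    si <- set_intersections(pick("1h", dir), pick("6h", dir), pick("12h", dir))
    data.frame(direction = dir, t(si$regions), t(si$totals),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Common DE-siRNA ids (differential at all three timepoints)
#'
#' @param de_table output of [de_analysis()].
#' @param direction `"all"`, `"up"` or `"down"`.
#' @return character vector of sirna ids.
#' @export
common_de_ids <- function(de_table, direction = "all") {
  sel <- function(comp) {
    st <- de_table[[paste0("status_", comp)]]
    if (direction == "all") st != "ns" else st == direction
  }
  de_table$sirna_id[sel("1h") & sel("6h") & sel("12h")]
}
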