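#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Replicate Ct values are averaged on the Ct scale; per timepoint,
#' `dCt = mean(ct_target) - mean(ct_reference)`; `ddCt = dCt(t) - dCt(0h)`;
#' relative expression is `2^-ddCt`, so the control timepoint is exactly 1.
#'
#' @param ct data.frame with columns sirna_id, timepoint (hours; 0 is the
#'   control), replicate, ct_target, ct_reference (internal-control RNA,
#'   e.g. 5S rRNA).
#' @param control_timepoint the reference timepoint (default 0).
#' @return data.frame: sirna_id, timepoint, delta_ct, delta_delta_ct,
#'   rel_expr (2^-ddCt) and log2fc (= -ddCt).
#' @export
delta_delta_ct <- function(ct, control_timepoint = 0) {
  needed <- c("sirna_id", "timepoint", "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(ct)))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    stop("missing reference or target Ct values", call. = FALSE)
  }
  if (any(ct$ct_target <= 0 | ct$ct_target >= 45 |
          ct$ct_reference <= 0 | ct$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ sirna_id + timepoint,
                          data = ct, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  for (id in unique(agg$sirna_id)) {
    if (!any(agg$sirna_id == id & agg$timepoint == control_timepoint)) {
      stop("missing control timepoint for ", id, call. = FALSE)
    }
  }
  ctrl <- agg[agg$timepoint == control_timepoint, c("sirna_id", "delta_ct")]
  names(ctrl)[2L] <- "delta_ct_control"
  agg <- merge(agg, ctrl, by = "sirna_id")
  agg$delta_delta_ct <- agg$delta_ct - agg$delta_ct_control
  agg$rel_expr <- 2^(-agg$delta_delta_ct)
  agg$log2fc <- -agg$delta_delta_ct
  out <- agg[order(agg$sirna_id, agg$timepoint),
             c("sirna_id", "timepoint", "delta_ct", "delta_delta_ct",
               "rel_expr", "log2fc")]
  rownames(out) <- NULL
  out
}

#' Agreement between sequencing and qPCR log2 fold changes
#'
#' Ordinary least squares of the sequencing log2 fold change on the qPCR
#' log2 fold change; r-squared is the squared Pearson correlation.
#'
#' @param seq_log2fc,qpcr_log2fc paired finite values (>= 3 pairs, both with
#'   nonzero variance).
#' @return list: slope, intercept, r_squared, n.
#' @export
agreement <- function(seq_log2fc, qpcr_log2fc) {
  stopifnot(length(seq_log2fc) == length(qpcr_log2fc))
  if (length(seq_log2fc) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(seq_log2fc)) || any(!is.finite(qpcr_log2fc))) {
    stop("non-finite fold changes", call. = FALSE)
  }
  if (stats::var(seq_log2fc) == 0 || stats::var(qpcr_log2fc) == 0) {
    stop("zero variance in fold changes", call. = FALSE)
  }
  fit <- stats::lm(seq_log2fc ~ qpcr_log2fc)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = stats::cor(seq_log2fc, qpcr_log2fc)^2,
       n = length(seq_log2fc))
}

#' Cross-validate sequencing DE results against a qPCR panel
#'
#' Computes 2^-ddCt relative expression from the Ct table, pairs each
#' panel siRNA's qPCR log2 fold change with the sequencing log2 ratio at
#' the matching timepoint (pairs pooled over 1/6/12 h) and fits the
#' agreement regression.
#'
#' @param ct Ct table (see [delta_delta_ct()]).
#' @param de_table output of [de_analysis()].
#' @param id_map optional data.frame (panel_id, sirna_id) translating Ct
#'   table ids to catalogue ids (synthetic-data plumbing); by default ids
#'   are assumed to match.
#' @return list: `rel_expr` (the [delta_delta_ct()] table), `pairs`
#'   (data.frame of pooled log2fc pairs) and `agreement` (see
#'   [agreement()]).
#' @export
qpcr_validate <- function(ct, de_table, id_map = NULL) {
  rel <- delta_delta_ct(ct)
  rel$de_id <- if (is.null(id_map)) rel$sirna_id else
    id_map$sirna_id[match(rel$sirna_id, id_map$panel_id)]
  tp_map <- c("1" = "1h", "6" = "6h", "12" = "12h")
  pairs <- list()
  for (tp in names(tp_map)) {
    sub <- rel[rel$timepoint == as.numeric(tp) & !is.na(rel$de_id), ,
               drop = FALSE]
    mi <- match(sub$de_id, de_table$sirna_id)
    ok <- !is.na(mi)
    if (!any(ok)) next
    pairs[[tp]] <- data.frame(
      sirna_id = sub$sirna_id[ok], timepoint = as.numeric(tp),
      qpcr_log2fc = sub$log2fc[ok],
      seq_log2fc = de_table[[paste0("log2_ratio_", tp_map[tp])]][mi[ok]])
  }
  pairs <- do.call(rbind, pairs)
  rownames(pairs) <- NULL
  list(rel_expr = rel[, setdiff(names(rel), "de_id")], pairs = pairs,
       agreement = agreement(pairs$seq_log2fc, pairs$qpcr_log2fc))
}
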