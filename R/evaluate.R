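# Truth-table evaluation helpers for the planted synthetic world.

#' Join called siRNAs to planted truth loci
#'
#' Matches catalogue duplexes to truth loci on exact plus-strand interval
#' coordinates.
#'
#' @param catalogue siRNA catalogue from [call_sirnas()].
#' @param truth truth table (from [plant_sirna_loci()] or read from
#'   `truth.tsv`).
#' @return data.frame (locus_id, sirna_id); unmatched loci are absent.
#' @export
match_truth_ids <- function(catalogue, truth) {
  key_c <- paste(catalogue$chrom, catalogue$plus_start, catalogue$plus_end)
  key_t <- paste(truth$chrom, truth$plus_start, truth$plus_end)
  mi <- match(key_t, key_c)
  ok <- !is.na(mi)
  data.frame(locus_id = truth$locus_id[ok],
             sirna_id = catalogue$sirna_id[mi[ok]],
             stringsAsFactors = FALSE)
}

#' Sensitivity and precision of siRNA calling against planted truth
#'
#' @inheritParams match_truth_ids
#' @return list: sensitivity (called planted loci / planted loci),
#'   precision (called duplexes at planted positions / called duplexes),
#'   tp, fp, fn.
#' @export
evaluate_calls <- function(catalogue, truth) {
  key_c <- paste(catalogue$chrom, catalogue$plus_start, catalogue$plus_end)
  key_t <- paste(truth$chrom, truth$plus_start, truth$plus_end)
  tp <- sum(key_t %in% key_c)
  fp <- sum(!(key_c %in% key_t))
  fn <- nrow(truth) - tp
  list(sensitivity = tp / nrow(truth),
       precision = if (nrow(catalogue)) tp / nrow(catalogue) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' DE-direction sensitivity and false discovery proportion against truth
#'
#' Each (locus, timepoint) pair is one decision. Sensitivity: fraction of
#' planted non-flat pairs called in the planted direction. FDP: fraction of
#' DE calls that are not planted in that direction (planted-flat pairs,
#' direction flips and calls on unplanted duplexes all count as false
#' discoveries).
#'
#' @param de_table output of [de_analysis()].
#' @param truth truth table.
#' @param id_map output of [match_truth_ids()].
#' @return list: sensitivity, fdp, n_calls, n_planted.
#' @export
evaluate_de <- function(de_table, truth, id_map) {
  truth_id <- id_map$locus_id[match(de_table$sirna_id, id_map$sirna_id)]
  ti <- match(truth_id, truth$locus_id)
  tp <- 0L; fp <- 0L; planted <- 0L
  for (comp in COMPARISONS) {
    called <- de_table[[paste0("status_", comp)]]
    planted_status <- truth[[paste0("status_", comp)]][ti]
    planted_status[is.na(planted_status)] <- "none"
    is_de_truth <- planted_status %in% c("up", "down")
    planted <- planted + sum(truth[[paste0("status_", comp)]] %in%
                               c("up", "down"))
    tp <- tp + sum(called != "ns" & called == planted_status)
    fp <- fp + sum(called != "ns" & called != planted_status)
  }
  n_calls <- tp + fp
  list(sensitivity = tp / planted,
       fdp = if (n_calls) fp / n_calls else 0,
       n_calls = n_calls, n_planted = planted)
}
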