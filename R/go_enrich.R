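#' Hypergeometric upper-tail enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that at
#' least `k` of `n` sampled genes carry an annotation present in `K` of `N`
#' background genes. Computed with the log-space-stable distribution
#' function; `k = 0` gives exactly 1.
#'
#' @param k annotated genes in the target set.
#' @param n target-set size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return upper-tail p-value (vectorised over `k`, `n`, `K`, `N`).
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > n) || any(k > K)) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up by default; Bonferroni selectable. Adjusted
#' values are capped at 1 and never smaller than the raw p-values.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = method)
}

#' GO-term enrichment of a target gene set
#'
#' One hypergeometric upper-tail test per GO term with at least one
#' annotated background gene; correction is applied within each namespace
#' separately; a term is significant when its adjusted p-value is at most
#' `alpha`.
#'
#' @param target_gene_ids genes of interest (must be a subset of the
#'   background).
#' @param background_gene_ids background universe (defaults to all genes in
#'   `go_map`).
#' @param go_map data.frame with columns gene_id, go_id, namespace.
#' @param method,alpha correction method and significance level.
#' @return data.frame of `EnrichmentResult` rows: go_id, namespace, k, n, K,
#'   N, p_value, adjusted_p, significant; sorted by adjusted_p, ties by
#'   go_id.
#' @export
enrich <- function(target_gene_ids, go_map, background_gene_ids = NULL,
                   method = "BH", alpha = 0.05) {
  stopifnot(all(c("gene_id", "go_id", "namespace") %in% names(go_map)))
  background <- unique(background_gene_ids %||% go_map$gene_id)
  target <- unique(target_gene_ids)
  if (!all(target %in% background)) {
    stop("target genes must be a subset of the background", call. = FALSE)
  }
  empty <- data.frame(go_id = character(0), namespace = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0))
  if (length(target) == 0L) {
    warning("empty target set; no enrichment computed")
    return(empty)
  }
  gm <- unique(go_map[go_map$gene_id %in% background,
                      c("gene_id", "go_id", "namespace")])
  if (nrow(gm) == 0L) return(empty)
  terms <- unique(gm[, c("go_id", "namespace")])
  N <- length(background)
  n <- length(target)
  K <- as.integer(table(factor(gm$go_id, levels = terms$go_id))[terms$go_id])
  in_target <- gm$gene_id %in% target
  k <- as.integer(table(factor(gm$go_id[in_target],
                               levels = terms$go_id))[terms$go_id])
  p <- hypergeom_pvalue(k, n, K, N)
  adjusted <- numeric(length(p))
  for (ns in unique(terms$namespace)) {
    ix <- terms$namespace == ns
    adjusted[ix] <- adjust_pvalues(p[ix], method = method)
  }
  out <- data.frame(go_id = terms$go_id, namespace = terms$namespace,
                    k = k, n = n, K = K, N = N,
                    p_value = p, adjusted_p = adjusted,
                    significant = adjusted <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
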