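# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity from first principles and share
# no code path with the package internals.

# Naive full-scan exact mapper: enumerate every genome substring of the tag
# length on both strands.
oracle_map <- function(tags, genome) {
  out <- list()
  for (ch in names(genome)) {
    gseq <- genome[[ch]]
    n <- nchar(gseq)
    for (L in sort(unique(nchar(tags)))) {
      if (L > n) next
      subs <- substring(gseq, 1:(n - L + 1L), L:n)
      for (tag in tags[nchar(tags) == L]) {
        for (s in which(subs == tag)) {
          out[[length(out) + 1L]] <- data.frame(
            tag = tag, chrom = ch, start = s - 1L, end = s - 1L + L,
            strand = "+")
        }
        for (s in which(subs == revcomp(tag))) {
          out[[length(out) + 1L]] <- data.frame(
            tag = tag, chrom = ch, start = s - 1L, end = s - 1L + L,
            strand = "-")
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand, df$tag), , drop = FALSE]
}

# O(n^2) all-pairs duplex oracle: both offset conditions checked explicitly.
oracle_duplexes <- function(hits) {
  plus <- hits[hits$strand == "+", , drop = FALSE]
  minus <- hits[hits$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(plus))) {
    # all-pairs check of both offset conditions against every minus hit
    ok <- which(plus$chrom[i] == minus$chrom &
                  plus$start[i] - minus$start == 2L &
                  plus$end[i] - minus$end == 2L)
    for (j in ok) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = plus$chrom[i],
        plus_start = plus$start[i], plus_end = plus$end[i],
        minus_start = minus$start[j], minus_end = minus$end[j])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), plus_start = integer(0),
                      plus_end = integer(0), minus_start = integer(0),
                      minus_end = integer(0)))
  }
  unique(do.call(rbind, out))
}

duplex_key <- function(df) {
  sort(paste(df$chrom, df$plus_start, df$plus_end, df$minus_start,
             df$minus_end))
}

# Hypergeometric upper tail by direct pmf summation.
oracle_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  xs <- k:min(n, K)
  sum(stats::dhyper(xs, K, N - K, n))
}

# Adjusted Rand index from the contingency table.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maximum - expected)
}

# Loop-based target-site scorers (independent of the package's vectorised
# lookup-table path). Antiparallel pairing: guide position i (1-based from
# the 5' end) pairs site position length(site) + 1 - i.
oracle_pair_penalty <- function(g, s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (s == comp[[g]]) return(0)
  if ((g == "G" && s == "T") || (g == "T" && s == "G")) return(0.5)
  1
}

oracle_score_a <- function(guide, site) {
  gv <- strsplit(guide, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  L <- length(gv)
  ungapped <- function(sv2) {
    tot <- 0
    for (i in seq_len(L)) {
      pen <- oracle_pair_penalty(gv[i], sv2[L + 1L - i])
      if (i >= 2 && i <= 13) pen <- pen * 2
      tot <- tot + pen
    }
    tot
  }
  if (length(sv) == L) return(ungapped(sv))
  stopifnot(length(sv) == L + 1L)
  best <- Inf
  for (k in 2:L) {
    gb <- L + 2L - k
    pen <- ungapped(sv[-k]) + ifelse(gb >= 2 && gb <= 13, 2, 1)
    best <- min(best, pen)
  }
  best
}

oracle_score_b <- function(guide, site) {
  gv <- strsplit(guide, "")[[1]]
  sv <- strsplit(site, "")[[1]]
  L <- length(gv)
  stopifnot(length(sv) == L)
  tot <- 0
  seed <- 0
  for (i in seq_len(L)) {
    pen <- oracle_pair_penalty(gv[i], sv[L + 1L - i])
    tot <- tot + pen
    if (i >= 2 && i <= 8) seed <- seed + pen
  }
  if (seed > 1 + 1e-9) return(Inf)
  tot
}

# Full-offset scan oracle: every window of length L (both schemes) and
# L + 1 (scheme A bulge) on one transcript.
oracle_scan <- function(guide, tx, cutoff_a = 4, cutoff_b = 2.5,
                        allow_bulge = TRUE) {
  L <- nchar(guide)
  n <- nchar(tx)
  rows <- list()
  for (w in seq_len(max(0L, n - L + 1L))) {
    site <- substr(tx, w, w + L - 1L)
    sa <- oracle_score_a(guide, site)
    sb <- oracle_score_b(guide, site)
    if (sa <= cutoff_a || sb <= cutoff_b) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = w - 1L, end = w - 1L + L, score_a = sa, score_b = sb,
        pass_a = sa <= cutoff_a, pass_b = is.finite(sb) & sb <= cutoff_b)
    }
  }
  if (allow_bulge) {
    for (w in seq_len(max(0L, n - L))) {
      site <- substr(tx, w, w + L)
      sa <- oracle_score_a(guide, site)
      if (sa <= cutoff_a) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = w - 1L, end = w + L, score_a = sa, score_b = Inf,
          pass_a = TRUE, pass_b = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      score_a = numeric(0), score_b = numeric(0),
                      pass_a = logical(0), pass_b = logical(0)))
  }
  df <- do.call(rbind, rows)
  df[order(df$start, df$end), , drop = FALSE]
}

# Per-element three-bit signature tally for set intersections.
oracle_venn <- function(s1, s2, s3) {
  u <- unique(c(s1, s2, s3))
  sig <- vapply(u, function(x) {
    paste0(as.integer(x %in% s1), as.integer(x %in% s2),
           as.integer(x %in% s3))
  }, character(1))
  tab <- table(factor(sig, levels = c("100", "010", "001", "110", "101",
                                      "011", "111")))
  stats::setNames(as.integer(tab), names(tab))
}
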