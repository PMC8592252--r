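# Position-weighted siRNA target-site scoring.
#
# Two independent penalty schemes approximate published plant small-RNA
# target predictors; only sites passing both at overlapping positions
# ("consensus") are trusted downstream. Pairing is antiparallel: guide
# position 1 (5' end) pairs with the last base of the site. Penalties:
# Watson-Crick match 0, G:U wobble 0.5, mismatch 1.0; scheme A doubles all
# penalties at guide positions 2-13 and allows at most one single-nucleotide
# target bulge (penalty 1.0); scheme B is ungapped and imposes a hard seed
# constraint of at most 1 penalty point within guide positions 2-8.

DNA_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

encode_dna <- function(x) {
  v <- DNA_CODES[strsplit(x, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("non-ACGTN character in sequence", call. = FALSE)
  unname(v)
}

# penalty[guide_base, site_base]
pair_penalty_matrix <- function() {
  P <- matrix(1, 5L, 5L, dimnames = list(names(DNA_CODES), names(DNA_CODES)))
  P[cbind(c(1L, 2L, 3L, 4L), c(4L, 3L, 2L, 1L))] <- 0      # Watson-Crick
  P[3L, 4L] <- 0.5                                          # guide G : site T
  P[4L, 3L] <- 0.5                                          # guide U : site G
  P[5L, ] <- Inf
  P[, 5L] <- Inf
  P
}
PAIR_PENALTY <- pair_penalty_matrix()

SCHEME_A_CORE <- 2:13   # guide positions with doubled penalties (scheme A)
SCHEME_B_SEED <- 2:8    # guide positions under the seed constraint (scheme B)

check_guide <- function(guide) {
  L <- nchar(guide)
  if (L < 20L || L > 24L) stop("guide must be 20-24 nt", call. = FALSE)
  L
}

# Ungapped penalty of guide vs equal-length site; per-column weights follow
# the guide position i = L + 1 - c for site column c.
score_ungapped <- function(g, s, core = NULL) {
  L <- length(g)
  i <- L:1
  pens <- PAIR_PENALTY[cbind(g[i], s)]
  if (!is.null(core)) pens <- pens * ifelse(i %in% core, 2, 1)
  sum(pens)
}

#' Scheme A target-site penalty (bulge-tolerant, core-weighted)
#'
#' Per-position costs: mismatch 1.0, G:U wobble 0.5, single-nucleotide
#' target bulge 1.0, each doubled when falling at guide positions 2-13
#' (1-based from the guide 5' end). The site may be the guide length
#' (ungapped) or one base longer (one interior target bulge; the best bulge
#' placement is scored).
#'
#' @param guide guide sequence, 20-24 nt.
#' @param site target-site sequence (transcript, 5'->3').
#' @return penalty (0 for a perfect complement).
#' @export
score_site_scheme_a <- function(guide, site) {
  L <- check_guide(guide)
  g <- encode_dna(guide)
  s <- encode_dna(site)
  if (length(s) == L) {
    return(score_ungapped(g, s, core = SCHEME_A_CORE))
  }
  if (length(s) != L + 1L) {
    stop("site length must equal guide length or guide length + 1",
         call. = FALSE)
  }
  best <- Inf
  for (k in 2:L) {   # interior skipped (bulged) site base
    gb <- L + 2L - k
    pen <- score_ungapped(g, s[-k], core = SCHEME_A_CORE) +
      1 * ifelse(gb %in% SCHEME_A_CORE, 2, 1)
    best <- min(best, pen)
  }
  best
}

#' Scheme B target-site penalty (ungapped, seed-constrained)
#'
#' Per-position costs: mismatch 1.0, G:U wobble 0.5, no position weighting
#' and no bulges, with a hard seed constraint: more than 1 penalty point in
#' total within guide positions 2-8 rejects the site (returns `Inf`).
#'
#' @inheritParams score_site_scheme_a
#' @return penalty, or `Inf` when the seed constraint is violated.
#' @export
score_site_scheme_b <- function(guide, site) {
  L <- check_guide(guide)
  g <- encode_dna(guide)
  s <- encode_dna(site)
  if (length(s) != L) stop("scheme B allows no bulges", call. = FALSE)
  i <- L:1
  pens <- PAIR_PENALTY[cbind(g[i], s)]
  seed <- sum(pens[i %in% SCHEME_B_SEED])
  if (seed > 1 + 1e-9) return(Inf)
  sum(pens)
}

# Concatenate transcripts with N spacers; windows crossing a boundary score
# Inf and can never pass a cutoff.
concat_transcripts <- function(transcripts) {
  nm <- names(transcripts)
  spacer <- strrep("N", 30L)
  big <- paste(transcripts, collapse = spacer)
  lens <- nchar(transcripts)
  starts <- cumsum(c(0L, utils::head(lens + 30L, -1L)))  # 0-based global
  list(codes = unname(DNA_CODES[strsplit(big, "", fixed = TRUE)[[1L]]]),
       names = nm, starts = starts, lens = lens)
}

# Sliding penalties of one guide over the concatenated transcript codes for
# window length `Lw`, with per-column guide positions given by `ivec`
# (guide index paired with each window column). Returns the per-column
# penalty contributions accumulated with `weights`.
sliding_penalty <- function(tc, g, Lw, ivec, weights) {
  nc <- length(tc)
  nw <- nc - Lw + 1L
  if (nw < 1L) return(numeric(0))
  acc <- numeric(nw)
  for (c in seq_len(Lw)) {
    if (is.na(ivec[c])) next
    prow <- PAIR_PENALTY[g[ivec[c]], ]
    acc <- acc + prow[tc[c:(nc - Lw + c)]] * weights[c]
  }
  acc
}

scan_one_guide <- function(tc, guide, cutoff_a, cutoff_b, allow_bulge) {
  L <- nchar(guide)
  g <- encode_dna(guide)
  nc <- length(tc$codes)
  i_u <- L:1
  wA <- ifelse(i_u %in% SCHEME_A_CORE, 2, 1)
  penA <- sliding_penalty(tc$codes, g, L, i_u, wA)
  penB <- sliding_penalty(tc$codes, g, L, i_u, rep(1, L))
  seedB <- sliding_penalty(tc$codes, g, L, i_u,
                           as.numeric(i_u %in% SCHEME_B_SEED))
  pass_a <- is.finite(penA) & penA <= cutoff_a
  pass_b <- is.finite(penB) & seedB <= 1 + 1e-9 & penB <= cutoff_b
  score_b <- ifelse(seedB > 1 + 1e-9, Inf, penB)

  sites <- list()
  emit <- which(pass_a | pass_b)
  if (length(emit)) {
    sites[[1L]] <- data.frame(gstart = emit - 1L, len = L,
                              score_a = penA[emit], score_b = score_b[emit],
                              pass_a = pass_a[emit], pass_b = pass_b[emit])
  }
  if (allow_bulge && nc >= L + 1L) {
    Lw <- L + 1L
    nw <- nc - Lw + 1L
    # prefix sums of columns paired as in the ungapped alignment (bulge to
    # the right of the column) and suffix sums of columns shifted by one
    # guide position (bulge to the left)
    csA <- vector("list", L)
    acc <- numeric(nw)
    for (cc in seq_len(L)) {
      i <- L + 1L - cc
      prow <- PAIR_PENALTY[g[i], ]
      acc <- acc + prow[tc$codes[cc:(nc - Lw + cc)]] *
        ifelse(i %in% SCHEME_A_CORE, 2, 1)
      csA[[cc]] <- acc
    }
    rbB <- vector("list", Lw + 1L)
    rbB[[Lw + 1L]] <- numeric(nw)
    for (cc in Lw:2) {
      i <- L + 2L - cc
      prow <- PAIR_PENALTY[g[i], ]
      rbB[[cc]] <- rbB[[cc + 1L]] +
        prow[tc$codes[cc:(nc - Lw + cc)]] * ifelse(i %in% SCHEME_A_CORE, 2, 1)
    }
    best <- rep(Inf, nw)
    for (k in 2:L) {
      gb <- L + 2L - k
      tot <- csA[[k - 1L]] + rbB[[k + 1L]] + ifelse(gb %in% SCHEME_A_CORE, 2, 1)
      best <- pmin(best, tot)
    }
    emit_b <- which(is.finite(best) & best <= cutoff_a)
    if (length(emit_b)) {
      sites[[length(sites) + 1L]] <- data.frame(
        gstart = emit_b - 1L, len = Lw,
        score_a = best[emit_b], score_b = Inf,
        pass_a = TRUE, pass_b = FALSE)
    }
  }
  if (!length(sites)) return(NULL)
  do.call(rbind, sites)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  ov >= 0.5 * (e1 - s1) & ov >= 0.5 * (e2 - s2)
}

#' Scan transcripts for siRNA target sites under both schemes
#'
#' Slides each guide along every transcript evaluating scheme A (including
#' single-bulge variants) and scheme B at every offset. Sites passing either
#' scheme are emitted; a site is flagged consensus when an A-passing and a
#' B-passing site coincide (intervals with >= 50 percent reciprocal
#' overlap) -- the in-silico analogue of requiring both prediction tools to
#' agree.
#'
#' @param sirnas siRNA catalogue (data.frame with sirna_id and guide_seq) or
#'   a named character vector of guide sequences.
#' @param transcripts named character vector, DNAStringSet, or FASTA path.
#' @param cutoff_a,cutoff_b penalty cutoffs (defaults 4.0 and 2.5).
#' @param allow_bulge evaluate single-bulge scheme A variants (default TRUE).
#' @return data.frame of target hits: sirna_id, transcript_id, site start /
#'   end (0-based half-open on the transcript), score_a, score_b, consensus;
#'   ordered by (sirna_id, transcript_id, start).
#' @export
scan_transcripts <- function(sirnas, transcripts, cutoff_a = 4,
                             cutoff_b = 2.5, allow_bulge = TRUE) {
  if (is.data.frame(sirnas)) {
    guides <- stats::setNames(sirnas$guide_seq, sirnas$sirna_id)
  } else {
    guides <- sirnas
    if (is.null(names(guides))) {
      names(guides) <- sprintf("guide_%03d", seq_along(guides))
    }
  }
  if (inherits(transcripts, "DNAStringSet")) {
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  } else if (is.character(transcripts) && length(transcripts) == 1L &&
             file.exists(transcripts) && is.null(names(transcripts))) {
    x <- Biostrings::readDNAStringSet(transcripts)
    transcripts <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  stopifnot(length(transcripts) >= 1L)
  tc <- concat_transcripts(transcripts)
  out <- list()
  for (gi in seq_along(guides)) {
    sites <- scan_one_guide(tc, guides[[gi]], cutoff_a, cutoff_b, allow_bulge)
    if (is.null(sites)) next
    txi <- findInterval(sites$gstart, tc$starts)
    local <- sites$gstart - tc$starts[txi]
    inside <- local + sites$len <= tc$lens[txi]
    sites <- sites[inside, , drop = FALSE]
    if (!nrow(sites)) next
    txi <- txi[inside]
    local <- local[inside]
    df <- data.frame(sirna_id = names(guides)[gi],
                     transcript_id = tc$names[txi],
                     start = local, end = local + sites$len,
                     score_a = sites$score_a, score_b = sites$score_b,
                     pass_a = sites$pass_a, pass_b = sites$pass_b,
                     stringsAsFactors = FALSE)
    # consensus per transcript: >= 50% reciprocal overlap between an
    # A-passing and a B-passing site
    df$consensus <- FALSE
    for (tx in unique(df$transcript_id)) {
      ix <- which(df$transcript_id == tx)
      a <- df[ix, ][df$pass_a[ix], , drop = FALSE]
      b <- df[ix, ][df$pass_b[ix], , drop = FALSE]
      if (!nrow(a) || !nrow(b)) next
      for (j in ix) {
        ov_a <- any(reciprocal_overlap(df$start[j], df$end[j], a$start, a$end))
        ov_b <- any(reciprocal_overlap(df$start[j], df$end[j], b$start, b$end))
        df$consensus[j] <- ov_a && ov_b
      }
    }
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) {
    return(data.frame(sirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      score_a = numeric(0), score_b = numeric(0),
                      pass_a = logical(0), pass_b = logical(0),
                      consensus = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sirna_id, res$transcript_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
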