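# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over a character vector of DNA sequences
#' (alphabet A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s); `n` lengths, one sequence per element.
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  big <- paste(bases, collapse = "")
  substring(big, starts, ends)
}

stopifnot_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-ACGT", if (allow_n) "N", " characters in sequence input (first offender: ",
         x[which(bad)[1L]], ")", call. = FALSE)
  }
  invisible(TRUE)
}

# Library labels used throughout: heat time course, control first.
LIB_LABELS <- c("0h", "1h", "6h", "12h")
COMPARISONS <- c("1h", "6h", "12h")

count_cols <- function() paste0("count_", LIB_LABELS)

# 0-based half-open interval overlap (>= 1 bp)
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
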