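# Internal helpers shared across modules. All genomic coordinates in this
# package are BED-style 0-based half-open; substr() calls therefore add 1.

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over \{A,C,G,T,N\}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Phred quality character for a substitution rate
#'
#' Phred score is round(-10 log10(rate)); a rate of 0 maps to Phred 40.
#' Encoding is Phred+33.
#' @param error_rate per-base substitution probability in [0, 1).
#' @return single quality character.
#' @export
phred_char <- function(error_rate) {
  stopifnot(error_rate >= 0, error_rate < 1)
  q <- if (error_rate == 0) 40L else as.integer(round(-10 * log10(error_rate)))
  rawToChar(as.raw(33L + q))
}

# Substring of a circular sequence starting at 0-based offset, wrapping
# modulo its length as often as needed (rolling circle).
circ_substr <- function(template, start0, len) {
  L <- nchar(template)
  stopifnot(L >= 1L, all(start0 >= 0L), all(start0 < L), all(len >= 1L))
  reps <- ceiling((max(start0) + max(len)) / L)
  tiled <- strrep(template, reps)
  substr(rep(tiled, length.out = max(length(start0), length(len))),
         start0 + 1L, start0 + len)
}

# One string key per junction; strand joins the key only in strict mode.
junction_key <- function(chrom, start, end, strand = NULL, strict_strand = FALSE) {
  if (strict_strand && !is.null(strand)) {
    paste(chrom, start, end, strand, sep = ":")
  } else {
    paste(chrom, start, end, sep = ":")
  }
}

# Does each mate of a fragment cross the back-splice junction (the point
# between template positions L-1 and 0)? A mate of length R starting at
# 0-based circle offset s crosses iff it wraps: s + R > L.
mate_spans_junction <- function(start0, frag_len, read_len, L) {
  m1 <- start0 + read_len > L
  s2 <- (start0 + frag_len - read_len) %% L
  m2 <- s2 + read_len > L
  cbind(mate1 = m1, mate2 = m2)
}

#' Junction-straddling substring of a circular template
#'
#' The sequence read across the back-splice junction: the last `flank` bases
#' of the template followed by its first `flank` bases. Before error
#' injection, any mate that crosses the junction exactly once is a substring
#' of this string when flank = read_len - 1.
#'
#' @param template circular template sequence (character scalar).
#' @param flank bases taken from each side of the junction.
#' @return character scalar of length 2 * flank (shorter if flank > L).
#' @export
junction_substring <- function(template, flank) {
  L <- nchar(template)
  stopifnot(flank >= 1)
  flank <- min(flank, L)
  paste0(substr(template, L - flank + 1L, L), substr(template, 1L, flank))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
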