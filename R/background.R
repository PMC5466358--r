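# Linear-mRNA background generator: paired-end reads from linear transcripts
# with uniform substitution errors (and an optional short-indel model). This
# natively re-expresses an ART-style invocation: 101-bp pairs, 350 +/- 10 bp
# inserts, qualities shifted down to raise the substitution rate.

#' Background simulation configuration
#'
#' The default substitution rate is derived from the quality shift: a
#' baseline Phred 30 shifted down by `quality_shift` gives
#' 10^-((30 - quality_shift)/10), i.e. about 2% at the default shift of 13,
#' emulating deliberately poor sequencing quality.
#'
#' @param fold_coverage fold coverage per transcript.
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd insert size distribution (Normal, rounded,
#'   truncated to [read_len, transcript length]).
#' @param error_rate per-base substitution probability; NULL derives it from
#'   `quality_shift`.
#' @param indel_rate per-base indel rate (default 0 = off); indel lengths are
#'   geometric, truncated to 1--3 bp.
#' @param quality_shift Phred points subtracted from the baseline quality.
#' @param seed integer seed; NULL leaves the RNG state untouched.
#' @return object of class `background_config`.
#' @export
background_config <- function(fold_coverage = 200, read_len = 101L,
                              insert_mean = 350L, insert_sd = 10,
                              error_rate = NULL, indel_rate = 0,
                              quality_shift = 13L, seed = 20160830L) {
  if (fold_coverage <= 0) stop("config error: fold_coverage must be > 0")
  if (read_len < 1) stop("config error: read_len must be >= 1")
  if (insert_mean < read_len) stop("config error: insert_mean < read_len")
  if (is.null(error_rate)) error_rate <- 10^(-(30 - quality_shift) / 10)
  if (error_rate < 0 || error_rate >= 1) stop("config error: error_rate must be in [0, 1)")
  if (indel_rate < 0 || indel_rate >= 1) stop("config error: indel_rate must be in [0, 1)")
  structure(list(fold_coverage = fold_coverage, read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, indel_rate = indel_rate,
                 quality_shift = as.integer(quality_shift), seed = seed),
            class = "background_config")
}

# Geometric-length (1-3 bp) insertions/deletions at a per-base rate.
apply_indels <- function(seq, rate, read_len) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (length(pos) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in rev(pos)) {
    len <- sample(1:3, 1L, prob = c(0.5, 0.25, 0.25))
    if (stats::runif(1) < 0.5) {
      ch <- ch[-(p:min(p + len - 1L, length(ch)))]
    } else {
      ch <- append(ch, sample(c("A", "C", "G", "T"), len, replace = TRUE), after = p)
    }
  }
  out <- paste(ch, collapse = "")
  if (nchar(out) < read_len) seq else out  # too short to carry both mates: keep original
}

#' Simulate background reads from linear mRNA sequences
#'
#' Per transcript, pair count = round(fold_coverage * len / (2 * read_len));
#' fragment starts are uniform on [0, len - fragment_len] so no fragment
#' wraps and no read can support a back-splice junction. Transcripts no
#' longer than the mean insert are skipped with a warning.
#'
#' @param mrna named character vector of mRNA sequences (e.g. from
#'   [read_fasta()]).
#' @param config a [background_config()].
#' @return data.frame of read pairs in the same layout as
#'   [simulate_circ_reads()], with origin "linear:<id>" and junction flags
#'   all FALSE.
#' @export
simulate_background <- function(mrna, config) {
  stopifnot(inherits(config, "background_config"), length(mrna) > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$read_len
  lens <- nchar(mrna)
  eligible <- lens > config$insert_mean
  if (!any(eligible)) stop("all transcripts are shorter than the insert size")
  if (any(!eligible)) {
    warning(sum(!eligible), " transcript(s) no longer than insert_mean (",
            config$insert_mean, " bp) skipped")
  }
  out <- vector("list", sum(eligible))
  k <- 0L
  for (id in names(mrna)[eligible]) {
    len <- nchar(mrna[[id]])
    n <- max(0L, as.integer(round(config$fold_coverage * len / (2 * R))))
    if (n == 0L) next
    flens <- pmin(len, pmax(R, as.integer(round(
      stats::rnorm(n, config$insert_mean, config$insert_sd)))))
    starts <- as.integer(floor(stats::runif(n) * (len - flens + 1L)))
    frags <- substr(rep(mrna[[id]], n), starts + 1L, starts + flens)
    if (config$indel_rate > 0) {
      frags <- vapply(frags, apply_indels, "", rate = config$indel_rate,
                      read_len = R, USE.NAMES = FALSE)
      flens <- nchar(frags)
    }
    m1 <- substr(frags, 1L, R)
    m2 <- revcomp(substr(frags, flens - R + 1L, flens))
    e1 <- inject_errors(m1, config$error_rate)
    e2 <- inject_errors(m2, config$error_rate)
    k <- k + 1L
    out[[k]] <- data.frame(
      pair_id = sprintf("%s_b%06d", id, seq_len(n)),
      origin = paste0("linear:", id),
      mate1_seq = e1$seq, mate2_seq = e2$seq,
      mate1_qual = e1$qual, mate2_qual = e2$qual,
      mate1_spans = FALSE, mate2_spans = FALSE,
      frag_start = starts, frag_len = flens,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out[seq_len(k)])
}
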