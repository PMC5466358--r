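# Circular-transcript read simulator: builds circularized spliced templates,
# samples paired-end fragments on the circle (rolling over the back-splice
# junction when the fragment outruns the spliced length) and keeps truth
# accounting of junction-supporting pairs.

#' Simulation configuration for circular reads
#'
#' Exactly one of `coverage` (fold coverage per circle) or `target_support`
#' (junction-supporting pairs per circle, scalar or one value per template)
#' must be set. Defaults mirror the positive-dataset conditions: 101-bp
#' reads, fixed 350-bp inserts, 1% substitution errors, realized support
#' kept within 2--24 pairs.
#'
#' @param read_len read length in bp.
#' @param insert_mean mean insert (fragment) size in bp; must be >= read_len.
#' @param insert_sd insert size standard deviation (0 = fixed inserts).
#' @param error_rate per-base substitution probability in [0, 1).
#' @param coverage fold coverage per circle, or NULL.
#' @param target_support junction-supporting pairs per circle, or NULL.
#' @param min_support,max_support admissible realized support range enforced
#'   in coverage mode.
#' @param seed integer seed; NULL leaves the RNG state untouched.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(read_len = 101L, insert_mean = 350L, insert_sd = 0,
                       error_rate = 0.01, coverage = NULL,
                       target_support = NULL, min_support = 2L,
                       max_support = 24L, seed = 20160830L) {
  if (read_len < 1) stop("config error: read_len must be >= 1")
  if (insert_mean < read_len) stop("config error: insert_mean < read_len")
  if (error_rate < 0 || error_rate >= 1) stop("config error: error_rate must be in [0, 1)")
  if (is.null(coverage) == is.null(target_support)) {
    stop("config error: set exactly one of coverage / target_support")
  }
  if (min_support < 0 || max_support < min_support) {
    stop("config error: need 0 <= min_support <= max_support")
  }
  structure(list(read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, coverage = coverage,
                 target_support = target_support,
                 min_support = as.integer(min_support),
                 max_support = as.integer(max_support), seed = seed),
            class = "sim_config")
}

#' Build the circularized spliced template for one circRNA
#'
#' The template is the spliced exonic sequence of the circle read 5'->3' on
#' the transcript strand; the back-splice junction lies between template
#' positions L-1 and 0. The exon structure is taken from the annotated
#' transcript with the largest exonic overlap with [start, end), each exon
#' intersected with that interval; with no overlapping transcript the whole
#' interval is a single exon.
#'
#' @param circ one junction: a list or 1-row data.frame with circ_id, chrom,
#'   start, end, strand (0-based half-open).
#' @param transcripts exon data.frame from [read_gtf_exons()], or NULL.
#' @param genome named character vector of chromosome sequences.
#' @return object of class `circular_template` with fields circ_id, chrom,
#'   start, end, strand, exons, sequence, spliced_length, genomic_span.
#' @export
build_circular_template <- function(circ, transcripts = NULL, genome) {
  chrom <- as.character(circ$chrom)
  start <- as.integer(circ$start)
  end <- as.integer(circ$end)
  strand <- as.character(circ$strand %||% ".")
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  if (start < 0 || end > nchar(genome[[chrom]])) {
    stop("circRNA '", circ$circ_id, "' outside chromosome bounds")
  }
  if (start >= end) stop("circRNA '", circ$circ_id, "' has start >= end")

  exons <- data.frame(start = start, end = end)
  if (!is.null(transcripts) && nrow(transcripts) > 0) {
    tx <- transcripts[transcripts$chrom == chrom, , drop = FALSE]
    if (nrow(tx) > 0) {
      ov <- pmax(0L, pmin(tx$end, end) - pmax(tx$start, start))
      per_tx <- tapply(ov, tx$transcript_id, sum)
      per_tx <- per_tx[per_tx > 0]
      if (length(per_tx) > 0) {
        best <- names(per_tx)[order(-per_tx, names(per_tx))][1]
        bx <- tx[tx$transcript_id == best, , drop = FALSE]
        s <- pmax(bx$start, start)
        e <- pmin(bx$end, end)
        keep <- s < e
        exons <- data.frame(start = s[keep], end = e[keep])
        exons <- exons[order(exons$start), , drop = FALSE]
      }
    }
  }
  seq <- paste(substr(rep(genome[[chrom]], nrow(exons)),
                      exons$start + 1L, exons$end), collapse = "")
  if (nchar(seq) == 0) stop("circRNA '", circ$circ_id, "' has zero-length spliced sequence")
  if (strand == "-") seq <- revcomp(seq)
  structure(list(circ_id = as.character(circ$circ_id), chrom = chrom,
                 start = start, end = end, strand = strand, exons = exons,
                 sequence = seq, spliced_length = nchar(seq),
                 genomic_span = end - start),
            class = "circular_template")
}

#' @export
print.circular_template <- function(x, ...) {
  cat(sprintf("circular template %s  %s:%d-%d(%s)  spliced %d bp / span %d bp, %d exon(s)\n",
              x$circ_id, x$chrom, x$start, x$end, x$strand,
              x$spliced_length, x$genomic_span, nrow(x$exons)))
  invisible(x)
}

#' Sample a fragment start offset on a circle
#'
#' Starts are uniform on 0..L-1; the fragment is then read from the circular
#' template starting there, wrapping modulo L until fragment_len bases are
#' taken (rolling circle when fragment_len > L).
#'
#' @param L spliced length of the circle (>= 1).
#' @param fragment_len fragment length (unused for the draw itself; kept so
#'   callers can pass geometry through).
#' @param n number of starts to draw.
#' @return integer vector of 0-based start offsets.
#' @export
sample_fragment_start <- function(L, fragment_len = NULL, n = 1L) {
  stopifnot(L >= 1)
  sample.int(L, n, replace = TRUE) - 1L
}

# Draw integer fragment lengths: Normal(insert_mean, insert_sd) rounded,
# truncated below at read_len.
draw_fragment_len <- function(n, config) {
  f <- round(stats::rnorm(n, config$insert_mean, config$insert_sd))
  pmax(as.integer(f), config$read_len)
}

# 0-based start offsets on a circle of length L from which a fragment of
# length F yields at least one junction-crossing mate.
spanning_starts <- function(L, frag_len, read_len) {
  s <- 0:(L - 1L)
  sp <- mate_spans_junction(s, frag_len, read_len, L)
  s[sp[, 1L] | sp[, 2L]]
}

# Emit n pairs for one template given start offsets and fragment lengths.
emit_pairs <- function(tpl, starts, frag_lens, config, pair_prefix) {
  R <- config$read_len
  L <- tpl$spliced_length
  n <- length(starts)
  if (n == 0L) {
    return(data.frame(pair_id = character(0), origin = character(0),
                      mate1_seq = character(0), mate2_seq = character(0),
                      mate1_qual = character(0), mate2_qual = character(0),
                      mate1_spans = logical(0), mate2_spans = logical(0),
                      frag_start = integer(0), frag_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  frags <- circ_substr(tpl$sequence, starts, frag_lens)
  m1 <- substr(frags, 1L, R)
  m2 <- revcomp(substr(frags, frag_lens - R + 1L, frag_lens))
  sp <- mate_spans_junction(starts, frag_lens, R, L)
  e1 <- inject_errors(m1, config$error_rate)
  e2 <- inject_errors(m2, config$error_rate)
  data.frame(pair_id = sprintf("%s_p%05d", pair_prefix, seq_len(n)),
             origin = tpl$circ_id,
             mate1_seq = e1$seq, mate2_seq = e2$seq,
             mate1_qual = e1$qual, mate2_qual = e2$qual,
             mate1_spans = sp[, 1L], mate2_spans = sp[, 2L],
             frag_start = starts, frag_len = frag_lens,
             stringsAsFactors = FALSE)
}

#' Simulate paired-end reads from circular templates
#'
#' In coverage mode the number of pairs per circle is
#' round(coverage * L / (2 * read_len)) with fragment starts uniform on the
#' circle; circles whose realized junction support falls outside
#' [min_support, max_support] are re-drawn in target-support mode with a
#' support sampled uniformly from that range. In target-support mode
#' fragment starts are drawn conditioned on junction crossing until exactly
#' the requested number of supporting pairs exists. Mate 1 is the first
#' read_len bases of the fragment; mate 2 the reverse complement of its last
#' read_len bases; a mate supports the junction iff its interval on the
#' circle wraps across offset 0, and a pair is counted once however many of
#' its mates (or wraps) cross.
#'
#' @param templates list of `circular_template` objects.
#' @param config a [sim_config()].
#' @return list with `reads` (one row per pair: sequences, qualities,
#'   junction flags and fragment coordinates) and `truth` (one row per
#'   circle: support_pairs, total_pairs, spliced_length, genomic_span).
#' @export
simulate_circ_reads <- function(templates, config) {
  stopifnot(inherits(config, "sim_config"), length(templates) > 0)
  if (config$insert_mean < config$read_len) stop("config error: insert_mean < read_len")
  if (!is.null(config$seed)) set.seed(config$seed)
  target <- config$target_support
  if (!is.null(target)) target <- rep_len(as.integer(target), length(templates))

  reads <- vector("list", length(templates))
  truth <- vector("list", length(templates))
  for (i in seq_along(templates)) {
    tpl <- templates[[i]]
    L <- tpl$spliced_length
    if (is.null(target)) {
      n <- max(0L, as.integer(round(config$coverage * L / (2 * config$read_len))))
      starts <- if (n > 0) sample_fragment_start(L, n = n) else integer(0)
      flens <- draw_fragment_len(n, config)
      sp <- mate_spans_junction(starts, flens, config$read_len, L)
      supp <- sum(sp[, 1L] | sp[, 2L])
      if (supp < config$min_support || supp > config$max_support) {
        t_i <- sample(config$min_support:config$max_support, 1L)
        drawn <- draw_conditioned(tpl, t_i, config)
        starts <- drawn$starts; flens <- drawn$flens
      }
    } else {
      drawn <- draw_conditioned(tpl, target[i], config)
      starts <- drawn$starts; flens <- drawn$flens
    }
    rr <- emit_pairs(tpl, starts, flens, config, tpl$circ_id)
    supp <- sum(rr$mate1_spans | rr$mate2_spans)
    reads[[i]] <- rr
    truth[[i]] <- data.frame(
      circ_id = tpl$circ_id, chrom = tpl$chrom, start = tpl$start,
      end = tpl$end, strand = tpl$strand, spliced_length = L,
      genomic_span = tpl$genomic_span, support_pairs = supp,
      total_pairs = nrow(rr), stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}

# Fragment starts conditioned on junction crossing: exactly n_support
# supporting pairs, each drawn uniformly from the spanning-start set of its
# fragment length.
draw_conditioned <- function(tpl, n_support, config) {
  L <- tpl$spliced_length
  flens <- draw_fragment_len(n_support, config)
  starts <- integer(n_support)
  if (n_support > 0) {
    if (config$insert_sd == 0) {
      ok <- spanning_starts(L, flens[1L], config$read_len)
      starts <- ok[sample.int(length(ok), n_support, replace = TRUE)]
    } else {
      for (j in seq_len(n_support)) {
        ok <- spanning_starts(L, flens[j], config$read_len)
        starts[j] <- ok[sample.int(length(ok), 1L)]
      }
    }
  }
  list(starts = starts, flens = flens)
}

#' Inject substitution errors and emit quality strings
#'
#' Each base is substituted independently with probability `error_rate`,
#' uniformly among the 3 alternative bases; N bases are never mutated.
#' Quality is a constant Phred character: round(-10 log10(error_rate))
#' (Phred 20 at 1%), Phred 40 when the rate is 0.
#'
#' @param seq character vector of sequences.
#' @param error_rate per-base substitution probability in [0, 1).
#' @return list with `seq` (mutated sequences) and `qual` (quality strings).
#' @export
inject_errors <- function(seq, error_rate) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  qual <- strrep(phred_char(error_rate), nchar(seq))
  if (error_rate == 0 || length(seq) == 0) return(list(seq = seq, qual = qual))
  bases <- c("A", "C", "G", "T")
  alt <- matrix(c("C", "G", "T",   # alternatives to A
                  "A", "G", "T",   # C
                  "A", "C", "T",   # G
                  "A", "C", "G"),  # T
                nrow = 3L)
  mutate_block <- function(ss) {
    # equal-length block: vectorized over a base matrix
    n <- nchar(ss[1L])
    m <- matrix(unlist(strsplit(ss, "", fixed = TRUE), use.names = FALSE),
                nrow = n)
    hit <- which(stats::runif(length(m)) < error_rate & m != "N")
    if (length(hit)) {
      k <- sample.int(3L, length(hit), replace = TRUE)
      m[hit] <- alt[cbind(k, match(m[hit], bases))]
    }
    if (length(ss) == 1L) return(paste(m, collapse = ""))
    do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
  }
  out <- character(length(seq))
  for (len in unique(nchar(seq))) {
    idx <- which(nchar(seq) == len)
    out[idx] <- mutate_block(seq[idx])
  }
  list(seq = out, qual = qual)
}

#' Mix positive and background FASTQ pairs
#'
#' Concatenates two paired FASTQ datasets; read ids must be disjoint, and
#' the truth of the mixture is the positive truth unchanged.
#'
#' @param positive_pair,background_pair character(2): mate-1 and mate-2 files.
#' @param out_pair character(2): output mate-1 and mate-2 files.
#' @return `out_pair`, invisibly.
#' @export
mix_datasets <- function(positive_pair, background_pair, out_pair) {
  pos <- read_fastq_pair(positive_pair[1], positive_pair[2])
  bg <- read_fastq_pair(background_pair[1], background_pair[2])
  if (length(intersect(pos$pair_id, bg$pair_id)) > 0) {
    stop("read id collision between positive and background datasets")
  }
  write_fastq_pair(rbind(pos, bg), out_pair[1], out_pair[2])
  invisible(out_pair)
}
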