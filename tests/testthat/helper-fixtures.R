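# Shared test helpers: a cached desk-scale fixture, independent brute-force
# oracles, and small constructors.

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- make_fixture(fixture_spec(
      n_chromosomes = 2, chrom_length = 120000, n_genes = 8,
      n_circles = 12, circle_span = c(51, 20000), seed = 101))
  }
  .fixture_cache$fx
}

fixture_templates <- function(fx = small_fixture()) {
  lapply(seq_len(nrow(fx$circles)), function(i)
    build_circular_template(fx$circles[i, ], fx$exons, fx$genome))
}

# a bare circular template from an explicit sequence
template_from_seq <- function(seq, circ_id = "c1", chrom = "chr1", start = 0) {
  structure(list(circ_id = circ_id, chrom = chrom, start = start,
                 end = start + nchar(seq), strand = "+",
                 exons = data.frame(start = start, end = start + nchar(seq)),
                 sequence = seq, spliced_length = nchar(seq),
                 genomic_span = nchar(seq)),
            class = "circular_template")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Independent quadratic matcher: for every prediction, scan every truth row.
brute_match <- function(preds, truth, tolerance = 0, strict_strand = FALSE) {
  vapply(seq_len(nrow(preds)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(truth))) {
      same_chr <- preds$chrom[i] == truth$chrom[j]
      same_str <- !strict_strand || preds$strand[i] == truth$strand[j]
      if (same_chr && same_str &&
          abs(preds$start[i] - truth$start[j]) <= tolerance &&
          abs(preds$end[i] - truth$end[j]) <= tolerance) hit <- TRUE
    }
    hit
  }, logical(1))
}

# Exhaustive-offset junction-crossing oracle: enumerate every integer start
# on the circle and walk the positions a mate covers, looking for the
# L-1 -> 0 transition. Independent of the package's modular-arithmetic test.
oracle_span_fraction <- function(L, frag_len, read_len) {
  crosses <- function(s0) {
    pos <- (s0 + seq_len(read_len) - 1L) %% L
    any(pos[-length(pos)] == L - 1L & pos[-1L] == 0L)
  }
  hits <- vapply(0:(L - 1L), function(s) {
    m2s <- (s + frag_len - read_len) %% L
    crosses(s) || crosses(m2s)
  }, logical(1))
  mean(hits)
}

make_preds <- function(chrom, start, end, support, strand = "+",
                       tool = "toolX") {
  data.frame(tool = rep(tool, length(chrom)),
             circ_id = if (length(chrom)) paste0(chrom, ":", start, "-", end)
                       else character(0),
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = rep(strand, length.out = length(chrom)),
             support = as.integer(support),
             stringsAsFactors = FALSE)
}

truth_as_predictions <- function(truth, tool = "truth") {
  data.frame(tool = tool, circ_id = truth$circ_id, chrom = truth$chrom,
             start = truth$start, end = truth$end, strand = truth$strand,
             support = truth$support_pairs, stringsAsFactors = FALSE)
}
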