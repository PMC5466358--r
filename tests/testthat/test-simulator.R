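test_that("circular templates splice exons, fall back to the interval, and respect strand", {
  genome <- c(chr1 = paste(rep(c("ACGTTGCAAT"), 3), collapse = ""))  # 30 bp
  tx <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                   strand = "+", start = c(0L, 20L), end = c(10L, 30L),
                   stringsAsFactors = FALSE)
  circ <- list(circ_id = "c1", chrom = "chr1", start = 0L, end = 30L, strand = "+")
  tpl <- build_circular_template(circ, tx, genome)
  expect_identical(tpl$spliced_length, 20L)
  expect_identical(tpl$genomic_span, 30L)
  expect_identical(tpl$sequence,
                   paste0(substr(genome, 1, 10), substr(genome, 21, 30)))

  circ$strand <- "-"
  tpl_minus <- build_circular_template(circ, tx, genome)
  expect_identical(tpl_minus$sequence, revcomp(tpl$sequence))

  # no overlapping transcript: the whole interval is one exon
  naked <- build_circular_template(
    list(circ_id = "c2", chrom = "chr1", start = 5L, end = 25L, strand = "+"),
    NULL, genome)
  expect_identical(naked$spliced_length, naked$genomic_span)
  expect_identical(naked$spliced_length, 20L)

  expect_error(build_circular_template(
    list(circ_id = "c3", chrom = "chr1", start = 5L, end = 500L, strand = "+"),
    tx, genome), "bounds")
})

test_that("the maximally overlapping transcript defines the exon structure", {
  genome <- c(chr1 = random_seq(1000))
  tx <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    transcript_id = c("t1", "t1", "t2"), chrom = "chr1", strand = "+",
    start = c(100L, 300L, 100L), end = c(200L, 400L, 150L),
    stringsAsFactors = FALSE)
  tpl <- build_circular_template(
    list(circ_id = "c", chrom = "chr1", start = 100L, end = 400L, strand = "+"),
    tx, genome)
  # t1 overlaps 200 bp, t2 only 50: exons of t1 are used
  expect_identical(nrow(tpl$exons), 2L)
  expect_identical(tpl$spliced_length, 200L)
})

test_that("fragment starts are uniform on the circle and seeded draws repeat", {
  set.seed(11)
  s <- sample_fragment_start(100L, n = 5000L)
  expect_true(all(s >= 0 & s <= 99))
  expect_gt(stats::chisq.test(table(cut(s, breaks = seq(0, 100, 20))))$p.value, 1e-4)
  set.seed(42); a <- sample_fragment_start(1000L, n = 20L)
  set.seed(42); b <- sample_fragment_start(1000L, n = 20L)
  expect_identical(a, b)
})

test_that("rolling-circle geometry forces junction crossing on small circles", {
  # L = 100 with 350-bp fragments: both mates always cross
  tpl <- template_from_seq(random_seq(100))
  cfg <- sim_config(coverage = 60, seed = 3, min_support = 0L,
                    max_support = .Machine$integer.max)
  sim <- simulate_circ_reads(list(tpl), cfg)
  expect_true(all(sim$reads$mate1_spans))
  expect_true(all(sim$reads$mate2_spans))
  expect_identical(sim$truth$support_pairs, sim$truth$total_pairs)

  # L = 80 < read_len: every mate wraps and spans
  tpl80 <- template_from_seq(random_seq(80))
  sim80 <- simulate_circ_reads(list(tpl80),
                               sim_config(coverage = 60, seed = 4, min_support = 0L,
                                          max_support = .Machine$integer.max))
  expect_identical(sim80$truth$support_pairs, sim80$truth$total_pairs)
  expect_gt(sim80$truth$total_pairs, 0L)

  # hand geometry: L = 10000, start 9990 -> mate1 crosses the junction
  sp <- circbench:::mate_spans_junction(9990L, 350L, 101L, 10000L)
  expect_true(sp[, "mate1"])
  sp2 <- circbench:::mate_spans_junction(5000L, 350L, 101L, 10000L)
  expect_false(any(sp2))
})

test_that("target-support mode realizes exactly the requested junction support", {
  tpl <- template_from_seq(random_seq(100))
  sim <- simulate_circ_reads(list(tpl), sim_config(target_support = 5, seed = 5))
  expect_identical(sim$truth$support_pairs, 5L)

  # per-template targets
  tpls <- list(template_from_seq(random_seq(150), "a"),
               template_from_seq(random_seq(3000), "b"))
  sim2 <- simulate_circ_reads(tpls, sim_config(target_support = c(2L, 24L), seed = 6))
  expect_identical(sim2$truth$support_pairs, c(2L, 24L))
})

test_that("coverage mode keeps realized support within the admissible range", {
  fx <- small_fixture()
  tpls <- fixture_templates(fx)
  sim <- simulate_circ_reads(tpls, sim_config(coverage = 1, seed = 8))
  expect_true(all(sim$truth$support_pairs >= 2 & sim$truth$support_pairs <= 24))
})

test_that("recorded junction flags agree with recomputation from fragment coordinates", {
  fx <- small_fixture()
  tpls <- fixture_templates(fx)
  sim <- simulate_circ_reads(tpls, sim_config(coverage = 2, seed = 9))
  for (tpl in tpls) {
    rr <- sim$reads[sim$reads$origin == tpl$circ_id, , drop = FALSE]
    sp <- circbench:::mate_spans_junction(rr$frag_start, rr$frag_len, 101L,
                                          tpl$spliced_length)
    expect_identical(rr$mate1_spans, unname(sp[, "mate1"]))
    expect_identical(rr$mate2_spans, unname(sp[, "mate2"]))
    k <- sim$truth$support_pairs[sim$truth$circ_id == tpl$circ_id]
    expect_identical(sum(sp[, 1] | sp[, 2]), as.integer(k))
  }
})

test_that("error-free mates sit where the fragment coordinates say (string-search oracle)", {
  tpls <- list(template_from_seq(random_seq(500), "a"),
               template_from_seq(random_seq(1200), "b"))
  cfg <- sim_config(coverage = 10, error_rate = 0, seed = 10, min_support = 0L,
                    max_support = .Machine$integer.max)
  sim <- simulate_circ_reads(tpls, cfg)
  for (tpl in tpls) {
    rr <- sim$reads[sim$reads$origin == tpl$circ_id, , drop = FALSE]
    J <- junction_substring(tpl$sequence, 100L)  # read_len - 1 per side
    m2_fwd <- revcomp(rr$mate2_seq)              # back to template orientation
    for (i in seq_len(nrow(rr))) {
      if (rr$mate1_spans[i]) expect_true(grepl(rr$mate1_seq[i], J, fixed = TRUE))
      else expect_true(grepl(rr$mate1_seq[i], tpl$sequence, fixed = TRUE))
      if (rr$mate2_spans[i]) expect_true(grepl(m2_fwd[i], J, fixed = TRUE))
      else expect_true(grepl(m2_fwd[i], tpl$sequence, fixed = TRUE))
    }
  }
})

test_that("empirical junction-support fraction matches the exhaustive-offset oracle", {
  L <- 1500L
  tpl <- template_from_seq(random_seq(L))
  cfg <- sim_config(coverage = 40, seed = 12, min_support = 0L,
                    max_support = .Machine$integer.max)
  sim <- simulate_circ_reads(list(tpl), cfg)
  n <- sim$truth$total_pairs
  p_hat <- sim$truth$support_pairs / n
  p <- oracle_span_fraction(L, 350L, 101L)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("substitution errors follow the configured rate and quality encoding", {
  s <- random_seq(50)
  out <- inject_errors(s, 0)
  expect_identical(out$seq, s)
  expect_identical(out$qual, strrep("I", 50))   # Phred 40
  expect_error(inject_errors(s, 1), "\\[0, 1\\)")
  expect_identical(phred_char(0.01), "5")       # Phred 20

  set.seed(13)
  long <- random_seq(2e5)
  mut <- inject_errors(long, 0.01)$seq
  mism <- sum(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(mism - 2e3), 3 * sqrt(2e5 * 0.01 * 0.99))

  # N bases are never mutated
  set.seed(14)
  outN <- inject_errors(strrep("N", 1000), 0.5)$seq
  expect_identical(outN, strrep("N", 1000))
})

test_that("realized support scales with coverage at fixed spliced length", {
  tpl <- template_from_seq(random_seq(2000))
  covs <- c(2, 4, 8, 16, 24, 32, 48, 64)
  supp <- vapply(seq_along(covs), function(i) {
    cfg <- sim_config(coverage = covs[i], seed = 100 + i, min_support = 0L,
                      max_support = .Machine$integer.max)
    simulate_circ_reads(list(tpl), cfg)$truth$support_pairs
  }, integer(1))
  expect_gt(stats::cor(covs, supp, method = "spearman"), 0.95)
})

test_that("identical configuration gives byte-identical FASTQ and truth files", {
  fx <- small_fixture()
  tpls <- fixture_templates(fx)[1:5]
  run <- function(dir) {
    cfg <- sim_config(target_support = c(3L, 5L, 2L, 9L, 24L), seed = 99)
    sim <- simulate_circ_reads(tpls, cfg)
    write_fastq_pair(sim$reads, file.path(dir, "r1.fastq"), file.path(dir, "r2.fastq"))
    write_truth(sim$truth, file.path(dir, "truth.tsv"))
    vapply(file.path(dir, c("r1.fastq", "r2.fastq", "truth.tsv")),
           function(f) unname(tools::md5sum(f)), "")
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  expect_identical(unname(run(d1)), unname(run(d2)))
})

test_that("mixing datasets concatenates pairs, forbids id collisions, and preserves truth", {
  fx <- small_fixture()
  tpls <- fixture_templates(fx)
  sim <- simulate_circ_reads(tpls, sim_config(target_support = 3, seed = 21))
  d <- withr::local_tempdir()
  pos <- file.path(d, c("p1.fastq", "p2.fastq"))
  write_fastq_pair(sim$reads, pos[1], pos[2])

  bg <- simulate_background(fx$mrna[nchar(fx$mrna) > 350][1:2],
                            background_config(fold_coverage = 2, seed = 22))
  bgf <- file.path(d, c("b1.fastq", "b2.fastq"))
  write_fastq_pair(bg, bgf[1], bgf[2])

  mixed <- file.path(d, c("m1.fastq", "m2.fastq"))
  mix_datasets(pos, bgf, mixed)
  got <- read_fastq_pair(mixed[1], mixed[2])
  expect_identical(nrow(got), nrow(sim$reads) + nrow(bg))

  # truth-as-predictions scores identically on positive and mixed data
  preds <- truth_as_predictions(sim$truth)
  cm <- confusion(preds, sim$truth, min_support = 2)
  expect_identical(cm$n_tp, cm$n_detected)

  # empty background leaves the positive dataset unchanged
  emp <- file.path(d, c("e1.fastq", "e2.fastq"))
  write_fastq_pair(sim$reads[0, ], emp[1], emp[2])
  out2 <- file.path(d, c("o1.fastq", "o2.fastq"))
  mix_datasets(pos, emp, out2)
  expect_identical(read_fastq_pair(out2[1], out2[2]),
                   read_fastq_pair(pos[1], pos[2]))

  expect_error(mix_datasets(pos, pos, mixed), "collision")
})
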