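# Deterministic toy-fixture generator: a random genome, multi-exon gene
# models, exon-bounded circRNA junctions and spliced mRNAs, so every pipeline
# stage runs at desk scale without downloads. It emulates a CircBase-style
# input list: exonic circles with genomic spans from tens of bp up to tens
# of kb and junction support in the 2-24 pair range.

#' Fixture specification
#'
#' @param n_chromosomes number of random chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_genes number of genes (one transcript each), spread round-robin
#'   over chromosomes.
#' @param exons_per_gene length-2 range of exon counts per gene.
#' @param n_circles number of exon-bounded circRNAs to draw.
#' @param circle_span length-2 admissible genomic span range in bp.
#' @param support_range length-2 junction-support range (pairs per circle).
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chromosomes = 2L, chrom_length = 200000L,
                         n_genes = 20L, exons_per_gene = c(3L, 8L),
                         n_circles = 50L, circle_span = c(51L, 50000L),
                         support_range = c(2L, 24L), seed = 20160830L) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 1000, n_genes >= 1,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
            diff(exons_per_gene) >= 0, n_circles >= 0,
            length(circle_span) == 2, circle_span[1] >= 1,
            diff(circle_span) >= 0, length(support_range) == 2,
            support_range[1] >= 0, diff(support_range) >= 0)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 n_circles = as.integer(n_circles),
                 circle_span = as.integer(circle_span),
                 support_range = as.integer(support_range),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a deterministic toy fixture
#'
#' Builds a random genome, gene models with multi-exon transcripts, circRNAs
#' chosen as exon-bounded sub-intervals of transcripts, and spliced linear
#' mRNAs for the background simulator. Fully deterministic under the spec
#' seed. When `out_dir` is given, writes genome.fa, genes.gtf, circles.bed
#' and mrna.fa there.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional output directory (created if missing).
#' @return list with `genome` (named character), `exons` (data.frame),
#'   `circles` (data.frame), `mrna` (named character), `spec`, and `paths`
#'   when files were written.
#' @export
make_fixture <- function(spec = fixture_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genome <- stats::setNames(
    vapply(seq_len(spec$n_chromosomes), function(i) random_dna(spec$chrom_length), ""),
    paste0("chr", seq_len(spec$n_chromosomes)))

  # genes laid out left to right, round-robin over chromosomes
  cursor <- stats::setNames(rep(1000L, spec$n_chromosomes), names(genome))
  ex_rows <- list()
  for (g in seq_len(spec$n_genes)) {
    chrom <- names(genome)[((g - 1L) %% spec$n_chromosomes) + 1L]
    n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
    ex_len <- sample(80:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(100:2000, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- cursor[[chrom]] + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    if (ends[n_ex] + 1000L > spec$chrom_length) {
      stop("infeasible fixture spec: gene ", g, " does not fit on ", chrom,
           " (chrom_length too small for n_genes/exons_per_gene)")
    }
    cursor[[chrom]] <- ends[n_ex] + 1000L
    gid <- sprintf("gene%03d", g)
    ex_rows[[g]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = chrom,
      strand = if (g %% 2L == 0L) "-" else "+",
      start = starts, end = ends, stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, ex_rows)

  circles <- data.frame(circ_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  if (spec$n_circles > 0) {
    tx_ids <- unique(exons$transcript_id)
    got <- 0L
    rows <- list()
    seen <- character(0)
    for (attempt in seq_len(200L * spec$n_circles)) {
      if (got >= spec$n_circles) break
      tx <- exons[exons$transcript_id == sample(tx_ids, 1L), , drop = FALSE]
      ij <- sort(sample.int(nrow(tx), 2L, replace = TRUE))
      start <- tx$start[ij[1]]; end <- tx$end[ij[2]]
      span <- end - start
      if (span < spec$circle_span[1] || span > spec$circle_span[2]) next
      key <- paste(tx$chrom[1], start, end)
      if (key %in% seen) next
      seen <- c(seen, key)
      got <- got + 1L
      rows[[got]] <- data.frame(circ_id = sprintf("circ%03d", got),
                                chrom = tx$chrom[1], start = start, end = end,
                                strand = tx$strand[1], stringsAsFactors = FALSE)
    }
    if (got < spec$n_circles) {
      stop("infeasible fixture spec: only ", got, " of ", spec$n_circles,
           " circles satisfy circle_span = [", spec$circle_span[1], ", ",
           spec$circle_span[2], "] over the generated exon pairs")
    }
    circles <- do.call(rbind, rows)
  }

  mrna <- vapply(split(exons, exons$transcript_id), function(tx) {
    s <- paste(substr(rep(genome[[tx$chrom[1]]], nrow(tx)),
                      tx$start + 1L, tx$end), collapse = "")
    if (tx$strand[1] == "-") revcomp(s) else s
  }, "")

  out <- list(genome = genome, exons = exons, circles = circles,
              mrna = mrna, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("genome.fa", "genes.gtf", "circles.bed", "mrna.fa"))
    names(paths) <- c("genome", "gtf", "circles", "mrna")
    write_fasta(genome, paths[["genome"]])
    write_gtf_exons(exons, paths[["gtf"]])
    write_circ_bed(circles, paths[["circles"]])
    write_fasta(mrna, paths[["mrna"]])
    out$paths <- paths
  }
  out
}

#' Run the full pipeline on a toy fixture
#'
#' fixture -> circular-read simulation -> background simulation -> mixing ->
#' evaluation (truth-as-predictions and a 1-bp-shift perturbation) ->
#' overlap and RNase-R style analyses on two seeded pseudo-samples. Writes
#' FASTQ/truth files plus a single JSON report under `out_dir`.
#'
#' @param spec a [fixture_spec()]; defaults to a small desk-scale fixture.
#' @param out_dir output directory.
#' @param bg_coverage background fold coverage (desk-scale default 20).
#' @param perturb_frac fraction of truth junctions shifted by 1 bp to form
#'   the imperfect pseudo-caller.
#' @return the report, invisibly (also written to report.json).
#' @export
end_to_end_demo <- function(spec = fixture_spec(), out_dir = tempfile("circbench_demo"),
                            bg_coverage = 20, perturb_frac = 0.1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_fixture(spec, out_dir)

  templates <- lapply(seq_len(nrow(fx$circles)), function(i)
    build_circular_template(fx$circles[i, ], fx$exons, fx$genome))

  set.seed(spec$seed + 1L)
  supports <- sample(spec$support_range[1]:spec$support_range[2],
                     length(templates), replace = TRUE)
  cfg <- sim_config(target_support = supports, seed = spec$seed + 2L)
  sim <- simulate_circ_reads(templates, cfg)
  pos_fq <- file.path(out_dir, c("positive_1.fastq", "positive_2.fastq"))
  write_fastq_pair(sim$reads, pos_fq[1], pos_fq[2])
  write_truth(sim$truth, file.path(out_dir, "positive.truth.tsv"))

  bcfg <- background_config(fold_coverage = bg_coverage, seed = spec$seed + 3L)
  bg <- simulate_background(fx$mrna, bcfg)
  bg_fq <- file.path(out_dir, c("background_1.fastq", "background_2.fastq"))
  write_fastq_pair(bg, bg_fq[1], bg_fq[2])

  mix_fq <- file.path(out_dir, c("mixed_1.fastq", "mixed_2.fastq"))
  mix_datasets(pos_fq, bg_fq, mix_fq)

  truth <- sim$truth
  perfect <- data.frame(tool = "truth", circ_id = truth$circ_id,
                        chrom = truth$chrom, start = truth$start,
                        end = truth$end, strand = truth$strand,
                        support = truth$support_pairs, stringsAsFactors = FALSE)
  cm_perfect <- confusion(perfect, truth, min_support = 1L)
  pr_perfect <- pr_curve(perfect, truth)

  set.seed(spec$seed + 4L)
  n_shift <- as.integer(round(perturb_frac * nrow(perfect)))
  shifted <- perfect
  idx <- sample.int(nrow(shifted), n_shift)
  shifted$start[idx] <- shifted$start[idx] + 1L
  shifted$end[idx] <- shifted$end[idx] + 1L
  cm_shift <- confusion(shifted, truth, min_support = 1L)

  # two pseudo-samples for the comparative analyses
  set.seed(spec$seed + 5L)
  sub <- function(frac) perfect[sort(sample.int(nrow(perfect),
                                     ceiling(frac * nrow(perfect)))), , drop = FALSE]
  sets <- list(methodA = sub(0.8), methodB = sub(0.7))
  ov <- overlap_matrix(lapply(sets, function(s) s[, c("chrom", "start", "end", "strand")]))

  treated <- perfect
  set.seed(spec$seed + 6L)
  keep <- stats::runif(nrow(treated)) < 0.7
  treated$support <- ifelse(keep, treated$support * 3L, 0L)
  treated <- treated[treated$support > 0, , drop = FALSE]
  enr <- classify_enrichment(perfect, treated, depth_u = 1e6, depth_t = 1e6)
  es <- enrichment_summary(enr)
  top10 <- top_n_summary(enr, 10L)

  report <- list(
    fixture = list(n_circles = nrow(fx$circles), n_genes = spec$n_genes,
                   genome_bp = sum(nchar(fx$genome))),
    simulation = list(positive_pairs = nrow(sim$reads),
                      background_pairs = nrow(bg),
                      support_min = min(truth$support_pairs),
                      support_max = max(truth$support_pairs)),
    truth_as_predictions = summary(cm_perfect),
    truth_as_predictions_auc = pr_perfect$auc,
    perturbed = c(summary(cm_shift), list(n_shifted = n_shift)),
    overlap_P = ov$P,
    rnase_r = list(percent_not_depleted = es$percentage,
                   n_domain = es$n_domain,
                   top10_enriched = top10$n_enriched),
    seed = spec$seed)
  write_metrics(report, file.path(out_dir, "report.json"))
  invisible(report)
}
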