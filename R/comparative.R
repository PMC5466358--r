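# Comparative analyses across detection methods on a shared sample:
# pairwise overlap proportions, RNase R depletion/enrichment classification
# with top-N summaries, read-level sensitivity matrices with UPGMA
# clustering, and validated-circRNA recovery.

#' Pairwise method-overlap proportions
#'
#' For methods i, j with candidate-set sizes N_i, N_j and common-candidate
#' count C(i,j), the proportion of method i's candidates shared with j is
#' P(i,j) = C(i,j) / N_i. Input sets are assumed already support-filtered.
#'
#' @param candidate_sets named list of data.frames (chrom, start, end,
#'   strand), one per method; duplicate junctions within a set are dropped.
#' @param tolerance matching slack in bp (0 = exact junctions).
#' @return object of class `overlap_matrix`: `methods`, `N`, matrices `C`
#'   and `P` (rows of P are NA for methods with N = 0).
#' @export
overlap_matrix <- function(candidate_sets, tolerance = 0L) {
  stopifnot(is.list(candidate_sets), !is.null(names(candidate_sets)))
  methods <- names(candidate_sets)
  sets <- lapply(candidate_sets, function(s) {
    if (nrow(s) == 0) return(s)
    s[!duplicated(junction_key(s$chrom, s$start, s$end)), , drop = FALSE]
  })
  n <- length(sets)
  N <- vapply(sets, nrow, integer(1))
  C <- matrix(0L, n, n, dimnames = list(methods, methods))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) N[i] else
        sum(match_predictions(sets[[i]], sets[[j]], tolerance))
    }
  }
  P <- C / N  # rows divide by the row method's N; N = 0 rows become NaN
  P[N == 0, ] <- NA_real_
  structure(list(methods = methods, N = N, C = C, P = P),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, digits = 3, ...) {
  cat("overlap proportions P(i,j) = C(i,j)/N_i (rows = method i):\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Classify candidates by RNase R depletion
#'
#' Junction read counts are normalized to counts per million sequenced read
#' pairs (CPM); the ratio of treated to untreated CPM classifies each
#' candidate as depleted (ratio < 1), not depleted (ratio >= 1) or enriched
#' (ratio >= 5). The domain is the candidates with support >= min_support in
#' the untreated sample; candidates absent from the treated sample get a raw
#' treated count of 0.
#'
#' @param untreated_preds,treated_preds prediction data.frames.
#' @param depth_u,depth_t total sequenced read pairs per sample (> 0).
#' @param min_support support filter applied to the untreated sample.
#' @return data.frame with one row per domain candidate: raw and normalized
#'   counts, ratio and class.
#' @export
classify_enrichment <- function(untreated_preds, treated_preds, depth_u,
                                depth_t, min_support = 2L) {
  if (depth_u <= 0 || depth_t <= 0) stop("sequencing depth must be > 0")
  dom <- untreated_preds[untreated_preds$support >= min_support, , drop = FALSE]
  tk <- junction_key(treated_preds$chrom, treated_preds$start, treated_preds$end)
  dk <- junction_key(dom$chrom, dom$start, dom$end)
  raw_t <- treated_preds$support[match(dk, tk)]
  raw_t[is.na(raw_t)] <- 0L
  norm_u <- dom$support * 1e6 / depth_u
  norm_t <- raw_t * 1e6 / depth_t
  ratio <- norm_t / norm_u
  class <- ifelse(ratio >= 5, "enriched",
                  ifelse(ratio >= 1, "not_depleted", "depleted"))
  data.frame(circ_id = dom$circ_id, chrom = dom$chrom, start = dom$start,
             end = dom$end, strand = dom$strand,
             raw_untreated = dom$support, raw_treated = raw_t,
             norm_untreated = norm_u, norm_treated = norm_t,
             ratio = ratio, class = class, stringsAsFactors = FALSE)
}

#' Summary of an enrichment classification
#'
#' @param records output of [classify_enrichment()].
#' @return list: domain size, count with ratio >= 1 (not depleted or
#'   enriched) and its percentage of the domain.
#' @export
enrichment_summary <- function(records) {
  n <- nrow(records)
  nd <- sum(records$ratio >= 1)
  list(n_domain = n, n_not_depleted = nd,
       percentage = if (n > 0) round(100 * nd / n, 2) else NA_real_)
}

#' Class counts among the top-N most highly expressed candidates
#'
#' Candidates are ranked by `rank_key` descending, ties broken by genomic
#' coordinate (chrom, start, end); classes are counted within the top n.
#'
#' @param records output of [classify_enrichment()].
#' @param n top-N cutoff (>= 1); with fewer records all are used and the
#'   result carries attribute `n_used`.
#' @param rank_key ranking column (default "norm_untreated").
#' @return list with `n_enriched` (ratio >= 5) and `n_not_depleted`
#'   (ratio >= 1).
#' @export
top_n_summary <- function(records, n, rank_key = "norm_untreated") {
  stopifnot(n >= 1, rank_key %in% names(records))
  o <- order(-records[[rank_key]], records$chrom, records$start, records$end)
  top <- records[o, , drop = FALSE][seq_len(min(n, nrow(records))), , drop = FALSE]
  out <- list(n_enriched = sum(top$ratio >= 5),
              n_not_depleted = sum(top$ratio >= 1))
  attr(out, "n_used") <- nrow(top)
  out
}

#' Read-level sensitivity matrix
#'
#' Rows are methods and columns the candidates detected by every method
#' (when `common_only`); candidates whose spliced length is smaller than the
#' insert size are excluded, and values are log2(support + 1).
#'
#' @param per_method_preds named list of prediction data.frames.
#' @param spliced_lengths data.frame with chrom, start, end and
#'   spliced_length (e.g. a simulation truth table).
#' @param insert_size library insert size in bp used for the exclusion rule.
#' @param common_only keep only candidates detected by all methods.
#' @return numeric matrix (methods x candidates); empty with a warning when
#'   no candidate survives.
#' @export
read_level_matrix <- function(per_method_preds, spliced_lengths, insert_size,
                              common_only = TRUE) {
  stopifnot(is.list(per_method_preds), !is.null(names(per_method_preds)))
  keys <- lapply(per_method_preds, function(p)
    junction_key(p$chrom, p$start, p$end))
  common <- Reduce(if (common_only) intersect else union, keys)
  slk <- junction_key(spliced_lengths$chrom, spliced_lengths$start,
                      spliced_lengths$end)
  sl <- spliced_lengths$spliced_length[match(common, slk)]
  common <- common[!is.na(sl) & sl >= insert_size]
  if (length(common) == 0) {
    warning("no common candidates left after the spliced-length filter")
    return(matrix(numeric(0), nrow = length(per_method_preds), ncol = 0,
                  dimnames = list(names(per_method_preds), NULL)))
  }
  m <- vapply(per_method_preds, function(p) {
    s <- p$support[match(common, junction_key(p$chrom, p$start, p$end))]
    s[is.na(s)] <- 0L
    log2(s + 1)
  }, numeric(length(common)))
  m <- t(m)
  colnames(m) <- common
  m
}

#' Convert once-per-pair junction counts to the counted-twice convention
#'
#' Some callers count a read pair once however many of its mates span the
#' junction, others count each spanning mate; the conversion adds one per
#' pair whose both mates span. With per-pair flags the conversion is exact;
#' without them, a documented approximation doubles the count for circles
#' whose spliced length is below the insert size (geometry then forces both
#' mates across the junction).
#'
#' @param support_once once-per-pair support count(s).
#' @param n_both_span number of pairs with both mates spanning (exact path).
#' @param spliced_length,insert_size approximation path inputs when
#'   `n_both_span` is NULL.
#' @return support under the counted-twice convention (never smaller than
#'   `support_once`).
#' @export
convert_pair_counting <- function(support_once, n_both_span = NULL,
                                  spliced_length = NULL, insert_size = NULL) {
  stopifnot(all(support_once >= 0))
  if (!is.null(n_both_span)) {
    stopifnot(all(n_both_span >= 0), all(n_both_span <= support_once))
    return(support_once + n_both_span)
  }
  if (is.null(spliced_length) || is.null(insert_size)) {
    stop("supply n_both_span, or spliced_length and insert_size")
  }
  ifelse(spliced_length < insert_size, 2L * support_once, support_once)
}

#' Cluster methods by their read-level profiles
#'
#' Agglomerative average-linkage (UPGMA) clustering of the rows of a
#' read-level matrix under Euclidean distance.
#'
#' @param matrix numeric matrix, methods in rows (>= 2 rows).
#' @return `hclust` object; serialize with [cluster_newick()].
#' @export
cluster_methods <- function(matrix) {
  if (nrow(matrix) < 2) stop("need at least 2 methods to cluster")
  stats::hclust(stats::dist(matrix, method = "euclidean"), method = "average")
}

#' Newick serialization of a method dendrogram
#'
#' @param hc `hclust` object from [cluster_methods()].
#' @return single newick string with merge heights as branch lengths.
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Recovery of experimentally validated circRNAs
#'
#' @param preds prediction data.frame.
#' @param validated data.frame of validated junctions (chrom, start, end).
#' @param tolerance matching slack in bp.
#' @return named integer vector: `n_ge1` and `n_ge2`, the validated
#'   junctions matched by predictions with support >= 1 and >= 2.
#' @export
validated_recovery <- function(preds, validated, tolerance = 0L) {
  count_at <- function(min_support) {
    det <- preds[preds$support >= min_support, , drop = FALSE]
    sum(match_predictions(validated, det, tolerance))
  }
  c(n_ge1 = count_at(1L), n_ge2 = count_at(2L))
}
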