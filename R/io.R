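# File formats. One coordinate convention everywhere: 0-based half-open
# (BED-style). GTF (1-based closed) is converted on read, and back on write.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences, one per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(stats::setNames(character(0), character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[nonblank[1]]) {
    stop("FASTA format error at line ", nonblank[1], ": expected '>' header")
  }
  # headers with empty names, or headers followed by no sequence
  for (i in which(hdr)) {
    if (!nzchar(trimws(sub("^>", "", lines[i])))) {
      stop("FASTA format error at line ", i, ": empty record name")
    }
    nxt <- if (i == length(lines)) "" else lines[i + 1L]
    if (i == length(lines) || startsWith(nxt, ">") || !nzchar(trimws(nxt))) {
      stop("FASTA format error at line ", i, ": record has empty sequence")
    }
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("FASTA format error: duplicate record name '",
         names(seqs)[duplicated(names(seqs))][1], "'")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read exon models from a GTF file
#'
#' Keeps `exon` features only, groups them by transcript and converts the
#' GTF 1-based closed coordinates to 0-based half-open.
#'
#' @param path GTF file with gene_id and transcript_id attributes.
#' @return data.frame with columns gene_id, transcript_id, chrom, strand,
#'   start, end; exons sorted by start within transcript.
#' @export
read_gtf_exons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF format error: ", conditionMessage(e))
  )
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (!all(strand %in% c("+", "-"))) {
    stop("GTF format error: unknown strand symbol '",
         strand[!strand %in% c("+", "-")][1], "' on an exon feature")
  }
  ex <- data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr) - 1L,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(ex$end <= ex$start)) stop("GTF format error: exon with end <= start")
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
  for (tx in split(ex, ex$transcript_id)) {
    if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L) {
      stop("GTF format error: transcript '", tx$transcript_id[1],
           "' spans multiple chromosomes or strands")
    }
    if (nrow(tx) > 1L && any(tx$start[-1L] < tx$end[-nrow(tx)])) {
      stop("GTF format error: transcript '", tx$transcript_id[1],
           "' has overlapping exons")
    }
  }
  rownames(ex) <- NULL
  ex
}

#' Write exon models to GTF
#'
#' @param exons data.frame as returned by [read_gtf_exons()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf_exons <- function(exons, path) {
  lines <- sprintf(
    '%s\tcircbench\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a circRNA junction list (BED6)
#'
#' @param path BED file, 0-based half-open; columns chrom, start, end
#'   (optionally name, score, strand).
#' @return data.frame with columns circ_id, chrom, start, end, strand.
#' @export
read_circ_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) return(empty)
  if (ncol(raw) < 3) stop("BED format error: fewer than 3 columns")
  out <- data.frame(
    circ_id = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      paste0(raw[[1]], ":", raw[[2]], "-", raw[[3]]),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    stop("BED format error: non-numeric coordinates")
  }
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("BED format error: requires 0 <= start < end")
  }
  if (!all(out$strand %in% c("+", "-", "."))) {
    stop("BED format error: unknown strand symbol")
  }
  out
}

#' Write a circRNA junction list to BED6
#'
#' @param circs data.frame with circ_id, chrom, start, end, strand.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(circs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   circs$chrom, circs$start, circs$end, circs$circ_id,
                   circs$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a prediction table from one detection method
#'
#' Accepts either a header-bearing TSV (columns chrom, start, end, circ_id,
#' support, strand) or a headerless BED-like file with the junction read
#' count in column 5. Duplicate junctions (same chrom, start, end, strand)
#' are merged by summing support, with a warning.
#'
#' @param path prediction file, 0-based half-open coordinates.
#' @param tool method name attached to every record.
#' @return data.frame with columns tool, circ_id, chrom, start, end, strand,
#'   support.
#' @export
read_predictions <- function(path, tool) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  empty <- data.frame(tool = character(0), circ_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      support = integer(0), stringsAsFactors = FALSE)
  if (length(first) == 0 || !nzchar(first)) return(empty)
  has_header <- grepl("^chrom\t", first)
  raw <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0) return(empty)
  if (has_header) {
    need <- c("chrom", "start", "end", "support")
    if (!all(need %in% names(raw))) {
      stop("prediction format error: missing column(s) ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    }
    out <- data.frame(
      tool = tool,
      circ_id = if ("circ_id" %in% names(raw)) as.character(raw$circ_id) else
        paste0(raw$chrom, ":", raw$start, "-", raw$end),
      chrom = as.character(raw$chrom),
      start = as.integer(raw$start), end = as.integer(raw$end),
      strand = if ("strand" %in% names(raw)) as.character(raw$strand) else ".",
      support = as.integer(raw$support),
      stringsAsFactors = FALSE
    )
  } else {
    if (ncol(raw) < 5) {
      stop("prediction format error: need >= 5 columns (support in column 5)")
    }
    out <- data.frame(
      tool = tool,
      circ_id = as.character(raw[[4]]),
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
      strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else ".",
      support = as.integer(raw[[5]]),
      stringsAsFactors = FALSE
    )
  }
  if (any(is.na(out$support)) || any(out$support < 0)) {
    stop("prediction format error: support must be a non-negative integer")
  }
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("prediction format error: requires 0 <= start < end")
  }
  key <- paste(out$chrom, out$start, out$end, out$strand, sep = ":")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    supp <- tapply(out$support, key, sum)
    keep <- out[!duplicated(key), , drop = FALSE]
    keep$support <- as.integer(supp[paste(keep$chrom, keep$start, keep$end,
                                          keep$strand, sep = ":")])
    warning(n_dup, " duplicate junction row(s) in '", path,
            "' merged by summing support")
    out <- keep
  }
  rownames(out) <- NULL
  out
}

#' Write a prediction table
#'
#' @param preds data.frame as returned by [read_predictions()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(
    preds[, c("chrom", "start", "end", "circ_id", "support", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write paired-end reads to two FASTQ files
#'
#' Mate ids are suffixed /1 and /2. Identical input yields byte-identical
#' output.
#'
#' @param reads data.frame with pair_id, mate1_seq, mate2_seq, mate1_qual,
#'   mate2_qual (as produced by the simulators).
#' @param path1,path2 output FASTQ files for mate 1 and mate 2.
#' @return c(path1, path2), invisibly.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  stopifnot(is.data.frame(reads))
  if (length(reads$mate1_seq) != length(reads$mate2_seq)) {
    stop("mate1/mate2 lists differ in length")
  }
  write_one <- function(seqs, quals, ids, path) {
    if (length(seqs) == 0) {
      writeLines(character(0), path)
      return(invisible())
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  write_one(reads$mate1_seq, reads$mate1_qual, paste0(reads$pair_id, "/1"), path1)
  write_one(reads$mate2_seq, reads$mate2_qual, paste0(reads$pair_id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read paired-end reads from two FASTQ files
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return data.frame with pair_id, mate1_seq, mate2_seq, mate1_qual,
#'   mate2_qual.
#' @export
read_fastq_pair <- function(path1, path2) {
  read_one <- function(path) {
    if (file.size(path) == 0) {
      return(list(id = character(0), seq = character(0), qual = character(0)))
    }
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(id = names(x), seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  m1 <- read_one(path1)
  m2 <- read_one(path2)
  if (length(m1$id) != length(m2$id)) stop("FASTQ mate files differ in length")
  id1 <- sub("/1$", "", m1$id)
  id2 <- sub("/2$", "", m2$id)
  if (!identical(id1, id2)) stop("FASTQ mate files have mismatched pair ids")
  data.frame(pair_id = id1,
             mate1_seq = unname(m1$seq), mate2_seq = unname(m2$seq),
             mate1_qual = unname(m1$qual), mate2_qual = unname(m2$qual),
             stringsAsFactors = FALSE)
}

#' Write and read the simulation truth table
#'
#' Header-bearing TSV with one row per simulated circRNA: realized
#' junction-supporting pair count (each pair counted once) and total pairs.
#'
#' @param truth data.frame with circ_id, chrom, start, end, strand,
#'   spliced_length, genomic_span, support_pairs, total_pairs.
#' @param path TSV file.
#' @return `path` (write) or the truth data.frame (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(truth$support_pairs <= truth$total_pairs),
            all(truth$spliced_length <= truth$genomic_span))
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a metrics report
#'
#' JSON for paths ending in .json (scalars unboxed, full precision),
#' otherwise a header-bearing TSV (the report must be a data.frame).
#'
#' @param report named list (JSON) or data.frame (TSV).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  } else {
    stopifnot(is.data.frame(report))
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
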