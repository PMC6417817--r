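#' A per-sample read set
#'
#' @param sample_id sample identifier (non-empty string).
#' @param reads character vector of read sequences (qualities are ignored
#'   throughout; matching is exact).
#' @return an object of class `kir_read_set`.
#' @export
kir_read_set <- function(sample_id, reads) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a non-empty string")
  reads <- as.character(reads)
  if (any(!nzchar(reads))) stop("empty read sequence")
  structure(list(sample_id = sample_id, reads = reads), class = "kir_read_set")
}

#' Read sample reads from FASTQ/FASTA
#'
#' @param path FASTQ or FASTA file, plain or gzipped.
#' @param sample_id sample identifier; defaults to the file name.
#' @param format `"auto"` guesses from the extension.
#' @return a [kir_read_set()].
#' @export
read_sample_reads <- function(path, sample_id = basename(path),
                              format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  kir_read_set(sample_id, as.character(seqs))
}

#' Extract candidate reads from an indexed BAM
#'
#' Pulls the sequences of all primary alignments overlapping a genomic
#' region (for the KIR locus: `chr19:54025634-55084318` on GRCh38) plus,
#' optionally, all unmapped reads. Secondary and supplementary alignments
#' are skipped; duplicate records of the same read segment (read name +
#' mate) are collapsed to one.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param region region string `"chr:start-end"` (1-based, inclusive).
#' @param include_unmapped also pull unmapped reads (default `TRUE`).
#' @param sample_id sample identifier; defaults to the BAM file name.
#' @return a [kir_read_set()].
#' @export
extract_candidate_reads <- function(bam, region, include_unmapped = TRUE,
                                    sample_id = basename(bam)) {
  gr <- GenomicRanges::GRanges(region)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  contig <- as.character(GenomicRanges::seqnames(gr))
  if (!contig %in% names(hdr))
    stop("contig '", contig, "' absent from BAM; available: ",
         paste(names(hdr), collapse = ", "))
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for '", bam, "'")

  what <- c("qname", "flag", "seq")
  mapped <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = what, which = gr,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  ))[[1]]
  qname <- mapped$qname
  flag <- mapped$flag
  seqs <- as.character(mapped$seq)

  if (include_unmapped) {
    un <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = what,
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    ))[[1]]
    qname <- c(qname, un$qname)
    flag <- c(flag, un$flag)
    seqs <- c(seqs, as.character(un$seq))
  }
  # one record per read segment: name + mate-of-pair bits (0x40 | 0x80)
  key <- paste(qname, bitwAnd(flag, 192L))
  keep <- !duplicated(key)
  kir_read_set(sample_id, seqs[keep])
}

#' Count unique and background k-mer occurrences in a read set
#'
#' Every length-k window of every read is canonicalized and, when present
#' in the combined index, counted; overlapping windows each count.
#' `reads_with_hit` counts, per gene, the reads containing at least one of
#' that gene's k-mers (each read counted once per gene).
#'
#' @param reads a [kir_read_set()].
#' @param index a `kir_kmer_index`.
#' @param background optionally a `kir_background_kmers` at the same k.
#' @return an object of class `kir_kmer_counts` with fields `sample_id`,
#'   `k`, `counts` (named integer vector over all indexed k-mers),
#'   `reads_with_hit` (named by gene) and `n_reads`.
#' @export
count_kmers <- function(reads, index, background = NULL) {
  stopifnot(inherits(reads, "kir_read_set"), inherits(index, "kir_kmer_index"))
  if (!is.null(background) && background$k != index$k)
    stop("background k (", background$k, ") does not match index k (", index$k, ")")
  per_gene <- index$per_gene
  if (!is.null(background)) per_gene <- c(per_gene, background$per_gene)
  genes <- names(per_gene)
  kmers <- unlist(per_gene, use.names = FALSE)
  gene_id <- rep(seq_along(per_gene), lengths(per_gene))

  if (length(kmers)) {
    res <- kmer_scan_cpp(reads$reads, kmers, gene_id, length(genes), index$k)
    counts <- stats::setNames(res$counts, kmers)
    hits <- stats::setNames(res$gene_hits, genes)
  } else {
    counts <- stats::setNames(integer(0), character(0))
    hits <- stats::setNames(integer(length(genes)), genes)
  }
  structure(
    list(sample_id = reads$sample_id, k = index$k, counts = counts,
         reads_with_hit = hits, n_reads = length(reads$reads)),
    class = "kir_kmer_counts"
  )
}

#' Per-gene mean k-mer counts
#'
#' For each gene holding at least one unique k-mer, the arithmetic mean of
#' its k-mers' occurrence counts (zero-count k-mers included). The mean,
#' rather than the sum, keeps genes with different k-mer richness on one
#' comparable frequency axis. Genes with no unique k-mers are absent.
#'
#' @param counts a [count_kmers()] result.
#' @param index the `kir_kmer_index` (or `kir_background_kmers`) whose
#'   genes to aggregate.
#' @return named numeric vector, gene -> mean per-k-mer count.
#' @export
aggregate_gene_counts <- function(counts, index) {
  stopifnot(inherits(counts, "kir_kmer_counts"))
  per_gene <- index$per_gene[lengths(index$per_gene) > 0L]
  vapply(per_gene, function(kms) mean(counts$counts[kms]), numeric(1))
}

#' Summed k-mer coverage over the KIR and background sets
#'
#' Total occurrence counts over the KIR unique-k-mer set and over the
#' background set, the quantities the cohort coverage filters act on.
#'
#' @param counts a [count_kmers()] result.
#' @param index the `kir_kmer_index`.
#' @param background the `kir_background_kmers`.
#' @return list with `kir_total` and `background_total`.
#' @export
coverage_totals <- function(counts, index, background) {
  kir_kmers <- unlist(index$per_gene, use.names = FALSE)
  bg_kmers <- unlist(background$per_gene, use.names = FALSE)
  list(
    kir_total = sum(counts$counts[kir_kmers]),
    background_total = sum(counts$counts[bg_kmers])
  )
}

#' Write per-sample k-mer counts as TSV
#'
#' @param counts a [count_kmers()] result.
#' @param index the index used (for the gene column).
#' @param path output TSV path.
#' @param background optional background set counted alongside.
#' @return `path`, invisibly.
#' @export
write_kmer_counts <- function(counts, index, path, background = NULL) {
  per_gene <- index$per_gene
  if (!is.null(background)) per_gene <- c(per_gene, background$per_gene)
  df <- data.frame(
    kmer = unlist(per_gene, use.names = FALSE),
    gene = rep(names(per_gene), lengths(per_gene)),
    stringsAsFactors = FALSE
  )
  df$count <- unname(counts$counts[df$kmer])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.kir_read_set <- function(x, ...) {
  cat("<kir_read_set>", x$sample_id, "-", length(x$reads), "reads\n")
  invisible(x)
}

#' @export
print.kir_kmer_counts <- function(x, ...) {
  cat("<kir_kmer_counts>", x$sample_id, "- k =", x$k, ",",
      length(x$counts), "k-mers,", x$n_reads, "reads\n")
  invisible(x)
}
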