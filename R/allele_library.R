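#' Construct an allele library
#'
#' An allele library maps each gene to its set of known allele sequences.
#' It is the reference over which k-mer uniqueness is evaluated: a k-mer is
#' unique to a gene only if it occurs (as itself or its reverse complement)
#' in every allele of that gene and in no allele of any other gene.
#'
#' @param genes named list; each element is a named character vector of
#'   allele sequences (names are allele identifiers).
#' @param source free-text provenance label.
#' @return an object of class `kir_allele_library`.
#' @export
kir_allele_library <- function(genes, source = "in-memory") {
  if (length(genes) == 0L) stop("allele library has no genes")
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("gene identifiers must be unique and non-empty")
  for (g in names(genes)) {
    al <- genes[[g]]
    if (length(al) == 0L) stop("gene '", g, "' has no alleles")
    if (is.null(names(al)) || anyDuplicated(names(al)))
      stop("allele identifiers within gene '", g, "' must be unique")
    if (any(!nzchar(al))) stop("gene '", g, "' contains an empty allele sequence")
    genes[[g]] <- toupper(al)
  }
  obj <- structure(
    list(genes = genes, source = source, checksum = NA_character_),
    class = "kir_allele_library"
  )
  obj$checksum <- library_checksum(obj)
  obj
}

library_checksum <- function(lib) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  lines <- unlist(lapply(names(lib$genes), function(g) {
    paste(g, names(lib$genes[[g]]), lib$genes[[g]], sep = "\t")
  }))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a multi-allele gene reference from FASTA
#'
#' Record headers are parsed into (gene, allele) with a regular expression
#' containing named capture groups `gene` and `allele`. The default matches
#' IPD-style headers of the form `GENE*allele`.
#'
#' @param path FASTA file (plain or gzipped).
#' @param header_pattern PCRE with named groups `gene` and `allele`.
#' @param min_allele_length drop allele records shorter than this before
#'   building the library (0 keeps everything, including partial entries).
#' @return a [kir_allele_library()].
#' @export
read_allele_library <- function(path,
                                header_pattern = "^(?<gene>[^*\\s]+)\\*(?<allele>\\S+)",
                                min_allele_length = 0L) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(seqs) == 0L) stop("no records in FASTA '", path, "'")
  headers <- names(seqs)
  m <- regexpr(header_pattern, headers, perl = TRUE)
  bad <- which(m == -1L)
  if (length(bad))
    stop("FASTA headers do not match the header pattern: ",
         paste(utils::head(headers[bad], 5L), collapse = ", "))
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  if (is.null(cs) || !all(c("gene", "allele") %in% colnames(cs)))
    stop("header pattern must define named capture groups 'gene' and 'allele'")
  gene <- substr(headers, cs[, "gene"], cs[, "gene"] + cl[, "gene"] - 1L)
  allele <- substr(headers, cs[, "allele"], cs[, "allele"] + cl[, "allele"] - 1L)
  key <- paste(gene, allele, sep = "*")
  if (anyDuplicated(key))
    stop("duplicate (gene, allele) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  seq_chr <- as.character(seqs)
  keep <- nchar(seq_chr) >= min_allele_length
  if (!any(keep)) stop("no allele records pass min_allele_length")
  # preserve gene order of first appearance and record order within gene
  genes <- split(stats::setNames(seq_chr[keep], allele[keep]),
                 factor(gene[keep], levels = unique(gene[keep])))
  kir_allele_library(lapply(genes, identity), source = path)
}

#' Write an allele library to FASTA
#'
#' Records are written as `GENE*ALLELE` headers, one per allele.
#'
#' @param library a [kir_allele_library()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_library <- function(library, path) {
  stopifnot(inherits(library, "kir_allele_library"))
  seqs <- unlist(lapply(names(library$genes), function(g) {
    stats::setNames(library$genes[[g]],
                    paste(g, names(library$genes[[g]]), sep = "*"))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
print.kir_allele_library <- function(x, ...) {
  cat("<kir_allele_library>", length(x$genes), "genes,",
      sum(lengths(x$genes)), "alleles\n")
  cat("  source:", x$source, "\n")
  invisible(x)
}
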