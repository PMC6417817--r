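#' Population gene frequencies from copy-number calls
#'
#' The gene frequency is the average gene copy number per haplotype: the
#' mean copy number over non-excluded samples divided by 2. "3+" cells are
#' counted as exactly 3. Genes with every cell excluded are omitted with a
#' warning.
#'
#' @param cn a `kir_copy_number` (or a plain integer matrix samples x genes
#'   with `NA` for excluded cells).
#' @return named numeric vector, gene -> frequency (in `[0, ~2]`).
#' @export
gene_frequencies <- function(cn) {
  m <- if (inherits(cn, "kir_copy_number")) cn$calls else cn
  freq <- colMeans(m, na.rm = TRUE) / 2
  empty <- !is.finite(freq)
  if (any(empty)) {
    warning("genes with all cells excluded omitted: ",
            paste(names(freq)[empty], collapse = ", "))
    freq <- freq[!empty]
  }
  freq
}

#' Correlate predicted and reference gene frequencies
#'
#' Pearson correlation over the genes shared between a predicted frequency
#' table and a reference population table, the standard concordance check
#' against an experimentally typed population.
#'
#' @param predicted named numeric vector from [gene_frequencies()].
#' @param reference named numeric vector of reference frequencies.
#' @return list with `r`, `r_squared`, `n_genes`, `genes`.
#' @export
correlate_frequencies <- function(predicted, reference) {
  shared <- intersect(names(predicted), names(reference))
  if (length(shared) < 3L)
    stop("need at least 3 shared genes; got ", length(shared))
  p <- predicted[shared]
  q <- reference[shared]
  if (stats::var(p) == 0 || stats::var(q) == 0)
    stop("zero variance in a frequency table")
  r <- stats::cor(p, q)
  list(r = r, r_squared = r^2, n_genes = length(shared), genes = shared)
}

#' Read a reference gene-frequency table
#'
#' @param path TSV with columns `gene` and `frequency`.
#' @return named numeric vector.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "frequency") %in% names(df)))
  stats::setNames(as.numeric(df$frequency), df$gene)
}

#' Write a gene-frequency table
#'
#' @param frequencies named numeric vector.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(frequencies, path) {
  utils::write.table(
    data.frame(gene = names(frequencies), frequency = unname(frequencies)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
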