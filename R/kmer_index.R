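#' Extract the unique k-mer index of an allele library
#'
#' A k-mer is unique to a gene when it (or its reverse complement) occurs in
#' every allele of that gene and in no allele of any other gene in the
#' library. All matching is done in canonical k-mer space (lexicographic
#' minimum of a k-mer and its reverse complement). Windows containing a
#' non-ACGT base are never candidates. Genes for which no k-mer satisfies
#' both criteria map to empty sets; their copy number is later recovered by
#' co-segregation inference.
#'
#' @param library a [kir_allele_library()].
#' @param k k-mer length (>= 1).
#' @return an object of class `kir_kmer_index` with fields `k`, `per_gene`
#'   (gene -> sorted character vector of canonical k-mers) and `provenance`
#'   (library checksum).
#' @export
extract_unique_kmers <- function(library, k) {
  stopifnot(inherits(library, "kir_allele_library"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  genes <- names(library$genes)

  # canonical window set per allele
  allele_sets <- lapply(library$genes, function(alleles) {
    lapply(alleles, function(s) {
      w <- kmer_windows(s, k)
      w <- w[grepl("^[ACGT]+$", w)]
      if (length(w) == 0L) return(character(0))
      unique(canonical_kmer(w))
    })
  })
  gene_union <- lapply(allele_sets, function(s) unique(unlist(s, use.names = FALSE)))
  gene_common <- lapply(allele_sets, function(s) Reduce(intersect, s))

  if (all(lengths(gene_union) == 0L))
    warning("k = ", k, " exceeds the length of every allele; index is empty")

  per_gene <- vector("list", length(genes))
  names(per_gene) <- genes
  for (i in seq_along(genes)) {
    others <- unlist(gene_union[-i], use.names = FALSE)
    per_gene[[i]] <- sort(setdiff(gene_common[[i]] %||% character(0), others))
  }
  structure(
    list(k = k, per_gene = per_gene, provenance = library$checksum),
    class = "kir_kmer_index"
  )
}

#' Select background normalization k-mers
#'
#' Chooses up to `max_per_gene` k-mers per background gene that are unique
#' within the combined reference (all background genes plus the whole KIR
#' allele library), so that background counts cannot absorb KIR signal.
#' Among eligible k-mers, selection is a seeded shuffle of the sorted
#' eligible set, making the result reproducible.
#'
#' @param background_library a [kir_allele_library()] of background genes
#'   (disjoint from the KIR genes).
#' @param kir_library the KIR [kir_allele_library()] the index was built from.
#' @param kir_index the [extract_unique_kmers()] result; its `k` must equal `k`.
#' @param k k-mer length (default 30).
#' @param max_per_gene maximum k-mers kept per background gene (default 100).
#' @param seed integer seed controlling the selection.
#' @return an object of class `kir_background_kmers`.
#' @export
select_background_kmers <- function(background_library, kir_library, kir_index,
                                    k = 30L, max_per_gene = 100L, seed = 1L) {
  stopifnot(inherits(background_library, "kir_allele_library"),
            inherits(kir_library, "kir_allele_library"),
            inherits(kir_index, "kir_kmer_index"))
  k <- as.integer(k)
  if (k != kir_index$k)
    stop("k (", k, ") does not match the KIR index k (", kir_index$k, ")")
  bg_genes <- names(background_library$genes)
  if (length(intersect(bg_genes, names(kir_library$genes))))
    stop("background genes overlap KIR genes")

  combined <- kir_allele_library(
    c(background_library$genes, kir_library$genes),
    source = "combined background + KIR"
  )
  combined_index <- extract_unique_kmers(combined, k)

  per_gene <- vector("list", length(bg_genes))
  names(per_gene) <- bg_genes
  for (g in bg_genes) {
    elig <- sort(combined_index$per_gene[[g]])
    if (length(elig) == 0L) {
      warning("background gene '", g, "' has no eligible unique k-mers")
      per_gene[[g]] <- character(0)
      next
    }
    shuffled <- with_seed(derive_seed(seed, 11L, match(g, bg_genes)),
                          sample(elig))
    per_gene[[g]] <- sort(utils::head(shuffled, max_per_gene))
  }
  structure(
    list(k = k, per_gene = per_gene, max_per_gene = as.integer(max_per_gene),
         provenance = background_library$checksum),
    class = "kir_background_kmers"
  )
}

#' Serialize a k-mer index to TSV (+ JSON sidecar)
#'
#' Writes one row per (gene, kmer) and a `<path>.json` sidecar carrying k,
#' the library checksum and the object class, so the index can be reloaded
#' losslessly with [read_kmer_index()].
#'
#' @param index a `kir_kmer_index` or `kir_background_kmers`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, c("kir_kmer_index", "kir_background_kmers")))
  df <- data.frame(
    gene = rep(names(index$per_gene), lengths(index$per_gene)),
    kmer = unlist(index$per_gene, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(class = class(index)[1], k = index$k,
               provenance = index$provenance,
               genes = names(index$per_gene))
  if (!is.null(index$max_per_gene)) meta$max_per_gene <- index$max_per_gene
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a k-mer index written by [write_kmer_index()]
#'
#' @param path TSV path (the `<path>.json` sidecar must sit beside it).
#' @return the reconstructed index object.
#' @export
read_kmer_index <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  per_gene <- lapply(stats::setNames(meta$genes, meta$genes), function(g) {
    sort(df$kmer[df$gene == g])
  })
  out <- list(k = as.integer(meta$k), per_gene = per_gene,
              provenance = meta$provenance)
  if (!is.null(meta$max_per_gene)) out$max_per_gene <- as.integer(meta$max_per_gene)
  structure(out, class = meta$class)
}

#' Validate index invariants
#'
#' Checks canonical closure, pairwise disjointness across genes, and (for
#' unique-k-mer indexes built from a library) presence in every allele of
#' the owning gene and absence from all other genes.
#'
#' @param index a `kir_kmer_index`.
#' @param library optionally, the library it was built from, enabling the
#'   presence/absence check.
#' @return `TRUE`, invisibly; errors describe any violated invariant.
#' @export
validate_kmer_index <- function(index, library = NULL) {
  all_kmers <- unlist(index$per_gene, use.names = FALSE)
  if (length(all_kmers)) {
    if (anyDuplicated(all_kmers)) stop("per-gene k-mer sets are not disjoint")
    if (!all(canonical_kmer(all_kmers) == all_kmers))
      stop("stored k-mers are not canonical")
    if (any(grepl("[^ACGT]", all_kmers))) stop("non-ACGT k-mer stored")
  }
  if (!is.null(library)) {
    for (g in names(index$per_gene)) {
      kms <- index$per_gene[[g]]
      if (length(kms) == 0L) next
      rcs <- revcomp(kms)
      for (h in names(library$genes)) {
        for (al in library$genes[[h]]) {
          present <- vapply(seq_along(kms), function(j) {
            grepl(kms[j], al, fixed = TRUE) || grepl(rcs[j], al, fixed = TRUE)
          }, logical(1))
          if (h == g && !all(present))
            stop("k-mer of '", g, "' missing from one of its alleles")
          if (h != g && any(present))
            stop("k-mer of '", g, "' occurs in gene '", h, "'")
        }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.kir_kmer_index <- function(x, ...) {
  cat("<kir_kmer_index> k =", x$k, "\n")
  n <- lengths(x$per_gene)
  for (g in names(n)) cat(sprintf("  %-12s %6d k-mers\n", g, n[[g]]))
  invisible(x)
}

#' @export
print.kir_background_kmers <- function(x, ...) {
  cat("<kir_background_kmers> k =", x$k, ";", length(x$per_gene),
      "genes; <=", x$max_per_gene, "k-mers each\n")
  invisible(x)
}
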