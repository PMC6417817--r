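# Independent brute-force oracles, implemented without the package's
# internals: plain string operations and explicit per-window loops.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- oracle_revcomp(x)
  ifelse(x <= rc, x, rc)
}

# every k-mer of every allele, checked for presence (self or revcomp) in
# all alleles of the gene and absence from every allele of any other gene
oracle_unique_kmers <- function(lib, k) {
  genes <- names(lib$genes)
  out <- vector("list", length(genes))
  names(out) <- genes
  for (g in genes) {
    own <- unname(lib$genes[[g]])
    others <- unname(unlist(lib$genes[setdiff(genes, g)]))
    cand <- character(0)
    for (al in own) {
      n <- nchar(al)
      if (n >= k) {
        for (i in seq_len(n - k + 1L)) cand <- c(cand, substr(al, i, i + k - 1L))
      }
    }
    cand <- unique(cand)
    cand <- cand[!grepl("[^ACGT]", cand)]
    keep <- vapply(cand, function(km) {
      rc <- oracle_revcomp(km)
      in_all <- all(grepl(km, own, fixed = TRUE) | grepl(rc, own, fixed = TRUE))
      in_other <- length(others) > 0 &&
        any(grepl(km, others, fixed = TRUE) | grepl(rc, others, fixed = TRUE))
      in_all && !in_other
    }, logical(1))
    out[[g]] <- sort(unique(oracle_canonical(cand[keep])))
  }
  out
}

# naive per-read sliding-window scan over a canonical k-mer -> gene map
oracle_count_kmers <- function(reads, per_gene, k) {
  kmers <- unlist(per_gene, use.names = FALSE)
  gene_of <- rep(names(per_gene), lengths(per_gene))
  counts <- stats::setNames(integer(length(kmers)), kmers)
  hits <- stats::setNames(integer(length(per_gene)), names(per_gene))
  for (r in reads) {
    seen <- character(0)
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- oracle_canonical(substr(r, i, i + k - 1L))
      j <- match(w, kmers)
      if (!is.na(j)) {
        counts[j] <- counts[j] + 1L
        seen <- union(seen, gene_of[j])
      }
    }
    for (g in seen) hits[g] <- hits[g] + 1L
  }
  list(counts = counts, reads_with_hit = hits)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# toy library with a shared segment (to force non-unique k-mers) and
# per-gene private segments, alleles differing by substitutions
random_toy_library <- function(n_genes = 4, n_alleles = 2, len = 120,
                               shared_fraction = 0.5) {
  shared <- random_seq(round(len * shared_fraction))
  genes <- list()
  for (gi in seq_len(n_genes)) {
    base <- paste0(shared, random_seq(len - nchar(shared)))
    alleles <- character(n_alleles)
    for (ai in seq_len(n_alleles)) {
      s <- base
      if (ai > 1) {
        p <- sample.int(nchar(s), 2)
        for (pp in p) {
          cur <- substr(s, pp, pp)
          substr(s, pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        }
      }
      alleles[ai] <- s
    }
    names(alleles) <- sprintf("%03d", seq_len(n_alleles))
    genes[[sprintf("GENE%02d", gi)]] <- alleles
  }
  kir_allele_library(genes, source = "toy")
}
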