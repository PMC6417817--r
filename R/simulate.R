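#' Simulation configuration for synthetic KIR cohorts
#'
#' The simulator emulates the population structure the caller assumes: a
#' family of homologous genes sharing a common backbone (so most k-mers are
#' non-unique), allelic variation by point substitution, diploid genotypes
#' drawn from per-haplotype gene frequencies, a co-segregating gene with no
#' unique k-mers, a diploid background gene panel, lognormal per-sample
#' depth variation and uniform base error.
#'
#' Default gene frequencies encode the three categories: anchor genes on
#' every haplotype, high-frequency genes at 0.7 per haplotype (so copies
#' 0/1/2 all occur, with 2 most common), low-frequency genes at 0.15 (most
#' samples at 0 copies). KIR2DS1 is simulated as a truncation of KIR3DS1,
#' yielding zero unique k-mers while KIR3DS1 keeps a private segment.
#'
#' @param seed master seed; all stages derive their streams from it.
#' @param genes data.frame with columns `gene`, `category` (`anchor`,
#'   `high_freq`, `low_freq`, `coseg`), `hap_freq` (per-haplotype presence
#'   probability; ignored for anchors and coseg genes) and `coseg_source`
#'   (`NA` except for coseg genes).
#' @param alleles_per_gene alleles simulated per gene (default 3).
#' @param allele_length full allele length in bp (default 800).
#' @param homology_fraction fraction of the allele shared across all genes
#'   (default 0.75).
#' @param allele_substitutions point substitutions distinguishing each
#'   non-reference allele (default 3).
#' @param n_background_genes diploid background genes (default 20).
#' @param background_gene_length background gene length in bp (default 500).
#' @param n_samples cohort size (default 500).
#' @param read_length read length in bp (default 100).
#' @param mean_depth mean per-copy (haploid) read depth (default 30,
#'   typical of on-target exome coverage).
#' @param depth_cv coefficient of variation of the lognormal per-sample
#'   depth (default 0.3).
#' @param base_error_rate per-base substitution error rate (default 0.001).
#' @return an object of class `kir_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genes = default_sim_genes(),
                              alleles_per_gene = 3L,
                              allele_length = 800L,
                              homology_fraction = 0.75,
                              allele_substitutions = 3L,
                              n_background_genes = 20L,
                              background_gene_length = 500L,
                              n_samples = 500L,
                              read_length = 100L,
                              mean_depth = 30,
                              depth_cv = 0.3,
                              base_error_rate = 0.001) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "category", "hap_freq", "coseg_source") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("duplicate simulated gene names")
  if (!all(genes$category %in% c("anchor", "high_freq", "low_freq", "coseg")))
    stop("unknown simulated gene category")
  free <- genes$category %in% c("high_freq", "low_freq")
  if (any(is.na(genes$hap_freq[free])) ||
      any(genes$hap_freq[free] < 0 | genes$hap_freq[free] > 1))
    stop("hap_freq must lie in [0, 1]")
  cs <- genes$coseg_source[genes$category == "coseg"]
  if (any(is.na(cs)) || !all(cs %in% genes$gene[genes$category != "coseg"]))
    stop("every coseg gene needs a non-coseg coseg_source")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (base_error_rate < 0 || base_error_rate > 0.1)
    stop("base_error_rate must lie in [0, 0.1]")
  if (homology_fraction < 0 || homology_fraction >= 1)
    stop("homology_fraction must lie in [0, 1)")
  if (read_length > allele_length || read_length > background_gene_length)
    stop("read_length exceeds a simulated gene length")
  structure(
    list(seed = as.integer(seed), genes = genes,
         alleles_per_gene = as.integer(alleles_per_gene),
         allele_length = as.integer(allele_length),
         homology_fraction = homology_fraction,
         allele_substitutions = as.integer(allele_substitutions),
         n_background_genes = as.integer(n_background_genes),
         background_gene_length = as.integer(background_gene_length),
         n_samples = as.integer(n_samples),
         read_length = as.integer(read_length),
         mean_depth = mean_depth, depth_cv = depth_cv,
         base_error_rate = base_error_rate),
    class = "kir_sim_config"
  )
}

#' Default simulated gene table
#'
#' @return data.frame of the nine default genes (two anchors, two
#'   high-frequency, four low-frequency, one zero-unique-k-mer coseg gene).
#' @export
default_sim_genes <- function() {
  data.frame(
    gene = c("KIR3DL3", "KIR3DL2", "KIR2DL1", "KIR2DS4",
             "KIR2DS2", "KIR3DS1", "KIR2DS3", "KIR2DS5", "KIR2DS1"),
    category = c("anchor", "anchor", "high_freq", "high_freq",
                 "low_freq", "low_freq", "low_freq", "low_freq", "coseg"),
    hap_freq = c(1, 1, 0.7, 0.7, 0.15, 0.15, 0.15, 0.15, NA),
    coseg_source = c(NA, NA, NA, NA, NA, NA, NA, NA, "KIR3DS1"),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, n_subs) {
  if (n_subs == 0L) return(seq)
  len <- nchar(seq)
  pos <- sample.int(len, min(n_subs, len))
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  seq
}

#' Simulate a homologous multi-allele gene library
#'
#' All genes share a common backbone over `homology_fraction` of their
#' length and carry a gene-specific terminal segment; alleles differ by
#' point substitutions. Each coseg gene is the truncation of its source
#' gene to the backbone plus half the specific segment, so every one of its
#' k-mers also occurs in the source and it has zero unique k-mers, while
#' the source keeps unique k-mers in its private remainder.
#'
#' @param config a [simulation_config()].
#' @return a [kir_allele_library()]; deterministic given the config seed.
#' @export
simulate_allele_library <- function(config) {
  stopifnot(inherits(config, "kir_sim_config"))
  hb <- round(config$homology_fraction * config$allele_length)
  spec_len <- config$allele_length - hb
  if (spec_len < 1L)
    stop("homology_fraction leaves no room for a gene-specific segment")
  with_seed(derive_seed(config$seed, 1L), {
    backbone <- random_dna(hb)
    genes <- list()
    plain <- config$genes[config$genes$category != "coseg", , drop = FALSE]
    for (g in plain$gene) {
      base <- paste0(backbone, random_dna(spec_len))
      alleles <- character(config$alleles_per_gene)
      alleles[1] <- base
      for (j in seq_len(config$alleles_per_gene)[-1])
        alleles[j] <- mutate_sequence(base, config$allele_substitutions)
      names(alleles) <- sprintf("%03d", seq_along(alleles))
      genes[[g]] <- alleles
    }
    coseg <- config$genes[config$genes$category == "coseg", , drop = FALSE]
    for (i in seq_len(nrow(coseg))) {
      src <- genes[[coseg$coseg_source[i]]]
      trunc_len <- hb + max(1L, spec_len %/% 2L)
      genes[[coseg$gene[i]]] <- stats::setNames(substr(src, 1L, trunc_len),
                                                names(src))
    }
    kir_allele_library(genes, source = sprintf("simulated (seed %d)", config$seed))
  })
}

#' Simulate the background gene panel
#'
#' Random unrelated genes (one allele each), diploid in every sample,
#' standing in for the random-gene panel used for depth normalization.
#'
#' @param config a [simulation_config()].
#' @return a [kir_allele_library()].
#' @export
simulate_background_library <- function(config) {
  stopifnot(inherits(config, "kir_sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    genes <- lapply(seq_len(config$n_background_genes), function(i) {
      stats::setNames(random_dna(config$background_gene_length), "001")
    })
    names(genes) <- sprintf("BG%03d", seq_len(config$n_background_genes))
    kir_allele_library(genes, source = sprintf("simulated background (seed %d)",
                                               config$seed))
  })
}

#' Simulate a diploid cohort with known copy numbers
#'
#' Each sample draws two haplotypes; gene presence on a haplotype is
#' Bernoulli(hap_freq). Anchor genes are present on both haplotypes; coseg
#' genes copy their source gene's count. Truth also carries the default
#' co-segregation rule targets (computed from the simulated sources), so
#' inferred calls can be checked against a consistent truth.
#'
#' @param config a [simulation_config()].
#' @param rules co-segregation rules used to extend the truth (default: the
#'   rules of [kir_default_config()] whose sources are all simulated).
#' @return an object of class `kir_truth_set` with `copies` (samples x
#'   genes integer matrix), `depth`, `sample_ids`, `genes_simulated`,
#'   `genes_inferred`.
#' @export
simulate_cohort <- function(config, rules = NULL) {
  stopifnot(inherits(config, "kir_sim_config"))
  n <- config$n_samples
  gt <- config$genes
  with_seed(derive_seed(config$seed, 3L), {
    copies <- matrix(NA_integer_, n, nrow(gt),
                     dimnames = list(sprintf("S%04d", seq_len(n)), gt$gene))
    for (i in seq_len(nrow(gt))) {
      copies[, i] <- switch(
        gt$category[i],
        anchor = rep(2L, n),
        coseg = NA_integer_,  # filled from source below
        rbinom(n, 2L, gt$hap_freq[i])
      )
    }
    for (i in which(gt$category == "coseg"))
      copies[, i] <- copies[, gt$coseg_source[i]]

    sdlog <- sqrt(log(1 + config$depth_cv^2))
    depth <- rlnorm(n, meanlog = log(config$mean_depth) - sdlog^2 / 2,
                    sdlog = sdlog)

    if (is.null(rules)) {
      rules <- Filter(function(r) all(r$sources %in% gt$gene),
                      kir_default_config()$coseg_rules)
    }
    inferred <- character(0)
    for (r in rules) {
      if (r$target %in% colnames(copies)) next
      total <- rowSums(copies[, r$sources, drop = FALSE])
      val <- if (r$op == "sum") total else pmax(0L, 2L - total)
      val <- pmin(val, 3L)
      copies <- cbind(copies, matrix(as.integer(val), n, 1,
                                     dimnames = list(NULL, r$target)))
      inferred <- c(inferred, r$target)
    }
    structure(
      list(copies = copies, depth = depth, sample_ids = rownames(copies),
           genes_simulated = gt$gene, genes_inferred = inferred),
      class = "kir_truth_set"
    )
  })
}

# reads for one sample; deterministic given (config$seed, sample index)
simulate_sample_reads_ <- function(library, background_library, truth, config, i) {
  rl <- config$read_length
  with_seed(derive_seed(config$seed, 4L, i), {
    seqs <- character(0)
    for (g in truth$genes_simulated) {
      cc <- truth$copies[i, g]
      if (cc > 0L) {
        al <- library$genes[[g]]
        seqs <- c(seqs, al[sample.int(length(al), cc, replace = TRUE)])
      }
    }
    if (!is.null(background_library)) {
      for (g in names(background_library$genes))
        seqs <- c(seqs, rep(background_library$genes[[g]][1], 2L))
    }
    lens <- nchar(seqs)
    n_reads <- rpois(length(seqs), truth$depth[i] * lens / rl)
    idx <- rep(seq_along(seqs), n_reads)
    if (length(idx) == 0L)
      return(kir_read_set(truth$sample_ids[i], "N"))
    starts <- floor(runif(length(idx), 1, lens[idx] - rl + 2))
    reads <- substring(seqs[idx], starts, starts + rl - 1L)
    flip <- runif(length(reads)) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    if (config$base_error_rate > 0) {
      ne <- rbinom(length(reads), rl, config$base_error_rate)
      for (j in which(ne > 0L)) reads[j] <- mutate_sequence(reads[j], ne[j])
    }
    kir_read_set(truth$sample_ids[i], reads)
  })
}

#' Simulate per-sample reads
#'
#' Per sample, reads are drawn uniformly from the sample's allele copies
#' (genes at 0 copies contribute nothing; background genes contribute two
#' copies each), both strands equiprobable, with independent base errors.
#' The expected number of reads per gene copy is
#' `depth * allele_length / read_length`. Deterministic given the seed.
#'
#' @param library the simulated [kir_allele_library()].
#' @param truth a [simulate_cohort()] result.
#' @param config the [simulation_config()].
#' @param background_library optional background [kir_allele_library()].
#' @param samples integer indices of samples to simulate (default: all).
#' @return named list of [kir_read_set()] objects.
#' @export
simulate_reads <- function(library, truth, config, background_library = NULL,
                           samples = NULL) {
  stopifnot(inherits(truth, "kir_truth_set"), inherits(config, "kir_sim_config"))
  samples <- samples %||% seq_along(truth$sample_ids)
  out <- lapply(samples, function(i)
    simulate_sample_reads_(library, background_library, truth, config, i))
  stats::setNames(out, truth$sample_ids[samples])
}

#' Write a read set as FASTQ or FASTA
#'
#' FASTQ qualities are constant (matching is exact and quality-blind).
#'
#' @param reads a [kir_read_set()].
#' @param path output path (a `.gz` suffix gzips).
#' @param format `"fastq"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_read_set <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ids <- sprintf("%s_read%06d", reads$sample_id, seq_along(reads$reads))
  dss <- Biostrings::DNAStringSet(stats::setNames(reads$reads, ids))
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(vapply(nchar(reads$reads), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    dss <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(dss, path,
                                             compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(dss, path, compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

#' Write a truth set as TSV
#'
#' @param truth a [simulate_cohort()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_set <- function(truth, path) {
  df <- cbind(data.frame(sample_id = truth$sample_ids,
                         depth = truth$depth),
              as.data.frame(truth$copies))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
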