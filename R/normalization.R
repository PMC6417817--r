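#' Compute a sample's depth normalizer from background genes
#'
#' Each background gene contributes one statistic: for
#' `unit = "kmer_occurrences"` its mean per-k-mer count, for
#' `unit = "reads_with_hit"` the number of reads containing at least one of
#' its k-mers. The normalizer is the mean or median of these per-gene
#' statistics. The four (statistic, unit) combinations are the candidate
#' normalization methods; the shipped default is (mean, kmer_occurrences).
#'
#' @param counts a [count_kmers()] result (background must have been counted).
#' @param background the `kir_background_kmers` set.
#' @param statistic `"mean"` or `"median"`.
#' @param unit `"kmer_occurrences"` or `"reads_with_hit"`.
#' @return strictly positive scalar.
#' @export
compute_normalizer <- function(counts, background,
                               statistic = c("mean", "median"),
                               unit = c("kmer_occurrences", "reads_with_hit")) {
  statistic <- match.arg(statistic)
  unit <- match.arg(unit)
  stopifnot(inherits(counts, "kir_kmer_counts"),
            inherits(background, "kir_background_kmers"))
  nonempty <- names(background$per_gene)[lengths(background$per_gene) > 0L]
  if (length(nonempty) == 0L) stop("background set is empty")
  per_gene <- if (unit == "kmer_occurrences") {
    vapply(background$per_gene[nonempty],
           function(kms) mean(counts$counts[kms]), numeric(1))
  } else {
    counts$reads_with_hit[nonempty]
  }
  norm <- if (statistic == "mean") mean(per_gene) else stats::median(per_gene)
  if (!is.finite(norm) || norm <= 0)
    stop("sample '", counts$sample_id, "' has no background coverage")
  norm
}

#' Normalize per-gene aggregate counts to frequencies
#'
#' @param aggregates named numeric vector from [aggregate_gene_counts()].
#' @param normalizer positive scalar from [compute_normalizer()].
#' @return named numeric vector of frequencies.
#' @export
normalize_frequencies <- function(aggregates, normalizer) {
  if (!is.numeric(normalizer) || length(normalizer) != 1L || normalizer <= 0)
    stop("normalizer must be a positive scalar")
  aggregates / normalizer
}

#' Build the sample x gene frequency matrix for a cohort
#'
#' Applies [aggregate_gene_counts()], [compute_normalizer()] and
#' [normalize_frequencies()] to each sample and stacks the results. This
#' matrix is the quantity whose population density is segmented into copy
#' numbers.
#'
#' @param counts_list list of [count_kmers()] results (one per sample).
#' @param index the `kir_kmer_index`.
#' @param background the `kir_background_kmers`.
#' @param statistic,unit normalization method (see [compute_normalizer()]).
#' @return numeric matrix (samples x genes) with attributes `k` and
#'   `method`; class `kir_freq_matrix`.
#' @export
cohort_frequency_matrix <- function(counts_list, index, background,
                                    statistic = "mean",
                                    unit = "kmer_occurrences") {
  rows <- lapply(counts_list, function(ct) {
    agg <- aggregate_gene_counts(ct, index)
    normalize_frequencies(agg, compute_normalizer(ct, background, statistic, unit))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(counts_list, `[[`, character(1), "sample_id")
  structure(mat, k = index$k,
            method = list(statistic = statistic, unit = unit),
            class = c("kir_freq_matrix", class(mat)))
}

#' Evaluate normalization methods and k by anchor-gene variance
#'
#' The anchor gene (KIR3DL3 by default) is diploid in nearly everyone, so
#' across a cohort its normalized frequency should be constant; residual
#' variance measures how well a (k, method) combination removes depth
#' differences. Because the four methods (and different k) place the
#' frequency on different absolute scales, each cell is the variance of the
#' frequency divided by its cohort mean (the squared coefficient of
#' variation) — a scale-free quantity that makes the candidates comparable.
#' Every candidate k is evaluated against all four methods. Because the
#' sample variance itself carries estimation noise (relative standard error
#' about sqrt(2/n)), candidates whose variance lies within `near_tie_tol`
#' of the minimum are treated as tied; ties resolve toward larger k (longer
#' k-mers cover low-frequency KIR genes better), then toward the mean
#' statistic and the k-mer-occurrence unit.
#'
#' @param counts_by_k named list (names = k values) of per-sample
#'   [count_kmers()] lists.
#' @param indexes_by_k named list of `kir_kmer_index` objects, same names.
#' @param backgrounds_by_k named list of `kir_background_kmers`, same names.
#' @param anchor_gene the diploid anchor gene (default `"KIR3DL3"`).
#' @param near_tie_tol relative margin within which variances count as tied
#'   (default 0.1; set 0 for a strict argmin).
#' @return list with `variance` (k x method matrix of unbiased sample
#'   variances of the mean-scaled frequency), `unnormalized` (per-k
#'   variance of the mean-scaled raw anchor aggregate), and `best`
#'   (k, statistic, unit); class `kir_norm_eval`.
#' @export
evaluate_normalization <- function(counts_by_k, indexes_by_k, backgrounds_by_k,
                                   anchor_gene = "KIR3DL3",
                                   near_tie_tol = 0.1) {
  ks <- names(counts_by_k)
  stopifnot(length(ks) > 0, setequal(ks, names(indexes_by_k)),
            setequal(ks, names(backgrounds_by_k)))
  methods <- expand.grid(statistic = c("mean", "median"),
                         unit = c("kmer_occurrences", "reads_with_hit"),
                         stringsAsFactors = FALSE)
  method_names <- paste(methods$statistic, methods$unit, sep = "_")
  vmat <- matrix(NA_real_, nrow = length(ks), ncol = nrow(methods),
                 dimnames = list(ks, method_names))
  unnorm <- stats::setNames(numeric(length(ks)), ks)

  for (kk in ks) {
    idx <- indexes_by_k[[kk]]
    bg <- backgrounds_by_k[[kk]]
    cl <- counts_by_k[[kk]]
    if (length(cl) < 2L) stop("need at least 2 samples to evaluate normalization")
    if (length(idx$per_gene[[anchor_gene]]) == 0L)
      stop("anchor gene '", anchor_gene, "' has no unique k-mers at k = ", kk)
    anchor_agg <- vapply(cl, function(ct) {
      mean(ct$counts[idx$per_gene[[anchor_gene]]])
    }, numeric(1))
    scaled_var <- function(v) stats::var(v / mean(v))
    unnorm[[kk]] <- scaled_var(anchor_agg)
    for (m in seq_len(nrow(methods))) {
      normed <- vapply(seq_along(cl), function(i) {
        anchor_agg[i] / compute_normalizer(cl[[i]], bg,
                                           methods$statistic[m],
                                           methods$unit[m])
      }, numeric(1))
      vmat[kk, m] <- scaled_var(normed)
    }
  }
  # near-ties (within near_tie_tol of the minimum) resolve toward larger k,
  # then method column order
  kvals <- as.numeric(ks)
  cells <- expand.grid(ki = seq_along(ks), mi = seq_len(nrow(methods)))
  cells$v <- vmat[cbind(cells$ki, cells$mi)]
  tied <- cells$v <= min(cells$v) * (1 + near_tie_tol)
  cand <- cells[tied, ]
  bestcell <- cand[order(-kvals[cand$ki], cand$mi)[1], ]
  structure(
    list(variance = vmat, unnormalized = unnorm,
         best = list(k = as.integer(kvals[bestcell$ki]),
                     statistic = methods$statistic[bestcell$mi],
                     unit = methods$unit[bestcell$mi]),
         anchor_gene = anchor_gene),
    class = "kir_norm_eval"
  )
}

#' Cohort coverage filters
#'
#' A sample is retained iff its background-set total k-mer coverage is at
#' least `random_gene_min` AND its KIR-set total is at least `kir_min`
#' (samples strictly below either threshold are excluded). The defaults are
#' the cohort-scale values used with a 100-gene background panel at k = 30
#' and full-exome depth; desk-scale cohorts need proportionally smaller
#' thresholds.
#'
#' @param totals data.frame with columns `sample_id`, `background_total`,
#'   `kir_total` (see [coverage_totals()]).
#' @param random_gene_min minimum background coverage (default 40000).
#' @param kir_min minimum KIR coverage (default 20000).
#' @return list with `retained` (character vector of sample ids) and
#'   `exclusions` (data.frame sample_id, reason).
#' @export
apply_coverage_filters <- function(totals, random_gene_min = 40000,
                                   kir_min = 20000) {
  stopifnot(all(c("sample_id", "background_total", "kir_total") %in% names(totals)))
  bg_ok <- totals$background_total >= random_gene_min
  kir_ok <- totals$kir_total >= kir_min
  keep <- bg_ok & kir_ok
  reason <- ifelse(!bg_ok & !kir_ok, "background+kir",
                   ifelse(!bg_ok, "background", "kir"))
  list(
    retained = totals$sample_id[keep],
    exclusions = data.frame(sample_id = totals$sample_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

#' Cohort embedding of background k-mer profiles (batch diagnostics)
#'
#' Projects each sample's background-gene k-mer frequency profile (per-gene
#' mean count divided by the sample normalizer) onto its first principal
#' components. On heterogeneous cohorts, clusters in this embedding
#' indicate batch structure such as different exome capture kits, which
#' confounds frequency comparisons; the caller should then be run within
#' one batch. Diagnostic only — no part of the calling path depends on it.
#'
#' @param counts_list list of [count_kmers()] results.
#' @param background the `kir_background_kmers` set.
#' @param n_components number of components returned (default 2).
#' @return matrix (samples x components) of PCA scores.
#' @export
background_embedding <- function(counts_list, background, n_components = 2L) {
  profiles <- t(vapply(counts_list, function(ct) {
    per_gene <- vapply(background$per_gene[lengths(background$per_gene) > 0L],
                       function(kms) mean(ct$counts[kms]), numeric(1))
    per_gene / mean(per_gene)
  }, numeric(sum(lengths(background$per_gene) > 0L))))
  rownames(profiles) <- vapply(counts_list, `[[`, character(1), "sample_id")
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
}

#' @export
print.kir_norm_eval <- function(x, ...) {
  cat("<kir_norm_eval> anchor:", x$anchor_gene, "\n")
  print(signif(x$variance, 4))
  cat("best: k =", x$best$k, ",", x$best$statistic, "of", x$best$unit, "\n")
  invisible(x)
}
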