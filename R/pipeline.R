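#' Run the full pipeline on a simulated cohort
#'
#' Convenience driver used by the worked examples and the package's own
#' validation: simulates the allele library, background panel and cohort,
#' builds the unique-k-mer index and background set, then streams each
#' sample's reads through the counter (reads are discarded after counting,
#' keeping memory flat) and assembles the normalized frequency matrix.
#'
#' @param config a [simulation_config()].
#' @param k k-mer length for the index (default 30).
#' @param max_background_kmers background k-mers per gene (default 100).
#' @param statistic,unit normalization method (see [compute_normalizer()]).
#' @return list with `config`, `library`, `background_library`, `index`,
#'   `background`, `truth`, `counts` (per-sample [count_kmers()] results)
#'   and `freqs` (the [cohort_frequency_matrix()]).
#' @export
run_simulation_study <- function(config, k = 30L, max_background_kmers = 100L,
                                 statistic = "mean",
                                 unit = "kmer_occurrences") {
  stopifnot(inherits(config, "kir_sim_config"))
  library <- simulate_allele_library(config)
  background_library <- simulate_background_library(config)
  index <- extract_unique_kmers(library, k)
  background <- select_background_kmers(background_library, library, index,
                                        k = k,
                                        max_per_gene = max_background_kmers,
                                        seed = config$seed)
  truth <- simulate_cohort(config)
  counts <- lapply(seq_len(config$n_samples), function(i) {
    rs <- simulate_sample_reads_(library, background_library, truth, config, i)
    count_kmers(rs, index, background)
  })
  freqs <- cohort_frequency_matrix(counts, index, background, statistic, unit)
  list(config = config, library = library,
       background_library = background_library, index = index,
       background = background, truth = truth, counts = counts,
       freqs = freqs)
}

#' Compare copy-number calls against a simulation truth set
#'
#' @param cn a `kir_copy_number` from [call_copy_numbers()].
#' @param truth the matching [simulate_cohort()] truth set.
#' @return list with `measured_accuracy` (fraction of non-excluded measured
#'   calls equal to truth, "3+" compared as 3), `excluded_fraction`
#'   (excluded cells over all called cells), `inferred_accuracy` (fraction
#'   of non-excluded inferred calls matching truth among samples whose
#'   source calls are all correct), and supporting counts.
#' @export
call_accuracy <- function(cn, truth) {
  stopifnot(inherits(cn, "kir_copy_number"), inherits(truth, "kir_truth_set"))
  stopifnot(identical(rownames(cn$calls), truth$sample_ids))
  tcap <- pmin(truth$copies, 3L)

  genes <- intersect(colnames(cn$calls), colnames(tcap))
  calls <- cn$calls[, genes, drop = FALSE]
  flag <- cn$flag[, genes, drop = FALSE]
  tm <- tcap[, genes, drop = FALSE]

  measured <- flag == "measured"
  m_called <- measured & !is.na(calls)
  measured_accuracy <- mean(calls[m_called] == tm[m_called])
  excluded_fraction <- mean(is.na(calls[!is.na(flag)]))

  inf_ok <- 0L
  inf_tot <- 0L
  for (r in cn$config$coseg_rules) {
    if (!r$target %in% genes) next
    src_calls <- cn$calls[, r$sources, drop = FALSE]
    src_truth <- tcap[, r$sources, drop = FALSE]
    src_correct <- rowSums(is.na(src_calls)) == 0L &
      rowSums(src_calls != src_truth) == 0L
    tgt <- calls[, r$target]
    use <- src_correct & !is.na(tgt)
    inf_tot <- inf_tot + sum(use)
    inf_ok <- inf_ok + sum(tgt[use] == tm[use, r$target])
  }
  list(
    measured_accuracy = measured_accuracy,
    excluded_fraction = excluded_fraction,
    inferred_accuracy = if (inf_tot > 0L) inf_ok / inf_tot else NA_real_,
    n_measured_called = sum(m_called),
    n_inferred_checked = inf_tot
  )
}
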