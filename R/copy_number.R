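#' Gene category and co-segregation configuration
#'
#' Copy-number thresholding is category-driven: *anchor* genes are diploid
#' in nearly everyone (unimodal density, highest peak = 2 copies),
#' *high-frequency* non-anchor genes are present at least once in most
#' people (three peaks mapping to 0/1/2 copies), *low-frequency* non-anchor
#' genes are present less than once on average (two peaks mapping to 0/1,
#' higher copies extrapolated from the inter-peak distance). *Inferred*
#' genes carry no unique k-mers and are recovered by co-segregation rules.
#'
#' @param categories named character vector, gene -> one of `"anchor"`,
#'   `"high_freq"`, `"low_freq"`, `"inferred"`.
#' @param prior_modal_ploidy named integer vector, gene -> most common
#'   population copy number (2 for anchors and high-frequency genes, 0 for
#'   low-frequency genes).
#' @param coseg_rules list of rules `list(target=, sources=, op=)` with op
#'   `"sum"` (target copies = sum of source copies) or `"inverse"` (target
#'   copies = 2 - sum of source copies, clamped at 0). Each inferred gene
#'   must be the target of exactly one rule.
#' @param inhibitory_genes character vector of inhibitory KIR genes used by
#'   the burden analysis.
#' @return an object of class `kir_config`.
#' @export
kir_config <- function(categories, prior_modal_ploidy = NULL,
                       coseg_rules = list(), inhibitory_genes = character(0)) {
  ok <- c("anchor", "high_freq", "low_freq", "inferred")
  if (!all(categories %in% ok))
    stop("categories must be one of: ", paste(ok, collapse = ", "))
  targets <- vapply(coseg_rules, `[[`, character(1), "target")
  if (anyDuplicated(targets))
    stop("a gene is the target of more than one co-segregation rule")
  inferred <- names(categories)[categories == "inferred"]
  missing_rule <- setdiff(inferred, targets)
  if (length(missing_rule))
    stop("inferred genes without a co-segregation rule: ",
         paste(missing_rule, collapse = ", "))
  for (r in coseg_rules) {
    if (!r$op %in% c("sum", "inverse")) stop("rule op must be 'sum' or 'inverse'")
    if (length(r$sources) < 1L) stop("rule for '", r$target, "' has no sources")
  }
  if (is.null(prior_modal_ploidy)) {
    prior_modal_ploidy <- ifelse(categories == "low_freq", 0L, 2L)
    names(prior_modal_ploidy) <- names(categories)
  }
  structure(
    list(categories = categories, prior_modal_ploidy = prior_modal_ploidy,
         coseg_rules = coseg_rules, inhibitory_genes = inhibitory_genes),
    class = "kir_config"
  )
}

#' Default KIR configuration
#'
#' Categories follow the documented population structure of the locus.
#' KIR2DL2 is listed here as inferred (from KIR2DS2, with which it
#' co-segregates) rather than as an anchor; users tracking a cohort where
#' KIR2DL2 behaves as an anchor can override the category. The shipped
#' normalization default is k = 30 with the mean of background-gene
#' per-k-mer counts. The inhibitory gene list is the canonical set and
#' should be reviewed for the cohort at hand.
#'
#' @return a [kir_config()] with an extra `normalization` element
#'   (`k`, `statistic`, `unit`).
#' @export
kir_default_config <- function() {
  categories <- c(
    KIR3DL3 = "anchor", KIR3DP1 = "anchor", KIR3DL2 = "anchor",
    KIR2DP1 = "high_freq", KIR2DL1 = "high_freq", KIR2DS4 = "high_freq",
    KIR2DL5 = "high_freq",
    KIR2DS3 = "low_freq", KIR2DS2 = "low_freq", KIR2DS5 = "low_freq",
    KIR3DS1 = "low_freq",
    KIR2DS1 = "inferred", KIR2DL2 = "inferred", KIR3DL1 = "inferred",
    KIR2DL5A = "inferred", KIR2DL3 = "inferred"
  )
  rules <- list(
    list(target = "KIR2DS1", sources = "KIR3DS1", op = "sum"),
    list(target = "KIR2DL2", sources = "KIR2DS2", op = "sum"),
    list(target = "KIR3DL1", sources = "KIR2DS4", op = "sum"),
    list(target = "KIR2DL5A", sources = c("KIR2DS3", "KIR2DS5"), op = "sum"),
    list(target = "KIR2DL3", sources = "KIR2DS2", op = "inverse")
  )
  cfg <- kir_config(
    categories, coseg_rules = rules,
    inhibitory_genes = c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR2DL5",
                         "KIR3DL1", "KIR3DL2", "KIR3DL3")
  )
  cfg$normalization <- list(k = 30L, statistic = "mean", unit = "kmer_occurrences")
  cfg
}

#' Population density of one gene's frequencies
#'
#' Gaussian kernel density on a fixed uniform grid spanning
#' `[0, 1.1 * max(frequency)]`, with reflection at zero so mass of samples
#' near zero copies is not lost below the boundary. Bandwidth defaults to
#' Silverman's rule of thumb.
#'
#' @param frequencies per-sample frequencies for one gene (non-negative).
#' @param gene gene label carried on the result.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @param n_grid number of grid points (default 512).
#' @param min_samples cohort-size floor (default 50); the thresholding is a
#'   population method and degenerates on small cohorts.
#' @return an object of class `kir_density` with `grid`, `density`,
#'   `bandwidth`, `n`, `gene`.
#' @export
estimate_density <- function(frequencies, gene = NA_character_,
                             bandwidth = NULL, n_grid = 512L,
                             min_samples = 50L) {
  x <- frequencies[!is.na(frequencies)]
  if (length(x) < min_samples)
    stop("only ", length(x), " samples; copy-number densities need a cohort ",
         "of at least ", min_samples, " (population method)")
  if (any(x < 0)) stop("negative frequencies")
  bw <- bandwidth %||% tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3 * max(mean(abs(x)), 1)
  to <- max(x) * 1.1
  if (to <= 0) to <- 1
  grid <- seq(0, to, length.out = n_grid)
  # Gaussian KDE with reflection at 0
  d_direct <- rowMeans(dnorm(outer(grid, x, "-") / bw)) / bw
  d_reflect <- rowMeans(dnorm(outer(grid, x, "+") / bw)) / bw
  structure(
    list(gene = gene, grid = grid, density = d_direct + d_reflect,
         bandwidth = bw, n = length(x)),
    class = "kir_density"
  )
}

#' Detect peaks and valleys of a population density
#'
#' Peaks are local maxima of the density (boundary maxima included, so a
#' copy-0 mode at frequency zero is detected) whose prominence exceeds
#' `min_prominence` times the maximum density. Valleys are the
#' minimum-density grid points between consecutive retained peaks.
#'
#' @param density a [estimate_density()] result.
#' @param min_prominence prominence floor as a fraction of the maximum
#'   density (default 0.02).
#' @return list with data.frames `peaks` (location, height, prominence,
#'   index) and `valleys` (location, height, index), both sorted by
#'   location.
#' @export
find_peaks_valleys <- function(density, min_prominence = 0.02) {
  y <- density$density
  g <- density$grid
  n <- length(y)
  cand <- integer(0)
  if (n >= 2L && y[1] > y[2]) cand <- c(cand, 1L)
  if (n >= 3L) {
    interior <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
    cand <- c(cand, interior)
  }
  if (n >= 2L && y[n] > y[n - 1L]) cand <- c(cand, n)
  cand <- sort(unique(cand))

  prom <- vapply(cand, function(i) {
    h <- y[i]
    lbase <- NA_real_
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      lbase <- min(lbase, y[j], na.rm = TRUE)
    }
    rbase <- NA_real_
    j <- i
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      rbase <- min(rbase, y[j], na.rm = TRUE)
    }
    # a boundary peak has only one side; its prominence is measured there
    if (is.na(lbase) && is.na(rbase)) return(h)
    h - max(lbase, rbase, na.rm = TRUE)
  }, numeric(1))

  keep <- prom >= min_prominence * max(y)
  if (!any(keep)) stop("degenerate density: no peak above the prominence floor")
  peaks <- data.frame(location = g[cand[keep]], height = y[cand[keep]],
                      prominence = prom[keep], index = cand[keep])
  valleys <- if (nrow(peaks) > 1L) {
    idx <- vapply(seq_len(nrow(peaks) - 1L), function(i) {
      lo <- peaks$index[i]
      hi <- peaks$index[i + 1L]
      lo + which.min(y[lo:hi]) - 1L
    }, integer(1))
    data.frame(location = g[idx], height = y[idx], index = idx)
  } else {
    data.frame(location = numeric(0), height = numeric(0), index = integer(0))
  }
  list(peaks = peaks, valleys = valleys)
}

# extent of a peak: nearest grid points left/right of `index` where the
# density drops below `fraction` * peak height (grid ends if it never does)
peak_extent <- function(density, index, fraction) {
  y <- density$density
  h <- y[index] * fraction
  li <- index
  while (li > 1L && y[li - 1L] >= h) li <- li - 1L
  ri <- index
  n <- length(y)
  while (ri < n && y[ri + 1L] >= h) ri <- ri + 1L
  c(left = density$grid[li], right = density$grid[ri])
}

#' Derive copy-number cutoffs from a gene's density
#'
#' Category-specific segmentation of the population density:
#' \describe{
#' \item{anchor}{The highest peak is two copies. Its left/right extent
#'   (where the density falls below `anchor_edge_fraction` of the peak
#'   height) bounds the copy-2 interval; one peak-width further left bounds
#'   copy 1 vs copy 0; beyond the right extent is 3+.}
#' \item{high_freq}{Three peaks map left-to-right to 0, 1 and 2 copies; the
#'   valleys between them are the 0/1 and 1/2 cutoffs, and the right extent
#'   of the third peak is the 2/3+ cutoff.}
#' \item{low_freq}{Two peaks map to 0 and 1 copies; the valley between them
#'   is the 0/1 cutoff, and hypothetical higher-copy peaks are placed at
#'   multiples of the inter-peak distance beyond the copy-1 peak, with
#'   cutoffs at the midpoints (copy-1 peak + 0.5 and 1.5 inter-peak
#'   distances).}
#' }
#' The exclusion margin is the 1/2 cutoff divided by `exclusion_divisor`
#' (for low-frequency genes that cutoff is the extrapolated one).
#'
#' @param density a [estimate_density()] result.
#' @param peaks_valleys a [find_peaks_valleys()] result.
#' @param category `"anchor"`, `"high_freq"` or `"low_freq"`.
#' @param anchor_edge_fraction fraction of peak height defining the peak
#'   extent (default 0.1).
#' @param exclusion_divisor denominator of the exclusion margin (default 50).
#' @return an object of class `kir_thresholds` with ascending `cutoffs`
#'   (named `0/1`, `1/2`, `2/3+`), `exclusion_margin`, `category`, `gene`.
#' @export
derive_thresholds <- function(density, peaks_valleys, category,
                              anchor_edge_fraction = 0.1,
                              exclusion_divisor = 50) {
  stopifnot(category %in% c("anchor", "high_freq", "low_freq"))
  pk <- peaks_valleys$peaks
  y <- density$density

  pick_top <- function(m) {
    if (nrow(pk) < m)
      stop("gene '", density$gene, "': ", nrow(pk), " peak(s) found but the '",
           category, "' category expects ", m,
           "; consider a manual category override")
    if (nrow(pk) > m) {
      warning("gene '", density$gene, "': ", nrow(pk), " peaks; keeping the ",
              m, " most prominent")
      pk <- pk[order(-pk$prominence)[seq_len(m)], ]
    }
    pk[order(pk$location), ]
  }
  valley_between <- function(i1, i2) {
    density$grid[i1 + which.min(y[i1:i2]) - 1L]
  }

  if (category == "anchor") {
    main <- pk[which.max(pk$height), ]
    ext <- peak_extent(density, main$index, anchor_edge_fraction)
    width <- ext["right"] - ext["left"]
    cutoffs <- c(max(0, ext[["left"]] - width), ext[["left"]], ext[["right"]])
  } else if (category == "high_freq") {
    pk3 <- pick_top(3L)
    v1 <- valley_between(pk3$index[1], pk3$index[2])
    v2 <- valley_between(pk3$index[2], pk3$index[3])
    ext3 <- peak_extent(density, pk3$index[3], anchor_edge_fraction)
    cutoffs <- c(v1, v2, ext3[["right"]])
  } else {
    pk2 <- pick_top(2L)
    v <- valley_between(pk2$index[1], pk2$index[2])
    d <- pk2$location[2] - pk2$location[1]
    cutoffs <- c(v, pk2$location[2] + d / 2, pk2$location[2] + 3 * d / 2)
  }
  if (any(diff(cutoffs) <= 0))
    stop("gene '", density$gene, "': could not derive ordered cutoffs")
  names(cutoffs) <- c("0/1", "1/2", "2/3+")
  structure(
    list(gene = density$gene, category = category, cutoffs = cutoffs,
         exclusion_margin = cutoffs[["1/2"]] / exclusion_divisor,
         peaks = peaks_valleys$peaks),
    class = "kir_thresholds"
  )
}

#' Assign copy numbers from frequencies
#'
#' Maps each frequency to the copy-number label of its interval
#' (`[0, c01) -> 0`, `[c01, c12) -> 1`, `[c12, c23) -> 2`, `[c23, Inf) -> 3`,
#' where 3 encodes "3 or more"). Frequencies within the exclusion margin of
#' any cutoff are excluded (`NA`): samples sitting on a boundary cannot be
#' called reliably.
#'
#' @param frequency numeric vector of non-negative frequencies.
#' @param thresholds a [derive_thresholds()] result.
#' @return integer vector in `{0,1,2,3}` with `NA` for excluded samples and
#'   a logical attribute `excluded`.
#' @export
assign_copy_number <- function(frequency, thresholds) {
  stopifnot(inherits(thresholds, "kir_thresholds"))
  if (any(frequency < 0, na.rm = TRUE)) stop("negative frequency")
  lab <- findInterval(frequency, thresholds$cutoffs)
  dist <- abs(outer(frequency, thresholds$cutoffs, "-"))
  excl <- apply(dist, 1L, min) < thresholds$exclusion_margin
  lab[excl] <- NA_integer_
  lab <- as.integer(lab)
  attr(lab, "excluded") <- excl
  lab
}

#' Call copy numbers for a whole cohort
#'
#' For every measured gene (a column of the frequency matrix), estimates
#' the population density, detects peaks and valleys, derives
#' category-specific thresholds and assigns per-sample copy numbers; then
#' fills in co-segregating (inferred) genes via [infer_cosegregating()].
#'
#' @param freqs a [cohort_frequency_matrix()] (samples x genes).
#' @param config a [kir_config()].
#' @param min_prominence,anchor_edge_fraction,exclusion_divisor,bandwidth,
#'   min_samples tuning parameters passed through to the steps above.
#' @return an object of class `kir_copy_number` with `calls` (integer
#'   matrix, `NA` = excluded), `flag` (`"measured"`/`"inferred"`),
#'   `clamped` (logical matrix), `thresholds` (per measured gene) and
#'   `config`.
#' @export
call_copy_numbers <- function(freqs, config, min_prominence = 0.02,
                              anchor_edge_fraction = 0.1,
                              exclusion_divisor = 50, bandwidth = NULL,
                              min_samples = 50L) {
  stopifnot(inherits(config, "kir_config"))
  genes <- colnames(freqs)
  unknown <- setdiff(genes, names(config$categories))
  if (length(unknown))
    stop("genes without a category: ", paste(unknown, collapse = ", "))
  measured_cat <- config$categories[genes]
  if (any(measured_cat == "inferred"))
    stop("genes categorized as inferred appear in the frequency matrix: ",
         paste(genes[measured_cat == "inferred"], collapse = ", "))

  targets <- vapply(config$coseg_rules, `[[`, character(1), "target")
  all_genes <- c(genes, setdiff(targets, genes))
  n <- nrow(freqs)
  calls <- matrix(NA_integer_, n, length(all_genes),
                  dimnames = list(rownames(freqs), all_genes))
  flag <- matrix(NA_character_, n, length(all_genes),
                 dimnames = dimnames(calls))
  clamped <- matrix(FALSE, n, length(all_genes), dimnames = dimnames(calls))
  thresholds <- vector("list", length(genes))
  names(thresholds) <- genes

  for (g in genes) {
    dens <- estimate_density(freqs[, g], gene = g, bandwidth = bandwidth,
                             min_samples = min_samples)
    pv <- find_peaks_valleys(dens, min_prominence = min_prominence)
    th <- derive_thresholds(dens, pv, measured_cat[[g]],
                            anchor_edge_fraction = anchor_edge_fraction,
                            exclusion_divisor = exclusion_divisor)
    calls[, g] <- assign_copy_number(freqs[, g], th)
    flag[, g] <- "measured"
    thresholds[[g]] <- th
  }
  cn <- structure(
    list(calls = calls, flag = flag, clamped = clamped,
         thresholds = thresholds, config = config),
    class = "kir_copy_number"
  )
  infer_cosegregating(cn, config$coseg_rules)
}

#' Infer co-segregating gene copy numbers
#'
#' Genes without unique k-mers co-segregate with indexed genes, so their
#' copy number follows from the rules: by default KIR2DS1 = KIR3DS1,
#' KIR2DL2 = KIR2DS2, KIR3DL1 = KIR2DS4, KIR2DL5A = KIR2DS3 + KIR2DS5 and
#' KIR2DL3 = 2 - KIR2DS2 (inverse co-segregation). Sums above 3 are capped
#' at 3 ("3+"); inverse results below 0 are clamped to 0 and flagged. A
#' target is excluded for a sample whenever any source is excluded.
#'
#' @param cn a `kir_copy_number` object.
#' @param rules co-segregation rules (see [kir_config()]).
#' @return the extended `kir_copy_number`.
#' @export
infer_cosegregating <- function(cn, rules) {
  stopifnot(inherits(cn, "kir_copy_number"))
  for (r in rules) {
    missing_src <- setdiff(r$sources, colnames(cn$calls))
    if (length(missing_src))
      stop("co-segregation rule for '", r$target,
           "' references unknown gene(s): ",
           paste(missing_src, collapse = ", "))
    src <- cn$calls[, r$sources, drop = FALSE]
    total <- rowSums(src)              # NA if any source excluded
    val <- if (r$op == "sum") total else 2 - total
    clamp <- !is.na(val) & val < 0
    val[clamp] <- 0
    val[!is.na(val) & val > 3] <- 3
    if (!r$target %in% colnames(cn$calls)) {
      cn$calls <- cbind(cn$calls,
                        matrix(NA_integer_, nrow(cn$calls), 1,
                               dimnames = list(NULL, r$target)))
      cn$flag <- cbind(cn$flag, matrix(NA_character_, nrow(cn$flag), 1,
                                       dimnames = list(NULL, r$target)))
      cn$clamped <- cbind(cn$clamped, matrix(FALSE, nrow(cn$clamped), 1,
                                             dimnames = list(NULL, r$target)))
    }
    cn$calls[, r$target] <- as.integer(val)
    cn$flag[, r$target] <- "inferred"
    cn$clamped[, r$target] <- clamp
  }
  cn
}

#' Write a copy-number matrix as TSV
#'
#' Values are 0/1/2/3+ with NA for excluded cells; a `<path>.flags.tsv`
#' sidecar records the measured/inferred provenance per cell.
#'
#' @param cn a `kir_copy_number`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_copy_numbers <- function(cn, path) {
  m <- cn$calls
  out <- as.data.frame(ifelse(is.na(m), NA, ifelse(m >= 3, "3+", m)))
  out <- cbind(sample_id = rownames(m), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- cbind(sample_id = rownames(m), as.data.frame(cn$flag))
  utils::write.table(fl, paste0(path, ".flags.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.kir_copy_number <- function(x, ...) {
  cat("<kir_copy_number>", nrow(x$calls), "samples x", ncol(x$calls),
      "genes;", sum(is.na(x$calls)), "excluded cells\n")
  invisible(x)
}

#' @export
print.kir_thresholds <- function(x, ...) {
  cat("<kir_thresholds>", x$gene, "(", x$category, ")\n")
  cat("  cutoffs:", paste(sprintf("%s=%.4f", names(x$cutoffs), x$cutoffs),
                          collapse = ", "), "\n")
  cat("  exclusion margin:", signif(x$exclusion_margin, 4), "\n")
  invisible(x)
}

#' Plot a gene's population density with its thresholds
#'
#' @param x a [estimate_density()] result.
#' @param thresholds optionally, the gene's [derive_thresholds()] result,
#'   drawn as vertical cutoff lines.
#' @param ... passed to [graphics::plot()].
#' @method plot kir_density
#' @export
plot.kir_density <- function(x, thresholds = NULL, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "normalized k-mer frequency", ylab = "density",
                 main = x$gene, ...)
  if (!is.null(thresholds))
    graphics::abline(v = thresholds$cutoffs, col = "darkgreen", lty = 2)
  invisible(x)
}
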