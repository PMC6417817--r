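#' Per-sample inhibitory KIR gene burden
#'
#' The burden is the sum of copy numbers over the inhibitory gene list
#' ("3+" counted as 3). Samples with an excluded call at any inhibitory
#' gene are dropped with a warning rather than partially summed.
#'
#' @param cn a `kir_copy_number` (or integer matrix with `NA` = excluded).
#' @param inhibitory_genes character vector of inhibitory genes; must all
#'   be called.
#' @return named integer vector, sample -> burden.
#' @export
inhibitory_burden <- function(cn, inhibitory_genes) {
  if (length(inhibitory_genes) == 0L)
    stop("inhibitory gene list is empty")
  m <- if (inherits(cn, "kir_copy_number")) cn$calls else cn
  missing <- setdiff(inhibitory_genes, colnames(m))
  if (length(missing))
    stop("inhibitory genes not among called genes: ",
         paste(missing, collapse = ", "))
  sub <- m[, inhibitory_genes, drop = FALSE]
  burden <- rowSums(sub)
  drop <- is.na(burden)
  if (any(drop))
    warning(sum(drop), " sample(s) dropped: excluded inhibitory-gene call")
  stats::setNames(as.integer(burden[!drop]), rownames(m)[!drop])
}

#' Split a cohort at the median inhibitory burden
#'
#' The low group holds samples with burden less than or equal to the cohort
#' median; the high group holds those strictly above it.
#'
#' @param burdens named integer vector from [inhibitory_burden()].
#' @return data.frame with columns `sample_id`, `burden`, `group`
#'   (`"low"`/`"high"`), plus attribute `median`.
#' @export
split_by_median <- function(burdens) {
  if (length(burdens) < 2L) stop("need at least 2 samples")
  med <- stats::median(burdens)
  group <- ifelse(burdens <= med, "low", "high")
  if (all(group == "low"))
    stop("degenerate split: no sample above the median burden")
  out <- data.frame(sample_id = names(burdens), burden = unname(burdens),
                    group = unname(group), stringsAsFactors = FALSE)
  attr(out, "median") <- med
  out
}

#' Compare survival between low- and high-burden groups
#'
#' Kaplan-Meier estimates and the log-rank test (delegated to the survival
#' package), with Bonferroni adjustment over `n_tests` tumor types:
#' adjusted p = min(1, p * n_tests).
#'
#' @param groups data.frame from [split_by_median()].
#' @param times per-sample follow-up durations (same order as `groups`).
#' @param events per-sample event indicators (1 = death, 0 = censored).
#' @param n_tests number of tests for Bonferroni adjustment (default 1).
#' @return list with `p_value`, `p_adjusted`, `chisq`, `fit` (the
#'   [survival::survfit()] object) and `n` per group.
#' @export
compare_survival <- function(groups, times, events, n_tests = 1L) {
  stopifnot(nrow(groups) == length(times), length(times) == length(events))
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  grp <- factor(groups$group, levels = c("low", "high"))
  if (any(table(grp) == 0L)) stop("both burden groups must be non-empty")
  surv <- survival::Surv(times, events)
  sd_ <- survival::survdiff(surv ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  if (sd_$chisq == 0) p <- 1
  fit <- survival::survfit(surv ~ grp)
  list(p_value = p, p_adjusted = min(1, p * n_tests), chisq = sd_$chisq,
       fit = fit, n = table(grp))
}
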