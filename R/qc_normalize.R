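#' Convert exact-zero abundances to missing values
#'
#' Reporter-ion quantification reports unobserved peptides as zero; zeros are
#' therefore recoded as missing before any normalization. Strictly positive
#' values are left untouched.
#'
#' @param m a `PeptideMatrix`
#' @return a `PeptideMatrix` with every exact zero replaced by `NA`
#' @export
zeros_to_missing <- function(m) {
  ab <- m$abundance
  if (any(ab < 0, na.rm = TRUE)) stop("negative abundances are not allowed")
  ab[!is.na(ab) & ab == 0] <- NA_real_
  m$abundance <- ab
  m
}

#' Sample loading normalization
#'
#' Scales every channel so that total abundance (sum over present values) is
#' identical across channels; the common target is the grand mean of the
#' channel totals, which preserves the overall scale of the data.
#'
#' @param m a `PeptideMatrix`
#' @return a `PeptideMatrix` with equalized channel totals; the per-channel
#'   scaling factors are attached as attribute `"factors"`.
#' @export
sample_loading_normalize <- function(m) {
  ab <- m$abundance
  n_present <- colSums(!is.na(ab))
  if (any(n_present == 0))
    stop("channel(s) with no present values: ",
         paste(colnames(ab)[n_present == 0], collapse = ", "))
  totals <- colSums(ab, na.rm = TRUE)
  factors <- mean(totals) / totals
  m$abundance <- sweep(ab, 2, factors, `*`)
  attr(m, "factors") <- factors
  m
}

#' Remove peptides missing in the pooled controls of at least half the plexes
#'
#' A peptide is removed when the number of plexes in which *all* of its
#' pooled-control channels are missing reaches half the number of plexes
#' (`>= n_plexes / 2`, real-valued comparison). Such peptides cannot be
#' reliably bridged across plexes by internal reference scaling.
#'
#' @param m a `PeptideMatrix`
#' @return list with elements `matrix` (filtered `PeptideMatrix`) and
#'   `removed` (data.frame of peptide ids with reason `"pooled-missing"`)
#' @export
filter_pooled_missing <- function(m) {
  plexes <- unique(m$channels$plex)
  both_missing <- vapply(plexes, function(p) {
    cols <- m$channels$channel[m$channels$plex == p & m$channels$pooled]
    if (!length(cols)) stop("plex ", p, " has no pooled channels")
    rowSums(!is.na(m$abundance[, cols, drop = FALSE])) == 0
  }, logical(nrow(m$abundance)))
  both_missing <- matrix(both_missing, nrow = nrow(m$abundance))
  n_bad <- rowSums(both_missing)
  drop <- n_bad >= length(plexes) / 2
  removed <- data.frame(peptide = rownames(m$abundance)[drop],
                        reason = rep("pooled-missing", sum(drop)),
                        stringsAsFactors = FALSE)
  list(matrix = subset_peptides(m, rownames(m$abundance)[!drop]),
       removed = removed)
}

#' Remove peptides mapped to multiple proteins or genes
#'
#' @param m a `PeptideMatrix`
#' @return list with elements `matrix` (a `PeptideMatrix` whose surviving map
#'   is one-to-one) and `removed` (data.frame with reason `"multi-mapped"`)
#' @export
drop_multimapped <- function(m) {
  n_map <- table(unique(m$pep2prot)[["peptide"]])
  pres <- rownames(m$abundance)
  zero <- setdiff(pres, names(n_map))
  if (length(zero))
    stop("peptides with no protein mapping: ",
         paste(head(zero, 5), collapse = ", "))
  multi <- names(n_map)[n_map > 1]
  multi <- intersect(pres, multi)
  removed <- data.frame(peptide = multi,
                        reason = rep("multi-mapped", length(multi)),
                        stringsAsFactors = FALSE)
  list(matrix = subset_peptides(m, setdiff(pres, multi)), removed = removed)
}

#' Flag subject channels whose total abundance is an outlier
#'
#' Works on log2 channel totals; a subject channel is flagged when its total
#' deviates from the median by more than `k` scaled median absolute
#' deviations (MAD x 1.4826). Pooled channels are never flagged.
#'
#' @param m a `PeptideMatrix`
#' @param k positive multiplier on the scaled MAD (default 3); `Inf` disables
#'   flagging.
#' @return character vector of flagged channel ids with a data.frame of
#'   per-channel statistics attached as attribute `"stats"`
#' @export
detect_outlier_samples <- function(m, k = 3) {
  subj <- subject_channels(m)
  if (length(subj) < 3) stop("need at least 3 subject channels")
  totals <- colSums(m$abundance[, subj, drop = FALSE], na.rm = TRUE)
  lt <- log2(totals)
  med <- median(lt)
  s <- mad(lt)  # includes the 1.4826 consistency constant
  dev <- abs(lt - med)
  if (s == 0) {
    if (any(dev > 0))
      warning("zero MAD with unequal totals; flagging nothing")
    flagged <- character(0)
  } else {
    flagged <- subj[dev > k * s]
  }
  attr(flagged, "stats") <- data.frame(channel = subj, log2_total = lt,
                                       deviation = dev, row.names = NULL)
  flagged
}

#' Internal reference scaling (IRS) across plexes
#'
#' For each peptide and each plex the scaling factor is the ratio of the
#' overall mean of all present pooled-control values (across all plexes) to
#' the mean of that plex's present pooled-control values; all channels of the
#' plex are multiplied by the factor. Afterwards every peptide's within-plex
#' pooled mean equals its overall pooled mean wherever defined. Peptides
#' whose pooled controls are all missing in some plex have no valid factor
#' there: their values in that plex are set to missing.
#'
#' @param m a `PeptideMatrix` (pooled channels required)
#' @return an IRS-normalized `PeptideMatrix`
#' @export
irs_normalize <- function(m) {
  pooled_cols <- pooled_channels(m)
  if (!length(pooled_cols)) stop("no pooled channels present")
  overall <- rowMeans(m$abundance[, pooled_cols, drop = FALSE], na.rm = TRUE)
  ab <- m$abundance
  for (p in unique(m$channels$plex)) {
    in_plex <- m$channels$plex == p
    pcols <- m$channels$channel[in_plex & m$channels$pooled]
    plex_mean <- rowMeans(ab[, pcols, drop = FALSE], na.rm = TRUE)
    factor <- overall / plex_mean      # NaN where plex pooled mean undefined
    cols <- m$channels$channel[in_plex]
    ab[, cols] <- ab[, cols, drop = FALSE] * factor
  }
  ab[is.nan(ab)] <- NA_real_
  m$abundance <- ab
  m
}

#' Median normalization
#'
#' Scales each channel so that its median over present values equals the
#' overall median of all present values (computed before scaling).
#'
#' @param m a `PeptideMatrix`
#' @return a median-normalized `PeptideMatrix` with scaling factors attached
#'   as attribute `"factors"`
#' @export
median_normalize <- function(m) {
  ab <- m$abundance
  if (any(colSums(!is.na(ab)) == 0))
    stop("channel(s) with no present values")
  med <- apply(ab, 2, median, na.rm = TRUE)
  target <- median(ab, na.rm = TRUE)
  factors <- target / med
  m$abundance <- sweep(ab, 2, factors, `*`)
  attr(m, "factors") <- factors
  m
}

#' Present-call filter
#'
#' Retains peptides quantified in at least a given fraction of subject
#' (non-pooled) channels. `threshold = 1` keeps peptides present in 100% of
#' subjects; `threshold = 0.5` corresponds to a missing rate of at most 50%.
#'
#' @param m a `PeptideMatrix`
#' @param threshold required present fraction in (0, 1]
#' @return a filtered `PeptideMatrix`
#' @export
present_call_filter <- function(m, threshold) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  subj <- subject_channels(m)
  frac <- rowMeans(!is.na(m$abundance[, subj, drop = FALSE]))
  subset_peptides(m, rownames(m$abundance)[frac >= threshold])
}

#' Full peptide-level QC and normalization pipeline
#'
#' Applies, in order: zero-to-missing recoding, sample loading normalization,
#' removal of peptides missing in the pooled controls of at least half the
#' plexes, removal of multi-mapped peptides, outlier-sample removal, internal
#' reference scaling, median normalization, and the present-call filter.
#' Outlier status is judged on the raw (pre-normalization) channel totals,
#' since loading normalization equalizes totals by construction.
#'
#' @param m a raw `PeptideMatrix` (zeros allowed)
#' @param present_call present-call threshold in (0, 1] (default 1)
#' @param outlier_k MAD multiplier for outlier detection (default 3)
#' @param remove_outliers drop flagged channels before IRS (default TRUE)
#' @return list with `matrix` (the normalized `PeptideMatrix`) and `report`
#'   (a `NormalizationReport` list: per-channel missing rates, totals before
#'   and after, removed peptides with reasons, flagged outlier channels, and
#'   the stage order executed)
#' @export
normalize_psd <- function(m, present_call = 1, outlier_k = 3,
                          remove_outliers = TRUE) {
  report <- list(stages = character(0))
  m <- zeros_to_missing(m)
  report$missing_rate <- colMeans(is.na(m$abundance))
  report$totals_before <- colSums(m$abundance, na.rm = TRUE)
  report$stages <- c(report$stages, "zeros_to_missing")

  # outlier status is judged on the raw totals: loading normalization
  # equalizes totals by construction, erasing the signal
  flagged <- detect_outlier_samples(m, k = outlier_k)

  m <- sample_loading_normalize(m)
  report$loading_factors <- attr(m, "factors")
  report$stages <- c(report$stages, "sample_loading_normalize")

  fp <- filter_pooled_missing(m)
  m <- fp$matrix
  report$stages <- c(report$stages, "filter_pooled_missing")

  dm <- drop_multimapped(m)
  m <- dm$matrix
  report$removed_peptides <- rbind(fp$removed, dm$removed)
  report$stages <- c(report$stages, "drop_multimapped")

  report$outlier_channels <- as.character(flagged)
  if (remove_outliers && length(flagged)) m <- drop_channels(m, flagged)
  report$stages <- c(report$stages, "detect_outlier_samples")

  m <- irs_normalize(m)
  report$stages <- c(report$stages, "irs_normalize")

  m <- median_normalize(m)
  report$median_factors <- attr(m, "factors")
  report$stages <- c(report$stages, "median_normalize")

  m <- present_call_filter(m, present_call)
  report$stages <- c(report$stages, "present_call_filter")
  report$totals_after <- colSums(m$abundance, na.rm = TRUE)
  report$n_peptides_after <- nrow(m$abundance)
  class(report) <- "NormalizationReport"
  list(matrix = m, report = report)
}
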