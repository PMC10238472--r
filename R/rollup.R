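#' Multiply subject channels by their PSD yield
#'
#' PSD yield (micrograms of PSD protein per microgram of gray-matter protein)
#' is a global proxy for synapse loss; multiplying it back into the
#' normalized linear-scale abundances restores between-subject differences in
#' overall PSD content that loading normalization removed. Pooled channels
#' are left unchanged.
#'
#' @param m a normalized `PeptideMatrix`
#' @param meta sample metadata with columns `sample` and `psd_yield`
#' @return a yield-adjusted `PeptideMatrix`
#' @export
yield_adjust <- function(m, meta) {
  subj <- m$channels[!m$channels$pooled, ]
  yields <- meta$psd_yield[match(subj$sample, meta$sample)]
  bad <- is.na(yields) | yields <= 0
  if (any(bad))
    stop("missing or non-positive PSD yield for sample(s): ",
         paste(subj$sample[bad], collapse = ", "))
  m$abundance[, subj$channel] <-
    sweep(m$abundance[, subj$channel, drop = FALSE], 2, yields, `*`)
  m
}

# log2 values of subject channels, ordered as the channel metadata.
log2_subject_matrix <- function(m) {
  log2(m$abundance[, subject_channels(m), drop = FALSE])
}

#' Flag uncorrelated peptides within each protein
#'
#' For every peptide of a multi-peptide protein, all of the protein's peptide
#' observations (one per peptide x subject, log2 scale, centered per peptide)
#' are modeled as `value ~ group * is_target`, where `is_target` marks the
#' peptide under test. The group-by-peptide interaction F-test asks whether
#' the peptide's condition effect deviates from its protein-mates'. P-values
#' are Benjamini-Hochberg adjusted across all tested peptides; peptides with
#' adjusted p below `alpha` are flagged and later quantified as separate
#' entries by [rollup_protein()].
#'
#' @param m a normalized, yield-adjusted `PeptideMatrix` (linear scale;
#'   log2 is taken internally)
#' @param meta sample metadata with columns `sample` and `group`
#' @param alpha adjusted-p threshold for flagging (default 0.01)
#' @return data.frame (`PecoraFlags`) with columns `peptide`, `protein`,
#'   `f`, `p`, `p_adj`, `flagged`; single-peptide proteins are untested and
#'   absent.
#' @export
pecora_flag <- function(m, meta, alpha = 0.01) {
  x <- log2_subject_matrix(m)
  subj <- m$channels[!m$channels$pooled, ]
  grp <- factor(meta$group[match(subj$sample, meta$sample)])
  if (anyNA(grp)) stop("subject channels without group metadata")
  x <- x - rowMeans(x, na.rm = TRUE)
  map <- m$pep2prot
  prot_of <- map$protein[match(rownames(x), map$peptide)]
  out <- list()
  for (g in unique(prot_of)) {
    peps <- rownames(x)[prot_of == g]
    if (length(peps) < 2) next
    sub <- x[peps, , drop = FALSE]
    long_val <- as.vector(t(sub))
    long_pep <- rep(peps, each = ncol(sub))
    long_grp <- rep(grp, times = length(peps))
    ok <- !is.na(long_val)
    for (p in peps) {
      ind <- factor(long_pep == p)
      fit_full <- lm(long_val[ok] ~ long_grp[ok] * ind[ok])
      fit_red <- lm(long_val[ok] ~ long_grp[ok] + ind[ok])
      an <- anova(fit_red, fit_full)
      out[[length(out) + 1L]] <- data.frame(
        peptide = p, protein = g,
        f = an$F[2], p = an[["Pr(>F)"]][2], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(0), protein = character(0),
                      f = numeric(0), p = numeric(0), p_adj = numeric(0),
                      flagged = logical(0)))
  res <- do.call(rbind, out)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$flagged <- !is.na(res$p_adj) & res$p_adj < alpha
  rownames(res) <- NULL
  res
}

#' Roll peptides up to protein level by z-score averaging
#'
#' Each peptide's log2 values are z-scored across subject channels (mean 0,
#' SD 1 over present values); the protein value for a subject is the mean of
#' its available peptide z-scores. Peptides flagged as uncorrelated are
#' removed from their parent protein and emitted as separate entries named
#' `"<protein>|<peptide>"`. Peptides with zero variance across subjects have
#' no defined z-score and are excluded with a warning.
#'
#' @param m a normalized, yield-adjusted `PeptideMatrix` with a one-to-one
#'   peptide-to-protein map (run [drop_multimapped()] first)
#' @param flags optional `PecoraFlags` data.frame from [pecora_flag()]
#' @return an object of class `ProteinMatrix`: list with `values` (proteins x
#'   subjects matrix) and `provenance` (per entry, the contributing peptides)
#' @export
rollup_protein <- function(m, flags = NULL) {
  map <- unique(m$pep2prot)
  if (any(table(map$peptide) > 1))
    stop("multi-mapped peptides present; run drop_multimapped() first")
  x <- log2_subject_matrix(m)
  subj <- m$channels[!m$channels$pooled, ]
  colnames(x) <- subj$sample

  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, sd, na.rm = TRUE)
  degenerate <- !is.finite(sdv) | sdv == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " peptide(s) with undefined z-score excluded from roll-up")
    x <- x[!degenerate, , drop = FALSE]
    mu <- mu[!degenerate]
    sdv <- sdv[!degenerate]
  }
  z <- (x - mu) / sdv

  prot_of <- map$protein[match(rownames(z), map$peptide)]
  entry_of <- prot_of
  if (!is.null(flags) && nrow(flags)) {
    flagged <- flags$peptide[flags$flagged]
    hit <- rownames(z) %in% flagged
    entry_of[hit] <- paste0(prot_of[hit], "|", rownames(z)[hit])
  }
  entries <- unique(entry_of)
  values <- matrix(NA_real_, length(entries), ncol(z),
                   dimnames = list(entries, colnames(z)))
  provenance <- vector("list", length(entries))
  names(provenance) <- entries
  for (i in seq_along(entries)) {
    peps <- rownames(z)[entry_of == entries[i]]
    sub <- z[peps, , drop = FALSE]
    v <- colMeans(sub, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    values[i, ] <- v
    provenance[[i]] <- peps
  }
  structure(list(values = values, provenance = provenance),
            class = "ProteinMatrix")
}

#' @export
print.ProteinMatrix <- function(x, ...) {
  cat(sprintf("ProteinMatrix: %d protein entries x %d subjects\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
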