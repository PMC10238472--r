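# Independent brute-force oracles (explicit loops, no shared code with the
# implementation) and small fixture builders.

# Build a PeptideMatrix from a plain matrix. `plex` and `pooled` are
# per-column; samples are auto-named for non-pooled channels. `proteins`
# maps peptides to proteins (named list for multi-mapping).
toy_pm <- function(ab, plex = rep(1L, ncol(ab)),
                   pooled = rep(FALSE, ncol(ab)), proteins = NULL) {
  if (is.null(rownames(ab))) rownames(ab) <- paste0("pep", seq_len(nrow(ab)))
  if (is.null(colnames(ab))) colnames(ab) <- paste0("ch", seq_len(ncol(ab)))
  channels <- data.frame(
    channel = colnames(ab), plex = plex,
    sample = ifelse(pooled, NA_character_,
                    paste0("s", cumsum(!pooled))),
    pooled = pooled, stringsAsFactors = FALSE)
  if (is.null(proteins)) {
    p2p <- data.frame(peptide = rownames(ab),
                      protein = paste0("prot_", rownames(ab)))
  } else if (is.list(proteins)) {
    p2p <- do.call(rbind, lapply(rownames(ab), function(p)
      data.frame(peptide = p, protein = proteins[[p]])))
  } else {
    p2p <- data.frame(peptide = rownames(ab), protein = proteins)
  }
  peptide_matrix(ab, channels, p2p)
}

# Brute-force z-score roll-up with uncorrelated-peptide splitting:
# explicit loops over entries and subjects.
brute_rollup <- function(x_log2, pep2prot, flagged = character(0)) {
  entry_of <- character(nrow(x_log2))
  for (i in seq_len(nrow(x_log2))) {
    pep <- rownames(x_log2)[i]
    prot <- pep2prot$protein[pep2prot$peptide == pep]
    entry_of[i] <- if (pep %in% flagged) paste0(prot, "|", pep) else prot
  }
  z <- x_log2
  keep <- rep(TRUE, nrow(x_log2))
  for (i in seq_len(nrow(x_log2))) {
    v <- x_log2[i, ]
    mu <- mean(v[!is.na(v)])
    s <- sd(v[!is.na(v)])
    if (!is.finite(s) || s == 0) { keep[i] <- FALSE; next }
    for (j in seq_len(ncol(x_log2)))
      z[i, j] <- (x_log2[i, j] - mu) / s
  }
  entries <- unique(entry_of[keep])
  out <- matrix(NA_real_, length(entries), ncol(x_log2),
                dimnames = list(entries, colnames(x_log2)))
  for (e in entries) {
    rows <- which(entry_of == e & keep)
    for (j in seq_len(ncol(x_log2))) {
      vals <- z[rows, j]
      vals <- vals[!is.na(vals)]
      out[e, j] <- if (length(vals)) sum(vals) / length(vals) else NA_real_
    }
  }
  out
}

# Brute-force Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, n * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Brute-force Pearson chi-square on a 2x2 table.
brute_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Normal-equations least squares.
brute_lm <- function(X, y) solve(t(X) %*% X, t(X) %*% y)[, 1]

# A small normalized synthetic study shared by several tests.
small_study <- function(seed = 11, n_proteins = 60, ...) {
  cfg <- sim_config(n_adp = 16, n_adnp = 16, n_cn = 10,
                    n_proteins = n_proteins, rng_seed = seed, ...)
  cohort <- generate_cohort(cfg)
  gen <- generate_peptide_data(cfg, cohort)
  list(cfg = cfg, cohort = cohort, raw = gen$matrix, truth = gen$truth)
}
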