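#' Construct a signed signature
#'
#' The common currency of the repurposing chain: a set of entities (proteins
#' or genes), each carrying a direction of change (+1 or -1) and optionally a
#' magnitude (log2 fold change or Z score). Zero-signed entities are dropped
#' with a warning; entities must be unique.
#'
#' @param entity character vector of entity ids
#' @param sign numeric vector of directions; coerced with `sign()`
#' @param magnitude optional numeric magnitudes (kept with their sign)
#' @param label optional label describing provenance
#' @return an object of class `SignedSignature` (data.frame with columns
#'   `entity`, `sign`, and optionally `magnitude`)
#' @export
signed_signature <- function(entity, sign, magnitude = NULL, label = "") {
  entity <- as.character(entity)
  s <- base::sign(sign)
  zero <- s == 0 | is.na(s)
  if (any(zero)) {
    warning(sum(zero), " zero/undefined-sign entities dropped")
    entity <- entity[!zero]
    s <- s[!zero]
    if (!is.null(magnitude)) magnitude <- magnitude[!zero]
  }
  if (anyDuplicated(entity)) stop("duplicated entities in signature")
  df <- data.frame(entity = entity, sign = s, stringsAsFactors = FALSE)
  if (!is.null(magnitude)) df$magnitude <- magnitude
  structure(df, class = c("SignedSignature", "data.frame"), label = label)
}

#' Build the disease signature from a differential result
#'
#' @param result a `DifferentialResult`
#' @param mode `"full"` uses every protein with nonzero log2 fold change;
#'   `"top"` restricts to proteins with raw `p < alpha` (the nominally
#'   significant subset)
#' @param alpha raw-p threshold used by `mode = "top"` (default 0.05)
#' @return a `SignedSignature` with the log2 fold changes as magnitudes
#' @export
build_signature <- function(result, mode = c("full", "top"), alpha = 0.05) {
  mode <- match.arg(mode)
  keep <- is.finite(result$log2fc)
  if (mode == "top") keep <- keep & !is.na(result$p) & result$p < alpha
  r <- result[keep, , drop = FALSE]
  signed_signature(r$protein, r$log2fc, magnitude = r$log2fc,
                   label = paste0(attr(result, "contrast"), ":", mode))
}

#' Correlate knockdown signatures with a disease signature
#'
#' For each gene in the knockdown atlas, computes the rank (Spearman, the
#' default) or Pearson correlation between its signed knockdown values and
#' the disease signature's magnitudes (signs when no magnitudes are stored)
#' over shared entities. Genes with fewer than `min_shared` shared entities,
#' or with a constant value vector, are skipped with a reason.
#'
#' @param atlas data.frame with columns `gene`, `entity`, `value`
#' @param sig a `SignedSignature`
#' @param min_shared minimum shared entities (default 10)
#' @param method `"spearman"` (default) or `"pearson"`
#' @return data.frame with columns `gene`, `n_shared`, `rho`, `p`, `sign`,
#'   `status`
#' @export
correlate_knockdown <- function(atlas, sig, min_shared = 10,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ref <- if ("magnitude" %in% names(sig)) sig$magnitude else sig$sign
  names(ref) <- sig$entity
  genes <- unique(atlas$gene)
  out <- lapply(genes, function(g) {
    sub <- atlas[atlas$gene == g, , drop = FALSE]
    sub <- sub[sub$entity %in% names(ref), , drop = FALSE]
    n <- nrow(sub)
    if (n < min_shared)
      return(data.frame(gene = g, n_shared = n, rho = NA_real_, p = NA_real_,
                        sign = NA_real_, status = "too few shared entities"))
    x <- sub$value
    y <- unname(ref[sub$entity])
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(gene = g, n_shared = n, rho = NA_real_, p = NA_real_,
                        sign = NA_real_, status = "constant vector"))
    ct <- suppressWarnings(cor.test(x, y, method = method))
    data.frame(gene = g, n_shared = n, rho = unname(ct$estimate),
               p = ct$p.value, sign = sign(unname(ct$estimate)),
               status = "ok", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Action vocabulary: free-text-ish action strings normalized onto the closed
# vocabulary used by the nomination rule.
.action_map <- c(
  inhibitor = "inhibitor", antagonist = "antagonist",
  blocker = "antagonist", "negative modulator" = "negative modulator",
  "negative allosteric modulator" = "negative modulator",
  agonist = "agonist", potentiator = "potentiator",
  activator = "agonist", inducer = "potentiator",
  "positive modulator" = "positive modulator",
  "positive allosteric modulator" = "positive modulator")

.negative_actions <- c("inhibitor", "antagonist", "negative modulator")
.positive_actions <- c("agonist", "potentiator", "positive modulator")

normalize_action <- function(action) {
  unname(.action_map[tolower(trimws(action))])
}

#' Nominate drugs whose target action aligns with the knockdown correlation
#'
#' A gene whose knockdown signature correlates *negatively* with the disease
#' signature is one whose loss of function opposes the disease pattern, so
#' drugs that inhibit or antagonize it are predicted to reverse the
#' signature; a *positively* correlated gene is nominated with agonists,
#' potentiators or positive modulators. Only genes whose correlation passed
#' the significance screen (`p < alpha`) are considered. Rows with an action
#' outside the recognized vocabulary are skipped with a warning.
#'
#' @param correlations output of [correlate_knockdown()]
#' @param drugs data.frame with columns `drug`, `gene`, `action`
#' @param alpha significance threshold on the knockdown correlation p-value
#'   used as the screening step (default 0.01)
#' @return data.frame of candidates: `drug`, `gene`, `action`, `rho`,
#'   `sign`, `rule`
#' @export
nominate_drugs <- function(correlations, drugs, alpha = 0.01) {
  hits <- correlations[correlations$status == "ok" &
                         !is.na(correlations$p) & correlations$p < alpha, ,
                       drop = FALSE]
  cand <- merge(drugs, hits[, c("gene", "rho", "sign")], by = "gene")
  if (!nrow(cand))
    return(data.frame(drug = character(0), gene = character(0),
                      action = character(0), rho = numeric(0),
                      sign = numeric(0), rule = character(0)))
  act <- normalize_action(cand$action)
  unknown <- is.na(act)
  if (any(unknown)) {
    warning("skipping rows with unrecognized action: ",
            paste(unique(cand$action[unknown]), collapse = ", "))
    cand <- cand[!unknown, , drop = FALSE]
    act <- act[!unknown]
  }
  keep <- (cand$sign < 0 & act %in% .negative_actions) |
          (cand$sign > 0 & act %in% .positive_actions)
  rule <- ifelse(cand$sign < 0,
                 "negative knockdown correlation + inhibitory action",
                 "positive knockdown correlation + potentiating action")
  out <- data.frame(drug = cand$drug, gene = cand$gene, action = act,
                    rho = cand$rho, sign = cand$sign, rule = rule,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$drug, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates whose top-subset correlation flips sign
#'
#' Recomputes each candidate gene's knockdown correlation against the
#' restricted signature of the most differentially expressed proteins and
#' drops candidates whose top-subset correlation sign disagrees with the
#' full-signature correlation sign (the behavior that excluded MTOR-class
#' targets). Genes whose top-subset overlap is below `min_shared` are
#' retained but flagged untestable.
#'
#' @param atlas knockdown atlas data.frame (`gene`, `entity`, `value`)
#' @param full_sig,top_sig `SignedSignature`s built from the same contrast
#'   with `mode = "full"` and `mode = "top"`
#' @param candidates output of [nominate_drugs()]
#' @param min_shared minimum shared entities for the subset correlation
#' @param method correlation method, as in [correlate_knockdown()]
#' @return the candidate data.frame with added columns `rho_full`,
#'   `rho_top`, `consistent`, `untestable`, restricted to candidates that
#'   were not dropped
#' @export
subset_consistency_filter <- function(atlas, full_sig, top_sig, candidates,
                                      min_shared = 10,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!nrow(candidates)) {
    candidates$rho_full <- candidates$rho_top <- numeric(0)
    candidates$consistent <- candidates$untestable <- logical(0)
    return(candidates)
  }
  genes <- unique(candidates$gene)
  top <- correlate_knockdown(atlas[atlas$gene %in% genes, , drop = FALSE],
                             top_sig, min_shared = min_shared,
                             method = method)
  idx <- match(candidates$gene, top$gene)
  candidates$rho_full <- candidates$rho
  candidates$rho_top <- top$rho[idx]
  candidates$untestable <- top$status[idx] != "ok"
  candidates$consistent <- candidates$untestable |
    (sign(candidates$rho_top) == sign(candidates$rho_full))
  out <- candidates[candidates$consistent, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drug expression signature from LINCS-style Z-score profiles
#'
#' Keeps only tests on CNS-derived cell lines (when `cns_only`) at doses of
#' at least `min_dose` micromolar, averages the Z scores of repeated tests of
#' the same gene, and retains genes with `|mean Z| > z_thresh`; the sign of
#' the mean Z is the signature direction.
#'
#' @param profiles data.frame with columns `drug`, `gene`, `z`, `cell_line`,
#'   `is_cns` (logical), `dose_um`
#' @param drug drug name to extract
#' @param cns_only restrict to CNS cell lines (default TRUE)
#' @param min_dose minimum dose in micromolar (default 1)
#' @param z_thresh significance threshold on `|mean Z|` (default 1)
#' @return a `SignedSignature` (possibly empty) with mean Z magnitudes and a
#'   `status` attribute: `"ok"`, `"not found"`, `"not tested in CNS cells"`,
#'   or `"no test at qualifying dose"`
#' @export
lincs_signature <- function(profiles, drug, cns_only = TRUE, min_dose = 1,
                            z_thresh = 1) {
  empty <- function(status) {
    s <- signed_signature(character(0), numeric(0), numeric(0), label = drug)
    attr(s, "status") <- status
    s
  }
  rows <- profiles[profiles$drug == drug, , drop = FALSE]
  if (!nrow(rows)) return(empty("not found"))
  if (cns_only) {
    rows <- rows[as.logical(rows$is_cns), , drop = FALSE]
    if (!nrow(rows)) return(empty("not tested in CNS cells"))
  }
  rows <- rows[rows$dose_um >= min_dose, , drop = FALSE]
  if (!nrow(rows)) return(empty("no test at qualifying dose"))
  mz <- tapply(rows$z, rows$gene, mean)
  keep <- abs(mz) > z_thresh
  s <- signed_signature(names(mz)[keep], mz[keep], magnitude = mz[keep],
                        label = drug)
  attr(s, "status") <- "ok"
  s
}

#' Signed Jaccard Index of two signed signatures
#'
#' `J = (|A+ & B+| + |A- & B-| - |A+ & B-| - |A- & B+|) / |supp(A) u supp(B)|`
#' where the support is the set of signed entities. J ranges from +1 (same
#' direction pattern) to -1 (fully inverted pattern); an empty union gives 0.
#'
#' @param a,b `SignedSignature`s
#' @return a number in `[-1, 1]`
#' @export
signed_jaccard <- function(a, b) {
  union_n <- length(union(a$entity, b$entity))
  if (union_n == 0) return(0)
  sa <- a$sign[match(b$entity, a$entity)]
  shared <- !is.na(sa)
  concordant <- sum(sa[shared] == b$sign[shared])
  discordant <- sum(sa[shared] != b$sign[shared])
  (concordant - discordant) / union_n
}

#' Full drug-screening chain on signature inputs
#'
#' Runs knockdown correlation, action-aligned nomination, the top-subset
#' consistency filter, and LINCS-style validation, returning one row per
#' surviving candidate drug with its Signed Jaccard reversal score against
#' the disease signature. Output is ordered by J ascending (strongest
#' predicted reversal first), ties broken by drug name.
#'
#' @param atlas knockdown atlas data.frame (`gene`, `entity`, `value`)
#' @param drugs drug-target table (`drug`, `gene`, `action`)
#' @param lincs LINCS-style profile table (see [lincs_signature()])
#' @param full_sig,top_sig disease `SignedSignature`s (full and top subset)
#' @param alpha screening threshold for [nominate_drugs()]
#' @param min_shared minimum shared entities for correlations
#' @param method correlation method
#' @param cns_only,min_dose,z_thresh LINCS filter parameters
#' @return data.frame with columns `drug`, `gene`, `action`, `rho_full`,
#'   `rho_top`, `lincs_status`, `lincs_n`, `signed_jaccard`
#' @export
screen_drugs <- function(atlas, drugs, lincs, full_sig, top_sig,
                         alpha = 0.01, min_shared = 10,
                         method = c("spearman", "pearson"),
                         cns_only = TRUE, min_dose = 1, z_thresh = 1) {
  method <- match.arg(method)
  corr <- correlate_knockdown(atlas, full_sig, min_shared = min_shared,
                              method = method)
  cand <- nominate_drugs(corr, drugs, alpha = alpha)
  cand <- subset_consistency_filter(atlas, full_sig, top_sig, cand,
                                    min_shared = min_shared, method = method)
  if (!nrow(cand)) {
    return(data.frame(drug = character(0), gene = character(0),
                      action = character(0), rho_full = numeric(0),
                      rho_top = numeric(0), lincs_status = character(0),
                      lincs_n = integer(0), signed_jaccard = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    sig <- lincs_signature(lincs, cand$drug[i], cns_only = cns_only,
                           min_dose = min_dose, z_thresh = z_thresh)
    data.frame(drug = cand$drug[i], gene = cand$gene[i],
               action = cand$action[i], rho_full = cand$rho_full[i],
               rho_top = cand$rho_top[i],
               lincs_status = attr(sig, "status"),
               lincs_n = nrow(sig),
               signed_jaccard = if (nrow(sig)) signed_jaccard(sig, full_sig)
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$signed_jaccard, out$drug, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
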