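#' Per-protein treatment vs vehicle log2 fold change
#'
#' Mean difference (treated minus vehicle) of rolled-up protein values,
#' complete-case per protein within each arm.
#'
#' @param pm a `ProteinMatrix` from the treatment experiment
#' @param labels named character vector over the matrix's sample columns
#'   with values `"treated"` or `"vehicle"`
#' @return named numeric vector of log2 fold changes
#' @export
treatment_log2fc <- function(pm, labels) {
  stopifnot(inherits(pm, "ProteinMatrix"))
  labels <- labels[colnames(pm$values)]
  if (anyNA(labels)) stop("every sample column needs a treatment label")
  tr <- names(labels)[labels == "treated"]
  vh <- names(labels)[labels == "vehicle"]
  if (length(tr) < 2 || length(vh) < 2)
    stop("need at least 2 samples per arm")
  rowMeans(pm$values[, tr, drop = FALSE], na.rm = TRUE) -
    rowMeans(pm$values[, vh, drop = FALSE], na.rm = TRUE)
}

#' Evaluate a drug treatment against a disease signature
#'
#' Tests whether the treatment shifts the proteins of the disease signature
#' away from zero (one-sample two-sided t-tests on the treatment log2 fold
#' changes over (a) all proteins shared with the full disease signature and
#' (b) the subset also in the top differentially expressed signature), and
#' scores directional reversal with the Signed Jaccard Index between the
#' drug-effect signature (signs of the fold changes over the full overlap)
#' and the disease signature.
#'
#' @param fc named numeric vector of treatment log2 fold changes
#' @param disease_full full disease `SignedSignature`
#' @param disease_top top-subset disease `SignedSignature`
#' @return a `TreatmentResult` list: `fc`, `overlap_full`, `overlap_top`,
#'   `t_full`, `t_top` (each `list(t, df, p, mean)`), `drug_signature`, `j`
#' @export
reversal_test <- function(fc, disease_full, disease_top) {
  fc <- fc[is.finite(fc)]
  overlap_full <- intersect(names(fc), disease_full$entity)
  if (length(overlap_full) < 2)
    stop("fewer than 2 proteins overlap the disease signature")
  overlap_top <- intersect(overlap_full, disease_top$entity)
  one_sample <- function(v) {
    if (length(v) < 2 || sd(v) == 0)
      stop("zero-variance or too-short fold-change vector")
    tt <- t.test(v, mu = 0)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean = unname(tt$estimate))
  }
  nz <- overlap_full[fc[overlap_full] != 0]
  drug_sig <- signed_signature(nz, fc[nz], magnitude = fc[nz],
                               label = "treatment")
  structure(list(fc = fc,
                 overlap_full = overlap_full,
                 overlap_top = overlap_top,
                 t_full = one_sample(fc[overlap_full]),
                 t_top = if (length(overlap_top) >= 2)
                           one_sample(fc[overlap_top]) else NULL,
                 drug_signature = drug_sig,
                 j = signed_jaccard(drug_sig, disease_full)),
            class = "TreatmentResult")
}

#' @export
print.TreatmentResult <- function(x, ...) {
  cat(sprintf("TreatmentResult: %d/%d proteins overlap full/top disease signature\n",
              length(x$overlap_full), length(x$overlap_top)))
  cat(sprintf("  full-set shift: mean %.4f, t = %.2f, df = %d, p = %.3g\n",
              x$t_full$mean, x$t_full$t, x$t_full$df, x$t_full$p))
  if (!is.null(x$t_top))
    cat(sprintf("  top-subset shift: mean %.4f, t = %.2f, df = %d, p = %.3g\n",
                x$t_top$mean, x$t_top$t, x$t_top$df, x$t_top$p))
  cat(sprintf("  Signed Jaccard vs disease signature: %.5f\n", x$j))
  invisible(x)
}
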