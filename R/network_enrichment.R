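#' Read a protein-protein interaction edge list
#'
#' Accepts 2- or 3-column TSV (`protein_a`, `protein_b`[, `score`]), the
#' shape of a STRING-style export.
#'
#' @param path path to a TSV file
#' @param min_score drop edges with score below this value (default 0,
#'   i.e. accept all edges; ignored when the file has no score column)
#' @return data.frame with columns `protein_a`, `protein_b` and optionally
#'   `score`
#' @export
read_edge_list <- function(path, min_score = 0) {
  g <- read_tsv_file(path)
  names(g)[1:2] <- c("protein_a", "protein_b")
  if (ncol(g) >= 3) {
    names(g)[3] <- "score"
    g <- g[g$score >= min_score, , drop = FALSE]
  }
  g
}

#' Enrichment of interaction with a seed set among DE proteins
#'
#' A protein "interacts" when it has at least one edge to a seed-set member
#' (self-loops ignored; seed members are excluded from the background). The
#' association between differential expression and interaction is tested on
#' the 2x2 table {DE, non-DE} x {interacting, not} with Pearson's chi-square
#' statistic without continuity correction (df = 1).
#'
#' @param graph data.frame edge list (`protein_a`, `protein_b`[, `score`])
#' @param seed character vector, the seed proteins (e.g. a kinase set)
#' @param de character vector of differentially expressed proteins
#' @param background character vector of all analyzed proteins; seed members
#'   are removed from it (and from `de`) before tabulation
#' @param min_score optional score threshold applied to the edge list
#' @return list with `table` (2x2 counts), `chi2`, `df`, `p`, and
#'   `proportions` (interacting fraction in DE and non-DE); a `warning`
#'   element is attached when any expected cell count is below 1
#' @export
interaction_enrichment <- function(graph, seed, de, background,
                                   min_score = 0) {
  if ("score" %in% names(graph))
    graph <- graph[graph$score >= min_score, , drop = FALSE]
  graph <- graph[graph$protein_a != graph$protein_b, , drop = FALSE]
  partners <- unique(c(graph$protein_b[graph$protein_a %in% seed],
                       graph$protein_a[graph$protein_b %in% seed]))
  partners <- setdiff(partners, seed)

  background <- setdiff(unique(background), seed)
  de <- intersect(unique(de), background)
  nonde <- setdiff(background, de)
  if (!length(de) || !length(nonde))
    stop("both the DE and non-DE sets must be non-empty after excluding the seed")

  tab <- matrix(c(sum(de %in% partners), sum(!(de %in% partners)),
                  sum(nonde %in% partners), sum(!(nonde %in% partners))),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("DE", "nonDE"),
                                c("interacting", "not_interacting")))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- list(table = tab,
              chi2 = unname(ct$statistic),
              df = unname(ct$parameter),
              p = ct$p.value,
              proportions = c(DE = tab[1, 1] / sum(tab[1, ]),
                              nonDE = tab[2, 1] / sum(tab[2, ])))
  if (any(ct$expected < 1))
    out$warning <- "expected cell count below 1; chi-square approximation unreliable"
  out
}
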