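#' Construct a peptide abundance matrix with channel and mapping metadata
#'
#' The common quantitative container of the pipeline: a peptides x channels
#' matrix of non-negative linear-scale abundances (missing values as `NA`),
#' per-channel metadata assigning every channel to a multiplex (plex) and
#' marking the pooled-control channels, and a peptide-to-protein map that may
#' contain multi-mapped peptides until [drop_multimapped()] is applied.
#'
#' @param abundance numeric matrix, peptides in rows (rownames = peptide ids),
#'   channels in columns (colnames = channel ids). Values must be `>= 0` or
#'   `NA`; exact zeros are permitted on input and converted to missing by
#'   [zeros_to_missing()].
#' @param channels data.frame with columns `channel`, `plex`, `sample`
#'   (`NA` for pooled channels) and logical `pooled`; one row per column of
#'   `abundance`, in the same order.
#' @param pep2prot data.frame with columns `peptide` and `protein`; peptides
#'   mapping to several proteins occupy several rows.
#' @return an object of class `PeptideMatrix`.
#' @export
peptide_matrix <- function(abundance, channels, pep2prot) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("`abundance` must be a numeric matrix")
  if (nrow(abundance) > 0 && is.null(rownames(abundance)))
    stop("`abundance` needs peptide rownames")
  if (ncol(abundance) > 0 && is.null(colnames(abundance)))
    stop("`abundance` needs channel colnames")
  if (is.null(rownames(abundance))) rownames(abundance) <- character(0)
  if (is.null(colnames(abundance))) colnames(abundance) <- character(0)
  req <- c("channel", "plex", "sample", "pooled")
  if (!all(req %in% names(channels)))
    stop("`channels` must have columns ", paste(req, collapse = ", "))
  channels$channel <- as.character(channels$channel)
  channels$sample <- as.character(channels$sample)
  if (!identical(colnames(abundance), channels$channel))
    stop("channel metadata does not match abundance columns")
  if (any(duplicated(channels$channel)))
    stop("duplicated channel ids")
  if (any(channels$pooled & !is.na(channels$sample)))
    stop("pooled channels must not carry a sample id")
  if (any(abundance < 0, na.rm = TRUE))
    stop("negative abundances are not allowed")
  if (!all(c("peptide", "protein") %in% names(pep2prot)))
    stop("`pep2prot` must have columns peptide, protein")
  pep2prot$peptide <- as.character(pep2prot$peptide)
  pep2prot$protein <- as.character(pep2prot$protein)
  unmapped <- setdiff(rownames(abundance), pep2prot$peptide)
  if (length(unmapped))
    stop("peptides without a protein mapping: ",
         paste(head(unmapped, 5), collapse = ", "))
  structure(
    list(abundance = abundance,
         channels = channels[, req],
         pep2prot = pep2prot[pep2prot$peptide %in% rownames(abundance),
                             c("peptide", "protein")]),
    class = "PeptideMatrix")
}

#' @export
print.PeptideMatrix <- function(x, ...) {
  cat(sprintf("PeptideMatrix: %d peptides x %d channels (%d plexes, %d pooled channels)\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$channels$plex)), sum(x$channels$pooled)))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$abundance))))
  invisible(x)
}

#' Channel ids of subject (non-pooled) channels
#' @param m a `PeptideMatrix`
#' @return character vector of channel ids
#' @export
subject_channels <- function(m) m$channels$channel[!m$channels$pooled]

#' Channel ids of pooled-control channels
#' @param m a `PeptideMatrix`
#' @return character vector of channel ids
#' @export
pooled_channels <- function(m) m$channels$channel[m$channels$pooled]

# Keep a subset of peptides, preserving metadata.
subset_peptides <- function(m, keep) {
  keep <- intersect(rownames(m$abundance), keep)
  peptide_matrix(m$abundance[keep, , drop = FALSE], m$channels,
                 m$pep2prot[m$pep2prot$peptide %in% keep, , drop = FALSE])
}

# Remove channels (e.g. flagged outlier samples).
drop_channels <- function(m, drop) {
  keep <- !(m$channels$channel %in% drop)
  peptide_matrix(m$abundance[, keep, drop = FALSE],
                 m$channels[keep, , drop = FALSE], m$pep2prot)
}

#' Write / read a PeptideMatrix as a trio of TSV files
#'
#' Files are `<prefix>_abundance.tsv` (first column `peptide`, one column per
#' channel), `<prefix>_channels.tsv` and `<prefix>_pep2prot.tsv`. All files
#' are tab-separated with a header row; missing values are written as empty
#' fields.
#'
#' @param m a `PeptideMatrix`
#' @param prefix path prefix for the three files
#' @return `write_peptide_matrix` returns the file paths invisibly;
#'   `read_peptide_matrix` returns a `PeptideMatrix`.
#' @export
write_peptide_matrix <- function(m, prefix) {
  ab <- data.frame(peptide = rownames(m$abundance), m$abundance,
                   check.names = FALSE)
  paths <- paste0(prefix, c("_abundance.tsv", "_channels.tsv", "_pep2prot.tsv"))
  write_tsv_file(ab, paths[1])
  write_tsv_file(m$channels, paths[2])
  write_tsv_file(m$pep2prot, paths[3])
  invisible(paths)
}

#' @rdname write_peptide_matrix
#' @export
read_peptide_matrix <- function(prefix) {
  ab <- read_tsv_file(paste0(prefix, "_abundance.tsv"))
  channels <- read_tsv_file(paste0(prefix, "_channels.tsv"))
  channels$pooled <- as.logical(channels$pooled)
  pep2prot <- read_tsv_file(paste0(prefix, "_pep2prot.tsv"))
  mat <- as.matrix(ab[, -1, drop = FALSE])
  rownames(mat) <- ab$peptide
  peptide_matrix(mat, channels, pep2prot)
}

# TSV dialect shared by all tabular artifacts: header row, tab-separated,
# UTF-8, missing encoded as an empty field.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
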