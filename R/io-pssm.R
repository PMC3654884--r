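## PSI-BLAST ASCII PSSM parsing.
##
## The ASCII profile written by `psiblast -out_ascii_pssm` carries, per
## residue position: the position index, the query residue, 20 log-odds
## scores, 20 weighted-percentage columns, and two trailing statistics.
## Only the first 20 numeric columns (the log-odds block) are used here.

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the ASCII PSSM dialect produced by PSI-BLAST into an L x 20 score
#' matrix, keeping only the first 20 score columns of each row (the log-odds
#' block; the weighted-percentage block is ignored). Columns are reordered to
#' the alphabetical amino-acid order A, C, D, ..., Y using the amino-acid
#' header line when one is present; files without a header are assumed to use
#' BLAST's native column order (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param path Path to an ASCII PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A `pssm_matrix`: list with `protein_id`, `scores` (L x 20 numeric
#'   matrix, columns named by [AMINO_ACIDS]), and `residues` (the per-position
#'   query residue column, for cross-checking against the FASTA sequence).
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) rawalk_stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  aa_order <- NULL
  rows <- list()
  residues <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0L) next
    ## amino-acid header: >= 20 single-letter tokens, take the first 20
    if (is.null(aa_order) && length(tok) >= 20L &&
        all(nchar(tok[1:20]) == 1L) && all(tok[1:20] %in% AMINO_ACIDS)) {
      aa_order <- tok[1:20]
      next
    }
    ## data row: integer position, single-letter residue, then scores
    if (length(tok) >= 2L && grepl("^[0-9]+$", tok[[1L]]) &&
        nchar(tok[[2L]]) == 1L && grepl("^[A-Za-z]$", tok[[2L]])) {
      vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
      if (length(vals) < 20L || anyNA(vals[1:20]))
        rawalk_stop("PSSM '", path, "' line ", ln,
                    ": expected 20 numeric scores, found ",
                    sum(!is.na(vals)), " parsable value(s)")
      rows[[length(rows) + 1L]] <- vals[1:20]
      residues <- c(residues, toupper(tok[[2L]]))
    }
  }
  if (length(rows) == 0L)
    rawalk_stop("PSSM '", path, "' contains no score rows")
  scores <- do.call(rbind, rows)
  if (!all(is.finite(scores)))
    rawalk_stop("PSSM '", path, "' contains non-finite scores")
  aa_order <- aa_order %||% BLAST_AA_ORDER
  colnames(scores) <- aa_order
  scores <- scores[, AMINO_ACIDS, drop = FALSE]
  pssm_matrix(protein_id %||% sub("\\.[^.]*$", "", basename(path)),
              scores, residues)
}

#' Construct a PSSM matrix object
#'
#' @param protein_id Identifier of the protein the profile belongs to.
#' @param scores L x 20 numeric matrix, columns in alphabetical amino-acid
#'   order.
#' @param residues Optional character vector of the per-position query
#'   residues (length L).
#' @return A `pssm_matrix` object.
#' @export
pssm_matrix <- function(protein_id, scores, residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L)
    rawalk_stop("PSSM must have exactly 20 columns, got ", ncol(scores))
  if (nrow(scores) < 1L) rawalk_stop("PSSM has zero rows")
  if (!all(is.finite(scores))) rawalk_stop("PSSM contains non-finite entries")
  if (!is.null(residues) && length(residues) != nrow(scores))
    rawalk_stop("residue column length ", length(residues),
                " does not match PSSM row count ", nrow(scores))
  colnames(scores) <- AMINO_ACIDS
  structure(list(protein_id = as.character(protein_id), scores = scores,
                 residues = residues),
            class = "pssm_matrix")
}

#' @export
print.pssm_matrix <- function(x, ...) {
  cat("<pssm_matrix> ", x$protein_id, ": ", nrow(x$scores), " x 20 scores\n",
      sep = "")
  invisible(x)
}
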