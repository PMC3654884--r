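## FASTA input/output for protein records.

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a list of protein records. Each
#' record is a list with elements `id` (first word of the header), `sequence`
#' (uppercase residue string), `length`, and `removed` (1-based positions of
#' residues dropped in lenient mode, used downstream to drop the matching
#' PSSM rows).
#'
#' Only the 20 standard amino acids are accepted. In strict mode any other
#' symbol (B, J, O, U, X, Z, ...) is an error naming the residue and its
#' position; in lenient mode such residues are removed with a message.
#'
#' @param path Path to a FASTA file.
#' @param strict Logical; error on non-standard residues (default `TRUE`)
#'   instead of dropping them.
#' @return A list of `protein_record` objects, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "ACDEFG"), fa)
#' read_fasta(fa)[[1]]$length  # 6
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) rawalk_stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) rawalk_stop("malformed FASTA '", path, "': ",
                                                  conditionMessage(e)))
  if (length(set) == 0L) rawalk_stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids) | is.na(ids)))
    rawalk_stop("malformed FASTA header (empty id) in ", path)
  seqs <- toupper(as.character(set))
  lapply(seq_along(seqs), function(i) {
    sanitize_sequence(ids[[i]], seqs[[i]], strict = strict)
  })
}

## Validate a residue string against the 20-letter alphabet; returns a
## protein_record, recording removed positions in lenient mode.
sanitize_sequence <- function(id, sequence, strict = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AMINO_ACIDS)
  if (length(bad) > 0L) {
    if (strict) {
      rawalk_stop("illegal residue '", chars[bad[1L]], "' at position ", bad[1L],
                  " in sequence '", id, "' (strict mode)")
    }
    message("read_fasta: removed ", length(bad), " non-standard residue(s) (",
            paste(unique(chars[bad]), collapse = ","), ") from '", id, "'")
    chars <- chars[-bad]
  }
  if (length(chars) == 0L)
    rawalk_stop("sequence '", id, "' has no standard residues")
  protein_record(id, paste(chars, collapse = ""), removed = bad)
}

#' Construct a protein record
#'
#' @param id Record identifier.
#' @param sequence Residue string over the 20-letter amino-acid alphabet.
#' @param removed Integer positions removed from the raw sequence during
#'   sanitization (empty when none).
#' @return A `protein_record`: list with `id`, `sequence`, `length`, `removed`.
#' @export
protein_record <- function(id, sequence, removed = integer(0)) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < 1L) rawalk_stop("empty sequence for '", id, "'")
  if (!all(chars %in% AMINO_ACIDS))
    rawalk_stop("sequence '", id, "' contains non-standard residues")
  structure(list(id = as.character(id), sequence = sequence,
                 length = length(chars), removed = as.integer(removed)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", x$length, " aa)\n", sep = "")
  invisible(x)
}

#' Write protein records to a FASTA file
#'
#' @param records List of `protein_record` objects.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) == 0L) rawalk_stop("no records to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$sequence, starts, pmin(starts + width - 1L, r$length)), con)
  }
  invisible(path)
}
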