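## Protein descriptors: PSSM column means + type-1 pseudo-amino-acid
## composition (PseAA), concatenated into the combined feature vector.

#' Load the standardized amino-acid property tables
#'
#' Reads the shipped hydrophobicity, hydrophilicity and side-chain-mass
#' tables and standardizes each to mean 0 and unit population standard
#' deviation over the 20 amino acids — the classical normalization of the
#' type-1 PseAA construction.
#'
#' @param path Optional path to an alternative property table (TSV with
#'   columns `aa`, `hydrophobicity`, `hydrophilicity`, `side_chain_mass`).
#' @return A 20 x 3 numeric matrix, rows named by amino acid in alphabetical
#'   order, each column standardized.
#' @export
pseaa_properties <- function(path = NULL) {
  path <- path %||% system.file("extdata", "aa_properties.tsv",
                                package = "rawalk", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(AMINO_ACIDS %in% df$aa))
    rawalk_stop("property table must cover all 20 amino acids")
  df <- df[match(AMINO_ACIDS, df$aa), ]
  m <- as.matrix(df[, c("hydrophobicity", "hydrophilicity", "side_chain_mass")])
  rownames(m) <- AMINO_ACIDS
  ## population SD (denominator 20), per the classical PseAA normalization
  apply(m, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
}

#' PseAA parameters
#'
#' @param lambda_seq Number of sequence-order correlation tiers (lambda);
#'   default 49. Must be smaller than every sequence length it is applied to.
#' @param weight Weight of the correlation tiers relative to the composition
#'   part; default 0.05.
#' @param properties Standardized 20 x 3 property matrix; defaults to
#'   [pseaa_properties()].
#' @return A `pseaa_params` list.
#' @export
pseaa_params <- function(lambda_seq = 49L, weight = 0.05, properties = NULL) {
  lambda_seq <- as.integer(lambda_seq)
  if (lambda_seq < 0L) rawalk_stop("lambda_seq must be non-negative")
  if (weight <= 0) rawalk_stop("weight must be positive")
  structure(list(lambda_seq = lambda_seq, weight = weight,
                 properties = properties %||% pseaa_properties()),
            class = "pseaa_params")
}

#' Column means of a PSSM
#'
#' Collapses an L x 20 PSSM into a length-20 vector: entry j is the mean
#' over all L positions of the score for mutating into amino-acid type j.
#' This gives every protein, whatever its length, the same 20-dimensional
#' evolutionary profile.
#'
#' @param pssm A [pssm_matrix()] or an L x 20 numeric matrix.
#' @return Named numeric vector of length 20.
#' @export
pssm_row_means <- function(pssm) {
  scores <- if (inherits(pssm, "pssm_matrix")) pssm$scores else as.matrix(pssm)
  if (nrow(scores) < 1L || ncol(scores) != 20L)
    rawalk_stop("expected a non-empty L x 20 PSSM")
  setNames(colMeans(scores), AMINO_ACIDS)
}

#' Sequence-order correlation factor of tier k
#'
#' The k-th tier correlation factor averages, over all residue pairs k
#' positions apart, the mean squared difference of the three standardized
#' physicochemical properties:
#' theta_k = (1/(L-k)) * sum_i Theta(R_i, R_(i+k)) with
#' Theta(a,b) = (1/3) * sum_p (prop_p(b) - prop_p(a))^2.
#'
#' @param sequence Residue string over the 20-letter alphabet.
#' @param k Tier index, 1 <= k < L.
#' @param params A [pseaa_params()].
#' @return Non-negative scalar; 0 for homopolymers.
#' @export
correlation_factor <- function(sequence, k, params = pseaa_params()) {
  idx <- residue_indices(sequence)
  L <- length(idx)
  if (k < 1L || k >= L)
    rawalk_stop("tier k = ", k, " must satisfy 1 <= k < L = ", L)
  P <- params$properties
  a <- P[idx[1:(L - k)], , drop = FALSE]
  b <- P[idx[(1 + k):L], , drop = FALSE]
  mean(rowMeans((b - a)^2))
}

residue_indices <- function(sequence) {
  idx <- match(strsplit(toupper(sequence), "")[[1]], AMINO_ACIDS)
  if (anyNA(idx))
    rawalk_stop("sequence contains non-standard residues; sanitize first")
  idx
}

#' Pseudo-amino-acid composition vector
#'
#' Builds the (20 + lambda)-dimensional PseAA vector: the first 20 entries
#' are the weighted amino-acid occurrence frequencies, the remaining lambda
#' entries the weighted correlation factors, jointly normalized so the whole
#' vector sums to 1:
#' p_u = f_u / (sum f + w * sum theta) for u <= 20,
#' p_(20+k) = w * theta_k / (sum f + w * sum theta).
#'
#' Sequences with L <= lambda carry too little sequence-order signal and are
#' rejected (such proteins are excluded from featurization).
#'
#' @param sequence Residue string.
#' @param params A [pseaa_params()].
#' @return Numeric probability vector of length `20 + lambda_seq`.
#' @export
pseaa_vector <- function(sequence, params = pseaa_params()) {
  idx <- residue_indices(sequence)
  L <- length(idx)
  lambda <- params$lambda_seq
  if (L <= lambda)
    rawalk_stop("sequence length ", L, " must exceed lambda_seq = ", lambda,
                "; exclude this sequence")
  f <- tabulate(idx, nbins = 20L) / L
  theta <- if (lambda > 0L) {
    vapply(seq_len(lambda), function(k) correlation_factor(sequence, k, params),
           numeric(1))
  } else numeric(0)
  denom <- sum(f) + params$weight * sum(theta)
  p <- c(f, params$weight * theta) / denom
  names(p) <- c(AMINO_ACIDS,
                if (lambda > 0L) paste0("theta", seq_len(lambda)))
  p
}

#' Combined PSSM + PseAA descriptor for one protein
#'
#' Concatenates the 20 PSSM column means with the (20 + lambda) PseAA vector
#' into the (40 + lambda)-dimensional combined descriptor; with the default
#' lambda = 49 this is 89 features.
#'
#' If the record had residues removed during lenient sanitization and the
#' PSSM still has the original number of rows, the matching PSSM rows are
#' dropped before averaging.
#'
#' @param record A [protein_record()].
#' @param pssm A [pssm_matrix()] for the same protein.
#' @param params A [pseaa_params()].
#' @return A `descriptor`: list with `protein_id`, `pssm_means`, `pseaa`,
#'   and `combined`.
#' @export
combined_descriptor <- function(record, pssm, params = pseaa_params()) {
  stopifnot(inherits(record, "protein_record"), inherits(pssm, "pssm_matrix"))
  scores <- pssm$scores
  if (nrow(scores) != record$length) {
    if (length(record$removed) > 0L &&
        nrow(scores) == record$length + length(record$removed)) {
      scores <- scores[-record$removed, , drop = FALSE]
    } else {
      rawalk_stop("PSSM for '", record$id, "' has ", nrow(scores),
                  " rows but the sequence has ", record$length, " residues")
    }
  }
  if (record$length <= params$lambda_seq)
    rawalk_stop("sequence '", record$id, "' (length ", record$length,
                ") is too short for lambda_seq = ", params$lambda_seq)
  means <- pssm_row_means(scores)
  pseaa <- pseaa_vector(record$sequence, params)
  structure(list(protein_id = record$id, pssm_means = means, pseaa = pseaa,
                 combined = setNames(c(means, pseaa),
                                     c(paste0("pssm_", AMINO_ACIDS),
                                       paste0("pseaa_", seq_along(pseaa))))),
            class = "descriptor")
}

#' Featurize a collection of proteins
#'
#' Runs [combined_descriptor()] over matched sequence/PSSM collections,
#' excluding (and logging) proteins shorter than `lambda_seq + 1` residues,
#' and returns the remaining descriptors as a [feature_table()].
#'
#' @param records List of [protein_record()]s.
#' @param pssms List of [pssm_matrix()]s; matched to records by protein id.
#' @param params A [pseaa_params()].
#' @param labels Optional named character vector of class labels (names are
#'   protein ids).
#' @return List with `table` (a [feature_table()]) and `excluded`
#'   (data frame of id + reason, zero rows when all proteins admissible).
#' @export
featurize_collection <- function(records, pssms, params = pseaa_params(),
                                 labels = NULL) {
  rec_ids <- vapply(records, `[[`, character(1), "id")
  pssm_ids <- vapply(pssms, `[[`, character(1), "protein_id")
  missing_pssm <- setdiff(rec_ids, pssm_ids)
  if (length(missing_pssm) > 0L)
    rawalk_stop("no PSSM for protein id(s): ",
                paste(missing_pssm, collapse = ", "))
  rows <- list(); kept_ids <- character(0)
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (r in records) {
    if (r$length <= params$lambda_seq) {
      excluded <- rbind(excluded, data.frame(
        id = r$id,
        reason = sprintf("length %d <= lambda %d", r$length, params$lambda_seq),
        stringsAsFactors = FALSE))
      next
    }
    d <- combined_descriptor(r, pssms[[match(r$id, pssm_ids)]], params)
    rows[[length(rows) + 1L]] <- d$combined
    kept_ids <- c(kept_ids, r$id)
  }
  if (length(rows) == 0L)
    rawalk_stop("no admissible proteins (all shorter than lambda + 1)")
  X <- do.call(rbind, rows)
  lab <- if (!is.null(labels)) unname(labels[kept_ids]) else NULL
  list(table = feature_table(X, sample_ids = kept_ids, labels = lab),
       excluded = excluded)
}
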