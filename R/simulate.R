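## Synthetic inputs: Gaussian-mixture feature tables, random protein
## records, and PSI-BLAST-style synthetic PSSM files. Everything is a pure
## function of its arguments and seed.

#' Gaussian-mixture feature table
#'
#' Class c gets an isotropic unit-SD Gaussian cloud centred at
#' `separation * e_c` (orthogonal coordinate axes while d allows, random
#' unit directions beyond that, with a message). `separation` is therefore
#' the distance between class means in units of the within-class SD.
#'
#' @param n_per_class Integer vector: samples per class (class names
#'   c1..cm).
#' @param d Feature dimensionality.
#' @param separation Distance between class means in within-class SD units
#'   (0 gives a class-blind cloud).
#' @param seed Integer seed; same spec + seed reproduces bit-identically.
#' @return A labeled [feature_table()].
#' @export
gaussian_mixture_dataset <- function(n_per_class = c(50L, 50L, 50L), d = 8L,
                                     separation = 6, seed = 1L) {
  if (any(n_per_class < 1L)) rawalk_stop("class counts must be >= 1")
  if (separation < 0) rawalk_stop("separation must be non-negative")
  m <- length(n_per_class)
  with_seed(seed, {
    means <- matrix(0, m, d)
    if (m > d)
      message("more classes (", m, ") than dimensions (", d,
              "); using random unit directions for the surplus classes")
    for (c in seq_len(m)) {
      if (c <= d) {
        means[c, c] <- separation
      } else {
        u <- stats::rnorm(d)
        means[c, ] <- separation * u / sqrt(sum(u^2))
      }
    }
    X <- do.call(rbind, lapply(seq_len(m), function(c) {
      matrix(stats::rnorm(n_per_class[[c]] * d), n_per_class[[c]], d) +
        rep(means[c, ], each = n_per_class[[c]])
    }))
    labels <- rep(paste0("c", seq_len(m)), n_per_class)
    feature_table(X, sample_ids = paste0("s", seq_len(nrow(X))),
                  labels = labels)
  })
}

#' Random protein records
#'
#' Uniform-random sequences over the 20-letter alphabet with lengths drawn
#' uniformly from `length_range`.
#'
#' @param count Number of records (0 gives an empty list).
#' @param length_range Integer pair (min, max) of sequence lengths.
#' @param seed Integer seed.
#' @return List of [protein_record()]s with ids prot1..protN.
#' @export
random_protein_records <- function(count, length_range = c(50L, 200L),
                                   seed = 1L) {
  if (count < 0L) rawalk_stop("count must be non-negative")
  if (length(length_range) != 2L || any(length_range < 1L) ||
      length_range[[1L]] > length_range[[2L]])
    rawalk_stop("invalid length range")
  if (count == 0L) return(list())
  with_seed(seed, {
    lens <- seq(length_range[[1L]], length_range[[2L]])
    lapply(seq_len(count), function(i) {
      L <- if (length(lens) == 1L) lens else sample(lens, 1L)
      protein_record(paste0("prot", i),
                     paste(sample(AMINO_ACIDS, L, replace = TRUE),
                           collapse = ""))
    })
  })
}

#' Write a synthetic PSI-BLAST-style ASCII PSSM
#'
#' Emits a file in the ASCII dialect of `psiblast -out_ascii_pssm`: two
#' comment-style header lines, an amino-acid column header (BLAST's native
#' order, repeated for the percentage block), and one row per residue with
#' the position, the residue, 20 integer log-odds scores drawn uniformly
#' from \[-10, 10\], and a dummy percentage block. [read_pssm()] round-trips
#' the score block exactly.
#'
#' @param record A [protein_record()].
#' @param path Output path.
#' @param seed Integer seed; same record + seed gives identical bytes.
#' @return `path`, invisibly.
#' @export
write_synthetic_pssm <- function(record, path, seed = 1L) {
  stopifnot(inherits(record, "protein_record"))
  L <- record$length
  scores <- with_seed(seed, matrix(sample(-10:10, L * 20L, replace = TRUE),
                                   L, 20L))
  colnames(scores) <- AMINO_ACIDS
  native <- scores[, BLAST_AA_ORDER, drop = FALSE]
  res <- strsplit(record$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted percentages rounded down (synthetic)",
               paste0("            ",
                      paste(sprintf("%3s", BLAST_AA_ORDER), collapse = " "),
                      "  ",
                      paste(sprintf("%3s", BLAST_AA_ORDER), collapse = " "))),
             con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[[i]]),
                      paste(sprintf("%3d", native[i, ]), collapse = " "),
                      "  ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                      sprintf("  %.2f %.2f", 0, 0)),
               con)
  }
  invisible(path)
}

#' Generate a matched synthetic protein corpus
#'
#' Convenience wrapper: random records, a FASTA file, and one synthetic
#' PSSM file per record under `pssm_dir` (named `<id>.pssm`).
#'
#' @param count,length_range,seed As in [random_protein_records()].
#' @param fasta Output FASTA path.
#' @param pssm_dir Output directory for the PSSM files (created).
#' @return The list of records, invisibly.
#' @export
simulate_protein_corpus <- function(count, length_range = c(50L, 200L),
                                    seed = 1L, fasta, pssm_dir) {
  records <- random_protein_records(count, length_range, seed)
  if (length(records) == 0L) rawalk_stop("count must be positive")
  write_fasta(records, fasta)
  dir.create(pssm_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(records))
    write_synthetic_pssm(records[[i]],
                         file.path(pssm_dir, paste0(records[[i]]$id, ".pssm")),
                         seed = seed + i)
  invisible(records)
}
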