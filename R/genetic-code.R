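## Standard genetic code tables and the single-nucleotide-change structure
## that underlies the MG94-type codon rate matrix. Everything here is fixed
## at package load: 61 sense codons (standard code), in A<C<G<T lexicographic
## order, and the list of codon pairs reachable by one nucleotide change.

NUCLEOTIDES <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

.standard_code <- function() {
  ## amino acid for each of the 64 codons, "*" for stops
  bases <- NUCLEOTIDES
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd)))
  }, character(1))
  names(aa) <- codons
  aa
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons, sorted
#'   lexicographically (A < C < G < T). This ordering fixes the state order
#'   of every rate matrix and frequency vector in the package.
#' @export
sense_codons <- function() {
  if (is.null(.codon_cache$sense)) {
    aa <- .standard_code()
    .codon_cache$aa_full <- aa
    .codon_cache$sense <- names(aa)[aa != "*"]
    .codon_cache$aa <- aa[aa != "*"]
  }
  .codon_cache$sense
}

#' Amino acids encoded by the sense codons
#'
#' @return Named character vector (names = codons from [sense_codons()]).
#' @export
codon_amino_acids <- function() {
  sense_codons()
  .codon_cache$aa
}

is_stop_codon <- function(codon) {
  sense_codons()
  aa <- .codon_cache$aa_full[codon]
  !is.na(aa) & aa == "*"
}

## Table of permitted single-nucleotide codon changes among sense codons.
## Columns: i, j (1-based indices into sense_codons()), pos (1..3),
## transition (1 if A<->G or C<->T), nonsyn (1 if amino acid changes).
codon_change_table <- function() {
  if (!is.null(.codon_cache$changes)) {
    return(.codon_cache$changes)
  }
  codons <- sense_codons()
  aa <- codon_amino_acids()
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, ""))
  out <- vector("list", 3L)
  for (pos in 1:3) {
    same_other <- apply(mat[, -pos, drop = FALSE], 1, paste0, collapse = "")
    grp <- split(seq_len(n), same_other)
    rows <- lapply(grp, function(idx) {
      if (length(idx) < 2) return(NULL)
      pr <- t(utils::combn(idx, 2))
      cbind(i = pr[, 1], j = pr[, 2], pos = pos)
    })
    out[[pos]] <- do.call(rbind, rows)
  }
  ch <- as.data.frame(do.call(rbind, out))
  from <- mat[cbind(ch$i, ch$pos)]
  to <- mat[cbind(ch$j, ch$pos)]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ch$transition <- as.integer(purine[from] == purine[to])
  ch$nonsyn <- as.integer(aa[ch$i] != aa[ch$j])
  ch <- ch[order(ch$i, ch$j), ]
  rownames(ch) <- NULL
  .codon_cache$changes <- ch
  ch
}

#' Codon equilibrium frequencies from observed sequences
#'
#' Computes the stationary codon frequency vector pi used by the codon model,
#' from the codons observed in an alignment (or any codon character vector).
#'
#' * `"F3x4"`: product of position-specific nucleotide frequencies,
#'   renormalised after removing stop codons (default, the standard
#'   empirical choice for MG94-type models).
#' * `"F1x4"`: product of overall nucleotide frequencies.
#' * `"uniform"`: 1/61 for every sense codon.
#'
#' @param codons Character vector of codons (gaps/ambiguous codons are
#'   ignored), or a `codon_alignment`.
#' @param method One of `"F3x4"`, `"F1x4"`, `"uniform"`.
#' @return Named numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(codons, method = c("F3x4", "F1x4", "uniform")) {
  method <- match.arg(method)
  sense <- sense_codons()
  if (inherits(codons, "codon_alignment")) {
    codons <- unlist(codon_split(codons), use.names = FALSE)
  }
  codons <- toupper(codons)
  codons <- codons[codons %in% sense]
  if (method == "uniform") {
    pi <- rep(1 / 61, 61)
    names(pi) <- sense
    return(pi)
  }
  if (length(codons) == 0L) {
    stop("no unambiguous sense codons available to estimate frequencies")
  }
  mat <- do.call(rbind, strsplit(codons, ""))
  if (method == "F1x4") {
    nf <- table(factor(as.vector(mat), levels = NUCLEOTIDES))
    nf <- as.numeric(nf) / sum(nf)
    freqs_from_nuc(nf)
  } else {
    posf <- lapply(1:3, function(p) {
      f <- table(factor(mat[, p], levels = NUCLEOTIDES))
      as.numeric(f) / sum(f)
    })
    freqs_from_nuc(posf)
  }
}

#' Codon frequencies from nucleotide frequencies
#'
#' Builds the product-form codon frequency vector from either a single
#' nucleotide frequency vector (F1x4) or a list of three position-specific
#' vectors (F3x4); stop codons are removed and the vector renormalised.
#'
#' @param nuc_freqs Numeric vector of 4 frequencies in A, C, G, T order, or a
#'   list of three such vectors.
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
freqs_from_nuc <- function(nuc_freqs) {
  if (!is.list(nuc_freqs)) nuc_freqs <- list(nuc_freqs, nuc_freqs, nuc_freqs)
  stopifnot(length(nuc_freqs) == 3L)
  for (f in nuc_freqs) {
    if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-6) {
      stop("nucleotide frequencies must be 4 non-negative values summing to 1")
    }
  }
  sense <- sense_codons()
  mat <- do.call(rbind, strsplit(sense, ""))
  idx <- function(x) match(x, NUCLEOTIDES)
  pi <- nuc_freqs[[1]][idx(mat[, 1])] *
    nuc_freqs[[2]][idx(mat[, 2])] *
    nuc_freqs[[3]][idx(mat[, 3])]
  pi <- pi / sum(pi)
  names(pi) <- sense
  pi
}

check_codon_freqs <- function(pi, tol = 1e-6) {
  if (length(pi) != 61L) {
    stop("codon frequencies must have length 61 (one per sense codon)")
  }
  if (any(pi < 0)) stop("codon frequencies must be non-negative")
  if (abs(sum(pi) - 1) > tol) {
    stop(sprintf("codon frequencies must sum to 1 (got %.8f)", sum(pi)))
  }
  invisible(TRUE)
}
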