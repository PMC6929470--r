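## In-frame codon alignments. Sequences are stored as uppercase nucleotide
## strings; gaps "-" and ambiguity "N" are permitted and treated as missing
## data in the likelihood (a gap codon contributes a partial likelihood of 1
## over all compatible codons).

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned, in-frame nucleotide
#'   sequences (equal lengths, multiples of 3). Alphabet: `A C G T N -`.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named by taxon")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate taxon names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("all sequences must have equal length")
  }
  if (lens[1] %% 3L != 0L) {
    stop("alignment length must be a multiple of 3 (in-frame codons)")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("invalid characters in sequences: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  obj <- structure(list(seqs = seqs), class = "codon_alignment")
  stops <- vapply(codon_split(obj), function(x) any(is_stop_codon(x)),
                  logical(1))
  if (any(stops)) {
    stop("stop codons present in: ", paste(names(seqs)[stops], collapse = ", "))
  }
  obj
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d taxa, %d codons\n",
              length(x$seqs), n_codons(x)))
  invisible(x)
}

#' Number of codon sites in an alignment
#' @param aln A `codon_alignment`.
#' @return Integer count of codon columns.
#' @export
n_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  nchar(aln$seqs[[1]]) %/% 3L
}

#' Taxon names of an alignment
#' @param aln A `codon_alignment`.
#' @return Character vector.
#' @export
alignment_taxa <- function(aln) names(aln$seqs)

## split each sequence into its codon triplets (list of character vectors)
codon_split <- function(aln) {
  nc <- nchar(aln$seqs[[1]])
  starts <- seq.int(1L, nc, by = 3L)
  lapply(aln$seqs, function(s) substring(s, starts, starts + 2L))
}

## Encode the alignment for the pruning engine. Each distinct observed codon
## token maps to a row of a 0/1 "allowed state" table over the 61 sense
## codons; fully or partially ambiguous codons allow every compatible codon.
## Returns list(tip_state: ntaxa x nsite integer matrix of table rows,
##              state_table: nstates x 61 matrix).
encode_alignment <- function(aln) {
  sense <- sense_codons()
  cs <- codon_split(aln)
  tokens <- unique(unlist(cs, use.names = FALSE))
  allowed <- matrix(0, nrow = length(tokens), ncol = 61,
                    dimnames = list(tokens, sense))
  sense_mat <- do.call(rbind, strsplit(sense, ""))
  for (tok in tokens) {
    if (tok %in% sense) {
      allowed[tok, tok] <- 1
    } else {
      nts <- strsplit(tok, "")[[1]]
      ok <- rep(TRUE, 61)
      for (p in 1:3) {
        if (nts[p] %in% NUCLEOTIDES) ok <- ok & sense_mat[, p] == nts[p]
      }
      allowed[tok, ok] <- 1
    }
  }
  tip_state <- do.call(rbind, lapply(cs, function(x) match(x, tokens)))
  rownames(tip_state) <- names(cs)
  list(tip_state = tip_state, state_table = allowed)
}

## Collapse identical site patterns; returns list(tip_state, state_table,
## weights) with one column per distinct pattern.
compress_patterns <- function(enc) {
  key <- apply(enc$tip_state, 2, paste0, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[first])))
  list(tip_state = enc$tip_state[, first, drop = FALSE],
       state_table = enc$state_table, weights = w)
}

#' Extract a sub-alignment by taxa or sites
#'
#' @param aln A `codon_alignment`.
#' @param taxa Taxa to keep (default all).
#' @param sites Codon site indices to keep (default all).
#' @return A `codon_alignment`.
#' @export
subset_alignment <- function(aln, taxa = alignment_taxa(aln), sites = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  missing_taxa <- setdiff(taxa, alignment_taxa(aln))
  if (length(missing_taxa)) {
    stop("unknown taxa: ", paste(missing_taxa, collapse = ", "))
  }
  seqs <- aln$seqs[taxa]
  if (!is.null(sites)) {
    cs <- codon_split(structure(list(seqs = seqs), class = "codon_alignment"))
    seqs <- vapply(cs, function(x) paste0(x[sites], collapse = ""),
                   character(1))
    names(seqs) <- taxa
  }
  codon_alignment(seqs)
}
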