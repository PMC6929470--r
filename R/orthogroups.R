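## Orthogroup construction and filtering: from transcripts (or raw
## OrthoFinder-like groups) to analysis-ready orthogroups. The stages mirror
## a transcriptome-based comparative study: longest-ORF extraction,
## reference-genome matching, a collapsed-orthologue filter, merging of
## groups that hit the same reference gene set, deduplication, size/taxon
## bounds, overlap-based alignment trimming, and NJ tree building.

#' Extract the longest open reading frame of a transcript
#'
#' Scans all reading frames (both strands by default) for start-to-stop
#' ORFs; an ORF running off the 3' end without a stop is kept, truncated to
#' complete codons. The reported length is the nucleotide length including
#' the stop codon. Ties are broken towards the lowest start coordinate,
#' preferring the forward strand.
#'
#' @param transcript Nucleotide string over `A C G T N` (case-insensitive).
#' @param min_len Minimum ORF nucleotide length (default 200).
#' @param both_strands Search the reverse complement as well (default TRUE).
#' @param id Transcript id recorded in the result.
#' @return A list (class `orf_record`) with `transcript_id`, `start`, `end`
#'   (0-based half-open coordinates on the reported strand), `strand`,
#'   `frame`, `sequence`; or `NULL` if no qualifying ORF exists.
#' @export
longest_orf <- function(transcript, min_len = 200, both_strands = TRUE,
                        id = "transcript") {
  transcript <- toupper(transcript)
  if (grepl("[^ACGTN]", transcript)) {
    stop("transcript contains non-nucleotide characters (other than N)")
  }
  strands <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  for (st in strands) {
    seqc <- if (st == "+") transcript else revcomp(transcript)
    for (frame in 0:2) {
      cand <- orfs_in_frame(seqc, frame)
      for (orf in cand) {
        if (orf$len < min_len) next
        if (is.null(best) ||
            orf$len > best$len ||
            (orf$len == best$len && st == "+" && best$strand == "-") ||
            (orf$len == best$len && st == best$strand &&
             orf$start < best$start)) {
          best <- c(orf, list(strand = st, seqc = seqc))
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(list(transcript_id = id,
                 start = best$start, end = best$start + best$len,
                 strand = best$strand, frame = best$start %% 3L,
                 sequence = substr(best$seqc, best$start + 1L,
                                   best$start + best$len)),
            class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("ORF %s: [%d, %d) strand %s, %d nt\n", x$transcript_id,
              x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## all ATG->stop (or sequence-end) ORFs in one frame of one strand;
## start is 0-based on that strand
orfs_in_frame <- function(seqc, frame) {
  n <- nchar(seqc)
  if (n - 2L < frame + 1L) return(list())
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(seqc, starts, starts + 2L)
  stops <- codons %in% c("TAA", "TAG", "TGA")
  atg <- which(codons == "ATG")
  out <- list()
  used_until <- -1L
  for (a in atg) {
    if (a <= used_until) next  # nested start inside a previous ORF
    nxt <- which(stops & seq_along(codons) >= a)
    last <- if (length(nxt)) nxt[1] else length(codons)
    out[[length(out) + 1L]] <- list(start = starts[a] - 1L,
                                    len = 3L * (last - a + 1L))
    used_until <- last
  }
  out
}

#' Keep only orthogroup members that map to reference genes
#'
#' Retains, per raw orthogroup, the members whose gene maps to a reference
#' protein-coding gene; groups left with no members are dropped. Each kept
#' group gains a `ref_genes` signature (sorted unique reference genes of its
#' members).
#'
#' @param groups List of orthogroups: each a list with `id` and `members`
#'   (data.frame with `species`, `gene_id`, and optionally `sequence`).
#' @param reference_map data.frame mapping `gene_id` to `ref_gene`.
#' @return Filtered list of groups with `ref_genes` signatures.
#' @export
match_to_reference <- function(groups, reference_map) {
  out <- lapply(groups, function(g) {
    hit <- g$members$gene_id %in% reference_map$gene_id
    if (!any(hit)) return(NULL)
    g$members <- g$members[hit, , drop = FALSE]
    g$ref_genes <- sort(unique(
      reference_map$ref_gene[match(g$members$gene_id,
                                   reference_map$gene_id)]))
    g
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Collapsed-orthologue filter
#'
#' A group is kept only if every focal species contributes at least as many
#' orthologues as the reference genome has for this group (fewer focal
#' copies than reference copies indicates collapsed orthologues in the
#' assembly) and no more than four.
#'
#' @param focal_counts Named integer vector: orthologue count per focal
#'   species in the group.
#' @param reference_count Number of orthologous genes in the reference
#'   genome for this group.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
collapsed_orthologue_filter <- function(focal_counts, reference_count) {
  all(focal_counts >= reference_count) && all(focal_counts <= 4L)
}

#' Merge groups hitting the same reference gene set and drop duplicates
#'
#' Groups whose `ref_genes` signatures are identical are merged into one;
#' groups with byte-identical member sets collapse to a single copy. Output
#' order is deterministic (sorted by signature).
#'
#' @param groups List of groups carrying `ref_genes` signatures (see
#'   [match_to_reference()]).
#' @return Merged, deduplicated, signature-sorted list of groups.
#' @export
merge_and_dedup <- function(groups) {
  if (!length(groups)) return(groups)
  sig <- vapply(groups, function(g) paste(g$ref_genes, collapse = ";"),
                character(1))
  merged <- lapply(split(seq_along(groups), sig), function(idx) {
    g <- groups[[idx[1]]]
    if (length(idx) > 1L) {
      members <- unique(do.call(rbind, lapply(groups[idx], `[[`, "members")))
      g$members <- members[order(members$species, members$gene_id), ,
                           drop = FALSE]
      g$merged_from <- vapply(groups[idx], `[[`, "", "id")
    }
    g
  })
  merged[order(names(merged))]
}

#' Size and taxon-count filter
#'
#' @param groups List of orthogroups.
#' @param min_seqs,max_seqs Bounds on the number of member sequences
#'   (defaults 7 and 80).
#' @param min_taxa Minimum number of distinct species (default 7).
#' @return Groups within bounds.
#' @export
size_taxon_filter <- function(groups, min_seqs = 7, max_seqs = 80,
                              min_taxa = 7) {
  keep <- vapply(groups, function(g) {
    n <- nrow(g$members)
    n >= min_seqs && n <= max_seqs &&
      length(unique(g$members$species)) >= min_taxa
  }, logical(1))
  groups[keep]
}

#' Overlap-based alignment trimming
#'
#' Reimplements the trimAl-style spurious-sequence filter used with
#' `-resoverlap 1.0 -seqoverlap 0.38 -noallgaps`. In the default
#' `"pairwise"` mode the overlap of two sequences is the fraction of
#' columns in which their gap/non-gap states match; a sequence is kept
#' when at least `seqoverlap` of the *other* sequences overlap with it by
#' at least `resoverlap`. (This is the reading under which the canonical
#' settings behave sensibly: one mostly-gapped sequence is removed without
#' dragging everything else down.) Columns left all-gap afterwards are
#' removed (`-noallgaps`).
#'
#' Two alternative column-wise readings are available: `"gapstate"` — a
#' column of sequence `s` is "good" when the fraction of other sequences
#' matching `s`'s gap state there is at least `resoverlap`, and `s` needs
#' a `seqoverlap` fraction of good columns; `"residue"` — as `"gapstate"`
#' but a column counts as good when enough other sequences hold a residue.
#'
#' @param seqs Named character vector of aligned sequences (or a
#'   `codon_alignment`).
#' @param resoverlap Pairwise overlap (or column agreement) threshold
#'   (default 1.0).
#' @param seqoverlap Fraction of overlapping sequences (or of good
#'   columns) a sequence needs to survive (default 0.38).
#' @param mode `"pairwise"` (default), `"gapstate"` or `"residue"`.
#' @return Named character vector of retained, column-pruned sequences.
#' @export
trim_sequences <- function(seqs, resoverlap = 1.0, seqoverlap = 0.38,
                           mode = c("pairwise", "gapstate", "residue")) {
  mode <- match.arg(mode)
  if (inherits(seqs, "codon_alignment")) seqs <- seqs$seqs
  if (length(seqs) < 2L) stop("trimming needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned (equal lengths)")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  gap <- mat == "-"
  n <- nrow(mat)
  keep <- if (mode == "pairwise") {
    state <- !gap  # TRUE at residues
    agree <- tcrossprod(state) + tcrossprod(!state)  # matching columns
    o <- agree / ncol(mat)
    vapply(seq_len(n), function(s) {
      mean(o[s, -s] >= resoverlap) >= seqoverlap
    }, logical(1))
  } else vapply(seq_len(n), function(s) {
    others <- gap[-s, , drop = FALSE]
    good <- if (mode == "gapstate") {
      agree <- colSums(others == matrix(gap[s, ], n - 1L, ncol(mat),
                                        byrow = TRUE))
      agree / (n - 1L) >= resoverlap
    } else {
      colSums(!others) / (n - 1L) >= resoverlap
    }
    mean(good) >= seqoverlap
  }, logical(1))
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) return(stats::setNames(character(0), character(0)))
  allgap <- colSums(mat == "-") == nrow(mat)
  mat <- mat[, !allgap, drop = FALSE]
  stats::setNames(apply(mat, 1, paste0, collapse = ""), names(seqs)[keep])
}

#' Codon-level p-distance matrix
#'
#' Pairwise proportion of differing codons, gaps and ambiguous codons
#' pairwise-deleted.
#'
#' @param aln A `codon_alignment` or named character vector of aligned
#'   sequences.
#' @return A `dist`-convertible symmetric matrix.
#' @export
codon_p_distance <- function(aln) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  cs <- codon_split(aln)
  sense <- sense_codons()
  n <- length(cs)
  taxa <- alignment_taxa(aln)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  ok <- lapply(cs, function(x) x %in% sense)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[[i]] & ok[[j]]
      if (!any(both)) {
        stop(sprintf("no overlapping codon sites between %s and %s",
                     taxa[i], taxa[j]))
      }
      D[i, j] <- D[j, i] <- mean(cs[[i]][both] != cs[[j]][both])
    }
  }
  D
}

#' Neighbour-joining tree from a codon alignment
#'
#' NJ on codon-level p-distances (pairwise deletion); negative branch
#' lengths are clamped to zero. Labels are applied separately with
#' [label_foreground()].
#'
#' @param aln A `codon_alignment` (>= 3 sequences) or named character
#'   vector.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(aln) {
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (length(aln$seqs) < 3L) stop("NJ needs at least 3 sequences")
  D <- codon_p_distance(aln)
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Run the full orthogroup filter pipeline with an audit log
#'
#' Applies reference matching, the collapsed-orthologue filter, merging and
#' deduplication, and the size/taxon filter in order, recording for every
#' input group whether and where it was dropped.
#'
#' @param groups Raw orthogroups (list of `id`/`members` records).
#' @param reference_map data.frame with `gene_id`, `ref_gene`.
#' @param min_seqs,max_seqs,min_taxa Size/taxon bounds.
#' @return List with `groups` (retained) and `audit` (data.frame: group_id,
#'   stage, kept, reason).
#' @export
filter_orthogroups <- function(groups, reference_map, min_seqs = 7,
                               max_seqs = 80, min_taxa = 7) {
  audit <- data.frame(group_id = vapply(groups, `[[`, "", "id"),
                      stage = "input", kept = TRUE, reason = "")
  note <- function(ids, stage, reason) {
    hit <- audit$group_id %in% ids & audit$kept
    audit$kept[hit] <<- FALSE
    audit$stage[hit] <<- stage
    audit$reason[hit] <<- reason
  }
  matched <- match_to_reference(groups, reference_map)
  note(setdiff(vapply(groups, `[[`, "", "id"),
               vapply(matched, `[[`, "", "id")),
       "match_to_reference", "no member maps to a reference gene")

  kept <- Filter(function(g) {
    counts <- table(g$members$species)
    collapsed_orthologue_filter(as.integer(counts), length(g$ref_genes))
  }, matched)
  note(setdiff(vapply(matched, `[[`, "", "id"),
               vapply(kept, `[[`, "", "id")),
       "collapsed_orthologue_filter",
       "focal copies below reference count or above 4")

  merged <- merge_and_dedup(kept)
  absorbed <- setdiff(vapply(kept, `[[`, "", "id"),
                      vapply(merged, `[[`, "", "id"))
  note(absorbed, "merge_and_dedup", "merged into another group (same reference set)")

  final <- size_taxon_filter(merged, min_seqs, max_seqs, min_taxa)
  note(setdiff(vapply(merged, `[[`, "", "id"),
               vapply(final, `[[`, "", "id")),
       "size_taxon_filter", "size or taxon count out of bounds")
  list(groups = final, audit = audit)
}
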