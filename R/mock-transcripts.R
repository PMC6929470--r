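## Mock transcript fixture generator: builds a small reference gene map,
## embeds each CDS in random UTR flanks, and plants known violations of the
## orthogroup filters (collapsed orthologues, out-of-bounds sizes, missing
## reference hits, duplicated groups) plus reverse-strand and short-ORF
## transcripts. The planted truth is returned alongside, so the filter
## audit can be checked exactly.

random_cds <- function(n_codons) {
  sense <- sense_codons()
  body <- sample(setdiff(sense, "ATG"), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste0(body, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

## random UTR flanks; regenerate until the embedded CDS is exactly the
## longest ORF of the transcript
embed_cds <- function(cds, flank_range = c(20L, 80L), max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    f5 <- paste0(sample(NUCLEOTIDES, sample(flank_range[1]:flank_range[2], 1),
                        replace = TRUE), collapse = "")
    f3 <- paste0(sample(NUCLEOTIDES, sample(flank_range[1]:flank_range[2], 1),
                        replace = TRUE), collapse = "")
    tx <- paste0(f5, cds, f3)
    orf <- longest_orf(tx, min_len = 30, id = "probe")
    if (!is.null(orf) && orf$strand == "+" && orf$sequence == cds) {
      return(tx)
    }
  }
  cds  # give up on flanks; the bare CDS is always its own longest ORF
}

#' Generate mock transcripts with planted filter violations
#'
#' Builds a synthetic set of species, genes, coding sequences, a reference
#' gene map, transcripts (CDS embedded in random UTR flanks), raw
#' orthogroups, and a truth table of planted violations:
#'
#' * `unmapped`: no member maps to a reference gene;
#' * `collapsed`: one focal species has fewer orthologues than the
#'   reference genome (collapsed assembly);
#' * `duplicate`: byte-identical copy of another group;
#' * `too_small` / `too_large` / `few_taxa`: size/taxon bound violations.
#'
#' A configurable number of clean-group transcripts are additionally stored
#' reverse-complemented, and standalone short-ORF transcripts (below the
#' minimum ORF length) are included; both are recorded in the truth tables.
#'
#' @param n_species Number of focal species (default 10).
#' @param n_clean Number of clean orthogroups that must survive filtering.
#' @param n_codons_range CDS length range in codons.
#' @param n_reverse Number of transcripts stored on the reverse strand.
#' @param n_short Number of standalone short-ORF transcripts.
#' @param seed Integer seed; fully determines the output.
#' @return List with `transcripts` (named vector), `transcript_species`,
#'   `raw_groups`, `reference_map`, `planted` (group_id, violation),
#'   `reverse_transcripts`, `short_transcripts`, `cds` (the planted coding
#'   sequences).
#' @export
generate_mock_transcripts <- function(n_species = 10, n_clean = 8,
                                      n_codons_range = c(80, 160),
                                      n_reverse = 3, n_short = 2,
                                      seed = 1L) {
  with_seed(seed, {
    species <- sprintf("Sp%02d", seq_len(n_species))
    cds <- character(0)
    tx <- character(0)
    tx_species <- character(0)
    ref_map <- data.frame(gene_id = character(0), ref_gene = character(0))
    groups <- list()
    planted <- data.frame(group_id = character(0), violation = character(0))

    new_gene <- function(sp, gene, ref = NULL, n_codons = NULL) {
      if (is.null(n_codons)) {
        n_codons <- sample(n_codons_range[1]:n_codons_range[2], 1)
      }
      cd <- random_cds(n_codons)
      cds[[gene]] <<- cd
      tx[[gene]] <<- embed_cds(cd)
      tx_species[[gene]] <<- sp
      if (!is.null(ref)) {
        ref_map <<- rbind(ref_map, data.frame(gene_id = gene, ref_gene = ref))
      }
      gene
    }
    make_group <- function(gid, sp_genes, violation = NA) {
      groups[[gid]] <<- list(id = gid, members = sp_genes)
      if (!is.na(violation)) {
        planted <<- rbind(planted,
                          data.frame(group_id = gid, violation = violation))
      }
      gid
    }

    ## clean groups: one gene per species, one reference gene each
    for (g in seq_len(n_clean)) {
      gid <- sprintf("RG%03d", g)
      ref <- sprintf("ref_%s", gid)
      members <- data.frame(
        species = species,
        gene_id = vapply(species, function(sp) {
          new_gene(sp, sprintf("%s_%s", gid, sp), ref)
        }, character(1)))
      make_group(gid, members)
    }
    next_id <- n_clean

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # unmapped
    members <- data.frame(
      species = species,
      gene_id = vapply(species, function(sp) {
        new_gene(sp, sprintf("%s_%s", gid, sp), ref = NULL)
      }, character(1)))
    make_group(gid, members, "unmapped")

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # collapsed
    refs <- sprintf("ref_%s_%d", gid, 1:3)
    rows <- list()
    for (sp in species) {
      n_copies <- if (sp == species[1]) 2L else 3L  # species 1 collapsed
      for (cpy in seq_len(n_copies)) {
        gene <- new_gene(sp, sprintf("%s_%s_c%d", gid, sp, cpy), refs[cpy])
        rows[[length(rows) + 1L]] <- data.frame(species = sp, gene_id = gene)
      }
    }
    make_group(gid, do.call(rbind, rows), "collapsed")

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # duplicate of RG001
    groups[[gid]] <- list(id = gid, members = groups[["RG001"]]$members)
    planted <- rbind(planted,
                     data.frame(group_id = gid, violation = "duplicate"))

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # too_small (6 < 7)
    ref <- sprintf("ref_%s", gid)
    sp6 <- species[1:6]
    members <- data.frame(
      species = sp6,
      gene_id = vapply(sp6, function(sp) {
        new_gene(sp, sprintf("%s_%s", gid, sp), ref)
      }, character(1)))
    make_group(gid, members, "too_small")

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # few_taxa (5 < 7)
    refs <- sprintf("ref_%s_%d", gid, 1:4)
    rows <- list()
    for (sp in species[1:5]) {
      for (cpy in 1:4) {
        gene <- new_gene(sp, sprintf("%s_%s_c%d", gid, sp, cpy), refs[cpy])
        rows[[length(rows) + 1L]] <- data.frame(species = sp, gene_id = gene)
      }
    }
    make_group(gid, do.call(rbind, rows), "few_taxa")

    gid <- sprintf("RG%03d", next_id <- next_id + 1L)  # too_large (81 > 80)
    extra_species <- sprintf("Xp%02d", seq_len(27))
    refs <- sprintf("ref_%s_%d", gid, 1:3)
    rows <- list()
    for (sp in extra_species) {
      for (cpy in 1:3) {
        gene <- new_gene(sp, sprintf("%s_%s_c%d", gid, sp, cpy), refs[cpy],
                         n_codons = n_codons_range[1])
      rows[[length(rows) + 1L]] <- data.frame(species = sp, gene_id = gene)
      }
    }
    make_group(gid, do.call(rbind, rows), "too_large")

    ## reverse-strand transcripts among the clean groups
    clean_genes <- unlist(lapply(groups[seq_len(n_clean)],
                                 function(g) g$members$gene_id))
    rev_genes <- sample(clean_genes, min(n_reverse, length(clean_genes)))
    for (g in rev_genes) tx[[g]] <- revcomp(tx[[g]])

    ## standalone short-ORF transcripts (below the 200 nt default)
    short_genes <- character(0)
    for (i in seq_len(n_short)) {
      gene <- sprintf("short_orf_%d", i)
      short_genes <- c(short_genes, gene)
      new_gene(species[1], gene, ref = NULL, n_codons = 40L)
    }

    list(transcripts = tx, transcript_species = tx_species,
         raw_groups = unname(groups), reference_map = ref_map,
         planted = planted, reverse_transcripts = rev_genes,
         short_transcripts = short_genes, cds = cds, seed = seed)
  })
}
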