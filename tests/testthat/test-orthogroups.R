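test_that("longest_orf applies the length threshold and scans all frames", {
  ## a single clean ORF of 300 nt is returned whole
  cds <- paste0("ATG", paste0(rand_codons(98, seed = 2), collapse = ""),
                "TAA")
  orf <- longest_orf(cds, min_len = 200)
  expect_identical(orf$sequence, cds)
  expect_equal(c(orf$start, orf$end), c(0, 300))
  expect_identical(orf$strand, "+")
  ## too-short ORF yields nothing
  short <- paste0("ATG", paste0(rand_codons(40, seed = 3), collapse = ""),
                  "TGA")
  expect_null(longest_orf(short, min_len = 200))
  expect_identical(longest_orf(short, min_len = 100)$sequence, short)
  ## two ORFs: the longer one wins, regardless of order (exhaustive scan)
  orf_a <- paste0("ATG", paste0(rand_codons(68, seed = 4), collapse = ""),
                  "TAA")  # 210 nt
  orf_b <- paste0("ATG", paste0(rand_codons(148, seed = 5), collapse = ""),
                  "TAA")  # 450 nt
  both <- paste0(orf_a, "T", orf_b)  # frame shift between them
  got <- longest_orf(both, min_len = 200)
  expect_identical(got$sequence, orf_b)
  expect_equal(got$start, 211)
  ## reverse strand recovery, and strand restriction
  rc <- omegak:::revcomp(both)
  got_rc <- longest_orf(rc, min_len = 200)
  expect_identical(got_rc$sequence, orf_b)
  expect_identical(got_rc$strand, "-")
  fwd_only <- longest_orf(rc, min_len = 200, both_strands = FALSE)
  expect_true(is.null(fwd_only) || fwd_only$sequence != orf_b)
  expect_error(longest_orf("ATGXXX"), "non-nucleotide")
})

test_that("reference matching keeps mapped members and drops empty groups", {
  groups <- list(
    list(id = "g1", members = data.frame(
      species = c("s1", "s1", "s2", "s3", "s3"),
      gene_id = c("a", "b", "c", "d", "e"))),
    list(id = "g2", members = data.frame(species = "s1", gene_id = "zz")))
  ref <- data.frame(gene_id = c("a", "c", "d"),
                    ref_gene = c("r1", "r1", "r2"))
  out <- match_to_reference(groups, ref)
  expect_length(out, 1L)
  expect_equal(nrow(out[[1]]$members), 3)
  expect_equal(out[[1]]$ref_genes, c("r1", "r2"))
  expect_length(match_to_reference(list(), ref), 0L)
})

test_that("collapsed-orthologue rule enforces both bounds", {
  expect_false(collapsed_orthologue_filter(c(s1 = 2), 3))  # collapsed
  expect_true(collapsed_orthologue_filter(c(s1 = 3), 3))   # equality ok
  expect_false(collapsed_orthologue_filter(c(s1 = 5), 3))  # above 4
  expect_true(collapsed_orthologue_filter(c(s1 = 4, s2 = 3), 3))
  expect_false(collapsed_orthologue_filter(c(s1 = 4, s2 = 2), 3))
})

test_that("merging unifies identical reference signatures deterministically", {
  g <- function(id, genes, refs) {
    list(id = id,
         members = data.frame(species = "s1", gene_id = genes),
         ref_genes = refs)
  }
  groups <- list(g("b", c("x1"), c("g1", "g2")),
                 g("a", c("x2"), c("g1", "g2")),
                 g("c", c("x3"), c("g9")))
  out <- merge_and_dedup(groups)
  expect_length(out, 2L)
  sig <- vapply(out, function(x) paste(x$ref_genes, collapse = ";"), "")
  expect_equal(sig, sort(sig))  # signature-sorted output
  merged <- out[[which(sig == "g1;g2")]]
  expect_setequal(merged$members$gene_id, c("x1", "x2"))
  ## byte-identical duplicates collapse to one
  dup <- list(g("a", "x1", "g1"), g("b", "x1", "g1"))
  expect_length(merge_and_dedup(dup), 1L)
  ## disjoint signatures pass through
  expect_length(merge_and_dedup(list(g("a", "x", "g1"),
                                     g("b", "y", "g2"))), 2L)
})

test_that("size and taxon bounds are inclusive exactly as stated", {
  mk <- function(id, n, ntaxa) {
    list(id = id, members = data.frame(
      species = rep(paste0("s", seq_len(ntaxa)), length.out = n),
      gene_id = paste0(id, seq_len(n))))
  }
  groups <- list(mk("a", 6, 6), mk("b", 7, 7), mk("c", 80, 10),
                 mk("d", 81, 10), mk("e", 20, 6))
  out <- size_taxon_filter(groups)
  expect_setequal(vapply(out, `[[`, "", "id"), c("b", "c"))
  expect_length(size_taxon_filter(list()), 0L)
})

test_that("overlap trimming matches the hand-worked example", {
  ## four sequences; seq D is 70% gaps opposite residues of the others
  seqs <- c(A = "AAAAAAAAAA", B = "AAAAAAAAAA", C = "AAAAAAAAAT",
            D = "A---------")
  out <- trim_sequences(seqs, resoverlap = 1.0, seqoverlap = 0.38)
  ## for D: at column 1 all others are residues like D (good); at columns
  ## 2-10 D is a gap while all others are residues -> 1/10 good < 0.38
  expect_false("D" %in% names(out))
  expect_setequal(names(out), c("A", "B", "C"))
  ## gapless alignments are untouched
  clean <- c(A = "ACGT", B = "ACGA", C = "ACGG")
  expect_identical(trim_sequences(clean), clean)
  ## columns left all-gap after removal disappear
  seqs2 <- c(A = "AC-GT", B = "AC-GT", C = "AC-GT", D = "T----")
  out2 <- trim_sequences(seqs2, resoverlap = 1.0, seqoverlap = 0.5)
  expect_false("D" %in% names(out2))
  expect_identical(unname(out2), rep("ACGT", 3))
  expect_error(trim_sequences(c(A = "ACGT")), "at least 2")
})

test_that("NJ recovers the generating topology and clamps negatives", {
  ## clean simulated data on the default study tree
  big <- simulate_alignment(default_study_tree(), default_study_model(),
                            800, seed = 61)
  nj10 <- nj_tree(big)
  expect_equal(ape::dist.topo(nj10,
                              ape::unroot(default_study_tree()$tree)), 0,
               ignore_attr = TRUE)
  ## 3-taxon exact lengths from the three-point formulas
  aln <- codon_alignment(c(A = "ATGAAATTTCCC", B = "ATGAAATTTCCG",
                           C = "ATGAAGTTGCCG"))
  tree3 <- nj_tree(aln)
  expect_equal(length(tree3$tip.label), 3L)
  D3 <- codon_p_distance(aln)
  ## three-point formulas
  dAB <- D3["A", "B"]; dAC <- D3["A", "C"]; dBC <- D3["B", "C"]
  lens <- setNames(tree3$edge.length[match(match(c("A", "B", "C"),
                                                 tree3$tip.label),
                                           tree3$edge[, 2])],
                   c("A", "B", "C"))
  expect_equal(unname(lens["A"]), (dAB + dAC - dBC) / 2, tolerance = 1e-12)
  expect_equal(unname(lens["B"]), (dAB + dBC - dAC) / 2, tolerance = 1e-12)
  expect_true(all(nj_tree(aln)$edge.length >= 0))
  expect_error(nj_tree(codon_alignment(c(A = "ATG", B = "ATG"))),
               "at least 3")
  expect_error(codon_p_distance(codon_alignment(c(A = "---", B = "ATG"))),
               "A and B")
})

test_that("foreground labelling covers clades, stems and tips", {
  tr <- default_study_tree()$tree
  ## single leaf: terminal branch only, both modes
  for (mode in c("clade", "tips")) {
    lt <- label_foreground(tr, "F1a", mode = mode)
    expect_equal(n_test_branches(lt), 1L)
    child <- lt$tree$edge[lt$edge_label == "test", 2]
    expect_equal(lt$tree$tip.label[child], "F1a")
  }
  ## a cherry in clade mode: two tips + stem
  lt <- label_foreground(tr, c("F1a", "F1b"), mode = "clade")
  expect_equal(n_test_branches(lt), 3L)
  lt_tips <- label_foreground(tr, c("F1a", "F1b"), mode = "tips")
  expect_equal(n_test_branches(lt_tips), 2L)
  ## all leaves: every branch
  lt_all <- label_foreground(tr, tr$tip.label, mode = "clade")
  expect_equal(n_test_branches(lt_all), nrow(tr$edge))
  expect_error(label_foreground(tr, "nope"), "nope")
})

test_that("the filter pipeline is idempotent and auditable", {
  mock <- generate_mock_transcripts(seed = 21)
  res <- filter_orthogroups(mock$raw_groups, mock$reference_map)
  dropped <- res$audit$group_id[!res$audit$kept]
  expect_setequal(dropped, mock$planted$group_id)
  ## re-running on the output changes nothing
  res2 <- filter_orthogroups(res$groups, mock$reference_map)
  expect_equal(length(res2$groups), length(res$groups))
  expect_true(all(res2$audit$kept))
  expect_identical(vapply(res2$groups, `[[`, "", "id"),
                   vapply(res$groups, `[[`, "", "id"))
})
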