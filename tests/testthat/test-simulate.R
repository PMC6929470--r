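test_that("zero branch lengths copy the root draw to every tip", {
  tr <- ape::read.tree(text = "(A:0,B:0,(C:0,D:0):0);")
  m <- default_study_model()
  aln <- simulate_alignment(labelled_tree(tr), m, 50, seed = 8)
  expect_equal(length(unique(aln$seqs)), 1L)
})

test_that("long-run codon frequencies approach the stationary law", {
  tr <- ape::read.tree(text = "(A:30,B:30);")
  m <- default_study_model()
  aln <- simulate_alignment(labelled_tree(tr), m, 50000, seed = 12)
  emp <- table(factor(unlist(omegak:::codon_split(aln)),
                      levels = sense_codons()))
  emp <- as.numeric(emp) / sum(emp)
  tv <- sum(abs(emp - m$codon_freqs)) / 2
  expect_lt(tv, 0.05)
})

test_that("lower omega depresses the nonsynonymous difference fraction", {
  tr <- labelled_tree(ape::read.tree(text = "(A:0.4,B:0.4);"))
  pi <- freqs_from_nuc(c(0.25, 0.25, 0.25, 0.25))
  wins <- 0
  for (i in 1:20) {
    a_low <- simulate_alignment(tr, codon_model(2, pi, omega = 0.2), 400,
                                seed = 1000 + i)
    a_neu <- simulate_alignment(tr, codon_model(2, pi, omega = 1), 400,
                                seed = 1000 + i)
    wins <- wins + (nonsyn_diff_fraction(a_low) <
                      nonsyn_diff_fraction(a_neu))
  }
  expect_gte(wins, 19)
})

test_that("seeds determine alignments byte for byte", {
  lt <- default_study_tree()
  m <- default_study_model(k = 0.5)
  a1 <- simulate_alignment(lt, m, 60, seed = 99)
  a2 <- simulate_alignment(lt, m, 60, seed = 99)
  a3 <- simulate_alignment(lt, m, 60, seed = 100)
  expect_identical(a1$seqs, a2$seqs)
  expect_false(identical(a1$seqs, a3$seqs))
})

test_that("studies are reproducible and consistent with their truth", {
  cls <- study_classes(2, 2, 2, 1)
  s1 <- simulate_study(classes = cls, n_codons = 40, seed = 7)
  s2 <- simulate_study(classes = cls, n_codons = 40, seed = 7)
  expect_identical(lapply(s1$alignments, `[[`, "seqs"),
                   lapply(s2$alignments, `[[`, "seqs"))
  expect_identical(s1$go_map, s2$go_map)
  expect_equal(nrow(s1$truth), 7)
  expect_setequal(names(s1$alignments), s1$truth$orthogroup_id)
  ## every annotated orthogroup exists, truth classes match the class table
  expect_true(all(s1$go_map$orthogroup_id %in% s1$truth$orthogroup_id))
  expect_equal(as.vector(table(s1$truth$class)[c("relaxed", "neutral",
                                                 "intensified",
                                                 "episodic")]),
               c(2, 2, 2, 1))
  expect_true(all(s1$truth$true_k[s1$truth$class == "relaxed"] < 1))
  expect_true(all(s1$truth$true_k[s1$truth$class == "neutral"] == 1))
  epi <- s1$truth[s1$truth$class == "episodic", ]
  expect_false(is.na(epi$episodic_branch))
  expect_identical(s1$tree$edge_label[epi$episodic_branch], "test")
  ## neutral-only class table gives all-one truth
  s0 <- simulate_study(classes = study_classes(0, 3, 0), n_codons = 30,
                       seed = 3)
  expect_true(all(s0$truth$true_k == 1))
})

test_that("written studies round-trip through the standard formats", {
  dir <- tempfile("study")
  s <- simulate_study(classes = study_classes(1, 1, 0), n_codons = 30,
                      seed = 11, dir = dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  fa <- read_fasta(file.path(dir, "OG0001.fasta"))
  expect_identical(fa, s$alignments$OG0001$seqs)
  lt <- read_newick(file.path(dir, "OG0001.nwk"))
  expect_equal(n_test_branches(lt), n_test_branches(s$tree))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$orthogroup_id, s$truth$orthogroup_id)
  unlink(dir, recursive = TRUE)
})

test_that("site omega-category proportions follow the mixture weights", {
  m <- default_study_model()
  lt <- default_study_tree()
  aln <- simulate_alignment(lt, m, 3000, seed = 44)
  cats <- attr(aln, "site_categories")
  expect_length(cats, 3000)
  frac <- tabulate(cats, length(m$p)) / 3000
  se <- sqrt(m$p * (1 - m$p) / 3000)
  expect_true(all(abs(frac - m$p) < 4 * se))
  ## episodic sites are recorded and occur near the configured fraction
  epi <- simulate_alignment(lt, m, 2000, seed = 45,
                            episodic = list(edge = which(
                              lt$edge_label == "test")[1],
                              omega = 5, fraction = 0.2))
  f <- length(attr(epi, "episodic_sites")) / 2000
  expect_true(abs(f - 0.2) < 4 * sqrt(0.2 * 0.8 / 2000))
})
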