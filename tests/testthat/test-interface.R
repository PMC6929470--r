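test_that("FASTA round-trips, rejects duplicates, normalises case", {
  recs <- c(seq1 = paste0(rand_codons(40, seed = 1), collapse = ""),
            seq2 = paste0(rand_codons(40, seed = 2), collapse = ""))
  tf <- tempfile(fileext = ".fasta")
  write_fasta(recs, tf)
  expect_identical(read_fasta(tf), recs)
  ## 80-column wrapping on write
  expect_true(all(nchar(readLines(tf)) <= 80))
  ## empty file
  empty <- tempfile(); file.create(empty)
  expect_length(read_fasta(empty), 0L)
  ## duplicate ids rejected by name
  writeLines(c(">a", "ACGT", ">a", "ACGG"), tf)
  expect_error(read_fasta(tf), "duplicate.*a")
  ## lowercase normalised with a note
  writeLines(c(">a", "acgt"), tf)
  expect_message(got <- read_fasta(tf), "uppercase")
  expect_identical(unname(got), "ACGT")
  ## text before the first header is malformed
  writeLines(c("ACGT", ">a", "ACGT"), tf)
  expect_error(read_fasta(tf), "line 1")
  expect_error(write_fasta(c("ACGT"), tempfile()), "named")
})

test_that("newick round-trips labels, lengths and zero-length branches", {
  lt <- read_newick(textConnection_file("(A:1,(B:1,C:1):0.5);"))
  expect_equal(length(lt$tree$tip.label), 3L)
  internal_edge <- which(lt$tree$edge[, 2] > 3)
  expect_equal(lt$tree$edge.length[internal_edge], 0.5)
  ## labelled 10-taxon round trip is canonical
  study <- default_study_tree()
  tf <- tempfile(fileext = ".nwk")
  s1 <- write_newick(study, tf)
  rt <- read_newick(tf)
  tf2 <- tempfile(fileext = ".nwk")
  s2 <- write_newick(rt, tf2)
  expect_identical(s1, s2)
  expect_equal(n_test_branches(rt), n_test_branches(study))
  expect_equal(ape::dist.topo(rt$tree, study$tree), 0, ignore_attr = TRUE)
  ## zero-length branch preserved, not dropped
  lt0 <- read_newick(textConnection_file("(A:0,(B:0.1,C:0):0.2);"))
  expect_true(any(lt0$tree$edge.length == 0))
  expect_equal(sum(lt0$tree$edge.length), 0.3)
  ## unbalanced parentheses and unknown tags rejected
  expect_error(read_newick(textConnection_file("((A:1,B:1);")),
               "parentheses")
  expect_error(read_newick(textConnection_file("(A{foo}:1,B:1);")),
               "foo")
})

test_that("GMT parsing enforces the three-column minimum", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), tf)
  sets <- read_gmt(tf)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  writeLines("bad\tonlydesc", tf)
  expect_error(read_gmt(tf), "malformed")
})

test_that("the pipeline composes, audits itself and is reproducible", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  cfg <- pipeline_config(out1, seed = 5,
                         classes = study_classes(2, 2, 2),
                         n_codons = 50,
                         go = list(n_terms = 12, mean_terms = 3,
                                   odds_ratio = 10),
                         n_perm = 200, n_starts = 1)
  res <- run_pipeline(cfg)
  expect_setequal(names(res$manifest),
                  c("simulate", "relax", "branchsite", "classify",
                    "enrich", "gsea"))
  expect_true(file.exists(file.path(out1, "relax.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  relax_tbl <- read.delim(file.path(out1, "relax.tsv"))
  expect_equal(nrow(relax_tbl), 6)
  expect_true(all(c("orthogroup_id", "k_hat", "lnL_null", "lnL_alt",
                    "LRT", "p", "q_BH", "p_bonferroni", "direction") %in%
                    names(relax_tbl)))
  ## identical seed -> identical output hashes
  cfg2 <- cfg; cfg2$out_dir <- out2
  run_pipeline(cfg2)
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  h <- function(m) unlist(lapply(m, function(st) unname(unlist(st$outputs))))
  expect_identical(unname(h(m1)), unname(h(m2)))
  ## stage gating: classify without relax fails by name
  cfg3 <- pipeline_config(tempfile(), stages = c("simulate", "classify"))
  expect_error(run_pipeline(cfg3), "relax")
  ## simulate-only config emits the dataset and stops
  cfg4 <- pipeline_config(tempfile("solo"), seed = 2,
                          stages = "simulate",
                          classes = study_classes(1, 1, 0), n_codons = 30)
  res4 <- run_pipeline(cfg4)
  expect_named(res4$manifest, "simulate")
  expect_true(file.exists(file.path(cfg4$out_dir, "study", "truth.tsv")))
  unlink(c(out1, out2, cfg4$out_dir), recursive = TRUE)
})
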