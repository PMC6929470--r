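test_that("signed-rank test matches hand enumeration and conventions", {
  ## the 2^5 case worked by hand: all differences positive
  t1 <- wilcoxon_signed_rank(c(1.1, 1.2, 1.3, 1.4, 1.5), mu = 1)
  expect_equal(unname(t1$statistic), 15)
  expect_equal(t1$p_value, 0.0625)
  expect_identical(t1$method, "exact")
  ## symmetric values: V near n(n+1)/4, no evidence
  sym <- 1 + c(-0.4, -0.3, -0.2, -0.1, 0.1, 0.2, 0.3, 0.4)
  t2 <- wilcoxon_signed_rank(sym, mu = 1)
  expect_equal(unname(t2$statistic), 8 * 9 / 4)
  expect_gt(t2$p_value, 0.5)
  ## zero differences are dropped; all-zero input degenerates to p = 1
  t3 <- wilcoxon_signed_rank(c(1, 1, 1), mu = 1)
  expect_equal(t3$p_value, 1)
  expect_equal(t3$n_effective, 0L)
  t4 <- wilcoxon_signed_rank(c(1, 1.3, 0.4), mu = 1)
  expect_equal(t4$n_effective, 2L)
  ## ties fall back to the corrected normal approximation
  t5 <- wilcoxon_signed_rank(c(1.2, 1.2, 0.8, 1.4, 0.9), mu = 1)
  expect_identical(t5$method, "normal approximation")
  expect_true(t5$p_value >= 0 && t5$p_value <= 1)
})

test_that("exact signed-rank p equals full 2^n enumeration", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:12, 1)
    x <- 1 + round(runif(n, -1, 1), 3)
    x <- x[x != 1]
    if (length(x) < 2 || anyDuplicated(abs(x - 1))) next
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(x, mu = 1, alternative = alt)
      expect_equal(got$p_value, enumerate_signed_rank(x, 1, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-GO k tests respect min_n and report direction", {
  k_table <- data.frame(orthogroup_id = sprintf("OG%02d", 1:20),
                        k_hat = c(rep(0.2, 8), rep(1.6, 8), rep(1, 4)))
  go_map <- rbind(
    data.frame(orthogroup_id = sprintf("OG%02d", 1:8), term = "GO:0000001"),
    data.frame(orthogroup_id = sprintf("OG%02d", 9:16), term = "GO:0000002"),
    data.frame(orthogroup_id = sprintf("OG%02d", 17:20), term = "GO:0000003"))
  res <- go_term_k_tests(go_map, k_table, min_n = 5)
  expect_setequal(res$term, c("GO:0000001", "GO:0000002"))  # third < min_n
  r1 <- res[res$term == "GO:0000001", ]
  expect_identical(r1$direction, "relaxed")
  expect_lt(r1$p, 0.05)
  r2 <- res[res$term == "GO:0000002", ]
  expect_identical(r2$direction, "intensified")
  expect_equal(r2$median_k, 1.6)
})

test_that("Fisher enrichment reproduces hand-computed tail probabilities", {
  ## 2702 orthogroups, 122 selected, a term annotating exactly the 2
  ## selected orthogroups that carry it: p = (122*121)/(2702*2701)
  universe <- sprintf("U%04d", 1:2702)
  selected <- universe[1:122]
  go_map <- data.frame(orthogroup_id = universe[1:2],
                       term = "GO:0000010")
  p <- fisher_enrichment("GO:0000010", selected, universe, go_map)
  expect_equal(p, (122 * 121) / (2702 * 2701), tolerance = 1e-12)
  ## balanced 10/10 split of a 20-strong universe, term on half of each
  uni2 <- sprintf("V%02d", 1:20)
  sel2 <- uni2[1:10]
  gm2 <- data.frame(orthogroup_id = uni2[c(1:5, 11:15)], term = "GO:0000011")
  p2 <- fisher_enrichment("GO:0000011", sel2, uni2, gm2)
  expect_equal(p2, sum(dhyper(5:10, 10, 10, 10)), tolerance = 1e-12)
  expect_equal(p2, 0.6718591, tolerance = 1e-6)
  ## absent term and tail consistency
  expect_equal(fisher_enrichment("GO:zzz", sel2, uni2, gm2), 1)
  p_under <- fisher_enrichment("GO:0000011", sel2, uni2, gm2, tail = "under")
  expect_equal(p_under + p2, 1 + dhyper(5, 10, 10, 10), tolerance = 1e-12)
  expect_error(fisher_enrichment("GO:0000011", "W99", uni2, gm2), "subset")
})

test_that("overlap expectations follow |A||B|/N and Monte-Carlo sampling", {
  expect_equal(overlap_stats(character(0), c("a", "b"), 10)$expected, 0)
  expect_equal(overlap_stats(character(0), c("a", "b"), 10)$p_value, 1)
  ov <- overlap_stats(sprintf("x%d", 1:122), sprintf("x%d", 1:92), 2702)
  expect_equal(ov$expected, 122 * 92 / 2702, tolerance = 1e-12)
  expect_equal(ov$expected, 4.154, tolerance = 1e-3)
  expect_error(overlap_stats("a", "b", 0), "positive")
  ## Monte-Carlo: mean observed overlap of random same-size sets matches
  set.seed(12)
  uni <- sprintf("u%d", 1:500)
  obs <- replicate(4000, length(intersect(sample(uni, 60),
                                          sample(uni, 40))))
  exp_overlap <- 60 * 40 / 500
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - exp_overlap), 3 * se + 1e-9)
})

test_that("the k score transform is bounded, monotone and sign-correct", {
  expect_equal(transform_k(1), 0)
  expect_equal(transform_k(0), -1)
  expect_equal(transform_k(50), 49 / 51)
  ks <- seq(0, 50, length.out = 200)
  sc <- transform_k(ks)
  expect_true(all(diff(sc) > 0))
  expect_true(all(sc >= -1 & sc <= 1))
  expect_true(all(sign(sc) == sign(ks - 1)))
  expect_error(transform_k(-0.1), "non-negative")
})

test_that("GSEA recovers planted sets and respects its p-value floor", {
  set.seed(2)
  n <- 200
  scores <- setNames(rnorm(n), sprintf("G%03d", 1:n))
  top <- names(sort(scores, decreasing = TRUE))[1:10]
  sets <- list(planted = top,
               random = sample(names(scores), 25),
               everything = names(scores),
               tiny = names(scores)[1:2])
  res <- gsea(scores, sets, n_perm = 500, seed = 4)
  expect_identical(attr(res, "skipped"), "tiny")
  planted <- res[res$set == "planted", ]
  expect_gt(planted$NES, 0)
  expect_lte(planted$p, 0.01)
  expect_true(all(res$p >= 1 / 501))
  expect_equal(res[res$set == "everything", "ES"], 0)
  expect_true(all(sign(res$NES[res$ES != 0]) == sign(res$ES[res$ES != 0])))
  ## leading edge of the planted set sits at the top of the ranking
  lead <- strsplit(planted$leading_edge, ";")[[1]]
  expect_true(all(lead %in% top))
  expect_gt(length(lead), 5)
})

test_that("the running-sum statistic agrees with an independent GSEA
           implementation", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  scores <- setNames(rnorm(80), sprintf("g%02d", 1:80))
  ord <- order(scores, decreasing = TRUE)
  for (i in 1:5) {
    members <- sample(names(scores), 12)
    mine <- gsea(scores, list(s = members), n_perm = 50, min_set_size = 5,
                 seed = 1)$ES
    ref <- fgsea::calcGseaStat(scores[ord],
                               selectedStats = which(names(scores)[ord]
                                                     %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("classification flags mirror the q-value and k rules", {
  kt <- data.frame(orthogroup_id = sprintf("OG%d", 1:6),
                   k_hat = c(0.3, 1.0, 4, 0.5, 2, 0.9),
                   relax_p = c(0.001, 0.001, 0.002, 0.9, 0.5, NA),
                   branchsite_p = c(0.9, 0.8, 0.004, 0.001, 0.7, 0.9))
  expect_message(cls <- classify_orthogroups(kt, fdr = 0.10),
                 "unclassified")
  expect_true(cls$relaxed[1])
  expect_false(cls$relaxed[2] || cls$intensified[2])  # k exactly 1
  expect_true(cls$intensified[3] && cls$diversifying[3])  # non-exclusive
  expect_false(cls$relaxed[4])
  expect_true(cls$diversifying[4])  # diversifying only
  expect_true(is.na(cls$relaxed[6]))
  ## counts shrink (weakly) as the threshold tightens
  n_flag <- function(fdr) {
    c2 <- suppressMessages(classify_orthogroups(kt, fdr = fdr))
    sum(c2$relaxed, c2$intensified, c2$diversifying, na.rm = TRUE)
  }
  thresholds <- c(0.2, 0.1, 0.05, 0.01)
  expect_true(all(diff(vapply(thresholds, n_flag, 0)) <= 0))
})
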