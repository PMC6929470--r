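test_that("degenerate tree reduces to the stationary log-density", {
  pi <- freqs_from_nuc(c(0.1, 0.2, 0.3, 0.4))
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  seq1 <- paste0(rand_codons(7, seed = 11), collapse = "")
  aln <- codon_alignment(c(A = seq1, B = seq1, C = seq1))
  m <- codon_model(2, pi, omega = 0.5)
  ll <- codon_loglik(aln, labelled_tree(tr0), m)
  sense <- sense_codons()
  idx <- match(substring(seq1, seq(1, 19, 3), seq(3, 21, 3)), sense)
  expect_equal(ll, sum(log(pi[idx])), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small instances", {
  set.seed(7)
  cases <- list(
    list(tree = tiny_tree3(), fg = "A", n = 5, k = 0.5),
    list(tree = tiny_tree3(), fg = "B", n = 10, k = 3),
    list(tree = tiny_tree4(), fg = c("A", "B"), n = 5, k = 0.2),
    list(tree = tiny_tree4(), fg = "D", n = 8, k = 1)
  )
  for (cs in cases) {
    lt <- label_foreground(cs$tree, cs$fg, mode = "tips")
    aln <- rand_alignment(cs$tree$tip.label, cs$n,
                          seed = 100 + cs$n)
    pi <- freqs_from_nuc(c(0.15, 0.35, 0.2, 0.3))
    m <- codon_model(2.2, pi, omega = c(0.2, 1.6), p = c(0.7, 0.3),
                     k = cs$k)
    ll <- codon_loglik(aln, lt, m)
    oracle <- brute_force_loglik(aln, lt, m)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("k = 1 collapses the test/reference partition", {
  lt <- label_foreground(tiny_tree4(), c("A", "B"), mode = "clade")
  aln <- rand_alignment(tiny_tree4()$tip.label, 20, seed = 3)
  pi <- codon_frequencies(aln, "F3x4")
  m1 <- codon_model(2, pi, omega = c(0.1, 0.9, 2), p = c(0.5, 0.3, 0.2),
                    k = 1)
  plain <- labelled_tree(tiny_tree4())
  expect_equal(codon_loglik(aln, lt, m1), codon_loglik(aln, plain, m1),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to re-rooting", {
  tr <- default_study_tree()
  aln <- simulate_alignment(tr, default_study_model(k = 0.5), 40, seed = 9)
  m <- codon_model(1.8, codon_frequencies(aln),
                   omega = c(0.2, 1.4), p = c(0.6, 0.4), k = 0.5)
  base <- codon_loglik(aln, tr, m)
  for (node in c("B4", "OUT", "B1")) {
    rerooted <- ape::root(tr$tree, outgroup = node, resolve.root = FALSE)
    ## recompute labels on the rerooted topology
    lt2 <- label_foreground(rerooted, list(c("F1a", "F1b"),
                                           c("F2a", "F2b")))
    expect_equal(codon_loglik(aln, lt2, m), base, tolerance = 1e-8)
  }
})

test_that("gaps and ambiguity codes act as missing data", {
  lt <- labelled_tree(tiny_tree3())
  pi <- rep(1 / 61, 61)
  m <- codon_model(2, pi, omega = 0.4)
  aln_full <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGAAT"))
  aln_gap <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATG---"))
  ## gap codon sums over all codons: equals dropping C's second site from
  ## its tip partial, i.e. marginal likelihood over C's state
  manual <- 0
  sense <- sense_codons()
  for (cd in sense) {
    a2 <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG",
                            C = paste0("ATG", cd)))
    manual <- manual + exp(codon_loglik(a2, lt, m))
  }
  expect_equal(codon_loglik(aln_gap, lt, m), log(manual),
               tolerance = 1e-8)
  ## partially ambiguous codon restricts the sum
  aln_amb <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATGAAN"))
  manual2 <- 0
  for (nt in c("A", "C", "G", "T")) {
    cd <- paste0("AA", nt)
    if (!(cd %in% sense)) next
    a2 <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG",
                            C = paste0("ATG", cd)))
    manual2 <- manual2 + exp(codon_loglik(a2, lt, m))
  }
  expect_equal(codon_loglik(aln_amb, lt, m), log(manual2),
               tolerance = 1e-8)
  expect_lt(codon_loglik(aln_full, lt, m),
            codon_loglik(aln_gap, lt, m))
})

test_that("alignment taxa must be tips of the tree", {
  lt <- labelled_tree(tiny_tree3())
  aln <- rand_alignment(c("A", "B", "Z"), 5, seed = 1)
  m <- codon_model(2, rep(1 / 61, 61), omega = 0.5)
  expect_error(codon_loglik(aln, lt, m), "Z")
})

test_that("branch-site mixture likelihood agrees between the assembled and
           profiled code paths", {
  lt <- default_study_tree()
  aln <- simulate_alignment(lt, default_study_model(), 30, seed = 21)
  data <- omegak:::prep_likelihood_data(aln, lt)
  pi <- codon_frequencies(aln, "F3x4")
  pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
  target <- which(data$is_test)[2]
  omegas <- c(0.3, 4)
  w <- c(0.85, 0.15)
  nedge <- nrow(data$edge)
  om_mat <- matrix(0.5, nedge, 2); wt_mat <- matrix(0, nedge, 2)
  wt_mat[, 1] <- 1
  om_mat[target, ] <- omegas
  wt_mat[target, ] <- w
  direct <- sum(omegak:::cpp_edge_mixture_loglik(
    2, pi, data$ci, data$cj, data$ts, data$ns, data$edge,
    data$edge_len, om_mat, wt_mat, data$tip_code, data$tip_state,
    data$state_table, data$root) * data$weights)
  caches <- omegak:::cpp_focal_edge_cache(
    2, pi, data$ci, data$cj, data$ts, data$ns, data$edge, data$edge_len,
    rep(0.5, nedge), data$tip_code, data$tip_state, data$state_table,
    data$root, target)
  M <- omegak:::cpp_focal_loglik(2, pi, data$ci, data$cj, data$ts,
                                 data$ns, omegas, caches[[1]]$t,
                                 caches[[1]]$outside, caches[[1]]$inside,
                                 caches[[1]]$scale)
  mixed <- sum(log(exp(M) %*% w) * data$weights)
  expect_equal(mixed, direct, tolerance = 1e-8)
})
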