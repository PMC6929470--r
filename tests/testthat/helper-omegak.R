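# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the implementation paths they check.

rand_codons <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(sense_codons(), n, replace = TRUE)
}

rand_alignment <- function(taxa, n_codons, seed = 1) {
  set.seed(seed)
  seqs <- vapply(taxa, function(tx) {
    paste0(rand_codons(n_codons), collapse = "")
  }, character(1))
  codon_alignment(seqs)
}

tiny_tree3 <- function() {
  ape::read.tree(text = "(A:0.1,B:0.2,C:0.15);")
}

tiny_tree4 <- function() {
  ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.15,D:0.3);")
}

# Brute-force log-likelihood by explicit summation over all internal-node
# codon states (independent of the pruning code path; uses only the exported
# rate-matrix/transition functions).
brute_force_loglik <- function(aln, ltree, model) {
  tree <- ltree$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  pi <- model$codon_freqs
  A <- omegak:::substitution_rate_coefs(model$kappa, pi)
  rho <- A[["A"]] + A[["B"]] * sum(model$p * model$omega)
  cs <- omegak:::codon_split(aln)
  sense <- sense_codons()
  n_sites <- n_codons(aln)
  Ps <- lapply(seq_along(model$omega), function(cc) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      om <- model$omega[cc]
      if (ltree$edge_label[e] == "test") om <- omegak:::omega_pow(om, model$k)
      Q <- codon_rate_matrix(model$kappa, om, pi, scale = FALSE)
      transition_probabilities(Q, tree$edge.length[e] * model$scaler / rho,
                               pi)
    })
  })
  internal <- ntip + seq_len(nnode)
  grids <- rep(list(seq_len(61)), nnode)
  states_grid <- as.matrix(expand.grid(grids))
  total <- 0
  for (s in seq_len(n_sites)) {
    tip_state <- vapply(tree$tip.label, function(tx) {
      match(cs[[tx]][s], sense)
    }, integer(1))
    lik_site <- 0
    for (cc in seq_along(model$omega)) {
      lik_cat <- 0
      for (g in seq_len(nrow(states_grid))) {
        assign_state <- c(tip_state, states_grid[g, ])
        prob <- pi[assign_state[ntip + 1L]]  # root = first internal node
        for (e in seq_len(nrow(tree$edge))) {
          prob <- prob * Ps[[cc]][[e]][assign_state[tree$edge[e, 1]],
                                       assign_state[tree$edge[e, 2]]]
        }
        lik_cat <- lik_cat + prob
      }
      lik_site <- lik_site + model$p[cc] * lik_cat
    }
    total <- total + log(lik_site)
  }
  unname(total)
}

# Exact one-sample signed-rank p by enumeration of all 2^n sign patterns.
enumerate_signed_rank <- function(values, mu = 1,
                                  alternative = "two.sided") {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_V <- signs %*% r
  switch(alternative,
         two.sided = {
           mu_V <- n * (n + 1) / 4
           min(1, mean(abs(null_V - mu_V) >= abs(V - mu_V)))
         },
         greater = mean(null_V >= V),
         less = mean(null_V <= V))
}

# NG86-flavoured counting estimate of the nonsynonymous/synonymous
# difference proportion between two sequences (direction oracle only).
nonsyn_diff_fraction <- function(aln) {
  cs <- omegak:::codon_split(aln)
  aa <- codon_amino_acids()
  s1 <- cs[[1]]; s2 <- cs[[2]]
  diff <- which(s1 != s2)
  if (!length(diff)) return(0)
  mean(aa[s1[diff]] != aa[s2[diff]])
}

# write text to a temp file and return its path (newick snippets etc.)
textConnection_file <- function(txt) {
  f <- tempfile(fileext = ".txt")
  writeLines(txt, f)
  f
}
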