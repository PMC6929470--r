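## Phylogenetic likelihood of a codon alignment under the selection-intensity
## model: a shared mixture of dN/dS categories (omega_i, p_i), with every
## omega_i raised to the exponent k on test (foreground) branches. Site
## likelihoods are computed by Felsenstein pruning in compiled code, with one
## pass per mixture category; the per-site category mixture is combined by
## log-sum-exp.

#' Construct a codon substitution model
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param codon_freqs 61 stationary codon frequencies ([sense_codons()]
#'   order, summing to 1).
#' @param omega Numeric vector of dN/dS category values (>= 0).
#' @param p Mixture proportions for the categories (sum to 1). Default:
#'   equal weights.
#' @param k Selection-intensity exponent applied to test branches, in
#'   `[0, 50]`. `k = 1` makes test and reference branches identical; `k < 1`
#'   relaxes selection (all omega pulled towards 1), `k > 1` intensifies it.
#' @param scaler Global multiplier applied to all branch lengths (the
#'   branch-length scale is re-estimated rather than each length).
#' @return An object of class `codon_model`.
#' @export
codon_model <- function(kappa, codon_freqs, omega, p = NULL, k = 1,
                        scaler = 1) {
  if (kappa <= 0) stop("kappa must be positive")
  check_codon_freqs(codon_freqs)
  if (any(omega < 0)) stop("omega categories must be non-negative")
  if (is.null(p)) p <- rep(1 / length(omega), length(omega))
  if (length(p) != length(omega)) {
    stop("omega and p must have the same length")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("mixture proportions must be non-negative and sum to 1")
  }
  if (k < 0 || k > 50) stop("k must lie in [0, 50]")
  if (scaler <= 0) stop("scaler must be positive")
  structure(list(kappa = kappa, codon_freqs = codon_freqs,
                 omega = as.numeric(omega), p = as.numeric(p),
                 k = k, scaler = scaler),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("codon model (MG94xHKY mixture)\n")
  cat(sprintf("  kappa = %.4g, k = %.4g, scaler = %.4g\n",
              x$kappa, x$k, x$scaler))
  cat(sprintf("  omega: %s\n", paste(signif(x$omega, 4), collapse = ", ")))
  cat(sprintf("  p:     %s\n", paste(signif(x$p, 4), collapse = ", ")))
  invisible(x)
}

## omega^k with the 0^0 = 1 convention (k = 0 drives every category to
## neutrality, including omega = 0)
omega_pow <- function(omega, k) {
  out <- omega^k
  out[omega == 0 & k == 0] <- 1
  out
}

## Assemble everything the compiled pruning core needs. Tree tips absent
## from the alignment are treated as fully missing data.
prep_likelihood_data <- function(aln, ltree) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!inherits(ltree, "labelled_tree")) ltree <- labelled_tree(ltree)
  tree <- ltree$tree
  tips <- tree$tip.label
  extra <- setdiff(alignment_taxa(aln), tips)
  if (length(extra)) {
    stop("alignment taxa not in tree: ", paste(extra, collapse = ", "))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste0(post$edge[, 1], "-", post$edge[, 2]),
               paste0(tree$edge[, 1], "-", tree$edge[, 2]))
  enc <- encode_alignment(aln)
  nstates <- nrow(enc$state_table)
  state_table <- rbind(enc$state_table, MISSING = rep(1, 61))
  tip_state <- matrix(nstates + 1L, nrow = length(tips),
                      ncol = ncol(enc$tip_state), dimnames = list(tips, NULL))
  present <- intersect(tips, rownames(enc$tip_state))
  tip_state[present, ] <- enc$tip_state[present, , drop = FALSE]
  comp_key <- apply(tip_state, 2, paste0, collapse = ",")
  keep <- !duplicated(comp_key)
  weights <- as.numeric(table(factor(comp_key, levels = comp_key[keep])))
  ch <- codon_change_table()
  ## fast path for unambiguous codons: 0-based codon index, -1 otherwise
  token_code <- c(match(rownames(enc$state_table), sense_codons()),
                  NA_integer_)
  token_code <- ifelse(is.na(token_code), -1L, token_code - 1L)
  tip_code <- matrix(token_code[tip_state[, keep, drop = FALSE]],
                     nrow = nrow(tip_state))
  list(edge = post$edge, edge_len = post$edge.length,
       orig_edge = ord,  # postorder row -> row of the input tree$edge
       is_test = ltree$edge_label[ord] == "test",
       tip_state = tip_state[, keep, drop = FALSE],
       tip_code = tip_code,
       state_table = state_table, weights = weights,
       root = length(tips) + 1L,
       ci = ch$i - 1L, cj = ch$j - 1L, ts = ch$transition, ns = ch$nonsyn,
       n_sites = ncol(enc$tip_state), site_index = match(comp_key,
                                                         comp_key[keep]))
}

## lnL given prepared data; returns total (and per-site vector as attribute
## if per_site). Branch lengths are divided by the expected substitution
## rate of the reference-branch mixture so that input lengths keep their
## substitutions-per-site meaning.
relax_loglik_data <- function(data, kappa, pi, omega, p, k, scaler) {
  coefs <- substitution_rate_coefs(kappa, pi)
  rho <- coefs[["A"]] + coefs[["B"]] * sum(p * omega)
  M <- siteloglik_configs(data, kappa, pi, omega, k,
                          branch_scale = scaler / rho)
  lw <- sweep(M, 2, log(p), "+")
  m <- apply(lw, 1, max)
  site <- m + log(rowSums(exp(lw - m)))
  structure(sum(site * data$weights), site_loglik = site[data$site_index])
}

## per-pattern log-likelihood, one column per omega category (test edges
## use omega^k); branch_scale multiplies all edge lengths
siteloglik_configs <- function(data, kappa, pi, omega, k, branch_scale) {
  nedge <- nrow(data$edge)
  configs <- vapply(seq_along(omega), function(c) {
    ifelse(data$is_test, omega_pow(omega[c], k), omega[c])
  }, numeric(nedge))
  if (nedge == 1L) configs <- matrix(configs, nrow = 1L)
  cpp_siteloglik_matrix(kappa, pi, data$ci, data$cj, data$ts, data$ns,
                        data$edge, data$edge_len * branch_scale, configs,
                        data$tip_code, data$tip_state, data$state_table,
                        data$root)
}

## maximise sum_s w_s log(sum_c p_c exp(M_sc)) over the probability simplex
## by EM, warm-started; returns list(p, loglik)
profile_mixture <- function(M, weights, p0 = NULL, tol = 1e-8,
                            max_iter = 60L) {
  C <- ncol(M)
  if (C == 1L) {
    return(list(p = 1, loglik = sum(M[, 1] * weights)))
  }
  p <- if (is.null(p0) || length(p0) != C) rep(1 / C, C) else
    pmax(p0, 1e-8) / sum(pmax(p0, 1e-8))
  m <- as.numeric(Reduce(pmax, asplit(M, 2)))
  E <- exp(M - m)
  W <- sum(weights)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mix <- as.vector(E %*% p)
    ll <- sum(weights * (log(mix) + m))
    if (ll - ll_old < tol && it > 2L) break
    ll_old <- ll
    resp <- E * rep(p, each = nrow(E)) / mix
    p <- as.vector(crossprod(resp, weights)) / W
    p <- pmax(p, 1e-12); p <- p / sum(p)
  }
  mix <- as.vector(E %*% p)
  list(p = p, loglik = sum(weights * (log(mix) + m)))
}

#' Log-likelihood of a codon alignment on a labelled tree
#'
#' @param aln A `codon_alignment` whose taxa are all tips of the tree (tree
#'   tips without sequence data are treated as missing).
#' @param tree A `labelled_tree` (or plain `phylo`, all-reference).
#' @param model A `codon_model`.
#' @param per_site If `TRUE`, also return the per-codon-site log-likelihood
#'   vector as attribute `"site_loglik"`.
#' @return Numeric scalar log-likelihood.
#' @export
codon_loglik <- function(aln, tree, model, per_site = FALSE) {
  stopifnot(inherits(model, "codon_model"))
  data <- prep_likelihood_data(aln, tree)
  res <- relax_loglik_data(data, model$kappa, model$codon_freqs,
                           model$omega, model$p, model$k, model$scaler)
  if (!per_site) attributes(res) <- NULL
  res
}
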