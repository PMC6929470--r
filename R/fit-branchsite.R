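## Simplified adaptive branch-site test for episodic diversifying
## selection. A single background omega (with kappa and a global
## branch-length scale) is fitted once; then each test branch receives its
## own omega mixture, mixed independently of other branches. Category
## counts grow adaptively (1, 2, ... up to the cap) and stop as soon as
## AICc worsens. Each chosen branch model is compared against the same
## model refitted with all of that branch's omega categories constrained
## to <= 1; the statistic is referred to chi-squared with 1 df (a
## conservative stand-in for the boundary-mixture null). When the
## unconstrained optimum already satisfies the constraint the LRT is 0 and
## no refit is needed. Branch p-values are Holm-corrected within the
## orthogroup; the orthogroup-level p is their minimum.

## fit `ncat` omegas (weights profiled by EM) on one branch under an upper
## bound omega_cap, using the branch's inside/outside cache; returns lnL,
## omega, weight
fit_branch_mixture <- function(data, kappa, pi, cache, ncat, omega_cap) {
  lo <- rep(log(1e-6), ncat)
  hi <- rep(log(omega_cap), ncat)
  start <- log(pmin(c(0.2, 2.5, 10)[seq_len(ncat)], omega_cap * 0.9))
  p_env <- new.env(parent = emptyenv())
  obj <- function(x) {
    M <- cpp_focal_loglik(kappa, pi, data$ci, data$cj, data$ts, data$ns,
                          exp(x), cache$t, cache$outside, cache$inside,
                          cache$scale)
    prof <- profile_mixture(M, data$weights, p0 = p_env$p)
    p_env$p <- prof$p
    -prof$loglik
  }
  res <- relax_optim(pmin(pmax(start, lo), hi), obj, lo, hi, maxit = 100L)
  ord <- order(res$par)
  list(lnL = -res$value, omega = exp(res$par)[ord],
       weight = if (ncat == 1L) 1 else p_env$p[ord],
       convergence = res$convergence)
}

#' Fit the adaptive branch-site diversifying-selection test
#'
#' For every test branch, fits branch-specific dN/dS mixtures with an
#' adaptively chosen number of categories (small-sample AICc, growing until
#' it stops improving, capped at `max_categories`) and tests the chosen
#' model against the same model with all of that branch's omega values
#' constrained to at most 1. An orthogroup is a candidate for episodic
#' diversifying selection when its smallest Holm-corrected branch p-value
#' is small.
#'
#' @inheritParams fit_relax
#' @param max_categories Maximum number of omega categories per test
#'   branch.
#' @param omega_max Upper bound on any omega category.
#' @return Object of class `branchsite_fit`: a per-branch table
#'   (`branches`), the orthogroup-level p-value (`p_orthogroup` = min Holm
#'   corrected branch p), and the shared background fit.
#' @export
fit_branch_site <- function(aln, tree, frequencies = "F3x4",
                            max_categories = 3, omega_max = 50,
                            n_starts = 1, seed = 1L) {
  if (!inherits(tree, "labelled_tree")) {
    stop("tree must be a labelled_tree; use label_foreground() first")
  }
  if (n_test_branches(tree) < 1L) {
    stop("tree must have at least one test branch")
  }
  pi <- codon_frequencies(aln, frequencies)
  pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
  data <- prep_likelihood_data(aln, tree)
  n <- data$n_sites

  base <- fit_single_omega(data, pi, n_starts = n_starts, seed = seed)
  kappa <- base$kappa; u <- base$u; omega_bg <- base$omega

  aicc <- function(lnL, np) {
    if (n - np - 1L <= 0L) return(Inf)
    2 * np - 2 * lnL + 2 * np * (np + 1) / (n - np - 1)
  }

  test_edges <- which(data$is_test)
  caches <- cpp_focal_edge_cache(kappa, pi, data$ci, data$cj, data$ts,
                                 data$ns, data$edge, data$edge_len * u,
                                 rep(omega_bg, nrow(data$edge)),
                                 data$tip_code, data$tip_state,
                                 data$state_table, data$root, test_edges)
  rows <- lapply(seq_along(test_edges), function(bi) {
    b <- test_edges[bi]
    cache <- caches[[bi]]
    fits <- list()
    best_j <- 1L
    for (j in seq_len(max_categories)) {
      fits[[j]] <- fit_branch_mixture(data, kappa, pi, cache, j, omega_max)
      if (j > 1L &&
          aicc(fits[[j]]$lnL, 2L * j - 1L) >
          aicc(fits[[best_j]]$lnL, 2L * best_j - 1L)) {
        break  # adding categories stopped paying; stop growing
      }
      best_j <- j
    }
    best <- fits[[best_j]]
    if (max(best$omega) <= 1) {
      lnL_con <- best$lnL  # constraint already satisfied at the optimum
    } else {
      lnL_con <- fit_branch_mixture(data, kappa, pi, cache, best_j,
                                    omega_cap = 1)$lnL
    }
    lrt <- max(0, 2 * (best$lnL - lnL_con))
    data.frame(edge = data$orig_edge[b],  # row of the input tree$edge
               child = data$edge[b, 2],
               n_categories = best_j,
               omega_max_hat = max(best$omega),
               prop_max = best$weight[which.max(best$omega)],
               lnL = best$lnL, lnL_constrained = lnL_con,
               lrt = lrt,
               p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  })
  branches <- do.call(rbind, rows)
  branches$p_holm <- stats::p.adjust(branches$p, method = "holm")
  structure(list(branches = branches,
                 p_orthogroup = min(branches$p_holm),
                 kappa = kappa, scaler = u, omega_bg = omega_bg,
                 lnL_background = base$lnL,
                 n_codons = n, n_taxa = nrow(data$tip_state),
                 seed = seed, call = match.call()),
            class = "branchsite_fit")
}

#' @export
print.branchsite_fit <- function(x, ...) {
  cat("Branch-site diversifying-selection test\n")
  cat(sprintf("  data: %d taxa, %d codons; background omega = %.3g\n",
              x$n_taxa, x$n_codons, x$omega_bg))
  cat(sprintf("  %d test branches, orthogroup p (min Holm) = %.4g\n",
              nrow(x$branches), x$p_orthogroup))
  print(x$branches[, c("edge", "n_categories", "omega_max_hat", "lrt",
                       "p", "p_holm")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.branchsite_fit <- function(object, ...) print(object)

#' @export
coef.branchsite_fit <- function(object, ...) {
  c(kappa = object$kappa, scaler = object$scaler,
    omega_bg = object$omega_bg)
}
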