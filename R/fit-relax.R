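## The selection-intensity (relaxation/intensification) test. A three
## category dN/dS mixture (omega1 <= omega2 <= 1 <= omega3) is shared by
## all branches; on test branches every category is raised to the exponent
## k. The null model fixes k = 1, the alternative frees k in [0, k_max].
## The likelihood-ratio statistic is referred to chi-squared with 1 df.
##
## Fitting strategy: the category proportions are profiled out by an inner
## EM (the site likelihood is linear in them), and the substitution-rate
## normalisation is absorbed into the free branch-length scaler, so the
## outer bounded quasi-Newton search runs over (kappa, scaler, omega1,
## omega2, omega3[, k]) only. Multi-starts run on a short budget and the
## best start is polished to the final tolerance.

relax_lower <- function() {
  c(lkappa = log(0.05), lu = log(0.005), o1 = 1e-6, o2 = 1e-6, lo3 = 0)
}
relax_upper <- function() {
  c(lkappa = log(50), lu = log(200), o1 = 1, o2 = 1, lo3 = log(50))
}

## outer parameters -> model pieces (omega small pair sorted)
relax_outer_unpack <- function(x) {
  o_small <- sort(c(x[["o1"]], x[["o2"]]))
  list(kappa = exp(x[["lkappa"]]), u = exp(x[["lu"]]),
       omega = c(o_small, exp(x[["lo3"]])))
}

## short multi-start exploration, then polish the best candidate
staged_optim <- function(starts, obj, lower, upper, short_maxit = 15L,
                         polish_maxit = 250L) {
  if (length(starts) == 1L) {
    st <- pmin(pmax(starts[[1]], lower), upper)
    res <- try(stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e10,
                                           maxit = polish_maxit)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      return(list(par = st, value = obj(st), convergence = 99L))
    }
    return(res)
  }
  short <- lapply(starts, function(st) {
    st <- pmin(pmax(st, lower), upper)
    res <- try(stats::optim(st, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e12,
                                           maxit = short_maxit)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      list(par = st, value = obj(st), convergence = 99L)
    } else res
  })
  best <- short[[which.min(vapply(short, `[[`, 0, "value"))]]
  res <- try(stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(factr = 1e10,
                                         maxit = polish_maxit)),
             silent = TRUE)
  if (inherits(res, "try-error") || res$value > best$value) best else res
}

## single bounded fit used for small problems (branch-site mixtures etc.)
relax_optim <- function(start, obj, lower, upper, maxit = 250L) {
  staged_optim(list(start), obj, lower, upper, polish_maxit = maxit)
}

## quick single-omega fit of (kappa, branch scale, omega); the starting
## point for both tests
fit_single_omega <- function(data, pi, n_starts = 1, seed = 1L) {
  obj <- function(x) {
    M <- siteloglik_configs(data, exp(x[1]), pi, exp(x[3]), 1, exp(x[2]))
    -sum(M[, 1] * data$weights)
  }
  lo <- c(log(0.05), log(0.005), log(1e-4))
  hi <- c(log(50), log(200), log(5))
  starts <- multi_starts(c(log(2), 0, log(0.3)), n_starts, lo, hi, seed)
  res <- staged_optim(starts, obj, lo, hi, polish_maxit = 100L)
  list(kappa = exp(res$par[1]), u = exp(res$par[2]), omega = exp(res$par[3]),
       lnL = -res$value, convergence = res$convergence)
}

#' Fit the selection-intensity (RELAX-style) test
#'
#' Fits the shared-mixture codon model under `k = 1` (null) and with `k`
#' free (alternative) by bounded maximum likelihood with seeded random
#' multi-starts, and reports the likelihood-ratio test of a shift in
#' selection intensity on the test branches.
#'
#' @param aln A `codon_alignment`.
#' @param tree A `labelled_tree` with at least one test and one reference
#'   branch (e.g. from [label_foreground()]).
#' @param frequencies Codon frequency model passed to [codon_frequencies()].
#' @param k_max Upper bound for the selection-intensity exponent.
#' @param n_starts Number of random multi-starts for each optimisation
#'   (exploration runs on a short budget; the best is polished).
#' @param seed Integer seed controlling the multi-start jitter.
#' @return Object of class `relax_fit` with components `k_hat`, `lnL_null`,
#'   `lnL_alt`, `lrt`, `p_value`, `direction`, the fitted null/alternative
#'   model parameters, and a `converged` flag.
#' @export
fit_relax <- function(aln, tree, frequencies = "F3x4", k_max = 50,
                      n_starts = 3, seed = 1L) {
  if (!inherits(tree, "labelled_tree")) {
    stop("tree must be a labelled_tree; use label_foreground() first")
  }
  if (n_test_branches(tree) < 1L ||
      sum(tree$edge_label == "reference") < 1L) {
    stop("tree must have at least one test and one reference branch")
  }
  pi <- codon_frequencies(aln, frequencies)
  pi <- pmax(pi, 1e-8); pi <- pi / sum(pi)
  data <- prep_likelihood_data(aln, tree)
  lower <- relax_lower(); upper <- relax_upper()

  p_env <- new.env(parent = emptyenv())
  col_cache <- new.env(parent = emptyenv())
  mix_obj <- function(kappa, u, omega, k) {
    ## per-category site-loglik columns are memoised so that coordinate
    ## perturbations of a single omega only recompute one column
    keys <- sprintf("%.14g|%.14g|%.14g|%.14g", kappa, u, omega, k)
    miss <- which(!vapply(keys, exists, NA, envir = col_cache,
                          inherits = FALSE))
    if (length(miss)) {
      Mnew <- siteloglik_configs(data, kappa, pi, omega[miss], k, u)
      for (ii in seq_along(miss)) {
        assign(keys[miss[ii]], Mnew[, ii], envir = col_cache)
      }
    }
    M <- vapply(keys, get, numeric(length(data$weights)),
                envir = col_cache)
    prof <- profile_mixture(M, data$weights, p0 = p_env$p)
    p_env$p <- prof$p
    -prof$loglik
  }
  obj_null <- function(x) {
    pr <- relax_outer_unpack(stats::setNames(x, names(lower)))
    mix_obj(pr$kappa, pr$u, pr$omega, 1)
  }
  obj_alt <- function(x) {
    pr <- relax_outer_unpack(stats::setNames(x[-length(x)], names(lower)))
    mix_obj(pr$kappa, pr$u, pr$omega, exp(x[[length(x)]]))
  }

  base <- fit_single_omega(data, pi)
  start0 <- c(lkappa = log(base$kappa), lu = log(base$u),
              o1 = min(1, max(1e-5, base$omega / 4)),
              o2 = min(1, max(1e-4, base$omega)), lo3 = log(1.5))
  null_starts <- multi_starts(start0, n_starts, lower, upper, seed)
  best_null <- staged_optim(null_starts, obj_null, lower, upper)
  lnL_null <- -best_null$value
  p_null <- p_env$p

  ## alternative: profile k from the null solution, then free everything
  lk_lower <- log(1e-4); lk_upper <- log(k_max)
  k_grid <- log(c(0.05, 0.2, 0.5, 1, 2, 5, 20))
  k_grid <- k_grid[k_grid >= lk_lower & k_grid <= lk_upper]
  prof <- vapply(k_grid, function(lk) obj_alt(c(best_null$par, lk = lk)),
                 numeric(1))
  alt_start0 <- c(best_null$par, lk = k_grid[which.min(prof)])
  alt_starts <- multi_starts(alt_start0, n_starts,
                             c(lower, lk = lk_lower),
                             c(upper, lk = lk_upper), seed + 1L)
  best_alt <- staged_optim(alt_starts, obj_alt, c(lower, lk = lk_lower),
                           c(upper, lk = lk_upper))
  lnL_alt <- -best_alt$value
  p_alt <- p_env$p

  ## symmetric refinement: shared parameters found by the alternative may
  ## also improve the null; re-polish the null from them so the LRT is not
  ## inflated by uneven optimisation effort. Skipped when the preliminary
  ## LRT is far below any decision threshold (the refit can only shrink it).
  if (2 * (lnL_alt - lnL_null) > 1) {
    null_refit <- staged_optim(list(best_alt$par[seq_along(lower)]),
                               obj_null, lower, upper, polish_maxit = 100L)
    if (-null_refit$value > lnL_null) {
      best_null <- null_refit
      lnL_null <- -null_refit$value
      p_null <- p_env$p
    }
  }

  pr_alt <- relax_outer_unpack(
    stats::setNames(best_alt$par[-length(best_alt$par)], names(lower)))
  k_hat <- exp(best_alt$par[[length(best_alt$par)]])
  if (k_hat <= 1.1e-4) k_hat <- 0
  pr_null <- relax_outer_unpack(stats::setNames(best_null$par,
                                                names(lower)))
  if (lnL_alt < lnL_null) {
    ## the null is nested in the alternative; fall back to the null optimum
    lnL_alt <- lnL_null
    pr_alt <- pr_null
    p_alt <- p_null
    k_hat <- 1
  }
  k_hat <- min(max(k_hat, 0), k_max)
  lrt <- max(0, 2 * (lnL_alt - lnL_null))
  report_model <- function(pr, p, k) {
    coefs <- substitution_rate_coefs(pr$kappa, pi)
    rho <- coefs[["A"]] + coefs[["B"]] * sum(p * pr$omega)
    list(kappa = pr$kappa, scaler = pr$u * rho, omega = pr$omega, p = p,
         k = k)
  }
  structure(list(
    k_hat = k_hat,
    lnL_null = lnL_null, lnL_alt = lnL_alt,
    lrt = lrt,
    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    direction = if (k_hat < 1) "relaxed" else if (k_hat > 1) "intensified"
                else "neutral",
    null_model = report_model(pr_null, p_null, 1),
    alt_model = report_model(pr_alt, p_alt, k_hat),
    codon_freqs = pi, frequencies = frequencies,
    n_codons = data$n_sites, n_taxa = nrow(data$tip_state),
    n_test_branches = sum(data$is_test),
    converged = best_null$convergence == 0L && best_alt$convergence == 0L,
    seed = seed,
    call = match.call()), class = "relax_fit")
}

## jittered copies of a start vector under a private, restored RNG state
multi_starts <- function(start, n, lower, upper, seed) {
  if (n <= 1L) return(list(start))
  with_seed(seed, c(list(start), lapply(seq_len(n - 1L), function(i) {
    pmin(pmax(start + stats::runif(length(start), -0.6, 0.6), lower), upper)
  })))
}

#' @export
print.relax_fit <- function(x, ...) {
  cat("Selection-intensity test (k in omega^k on test branches)\n")
  cat(sprintf("  data: %d taxa, %d codons, %d test branches\n",
              x$n_taxa, x$n_codons, x$n_test_branches))
  cat(sprintf("  k_hat = %.4g (%s)\n", x$k_hat, x$direction))
  cat(sprintf("  lnL null (k = 1) = %.3f, lnL alt = %.3f\n",
              x$lnL_null, x$lnL_alt))
  cat(sprintf("  LRT = %.4g, p = %.4g (chi-squared, 1 df)\n",
              x$lrt, x$p_value))
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
summary.relax_fit <- function(object, ...) {
  print(object)
  m <- object$alt_model
  cat(sprintf("  kappa = %.3g, branch scaler = %.3g\n", m$kappa, m$scaler))
  cat("  omega categories (reference):",
      paste(signif(m$omega, 3), collapse = ", "), "\n")
  cat("  proportions:", paste(signif(m$p, 3), collapse = ", "), "\n")
  cat("  omega categories (test, omega^k):",
      paste(signif(omega_pow(m$omega, object$k_hat), 3), collapse = ", "),
      "\n")
  invisible(object)
}

#' @export
coef.relax_fit <- function(object, ...) {
  m <- object$alt_model
  c(k = object$k_hat, kappa = m$kappa, scaler = m$scaler,
    stats::setNames(m$omega, paste0("omega", seq_along(m$omega))),
    stats::setNames(m$p, paste0("p", seq_along(m$p))))
}

#' @export
logLik.relax_fit <- function(object, ...) {
  structure(object$lnL_alt, df = 8, class = "logLik")
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg FDR (step-up) or Bonferroni adjustment, as used for
#' the orthogroup-level selection screens.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values (same length and order).
#' @export
multiple_correction <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = method)
}
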