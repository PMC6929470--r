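## Downstream statistics on the per-orthogroup selection-intensity table:
## one-sample Wilcoxon signed-rank tests of k against the neutral value 1
## (overall and per GO term), Fisher enrichment with FDR control, overlap
## hypergeometrics between selection classes, the bounded k score transform
## and a label-permutation GSEA.

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetrically distributed around `mu`.
#' Differences equal to zero are dropped; tied absolute differences get
#' averaged ranks. The null distribution is exact (sign-pattern
#' enumeration) for n <= 25 without ties, otherwise a normal approximation
#' with continuity and tie correction is used. With no nonzero differences
#' the test is undefined and p = 1 is reported with `n_effective = 0`.
#'
#' @param values Numeric vector.
#' @param mu Null centre (default 1, the neutral selection intensity).
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @return List (class `omegak_test`) with `statistic` (V), `p_value`,
#'   `method`, `n_effective`, `alternative`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 1,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (length(values) < 1L) stop("need at least one value")
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = c(V = NA_real_), p_value = 1,
                          method = "degenerate", n_effective = 0L,
                          alternative = alternative),
                     class = "omegak_test"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p <- switch(alternative,
      two.sided = {
        if (V > n * (n + 1) / 4) {
          min(1, 2 * stats::psignrank(V - 1, n, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::psignrank(V, n))
        }
      },
      greater = stats::psignrank(V - 1, n, lower.tail = FALSE),
      less = stats::psignrank(V, n))
    method <- "exact"
  } else {
    mu_V <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu_V
    cc <- switch(alternative, two.sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal approximation"
  }
  structure(list(statistic = c(V = V), p_value = p, method = method,
                 n_effective = n, alternative = alternative),
            class = "omegak_test")
}

#' @export
print.omegak_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s, %s): V = %g, n = %d, p = %.4g\n",
              x$alternative, x$method, x$statistic[["V"]], x$n_effective,
              x$p_value))
  invisible(x)
}

#' Per-GO-term selection-intensity deviation tests
#'
#' For every GO term with at least `min_n` annotated orthogroups, tests the
#' term's k values against the neutral expectation of 1 with a two-sided
#' one-sample Wilcoxon signed-rank test, and reports the term's median k
#' and direction (relaxed when median < 1).
#'
#' @param go_map data.frame with columns `orthogroup_id`, `term`.
#' @param k_table data.frame with columns `orthogroup_id`, `k_hat`.
#' @param alpha Deviation flag threshold on the raw p-value (default 0.05).
#' @param min_n Minimum annotated orthogroups per term (default 5).
#' @return data.frame (term, n, median_k, mean_k, V, p, direction,
#'   deviating) sorted by p.
#' @export
go_term_k_tests <- function(go_map, k_table, alpha = 0.05, min_n = 5) {
  k <- stats::setNames(k_table$k_hat, k_table$orthogroup_id)
  sp <- split(go_map$orthogroup_id, go_map$term)
  rows <- lapply(names(sp), function(term) {
    ks <- k[unique(sp[[term]])]
    ks <- ks[!is.na(ks)]
    if (length(ks) < min_n) return(NULL)
    tst <- wilcoxon_signed_rank(ks, mu = 1)
    data.frame(term = term, n = length(ks),
               median_k = stats::median(ks), mean_k = mean(ks),
               V = tst$statistic[["V"]], p = tst$p_value,
               direction = if (stats::median(ks) < 1) "relaxed"
                           else "intensified")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), n = integer(0),
                      median_k = numeric(0), mean_k = numeric(0),
                      V = numeric(0), p = numeric(0),
                      direction = character(0), deviating = logical(0)))
  }
  out$deviating <- out$p < alpha
  out[order(out$p), ]
}

#' Fisher enrichment of one GO term in a selected orthogroup set
#'
#' One-tailed hypergeometric test of over- or under-representation of a
#' term among selected orthogroups relative to the universe.
#'
#' @param term GO term id.
#' @param selected_set Character vector of selected orthogroup ids (subset
#'   of `universe`).
#' @param universe Character vector of all orthogroup ids under
#'   consideration.
#' @param go_map data.frame (`orthogroup_id`, `term`).
#' @param tail `"over"` (default) or `"under"`.
#' @return One-tailed p-value (1 when the term does not occur).
#' @export
fisher_enrichment <- function(term, selected_set, universe, go_map,
                              tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (!all(selected_set %in% universe)) {
    stop("selected_set must be a subset of the universe")
  }
  with_term <- unique(go_map$orthogroup_id[go_map$term == term])
  with_term <- intersect(with_term, universe)
  K <- length(with_term)
  if (K == 0L) return(1)
  N <- length(universe)
  n_sel <- length(selected_set)
  x <- length(intersect(selected_set, with_term))
  if (tail == "over") {
    stats::phyper(x - 1, K, N - K, n_sel, lower.tail = FALSE)
  } else {
    stats::phyper(x, K, N - K, n_sel)
  }
}

#' Batch GO enrichment table with FDR control
#'
#' Applies [fisher_enrichment()] to every annotated term, adjusts by
#' Benjamini-Hochberg, and flags both significant terms (q < `fdr`) and
#' uncorrected "trends" (p < `alpha`).
#'
#' @inheritParams fisher_enrichment
#' @param fdr FDR threshold (default 0.10).
#' @param alpha Trend threshold on raw p (default 0.05).
#' @return data.frame (term, n_selected, n_universe, p, q, significant,
#'   trend) sorted by p.
#' @export
enrichment_table <- function(selected_set, universe, go_map,
                             tail = "over", fdr = 0.10, alpha = 0.05) {
  gm <- go_map[go_map$orthogroup_id %in% universe, , drop = FALSE]
  terms <- sort(unique(gm$term))
  rows <- lapply(terms, function(tm) {
    with_term <- unique(gm$orthogroup_id[gm$term == tm])
    data.frame(term = tm,
               n_selected = length(intersect(selected_set, with_term)),
               n_universe = length(with_term),
               p = fisher_enrichment(tm, selected_set, universe, gm, tail))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), n_selected = integer(0),
                      n_universe = integer(0), p = numeric(0))
  }
  out$q <- multiple_correction(out$p, "BH")
  out$significant <- out$q < fdr
  out$trend <- out$p < alpha
  out[order(out$p), ]
}

#' Overlap between two selection classes
#'
#' Expected overlap of two orthogroup sets drawn from a universe of size
#' `universe_size` (`|A| |B| / N`), the observed overlap, and a one-tailed
#' Fisher test of excess overlap.
#'
#' @param set_a,set_b Character vectors of orthogroup ids.
#' @param universe_size Number of orthogroups in the universe (> 0).
#' @return List with `expected`, `observed`, `p_value`.
#' @export
overlap_stats <- function(set_a, set_b, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive")
  nA <- length(unique(set_a)); nB <- length(unique(set_b))
  obs <- length(intersect(set_a, set_b))
  expected <- nA * nB / universe_size
  p <- if (nA == 0L || nB == 0L) 1 else {
    stats::phyper(obs - 1, nA, universe_size - nA, nB, lower.tail = FALSE)
  }
  list(expected = expected, observed = obs, p_value = p)
}

#' Transform selection intensity k to a bounded score
#'
#' Maps k in `[0, 50]` to `(k - 1) / (k + 1)` in `[-1, 1)`: strictly
#' increasing, 0 at the neutral k = 1, negative under relaxed and positive
#' under intensified selection.
#'
#' @param k Numeric vector of selection-intensity values (>= 0).
#' @return Numeric scores in `[-1, 1]`.
#' @export
transform_k <- function(k) {
  if (any(is.na(k)) || any(k < 0)) stop("k must be non-negative")
  (k - 1) / (k + 1)
}

#' Gene set enrichment analysis on transformed k scores
#'
#' Weighted Kolmogorov-Smirnov running-sum GSEA on orthogroups ranked by
#' score (descending). The null is generated by permuting gene labels
#' (random sets of the same size), since each orthogroup carries a single
#' score. `NES = ES / mean(|null ES| of matching sign)`;
#' `p = (1 + #{null >= observed, matching sign}) / (1 + #{null of matching
#' sign})` — the usual sign-conditional permutation p, which is uniform
#' under the null and never falls below `1/(n_perm + 1)`; q is BH-adjusted
#' across sets.
#'
#' @param scores Named numeric vector (names = orthogroup ids).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Number of permutations (default 10000).
#' @param weight Running-sum weight exponent (default 1).
#' @param min_set_size Sets with fewer present members are skipped.
#' @param seed Integer seed for the permutations.
#' @return data.frame (set, size, ES, NES, p, q, leading_edge) plus
#'   attribute `"skipped"` naming sets with too few members.
#' @export
gsea <- function(scores, gene_sets, n_perm = 10000, weight = 1,
                 min_set_size = 5, seed = 1L) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  N <- length(genes)
  sizes <- vapply(gene_sets, function(g) length(intersect(g, genes)),
                  integer(1))
  skipped <- names(gene_sets)[sizes < min_set_size]
  gene_sets <- gene_sets[sizes >= min_set_size]
  if (!length(gene_sets)) {
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0), q = numeric(0),
                      leading_edge = character(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  w_abs <- abs(s)^weight

  es_stat <- function(hit) {
    nh <- sum(hit)
    if (nh == N) return(list(es = 0, peak = 0L))
    denom_hit <- sum(w_abs[hit])
    inc <- ifelse(hit, if (denom_hit > 0) w_abs / denom_hit else
                    1 / nh, -1 / (N - nh))
    run <- cumsum(inc)
    peak <- which.max(abs(run))
    list(es = run[peak], peak = peak)
  }

  rows <- with_seed(seed, lapply(names(gene_sets), function(nm) {
    hit <- genes %in% gene_sets[[nm]]
    obs <- es_stat(hit)
    nh <- sum(hit)
    null_es <- vapply(seq_len(n_perm), function(i) {
      ph <- logical(N)
      ph[sample.int(N, nh)] <- TRUE
      es_stat(ph)$es
    }, numeric(1))
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else
      null_es[null_es < 0]
    nes <- if (length(same_sign) && mean(abs(same_sign)) > 0) {
      obs$es / mean(abs(same_sign))
    } else NA_real_
    ## conditional on the sign of ES, as in standard GSEA practice: this
    ## keeps null p-values uniform while preserving the permutation floor
    p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
    lead <- if (obs$es >= 0) {
      genes[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
    } else {
      genes[obs$peak:N][hit[obs$peak:N]]
    }
    data.frame(set = nm, size = nh, ES = obs$es, NES = nes, p = p,
               leading_edge = paste(lead, collapse = ";"))
  }))
  out <- do.call(rbind, rows)
  out$q <- multiple_correction(out$p, "BH")
  out <- out[order(out$p), c("set", "size", "ES", "NES", "p", "q",
                             "leading_edge")]
  attr(out, "skipped") <- skipped
  out
}

#' Top enriched sets by direction
#'
#' Convenience view of a [gsea()] table: the `n` most enriched sets with
#' positive NES (intensified selection) and negative NES (relaxed
#' selection).
#'
#' @param gsea_table Output of [gsea()].
#' @param n Sets per direction (default 10).
#' @return List with `intensified` and `relaxed` data.frames.
#' @export
gsea_top_sets <- function(gsea_table, n = 10) {
  pos <- gsea_table[!is.na(gsea_table$NES) & gsea_table$NES > 0, ]
  neg <- gsea_table[!is.na(gsea_table$NES) & gsea_table$NES < 0, ]
  list(intensified = utils::head(pos[order(pos$p), ], n),
       relaxed = utils::head(neg[order(neg$p), ], n))
}

#' Classify orthogroups by selection type
#'
#' Flags each orthogroup as relaxed (k < 1 and relax-q below the FDR
#' threshold), intensified (k > 1, relax-q below threshold) and/or
#' diversifying (branch-site q below threshold); the flags are
#' non-exclusive across the two tests. Orthogroups with missing fits stay
#' unclassified (NA flags).
#'
#' @param k_table data.frame with columns `orthogroup_id`, `k_hat`,
#'   `relax_p` and optionally `branchsite_p`.
#' @param fdr FDR threshold (default 0.10).
#' @return `k_table` augmented with `relax_q`, `branchsite_q`, `relaxed`,
#'   `intensified`, `diversifying`.
#' @export
classify_orthogroups <- function(k_table, fdr = 0.10) {
  kt <- k_table
  kt$relax_q <- NA_real_
  okr <- !is.na(kt$relax_p)
  kt$relax_q[okr] <- multiple_correction(kt$relax_p[okr], "BH")
  kt$relaxed <- kt$k_hat < 1 & kt$relax_q < fdr
  kt$intensified <- kt$k_hat > 1 & kt$relax_q < fdr
  if (!is.null(kt$branchsite_p)) {
    kt$branchsite_q <- NA_real_
    okb <- !is.na(kt$branchsite_p)
    kt$branchsite_q[okb] <- multiple_correction(kt$branchsite_p[okb], "BH")
    kt$diversifying <- kt$branchsite_q < fdr
  }
  n_missing <- sum(!okr)
  if (n_missing > 0L) {
    message(n_missing, " orthogroup(s) without a selection fit left unclassified")
  }
  kt
}
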