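## Forward simulation of codon alignments under the selection-intensity
## model, and generation of whole synthetic orthogroup studies with planted
## selection classes and GO enrichments. All outputs are fully determined by
## the seed; per-orthogroup RNG streams are derived from (master seed,
## orthogroup index) so any subset regenerates identically.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483629)
}

#' Simulate a codon alignment along a labelled tree
#'
#' Sites are assigned to dN/dS categories with the model's mixture
#' proportions; the root codon is drawn from the stationary distribution;
#' evolution proceeds along each branch with the category's omega on
#' reference branches and omega^k on test branches. Optionally a single
#' branch carries an episodic class: a fraction of sites evolve with an
#' elevated omega on that branch only (diversifying-selection episodes).
#'
#' @param tree A `labelled_tree` (or `phylo`, treated as all-reference).
#' @param model A `codon_model`.
#' @param n_codons Number of codon sites (>= 1).
#' @param seed Integer seed; fully determines the alignment.
#' @param episodic Optional list `list(edge =, omega =, fraction =)`:
#'   index into `tree$tree$edge` rows, episodic omega, fraction of sites.
#' @return A `codon_alignment` with attribute `"episodic_sites"` (integer
#'   site indices) when an episode was planted.
#' @export
simulate_alignment <- function(tree, model, n_codons, seed = 1L,
                               episodic = NULL) {
  stopifnot(inherits(model, "codon_model"))
  if (!inherits(tree, "labelled_tree")) tree <- labelled_tree(tree)
  if (n_codons < 1) stop("n_codons must be >= 1")
  phy <- tree$tree
  ntip <- length(phy$tip.label)
  pi <- model$codon_freqs
  coefs <- substitution_rate_coefs(model$kappa, pi)
  rho <- coefs[["A"]] + coefs[["B"]] * sum(model$p * model$omega)
  sense <- sense_codons()

  ## preorder: parents before children
  post <- ape::reorder.phylo(phy, "postorder")
  ord <- match(paste0(post$edge[, 1], "-", post$edge[, 2]),
               paste0(phy$edge[, 1], "-", phy$edge[, 2]))
  pre <- rev(seq_len(nrow(post$edge)))

  with_seed(seed, {
    cat_of_site <- sample.int(length(model$omega), n_codons, replace = TRUE,
                              prob = model$p)
    epi_sites <- integer(0)
    if (!is.null(episodic)) {
      epi_sites <- which(stats::runif(n_codons) < episodic$fraction)
    }
    states <- matrix(NA_integer_, nrow = ntip + phy$Nnode, ncol = n_codons)
    root <- ntip + 1L
    states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    Qs <- lapply(model$omega, function(om) {
      codon_rate_matrix(model$kappa, om, pi, scale = FALSE)
    })
    for (e in pre) {
      par <- post$edge[e, 1]; ch <- post$edge[e, 2]
      is_test <- tree$edge_label[ord[e]] == "test"
      t_e <- post$edge.length[e] * model$scaler / rho
      states[ch, ] <- states[par, ]
      for (c in seq_along(model$omega)) {
        idx <- which(cat_of_site == c)
        if (!length(idx)) next
        om_eff <- if (is_test) omega_pow(model$omega[c], model$k)
                  else model$omega[c]
        Q <- if (om_eff == model$omega[c]) Qs[[c]] else
          codon_rate_matrix(model$kappa, om_eff, pi, scale = FALSE)
        P <- transition_probabilities(Q, t_e, pi)
        states[ch, idx] <- evolve_states(states[par, idx], P)
      }
      if (!is.null(episodic) && ord[e] == episodic$edge &&
          length(epi_sites)) {
        Qe <- codon_rate_matrix(model$kappa, episodic$omega, pi,
                                scale = FALSE)
        Pe <- transition_probabilities(Qe, t_e, pi)
        states[ch, epi_sites] <- evolve_states(states[par, epi_sites], Pe)
      }
    }
    seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(s) {
      paste0(sense[s], collapse = "")
    })
    names(seqs) <- phy$tip.label
    aln <- codon_alignment(seqs)
    attr(aln, "site_categories") <- cat_of_site
    if (length(epi_sites)) attr(aln, "episodic_sites") <- epi_sites
    aln
  })
}

## vectorised one-branch evolution: children drawn state-by-parent-state
evolve_states <- function(parent, P) {
  child <- integer(length(parent))
  for (s in unique(parent)) {
    i <- which(parent == s)
    child[i] <- sample.int(61, length(i), replace = TRUE, prob = P[s, ])
  }
  child
}

#' Default study tree
#'
#' A fixed 10-taxon topology emulating the study design: two 2-taxon
#' foreground clades (`F1a/F1b` and `F2a/F2b`, non-sister), five background
#' lineages and one outgroup, with branch lengths in the 0.02-0.2
#' substitutions/site range. Foreground branches are labelled in clade mode
#' (cherries plus stems).
#'
#' @return A `labelled_tree`.
#' @export
default_study_tree <- function() {
  nwk <- paste0("(((((F1a:0.1,F1b:0.1):0.12,(B1:0.08,B2:0.08):0.08):0.05,",
                "((F2a:0.1,F2b:0.1):0.12,B3:0.12):0.05):0.05,B4:0.12):0.06,",
                "B5:0.15,OUT:0.2);")
  tree <- ape::read.tree(text = nwk)
  label_foreground(tree, list(c("F1a", "F1b"), c("F2a", "F2b")),
                   mode = "clade")
}

#' Default simulation base model
#'
#' The reference-branch dN/dS mixture used by the study simulator: mostly
#' purifying selection with a small nearly-neutral and a small permissive
#' category, kappa = 2, mildly AT-rich F1x4 frequencies.
#'
#' @param k Selection-intensity exponent for test branches.
#' @return A `codon_model`.
#' @export
default_study_model <- function(k = 1) {
  pi <- freqs_from_nuc(c(0.28, 0.22, 0.24, 0.26))
  codon_model(kappa = 2, codon_freqs = pi,
              omega = c(0.05, 0.5, 1.5), p = c(0.5, 0.4, 0.1), k = k)
}

#' Default class table for synthetic studies
#'
#' @param n_relaxed,n_neutral,n_intensified,n_episodic Orthogroup counts per
#'   planted class.
#' @param k_relaxed,k_intensified True selection-intensity exponents.
#' @param episodic_omega,episodic_fraction Episode parameters (one test
#'   branch, two-category site mixture).
#' @return data.frame with one row per class.
#' @export
study_classes <- function(n_relaxed = 20, n_neutral = 20, n_intensified = 20,
                          n_episodic = 0, k_relaxed = 0.2,
                          k_intensified = 5, episodic_omega = 5,
                          episodic_fraction = 0.2) {
  df <- data.frame(
    class = c("relaxed", "neutral", "intensified", "episodic"),
    count = c(n_relaxed, n_neutral, n_intensified, n_episodic),
    k = c(k_relaxed, 1, k_intensified, 1),
    episodic_omega = c(NA, NA, NA, episodic_omega),
    episodic_fraction = c(NA, NA, NA, episodic_fraction))
  df[df$count > 0, , drop = FALSE]
}

#' Simulate a synthetic orthogroup study
#'
#' Generates per-orthogroup codon alignments under planted selection
#' classes, a GO annotation map with planted enriched terms, and the truth
#' table against which recovery can be scored.
#'
#' @param classes Class table from [study_classes()].
#' @param n_codons Codons per orthogroup (single value or sampled range
#'   `c(min, max)`).
#' @param tree A `labelled_tree` shared by all orthogroups.
#' @param model Base `codon_model` (its `k` is overridden per class).
#' @param go Gene Ontology configuration: `n_terms`, `mean_terms` (mean
#'   annotations per orthogroup), `odds_ratio` (planting strength), and
#'   `planted` (data.frame term/class, default one term per non-neutral
#'   class).
#' @param seed Master seed; orthogroup i uses a stream derived from
#'   `(seed, i)`.
#' @param dir Optional directory: writes per-orthogroup FASTA and newick
#'   plus `go_map.tsv` and `truth.tsv`.
#' @return Object of class `synthetic_study`: `alignments` (named list),
#'   `tree`, `truth`, `go_map`, `go_truth`, `seed`.
#' @export
simulate_study <- function(classes = study_classes(), n_codons = 300,
                           tree = default_study_tree(),
                           model = default_study_model(),
                           go = list(n_terms = 40, mean_terms = 3,
                                     odds_ratio = 10),
                           seed = 1L, dir = NULL) {
  stopifnot(all(classes$count >= 0))
  n_total <- sum(classes$count)
  class_of <- rep(classes$class, classes$count)
  k_of <- rep(classes$k, classes$count)
  epi_om <- rep(classes$episodic_omega, classes$count)
  epi_fr <- rep(classes$episodic_fraction, classes$count)
  ids <- sprintf("OG%04d", seq_len(n_total))
  test_edges <- which(tree$edge_label == "test")

  alignments <- vector("list", n_total)
  names(alignments) <- ids
  truth <- data.frame(orthogroup_id = ids, class = class_of, true_k = k_of,
                      episodic_branch = NA_integer_,
                      episodic_fraction = NA_real_,
                      n_codons = NA_integer_)
  for (i in seq_len(n_total)) {
    s_i <- derive_seed(seed, i)
    nc <- if (length(n_codons) == 2L) {
      with_seed(s_i + 1L, sample(seq(n_codons[1], n_codons[2]), 1))
    } else n_codons
    m_i <- model
    m_i$k <- k_of[i]
    episodic <- NULL
    if (class_of[i] == "episodic") {
      br <- test_edges[1 + (i %% length(test_edges))]
      episodic <- list(edge = br, omega = epi_om[i], fraction = epi_fr[i])
      truth$episodic_branch[i] <- br
      truth$episodic_fraction[i] <- epi_fr[i]
    }
    alignments[[i]] <- simulate_alignment(tree, m_i, nc, seed = s_i,
                                          episodic = episodic)
    truth$n_codons[i] <- nc
  }

  ## GO annotations: planted terms attach to their class at `odds_ratio`
  ## times the baseline weight
  terms <- sprintf("GO:%07d", seq_len(go$n_terms))
  planted <- go$planted
  if (is.null(planted)) {
    cls <- setdiff(unique(class_of), "neutral")
    planted <- data.frame(term = terms[seq_along(cls)], class = cls)
  }
  go_rows <- with_seed(derive_seed(seed, n_total + 1L), {
    lapply(seq_len(n_total), function(i) {
      n_ann <- 1L + stats::rpois(1, go$mean_terms - 1)
      n_ann <- min(n_ann, length(terms))
      w <- rep(1, length(terms))
      mine <- planted$term[planted$class == class_of[i]]
      w[match(mine, terms)] <- go$odds_ratio
      data.frame(orthogroup_id = ids[i],
                 term = sample(terms, n_ann, prob = w / sum(w)))
    })
  })
  go_map <- do.call(rbind, go_rows)
  study <- structure(list(alignments = alignments, tree = tree,
                          truth = truth, go_map = go_map,
                          go_truth = planted, terms = terms, seed = seed),
                     class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d orthogroups (%s), seed %d\n",
              nrow(x$truth),
              paste(sprintf("%d %s", table(x$truth$class)[unique(x$truth$class)],
                            unique(x$truth$class)), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits `<id>.fasta` and `<id>.nwk` per orthogroup, plus `go_map.tsv` and
#' `truth.tsv`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$alignments)) {
    write_fasta(study$alignments[[id]]$seqs, file.path(dir, paste0(id, ".fasta")))
    write_newick(study$tree, file.path(dir, paste0(id, ".nwk")))
  }
  utils::write.table(study$go_map, file.path(dir, "go_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
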