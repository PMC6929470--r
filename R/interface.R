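## File formats and the end-to-end pipeline driver:
## simulate -> fit -> classify -> enrich -> gsea -> report, with TSV
## outputs and a JSON manifest (stage, seed, input hashes, row counts)
## making every bundle reproducible from its manifest.

#' Read a FASTA file
#'
#' @param path Readable FASTA file.
#' @return Named character vector of uppercase sequences (empty vector for
#'   an empty file). Duplicate ids and malformed records are rejected;
#'   lowercase input is normalised to uppercase with a message.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return(stats::setNames(character(0), character(0)))
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA in %s: line %d is not a header", path,
                 first))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase letters in ", path, " normalised to uppercase")
    seqs <- toupper(seqs)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param records Named character vector of sequences (or a
#'   `codon_alignment`).
#' @param path Output path; sequences are wrapped at 80 columns.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "codon_alignment")) records <- records$seqs
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the thresholds, stage toggles and seeds for [run_pipeline()].
#' Defaults mirror the study settings: minimum ORF length 200 nt,
#' orthogroup size 7-80 sequences from >= 7 taxa, FDR 0.10, alpha 0.05,
#' 10000 GSEA permutations, k capped at 50.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param stages Stages to run, in order, out of `"simulate"`, `"relax"`,
#'   `"branchsite"`, `"classify"`, `"enrich"`, `"gsea"`.
#' @param classes,n_codons,go Study design passed to [simulate_study()].
#' @param fdr,alpha,n_perm,k_max,min_set_size,min_go_n Analysis thresholds.
#' @param n_starts Optimiser multi-starts per fit.
#' @param min_orf_len,min_seqs,max_seqs,min_taxa Orthogroup filter bounds
#'   (recorded for provenance; used when raw transcript input is filtered).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "relax", "branchsite",
                                       "classify", "enrich", "gsea"),
                            classes = study_classes(), n_codons = 300,
                            go = list(n_terms = 40, mean_terms = 3,
                                      odds_ratio = 10),
                            fdr = 0.10, alpha = 0.05, n_perm = 10000,
                            k_max = 50, min_set_size = 5, min_go_n = 5,
                            n_starts = 3, min_orf_len = 200, min_seqs = 7,
                            max_seqs = 80, min_taxa = 7) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, classes = classes, n_codons = n_codons,
                 go = go, fdr = fdr, alpha = alpha, n_perm = n_perm,
                 k_max = k_max, min_set_size = min_set_size,
                 min_go_n = min_go_n, n_starts = n_starts,
                 min_orf_len = min_orf_len, min_seqs = min_seqs,
                 max_seqs = max_seqs, min_taxa = min_taxa),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Fit the selection-intensity test across a study
#'
#' Runs [fit_relax()] on every orthogroup of a synthetic study (or any
#' named list of alignments sharing a labelled tree) and assembles the
#' orthogroup-level k table with BH and Bonferroni adjusted p-values.
#' Non-converged fits are kept but flagged.
#'
#' @param study A `synthetic_study`, or a named list of `codon_alignment`s.
#' @param tree Labelled tree (taken from the study when omitted).
#' @param n_starts,seed Fitting options; orthogroup i uses seed stream
#'   `(seed, i)`.
#' @return data.frame: orthogroup_id, k_hat, lnL_null, lnL_alt, LRT, p,
#'   q_BH, p_bonferroni, direction, converged.
#' @export
relax_screen <- function(study, tree = NULL, n_starts = 3, seed = 1L) {
  alns <- if (inherits(study, "synthetic_study")) study$alignments else study
  if (is.null(tree)) tree <- study$tree
  rows <- lapply(seq_along(alns), function(i) {
    fit <- fit_relax(alns[[i]], tree, n_starts = n_starts,
                     seed = derive_seed(seed, i))
    data.frame(orthogroup_id = names(alns)[i], k_hat = fit$k_hat,
               lnL_null = fit$lnL_null, lnL_alt = fit$lnL_alt,
               LRT = fit$lrt, p = fit$p_value, direction = fit$direction,
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  out$q_BH <- multiple_correction(out$p, "BH")
  out$p_bonferroni <- multiple_correction(out$p, "bonferroni")
  out[, c("orthogroup_id", "k_hat", "lnL_null", "lnL_alt", "LRT", "p",
          "q_BH", "p_bonferroni", "direction", "converged")]
}

#' Fit the branch-site test across a study
#'
#' @inheritParams relax_screen
#' @return List with `orthogroups` (orthogroup_id, p, q_BH) and `branches`
#'   (one row per test branch per orthogroup).
#' @export
branchsite_screen <- function(study, tree = NULL, n_starts = 1, seed = 1L) {
  alns <- if (inherits(study, "synthetic_study")) study$alignments else study
  if (is.null(tree)) tree <- study$tree
  fits <- lapply(seq_along(alns), function(i) {
    fit_branch_site(alns[[i]], tree, n_starts = n_starts,
                    seed = derive_seed(seed, i))
  })
  og <- data.frame(orthogroup_id = names(alns),
                   p = vapply(fits, `[[`, 0, "p_orthogroup"))
  og$q_BH <- multiple_correction(og$p, "BH")
  branches <- do.call(rbind, lapply(seq_along(fits), function(i) {
    cbind(orthogroup_id = names(alns)[i], fits[[i]]$branches)
  }))
  list(orthogroups = og, branches = branches)
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order on a synthetic study, writing
#' per-stage TSVs and a JSON manifest (stage, seed, output md5 hashes, row
#' counts) to `config$out_dir`. A later stage requested without its
#' upstream stage fails with the name of the missing stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list()
  res <- list()
  add_manifest <- function(stage, files, rows) {
    manifest[[stage]] <<- list(
      stage = stage, seed = config$seed,
      outputs = as.list(tools::md5sum(files)),
      row_counts = as.list(rows))
  }
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop(sprintf("stage '%s' requires missing upstream stage '%s'",
                   stage, what))
    }
  }

  if ("simulate" %in% stages) {
    study_dir <- file.path(config$out_dir, "study")
    res$simulate <- simulate_study(classes = config$classes,
                                   n_codons = config$n_codons,
                                   go = config$go, seed = config$seed,
                                   dir = study_dir)
    files <- file.path(study_dir, c("truth.tsv", "go_map.tsv"))
    add_manifest("simulate", files,
                 c(orthogroups = nrow(res$simulate$truth),
                   go_annotations = nrow(res$simulate$go_map)))
  }

  if ("relax" %in% stages) {
    need("simulate", "relax")
    res$relax <- relax_screen(res$simulate, n_starts = config$n_starts,
                              seed = derive_seed(config$seed, 1000L))
    f <- write_tsv(res$relax, file.path(config$out_dir, "relax.tsv"))
    add_manifest("relax", f, c(orthogroups = nrow(res$relax)))
  }

  if ("branchsite" %in% stages) {
    need("simulate", "branchsite")
    res$branchsite <- branchsite_screen(res$simulate,
                                        seed = derive_seed(config$seed,
                                                           2000L))
    f1 <- write_tsv(res$branchsite$orthogroups,
                    file.path(config$out_dir, "branchsite.tsv"))
    f2 <- write_tsv(res$branchsite$branches,
                    file.path(config$out_dir, "branchsite_branches.tsv"))
    add_manifest("branchsite", c(f1, f2),
                 c(orthogroups = nrow(res$branchsite$orthogroups),
                   branches = nrow(res$branchsite$branches)))
  }

  if ("classify" %in% stages) {
    need("relax", "classify")
    kt <- data.frame(orthogroup_id = res$relax$orthogroup_id,
                     k_hat = res$relax$k_hat, relax_p = res$relax$p)
    if (!is.null(res$branchsite)) {
      kt$branchsite_p <- res$branchsite$orthogroups$p[
        match(kt$orthogroup_id, res$branchsite$orthogroups$orthogroup_id)]
    }
    res$classify <- classify_orthogroups(kt, fdr = config$fdr)
    f <- write_tsv(res$classify, file.path(config$out_dir, "classes.tsv"))
    add_manifest("classify", f, c(orthogroups = nrow(res$classify)))
  }

  if ("enrich" %in% stages) {
    need("classify", "enrich")
    go_map <- res$simulate$go_map
    universe <- unique(go_map$orthogroup_id)
    cls <- res$classify
    res$enrich <- list(
      go_k = go_term_k_tests(go_map, res$relax, alpha = config$alpha,
                             min_n = config$min_go_n),
      relaxed = enrichment_table(
        cls$orthogroup_id[cls$relaxed %in% TRUE], universe, go_map,
        fdr = config$fdr, alpha = config$alpha),
      intensified = enrichment_table(
        cls$orthogroup_id[cls$intensified %in% TRUE], universe, go_map,
        fdr = config$fdr, alpha = config$alpha))
    f1 <- write_tsv(res$enrich$go_k, file.path(config$out_dir, "go_k.tsv"))
    f2 <- write_tsv(res$enrich$relaxed,
                    file.path(config$out_dir, "enrich_relaxed.tsv"))
    f3 <- write_tsv(res$enrich$intensified,
                    file.path(config$out_dir, "enrich_intensified.tsv"))
    ov <- NULL
    if (!is.null(cls$diversifying)) {
      ov <- list(
        relaxed_diversifying = overlap_stats(
          cls$orthogroup_id[cls$relaxed %in% TRUE],
          cls$orthogroup_id[cls$diversifying %in% TRUE], nrow(cls)),
        intensified_diversifying = overlap_stats(
          cls$orthogroup_id[cls$intensified %in% TRUE],
          cls$orthogroup_id[cls$diversifying %in% TRUE], nrow(cls)))
      jsonlite::write_json(ov, file.path(config$out_dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      res$enrich$overlap <- ov
    }
    add_manifest("enrich", c(f1, f2, f3),
                 c(go_terms_tested = nrow(res$enrich$go_k)))
  }

  if ("gsea" %in% stages) {
    need("relax", "gsea")
    go_map <- res$simulate$go_map
    scores <- stats::setNames(transform_k(res$relax$k_hat),
                              res$relax$orthogroup_id)
    sets <- split(go_map$orthogroup_id, go_map$term)
    res$gsea <- gsea(scores, sets, n_perm = config$n_perm,
                     min_set_size = config$min_set_size,
                     seed = derive_seed(config$seed, 3000L))
    f <- write_tsv(res$gsea, file.path(config$out_dir, "gsea.tsv"))
    add_manifest("gsea", f, c(sets_tested = nrow(res$gsea)))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Read a GMT gene-set file
#'
#' @param path Tab-separated GMT file (set name, description, members...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >= 1 member): ", ln)
    }
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}
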