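---
title: "Detecting relaxed, intensified and episodic selection with omegak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting relaxed, intensified and episodic selection with omegak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Comparative transcriptome studies often ask whether a designated set of
lineages — the *foreground* or *test* branches of a species tree — has
experienced a shift in the intensity of natural selection on protein-coding
genes, relative to the remaining *reference* (background) branches. Three
signatures are of interest per orthogroup (a set of orthologous coding
sequences across species):

* **relaxed selection** — selective constraint weakened on the foreground;
* **intensified selection** — constraint strengthened;
* **episodic diversifying selection** — a fraction of codon sites on a
  foreground branch driven by positive selection (dN/dS > 1).

omegak implements the full analysis stack around these questions: codon
model fitting, orthogroup construction and filtering from transcript data,
downstream Gene Ontology statistics, a permutation GSEA, and a seeded
simulator that plants known selection classes so that every stage can be
validated without any external data.

## The selection-intensity model

Codon evolution follows an MG94-type model on the 61 sense codons of the
standard genetic code. Off-diagonal rates are nonzero only for
single-nucleotide codon changes and take the form

$$ q_{ij} \propto \kappa^{\,t_{ij}}\; \omega^{\,a_{ij}}\; \pi_j , $$

where $t_{ij}$ indicates a transition (A↔G, C↔T), $a_{ij}$ a
nonsynonymous change, $\kappa > 0$ the transition/transversion ratio,
$\omega \ge 0$ the nonsynonymous/synonymous rate ratio and $\pi_j$ the
stationary frequency of the target codon. Weighting by the *target codon*
frequency (rather than the target nucleotide) makes the chain time
reversible for *any* valid frequency vector, which both the simulator and
the re-rooting invariance of the likelihood rely on. Frequencies default to
the F3x4 empirical estimator (position-specific nucleotide frequencies,
stop codons removed and renormalised); F1x4 and uniform are options.

Site-to-site variation in selective pressure is captured by a three
category mixture $\omega_1 \le \omega_2 \le 1 \le \omega_3$ with
proportions $p_1, p_2, p_3$ shared by all branches. The selection-intensity
parameter $k \in [0, 50]$ acts only on test branches, where every category
is deformed to $\omega_i^{\,k}$:

* $k = 1$: test and reference branches evolve identically;
* $k < 1$: all $\omega_i$ are pulled towards 1 — *relaxation* (both
  purifying and positive selection weaken);
* $k > 1$: all $\omega_i$ are pushed away from 1 — *intensification*.

`fit_relax()` fits the model twice — with $k$ fixed at 1 (null) and free
(alternative) — and refers $\mathrm{LRT} = 2(\ln L_1 - \ln L_0)$ to
$\chi^2_1$. The upper bound $k \le 50$ matches the convention of the
selection-intensity framework this test follows.

### Branch-site test

`fit_branch_site()` is a deliberately simplified adaptive branch-site
random-effects test. A single background $\omega$ (with $\kappa$ and a
global branch-length scaler) is fitted once. Each test branch then
receives its own $\omega$ mixture, mixed *independently across branches*,
so the branch's effective transition matrix is the mixture average. The
category count per branch grows adaptively (1, 2, 3) and stops as soon as
small-sample AICc worsens. The chosen model is compared against the same
model with all of that branch's $\omega$ values constrained to at most 1;
because the constrained model has the same parameter count, the LRT is
referred to $\chi^2_1$ as a conservative stand-in for the exact boundary
mixture null (simulation below confirms the test is conservative). Branch
p-values are Holm-corrected within the orthogroup; the orthogroup-level p
is their minimum, and FDR control across orthogroups uses
Benjamini–Hochberg.

Relative branch lengths are always taken from the input tree; one global
scaler per fit re-optimises the overall substitution scale. Gaps and
ambiguity codes are treated as missing data (the tip partial likelihood is
1 over all compatible codons). Zero-length branches contribute identity
transition matrices.

## Fitting strategy and numerical choices

* The per-site likelihood is linear in the mixture proportions, so they
  are profiled out by an inner EM given the per-category site
  log-likelihood columns. The outer bounded quasi-Newton (L-BFGS-B) search
  therefore runs over $(\kappa, s, \omega_1, \omega_2, \omega_3[, k])$
  only, with $\kappa$, $s$, $\omega_3$, $k$ on log scale and
  $\omega_1, \omega_2$ box-bounded in $[0,1]$ and sorted.
* The substitution-rate normalisation (expected substitutions per unit
  time = 1 under the reference-branch mixture) is absorbed into the free
  scaler during optimisation and restored in the reported scaler, so the
  input branch lengths keep their substitutions-per-site meaning.
* Multi-starts (default 3) run a short exploration budget; the best
  candidate is polished. The alternative fit warm-starts from the null
  optimum after a coarse profile over $k$; afterwards, whenever the
  preliminary LRT is non-negligible (> 1), the null is re-polished from
  the alternative's shared parameters so the LRT is not inflated by
  uneven optimisation effort, and the alternative is floored at the null
  (the models are nested), so LRT ≥ 0 always.
* Convergence is controlled by the L-BFGS-B relative-progress criterion
  (`factr = 1e10`), i.e. roughly 0.001–0.01 log-likelihood units at
  typical data sizes — ample for $\chi^2$-scale inference.
* Pruning runs in compiled code (RcppArmadillo): transition matrices come
  from the symmetric eigendecomposition available for reversible chains
  and are cached per $(\omega, t)$; per-branch refits in the branch-site
  test use an inside–outside decomposition, so changing one branch's
  $\omega$ mixture costs a single 61×61 propagation instead of a full
  tree pass.
* Degenerate inputs: ties in the $\omega$ ordering are permitted;
  $0^0 = 1$ so $k = 0$ drives every category to neutrality; codon
  frequencies are floored at $10^{-8}$ and renormalised before fitting.

## The synthetic study generator

`simulate_study()` emulates the design of a salmonid-style comparative
study: a fixed 10-taxon tree with two 2-taxon foreground clades (cherries
plus stems labelled in clade mode, 6 test branches), five background
lineages and an outgroup. Foreground tips have length 0.1 and stems 0.12
substitutions/site, backgrounds 0.05–0.2 — chosen so that a planted
episode (ω = 5 on 20% of sites of one test branch, the generator default)
carries on the order of ten expected substitutions and is therefore
detectable in principle; exact published branch lengths are not available,
so these defaults are synthetic and configurable. The base model uses
κ = 2, mildly AT-rich F1x4 frequencies and the mixture
ω = (0.05, 0.5, 1.5) with p = (0.5, 0.4, 0.1) — mostly purifying selection
with a small permissive tail, typical of conserved protein-coding genes.

Orthogroup classes are planted by deforming this base model: relaxed
(k = 0.2), neutral (k = 1), intensified (k = 5), and episodic (k = 1 plus
a two-category episode on one rotating test branch). GO annotations are
drawn per orthogroup (1 + Poisson(2) terms from a 40-term universe by
default), with planted enriched terms attached to their class at a
configurable odds ratio (default 10). Each orthogroup consumes an RNG
stream derived from (master seed, orthogroup index), so subsets regenerate
identically and identical seeds give byte-identical files.

`generate_mock_transcripts()` builds the fixture for the orthogroup
filtering stages: coding sequences embedded in random UTR flanks, some
stored reverse-complemented, standalone transcripts whose ORFs fall below
the 200 nt threshold, and groups violating each filter (no reference hit,
collapsed orthologues, duplicates, size/taxon bounds) — all recorded in a
planted-truth table that the filter audit must reproduce exactly.

What the simulator does *not* emulate: indel evolution (alignments are
simulated gapless; gaps enter only through the trimming fixtures),
alignment error, assembly artefacts beyond the planted collapsed
orthologues, among-site synonymous rate variation, and lineage-specific
codon usage. Passing tests therefore demonstrate correctness of the
statistical machinery under the model's own assumptions, not robustness to
real-data violations of them.

## Orthogroup pipeline conventions

* ORFs: longest start-to-stop reading frame, both strands searched by
  default, minimum 200 nt applied to the nucleotide length (stop
  included); ties break to the lowest start coordinate, forward strand
  preferred. Coordinates are 0-based half-open on the reported strand.
* Reference matching keeps members that map to reference protein-coding
  genes; the collapsed-orthologue rule keeps a group only if every focal
  species has at least as many orthologues as the reference genome (and
  at most four). The rule is evaluated per species.
* Groups matching the same reference gene set merge; byte-identical groups
  deduplicate; size (7–80 sequences) and taxon (≥ 7) bounds apply.
* Trimming reimplements the trimAl-style spurious-sequence filter with
  `-resoverlap 1.0 -seqoverlap 0.38 -noallgaps` defaults. The default
  reading is pairwise: two sequences "overlap" by the fraction of columns
  whose gap states match, and a sequence survives when at least 38% of
  the other sequences overlap with it on 100% of columns; all-gap columns
  are then removed. This is the reading under which the canonical
  settings remove a mostly-gapped sequence without dragging down the rest
  of the alignment; the strict column-wise gap-state and residue-presence
  readings are available via `mode`.
* Orthogroup trees come from neighbour joining on codon-level p-distances
  (pairwise deletion, negative branch lengths clamped to zero) — a
  deliberate, documented replacement for balanced minimum evolution;
  topology-level agreement is expected on clean data.
* Mitochondrial-code sequences are out of scope (standard code only).

## Downstream statistics

* `wilcoxon_signed_rank()` — one-sample signed-rank test of k against the
  neutral value 1, exact by enumeration for n ≤ 25 without ties, normal
  approximation with continuity and tie corrections otherwise. Per-GO-term
  tests (`go_term_k_tests()`) apply it to each term with ≥ 5 annotated
  orthogroups and report the member-level test with the term median
  alongside (the alternative mean-then-test reading aggregates away the
  within-term information).
* `fisher_enrichment()` / `enrichment_table()` — one-tailed hypergeometric
  enrichment with BH-FDR at 0.10 and uncorrected p < 0.05 "trends"
  reported separately. The enrichment universe is every orthogroup with at
  least one GO annotation.
* `overlap_stats()` — expected overlap |A||B|/N of two selection classes
  plus a one-tailed Fisher test of excess overlap.
* `transform_k()` — the bounded score (k − 1)/(k + 1): strictly
  increasing, 0 at k = 1, −1 at k = 0, and ≈ +0.96 at the k = 50 cap.
  Chosen over alternatives (rank scores, log k) because it is bounded on
  both sides, sign-correct around neutrality, and insensitive to the hard
  k cap.
* `gsea()` — weighted Kolmogorov–Smirnov running-sum enrichment on
  orthogroups ranked by transformed k. Because each orthogroup carries a
  single score, the permutation null shuffles gene labels (random sets of
  the same size); NES divides ES by the mean |null ES| of matching sign,
  and p is the sign-conditional permutation p-value
  (1 + #{matching-sign null ≥ observed}) / (1 + #matching-sign null) —
  uniform under the null, never below 1/(n_perm + 1). A set containing
  every ranked gene has no complement to compare against and is assigned
  ES = 0.

## Validation studies and the sizes they use

The test suite regenerates all of its data and runs these studies (sizes
chosen as the package's validation settings):

* pruning likelihood vs brute-force ancestral-state enumeration on 3–4
  taxon, ≤ 10-codon instances (relative error < 1e-10);
* k recovery: 20 replicates each at true k ∈ {0.2, 1, 5} (10 taxa, 500
  codons) — medians must fall in [0.1, 0.4], [0.7, 1.4], [3, 8];
* type-I error: 200 null replicates at 200 codons — relax rejection at
  α = 0.05 must lie in [0.02, 0.09] and the branch-site orthogroup rate
  below 0.09 (it is strongly conservative in practice);
* end-to-end: a 60-orthogroup study (20/20/20) at 300 codons must be
  classified in the correct direction (q < 0.10) for ≥ 70% of non-neutral
  orthogroups;
* planted GO enrichment (odds ratio 10) must reach p < 0.05 in ≥ 80% of
  20 replicate studies; GSEA must flag a planted top-5% set (p ≤ 0.01 at
  1000 permutations) and stay uniform under a global null;
* the filter audit must drop exactly the planted violations.

Replicated fits use a single optimiser start (`n_starts = 1`); the
multi-start default matters for individual reported fits, not for
aggregate calibration, and the short-budget exploration keeps the
replicated studies at desk scale.

## Known limitations

* No synonymous rate variation, no partitioned k, no mixture-χ² null for
  the branch-site test (χ²₁ is conservative), and no codon models beyond
  MG94×HKY.
* The branch-site background is a single ω rather than a full per-branch
  adaptive background; this trades some power for a large speed-up and is
  the main deliberate simplification relative to full HYPHY-style
  machinery.
* Foreground labelling defaults to whole foreground clades including stem
  branches; tip-only labelling is available via `mode = "tips"` (the
  underlying study description is ambiguous on this point, so both are
  provided).
* p-distances saturate on very divergent sequences; the NJ stage is meant
  for closely related taxa (within-family scale).
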