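---
title: "Scanning for lineage-specific positive selection with psgscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for lineage-specific positive selection with psgscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A recurring question in comparative genomics is which protein-coding genes
changed under positive selection on one particular lineage — say, the
terminal branch leading to the bottlenose dolphin within a mammalian
phylogeny. The strength and direction of selection on a coding sequence is
summarized by $\omega = d_N/d_S$, the ratio of nonsynonymous to synonymous
substitution rates: $\omega \approx 1$ is consistent with neutral change,
$\omega < 1$ with purifying selection, and $\omega > 1$ with positive
selection. Because adaptive episodes typically touch a few sites on a few
branches, genome scans use *branch-site* codon models, which let $\omega$
exceed one only at a subset of sites and only on a designated *foreground*
branch.

`psgscan` implements the full desk-scale pipeline around that test:
filtering collections of single-copy ortholog groups by species
composition, pruning a master species topology to each group, assembling
codon alignments from aligned proteins and unaligned CDS, fitting the
branch-site model and its null by maximum likelihood, the likelihood
ratio test (LRT), symmetric dual-foreground comparisons, and a binomial
test for Gene Ontology category overrepresentation among the positively
selected genes (PSGs). A synthetic-data module generates every input with
known ground truth, so the whole chain is testable without genome-scale
data.

## The model

The substitution process runs on the 61 sense codons of the standard
genetic code. Single-nucleotide changes $i \to j$ occur at rate

$$q_{ij} = \pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\,
  \omega^{\mathbb{1}[\text{nonsynonymous}]},$$

with all multi-position changes forbidden and the diagonal set so rows sum
to zero (`build_rate_matrix()`). $\pi$ holds the equilibrium codon
frequencies, by default estimated with the F3x4 convention — products of
empirical position-specific nucleotide frequencies renormalized over sense
codons (`estimate_codon_frequencies_f3x4()`); F1x4 (a single pooled nucleotide
distribution, `estimate_codon_frequencies_f1x4()`) and uniform
frequencies (`equal_codon_frequencies()`) are the alternatives. The generator is
reversible with stationary law $\pi$, so transition matrices
$P(t) = e^{Qt}$ are computed through a symmetric eigendecomposition.

Model A mixes four site classes with proportions
$(p_0, p_1, p_{2a}, p_{2b})$, where
$p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0+p_1)$:

| class | background $\omega$ | foreground $\omega$ |
|-------|--------------------|---------------------|
| 0     | $\omega_0 \in [0,1]$ | $\omega_0$ |
| 1     | 1                  | 1 |
| 2a    | $\omega_0$         | $\omega_2 \ge 1$ |
| 2b    | 1                  | $\omega_2 \ge 1$ |

The alternative model frees $\omega_2 \ge 1$; the null fixes
$\omega_2 = 1$. Site likelihoods are computed by Felsenstein pruning over
the class mixture (`model_a_loglik()`); gap triplets and IUPAC-ambiguous
codons contribute a partial likelihood of one over all compatible states
(the missing-data convention, analogous to running codeml-style software
without column deletion). The test statistic is
$2(\ell_{\mathrm{alt}} - \ell_{\mathrm{null}})$, clamped at zero, referred
to $\chi^2_1$, significant at $p < 0.05$.

### Branch length scaling

Branch lengths are expected substitutions per codon. Because the mixture
uses several generators at once, a single scale factor per parameter
vector divides all of them: the class-weighted expected rate under each
class's *background* $\omega$,
$\rho = (p_0+p_{2a})\,r(\omega_0) + (p_1+p_{2b})\,r(1)$, where
$r(\omega) = -\sum_i \pi_i q_{ii}(\omega)$. The background regime governs
every branch but one, which makes $t$ comparable between the null and
alternative fits and between genes. The simulator uses the identical
convention, so simulated and fitted branch lengths mean the same thing.

### Null distribution at the boundary

Because the null pins $\omega_2$ to the boundary of the alternative's
parameter space, the asymptotic null law of the LRT is the 50:50 mixture
of a point mass at zero and $\chi^2_1$, which makes the plain $\chi^2_1$
reference conservative. The package defaults to $\chi^2_1$ — the decision
rule in common genome-scan use — and exposes the mixture via
`likelihood_ratio_test(..., mixture = TRUE)`. The calibration acceptance
test confirms the conservatism empirically.

## Fitting protocol

Per gene the pipeline (`run_scan()`):

1. prunes the master topology to the group's species
   (`prune_master_tree()`); groups whose pruned tree has fewer than three
   leaves are flagged `skipped`;
2. back-translates the aligned proteins into a codon alignment
   (`back_translate()`), with strict frame/translation/stop validation;
3. estimates branch lengths once under the one-ratio (M0) model
   (`fit_m0()`) and holds them fixed through both branch-site fits — the
   usual desk-scale protocol; alternatively `branch_lengths = "master"`
   reuses the master topology's lengths;
4. fits null and alternative with a multi-start protocol and runs the LRT
   (`branch_site_test()`).

Optimization is box-constrained quasi-Newton (`optim(method =
"L-BFGS-B")`) on transformed parameters: $\log \kappa$,
$\mathrm{logit}\,\omega_0$, a logit pair for $(p_0 + p_1,\,
p_0/(p_0+p_1))$, and $\omega_2$ directly with a lower box bound at 1 so
the boundary is exactly reachable. The convergence tolerance corresponds
to about $10^{-8}$ on the log-likelihood. Gradients are forward finite
differences with the objective value at the current point reused; a
per-fit cache memoizes eigendecompositions per $(\kappa, \omega)$ and the
two background pruning passes, so optimizer steps that only move
$\omega_2$ cost a fraction of a full evaluation.

The multi-start protocol runs one optimization per starting $\omega$
value (default 0.5, 1, 2), seeding the free $\omega_2$ at
$\max(\text{start}, 1)$ and the initial $\omega_0$ at
$\min(\text{start}, 0.9)$; the run with the best log-likelihood wins,
ties broken by start order, and duplicate effective starts collapse (the
`starts` table of a `bs_fit` records what actually ran).
`branch_site_test()` warm-starts the alternative from the null's
estimates, but only for starts at the $\omega_2 = 1$ boundary — that run
guarantees the nesting inequality up to optimizer noise — while larger
starts keep their own diversified initial values, preserving genuine
multi-start exploration of local optima. The LRT treats an
alternative-below-null deficit under $10^{-4}$ log-units as optimizer
termination noise (the statistic is clamped at zero) and errors beyond
it.

## What the synthetic data does and does not emulate

`simulate_codon_alignment()` is the exact generative counterpart of the
fitted model: per site a class is drawn from
$(p_0, p_1, p_{2a}, p_{2b})$, the root codon from $\pi$, and each branch
samples the child codon directly from $P(t)$ under that branch's
class-appropriate $\omega$ — no event-by-event simulation is needed for
exactness. `simulate_group_collection()` emulates the *composition* of
mammalian ortholog collections (a required species set present in every
group — e.g. dolphin, cow, bat, dog, horse — plus extra mammals, group
sizes 10–33 with most groups between 27 and 33, a discretized normal with
mean 28 and sd 4); its sequences are random sense codons, not phylogenetic
data, because only filtering and plumbing consume them.
`simulate_annotations()` plants category enrichment by weighted PSG
sampling at a chosen fold.

The generators deliberately omit indels, alignment error, sequencing
error and annotation noise. A green test suite therefore establishes that
the *inference machinery* is correct and calibrated under the model; it
does not establish robustness to misalignment or data quality — on real
data those remain the scientist's responsibility.

The validation world for calibration and power is fixed a priori: a
symmetric 10-taxon tree with every branch at 0.15 expected substitutions
per codon (mid-range for a mammalian radiation in codon units) and a
terminal foreground branch. Null calibration simulates $\omega_2 = 1$
(300 codons) and requires an empirical rejection rate at $p < 0.05$ of at
most 0.08; it runs 100 replicates rather than 200 to fit the test-time
budget, which narrows nothing of substance because the boundary null
makes the test conservative (observed rates sit well below nominal).
Power simulates $\omega_2 = 5$ at 10% of sites (500 codons) and requires
significance in at least 80% of 30 replicates with $\hat\omega_2 > 1$ in
at least 90%.

## Enrichment conventions

`binomial_enrichment()` follows whole-list conventions: with $n$
reference genes annotated to a category, $G$ PSGs among $N$ analyzed
genes, the expected count is $n\,G/N$ and the raw p-value is the
one-sided binomial upper tail at the observed count with success
probability $q = G/N$. Unannotated genes stay in the denominators. The
Bonferroni factor $m$ is the number of categories with at least one
annotated reference gene (recorded as the `m_tests` attribute);
significance is called on the corrected p-value at 0.05.
Underrepresentation is available behind `direction = "less"`. Category
membership follows `is_a` ancestor closure in the GO DAG; `part_of`
edges are traversed only on request. The OBO reader covers the `[Term]`
subset needed here; unknown annotation terms are dropped with a message.

## Numerical choices and edge cases

- Codon frequencies of zero (possible under F3x4 when a nucleotide is
  absent at a position) shrink the state space: such codons are excluded
  from the eigendecomposition and can never be observed in the data that
  produced the frequencies.
- Site likelihoods are floored at $10^{-300}$ before logging; per-node
  rescaling is unnecessary at desk scale (tens of species).
- Significance uses strict $p < \alpha$ with a $10^{-8}$ epsilon guard so
  a statistic equal to the $\chi^2_1$ quantile at printed precision reads
  as the boundary, not a rejection.
- Terminal stop codons are stripped before back-translation length
  checks; internal stops are hard errors; `U` is normalized to `T` and
  case is folded.
- Group iteration order is input order and all outputs are deterministic
  given inputs and seeds; scan rows are invariant to permuting the input
  groups.
- With two foregrounds, pruned trees, alignments, frequencies and M0
  branch lengths are shared per gene; only the foreground flag differs.
- Duplicate species within a group are rejected as malformed input.

## Limitations

- Per-site identification of selected positions (empirical Bayes) is out
  of scope; results are gene-level.
- Only the standard genetic code is supported.
- The M0 branch-length step assumes the pruned topology is correct; tree
  search is not performed.
- A foreground branch adjacent to the root of a rooted tree is only
  partially identifiable under reversibility; place the root so the
  foreground branch is internal to the rooted topology (with a genuine
  outgroup this does not arise).
- No multiple-testing correction is applied across genes in the headline
  counts (each gene is an independent hypothesis, per common genome-scan
  practice); an FDR column can be added downstream from the per-gene
  p-values if desired.
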