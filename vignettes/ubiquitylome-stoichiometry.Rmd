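---
title: "Stoichiometry-resolved ubiquitylome analysis: models and methods"
author: "ubistoich authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometry-resolved ubiquitylome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubistoich)
```

# The problem

A change in the measured abundance of a ubiquitylated (K-&epsilon;-GG) peptide
confounds two biological signals: the fraction of the protein's molecules
carrying the modification (site occupancy, or *stoichiometry*) may have
changed, or the total amount of the protein may have changed while the
occupancy stayed constant. In aging tissue, where protein abundances drift
broadly, separating these signals is essential before interpreting any PTM
fold change. `ubistoich` implements the analytical chain for this
separation and the comparisons built on top of it: correction of
modified-peptide quantities for protein abundance, moderated differential
statistics with two multiplicity conventions, cross-species site liftover
with a lysine-conservation call, classification of intervention responses,
TMT PSM summarization, AQUA spike-in absolute quantification of
ubiquitin-chain linkages, and rank-based gene-set enrichment.

All stages operate on synthetic data with recorded ground truth, generated
by the package itself, so every claim the test suite makes is checkable
without access to any deposited raw data.

# The correction model

For protein group $g$ and condition $c$ with reference condition $r$ (the
young age group in an aging design), the correction factor is a ratio of
medians over that condition's samples:

$$f_{g,c} = \frac{\operatorname{median}_{j \in c}\, P_{gj}}
                 {\operatorname{median}_{j \in r}\, P_{gj}},$$

computed on linear-scale quantities with missing values ignored. A modified
peptide mapped to proteins $g_1, \dots, g_m$ ($m \ge 2$) uses the factor of
the *summed* per-sample quantities of those proteins. The corrected value of
peptide $i$ in sample $j$ of condition $c$ is $\log_2(Y_{ij} / f_{g(i),c})$.
By construction $f_{g,r} = 1$: reference samples are only log-transformed.

Consequences used as exact test oracles:

* a site whose peptide tracks its protein perfectly (pure abundance change)
  has corrected log2 fold change 0;
* a site with a planted occupancy shift $\delta$ on an unchanged protein
  retains exactly $\delta$ after correction;
* for any single-protein site, the corrected median log2 difference equals
  the raw difference minus $\log_2 f$, identically.

Two rules are deliberate choices where the procedure admits variants. First,
the factor is per *condition*, not per sample — the median ratio rule
applied literally. Second, inside a multi-protein sum, a sample
contributes the sum of whichever member proteins were measured; a sample
where all members are missing stays missing. Proteins with no non-missing
reference value cannot define a factor; their sites are retained with a
`corrected = FALSE` flag rather than dropped, preserving the accounting of
how much of a dataset was correctable.

# Differential statistics

The two-sample machinery offers the plain unpaired t-test (pooled variance
by default, Welch behind a flag) and the empirical-Bayes moderated t-test.
Moderation follows the standard moment-matching scheme: with per-feature
variances $s_g^2$ on $d_g$ degrees of freedom, set
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$; the excess of
$\operatorname{var}(e)$ over $\operatorname{mean}(\psi'(d_g/2))$ determines
the prior degrees of freedom $d_0$ by trigamma inversion (Newton), and the
prior variance $s_0^2$ follows from $\operatorname{mean}(e)$. When the
excess is non-positive the prior is degenerate ($d_0 = \infty$) and
$s_0^2$ is the mean observed variance. The moderated statistic uses
$\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on $d_0 + d_g$ degrees
of freedom; $d_0 \to 0$ recovers the plain pooled t, $d_0 = \infty$ fixes
all variances at $s_0^2$. The implementation is validated against an
independent `uniroot` solve of the moment equations and against `limma` as
an external cross-check.

Multiplicity control follows the field's split convention: BH adjustment
(`adj_p`) for protein-level TMT/proteome contrasts, Storey q-values for PTM
datasets. The q-value uses the fixed-$\lambda$ estimator
$\hat\pi_0 = \min\{1, \#\{p > \lambda\} / (m(1-\lambda))\}$ with
$\lambda = 0.5$; the smoother variant is intentionally not implemented —
a deterministic estimator keeps every run reproducible, and with
$\hat\pi_0 = 1$ the q-values coincide with BH exactly. P-values of exactly
zero are floored at the smallest positive normal double before q
computation. Features with fewer than two observations in either group get
a missing p and are excluded from multiplicity denominators.

Significance calls combine both conventions' thresholds: `q < 0.05` *and*
`|log2 FC| > 0.58` (1.5-fold) by default; a stricter `q < 0.01` variant used
for the "ubiquitylation only" class is exposed as an argument rather than
hard-coded, since both thresholds appear in practice.

# Cross-species liftover

Modified lysines are projected between species through optimal local
alignments: the query protein is aligned against every target protein
(Smith–Waterman, BLOSUM62, affine gaps 11/1 — protein BLAST's default
scoring), the ten best-scoring targets are kept (one optimal alignment per
target; ties broken by accession for determinism), and the modified
position is read through each alignment's columns. A lysine is *conserved*
if any of the top hits places it opposite a lysine; a site is
*modified-in-both* if the projected position is itself in the target
species' site table.

Heuristic seeded search, E-value statistics, and composition-based score
adjustment are deliberately not emulated: at the scale of a per-protein
query list, exact alignment is affordable and strictly more reproducible,
and ranking by raw score replaces ranking by E-value. The dynamic
programming itself is delegated to `Biostrings::pairwiseAlignment`; the
test suite pins its scores to a brute-force affine-gap DP oracle on short
sequences and to a hand-worked gapped example (`MKTAYKLL` vs `MKTYKLL`,
score 23, query K6 &rarr; target K5).

```{r liftover-example}
hit <- localAlign("MKTAYKLL", "MKTYKLL")
alignmentScore(hit)
projectSite(6, hit)
```

# Intervention-response classification

Matched contrasts (aging vs dietary restriction / re-feeding) are joined on
shared sites; every site significant in at least one dataset receives one
category. *Exacerbated*: significant in both, same direction.
*Reverted-down / reverted-up*: significantly changed by the intervention in
the direction opposite to the age-related change — the age side contributes
only its sign, not its significance, mirroring how such scatterplots are
conventionally read. *Congruent trend*: same direction, significant in
exactly one. Everything else is *other*. Cross-species comparisons instead
use the two-threshold consistency scheme (strict p &lt; 0.05 in both,
relaxed p &lt; 0.25 in both, with "not consistent" requiring p &lt; 0.25 in
both at opposite signs; the both-sided reading of the relaxed threshold is
a documented choice where the convention is ambiguous).

# AQUA-PRM absolute quantification

Heavy-labelled reference peptides spiked at a known amount (20 fmol per µg
of input protein) make the endogenous amount a pure ratio:
$\text{amount} = (L/H) \times \text{spike}$. A missing or zero heavy
intensity flags the assay below detection (`NA`) rather than amount zero; a
zero light intensity is a detected zero. The polyubiquitin percentage is
$100 \times \sum \text{linkage amounts} / \text{total ubiquitin}$, with
below-detection linkages contributing zero to the numerator but excluded
from group statistics — conservative for both uses. Multiple peptides
reporting one target (e.g. two total-ubiquitin assays) are averaged. The
K29 linkage, which lacks a quantifiable assay in practice, is simply an
absent panel row; the percentage is taken over available linkages.

# Enrichment

Preranked GSEA uses the weighted Kolmogorov–Smirnov running sum: hits
advance by $|s|^w / \sum_{\text{hits}} |s|^w$ (default $w = 1$), misses
retreat by $1/(N - N_h)$, and the enrichment score is the extreme deviation
(signed). Null scores come from gene-label permutation — at the preranked
stage sample-level data no longer exist, so phenotype permutation is not an
option. $\text{NES} = ES / \operatorname{mean}|ES_{\text{null}}|$ over
same-sign permutations, with a +1 pseudo-count in the p-value so no
permutation p is exactly zero. Over-representation is a plain upper-tail
hypergeometric test against the annotated background — a deliberate
replacement for DAG-aware term elimination, which is out of scope. Site
statistics reach gene level via an explicit site&rarr;gene map with a
`max_abs` default (a single strongly-changed site should represent its
protein), with `mean`/`median` as alternatives; no orthology inference is
performed.

# The synthetic-data generator

`simulateQuantExperiment()` emulates the study's two-group DIA design:
log-normal protein abundances (log2 baseline $\mathcal N(20, 2^2)$, the
typical DIA intensity range), 5 replicates per group, log2 measurement
noise of 0.25 with the peptide and protein channels independent (they come
from separate MS runs), modified peptides offset $\mathcal N(-2, 1)$ below
their protein, and unit (2-fold) planted effects. Site classes are assigned
per protein — a protein is either unchanged, abundance-changed
(`protein_driven` sites), or occupancy-changed (`stoich_driven` sites) —
with exact largest-remainder counts, so a noise-free run recovers the
planted class fractions exactly; with one site per protein the site-level
fractions are exact too. Effect magnitudes are fixed with random signs
rather than drawn from a distribution: the real effect-size distribution is
unknown, and fixed magnitudes make recovery claims sharp. Missingness is
logistic in true log2 intensity (left-censoring, as in DIA), with the
asymptotic low-intensity rate, midpoint and slope all configurable and
defaulting to off for exactness tests.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: correlated peptide/protein measurement
error, retention-time or batch structure, interference and ratio
compression in TMT channels, shared peptides between protein groups beyond
the explicit multi-accession mechanism, and any realistic effect-size
distribution. The generator demonstrates correctness of the estimators
under the stated model, not robustness to violations of it.

Companion generators cover the remaining inputs: `simulateOrthologPair()`
(substitutions, indels and a dedicated lysine-loss rate, with the true
position map and per-lysine fates recorded; lost lysines become arginine,
the most common conservative exchange), `simulatePrm()` (light/heavy pairs
sharing a per-peptide response constant, log-normal noise of configurable
CV), `simulateGenesets()` (disjoint sets over a synthetic universe, one set
shifted by a configurable amount), and `simulateInterventionPair()`
(matched contrasts with planted exacerbated/reverted classes).

# Numerical choices and degenerate inputs

* Medians of even counts are the mean of the two central values; medians
  ignore missing values throughout.
* Zero within-group variance with a non-zero difference yields $p = 0$
  ("data essentially constant" convention), $p = 1$ at zero difference;
  the workflows fall back from moderated to plain testing when *every*
  feature is variance-free, since the prior is then undefined.
* TMT "normalization" is channel-median centering to the grand median —
  monotone, deterministic, and the conventional reading; the exact scheme
  is exposed rather than guessed. "At most one missing channel" is the
  reading of the peptide quantification rule, since the stricter reading
  would discard complete peptides.
* Alignment tie-breaks (diagonal preference, smallest end coordinates) are
  fixed for determinism; all seeds are surfaced in configs and the test
  suite uses a fixed default (20250606).
* Writers emit quantities at 15 significant digits so read–write round
  trips hold to at least 12; TSV/GMT files carry `#`-prefixed version and
  provenance (stage, parameter-hash) headers. FASTA output is plain FASTA —
  a comment line would corrupt the format.
* Decimal points only; no locale-dependent parsing.

# Problem sizes

The shipped checks run at deliberately modest scale, chosen so the whole
suite completes in well under a minute of compute per concern: 2000-feature
null and mixture experiments at $n = 5$ per group (20 seeds for FDR and
classification claims), 500 planted stoichiometry sites, proteomes of a few
hundred residues for alignment properties, 30–50 gene sets with 200–400
permutations. These sizes give Monte-Carlo error comfortably inside the
asserted tolerances; all of them scale up by changing config values only.

# Known limitations

* Only two-group designs are simulated and tested end to end; paired and
  multi-factor designs are out of scope.
* The correction transfers protein-level *median* shifts only; sample-level
  covariation between peptide and protein channels is neither modelled nor
  exploited.
* Liftover reports one optimal alignment per target; suboptimal
  within-target alignments (multiple HSPs) are not projected.
* The q-value implementation fixes $\lambda$; datasets whose p-value
  distribution is badly behaved near $\lambda = 0.5$ may prefer the
  smoother estimator found elsewhere.
* GSEA p-values are lower-bounded by $1/(n_{\text{perm}}+1)$; multiple
  testing across many sets at small $n_{\text{perm}}$ is correspondingly
  coarse.
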