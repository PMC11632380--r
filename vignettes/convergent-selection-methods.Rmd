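---
title: "Detecting convergent shifts in selection for a binary trait: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent shifts in selection for a binary trait: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific setting

`convsel` implements the downstream statistical pipeline of a comparative
genomics study of convergent trait loss — the motivating case being bee
lineages that independently lost prepupal (developmental) diapause, a trait
shift hypothesised to precede lifespan extension and sociality. Given a
species tree, a binary *foreground* flag (species carrying the derived
state), per-orthogroup gene trees, and codon alignments, the package asks
three complementary questions per orthogroup:

1. **Rate convergence.** Did the gene evolve faster or slower than expected
   in the foreground lineages (relative evolutionary rates, RER)?
2. **Selection intensity.** Did the distribution of dN/dS on foreground
   branches move toward 1 (relaxation) or away from 1 (intensification),
   summarised by the selection-intensity exponent K?
3. **Episodic positive selection.** Does any single foreground branch carry
   a site class with dN/dS > 1?

The three answers are then combined into interpretable categories
(possible positive / purifying / relaxed / intensified selection, plus
best-evidence sets), screened against gene-family losses, and related to
species traits by phylogenetic regression.

# Relative evolutionary rates and the permulation null

For orthogroup $g$ with branch lengths $b_{g,i}$ matched to master-tree
branches $m_i$ (matching is by the clade of tip labels below each branch, so
orthogroups missing species are handled), we floor both at $10^{-9}$, take
logs, and regress $\log b_{g,i}$ on $\log m_i$ by ordinary least squares
with free slope and intercept. The residuals are the RERs: the intercept
absorbs proportional rate differences (a uniformly fast gene is *not*
rate-shifted), and the slope absorbs any global power-law distortion. This
is a deliberate simplification relative to weighted RER estimators with
square-root transforms; it is isolated in one function (`compute_rers()`)
so the estimator can be swapped without touching anything else.

The trait correlation uses **terminal branches only**: the statistic
$\rho$ is a rescaled Mann–Whitney statistic (Cliff's delta) between
foreground and background terminal RERs, in $[-1, 1]$, positive when
foreground branches evolve faster ($\rho^+$ = acceleration, $\rho^-$ =
deceleration/constraint). Internal branches of all-foreground clades are
excluded by default because a single ancestral transition makes them
non-independent evidence for convergence; the codon tests expose an
`include_internal` flag where the user prefers the other reading.

Parametric rank-sum p-values are anti-conservative on a tree, because
related species do not contribute independent observations. The package
therefore calibrates empirically with **permulations**: simulate Brownian
motion on the master tree, rank the tip values (ties broken by a seeded
random tie-break; a probability-zero event under continuous Brownian
motion, but required for determinism), and assign the foreground label to
the top-$k$ tips. This produces null foreground sets with the same
phylogenetic clustering propensity as real convergent trait losses. The
empirical p-value is the plain proportion of null statistics at least as
extreme (two-sided, on $|\rho|$) as the observed one; a proportion of
exactly 0 is reported as 0 and flagged, with the $(1+k)/(1+N)$ estimator
available by argument, since the plain proportion is the primary
definition and the pseudo-count version is statistical hygiene, not
fidelity. Benjamini–Hochberg correction across orthogroups yields the
significance sets.

# The codon model and the two likelihood-ratio tests

Both selection tests share a deliberately transparent codon model: an
MG94/GY-style rate matrix over the 61 sense codons in which a single-
nucleotide change $i \to j$ has rate $\pi_j \,\kappa^{[\mathrm{ts}]}\,
\omega^{[\mathrm{nonsyn}]}$, multi-nucleotide changes have rate 0, and each
category matrix is scaled to one expected substitution per unit branch
length at stationarity. Codon frequencies are estimated from the alignment
by an F1x4-style product over positions, normalised over sense codons and
floored so no sense codon has probability zero. Site likelihoods come from
Felsenstein pruning (a small C++ kernel, as is conventional for pruning
loops in this field), with ambiguous codons treated as missing data and
branch lengths floored at $10^{-8}$ to keep transition matrices
nonsingular. Branch lengths are otherwise taken exactly as given — gene
trees are inputs, matching the practice of feeding externally estimated
trees to selection-testing software — and are not re-optimised.

**Selection-intensity (K) test.** A shared three-class omega mixture
$\omega_1 \le \omega_2 \le 1 \le \omega_3$ with free weights and $\kappa$
is estimated by bounded maximum likelihood (box-constrained quasi-Newton,
three seeded starts: one from canonical values
$\{0.1, 1, 1.5\}/\{0.7, 0.25, 0.05\}$, the others jittered; the extra
starts run short exploratory passes and the best endpoint is polished).
Under the alternative every category omega is exponentiated on the
foreground branches, $\omega \mapsto \omega^K$ with $K \in [0.01, 50]$:
$K < 1$ compresses selection toward neutrality (relaxation), $K > 1$
amplifies it (intensification). The null fixes $K = 1$; because that value
is interior, the LRT is referred to $\chi^2_1$. The alternative is started
from the null solution (among other starts), so the nesting inequality
$\ell_1 \ge \ell_0$ holds by construction and is asserted in the tests.

**Per-branch positive selection.** Following the random-effects branch-site
idea, every branch carries its own omega distribution drawn independently
per site and per branch, so a branch's transition matrix is simply the
weighted mixture of category matrices. After fitting a shared background
model, each tested branch gets a null with two classes
$\{\omega_1 \le 1, \omega_2 = 1\}$ and an alternative adding
$\{\omega_3 \ge 1\}$ with a free weight. Because the null pins the extra
class to a boundary, the LRT is referred to the 50:50 mixture of
$\chi^2_0$ and $\chi^2_2$. Holm correction is applied across the tested
branches within an orthogroup, and the orthogroup is called positively
selected if any adjusted p falls below the threshold (0.05 by default).

This module is a transparent reimplementation of the *statistical
contracts* of the field's selection tests, not a numerical re-creation of
any particular tool: there is no site-to-site synonymous rate variation and
no double/triple multiple-hit substitution class, and the branch-site test
uses a fixed 2-versus-3 class structure rather than adaptive complexity
selection. P-values therefore differ from heavier implementations even on
identical data; what is preserved is the nested-LRT logic, the boundary
corrections, and the multiple-testing scheme.

# Combining evidence

With significance sets from the three tests (RER split into $\rho^+$ and
$\rho^-$; K test split into relaxed $K<1$ and intensified $K>1$; the
branch-positive calls), the classifier builds four mutually exclusive
"possible" categories:

* possible positive = ($\rho^+$ ∪ branch-positive) \\ relaxed
* possible purifying = $\rho^-$ \\ (branch-positive ∪ relaxed)
* possible relaxed = relaxed \\ (branch-positive ∪ $\rho^+$ ∪ $\rho^-$)
* possible intensified = intensified \\ (branch-positive ∪ $\rho^+$ ∪ $\rho^-$)

and two best-evidence flags: best positive (at least 2 of
{branch-positive, $\rho^+$, intensified} — intensification counts because
it cannot distinguish positive from purifying pressure on its own) and
best purifying ($\rho^-$ ∩ intensified). The intensification votes use the
raw K-test significant set, not the set after the relaxed-overlap
subtraction, which is the natural reading of the rule. Disjointness of the
four categories is enforced by construction and property-tested over
random call sets.

Term enrichment is classic per-term Fisher (upper-tail hypergeometric)
against the universe of annotated orthogroups, testing only terms with
strictly more than 5 annotated members and flagging p < 0.01. This
deliberately replaces ontology-graph-weighted algorithms (weight01-style
elimination); p-values are therefore not comparable to graph-aware tools,
and the choice is surfaced prominently here because it changes which terms
look significant. Gene-list overlaps (e.g. against curated longevity gene
sets joined by reciprocal best hits) use the same upper-tail
hypergeometric.

# Orthogroup and family filters

The retention rule keeps orthogroups present in *every* species but
single-copy in at least 70% of them; "at least 70%" rounds up
(`ceiling(0.7 n)`), and species with paralogs are excluded from the
retained orthogroup rather than dropping the orthogroup. The 70% fraction
is evaluated against the full species list (not the post-exclusion count),
the more conservative of the two readings. Orthogroups reduced below 4
species are flagged and skipped by tree-based stages, since likelihood
tests need at least 4 taxa. Alignment columns are dropped when *strictly
more* than 50% of sequences have a gap or N in that column — exactly half
missing is kept. Family-loss screening first removes families with 100 or
more total genes (presence/absence calls in huge, fast-turnover families
are unreliable), then flags families absent in all, or all-but-one, species
of one trait group while present in the other; a strict-majority
alternative is selectable, and exception species are reported by name
because near-universal losses with a single exception are exactly the
pattern of interest.

# Trait association

Gene presence/absence (0/1) is regressed on categorical species traits by
generalized least squares with Brownian covariance (shared root-to-tip path
lengths), fitted by Cholesky whitening so an identity covariance reduces
exactly to OLS. Using Gaussian PGLS for a binary response mirrors standard
comparative practice and keeps coefficients interpretable as probability
differences; it is a documented fidelity choice rather than the
statistically ideal model (phylogenetic logistic regression), and no
branch-length transformation (lambda) is estimated by default. Single- and
joint-predictor models are both supported, since the two traits of interest
(diapause loss and sociality) are themselves correlated — which is
precisely what the accompanying Fisher exact 2x2 test quantifies. The GLS
estimator is unbiased for the linear coefficient whatever the true error
structure of the 0/1 response, which is what the coefficient-recovery
check in the test suite verifies.

Reciprocal-best-hit joining reduces each similarity table to one best hit
per query (maximum bit score, ties by smaller e-value, then lexicographic
subject id — a total order, so results are deterministic) and keeps
mutually-best pairs, after filtering at e-value 1e-10.

# The synthetic-data generator

Every stage is testable without external data because the generator
emulates the *structure* of the study design:

* a pure-birth species tree rescaled to unit depth, default 27 species;
* 17 foreground species by default, placed `clustered` (greedy clade fill,
  mimicking phylogenetically clustered convergent losses) or `dispersed`;
  the bundled study generator caps any single clade at
  `ceiling(n_foreground / 3)` so the derived state has at least three
  independent origins — without multiple origins there is no convergence to
  detect;
* a sociality label correlated with the foreground flag
  (P(social | foreground) = 0.8 vs 0.1 by default), so the PGLS stage has a
  genuine confounder to untangle;
* gene trees sharing the species topology exactly (the analysis assumption;
  no discordance is simulated) with per-orthogroup lognormal rates
  (sd 0.3), per-branch lognormal noise (sd 0.2), and a foreground
  terminal-branch multiplier on a designated fraction of orthogroups;
* codon alignments evolved site-independently under the mixture
  $\{0.1, 1, 1.5\}$ with weights $\{0.7, 0.25, 0.05\}$ and the foreground
  $\omega^K$ convention (defaults $K = 0.3$ / $1$ / $3$ for the relaxed /
  null / intensified arms), 300 codons by default;
* count tables with planted patterns: a universal single-copy family, a
  family lost in all foreground species, the near-universal loss with one
  exception species, a background loss, one family over 100 genes for the
  size filter, and Poisson-count fillers.

What the generator does **not** emulate: alignment error, indels,
gene-tree/species-tree discordance, GC-biased frequencies, synonymous rate
variation, or multi-nucleotide mutations. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the model's own assumptions — not that the pipeline is robust to the
violations real genomic data exhibit.

# Numerical choices and problem sizes

* Branch lengths are floored at 1e-8 inside codon likelihoods and at 1e-9
  inside the RER log-regression; zero-length branches are otherwise legal.
* The reversible rate matrix is diagonalised through its symmetrised form,
  so transition probabilities for any branch length cost two small matrix
  products; round-off negatives are clamped to zero.
* Within one model fit, eigendecompositions, per-edge transition matrices,
  and whole per-category site-likelihood vectors are memoised, because
  finite-difference gradient evaluations perturb one parameter at a time.
* Optimisation is box-constrained L-BFGS-B on log/logit-transformed
  parameters with `factr = 1e8`; weight simplexes use stick-breaking.
* Calibration checks in the test suite run at sizes chosen once as
  realistic for the statistics being checked: 50 null
  replicates (8 taxa, 300 codons, 4 foreground) for the type-I rate of the
  K test, 20 replicates per arm for K recovery, 200 null orthogroups on a
  27-species/17-foreground tree with 500 permulations for null-p
  uniformity, and 6,000 replicates for the star-tree exchangeability check.
* Ranking ties anywhere (permulation ranks, RBH best hits) are broken by
  explicit, seeded, documented rules so that identical configurations are
  bit-reproducible.

# Known limitations

* The genome-scale counts of a real study (thousands of orthogroups over
  dozens of genomes, with alignment pipelines and tool-specific model
  extensions) are out of reach of this reimplementation by design; the
  package validates property-level behaviour, not numerical parity with
  HyPhy/RERconverge outputs.
* Gaussian PGLS on a binary response can predict outside [0, 1] and its
  p-values are approximate near separation.
* The branch-site test's fixed class structure can underfit branches with
  more complex omega distributions; its calls are conservative.
* Empirical p-values are bounded below by 1/N permulations; at N = 1000
  the smallest achievable q-values are limited accordingly, exactly as in
  the empirical-calibration literature.
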