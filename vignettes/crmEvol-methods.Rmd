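---
title: "crmEvol: models, scoring and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crmEvol: models, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmEvol)
```

This vignette is the package's own account of its methods: the processes it
fits, the scorer it uses as a trait, the numerical choices that matter, and
the places where the design was genuinely open and a convention had to be
fixed. The companion README shows the end-to-end worked example; here we
explain *why* the pieces look the way they do.

## 1. The trait: homotypic-cluster CRM scores

A cis-regulatory module often works through several binding sites for the
*same* factor. `crmScore()` therefore scores a region against one PWM with
a two-state hidden Markov model: walking along a candidate subsegment, the
cluster model either emits a background base (probability $1-\tau$) or
starts a motif occurrence (probability $\tau$, strands equiprobable) whose
$w$ bases are emitted from the PWM columns. The forward algorithm sums over
*every* legal parse, so the score aggregates all possible site placements
rather than committing to one. Because background emissions appear in both
the cluster and the background-only model, they cancel, and the segment
statistic reduces to a sum over placement sets of products of per-site odds
ratios weighted by $\tau/2$ per site and $(1-\tau)$ per background base.
The reported CRM score is $\log_2$ of this ratio, maximised over all
subsegments and floored at 0 (an empty cluster is ratio 1); a single strong
match is a one-site cluster and scores on its own.

Tunable parameters, with defaults and rationale:

* **`expectedGap` = 35 bp.** $\tau = 1/(1+\text{gap})$ makes inter-site
  gaps geometric with this mean. 35 bp is the conventional within-cluster
  spacing scale for homotypic clusters; the sources describing this class
  of scorer do not pin the value, so it is exposed and documented rather
  than hidden.
* **`pseudocount` = 0.375 per count cell**, the Cluster-Buster-compatible
  convention; guarantees strictly positive probabilities so log-odds stay
  finite. Probability-valued JASPAR matrices are rescaled to counts from
  100 observations before pseudocounting, otherwise a pseudocount sized
  for counts would flatten them.
* **Background**: 0th-order base frequencies estimated from the scored
  region itself, *strand-symmetrised* ($q_A=q_T$, $q_C=q_G$). The
  symmetrisation is what makes `score(seq) == score(revcomp(seq))` exact
  rather than approximate; a genome-wide composition can be supplied
  instead. `N` bases contribute factor 1 to both models (score-neutral).

**Exact subsegment maximisation.** A reset-at-zero (Kadane-style)
recursion is the textbook way to find a maximal-scoring segment, but it is
only exact for *additive* scores. The forward statistic is a sum of
products, so resetting is a heuristic there. The implementation instead
carries the forward vector over *all* segment starts simultaneously (one
$O(n)$ vector operation per position, $O(n^2)$ arithmetic overall, with a
running renormalisation so arbitrarily strong clusters cannot overflow).
This makes the max-over-subsegments and the floor at 0 exact, which is
what lets the test suite demand agreement with exhaustive parse
enumeration to $10^{-9}$ log2 units. Site annotations (positions, strands)
come from a max-product Viterbi parse of the best segment; the score never
does.

## 2. Trait evolution: BM, OU and branch shifts

Given a rooted tree with branch lengths and a trait vector
$X$ at the tips, three processes are fitted:

* **BM**: $dX = \sigma\,dB(t)$ — drift; variance grows linearly.
* **M0**: $dX = \alpha[\theta - X]\,dt + \sigma\,dB(t)$ — one optimum
  $\theta$ for all branches (stabilising selection of strength $\alpha$).
* **Branch-shift (Hansen) models**: one clade, plus its stem branch,
  carries $\theta_{\text{shift}}$; everything else $\theta_{\text{base}}$.

All three are Gaussian, so the likelihood is a multivariate normal density
whose moments follow from the process: with $s_i$ the root-to-tip depth
and $t_{ij}$ the root-to-MRCA depth,

$$E[X_i] = x_0 e^{-\alpha s_i} + \sum_{b \in \text{path}(i)}
\theta_{r(b)}\left(e^{-\alpha(s_i - t^{\text{end}}_b)} -
e^{-\alpha(s_i - t^{\text{start}}_b)}\right), \qquad
V_{ij} = \frac{\sigma^2}{2\alpha}
e^{-\alpha(s_i+s_j-2t_{ij})}\left(1 - e^{-2\alpha t_{ij}}\right).$$

Conventions that change likelihoods, and therefore had to be fixed and
documented:

* **Root state pinned to the root regime's optimum** ($x_0 =
  \theta_{\text{root}}$), not separately estimated. This gives $k = 2$
  (BM), $3$ (M0), $4$ (branch shift), so the M0-vs-Mx LR has exactly one
  degree of freedom.
* **Zero variance at the root** (the process starts at $x_0$), not a
  stationary-root draw. Alternatives are legitimate but produce different
  likelihoods; this package implements only the zero-variance start.
* **Stem branch included** in the shifted regime: a "branch-specific
  optimum" biologically means the optimum changed on the lineage *leading
  to* the clade.
* **Missing species** are pruned and the painting re-derived on the
  induced subtree; a model whose entire shifted clade is missing is
  reported *untestable*, a distinct state from a failed fit.

**Fitting.** At fixed $\alpha$ the tip means are linear in the
$\theta$-vector through the exponential weight matrix, so $\theta$ is
solved by generalised least squares and $\sigma^2$ in closed form from the
weighted residuals; the profile likelihood is then maximised over
$\alpha \in [10^{-8},\, 100/\text{tree height}]$ by a deterministic
9-point log-spaced grid followed by 1-D `optimize()` refinement in the
best bracket. `fitRegion()` additionally injects M0's $\hat\alpha$ into
every branch-shift profile, which enforces the nesting inequality
$\max \log L(M_x) \ge \max \log L(M_0)$ to optimizer tolerance. Numerical
details: $1-e^{-2\alpha t}$ is computed with `expm1` (full precision at
any $\alpha t$, no series branch needed); when $\alpha \to 0$ makes the
regime columns collinear, the GLS collapses to the equal-optima solution,
which is the correct supremum there; a constant trait floors
$\hat\sigma^2$ at $10^{-12}$ with a degeneracy flag.

**$\alpha$ is weakly identified on 12 tips.** Under drift-generated data
the M0 profile in $\alpha$ is nearly flat; fits frequently collapse to the
lower search bound (the modal outcome in the package's own simulations)
and otherwise scatter widely. `ModelFit` therefore reports
`alphaAtBound`, true whenever the profile value at a bound is within
$10^{-6}$ of the maximum — a statement about identifiability, not an
error.

**The 12-species fixture tree.** The literature on this framework never
states which chronogram was used, so `drosophilaTree()` ships the accepted
topology of the 12 sequenced *Drosophila* genomes with ultrametric branch
lengths proportional to round divergence-time estimates, normalised to
height 1. All fitting accepts any user newick; the fixture exists so that
examples, tests and simulations are self-contained. Note one topological
consequence: the M6 tip set (*D. willistoni* + the *Drosophila* subgenus)
is **not** a clade on this topology, so M6 is painted by complement — the
shift regime is everything outside the melanogaster+obscura clade and
contains the root. `paintClade()` only does this when explicitly allowed;
by default a non-monophyletic tip set is an error.

## 3. Model comparison and divergence calls

The LR statistic $2(\log L_{M_x} - \log L_{M_0})$ is referred to
$\chi^2_1$; Akaike weights $w_i = e^{-\Delta_i/2}/\sum_r e^{-\Delta_r/2}$
(computed in shifted form, overflow-free) compare any model set including
non-nested ones. The default calling mode is **pairwise** ($M_x$ vs $M_0$,
divergent iff $w(M_x) > 0.5$), which is equivalent to an AIC comparison
and, with one extra parameter, to LR $> 2$. `triple` (BM, M0, Mx) and
`all` modes are stricter argmax-weight comparisons for survey analyses.
Ties break toward the simpler model. BH adjustment is applied across
regions × models; the optional minimum-score filter (e.g. max tip score
$\ge 6$) mirrors focussed case-study practice and is off by default.

A caveat the package measures rather than hides: at $n = 12$ tips the
$\chi^2_1$ reference for the LR is anti-conservative, because the residual
variance is estimated (the exact null is t/F-like: $n\log(1 + t^2/\nu)$
with $\nu \approx 10$, and $P(\mathrm{LR} > 3.84)$ is then 8–10%, not 5%).
`scripts/acceptance.R` recomputes this null rejection rate from 1,000
simulations on every run. The Akaike-weight decision rule inherits the
same finite-sample optimism; the parametric bootstrap below is the
package's calibrated alternative for any region that matters.

## 4. Parametric bootstrap (phylogenetic Monte Carlo)

`simulateTrait()` draws traits by the exact pre-order transition
$X_{\text{child}} \sim N(\theta_b + (X_{\text{parent}}-\theta_b)
e^{-\alpha t},\, \sigma^2(1-e^{-2\alpha t})/2\alpha)$, so simulation and
likelihood share no code path with each other beyond the process
definition (the test suite checks their moments against each other and
against closed forms). `pmcPower(a, b)` fits both models to the observed
trait, simulates `nBoot` datasets under each fitted model, refits **both**
models on every dataset, and reports the two distributions of
$\delta = 2(\log L_a - \log L_b)$, the observed $\delta$, its quantile in
each distribution, and their overlap. With the convention that `a` is the
richer model and `b` nested in it, $\delta$ is the familiar LR and both
distributions are non-negative up to optimizer noise. Overlap is
$1 - $ total-variation distance estimated from pooled histograms with
Freedman–Diaconis bins — the sources describe the overlap only
graphically, so the TV estimate is this package's explicit convention.
Default `nBoot` is 1,000; desk-scale runs use 100–200. Failed refits are
skipped and counted, never silently replaced by the generating values.

## 5. Synthetic data: what it does and does not emulate

The generators make every stage testable without downloads:

* `genTraitDataset()` — traits under any painting/parameters; the truth
  label is the generating model.
* `genSequencePanel()` — per-species ortholog sequences with PWM-sampled
  sites planted at clustered positions (window $3\times$ the scorer's
  expected gap, so single-cluster structure is guaranteed) in the clade
  (gain), outside it (loss), or everywhere/nowhere 50/50 (conserved);
  optional ortholog dropout; uniform or AT-rich background.
* `genEnrichmentBenchmark()` — a region universe, an "experimental" input
  set with configurable label noise, and the planted truth tuple.

All generators are pure functions of (parameters, seed). One deliberate
simplification must be kept in mind when interpreting green tests:
**sequence evolution along the tree is not modelled.** Species backgrounds
are independent i.i.d. draws; there is no substitution process, no indels,
no phylogenetic correlation between orthologous background positions.
This is a *non-phylogenetic sequence null*: it exercises the scorer and
the OU machinery end to end, but passing it says nothing about alignment
quality, background conservation or substitution-model realism on real
genomes. Trait-level simulations, by contrast, are exactly the fitted
processes.

Default study conditions used by the tests and the acceptance script,
chosen once as representative desk-scale sizes: regions of 400–600 bp
(real regulatory-genome partitions average ~1 kb), 3 planted sites of an
~9-bit motif, shift magnitude 5 stationary standard deviations
($\theta$-difference $= 5\sigma/\sqrt{2\alpha}$ with $\alpha = 2$,
$\sigma^2 = 1$), 200 regions for recovery runs, 1,000 replicates for
calibration, 50 seeded runs for the discovery benchmark.

## 6. Divergent-motif discovery

`discoverMotifs()` performs one upper-tail hypergeometric test per
(PWM, model, direction) set with at least one predicted region, in log
space (overlaps this extreme underflow a naive sum), Bonferroni-corrects
over the tests actually performed, and ranks by adjusted then raw p with
**competition ranking**: sets with identical statistics share a rank.
That matters because of a structural non-identifiability: a gain planted
in one species is also, verbatim, a gain in every enclosing clade whose
model fires on the same regions — overlap counts cannot separate a clade
model from its sub-clade. The package's discovery benchmark therefore
compares mutually disjoint lineage models (melanogaster group, obscura
group, *D. virilis*), and users ranking nested models should read tied or
near-tied ranks as "this lineage or a sub-lineage". Direction matching is
deliberately not enforced — a gain input may legitimately enrich for
losses in the out-group. The universe $N$ defaults to the supplied region
catalog and is overridable, since published overlap tests are ambiguous
about their universe.

## 7. Known limitations

* $\chi^2_1$ LR p-values are anti-conservative at 12 tips (measured, see
  §3); use the parametric bootstrap for calibrated significance.
* Only two optima per fit (base + shift); no multi-regime mosaics, no
  measurement-error variance, no multivariate traits.
* The scorer is homotypic and 0th-order-background only; heterotypic
  clusters and higher-order backgrounds are out of scope.
* Nested-clade discovery ranks can tie (§6).
* The sequence generator is a non-phylogenetic null (§5).
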