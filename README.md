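# crmEvol

Detecting lineage-specific selection on cis-regulatory modules (CRMs)
across a phylogeny.

Transcription factor binding sites turn over quickly: an enhancer can gain
or lose a homotypic cluster of sites in one lineage while staying intact in
the others. `crmEvol` quantifies this by treating the **CRM score** of a
genomic region — the log-likelihood ratio that the region contains a
homotypic motif cluster rather than background sequence — as a quantitative
trait evolving along a rooted species tree, and asking which *selective
regime* explains the cross-species score profile best. It targets
comparative regulatory genomics: cross-species open-chromatin (FAIRE/ATAC),
ChIP-Seq or STARR-Seq studies that need to say *which factor's binding
diverged, in which lineage, and in which direction*.

## The model

**Scoring (the trait).** For a PWM with per-position base probabilities
`p_j(b)` and background frequencies `q(b)`, a region is scored with a
forward-algorithm HMM that sums over *every* parse of a subsegment into
motif occurrences (both strands) and background gaps, with a geometric
prior on gap lengths (default mean 35 bp). The CRM score is

    score = log2 [ P(best subsegment | cluster model) / P(best subsegment | background) ]

floored at 0; single strong matches count as one-site clusters.

**Evolution.** Each region × PWM trait vector `X` is fitted by maximum
likelihood under three nested views of evolution along the tree:

* **BM** (drift): `dX(t) = σ dB(t)`
* **M0** (one global optimum, stabilising selection):
  `dX(t) = α [θ − X(t)] dt + σ dB(t)`
* **M1–M10** (branch shift / Hansen models): the branches of one clade
  carry their own optimum `θ_shift`, all others `θ_base`. The ten built-in
  scenarios cover the classic clades of the 12 sequenced *Drosophila*
  genomes (melanogaster subgroup/group, obscura group, the *D. moj/vir/gri*
  radiation, and four single-species regimes).

`α` is the strength of selection (1/time), `σ²` the diffusion intensity,
`θ` the trait optimum. The root state is pinned to the root regime's
optimum, so BM has 2 free parameters, M0 has 3 and each branch-shift model
has 4 — the M0-vs-Mx likelihood-ratio statistic has 1 degree of freedom.

**Inference.** Models are compared per region by the LR test
(`2(logL_Mx − logL_M0)` against χ²(1)) and by Akaike weights
`w_i = exp(−Δ_i/2)/Σ exp(−Δ_r/2)`; a region is called *divergent* under Mx
when `wAIC(Mx) > wAIC(M0)`, with the shift direction (`gain`/`loss`) read
off `θ_shift − θ_base`. Power for a given region is assessed by parametric
bootstrap ("phylogenetic Monte Carlo"): simulate under each fitted model,
refit both, and compare the two distributions of
`δ = 2(logL_a − logL_b)`. Finally, *divergent motif discovery* takes an
experimentally divergent region set and ranks every (PWM, model,
direction) prediction set by hypergeometric overlap, Bonferroni-corrected.

## Worked example

Plant a 3-site cluster of an 8-bp motif (9.3 bits) into the *D. virilis*
copy of three synthetic ortholog panels, score, and test the *D. virilis*
shift model:

```r
library(crmEvol)
tr   <- drosophilaTree()
regs <- builtinRegimes(tr)                    # BM, M0, M1..M10
pwm  <- readJaspar(system.file("extdata", "example.jaspar",
                               package = "crmEvol"))[[1]]

panel <- genSequencePanel(tr, pwm,
           list(cladeTips = "Dvir", direction = "gain",
                nSites = 3, regionLength = 500, nRegions = 3), seed = 42)
sm <- scoreOrthologs(panelSequences(panel), pwm)
round(scoreValues(sm), 2)
#>            Dmel Dsim Dsec Dyak Dere Dana Dpse Dper Dwil Dmoj  Dvir Dgri
#> region0001 0.56 4.09 0.73 3.95 7.96 0.73 0.75 0.65 0.92 0.86  8.48 0.65
#> region0002 1.23 1.37 1.71 0.92 3.97 0.73 3.98 0.78 0.74 1.44 10.91 4.64
#> region0003 0.72 0.86 1.19 0.73 1.26 7.99 4.36 1.36 0.84 0.83  9.09 3.86

fits <- fitRegion(tr, scoreValues(sm)["region0001", ],
                  regs[c("BM", "M0", "M10")])
callDivergence(fits, mode = "pairwise", region = "region0001")
#>       region model  wAIC wAIC_M0   LR      p direction divergent
#> 1 region0001   M10 0.878   0.122 5.95 0.0147      gain      TRUE
```

The *D. virilis* copy scores 8.5 (log2) against ~1 elsewhere; the
branch-shift model M10 wins the pairwise Akaike-weight comparison (0.878
vs 0.122), the fitted optima are `θ_base = 2.0`, `θ_shift = 8.5`, and the
call is a *D. virilis*-specific **gain**. A parametric bootstrap
(`pmcPower(tr, trait, regs$M10, regs$M0, nBoot = 100, seed = 7)`) puts the
observed `δ = 5.95` well clear of the M0 null distribution
(distribution overlap 0.34).

Real analyses replace the synthetic panel with per-species FASTA files
(`readFastaPanel`), a JASPAR PWM collection (`readJaspar`), or skip
scoring entirely and feed any region × species trait table
(`readScoreMatrix`) — e.g. normalised chromatin accessibility — into
`fitRegion`/`divergenceTable`. A thin command-line front-end with
subcommands `score`, `fit`, `pmc`, `discover`, `simulate` lives at
`inst/cli/crmevol.R` (flat key=value configs, every flag overridable).

## Divergence database layout

`cmdFit`/`writeDivergenceDb` lay out one directory per PWM containing
`calls.tsv` (all per-region calls with wAIC, LR, p, BH-adjusted p,
direction) and one `<model>_<direction>.txt` region-id list per predicted
divergent set; `discoverMotifs`/`cmdDiscover` consume this layout.
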