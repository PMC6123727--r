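---
title: "Detecting, placing and dating introgression with f-statistics"
author: "introkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, placing and dating introgression with f-statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introkit)
```

## The problem

When formerly isolated lineages meet again — for example populations that
diverged in separate glacial refugia and re-expanded into contact — their
genomes record both the divergence and any subsequent interbreeding.
`introkit` implements the standard allele-frequency toolkit for reading
that record from whole-genome SNP data: drift statistics (f2, f3, f4)
with block-jackknife errors, a three-population admixture scan,
admixture-graph fitting that places a hybrid population onto a
non-admixed backbone, and a conversion of post-admixture drift into
calendar time. A graph-based frequency simulator and a forward
Wright–Fisher simulator make each stage testable without any real data.

## The drift model

All statistics live in the Gaussian (Brownian) approximation to genetic
drift. For populations $i, j$ with derived-allele frequencies $p_i, p_j$
at a biallelic site,

$$ f_2(i,j) = \mathbb{E}\,(p_i - p_j)^2 $$

is additive along the branches of a population tree. With path weights
$w_i(e) \in [0,1]$ — the fraction of leaf $i$'s ancestry that drifted
along edge $e$, splitting $\alpha : (1-\alpha)$ at admixture nodes — the
expected statistic under any admixture graph is

$$ f_2(i,j) = \sum_e d_e \,\bigl(w_i(e) - w_j(e)\bigr)^2, $$

where $d_e \ge 0$ is the drift length of edge $e$ in f2 units. f3 and f4
are linear combinations:

$$ f_3(C;A,B) = \tfrac12\left[f_2(C,A) + f_2(C,B) - f_2(A,B)\right],
\qquad
f_4(A,B;C,D) = \tfrac12\left[f_2(A,D) + f_2(B,C) - f_2(A,C) - f_2(B,D)\right]. $$

These identities are exact for the uncorrected (plain moment) sample
estimators, which is why the uncorrected form is the package default:
the identities then hold to machine precision on *any* input, which the
test suite exploits heavily. A significantly negative f3 proves the
target is admixed; f4 is zero in expectation for tree-concordant pairs
and measures excess allele sharing otherwise.

### Finite samples and the corrected estimators

With $n$ sampled allele copies, $\hat p$ carries binomial noise
$p(1-p)/n$, which biases $\hat f_2$ upward by $h_A/n_A + h_B/n_B$ and
$\hat f_3$ upward by $h_C/n_C$ (with $h = p(1-p)$). The `corrected`
estimators subtract the unbiased per-site terms
$\hat p(1-\hat p)/(n-1)$. Two defaults follow from this:

* `three_pop_scan()` uses **corrected** f3. With a handful of diploids
  per population, the target's sampling term can exceed a genuine
  admixture signal and mask it entirely; the corrected form is the
  standard three-population test.
* All f2 input to graph fitting (`run_full_analysis`, stage drivers) is
  **corrected**. In the graph, each leaf's bias $h/n$ is absorbed by its
  own pendant edge, so uncorrected f2 would inflate every pendant
  drift — including the hybrid's mixed drift, and with it the admixture
  date. f4 needs no correction: with four distinct populations the
  moment estimator is already unbiased.

### Uncertainty

Neighbouring SNPs are linked, so per-site variances understate the
error. Standard errors come from a weighted delete-one-block jackknife
over contiguous blocks of 50 SNPs within a pseudo-chromosome (block
size configurable), using the unequal-block-size formulas; Z-scores are
estimate/stderr. A block bootstrap (default 1000 replicates) supplies
percentile intervals where a full sampling distribution is wanted
(mixed drift, admixture proportion). Thresholds default to Z ≤ −3 to
flag an f3 target as admixed (the conventional three-population-test
cutoff) and |Z| ≥ 5 to call an f4 significant; both are arguments.

## Graph fitting and hybrid placement

`fit_graph()` minimises
$\sum_{\text{pairs}} \left[(\hat f_2 - f_2^{\text{graph}})/\text{se}\right]^2$
over $d_e \ge 0$ and $\alpha \in [0,1]$ for a fixed topology. The
objective uses the f2 basis only: f3 and f4 are linear in f2, so adding
them would add correlated residuals but no information. Weighting is by
jackknife stderr rather than a full covariance, which would be singular
with few populations. For fixed admixture proportions the expected f2
values are **linear** in the drifts, so the drifts are profiled out
exactly by non-negative least squares; the search over each proportion
is a dense grid (11 starts by default) plus bounded local refinement —
deterministic, and robust for the 1–2 admixture nodes these graphs
carry. Edges whose drift is pre-set (not `NA`) are held fixed.

`enumerate_hybrid_placements()` grafts the hybrid onto every unordered
pair of backbone edges (the two edges meeting at the root count once —
root placement cannot affect f2, an invariant the tests assert) and
ranks the fits. Attachment positions need no extra parameters: splitting
an edge leaves both halves free. Two caveats the package states rather
than hides:

* Some drift combinations are inherently confounded. The two root edges
  enter every pair identically (only their sum is identified), and
  post-admixture drift on the source branches is indistinguishable from
  mixed drift on the hybrid pendant ($d_X + \alpha^2 d_1 + (1-\alpha)^2
  d_2$ is what the data determine). The fitter therefore reports the
  hybrid's pendant drift as *the* mixed drift, with the source edges of
  the placement fixed at zero; the tests exhibit two parameterisations
  with identical expected f2 matrices.
* The fit score ranks placements; it is not a calibrated likelihood.

The default backbone is a neighbour-joining tree on the corrected f2
distances of the non-flagged populations, rooted at the outgroup; a
fixed topology can be supplied instead.

## From drift to calendar time

Drift accrues with time as $D = 1 - e^{-t/2N_e}$ ($t$ in generations,
diploid effective size $N_e$), inverted as
$t = -2 N_e \log(1-D)$ and scaled by the generation time (default
2 years). $N_e$ is always an explicit argument: the appropriate value
for a hybrid's pendant branch is the combined size of the contributing
source populations (the worked analyses use 375,000, the sum of
clade-level estimates of 250k, 75k and 50k for the source-side groups),
and no uncertainty in $N_e$ is propagated — `ne_sensitivity()` reports
the date across a user-chosen $N_e$ grid instead, since the date is
linear in $N_e$.

Fitted drift is in f2 units; the dating formula wants dimensionless
drift (fraction of heterozygosity lost). Since a pendant drift
$d = F\,h_{\text{anc}}$ and leaf heterozygosity
$h_{\text{leaf}} = (1-F)\,h_{\text{anc}}$, the conversion
$F = d/(h_{\text{leaf}} + d)$ uses only observables, with
$h_{\text{leaf}}$ estimated by the unbiased
$\hat p(1-\hat p)\,n/(n-1)$. Note `date_interval()` maps interval
endpoints monotonically, so a bootstrap interval on $D$ becomes an
interval on years directly.

## The synthetic study design

`make_refugial_scenario()` fixes the simulation the whole pipeline is
exercised on: an outgroup; a deeply diverged West lineage; East;
sister Beringia and NPC with NPC carrying the largest pendant drift
(F = 0.3, an island-bottleneck analogue); and a hybrid drawing
$\alpha = 0.6$ of its ancestry from the East lineage and 0.4 from
Beringia, with mixed drift F = 0.02. Internal drifts are 0.04–0.10,
pendant drifts 0.02–0.3; the ancestral frequency is uniform on
[0.05, 0.95]; sample sizes are 2–4 diploids per population (a small
whole-genome resequencing panel); per-call missingness is 2%. These
choices emulate a refugial phylogeography: deep inter-clade divergence,
one bottlenecked insular lineage, one admixed contact-zone population,
and few genomes per clade.

Frequencies evolve by a Balding–Nichols transition: child frequency
$\sim \text{Beta}$ with mean $p$ and variance $F p(1-p)$ (a
moment-matched Beta keeps frequencies in $[0,1]$ with no clipping bias;
fixed frequencies stay fixed; $F$ is the fraction of heterozygosity
lost, matching $1-(1-1/2N)^t$ in a Wright–Fisher population — asserted
against the forward simulator). Admixture is an instantaneous pulse,
$p_X = \alpha p_1 + (1-\alpha) p_2$, matching the one-event model the
f-statistics assume. Genotypes are Binomial(2, p) per diploid; sites are
independent (no LD) and laid out at 100 bp spacing on synthetic
scaffolds.

Because the process is a martingale with known second moments,
`graph_moments()` propagates $E[p_u p_v]$ exactly through the graph and
yields closed-form expected f2 values and heterozygosities;
`as_f2_graph()` converts the simulation's F-units to f2 units
($d_e = F_e h_{\text{parent}}$). This is the independent oracle the
Monte-Carlo tests compare against, and it agrees with the path-weight
algebra to machine precision.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: linkage disequilibrium (real blocks
of 50 SNPs are correlated; here block resampling is validated on
independent sites), ascertainment and genotyping error beyond random
missingness, continuous or recurrent gene flow, and selection.

## Numerical choices and degenerate inputs

* Filtering masks individual calls below DP/GQ thresholds (keeping the
  site), then applies site rules in a fixed order: multiallelic, indel,
  missingness, pooled MAF (missing calls excluded from the
  denominator), scaffold length, private alleles (minor allele carried
  by exactly one sample). MAF is computed before private-site removal;
  filtering is idempotent. Emptying the matrix warns, it does not error.
* LD thinning keeps the first site per tiled window anchored at
  coordinate 1; coordinates are 1-based throughout. Pseudo-chromosomes
  are built by greedy largest-first bin packing (deterministic and
  near-balanced).
* Sites with an undefined frequency in any population named by a
  statistic are dropped for that statistic only.
* The jackknife needs two blocks; with fewer, the stderr is reported as
  `NA` rather than guessed. The f4-ratio refuses denominators below
  1e-9. Non-negative least squares collapses exactly duplicated design
  columns (confounded edges) and falls back to a bounded quasi-Newton
  solve if the active-set solver hits a singular subset.
* Bootstrap percentile endpoints are widened minimally when optimiser
  granularity would otherwise exclude the point estimate.

## Problem sizes

The shipped analyses and tests run at sizes a laptop handles in
minutes: 100,000 independent sites for the study-condition checks
(detection across 20 seeds, admixture-proportion recovery), 200,000
sites for Monte-Carlo-versus-closed-form comparisons, 50 replicates of
20,000 sites for jackknife calibration, and 5,000 loci for the
Wright–Fisher oracle. At these sizes the detection and recovery results
are stable to the third decimal; larger runs only shrink the Monte-Carlo
noise.

## Interface choice

The package is organised as an analysis workflow: the numbered drivers
under `analysis/` run the stages (simulate → filter → f-statistics →
placement → dating) and write their tables under `results/`, while every
computation lives in exported functions so the same steps compose in R
(`run_full_analysis()` for the end-to-end path). No shell subcommand
wrapper is provided; the scripts and functions are the interface.

## Known limitations

* The placement search assumes exactly one admixture event for the
  hybrid; multi-way or recurrent admixture is out of scope.
* Dates inherit all the caveats of the drift clock: they are linear in
  the assumed $N_e$, and the MAF filter (which distorts the frequency
  spectrum) slightly perturbs the f2-to-dimensionless conversion — at
  the shipped study conditions the truth stays well inside the
  bootstrap interval, but the residual bias is not modelled.
* The f3/f4 orientation conventions follow the usual tables (outgroup
  first, hybrid second); rotating a pair flips the sign, and the
  reported placement $\alpha$ is the fraction inherited via the
  first-listed attachment edge.
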