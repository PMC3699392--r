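---
title: "Designing and using small ancestry-informative SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and using small ancestry-informative SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many genetic studies — candidate-gene association studies, historical
collections, forensic applications — need the continental origin and
admixture proportions of their subjects but cannot afford genome-wide
genotyping. A small panel of ancestry-informative SNPs (AISNPs), chosen for
extreme allele-frequency differences among continental regions, can recover
this information from a few dozen markers. `aimpanel` implements the full
workflow: scoring markers, assembling a multiplex-sized panel, quantifying
what the panel can distinguish, and estimating individual ancestry with it.

# Marker statistics

For a biallelic locus with counted-allele frequencies $p_1,\dots,p_K$ in $K$
groups, the informativeness for assignment is the entropy difference

$$
I_n \;=\; \sum_{j\in\{\text{allele},\;\text{other}\}}
\Bigl(-\bar p_j \ln \bar p_j \;+\; \tfrac1K \sum_{i=1}^{K} p_{ij}\ln p_{ij}\Bigr),
\qquad \bar p_j = \tfrac1K\sum_i p_{ij},
$$

with $0\ln 0 := 0$. It is zero iff all groups share a frequency and bounded
by $\ln K$. We use natural logarithms throughout (the convention of the
standard implementation of this statistic); rescale by $1/\ln 2$ for bits.
Groups enter unweighted — region sample sizes do not weight the mean — and
group frequencies are computed from individuals pooled by region, not by
averaging population-level frequencies. The pairwise statistic
$\delta = |p_i - p_k|$ is the classic two-group criterion; for a biallelic
marker it equals half the $L_1$ distance over both alleles. Loci with an
undefined frequency in any group (zero non-missing calls) are excluded from
scoring rather than imputed.

# The selection pipeline

`run_pipeline()` chains five stages, each exposed as its own function:

1. **Candidate filtering** (`filter_candidates`): autosomal loci with a
   strand-unambiguous allele pair (A/C, A/G, T/C, T/G — never A/T or C/G,
   which cannot be reconciled across platforms), optionally restricted to
   markers present on the genotyping array.
2. **Top-$I_n$ capping** (`rank_markers`): keep the `top_n_by_In` most
   informative loci (default 5,000). Ties are broken by locus id so the cut
   is deterministic.
3. **LD pruning** (`vif_prune`): sliding window (default 50 SNPs, step 5);
   within a window, while any locus has variance inflation factor
   $\mathrm{VIF} = 1/(1-R^2) > 1.5$ ($R^2$ from regressing its mean-imputed
   dosage on the other retained window loci), the worst locus is removed
   permanently. VIF ties remove the later locus in map order. The default
   window suits genome-scale data with hundreds to thousands of samples;
   with few samples the chance multiple correlation of one locus on $m$
   others grows like $m/n$, so scaled-down analyses should scale the window
   down as well (our tests use windows of 10–20 SNPs at $n \approx 200$).
4. **Top-$\delta$ claiming** (`select_top_delta_per_pair`): each of the
   $\binom{K}{2}$ group pairs, processed in a fixed order (ascending first
   then second group index), claims the `per_pair` (default 10) highest-δ
   markers not yet claimed by an earlier pair. With enough distinct markers
   the union holds exactly `per_pair` × pairs loci (210 for $K=7$). The
   claiming rule is one consistent reading of "top ten per pair yielding
   210"; keeping pairs disjoint maximizes the panel's coverage and makes
   provenance unambiguous.
5. **Reduction to multiplex size** (`reduce_panel`): the real-world
   reduction is driven by assay chemistry that cannot be reproduced in
   software, so the package optimizes a proxy objective that preserves the
   design intent — every pair keeps several high-δ markers. The objective is
   the minimum over pairs of the sum of each pair's top-3 retained δ values.
   Small problems (≤ 20,000 candidate subsets) are solved exactly by
   enumeration; larger ones by greedy backward elimination. An
   `exclusion_list` lets users encode genuine assay constraints. Ties break
   by lower $I_n$, then locus id.

Every stage is deterministic given its inputs, so a pipeline rerun under the
same configuration is bit-identical; provenance (admitting stage, claiming
pair, δ at admission) is kept per marker.

# Differentiation statistics

Pairwise $F_{ST}$ uses the Weir–Cockerham (1984) estimator: per-locus
variance components $a$ (among groups), $b$ (among individuals within
groups) and $c$ (within individuals, from observed heterozygosity — the
genotype-aware form, since genotypes rather than haplotypes are available),
combined over loci as a ratio of sums $\hat\theta = \sum a / \sum(a+b+c)$.
Negative estimates are reported as computed (a floor-at-zero flag exists);
users comparing against AMOVA-based software should expect small numerical
differences of estimator family, on the order of ±0.01 for well-sampled
groups. Significance comes from permuting individuals between the two groups
with sizes preserved; all permutation p-values use the $(b+1)/(n+1)$
convention and are therefore never exactly zero. The Mantel test between two
distance matrices correlates lower-triangle entries and jointly permutes
rows and columns of the second matrix with a two-sided $|r|$ criterion —
conventions chosen for symmetry with the other permutation tests (common
implementations are one-sided, so p-values may differ; the statistic $r$
does not).

# The admixture model

The ancestry engine is a maximum-likelihood replacement for the usual
Bayesian MCMC clustering: the quantity of interest (the membership matrix
$Q$) is the same, but estimation is deterministic and testable. Each
individual's two allele copies at locus $l$ independently draw an ancestral
cluster from $q$ and then the counted allele with probability $p_{lk}$, so
for dosage $g_l$ over non-missing loci

$$
\ell(q) = \sum_l \Bigl[ g_l \ln \textstyle\sum_k q_k p_{lk}
 + (2-g_l) \ln \sum_k q_k (1-p_{lk}) \Bigr].
$$

`admixture_fit()` maximizes this by EM. Supervised mode fixes $p_{lk}$ at
reference-panel estimates (pseudocount 0.5, Jeffreys-like; frequencies
clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, so the
likelihood never sees 0 or 1) and fits each sample independently
(tolerance $10^{-7}$ on the log-likelihood, at most 2,000 iterations).
Unsupervised mode alternates the same per-sample update with a
responsibility-weighted update of $p_{lk}$, from 10 random
Dirichlet$(1,\dots,1)$ starts by default (tolerance $10^{-6}$, 500
iterations), keeping the best final likelihood; the first $p$ update uses
$q$-weighted allele frequencies as a starting point. The log-likelihood is
non-decreasing at every step in both modes — asserted in tests. Loci are
treated as independent, which is consistent with a VIF-pruned panel. Label
switching across replicate runs is resolved by `align_replicates()`, an
exhaustive search over the $K!$ column permutations maximizing row inner
products with the first run ($K \le 10$).

Cluster assignment uses a strict membership cutoff: a sample joins cluster
$k$ iff $q_k >$ threshold (conventionally 0.85 or 0.5), otherwise it is
unassigned; a 50/50 sample at threshold 0.5 stays unassigned. Strictness is
a choice — published descriptions of such cutoffs rarely specify the
boundary — and makes assignment sets nested across thresholds.

# The simulator

`simulate_scenario()` provides a truth-known test surface. Ancestral
frequencies are uniform on $[0.1, 0.9]$; region frequencies follow the
Balding–Nichols model, $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, whose divergence parameter $F$ equals the
expected $F_{ST}$ against the ancestral pool. Genotypes are drawn gene-copy
by gene-copy from each sample's true $q$; missingness is i.i.d. The default
configuration mirrors a seven-region continental study: $F = (0.15, 0.03,
0.03, 0.05, 0.10, 0.20, 0.18)$ for Africa, Middle East, Europe, CS Asia,
E Asia, Americas, Oceania — chosen so Eurasian pairs are least
differentiated, echoing the qualitative ordering of published continental
$F_{ST}$ tables (illustrative, not fitted) — with 50 samples per region,
2,000 loci, and two admixed series (Africa/Europe and Americas/Europe, minor
fraction 0.05–0.95). The 2,000-locus default keeps a full pipeline run in
tens of seconds; it stands in for a genome scan two orders of magnitude
larger, so simulated panels have a smaller score range (top $I_n \approx
0.2$) than panels mined from real genome-wide data.

What the simulator does *not* emulate: linkage disequilibrium (the panel is
LD-pruned by construction and the likelihood assumes independent loci),
clinal frequency gradients within regions, genotyping error, and the extreme
single-marker frequency differentials that 600k-marker scans of real human
data turn up. Passing tests therefore demonstrate correctness of the
estimators and the pipeline mechanics under the stated model, not
performance guarantees on any particular real cohort.

# What the panel can and cannot do

Two limitations documented by studies of such panels reproduce here as
properties:

- **Eurasian resolution.** Regions at $F \approx 0.03$–$0.05$ (Middle East,
  Europe, CS Asia in the default scenario) yield low pairwise $F_{ST}$ on
  the selected panel and strict-cutoff (85%) assignment fractions far below
  those of strongly diverged regions; at the 50% cutoff the strongly
  diverged regions ($F \ge 0.10$) assign correctly for >90% of samples.
- **Low admixture.** A 41-marker panel estimates a minor ancestry fraction
  of 0.1 with a *relative* RMSE several times larger than a balanced 0.5
  mixture. Note the absolute RMSE is *smaller* at $q = 0.1$: the simplex
  boundary truncates the error distribution. Claims about insensitivity to
  low-level admixture are therefore formulated (and tested) on the relative
  scale.

# Numerical and convention choices

- Counted allele = `allele_a` = first allele observed in file order for
  PED/MAP (REF for VCF) unless a counted-allele map is supplied; every
  output table records it, so frequency tables from different sources can be
  reconciled. All statistics are invariant to the choice.
- Half-missing PED genotypes are treated as fully missing (conservative).
- The region set is configurable (default 7; add e.g. "Siberia" via
  `default_regions(extra=)`) because real cohorts contain populations that
  fit no default cluster.
- PCA uses the posterior-frequency normalization of the standard
  population-genetics PCA software — center $2\hat p$, scale
  $\sqrt{\hat p(1-\hat p)}$ with $\hat p = (1+\text{count})/(2+2n)$, missing
  set to 0 after centering, monomorphic loci dropped — and orients each
  component so its largest-magnitude loading is positive, making output
  deterministic. Classical MDS of identity-by-state distances double-centers
  and eigendecomposes, dropping negative eigenvalues with a warning (IBS
  distances are not Euclidean).
- Singular regressions inside `vif_prune` fall back to a pseudoinverse;
  exactly collinear loci get infinite VIF. Monomorphic loci have VIF 1.
- All seeded helpers save and restore the caller's RNG state.

# Problem sizes

The test suite and the acceptance script run everything at desk scale:
simulated scenarios of 60–5,000 loci and 10–50 samples per region, panels of
9–41 markers, 199–10,000 permutations, 200-replicate calibration of the
permutation test. These sizes were chosen so the full suite completes in
about a minute while every statistical claim is still measurable; the same
code paths run unchanged on genome-scale inputs.
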