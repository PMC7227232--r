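---
title: "Multi-statistic selection scans with sweepscan: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-statistic selection scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A selective sweep drives a beneficial variant — and the haplotype it sits on
— to high frequency in a population, leaving a local footprint: reduced
nucleotide diversity, an excess of one or two long frequent haplotypes, a
skewed site-frequency spectrum, and elevated allele-frequency
differentiation against related populations. No single statistic captures
all of these, and each has its own false-positive modes. `sweepscan`
implements a composite scan for dense SNP genotype data from many
populations (breeds, in its motivating livestock setting): five per-breed
statistics are combined into one de-correlated composite (DCMS), an
orthogonal single-SNP FLK test contrasts allele frequencies against a
drift-tree null, and both feed one region-calling and gene-ranking rule.

# The statistics

All statistics are computed per breed and aligned to a single
variant grid so they can be combined locus by locus.

* **H1 and H12** (`scan_h_stats`): over sliding windows of 25 consecutive
  SNVs (step 1), haplotypes are compared as exact allele strings and their
  frequency spectrum $p_1 \ge p_2 \ge \dots$ computed. $H1 = \sum_i p_i^2$
  is haplotype homozygosity; $H12 = (p_1 + p_2)^2 + \sum_{i \ge 3} p_i^2$
  pools the two most frequent haplotypes, gaining power when an incomplete
  or soft sweep segregates as two frequent haplotypes. The window value is
  anchored at the centre SNP; the first and last 12 SNPs of a chromosome
  are undefined. Any window touching a missing haplotype entry is undefined
  rather than imputed (`mismatch_allow = 0`), which is why these statistics
  require phased, fully called haplotypes.
* **Tajima's D** (`tajima_d_windows`): on the same 25-SNV windows,
  $D = (\hat\pi - S/a_1) / \widehat{sd}$ with the standard constants
  $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ for $n$ haplotypes. Monomorphic
  windows ($S = 0$) are undefined. We compute D on the same windows as
  H1/H12 so that every statistic lives on the same per-SNP anchor grid.
* **F_ST** (`fst_one_vs_rest`): the Weir–Cockerham (1984) two-population
  variance-component estimator $\hat\theta = a/(a+b+c)$, with the focal
  breed against the pooled remainder of the dataset. Negative estimates are
  truncated to zero, then the track is smoothed per chromosome with a
  31-SNP running median ("constant" end rule) to reduce per-SNP sampling
  noise — in that order.
* **π** (`site_pi`): per-site mean pairwise difference
  $n_{ref} \, n_{alt} / \binom{n}{2}$ over the breed's called alleles,
  smoothed with the same 31-SNP running median.

# The DCMS composite

Each statistic is converted to genome-wide empirical one-tailed p-values
(`rank_pvalues`): right-tailed for H1, H12 and F_ST (large values are
sweep-like), left-tailed for π and Tajima's D. With $n$ defined values the
denominator is $n + 1$, keeping $p$ strictly inside $(0, 1)$ so the
log-odds transform below stays finite.

**Tie handling.** Ties take midranks: half of a tied mass counts as
extreme. This matters more than it may look. A 25-SNV haplotype statistic
over $2N$ haplotypes takes few distinct values — with 40 haplotypes and
little linkage, most windows sit exactly at the all-distinct floor
$H1 = 1/40$. If the whole tied mass counted as non-extreme, those SNPs
would receive $p \approx 1$ (a log-odds score of about $-10$) while a
single duplicated haplotype in the window would jump the score by $+10$,
making the composite's null distribution bimodal and its normal fit
meaningless. Midranks map the tied mass to $p \approx 0.5$ and keep the
composite's null unimodal. The fully-extreme counting rule remains
available as `ties = "extreme"`.

The composite at locus $l$ is
$$\mathrm{DCMS}_l = \sum_{i=1}^{k} \frac{1}{s_i}
  \log\frac{1 - p_{l,i}}{p_{l,i}}, \qquad s_i = \sum_j |r_{ij}|,$$
where $r_{ij}$ is the correlation between statistics $i$ and $j$ estimated
robustly: the covariance of the five statistics over up to 300,000 randomly
sampled complete SNP rows by the Minimum Covariance Determinant with subset
fraction $\alpha = 0.75$ (`fit_robust_covariance`). The weights $s_i \in
[1, k]$ discount duplicated evidence — two perfectly correlated statistics
each get weight $1/2$, so duplicating a statistic leaves the composite
unchanged (an identity the test suite checks numerically).

Significance then follows the robust-normal route
(`fit_normal_robust` → `normal_pvalues` → `storey_qvalues`): an
intercept-only Huber M-estimate (tuning constant 1.345, relative tolerance
$10^{-8}$, at most 50 iterations; scale = the fit's MAD-anchored robust
residual scale) gives $\mu$ and $\sigma$ insensitive to the outlying
selected fraction; upper-tail normal p-values of the Z-transformed
composite follow; Storey q-values correct for multiple testing, with
$\hat\pi_0$ estimated on the $\lambda$ grid $0.05, 0.10, \dots, 0.95$ by a
cubic smoother evaluated at the grid's end and clamped to $(0, 1]$. With
fewer than 100 p-values $\pi_0$ falls back to 1, which reduces exactly to
Benjamini–Hochberg.

# The FLK engine

FLK asks whether a SNP's allele frequencies across populations are more
dispersed than neutral drift allows. The null is encoded in a kinship
matrix $F$ built from the data:

1. **Reynolds distances** (`reynolds_distances`):
   $D_R(a,b) = \sum_l (p_{al} - p_{bl})^2 \big/ \sum_l (p_{al} + p_{bl} -
   2 p_{al} p_{bl})$. By default the numerator subtracts the finite-sample
   terms $\hat p(1-\hat p)/(m-1)$ for each population. Without them, sample
   frequencies from $m$ alleles inflate every distance by roughly $1/m$ —
   at 40 alleles per breed that is $+0.025$ on distances whose true scale
   is $0.05$–$0.15$, enough to visibly distort the kinship. The plug-in
   form is available with `correct = FALSE`.
2. **Tree building** (`nj_tree`, `midpoint_root`): neighbour joining on
   $2 D_R$, then midpoint rooting. The doubling matters: under pure drift
   $E[D_R] \approx (F_{ii} + F_{jj} - 2F_{ij}) / 2$, i.e. Reynolds
   distances are *half* the drift-scale patristic distance, so the tree is
   rescaled before branch lengths are read as drift amounts.
3. **Kinship** (`kinship_from_tree`): $F_{ij}$ is the summed length of the
   branches shared by the root-to-$i$ and root-to-$j$ paths; $F_{ii}$ the
   total root-to-leaf drift. A pure star polytomy is accepted as a rooted
   star (the natural reading for populations radiating from one ancestor);
   an unrooted tree with internal structure is rejected.

The test itself (`flk_test`) uses the generalised-least-squares ancestral
frequency $\hat p_0 = (\mathbf 1' V^{-1} \hat p)/(\mathbf 1' V^{-1}
\mathbf 1)$ and
$T = (\hat p - \hat p_0 \mathbf 1)' [\hat p_0 (1 - \hat p_0) V]^{-1}
(\hat p - \hat p_0 \mathbf 1)$, which is $\chi^2_{k-1}$ under neutral
drift. When per-population allele counts $m_i$ are available (the default
takes their per-population medians), $V = F + \mathrm{diag}((1 -
F_{ii})/m_i)$: the binomial sampling variance of observed frequencies is
part of the null. Omitting this term (with 40 alleles per population and
drift 0.05, sampling noise is half as large as drift noise) inflates the
nominal 5% rejection rate to roughly 14%; with it, simulated type-I error
sits at 4–5%.

Following the scan's overall design, region calling uses not the $\chi^2$
p-values but the same robust-normal → q-value post-processing as DCMS
(`flk_pvalues`), which also applies unchanged to externally computed
hapFLK tracks ingested with `read_hapflk_track`. The haplotype-cluster
hapFLK likelihood itself (fastPhase-style EM) is out of scope here: the
engine computes single-SNP FLK natively and post-processes external
hapFLK output.

# Regions and candidate genes

`call_regions` scans each chromosome for maximal runs of consecutive SNPs
with $q \le 0.1$ containing at least one SNP with $q < 0.01$; the run's
first and last SNP positions bound the region (a single-SNP run is a 1-bp
region), and runs never cross chromosomes or undefined q-values. Both
thresholds are arguments.

`identify_genes` implements a drop-from-peak rule: the gene window is the
maximal contiguous SNP run containing the peak in which every SNP's
statistic stays within $1\sigma$ of the peak value, where $\sigma$ is the
genome-wide robust scale of the statistic and the multiplier is
configurable. A sharp single-SNP peak thus reports only genes spanning the
peak, while a plateau of uniformly extreme SNPs reports genes across the
plateau. `rank_genes` orders genes by distance from the peak SNP (0 if the
gene spans it; ties broken by gene start, then identifier), and the region
writer collapses runs of three or more same-prefix numbered genes to a
cluster shorthand (`KRT@ (1-3)`).

# The synthetic-data generator

`simulate_neutral` draws, per SNP, an ancestral frequency $p_0 \sim
U(0.05, 0.95)$ and per-breed frequencies from the Balding–Nichols Beta
distribution with drift $F$; haplotype alleles are independent Bernoulli
draws per site. `simulate_tree_drift` runs the same Beta step along each
branch of a rooted drift tree, recording the true kinship.
`inject_sweep` copies one carrier haplotype over a random subset of a
breed's haplotypes inside a chosen window until it reaches the target
frequency — a hard-sweep caricature with an exact truth window and no
change outside it. `inject_missingness` and `make_annotation` complete the
fixtures (missing genotypes drop the haplotype matrix, since haplotypes
never carry missing entries; one gene is forced into every truth window).

Default study conditions are 20 diploid individuals per breed — 40
autosomes, a realistic and deliberately small per-breed sample for
multi-breed array studies — a handful of breeds with drift around
0.05–0.1, and array-like inter-SNP spacing (geometric gaps, mean 4 kb).
The test suite and the acceptance script use 2–4 breeds at 20,000 SNPs
(50,000 for kinship recovery), sizes chosen so every property is measured
on a single CPU in minutes.

**What the generator does not emulate.** Sites are in linkage equilibrium
outside sweep windows. Real dense-array data has pervasive LD, which makes
the H1/H12 background continuous and higher; under LE the background sits
at the all-distinct floor and is strongly tied (the midrank design above
exists because of this). There is also no recombination map, no soft
sweeps, and the Balding–Nichols site-frequency spectrum is not the neutral
coalescent SFS — windowed Tajima's D is systematically positive on these
simulations (diversity is drawn toward intermediate frequencies), which is
immaterial for the rank-based composite but means "D near zero" holds only
for coalescent-SFS windows, which the tests generate separately.

# Calibration and recovery behaviour, measured

The test suite and `scripts/acceptance.R` recompute these from scratch:

* FLK against the true star kinship on neutral data (4 breeds × 20
  diploids × 20,000 SNPs): $\chi^2_3$ rejection at nominal 0.05 lands at
  0.042–0.045 (slightly conservative: Beta drift is not exactly normal).
* The full DCMS pipeline on the same neutral data: the fraction of SNPs at
  $q < 0.01$ is about 0.1–0.2% per breed.
* Mean one-vs-rest F_ST at drift 0.1 agrees with an independently coded
  Weir–Cockerham oracle over replicate simulations to under 0.001.
* The kinship matrix of a 4-population balanced drift tree is recovered
  from 50,000 SNPs with maximum entrywise error below 0.01.
* All 10 injected hard sweeps (50 SNPs, final frequency 0.95) are
  recovered with region peaks inside the truth windows.

**Known limitation — false regions under many discoveries.** The composite
is a weighted sum of logit-transformed uniform p-values: its null tail is
logistic-like, heavier than the normal fitted to its bulk, so upper-tail
normal p-values are anti-conservative at $z \gtrsim 3$. On fully neutral
data this matters little (the q-value step absorbs it). But when thousands
of truly swept SNPs enter the ranking, the q threshold at $q < 0.01$
relaxes to raw $p \sim 10^{-3.5}$, exactly where the tail misfit lives: in
the sweep-recovery simulations each breed accrues on the order of 20–30
small false regions alongside the perfectly recovered sweeps. This is a
property of the normal-fit-plus-FDR design itself, not of a particular
implementation choice; the honest mitigation on real data is LD-aware
follow-up of small isolated regions (most false regions here span 1–8
SNPs, while true sweep regions span dozens). The single-SNP FLK q-track
shows the same pattern, amplified by its $\chi^2_1$-like skew; sweep
windows still stand out by 10–50 orders of magnitude in $q$.

# Numerical and degenerate-input choices

* Missingness sentinel is `NA` throughout; any statistic that cannot be
  computed (short chromosome, monomorphic window, empty pool) yields `NA`,
  and `NA` q-values break region runs.
* MCD needs a non-singular h-subset. Exactly collinear statistic columns
  are collapsed before estimation and re-expanded (their correlation is 1
  by construction); a heavily zero-inflated column (median-smoothed F_ST
  can be mostly zeros on weakly differentiated simulated data) can still
  defeat it, in which case the classical covariance of the sampled rows is
  used with a warning. Univariate MCD (k = 1) is computed exactly — the
  minimum-variance contiguous sorted subset — and rescaled by the standard
  normal-consistency factor.
* QC filter order is autosome restriction, then sample missingness, then
  locus missingness (recomputed on surviving samples), then MAF, mirroring
  standard genotype toolkits; the per-step report makes other orders
  auditable. MAF is computed on the dataset being filtered, so per-unit QC
  is "slice first, then `apply_qc`".
* Negative NJ branch lengths are clamped to zero with a warning. The
  2-population "tree" is the midpoint-split single edge.
* Rank p-value denominators use $n + 1$; DCMS treats exact 0 or 1 as an
  error since the rank construction cannot produce them.
* All randomness flows from explicit integer seeds (`SimConfig$seed`, the
  MCD `seed`, per-operation seeds for sweeps and missingness); identical
  seeds give bit-identical datasets, models and q-tracks.
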