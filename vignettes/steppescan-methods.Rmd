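---
title: "Selection scans and their synthetic testbed: models, conventions, limits"
author: "steppescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans and their synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(steppescan)
```

# What the package computes

`steppescan` implements the statistics of a multi-population genome scan
for recent positive selection on SNP-array data, together with the
population-structure utilities such a study needs and a synthetic-data
generator rich enough to exercise every stage.  The motivating setting
is an admixed highland population: haplotype-based scans (iHS within a
population, XP-EHH against a lowland reference) find sweeps at
intermediate and high frequency, allele-frequency-based scans (the
population branch statistic and a multiple-regression divergence score)
control for admixture, candidate regions are called from genome-wide
empirical distributions, and a hemoglobin-concentration association
stage asks whether candidate haplotypes shift the adaptive phenotype.

This vignette records the models, the conventions that the formulas do
not pin down by themselves, the design choices that were genuinely open,
and what the synthetic generator can and cannot establish.

# Haplotype statistics

## EHH

For a core SNP and a class of carrier haplotypes (derived-allele
carriers, ancestral-allele carriers, or all haplotypes), the extended
haplotype homozygosity at a flanking marker $m$ is the probability that
two random carriers are identical at every site from the core to $m$:

$$\mathrm{EHH}(m) = \frac{\sum_h \binom{n_h}{2}}{\binom{n_c}{2}},$$

where the $n_h$ count distinct extended haplotypes among the $n_c$
carriers.  Conventions:

* EHH at the core itself is 1 by definition.
* A missing allele breaks identity permanently: the haplotype moves to a
  singleton class and never rejoins.  This is conservative — missing
  data can only lower homozygosity.
* Fewer than two carriers leaves the curve undefined (flagged, not
  dropped).

The implementation (partition refinement in C++) is tested for exact
equality against an exhaustive pair-enumeration oracle on a thousand
random panels.

## iHH and iHS

iHH is the trapezoidal integral of the EHH decay curve over genetic
distance, out to **and including** the first marker whose EHH is at or
below the truncation threshold (0.10 for iHS); there is no
interpolation beyond observed markers.  The inclusive-endpoint rule is
the simplest defensible one and is frozen so the integration oracle and
the implementation agree.  Distance is the genetic-map position when a
map is supplied and physical distance at 1 cM/Mb otherwise; which of
the two a run used is recorded by the caller, since published scans
rarely state it.  A core whose EHH never decays to the threshold before
the chromosome end is dropped (flagged invalid) rather than truncated
at the end: truncating would bias its iHH downward and fabricate a
spurious score.

Raw iHS at a site is $\ln(\mathrm{iHH}_A / \mathrm{iHH}_D)$ with both
directions summed within each allele class before the ratio.  Sites
need a known ancestral state and pass a minor-allele-frequency floor
(default 0.05; the floor any EHH statistic effectively requires, since
a two-carrier class has an essentially unmeasurable decay curve).
Scores are standardized within derived-allele-frequency bins of width
0.025; bins with fewer than 20 scores merge into their right-hand
neighbour (the last occupied bin merges leftward) until all bins are
viable.  The bin scheme is exposed because no standard reference fixes
it; the merge rule is deterministic by construction.  Negative
standardized iHS marks unusually long derived haplotypes.

## XP-EHH

XP-EHH compares whole panels, so it needs no ancestral polarity: per
site, EHH is computed over all haplotypes within each population, both
integrals are truncated where the **pooled** two-population EHH reaches
0.05, and the raw score is $\ln(\mathrm{iHH}_\mathrm{target} /
\mathrm{iHH}_\mathrm{reference})$, standardized genome-wide.  Positive
scores mean longer haplotypes — more recent coalescence — in the
target.  Truncating both populations at the same pooled marker keeps
the two integrals commensurable; truncating each at its own threshold
would bias the ratio toward zero.

# Frequency statistics

## F_ST

The default estimator is Hudson's, in ratio-of-averages form
(mean numerator over SNPs divided by mean denominator over SNPs):

$$\hat F_{ST} = \frac{\overline{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1}
- \frac{p_2(1-p_2)}{n_2-1}}}{\overline{p_1(1-p_2) + p_2(1-p_1)}}$$

with $n_i$ the allele sample counts.  It is robust to unequal sample
sizes and to the ratio-of-averages/average-of-ratios distinction that
plagues per-SNP estimators.  A Weir–Cockerham variant is available
behind a flag; because the frequency table carries no heterozygosity,
it is the allele-count (haploid-sample) form, which for two populations
of equal size coincides numerically with Hudson's — the flag exists for
completeness, not because the two differ materially here.

## PBS and its scale

The population branch statistic for target $A$ against references $B$,
$C$ is

$$\mathrm{PBS}_A = \tfrac{1}{2}\left(T_{AB} + T_{AC} - T_{BC}\right),
\qquad T = -\ln(1 - F_{ST}),$$

computed per SNP from single-SNP Hudson estimates with two clamps:
negative estimates to 0 (they otherwise make $T$ undefined in spirit)
and $F_{ST}$ to $1 - 10^{-9}$ (they otherwise make $T$ infinite).
Negative PBS is legal and meaningful (excess drift shared by the
references).

One scale property deserves emphasis because it is easy to
misread: any pairwise two-sample $F_{ST}$ estimator — Hudson's
included — estimates the **average** of the two populations' branch
drifts, not their sum.  Under a drift model where the target branch has
Balding–Nichols parameter $F_t$ and the references $F_r$, the expected
pairwise estimates are $(F_t+F_r)/2$ and $F_r$, so the mean per-SNP PBS
converges on $\tfrac{1}{2}(2\,T(\tfrac{F_t+F_r}{2}) - T(F_r)) \approx
F_t/2$, i.e. **half** the target branch parameter.  PBS is a ranking
statistic and this global scale does not affect candidate calling, but
any comparison of PBS magnitudes against branch-length expectations
must use the halved scale.  The test suite pins the implementation to
this analytic value; a companion check states the naive (unhalved)
expectation and is expected to stay red.

## The MR divergence score

The target population's derived-allele frequencies are regressed by
OLS (SNPs as observations, intercept included) on the frequencies of a
panel of reference populations; the MR Score of a SNP is the
externally studentized residual of observed vs predicted frequency.
External studentization (leave-one-out residual variance) is the
standard outlier-scoring choice and makes null scores
t-distributed — the calibration the test suite checks.  Tail
membership is two-sided on $|$score$|$ (selection can push a frequency
either way) at the 5%, 1% and 0.5% empirical quantiles of all
gene-region SNPs.  Per gene (transcribed span ±10 kb, clipped at
position 0), the MR Factor is the gene's tail proportion divided by the
global gene-region tail proportion; genes with at least 10 scored SNPs
are ranked by factor (ties broken by tail count, then label) and the
empirical p is rank/(number ranked) with maximum-rank ties — so
all-equal factors give everyone p = 1, and "top 2%" means p ≤ 0.02.

# Region aggregation and overlap

Windows are fixed 200-kb tiles anchored at position 0 on every
chromosome (the anchor is a convention; nothing in the statistics picks
one), the terminal partial window retained but flagged.  A SNP at
1-based position $p$ belongs to the window with
$\lfloor p / w \rfloor$; the boundary SNP at $p = w$ therefore falls in
the second window.  Region statistics are the signed maximum score (XP-EHH,
PBS; an absolute-maximum flag exists because published "max score"
language rarely says which) or, for iHS, the fraction of SNPs with
$|$iHS$| > 2.0$ among windows with at least 5 scored SNPs.  Empirical
p-values are one-sided high with ties sharing the maximal count
(minimum attainable p is 1/#regions); candidates are regions with
p < 0.02.

The cross-population overlap null redraws, per population, a uniform
random subset of the region universe matching that population's
candidate count, and records the intersection size; the p-value uses
the add-one convention $(r+1)/(n_\mathrm{sims}+1)$, so a "p = 0"
observation is reported as p < 1/n_sims rather than as an impossible
zero.

# The phenotype stage

Group-summary t-tests (for published tables that report only mean, SD,
n) default to Welch; the pooled variant exists because rounded
summaries reproduce published p-values only approximately under either
variant, and which one a study used is often unstated.  Haplotype
copies are counted from phased data as the number of an individual's
haplotypes matching the selected allele at all three core SNPs; a
missing allele makes that haplotype "unknown" and flags the individual
rather than guessing.  Stepwise regression uses forward selection by
smallest partial-F p below 0.05 and backward elimination above 0.10
(the common default of the numerical environment such analyses are run
in), with ties broken by column order so the procedure is deterministic
and idempotent.

# The synthetic world

The generator exists so that every stage is testable without restricted
genotype data.  Its defaults are one fixed stated world, chosen once:

* **Balding–Nichols frequencies** (`sim_balding_nichols`): ancestral
  frequencies uniform on (0.05, 0.95) — array-like common variants —
  population frequencies Beta-distributed with variance $F p(1-p)$,
  genotypes binomial.  This is the exact null model of the F_ST, PBS
  and MR recovery tests.
* **Forward Wright–Fisher haplotypes** (`sim_wf_haplotypes`): 1,000
  haplotypes × 5,000 sites on a 15-Mb chromosome.  The panel descends
  from 40 founder haplotypes whose derived-allele counts are uniform
  (mimicking the common-variant ascertainment of genotyping arrays; a
  neutral 1/k spectrum would put most sites under the iHS MAF floor),
  with 60 generations of neutral burn-in.  The recombination rate is
  rescaled upward to 1e-7 per bp per generation so that this
  shallow genealogy reproduces the LD decay length a human-depth
  genealogy (~10⁴ generations at 1 cM/Mb) would show — the standard
  rescaling trick of desk-scale forward simulation.  Deeper burn-in
  was deliberately rejected: drift in a small panel manufactures
  recently coalesced haplotype pairs that mimic sweeps and mask real
  ones.
* **Sweeps**: the derived allele at the site nearest the chromosome
  midpoint is re-seeded as a single new copy with multiplicative
  fitness 1+s (a hard sweep) and the run is conditioned, by restarting
  the selected phase from the same burned-in panel, on reaching the
  target frequency; runs that fail to establish early are also
  restarted.  Conditioning by restart biases accepted runs toward fast
  sweeps — documented, and in fact the regime where haplotype tests
  have power.  Injecting a standing variant at 5–20% instead produces a
  soft sweep whose carriers do not share recent ancestry; the iHS
  signal all but vanishes.  That failure mode was observed directly and
  is why the generator seeds sweeps from a single copy.
* **Phenotypes** (`sim_phenotypes`): [Hb] = 13.5 g/dL baseline, 1.4
  g/dL residual SD (values in the range published for highland
  populations), a small age effect, non-smoking females — the
  composition of the phenotype stage this emulates.

What the generator does **not** emulate: real array ascertainment
schemes, genotyping error, demographic history (bottlenecks,
expansions, migration), variable recombination maps, and phasing error.
A green sweep-detection test therefore establishes that the scan
pipeline detects a hard sweep of the stated strength against this
stylized background — not that its power matches any published scan on
real data, and published headline counts (candidate regions, gene
lists, pairwise F_ST tables) are not reproducible without the original
genotypes.

# Numerical conventions

* Coordinates: 1-based physical positions for SNPs (VCF convention);
  0-based half-open intervals for genes, windows and all BED output.
* Polarity: haplotype and dosage matrices are coded 0 = ancestral,
  1 = derived.  Sites with unknown ancestral state keep REF-as-0 coding
  and are flagged; they are excluded from iHS (which needs polarity)
  but retained for XP-EHH and the frequency scans (which do not).
* Multiallelic and indel records are skipped with a logged count, not
  split — the array-SNP scope of the pipeline.
* F_ST clamps: negatives to 0 before $T$; $1-10^{-9}$ cap before the
  log.
* Degenerate standardization bins (zero variance) invalidate their
  scores instead of emitting infinities.
* LD pruning slides 50-SNP windows by 25 (the window size and r²
  threshold are standard; the step is the conventional half-window),
  dropping the later SNP of an offending pair; monomorphic SNPs have
  r² defined as 0.
* Negative NJ branch lengths are clamped to zero with the deficit moved
  to a sibling branch; taxa are canonically ordered by label first so
  the tree is invariant to input order.

# Known limitations

* The Wright–Fisher model is haploid-gamete based (selection acts on
  gametes, not diploid genotypes); at the simulated selection strengths
  the distinction is negligible, but dominance cannot be represented.
* The mutation process toggles alleles (finite-sites), so a site can
  mutate back; rates are set low enough that this is a perturbation.
* The unphased fallback for haplotype copies counts only
  genotype-unambiguous cases; with phased input this is exact.
* Per-SNP PBS inherits the per-SNP F_ST ratio noise; regional
  aggregation (the max statistic) is where its signal is meant to be
  read.
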