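---
title: "Models and methods behind ovipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ovipop characterizes structured diploid populations — breed panels of
sheep and similar livestock — from biallelic SNP-array genotypes. This
vignette explains the statistical models the package implements, the
parameters that matter and their defaults, what the built-in simulator
does and does not emulate, and the numerical choices made where the
methods literature leaves latitude.

## Data model

A dataset is a `genotypes` object: a samples × SNPs matrix of A2
allele-dosage codes (0/1/2, `NA` for missing calls), a marker map
(chromosome, base-pair position, alleles; codes 1–26 are treated as
sheep autosomes) and a sample table with a breed code per individual.
Coordinates are 1-based inclusive everywhere; segment lengths are
`end − start + 1`. Missing genotypes stay missing: no step imputes
them, except PCA's mean imputation, which is explicit and documented
below.

## Quality control

`qc_filter` removes unplaced and non-autosomal markers, then SNPs with
more than `max_snp_missing` (default 0.10) missing calls, then samples
with more than `max_sample_missing` (default 0.05) missing calls
evaluated on the surviving SNPs. Because removing samples can change
SNP missingness (and vice versa), the two filters are repeated until
nothing more is removed. The first pass is exactly the documented
SNP-then-sample order; iterating to the fixpoint is what makes the
filter idempotent, a property the test suite asserts. There is no
minor-allele-frequency filter: monomorphic SNPs are legitimate for
diversity denominators and are retained (they are skipped where a
statistic is undefined on them, e.g. r²).

## Diversity statistics

For one breed with allele frequency estimate $\hat p_j$ at SNP $j$ from
$n_j$ genotyped individuals:

* observed heterozygosity is the fraction of heterozygous calls among
  an individual's non-missing genotypes, averaged over individuals;
  its standard error is over individuals (matching the magnitude of
  published per-breed SEs, which reflect tens of animals);
* expected heterozygosity uses the small-sample-unbiased estimator
  $H_{e,j} = 2\hat p_j(1-\hat p_j)\,\frac{2n_j}{2n_j-1}$, averaged over
  all SNPs (monomorphic included), SE over SNPs — hence SEs near zero
  for panels with $10^5$ markers;
* $F_{IS}$ is the per-individual method-of-moments coefficient
  $(O_{hom} - E_{hom})/(L_{obs} - E_{hom})$, where $E_{hom}$ sums
  $1 - H_{e,j}$ over the SNPs observed in that individual. This is the
  PLINK `--het` bookkeeping applied within a breed.

## Differentiation

`pairwise_fst` implements the Weir–Cockerham (1984) two-population
estimator. Per SNP the variance components $a$ (between populations),
$b$ (between individuals within populations) and $c$ (within
individuals) are computed from sample sizes, allele frequencies and
observed heterozygote fractions; the combined estimate is the ratio of
sums $\sum_j a_j / \sum_j (a_j+b_j+c_j)$. SNPs monomorphic across both
breeds, or with fewer than two genotyped individuals in either breed,
carry no information and are excluded. Negative estimates are reported
as computed. The Hudson estimator (Bhatia et al. ratio of averages) is
available via `method = "hudson"`; the Weir–Cockerham default is the
field standard and well-defined for unbalanced samples. `mean_fst` is
the arithmetic mean of a breed's off-diagonal pairwise values over the
included breed set — so it depends on that set, exactly as published
mean-F_ST columns do.

Nei's (1972) standard distance is computed from per-population allele
frequencies with the gene identities $J_x$, $J_y$, $J_{xy}$ summed over
all loci *before* the ratio, $D = -\ln(J_{xy}/\sqrt{J_xJ_y})$. Because
$D$ has no finite-sample correction, two finite samples of one
panmictic population have $E[D] \approx \overline{2pq}/(2n\,\bar J)$
rather than exactly zero; tests bound the null case accordingly. A
Reynolds-type drift-only distance ($-\ln(1-\theta)$ with
$\theta = \sum(p_1-p_2)^2 / \sum(1 - p_1p_2 - q_1q_2)$) is exposed as an
alternative because the ancestry literature is ambiguous about which
correction produced some published split networks; Nei 1972 is the
default. Distance matrices export to PHYLIP square and NEXUS distance
formats for neighbor-net rendering, which is out of scope here.

PCA follows the genotype-PCA convention: center each SNP by $2\hat p$,
scale by $\sqrt{\hat p(1-\hat p)}$, set missing cells to zero after
centering (mean imputation — deterministic and standard for genotype
PCA), and eigendecompose the sample covariance. Variance fractions are
percentages of the positive spectrum; monomorphic SNPs are dropped
because their scale is undefined.

## Runs of homozygosity and F_ROH

A run of homozygosity is evidence that both haplotypes descend from a
recent common ancestor. Calling runs from array data needs a guard
against chance homozygosity: with mean heterozygosity $het$ across
SNPs, a stretch of $l$ SNPs is homozygous by state with probability
roughly $(1-het)^l$, so requiring

$$ l \;=\; \left\lfloor \frac{\ln\!\big(\alpha/(n_s\,n_i)\big)}
   {\ln(1-het)} \right\rfloor $$

keeps the expected number of spurious runs across all $n_s n_i$
genotype positions at $\alpha$ (default 0.05). `roh_params` derives
$n_s$, $n_i$ and $het$ from the dataset by default (all overridable;
the floor is clamped at 1). For a 470,962-SNP, 211-animal panel at
$het = 0.343$ this gives $l = 50$.

The remaining criteria follow HD-array practice: maximum gap between
adjacent SNPs in a run 250 kb; density at least 1 SNP per 50 kb over
the run; minimum length 2 Mb; and length classes [2,4), [4,8), [8,16),
[16,∞) Mb (half-open, so classes partition without double counting)
with heterozygote allowances 0/1/2/4 and missing-call allowances
2/4/8/16 per class. The allowance schedule is configurable; the
defaults grow with run length in the spirit of the genotyping-error
tolerances customary for these classes.

The scan itself is defined declaratively so it can be checked against
a brute-force oracle: an interval qualifies when its endpoints are
homozygous calls and every criterion above holds for the interval as a
whole; all *maximal* qualifying intervals (those not extendable to a
larger qualifying interval) are enumerated; the reported segments are
chosen longest-first, dropping any that overlap an already chosen run
(ties resolved leftmost). The implementation enumerates maximal
intervals in near-linear time (two-pointer budget bounds, prefix
counts, and the observation that only intervals reaching beyond all
previous right endpoints can be maximal); the test suite proves it
equal to an exhaustive $O(n^2)$ enumeration on 100 random chromosomes
and exercises planted tracts, oversized gaps and het/missing budgets
explicitly. Results are deterministic and independent of chromosome
processing order.

$F_{ROH}$ divides an individual's summed run length by the SNP-covered
autosome length (per chromosome, last minus first SNP position + 1,
summed) — the same denominator for every class, so class-wise
coefficients add exactly to the total. Note the criteria presuppose
array-like marker density: at 1 SNP per 50 kb required density, maps
sparser than ~20 SNPs/Mb cannot support calls at all, which matters
when simulating validation data (below).

## Effective population size from LD

Under the Sved relation, the expected squared correlation between loci
at recombination fraction $c$ in a population of effective size $N_e$
is approximately $1/(1 + 4N_ec)$, and a sample of $n$ individuals adds
roughly $1/n$: $E[\hat r^2] \approx 1/(1+4N_ec) + 1/n$. `binned_r2`
computes mean $\hat r^2$ (squared dosage correlation,
pairwise-complete, monomorphic SNPs excluded up front) in bins of $c$,
mapping physical distance through a uniform genetic map (default
1 cM/Mb — no sheep-specific map is assumed) and Haldane's function
$c = \tfrac12(1-e^{-2d})$. Pairs are drawn within chromosomes only,
subsampled uniformly per bin under a recorded seed (default cap 2000
pairs/bin, bins under 500 usable pairs are flagged unusable).
`ne_from_bin` inverts the relation,
$\hat N_e = (1/\hat r^2_{adj} - 1)/(4c_{mid})$ with
$\hat r^2_{adj} = \bar r^2 - 1/n$, flagging the estimate undefined when
the adjusted value is non-positive. `ne_trajectory` reports one point
per usable bin at generation $t = 1/(2c_{mid})$, truncated at 50
generations by default, with "current" $N_e$ from the largest usable
$c$ bin.

Two calibration facts shape how these estimates should be read. First,
Sved's formula is accurate for $4N_ec \gtrsim 10$ but overstates
equilibrium $r^2$ at smaller $4N_ec$ (the Ohta–Kimura
$\sigma_d^2 = (10+\rho)/(22+13\rho+\rho^2)$ sits below $1/(1+\rho)$),
and its unlinked-limit constant differs at large $c$; per-bin estimates
therefore carry a mild, deterministic, $c$-dependent upward bias even
for a truly constant $N_e$, and a strict zero-trend test across bins
would reject for that reason alone. Second, the $1/n$ correction is
Hill's approximation for unphased data at moderate $n$; $\alpha$-weight
refinements are deliberately omitted. Consequently the package's
simulation-recovery checks aggregate bins with
$c \in [0.01, 0.05]$ — the window where the inversion is approximately
calibrated for the sizes of interest — and constant-$N_e$ behaviour is
asserted as a flat band (no step-like structure), contrasted with a
simulated bottleneck that must bend the trajectory by more than
two-fold. Recovered medians for constant $N_e \in \{50, 100, 500\}$
land within 13–21% of truth under the test conditions, inside the ±30%
band used for acceptance. Full demographic-history optimization in the
style of GONE is intentionally out of scope: this module provides the
transparent bin inversion, and absolute agreement with
genetic-algorithm software on real data is not claimed.

## The Wright–Fisher simulator

`simulate_population` starts from founders drawn in linkage
equilibrium with allele frequencies uniform on [0.05, 0.95] —
emulating array ascertainment of common standing variation — and
reproduces for a scheduled sequence of diploid sizes with random
distinct parent pairs, Poisson-count crossovers placed uniformly per
chromosome (no interference) at the configured rate, and no mutation.
Sheep-like defaults: 26 chromosomes × 100 Mb, 1500 SNPs/chromosome,
1 cM/Mb. All randomness flows from one mandatory seed through a
counter-based splitting scheme, so each scenario is reproducible
independently of call order; the same seed regenerates fixtures
byte-identically, including through the stored YAML config.

`simulate_split_pair` evolves one ancestral population, then two
isolated copies for `t_split` further rounds at size $N$, recording the
pure-drift expectation $F_{ST} = 1-(1-1/(2N))^{t}$. One detail matters
for validating estimators against that expectation: sampling a large
fraction of a small population violates the binomial-sampling
assumption inside the F_ST estimators' corrections (they overcorrect by
about $1/(2N)$, a ~9% downward bias at $N=100$, $t=10$). The simulator
therefore appends a census-expansion generation (default cohort
$\max(N, 4\,n_{per pop})$) whose parents are still the $N$-sized pool:
each of the $t$ rounds keeps drift $1/(2N)$, while the expansion
round's own drift ($\approx 1/(2\,\mathrm{cohort})$) cancels, to first
order, the residual finite-census part of the sampling correction.
This mirrors real studies, where the genotyped cohort is a small
sample of a census far larger than $N_e$.

`plant_inbred_offspring` creates parent–offspring or full-sib matings
from the final generation and appends their offspring (pedigree
$F = 0.25$), whose genomes carry identity-by-descent tracts produced by
the same recombination process. Validation fixtures for ROH use 4000
SNPs/chromosome (40/Mb): the ROH criteria are stated for HD-array
density and are unsatisfiable at the generator's sparser default map
(15/Mb mean spacing of 67 kb cannot meet 1 SNP/50 kb). With that
density, 20 planted parent–offspring offspring recover mean
$F_{ROH>2Mb}$ within ±0.05 of 0.25 while outbred controls stay below
0.02.

What the simulator does *not* emulate: mutation (fixtures are standing
variation only), crossover interference, sex chromosomes, selection,
migration/admixture, genotyping error beyond uniform missingness, and
array ascertainment against a reference panel. Passing recovery tests
therefore demonstrates estimator correctness under drift,
recombination and sampling — not robustness to admixture or
ascertainment bias in real data.

## Pipeline and reproducibility

`run_characterization` executes QC → diversity → F_ST → distances →
PCA → pruning → ROH → F_ROH → N_e in that order, failing fast with the
stage named. Configurations are plain YAML with a strict schema
(unknown keys are rejected), and every output table carries an FNV-1a
hash of the configuration; re-running the same configuration on the
same input reproduces every file byte-for-byte. Bit-exactness is
promised for fixed-seed reruns on one platform, not across platforms —
floating-point differences are noted in the run manifest.

Problem sizes in the test suite are chosen to exercise each property
at the smallest scale where its expectation is sharp: oracle
equivalence on 100 chromosomes of 80–400 SNPs; drift-F_ST recovery on
2×100 Mb genomes over 5 seeds; pedigree-F recovery on a full 26×100 Mb
genome at array density; N_e recovery on 26 chromosomes at 250
SNPs/chromosome with 200 burn-in generations and 5 replicates per size.

## Known limitations

* The ROH scanner is a reproducible re-specification of criteria whose
  published implementations are proprietary; on real data, per-breed
  $F_{ROH}$ should agree approximately, not identically, with
  commercial callers (window semantics differ).
* LD-based $N_e$ inherits every caveat of the Sved inversion listed
  above, plus sensitivity to admixture and substructure, which inflate
  $N_e$; no admixture correction is attempted.
* The uniform 1 cM/Mb map is a deliberate simplification; supplying a
  breed-specific recombination rate changes bin placement but not the
  machinery.
* `merge_datasets` drops strand-ambiguous (A/T, C/G) SNPs whenever a
  strand flip would be needed to reconcile alleles; it never guesses
  strand from frequency.
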