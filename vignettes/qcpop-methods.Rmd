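---
title: "Methods: genotyping QC and population structure in qcpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping QC and population structure in qcpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

qcpop implements the quality-control and population-genetics pipeline used to
prepare large genotyping-array cohorts for genome-wide association analysis:
variant-level QC driven by plate- and batch-effect regressions, sample-level
QC from call rates, heterozygosity and chromosome-X intensity summaries,
pairwise relatedness, principal-component analysis with iterative removal of
long-range linkage-disequilibrium (LRLD) regions, and the subset and filter
construction for case-control scans. Because the cohorts this pipeline is
designed for cannot be redistributed, the package ships a synthetic-cohort
generator that reproduces the statistical structure every stage relies on,
with ground-truth labels for every planted artifact, and the test suite
exercises the pipeline end to end against that truth.

This vignette records the models, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## The synthetic cohort

`simulate_cohort()` generates a cohort with discrete recruitment regions on a
north-south gradient of differentiation. Founder allele frequencies follow
the Balding-Nichols model: an ancestral frequency $p \sim U(0.05, 0.95)$ per
variant, and per-region frequencies
$p_r \sim \mathrm{Beta}\!\big(p(1-F_r)/F_r,\ (1-p)(1-F_r)/F_r\big)$, with
$F_r$ rising from 0.005 to 0.035 along the latitude gradient by default —
differentiation of the order seen between recruitment regions of a single
large East Asian cohort. Founder haplotypes are independent Bernoulli draws,
so founders are in Hardy-Weinberg equilibrium within region (a property the
suite asserts: the median per-variant 1-df HWE statistic is the
$\chi^2_1$ median, 0.455).

Families are created by gamete dropping: one recombined gamete per parent,
with per-chromosome crossover counts Poisson in the genetic map length
(default: two 100-Mbp autosomes plus X at 1 cM/Mbp; desk scale, all sizes
configurable). The pedigree battery covers trios, full- and half-sibling
pairs, parent-offspring pairs, intentional duplicate pairs, and two
consanguinity constructs: offspring of first cousins (inbreeding coefficient
$F = 1/16$, detectable as runs of homozygosity) and *triple second cousin*
pairs — three independent 6-meiosis connections through three ancestral
couples, the relationship signature of historical consanguinity, with
expected IBD $3 \times 0.03125 = 0.09375$.

Planted artifacts, each recorded in the returned truth labels:

* **LRLD blocks** — within a declared interval, every founder haplotype is a
  copy of one of a small pool of template haplotypes (default 4; 2 mimics an
  inversion). This produces the loading inflation in PCA that real
  long-range LD causes, without modelling background LD (a stated non-goal).
* **Plate effects** — on an affected plate, heterozygous calls at selected
  probesets are miscalled to the counted-allele homozygote with probability
  $\delta$ (default 0.5). Affected probeset/batch rows of the clustering
  metrics table get FLD drawn below 8 (and HetSO/HomRO in the poor range),
  mimicking a genotyping-cluster failure. The magnitude distribution of real
  plate effects is unknown, so $\delta$ is an explicit free parameter.
* **Sex-chromosome karyotypes** — males are haploid on X (0/2 dosage).
  Planted karyotypes set the intensity summaries: XO at mean chrX LRR
  $-0.6$ with no heterozygous BAF band; XXX at $+0.4$ with band modes at
  1/3 and 2/3; XXY-like males with intermediate heterozygosity F
  ($\approx 0.5$) and depressed chrY/chrX ratio. Mosaic XO values
  interpolate by cell fraction; the default 70% mosaic gives LRR $-0.42$
  and band modes at $(1-m)/(2-m) = 0.27$ and $1/(2-m) = 0.73$.
* **Plate layout** — 96-well plates; well H12 of a plate holds a duplicate
  of the sample at D1 on the previous plate, the fixed-position design used
  to verify plate order. Duplicate copies differ by a small adjacent-class
  genotype error rate (hom $\leftrightarrow$ het; array miscalls come from
  neighbouring intensity clusters, so opposite-homozygote discordance
  between duplicates is essentially absent).
* **Boxes and ascertainment** — cohort members are stored in boxes; a
  per-box fraction is selected for genotyping, and disease cases are
  additionally selected with high probability regardless of box. This
  reproduces the mechanism that makes a naive genotyped set case-enriched
  while boxes with a high selected fraction remain representative.
* **Migrants** — samples whose manifest region differs from the region
  their genotypes were drawn from, the target of the regional
  (non-local-ancestry) outlier stage.

What the generator does **not** emulate: realistic background LD (only
block structure), raw probe intensities, imputation, and batch-specific
cluster geometry. Tests passing on these cohorts therefore demonstrate that
the decision rules and estimators behave as specified under the generative
assumptions, not that the pipeline's empirical yields on real data are
reproduced.

## Variant QC

The plate-effect test treats each plate in turn as "case" against the other
plates of its batch in a logistic regression of plate membership on
genotype, with recruitment region as covariate, and a likelihood-ratio
test on the genotype term. The genotype enters as **class indicators**
(1-2 df) by default rather than an additive dosage term. This is a
deliberate choice: the artifacts the test exists to catch are
heterozygote-cluster collapses (het calls migrating into a homozygote
cluster), which leave the dosage mean almost unchanged — at the planted
scenario ($\delta = 0.5$, MAF 0.3, 96 samples/plate, 20 plates) the 1-df
dosage test essentially never reaches the $10^{-10}$ fail tier (median
p $\sim 5\times 10^{-3}$), while the class-coded test reaches $10^{-10}$
in about half of probesets and $10^{-8}$ in about 60%. `encoding =
"dosage"` restores the additive test.

Fail rules, applied per probeset within a batch: any plate effect
$p < 10^{-10}$; more than 3 plates with $p < 10^{-4}$; or any plate effect
$p < 10^{-8}$ together with clustering metrics FLD < 8, HetSO < 0.68 and
HomRO < 3.7. The manual cluster-plot review tiers (plate $p < 2\times
10^{-5}$; batch $p < 10^{-3}$) cannot be automated faithfully and are
represented as `review` flags, never silent passes; missing metrics in the
metric-dependent band likewise yield `review`. Batch effects use the same
regression across batches on unrelated samples, with the version-specific
multi-batch limits (more than 2 batches at $p < 10^{-4}$ for array version
1, more than 7 for version 2).

Hardy-Weinberg testing is region-stratified: a 1-df genotype-count
chi-square per region, summed, with degrees of freedom equal to the number
of contributing regions (10 in the full design) and exclusion at
$p < 10^{-6}$. Regions with fewer than 2 genotyped samples or monomorphic
counts contribute 0 with reduced df — the reduced-df convention is our
resolution of an unstated corner case. Chromosome X uses females only.

Reference-frequency concordance harmonises alleles by direct match, allele
swap, strand flip or both; variants whose MAF differs from the reference by
more than 0.2 are dropped. Strand-ambiguous A/T and C/G pairs are compared
without flipping only when both MAFs are below 0.4 and otherwise dropped as
ambiguous — a conservative default where the procedure was silent.
Duplicate probesets assaying one variant keep the higher call rate, with a
deterministic lexicographic tie-break that is logged.

## Sample QC

Heterozygosity is standardised within recruitment region (the north-south
gradient spans more than one SD, so a global rule would misfire); samples
with region Z > +3 fail. Low heterozygosity (Z < -3) fails only when the
total length of runs of homozygosity is unremarkable (ROH Z < 2): low
heterozygosity explained by autozygosity marks consanguineous ancestry, not
poor DNA. The ROH caller is a sliding-window scan (50 SNPs, at most 1
heterozygous and 5 missing calls per window; segments of at least 50 SNPs
and 1000 kb, split at gaps above 1000 kb); only the 1000-kb floor is fixed
by the protocol, the remaining parameters are the cited toolchain's
defaults and are exposed.

Sex inference fits a 2-component Gaussian mixture to the (chrX
heterozygosity F, chrY/chrX intensity ratio) plane and classifies by the
midpoints between cluster means, because the original procedure describes
cluster inspection rather than fixed cutoffs. A reported male with F
between 0.2 and 0.8 is called XXY-like regardless of the midpoint
assignment: F near 0.5 is exactly where midpoint rules are unstable, and F
near 0 in a reported male is a sample mix-up rather than an extra X (the
lower bound separates the two).

The chromosome-X aneuploidy stage screens females whose mean chrX LRR is
more than 3 robust SDs (median/MAD) from the female centre — robust,
because at desk scale the planted aneuploids are a large enough fraction of
females to inflate a plain SD and hide themselves. The heterozygous-probe
BAF band then resolves the call: no band = XO; displaced band with low LRR
= XO mosaic; band modes nearer (1/3, 2/3) than 0.5 with high LRR = XXX;
displaced high-LRR band otherwise = structural change. Two deliberate
choices: (i) a screen-positive sample with a *normal* band is reported as
an intensity outlier, not aneuploid — with only a chromosome-mean LRR
available, nothing else can be justified; (ii) a clearly displaced band
(median |BAF - 0.5| > 0.08 over at least 30 probes) triggers examination
even when the LRR screen narrowly misses, because mosaic and XXX samples
sit at |LRR z| around 3-4 where a screen-only workflow misses roughly 10%,
while euploid bands are never displaced, so the zero-false-call property
is untouched.

Plate-orientation tracing compares reported-vs-inferred sex mismatches
under the identity layout and under a 180-degree rotation (well $(r,c)
\mapsto (R{+}1{-}r, C{+}1{-}c)$); a plate is declared rotated only when the
rotation removes *all* mismatches and the identity layout has at least 2.
Anything else stays unresolved, and the affected block is marked for
wholesale exclusion as a linkage error. Ancestry outliers are flagged by
projecting onto reference-panel principal components and cutting at 10
cohort SDs on any of the first 10 PCs. Duplicate discovery reports pairs
with PI_HAT > 0.95 on a thinned variant set, confirms the fixed-position
expected duplicates (a missing one raises a plate-tracking alert), and
excludes the lower-call-rate copy.

## Relatedness

`estimate_ibd()` is the method-of-moments inversion of the expected
identity-by-state distribution given allele frequencies, yielding genome
proportions $(Z_0, Z_1, Z_2)$ sharing 0/1/2 alleles identical by descent
and $\hat\pi = Z_1/2 + Z_2$. Negative components are clipped to zero and
the triple renormalised; the raw values are retained because the clipping
induces a small positive floor under the null (unrelated pairs average
$\hat\pi \approx 0.016$ at 10k SNPs even though the raw estimator is
unbiased at zero — the suite asserts both facts). Frequencies should come
from the analysis population; misspecification bias is covered by a
property test rather than corrected. `king_kinship()` is the KING-robust
between-family estimator from heterozygote concordance and
opposite-homozygote counts.

Classification uses the study thresholds: $\hat\pi > 0.95$ duplicate/MZ;
$> 0.375$ first degree, split into parent-child ($Z_0 < 0.05$ and $Z_1 >
0.5$, the parent being the older member) versus full siblings; $> 0.1875$
second degree; a kinship band (0.0442, 0.0884] third degree (standard
degree bins; only the 0.05 unrelated cutoff is fixed by the protocol, and
third-degree calls drive no exclusions). `expected_ibd()` computes analytic
expectations for unions of independent pedigree connections via kinship
summation ($\hat\pi = 2\sum_c \phi_c$, $\phi_c = a_c \cdot 2^{-(m_c+1)}$
for $a_c$ shared ancestors and $m_c$ meioses), with $Z_2$ assembled from
the parental channels each connection runs through; the default channel
assignment matches the canonical triple-second-cousin pedigree the
simulator builds, and a single-locus gene-dropping oracle verifies every
relationship in the battery to Monte-Carlo precision.

The unrelated-set selector greedily removes the sample with the most
kinship pairs above the cutoff (ties: lower call rate, then lexicographic
id), then re-admits any removed sample whose every above-cutoff partner was
itself removed later — the repair guarantees maximality, which the plain
greedy loop does not.

## Population structure

PCA standardises genotypes per variant by mean $2\hat p$ and scale
$\sqrt{2\hat p(1-\hat p)}$, sets missing values to zero after centring, and
uses a truncated SVD; loadings, centres and scales are retained so held-out
samples project exactly onto the training scores. LD pruning is the
sliding-window recipe (50 SNPs, step 5, r² 0.2; the relatedness set uses
0.1), removing the lower-MAF member of an offending pair.

The LRLD detector is a two-state hidden Markov model along each
chromosome. Per PC, loadings are standardised across variants and a
two-component scaled-$\chi^2_1$ mixture is fitted to $Z^2$ by EM (null
scale fixed at 1; inflated scale free with floor 3; fitted per PC and
re-fitted each iteration). Two numerical choices matter:

* **Emission**: the per-variant emission likelihoods are the two component
  densities — equivalently the equal-weight posterior $f_1/(f_0+f_1)$ —
  *not* the fitted-weight mixture posterior. The fitted weight is the
  marginal prior of the inflated component; the chain's stationary prior
  already carries that information, and multiplying a run of $L$ in-state
  variants by $w^L$ (with $w$ of order $10^{-2}$) makes long regions
  effectively unreachable. With likelihood emissions the moderate evidence
  of consecutive block variants accumulates as it should.
* **Scan gate**: a PC is scanned only when the mixture improves on the pure
  null by a likelihood-ratio statistic of at least 6. On null loadings the
  statistic is below 2 in over 95% of replicates while planted 2-Mbp
  blocks with 10-fold loading variance give 10-100+, so the gate removes
  essentially all false regions at no cost in power.

Transitions between adjacent variants use the genetic map: switch
probability $1 - e^{-\rho \Delta d}$ ($\Delta d$ in cM, floor $10^{-6}$;
$\rho = 1$/cM), balanced to the stationary prior $\pi_{in} = 0.05$.
Variants with forward-backward posterior above 0.5 form runs; runs closer
than 1 Mbp merge; boundaries extend to the midpoint toward the neighbouring
variant. Forward-backward is verified against exhaustive path enumeration
on small instances to $10^{-12}$.

The iterative cleanup alternates PCA, BIC-based informative-PC selection
(multinomial region model; PCs added in order, k = the largest prefix in
which every addition reduced BIC), HMM scans of PCs $1..k{+}1$ (the +1
mirrors the non-informative control PC), exclusion of newly found regions,
and repeat until no new region appears or an iteration cap (default 10,
with a warning). Note one desk-scale caveat the tests respect: a planted
block must carry enough variance to rank within the scanned leading PCs;
small blocks behind the regional axes require a deeper fixed scan.

Regional (non-local-ancestry) outliers use a robust Mahalanobis distance
per region on the informative PCs — minimum covariance determinant with
75% support, the "robust" reading we adopted since the cited base function
is not robust — cut at the chi-square quantile matching the two-sided
normal mass of 3 SDs (so for one PC the rule is exactly |Z| > 3); singular
scatter falls back to a per-PC |Z| > 3 rule. Pairwise Fst is the
Weir-Cockerham variance-components estimator, ratio-of-sums across
variants, reported as computed (including negative estimates).

## GWAS preparation

The representative subset keeps samples whose storage box had a genotyping
selection fraction of at least 0.40 (boundary inclusive); the report
compares ascertained-case prevalence inside and outside. Case definitions
are per 3-character diagnosis code with at least 100 genotyped cases,
controls being non-case members of the representative subset; sex-specific
codes restrict both sides *before* the count check (our resolution of an
unstated ordering). The variant filter is exact arithmetic:
$\mathrm{MAC_{eff}} = 2 \cdot \mathrm{MAF} \cdot \mathrm{info} \cdot
N_{eff}$ with $N_{eff} = 4/(1/N_{cases} + 1/N_{controls})$, dropping below
20.

The association scan is a plain per-variant logistic regression with the
standard covariate recipe (array version, sex, age, age², region
indicators, leading PCs) and a Firth-penalised fallback on separation or
non-convergence; output is labelled as a stand-in for the
saddlepoint-corrected mixed-model scan used at cohort scale, which is out
of scope — the module's subject is the subset, filter and stratification
design. Meta-analysis across region strata is fixed-effect inverse-variance
pooling with Cochran's Q and I² (the protocol does not specify the model;
the closed form is cross-checked against an independent meta-analysis
package in the tests). LD clumping is the greedy index-variant procedure
with the 5e-8 / 5000 kb / 0.05 / 0.05 defaults, verified against a
brute-force reimplementation.

## Problem sizes and determinism

The shipped tests run cohorts of roughly 300-1200 samples and 300-3500
variants, 200 pairs per relationship at 10,000 unlinked SNPs, 200-replicate
null batteries for the HMM, and a 20,000-variant null association scan —
sizes chosen so the whole suite completes in a few minutes while keeping
Monte-Carlo error well inside each asserted tolerance. Every stochastic
stage flows from a single integer seed; identical configuration and seed
reproduce every output bitwise, which the suite asserts.

## Known limitations

* Background LD is block-only; estimators that would be biased by realistic
  short-range LD (e.g. the IBD method-of-moments on unpruned data) are only
  exercised on unlinked or pruned sets, as in the real workflow.
* Manual cluster-plot review cannot be automated; `review` flags mark where
  a human would look.
* The X-aneuploidy stage sees only chromosome-mean LRR, so partial
  deletions/duplications are not separable from mosaicism; truly partial
  events would need per-probe LRR tracks.
* The association stand-in is an unrelated-samples logistic model; related
  samples must be removed via the unrelated-set selector first.
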