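---
title: "Drift-model FST selection scans: methods and design notes"
author: "driftScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-model FST selection scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftScan)
```

# The model

driftScan scans dense biallelic SNP genotypes for genomic regions whose
differentiation between populations is unusually high (candidate
positive/directional selection) or unusually low (candidate balancing
selection, or shared purifying pressure). The statistical backbone is a
pure-drift allele-frequency model: all populations descend from one
ancestral population, and population *j*'s frequency at SNP *i* deviates
from the ancestral frequency $\pi_i$ by drift alone, with variance
$c_j\,\pi_i(1-\pi_i)$. The drift parameter $c_j \ge 0$ is dimensionless
and absorbs the population's effective size and divergence time; it is
the only population-level parameter the scan estimates implicitly.

The per-SNP statistic is

$$F_{ST}(i) \;=\; \frac{1}{n}\sum_{j=1}^{n}
  \frac{(p_{ij}-\bar p_i)^2}{\bar p_i\,(1-\bar p_i)},$$

where $p_{ij}$ is the observed frequency of the counted allele in group
*j* and $\bar p_i$ the unweighted group mean, which estimates $\pi_i$.
Key properties, each enforced by a test:

* non-negative, and zero iff all group frequencies coincide;
* equal to 1 when two groups are fixed for alternate alleles;
* invariant to allele relabeling ($p \to 1-p$), so the deterministic
  "count the lexicographically larger allele" coding used by the PED
  reader cannot affect results;
* for $n$ populations with equal drift $c$ and frequencies observed
  without sampling noise, $E[F_{ST}] = \frac{n-1}{n}\,c$ — the
  $\frac{n-1}{n}$ factor arises because $\bar p_i$ is estimated from the
  same $n$ frequencies.

With genotype data the group frequencies carry binomial sampling noise,
which inflates the statistic by roughly $1/(2N_j)$ per group relative to
the frequency-level value; with 75 diploids per group at $c = 0.1$ the
inflation is on the order of 10--15% of the signal. The scan is
threshold-based (empirical percentiles), so this uniform inflation does
not shift which regions are called.

Monomorphic-overall SNPs ($\bar p_i \in \{0,1\}$) have an undefined
statistic; they are flagged unusable and excluded from smoothing support
and from bandwidth SNP counts — never silently zero-filled, which would
drag smoothed values toward zero in poorly ascertained regions.

# Smoothing

Single-SNP $F_{ST}$ values are noisy (at $n=2$ the statistic is roughly a
scaled 1-d.f. chi-square), so the track is smoothed along each chromosome
before thresholding. `smoothTrack()` uses a Nadaraya–Watson mean with the
Epanechnikov kernel $K(u) = 0.75(1-u^2)$ on $|u|\le 1$ and a
k-nearest-SNP local bandwidth: at each usable SNP position $x$, the
bandwidth $b(x)$ is the smallest half-width containing the `spanSnps`
(default 15) nearest usable SNPs, self included. This keeps a fixed
*count* of SNPs per smoothed value, so the physical span adapts to local
marker density — approximately 15 × the median gap on an even map, i.e.
the ~50–75 kb scale at high-density-array spacing, which matches the
typical extent of LD in cattle populations. A positive-weight local mean
preserves the two properties downstream stages rely on: every smoothed
value lies within the range of its contributing raw values, and values on
one chromosome never influence another.

Numerical details, fixed for determinism:

* the best k-window around each point is found by a two-pointer sweep
  (the window cost is V-shaped in the start index); ties take the
  leftmost window, though the resulting bandwidth is identical either
  way;
* SNPs exactly at distance $b(x)$ are inside the support but receive
  Epanechnikov weight 0; the centre point always has weight 0.75, so the
  weight sum is strictly positive;
* chromosome edges simply use the available $\le$ `spanSnps` neighbours
  (the window becomes one-sided);
* chromosomes with fewer than two usable SNPs are skipped with a warning.

The operative description "every fifteen SNP values generate one smoothed
value" is ambiguous between a sliding 15-SNP support and disjoint 15-SNP
blocks; both are implemented (`mode = "sliding"` / `"block"`), sliding
being the default because it evaluates at every SNP and does not make
region boundaries depend on an arbitrary block phase. Block mode places
each block's value at the block's median SNP position and keeps a shorter
trailing block.

# Region calling

`callRegions()` computes the upper $1-q_{top}$ and lower $q_{bottom}$
empirical quantiles (linear interpolation of order statistics, R type 7)
of the pooled **autosomal** smoothed values and flags points at or beyond
them. Ties at a threshold are flagged inclusively, so a degenerate
all-equal track flags everything and warns, rather than failing silently.
The X chromosome is optionally thresholded against its own quantiles
(`xChrom=`): the X is expected to be far more drifted than autosomes
(uniparental inheritance, stronger bottlenecks), and pooling it would
both swamp the autosomal top tail and make X-balancing calls impossible.
X-specific quantiles were chosen over applying autosomal thresholds to X
because the latter reduces the X report to "almost everything is
extreme"; the choice is configurable.

Maximal runs of consecutive flagged points (same chromosome, same
direction) merge into one region, reported with the positions of the
first and last flagged SNP, the extreme smoothed value (max for positive,
min for balancing) and the point count. Only strictly consecutive points
merge (gap tolerance 0): published region tables do not disambiguate
their merging rule, and zero tolerance is the most conservative and the
easiest to reason about; a gap parameter can be layered on later without
changing any other contract.

# Quality control and structure

* **Call-rate filter** (`filterByCallRate`): samples first (retain rate
  $\ge$ 0.98), then SNPs on the retained samples (retain rate strictly
  $>$ 0.95). The operators mirror the conventional "at least 98%" /
  "more than 95%" phrasing; both are parameters, since the equality case
  is a genuine ambiguity in most published filter descriptions.
* **Relatedness filter** (`relatednessFilter`): PI_HAT for a pair is
  estimated as the off-diagonal GRM entry clipped to [0,1] — both are
  estimators of the genome-wide relationship coefficient, and reusing
  the GRM kernel keeps one audited code path (a deliberate deviation
  from method-of-moments IBD estimation). Pairs above the threshold
  (strict inequality, default 0.8) are resolved deterministically: drop
  the lower-call-rate member, ties drop the later sample; the GRM is
  computed once on the input. The output is audited to contain no pair
  above threshold.
* **GRM** (`computeGrm`): VanRaden standardized genotype covariance with
  pairwise-complete missingness (each pair divides by its own count of
  jointly called SNPs) — chosen over mean imputation because it
  introduces no between-sample dependence; configurable upstream via
  imputation if desired. Note the finite-sample property that
  off-diagonals of a GRM built with sample-estimated frequencies have
  expectation $-1/(n-1)$, not 0; the test suite asserts that form.
* **PCA** (`grmPca`): eigen-decomposition of the GRM, scores scaled by
  the square root of the eigenvalue, sign fixed so each component's
  largest-magnitude loading is positive (outputs comparable across
  runs).
* **LD pruning** (`ldPrune`): PLINK-style 50-SNP windows advanced by 10,
  removing one member of any retained pair with $r^2 > 0.1$. $r^2$ is
  the squared Pearson correlation of dosage vectors (composite LD) over
  pairwise-complete samples — the genotype-level semantics of the
  pruning command the scan community uses; EM-phased haplotype $r^2$ is
  out of scope. The removal rule (first violating pair in map order;
  drop the lower-MAF member, ties drop the later position) is not
  specified by the original tool's documentation, so it is fixed here
  explicitly and mirrored verbatim in the brute-force test oracle. The
  pruned set feeds **only** the structure stages (GRM, PCA); the scan
  always uses the full QC-passed marker set, since pruning would thin
  exactly the high-LD regions the smoother needs.

# The simulator

`simulateDataset()` generates the data structure the estimator assumes:
ancestral frequencies $\pi_i \sim U(0.05, 0.95)$; group (subspecies)
frequencies drifted with $c_{group}$; breed frequencies drifted from
their group with $c_{breed}$; diploid genotypes Binomial(2, breed
frequency); missing calls masked uniformly. Defaults — 5 chromosomes × 10
Mb × 2,000 SNPs (5 kb gaps, high-density-array spacing), 2 groups × 3
breeds × 25 samples, $c_{group} = 0.1$, $c_{breed} = 0.05$, 0.2% missing
— emulate a two-subspecies panel with a realistic drift hierarchy: 0.1 is
the magnitude of between-subspecies differentiation in cattle, 0.05 the
scale of between-breed differentiation within a type, and 25 samples a
typical smaller breed panel. The ancestral-frequency range mirrors array
ascertainment against rare variants.

The drift transition is a clamped Normal: descendant frequency
$\mathcal{N}(\pi, c\,\pi(1-\pi))$ truncated to [0,1] by projection. The
point masses that clamping creates at 0 and 1 stand in for
fixation/loss; the full spectral form of the drift-diffusion boundary
behaviour is not needed because the pipeline consumes only the moment
structure. Clamping slightly reduces the realized variance when
$c\,\pi(1-\pi)$ is large relative to the distance to a boundary; at
$c=0.1$ over $U(0.05,0.95)$ ancestral frequencies this lowers mean
$F_{ST}$ a few percent below $c/2$, which the calibration test's 10%
band absorbs.

Ground-truth selection is injected at the group level: a **positive**
interval multiplies $c_{group}$ by `multiplier` (> 1) inside the
interval; a **balancing** interval replaces the group frequencies by the
shared ancestral $\pi$ (multiplier 0), or leaves residual jitter
$c_{group}\times$ multiplier for multipliers in (0,1) — mirroring the
interpretation of low-differentiation regions as groups being held at a
common frequency. Breed-level drift and genotype sampling still apply
inside injected intervals, so recovery is a genuine end-to-end test, not
a tautology.

What the simulator does **not** emulate: within-population LD and
haplotype structure (SNPs are independent given the frequencies),
recombination, mutation, admixture/introgression, ascertainment bias
beyond the frequency range, and genotyping error other than missingness.
Passing recovery tests therefore show that the scan detects localized
drift anomalies of the configured magnitude under the model's own
assumptions — they do not certify behaviour under realistic LD, where
neighbouring raw values are correlated and effective degrees of freedom
per smoothing window are lower.

# Test and acceptance problem sizes

The package chooses desk-scale problem sizes for its own verification:
estimator calibration at $10^5$ SNPs (frequency level, no genotype
noise), null calibration and interval recovery at 100 replicates × $10^4$
SNPs × 150 samples, structure separation at 20 replicates of a 500-SNP ×
48-sample panel, and oracle-equivalence checks at $\le 10^3$ elements.
The injected intervals span 250 kb (50 SNPs) at drift multiplier 10
(positive) and 0 (balancing), with $c_{group} = 0.05$ for the recovery
experiment — an interval comfortably smaller than the 1% flag budget of a
$10^4$-point track, so recovery is not forced by bookkeeping. All
randomness descends from a single integer seed, and identical
configuration plus seed reproduces every output byte-for-byte.

# Known limitations

* The drift model assumes a star phylogeny from one ancestor; serial
  founder events or admixture violate it and bias $c$ estimates locally.
* Percentile thresholds always flag ~1% per side by construction; the
  null-calibration property (no positional enrichment across replicates)
  is what distinguishes signal from noise, and users should interpret
  region lists relative to that baseline, not as hypothesis tests.
* Composite (dosage) $r^2$ slightly underestimates haplotype $r^2$ under
  inbreeding.
* PED/MAP parsing canonicalizes allele polarity per SNP; a SNP written
  with only one observed allele cannot preserve a nonzero dosage coding
  through a write–read cycle (it has no second allele to count), which
  is irrelevant to all frequency-based statistics.
* Binary PLINK, VCF and phased-haplotype inputs are out of scope, as are
  model-based admixture clustering and CNV discovery (CNVs are consumed
  as BED intervals).
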