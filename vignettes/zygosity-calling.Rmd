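---
title: "Calling transgene zygosity from log-phase PCR peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transgene zygosity from log-phase PCR peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygocall)
```

## The measurement principle

Distinguishing a transgene homozygote (two copies of the insertion) from a
hemizygote (one copy) with ordinary endpoint PCR is normally impossible:
after 20-plus cycles every reaction saturates and yields roughly the same
amount of product regardless of starting template. The trick this package
operationalizes is to stop PCR while it is still in the logarithmic phase
— around 10 cycles after a touchdown preamble — where product remains
proportional to template, so a hemizygote produces about half the product
of a homozygote. Product is quantified on a capillary fragment analyzer,
which reports for each amplicon a size (bp), a peak height (RFU) and a
peak area; these are the "traits" the pipeline works with. Too few cycles
(about 5) leave the product below the instrument's detection threshold;
too many equalize the genotypes. The 10-cycle window is the regime in
which allele dosage is readable.

Four markers are scored per sample: three amplifying conserved elements
of the integrated T-DNA construct (a 35S promoter segment `35S_S`, an OCS
terminator segment `OCS_S`, and the NPTII selectable marker `NPTII-3`)
and one single-copy native reference gene (`GhUBC1` in cotton), which
doubles as an internal PCR control.

## Normalization

Raw peak traits vary sample-to-sample with DNA input, reaction efficiency
and injection. Each transgene-marker trait value $X$ is therefore
normalized against the same sample's reference-gene value $Y$ and
restored to the population scale with the group median $Z$ of the
reference values:

$$T = \frac{X}{Y} \cdot Z .$$

Dividing by $Y$ cancels any multiplicative per-sample factor exactly:
diluting one sample's PCR product leaves its $T$ unchanged (so long as it
does not shift the group median), and rescaling every sample rescales all
$T$ equally, leaving every downstream classification invariant. The
median rather than the mean is used for $Z$ because a segregating
population's trait distribution is a genotype mixture and far from
normal. The normalization group defaults to the population (one $Z$ per
population and trait); the grouping is an explicit argument so other
schemes (per plate, per experiment) can be substituted. Samples with no
detected reference product cannot be normalized and are classed
`missing`, and they do not contribute to $Z$.

Both peak height and peak area are normalized and carried through
independently; the default classification trait is OCS_S height, which in
practice amplifies most consistently and separates the genotype classes
most cleanly, but marker and trait are configuration options.

## Presence calling

A sample is `transgenic` only when *all* transgene markers and the
reference amplified; `null` when *only* the reference amplified. Anything
in between — reference failure, or partial transgene amplification — is
`missing`: partial amplification is treated as a failed assay, not as
evidence about genotype, which is the conservative completion of the two
rules. Absence is represented uniformly: a zero-height row in the input
and a missing row mean the same thing, because capillary software simply
omits undetected peaks.

## Splitting homozygotes from hemizygotes

Within a segregating population, the normalized values of transgenic
individuals form a two-component mixture whose component means are in
ratio approximately 2:1. Two independent classifiers are run on each
population's transgenic samples.

**Pit (natural split).** The density of the values is estimated with a
Gaussian kernel on a 512-point grid spanning the data range, using
Silverman's rule-of-thumb bandwidth $0.9\,\min(\hat\sigma,
\mathrm{IQR}/1.34)\, n^{-1/5}$. If the density shows two modes, the grid
point of minimum density strictly between them — the "pit" — is the
natural split: values above it are called `AA` (homozygous), values below
or exactly at it `AB` (hemizygous). The tie at the pit goes to the
hemizygous side because hemizygotes are the larger expected class (2/4
under 1:2:1), minimizing expected misassignment. Two guards temper raw
mode counting, which otherwise mistakes sampling wiggles in unimodal data
for second modes: a candidate mode must reach at least 5% of the maximum
density, and the pit density must fall below 90% of the smaller mode's
density. With these defaults, unimodal populations of the sizes used here
are only rarely (a few percent of seeds) called bimodal, while mixtures
at the study's separation and dispersion are detected essentially always;
the test suite bounds both behaviors. Both thresholds are exposed as
configuration.

**K-means, exactly.** In one dimension the optimal two-cluster partition
is contiguous in sorted order, so instead of iterating Lloyd's algorithm
from random starts the package scans all $n-1$ contiguous splits and
returns the global minimum of the within-cluster sum of squares —
deterministic and exactly optimal. A deterministic Lloyd variant
(centroids initialized at the 10th/90th percentiles) is provided for
comparison; it can only tie, never beat, the exact search, and the exact
optimum is verified to be a fixed point of the Lloyd update. The cluster
with the larger centroid is `AA`.

**Model support.** A two-cluster K-means fit always *produces* two
clusters, even on one genotype class; the remark that points gravitate to
the larger cluster is precisely why a fit criterion is needed rather than
a biased assignment rule. Sarle's cubic clustering criterion compares the
observed $R^2 = 1 - \mathrm{SSW}/\mathrm{SST}$ with its expectation under
a uniform null; specialized to one dimension and two clusters,

$$E(R^2) = 1 - \frac{1/(n+2)}{4}\cdot\frac{(n-2)^2}{n}\left(1 +
\frac{4}{n}\right), \qquad
\mathrm{CCC} = \ln\!\frac{1 - E(R^2)}{1 - R^2} \cdot
\frac{\sqrt{n/2}}{(0.001 + E(R^2))^{1.2}} .$$

CCC is zero when the observed $R^2$ equals its null expectation and
values of at least 2 are taken as evidence of genuine two-cluster
structure. A population in which *neither* method finds support — pit
not bimodal and CCC below threshold — gets no forced `AA`/`AB` final
calls: its transgenic samples stay uncalled and the population is
flagged. This is what keeps an all-homozygous parent line from being
split in half. Where both methods run, per-sample concordance between
them is recorded, and a Tukey–Kramer HSD (the two-group studentized
range, $q = t\sqrt{2}$, with the unequal-$n$ standard error) quantifies
the separation of the cluster means.

## Segregation statistics

Single-locus Mendelian expectations are tested with both the Pearson
chi-square $\sum (O-E)^2/E$ and the likelihood-ratio statistic
$G = 2\sum O\ln(O/E)$ (with $0\ln 0 = 0$), each on $k-1$ degrees of
freedom without continuity correction: 3:1 for transgenic:null presence
counts, 1:2:1 for homozygous:hemizygous:null final calls. A distribution
"fits" only when *both* tests are non-significant — a conservative
conjunction, chosen because the two tests are reported side by side
without a stated combination rule and they agree to first order anyway.
No multiple-testing correction is applied across populations. The
`missing` class is excluded from all segregation totals.

Parental zygosity predictions are confirmed in selfed progeny families:
a predicted homozygote is confirmed by *no construct segregation* — zero
null progeny and a unimodal family trait distribution — while a
predicted hemizygote is confirmed when its progeny counts fit 1:2:1.
Family confirmation therefore needs no dosage split at all in the
homozygous case, which is why forced cluster labels are never held
against a uniformly transgenic family.

## The simulator

Every stage above is testable without laboratory data through a
generative model of the assay. Per cycle, product follows the discrete
logistic recursion

$$P_{i+1} = P_i + e\,P_i\left(1 - \frac{P_i}{K}\right),$$

with $P_0$ proportional to template copies (transgene markers carry 0, 1
or 2 copies by genotype; the reference always 2). Unsaturated, this is
geometric growth and the hemizygous:homozygous product ratio is exactly
0.5; as products approach the capacity $K$ the ratio climbs toward 1,
reproducing both the 10-cycle discrimination window and the plateau at
20–40 cycles. The logistic form (rather than capped exponential) was
chosen so the plateau emerges smoothly. Touchdown pre-cycles, common to
all samples, are absorbed into the calibration constants.

Measurement adds independent multiplicative lognormal noise to height
and area, per-marker amplification failure, a detection threshold, and
an optional dilution factor applied to all of a sample's peaks (which
downstream calls must be — and are — invariant to).

Defaults, chosen once to mirror the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `efficiency` | 0.9 | per-cycle gain of a well-optimized reaction |
| `cycles` | 10 | the log-phase window |
| `initial_template` | 1 | product units per template copy |
| `capacity` | 1e5 | keeps the 10-cycle regime essentially unsaturated while plateauing by 30 cycles |
| `height_scale` / `area_scale` | 0.65 / 4.5 | put normalized heights near 400 (hemizygous) and 800 (homozygous) RFU, the scale of real exports |
| `detection_threshold` | 50 RFU | 5-cycle products (~30 RFU) fall below it; 10-cycle products are far above |
| `noise_cv` | 0.085 | per-measurement CV; normalized traits divide two noisy measurements, so their class CV compounds to ≈ 12%, the dispersion at which segregating populations are reliably bimodal with CCC well above 2 |
| `marker_failure_rate` | 0.01 (NPTII-3: 0.05) | occasional amplification dropout; elevated for the marker that amplifies least consistently |

With these settings a simulated 240-plant 1:2:1 population yields ≈ 70%
transgenic, ≈ 25% null and ≈ 5% missing samples, and class recovery
against the simulated truth exceeds 95% — the package's validation runs
use 20 such populations, plus 2000 multinomial null replicates to check
the empirical size of the 1:2:1 tests.

What the simulator does *not* emulate: inter-marker efficiency
differences beyond dropout, fragment-sizing error structure, plate and
batch effects, DNA quality gradients, or pipetting correlation between
markers of one sample. Passing the simulation-based tests therefore
demonstrates the statistical machinery is correct under the model's
assumptions, not that any particular laboratory will achieve the same
error rates.

## Numerical choices and degenerate inputs

* Density grid: 512 points from the minimum to the maximum observation
  (no tail padding); boundary grid points may be modes, which matters for
  near-point-mass clusters.
* K-means ties (equal within-SS at two splits): the first split in sorted
  order is kept; assignment ties in the Lloyd variant go to the lower
  cluster.
* Zero-variance inputs, single-class K-means input, and empty groups
  raise typed errors (`zygocall_degenerate_error`,
  `zygocall_validation_error`) rather than returning silently wrong
  structures; $R^2 = 1$ makes CCC $+\infty$ with a warning.
* All file output prints numerics at full precision so write/read cycles
  are exact; call files order rows by sample id so outputs are
  byte-deterministic.

## Known limitations

Single biallelic locus only: copy numbers above 2, multi-locus
insertions, and linkage are out of scope. One expected amplicon per
primer pair — multi-peak markers are rejected, not resolved. The pit
detector assumes enough samples (default minimum 20) for a usable
density estimate; small families rely on the K-means/CCC route or on
presence counts alone. And the choice between peak height and area is
left to the user; both are computed, height is the default, and the two
are reported side by side rather than fused.
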