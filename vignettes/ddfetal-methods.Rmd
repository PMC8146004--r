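---
title: "Methods: droplet-count fetal genotyping and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet-count fetal genotyping and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddfetal)
```

## The measurement model

A duplex ddPCR well partitions cell-free DNA from maternal plasma into
`n` droplets (typically 11,000–18,000) and reads each droplet as
positive or negative in two fluorescence channels. Each channel detects
one allele of a blood-group locus — or, for the RHD assay, the RHD
target in FAM and a β-globin total-DNA control in HEX. Two assumptions
make fetal genotyping possible from a single well:

1. **Maternal homozygosity.** The analysis is only applied when the
   mother is homozygous at the locus. Every positive droplet in the
   other allele's channel (the *fetus-specific* channel) then comes from
   fetal DNA or from noise. `maternal_context()` enforces this and
   refuses heterozygous mothers; for the RHD assay it also refuses
   RHD-positive mothers, whose own signal would mask the fetus. RhD
   negativity is modeled as whole-gene deletion (the dominant mechanism
   in European populations), so RHD is presence/absence rather than a
   SNP.
2. **One molecule per positive droplet.** At the occupancies of cfDNA
   wells (a few percent of droplets positive) multi-molecule droplets
   are rare, so droplet counts approximate molecule counts. The
   simulator deliberately does *not* build this assumption in — molecule
   counts are Poisson per droplet — so its failure at high occupancy is
   observable.

Under these assumptions, with FSP fetus-specific and MSP
maternal-specific positives, a heterozygous fetus contributes one
fetus-specific copy per fetal genome while all genomes contribute two
maternal-allele copies, giving the fetal fraction

$$\mathrm{FF} = \frac{\mathrm{FSP}}{(\mathrm{MSP} - \mathrm{FSP})/2},$$

the ratio of fetal to *maternal* genome-equivalents (not fetal/total;
the two differ by a factor $1+\mathrm{FF}$). For the RHD assay MSP is
the total-DNA control count and the same formula is applied by
convention, reproducing the published reporting; the estimand there is
$2f/(2+f)$ rather than $f$, a ≤11% relative understatement across the
observed FF range. The opt-in `total-reference` method ($2\,
\mathrm{FSP}/\mathrm{MSP}$) documents that semantics gap; neither it nor
the Poisson-corrected method is the default, because the raw-count
formula is the field's reporting convention for these wells.

## Quantification

`lambda_estimate()` is the standard digital-PCR Poisson inversion
$\lambda = -\ln(1 - n_{pos}/n)$, with a saturation error when every
droplet is positive. `copies_per_microliter()` converts occupancy to
concentration with a droplet volume of 0.85 nL by default (the common
instrument convention; configurable). The `poisson-corrected` FF method
replaces each count by $n\lambda$ before applying the FF formula; it
agrees with raw counts to within ~$\lambda/2$ relative, i.e. ≈2% when
all occupancies are below 0.05, and diverges predictably above that.

### Uncertainty

`fetal_fraction_ci()` treats FSP and MSP as independent Poisson counts
and propagates to $\log \mathrm{FF}$ by the delta method:

$$\operatorname{Var}(\log \mathrm{FF}) \approx
\left(\tfrac{1}{\mathrm{FSP}} + \tfrac{1}{\mathrm{MSP}-\mathrm{FSP}}\right)^2
\mathrm{FSP} + \frac{\mathrm{MSP}}{(\mathrm{MSP}-\mathrm{FSP})^2},$$

giving a multiplicative interval that always contains the point
estimate and respects FF > 0. A log-scale delta method was chosen over a
bootstrap for transparency and determinism; measured against simulator
truth (the acceptance suite, 1,000 wells across all five informative
scenarios) its 95% coverage is ≈94%, with the small shortfall driven by
the raw-count bias at the highest-occupancy scenarios. With FSP = 0 the
upper bound uses the rule of three. `lambda_ci()` uses the analogous
delta method on the occupancy scale.

Reported percentages follow the clinical reporting convention: whole
percent at ≥10%, one decimal below 10%.

## Classification

`auto_threshold()` is an exact one-dimensional two-means: every split of
the sorted amplitudes is scored by within-cluster sum of squares
(computed in O(n) by prefix sums). The split is accepted as bimodal when
it reduces the total sum of squares by at least a factor of 4
(`bimodality_factor`); the cutoff is then the midpoint between the
cluster means. Otherwise the channel is treated as a single negative
cloud and the cutoff falls back to the 10%-trimmed mean plus 7 trimmed
SDs, which places a clean NTC entirely below threshold; degenerate
constant input yields a zero-SD fallback and therefore zero positives.
Instrument software performs this step opaquely on real data (and
sometimes fails, requiring a manual line); here a manual cutoff always
overrides the automatic one and the provenance (`auto`/`manual`) is
recorded in every report. Ties at the cutoff classify negative — the
conservative direction for fetal detection. A double-positive droplet
counts in both channels' tallies (the instrument-export convention);
the four joint classes are checked to partition the well exactly.

## Decision rules

`decision_thresholds()` defaults: NTC ≤ 4 positives per channel
(per-channel, matching per-channel NTC tallies); positive call from
FSP ≥ 5; repeat zone `[3, 7]` (the mandated "repeat around the limit"
with a configurable half-width of 2, recorded in every report); and
MSP ≥ 200 for any conclusive result — chosen just below the smallest
maternal-channel count observed across the study wells (239), so a
fetal-negative call is only issued when enough cell-free DNA was
measured for absence to be informative. With non-default thresholds
that open a gap between the NTC ceiling and the calling limit, counts
inside the gap return INCONCLUSIVE rather than a silent call. The
decision function is monotone in FSP and is tested exhaustively against
a brute-force rule table over FSP 0–12.

## The simulator and what it does (not) show

`simulate_well()` draws per-droplet molecule counts
$k_c \sim \text{Poisson}(\lambda_c)$ independently per channel, with
$\lambda_c = (\text{maternal copies} + f\cdot\text{fetal copies})\,
\lambda_g$; thins by a per-molecule detection dropout (default 0);
marks molecule-free droplets positive with probability
`false_positive_rate` (default 2×10⁻⁵ per droplet per channel, matching
the 0–4 positives observed in ~15,600-droplet NTCs); and draws
amplitudes from Gaussian clouds (negative 1,000 ± 150, positive
8,000 ± 400 arbitrary units) with 1% uniform "rain" between the cloud
means. No amplitude statistics are published for these assays — only
plot morphology — so the clouds are chosen cleanly separable with
visible rain, and `expected_counts()` provides the closed-form oracle
$n[(1-e^{-\lambda(1-d)}) + e^{-\lambda(1-d)}\,\mathrm{fp}]$ that the
simulator is tested against.

`published_scenarios()` calibrates one scenario per cohort genotype
group: well size and maternal-channel load are back-solved from the
published group means, and fetal fractions span the observed 3.5–26%.
Defaults elsewhere (14,000 droplets, $\lambda_g = 0.025$, i.e. ~700
maternal-channel positives) sit in the middle of those ranges.

Passing the recovery tests therefore shows that the pipeline inverts
*this* generative model at realistic loads — it does not validate
instrument-specific amplitude behavior, inter-well drift, droplet
volume variability, or contamination/carry-over, none of which are
modeled. Real amplitude distributions are heavier-tailed and
assay-dependent; the poorly separated assays that need manual cutoffs in
practice are represented only through the manual-override path.

## Validation problem sizes

The test suite checks: exact replay of the two published per-sample
wells (FF 26% and 23%); the rule table over FSP 0–12; per-droplet-loop
equivalence on 1,000 random droplets; simulator-versus-closed-form
fidelity at 200,000 droplets for occupancies 0.005/0.05/0.2 (99%
binomial bands); end-to-end recovery on 200 wells × 5 scenarios with
call accuracy ≥ 99% (for true FF ≥ 5% and ≥ 300 maternal positives) and
interval coverage in 92–98%; and occupancy-interval coverage ≥ 90/100 at
λ = 0.05, n = 14,000. These sizes keep the full suite under a minute on
a laptop while leaving the binomial bands tight enough to detect
calibration errors of a few percent.

## Known limitations

- Cohort-level published figures (group-mean FFs, cohort concordance)
  cannot be recomputed because per-sample counts are published for only
  one group; they are covered indirectly by the property-based suite.
- The RHD fetal fraction inherits the total-DNA-reference semantics gap
  described above.
- Heterozygous mothers, multi-well merging, and gestational-age priors
  are out of scope by design; the caller flags, but does not manage,
  the repeat workflow.
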