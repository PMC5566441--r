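---
title: "Selfie-dPCR: model, estimators and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selfie-dPCR: model, estimators and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Selfie-dPCR quantifies an exonic amplicon twice in the same unpurified
lysate: in an aliquot that underwent reverse transcription (RT+, measuring
gene DNA plus cDNA made from the gene's transcripts) and in a paired
aliquot without the enzyme (RT−, gene DNA only). With both measurements on
matched units, the absolute number of transcripts per copy of the encoding
gene is

$$t/g = \frac{N_{RT+} - N_{RT-}}{N_{RT-}}.$$

Because the statistic is a ratio of concentrations measured with the same
primers in the same sample, per-sample extraction efficiency, droplet
volume and dilution factors cancel; only the classification of droplets
into positive and negative enters.

Each dPCR well partitions the reaction into ~20,000 nanolitre droplets.
Under random partitioning the per-droplet copy number is Poisson, so the
mean copies per droplet is recovered from the fraction of *negative*
droplets:

$$\hat\lambda = -\ln\frac{\text{negatives}}{\text{total}},
\qquad
\widehat{\mathrm{var}}(\hat\lambda) = \frac{1-\hat p}{n\,\hat p},
\quad \hat p = \frac{\text{negatives}}{\text{total}}.$$

Copies per reaction are $\hat\lambda \times n$ over the accepted droplets,
and copies per µl of original sample divide by the *effective sample
volume*: the volume of lysate contained in one reaction, obtained by
multiplying the sample input volume by the fraction carried forward at
each step of the dilution chain. For the default protocol chain (0.5 µl
lysate → 5 µl pre-annealing → 10 µl RT → 95 µl dilution → 9.5 µl into the
20 µl reaction) this is $0.5 \times 9.5/95 = 0.05$ µl. A well with no
negative droplets carries no information about $\lambda$ beyond a lower
bound and is reported as `SATURATED` rather than as a number.

Derived metrics are arithmetic on these absolute estimates:

* **copies per genome** — ratio of a target's RT− concentration to that of
  a single-copy reference gene on the same sample, each through its own
  dilution chain (high-copy targets are measured at stronger dilution);
* **transcripts per genome** — product of t/g and copies per genome;
* **strand-specific mtDNA transcription** — t/g measured with H-only,
  L-only or combined RT priming of the same mtDNA amplicon; the sum of the
  separate strand measurements should agree with the combined measurement,
  which the `strand_metrics()` consistency z-score checks;
* **integrations per genome** — copies per genome of a proviral marker
  (WPRE), with native gene copies added to give template genes per genome;
* **percent differences and silencing** — signed
  $100(\mathrm{obs}-\mathrm{exp})/\mathrm{exp}$ and
  $100(\mathrm{unsil}-\mathrm{sil})/\mathrm{unsil}$.

## Uncertainty propagation

Within-well uncertainty comes from the occupancy estimate. Confidence
intervals on $\lambda$ use the normal (Wald) approximation with the
delta-method variance above; when either droplet class has fewer than 30
members — where the normal approximation is poorest — the interval is
replaced by an exact Clopper–Pearson interval on the negative fraction,
transformed through $-\ln$. The 30-count switch point is the conventional
boundary for binomial normality and is configurable.

Difference and ratio statistics (RNA copies, t/g, copies per genome)
propagate the two independent well variances by the delta method; for a
ratio $R = a/b$,
$\mathrm{var}(R) \approx R^2\,(v_a/a^2 + v_b/b^2)$. A t/g estimate is
flagged `detected` when its interval excludes 0. Negative t/g values are
reported as-is: they are the expected sampling behaviour of an
untranscribed gene, and the detection flag — not truncation — carries the
inference. Replicate-level results are summarised as mean ± SEM, and group
comparisons use one-way ANOVA with Bonferroni-adjusted pairwise
pooled-variance t tests (`compare_groups()`, with `tidy()`/`glance()`
accessors).

RT efficiency is treated as 1 in estimation — the protocol's gene-specific
high-temperature priming makes reverse transcription of the target
effectively complete — so no correction is applied; the simulator can set
`rt_efficiency < 1` to quantify the bias this would cause (t/g scales
linearly with it).

## Thresholding

The droplet reader's automatic threshold is vendor-defined and
unspecified; the package uses a deterministic, parameter-light equivalent:
an Otsu-style two-class variance-maximising split of the amplitude
histogram (256 bins spanning the observed range), with ties broken toward
the lowest split point. Droplets exactly at the threshold count as
negative.

Two safeguards make the split honest:

* **Unimodality guard.** Splitting a single Gaussian mode at its centre
  yields class means ~1.6σ apart with within-class SDs ~0.6σ. If the class
  separation is below 4× the larger class SD, the well is treated as
  having no valley between modes and is flagged all-negative (threshold at
  max amplitude + 1). This correctly flags empty wells and NTCs.
* **Rare-positive limitation.** When positives are below roughly 0.2% of
  droplets, the between-class variance of the true split can fall below
  that of a split inside the negative mode and Otsu mis-splits. The
  pipeline therefore classifies NTC and flagged wells with the *consensus*
  (median unflagged) threshold of their target, and per-target manual
  thresholds can be set in the run config — mirroring common practice.

## The generative simulator

`simulate_selfie_pair()` draws one RT+/RT− pair from the measurement
model itself:

1. expected amplifiable DNA fragments per reaction
   $= \text{genomes/µl} \times V_\text{eff} \times \text{copies/genome} /
   \text{copies per fragment}$; each aliquot receives an independent
   Poisson draw;
2. expected transcripts $= \text{genomes/µl} \times V_\text{eff} \times
   \text{copies/genome} \times t/g$; the RT+ aliquot receives
   $\mathrm{Binomial}(\mathrm{Poisson}(\cdot),\ \varepsilon_{RT})$ cDNA
   molecules; the RT− aliquot never contains cDNA;
3. molecules fall into droplets uniformly at random (a multinomial split
   of a Poisson total, i.e. exactly independent Poisson occupancy);
4. fluorescence is Gaussian around a negative mode (2000 a.u.) and a
   positive mode (9000 a.u.) with common SD 300 a.u.; a `rain_fraction`
   (default 1%) of *occupied* droplets amplify only partially and are
   redrawn uniformly between the modes. Rain is restricted to occupied
   droplets because it models partial amplification; empty droplets have
   nothing to amplify, and NTC wells stay clean, as they do on the
   instrument. The amplitude values are fixture conventions, not claims
   about the instrument.

Default study conditions mirror the biology the method was demonstrated
on: 12,000 genome equivalents/µl (≈600 single-copy genes per reaction at
$V_\text{eff} = 0.05$ µl), 20,000 droplets of 0.85 nl (the accepted
nominal partition volume for the droplet system; all reported ratios are
volume-independent), and the tissue panel of `default_tissue_truth()`:
single-copy gene t/g {2.03, 0, 0.25, 0.25}, rRNA gene at 107 copies/genome
with t/g {349, 1496, 27, 6}, and mtDNA at {1096, 2302, 1759, 1774}
copies/genome with H-strand {0.55, 0.58, 1.70, 0.56} and L-strand
{0.37, 0.37, 0.44, 0.36} transcripts per copy for brain, heart, liver and
skeletal muscle. Heart's single-copy t/g is 0: the small negative printed
mean is a sampling fluctuation around no transcription, and a generative
transcript count cannot be negative. RNase and dsDNase treatments are
modelled as multiplicative survival of the RNA and DNA pools (RNase: 0%
RNA, 81% DNA; dsDNase: 10% DNA), enabling in-silico enzyme-control
experiments.

`simulate_tissue_panel()` adds the characterization step a careful
operator performs: each assay gets an extra dilution step sized so the RT+
well lands near 1.2 mean copies per droplet, keeping every well inside the
dynamic range (ceiling $10^5$ copies/reaction) and away from high
subsampling error. `linkage_bias_experiment()` varies `copies_per_fragment`
to show why restriction digestion matters for tandem multi-copy genes:
dPCR counts amplifiable *fragments*, so the copies-per-genome estimate
falls as copies/fragment rises and collapses to ~1 at full linkage.

What the simulator does **not** emulate: PCR amplification kinetics within
droplets, droplet volume variation, PCR inhibitors, nonspecific priming
products (which on the instrument appear at distinct amplitudes), or
between-animal biological variance. Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated sampling
model, not robustness to instrument artefacts.

## Numerical and design choices

* Poisson λ of a merged set of replicate wells is computed from pooled
  counts, which for equal wells coincides with the precision-weighted
  mean; pooling is restricted to wells sharing sample, target, RT
  condition and dilution chain.
* Whether vendor-reported copy numbers are per reaction or per µl is
  ambiguous in practice; the package reports both
  (`copies_per_reaction`, `copies_per_ul_sample`). Every ratio statistic
  is invariant to the choice.
* QC defaults: dynamic-range ceiling $10^5$ copies/reaction, droplet floor
  10,000, NTC ceiling 5 positive droplets, subsampling cap 25% relative CI
  half-width. All configurable in the run config.
* No third "nonspecific product" amplitude class is modelled or called;
  wells where that matters should use manual thresholds.
* End-to-end runs are seeded and write a manifest (package version, seed,
  config hash, well set), and repeated runs are byte-identical.

## Validation problem sizes

The test suite validates the estimators at sizes chosen to make the checks
sharp while keeping the suite quick: estimator bias at λ ∈ {0.01, 0.1, 1,
3} over 500 wells of 20,000 droplets (< 1% relative bias); 95% interval
coverage over 2,000 wells at λ = 1 (observed within [93%, 97%]); t/g and
copies-per-genome recovery within the propagated 95% CI in ≥ 90% of 200
simulated experiments; occupancy-law and conservation properties over 50
seeded runs; and zero classification errors on 100 wells with
well-separated modes. The full tissue panel is exercised at reduced
replicate counts; its defaults are the study conditions above.

## Known limitations

* The Otsu-style threshold needs ≥ ~0.2% positives or an external
  threshold; true single-molecule wells rely on consensus/manual
  thresholds.
* Delta-method intervals on ratios are first-order; with very few RT−
  positives the t/g interval is approximate even though the underlying λ
  interval is exact.
* The RT− aliquot is taken to measure double-stranded gene copies only;
  single-stranded DNA priming is not modelled.
* Isoform- or processing-level resolution is out of scope: the method
  counts total transcripts carrying the amplicon.
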