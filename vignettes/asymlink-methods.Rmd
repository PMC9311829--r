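---
title: "Quantifying fluctuating asymmetry and linking it to inbreeding and pollutant burdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluctuating asymmetry and linking it to inbreeding and pollutant burdens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymlink)
```

## The problem

Fluctuating asymmetry (FA) — small, random deviations from perfect
bilateral symmetry — is widely used as a proxy for developmental
instability in wild populations under stress, for example from
persistent, bioaccumulative, toxic chemicals (PBTs) such as mercury and
indicator PCB congeners. Detecting FA credibly requires three things
that this package bundles into one tested workflow:

1. **Geometry.** Asymmetry must be measured on superimposed landmark
   configurations, separately for *matching symmetry* (a paired
   structure such as left and right wings, digitized as two
   configurations) and *object symmetry* (a single structure with an
   internal midline, such as a head).
2. **Measurement-error control.** FA signals are tiny; imaging and
   digitizing error must be shown to be negligible with nested
   replicate measurements in a Procrustes ANOVA.
3. **Careful inference downstream.** Chemical burdens are typically
   measured on *pooled* samples, so the burden covariate takes only as
   many distinct values as there are pools; and inbreeding (indexed
   from microsatellites) can mimic or mask pollutant effects and must
   be screened alongside.

## Superimposition

`gpa()` performs generalized Procrustes analysis: all configurations
are centered, scaled to unit centroid size, and iteratively rotated to
a consensus re-estimated as the (re-normalized) mean, until its RMS
change is below `1e-10` (default; 200-iteration cap, non-convergence is
flagged, not thrown). Rotations are solved in closed form from the
cross-covariance of the centered, scaled configurations, so the fit is
deterministic. Because the fit fixes all configurations at unit
centroid size, shape and size are cleanly separable: size enters the FA
analysis only through the retained per-configuration centroid sizes.

Two numerical choices matter:

* **Orientation canonicalization.** A GPA fit is defined only up to a
  joint rotation. We rotate the converged solution so the consensus'
  first landmark lies on the positive x-axis, making the output
  strictly invariant (to ~1e-15 in practice) under arbitrary similarity
  transforms of the inputs. This is degenerate only if landmark 1 sits
  exactly at the centroid of the consensus.
* **Initialization.** The provisional consensus is the first
  configuration after centering/scaling; ties cannot arise, so the
  algorithm is reproducible bit for bit.

`opa_align()` exposes the pairwise solution (SVD-based, reflection
excluded by default by forcing a positive-determinant rotation) and is
cross-checked in the tests against an exhaustive rotation-grid search.

## Symmetry decomposition and Procrustes ANOVA

Under **matching symmetry**, left configurations are reflected about
the y-axis and all configurations enter one joint GPA
(`matching_decomposition()`). Under **object symmetry**
(`object_decomposition()`), each configuration is doubled by a
reflected copy with paired landmark labels swapped (the pairing is
validated as a partition of `1..k` into pairs plus midline); the
symmetric component of a specimen is the mean of the original and
reflected aligned copies, the asymmetric component half their
difference. The doubled-set consensus is reflection-symmetric to
machine precision, which the tests assert via a rotation-only
alignment of its reflected relabeled copy.

`procrustes_anova()` partitions summed squared coordinate deviations
over the nested design (Goodall-style), with degrees of freedom equal
to conventional univariate df times the shape dimension:

* matching symmetry: `2k - 4`;
* object symmetry with `p` pairs and `m` midline landmarks: the
  symmetric and asymmetric components each span `2p + m - 2`
  dimensions (the translation/rotation/scaling degrees of freedom
  split two-and-two between the components), and the implementation
  asserts the two add up to `2k - 4`.

The strata, in testing order, are: location (object mode, between
individuals), individual, directional asymmetry (the side main effect,
or the grand-mean asymmetric component), fluctuating asymmetry (the
individual-by-side interaction, or individual deviations of the
asymmetric component), imaging error, digitizing error. Each F ratio
uses the next stratum down as denominator; individual and directional
asymmetry are both tested over FA, and the lowest stratum carries no F
or p. In particular, an object-symmetry analysis *without* replicate
measurements reports the FA row with no F or p — there is no error
stratum to test it against — which is why an error study with a second
digitization matters.

A `directional_asymmetry` row is always emitted even though many
published tables omit it: without that row the table's sums of squares
would not add to the total (additivity is exact for balanced designs
and for all purely nested strata), and directional asymmetry must be
separated from FA regardless, otherwise it inflates every FA score.
Unbalanced side-by-individual cell counts are handled by computing the
crossed strata from cell means with harmonic-mean replicate weighting;
such tables are flagged unbalanced and additivity is then approximate.

`error_study()` wraps this into the standard verdict: measurement
error is "nonsignificant" when both the individual and the FA mean
squares significantly exceed the error mean square at `alpha = 0.05`.

## FA scores

`fa2(R, L)` is the size-standardized signed index
`(R - L) / ((R + L)/2)` on side centroid sizes — antisymmetric, scale
invariant, zero iff `R = L`. For object-symmetric structures there is
no canonical definition of a side "size", so the
package's documented convention is the centroid sizes of the
pairing-defined left and right landmark subsets (midline landmarks
belong to neither side).

`fa_scores()` additionally reports `fa_shape`, the Procrustes distance
between an individual's two side configurations after subtracting the
sample-mean directional asymmetry (replicates are averaged first).
Whether a "shape FA" covariate in downstream models should be the
size-based FA2, its magnitude, or the shape distance is genuinely
ambiguous in field practice; the pipeline exposes all three through
the `response` switch (`fa2`, `fa2_abs`, `fa_shape`, default
`fa_shape`) rather than guessing. Note that signed FA2 has mean ~0 by
construction, so variance-type effects on asymmetry are visible only
in the magnitude-type responses.

## Marker screening and inbreeding indices

Loci are screened with `het_stats()` (observed heterozygosity, and
expected heterozygosity with the small-sample factor `2n/(2n-1)`,
appropriate for small per-nest samples), `hwe_exact()` (the exact
conditional test given allele counts under the Levene distribution:
full enumeration of genotype arrays when the array space is small,
otherwise seeded Monte-Carlo shuffling of the allele vector with the
`+1` correction so p is never 0), and `ld_test()` (a genotypic
G-statistic permutation test — no haplotype-phase estimation, since
phase is unknown in diploids). Holm's step-down correction
(`holm_adjust()`, backed by `stats::p.adjust`) is applied within each
test family.

`inbreeding_indices()` computes, per individual, multilocus
heterozygosity (`mlh`, the fraction of typed loci that are
heterozygous) and `d2`, the mean squared difference between the two
alleles in repeat units, averaged over typed loci (the plain mean, no
outlier trimming). Alleles are expected in repeat units; the CSV and
Genepop readers divide base-pair sizes by per-locus motif lengths when
supplied. Missing data are handled by pairwise deletion. `d2` depends
only on allele differences, so any additive relabeling leaves it
unchanged — a tested invariant.

`compare_groups()` mirrors common field practice: Shapiro-Wilk on each
group at `alpha = 0.05`, then a Welch t-test when both pass and a
Mann-Whitney U test otherwise, with Holm correction across whatever
batch of comparisons is submitted together.

## Linking pooled burdens to individual asymmetry

`expand_pools()` assigns each individual its pool's concentration for
every analyte (Hg and PCB congeners 28, 52, 101, 138, 153, 180;
`sumPCB` is validated against the congener sum but not modeled). The
function warns that effective replication is at pool level, and the
model results record the number of distinct covariate values: with two
pools, every analyte covariate is an affine image of every other, so
|t2| is *identical* across all seven analytes — a structural fact the
tests assert, and a caution against over-reading per-analyte results.

`fit_linkage_model()` is ordinary least squares (plain OLS standard
errors, no clustering) of an FA response on an inbreeding index, an
analyte, and optionally location, reporting t-values in fixed order
(t1 inbreeding, t2 analyte, t3 location), adjusted R² (which can be
negative), and a Kolmogorov-Smirnov test of standardized residuals
against the standard normal (skipped below 10 residuals or for
degenerate fits). Rank deficiency — e.g. a single pool making the
analyte constant — yields a flagged result naming the offending
columns rather than an exception.

`run_model_battery()` runs the Cartesian battery {responses} x {mlh,
d2} x {7 analytes} (28 models for fore+hind wings, 14 for heads). When
any model for a response fails the residual check at `alpha`, that
response is transformed once with `tukey_transform()` — the ladder of
powers `x^l` (l > 0), `log x` (l = 0), `-x^l` (l < 0, sign flip
preserving order) over the grid `-5..5` in steps of 0.025, selecting
the exponent maximizing the Shapiro-Wilk W — and all of that
response's models are refit with the selected exponent recorded. The
fine grid step is chosen because published selections are often off a
coarse 0.25 grid. Two caveats are deliberate: non-positive responses
are shifted by `-min + eps` first (logged), and on data whose
coefficient of variation is small the W profile is nearly flat in the
exponent, so the selected value is noisy — near-identity selection is
only identifiable when the spread is an appreciable fraction of the
mean.

## The synthetic-study generator

`make_landmarks()` emulates the measurement design: template shape
(unit centroid size) + per-individual shape deviation (`sd_individual`
per coordinate) + antisymmetric FA deviation + optional directional
offset + per-photograph (`sd_image`) and per-digitization (`sd_digit`)
isotropic Gaussian noise, with each stored configuration under a
random rigid rotation/translation so superimposition is actually
exercised. `sd_fa` is scaled so the nested-ANOVA identity
`(MS_FA - MS_err) / r = sd_fa^2` holds exactly in expectation, which
is what the variance-recovery test checks (within 15% at n = 200, two
digitizing replicates). Size asymmetry is injected as `R = L(1 + d)`,
giving mean FA2 of `d/(1 + d/2)` in closed form.

`make_genotypes()` draws allele pairs that are identical by descent
with probability `F`, so expected heterozygosity scales by `(1 - F)`.
`make_study()` assembles a two-location study shaped like a field
campaign — two bumblebee pools (64 + 4 individuals by default) with
20-landmark forewings and 6-landmark hindwings, four ant pools
(67/49/48/40) with 29-landmark object-symmetric heads (13 pairs +
3 midline points, the package's documented scheme), genotypes at 7 and
13 loci, and pooled concentrations spanning field-realistic ranges
(Hg ~1.2-11, congeners ~0.05-0.45 µg/kg fresh weight, kept distinct
across pools). The optional positive control couples burden to FA
*variance* (not mean), because FA is a variance phenomenon; it is
detectable through magnitude responses.

What the generator does *not* emulate — and hence what passing tests
cannot certify about real data: non-Gaussian digitizing blunders,
landmark-specific error covariance, allometry, antisymmetry,
linkage between loci, null alleles, and congener profiles that covary
biologically. It is a calibration instrument, not a field simulator.

## Problem sizes and determinism

All simulation-based checks fix their seeds and use sizes chosen to
make the assertions sharp at desk scale: 2000 null datasets (n = 30
individuals, k = 10) for the FA type-I calibration, n = 200
individuals with two replicates for variance recovery, 10^4 Monte-Carlo
permutations against full enumeration for the HWE oracle, 1000 null
fits for the analyte-t calibration, and n = 500 individuals per
inbreeding level. Every generator is a pure function of its arguments
and seed, and `run_all()` writes byte-identical stage CSVs on rerun
(manifest timestamps aside), fanning one top-level seed out to stages
by fixed offsets.

## Known limitations

* Matching-symmetry ANOVA does not include location/nest strata;
  multi-site wing analyses are run per site (the object-symmetry
  design does support a location stratum).
* OLS on pool-expanded covariates understates uncertainty when
  individual-level errors are correlated within pools; the output
  records `n_pools` so the pseudo-replication is visible, but no
  clustered or mixed-effects correction is applied.
* No allometry correction, tangent-space diagnostics, antisymmetry/
  kurtosis screening of FA distributions, or shape visualization.
* The exact HWE test enumerates only when the array space is small;
  otherwise Monte-Carlo error of order `1/sqrt(B)` applies.
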