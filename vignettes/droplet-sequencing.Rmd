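---
title: "Droplet-ordered single-molecule sequencing: simulation model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet-ordered single-molecule sequencing: simulation model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropseqr)
```

# The measurement being modelled

In droplet-ordered single-molecule sequencing, nucleotides are cleaved one
at a time from the end of a single template strand (by pyrophosphorolysis,
the reverse polymerase reaction) while a stream of microdroplets passes
over the template at a fixed rate. Each droplet captures whatever dNTPs
were released during its transit, and a downstream enzymatic detection
reaction converts the captured dNTP into a fluorescence signal in a
base-specific colour channel. Because droplets pass in a known order, the
droplet sequence *is* the base sequence — up to three complications that
drive everything in this package:

1. **Occupancy is random.** Release and passage are not synchronized, so
   some droplets capture nothing and some capture several consecutive
   bases ("multi-base droplets"), whose within-droplet order is lost.
2. **Detection is analogue.** A channel's fluorescence is a draw from an
   "occupied" or "unoccupied" intensity distribution; the two overlap,
   so occupancy must be inferred, with quantifiable false-positive and
   false-negative rates.
3. **Contamination happens.** Free dNTPs unrelated to the template give
   occupied signals in droplets that never saw the DNA ("stochastic
   false positives"), observable directly in blank droplet arrays.

`dropseqr` implements both the generative model (a simulator standing in
for real droplet-array recordings) and the analysis chain: mixture
fitting, occupancy calling, error-rate estimation, read reconstruction,
alignment, two-channel 5-methylcytosine classification and GC profiling.

# The generative model

## Base capture

Each droplet captures `k ~ Poisson(capture_rate)` bases. The literature
this package models does not name a capture-count law; Poisson is the
natural choice for rate-limited enzymatic release sampled by droplets at
a fixed frequency, and it reproduces the observed multi-base statistic
with a single parameter. Capture is truncated so the cumulative total
never exceeds the reference length, and each droplet's bases are the
next consecutive reference bases — stored as an unordered multiset,
because within-droplet order is physically meaningless.

The default `capture_rate = 0.455` is calibrated against the reported
operating point at which 21% of occupied droplets hold more than one
base. Under the truncated Poisson this fraction is

$$\frac{P(k \ge 2)}{P(k \ge 1)} = \frac{1 - e^{-\lambda}(1+\lambda)}{1 - e^{-\lambda}} = 0.21 .$$

The exact root is $\lambda = 0.45428$; the package uses 0.455, which
matches the calibration target at its printed precision
(`calibrate` yourself with `uniroot` if you need more digits).

One consequence of boolean per-channel detection is worth stating
plainly: a droplet that captures two bases *of the same colour* reports
that channel once, so the reconstructed read loses a base. This is an
inherent information loss of the measurement, not a simulator artifact,
and it is why the error-free limit of the pipeline is exercised on
references without short-range base repeats (see below).

## Contamination and misidentification

Independently per droplet per colour, a contaminant dNTP is present with
probability `contamination_rate` (default 0.031 per droplet per colour,
the rate observed in blank arrays for the best-characterized run; 0.040
is a typical run-to-run alternative). The pooled rate is reported
per-colour without structure, so contaminants are colour-uniform and
independent, and contamination may co-occur with genuine capture (the
less restrictive model). Every present dNTP reports its own channel
except with probability `misidentify_rate` (default 0.001, matching a
capture specificity above 99.9%), when it reports a uniformly chosen
wrong channel.

## Intensities

Occupied and unoccupied droplets each draw fluorescence from a
heavy-tailed distribution. The family is log-normal — Gaussian on log10
intensity — which is heavy-tailed on the linear scale, matches the
visible shape of droplet intensity histograms, and makes EM fitting
standard. The `family` tag is carried through the configuration so a
location-scale Student-t variant can be swapped into the simulator;
the EM fitter currently implements the log-normal family only.
A channel with two or more same-colour dNTPs draws from the same
occupied component as a singly occupied one — "one or more" is a single
population.

The default component parameters are not arbitrary: with locations fixed
at 2.0 and 3.2 log10 units and 30% occupancy, the two scales are solved
(closed form in `calibrate_intensity_model()`) so that the crossing
point of the weighted densities leaves exactly 0.1% of the unoccupied
component above it and 1.6% of the occupied component below it — the
two overlap error rates the analysis chain is expected to recover:

```{r}
default_intensity_model()
```

Droplet diameters are cosmetic realism: normal(10 µm, 1.5 µm) truncated
to (4, 15) µm, the upper cap reflecting removal of oversized droplets
upstream of detection. No diameter–intensity coupling is modelled, and
the analysis deliberately performs no per-droplet volume normalization.

## What the simulator does not emulate

Enzyme kinetics and their temperature dependence, droplet-to-droplet
chemistry variation beyond what the intensity mixture absorbs, droplet
merging mechanics, raw micrographs, and any correlation between
contamination and template position. Passing tests therefore demonstrate
the *analysis* is correct under the stated statistical model, not that
real arrays satisfy that model; the blank-array and overlap statistics
are the points of contact with reality.

# The analysis chain

## Mixture fitting and occupancy calling

`fit_mixture()` runs two-component EM on log10 intensity.
Initialization splits the data at the 60th percentile — deterministic,
order-independent, and robust across the 3–40% occupancy range the
pipeline encounters (blank arrays sit near 3%, sequencing channels near
10%, calibration plates at 30–60%). Convergence is declared when the
relative log-likelihood change drops below 1e-8, with a 500-iteration
cap; non-convergence flags the fit rather than erroring. Data that are
effectively single-population — identical values, a collapsed weight
below 1e-4, or no density crossing between the component locations —
raise a classed degenerate-fit error, because occupancy is genuinely
indeterminate there.

A droplet is called occupied when the weighted occupied density exceeds
the unoccupied density at its intensity (posterior > 0.5). A tie is
called unoccupied — conservative against insertions, which matters
because insertions (not miscalled bases) dominate the error budget. The
implementation uses a 1e-9 guard band so that an intensity sitting
exactly on the crossing root always resolves to the tie rule despite
roundoff.

The crossing point is found by bisection of the weighted-density
difference between the two component locations. With very unequal
scales a second root can exist far in the tail; the root nearest the
midpoint of the locations is used and a warning logged. Overlap error
rates are *component* tail masses beyond the crossing — the fraction of
the unoccupied peak above it (false positive) and of the occupied peak
below it (false negative) — not mixture masses, and the closed forms are
cross-checked against adaptive quadrature in the tests.

## Read reconstruction and order resolution

Occupied channels per droplet become base multisets; empty droplets are
skipped; acquisition order is preserved. Random linearizations permute
each multiset uniformly over its *distinct* arrangements (duplicate
bases carry no order information, so {A,A} has one). The
permutation-averaged identity over 20 draws is the headline accuracy of
a run; 20 is the reference protocol's draw count.

`best_order_search()` answers the complementary question — how good the
read would be if multi-base order were chosen to fit the reference. The
joint ordering space grows exponentially, so the search enumerates
exhaustively only when the product of per-droplet arrangement counts is
at most 1e4, and otherwise hill-climbs from 20 random restarts, sweeping
droplets and accepting strict identity improvements until a sweep is
quiet. The result dominates every ordering it evaluated, and equals the
exhaustive optimum whenever enumeration is feasible (tested against an
independent enumeration).

## Alignment conventions

Smith–Waterman with affine gaps, match +2, mismatch −2, gap opening −3,
gap extension −1. Three conventions are fixed and recorded because the
printed parameters alone do not pin them down:

* **Gap cost**: a gap of length L costs `|open| + (L−1)·|extend|` (the
  first gap symbol pays the opening penalty).
* **Identity**: matches divided by alignment columns *including* gap
  columns, over the local alignment span; recorded in each result as
  `identity_convention`. An empty alignment has identity 0.
* **Traceback**: deterministic — the maximal cell earliest in row-major
  order, ties within a cell resolved diagonal > up > left — so results
  are byte-reproducible.

`N` scores as a mismatch everywhere, including against `N`.

## 5-methylcytosine classification

The two-channel assay hinges on a modification-sensitive restriction
step: channel 1 fluoresces for either dCTP or 5mdCTP, channel 2 only
for unmethylated dCTP. Classification is per-channel occupancy calling
followed by a truth table — not 2-D clustering — because the populations
are defined by the per-channel probabilities. The (ch1−, ch2+) cell is
biochemically impossible and is reported as `inconsistent` rather than
merged; its rate is a direct estimate of modification-call error.

## GC profiling

Local GC content is the G/C indicator convolved with a discrete
Gaussian kernel (σ in bases, default 20, interpreted as the standard
deviation), truncated at 4σ (mass loss < 1e-4) and renormalized.
Sequence ends are handled by whole-sample reflection, which avoids the
edge droop of zero-padding in exactly the plots this profile feeds. `N`
positions are excluded from both the numerator and the normalizing
weight. Output values are convex combinations of the indicator, hence
always in [0, 1], and converge to the raw indicator as σ → 0.

# Problem sizes and numerical checks in the test suite

The statistical tests run at the sizes at which their targets are
sharp: occupancy and overlap statistics at 1e5 droplets (Monte-Carlo
standard errors of ~0.13 percentage points on the multi-base fraction,
~0.06 on the fitted false-negative rate), blank-array recovery at 1e5
droplets per colour, plate classification at 1e4, parameter recovery at
1e5, and oracle comparisons for the aligner over 200 random pairs of
length up to 30 against an independent plain-R affine dynamic program
(plus a convention-mapped `Biostrings::pairwiseAlignment` cross-check).
End-to-end pipeline checks use runs of 300–700 droplets over references
of 150–400 bases, where a full analysis takes seconds. The
default-calibrated end-to-end best-order identity is logged against its
plausibility band (0.70–0.85) but is non-gating: the corresponding
printed value was measured on deposited droplet arrays that a synthetic
run can match only in magnitude.

# Known limitations

* Only the log-normal mixture family is fitted; the Student-t tag is a
  simulator-side extension point.
* The reconstructed read cannot represent two same-colour bases captured
  by one droplet (boolean channels); deletions from this mechanism are
  inherent at nonzero multi-base rates.
* Best-order search is a local optimizer above the exhaustive-enumeration
  threshold; its value is a lower bound on the true optimum.
* No diameter- or volume-based intensity normalization is attempted.
* The loader for externally deposited droplet arrays is limited to the
  documented CSV dialects; no instrument-specific schema is assumed.
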