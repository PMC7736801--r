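# dropseqr

Simulation and analysis of **droplet-ordered single-molecule DNA
sequencing** runs.

In this measurement scheme, bases are cleaved one at a time from a single
template strand (pyrophosphorolysis) while microdroplets stream past at a
fixed rate; each droplet captures the dNTPs released during its transit
and identifies them by an enzymatic fluorescence reaction, one colour
channel per base. Droplet order encodes base order, so a sequencing read
is recovered by deciding, per droplet and per channel, whether the
droplet was *occupied* — and then dealing with the droplets that captured
several bases at once, whose internal order is lost.

`dropseqr` is aimed at people developing or evaluating this kind of
assay: it provides a calibrated stochastic simulator of a droplet run and
the complete analysis chain used to score one.

## The model in brief

* **Capture**: per droplet, `k ~ Poisson(λ)` consecutive template bases,
  truncated at the template end; the default λ = 0.455 solves the
  truncated-Poisson calibration
  `(1 − e^{−λ}(1+λ)) / (1 − e^{−λ}) = 0.21`,
  the observed fraction of occupied droplets holding more than one base.
* **Contamination**: independently per droplet per colour with
  probability 0.031 (the stochastic false-positive rate measured on
  blank arrays); misidentification of a present dNTP with probability
  0.001.
* **Intensities**: per channel, a two-component heavy-tailed (log-normal)
  mixture. Occupancy is called where the weighted occupied density
  exceeds the unoccupied one (posterior > 0.5; ties unoccupied). The
  component tail masses beyond the density **crossing point** estimate
  the overlap error rates; the default model is calibrated so these are
  0.1% false positive (per droplet per colour) and 1.6% false negative
  (per base per colour).
* **Reads**: an ordered list of unordered base multisets (`set_read`).
  Accuracy is summarized by Smith–Waterman local alignment (match +2,
  mismatch −2, gap open −3, gap extend −1; gap of length L costs
  3 + (L−1); identity = matches / alignment columns, gaps included)
  averaged over 20 random multi-base orderings, and by a best-order
  search that resolves multi-base order against the reference.
* **5-methylcytosine**: a two-channel plate assay (channel 1 fires for
  dCTP or 5mdCTP, channel 2 for dCTP only) classified by per-channel
  occupancy and a truth table.

See the vignette `vignettes/droplet-sequencing.Rmd` for the full account
of the model, its calibration and the numerical conventions.

## Worked example

Simulate a 700-droplet run over a random 400-base reference with the
default (calibrated) configuration, analyse it end to end, and inspect
the report:

```r
library(dropseqr)

cfg <- pipeline_config(
  sim = sim_config(n_droplets = 700, seed = 0),
  ref_length = 400, n_blanks = 5000, seed = 11)
report <- run_pipeline(cfg)

print(report$fits$ch655)
#> Two-component lognormal mixture fit (n = 700)
#>   unoccupied: w = 0.8361, location = 1.9989, scale = 0.0862
#>   occupied:   w = 0.1639, location = 3.1921, scale = 0.4351
#>   crossing: 2.2830 log10 units (intensity 191.9)
#>   overlap: FP 0.000491 (unoccupied mass above crossing), FN 0.0183 (occupied mass below)
#>   loglik 235.2668 after 16 iterations (converged)

cat(sprintf("occupied droplets:        %d\n", report$n_occupied))
#> occupied droplets:        327
cat(sprintf("multi-base fraction:      %.3f\n", report$multibase_fraction))
#> multi-base fraction:      0.196
cat(sprintf("stochastic FP per colour: %.4f\n", report$stochastic_fp_mean))
#> stochastic FP per colour: 0.0338
print(report$identity)
#> Mean identity over 20 permutation draws: 0.7485 (sd 0.0134)
cat(sprintf("best-order identity:      %.3f\n", report$best_order_identity))
#> best-order identity:      0.821
```

Reading the numbers: about 47% of droplets were called occupied in at
least one channel — roughly 37% carry template bases (1 − e^{−0.455})
and the rest are contamination hits; of the occupied droplets, 19.6%
were multi-base (close to the 21% calibration point —
this is a 700-droplet run, so Monte-Carlo spread is visible). The
per-channel mixture fit recovers the generating components, and its
crossing-point overlap estimates (0.05% FP, 1.8% FN here) sit near the
calibrated 0.1% / 1.6%. The blank array gives a stochastic
false-positive rate of 3.4% per droplet per colour (generated at 3.1%).
Averaged over 20 random orderings of the multi-base droplets the read
aligns at 0.75 identity; choosing multi-base order to best fit the
reference raises it to 0.82 — the gap between the two is the transposition
cost of multi-base droplets, and the shortfall from 1.0 is dominated by
contamination-induced insertions.

With contamination and misidentification switched off and well-separated
intensity components, the same pipeline returns a best-order identity of
exactly 1.0 (the error-free limit; see the test suite).

`run_pipeline(cfg, out_dir = "run1")` additionally writes every
intermediate artifact: the droplet table and truth sidecar (CSV), fit
report (JSON), occupancy calls (CSV), the set-read (CSV), the resolved
read and reference (FASTA) and the full report (JSON).

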