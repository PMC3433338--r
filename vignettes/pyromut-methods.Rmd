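---
title: "Pyrogram mixture deconvolution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyrogram mixture deconvolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyromut)
```

# The signal model

Pyrosequencing interrogates a short targeted sequence by dispensing
nucleotides one at a time in a fixed, assay-specific *dispensation order*.
When the dispensed base is complementary to the template at the current
synthesis position it is incorporated — as many times in a row as the
template repeats that base — and the released pyrophosphate is converted to
a light peak whose height is proportional to the number of incorporations.
`incorporation_walk()` implements exactly this deterministic chemistry: a
cursor walks the analysed read (the synthesised-strand sequence, which for
reverse-sequencing assays such as KRAS codon 61 and BRAF codon 600 is the
reverse complement of the sense context), and each dispensation emits the
maximal run length at the cursor.

A clinical specimen is a mixture of wildtype and mutant template molecules.
Because each molecule contributes light independently, the expected pyrogram
of a mixture with mutant fraction $f$ is exactly linear:

$$h_i = s\,\big[(1-f)\,\mathrm{wt}_i + f\,\mathrm{mut}_i\big],$$

where $\mathrm{wt}_i$ and $\mathrm{mut}_i$ are the integer run-length
patterns of the two templates at dispensation $i$ and $s$ is the instrument
scale (light units per single incorporation).  This linearity is the entire
basis of quantification, and is asserted exactly (not approximately) by the
test suite.  Chemistry non-idealities — incomplete incorporation,
plus/minus frameshift carryover, apyrase kinetics, light saturation — are
deliberately not modelled; the analysis assumes proportional peak heights
throughout.

# The assay catalog

Eight assays cover the EGFR (codons 719, 746–753, 768, 790, 858), KRAS
(codons 12, 13, 61) and BRAF (codon 600) hotspots.  Each assay stores the
targeted sequence (IUPAC-degenerate at the hotspot positions), one
wildtype resolution of it, the dispensation order, a variant catalog of
read-space edits, and two calibration sets:

* **Reference positions** — dispensations whose expected height is exactly
  one incorporation.  Their mean height $B$ estimates $s$; their sample
  (n−1) standard deviation measures normal peak variation.  For the
  exon-21 and BRAF assays the sets are fixed to the ones used by the
  quantification rules ({2, 9, 11, 12, 14} and {9, 10, 12}); for the other
  assays they are derived as the dispensations that are single-copy under
  wildtype *and every catalog variant*.
* **Unexpected positions** — dispensations with zero expected signal under
  every template (e.g. {1, 3, 6} for BRAF).  Signal observed there can only
  be non-specific.

The exon-19 catalog ships ten common deletion events (COSMIC-style,
centred on the 15-base block whose loss is E746_A750del).  Two candidate
events that looked distinct in genomic notation turned out to be
alignment-ambiguous duplicates of catalogued deletions (deleting the same
length one position later inside a repeat yields the same read); they were
replaced by distinct common events (c.2236_2253del18, c.2240_2251del12),
since a catalog with indistinguishable entries cannot be identified from
signal at all.  One mutation per specimen is assumed; compound variants are
out of scope.

# Pre-processing

Non-specific peaks are handled with the unexpected-position rule: the
*artifact cutoff* is `multiplier` (default 2) times the mean height at the
unexpected positions, and any peak strictly below the cutoff is flagged as
artifact.  Flagged peaks are labelled `Noise` in reports, and a mutant
signature peak must exceed the cutoff before the V600K discriminator will
accept it.

One design choice deserves emphasis: **flagged peaks are not zeroed before
the mixture fits**.  `normalize_pyrogram()` offers masking for callers that
want it, but `call_pyrogram()` fits the unmasked heights.  At mutant
fractions near the 5 % sensitivity limit the diagnostic signature peaks
have expected height $\approx f \cdot B$, of the same order as the cutoff
($\approx 0.02$–$0.05\,B$ under typical background); masking them would
systematically erase exactly the evidence the assay exists to detect, and
measurably degrades identification of 10 % mixtures.  The cutoff therefore
qualifies small peaks rather than mutilating the fit input — matching the
rule's purpose, which is deciding whether a small peak is real.

Division by $B$ makes the pipeline exactly invariant to positive rescaling
of the pyrogram (a property the tests assert), so instrument gain never
affects a call.

# Candidate fitting and ranking

For one hypothesised variant, the mutant fraction is a one-dimensional
linear least-squares problem with a closed form; `fit_candidate()`
implements it on normalized heights with the estimate clipped to $[0,1]$
(clipping is flagged in QC).  On ideal exon-21 data it coincides, exactly
and provably, with the assay's printed closed-form rule

$$\Big[\tfrac{1}{3}\,\tfrac{A}{B} + \big(1-\tfrac{C}{B}\big) +
\big(1-\tfrac{D}{E}\big)\Big] / 3 \times 100,$$

implemented as `quant_l858r()`: each of the three terms equals $f$ on
noiseless mixtures (the $1/3$ factor undoes the three-base mutant run that
collapses into the signature G peak).  Per-mutation closed forms for the
other assays are not published; the least-squares estimator generalises
them uniformly, and the equivalence is asserted on ideal data.

`rank_candidates()` fits every catalog variant and orders by residual.  Its
numerics differ from the naive recipe in one way: the instrument scale is
*profiled out* of each fit by solving
$\min_{u,v \ge 0} \lVert h - u\,\mathrm{wt} - v\,\mathrm{mut}\rVert^2$
(closed form, with $f = v/(u+v)$ and $s = u+v$).  On noiseless data this is
identical to the fixed-scale fit, but on real data it removes the
calibration noise of estimating $B$ from three to five reference peaks,
which otherwise leaks into every candidate's residual and measurably
degrades variant identification.  It also automatically re-calibrates
candidates that alter a reference peak (an exon-19 deletion that removes a
reference dispensation, or L861Q which consumes the dispensation-11 T),
which is necessary for exact fraction recovery of those variants.

Ties are broken lexicographically, and the ranking carries an *ambiguity
flag* when the two best residuals differ by less than 10 % relatively.

# The call

`call_pyrogram()` assembles the pipeline: artifact cutoff → reference
statistics → normalization → wildtype comparison → candidate ranking →
(BRAF only) V600K discrimination → threshold rule.  The decision logic is:

1. If the wildtype pattern explains the pyrogram within
   `wildtype_residual_tol` (default 0.15 per-copy RMS) *and at least as
   well as the best candidate*, the call is wildtype.  An unconditional
   wildtype short-circuit would be wrong: a 6 % mutant mixture deviates
   from wildtype by only 0.06 RMS yet must be called, so "fits wildtype"
   can only mean "no candidate explains it better".
2. If no candidate comes within three times the tolerance, the pyrogram is
   `indeterminate`.
3. Otherwise the best candidate's percentage is compared with the calling
   threshold (default 5 %, the validated assay sensitivity).  The
   comparison is strict: exactly 5.0 % is *not* called.

## V600E versus V600K

The V600E and V600K patterns share the mutant T at dispensation 4; V600K
additionally lowers the C and T peaks at dispensations 7 and 8 from $B$ to
$(1-f)B$.  At low mutant fraction this is a genuinely hard discrimination,
and a fixed percentage rule is dominated by normal peak variation, so the
rule is expressed in standard deviations: the discriminator returns true
when both peaks fall below $B - 2\,\mathrm{SD}$ of the reference peaks
while a T signal above the artifact cutoff is present at dispensation 4.
`call_pyrogram()` consults it only when the V600E and V600K residuals are
within the 10 % relative ambiguity margin — when the least-squares ranking
is decisive it is left alone, because the discriminator's own error rate
(its SD is estimated from just three peaks) exceeds the ranking's in the
unambiguous regime.

# The synthetic generator

`synth_pyrogram()` is the package's only data source and defines the
conditions under which every property is tested: per-copy scale 100
instrument units, i.i.d. Gaussian peak noise with standard deviation 3 %
of a single-copy peak, uniform non-specific peaks of 1–5 % of a
single-copy peak at the unexpected positions, and truncation of heights at
zero (light intensities are physical).  Randomness is strictly seeded and
the global RNG state is never touched.

What it emulates — proportional signals, homoscedastic peak noise, small
non-specific background at signal-free dispensations.  What it does not —
inter-dispensation carryover, baseline drift, per-nucleotide response
differences (the dispensation-11 A peak of the exon-21 assay, excluded
from the reference set in favour of C/T/G peaks, hints at such effects in
real instruments), PCR artifacts, and template degradation.  Passing tests
therefore demonstrate correctness of the analysis given the proportional
model, not robustness to every failure mode of real chemistry.

# Numerical choices and degenerate inputs

* Fractions are estimated in closed form; no iterative optimisation.
* Estimates outside $[0,1]$ are clipped and flagged.
* A variant whose expected pattern equals wildtype has an undefined
  fraction and is rejected.
* An empty unexpected set yields cutoff 0 with a warning; an all-zero
  pyrogram ($B = 0$) is unanalyzable and raises a dedicated error (CLI
  exit code 2).
* Peaks exactly at the artifact cutoff are kept ("lower than" is strict).
* Sample (n−1) standard deviation is used for reference peaks.
* Residual comparisons use a 10 % relative margin with a machine-epsilon
  floor to avoid flagging exact ties on noiseless data.

# Problem sizes

The test suite simulates all of its own data: exact-recovery sweeps run
every built-in variant (35) over a 5 %-step fraction grid; the stochastic
identification study uses 200 seeded replicates per variant at 10 % mutant
fraction and 3 % peak noise; oracle comparisons use 20–60 randomized
instances per operation.  The full suite completes in well under a minute
on one CPU.

# Known limitations

* **Identification near the information floor.**  At 10 % mutant fraction
  with 3 % peak noise, a few variants sit at the statistical limit of what
  the signal supports.  For a true V600E, the nearest V600K mixture
  differs by a vector of norm $f\sqrt{2 - 16/12} \approx 0.082$ per-copy
  units against per-peak noise of 0.03, giving an irreducible E/K
  confusion of roughly 8–9 % for any unbiased residual ranking; the
  discriminator trades most of that away against V600K's large margin,
  but its own false-positive rate (SD from three reference peaks) caps
  V600E identification near 94 %.  G12R similarly faces three codon-12
  competitors at orthogonal distance $\approx 0.12$ and lands within
  binomial noise of 95 %.  These are properties of the assay design and
  noise level, not of the estimator.
* Only one mutation per specimen is modelled; compound or out-of-catalog
  variants surface as poor fits (`indeterminate`), not as discoveries.
* The 2×2 concordance utility computes the standard Pearson chi-square
  without continuity correction; no confidence intervals are attached to
  mutant percentages (point estimates only).
* Catalog coordinates are read-space; there is no genomic/HGVS lift-over.
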