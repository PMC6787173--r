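---
title: "Models and methods behind phagoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phagoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoscreen)
```

# The assay and what the package computes

A flow-cytometry phagocytosis screen transfects macrophage-like cells
(PMA-activated THP-1 cells) in 96-well plates with one miRNA mimic per well,
feeds them serum-opsonized FITC-labelled latex beads, and records for every
acquired event five channels: forward and side scatter (FSC/SSC), propidium
iodide (PI, viability), AF647 (a co-transfected labelled control siRNA
marking transfected cells) and FITC (internalized beads). The two readouts
per well are

* the *percentage of phagocytic cells*: the FITC+ fraction of the viable,
  transfected population (PI− AF647+), and
* the *phagocytic activity*: the mean fluorescence intensity (MFI) of that
  FITC+ population, a semi-quantitative measure of bead load.

`phagoscreen` provides (i) a generative model for event-level data with
known ground truth, (ii) the hierarchical gating reduction, (iii) the
hit-calling statistics of a two-stage screen, (iv) the validation-arm
statistics (repeated-measures ANOVA with Greenhouse–Geisser correction,
qPCR `2^(-dCT)`, dual-luciferase normalization, CFU titres), and (v) a
canonical miRNA seed-site scanner with binding-site mutagenesis.

# The synthetic-data generator

`simulate_well()` draws events hierarchically: an event is debris/free bead
with probability `debris_fraction`, otherwise a cell; a cell is viable with
probability `viability` (default 0.80); a viable cell is transfected with
probability `transfection` (0.80) and phagocytic with probability
`phago_prob` (0.51). These defaults are the study conditions of the
non-targeting (NT) control population the assay was calibrated on: ~80%
viability and transfection efficiency, and ~51% FITC+ cells among viable NT
macrophages. The cytochalasin D functional control (`cytod_profile()`)
multiplies `phago_prob` by 7.4/51, reproducing the ~7.4% FITC+ observed
under actin-polymerization blockade.

**Bead counts.** Electron-microscopy counts of the assay are reported only
in bins (no bead, 1–2 beads, three or more), with most untreated cells
carrying three or more beads. The simplest count law consistent with every
phagocytic cell containing at least one bead and a mean near three is the
zero-truncated Poisson; we use it with `bead_mean = 3` (truncated mean
≈ 3.16). Sampling is by CDF inversion restricted above `P(X = 0)`; the
tests cross-check it against a rejection sampler.

**Fluorescence.** Each channel is class-conditional lognormal. The FITC
signal of a phagocytic cell is the *sum* of per-bead lognormal brightnesses
plus cellular autofluorescence, so the MFI of the FITC+ gate grows with the
mean bead load — this is what makes MFI a bead-load readout and what the
`bead_effect` multiplier acts on. Channel scales are arbitrary units chosen
once so that every default gate sits at least 3 lognormal SD from both
class modes; with that separation, gated percentages are unbiased estimates
of the hidden rates to well within counting noise (verified by
parameter-recovery tests at 10^5 events).

**Plate geometry.** The source protocol does not state wells per plate or
controls per plate; we fix 96-well plates with 6 NT wells, 2 CytoD wells
and 1 untreated well, and place each miRNA's three replicate wells on a
single plate (required for per-plate raw-data statistics). Acquisition
depth defaults to 5,000 events/well, a typical bench figure; it is a config
knob, and the calibration-sensitive tests use 10^5-event wells.

**What the generator does not emulate.** No spectral spillover or
compensation, no doublets, no well-position (edge) effects, no plate-to-
plate or day-to-day biological drift beyond sampling noise, and no
miRNA-specific off-target structure. Consequently the null calibration and
power results below describe counting noise under ideal optics; on real
instruments the null hit rate is expected to be higher and dominated by the
unmodelled systematic components.

# Gating

`gate_well()` applies gates strictly in the order cells (FSC/SSC rectangle)
→ PI− → AF647+ → FITC+, with *strict* inequality for positivity (an event
is positive iff intensity > threshold; PI− means not PI+). Percentages are
always relative to the stated parent population, so the gated counts are
nested by construction. An empty FITC+ gate yields an undefined MFI (`NA`),
never 0 — the well is then dropped from that readout's ANOVA rather than
imputing a value; a well with nothing in the scatter gate returns a flagged
summary instead of an error so a screen run survives bad wells. MFI is the
arithmetic mean by default (the geometric mean is available by flag).

Numeric gate positions are not prescribed by the assay description (two
different cytometers were used); the defaults are ours and are placed ≥3 SD
from both class modes of the default channel model. `resolve_gates()`
supports data-driven thresholds as quantile rules against designated
control wells (e.g. FITC gate = 99.5th percentile of a no-bead control),
and is idempotent on concrete configurations.

# Hit calling

Per plate and readout, `normalize_plate()` divides every well by the mean
of the same plate's NT wells (their normalized mean is exactly 1), which
makes relative values comparable across plates and cancels any common
plate-wide scale factor. Significance, however, is computed on the *raw*
per-plate triplicates: `anova_dunnett()` pools the within-group variance
across all groups of a plate (one-way ANOVA error) and tests every miRNA
against the plate's NT wells with two-sided Dunnett-adjusted p-values. No
genome-wide FDR is applied on top; the family is the plate, matching the
screen's design.

The Dunnett adjustment needs `P(max_j |T_j| <= c)` under a multivariate t
with product correlation `r_ij = sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`
(1/2 for balanced designs). We evaluate it by deterministic quadrature over
the common-factor representation — Gauss–Hermite in the shared normal
factor, Gauss–Legendre on the probability scale of the pooled-SD factor —
accurate to ~1e-5 (documented tolerance 1e-4) with the default 32×32 rule;
a seeded Monte-Carlo path exists for non-product correlation structures. A
single contrast uses the exact t CDF, so with one treatment the procedure
*is* the pooled-variance t-test. Tests cross-check the quadrature against
`multcomp::glht` and a 10^6-draw Monte-Carlo max-|t| oracle.

A miRNA is a stage hit on a readout iff its relative value is ≤ 0.8 or
≥ 1.2 *and* its adjusted p-value is ≤ 0.01, all boundaries inclusive
(`hit_criteria()`). `two_stage_intersect()` requires the criterion met in
both the primary and the secondary screen *with the same direction*; the
direction requirement is our interpretation of "robustly and reproducibly",
consistent with every reported final hit having concordant directions.
Final hits are partitioned into pct-only / mfi-only / both, and the
inclusion–exclusion identity |pct| + |mfi| − |any| = |both| is checked on
every run.

Under the generator's study conditions (triplicates, 5,000 events/well,
sampling noise only) the dual cut-off is strongly conservative for nulls —
the fold-change filter alone sits many SEs from 1 — and a planted 2-fold
reduction in phagocytosis probability (the magnitude of the screen's
validated hit, ~14% vs ~30% FITC+) is recovered with sensitivity 1 across
seeds. The acceptance suite measures both: a 500-miRNA null screen repeated
20 times (stage-1 hit rate vs alpha, zero final hits), and 20 planted
reducers among 500 nulls across 5 seeds. These sizes keep the suite within
a normal CI run while leaving the binomial bounds meaningful.

# Validation statistics

* `rm_anova_gg()` — within-subject one-way ANOVA; Greenhouse–Geisser
  epsilon from the double-centered covariance of conditions,
  `eps = (tr C)^2 / ((k-1) tr C^2)`, clamped to its analytic range
  `[1/(k-1), 1]`; k = 2 gives eps = 1 exactly and the paired t-test.
  Missing subjects are handled complete-case.
* `dunnett_rm()` — many-to-one contrasts on the RM error term with
  correlation 1/2 and df `(n-1)(k-1)`; k = 2 reduces to the paired t-test.
* `ttest()` — pooled-variance Student by default (Welch by flag), paired on
  request; wraps `stats::t.test()`.
* `ddct()` — `2^-(CT_target - CT_reference)`; below-detection samples are
  censored (`NA` + flag, with `n_detected` reported), never set to 0,
  because a zero would silently deflate group means.
* `luciferase_relative()` — per-well firefly/Renilla ratio, normalized to
  the same construct's NT arm (NT mean exactly 1); non-positive Renilla
  wells are excluded with a warning.
* `cfu_per_ml()` — selects the most concentrated dilution whose mean spot
  count lies in the countable range (default 3–30 colonies per 10 µl spot,
  a microbiological convention; the protocol itself is silent) and scales
  by volume and dilution. The estimator inverts the Poisson spot model in
  expectation (checked over 10^3 simulations).

# Seed-site scanning and mutagenesis

`scan_sites()` implements the canonical site classes against miRNA seed
positions 2–8 in DNA space on the given 5'→3' sense strand: 6mer
(positions 2–7), 7mer-A1 (2–7 plus an adenine opposite position 1),
7mer-m8 (2–8), 8mer (2–8 plus the A1 adenine). Overlapping matches resolve
to the strongest class (8mer > 7mer-m8 > 7mer-A1 > 6mer); `N` never
matches; coordinates are 0-based half-open. This scanner is a deterministic
*stand-in* for the multi-database target-prediction service used upstream
of the reporter assays — it reproduces the canonical-seed subset of such
predictions, not their union, and does no thermodynamics or conservation
scoring.

`mutate_site()` implements the reporter mutagenesis rule — replace each
seed-paired target base by the base *identical* to the miRNA base at that
position — which abolishes Watson–Crick pairing at every seed position. The
quoted rule is directionally ambiguous; we chose the reading that
guarantees loss of complementarity and verify after every mutation that the
output contains no site for the same miRNA (re-mutating any chance match
straddling the window, with a convergence guard). Mutating an
already-mutated site returns it unchanged.

# Numerical and degenerate-input choices

* Quadrature tolerance 1e-4 for Dunnett probabilities (32×32 nodes);
  probabilities clipped to [0, 1].
* Zero within-group (or within-subject) variance raises a degenerate-design
  error rather than returning p = 0 or NaN.
* Non-finite replicates are dropped with a warning when ≥2 remain,
  otherwise the group errors out.
* Epsilon is clamped to `[1/(k-1), 1]` so floating-point noise cannot
  violate the analytic bounds.
* Ties at the cut-offs (rel = 0.8, 1.2; p = 0.01) count as hits, matching
  the inclusive wording of the criteria.
* All generators take explicit seeds; identical seeds give byte-identical
  outputs, and `run_screen()` is reproducible from its persisted config.

# Known limitations

The simulator's independence assumptions make the screen's null
distribution cleaner than real plates (no edge effects, no drift), so the
package's null-calibration results are a lower bound on real false-positive
rates. The Dunnett family is the plate, as in the original design; users
screening many plates who want genome-wide error control must add it
themselves. The seed scanner intentionally ignores non-canonical and
3'-supplementary pairing. FCS files are not parsed; event tables enter as
CSV (one row per event).
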