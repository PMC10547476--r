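---
title: "Decomposing islet calcium oscillations and integrating them with proteomic and GWAS evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing islet calcium oscillations and integrating them with proteomic and GWAS evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletwave)
```

## The scientific problem

Pancreatic islets respond to nutrient stimulation with pulsatile Ca²⁺
influx, and the shape of those oscillations — not just their average level —
carries mechanistic information about β-cell function. An islet imaged under
a four-condition perifusion protocol (8 mM glucose; plus amino acids; plus
the incretin GIP; then basal 2 mM glucose, 40 min each at one frame per 6 s)
produces a ratio trace per islet whose per-condition waveform can be
summarized by six parameters:

- **peak** — mean oscillation maximum (ratio units);
- **period** — mean time between consecutive peaks (min);
- **active duration** (A_D) — per-pulse time the signal spends above 50% of
  peak amplitude (min);
- **pulse duration** (P_D) — A_D plus the extra near-baseline tail while
  Ca²⁺ is extruded (min), measured here between crossings of a
  near-baseline level (10% of amplitude by default);
- **silent duration** S_D = period − A_D — the inactive triggering phase;
- **plateau fraction** P_F = A_D / period — the fraction of each cycle spent
  secreting.

Two degenerate responses get explicit numeric codes so they can enter
animal-level averages: a segment that *plateaus* (continuous peak activity)
is assigned P_F = 1, period = 0, and A_D = P_D = the segment length; a
segment that falls *silent* is assigned P_F = 0, A_D = P_D = 0, and period =
the segment length (40 min under the default schedule). Oscillating records
are classed *fast* (period < 2 min) or *slow* (period 2–10 min).

Downstream, animal-level averages of these parameters are Z-scored and
correlated (Pearson, pairwise-complete) against a protein abundance matrix;
proteins with |r| ≥ 0.5 to at least three of six focus parameters (basal
average Ca²⁺, 8G A_D, 8G P_D, and the three stimulated-condition S_D values)
are flagged as candidate regulators. Finally, candidate genes are nominated
when genome-wide-significant glycemic-trait SNPs (−log₁₀(p) strictly
greater than 8) fall within the gene body extended by ±100 kbp, or within a
promoter-capture HiC loop anchor whose partner anchor overlaps the gene's
promoter.

## Pipeline overview

```{r, eval = FALSE}
coh <- make_cohort(cohort_spec(
  strains = c("A/J", "B6", "129", "NOD", "NZO", "CAST", "PWK", "WSB"),
  archetype_map = default_archetype_map(), seed = 1))
res     <- analyze_cohort(coh)      # waveform + spectral, islet and animal level
prot    <- make_protein_matrix(res$traits, n_proteins = 100, seed = 1)
cands   <- flag_candidates(correlate_matrix(res$traits, prot))
fx      <- gwas_demo_fixture()
genes   <- nominate(fx$snps, fx$genes, fx$loops)
```

## The waveform detector

Each segment is detrended, thresholded, and summarized:

1. **Detrending.** The default trend estimate is a running median applied to
   a one-cycle running-mean pre-smooth. The pre-smooth matters: a plain
   running median of a square-like wave near 50% duty cycle flips between
   the two plateau levels as the window slides (the majority level
   alternates), which destroys the waveform it is meant to preserve. A
   running mean whose width is one dominant period cancels the oscillation
   exactly, after which the median stage tracks drift while remaining robust
   to spikes and condition transients. The window defaults to 3× the
   segment's dominant period (periodogram argmax, clipped to a quarter of
   the segment, falling back to 10 min for aperiodic segments); the segment
   mean is restored afterwards so plateau levels survive. A least-squares
   linear detrend is available by flag and is used before spectral
   estimation, where only frequency content matters.
2. **Reference levels.** Baseline and robust peak are the 5th and 95th
   percentiles of the detrended segment; their difference is the amplitude.
   Percentiles resist single-frame spikes, and the 5/95 pair stays valid for
   duty cycles between roughly 10% and 90%, where a 10/90 pair would land on
   the step of the value distribution and collapse the amplitude estimate.
   If the percentile spread is below the amplitude floor but the 99.5th
   percentile rises at least two floors above baseline, the segment holds
   sparse bursts (e.g. a single pulse in 40 min) and that upper percentile
   serves as the robust peak.
3. **Pulse detection.** Pulses are maximal runs at or above baseline + 50%
   of amplitude containing a local maximum with prominence ≥ 25% of
   amplitude. A run holding several local maxima is one pulse whose peak is
   the larger maximum (earlier on an exact tie). Crossing times are linearly
   interpolated between frames, so durations have sub-frame resolution.
   Pulses truncated by a segment edge are kept in the table but excluded
   from duration and period averages; the period needs two complete pulses,
   so a one-pulse segment reports its durations with a missing period, S_D,
   and P_F (excluded from period averages rather than imputed).
4. **Plateau versus silent.** With zero detected pulses, a segment whose
   mean sits at least half an amplitude floor (0.05 ratio units by default)
   above the reference baseline is a plateau; otherwise it is silent. The
   reference baseline is the 5th percentile of the islet's own basal (2G)
   segment after detrending — detrended like the segments it is compared
   against, since photobleaching drift alone can otherwise push a silent
   islet past the plateau criterion.

Tunable parameters, all in ratio units or minutes: `threshold_frac` (0.5,
the defining 50% rule), `min_prominence_frac` (0.25), `pd_frac` (0.1, the
near-baseline level bounding P_D), `amplitude_floor` (0.05 ratio units),
`fast_cutoff` (2 min), `slow_upper` (10 min).

## Spectral summaries

The estimator is the mean-removed rectangular-window periodogram on the
one-sided grid k/(N·Δt); bin powers sum to the signal variance (Parseval).
Segments of 400 frames give a resolution of 0.025 min⁻¹, which is why no
Welch averaging is applied by default — halving an already short segment
would double the bin width. The first component is the argmax (ties resolve
to the lower frequency); the second is the argmax at least two bins away, so
a leakage sidelobe of the dominant peak is not reported as an independent
rhythm. "Amplitude" is the periodogram power at the selected bin, not its
square root, and is not normalized to total power. Flat segments get a
near-zero first amplitude rather than a missing value, so plateau and silent
islets stay in the table.

## Z-scores, correlation, and candidate flagging

Z-scores use the sample SD (n − 1) over non-missing animal averages;
constant columns are skipped with a warning rather than producing
infinities. The Pearson coefficient is computed in its explicit
cross-product form on pairwise-complete observations, with the pair count
recorded; correlation is invariant to the Z-scoring, which is kept because
the flagging rule is defined on Z-score correlations. When the imaging and
proteomic animals differ, rows align on strain-by-sex means rather than
animal ids (`align = "group"`; `"auto"` picks for you). No multiple-testing
correction is applied to the |r| ≥ 0.5 filter — it is a fixed-effect-size
screen, not a hypothesis test — while the strain/sex term-effect table
reports raw p-values with optional Benjamini–Hochberg adjustment off by
default. Z-scoring pools sexes; the flagging rule uses ≥ (so r = 0.5
exactly is flagged), following the definition given with the rule rather
than the looser restatement elsewhere.

Term effects fit `trait ~ strain * sex` by least squares; each term's effect
size is √(term mean square)/raw SD with its sequential F-test p-value, and a
composite *signal* term tests all strain-involving terms (strain and
strain:sex) jointly against the sex-only model. Designs that cannot support
a term (a single sex, say) report that term as missing instead of failing.

## SNP-to-gene assignment

Coordinates are BED-convention 0-based half-open internally; SNP positions
are 1-based on disk and converted on read. The ±100 kbp window extends the
gene body as a single widened interval (a SNP inside the gene counts via the
`body` route, in the flank via `window`). The significance filter is strict:
−log₁₀(p) must exceed 8, so p = 10⁻⁸ exactly is excluded — the two
statements of the cutoff agree on strictness and the boundary case is
resolved by the strict inequality. Loop assignment requires one anchor to
overlap the gene's promoter anchor and the other to contain the SNP exactly;
SNPs merely adjacent to an anchor do not count. Promoter anchors from
promoter-capture data are used when supplied; otherwise TSS ± 2 kbp is
derived from the strand. A gene-SNP pair supported by both routes is
recorded once with both routes. Chromatin-state columns (ATAC, histone
marks), when present, ride along as annotation and never filter. Overlap is
computed with GenomicRanges interval indexes and is checked against an
all-pairs brute-force scan in the test suite.

## The synthetic generator

The generator is phenomenological, not mechanistic: no electrophysiology or
dual-oscillator model, just the statistical structure the analysis assumes.

- **Waveform.** Oscillating archetypes are logistic-edged square waves — the
  edge value is exactly 0.5 at the active/silent boundary, so the
  generator's duty cycle and the 50%-threshold active duration coincide by
  construction, which is what makes duty a usable ground truth. Edges
  default to a quarter of a sampling interval, i.e. nearly step-like.
  `slow` draws its period from 2–10 min and `fast` from below 2 min when not
  given one. `plateau` holds baseline + amplitude; `silent` holds baseline;
  `mixed` (a NOD-like response) sums a slow and a fast square wave with a
  2:1 amplitude ratio.
- **Noise and drift** are i.i.d. Gaussian on the ratio and linear per
  segment. Defaults: baseline 1.0, amplitude 0.5, noise SD 0.01 ratio
  units, drift −0.002 ratio units/min (slow bleaching). These magnitudes are
  free parameters chosen once as plausible for ratiometric islet imaging;
  the source protocol reports none, and they are deliberately not calibrated
  to any measured cohort.
- **Cohorts** derive per-islet seeds from the root seed by counter, so any
  subset of a cohort regenerates identically. Waveform phase restarts at
  each solution transition.
- **Protein matrices** plant target correlations by mixing a parameter's
  Z-score with Gaussian noise at weight t = |r|·σ/√(1 − r²), so the expected
  Pearson correlation equals the target; null proteins are independent
  noise. Two caveats are inherent to planting: with zero noise a planted
  column is an exact ± copy (|r| = 1 regardless of target), and targets on
  several parameters combine — a large target on three mutually independent
  parameters is infeasible outright, since squared correlations to
  independent targets sum to at most 1, while targets on mutually
  correlated parameters realise correlations above the individual values.
- **Genomic fixtures** place non-overlapping genes on a toy chromosome with
  SNPs at controlled distances (in-body, in-window, out-of-window, uniform)
  and promoter-to-distal loops.

The recovery fixtures for candidate flagging give the three silent-duration
focus parameters a shared latent factor (pairwise correlation ≈ 0.85) and
keep the other three focus parameters independent. This mirrors the real
correlation structure — the stimulated-condition silent durations are
near-duplicates of one another in islet data — and it is also the only
structure under which a regulator can legitimately show |r| ≈ 0.9 to three
parameters at once (see the infeasibility note above). Under that structure
five planted regulators are recovered with, in expectation, fewer than two
false positives among 95 nulls at n = 16 animals.

What the generator does *not* emulate: amplitude heterogeneity across islets
of one animal, non-Gaussian photon noise, slow waveform drift within a
segment, partial plateau escapes, or movement artifacts. Passing tests on
synthetic cohorts therefore demonstrate that the estimators recover the
parameters they define, on clean-to-moderately-noisy square-like input — not
that those estimates are unbiased on arbitrary real traces.

## Numerical choices and degenerate inputs

- Time grids must be uniform to 1e-9 relative tolerance; missing frames are
  a hard error, never interpolated, because duration statistics are
  frame-count based.
- Segment membership is half-open (start ≤ t < end): a frame on a boundary
  belongs to the later segment, and a contiguous schedule reconstructs the
  trace exactly.
- The Fura ratio is oriented bound (405-nm excited) over free (488-nm
  excited), rising with Ca²⁺; the orientation is a convention recorded here
  because the source does not define the numerator. No background
  subtraction is applied.
- Exact periodogram power ties report the lower frequency.
- Constant trait columns are skipped (with a warning) in Z-scoring;
  correlations with fewer than three pairwise-complete points are missing,
  never numbers.
- p-values are clamped away from zero at 1e-300 before −log₁₀ to keep
  volcano-style output finite.
- Excitatory-segment average Ca²⁺ is reported both ways (`avg_signal`
  detrended, `avg_signal_raw` raw) since the source is ambiguous about which
  entered its correlations; with mean-preserving detrending the two
  coincide.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
40-min, 400-frame segments; recovery grids of 30 period-duty combinations;
50-seed noise replicates; cohorts of up to 96 islets (8 strains × 2 sexes ×
2 animals × 3 islets); 100 proteins × 16 animals for integration; and 100
random 50-gene × 500-SNP fixtures for the interval-overlap oracle. These
sizes were chosen to exercise every code path at full statistical resolution
while keeping a complete run in the order of a minute.

## Known limitations

- The detector assumes square-like bursts; strongly sawtooth or sinusoidal
  oscillations will report a biased A_D relative to a half-maximum
  definition applied per cycle.
- Period estimation uses peak-to-peak intervals of complete pulses only;
  segments with exactly one complete pulse contribute durations but no
  period.
- The plateau/silent call depends on a basal reference segment; without one
  it falls back to the segment's own baseline, which cannot distinguish an
  all-segment plateau from silence at an elevated baseline.
- Loop assignment requires exact anchor containment; SNPs immediately
  proximal to a contact are not counted.
- No LD expansion, orthologue inference, or external catalogue queries:
  orthologue and SNP tables are inputs.
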