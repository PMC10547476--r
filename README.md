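# isletwave

Waveform analysis of pancreatic-islet Ca²⁺ oscillations, with Z-score/Pearson
integration against protein abundances and GWAS-overlap candidate-gene
nomination.

Islets respond to nutrients with pulsatile Ca²⁺ influx whose *shape* — not
just its mean — reflects β-cell mechanism. For each islet and stimulus
segment (8 mM glucose; + glutamine/leucine/alanine; + GIP; basal 2 mM
glucose; 40 min each, one frame per 6 s), `isletwave` computes the six
standard waveform parameters:

- peak and period (mean peak-to-peak interval, min);
- active duration *A*_D: per-pulse time above 50% of peak amplitude;
- pulse duration *P*_D: *A*_D plus the Ca²⁺-extrusion tail;
- silent duration *S*_D = period − *A*_D;
- plateau fraction *P*_F = *A*_D / period.

Segments that plateau are coded *P*_F = 1, period = 0, *A*_D = *P*_D = 40
min; silent segments are coded *P*_F = 0, *A*_D = *P*_D = 0, period = 40 min;
oscillating segments are classed fast (period < 2 min) or slow (2–10 min).
Each segment also gets a periodogram summary (top two component frequencies
and powers). Animal-level averages are Z-scored (*z* = (*x* − *μ*)/*σ*,
sample SD) and correlated pairwise-complete against a protein matrix;
proteins with |*r*| ≥ 0.5 to ≥ 3 of six focus parameters are flagged.
Candidate genes are nominated when glycemic-trait SNPs with −log₁₀(*p*) > 8
fall within a gene body ± 100 kbp or inside a promoter-capture HiC loop
anchor contacting the gene promoter.

A synthetic-data module generates square-like oscillation traces (with duty
cycle, drift, and noise), strain-by-sex cohorts, protein matrices with
planted correlations, and toy genomic fixtures, so the entire pipeline is
testable without any external download.

## Worked example

```r
library(isletwave)

coh <- make_cohort(cohort_spec(
  strains = c("B6", "CAST"), sexes = c("F", "M"),
  animals_per_group = 2, islets_per_animal = 3,
  archetype_map = default_archetype_map(), seed = 1))
res <- analyze_cohort(coh)
head(res$params[c("islet_id", "segment", "regime", "speed_class",
                  "period_min", "active_min", "silent_min",
                  "plateau_fraction")], 4)
#>   islet_id    segment      regime speed_class period_min active_min silent_min plateau_fraction
#> 1 B6_F_1_1         8G oscillating        slow       4.11       1.60       2.51            0.389
#> 2 B6_F_1_1     8G/QLA oscillating        slow       4.67       2.99       1.68            0.641
#> 3 B6_F_1_1 8G/QLA/GIP oscillating        slow       3.97       2.00       1.97            0.504
#> 4 B6_F_1_1         2G      silent        none      40.00       0.00      40.00            0.000
```

The B6 islet oscillates slowly (period ≈ 4 min, close to the generator's
ground truth), lengthens its active phase under amino acids (plateau
fraction 0.39 → 0.64), and falls silent at basal glucose, where it receives
the edge-case codes (*P*_F = 0, period = 40). Animal averages separate the
strains cleanly — CAST islets run fast (period ≈ 1 min):

```r
res$animal[res$animal$segment == "8G",
           c("strain", "sex", "animal", "period_min", "plateau_fraction")]
#>    strain sex   animal period_min plateau_fraction
#> 2      B6   F   B6_F_1      4.030            0.397
#> ...
#> 18   CAST   F CAST_F_1      0.999            0.305
```

Correlating the animal-by-trait matrix against a protein matrix with one
planted regulator recovers it at the top of the ranking, and the three-gene
demonstration fixture nominates exactly the in-window and loop-only genes:

```r
prot <- make_protein_matrix(res$traits, n_proteins = 20,
  planted = data.frame(protein = "CAND1", parameter = "8G_silent_min",
                       target_r = 0.9),
  noise_sd = 1, seed = 2)
cr <- correlate_matrix(res$traits, prot, align = "animal")
head(cr[order(-abs(cr$r)), ], 1)
#>    parameter protein      r n_used
#> 50   8G_amp2   CAND1 -0.921      8

fx <- gwas_demo_fixture()
nominate(fx$snps, fx$genes, fx$loops)
#>       gene_id n_snps routes          traits best_neg_log10_p
#> 1   GENE_LOOP      1   loop             T2D                9
#> 2 GENE_WINDOW      1 window fasting glucose               10
```

(With only 8 animals the planted protein correlates strongly with several
strain-separating traits at once, as real regulators do; the `8G_silent_min`
target itself sits among its top correlations.)

See `vignettes/islet-calcium-waveforms.Rmd` for the full account of the
detector, its thresholds, and the generator's assumptions.

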