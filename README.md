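# skipticr

Detection and characterization of **constitutive exon skipping driven by
elevated nuclear TDP-43**, from splice-junction read counts.

TDP-43 is an autoregulated splicing repressor. Its *loss* from the
nucleus de-represses nonconserved cryptic exons; its *excess* in the
nucleus — from overexpression of wild-type, mutant, or
NLS-deficient-but-passively-diffusing constructs — represses exons that
are normally constitutively included ("skiptic" exons). Distinguishing
these two regimes matters for anyone building or interpreting TDP-43
proteinopathy models: skipticr provides the quantification, calling,
motif, NMD, and dose-model machinery to do that from standard RNA-seq
junction outputs.

## What it computes

* **PSI** — per exon and sample, the 3'SS and 5'SS percent-spliced-in

  `PSI_site = I_site / (I_site + E)`

  where `I_site` counts junction reads landing exactly on the exon's
  acceptor/donor coordinate (strand-aware) and `E` counts junctions
  spanning the exon strictly; the combined PSI is the mean of the
  defined site values.
* **Skiptic calls** — exons constitutive at steady state
  (control PSI > 0.90) whose PSI drops by ≥ 0.20 (both thresholds are
  parameters) under TDP-43 overexpression, with coverage gating,
  cross-species overlap via an explicit ortholog map, and BED output
  for browser viewing.
* **UG/GU repeat metaprofiles** — per-position frequency of qualifying
  UG-repeat runs (≥ 5 masked positions, one interior mismatch allowed)
  in ±400 bp windows aligned to the 3'/5' splice sites.
* **NMD prediction** — reading-frame rule by default, with a full
  premature-termination-codon + 50-nt last-junction rule for supplied
  transcript models.
* **Dose model** — total nuclear TDP-43 from construct expression
  (`total = endogenous + 0.45 × NLSm level` by default), isotonic
  dose-response fitting, passive-diffusion-fraction estimation by
  equal-response matching, and skipping-onset extrapolation.
* **Synthetic data** — seed-deterministic generators with truth tables
  for every stage (junction counts with known PSI, genomes with planted
  UG runs, dose series with known diffusion fraction).

Input formats: STAR `SJ.out.tab` or junction BED6, GENCODE-style GTF,
FASTA, and a plain dose TSV. See `vignettes/skipticr-methods.Rmd` for
the models, parameter meanings, and design decisions.

## Worked example

Simulate a control vs. overexpression experiment with known truth (40
constitutive exons plus 6 planted skipping events), quantify, and call:

```r
library(skipticr)

cfg <- sim_config(seed = 42, junctions = list(
  n_constitutive = 40, n_skiptic = 6, read_depth = 500))
sim <- simulate_junctions(cfg)

ctrl <- lapply(sim$samples[grep("ctrl", names(sim$samples))], index_junctions)
tdp  <- lapply(sim$samples[grep("tdp",  names(sim$samples))], index_junctions)
calls <- call_skiptics(delta_psi(psi_matrix(sim$exons, ctrl),
                                 psi_matrix(sim$exons, tdp)))
#> skiptic calls: constitutive_unchanged=40, skiptic=6, alternative=0, low_coverage=0
head(calls[, c("exon_id", "psi_control", "psi_treated", "delta_psi", "label")], 4)
#>   exon_id psi_control psi_treated delta_psi   label
#> 1  ex0031       0.957       0.166    -0.791 skiptic
#> 2  ex0014       0.959       0.241    -0.718 skiptic
#> 3  ex0002       0.961       0.284    -0.677 skiptic
#> 4  ex0032       0.988       0.312    -0.676 skiptic
```

All six planted events are recovered, sorted by the strength of the PSI
drop. Downstream, the frame rule summarizes which skipped exons should
trigger nonsense-mediated decay, and the dose model recovers the
passive-diffusion fraction the series was generated with (truth 0.45)
and the fold-increase at which skipping becomes detectable:

```r
nmd <- summarize_nmd(predict_nmd_frame(subset(calls, label == "skiptic")))
#> NMD predicted for 2/6 skiptic exons (33%)

dose <- simulate_dose(sim_config(seed = 42))$observations
est <- estimate_diffusion_fraction(subset(dose, construct == "WT"),
                                   subset(dose, construct == "NLSm"))
#> diffusion fraction: 0.453 (range 0.377-0.491)
skipping_threshold(est$wt_curve, 8)
#> [1] 1.10   # skipping onset at 1.10-fold nuclear TDP-43, 8% detection floor
```

The full pipeline (PSI → ΔPSI → calls → motif profiles → NMD → dose
fit, with a manifest of every threshold) runs via `run_end_to_end()` or
`skipticr run --config run.cfg`.

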