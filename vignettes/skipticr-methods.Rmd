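---
title: "Models and methods behind skipticr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind skipticr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

TDP-43 is a splicing repressor under tight autoregulation. When its
nuclear concentration rises above normal — through overexpression of the
wild-type protein, of disease-associated mutants, or of
nuclear-import-deficient (NLS-mutant) constructs that still diffuse into
the nucleus passively — exons that are constitutively included at steady
state begin to be skipped ("skiptic" exons). skipticr implements the
computational side of that analysis as a reusable, testable pipeline:

1. junction-level percent-spliced-in (PSI) quantification,
2. skiptic-exon calling from control vs. overexpression PSI,
3. UG/GU dinucleotide repeat metaprofiles around splice sites,
4. nonsense-mediated decay (NMD) prediction for skipped exons,
5. an arithmetic dose model linking construct expression, nuclear
   TDP-43 level, and skipping response.

Everything operates on splice-junction count tables (STAR `SJ.out.tab`
or a BED6 dialect), GTF exon annotation, and FASTA sequence; no
alignment or read-level processing is performed. Internal coordinates
are uniformly 0-based half-open; all conversions happen in the readers.

# PSI from junction counts

For an exon, inclusion reads at the 3' splice site (3'SS, acceptor) are
reads of junctions whose downstream boundary coincides with the exon's
acceptor coordinate, and similarly at the 5'SS (donor); on the `-`
strand the acceptor is the higher-coordinate boundary. Exclusion reads
$E$ come from junctions spanning the exon strictly. Then

$$\mathrm{PSI}_{3} = \frac{I_3}{I_3 + E}, \qquad
  \mathrm{PSI}_{5} = \frac{I_5}{I_5 + E},$$

and the combined PSI is the arithmetic mean of the defined site values.
Design choices worth making explicit:

* **Strict spanning.** A junction touching an exon boundary is
  inclusion, never exclusion. This is the conservative reading of
  "junctions from one exon to another"; counting boundary junctions as
  exclusion would double-count inclusion evidence.
* **Combined PSI = mean of the two site values.** The per-site values
  are always reported alongside, so nothing is lost; the mean is
  symmetric in the two sites.
* **Coverage gate.** `min_reads` (default 10) total informative reads
  are required at *both* sites for an exon/sample to count as covered.
  PSI itself is still reported whenever a denominator is positive;
  `covered` is a separate flag, so low-coverage estimates are visible
  but excluded from calling.
* **Unstranded junctions.** STAR emits strand-code-0 junctions; they are
  retained by the readers but excluded from PSI unless
  `include_unstranded = TRUE`, since an unstranded junction cannot be
  assigned to a donor/acceptor unambiguously.
* **Replicate aggregation.** The default pools read counts across a
  condition's replicates before forming the ratio ("pooled-reads PSI"),
  which is stable for low-coverage exons; the mean of per-sample PSI
  over covered samples is available via `aggregator = "mean"`.

# Skiptic calling

An exon is *constitutive* when its steady-state (control) PSI exceeds
0.90, the operational threshold used throughout; a constitutive exon is
called *skiptic* when its PSI drops by at least `skip_threshold`
(default 0.20, a conservative choice — reported events range up to ~0.9
PSI loss, but no published calling cutoff exists, so the parameter is
explicit and recorded in the run manifest). The four labels
(`constitutive_unchanged`, `skiptic`, `alternative`, `low_coverage`)
partition the exon set. Calls are threshold-based point estimates with
no multiple-testing machinery, matching the descriptive character of
the analysis; error control, where needed, should come from replication
and depth, both of which the synthetic generators let you explore.

Cross-species comparison (`compare_species()`) takes an *explicit*
ortholog exon map; no liftover is computed internally, because synteny
assessment is an annotation-level judgement that should not be buried
inside a calling function.

# UG repeat metaprofiles

TDP-43's consensus binding site is a UG repeat. The profiling algorithm
works on the sense-strand sequence in a ±400 bp window around the 3'SS
or 5'SS:

1. every position participating in at least one `UG`/`GU` dinucleotide
   (overlaps allowed, so `UGUGUG` is fully masked) becomes `Y`, all
   others `N`;
2. stretches with at least `min_len = 5` `Y`s and at most
   `max_inner_N = 1` single interior `N` insertion (flanked by `Y` on
   both sides) qualify; their `Y` positions score 1, everything else 0
   (the interior `N` itself scores 0);
3. scores are averaged across sequences at each offset.

Offset 0 is the first exonic base at the 3'SS anchor and the last
exonic base at the 5'SS anchor; windows are always anchored on the
splice site (never the exon midpoint), reverse-complemented for `-`
exons, and `N`-padded (and flagged) when truncated by contig ends.
Assembly `N`s and ambiguity codes mask to `N` since they cannot support
a UG dinucleotide. The run-scoring implementation merges Y-runs across
single-N gaps; the test suite checks it against exhaustive substring
enumeration over all masks up to length 12 plus 10,000 random masks.

# NMD prediction

The default rule is the **frame rule**: skipping an exon whose length is
not divisible by 3 shifts the downstream reading frame and is predicted
to trigger NMD. A **full PTC rule** is also provided for users with
complete transcript models: the transcript is re-translated without the
exon, and NMD is predicted when a premature stop appears upstream of the
annotated stop *and* lies more than 50 nt upstream of the final
exon–exon junction. The frame rule is the default because it needs no
CDS model and is the most plausible basis for the reported ~43%
NMD fraction among skipped exons; the two rules disagree exactly where a
transcript-aware analysis would (frameshifts whose first stop falls near
the last junction), which is why both are exposed rather than silently
merged. When an exon belongs to several transcripts the caller chooses
the transcript; determinism is then the caller's responsibility (the
pipeline uses the frame rule, which depends only on exon length).

# The dose model

Levels are expressed in multiples of normal endogenous TDP-43. A
fully nuclear (WT) construct contributes its whole level to the
nucleus; an NLS-mutant construct contributes only its passively
diffusing fraction:

$$[\mathrm{total\ nuclear}] = [\mathrm{endogenous}] + f \cdot
  [\mathrm{construct}], \qquad f_{\mathrm{WT}} = 1,\;
  f_{\mathrm{NLSm}} = 0.45 \text{ by default.}$$

The response curve mapping total nuclear fold to percent skipping is
fitted as an **isotonic piecewise-linear** curve
(pool-adjacent-violators via `stats::isoreg`, linear interpolation
between knots, clamping outside). A parametric Hill/logistic form was
deliberately avoided: the experimental design interpolates between
measured expression bins and asserts monotonicity, not a functional
form, and an isotonic fit adds no shape assumptions.

The passive-diffusion fraction is estimated by **equal-response
matching**: each NLSm observation whose skipping response is bracketed
by the WT curve is inverted through that curve to an equivalent nuclear
fold, giving $\hat f = (\mathrm{fold} - \mathrm{endogenous}) /
\mathrm{level}$; the estimate is the median across bins with the
min–max range reported, mirroring how the spread across expression bins
is usually quoted (a range like 10–45%) rather than forcing one number.
Inversion takes the leftmost solution, so flat stretches of the fitted
curve resolve deterministically. The skipping-onset threshold is the
smallest fold at which the curve reaches `detection_floor` percent
skipping (default 5% — a detection floor for gel-based quantification;
the parameter is explicit because "begins to induce skipping" has no
universal floor). Endogenous levels are *inputs* per observation, not a
model: autoregulation is measured, not simulated.

# Synthetic data and what it does (and does not) show

The generators are seed-deterministic and every emitted file validates
against the package's own readers; truth tables describe the outputs
exactly.

**Junction counts.** Per exon, sample and splice site, inclusion reads
are drawn $I \sim \mathrm{Pois}(d\,\psi)$ and shared exclusion reads
$E \sim \mathrm{Pois}(d(1-\psi))$ with site depth $d$ (default 1000).
By Poisson thinning, the site total $I+E \sim \mathrm{Pois}(d)$ and
$I \mid I+E \sim \mathrm{Binomial}(I+E, \psi)$ — *exactly*, at both
sites simultaneously, which a direct "draw a binomial at each site"
scheme cannot achieve with a single shared exclusion junction. This is
what makes the statistical-consistency checks exact rather than
approximate. Defaults describe the reference conditions: 500
constitutive exons (true PSI ≥ 0.92) plus 78 planted skipping events
with ΔPSI between −0.9 and −0.5, two replicates per condition. Exon
lengths are drawn so that 39/69 of them are frame-preserving, matching
the reported composition of skipped exons. Counts are *not*
overdispersed: real junction counts are, so recovery rates on real data
will be somewhat worse than on these fixtures — the generator
establishes correctness, not field performance.

**Genome fixtures.** Background sequence is drawn over `{A, C}`, which
contains no `UG`/`GU` on the plus strand, so planted `(TG)k` runs are
the *only* signal and expected profiles are exact (frequency =
proportion planted at planted offsets, 0 elsewhere). One subtlety: the
reverse complement of an `{A, C}` sequence is `{G, T}` — almost every
position masks `Y`. The default fixture therefore uses all-`+` exons;
for mixed-strand fixtures the generator accepts
`background = c("A", "T")`, which is UG-free on *both* strands, and
every planted run is flanked by guard bases chosen so the mask cannot
extend past the planted offsets. Exons are 1000 bp — longer than the
2 × 400 bp window — so the 3'SS and 5'SS windows never overlap and each
anchor sees only its own plantings.

**Dose series.** The true response curve has knots (1.0, 0), (1.5, 40),
(2.0, 90), (2.5, 95) — onset within the 1.1–1.5× band, ~40% skipping at
1.5× total nuclear TDP-43, ~90–95% saturation near 2–2.5× — with true
diffusion fraction 0.45, seven expression bins per construct (the
FACS-fraction design), and 5% multiplicative response noise by default.
The WT bins are placed so the sampled folds include the knots; since
the generating curve is itself piecewise-linear, the fitted isotonic
curve then coincides with the truth on the sampled range and the
noiseless closed loop recovers the diffusion fraction to machine
precision — a deliberate identifiability choice, not a fit-quality
claim.

# Numerical and degenerate-input conventions

* PSI is `NA` (undefined) wherever its denominator is zero; undefined
  values propagate to `delta_psi` and surface as `low_coverage` labels.
* Duplicated identical junction intervals are merged with summed reads
  and a warning.
* Curve inversion returns the leftmost fold attaining the target;
  thresholds never fall below fold 1; a floor the curve never reaches
  yields `NA` ("not attained").
* `find_repeat_runs` scores a position 1 if *any* qualifying stretch
  covers it (the union-of-substrings semantics); terminal `N`s never
  extend a run and the Y-count, not the span, must reach `min_len`.
* All generator draws derive from one integer seed; re-running any
  generator or the whole pipeline with the same configuration is
  byte-identical.

# Problem sizes used by the test suite

The packaged checks run at the reference conditions: 578 exons × 4
samples at depth 1000 for recovery, 500 exons for the binomial
consistency check, 1000 random instances for the brute-force PSI
oracle, all 8190 masks up to length 12 plus 10,000 random masks of
length ≤ 30 for the repeat-run oracle, and 200 replicates for the
noisy diffusion-fraction recovery. The full suite completes in well
under a minute per module on one CPU.

# Known limitations

* Junction counts only: no isoform-level or EM-based quantification,
  and no read simulation — upstream alignment artefacts are out of
  scope.
* Calling is descriptive (thresholds, no error control); the thresholds
  are parameters, not discoveries.
* The frame rule ignores 3'UTR introns and exon-junction-complex
  deposition details; the full PTC rule assumes a single supplied
  transcript model.
* The dose model is arithmetic, not kinetic: autoregulation dynamics,
  aggregation and saturation mechanisms are represented only through
  the measured inputs.
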