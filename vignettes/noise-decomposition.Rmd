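---
title: "Decomposing sequencing noise in UMI-tagged cell-free DNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing sequencing noise in UMI-tagged cell-free DNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfnoise)
```

## The problem

Detecting circulating tumor DNA (ctDNA) at very low allele frequency is
limited less by sequencing throughput than by the background error of the
assay. Unique molecular identifiers (UMIs) remove most sequencing-layer
errors by collapsing PCR duplicate families to consensus sequences, but a
substitution introduced in the *first copy event* of a template strand is
inherited by half of that strand's amplicons: if the erroneous clade is
over-represented among the sampled reads, the consensus itself is wrong.
Such early, random PCR errors survive consensus calling, do not recur at
the same position across samples, and — crucially — do not recur between
two independently prepared libraries of the same sample. On top of this
stochastic channel sit three structured channels: clonal-hematopoiesis
(CHIP) variants, which are real somatic variants of blood cells visible in
matched buffy-coat DNA at roughly 2–30% allele frequency; patterned error,
position-specific artifacts of sequence context and alignment shared
across unrelated samples; and any true variants present in the sample.

`ccfnoise` implements this error model end to end: a branching-process PCR
simulator with complete error provenance, UMI family grouping and
consensus calling for singleton (single 8-mer UMI per strand) and duplex
(3+3 dual UMI, strand-pairable) adapter schemes, two base-level error
estimators, and a correction ledger that removes CHIP artifacts (**C**),
patterned positions (**P**), and duplicate-unconfirmed alleles (**D**),
and accounts for what each step removed.

## The generative model

`simulate_library()` composes, per library:

1. **Molecules.** `molecules_per_sample` double-stranded fragments of
   `fragment_length` bases with uniform start positions. Molecule-level
   truth is injected here: each molecule covering a CHIP, patterned, or
   spiked position carries the alternate allele with probability equal to
   the channel's allele frequency. CHIP and patterned alleles go into both
   ccfDNA and buffy-coat material; spiked variants into ccfDNA only.
2. **PCR.** Each template strand founds a lineage. Every cycle, each
   amplicon copies with probability `pcr_efficiency`, and each copied base
   substitutes with probability `pcr_error_rate`. A strand's "first cycle"
   is its first copy event (with limiting-primer chemistry only one primer
   acts on the template initially), so first-cycle errors are a precise,
   queryable truth label and propagate to exactly the descendants of that
   copy — half the lineage if every amplicon duplicates each cycle.
3. **UMIs.** Singleton adapters give the two lineages independent 8-mers;
   duplex adapters give one (alpha, beta) 3+3 pair read in opposite
   rotation from the two strands, which is what makes the lineages
   pairable after consensus.
4. **Sequencing.** `reads_sampled` amplicons are drawn without
   replacement; each base substitutes with `seq_error_rate` and receives a
   two-point quality (Q37, or Q11 with probability `q_low` — enough
   structure to exercise the Q20 gates without a full quality model).

Every read carries `truth_tags` (`first_cycle_error@pos`,
`late_pcr_error@pos`, `seq_error@pos`, `chip_variant@pos`,
`patterned_error@pos`, `true_variant@pos`), so any downstream observation
can be traced to its generating mechanism. A *full* sample duplicate
re-runs everything from fresh molecules; a *sequencing* duplicate resamples
reads from the same post-PCR pool, which is exactly why it cannot remove
early PCR errors.

## Consensus calling

Families are reads sharing (chromosome, unclipped start, mate unclipped
start, UMI), with exact UMI matching — a single UMI read error founds a
spurious family, an inflation the simulator can reproduce via
`umi_error_rate`. At each position the consensus takes the predominant
base only if its fraction strictly exceeds 0.66 (so 2/3 passes, 1/2 and
3/5 do not), with the maximum quality observed among the reads carrying
it; otherwise an N with quality zero, which the Q20 pileup gate silently
discards downstream. Duplex step 2 (`pair_duplex_strands()`) collapses
rotated-UMI strand pairs with the same rule, so any single-strand artifact
becomes N. As in real duplex data — where both strands of a molecule are
recovered for only a tiny fraction of reads when sampling is sparse —
step-1 consensus is the default analysis level and step 2 is optional.

## Error estimation

`estimate_error_rates()` implements a region-gated global estimator: it
slides a 7-position window over runs of adjacent covered positions and
requires every column to have quality depth (bases ≥ Q20 on reads ≥ MQ20)
of at least `min_depth`, no indel evidence, and no alternate allele above
`max_af = 0.4` (the germline het/hom exclusion). Only the center base of
each passing window is tabulated; overlapping windows mean each interior
position of a clean run is a center exactly once. The error rate is
nonreference center observations over quality center observations.
`parse_positions()` is the per-position counterpart, emitting one record
per observed alternate allele at covered, non-germline positions (the BED
track), with the GC fraction of the ±10 bp context attached.

## The correction ledger

`run_decomposition()` computes, per family-size threshold and per subset
of {C, P, D}:

* **C** — CHIP variants are detected as buffy-coat NRAs with AF in
  [0.02, 0.30]; positions recurring in ≥ 6 samples are reclassified as
  patterned (recurrent positions are artifacts, not independent clonal
  hematopoiesis; the cutoff is a parameter, defaulting to the conventional
  6-of-7). Matching (position, allele) observations are removed from that
  sample's tally — numerator and denominator, since they are real
  molecules, with the position kept in the footprint.
* **P** — positions with NRAs in at least `relatedness_k` samples
  (default: all of them, "highly patterned") are dropped from the
  footprint entirely. Relatedness is position-level: mapping artifacts are
  positional. Lower `relatedness_k` removes more error and more footprint;
  `relatedness_sweep` in the result quantifies the trade.
* **D** — only alleles confirmed in the sample duplicate stay in the
  numerator; the denominator keeps the position's depth so rates remain
  comparable. Allele-level matching is the default
  (`match_on_alt = TRUE`); position-level matching is available because
  either reading of duplicate confirmation is defensible.

C and P commute (they act on disjoint axes); D is applied last.
`audit_truth()` then classifies every surviving NRA by the truth tags of
the consensus reads carrying it, which turns the central claim — residual
error after C and P is dominated by early, random PCR events plus true
variants, and only duplicates can remove the former — into a measurable
number.

## Desk-scale study conditions

The default `sim_config()` is a complete study sized to run in seconds
rather than cluster-hours, chosen once as a coherent set:

* **7 samples**, the cohort size typical of healthy-control comparisons,
  each with a ccfDNA library, a full duplicate, a sequencing duplicate,
  and a matched buffy coat.
* **600 bp reference, 150 bp fragments, 300 molecules, 3000 reads per
  library.** This concentrates coverage so each plateau position is
  covered by ~75 molecules and ~140 consensus families at family size ≥ 2.
  Coverage density is the load-bearing choice: with ~45 covering molecules
  a patterned position draws zero carriers in one sample often enough to
  escape the relatedness catalog, and extreme carrier draws cross the 0.4
  germline gate — failure modes that do not exist at a real experiment's
  ~3,000X depth. Analysis is restricted to the coverage plateau (at least
  one fragment length from the contig ends), the synthetic analogue of
  capture targets on well-covered exons, and truth positions are placed
  there for the same reason.
* **10 PCR cycles** (the standard low-input library protocol), efficiency
  0.35, PCR error 3×10⁻⁴ per base per copy, sequencing error 10⁻³ per
  base, 2% of bases at Q11. The two error rates are free parameters of the
  real chemistry; these values put every channel at measurable counts on a
  600 bp footprint while keeping the orderings (sequencing ≫ PCR per
  event; early PCR errors rare but consensus-surviving) intact.
* **Truth channels:** 2 CHIP variants per sample with AF drawn from
  U(0.05, 0.25) — inside the canonical 2–30% detection window, so window
  membership is decided by truth rather than by binomial noise at ~150X
  buffy depth; buffy libraries use 3× the ccfDNA molecule input (real
  protocols use roughly 10× more white-cell DNA); 20 patterned positions
  at per-library AF 0.15, affecting every sample by default
  (`patterned_hit_prob = 1`) because context-driven artifacts are
  properties of the position — observed relatedness still varies through
  detection, and partially shared artifacts are available by lowering the
  hit probability; 3 spiked variants per sample at AF 5/10/15%. Spikes are
  per-sample because ctDNA variants are patient-specific — a "true"
  variant shared by all samples is, operationally, patterned error, and
  would correctly be removed by P.
* **Gates:** the estimators default to the production values (depth ≥ 100,
  AF ≤ 0.4, 7-base windows, Q20/MQ20); the cohort driver passes
  `min_depth = 50` because desk-scale consensus depth is ~100–150X and the
  sweep must stay valid at family size ≥ 3.
* **Index hopping** is simulated at 2×10⁻⁴ with 10⁵ reads per sample, the
  order of magnitude at which unique dual indexes hold hopping below
  0.02%.

## What the simulation does and does not show

The generator reproduces the *mechanisms* — early-PCR clades surviving
consensus, sample-shared patterned positions, CHIP contamination visible
in buffy coat, duplicate confirmation removing exactly the
non-reproducible channel — and the package's tests assert the orderings
those mechanisms imply: the consensus-driven error drop from family size
1 to 2; corrected
error below patterned-only below uncorrected; full duplicates
out-suppressing sequencing duplicates; footprint shrinking with
patterned-removal leniency. It does not reproduce a real cohort's
numbers. At ~100X consensus depth the minimum observable allele frequency
is ~1%, so the real-data hallmark that ~90% of NRAs sit below 0.1% AF
cannot appear; channel proportions (patterned error dominates the desk
baseline) and absolute rates differ from a 124 kb panel at 2,800X; no
indels, no GC-dependent amplification, no capture bias, no
polymerase-specific substitution spectrum (the simulator's spectrum is
uniform over the 12 types by construction, and the spectrum functions
exist to summarize, not to model). Passing tests certify the algebra and
the mechanisms, not field performance.

One structural property of the consensus rule deserves a flag: beyond
family size 2 the expected residual error is *not* strictly decreasing in
the threshold. A two-member family passes a clonal early-PCR error only
at unanimity (probability \(f^2\) for a clade at fraction \(f\)), whereas
a three-member family passes at 2-of-3 (\(f^2(3-2f) > f^2\)), so size-2
families are the least error-permissive class and excluding them can
slightly raise the mean residual rate. In real data the decline with
family size continues because channels this generator deliberately omits
(UMI read errors creating spurious singletons, correlated base
qualities) keep shrinking; in the simulation the effect is visible as a
flat-to-slightly-rising tail after family size 2.

## Numerical choices and degenerate inputs

Ties and sub-threshold columns become N (the 0.66 comparison is strict,
so 2/3 = 0.667 passes by construction, not by tolerance); N bases carry
quality zero and are excluded by the same Q20 gate that drops low-quality
raw bases. Consensus members of unequal span use the covering subset as
denominator, and span positions covered by nobody are emitted as N (only
hand-built fixtures exercise this; the simulator emits equal spans).
Empty pileups yield a flagged report with an NA rate rather than an
error; a zero baseline with nonzero corrected error makes the reduction
undefined (NA with a warning). Back-mutations (a second substitution
restoring the reference) keep their truth tags but are invisible to the
estimators, which is correct behavior for counting *observed* error. All
randomness flows from one integer seed through per-stream derived seeds,
so a sequencing duplicate can rebuild its sibling's PCR pool exactly
without the pool being stored.

## A worked run

```{r study, eval = FALSE}
study <- run_pipeline(sim_config(seed = 1))
print(study)
study$decomposition$summary
attr(study$audit, "fraction_early_or_true")
```

The printed summary lists, per family size and correction set, the mean ±
SD error across samples and the percent reduction versus the uncorrected
consensus baseline and versus the pre-UMI error. `scripts/acceptance.R`
re-derives the headline quantities from scratch for a given seed.
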