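---
title: "Models and methods behind barseqcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barseqcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqcomp)
```

# The experiment this package models

`barseqcomp` analyses pooled competition experiments in *Bacillus subtilis*
in which 79 strains — the wild type, all 12 single deletions of the
rap–phr regulator pairs (*rapA*–*rapK* plus the plasmid-borne *rapP*), and
all 66 double deletions — are mixed at equal ratios and propagated through
nine serial-transfer cycles under four regimes (planktonic or pellicle
biofilm culture, harvested after 2 or 5 days). At the end of each cycle the
culture is heat-treated (80 °C, 20 min), which kills every vegetative cell,
so only mature spores seed the next cycle: a *sporulation bottleneck*. One
twentieth of the surviving suspension is transferred.

Each strain carries a unique random 12-bp DNA barcode integrated at the
*amyE* locus. Strain abundances are read out by PCR-amplifying the barcode
locus with primers that add inline sample tags (5 nt on read 1, 7 nt on
read 2 — a 4 × 12 grid resolving up to 48 samples per run) and sequencing
the amplicons paired-end.

# The forward simulator

Because the study's raw reads and CFU tables are not desk-reproducible, the
package ships a first-class generative model of the experiment. One cycle of
`simulate_cycle()` is, in order:

1. **Growth.** Each strain's vegetative count is multiplied by its
   `growth_yield` (expected fold-increase per cycle). If the total would
   exceed `carrying_capacity`, all strains are rescaled proportionally —
   resource limitation is not strain-structured, so the composition is
   preserved.
2. **Sporulation.** Each cell is a mature spore at harvest with probability
   `sporulation_fraction` (binomial draw per strain).
3. **Heat-kill.** Vegetative cells survive with probability
   `heat_kill_survival_vegetative`, default 0.
4. **Bottleneck.** The transferred inoculum is a single multinomial draw of
   size Binomial(survivors, `dilution_fraction`), modelling volume transfer
   of a well-mixed suspension. When the whole volume transfers
   (`dilution_fraction = 1` and every particle is drawn) the draw is the
   identity, so no artificial resampling noise is introduced. Transferred
   spores germinate and enter the next cycle as vegetative cells.

The recorded composition after each cycle is the post-growth,
pre-heat-treatment state, because that is when DNA was sampled for
sequencing in the wet protocol.

For two strains with equal yields and sporulation fractions in ratio *r*,
the expected one-cycle update is the replicator equation
*f′ = f·r / (f·r + (1 − f))* — the test suite checks this closed form, along
with strict particle conservation and neutrality (mean final frequency 1/n
over replicate simulations of identical strains).

## Parameter defaults and what they mean

| parameter | default | rationale |
|---|---|---|
| `growth_yield` | 20 | a 1/20-diluted culture regrows to the same stationary density; also makes log2(20) ≈ 4.32 generations/cycle, ≈ 38.9 over 9 cycles, consistent with the experiment's "more than 39 generations" order of magnitude |
| `sporulation_fraction` | 0.5 | sporulation is a bet-hedged, partially penetrant decision; one half by harvest is a realistic neutral default for a multi-day incubation |
| `heat_kill_survival_vegetative` | 0 | the 80 °C / 20 min treatment is described as killing *all* vegetative cells |
| `dilution_fraction` | 1/20 | 0.5 ml into 9.5 ml (planktonic) and 100 µl into 1900 µl (pellicle) are both 1/20 |
| `n_cycles` | 9 | the experiment's nine reinoculation cycles |
| `initial_cells` | 10⁶ | OD-adjusted overnight mixes; large enough that the equal-ratio inoculum (~1.3 × 10⁴ cells/strain) is far from drift-dominated at t0 |
| `carrying_capacity` | 10⁹ | a saturated 10-ml culture order of magnitude |

The study never quantifies per-strain growth or sporulation parameters, so
these stay free parameters with a neutral default. `scenario_params()`
provides qualitative presets (`early_sporulator`, `late_sporulator`,
`growth_deficient`) mirroring the kinds of strain behaviour the competition
revealed; they are illustrative regimes, not estimates of any real strain.

## Randomness contract

One root seed governs an experiment. Sub-streams are derived
deterministically from the index path (mix, replicate, cycle) by
`derive_seed()`, so any replicate or cycle can be reproduced in isolation
and trajectories are bit-identical under the same root seed.

## The read generator

`render_reads()` draws `depth` read pairs multinomially from a known
composition and builds each amplicon as

```
forward_tag(5) + left_flank + barcode(12) + right_flank + revcomp(reverse_tag(7))
```

Read 1 is the template's prefix at the configured read length; read 2 the
prefix of its reverse complement, so it starts with the reverse tag.
Substitution errors are applied iid per base at `error_rate`; quality
strings are constant placeholders because the counting rules use no quality
information. The ground-truth draw is returned (and optionally written as a
TSV sidecar), which is what makes exact round-trip testing possible. PCR
chimeras and index hopping are deliberately not modelled; acquired
beneficial mutations are available only as an abstract
`fitness_modifier(cycle)` hook on growth yield.

# Counting rules

Demultiplexing compares tag prefixes exactly (a mismatch tolerance exists as
a knob but defaults to 0, since the protocol describes none). Barcode
assignment follows the study's rule: a pair is linked to a barcode if at
least one mate contains it verbatim over its full length; pairs hitting two
or more distinct barcodes are ambiguous and excluded; pairs hitting none
are unassigned. Two choices the protocol leaves open are made explicit:

* **Reverse-complement search is on by default** (amplicon orientation after
  paired sequencing is not stated); a strand-specific mode exists. Library
  construction must therefore avoid barcodes that are palindromes or mutual
  reverse complements — `generate_barcodes()`' Hamming floor makes this
  astronomically unlikely at 12 bp, and `validate_library_context()` rejects
  collisions with the fixed amplicon context.
* **Frequencies use assigned counts as the denominator**: excluded products
  were excluded from the study, so they should not dilute frequencies.

The implementation is backed by Biostrings (`PDict` exact multi-pattern
search); every policy decision is cross-checked in the test suite against a
naive all-barcodes × all-positions substring oracle, and the conservation
identity assigned + ambiguous + unassigned + tag-unmatched = total pairs is
asserted throughout.

# Dynamics summaries

* `to_frequencies()` normalises assigned counts per sample and joins the
  sample sheet metadata.
* `persistence()` counts, per strain and condition, the replicate
  populations whose frequency *strictly* exceeds a threshold — by default
  the exact equal-ratio input 1/79 (printed as 1.27%). The comparison is
  strict because persistence is defined as exceeding the putative input.
* `winners()` lists strains above a dominance threshold (default 25%);
  at most ⌊1/threshold⌋ strains can win in one sample, which is asserted as
  a property.

# Fitness estimators

For pairwise CFU competitions, relative fitness is implemented exactly as
the study defines it:

$$W_A = \frac{\ln(\mathrm{CFU}_{A,48h}) / \ln(\mathrm{CFU}_{A,start})}
            {\ln(\mathrm{CFU}_{B,48h}) / \ln(\mathrm{CFU}_{B,start})}$$

Note this is a ratio of logs of *absolute* counts, not of fold-changes; it
is therefore not invariant to a common rescaling of all CFU values (a
property the tests document on randomised records). A conventional
Malthusian estimator `malthusian_fitness()` is provided for comparison but
is never used in acceptance testing. Sporulation fitness is the spore yield
per inoculated cell, strain A over strain B:

$$SF_A = \frac{\mathrm{spores}_{A,48h} / \mathrm{CFU}_{A,start}}
             {\mathrm{spores}_{B,48h} / \mathrm{CFU}_{B,start}}$$

The printed source formula contains a stray "l" in the denominator, treated
here as a typographical artifact. Both estimators satisfy reciprocity
(W(A,B) · W(B,A) = 1) to 10⁻¹² relative tolerance.

For evolved-vs-ancestor competitions the marker arithmetic is
`split_plate_counts()`: evolved = CFU on selective (LB+chl) plates,
ancestor = permissive − selective, truncated at zero with a plating-noise
flag rather than an error.

`fitness_inference()` log10-transforms replicate values and applies a
two-sided one-sample t-test against 0 (W = 1), with a Shapiro–Wilk
normality check at α = 0.05 reported as a caveat rather than a gate —
matching how the analysis is reported. Zero-variance inputs are reported as
degenerate with no stars. Stars follow the unusual thresholds
0.05 / 0.005 / 0.001. Because it is unstated whether reported means are
arithmetic or geometric, both are exported.

# Statistics

**PERMANOVA** is implemented from first principles on Euclidean distances:
SS_total = Σ_{i<j} d²_ij / n, within-group SS analogously per group,
pseudo-F = (SS_between/(g−1))/(SS_within/(n−g)), and
p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm) over label permutations. The
permutation count is unstated in the source analysis, so the default is 999
with the +1 correction; the stream is seedable, and an exhaustive mode
enumerates all n! orderings for small designs. Tests verify equality with a
coordinate-space ANOVA oracle, with `vegan::adonis2`, and — exhaustively at
n = 6 — with a brute-force enumeration oracle, plus empirical type-I
calibration at α = 0.05 over 100 null trials. Note that with exchangeable
duplicated compositions, label permutations reproducing the observed
partition tie the observed F, so the attainable minimum p is slightly above
1/(n_perm+1) for small balanced designs.

**PCA** is column standardisation followed by SVD (`stats::prcomp`);
zero-variance columns are dropped with a warning. "Aggregated by replicate
means" is interpreted as averaging technical replicates within each
mix × condition before ordination; this is the caller's aggregation choice,
not hard-coded.

**Spearman input–output correlation** uses average-rank ties, with
Benjamini–Hochberg adjustment across the four conditions by default (the
adjustment method is unstated in the source; Holm is available by flag).

**Growth increment** is OD at the sample point nearest the 16-h horizon
minus OD at time zero, with ties resolved to the earlier point — a
nearest-sample rule matching 15-min plate-reader sampling, deliberately not
interpolation.

# What a green test establishes — and what it does not

The synthetic generator emulates the *design* of the experiment: panel
combinatorics, equal-ratio input, the tag/barcode read structure, the
bottleneck regime, and substitution sequencing noise. It does not emulate
real strain biology (no strain-specific parameter estimates exist), PCR
amplification bias, chimeras, index hopping, or the phage-driven genetic
adaptation observed in the evolved isolates. Green acceptance tests
establish that the pipeline's arithmetic, matching rules, estimators and
statistics are correct and self-consistent at the stated tolerances — not
that any biological conclusion about particular rap–phr mutants is
reproduced. Reproducing the study's figure-level values would require the
deposited raw reads and unpublished CFU tables, which are out of scope.

# Numerical and degenerate-input choices

* Cell counts are held as integers; growth is deterministic with rounding
  after capacity rescaling, and all stochastic steps are exact binomial or
  multinomial draws.
* Extinction (zero survivors at a bottleneck) flags the state instead of
  raising, so whole-experiment sweeps do not abort.
* CFU values ≤ 1 make the as-printed W undefined (a log hits 0 or flips
  sign); the error names the offending field.
* Barcode generation is rejection sampling against a Hamming floor with a
  bounded attempt budget; infeasible requests fail loudly.
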