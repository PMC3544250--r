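---
title: "Marker-assisted backcrossing with mabcr: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-assisted backcrossing with mabcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabcr)
```

## The problem

Marker-assisted backcrossing (MABC) introgresses a target locus — here the
*Saltol* QTL for vegetative-stage salinity tolerance in rice, carried by the
donor line FL478 — into an elite recurrent parent (BT7) while recovering the
recurrent parent's genome everywhere else. Selection is three-tiered in each
backcross generation:

1. **Foreground selection** keeps plants heterozygous at SSR markers tightly
   linked to the target (RM493 and RM3412b on chromosome 1).
2. **Recombinant selection** keeps, among those, plants homozygous for the
   recipient allele at a flanking marker, i.e. plants carrying a crossover
   between the target and the flank, which trims linkage drag. The schedule
   demands a distal crossover (RM10825) in BC1 and a proximal one (RM10694)
   in BC2/BC3, so the retained donor segment shrinks to the interval between
   the flanks.
3. **Background selection** ranks the survivors by recurrent-parent genome
   recovery over genome-wide markers and advances the best few as parents of
   the next backcross.

`mabcr` implements this pipeline end to end, together with a backcross
genetics simulator that generates statistically faithful genotype data.
Breeding programmes rarely publish their raw plant × marker matrices; the
simulator makes every stage of the pipeline testable at desk scale and
provides ground truth (`true_rpg()`) that marker-based statistics can be
audited against.

## Genome and meiosis model

A plant is a diploid mosaic of ancestry segments: per chromosome, two
haplotypes, each an ordered run of maximal `recipient`/`donor` segments that
tile the chromosome exactly (0-based half-open coordinates internally;
marker tables use 1-based inclusive positions and are converted exactly
once, at genotyping).

Meiosis uses a linear genetic map (`genetic_map()`): a chromosome of `L` bp
at `c` cM/Mb has map length `L·c/10^8` Morgans. Per gamete and chromosome,
the crossover count is Poisson with that mean (no interference), crossover
positions are uniform in physical coordinates, and the gamete alternates
between the parental haplotypes starting from a fair random one. This is
exactly the model underlying the Haldane map function
`r = ½(1 − e^{−2d})` (`haldane_recomb_fraction()`), which makes the
simulator analytically checkable: segment breaks in an F1 gamete count
crossovers, and unselected BC\_nF\_1 populations have expected recipient
fraction `1 − 2^{−(n+1)}` (75, 87.5, 93.75 % for n = 1–3). Crossover
interference (e.g. a Kosambi-consistent process) is deliberately not
modelled; at the marker densities used here interference mainly affects
segment-length variance, not the recovery expectations the pipeline is
tested against.

Defaults that matter:

* **Chromosome lengths** (`rice_chromosome_lengths()`): 12 rice-like
  pseudo-chromosomes, chromosome 1 = 45 Mb, total 375.5 Mb. No length table
  is published with the marker data, so these are configurable round
  numbers; all shipped tests pin them.
* **cM/Mb = 4.0**, globally. With the default lengths this gives a
  ~1500 cM genome, the right order for rice. Configurable per chromosome.
* **Missing-call rate = 0** — the motivating data set reports none;
  `missing_rate` exists so robustness can be tested (missing calls
  disqualify in foreground/recombinant selection and are excluded from
  %A/%R denominators).

## Marker panels

`saltol_panel()` ships the chromosome-1 foreground/flank panel with primer
sequences, motifs, repeat counts and SSR spans. `check_ssr_span()` audits
the printed arithmetic: the implied repeat count is
`(ssr_end − ssr_start + 1)/nchar(motif)`. Five markers verify exactly
(RM10694 = 18, RM10748 = 14, RM493 = 9, RM140 = 12, RM10825 = 10); RM562's
span implies 15 AAG units against a printed 13. The panel keeps the printed
value and flags the row — auditing tables is the package's job, correcting
them silently is not. Two markers (RM3412b, AP3206f) have no printed
coordinates beyond a Mb-scale position; their optional fields load as
absent, never as zero, and they participate in selection by role only.

`synthetic_background_panel()` builds the genome-wide background panel: 89
markers (matching the 89-of-477 = 18.7 % polymorphic screen,
`polymorphism_rate()`), allocated per chromosome by largest remainder
proportional to length with at least four per chromosome, evenly spaced,
and kept out of a 9–16 Mb window on chromosome 1 so background markers stay
unlinked to the target region. The construction is deterministic: the
acceptance simulations run on a fixed panel composition rather than a
random 18.7 % thinning, so that run-to-run variation reflects meiosis and
selection only.

## The campaign driver

`run_campaign()` executes F1 → BC1F1 → BC2F1 → BC3F1 with, per generation,
`pop_size` progeny per advanced parent (default 300, within the programme's
reported 300–478 per generation; the exact sizes are not published),
`n_parents = 2` plants advanced, and the three selection tiers above.
Background ranking is by descending %R, ties by descending %A, then
ascending plant id — the data determine the first two keys; the id key is a
deterministic tie-break of our choosing.

Markers that are recipient-homozygous in **all** selected plants of a
generation are dropped from the next generation's screening list
(`drop_fixed_markers()`): this mirrors how programmes stop scoring fixed
loci. Dropped markers enter a *fixed-for-recipient ledger* and count as `A`
calls in every later %A/%R computation, so percentages stay comparable
across generations even as the screened list shrinks (a plant's %R in BC3
is always over the full background panel, screened plus ledger). A missing
call blocks dropping — absence of evidence is not fixation.

If foreground or recombinant selection leaves no survivors the campaign
halts with a diagnostic naming the generation. Resampling would silently
paper over configuration pathologies (e.g. an unsatisfiable flank
requirement); halting surfaces them. At the default sizes an empty
recombinant pool is a rare but real event (the BC1 flank sits ~4 cM from
the target, so ~6 of ~150 foreground survivors are expected recombinants),
which is why scripted multi-seed summaries treat a halted campaign as a
missing value rather than an error.

Everything stochastic flows from the single config seed: one `set.seed()`
at campaign start, then draws in a fixed order (per generation: gametes
plant by plant, mother before father, then one missing-data mask over the
whole matrix in column-major order). Identical seed and config therefore
reproduce byte-identical outputs, which `write_selection_trace()` and the
run manifest make checkable.

## Recovery statistics and reports

For a call vector with counts `n_A`, `n_H`, `n_B` (missing excluded):

* `%A = 100·n_A/(n_A + n_B + n_H)` — markers homozygous recipient;
* `%R = 100·(n_A + ½·n_H)/(n_A + n_B + n_H)` — percent recipient alleles,
  heterozygotes at half weight.

The %R formula is the standard allele-counting definition; it is stated
here prominently because recovery percentages are often reported without
one. `%R ≥ %A` always, with equality exactly when no heterozygote remains,
and `%R = 100` exactly when the plant is recipient-homozygous at every
non-missing marker. On simulated populations the marker-based %R tracks the
bp-weighted `true_rpg()` and tightens as marker density grows; at the
89-marker density it sits within 5 percentage points of truth for ≥95 % of
BC2 plants in the shipped property test. That is also the honest caveat:
with ~13 markers still segregating in BC3, a plant can show %R = 100 while
its true recovery is ~99 % — marker panels cannot see between their
markers, on real data exactly as here.

`rpg_histogram()` bins per-plant %R (default bin width 2.5 %, a choice —
the source figure does not state one) with right-open bins and a final bin
closed at 100 so complete recovery is counted, conserving plant counts.

`graphical_genotype()` renders per-chromosome ancestry bars. The published
figures do not document their interval rule, so ours is explicit: an
inter-marker interval takes recipient glyph when both flanks are `A`, donor
glyph when any flank is `B`, otherwise the heterozygous glyph; chromosome
ends take their nearest marker's class; missing calls are imputed from the
nearest non-missing call (leftward on ties) before classification. The text
rendering (`.` recipient, `#` donor, `+` heterozygous, `|` marker tick) is
one glyph per interval and is exactly invertible by
`parse_graphical_genotype()`; the plotted figure scales the same intervals
to physical coordinates.

## Duncan's multiple-range test

`duncan_mrt()` implements the classical post-hoc used in agronomic trait
tables: one-way ANOVA error mean square (via `stats::aov`; with unequal
group sizes the harmonic mean size is used), then least significant ranges
`LSR_p = q_p·√(MSE/n)` with `q_p` the studentized-range quantile at
Duncan's protection level `(1−α)^{p−1}` (`stats::qtukey`). Ordered means
within a range not exceeding its LSR — or inside such a range — are
homogeneous; maximal homogeneous stretches become letter groups, and the
t-based LSD is reported alongside, as trait tables print it. With two
groups the procedure reduces exactly to the pooled two-sample t-test, which
the test suite exploits as an independent oracle. Zero error variance
degenerates cleanly: distinct means separate, identical means share a
letter.

Two conventions were genuinely open:

* **Letter order.** Letters are assigned to homogeneous groups in order of
  first appearance in the *input* group order, not by descending mean —
  agronomic tables label the control row `a` whether or not it has the
  largest mean, and reproducing a published letter column requires the
  table-order convention.
* **Replicate count.** The motivating trait table states measurements were
  taken at least in triplicate but not the exact n; fixtures use 3
  replicates constructed with exact means and exact error variance
  (residual pattern −d, 0, +d), so ANOVA quantities are closed-form.

A caution that the test suite documents rather than hides: a letter display
and an LSD row can contradict each other. If two group means differ by more
than the LSD yet share a letter, no within-group variance can reproduce
both — the package reproduces the letter partition under a variance
consistent with it, and reports the LSD that variance implies.

## The salinity yield-loss utility

`salinity_yield_loss()` is the standard threshold-slope model for a
salt-sensitive rice crop: no loss up to 3 dS/m, then 12 % yield per dS/m,
clamped at 100 %. It is a linear rule; literature statements of "up to
50 % at 6 dS/m" exceed its 36 % and are not part of this model.

## What the simulator does and does not emulate

The generator reproduces the design quantities of a backcross programme:
Mendelian transmission with Poisson crossovers, the BC\_nF\_1 guarantee
that no locus is donor-homozygous, neutral recovery expectations, linkage
between the target and its flanks, and a fixed genome-wide background
panel. It does not emulate segregation distortion, genotyping error (beyond
a uniform missing rate), marker-order errors, crossover interference, or
phenotypic selection — conclusions from passing tests are about the
selection arithmetic and the statistical machinery, not about field
performance of real lines. Trait-table comparisons (Duncan) therefore treat
published means as *inputs* on synthetic replicates; the package makes no
claim of re-deriving field measurements.

## Problem sizes and numerical choices

Shipped tests and the acceptance script run at the study's own scale: 300
progeny per parent and 3 generations per campaign, 20 seeds for the
headline median (~1500 plants × ~100 markers per campaign), and 1000-plant
populations per generation for the neutral-expectation checks. Monte-Carlo
assertions use 3 standard errors of the simulated sample. Percentages are
kept at full precision internally; printed-percentage parity uses half-up
rounding to one decimal (`polymorphism_rate()`), and %A/%R are rounded only
for display. Coordinate convention, tie-breaks, degenerate inputs (empty
panels, all-missing plants, empty candidate sets, zero variance) each have
a defined behaviour tested in the suite: warnings for empty-but-legal
inputs, errors that name the offending marker, plant or generation for
contract violations.
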