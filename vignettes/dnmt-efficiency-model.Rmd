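---
title: "Methods: dyad calling and the Dnmt efficiency model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyad calling and the Dnmt efficiency model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the model and its assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Why double-stranded calling

A CpG site is palindromic: the dyad carries one cytosine per strand, and
its state after replication is the substrate on which maintenance
methylation acts. Single-strand bisulfite data collapse the four dyad
states (`U`, `HU`, `HL`, `M`) into two observable ones and cannot separate
an unmethylated cytosine from a genomic CpG→TpG transition. Reading both
strands of one molecule resolves both ambiguities: hemimethylation is seen
directly, and a mutation betrays itself as an adenine opposite a position
where the reference has a guanine — guanines are untouched by bisulfite, so
no conversion outcome can produce that base.

### The dyad decision table

`call_dyad()` receives the four informative bases of a dyad in strand-local
reading (`u_i`, `u_{i+1}` on the upper strand; `l_i`, `l_{i+1}` on the
lower). The logic, derived from the generative possibilities:

1. `l_i = A` (and not also `u_{i+1} = A`) → upper-strand CpG→TpG mutation.
2. `u_{i+1} = A` symmetric → lower-strand mutation.
3. Both adenine signatures at once cannot arise from a single germline
   transition; at amplicon scale it is indistinguishable from alignment
   error → `UNRESOLVED`.
4. With both guanines intact, the two cytosine readouts map
   C (methylated) / T (converted) onto `FULL`, `HEMI_UPPER`, `HEMI_LOWER`,
   `UNMETH`.
5. Anything else — gaps at any informative base, sequencing errors at
   guanine positions — is `UNRESOLVED`, the "not analysable" sink. We
   deliberately never partially call a gapped dyad. The mutation signature,
   however, takes precedence over a noisy partner base (rule 1/2 fires on
   the A alone): a transition is the only parsimonious explanation of the
   adenine.

Mutated and unresolved dyads are excluded from every methylation statistic
and from the model likelihood.

The test suite checks this table against an independently constructed
oracle (generative enumeration of state × mutation × conversion outcome)
over all 256 base quadruples.

### Coordinates

All positions are 1-based and inclusive, the R and Bioconductor
convention. A dyad is indexed by its upper-strand cytosine; the partner
cytosine on the lower strand sits at `i + 1`, so partner arithmetic stays
trivial. Lower-strand cytosines appear at upper-strand guanine positions,
and their dinucleotide context is read 5'→3' along the lower strand, i.e.
towards decreasing upper-strand coordinates.

## Read processing

**Linker detection.** The hairpin linker carries five to seven deliberately
unmethylated cytosines. The scanner matches the linker against the read and
its reverse complement, allowing C *or* T at those marked offsets (the C
survives when conversion fails) and requiring exact identity elsewhere, up
to `max_mismatches = 2`. Ties between equally good placements reject the
read as `ambiguous_linker` rather than guessing. The fraction of T among
the marked offsets is the per-molecule conversion rate; its complement is
the background used for all non-CpG significance tests.

**Alignment.** Each arm is aligned globally (Needleman–Wunsch/Gotoh,
affine gaps) against its strand-local reference — the given strand for the
upper arm, the reverse complement for the lower arm. The substitution
function is bisulfite-aware and asymmetric: reference C against read T is a
match (conversion), reference C against read C is a match (methylation),
everything else is penalized. Scores are `match +1, mismatch −2, gap open
−4, gap extend −1`: conservative values for short amplicon arms where a
gap should cost clearly more than a mismatch, exposed in the run
configuration. Traceback ties are broken towards the diagonal (substitution
over gap) so alignments are deterministic. Alignment identity is computed
over non-C reference positions only, because C positions legitimately vary
with methylation; read insertions are dropped, deletions surface as `-`
calls and make any affected dyad `UNRESOLVED`.

**Filters.** Defaults: `min_conversion = 0.90`, `min_identity = 0.80`,
`min_covered_dyads = 3`. Reads cover of the order of 3–12 dyads, so three
fully-called dyads is the floor of usefulness; the conversion gate is
deliberately not stricter because with ~6 linker cytosines a single
conversion failure already drops a molecule to 5/6 ≈ 0.83, and samples with
genuinely lower linker conversion (degenerate, back-folding-prone elements)
would otherwise lose most reads. FASTQ qualities are parsed but ignored —
no homopolymer-aware error model is attempted.

## Summary statistics

* **Overall methylation** weights hemimethylated dyads as half:
  `(0.5·(HU + HL) + M) / (U + HU + HL + M)`.
* **Hemimethylation fraction** is primarily `(HU + HL) / (HU + HL + M)` —
  the share of methylated dyads that are hemimethylated, which is the form
  in which such percentages are usually quoted. The alternative reading
  (hemi share of all dyads normalized by the weighted level) is available
  under `of = "level"`; the two must never be mixed within one comparison.
* **Read categories** use the precedence dispersed-hemi →
  full-and-hemi → full-only → hemi-only → unmeth-only, so every read with
  at least one analyzable dyad lands in exactly one bin and unmethylated
  dyads never change the category.
* **Per-read CpG level bins** for the CpA analysis close the conventional
  gapped grouping (0–25%, 33–66.7%, 75–100%) to `[0, .25]`, `(.25, .70]`,
  `(.70, 1]`. For reads with about four dyads the achievable levels are
  quartile multiples, so membership is unchanged; the closure only
  guarantees that every read is binned.
* **Non-CpG significance** is a one-sided exact binomial test of each
  position's level against the sample's conversion background, with
  Benjamini–Hochberg control at `q = 0.05` across positions and a minimum
  coverage of 20 reads. This replaces an informal "clearly above
  background" judgement with a calibrated criterion; the suite verifies
  ≤ 5% of null replicates flag anything.
* **Co-methylation** between a non-CpG cytosine and a CpG dyad is the phi
  coefficient of the binary indicators across reads, strand-locally: on the
  upper strand `FULL` or `HEMI_UPPER` count as methylated. Phi is chosen
  because both indicators are binary and it degrades gracefully to `NA` on
  degenerate columns; pairs need ≥ 30 informative reads.

## The inheritance model

One generation is replication followed by a single simultaneous enzymatic
pass:

* Segregation `S`: `M → HU, HL` (½ each), `HU → HU, U` (½ each), `HL`
  symmetric, `U → U`. This is the passive-dilution backbone: with all
  efficiencies zero the weighted methylation level decays exactly as
  `2^-g`, which the suite asserts both analytically and by simulation.
* Enzymatic pass: active enzymes act independently, so maintenance
  combines as `h* = 1 − ∏(1 − μ_e)` and de novo as `d* = 1 − ∏(1 − δ_e)`.
  Independence is an explicit modelling assumption — no cooperative or
  competitive interaction between enzymes within one pass. De novo acts per
  cytosine of an unmethylated dyad independently (`U → M` with `d*²` in one
  generation); the hemi dyad's empty cytosine is filled with probability
  `h*` in the default `free` parameterization, or
  `1 − (1 − h*)(1 − d*)` in the `tied` one (de novo equally active at
  unmethylated and hemimethylated positions). A cytosine methylated in the
  current pass cannot trigger maintenance of its partner in the same pass;
  a sequential de novo→maintenance variant is not the default because the
  single-pass model is the more parsimonious reading of per-replication
  efficiencies. `free` is the default because it reports what the data can
  separate; `tied` is available where the equal-probability assumption is
  wanted.
* Emission: per-cytosine observation errors are independent — an
  unmethylated C reads methylated with `c_fail`, a methylated C reads
  converted with `c_over`. `c_fail` defaults to the sample's measured
  linker failure rate and is **fixed, not fitted** (it is measured with far
  more precision by the linker than the fit could achieve); `c_over`
  defaults to 0 since no over-conversion estimate is generally available.

The model contains no strand-asymmetric term, so `P` and `E` are invariant
under relabelling `HU ↔ HL` and predicted hemimethylation is always split
evenly between strands — a property the tests assert.

### Likelihood and fitting

Each cell line contributes a multinomial likelihood of its analyzable
class counts under `π₀ P^g E`. The knockout lines are the informative
contrasts; the parental wild type enters only as the initial distribution
`π₀` and as held-out validation (`predict_wt()`), because using it in the
likelihood would let the stationary wild type dominate the fit of exactly
those parameters the knockouts are meant to separate. A flag can add it
back. `π₀` uses the observed wild-type class proportions directly as state
proportions; at ~1% conversion error the deconvolution through `E` changes
them by less than the sampling noise, so the optional constrained
least-squares deconvolution is off by default.

Class probabilities are floored at `1e-300` before the log, so empty
classes never produce `-Inf`. Generation counts are fixed from the design
when known; otherwise a single shared scale on the per-line generation
counts can be fitted in bounds (a per-line free generation count is
deliberately not offered — with one time point per line it trades off
almost perfectly against the efficiencies).

Optimisation is bounded quasi-Newton (`L-BFGS-B`) with numerical
gradients from 10 Latin-hypercube starting points drawn under fixed seed
17; the best optimum is kept, with exact ties broken towards the smallest
parameter L2 norm for determinism. Standard deviations come from the
inverse observed Fisher information — a central-difference Hessian with
step `1e-4`, evaluated at the estimate projected into the interior of the
box. Singular curvature falls back to the Moore–Penrose pseudo-inverse and
is flagged; any parameter with SD above 0.15, at a box bound, or with
non-positive curvature is flagged `non_identifiable`. The 0.15 threshold
marks the point where a probability estimate stops supporting any
directional conclusion.

With the full four-knockout design (20,000 dyads per regime, 20
generations) all six efficiencies are recovered to within ±0.03; removing
the two single-Dnmt3 knockouts leaves Dnmt3a and Dnmt3b mutually
confounded (their SDs explode and are flagged) while the double knockout
still pins Dnmt1's parameters below 0.01 SD — the characteristic partial
identifiability of reduced designs.

## The synthetic generator

The generator produces data at two levels. `simulate_states()` evolves
each molecule's dyads independently through the exact transition chain —
so simulation and likelihood share no code path beyond the transition
matrix itself, and their agreement (within multinomial 3σ bands) is a
meaningful invariant. `render_reads()` turns states into raw reads:
germline-like CpG→TpG mutations (placed once per molecule, not per
generation — repeat-element CpG decay is ancestral, not culture-acquired),
per-cytosine bisulfite conversion with `c_fail`/`c_over`, assembly as
upper arm + converted linker + lower arm (5'→3'), uniform substitution
sequencing error, and a uniformly random read orientation. Everything is
deterministic given the seed.

What it emulates: dyad-state populations under the generational model,
linker-measured conversion failure around 1–2%, heavy mutation loads (up
to the ~44% seen in degenerate SINE-like elements), and position-specific
CpA methylation whose odds are multiplied by a factor κ when the nearest
same-strand CpG is methylated. What it does **not** emulate: PCR
duplicates and chimeras, 454-style homopolymer errors (substitutions
only), common ancestry between molecules (off by default), per-position
efficiency variation, and 5-hydroxymethylcytosine. Passing tests therefore
demonstrate correctness of the computational pipeline under its own model
assumptions — not robustness to those unmodelled features of real data.

Default scale: 5,000 molecules per regime with 4 dyads each (20,000 dyads
per regime) — the order of magnitude of a deep amplicon experiment. The
test suite uses the same design with fewer replicates; the recovery
experiments in `scripts/acceptance.R` run ten seeded replicates per
regime.

## Degenerate inputs and edge cases

* Zero analyzable dyads → `"no_data"` errors rather than `NaN`.
* No methylated dyads → `hemi_fraction` errors `"no_methylation"` (0/0).
* Coupled CpA probabilities exceeding 1 under large κ are clipped with a
  warning.
* Stationarity is declared at `max |π_{t+1} − π_t| < 1e-10`; matrix powers
  use squaring for integer `g` and an eigendecomposition for fractional
  `g` (only reachable when fitting the generation scale).
* Knocked-out enzymes are exactly 0, never merely small; enzymes active in
  no regime are excluded from the parameter vector entirely and reported
  as fixed zeros.

## Limitations

* Dyads are modelled independently: no neighbouring-site dependence or
  enzyme processivity. Efficiencies are per-element averages, not
  site-specific.
* Bisulfite chemistry cannot distinguish 5hmC from 5mC; where 5hmC is
  abundant, maintenance efficiencies absorb its effects.
* The emission layer models conversion error only; systematic alignment
  artefacts are handled by filtering, not modelled.
* With one observation time point per line, generation counts and
  efficiencies are jointly only weakly identified; fixing `g` from passage
  records is strongly preferred.
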