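---
title: "Constraint-conditioned structure optimization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-conditioned structure optimization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvfold)
```

## The problem

Co-folding structure predictors struggle with complexes dominated by
intrinsically disordered regions: confidence is high inside structured
domains, inter-domain packing is essentially random, and no reliable
binding pose emerges. When independent biochemical knowledge identifies
which regions interact — for G3BP1–GR20, the acidic IDR1 attracting the
arginine-rich GR20 peptide — that knowledge can be injected as spatial
constraints and the predictor's output *conditioned* on them. `cvfold`
implements the constraint machinery, the annealed optimization loop over a
pluggable generator, and the analytics used to audit the resulting models
and ensembles.

## The composite loss

All CV terms act on Cα coordinates under a global 1-based residue
indexing that runs through the chains in input order (for the 466 + 40
residue G3BP1–GR20 complex, GR20 occupies indices 467–506). The composite
is

$$L_\mathrm{AFEX} = w_c\,L_\mathrm{CV} + w_r\,L_\mathrm{regular},
\qquad L_\mathrm{CV} = L_\mathrm{rest} + L_\mathrm{attr} + L_\mathrm{repl}$$

* **Positional restraint** $L_\mathrm{rest} = \mathrm{mean}_i\,
  \lVert r_i - r_{i,\mathrm{ref}}\rVert^2$ over the restrained residues
  (the structured domains). The sum over the three coordinate components
  sits inside, the mean over residues outside, so the value is in Å² and
  independent of domain size.
* **Attractive term** $L_\mathrm{attr} = \max(\mathrm{mean}(d - d_c), 0)$
  and **repulsive term** $L_\mathrm{repl} = \max(\mathrm{mean}(d_c - d),
  0)$ over the array $d$ of Cα–Cα distances between two residue groups,
  with cutoff $d_c = 8$ Å by default. The clamp applies to the **mean**,
  not per pair: pairs inside the cutoff offset pairs outside it. This is
  deliberate fidelity to the defining formula; the more conventional
  flat-bottom variant (clamp each pair, then average) is available as
  `per_pair_clamp = TRUE` but is off by default.
* **Confidence regularizer** $L_\mathrm{regular} = (1 - \overline{\mathrm{pLDDT}})
  + (1 - \mathrm{pTM}) + (1 - \mathrm{ipTM})$, bounded in $[0, 3]$. pLDDT
  is held internally on $[0,1]$ so the three terms are commensurate;
  predictor-style 0–100 values are divided by 100 on input and multiplied
  back for reporting. pLDDT is treated as per-residue and averaged over
  residues (the natural reading for predictor outputs, where "atoms" and
  residues coincide at the Cα level).

**Pairing.** Group-to-group distances default to `all_pairs` (the
Cartesian product), which is well defined for any group sizes; a
`positional` mode (i-th with i-th, equal sizes required) is provided
because size-matched groups admit either reading. Neither is presented as
canonical; the choice is recorded in configs and reports.

**Gradients.** All coordinate-dependent terms have analytic gradients. At
a clamp boundary (mean distance exactly at $d_c$) the zero-side
subgradient is returned, so a satisfied constraint exerts no force —
conservative, and it avoids pushing structures that already comply.
Coincident pairs ($d = 0$) contribute a zero direction rather than an
undefined one. Correctness is guarded by central-finite-difference checks
($h = 10^{-4}$ Å, agreement well below $10^{-5}$ per component).

## Scheduled annealing

The constraint weight $w_c$ starts at 1 — constraints strongly enforced —
and is annealed to 0.1; the regularizer weight $w_r$ rises from 0 to 1.
Steps are indexed $0, \dots, n-1$ and the interpolation uses the convex
combination $(1-t)\,w_\mathrm{start} + t\,w_\mathrm{end}$, which makes
both endpoints exact in floating point rather than exact-within-rounding.
A staircase mode with $k$ levels is available for coarser annealing. The
number of steps and the spacing are tunable configuration (default: 500
steps, linear); the defaults were chosen once as the smallest round count
at which the bundled examples converge comfortably.

## The generator contract and the toy generator

The optimizer is agnostic to how coordinates are produced. A generator
supplies `theta_init`, a deterministic `produce(theta)` returning Cα
coordinates plus a confidence bundle, and a `pullback` mapping
$\partial L/\partial \mathrm{coords}$ (and optionally
$\partial L/\partial \mathrm{confidence}$) to $\partial L/\partial
\theta$. An adapter to a real predictor would implement exactly this
surface; none is bundled, since predictor inference (trained weights,
GPU) is out of scope here.

The bundled `toy_chain_generator` is a desk-scale stand-in: $\theta$ is a
per-residue Cα displacement field over the flexible residues, $\theta = 0$
reproduces the reference exactly, and the confidence surrogate ties
per-residue pLDDT to displacement, $\mathrm{pLDDT}_i =
\exp(-\lVert\Delta_i\rVert^2/\sigma^2)$ with $\sigma = 4$ Å by default
(pTM/ipTM are fixed constants). The surrogate is internal to this
generator — it is *not* a model of predictor confidence; it exists so the
annealing trade-off (constraints early, confidence late) can be exercised
end to end. Two consequences worth knowing:

* residues move independently — there is no chain coupling, so a single
  attractive pair is pulled together readily, while dragging a whole
  domain across hundreds of Å within a few hundred steps is not something
  this generator can do (and the bundled preset demo honestly shows
  distances decreasing without reaching satisfaction);
* the surrogate's pull back toward the reference is weak
  ($\propto \mathrm{pLDDT}_i\,2\lVert\theta_i\rVert/\sigma^2 / n$), so
  satisfied constraints stay satisfied late in the annealing.

The optimizer itself is plain gradient descent with optional momentum —
the simplest method that exhibits the scheduled behavior. The returned
fit keeps the **best iterate by composite loss**, not the last: under
annealing the composite can rise late in a run as $w_r$ grows. The fit is
deterministic given seed and configuration; identical runs produce
byte-identical traces and model files.

## Evaluation stack

* **Multimer confidence** $0.8 \times \mathrm{ipTM} + 0.2 \times
  \mathrm{pTM}$, with ranking descending by that score; ties break by
  mean pLDDT, then label — the tie-breaks are this package's convention,
  chosen only for reproducible output.
* **PAE block summaries** average the predicted-aligned-error matrix over
  ordered (aligned-on, scored) domain blocks; asymmetric by construction.
* **Contact maps**: a residue pair is in contact when its Cα–Cα distance
  is within 12 Å, read inclusively (exactly 12.0 Å counts). Probabilities
  pool all frames of all replicates — contacts are summed across every
  frame and normalized once — so the pooled probability equals contact
  frames over total frames exactly. Predictor model sets are treated as
  one frame per model.
* **Per-domain RMSD**: each frame is superposed on the reference by a
  least-squares (Kabsch) rigid fit of the Cα atoms of one alignment
  domain — default NTF2L, always configurable and always recorded — and
  heavy-atom RMSD is then measured per domain *without re-fitting*, so
  domain motion relative to the alignment frame is measured rather than
  removed. The fit uses Cα only (a conventional backbone fit), the
  measurement heavy atoms only. Replicate aggregation uses the population
  standard deviation (n divisor), matching its use as a shading band
  rather than an inferential estimate. The Kabsch implementation corrects
  reflections (proper rotation guaranteed) and is cross-checked against
  an independent fit in the tests.

## Fixtures: what they emulate, and what they do not

`make_toy_complex` builds deterministic multi-domain complexes: structured
ranges as ideal helical Cα traces (100°/residue turn, 1.5 Å rise, radius
set so consecutive Cα atoms are exactly 3.8 Å apart), disordered ranges as
fixed-step 3.8 Å random walks with minimal self-avoidance (reject steps
closer than 2 Å to the 20 most recent residues). Chains are laid out with
a 40 Å gap so inter-chain constraints start unformed. Optional CB atoms
(1.53 Å from the Cα) give every non-glycine residue a second heavy atom;
optional hydrogens exercise heavy-atom filtering. The
`g3bp1_gr20_fixture` preset reproduces the real system's *topology* —
chain lengths 466 + 40, NTF2L at 1–142, alternating Gly/Arg in GR20 — with
entirely synthetic geometry.

`make_synthetic_ensemble` plants contact occupancies by **exact count**,
not Bernoulli sampling: a planned pair is placed inside the cutoff in
exactly `round(occupancy × n_frames)` frames (6 Å) and outside in the rest
(20 Å), in seed-randomized order, on top of optional Gaussian Cα noise.
Contact analytics therefore recover planted occupancies exactly, which is
what the tests assert. Planted pairs must not share residues.

What passing tests show, and what they do not: the fixtures validate the
*mathematics* — losses, gradients, annealing, superposition, counting —
under controlled geometry. They are not physically realistic conformers,
carry no sequence-dependent geometry, no sterics and no energetics, so
agreement on fixtures says nothing about the biophysical plausibility of
any particular real-world model; that judgement still requires a real
generator and downstream simulation.

## Configuration defaults and open boundaries

The shipped G3BP1–GR20 preset carries the constraint set verbatim:
attractive IDR1 anchors {174, 187, 167, 163, 154} × GR20 anchors
{477, 475, 493, 495, 501}; attractive {202} × {452} linking IDR1 and IDR3;
repulsive {469, 473, 478, 474} × {503, 492, 498, 502} *within* GR20,
guarding against peptide self-aggregation; $d_c = 8$ Å throughout;
positional restraint on NTF2L and RRM. A repulsion between GR20 and IDR3
is a plausible alternative placement consistent with the biochemical
rationale (both are positively charged); the preset keeps the
within-GR20 form, and users wanting the alternative can add a term in one
config line.

Only the NTF2L boundary (residues 1–142) is stated numerically anywhere
authoritative. The default IDR1 (143–225), IDR2 (226–339), RRM (340–415)
and IDR3 (416–466) boundaries are schematic-derived conventions, flagged
as such in the documentation, and every function that consumes an
annotation accepts a user-supplied one.

## Problem sizes and numerical tolerances

The test suite runs at desk scale by choice: loss-oracle sweeps use 200
random structures of up to 50 residues; gradient checks use 30-residue
structures; conditioning demos use 2–506 residues over 300–500 steps;
contact analytics use 200-frame ensembles. Oracle agreement is asserted at
$10^{-9}$ relative for losses, $10^{-5}$ absolute per component for
gradients against finite differences, and $10^{-6}$ Å for superposition
against an independent optimizer-based fit. PDB round-trips are asserted
at the format's 3-decimal precision.

## Known limitations

* No predictor adapter ships; the generator contract documents what one
  must provide (coordinates, confidences, gradient pullback).
* The mean-then-clamp losses can report satisfaction while individual
  pairs remain far apart; inspect `cv_pair_distances()` when per-pair
  behaviour matters, or switch to `per_pair_clamp`.
* The toy generator's independence across residues makes long-range
  collective motion unrealistically hard; it is a test vehicle, not a
  sampler.
* Energetics (sterics, electrostatics, torsions) are intentionally
  absent: constraint satisfaction here is geometric, and models meant to
  be interpreted physically should be relaxed and simulated downstream.
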