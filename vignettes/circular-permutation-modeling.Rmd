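---
title: "Modeling circularly permuted proteins and designing termini linkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circularly permuted proteins and designing termini linkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirperm)
library(dplyr)
```

## The problem

A circular permutation (CP) joins a protein's native N- and C-termini and
opens new termini at another site. At the sequence level a circular
permutant (CPM) is a rotation of the native sequence; at the structure
level the fold is usually conserved, which is why the native structure is
an excellent modeling template — *if* its residue records are first
rearranged to match the permutant's sequence order. Conventional
comparative modeling pipelines do not perform that rearrangement and
therefore truncate, unfold, or misorient one of the two proportions
delimited by the CP site.

cirperm implements the full CP-aware pipeline on tidy data structures:

1. parse and renumber the native template;
2. build the **pseudo-CP template** by rotating the residue records at
   the CP site (`make_pseudo_cp_template()`);
3. design a **termini linker** when the native termini are too distant to
   join directly;
4. globally align the target CPM sequence to the pseudo-CP template under
   several scoring schemes and keep the alignment with the most aligned
   residues;
5. build a coarse model from the alignment;
6. refine the model by an exhaustive **rigid-body search hinged at the CP
   site**;
7. (externally) relax the model with molecular mechanics — out of scope
   here, exposed only as a backend hook.

Every user-facing function takes a data frame first and returns a tibble,
so the steps compose with the pipe.

## Structures as tibbles

A structure is a tibble of atom records (`serial`, `resname`, `atom`,
`x`, `y`, `z`). Residue positions are represented by their alpha-carbons
throughout; indices are 1-based and `renumber()` is the authority on
numbering (insertion-code dialects collapse there). The CP rotation is a
pure record permutation: residue order `(n, ..., L, 1, ..., n-1)`,
coordinates untouched — an involution whose inverse site is
`L - n + 2` (mod `L`).

```{r}
s <- make_ideal_chain(12, "ring", seed = 1)
p <- make_pseudo_cp_template(s, 5)
structure_sequence(s)
structure_sequence(p)
```

## Linker determination for CP pairs

Given two structures of a CP pair (Q, S) and their CP-aware residue
correspondence — two monotone runs of aligned pairs, because of the wrap
— `determine_linker()` extracts the fragment of S that bridges Q's native
termini. With `x`/`y` the first/last aligned pairs, the candidate linker
is the run of S residues strictly between `y_s` and `x_s`, walking
forward in S serial order. We walk **with wrap-around** past S's
terminus: the spanned region is circular by nature and the wrapped walk
is the only reading that always yields the bridging region. Unaligned Q
termini (`m` before `x_q`, `n` after `y_q`) shrink the linker to the span
between `y_s + n` and `x_s - m`; when `m + n >= l` no linker is needed.

## Solvent exposure and in-silico permutants

Synthetic CPMs for benchmarking are built the way a curated set would be:
residues with relative solvent accessibility (RSA) above 20% form
exposed fragments; the CP site is placed at the carboxyl end of a
fragment, the records are rotated, and the fragment is excised to become
the known "missing linker". Direct termini connection is only allowed
when the termini are within `3 * d` of each other, with `d = 3.36`
Angstrom shipped as a configurable constant (the PDB-wide average
consecutive-residue distance; we do not recompute it, which would require
a PDB snapshot).

RSA is computed by an in-package Shrake–Rupley implementation (probe
1.4 Angstrom, 92 deterministic golden-spiral points per atom) because no
installed R package provides solvent accessibility without external
binaries. All-atom structures are normalized by the Tien et al.
theoretical maximum ASA; CA-only traces use a per-residue sphere
(radius 2.5 Angstrom) normalized by the isolated-sphere area, so an
isolated residue reads ~100%.

## Sequence alignment choices

Global alignment is delegated to `Biostrings::pairwiseAlignment()`
(Needleman–Wunsch, affine gaps, end gaps penalized). Two scoring schemes
compete by default — EMBOSS-needle-like (BLOSUM62, open 10, extend 0.5)
and Stretcher-like (BLOSUM62, open 12, extend 2) — and
`select_alignment()` keeps the candidate with the largest number of
aligned residues (ties: higher score, then first occurrence). A
secondary-structure-aware aligner is not included; the selection rule is
the extension point for plugging one in. Identity and similarity are
reported over the alignment length; similarity counts columns whose pair
scores positively in BLOSUM45 (the matrix also used to compare designed
linkers with native ones). Note these are sequence-level identities; a
structure-alignment identity would generally differ.

## The linker design protocol

Design proceeds in six steps with knobs collected in `design_config()`
(full-scale defaults: `t = 200`, `t' = 20`, `k = 10`, `m = 10`, 30
reported candidates):

1. `t` **temporary linkers** of the estimated length are sampled from a
   propensity table (estimated from known linkers, uniform if none),
   inserted at the junction of the native termini, aligned, and modeled;
   the `t'` lowest-energy coarse models are kept.
2. For each kept coarse model, every linker position gets a 20-vector of
   **features**: for each amino-acid type, the sum of inverse squared
   CA–CA distances to residues of that type within 20 Angstrom. The
   residue itself and five sequence neighbors on each side are excluded —
   a designed linker has unknown local sequence, so known linkers are
   featurized under the same exclusion at training time.
3. A **bootstrap vote ensemble** — 250 depth-capped decision trees
   (rpart) and 50 single-hidden-layer neural nets (nnet, 16 units), each
   trained on an independent with-replacement resample — votes on one of
   three classes per position. Twenty answers are more than a small
   ensemble resolves reliably, so amino acids are pooled into
   hydrophilic {R, K, D, E, N, Q, H}, hydrophobic {A, V, L, I, M, F, C,
   W} and neutral {G, P, S, T, Y} (a Kyte–Doolittle-guided partition;
   configurable). Class probabilities are the vote fractions, restored to
   amino-acid probabilities by `pe(A) = pe(C) * p(A|C)` with `p(A|C)`
   the Laplace-smoothed composition of the training linkers.
4. `k` candidate sequences are sampled per coarse model from the
   per-position probabilities, pooling exactly `t' * k` candidates.
5. Each candidate is re-inserted, re-aligned and modeled `m` times,
   keeping its lowest backend energy.
6. Candidates are ranked by energy; ties break by provenance (coarse
   model id, then sample id) so the protocol is bit-reproducible under
   `seed`.

### Linker length

Below a termini distance of 20 Angstrom the length follows the
logarithmic fit `l = Round(21.8 ln b - 52.5)`, clamped at zero, with
Round half-away-from-zero (the convention is not fixed by the fit
itself; this choice is symmetric). The boundary `b = 20` is routed to the
iterative estimator, since the fit is stated for distances *below*
20 Angstrom. The iterative estimator scans `l = 20, 25, ...` up to one
fifth of the target size, keeps the per-length minimum energy over `t`
temporary linkers, refines `±4` around the best coarse length, and
returns the overall lowest-energy length; on ties the smallest scanned
length wins.

## Backends and the surrogate energy

Modeling and scoring hide behind one contract:
`backend(alignment, template) -> list(structure, energy)`, lower energy
better. The shipped surrogate builds a CA trace — aligned target
residues inherit template coordinates; unaligned runs are placed on a
circular arc between their anchors at 3.8 Angstrom spacing — and scores
it as

    E = sum over consecutive pairs (d - 3.8)^2
      + 10 * #{pairs with |i - j| >= 3 and d < 4}

which is rigid-motion invariant and vanishes on an ideally spaced,
clash-free chain. It is a deliberately simple, dependency-free stand-in
behind the backend contract: it ranks geometric plausibility, not
physical energy, and it is sequence-blind, so candidate linkers of equal
length tie and fall back to provenance order. An external statistical
potential or force field can be plugged in through the same contract.

## Hinge refinement

The model is divided at the CP site — the middle residue of the native
protein's linker, or the midpoint of the joined termini — into two
proportions; the smaller one moves (ties take the C-terminal
proportion). With the hinge `h`, small-proportion centroid `c_s` and
large-proportion centroid `c_l`: axis `r = unit(c_s - h)`, and plane `P`
through `h`, `c_s`, `c_l`. The small proportion is rotated on `P` about
the plane normal in 20-degree pauses over 180 degrees (9 values) and, at
each pause, spun about its hinge-to-centroid axis in 20-degree snapshots
over 360 degrees (18 values): exactly 162 poses, pose (0, 0) the
identity. The axial spin is taken about the *theta-rotated* axis — the
domain's own axis in its current pose — which keeps the second rotation
a self-rotation of the displaced domain; only the grid itself (180/20 x
360/20) is fixed by the protocol. Every pose is scored and the minimum
returned, so refinement can never raise the energy; ties break toward
the lexicographically smallest `(theta, phi)`. Degenerate frames
(collinear centroids) fall back to the perpendicular of `r` with the
largest z-component, tie-broken toward +x. The pseudo-bond across the
hinge is allowed to stretch during the search; the energy term penalizes
it naturally, and a molecular-mechanics relaxation that would relieve it
is left to external hooks.

```{r}
td <- make_two_domain(22, 14, seed = 6)
fr <- split_by_hinge(td$model, td$junction)
refined <- hinge_refine(td$model, fr)
attr(refined, "pose")
c(before = surrogate_energy(td$model), after = attr(refined, "energy"))
```

## What the fixtures emulate — and what they do not

`make_ideal_chain()` builds exactly-spaced CA traces (straight, helical,
or ring-closed); `make_cp_pair()` builds a ring protein and its
permutant with a planted arc-bridged linker and the true residue
correspondence; `make_ml_training_set()` builds three Gaussian clusters
in feature space with dialable separation; `make_linker_db()` groups
several permutants per parent protein with glycine/serine-rich planted
linkers; and `run_independent_test()` runs the grouped 90/10
train/test harness with an identity-based discard step, redesigning each
surviving linker at its known length (the length is available from the
pair correspondence, as in the original experiments).

These toys exercise every contract deterministically, but they are not
real proteins: rings have uniform exposure, the surrogate energy is
sequence-blind, and random sequences have a chance-identity floor of
roughly 10–25% under optimal global alignment — which is why the
harness's discard threshold must sit above that floor for synthetic
data (the tests use 25%), whereas curated structural data motivates the
15% default. Passing tests therefore demonstrate correctness of the
bookkeeping, geometry, screening and ranking logic — not predictive
accuracy on natural CPMs, which requires real structures and a physical
energy function.

Problem sizes used by the test suite are scaled for a single CPU:
fixture proteins of 20–40 residues, linkers of 2–7 residues, ensembles
of 12–60 minors in protocol tests (the full 250 + 50 ensemble is
exercised once on the separable benchmark), `t = 8–20`, `t' = 2–5`,
`k = 2–3`, and 6–10 harness rounds. The full-scale defaults
(`t = 200`, `t' = 20`, `k = 10`, `m = 10`, 500 rounds) remain available
through `design_config()` and `run_independent_test()` arguments.

## Numerical choices and degenerate inputs

* Arc placement solves `chord/arc = sin(theta/2)/(theta/2)` by
  `uniroot` (tolerance 1e-12); when the anchors are farther apart than
  the arc could span, residues interpolate linearly, and dangling
  termini extend along the last chain direction at 3.8 Angstrom.
* Rounding in the length fit is half-away-from-zero; energy ties
  everywhere resolve by earliest provenance for determinism.
* Structures must be renumbered (`serials 1..L`) before permutation;
  residues without an alpha-carbon are rejected at parse, since guessing
  missing backbone atoms (normally restored by external tools) is out of
  scope.
* Alternate locations keep the highest-occupancy conformer;
  selenomethionine and similar residues map to their parent amino acid,
  others are rejected.
* All randomness flows through explicit seeds (`withr::with_seed`), so
  every result in a report is recomputable from inputs plus seed.

## Known limitations

* The surrogate backend ranks geometry only; its optimum pose on a toy
  need not coincide with the reference structure's pose, and designed
  linkers of equal length tie in energy.
* CP detection from sequence alone (`cp_align_sequences()`, the
  doubled-sequence trick) is an approximation to a CP-aware structural
  alignment.
* Identity/similarity percentages are sequence-alignment quantities, not
  structure-alignment ones.
* Single chains only; no mmCIF, no multi-model NMR handling, no missing-
  atom reconstruction.
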