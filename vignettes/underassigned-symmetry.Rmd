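---
title: "Detecting underassigned rotational symmetry in protein crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting underassigned rotational symmetry in protein crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalsym)
```

## The problem

A protein crystal structure is deposited with a space-group assignment that
was made early in data processing, when only the unit-cell metric and the
merging statistics of the diffraction intensities were available.  Both
carry measurement uncertainty: lattice symmetry axes can deviate by more
than a degree from perfect alignment in a well-behaved experiment, and the
agreement of symmetry-related intensities can be degraded by tens of
percent without the symmetry being false.  If a true crystallographic axis
is passed over at this stage, the structure is nevertheless solved and
refined successfully — it simply contains redundant chains in the
asymmetric unit that appear to be related by "noncrystallographic"
symmetry.  Nothing later in refinement flags the oversight; the
crystallographic R factor is essentially blind to it.

`xtalsym` examines the finished coordinate model (and, when available, the
merged intensities) and asks: is this structure nearly invariant under
additional rotational symmetry operators of a higher-symmetry space group?
If so, which group, where must the model be placed relative to that
group's symmetry elements, and how large is the coordinate displacement
that imposing the extra symmetry would require?

Only the 65 Sohncke space groups are considered; proteins are chiral, so
mirror and inversion operations are excluded a priori.  Translational
pseudosymmetry (extra *centring* translations) is a different problem and
is deliberately out of scope.

## The pipeline

`checkSymmetry()` runs a fixed chain of reference-frame manipulations and
scores.  Every frame change is an exact rational operator `(R, T)` acting
covariantly on fractional coordinates, contravariantly on Miller indices
and by conjugation on symmetry operations, so the structure moves as a
rigid body and no score can change under re-basing (this is tested as a
metamorphic property).

1. **Centring removal and cell reduction.**  The assigned group's centring
   translations are absorbed into a primitive cell, which is then put into
   the Niggli reduced setting by the Krivy–Gruber iteration (relative
   tolerance 1e-5).  Any stable reduced setting would do, because every
   downstream score is basis-invariant.
2. **Lattice twofold search.**  Following Le Page, candidate twofold axes
   are pairs of a direct-lattice row `t = [u v w]` and a reciprocal-lattice
   row `tau = (h k l)` with `t . tau` equal to 1 or 2 and all indices
   within ±2 of zero, such that `W = 2 t tau' / (t . tau) - I` is an
   integer matrix.  The angle delta between `t` and `tau` in cartesian
   space is zero for an exact symmetry axis; axes with delta below 1.4
   degrees (configurable) are accepted.  The ±2 bound suffices for every
   Bravais holohedry reachable from a reduced cell.
3. **Patterson settings.**  The accepted twofolds are closed into the
   lattice rotation group (higher-order axes arise as products of
   twofolds), all distinct rotation subgroups are enumerated, and each is
   classified and assigned a conventional frame and Patterson symbol
   (`P4/m`, `C12/m1`, ...).  Orientational variants are kept as separate
   settings.  Because a 4- or 6-fold also requires the in-plane metric to
   fit, each higher-order operator inherits the worst delta of the
   accepted twofolds perpendicular to its axis; the setting's delta is the
   maximum over its operators.
4. **Intensity screening (`R_symop`).**  The model, expanded to P1, yields
   calculated intensities to 3.5 Å by direct summation over unit point
   scatterers.  Unit scatterers are not an approximation here: every
   statistic in the package is exactly invariant to the per-atom form
   factor, which cancels between symmetry mates.  Each candidate operator
   `W` is scored by
   `R_symop = sum |I_H - I_HW| / sum (I_H + I_HW)` over index pairs present
   in the set, skipping self-paired (W-invariant) indices; a setting is
   plausible when its worst operator stays below 0.25.  Observed
   amplitudes or intensities, when supplied, are expanded to P1 and scored
   the same way; their absence never blocks the coordinate-based verdict.
5. **Translation search.**  For each space group sharing the plausible
   setting's Patterson symmetry, the model must be positioned relative to
   the group's symmetry elements.  The Pearson correlation `r(x, G)`
   between the model's P1 intensities merged under G and the intensities
   of a superposed ensemble (the shifted model with every operator of G
   applied, one coherent copy per operator) is evaluated on a fractional
   grid with spacing of about half the resolution limit.  The peak
   `x_max` is the candidate origin shift; the map is constant along polar
   directions of G and invariant under G's discrete allowed-origin
   (Cheshire) translations, so polar components are canonicalized to zero.
6. **Phase screening (Phi).**  Intensities cannot distinguish a rotation
   from its screw counterpart, because a screw translation changes only
   structure-factor phases.  The amplitude-weighted phase-agreement score
   `Phi(g) = sum |F_H|^2 |wrap(phi_H - phi_HW - 2 pi H.w)| / ((pi/n) sum |F_H|^2)`
   is zero for an exactly invariant model and near 1 for random phase
   relationships.  The weights (squared amplitudes), wrap order `n = 1`
   and the normalization placing Phi in [0, 1] are this package's
   concretization; with it, a screw alternative evaluated against a
   pure-rotation crystal scores approximately the fraction of intensity on
   reflections whose screw-phase penalty wraps to pi (about 0.5), against
   essentially 0 for the true operator — a contrast of several hundred
   fold, which is what the ranking uses.  Candidates are ranked by worst
   Phi over their coset representatives (ascending), then by peak
   correlation (descending).
7. **Coset decomposition and chain matching.**  The target group G is
   decomposed into left cosets of the (transformed) input group H; only
   the `n - 1` non-identity coset representatives need to be evaluated as
   trial operators.  Within each coset the representative is chosen
   deterministically (lexicographically smallest rotation part, then
   translation).  A triple loop matches each chain X, mapped through a
   representative, against every chain Y (sequence-comparable: equal
   length, at least 95 % identity), every operator h of H and an integer
   lattice translation t, declaring a match when the mean C-alpha
   deviation stays below 2 Å without any rotational refit.  The map must
   be a bijection per coset.
8. **Origin refinement and the deviation split.**  With matches fixed, the
   residual sum of squared cartesian differences is exactly quadratic in
   the origin shift, so the optimum comes from the normal equations in
   closed form; flat (polar) directions are pinned to zero through the
   pseudo-inverse.  The deviation from perfect symmetry is
   `Delta r_sym = sqrt(f_min / N)` over all matched C-alpha pairs.  One
   reduced-ASU model per coset is then generated by transforming each
   matched chain back onto its primary partner (first-in-file chain of
   each mutual-match group); `Delta r_ASU` and `Delta r_chain` are the
   N-weighted RMS deviations between model pairs after whole-ASU and
   per-chain Kearsley superposition respectively.  Rigid-body differences
   between chains are absorbed by the alignment, so
   `Delta r_ASU ~ Delta r_sym` indicates pure per-atom scatter
   (underassigned symmetry), while `Delta r_ASU << Delta r_sym` indicates
   genuine rigid-body NCS differences (confident pseudosymmetry).

The verdict is positive when `Delta r_sym < 0.325` Å and the worst-case
`R_symop` over the coset representatives stays below 0.25 for calculated
(and, if present, observed) intensities.  The displacement cutoff is
intentionally conservative — of the order of the coordinate uncertainty of
typical structures — and is a default, not a claim.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `dMin` | 3.5 | Å | resolution limit of all intensity/phase statistics |
| `deltaTol` | 1.4 | degrees | Le Page acceptance for lattice axes |
| `rsymopMax` | 0.25 | fraction | plausibility bound on `R_symop` |
| `drSymMax` | 0.325 | Å | candidate cutoff on `Delta r_sym` |
| `rCorrMin` | 0.8 | — | eligibility bound on the correlation peak |
| `matchTol` | 2.0 | Å | mean C-alpha deviation for a chain match |

The match tolerance sits far below chain dimensions and far above the
displacement cutoff, so matching never decides the verdict.  All six are
arguments of `pipelineConfig()`.

## Behaviour of the correlation peak for screw alternatives

A point worth recording, because it shapes the ranking logic: when the
true group is a pure rotation group (say P4) and the screw twin (P4_2) is
evaluated, the superposed ensemble contains every asymmetric unit twice —
the model and a half-cell-shifted copy — whatever origin shift is tried.
The coherent sum then extinguishes the odd-`l` reflections and quadruples
the even ones, and the Pearson correlation against the merged model
intensities has a population value near 0.6 (for Wilson-like intensity
statistics), not 1.  The quarter-screws (P4_1/P4_3) fall lower still
(near 0.38).  The screw twin is therefore *not* reliably retained by a
correlation threshold of 0.8 on generic structures; discrimination between
rotation and screw rests on the phase score, which is unambiguous (0
versus ≈ 0.5).  `rankSpaceGroups()` accordingly computes `r` and `Phi`
for every candidate, uses the correlation threshold only as an
eligibility flag, and ranks by `Phi`.  Structures with incidental
pseudo-translational packing can push a screw twin's peak close to 1, but
the ranking does not depend on it.

## The synthetic-crystal generator

`makeUnderassignedStructure()` manufactures ground-truth test cases: C-alpha
traces are generated as compact self-avoiding walks (3.8 Å consecutive
spacing, ≥ 4.0 Å non-consecutive separation), placed without clashes in
the asymmetric unit of a chosen true group, expanded through the coset
representatives into the asymmetric unit of the assigned subgroup (cell
content is conserved exactly), perturbed with independent isotropic
Gaussian noise per cartesian coordinate, origin-shifted, and optionally
re-based by a random unimodular transformation.  Every random choice hangs
off one integer seed.

Defaults emulate a small protein crystal: cells are sized for loose
protein-like packing (~170 Å^3 per residue), with distinct axis ratios per
crystal system so that no accidental metric symmetry beyond the intended
one arises.  Under per-coordinate noise sigma, a matched C-alpha pair
differs by two independent 3-D perturbations, so
`E[Delta r_sym] ≈ sqrt(6) sigma`; this closed-form expectation is used as
an oracle in the tests (at sigma = 0.05 Å, ≈ 0.122 Å).  A rigid-body mode
(random per-chain rotation and translation) creates true-pseudosymmetry
negatives in which `Delta r_ASU` stays far below `Delta r_sym`.

What the generator does *not* emulate: real side-chain packing, secondary
structure, solvent, anisotropy, absorption or radiation damage in the
simulated intensities, and partial disorder.  Passing tests therefore
demonstrate the correctness of the algebra, the scores and the decision
logic under the stated noise model — not robustness to every pathology of
real depositions.

## Numerical choices and problem sizes

* All space-group algebra is exact rational arithmetic (integer numerators
  over a common denominator); group closure, coset decomposition and
  change of basis involve no floating point.
* Structure factors are computed by direct summation; the vectorized path
  is tested to 1e-8 relative against an explicit double-loop oracle, and
  the correlation map against an oracle that rebuilds the shifted ensemble
  coordinates from scratch.
* The Kearsley superposition solves the 4x4 quaternion eigenproblem and
  reports the residual of the minimizing rotation (numerically sharper
  than the eigenvalue route near rmsd = 0); it is tested against an
  SVD-based oracle.
* Grid ties in the correlation map break to the lexicographically smallest
  grid index; coset representatives and operator orderings are
  lexicographic; reports are byte-identical across runs.
* Test and validation fixtures use 1–6 chains of 6–25 residues in cells of
  roughly 16–40 Å — large enough for several hundred to a few thousand
  reflections at 3.5 Å, small enough that the full pipeline runs in
  seconds.  The statistical checks (noise scaling of `Delta r_sym`,
  recovery rate over 20 seeded crystals) use these sizes.

## Known limitations

* Only Sohncke groups in (or permuted from) their reference settings are
  accepted as input symmetry; rhombohedral data are handled in the
  hexagonal-axes setting.
* Reflection input covers mmCIF `_refln` loops and whitespace `h k l I
  [sigI]` text; binary MTZ is not read.
* Chains straddling special positions of a candidate group would break the
  bijection requirement of the matcher; the generator never produces such
  cases, and real ones surface as an explicit matching error, not a wrong
  verdict.
* The survey utilities rank and tabulate but deliberately make no
  final claim about any individual structure: the displacement cutoff is a
  screening default, and re-refinement in the higher group is the
  decisive test, which is outside this package's scope.
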