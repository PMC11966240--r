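---
title: "Detecting duplicate backbone depositions with rigid invariants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting duplicate backbone depositions with rigid invariants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupscan)
```

## The problem

A protein crystal structure is deposited as Cartesian coordinates in an
arbitrary frame. Two depositions of the *same* refined model can therefore
look entirely different at the coordinate level (after a rigid motion), or
entirely different at the sequence level (after relabelling residues
without touching coordinates), while being scientifically the same object.
Curation needs a representation in which "same up to rigid motion" becomes
"equal", equality is cheap to test at repository scale, and *near*
duplicates — coordinates differing in the last printed digit — stay near.

## The invariant

For residue *i* with trace atoms N, Cα, C we attach the frame

* origin at Cα,
* **e₁** the unit vector Cα→N,
* **e₃** the unit normal of the N–Cα–C plane (direction of
  (N−Cα)×(C−Cα)),
* **e₂** = **e₃**×**e₁**.

The backbone rigid invariant (BRI) of a chain of *m* residues is the
*m* × 9 matrix whose row *i* (*i* ≥ 2) lists the coordinates of Nᵢ, Cαᵢ, Cᵢ
in the frame of residue *i*−1. Row 1 lists residue 1's atoms in *its own*
frame: (|N−Cα|, 0, 0, 0, 0, 0, (C−Cα)·e₁, (C−Cα)·e₂, 0), with the eighth
entry positive by construction. This convention keeps the matrix exactly
*m* × 9, is itself rigid-invariant and continuous, and retains residue 1's
internal geometry, at the cost of row 1 not being comparable with interior
rows of a longer chain (see *Subchains* below).

Because frames are equivariant (a rigid motion of the atoms rotates the
frame with them), local coordinates — hence the whole matrix — are
invariant. The converse holds too: `reconstruct_backbone()` places residue
1 canonically (Cα at the origin, N on +x, C in the xy-plane with positive
y) and grows the chain row by row, so equal invariants imply congruent
chains. Reflection flips the handedness of every frame and so flips the
sign of the out-of-plane columns 3, 6, 9 (rows ≥ 2): mirror images are
distinguished, and `mirror_bri()` computes the mirror's invariant without
touching coordinates.

Averaging the nine columns (all rows weighted equally, fixed summation
order for bitwise reproducibility) gives the 9-vector Brain. With the
Chebyshev (L∞) metric on both objects,

d(Brain(A), Brain(B)) ≤ d(BRI(A), BRI(B)),

since an average of differences cannot exceed their maximum, columnwise.
This is the inequality that makes the cascade prefilter *exact* rather
than heuristic; an L2 metric would need a different (and weaker) argument,
so Chebyshev is the only metric exposed.

## The cascade

1. **Bucket by m.** Chains of different residue counts are never compared.
2. **Brain prefilter.** Within a bucket, an exact Chebyshev range query on
   the 9 averages (sort on the first coordinate, sliding window, full
   check on the survivors). By the lower bound, the output is a superset
   of the final answer — no false negatives by construction. At desk scale
   this simple scheme already reduces the work by orders of magnitude; any
   exact nearest-neighbour structure could be substituted behind the same
   contract.
3. **BRI confirmation.** Pairs with full invariant distance ≤ *t* are
   kept; pairs within one entry are dropped by default (two copies of a
   molecule in the same asymmetric unit are not a duplication).
4. **Forensics.** For every confirmed pair, `compare_pair_details()`
   reports the maximum Euclidean deviation over the 3*m* corresponding
   atoms *in the raw deposited frames* and the number of residue positions
   with differing amino-acid codes. No superposition is applied by
   default: genuine duplicates share their deposition frame, and a uniform
   0.001 Å shift of one axis — a real pattern among near-identical
   depositions — is visible only unsuperposed. `superpose = TRUE`
   additionally reports the deviation after an optimal (Kabsch) fit, which
   is the right statistic for rigidly disguised copies.

### The threshold

The duplicate cut-off *t* defaults to 0.01 Å and is deliberately a
parameter, not a constant. Deposited coordinates carry three decimals, so
two depositions of the same model differ by at most ~0.0005 Å per
coordinate from rounding alone; the invariant amplifies coordinate noise
by its continuity constant *C* (measured at ≈ 5–7 for protein-like
chains), placing true duplicates at invariant distances of a few times
10⁻³ Å — comfortably under 0.01 Å — while distinct structures of the same
length sit orders of magnitude away. Raising *t* trades precision for
recall of more heavily edited redepositions.

## Cleaning filters

Scanning only makes sense on chains whose trace is complete and
unambiguous. `clean_chains()` applies, per chain, in order: no standard
amino acids → `nonprotein`; any partial occupancy or altloc marker →
`partial_occupancy` (scope configurable to main-chain atoms only — both
readings of "disordered" are defensible, the strict any-atom rule is the
default); non-consecutive numbering or insertion codes →
`nonconsecutive_numbering`; an interior residue missing N, Cα or C →
`missing_mainchain`, but incomplete residues at the termini only are
trimmed and the shortened chain kept; any nonstandard residue (including
MSE) → `nonstandard_residue`; fewer than 2 residues remaining →
`too_short`. Every input chain appears exactly once in the report, so
kept + trimmed + rejected always reconciles with the input. Entries are in
scope when their resolution is ≤ 4 Å and they are not group depositions
(bulk submissions that are near-identical by design); a missing resolution
record puts an entry out of scope with a classed warning. Only the first
model of multi-model files is read.

## Synthetic fixtures

The generator builds backbones from internal coordinates: bond lengths
N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å; angles N–Cα–C 111.2°, Cα–C–N
116.2°, C–N–Cα 121.7°; torsions either fixed at (φ, ψ, ω) = (−57°, −47°,
180°) — an α-helix, exactly periodic, so every interior invariant row is
identical — or drawn per residue from broad plausible ranges. Placement
from internal coordinates guarantees the stated covalent geometry exactly
under any torsion draw, so planted deviations are exactly known. What the
generator does *not* emulate: real Ramachandran statistics, side chains,
solvent, crystal contacts, experimental noise correlations. Passing tests
therefore demonstrate the algebraic and pipeline contracts, not parsing
robustness against the full diversity of historical depositions.

`emit_corpus()` writes each synthetic entry as a PDB file and an mmCIF
twin (identical numeric fields, so dialect equality is testable), with
fabricated resolution/R-free headers, planted duplicates (exact,
sub-threshold perturbed, relabelled, rigidly moved), decoys (mirror
images, perturbations ≫ *t*), one chain per cleaning-filter violation, an
out-of-resolution entry and a group deposition, plus a ground-truth JSON.
Base coordinates are quantised to 0.001 Å *before* planting, so files
carry exactly the in-memory values; the perturbation default δ = 0.0005 Å
is sub-last-digit noise — the regime where two depositions print "the same
numbers" — chosen so that planted duplicates satisfy *C*·(δ + rounding) ≤
*t* and are duplicates by construction, not by luck. Decoy sources are
drawn without replacement so two decoys never coincide (two mirrors of the
same chain would be genuinely identical to each other). A fixed seed gives
byte-identical corpora.

## Numerical choices

* Frame degeneracy: the cross product (N−Cα)×(C−Cα) must exceed 10⁻⁶ Ų;
  real backbones are nowhere near this, it only guards synthetic edge
  cases. Degeneracy is reported with the residue number.
* Chains need m ≥ 2: a single residue has no predecessor frame, and a
  1 × 9 matrix would carry a different meaning.
* Rotations are validated to orthogonality and det = +1 within 10⁻¹⁰;
  reflections are rejected rather than silently absorbed.
* Kabsch superposition uses the SVD sign correction, so the recovered
  motion is always proper.
* Invariant TSVs serialise at 6 decimals — two orders below the
  meaningful precision of anything derived from 3-decimal coordinates.
* All tolerances quoted here are for 64-bit floats and are asserted as
  stated by the test suite.

## Subchains

For a contiguous subchain starting at residue *i* ≥ 2, every row except
its first equals the corresponding parent row *exactly* (same atoms, same
arithmetic); only its row 1 differs, because the subchain's first residue
is expressed in its own frame. This containment is what would make a
future search for duplicated *fragments* cheap: interior rows can be
indexed once and matched across chains of different lengths.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 20 × 100
rigid-motion invariance checks, 50 reconstruction round trips at m up to
200, ten ~30-chain corpora checked against exhaustive brute force, one
emitted ~22-entry corpus scanned end to end, and the forensic patterns at
m = 100. These sizes were chosen to exercise every contract with
comfortable margins while keeping a full run in well under a minute of CPU
for the script and a few minutes for the suite.

## Known limitations

* Pairing within a confirmed pair is positional (residue k to residue k);
  duplicates hidden behind renumbering are caught only if the numbering
  remains consecutive after cleaning.
* Subchain duplication (a chain embedded in a longer one) is out of scope:
  buckets compare equal-length chains only.
* Metadata forensics — comparing refinement statistics, data-collection
  records, B-factor patterns between the members of a reported pair — is
  deliberately left to the human inspecting the report; the package stops
  at the coordinate-level evidence.
* bio3d's mmCIF reader expects the standard wwPDB atom_site column set;
  exotic minimal CIFs may need conversion.
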