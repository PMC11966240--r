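# dupscan

Structure repositories accumulate depositions whose protein main-chain
coordinates are identical, or nearly so: redepositions that were never
obsoleted, models grafted onto another entry's coordinates, and entries
whose residue labels were changed without touching a single coordinate.
Sequence comparison cannot see these; raw coordinate comparison is defeated
by the arbitrary coordinate system, and all-versus-all RMSD is too slow for
repository scale. `dupscan` is an R package for crystallographers and
database curators that detects such pairs with a complete, continuous
invariant of the backbone under rigid motion.

## The invariant

For a chain of *m* residues with main-chain trace atoms N, Cα, C, attach to
each residue the right-handed orthonormal frame with origin at Cα, first
axis along Cα→N, third axis normal to the N–Cα–C plane. The **backbone
rigid invariant** (BRI) is the *m* × 9 matrix whose row *i* (*i* ≥ 2) holds
the local coordinates of residue *i*'s N, Cα, C atoms in the frame of
residue *i* − 1; row 1 holds residue 1's atoms in its own frame (five
structural zeros, so the matrix is exactly *m* × 9). Averaging the nine
columns gives the 9-vector **Brain**.

Key properties, all enforced by the test suite:

* **Invariance and completeness** — two chains have equal BRI iff their
  coordinates agree up to a proper rigid motion; the matrix inverts
  uniquely back to coordinates (`reconstruct_backbone()`).
* **Chirality** — mirror images differ (the out-of-plane columns change
  sign), unlike distance-matrix descriptors.
* **Continuity** — perturbing every atom by at most δ moves every entry by
  at most *C*·δ (empirically *C* ≈ 5–7 for protein-like chains), unlike
  averaged torsion angles, which are discontinuous at ±180°.
* **Lower bound** — in the Chebyshev (L∞) metric,
  d(Brain(A), Brain(B)) ≤ d(BRI(A), BRI(B)), which makes the 9-coordinate
  prefilter exact: no pair within a threshold *t* can be lost.

The duplicate search is a cascade: bucket chains by the integer invariant
*m*, prefilter each bucket on Brain, confirm on the full BRI, then report
per-pair forensics — maximum deviation between corresponding atoms in the
raw deposited frames (`max_dev`) and the number of relabelled residues
(`n_diff_res`).

## Worked example

Emit a synthetic corpus (6 independent chains plus planted exact,
perturbed, relabelled and rigidly moved duplicates, mirror and
far-perturbation decoys, and one chain per cleaning-filter violation),
then scan it:

```r
library(dupscan)
dir <- file.path(tempdir(), "demo")
corpus <- emit_corpus(fixture_spec(n_chains = 6, seed = 42), dir)
result <- scan_corpus(dir, filter_policy(threshold = 0.01))
result$pairs[, c("entry1", "entry2", "n_residues", "n_diff_res",
                 "d_brain", "d_bri", "max_dev")]
#>   entry1 entry2 n_residues n_diff_res      d_brain       d_bri max_dev
#> 1   s002   s008         96          0 0.0000000000 0.000000000    0.00
#> 2   s003   s010         60          0 0.0000000000 0.000000000    0.00
#> 3   s004   s007         84          0 0.0000000000 0.000000000    0.00
#> 4   s005   s012         69          0 0.0001117923 0.003259989  134.16
#> 5   s006   s009         95          0 0.0000000000 0.000000000    0.00
#> 6   s006   s011         95          9 0.0000000000 0.000000000    0.00
#> 7   s009   s011         95          9 0.0000000000 0.000000000    0.00
filter_counts(result$report)
#>                     kept                  trimmed               nonprotein
#>                       17                        0                        1
#>        partial_occupancy nonconsecutive_numbering        missing_mainchain
#>                        1                        1                        1
#>      nonstandard_residue                too_short
#>                        1                        1
```

Reading the rows: `s005/s012` is a rigidly moved copy — the raw coordinate
deviation is enormous (134 Å) but the invariant distance is 0.003 Å, well
under the 0.01 Å threshold, so the disguise fails. `s006/s011` has
identical coordinates (`max_dev = 0`, `d_bri = 0`) but nine residues
relabelled (`n_diff_res = 9`) — the signature of a relabelled
redeposition. Every planted duplicate is recovered; the mirror and
far-perturbed decoys are not reported; each cleaning-filter category
rejected exactly its one offending chain.

The same pipeline is available from a shell:

```sh
exec/dupscan fixtures corpus_dir --n-chains 6 --seed 42
exec/dupscan scan corpus_dir --threshold 0.01 --report pairs.csv
exec/dupscan compare corpus_dir/s006.pdb:A corpus_dir/s011.pdb:A --json pair.json
exec/dupscan invariant corpus_dir/s002.pdb --chain A --out bri.tsv
```

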