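---
title: "Methods: annotating and classifying hAT transposon consensus sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and classifying hAT transposon consensus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatannot)
```

`hatannot` annotates consensus sequences of *hAT*-superfamily DNA
transposons: it detects terminal inverted repeats (TIRs), grades the
encoded transposase against a five-residue activity signature, combines
both lines of evidence into an autonomous / nonautonomous call, and builds
neighbor-joining phylogenies with bootstrap support. This vignette
documents the model behind each stage, the tunable parameters, the
numerical conventions, and what the synthetic validation data do and do
not establish.

## Coordinates and alphabets

All sequence coordinates in results are 0-based, half-open, on the forward
strand. DNA is uppercase over `{A,C,G,T,N}`; `U` is mapped to `T` on input
and any other character is rejected with the offending record and offset.
`N` is treated conservatively everywhere: it never matches a concrete base
in arm-vs-arm comparisons, it only matches an all-base motif position, and
sites containing `N` are excluded from distance computations. Codons
containing `N` translate to `X`.

## TIR detection

A TIR pair is two equal-length arms, one near each element end, whose 5'
arm is approximately the reverse complement of the 3' arm. The detector
enumerates **all** pairs satisfying five predicates:

| parameter | default | meaning |
|---|---|---|
| `min_len` | 8 bp | minimal arm length; hAT TIRs are ≥ 8 bp by definition |
| `max_len` | 30 bp | caps arm length so near-palindromic sequence cannot produce degenerate whole-element "repeats" |
| `max_arm_mismatches` | 4 | Hamming budget between the 5' arm and the reverse complement of the 3' arm — the permissive setting used for sensitive scans of diverged consensus sequences |
| `max_anchor_mismatches` | 1 | budget for the degenerate anchor motif on the 5' arm |
| `terminal_window` | 200 bp | how far from an element end an arm may sit |
| `anchor` | `(T/C)A(A/G)NG` | the classical hAT TIR consensus motif |

Two budgets exist because arm-vs-arm complementarity and anchor-motif
identity are different questions: the 4-mismatch budget buys sensitivity
on the complementarity check, while the small anchor budget (1 mismatch on
a 5 nt motif) preserves the anchor's diagnostic role. Users who prefer to
spend the whole budget on the anchor can set `max_anchor_mismatches = 4`.
The anchor is enforced on the 5' arm only; under a fully permissive anchor
the scan is exactly strand-symmetric, which the test suite checks.

The default 200 bp window reflects that Repbase-style consensus sequences
may carry flanking host bases, so arms are not required to start at
position 0. Note that a permissive mismatch budget inside a wide window
admits many chance pairs on kilobase-scale sequences; the detector
deliberately reports all of them (the enumeration is checked against a
brute-force all-substring-pairs oracle), and `best_tir()` selects per
element by longest arm, then fewest mismatches, then leftmost position.
Downstream classification uses only the existence of a pair, which is
robust to this multiplicity.

## TIR consensus

Deduplicated 5' arms (`dedupe_tirs()`, exact-string identity on the 5'
arm, first occurrence kept — the simplest reproducible reading of
"nonidentical" arms) are truncated to `n_columns = 8` terminal positions
and summarised into a position frequency matrix. Per column:

* single letter if the modal base reaches `single_threshold` (0.6);
* `[X/Y]` if the top two bases jointly reach `pair_threshold` (0.8) and
  each reaches `1 - pair_threshold` (0.2);
* `N` otherwise.

The thresholds are exposed; the defaults make a 50/50 column a bracket
pair and a uniform column an `N`. Within a bracket the two bases are
written in the fixed order T, C, A, G — the order conventional in the hAT
TIR literature (`[T/C]`, `(A/G)`) — rather than by observed frequency.
This matters for reproducibility: in a column whose true composition is an
even split, frequency ordering would flip between samples on sampling
noise alone, whereas the fixed order makes the rendered consensus a
deterministic function of the *sets* of retained bases. The frequency
matrix itself, returned alongside and plotted by `autoplot()`, carries the
quantitative information a sequence logo would.

## Transposase grading

Consensus transposases are frequently frame fragments, so ORF discovery
requires no start codon: every maximal stop-free run of at least
`min_aa = 100` residues in any of the six frames is a candidate. The
default keeps internal-deletion derivatives visible (their fragments are
graded *truncated* rather than vanishing) while excluding most noise ORFs;
note that on multi-kilobase sequences chance stop-free runs above 100
residues do occur, and they are graded *truncated* because they lack the
signature — they never produce a spurious *active* call in practice, since
all five residues would have to appear at alignment-consistent positions.

Each candidate is globally aligned to the reference transposase
(BLOSUM62, gap open 10, gap extend 0.5 — standard protein defaults, all
configurable) and the best-scoring candidate is graded: the residue
aligned opposite each signature position must lie in the allowed set. A
gap at a signature site fails it — a deleted residue is a lacking residue,
not missing data. Two numbering presets ship: maize Activator (D301,
D367, R463, [W/F]464, E719) and Hermes (D180, D248, R318, W319, E572).
They are independent presets, not derived from one another. Each carries a
*synthetic* reference protein — a deterministic pseudo-random 750-aa
(Activator numbering) or 612-aa (Hermes numbering) sequence with the
signature residues planted at the preset coordinates — so the machinery is
exercised at realistic coordinates without shipping any curated sequence.
For real data, pass the actual reference via
`hat_signature(..., reference_protein = )`; construction verifies that any
reference passes its own signature.

Conserved-block extraction (`extract_blocks()`) marks maximal runs of
alignment columns that are gap-free in every row and whose modal residue
reaches `min_column_conservation = 0.5`, with width ≥ `min_block_len = 3`.
The thresholds are exposed because block counts are sensitive to them;
`block_frequencies()` returns the per-column residue counts.

## Autonomy classification

An element is *autonomous* iff a TIR pair was detected **and** its
transposase is active. Everything else is *nonautonomous* with explicit
reasons; elements with an active transposase but no TIRs are encoded as
nonautonomous with reason `no_tir` rather than as a third status, keeping
the call binary. Derivative linking is purely nominal: a nonautonomous
element whose name parses to `<stem>-N<k>` or `<stem numeric>N<k>` gets
`parent_id = stem` when that element exists in the dataset. The summary's
autonomous percentage is truncated (not rounded) to one decimal:
`floor(1000 * a / t) / 10`, so 35/276 prints as 12.6.

## Distances, neighbor joining, bootstrap

Distances use pairwise deletion (sites with a gap or `N` in either
sequence are skipped per pair) because transposon consensus alignments are
gappy enough that complete deletion can empty the comparison. The shipped
models are the raw p-distance and its Jukes–Cantor correction
`d = -(3/4) ln(1 - 4p/3)`; JC69 is the tree-building default as the
simplest correctable model. A saturated pair (`p ≥ 0.75`) inside a
bootstrap replicate falls back to its p-distance and is counted, rather
than aborting the replicate.

Neighbor joining follows the Saitou–Nei agglomeration exactly as usually
stated: join the pair minimising `Q(i,j) = (n-2) d(i,j) - R_i - R_j`,
branch lengths `b_i = d(i,j)/2 + (R_i - R_j)/(2(n-2))`, update
`d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2`. Numerical conventions: ties in
`Q` break to the smallest `(i, j)` pair in current matrix order; a
negative branch length is clamped to zero with the deficit moved to its
sibling so the joined pair's distance is preserved; the final three nodes
are joined at a root trifurcation by the three-point formulas, clamped at
zero. These conventions keep the output deterministic and the tree
invariant (lengths ≥ 0) testable; NJ remains exact on additive matrices,
which the tests verify against path-length oracles on random trees.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree, and counts bipartitions; supports are attached to the internal
edges of the full-data tree (no majority-rule consensus tree is built).
Bipartitions are canonicalised to the lexicographically smaller side so
keys are stable under side swap. Reproducibility contract: replicate `r`
draws its columns under `seed + r`, so one integer governs the whole
analysis. Newick serialisation goes through `ape` with supports as
internal node labels.

## The synthetic generator, and what passing tests show

`generate_dataset()` emulates a Repbase-like library with planted ground
truth. Element layout is `[TSD][5' TIR][filler][stop][ORF][stop][filler]
[revcomp TIR][TSD]` with: TSD length drawn uniformly from 4–8 bp (the
hAT target-site duplication range); TIR arms of 12 bp sampled from the
`[T/C]AGNGNNG` motif (degenerate positions uniform); element length
2700 bp, enough to host the 750-codon synthetic transposase; filler
uniform over the four bases. Defaults for the mixture are half the
elements transposase-bearing, a fifth of those knocked out (one signature
residue mutated to alanine — the minimal violation of the signature), and
nonautonomous `-N1` derivatives spawned from 30% of intact parents by an
internal deletion. The deletion always lies strictly between the TIRs and
always covers at least one signature-site codon; an unconstrained deletion
could miss every site and leave the derivative active, contradicting its
own truth label. Point mutation substitutes each site independently with
the configured probability.

Ground truth is a property of the **emitted** sequence, not of the
construction plan: after mutation, the planted coding region is
re-translated in its planted frame and the signature is intact iff all
five residues are allowed and no stop codon falls between the first and
last signature sites (a stop outside that span leaves one fragment
carrying all five residues, which the residue-based criterion counts as
active). A signature disrupted by mutation is recorded as knocked out, and
autonomy follows the same rule the classifier uses. This keeps the truth
honest at any mutation rate and makes end-to-end accuracy a measure of
*detection*, not of definitional drift.

Radiation along trees (`mutate_and_radiate()`) applies per-branch
substitution probabilities; the returned true tree carries branch lengths
`-(3/4) ln(1 - 4r/3)`, which makes path lengths additive and directly
comparable to JC-corrected distances (two branches with rates `r1, r2`
compose to an expected p-distance `(3/4)(1 - (1-4r1/3)(1-4r2/3))`, an
identity the tests check against simulation).

The generator does **not** emulate: indels inside TIRs (deletions are the
only indel operator, so planted TIR coordinates stay exact), host-genome
flanks beyond the TSD, base-composition bias, rate heterogeneity across
sites, horizontal transfer, or family structure within a species. Passing
the synthetic suite therefore shows that the implementation is correct
under the stated generative model — it does not show that the default
budgets are optimal for any particular real library, where TIR length
variation, nested insertions and diverged families will matter.

When scanning synthetic elements the examples and tests use
`terminal_window = 16` because generated elements carry only their 4–8 bp
TSD as flank; the 200 bp default remains appropriate for real consensus
records with uncertain flanking sequence.

## Validation scales

The test suite and `scripts/acceptance.R` exercise: oracle equivalence of
the TIR scan on 250 sequences (150–300 bp, brute-force all-pairs
comparison); consensus recovery from 500 motif-sampled arms; a 207-arm
deduplication fixture with 54 planted duplicates; 60 signature constructs
(intact references, all single-site alanine knockouts, random deletions
spanning a site); neighbor-joining exactness on 100 additive matrices
with 4–12 leaves (branch lengths reproduced to 1e-9); a three-clade
radiation on 10 kb sequences with 100 bootstrap replicates (all clade
supports at 100); and end-to-end autonomy recovery on ~200-element
synthetic libraries, exact at zero mutation and ≥ 90% at a per-site rate
of 0.05. These sizes were chosen as the smallest that make each property
sharp — NJ exactness and oracle equivalence are binary at any size, while
the stochastic checks (bootstrap supports, noisy-recovery accuracy) use
enough replication that their thresholds sit several standard errors from
the expected values.

## Known limitations

* TIR detection reports arm pairs, not the paired-arm-with-TSD evidence a
  genomic (non-consensus) scan could use; target-site duplications are
  only meaningful in the synthetic data, where they are planted.
* The signature check reads residues through a pairwise alignment; a
  highly diverged transposase could misalign a site and be graded
  truncated even if biochemically functional. The alignment parameters
  are exposed for such cases.
* The two signature numbering systems are independent presets; no mapping
  between them is computed.
* NJ and JC69 are deliberately simple; the package does not attempt
  maximum-likelihood inference or model selection, and makes no claim of
  reproducing any particular published tree topology.
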