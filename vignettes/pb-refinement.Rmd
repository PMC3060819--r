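---
title: "Protein Block refinement of structurally variable regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Block refinement of structurally variable regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrefine)
```

# The model

Rigid-body superposition of two homologous protein structures partitions
their alignment into regions that overlay well and regions that do not.
`pbrefine` treats the latter — structurally variable regions (SVRs) — as
objects worth a second look: a region can fail to superpose either
because its local conformation genuinely differs between the two
proteins, or merely because an internally conserved element (typically a
helix or strand) sits at a different orientation. The package separates
the two cases by re-describing the backbone in a structural alphabet
that is invariant under rigid motion.

## Protein Blocks

A Protein Block (PB) is one of 16 five-residue backbone prototypes,
labelled *a*–*p*, each defined by 8 dihedrals in window order
(ψ~i−2~, φ~i−1~, ψ~i−1~, φ~i~, ψ~i~, φ~i+1~, ψ~i+1~, φ~i+2~). PB *m* is
the central α-helix prototype and *d* the central β-strand; *a*–*c* and
*e*–*f* cap strands, *k*–*l* and *n*–*p* cap helices, *g*–*j* cover
coil. Assignment at residue *i* compares the observed window against all
16 prototypes with the angular RMSD

$$\mathrm{RMSDA}(w,p) = \sqrt{\tfrac{1}{8}\sum_{k=1}^{8} d(w_k,p_k)^2},$$

where $d$ is the wrapped angular difference in $[0°,180°]$, and takes
the argmin; ties (exactly equal RMSDA) break to the lexicographically
smaller label so output is reproducible. Positions without a full
window — the two residues at each end of every continuous stretch, and
any window crossing a chain break — carry the undefined symbol `Z`.
Because dihedrals are invariant under rotation and translation, so is
the PB string; this is the property that lets PB comparison see through
rigid displacements.

The prototype table ships as `inst/extdata/pb_prototypes.tsv` (the
canonical published 16 × 8 angle set) and is swappable.

## Segmentation

Following standard practice for structure-alignment databases, a
structurally conserved region (SCR) is a maximal run of at least
`min_scr_length` (default 3) consecutive aligned, gap-free columns whose
Cα–Cα deviation under the current superposition is each strictly below
`deviation_cutoff` (default 3.0 Å). Every other column belongs to
exactly one maximal SVR. Three consequences of reading the rule
literally, all tested: a sub-cutoff run of length < 3 is absorbed into
the surrounding SVR; gap columns are always SVR members (a deviation
must be *measured* for SCR membership — columns with a missing Cα
likewise cannot be SCR); and SCRs plus SVRs tile the alignment exactly.

An SVR is **complete** when its initial alignment contains strictly more
than `min_svr_aligned_pbs` (default 3) aligned PB pairs, pairs involving
`Z` not counting. SVRs touching either end of the alignment are flagged
`terminal` and are excluded from SDM analysis (their local superposition
is unconstrained on one side), though they are still scored and
classified.

## The global fit

The natural base procedure — fit on all equivalenced columns, segment,
refresh the fit on SCR columns, re-segment — proved fragile in testing:
when one large segment is displaced by several Ångström, the initial
all-column least-squares fit tilts toward it, the first segmentation
finds a wrong small "core", and the refresh converges to that attractor.
The package therefore seeds segmentation with an **outlier-trimmed,
multi-start fit** (`trimmed_fit`): starting from the all-column fit and
from fits on sliding 12-column windows, each start iterates
"refit on the columns currently below the cutoff" to convergence, and
the solution retaining the most sub-cutoff columns wins (ties: lower
RMSD over them). Maximising the count of well-fitting positions is the
standard rigid-core criterion; the SCR-refresh step is retained
afterwards. This robustification was adopted after the simpler loop
demonstrably mis-segmented conformational-swap fixtures.

Superpositions are Kabsch least-squares fits (SVD with the reflection
excluded by sign-flipping the smallest singular vector); the test suite
checks them against an independent quaternion (Davenport K-matrix)
oracle to 1e-6 on random clouds.

## PB re-alignment

Each SVR's two PB substrings (projections of the chain PB strings into
the SVR, gaps dropped, `Z` retained) are globally re-aligned by Gotoh
dynamic programming with affine gaps: a run of $L$ gap symbols costs
$\mathrm{open} + (L-1)\,\mathrm{extend}$ with open = 10 and
extend = 0.2, the values used with the alignment program in the source
protocol after disabling all residue- and position-specific penalties.
Inside the DP the substitution matrix is min–max scaled to $[0,10]$
("scaled between 0 and 10" names no function; the linear map is monotone
and so preserves the optimal-alignment ordering under a fixed gap
scheme). `Z` scores 0 against everything — no conformation is defined
there, so it neither rewards nor penalises any pairing. End gaps are
penalised by default because SVR boundaries are pinned by flanking SCRs,
making the alignment genuinely global; a flag disables this since the
original program's terminal-gap behaviour is not recorded. Traceback is
deterministic (tie order: match, then gap-in-second, then gap-in-first;
run continuation preferred), so identical inputs give byte-identical
output. The DP optimum is validated against exhaustive enumeration of
*all* global alignments for short strings.

## Scores, classification, SDM

Reported scores use the **raw** matrix, not the scaled one: published
score ranges for this kind of analysis are negative (a similarity cutoff
of −0.42, worked dissimilar examples near −2), which is impossible on a
$[0,10]$ scale. The scaled matrix exists only inside the DP.

* **SAP** — mean raw substitution value over aligned PB pairs (gaps and
  `Z`-pairs excluded). Undefined (an error) with zero pairs.
* **SCA** — (sum of pair values + gap_score × gap columns) / alignment
  length, gap_score = −3.
* **Classification** — similar iff SAP > −0.42, strictly: a score
  exactly at the cutoff is dissimilar ("above this threshold" read
  literally). Both the cutoff and the boundary convention are
  configurable. With a different matrix or corpus, `calibrate_cutoff`
  re-derives the analogous cutoff as the empirical 10% lower quantile
  (linear interpolation, `stats::quantile` type 7) of SCR SAP scores, so
  that 90% of conserved regions score above it.
* **SDM** — the source analysis transcribes its structural distance
  metric only as a figure, stating one modification: RMSD is divided by
  the corpus maximum 24.97 Å (instead of the customary 3.0) so the RMS
  term stays in $[0,1]$. The implementation follows the cited
  Johnson–Blundell weighted-log form,
  $\mathrm{SDM} = -100\,\ln(w_1\,\mathrm{PFTE} + w_2\,(1-\mathrm{RMS}))$
  with equal default weights, isolated in one function (`sdm`) so any
  variant is a one-line replacement. PFTE is the fraction of positions
  with an equivalenced residue pair; RMSD above 24.97 clamps RMS to 1
  with a warning (the constant was itself a corpus maximum, so larger
  values merely saturate the term). `sdm(0, n, n) = 0`; the metric is
  strictly increasing in RMSD and strictly decreasing in the
  equivalenced fraction — both asserted on grids.
* **Before/after comparison** — deltas are after − before; "better"
  means higher score, lower SDM; equality is $|\Delta| < 10^{-9}$. The
  grid cell is keyed on (SAP, SDM), with SCA deltas reported alongside
  so a complete-alignment-score version of the grid can be tabulated
  externally.

Local SDM inputs per SVR: the "before" equivalences are the input
alignment's residue pairs inside the SVR; the "after" equivalences map
each gapless PB-alignment column to the pair of central residues of the
two windows. Columns pairing `Z` with a symbol still yield a residue
pair (the residues exist geometrically; only scoring treats them as
uninformative). Fewer than 3 pairs → local RMSD and SDM undefined.

# The synthetic generator

`build_backbone` turns a PB string into Cartesian coordinates by
NeRF-style sequential placement with ideal peptide geometry (N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; N–CA–C 111.2°, CA–C–N 116.2°,
C–N–CA 121.7°; ω = 180°). Residue *i* takes (φ, ψ) from the **central
position** of its prototype. Full 8-angle window satisfaction is
impossible for arbitrary strings — overlapping windows over-constrain
the dihedral series — so round-tripping (reassigning the built backbone)
recovers the generating symbol only where the 5-symbol neighbourhood is
self-consistent. Crucially this is *exactly predictable by angle
arithmetic*: `pb_predict_assignment` computes the assignment of a built
backbone without any 3-D construction, and the geometric route is
asserted identical to it on arbitrary strings. "Transition-compatible"
strings — sampled by seeded backtracking search under that predicate
(`random_pb_string(compatible = TRUE)`) — round-trip at 100%,
position-for-position; this is the generator used by fixtures and
acceptance tests.

Fixture kinds (`make_pair_fixture`), all built from a capped helix
`kl m… nop` between β-strand flanks, sizes and magnitudes drawn from
seeded ranges chosen once as representative: flanks 14–18 residues,
helix 8–11, displacement 5–8 Å with 0–15° rotation (comfortably beyond
the 3 Å cutoff, as a displaced secondary-structure element in a real
pair would be):

* **identical** — two copies; truth: zero SVRs.
* **displaced** — the helix rigidly displaced in chain 2 *and*
  mis-registered by two positions in the supplied initial alignment,
  modelling the unreliable equivalences a rigid-body aligner produces
  under high deviation. Truth: one SVR, similar after re-alignment, with
  ΔSAP > 0 and ΔSDM < 0.
* **conformational** — the helix's coordinates replaced by a strand
  segment grafted at the upstream junction (the downstream junction
  opens a chain break, which is the point: the region changed shape,
  its ends no longer meet). Truth: dissimilar.
* **indel** — the helix lengthened by two residues in chain 2; the
  refined alignment must place two gap columns. Truth: similar.

What the generator does **not** emulate: side chains, real loop
irregularity, crystallographic noise, missing density, sequence
divergence (all residues are alanine). A green end-to-end test
establishes that the pipeline discriminates rigid displacement from
conformational change on clean geometry with known truth — not that it
reproduces any corpus-level statistic on real structures.

# Numerical and interface choices

* Dihedrals follow the IUPAC convention (trans = 180°, range
  (−180°, 180°]), verified against two independent formulations. A
  torsion angle is *invariant* under reversal of its four points (only
  mirror reflection flips the sign) — the suite pins both facts down.
* Chain breaks: peptide C–N distance > 2.5 Å (standard practice; the
  source is silent). Breaks kill φ/ψ across the junction and any PB
  window spanning it.
* Altloc resolution: highest occupancy, ties to first in file; HETATM
  records are used only for standard residues (e.g. MSE); model 1 by
  default; residues missing any of N/CA/C are dropped with a warning.
* Column ranges are half-open and 0-based internally; all reports use
  1-based author residue numbering (number + insertion code).
* The default substitution matrix is a synthetic stand-in (entry =
  5 − 10·RMSDA(x,y)/max RMSDA over prototypes; see `?pb_sm_synthetic`):
  the refined matrix used by the source analysis is unpublished, and the
  package treats the matrix strictly as a pluggable input. All tests
  pass with any valid symmetric 16×16 matrix; tests that need specific
  contrasts (helix-vs-strand strongly negative) assert those properties
  of the stand-in explicitly.
* Known limitations: no flexible/hinge superposition; no multiple-
  structure mode; the initial residue alignment is an input, never
  computed from scratch; loop modelling consumes the exported refined
  alignment but is out of scope.

# A worked run

```{r}
fx  <- make_pair_fixture("displaced", seed = 42)
ch1 <- read_structure(fx$pdb1)
ch2 <- read_structure(fx$pdb2)
aln <- read_alignment(fx$alignment, ch1, ch2)
rep <- suppressWarnings(refine_pair(ch1, ch2, aln))
print(rep)
print(rep$svr[[1]]$before_alignment)
print(rep$svr[[1]]$after_alignment)
```

The displaced helix's PB string is unchanged by the displacement, the
re-alignment pairs it position-for-position, and the local superposition
of the refined equivalences is exact — the region is similar, its
variability purely rigid-body.
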