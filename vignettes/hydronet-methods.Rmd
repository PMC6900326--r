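---
title: "Conserved water sites and recognition networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conserved water sites and recognition networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydronet)
```

## The problem

Multicopper oxidases such as human ceruloplasmin bind small-molecule
substrates (biogenic monoamines: serotonin, norepinephrine, epinephrine) in a
cavity lined by acidic residues, near a mononuclear "blue" T1 copper center,
with a trinuclear copper cluster further away at a domain interface. Two
classes of structural observations characterize such binding sites across an
MD ensemble or a set of superposed crystal structures:

* **Conserved water sites** — hydrophilic positions occupied frame after
  frame by water molecules, usually by *different* individual waters
  (identity exchange), which stabilize the ligand and bridge it to the
  protein and to the metal centers.
* **Recognition paths** — chains of hydrogen bonds, covalent links and metal
  coordination connecting a ligand atom (here the protonated ethylamine
  nitrogen, N1⁺) to a copper center, possibly routed through water sites.

`hydronet` implements the full workflow: superposition, geometric
interaction detection with occupation-frequency (O.F.) statistics, water-site
clustering and classification, RMSD/RMSF/torsion metrics, and graph search
over the typed interaction network. A seeded synthetic generator with
planted ground truth makes every stage testable without external data.

## Superposition

Frames are fitted to a reference by Kabsch least squares (SVD of the
weighted covariance; a reflection is corrected by flipping the smallest
singular vector, so the rotation is always proper). The default fit
selection is the protein backbone (N, CA, C, O), never waters, the ligand or
metals: those are the analytes, and fitting on them would bias both the
site detection and the interaction distances. The reference is frame 1 by
default; an external crystal structure can be passed instead.

One consequence worth knowing: when a deliberately *mobile* element (the
931–937 helix in the benchmark) is part of the fit selection, its motion
leaks into the fitted transforms and smears apparent fluctuation onto rigid
residues. The RMSF analyses in the tests and the acceptance script
therefore superpose on the stable core (backbone excluding the mobile
helix), which is the standard practice when quantifying a mobile element
against a rigid scaffold.

## Interaction criteria

All criteria are heavy-atom only. MD frames converted to a three-site water
model may or may not carry hydrogens, and crystal structures usually do
not; ignoring hydrogens everywhere makes the two input classes uniform.

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor heavy-atom distance | ≤ 3.5 Å |
| salt bridge | carboxylate O to basic N (Lys NZ, Arg NE/NH1/NH2, optionally His) | ≤ 4.0 Å |
| metal coordination | metal to N/O/S (waters included) | ≤ 3.0 Å |
| T-shaped π-stacking | ring-centroid distance and inter-plane angle | 4.0–7.0 Å, 60–120° |

Donor/acceptor roles come from a table keyed by (residue, atom) with
wildcards for the protein backbone and for ligand-like residues; water
oxygens are always both donor and acceptor. Pairs within one residue and
1-2/1-3 backbone pairs of consecutive residues are excluded. The hydrogen
bond criterion deliberately has no angle term: without hydrogens an angle
would have to be invented, and distance-only bookkeeping reproduces the
kind of heavy-atom distance tables this analysis is meant to produce.
Contacts beyond the cutoff can still be *measured* (`measure_distance`) and
reported; they are just not classified as hydrogen bonds.

The **occupation frequency** of a grouping key is
`100 × (frames with ≥ 1 event for the key) / (frames analysed)`. The
grouping rule is an explicit argument: atom-level keys by default, or
residue-level grouping (e.g. Asp1025 OD1 *or* OD2 counted as one "Asp1025"
contact) via `residue_label()`. Residue-level O.F. is therefore never
smaller than the best atom-level O.F. it contains. Whether a published
occupancy table grouped carboxylate oxygens is rarely stated; keeping the
rule caller-visible makes the choice auditable.

## Water-site clustering

Superposed water-oxygen positions are clustered with a pairing cutoff of
1.8 Å — the conventional threshold for calling two superposed waters "the
same site". Multi-frame clustering is deliberately simple and deterministic,
because auditable bookkeeping matters more here than clustering
sophistication:

1. **Leader pass.** Frames are processed in order. Each water joins the
   nearest existing site whose centroid is within 1.8 Å (ties to the lower
   site index) or seeds a new site. A site accepts at most one water per
   frame; when two compete, the nearer wins and the loser is re-queued with
   that site excluded. Centroids are running means, updated after each
   frame.
2. **Refinement pass.** All waters are re-assigned against the frozen
   centroids by minimum-distance greedy matching (one water per site per
   frame). Final centroids are the means of the refined memberships.

Sites are ordered by occupancy and labeled WS1, WS2, … so the naming is
stable across runs. Classification uses two thresholds exposed in
`cluster_params()`: **conserved** at O.F. ≥ 90 %, **semi-conserved** at
≥ 60 %, otherwise **transient**. The 90/60 values are this package's
convention — the field's usage ("conserved" near 100 %, "semi-conserved"
near 85 %) implies but never states thresholds — and both are
configuration, not constants. Sites under 10 % occupancy are dropped from
reports by default (`min_occupancy_report`); the alignment negative control
sets this to 0 because its whole point is to count the noise sites.

Site occupancy counts *site* occupation by any water id, not a specific
water molecule: a single hydrophilic position handed between W2326, W2056,
W2059 and W2283 over a trajectory is one 100 % site with four member ids.
The per-site `n_water_ids` column makes the identity exchange visible.

Pairing between two superposed single structures
(`match_waters_between_structures`) is one-to-one greedy matching on
ascending distance with the same 1.8 Å cutoff.

## Recognition graph and paths

Nodes are protein residues (side chains collapsed), metal ions, ligand
atoms, and water sites (individual waters are replaced by their site).
Edges are typed: `covalent_adjacent` between sequence-consecutive residues,
`hbond` from hydrogen-bond and salt-bridge events, `metal_coord` from the
coordination detector. Hydrogen-bond edges must clear an occupancy floor
(`occ_min`, default 50 % — the weakest contact still worth calling
stabilizing); each edge carries its mean distance and O.F. Salt bridges
enter as `hbond`-kind edges: the graph's type system tracks connectivity
classes, not chemistry subtypes, and a salt bridge is a (charged) hydrogen
bond for path purposes.

`find_path` is breadth-first minimal-hop search with two deterministic
tie-breaks: among equal-hop paths, the maximal minimum-edge occupancy wins;
among those, the lexicographically smallest node sequence. Hop count is the
only distance — the package makes no claim about electron-transfer physics,
so weighting edges by length or energy would suggest precision that is not
there. Water-mediated routes need no special machinery: they are simply
paths through water-site nodes, and `format_path` renders non-covalent
steps (and every step touching a water site) with "…", covalent and
coordination steps with "-":

```
N1(+)…Asp1025-His1026-Cu3052-Cys1021-His1022-Cu3048
N1(+)…Asp1025-His1026-Cu3052-Met1031-Glu1032…WS2…Cu3047
```

## The synthetic generator

`make_scaffold()` builds a deterministic binding-site scaffold: an acidic
triad planted as an exact triangle (default 5.1/4.7/6.6 Å, the
crystal-template variant 6.08/4.05/7.11 Å), a monoamine-like ligand with
requested χ1/χ2 torsions, copper-coordinating side chains at coordination
range, three mononuclear coppers mutually 18 Å apart, a trinuclear cluster,
and optionally crystal-style waters including a linear three-water bridge
from Glu1032 to the cluster copper. Atom placement is template-based, so
the scaffold is a geometric test harness, not a chemically valid structure;
any two atoms closer than 1.5 Å abort with a placement error.

`simulate_trajectory()` emulates the features of an analysed MD ensemble
that the detectors care about, and nothing else:

* per-residue Gaussian positional noise (default σ = 0.1 Å; metals fixed,
  as copper centers are in the simulations this mimics);
* planted interactions drawn Bernoulli(p) per frame, the moved partner
  placed exactly at its contact distance when present and at
  `cutoff + 0.5 Å` when absent — the margin makes detector truth
  unambiguous at the boundary;
* water sites drawn Bernoulli(p), the water placed uniformly within
  `0.5 × link_cutoff` of the centroid, with residue ids rotating every 10
  frames to emulate identity exchange;
* a random global rigid motion per frame (≤ 15°, ≤ 3 Å) so superposition is
  exercised — large enough that skipping alignment visibly shatters the
  site structure.

The benchmark (`benchmark_system()`) plants three binding-site water sites
at occupancy probabilities 1.0 / 0.85 / 0.5 with centroids ≥ 4.5 Å apart,
one fully-occupied bridge site, and the contact set that supports both
recognition paths. Sampling metadata mirrors a trajectory recorded every
2 ps. What the generator does **not** emulate: correlated motion, rotamer
dynamics, realistic water diffusion, force-field energetics, periodic
boundary effects. A green test suite therefore demonstrates that the
*bookkeeping* — superposition, detection, clustering, occupancy arithmetic,
path search — is correct under known truth; it does not validate any
physical model of real trajectories.

## Numerical choices and degenerate inputs

* Kabsch fit requires ≥ 3 points of rank ≥ 2; collinear sets raise a
  degenerate-fit error rather than returning an arbitrary rotation.
* Torsions use the atan2 formulation, signed per the IUPAC convention,
  range (−180°, 180°]; a collinear triple is an error.
* Ring planes come from the SVD of centered ring coordinates; the
  inter-plane angle is folded to [0°, 90°] and tested against the window on
  both orientations.
* RMSF is computed in two passes (mean, then squared deviations) —
  the one-pass moment formula loses ~7 digits for coordinates far from the
  origin.
* Snapshot times map to the nearest frame, ties toward the earlier frame.
* Events are deduplicated on (kind, unordered atom pair, frame) and sorted,
  so detector output is a canonical form independent of scan order.
* All randomness flows through one recorded integer seed; identical seeds
  give bit-identical ensembles and byte-identical reports.

## Problem sizes

The packaged analyses run at sizes chosen to make the statistics sharp but
the runs quick: occupancy recovery on 1000 frames (binomial standard error
≈ 1.1 points at p = 0.85, comfortably inside the 3-point recovery check),
RMSF recovery and the alignment negative control at 400–500 frames,
detector/oracle equivalence on 200 random 100-atom models, path/BFS
equivalence on 100 random graphs of up to 50 nodes. The `analysis/` scripts
use 200-frame ensembles for their narratives.

## Known limitations

* PDB is the only coordinate format; binary trajectory formats would be an
  adapter behind the same ensemble contract, and are not provided.
* The hydrogen-bond criterion is distance-only; systems with reliable
  hydrogens would support angular criteria this package does not implement.
* Water analyses are oxygen-only by design.
* The leader clustering is order-dependent by construction (deterministic,
  but a different frame order can shift borderline assignments); the
  refinement pass reduces, not eliminates, this.
* Residue-level graph nodes cannot distinguish two simultaneous contacts
  through different side-chain atoms of one residue.
* Crystal-structure checks in this repository run against synthetic
  reference structures that plant published template geometry; with
  deposited PDB files on disk the same functions apply unchanged.
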