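---
title: "Methods: conformational-landscape analysis of a core-plus-appendage kinase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-landscape analysis of a core-plus-appendage kinase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformscape)
```

## The problem

The DnaJB1--PKAc fusion kinase carries a 69-residue J-domain appended to
the N-terminal A-helix of an otherwise ordinary protein kinase A catalytic
subunit. Crystallographically the appendage tucks under the large lobe,
but in solution it is highly mobile: molecular-dynamics ensembles show it
detaching and swinging free, and NMR spin relaxation shows the appendage
reorienting faster than the catalytic core. `conformscape` packages the
analysis chain used to characterize such a landscape: superposition-based
RMSD/RMSF, a three-angle appendage descriptor, GROMOS conformational
clustering with transition counting, holoenzyme clash modelling, and
T1/T2 relaxation fitting -- together with seeded synthetic generators that
let every stage be tested without any external download.

## Coordinate frame and numbering

All superpositions fit on the two immobile large-lobe anchor helices,
E (native residues 140--160) and F (217--233), backbone atoms
\{N, CA, C, O\}. "Backbone" is taken as that four-atom set throughout; the
per-residue RMSF atom set defaults to C$\alpha$ only -- both conventional
choices where the underlying analysis leaves the atom set unstated.

Two numbering schemes coexist for the fusion protein: crystallographic
("chimera") numbering 1..405, and native kinase numbering in which
appendage residues are negative (-69..-1) and residue 15 is the first
residue shared with the wild type. The two published anchor pairs
(native 10 = chimera 65, native 15 = chimera 70) fix a constant offset of
+55, implemented as `numbering_map()`; the third derived anchor,
native -19 = chimera 36, follows. Negative residue numbers are first-class
everywhere.

## The three-angle appendage descriptor

Six C$\alpha$ anchors define the descriptor (`default_anchors()`):
A-helix top Lys29, mid Val15, base Pro2; appendage tip Lys(-19); and
large-lobe anchors Leu160, Glu140.

* $\theta_1$ (A-helix bend) is the angle at Val15 between the vectors to
  Lys29 and to Pro2, so a straight helix gives $\theta_1 \approx 180°$ and
  kinking lowers it. The source figure labels one vector endpoint "Lys15"
  while naming Val15 for the same position in the other vector; we treat
  this as a typo for Val15 (overridable through `default_anchors()`).
* $\theta_2$ (elevation) is the angle at Pro2 between the vectors to
  Val15 and to the appendage tip.
* $\theta_3$ (shear) is the magnitude of the dihedral
  Lys29--Leu160--Glu140--Lys(-19), reported unsigned in $[0, 180]°$
  because the descriptor's published range (24°--180°) contains no signed
  values. The signed dihedral (IUPAC convention) is available as
  `dihedral()`.

Vector directions are not stated in the source; the directions above are
the unique choice under which a straight A-helix scores near 180°,
matching the published crystal value of 164°. (The running text gives
161° for the same quantity where the summary table prints 164°; the table
value is used as the check value.) All three angles are invariant under
global rigid motion, so no superposition precedes their evaluation.

## Superposition, RMSD, RMSF

`kabsch()` solves the weighted least-squares superposition by SVD with
the determinant correction, returning proper rotations only; degenerate
(collinear) point sets are rejected rather than silently resolved.
`average_structure()` superposes every window frame onto the window's
first frame and averages atomwise -- single-pass, not iteratively
re-referenced, which is deterministic and standard. `rmsd_series()`
fits each frame on the anchor helices and measures over a separate
selection, which may exclude the mobile N-terminus (e.g. "backbone from
residue 15"). `rmsf()` measures fluctuations about the time-mean position
after superposing each frame onto the window average; fluctuations are
never measured against a crystal reference. `differential_rmsf()`
subtracts wild type from chimera on the shared range (residue >= 15),
positive meaning larger fluctuation in the chimera.

## GROMOS clustering and transitions

`pairwise_rmsd()` computes the all-versus-all matrix: frame $j$ is fitted
onto frame $i$ over the anchor helices, RMSD is measured over the
measurement selection, and the matrix is symmetrized by averaging the two
directions (they coincide when the selections coincide). The kernel is
C++ (quaternion superposition with a fixed-size Jacobi eigensolver) and
is contract-tested against a plain R Kabsch oracle.

`gromos_cluster()` implements neighbor-count peeling: the unassigned
frame with the most neighbors strictly within the cutoff (default 5 Å)
seeds each cluster and is removed with its neighbors. Two conventions the
original description leaves open are fixed deterministically: neighbor
ties break to the lowest frame index, and a frame exactly at the cutoff
is *not* a neighbor. Both a cluster *center* (max neighbor count) and a
*representative* (minimum mean intra-cluster RMSD) are reported, because
downstream summaries use the representative.

`count_transitions()` counts lag-1 transitions within each trajectory,
never across trajectory boundaries (pooled ensembles are physically
independent runs). `symmetry_score()` is
$1 - \sum|C - C^\top| / \sum(C + C^\top)$ over off-diagonal counts: 1 for
detailed-balance-like flow.

## Holoenzyme placement and clash scanning

`place_conformer()` fits a conformer's anchor-helix backbone onto the
corresponding helices of a catalytic subunit inside a holoenzyme template
and swaps it in, reporting the post-fit RMSD as a placement QC.
`clash_scan()` then lists all heavy-atom pairs between two disjoint
groups (e.g. appendage versus regulatory subunits) closer than a
threshold, default 2.5 Å -- a transparent hard-sphere proxy chosen
because the source assesses "steric hindrance" without stating a
criterion. Hydrogens are excluded (crystal templates lack them). The
spatial cell list is contract-identical to the brute-force scan, and the
brute-force route stays available as `method = "brute"`.

## Relaxation analysis

`fit_decay()` fits $I(t) = I_0 e^{-t/T}$ by unweighted least squares with
the derivative-free downhill-simplex method (restarted once from its own
optimum; initialization $I_0 = \max I$, $T$ = delay nearest $I_0/e$). The
standard delay grids are built in: T1 = 0, 10, 100, 300, 500, 700, 900,
1200, 1700 ms (nine values -- the source text says "8 delays" but lists
nine; the list wins) and T2 = 8.1..64.8 ms in 8.1 ms steps.

`ratio_profile()` inner-joins per-residue T1 and T2 fits;
`segment_regions()` splits the profile at native residue 1, separating
the appendage (negative numbering) from the catalytic core.
`estimate_tau_c()` inverts the rigid isotropic tumbling forward model
`t1t2_ratio()`: $^{15}$N dipolar (r$_{NH}$ = 1.02 Å) plus CSA
(-160 ppm) with a single-Lorentzian spectral density (order parameter 1),
solved by monotone root finding on $\tau_c \in [1, 100]$ ns. All physical
constants are arguments, not hidden.

Two limitations are worth stating plainly. First, this minimal model at
850 MHz maps $\tau_c$ = 24 ns to T1/T2 ≈ 112, whereas measured core
ratios for proteins this size are reported around 200; absolute ratio
levels depend on exchange contributions, anisotropy and trimming choices
that are out of scope here. Only the *round-trip* property (forward model
then inversion recovers $\tau_c$ to 10$^{-3}$ ns) is claimed or tested.
Second, fit precision under additive noise is intrinsic, not a software
property: at 5% additive noise on the T1 grid with T = 500 ms the median
relative error of *any* unweighted least-squares fit is ~5.4% (measured
on a 4000-replicate ensemble); with noise proportional to the decaying
signal it is ~2.4%. The tests freeze those honest values.

## The synthetic world

`make_toy_protein()` builds a stylized single-chain protein: ideal-helix
C$\alpha$ geometry for the two anchor helices, an A-helix arm (residues
2--29) that can kink at residue 15, and a 19-residue appendage hinged at
residue 2, each residue carrying N, CA, C, O at fixed offsets. The pose
is *constructed from* target $(\theta_1, \theta_2, \theta_3)$:
$\theta_1$ and $\theta_2$ analytically, and the appendage azimuth for
$\theta_3$ by bracketed root finding to 10$^{-13}$, so the descriptor has
an exact forward oracle. When several azimuths satisfy the target, the
pose whose tip lies farthest from the $\theta_3$ dihedral axis is chosen:
a near-axis tip makes the dihedral ill-conditioned under coordinate
noise (this failure mode was observed and is regression-tested).

`make_trajectory()` draws a state sequence from the reversible chain
$T = \rho I + (1-\rho)\,\mathbf{1}p^\top$ ("stay with probability
$\rho$, else resample from the stationary populations $p$"), poses each
frame, adds isotropic Gaussian coordinate noise (default $\sigma$ =
0.2 Å), and by default applies a random global rotation and translation
to every frame so that no downstream stage can skip superposition.
Ground-truth labels are returned. Defaults mirror the stated world of
the source analysis: 50 ps frame spacing, a 200 ns equilibration cut,
a 5 Å cluster cutoff, and a dominant-state population of 0.62. The
demonstration states sit at (164, 82, 164), (119, 64, 100) and
(150, 110, 150) degrees: the published cluster-2 combination
(119, 98, 101) is geometrically unreachable in the toy anchor layout
(the reachable $\theta_3$ range narrows as $\theta_2$ grows), so the
second state keeps the bend and shear targets but uses a reachable
elevation. Inter-state backbone RMSDs are 7.8--14.8 Å, far above the
5 Å cutoff, with intra-state noise ~0.3 Å -- the separation regime the
recovery criteria presuppose.

What a green recovery test establishes: that clustering, transition
counting and the descriptor recover a *stated* well-separated Markov
ensemble. What it does not establish: behaviour on real MD data with
overlapping states, slow non-Markov transitions, or solvent effects --
the generator has no physics.

Population-recovery tolerances use binomial standard errors at the
*effective* sample size $n_\mathrm{eff} = n(1-\rho)/(1+\rho)$, because a
persistence-0.98 chain of 5000 frames carries roughly 51 independent
draws; using raw $n$ would understate the generator's own sampling noise.

The crystal-descriptor acceptance check deserves an honest caveat: the
real crystal structure (PDB 4WB7) cannot be downloaded in the offline
build environment, so the check runs on a **synthetic stand-in** -- the
toy protein posed at the published crystal angles -- and validates the
descriptor machinery, not the accession geometry. Given network access,
the identical check runs on the real file via
`angle_triple(read_pdb("4wb7.pdb"), map = numbering_map())`.

## Numerical choices

* PDB coordinates are fixed-format %8.3f; round trips are exact to
  3 decimals. Only ATOM/HETATM/MODEL/ENDMDL records are interpreted;
  alternate locations keep the highest occupancy, first on ties;
  an unnamed chain defaults to A.
* `kabsch()` rejects fewer than 3 pairs and near-collinear sets
  (second singular value below $10^{-12}$ of the first).
* Angle outputs are rounded to 0.1° in TSV/report output only; internal
  values are full precision.
* The simplex fit runs at `reltol` $10^{-14}$ with one restart, which
  reaches the 10$^{-6}$ relative recovery required on noiseless data.
* The equilibration cut keeps frames with time strictly greater than the
  cut (frame 1 is t = 0).
* Cluster-report angles are evaluated on each cluster's representative
  frame (not cluster means) -- matching how per-cluster angle summaries
  are tabulated downstream; the alternative is one `angle_series()` call
  away.

## Known limitations

No mmCIF or binary trajectory formats (DCD/XTC); no mass-weighted or
iteratively re-referenced superposition; no Markov-state-model estimation
beyond lag-1 counting; no energetic clash scoring; relaxation fitting is
unweighted and exchange-free. These are contract boundaries, not
oversights.
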