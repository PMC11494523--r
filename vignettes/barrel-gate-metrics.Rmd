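---
title: "Quantifying lateral-gate lipid egress in membrane beta-barrels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral-gate lipid egress in membrane beta-barrels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelgate)
```

## The scientific question

Several outer-membrane proteins of gram-negative bacteria are thought to
deliver hydrophobic cargo sideways into the membrane through a *lateral
gate*: an opening in the wall of a membrane-embedded beta-barrel. The
canonical example is LptD, which exports lipopolysaccharide; GfcD, the
multibarrel this package's defaults are tuned to, carries an unusual
13-stranded C-terminal barrel (GfcD-C) whose missing 14th strand leaves a
permanent aperture between strands beta-1 and beta-13. The mechanistic
claim such a gate supports is testable in molecular-dynamics trajectories:
the aperture should stay open, membrane lipids should *not* flood inward
through it, and the aliphatic tails of a lipid anchor (lipid A, the anchor
of group 4 capsular polysaccharides) placed in the channel should exit
laterally into the membrane.

`barrelgate` packages the trajectory observables that operationalise this
argument:

* **Gate aperture** — Calpha–Calpha distances for residue pairs spread
  along the gate, with a closure report.
* **Flicker depth** — how far membrane-lipid atoms penetrate inward past
  the gate plane.
* **RMSD / RMSF** — overall fold stability, via in-package Kabsch
  superposition.
* **Head tilt** — the angle between the lipid's PA→PB phosphorus vector
  and the membrane normal.
* **Insertion fraction and egress order** — how much of each aliphatic
  tail has crossed the gate plane into the membrane, and in what order
  tails complete their exit.
* **Contact score** — per-residue lipid-contact frequencies per replica,
  combined across replicas by a geometric mean.

Everything is exercised against a synthetic trajectory generator whose
ground truth is exact by construction, so every observable has a
machine-checkable oracle.

## Definitions and conventions

### Superposition, RMSD, RMSF

`kabsch()` computes the proper rotation and translation minimising
coordinate RMSD (SVD of the cross-covariance; a reflection-optimal case is
corrected to determinant +1). `rmsd_series()` superposes every frame
independently onto the reference frame over the chosen selection.

"Backbone" defaults to N, CA, C — carbonyl O excluded — matching the
convention of the common MD backbone group; `backbone_names(with_o =
TRUE)` widens it. On the Calpha-only synthetic systems the backbone
selection is just CA.

`rmsf_profile()` aligns frames to the starting frame, computes the mean
structure, re-aligns the original frames onto that mean (one alignment
iteration — the standard fluctuation definition), and reports per-atom
root-mean-square displacement from the mean, averaged within residues.
Whether fluctuations are reported per atom or per residue is a flag
(`per_atom`), residue-averaged by default. Mass weighting is deliberately
absent: on backbone-only selections its effect is negligible.

One numerical property worth knowing: a rigid fit absorbs six degrees of
freedom, so under ideal isotropic noise the recovered RMSF is biased low
by roughly a factor `1/N` for an `N`-atom alignment set. At the default
247-residue toy barrel this is ~0.4% and invisible at test tolerances; on
very small alignment sets (tens of atoms) it reaches several percent. The
parameter-recovery checks therefore use the full barrel.

### The gate and its plane

The gate is **user-declared**, never inferred from topology. The default
`gate_definition()` carries the three GfcD pairs 437–668, 433–666,
427–663, measured Calpha to Calpha. Pairs are matched by residue number
only; residue names found are logged but not checked (published residue
identities and numbering can disagree at one position, the numbers are the
stable citation).

`closure_report()` needs a notion of "closed", which the source analyses
leave qualitative. The default closure threshold is 6 Å — approximately
the Calpha–Calpha distance of beta strands in pairing contact — and the
report always prints the per-pair below-threshold fractions, so the
conclusion never hides the choice.

`fit_gate_plane()` is the geometric anchor of the lipid observables: the
least-squares plane through the gate-flank Calphas (smallest-variance
direction of their scatter), with the normal oriented *outward* by
requiring a positive projection of (centroid − axis point). The barrel
axis point is configuration, not inference.

**Flicker depth** is, per frame, the maximum of minus the signed plane
distance over membrane atoms near the gate (within `gate_region_radius`,
default 8 Å, of the nearest flank Calpha), clamped at zero. The plane
convention is a declared proxy — penetration could also be measured from
the flank residues or the channel axis; the plane was chosen because it is
the same reference the insertion fraction uses, making "in" and "out"
complementary by construction.

### Lipid observables

**Tilt** is the angle between the PA→PB head-phosphorus vector and the
reference axis (default +Z, the membrane normal), in degrees on [0, 180].
The direction PA→PB is a declared convention (the source defines the
vector by its endpoints only); `flip = TRUE` reverses it, mapping every
angle to 180° − θ. Coincident phosphorus atoms (vector < 1e-6 Å) yield a
missing value rather than an error, so one corrupt frame cannot kill a
long analysis. The histogram bin width defaults to 2.5°, which places the
boundary value 112.5° — the lower edge of the stabilised tilt band
reported for the complexed simulations — exactly on a bin edge.

**Insertion fraction** counts tail heavy atoms on the outward side of the
oriented gate plane (signed distance > 0), per tail and overall; the
overall value is the atom-weighted mean of per-tail fractions. The source
measured a lipid *area* fraction with a visualisation tool; this package
deliberately uses the atom-count fraction across the gate plane instead:
the area method is underspecified (probe radius, surface algorithm), while
the atom-count proxy is deterministic, testable, and monotone in the same
egress events at tail resolution. Outputs label it "atom-fraction".
Tails-only is the default scope — the head group is expected to remain in
the channel while the tails exit. A lateral plane rather than a membrane
z-slab is used so that in-channel atoms (which sit at membrane depth but
inside the barrel) are never miscounted as inserted.

**Egress order** reports, per tail, the first frame at which its fraction
reaches `exit_threshold` (default 0.9 — "essentially fully out" while
tolerating one straggling atom on a 5–14-atom tail); ties are broken by
tail index.

### Contact analysis

A residue is in contact in a frame iff any heavy-atom pair (lipid,
residue) sits within the cutoff, 4.0 Å by default — the source does not
state its cutoff, so the common heavy-atom convention is used and echoed
in every output header. Contact is binary per frame; the per-replica
frequency is the fraction of frames in contact, and the cross-replica
score is the geometric mean of those frequencies. The geometric mean is
the point: it is exactly zero when any replica lacks the contact, so the
score table automatically isolates *reproducible* interactions, and it
never exceeds the arithmetic mean (AM–GM). Hydrogens are excluded by the
element field, with a name-based fallback (leading-H names) and a warning
when elements are absent.

`annotate_scores()` writes per-residue scores into every atom's score
slot, and `write_annotated_pdb()` emits them in the B-factor column
(range [−9.99, 999.99], two decimals), ready for colouring in a viewer.

## The synthetic generator

`synthetic_spec()` + `generate_trajectory()` build a Calpha-only barrel of
13 strands of 19 residues on a 12 Å cylinder, with one strand slot left
vacant so the first and last strands straddle a planar lateral opening;
residues are numbered from 424 so the default gate pairs land on the
flanking strands. The surrogate lipid is pure bookkeeping: two phosphorus
pseudo-atoms whose vector realises the tilt schedule exactly; six tails of
pseudo-atoms placed on either side of the construction's analytic gate
plane so per-frame inserted-atom counts match the egress schedule exactly;
per-residue contact probes that sit 3 Å from their (fluctuating) target
Calpha in exactly the scheduled fraction of frames, plus hydrogen decoys
that are *always* in range — counting them is a detectable bug; and a
membrane pseudo-atom reproducing the flicker schedule. Protein Calphas
receive i.i.d. per-coordinate Gaussian noise (`fluct_sigma`), giving the
closed-form RMSF target σ√3.

Randomness is seed-scoped: the noise stream is the only consumer of the
RNG, drawn in a single scoped block, so adding or removing scheduled
stages never perturbs it; replicas offset the seed deterministically.
Identical spec and seed give bit-identical trajectories.

`default_study_spec()` freezes the package's stand-in for the study
conditions (three complexed replicas): 200 frames at 2 ns spacing,
fluctuation σ = 0.3 Å, tilt relaxing from 90° to per-replica plateaus of
120°/150°/172° (inside the reported 112.5°–180° band), a sequential
six-tail egress in which replica 2 completes while replicas 1 and 3 stall
after the leading tails (replica 1 with a transient retreat of its second
tail), reproducible contacts on the six gate-pair residues plus one
single-replica contact that the geometric score must erase, and occasional
membrane flickers never deeper than ~3.8 Å. The 200-frame, 247-residue
scale keeps a full three-replica pipeline run near ten seconds while
exercising every code path; the RMSF recovery checks use 5000 frames where
the Monte-Carlo error of the σ√3 estimate falls below ~1.5%.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: there is no force field, no membrane
thermodynamics, no water, no correlated motions, no side chains; noise is
isotropic and frame-independent, whereas real fluctuations are
anisotropic and autocorrelated; contacts are realised by probes rather
than emerging from packing. The generator validates the *measurement*
machinery, not the biophysics.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; collinear sets raise a
  degeneracy error rather than returning an arbitrary rotation.
* Plane fitting rejects collinear flank sets the same way (two near-zero
  eigenvalues).
* Trajectories are topology-immutable: every model in a multi-model PDB
  must carry the same atom set, enforced at read time with a line-level
  pre-scan (malformed records are reported with their line number;
  insertion codes are rejected; the first altloc is kept).
* Fixed-width PDB carries 3-decimal coordinates and 2-decimal B-factors;
  round-trips are exact only to those precisions, and the pipeline tests
  assert at format-limited tolerances rather than machine epsilon.
* Replicas of unequal length are truncated to the shortest at aggregation,
  with a warning; mixed gate definitions are an error, not a warning.
* All output tables embed a configuration fingerprint and the active
  cutoffs as `#` comments; nothing in the header depends on time or file
  location, so identical inputs give byte-identical outputs.

## Limitations

Binary trajectory support is limited to a DCD adapter behind the same
trajectory contract; the reference interchange format is multi-model PDB.
There is no secondary-structure assignment, clustering, PCA, hydration
analysis, or free-energy estimate of egress — the package quantifies the
geometric observables of the lateral-exit mechanism and stops there.
Applying the defaults to proteins other than GfcD requires redeclaring the
gate pairs, flank residues, and domain map; nothing is auto-detected.
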