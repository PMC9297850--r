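---
title: "Methods: prochiral-face, contact and H-bond analysis of MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prochiral-face, contact and H-bond analysis of MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomd)
```

`stereomd` analyses conformational ensembles of ternary
enzyme–cofactor–substrate complexes to explain stereoselectivity in
hydride-transfer enzymes such as imine reductases (IREDs). This vignette
is the package's own account of the underlying models, the parameters
that matter, the synthetic-data generator used for validation, and the
design decisions taken where the methodology was genuinely open.

## 1. Prochiral face classification

A planar sp² carbon flanked by three distinct substituents has two
prochiral faces, named *re* and *si* by the Cahn–Ingold–Prelog (CIP)
convention: looking at the face, the face is *re* if the substituent
priorities decrease clockwise. For an imine being reduced, the face the
nicotinamide hydride approaches decides the configuration of the product
amine, so classifying the face presented to the nearest hydride, frame by
frame, summarizes the stereochemical outcome a binding mode would give.

**Priorities.** `rank_substituents()` implements a bounded CIP subset:
each substituent branch is grown breadth-first from the center;
per-sphere multisets of atomic numbers (sorted decreasing, missing
positions ranked as phantom atoms of atomic number 0) are compared
lexicographically; double bonds contribute phantom duplicate atoms on
both ends and ring closures contribute childless duplicates; the search
stops at 6 spheres. Isotopes and stereo-descriptors are not considered —
sufficient for small cyclic imines and ketones, and the test suite pins
the ranking to an independent full-CIP implementation on a 12-molecule
panel (the four study substrates — 2-methylpyrroline, 2-methylpiperideine,
2-phenylpiperideine, 1-methyl-3,4-dihydroisoquinoline — plus eight
others, including two deliberate ties). Branches still tied at depth 6
raise a tie flag and the caller must state the order explicitly; the
package never guesses.

**Geometry.** With substituent positions $a, b, c$ in decreasing
priority, center $x$ and probe $p$ (the hydride position),

$$ n = (a - x) \times (b - x), \qquad s = \operatorname{sign}\big(n \cdot (p - x)\big), $$

and the face toward the probe is *re* for $s < 0$, *si* for $s > 0$. Two
degeneracies are labelled `indeterminate` rather than forced: a
pyramidalized center (out-of-plane displacement of $x$ from the plane of
$a,b,c$ above `planarity_tol`, default 0.25 Å — a conservative bound for
a moiety modelled as planar) and an in-plane probe
($|\hat n \cdot (p-x)|$ below 0.05 Å). Both thresholds are arguments of
`prochiral_spec()`. The classifier is validated against an independent
signed-tetrahedron-volume oracle on 1000 random poses and for exact
SE(3) invariance and mirror antisymmetry.

**Probe choice.** The probe is the hydride *hydrogen*, selected per frame
as the candidate (by default the two nicotinamide C4 hydrogens) nearest
to the prochiral carbon, with exact ties broken toward the lower atom
index. MD frames carry hydrogens, so no heavy-atom proxy is needed; for
hydrogen-free input the C4 carbon can be supplied as the candidate
selection instead. Choosing the hydride per frame (rather than fixing it
per trajectory) reflects that the cofactor can flip during a run; a
fixed-hydride analysis can be had by passing a single-atom selection.

## 2. Close contacts and the per-residue report

A residue "contacts" the substrate imine nitrogen in a frame when the
minimum distance from its side-chain hydrogens to the nitrogen is
**strictly below** the cutoff (default 2.5 Å; a frame at exactly 2.5 Å is
not a contact). Backbone hydrogens are excluded by default because the
mechanistic question is about side-chain proton donors; a `polar-only`
policy further restricts to hydrogens on N/O/S heavy atoms. Per-replicate
frequencies are combined by an unweighted arithmetic mean, which is the
right pooling for replicates of equal length.

`contact_report()` cross-tabulates contacts with face labels. The re : si
ratio printed per residue is **conditioned on that residue's contact
frames** — the frames in which that residue could actually protonate the
nitrogen — because that is the quantity that links a binding mode to a
product enantiomer. Since conditioning conventions differ between
reports, the unconditional whole-trajectory ratio is emitted in a
separate column rather than silently chosen. Indeterminate frames are
counted separately and conserved
($n_{re} + n_{si} + n_{ind}$ = frames considered); an
`exclude_indeterminate` flag drops them before counting, as both
conventions exist in practice.

The face-label-to-product-chirality mapping (*re* → (*R*) or *re* →
(*S*)) is deliberately **not** hard-coded: it depends on the substituent
priorities of the product amine, which differ between substrates. Reports
print face labels; the mapping belongs in per-substrate configuration.

## 3. Dyad hydrogen bonding over distance

Hydrogen bonds are detected geometrically: donor–acceptor distance
$\le$ `max_da` (default 3.5 Å) **and** D–H···A angle $\ge$ `min_angle`
(default 120°). These are the common geometric criteria in MD analysis;
both are exposed because published analyses vary and the package's
validation depends only on planted synthetic values, not on the defaults.
For a serine→aspartate dyad, a frame is bonded if **either** carboxylate
oxygen satisfies the criterion (counted once); the direction is
reversible through the selections.

`hbond_profile()` reports the bonded fraction per donor–acceptor distance
bin (half-open `[lo, hi)` bins, default 0.1 Å wide over 2.2–5.0 Å,
extended automatically to cover all observed distances). Frames beyond
`max_da` still populate their distance bin — the distance axis must be
complete for the profile to show *why* bonding drops off — while bins
with no frames report `NA`, distinguishing "no data" from "never
bonded". The conservation identity
$\sum_b \text{count}_b \times \text{freq}_b = \text{total bonded frames}$
is tested.

## 4. Helix rotation between binding modes

To measure how a short binding-site helix (five residues in the
motivating case) reorients between two variants, structure B is
superposed onto structure A by Kabsch superposition (SVD with determinant
correction, so a reflection is never returned) over an anchor Cα set —
typically the cofactor-binding (Rossmann) domain, which is the rigid
common frame. The angle is
$\arccos\,|\hat u_A \cdot \hat u_B'| \in [0°, 90°]$, absolute-valued to
remove the axis-sign ambiguity.

**Axis fitting.** The axis of a 5-residue segment cannot be estimated
robustly by principal components: for one-to-two turns the centered
covariance eigenvalues are nearly degenerate (22.9 / 13.4 / 11.1 for the
ideal 5-point helix), and at 0.3 Å coordinate noise the PCA axis wanders
by ~16° on average — swamping a 15° signal. `helix_axis()` therefore
fits, by Kabsch, an ideal α-helix Cα template of the same length (rise
1.5 Å, twist 100° per residue, radius 2.3 Å — canonical α-helix
geometry) and carries the template's axis through the fitted rotation:
axis error ~3.6° per structure at the same noise, and an unbiased angle
estimate (15.2° mean over 100 noisy 15° pairs). The template assumes the
segment *is* α-helical; `method = "pca"` remains available for long or
non-canonical helices, and is selected automatically for collinear
input, where no helix exists to fit.

## 5. Polar cofactor fingerprints

Crystal structures usually lack hydrogens, so cofactor-anchoring
interactions are enumerated as heavy-atom donor/acceptor proximity:
protein side-chain N/O atoms within 3.5 Å of ligand N/O/P atoms.
`fingerprint_diff()` compares two structures keyed on (residue, protein
atom, ligand atom), which exposes, e.g., how a phosphate-loop mutation
rewires 2′-phosphate recognition. This is a proximity screen, not an
energetic H-bond assignment.

## 6. The synthetic-ensemble generator

Published MD trajectories are rarely deposited, so validation rests on
`generate_ternary_ensemble()`: a minimal ternary-complex topology — a
planar 2-methylpyrroline-like substrate (correct substituent
connectivity, so the CIP ranking gives ring-N > ring-CH₂ > methyl), a
nicotinamide-like fragment with two C4 hydride hydrogens, donor residues
with side-chain hydrogens, and a serine/aspartate dyad — in which every
downstream statistic is *planted* per frame:

- the face label places the nearest hydride 2.8 Å off the chosen face;
- each residue's contact hydrogen sits at 2.0 Å (contact) or 3.2 Å
  (no contact) from the imine N — both at least 0.5 Å clear of the 2.5 Å
  cutoff;
- the dyad hydrogen lies on the D→A line (angle 180°) for bonded frames
  and behind the donor (angle ≈ 0°) otherwise, at a donor–acceptor
  distance drawn uniformly from `da_range` (default 2.6–3.0 Å);
- optionally, a drawn fraction of frames pyramidalizes the center by
  0.75 Å (three times the planarity tolerance), making exactly those
  frames indeterminate;
- the whole frame then receives a random rigid motion and isotropic
  Gaussian coordinate noise.

The generator refuses `noise_sigma` above 0.05 Å (a quarter of the 0.2 Å
guard band between the placement margins and the cutoff), so planted
flags survive the noise and recovery tests can assert *exact* per-frame
agreement, not merely statistical closeness. Randomness is a single
seeded Mersenne-Twister stream (inversion for normals), restored on
exit, and the seed is mandatory — identical recipe and seed give
bit-identical ensembles on any platform.

**Default conditions.** The defaults encode the study conditions the
generator emulates: re-face fraction 0.548 and per-residue contact
occupancies {S95: 3.6·10⁻⁵, D171: 5.2·10⁻⁵, W179: 0.084}, matching a
representative reported system; dyad H-bond occupancy 0.8 over 2.6–3.0 Å
(the reported profiles print no numeric values, so this is the
validation calibration); 2000 frames per replicate and ten replicates
(per-replicate frame counts are not published; 2000 gives binomial
standard errors of ~1 % on the planted fractions, which is the precision
the recovery tests assert at 3 SE).

**What passing tests do and do not show.** The generator reproduces the
*statistical* structure of an MD ensemble — occupancies, face fractions,
replicate structure, coordinate noise, rigid tumbling — but not its
physics: no force field, no autocorrelation between frames, no solvent,
no conformational coupling between the planted channels. Recovery of
planted values therefore validates the *measurement* pipeline
(selections, geometry, counting, aggregation), not the realism of any
particular MD protocol; on real trajectories, frame autocorrelation
means the binomial standard errors used in the tests would understate
the true uncertainty of occupancy estimates.

## 7. Numerical choices and degenerate inputs

- Exact distance ties in `nearest_hydride()` break toward the lower atom
  index (deterministic replays).
- `classify_face()` raises a geometry error for a zero-area substituent
  triangle, rather than guessing.
- Kabsch requires ≥ 3 non-collinear points and reports rank-deficiency
  as a geometry error; the determinant correction guarantees det = +1.
- Profile bins are half-open `[lo, hi)`; the contact criterion is a
  strict `<`; the H-bond criterion uses `≤`/`≥` — each stated in its
  function's documentation so boundary frames are reproducible.
- Empty selection matches are legal and distinct from selection-syntax
  errors; pipeline runners resolve every configured role against the
  topology before any frame is processed and fail with the role's name.
- Report files carry no timestamps, so reruns are byte-identical.

## 8. Problem sizes

The shipped tests and the acceptance script run entirely on generated
data at the sizes chosen for the validation design: 1000 random poses for
the face-classifier and invariance checks, 2000-frame ensembles (a 3×3
grid of re-fraction × occupancy recipes; ten replicates in the
acceptance script), 100 seeds for the noisy helix-angle sweep. At these
sizes the binomial 3 SE bands the tests assert are ±3 % or tighter.

## 9. Known limitations

- The CIP subset ignores isotopes and stereo-descriptor tie-breaks;
  exotic centers that require them are reported as ties instead of
  being mis-ranked.
- The selection language covers chain/resid/resname/name/element/serial
  with boolean algebra — no distance-based or sequence-motif selections.
- Ensemble input is text (multi-model PDB, XYZ); binary trajectory
  formats are out of scope by design and belong in optional adapters.
- The helix template fit presumes canonical α-helix geometry for short
  segments; strongly distorted helices should use `method = "pca"` with
  a longer residue range.
- Contact statistics treat frames as independent; no autocorrelation or
  block-averaging correction is applied.
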