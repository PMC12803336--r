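---
title: "Assessing scoring functions for docked protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing scoring functions for docked protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscore)
```

# The problem

Rigid-body re-docking of a heterodimer — re-assembling the bound
conformations of two monomers into their complex — leaves only six pose
degrees of freedom, so generating candidate models is easy and the open
question is entirely one of *scoring*: can a scoring function rank
near-native poses above the rest? `ppiscore` provides the measurement
apparatus for that question: a ground-truth quality metric (DockQ), the
interface features that make targets easy or hard to score, a sampling
protocol that makes correlation and classification statistics comparable
across targets, and generators for synthetic inputs so every computation
can be exercised end to end at desk scale.

This vignette records the models implemented, the parameters that matter,
the numerical conventions, and what the synthetic fixtures do and do not
establish about real structures.

# Structures and interface definitions

A structure is a two-chain heavy-atom table. On reading PDB input we keep
`ATOM` records only, drop waters, ions and other heteroatoms, keep
alternate location ' ' or 'A' only (a deterministic single-conformer
model), and remove hydrogens and deuterium. Residue identity is the
triple (chain, residue number, insertion code). The receptor is the chain
with more residues, ties broken by lexicographic chain id. The original
datasets assign receptor and ligand "as in the target PDB file", which is
not machine-decidable from coordinates alone; the size-then-id rule is
deterministic, is applied to the target, and is inherited by every model
of that target, which is what the downstream statistics require.

Two interface definitions coexist, deliberately:

* **DockQ interface** — residues of the *native* with any heavy atom
  strictly closer than 10 Å to the partner chain. Computed on the native
  only and applied to both structures (the standard DockQ convention).
* **ΔrSASA interface** — residues whose relative solvent accessibility
  drops when the partner chain is present. Since occlusion is monotone
  (adding atoms can only block more of the probe sphere), ΔrSASA ≤ 0
  holds exactly residue by residue with a common point lattice, and the
  strict inequality ΔrSASA < 0 flags exactly the residues burying any
  surface. This definition feeds the conformational-change iRMSD and the
  separability point sets.

SASA uses the Shrake–Rupley algorithm with a deterministic golden-spiral
lattice of 960 points per atom, probe radius 1.4 Å, and Bondi heavy-atom
radii. Reference areas for relative SASA are extended Gly-X-Gly
tripeptide values. 960 points resolve per-atom areas to well under the 2%
level that the two-sphere closed form verifies in the tests.

# DockQ

DockQ averages three terms in [0, 1]:
Fnat, 1/(1 + (LRMSD/d1)²) and 1/(1 + (iRMSD/d2)²), with d1 = 8.5 Å and
d2 = 1.5 Å. Conventions worth stating:

* Contacts (native 5 Å, features 4.5 Å) and interface membership (10 Å)
  all compare with strict `<`.
* Fnat counts heavy-atom pairs, identified by (chain, residue, atom
  name); a residue-pair mode is available (`by_residue = TRUE`) for
  compatibility with implementations that collapse contacts to residue
  pairs.
* Backbone means {N, CA, C, O}; OXT is excluded. (The synthetic toy
  chains carry CA only, which the atom-matching machinery handles
  transparently.)
* LRMSD superposes receptor backbones, then measures the ligand backbone
  deviation *without* further fitting; iRMSD superposes and measures on
  the same interface backbone set.
* Superposition is the Kabsch algorithm restricted to proper rotations.
  `kabsch_superpose()` rejects < 3 points and collinear sets (the
  rotation is ill-defined); interface-RMSD internals use the unguarded
  core, because a rank-deficient point set still has a well-defined
  minimum RMSD even though the rotation achieving it is not unique —
  flat interfaces genuinely produce collinear interface C-alpha sets.

# Physical features

**N_c** is the number of cross-chain heavy-atom pairs closer than
d_c = 4.5 Å. A cutoff scan utility (`contact_cutoff_scan()`) exposes the
1–30 Å sweep used to justify that choice, but the cutoff-selection
benchmark on real targets is out of scope here.

**Separability S** is the *training* accuracy of a degree-3
polynomial-kernel soft-margin SVM predicting chain labels from atom
coordinates. Unstated conventions had to be fixed; they are: training
accuracy (not cross-validated — "perfectly separable" must map to
exactly 1), cost 1.0, kernel (γ·x·y + 1)³ with γ = 1/3 on standardized
coordinates, balanced class weights. The point set is the heavy atoms of
ΔrSASA-interface residues, falling back to all heavy atoms when the
interface is empty or very small (< 10 atoms per chain) so that
far-apart decoys remain scoreable; the choice is switchable
(`interface_only = FALSE`). libsvm training is deterministic given the
data, so S is reproducible without seed juggling.

**The two-feature SVR score** regresses DockQ on standardized (N_c, S)
with a Gaussian kernel. The hyperparameters are not dictated by the
source analyses, so conventional defaults are declared: γ = 0.5 (the
1/(2·variance) heuristic at unit variance), cost 1, ε-tube 0.1, all
exposed as arguments. Because the SVR predicts DockQ, its orientation is
higher-is-better — the opposite of energy scores — and evaluation calls
must set `lower_is_better` accordingly. Generalization is evaluated
leave-one-target-out (`svr_leave_target_out()`), the natural protocol
when targets are the exchangeable unit.

# The DockQ landscape and κ²

Each model is superposed on the native receptor C-alpha set; the ligand
C-alpha center of mass, translated to the native receptor frame, is
reduced to a direction (θ from +z, φ from +x) and plotted at the common
radius R — the native receptor–ligand C-alpha COM separation ("projected
R" convention: the landscape records *where* the ligand sits, not how
far). Centers of mass are unweighted C-alpha means; ligand orientation is
ignored. The inertia tensor of the point cloud, weighted by DockQ³ to
emphasize native-like models, gives eigenvalues λ₁ ≤ λ₂ ≤ λ₃ and

κ² = 1 − 3(λ₁λ₂ + λ₂λ₃ + λ₁λ₃)/(λ₁ + λ₂ + λ₃)².

κ² is symmetric in the eigenvalues, so the ascending-versus-descending
ordering ambiguity in the source material is immaterial; ascending is
used. Useful exact anchors, all asserted in the tests: equal eigenvalues
give 0; a single nonzero eigenvalue gives 1; a point cluster at one
direction gives λ = (0, m r², m r²), hence exactly 0.25. An all-zero
spectrum (every weight zero) has no defined anisotropy and is reported as
`NA` by the tensor summary, an error from `relative_anisotropy()`.

# Sampling protocol

DockQ bins are half-open [k/20, (k+1)/20) with the last bin right-closed
so DockQ = 1 lands in bin 19. Uniform subsampling keeps at most 50 per
bin, drawn without replacement. Balancing adds up to 1000 negatives from
the un-selected pool, then randomly trims the majority class to an exact
1:1 ratio; positives are DockQ ≥ 0.23, inclusive, exactly as the cutoff
is conventionally printed. Whether balancing should trim the majority or
top up the minority is not specified anywhere; random majority trimming
was chosen because it never manufactures duplicate records. The energy
minimization step that sits between subsampling and balancing in the
original pipeline requires an external engine and is a deliberate no-op
here.

# Evaluation statistics

* **Spearman ρ** is the Pearson correlation of average-tied ranks. Energy
  scores correlate negatively with DockQ; ρ is reported signed and never
  auto-flipped, so orientation stays the caller's explicit decision.
* **AUC** is the Mann–Whitney pair-counting form (ties half credit),
  with an orientation flag that negates scores first.
* **Hit rate h(R)**: fraction of targets with ≥ 1 positive in the top R;
  ties in rankings are broken by stable input order.
* **Effective hit rate h_k(R)**: fraction of Ns random subsets of size
  Nm whose top R contain a positive. The printed formula in the source
  carries a 1/N⁺ normalization that contradicts its own prose
  ("fraction of draws with at least one positive"); the prose is
  implemented, the discrepancy documented rather than resolved.
* **μ**: fraction of models that are negative and *strictly* outrank
  every positive. Any μ > 0 forces h_k(R) → 0 as Nm → Nt once the
  dominating negatives outnumber the rank window, which the acceptance
  suite demonstrates at Nt = 20 000, Ns = 200, R = 100.

For DockQ-uniform, class-balanced ensembles, AUC and ρ are linearly
related (AUC ≈ −0.5ρ + 0.5); the acceptance suite recovers slope and
intercept by regression across 30 synthetic targets of 2000 models each.

# Bound–unbound interpolation

Matched conformer pairs come from global sequence alignment (BLOSUM62,
gap open 10, extend 0.5): unaligned termini are trimmed, substituted
residues dropped, and residues whose heavy-atom name sets differ between
conformers dropped. Identity below 30% — measured as matches over the
shorter chain length, so gap-riddled alignments cannot pass — rejects the
pair. The unbound conformer is Kabsch-superposed onto the bound one
*before* the displacement matrix is formed; without this, the
"deformation" field would be dominated by global pose and the
interpolation images would mostly translate. This choice is not forced by
the defining equations, which are silent on the frame, and it is the
single most consequential convention in the module; `superpose = FALSE`
recovers the raw subtraction. Missing-residue reconstruction (an external
fixer in the original workflow) is replaced by residue dropping — a
deliberate divergence that changes which atoms enter the displacement
field but not the interpolation algebra.

Images are I_n = bound + (n/N_I)·D for n = 0..N_I inclusive, so both
endpoints are recovered exactly (to floating precision; the tests assert
identity at n = 0 and 1e-12 at n = N_I). N_I defaults to 6; `"auto"`
raises it until the inter-image spacing |D|/N_I ≤ 1 Å, where |D| is the
root-mean-square per-atom displacement (the matrix norm is otherwise
unspecified). iRMSD along the path uses the ΔrSASA interface of the bound
dimer and is normalized by the unbound endpoint to give iRMSD*, with
iRMSD*(N_I) = 1 by construction; a zero-deformation pair leaves iRMSD
identically zero and iRMSD* undefined (reported as 0/NA rather than
invented).

# What the synthetic generators emulate — and what they do not

`make_toy_dimer()` builds each chain as a self-avoiding serpentine of
C-alpha + pseudo-C-beta atoms on a 3.8 Å lattice (the virtual bond length
of real protein backbones), three layers deep per chain, packed against a
shared boundary. `intertwine = 0` leaves the boundary flat;
`intertwine = 1` corrugates it with a triangle wave (period 8 columns,
amplitude 2 layers), producing mutually interdigitated fingers. The
default 96 residues per chain reflects the ≥ 50-residue floor of curated
heterodimer sets while keeping SASA and SVM fits fast. Pseudo-side-chain
directions carry a small seeded jitter; bonds are exactly 3.8 Å within
columns and at most √2·3.8 Å at column turns.

These toys are *geometric*, not physical: no side-chain chemistry, no
packing energetics, no sequence realism (homopolymer alanine). They
exercise every computation — contacts, SASA burial, separability, DockQ
mechanics, landscapes — but a passing test says nothing about scoring
accuracy on real interfaces, force-field behavior, or the distribution of
N_c and S in crystal structures.

`make_decoy_set()` applies random rigid ligand perturbations with
log-uniform magnitudes (rotation up to 180°, translation up to 50 Å),
scores every candidate with `dockq()` itself, and stratified-rejects into
0.05-wide bins so the ensemble spans the full DockQ range; the
zero-perturbation decoy anchors DockQ = 1. DockQ values are therefore
always products of the metric, never synthesized numbers.

`make_score_dockq_dataset()` draws DockQ uniform (optionally balanced
1:1 at 0.23) and builds a score as ±DockQ plus Gaussian noise, with the
noise amplitude calibrated by bisection on the measured Spearman ρ
(to within 0.005 of target before μ injection). Exactly ⌈μ·n⌉ negatives
are then re-scored to strictly outrank every positive; this perturbs ρ,
so the re-measured value travels with the dataset as an attribute. At
μ = 0 the guarantee runs the other way: any negative that outranks all
positives by chance is nudged just behind the best positive, so the
constructed μ is exact in both directions.

# Problem sizes and numerical conventions

The test and acceptance runs use toy dimers of 40–96 residues per chain,
decoy ensembles of 120–500 models, synthetic score tables of 2000–20 000
rows, 30 targets for the AUC–ρ regression, and 1500 points per chain for
the interleaved separability check — sizes chosen so the full suite
completes in a few minutes on one core while every statistic sits well
inside its sampling tolerance. Other conventions: coordinates are
Angstrom throughout; PDB round trips are exact to the format's 10⁻³ Å;
rotation matrices are proper to 10⁻⁸; all stochastic steps take explicit
integer seeds and are bit-reproducible under them.

# Known limitations

* Receptor/ligand assignment can disagree with deposited annotations for
  near-equal chains; the rule is deterministic but not authoritative.
* S depends on the fixed SVM conventions above; a different cost or
  kernel constant shifts absolute values (the 1.0 / 0.5 anchors are
  robust, intermediate values are convention-dependent).
* Linear Cartesian interpolation is not a physical morph: images can
  transiently compress bonds, and no relaxation is applied.
* Multimeric (> 2 chain) complexes, mmCIF input, multi-model NMR files
  and hydrogen placement are out of scope.
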