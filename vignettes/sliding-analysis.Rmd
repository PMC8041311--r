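---
title: "Sliding versus hopping: the model behind slidescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding versus hopping: the model behind slidescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidescope)
```

# The physical picture

A DNA-binding protein diffusing along a duplex can translocate in two
qualitatively different ways. When it remains engaged with the major
groove, translation forces rotation about the helical axis: one full turn
per helical pitch (34 Å, 10 bp for canonical B-DNA). When it instead makes
micro-dissociations and rebinds (hopping), translation and rotation
decouple. The package quantifies this with the θ/Z statistic: θ is the
unwrapped azimuth of the tracked centre of mass around the DNA axis
(`atan2(y, x)` with 2π-jump correction), Z its height along the axis, and
an ordinary least-squares line through all frames gives the coupling
slope. Groove tracking corresponds to |slope| = 2π/34 ≈ 0.18 rad/Å;
decoupled diffusion to slope ≈ 0.

# The coarse-grained model

**Protein.** One bead per residue at the Cα position. The native (input)
conformation defines the minima of all bonded terms — bond lengths b⁰,
angles θ⁰, dihedrals φ⁰ — and the native-contact list: residue pairs at
sequence separation ≥ 3 with any heavy-atom pair within 4.5 Å, each
rewarded by a 12-10 potential with minimum at the native Cα–Cα distance
A_ij. This is a native-topology (Gō-type) model: the folded structure is
the energy minimum, and diffusion on DNA is driven by electrostatics and
shape, not by sequence-specific chemistry.

**DNA.** A static, linear, ideal B-DNA on the Z axis, three beads per
nucleotide (phosphate, sugar, base), rise 3.4 Å and twist 36° per bp. The
phosphate bead carries −1 e; other beads are neutral. Bead placements use
an internal idealized geometry table (phosphate at radius 8.9 Å, sugar at
6.9 Å, base at 2.3 Å, with azimuthal offsets of ±74°, ±55° and ±18° for the
two strands), so the two phosphate tracks are separated by 148° across the
minor groove and the major-groove centre lies opposite the base-pair
reference azimuth. Only this relative geometry — groove shape and charge
spacing — matters for the model's physics; the beads are not atomistic
group centroids from any particular crystal structure.

**Energy terms and constants** (kcal/mol units, Å distances):

| term | form | constant | default |
|------|------|----------|---------|
| bonds | K_b (b−b⁰)² | K_b | 100 kcal mol⁻¹ Å⁻² |
| angles | K_a (θ−θ⁰)² | K_a | 20 kcal mol⁻¹ |
| dihedrals | K_d[(1−cos Δφ) + ½(1−cos 3Δφ)] | K_d | 1 kcal mol⁻¹ |
| native contacts | K_c[5(A_ij/r)¹² − 6(A_ij/r)¹⁰] | K_c | 1 kcal mol⁻¹ |
| repulsion | K_rep (C_ij/r)¹² | K_rep | 1 kcal mol⁻¹ |
| electrostatics | K_el B(κ) q_i q_j e^{−κr}/(ε_r r) | K_el, ε_r | 332 kcal Å mol⁻¹ e⁻²; 70 |

C_ij is the sum of the two bead radii (2.0 Å per bead by default, for DNA
beads as well — only the backbone value is fixed by the model family, and
`build_bdna()`/`coarse_grain_protein()` expose the radius). The functional
forms are the canonical native-topology choices; they are isolated behind
the `ff_params()`/`cg_system()` interface so alternatives can be swapped.

**Interaction rules.** Protein pairs closer than 4 in sequence on one
chain are covered by bonded terms and excluded from nonbonded
interactions. Native-contact pairs get the 12-10 term only (no added
repulsion or Debye–Hückel; at one charge per residue this affects only the
rare charged contact pair). All other pairs — including every protein–DNA
pair — interact by repulsion plus, when both beads are charged,
Debye–Hückel. There are no protein–DNA native contacts and no
sequence-specific attraction. DNA–DNA interactions are constant (the
duplex is rigid) and skipped.

**Electrostatics.** κ is the inverse Debye length of a monovalent salt,
κ² = 8π l_B n with l_B the Bjerrum length at ε_r = 70 and 300 K, so
κ ≈ 0.035 Å⁻¹ at 0.01 M and scales as √C. The salt-dependent coefficient
is B(κ) = exp(κa)/(1+κa) with ion-exclusion radius a = 4.2 Å (a typical
Debye–Hückel ion-size parameter; B → 1 as κ → 0, and the sliding/hopping
contrast is driven by κ, not by the exact a). Because one bead subsumes a
whole residue, the effective salt concentration of the coarse-grained
model may correspond to a severalfold higher atomistic value; the
user-facing knob is the nominal concentration, and this caveat is the
reason the package's toy systems transition with charge neutralization
more readily than with salt (see below).

# Dynamics

Langevin dynamics with the BAOAB splitting: half kick, half drift,
full Ornstein–Uhlenbeck velocity update with exp(−γΔt) decay and thermal
noise, half drift, half kick. Defaults: reduced temperature T = 0.4
(k_B = 1, so k_BT = 0.4 kcal/mol — below the folding temperature of the
modelled proteins), friction γ = 0.05, time step Δt = 0.005, unit bead
masses. The stiff K_b = 100 bond terms set the step-size ceiling; Δt =
0.005 keeps bonded energies stable over 10⁷ steps, and a per-step
displacement guard (2 Å) aborts with the last stable frame rather than
propagating an overflow. A Verlet neighbour list (skin 4 Å, rebuilt on
half-skin displacement) is used when an electrostatic cutoff is set; the
dynamics default is a 30 Å cutoff (the screened interaction at 30 Å and
κ(0.01 M) is below 2×10⁻³ kcal/mol per unit-charge pair), while energy and
force evaluations for testing default to no cutoff.

**Geometry and boundaries.** The duplex axis is Z. The published
confinement box (300 Å) is smaller than a 100-bp duplex (≈337 Å), and the
original protocol for the DNA ends is unstated; the package instead treats
the duplex as effectively infinite — protein–DNA distances are
minimum-imaged along Z with period equal to the DNA length, and the
protein's Z coordinate is left unwrapped so the analysis sees a continuous
translocation. X and Y are bounded by reflecting walls (edge 300 Å by
default), which bounds excursions after dissociation. This is a documented
deviation of unclear magnitude from the original box treatment, not an
inference about it.

**Sign convention.** θ is measured with the two-argument arctangent of
(y, x). In that frame the builder applies the azimuthal advance with
handedness −1 (equivalent to viewing a right-handed duplex down the −Z
axis), so the major-groove track obeys θ = −(2π/34)·Z and sliding produces
the conventional negative slope. `groove_azimuth()` exposes the track; the
`handedness` argument flips it.

# The estimators

**Coupling fit.** Ordinary least squares of θ on Z over all frames of one
trajectory, with the residual-based standard error and R². Replicates are
combined by the unweighted mean of per-trajectory slopes ± its standard
error across replicates — matching the convention of error bars estimated
from independent simulations — rather than pooling frames, which would let
long excursions in one replicate dominate. Classification: sliding for
mean slope in [−0.21, −0.15] (a symmetric band around −2π/34), hopping for
|slope| ≤ 0.05, otherwise intermediate; both bands are arguments. A
trajectory with no net translation (degenerate Z) is classified
"undetermined" and contributes no slope.

**MSD.** Sliding-origin average MSD(τ) = ⟨|r(t₀+τ) − r(t₀)|²⟩ over all
valid origins, with D = slope/2d from a linear fit over lag indices 1–200
at the saved stride (both window and stride are arguments, and the
lag-index reading of the window is stride-dependent by construction). The
default d = 1 uses the Z coordinate — the quantity of interest is linear
diffusion along DNA — with d = 3 available for the full COM. A quadratic
curvature check flags windows where a single D is not meaningful
(e.g. ballistic segments). D is reduced-units only; no physical-time
mapping is attempted.

**Tracked selection.** For a compact protein the whole-protein COM is
tracked. For a closed ring encircling the duplex (a sliding clamp) the
trimer COM sits on the axis where θ is undefined; the convention is to
track one monomer (`selection = "chain:A"`), which the angular-trace
operation enforces by refusing an on-axis COM.

# Synthetic data: what it emulates, what it does not

`make_toy_protein()` builds ideal α-helical Cα traces (radius 2.3 Å, rise
1.5 Å, 100°/residue) with ±1 charges at chosen positions; the default
six-charge layout (`toy_slider_charges()`) places the charges on one face
of a 20-residue helix, emulating a recognition helix whose basic residues
engage the major groove. The equivalent PDB text round-trips through the
structure reader to the identical model. Because the toy has no side-chain
heavy atoms, its native contacts use a Cα-level 6.5 Å cutoff (the generic
4.5 Å heavy-atom criterion is for real structures).

`make_synthetic_trajectory()` generates trajectories with known truth: Z
is a Gaussian random walk with prescribed D (step variance 2DΔt); in
coupled frames θ = slope·Z plus Gaussian noise; in uncoupled frames θ is
an independent mean-reverting bounded walk (hopping is modelled
phenomenologically — its only job is to give the analysis labelled
negatives); the radial coordinate fluctuates AR(1)-style about its mean.
The switch between modes is a single changepoint at the prescribed
coupled fraction.

A green analysis test on these generators establishes that the estimators
recover prescribed coupling and diffusion under the generators'
assumptions (Gaussian steps, linear coupling, stationary radius). It does
not establish that the force field reproduces any particular protein's
mechanism — that is what the simulation-based contrast test does, at toy
scale — nor anything about atomistic detail, hydrogen bonding, DNA
flexibility or sequence specificity, all of which are outside the model.

One calibration note: the bounded angle walk of the hopping generator is
autocorrelated, so the iid-based OLS standard error is optimistic for
fully uncoupled traces; tests of that regime assert the operative hopping
band rather than a 2-SE interval.

# Numerical choices and degenerate inputs

- Dihedral angles use the atan2 formulation; analytic gradients follow the
  standard four-site expressions and are verified against central
  differences to 10⁻⁵ in the test suite. Near-linear angle triples guard
  sin θ below 10⁻⁸.
- Unwrapping corrects inter-frame jumps larger than π; it is exact
  whenever the true inter-frame rotation is below π, which holds at the
  default save stride by a wide margin.
- Text formats (CG models, trajectories) store doubles as `%.17g`, which
  round-trips IEEE doubles bit-exactly; readers validate a version line
  and frame counts, and refuse truncated files.
- Chain breaks (sequential Cα–Cα > 4.5 Å) warn by default (error on
  request) and never carry bonded terms across the gap. Alternate
  locations other than blank/A are dropped; HETATM records are skipped; a
  residue without a Cα is an error naming the residue.
- The first nucleotide keeps its 5′ phosphate (charged) by default;
  disabling it neutralizes the bead rather than removing it, preserving
  three beads per nucleotide.
- Seeds: every stochastic operation takes an explicit integer seed;
  scans derive per-replicate seeds from a master seed with a fixed integer
  hash (recorded per cell), so permuting the variant list permutes rows
  only.

# Known limitations

- The DNA is rigid and ideal: no sequence-dependent structure, bending,
  breathing, or end effects; the Z-periodic treatment removes ends
  entirely.
- Electrostatics is Debye–Hückel with point charges at bead centres; no
  explicit ions, no dielectric boundary, no polarization. Nominal salt
  concentrations should be compared between conditions, not mapped
  directly onto experimental molarities.
- The toy helix transitions to hopping under charge neutralization but
  remains a slider at 0.06 M nominal salt — its charge density per bead
  is higher than a real domain's and the effective-salt caveat above
  applies. Salt-driven transitions comparable to the published curves
  require the real protein structures as input.
- Diffusion coefficients are in reduced units; comparing to single-
  molecule measurements requires a time-scale calibration that the model
  does not fix.
- No dwell-time or segment-level (HMM) decomposition of sliding versus
  hopping episodes is attempted; classification is per-trajectory or
  per-condition.
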