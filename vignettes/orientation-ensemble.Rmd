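---
title: "Orientation-ensemble modelling of enzyme adsorption on a conducting electrode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-ensemble modelling of enzyme adsorption on a conducting electrode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsorient)
```

## The physical picture

A rigid enzyme, represented as fixed point charges at its atomic positions,
sits in an electrolyte above a planar conducting electrode held at a fixed
electric potential. Mobile ions screen all electrostatic interactions with
the Debye–Hückel constant

$$\kappa = \sqrt{\frac{2 e^2 N_A \cdot 1000\, I}{\varepsilon_0
\varepsilon_s k_B T}},$$

about 0.126 Å⁻¹ at $I = 0.15$ mol/L and 298.15 K in water
($\varepsilon_s = 80$) — an 8 Å screening length. The package treats the
electrode as an ideal conductor occupying the half-space $z \le 0$ and asks,
for every rigid-body orientation of the enzyme: how strongly does it adsorb,
and how fast can it exchange electrons with the surface?

```{r kappa}
debye_kappa(0.15, 298.15, 80)
```

## Orientation sampling

An orientation is a tilt $\theta$ and azimuth $\phi$. The grid steps the
tilt evenly ($d\theta = 10°$ by default) and samples
$n(\theta) = \max\{1, \mathrm{round}(36 \sin\theta)\}$ azimuths at each
tilt, so per-sample solid angles are roughly constant: 36 points on the
equator, a single point at each pole. The builder attaches exact band/cap
solid angles (they sum to $4\pi$) for diagnostics, but ensemble sums weight
orientations evenly — that is what the $\sin\theta$-proportional azimuth
count is for. With the defaults the grid has $M = 412$ samples (408 with
floor integerisation); $M$ is always reported, never assumed, since it
depends on the integerisation rule.

```{r grid}
g <- build_grid()
c(M = nrow(g), equator = sum(g$theta_deg == 90),
  solid_angle = sum(g$weight_sr) / (4 * pi))
```

**Rotation convention.** `orient()` centers the structure on its centroid
and applies $R_y(\theta) R_z(\phi)$: the azimuth spins the body about its
own $z$ axis, then the tilt leans that axis over. The order matters — if the
azimuthal rotation were applied last, about the laboratory $z$ axis, it
would change no atom height and the whole $\phi$ scan would collapse to a
single observable per tilt. With the intrinsic order, all azimuths coincide
at the poles (up to an in-plane spin that no observable sees), which is
precisely why the grid places one point there. The body frame at
$\theta = \phi = 0$ is the input structure's own frame; absolute
$(\theta, \phi)$ labels are therefore convention-dependent, and only
ensemble-level summaries ($K$, $J_0$, energy distributions) are
frame-robust, to within grid discretisation. A dedicated test verifies that
a global pre-rotation of the input moves $K$ and $J_0$ by less than 10% at
$d\theta = 10°$.

After rotation, `place()` translates the body along $z$ so
$\min_i(z_i - R_i)$, the gap between the electrode plane and the closest
van der Waals surface, equals 4.1 Å. That default keeps the ~2 Å
ion-exclusion (Stern) shells of protein and electrode from overlapping;
below it the continuum picture of the electrolyte becomes questionable. The
Stern thickness itself is carried as metadata only.

## The energy backends

### Screened-Coulomb image charges (built in)

The built-in backend is the exact Green's-function solution of the
linearized Poisson–Boltzmann equation in a conductor-bounded half-space.
Each charge feels (i) the screened potential of the electrode held at
$\phi_e$, and (ii) the attraction of the mirror images that enforce the
constant-potential boundary condition:

$$\Delta E = \underbrace{F \phi_e \sum_i q_i e^{-\kappa z_i}}_{\text{field}}
\;\underbrace{- \frac{k_e}{2 \varepsilon_s} \sum_{i,j} q_i q_j
\frac{e^{-\kappa d^*_{ij}}}{d^*_{ij}}}_{\text{image}},$$

with $d^*_{ij}$ the distance from atom $i$ to the mirror of atom $j$
(self-images $d^*_{ii} = 2 z_i$ included — they dominate the conductor
attraction), $k_e = 1389.35$ kJ mol⁻¹ Å e⁻² and $F = 96.485$ kJ mol⁻¹ e⁻¹
V⁻¹, both rederived from CODATA constants. The half factor on the image sum
reflects that image charges are induced, not fixed. The image term is
negative for any charge set and weakens monotonically with both gap and
salt.

This model deliberately omits what only a boundary-element solver can
provide: the low-dielectric protein cavity ($\varepsilon_1 = 4$ enters only
the constant intramolecular Coulomb term), the solvent-excluded-surface
dielectric boundary, and Stern-layer ion exclusion. The charges sit directly
in the screened solvent. Consequently its absolute energies are
surrogate-quality — smooth, correctly signed, correctly ordered with salt
and distance, exactly satisfying the Dirichlet condition on the plane (a
test checks $\phi = \phi_e$ to 1e−10 relative at random plane points) — but
not comparable number-for-number with full PB solutions. When such solutions
exist, the **table backend** ingests their per-orientation totals from CSV
and applies the isolated-state subtraction
$\Delta E = E_{\text{total}} - E_{\text{protein}} - E_{\text{electrode}}$.

The induced electrode charge is obtained by integrating the analytic surface
charge density $\sigma = -\varepsilon_0 \varepsilon_s
\partial\phi/\partial z|_{z=0}$ over a finite disc with a midpoint
ring-by-ring quadrature. In the grounded, salt-free limit it recovers minus
the protein net charge (Gauss's law), within 2% on a disc 50× the charge
height; a held potential adds a uniform, area-proportional term. Values for
a *finite* electrode of a particular size are geometry-specific and are not
targeted by the analytic plane.

## From energies to observables

With $M$ orientation energies $\Delta E_i$ (kJ/mol) at temperature $T$:

- **Probabilities** $P_i = e^{-\Delta E_i / k_B T} / N$. Computed with
  max-subtraction: salt-free energies reach tens of $k_B T$, and naive
  exponentiation would overflow long before that matters physically. Adding
  a constant to all energies provably cancels, so interaction energies can
  stand in for totals.
- **Langmuir constants** $K_i = \frac{1}{M} e^{-\Delta E_i / k_B T}$,
  $K = \sum_i K_i$. The $1/M$ prefactor is the rotational-entropy cost of
  adsorbing into one specific orientation. The unknowable bracket of
  vibrational and reference-state factors is fixed at one arbitrary unit
  (AU), so $K$ and the osmotic pressure $\Pi$ carry AU; they would become
  absolute only by fitting experiment.
- **Coverage** $\chi = K\Pi/(1 + K\Pi)$, split over orientations as
  $\chi_i = P_i \chi$. The identity
  $\sum_i K_i \Pi / (1 + K\Pi) = \chi$ ties the orientation-resolved and
  overall pictures together and is asserted numerically for random energy
  vectors.
- **Currents** $k_i = C e^{-\beta r_i}$ with $r_i$ the perpendicular height
  of the marked electron-entry atom above the plane (for a large planar
  electrode the perpendicular and nearest-point distances coincide);
  $J_0 = \frac{1}{a_0}\sum_i P_i k_i$; $J = A \chi J_0$. The default decay
  constant $\beta = 0.45$ Å⁻¹ follows tunnelling-rate calculations for a
  related hydrogenase on graphene; the steeper $\beta = 1.4$ Å⁻¹ sometimes
  used for protein electron transfer is available as
  `et_params(profile = "steep")`. $C$, $a_0$, $A$ default to 1 AU and are
  exposed as fit parameters.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `ionic_strength` | 0.15 | mol/L | sets κ; 0 for salt-free |
| `temperature` | 298.15 | K | thermal energy (k_BT ≈ 2.479 kJ/mol) |
| `eps_in` | 4 | — | protein interior (intramolecular Coulomb only) |
| `eps_solvent` | 80 | — | water |
| `phi_e` | 0 | V | electrode potential; linearized theory needs \|eφ\| < k_BT, i.e. \|φ\| ≲ 0.025 V |
| `gap` | 4.1 | Å | plane to closest van der Waals surface |
| `dtheta`, `equator_count` | 10°, 36 | | grid resolution |
| `beta` | 0.45 | Å⁻¹ | ET distance decay |

## What the synthetic fixtures emulate — and what they do not

`toy_protein()` builds a quasi-spherical cloud of point charges with radii:
uniform positions in a ball, gaussian partial charges affinely shifted to an
exact net charge (optionally tuned, via a zero-sum z-linear perturbation, to
a target dipole modulus), residues in consecutive triples of standard
amino-acid names, and a buried `FE` atom marked as the electron entry site.
Defaults (150 atoms, 15 Å radius, charge s.d. 0.3 e) give surface charge
densities and adsorption energies on the scale a small charged protein
shows: a few kJ/mol with salt, tens without. `dipole_fixture()` pins down
the dipole unit conventions, and `synthetic_energy_table()` evaluates a
chosen landscape on a grid alongside brute-force ground truth for $P$, $K$
and $J_0$ computed by direct summation, independent of the package's
stabilised path.

What passing tests on these fixtures demonstrate: the statistical machinery
(probabilities, constants, isotherms, currents) is exact to near machine
precision; the image-charge electrostatics obeys its boundary condition,
limits and monotonicities; the pipeline is deterministic and frame-robust.
What they cannot show: fidelity of absolute adsorption energies for a real
protein (no dielectric cavity, no SES, no Stern exclusion, no CHELPG-grade
cofactor charges), real orientational preferences (a random charge cloud has
no charge patches with evolved structure), or pH effects (protonation states
arrive fixed inside the input PQR; pH is a label on input variants, not a
computed quantity).

## Numerical choices

- **Dipole pole.** The dipole of a *charged* molecule depends on the pole.
  About the signed center of charge $\sum q_i r_i / \sum q_i$ the dipole is
  identically zero by construction, so the package uses absolute-value
  weights, $\sum |q_i| r_i / \sum |q_i|$ — the standard reading of "center
  of charge" for mixed-sign distributions — with a centroid fallback when
  $\sum |q_i| \le 10^{-6}$ e. Conversion: 1 e·Å = 4.803 D, rederived from
  constants.
- **Grid integerisation.** `round` by default, `floor` selectable; both are
  reported via `M` rather than assumed, since plausible conventions give
  different counts (412 vs 408).
- **Ties.** Nearest-residue ties break by (chain, residue sequence);
  patch charges round to the nearest integer, as force-field residue
  charges are near-integers.
- **Degenerate inputs.** Empty structures, coincident atoms (singular
  Coulomb), charges at or below the plane, probability vectors not summing
  to 1, and grid/table mismatches (missing orientations are listed) all
  error early with specific messages.
- **Problem sizes.** The test suite runs scans at $d\theta = 30°$ (46
  orientations) on 30–60-atom fixtures, with the full 412-orientation grid
  exercised where frame robustness or grid anatomy is the point; property
  suites use 100–1000 random instances. These sizes make the whole suite
  complete in about a minute while leaving every code path covered.

## Known limitations

The SCIC backend is a surrogate, not a PB solver: no reaction-field effects
of the low-dielectric interior, no finite-electrode geometry, no nonlinear
PB, no charge regulation (residue pKa shifts near the charged surface are
ignored — charges are fixed once, upstream). The Langmuir layer assumes
non-interacting adsorbates and no multilayers. Electron transfer is a single
exponential gate on distance — no Marcus reorganisation energies, no
inter-cluster hopping resolution. Within those bounds, the package's claims
are the ones its tests compute: exact ensemble statistics over whatever
energies a backend supplies, and qualitatively correct electrostatic trends
(salt screening, conductor attraction, charge neutralization, isotherm
shapes).
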