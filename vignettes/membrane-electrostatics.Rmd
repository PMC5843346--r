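---
title: "Macrodipole electrostatics of protein-membrane binding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrodipole electrostatics of protein-membrane binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdipole)
```

## Scope

Fatty-acid-binding proteins (FABPs) are small beta-barrel proteins that bind
peripherally to charged lipid membranes. Two observations motivate this
package: such proteins can bind an interface carrying the *same* sign of
charge as their own net charge, and they adopt a well-defined orientation at
the interface that inverts when the membrane polarity is inverted. Both are
explained by the protein *macrodipole* - the first moment of the atomic
charge distribution - coupling to the screened electric field of the charged
bilayer.

`memdipole` implements the four analysis stages that together make this case
quantitative:

1. **Electrostatics**: protonation states, net charge `z(pH)`, isoelectric
   point, and the macrodipole vector from atomic coordinates.
2. **Interface model**: a screened (linearized Gouy-Chapman) interfacial
   field and an overdamped rigid-body Brownian-dynamics (BD) simulator of a
   charged, dipolar body in that field.
3. **Trajectory observables**: the center-of-mass distance to the
   phosphorus plane (`z_L-P`), the dipole elevation above the membrane
   plane, Kabsch RMSD, and bound-state histograms.
4. **FTIR amide-I decomposition**: baseline and area normalization, Fourier
   self-deconvolution (FSD), Savitzky-Golay second derivatives, band
   identification and constrained Gaussian band fitting into
   secondary-structure class totals.

A fifth module generates synthetic inputs with recorded ground truth for
every stage, so the whole pipeline is testable without external downloads.

## Electrostatics

### Protonation and net charge

Ionizable sites are the Asp/Glu/Cys/Tyr and His/Lys/Arg side chains plus one
N- and C-terminus per chain. Each site carries a pKa, either ingested from an
external predictor's table or taken from the built-in intrinsic
(model-compound) set: Asp 3.65, Glu 4.25, His 6.0, Cys 8.3, Tyr 10.3,
Lys 10.5, Arg 12.5, N-terminus 8.0, C-terminus 3.6.

Discrete protonation is `pH <= pKa` (the tie is counted protonated, a
deterministic convention); fractional occupancy is the Henderson-Hasselbalch
form `1/(1 + 10^(pH - pKa))`. The net charge counts protonated bases as +1
and deprotonated acids as -1. The fractional net charge is strictly
decreasing in pH, so the isoelectric point is the unique root of `z(pH)`,
found by bisection on `[0, 14]` to `1e-4` pH units.

### Partial charges and the macrodipole

The default `"formal"` charge library places each group's integer formal
charge on its canonical heavy atoms (e.g. -0.5 on each carboxylate oxygen,
+1 on the Lys NZ, +1/3 on the three Arg guanidinium nitrogens, +0.5 on each
imidazole nitrogen of a protonated His). Crystal structures carry no
hydrogens and none are built; the charged side chains dominate the
macrodipole of a beta-barrel, so formal group charges are an adequate stand-in
for a full force-field charge set, and a per-atom charge-library file can be
supplied for exact replication. The macrodipole is

$$ \mu = \sum_i q_i\, (r_i - r_0), \qquad 1\ e\cdot\mathrm{\AA} = 4.80321\ \mathrm{D}, $$

about the mass-weighted center of the non-hydrogen protein atoms by default.
For a neutral charge set the result is origin independent; for a net-charged
protein it is not, which is why the origin and its rule are recorded in the
result (shifting the origin by $\Delta$ changes $\mu$ by exactly
$-Q\Delta$). HETATM records (waters, ions, ligands) are excluded from charge
and dipole sums by default: crystal solvent would contaminate a quantity that
is meant to characterize the protein itself.

## The interfacial field and the Brownian-dynamics model

The membrane is a uniformly charged plane at `plane_z` whose potential decays
exponentially with the Debye length of the electrolyte:

$$ \psi(z) = \psi_0\, e^{-\kappa (z - z_\mathrm{plane})}, \qquad
   \kappa^{-1} = \frac{0.304}{\sqrt{I\,[\mathrm{M}]}}\ \mathrm{nm\ (298\ K)}, $$

with the standard $\sqrt{\varepsilon_r(T)\,T}$ temperature correction
(Malmberg-Maryott water permittivity). This linearized Gouy-Chapman form is
a deliberate mean-field stand-in for the interfacial field: it has a single
closed form, analytic gradients, and the correct salt scaling. Surface
potentials of +200 and +150 mV correspond to the cationic lipids studied
(DOTAP- and EDPPC-like surfaces); negative values describe anionic
membranes.

The protein is a rigid set of charged sites. Its electrostatic energy is the
site sum $U = \sum_i q_i \psi(z_i)$ (1 e·mV = 0.0964853 kJ/mol), which
contains both the monopole ($Q\psi$) and dipole ($-\mu\cdot E$)
contributions of the continuum picture without a multipole truncation.
Overdamped Langevin dynamics advance the pose:

$$ \Delta r = \frac{D_t}{k_BT} F\,\Delta t + \sqrt{2 D_t \Delta t}\ \xi,
   \qquad
   \Delta\phi = \frac{D_r}{k_BT} \tau\,\Delta t + \sqrt{2 D_r \Delta t}\ \xi, $$

with analytic forces and torques, quaternion orientation updates
(renormalized every step), a reflecting wall at
`plane_z + contact_radius`, a reflecting ceiling at `z_max` (default 10 nm,
the height of the reference simulation box) so bulk-versus-bound statistics
are well defined, and rejection of any move that would sink a site below the
membrane plane. The default temperature is 320 K, the thermostat reference
of the all-atom simulations this model abstracts. A warning is raised when
the per-step RMS displacement exceeds a tenth of the Debye length, the scale
on which the force varies.

Defaults for the diffusion coefficients are protein-like
(`D_t = 0.1` nm²/ns, `D_r = 0.05` rad²/ns for a ~2 nm body); the closed-form
physics checks (below) use faster, dimensionless mixing parameters because
only the stationary distribution matters there.

### What the simulator is checked against

* **Orientational Boltzmann law.** For a point dipole in a *uniform* field
  (the `uniform_E` flag, i.e. the $\kappa \to 0$ limit) the long-run
  $\langle\cos\theta\rangle$ must equal the Langevin function
  $\coth x - 1/x$ at $x = \mu E/k_BT$; checked at $x \in \{0.5, 1, 2, 5\}$
  over $10^5$ steps against block-averaged Monte-Carlo errors.
* **Positional Boltzmann law.** A single charge between the reflecting wall
  and ceiling must sample $p(z) \propto e^{-U(z)/k_BT}$; checked by a
  chi-square test on decorrelated samples (thinned far beyond the measured
  relaxation time of the box).
* **Polarity inversion.** A dipolar body equilibrated at $+\psi_0$ and
  $-\psi_0$ must flip its mean orientation by about 180 degrees. The mean is
  the *circular* mean - the polar angle of the averaged unit dipole
  direction - because azimuthal symmetry cancels the in-plane components and
  leaves the polar axis, which is the quantity that inverts.
* **Like-charge binding.** A net-positive, high-dipole body near a
  +200 mV interface at 100 mM NaCl stays membrane-proximal relative to a
  zero-field control started from the same pose. 100 mM is the informative
  condition for a compact body: the dipole term scales as $\mu\kappa\psi$
  against the monopole's $Q\psi$, so the dipole can only outweigh the
  monopole once the screening length is shorter than the charge-separation
  scale. (At 10 mM a *point*-dipole model predicts net repulsion for
  $\mu = 175$ D and $Q = +2$; the real protein binds there because its
  charge distribution is extended, a feature the desk model reproduces only
  partially.)
* **Salt trend.** At a fixed pose with the dipole lying in the membrane
  plane (monopole-dominated coupling) the interaction magnitude must fall
  monotonically from 10 to 100 to 500 mM. The in-plane pose is used
  deliberately: for a tilted extended dipole the site-sum magnitude is not
  guaranteed monotone in $\kappa$ (the dipole coupling
  $\kappa e^{-\kappa d}$ is single-peaked), so the clean statement of the
  screening law is the monopole one.

The experiment bodies are deterministic "two-pole" constructions
(`two_pole_body()`): charged caps at $\pm 0.45$ nm spread over four sites
each, solving for cap charges that give exactly the requested dipole and net
charge. This mirrors the polar charge asymmetry of the beta-barrel/portal
architecture better than a least-norm random charge cloud, which spreads
charge diffusely and couples only weakly to the interface.

## Trajectory observables

`z_L-P` is the mass-weighted protein center of mass minus the mean z of the
cis-leaflet phosphorus atoms, in nm, positive above the leaflet. The dipole
orientation is reported as the elevation of $\mu$ above the membrane (x-y)
plane in $[-90^\circ, +90^\circ]$, negative when the dipole points toward a
membrane at lower z; the sign convention is configurable (`flip`) because
published figures do not define it unambiguously. RMSD uses the Kabsch
superposition with the determinant guard against improper rotations and is
cross-checked in the tests against an independent quaternion (Horn
eigenvalue) oracle. Bound-state histograms default to the final 70% of a
run, the convention of analysing the last 70 ns of 100-ns adsorption
trajectories.

## FTIR amide-I decomposition

The pipeline reproduces the standard protocol: a linear baseline anchored at
1600 and 1700 cm⁻¹ is subtracted (the grid is kept uncropped so Fourier
steps see decaying tails rather than cut edges), the area over
1600-1700 cm⁻¹ is normalized to 1, and components are identified by FSD and
the second derivative before a constrained fit.

**FSD.** Kauppinen self-deconvolution divides the interferogram-domain
signal by the decay of an assumed Lorentzian line (full width `bandwidth`,
here 18 cm⁻¹) and applies a Bessel-type apodization window
$(1-(x/X)^2)^2$ whose cutoff is chosen so that a matched Lorentzian
collapses to the window's line shape with FWHM `bandwidth/k` - the
narrowing-factor definition of `k` (here 2). The zero-frequency component is
untouched, so the integrated area is conserved; a cutoff beyond the grid's
Nyquist point is refused as over-deconvolution. `k = 1` requests no
enhancement and is implemented as the identity.

**Band identification.** Candidates are prominent second-derivative minima
of the normalized spectrum, united with curvature minima of the FSD trace
(which register shoulders of closely spaced components that never become
outright maxima of the trace). Two vetoes remove artifacts: a candidate from
the FSD trace must sit where the measured spectrum is concave
(deconvolution ringing lives only in one trace), and every candidate must
carry at least 5% of the window's peak absorbance (a component band absorbs;
derivative noise does not). Candidates closer than 2 cm⁻¹ merge.

**Fitting.** A sum of Gaussians is fitted by Levenberg-Marquardt with
centers confined to the identified positions ±2 cm⁻¹ (preventing band
swapping), widths in 6-40 cm⁻¹ and non-negative amplitudes; amplitudes are
initialized by a linear solve at fixed centers and several width starts
guard against local optima of the strongly overlapped problem. Gaussian
shape is used throughout (component area = amplitude × FWHM ×
$\sqrt{\pi/4\ln 2}$); the cited band-fitting protocol does not fix the
shape, and Gaussian keeps areas analytic. Percent areas are
component-relative (they sum to 100).

**Classification.** Band centers map to secondary structure as:
beta 1620-1642 and 1668-1678; unordered 1642-1648; alpha-helix 1648-1658;
turns 1658-1668 and 1678-1690 cm⁻¹. These ranges reproduce the published
per-band assignments of the four measured spectra (solution, DMPG, DMTAP,
EDMPC band tables, available as `amideI_preset()`).

### Synthetic spectra and their component width

The generator builds sums of Gaussians at the published centers and percent
areas, unit total area, optional white noise. The default component FWHM is
9 cm⁻¹: synthetic Gaussians lack the Lorentzian wings that FSD removes, so
wider Gaussian components would stay merged where the measured bands were
demonstrably resolvable under FSD(18, k = 2). This width is a property of
the synthetic stand-in, not a claim about the physical component widths.
With it, the full pipeline re-derives the solution-state class totals
(beta 68%, alpha 19%, turns 13%) and the DMPG-bound totals (46/16/23/15)
from nothing but the synthesized spectra. The EDMPC table contains two bands
5 cm⁻¹ apart (1666/1671), below the deconvolution resolution; the pipeline
merges them, which moves ~5 area points between beta and turns for that
column - a genuine resolution limit of the protocol on Gaussian data, left
visible rather than patched.

## Synthetic data and what passing tests mean

Generators exist for point-charge "proteins" with analytically prescribed
dipole and net charge (least-norm charge solve), residue-level ionizable
inventories, membrane frames with scripted `z(t)`/`theta(t)` and jittered
phosphorus planes, amide-I spectra, and pKa tables. Every generator records
its ground truth in a sidecar, and recovery tests compare only against the
sidecar.

Two residue-level fixtures encode the titration landmarks of the studied
proteins as design targets: an L-BABP-like inventory (net charge +2 at
pH 6.8 rising to +7 at pH 5.0 through exactly Glu25, Glu94, Glu101, His83,
His98) and a ReP1-NCXSQ-like inventory (-1 at pH 7, +1 at pH 5, isoelectric
point 5.85 with Glu72 and His113 as the pH-5 flips). The two free pKa values
of the ReP1-like table are set so that the fractional charge crosses zero at
pH 5.85; everything else keeps intrinsic values. Passing tests on these
fixtures demonstrates that the titration *arithmetic* is exact given a pKa
table; they say nothing about pKa prediction, which is out of scope, and
they are not the crystal structures themselves - the structure-dependent
dipole magnitudes are validated on point-charge stand-ins whose targets are
the published values (175 D / 400 D / 158 D), exercising the full
file-ingestion -> charge-assignment -> summation path.

## Numerical choices

* Internal length unit Å (PDB convention); distances reported in nm;
  trajectory times ns; energies kJ/mol.
* Bisection tolerance for the pI: 1e-4 pH units. Charge-sum consistency:
  1e-9 e.
* The BD integrator is Euler-Maruyama; quaternions are renormalized every
  step (norms stay within 1e-9 of unity over long runs).
* Unknown elements receive the mass of carbon with a warning, keeping COM
  computations defined for coarse synthetic sites.
* Alternate locations other than blank or 'A' are dropped on PDB input;
  multi-chain structures get one terminus pair per chain.
* Problem sizes used by the shipped checks: 60-site stand-ins, 10^5-step
  physics runs, 2×10^4-step orientation runs over 5 seeds, 1 cm⁻¹ spectra
  grids over 1550-1750 cm⁻¹.

## Known limitations

* The exponential field is a linearized mean-field model; only ordering and
  sign claims (flip, salt trend, like-charge retention) are meaningful at
  desk scale, not absolute binding energies or the numeric `z_L-P` ranges
  of all-atom simulations.
* Formal charges approximate a force-field charge set; dipole magnitudes
  computed this way carry ~10% charge-set ambiguity.
* No pKa prediction, no interfacial pKa shifts (charges are evaluated at
  bulk pH), no disulfide detection, no hydrogen building, no conformational
  flexibility (the body is rigid; conformational changes are characterized
  spectroscopically in the FTIR module instead).
* FSD assumes a Lorentzian line; on purely Gaussian synthetic bands the
  achievable resolution is bounded by the apodization line shape
  (~9 cm⁻¹ here), hence the EDMPC merging noted above.
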