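---
title: "Models and methods in ilbilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ilbilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilbilayer)
```

`ilbilayer` studies how imidazolium ionic-liquid (IL) cations partition
into phospholipid bilayers at coarse-grained (CG) resolution. This
vignette is the package's account of its science: the models, the
conventions that were genuinely open and how they were fixed, what the
synthetic generators do and do not emulate, and the known limitations.
Every number quoted here is computed by the test suite or the acceptance
script; nothing is asserted that the code does not measure.

## 1. The energy model

Beads interact through Mie potentials in the SDK convention, chosen so
that $\epsilon$ is the literal well depth:

$$U_{9\text{-}6}(r) = \tfrac{27}{4}\,\epsilon
  \left[\left(\tfrac{\sigma}{r}\right)^{9} -
        \left(\tfrac{\sigma}{r}\right)^{6}\right],
\qquad
U_{12\text{-}4}(r) = \tfrac{3\sqrt3}{2}\,\epsilon
  \left[\left(\tfrac{\sigma}{r}\right)^{12} -
        \left(\tfrac{\sigma}{r}\right)^{4}\right].$$

The 12-4 form applies to any pair involving a water bead, the 9-6 form to
all others; `parameter_set()` enforces this as a validation rule, along
with completeness and uniqueness of the pair table (a duplicated entry is
an error, not last-wins). The minima sit at $(3/2)^{1/3}\sigma$ and
$3^{1/8}\sigma$ with depth exactly $-\epsilon$; the test suite asserts
both to $10^{-10}$.

Electrostatics are plain Coulomb screened by a relative permittivity
$\epsilon_r = 16$ — the implicit-screening treatment appropriate when
water carries no explicit charges — truncated and shifted together with
the Mie terms at a 1.5 nm cutoff (skin 0.2 nm for neighbor lists). The
cutoff and shift are package choices: they are standard for this model
family, keep the energy continuous, and make the toy integrator stable;
no Ewald/mesh method is provided (a deliberate non-goal at desk scale).
One consequence worth stating: with a shifted potential the *pair* energy
at $r=\sigma$ is $-U(r_c)$ rather than exactly zero — a few times
$10^{-4}\epsilon$ — which the tests account for.

Units throughout: nm, ps, amu, kJ/mol, elementary charges;
$k_B = 0.0083144621$ kJ/mol/K. Reported bending moduli use J and
$10^{-20}$ J.

The shipped `example_parameter_set()` is schema-complete and physically
plausible (SDK-scale $\sigma$, $\epsilon$; Lorentz–Berthelot combination
for unlike pairs) but is **synthetic**: the published base values of the
lipid and cation models live in their original references, and the
package ships a schema plus a documented example, not a claim of
bit-identity to anyone's files. Topology templates are configurable, not
hard-coded: `lipid_template()` defaults to the 13-bead
phosphatidylcholine mapping (head, phosphate, glycerol, two 5-bead
tails); `cation_template(n)` maps [Cnmim]⁺ to one charged ring bead plus
`round(n/3)` tail beads.

## 2. Toy dynamics

The integrator is BAOAB Langevin splitting; with friction 0 it reduces
*exactly* to velocity Verlet, which the tests check bitwise. Defaults:
0.01 ps timestep (CG-appropriate; the stiff-pair tests use 0.002 ps),
303 K, friction 1 ps⁻¹. Pressure coupling is a Berendsen-style
semi-isotropic weak-coupling rescale — one factor for $L_x = L_y$, one
for $L_z$, factors clamped to [0.9, 1.1] per step — because a toy
equilibrator does not need correct volume fluctuations; observables that
are fluctuation-sensitive (the bending modulus) are measured on synthetic
or constant-volume data. Net momentum is re-zeroed after each barostat
rescale. Checkpoints store positions, velocities, box and the RNG state
(doubles as shortest-17 decimal strings, because JSON numbers do not
round-trip bitwise), so a restarted run reproduces a continuous one
bitwise.

NVE quality on a Mie dimer: energy drift $< 0.1\%$ of the well depth over
$10^4$ steps, halving the timestep reduces it at least twofold.

## 3. Umbrella sampling and WHAM

The reaction coordinate is the signed distance $z$ between the cation
ring bead and the bilayer midplane; harmonic windows $w_j(z) =
\tfrac{k}{2}(z - c_j)^2$. WHAM iterates the standard equations

$$P(z) \propto \frac{\sum_j n_j(z)}
 {\sum_j N_j e^{(F_j - w_j(z))/k_BT}},
\qquad
F_j = -k_BT \ln \sum_z P(z)\, e^{-w_j(z)/k_BT}$$

in log space, gauge-fixed to $F_1 = 0$, to a relative tolerance of
$10^{-8}$ with a $10^5$-iteration cap (exceeding it raises a typed
condition carrying the last iterate). Windows are sorted canonically by
center before solving, so the output is bitwise independent of input
order. WHAM was chosen over MBAR as the canonical estimator for
histogram-binned umbrella data; bootstrap resampling within windows
provides per-bin errors. Profiles are anchored either at their minimum or
over a 0.5 nm bulk-water plateau (`anchor_pmf()`); both CG and reference
profiles must be anchored identically before comparison.

On the analytic double well $U(z) = 4(z^2-1)^2$ kJ/mol with 24 windows
and $10^4$ samples each, the reconstruction agrees with $U$ to within
0.1 $k_BT$ on essentially all adequately sampled bins. One statistical
caveat, measured and documented rather than hidden: a bin with exactly
100 samples has $\mathrm{sd}(G) \approx k_BT/10$, so the *maximum*
deviation over ~75 bins occasionally exceeds 0.1 $k_BT$ for unlucky
seeds. The acceptance script reports the honest per-seed value.

## 4. PMF matching

`optimize_cross_parameters()` minimizes the RMS discrepancy between a CG
insertion profile and a reference profile over per-pair $\epsilon$ scale
factors, bounded to [0.2, 5], using derivative-free search (Brent in one
dimension, Nelder–Mead otherwise). Only $\epsilon$ is refined by default —
whether $\sigma$ should also move is not settled, so it is left to the
evaluator, which maps a scaling vector to a profile and can do anything
(re-run CG umbrella sampling, or an analytic surrogate in tests). The
refined pairs default to ring–head, ring–phosphate and
cation-tail–lipid-tail (`default_cross_pairs()`), and the objective
weighting over $z$ is uniform within the chosen window — both documented
assumptions, both configurable. The optimizer never returns parameters
worse than its starting point, and its accepted-iterate trace is
non-increasing by construction. Because scalings attach to bead *types*,
parameters calibrated on the butyl cation transfer unchanged to the decyl
cation built from the same types.

## 5. Leaflet assignment and insertion counting

Assignment starts from a global-mean split of phosphate $z$, builds
smoothed upper/lower candidate surfaces on a coarse periodic grid
(default 8×8), and re-assigns each lipid by the sign of its phosphate
height relative to the grid-local midplane. The package iterates this
refinement to a fixed point (capped at 10 passes) rather than stopping
after one pass: one pass suffices for bending amplitudes up to roughly
the leaflet half-thickness, but deeper folds — precisely the regime that
makes a local midplane necessary — need a few more, and the fixed point
is still deterministic. A frame whose lipids all fall on one side is a
degenerate-bilayer error. The method assumes the bilayer is not wrapped
across the periodic $z$ boundary.

A cation is counted as inserted in the upper leaflet iff its ring bead
satisfies $m(x,y) \le z \le s^+(x,y)$, with $m$ the local midplane and
$s^+$ the local upper phosphate surface; the boundary at the midplane is
closed on the upper side (documented, tested tie-break), and the lower
rule is the mirror image with an open midplane bound so no cation is
double-counted. Ratios divide by the number of lipids in that leaflet.
Saturation is the mean ratio over a trailing window, accepted only when
the window's linear slope is statistically zero. The threshold is 1.96
standard errors (95%), a deliberate design choice: a 1-SE rule would
reject a genuinely flat series about a third of the time, since under the
null the slope estimate falls outside ±1 SE with probability ~32%
regardless of the window length; onset is the first frame within 5% of
the plateau.

## 6. Surfaces, spectra and the bending modulus

`reconstruct_surface()` bins phosphate $z$ by $(x, y)$ into an $N\times
N$ periodic grid ($N$ a power of two, default 32), averages duplicates,
fills empty cells by iterative 4-neighbor averaging (an error if more
than half the cells are empty), and subtracts the mean. The Fourier
convention is $\hat h(\mathbf q) = N^{-2}\sum h\, e^{-i\mathbf q\cdot
\mathbf r}$ with spectral intensity $S(\mathbf q) = A\,\langle|\hat
h_{\mathbf q}|^2\rangle$, $A = L^2$. Radial bins group modes sharing the
same integer $k_x^2 + k_y^2$, so every bin sits at an *exact* $|q|$ and
the $q^{-4}$ fit carries no radial-smearing bias; $q = 0$ is excluded and
bins beyond the axis Nyquist radius dropped. For an anisotropic
single-cosine surface $h = a\cos(q_1 x)$ the *per-mode* intensity at
$\pm q_1$ is $A a^2/4$ (the closed-form coefficient, asserted in the
tests via `spectrum_2d()`), while the radial bin containing $|q_1|$
averages over the zero-amplitude perpendicular modes as well — the radial
statistic is designed for isotropic thermal spectra, not coherent
single-mode fields.

The bending modulus comes from the pure-bending Helfrich law
$S(q) = k_BT/(\kappa q^4)$, fitted as a weighted mean of $\log S + 4\log
q$ over bins with $q < q_\mathrm{max}$ (default 1.0 nm⁻¹, the
bending-dominated regime for nm-scale lipids; protrusion modes
contaminate higher $q$). A surface-tension term $\gamma q^2$ is available
behind a flag but off by default since κ is the quantity of interest.
Errors propagate from per-bin standard errors; block averaging over frame
blocks (default 5) mirrors the conventional ±-style reporting.

## 7. Synthetic data: the stated world

The generators produce every input with known ground truth:

* **Helfrich sampler** — draws each Fourier mode as a complex Gaussian
  with variance $k_BT/(A\kappa q^4)$ (Hermitian symmetry enforced via a
  white-noise FFT), i.i.d. frames. This is *exact* sampling of the target
  ensemble, not dynamics: the generator's κ is ground truth with zero
  model error, which is precisely what estimator validation needs. The
  round trip through `undulation_spectrum()` + `fit_bending_modulus()`
  recovers κ within 5% at 500 frames (both at 22.6 and 9 ×10⁻²⁰ J,
  T = 303 K, L = 25 nm, N = 32), within 15% at 50 frames; the full path
  through lipid-point sampling and `reconstruct_surface()` recovers it
  within 10%. What a green test establishes is the correctness of the
  estimator chain — not that a simulated membrane would show these κ
  values; that requires the full-scale simulations that are out of scope.
* **Umbrella sampler** — vectorized Metropolis MC from $e^{-[U(z)+
  w_j(z)]/k_BT}$, burn-in 1000 sweeps, thinning stride 10, automatic
  step-size halving if acceptance drops below 5%. MC rather than dynamics
  because sample independence and correctness are easier to guarantee.
* **Toy bilayer builder** — lipids on two opposing square lattices at
  0.65 nm² per lipid (a fluid-phase phosphatidylcholine value), tails
  inward with a 0.2 nm clearance between opposing tail ends and 0.4 nm
  between a lipid's two tails (so no pair starts on the repulsive wall);
  a prescribed number of cations placed with ring beads inside each
  leaflet, the remainder in the *upper* water slab together with
  charge-balancing chloride and optional NaCl — the one-sided-exposure
  scenario with ~200 mM IL against a 160 mM buffer is the physical
  situation this emulates. Construction labels (leaflet of every lipid,
  insertion state of every cation) are recorded as ground truth and the
  analysis chain reproduces them exactly on unperturbed constructions.
  The builder prescribes geometry; it does not emulate emergent
  self-assembly (micellization of long-chain cations is a non-goal).

Every generator is deterministic under a fixed seed and records seed and
spec in its outputs.

## 8. Numerical choices and degenerate inputs

* Log-sum-exp throughout WHAM; empty bins carry $+\infty$ free energy and
  propagate as such.
* Neighbor lists use a periodic cell list when the box admits ≥ 3 cells
  per edge, an $O(N^2)$ minimum-image scan otherwise; both paths are
  tested against a brute-force oracle.
* Angle forces regularize $\sin\theta$ below $10^{-8}$ to avoid the
  collinear singularity.
* Non-finite forces or energies abort integration with the offending
  frame written to disk.
* GRO IO preserves the format's fixed precision (3 decimals positions, 4
  velocities); lossless tables use TSV with unit-carrying headers and
  17-significant-digit floats, and refuse files whose headers disagree.

## 9. Known limitations

* Desk scale only: no Ewald electrostatics, no constraints, no
  parallelism; the 250 ns near-continuum simulations behind the
  full-scale κ and saturation numbers are explicitly out of reach, which
  is why acceptance is property-based on synthetic ensembles.
* The example force field is illustrative; quantitative membrane
  properties (area per lipid, order parameters) have not been tuned.
* Leaflet assignment assumes a bilayer topology (two sheets); it will
  mislabel vesicles, micelles or pores.
* The Berendsen barostat suppresses volume fluctuations; do not measure
  compressibilities from its trajectories.
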