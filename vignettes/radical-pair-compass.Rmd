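---
title: "Spin dynamics of flavin radical pairs as a magnetic compass: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin dynamics of flavin radical pairs as a magnetic compass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radicalpair)
```

## The model

Cryptochrome photochemistry creates a pair of radicals — the flavin anion
FAD•− and either a tryptophan cation (FAD-Trp) or, as a limiting
reference, a hypothetical partner Z• with no hyperfine couplings (FAD-Z) —
whose two unpaired electron spins start out in a singlet state.  Coherent
mixing between singlet and triplet configurations is driven by the spin
Hamiltonian

$$
H = \omega\,(\hat S_1 + \hat S_2)\cdot\hat b
  \;+\; 2\pi \sum_i \hat S_a \cdot A_i \cdot \hat I_i
  \;-\; 2\pi J\,(2 \hat S_1\cdot\hat S_2 + \tfrac12)
  \;+\; 2\pi \frac{2D}{3}\,[\,3(\hat S_1\cdot\hat n)(\hat S_2\cdot\hat n)
        - \hat S_1\cdot\hat S_2\,],
$$

with $\omega = 2\pi\, g\mu_B B/h$ the electron Larmor angular frequency at
field magnitude $B$ and direction $\hat b(\theta,\phi)$, $A_i$ the 3×3
hyperfine tensor of nucleus $i$ (MHz, flavin molecular frame), $J$ and $D$
the inter-electron exchange and dipolar couplings, and $\hat n$ the
inter-radical axis.  Both radicals take the free-electron g-value, so the
Zeeman term alone causes no singlet–triplet interconversion; anisotropic
hyperfine tensors (and $D$) are the only orientation-dependent terms,
which is what makes the reaction a direction sensor.

Singlet and triplet pairs react spin-selectively with **equal** rate
constants $k$ (Haberkorn recombination).  Equal rates reduce the kinetics
to a uniform exponential decay, and the fractional singlet yield for a
singlet-born pair with fully mixed nuclear spins
($\rho_0 = P_S/\mathrm{Tr}\,P_S$) has the closed spectral form

$$
\Phi_S \;=\; \frac{1}{\mathrm{Tr}\,P_S} \sum_{mn}
  \left|\langle m|P_S|n\rangle\right|^2
  \frac{k^2}{k^2 + (\omega_m - \omega_n)^2},
$$

evaluated in the eigenbasis of $H$.  `singlet_yield_spectral()` implements
this; `singlet_yield_timedomain()` computes the same quantity by direct
density-matrix propagation and quadrature of
$k\int_0^\infty e^{-kt}\,\mathrm{Tr}[P_S\rho(t)]\,dt$ and serves as an
independent oracle.  The compass observable is the reaction-yield
anisotropy over field directions,
$\Delta\Phi_S = \max_{\theta,\phi}\Phi_S - \min_{\theta,\phi}\Phi_S$,
with the isotropic component $\langle\Phi_S\rangle$ (solid-angle-weighted
spherical mean) and the residual map
$\bar\Phi_S = \Phi_S - \langle\Phi_S\rangle$ available through
`delta_phi_s()` and `anisotropic_part()`.

## Parameters and units

| quantity | default | unit | meaning |
|---|---|---|---|
| $B$ | 49 | µT | Earth-strength field magnitude |
| $k$ | $10^5$ | s⁻¹ | singlet = triplet recombination rate |
| $J$ | −0.65 | MHz | exchange coupling |
| $D$ | −11.2 | MHz | dipolar coupling (point-dipole distance 1.91 nm) |
| $\delta$ | ±5 | degrees | libration half-angle (two-site hop) |
| $k_m$ | $10^4$–$10^8$ | s⁻¹ | hop rate range scanned |
| $\gamma(^2H)/\gamma(^1H)$ | 0.154 | — | deuteration tensor scale |
| $\gamma(^{15}N)/\gamma(^{14}N)$ | −1.402 | — | ¹⁵N tensor scale |

Internally all dynamical quantities are angular frequencies in rad·µs⁻¹:
tensors enter in MHz (×2π), fields in µT (via the Larmor relation with
CODATA 2018 constants, centralized in `physical_constants()`), rates in
s⁻¹ (×10⁻⁶).  A 1 MHz isotropic coupling on one spin-½ nucleus produces
an eigenvalue span of exactly 2π rad·µs⁻¹, which the unit audit in the
test suite asserts.

Sign conventions: the exchange term $-J(2S_1\cdot S_2 + \frac12)$ makes the
singlet–triplet gap $2J$; the dipolar prefactor $\tfrac{2D}{3}$ pairs
$D = -11.2$ MHz with the point-dipole distance
$r = [\,-3\mu_0 g_e^2\mu_B^2/(8\pi h D)\,]^{1/3} = 1.91$ nm and an
equivalent field of $D/(g_e\mu_B/h) \approx -400$ µT.  Both conventions
are fixed here because they reproduce those printed pairings.

The ¹⁵N/¹⁴N scale is adopted as the constant −1.402.  Standard nuclear
moment tables give −1.40275; the difference is below every tolerance used
in this package, and the adopted value keeps the tensor-scaling rule
exactly reproducible.

## Orientation grids

`orientation_grid()` builds a regular $\theta\times\phi$ grid whose weights
are the exact solid angles of the grid cells (they sum to $4\pi$ to
machine precision), plus an optional Gauss–Legendre-in-$\cos\theta$ grid
for high-accuracy spherical means.  A regular grid was preferred over pure
Gauss nodes because the figures of interest (θ-profiles, residual maps)
want evenly spaced colatitudes; the cell-exact weights make the spherical
mean exact for maps that are piecewise constant on cells and accurate to
the grid scale otherwise.

Scans exploit the antipodal symmetry $\Phi_S(\hat b) = \Phi_S(-\hat b)$ —
a time-reversal property of a model whose tensors are real symmetric —
by diagonalizing only one hemisphere and mirroring.  The symmetry itself
is verified numerically in the test suite (and can be disabled with
`use_symmetry = FALSE`).  $\Delta\Phi_S$ is the max−min over the sampled
grid; on the systems shipped here a 30°→15° refinement changes it by well
under 15%, and the screen-scale runs use 10–15° grids.

## Two-site stochastic Liouville relaxation

Small-amplitude libration of the flavin inside its binding pocket is
modelled as hopping at rate $k_m$ between two equally probable
orientations whose flavin hyperfine tensors are rotated by ±δ about a
molecular axis (default x, y supported).  Only the flavin tensors rotate;
the partner radical, $J$, $D$ and the field stay fixed.  Writing
$L_j[\rho] = -i[H_j,\rho]$ for the two site Hamiltonians, the
time-integrated site density matrices solve the linear system

$$
(L_j - (k + k_m))\,\bar\rho_j + k_m\,\bar\rho_{j'} = -\tfrac12\rho_0,
\qquad
\Phi_S = k\,\big(\mathrm{Tr}[P_S\bar\rho_1] + \mathrm{Tr}[P_S\bar\rho_2]\big).
$$

This one-shot solve is exact for the linear model and far cheaper than
propagating the coupled equations; the vectorization is column-stacking,
$\mathrm{vec}(-i[H,\rho]) = -i(I\otimes H - H^{T}\otimes I)\mathrm{vec}\rho$.
The Liouville dimension is $2d^2$, so `two_site_yield()` enforces a
Hilbert-dimension limit (default 48, i.e. a 4608-dimensional dense solve);
systems used for relaxation scans are chosen small (one or two nitrogens).
Three limits pin the implementation down and are asserted in the tests:
$k_m = 0$ averages the two static site yields, δ = 0 reproduces the static
engine to 10⁻⁹, and $k_m \to \infty$ approaches the yield of the averaged
Hamiltonian (motional narrowing).  Between the static and narrowing
plateaus — hop rates comparable to the hyperfine frequencies — the
anisotropy is attenuated, which is the regime the $k_m$ scan
(`km_scan()`, `run_relaxation_scan()`) maps out.

## Isotopologues

Substitutions act on the radical specification, never on the Hamiltonian:

* `substitute_isotope()` rescales a tensor component-wise by the
  magnetogyric ratio and updates the spin multiplicity (¹H→²H: ×0.154,
  I=½→1; ¹⁴N→¹⁵N: ×(−1.402), I=1→½).
* `substitute_carbons()` appends spin-½ ¹³C nuclei with tensors from a
  catalogue; each insertion doubles the Hilbert dimension.  ¹²C has no
  spin and is represented by absence.
* `remove_nuclei()` deletes sites (the `-H` preset).
* `enumerate_carbon_sets(3)` yields the 220 three-carbon subsets of the
  12-carbon catalogue in lexicographic order, and `run_carbon_screen()`
  ranks the resulting isotopologues by $\Delta\Phi_S$.

The named presets (`U`, `N5`, `N10`, `N5,N10`, `D`, `-H`, and
combinations) act on the standard working set of seven flavin nuclei —
N5, N10, H6, the three H8α methyl protons and one H1′ proton — which is
the largest-coupling subset that keeps exact simulation affordable.  The
`D` preset deuterates exactly those five retained hydrogens; perdeuterating
all eleven flavin hydrogens requires supplying the full tensor table.
Which of the two H1′ protons is meant by the working set is a choice the
tensor table must record; the shipped skeleton carries both slots
(`H1prime1`, `H1prime2`).

## The synthetic generator

The quantitative hyperfine tensors of FAD•− come from density-functional
calculations that are not distributed with this package.  So that every
pipeline stage is testable, `flavin_like_radical(seed)` generates a
structurally faithful stand-in:

* two nitrogen tensors (I = 1) that are strongly axial along ~z, with
  $a_{iso} \in [3, 15]$ MHz and $|A_{zz}|$ 3–10× the perpendicular
  components, orientation-jittered by up to 10°;
* five proton tensors (I = ½) with $|a_{iso}| \in [0, 15]$ MHz and
  anisotropy at most 20% of $|a_{iso}|+1$ — the near-isotropic bath that
  dilutes the nitrogen anisotropy;
* a 12-carbon ¹³C catalogue split between an "axial" class (large
  $|A_{zz}|$, small perpendicular components, like C6/C8/C9a) and an
  "in-plane" class (large $|A_{xx}+A_{yy}|/2$, small $|A_{zz}|$, like
  C4/C4a/C8α), with random overall signs and small orientation jitter.

One integer seed drives the whole generator through a locally scoped RNG
(the caller's random stream is untouched), and the same seed reproduces
the tensors bit-identically.  The class ranges were chosen once to
reproduce the qualitative mechanisms — isotropic protons dilute the
signal, in-plane carbons offset the axial nitrogens — and are not tuned
further.  What passing tests on synthetic tensors demonstrate is that the
machinery (operator algebra, yield formulas, substitution rules,
screening, relaxation) is correct and that the mechanistic rankings
emerge from the advertised tensor structure; they do **not** reproduce
the quantitative anisotropies of the real radical pair, which require the
transcribed DFT tensors and the structure-derived inter-radical axis
(provenance `"SI-transcribed"` in the tensor table; the default pair uses
a fixed oblique synthetic axis $(1,1,2)/\sqrt6$).

## Numerical choices

* Hamiltonians are assembled from Kronecker products (never full-space
  matrix products), symmetrized as $(H+H^\dagger)/2$, and checked
  Hermitian at build time.
* The spectral yield handles degenerate eigenvalues naturally (Lorentzian
  weight 1); no special-casing.
* The time-domain oracle uses composite Simpson quadrature with a step
  resolving the largest eigen-gap (64 samples per fastest period), an
  integration horizon of $20/k$ and an analytic tail correction; the step
  count is capped and exceeding the cap is an error, not a silent
  accuracy loss.
* The orientation-scan kernel is compiled (RcppArmadillo): per direction
  one divide-and-conquer Hermitian eigendecomposition plus two
  rank-structured products with the singlet-projector factor
  ($P_S = QQ^\dagger$, $Q$ of rank $d/4$).  The R reference engine
  (`engine = "r"`) computes identical numbers and is cross-checked in the
  tests.
* The two-site solve is a dense complex LU; above the dimension limit it
  refuses rather than degrade.

## Problem sizes

The package's own test and acceptance runs use: reference systems of
dimension ≤ 24; an oracle battery up to dimension 64; the full seven-
nucleus synthetic FAD-Z pair (dimension 1152) on coarse grids; and the
complete 220-subset carbon screen on a reduced flavin (N5 + H6 + three
¹³C, dimension 192) with a 10–15° grid.  These sizes were chosen so the
whole suite runs on a single CPU in minutes while still exercising every
code path at realistic structure; the same functions scale to the full
3456-dimensional FAD-Trp working set when supplied with transcribed
tensors and more patience.

## Known limitations

* No quadrupolar couplings, g-tensor anisotropy or nuclear Zeeman terms —
  deliberately outside the model.
* Equal singlet/triplet rate constants only; the general (non-scalar)
  Haberkorn recombination is reserved API surface but untested.
* $J$ and $D$ are static scalars; no modulation of the inter-radical
  couplings.
* Relaxation is limited to the symmetric two-site hop; no Redfield or
  continuous-diffusion treatment.
* Absolute yield maps for the real system depend on hyperfine tensors and
  an inter-radical axis that must be supplied by the user; everything
  shipped here is synthetic and labelled as such.
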