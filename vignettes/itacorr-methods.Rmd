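---
title: "Methods: density descriptors, quadrature, regression and fragmentation in itacorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density descriptors, quadrature, regression and fragmentation in itacorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itacorr)
```

## The model

`itacorr` rests on one empirical observation and two pieces of exact
structure.

The observation: post-Hartree–Fock electron correlation energies of
homologous molecular series — polymers of increasing chain length,
clusters of increasing size — are very nearly linear in any one of a
family of information-theoretic functionals of the electron density.
The exact structure behind it: (i) the descriptors are integrals of
local functions of $\rho$, $\nabla\rho$ and $\nabla^2\rho$, so for
non-interacting copies of a motif they are strictly additive
(*extensive*); (ii) the correlation energy is itself nearly
size-extensive. Two extensive quantities indexed by the same size
parameter are collinear, so a one-parameter ordinary-least-squares model

$$\epsilon_{\mathrm{corr}} \approx a\,D + b$$

fitted on small members of a series predicts larger members at the cost
of evaluating $D$ — Hartree–Fock cost, or less.

The eleven descriptors are the Shannon entropy
$S_S = -\int \rho\ln\rho$, the Fisher information
$I_F = \int |\nabla\rho|^2/\rho$, the Ghosh–Berkowitz–Parr entropy
$S_{\mathrm{GBP}} = \int \tfrac32 k \rho\,[c + \ln(t/t_{\mathrm{TF}})]$,
the Onicescu energies $E_n = \tfrac1{n-1}\int\rho^n$ ($n = 2, 3$), the
relative Rényi integrals
$\Omega_n = \int \rho^n/(\rho^0)^{\,n-1}$ ($n = 2, 3$), the information
gain $I_G = \int \rho \ln(\rho/\rho^0)$, and three relative Fisher
measures $G_1$–$G_3$ summed over Hirshfeld atoms. The reference density
$\rho^0$ is the *promolecule*: the superposition of spherically averaged
neutral free-atom densities placed at the molecular geometry. All
internal math is in Hartree atomic units; XYZ input is Å and converted
on read (1 Å = 1.8897261254578281 bohr).

### Conventions that required a decision

Three conventions in the descriptor family are genuinely ambiguous in
the literature, and the package fixes them as follows.

* **Sign of $S_{\mathrm{GBP}}$.** The entropy is implemented with a
  positive overall sign (the original Ghosh–Berkowitz–Parr convention);
  with $k = 1$ (atomic units) and $t \equiv t_{\mathrm{TF}}$ it
  collapses to $\tfrac32 c N > 0$, consistent with published positive
  tabulations. The constants are computed from their defining
  expressions, $c_K = \tfrac3{10}(3\pi^2)^{2/3} = 2.871234$ and
  $c = \tfrac53 + \ln(4\pi c_K/3) = 4.153821$, which `gbp_constants()`
  reproduces to $10^{-12}$.
* **$R_{nr}$: integral vs. entropy form.** Published benchmark tables
  report values of magnitude $\approx N$ (the electron count), which is
  the *integral* $\Omega_n$, not the logarithmic entropy
  $\tfrac1{1-n}\log_{10}\Omega_n$. Both are exported
  (`relative_renyi_integral()`, `relative_renyi_entropy()`); the tables,
  the descriptor vector and the regression layer use the integral form.
* **$G_1$: logarithm vs. ratio.** $G_1$ is implemented as
  $\sum_A \int \nabla^2\rho_A \,\ln(\rho_A/\rho_A^0)$. The logarithmic
  form is the one consistent with the relative-Fisher family it belongs
  to ($G_3$ is built from $\nabla\ln(\rho_A/\rho_A^0)$) and with the
  tabulated magnitudes; a bare ratio in place of the logarithm would
  break the $\rho_A = \rho_A^0 \Rightarrow G_1 = 0$ identity that the
  family satisfies.

### Hirshfeld partition and the $G$ descriptors

The stockholder weights $\omega_A = \rho_A^0/\sum_B \rho_B^0$ give
$\rho_A = \omega_A\rho$, and the ratio
$\rho_A/\rho_A^0 = \rho/\rho^0$ is *atom-independent* — an identity the
implementation exploits: $G_3$ needs only the molecular and promolecular
gradients, while $G_1$/$G_2$ evaluate the per-atom Laplacians
analytically through
$\nabla^2\rho_A = q\,\nabla^2\rho_A^0 + 2\nabla\rho_A^0\!\cdot\!\nabla q
+ \rho_A^0\nabla^2 q$ with $q = \rho/\rho^0$. No numerical
differentiation is ever performed. Below a density floor of $10^{-12}$
(points that contribute below grid accuracy) logarithmic integrands are
skipped and stockholder weights fall back to a uniform share so the
partition of unity $\sum_A \omega_A = 1$ stays exact pointwise.

## Reference atoms

The promolecular reference atoms are shipped as per-element s-Gaussian
expansions $\rho^0(r) = \sum_k c_k (\alpha_k/\pi)^{3/2}
e^{-\alpha_k r^2}$ with $c_k \ge 0$ and $\sum_k c_k$ equal to the
neutral-atom electron count (H, Be, C, N, O, F, Mg, S, Cl). They were
fitted once, by non-negative least squares on a logarithmic radial grid,
to single-zeta Slater-shell atoms with Clementi–Raimondi exponents
(`inst/scripts/make_atom_refs.R`); non-negativity of the coefficients
guarantees $\rho^0 > 0$ everywhere, and the exponent grid is capped at
$3.5\times10^4$ bohr$^{-2}$ so the default radial grid resolves every
term. These are the package's own reference atoms: absolute values of
the relative descriptors ($I_G$, $G_1$–$G_3$, $\Omega_n$) depend on this
choice and will differ from implementations using other atomic
references (e.g. ROHF atoms); the *structure* of the descriptors —
identities, extensivity, linearity across a series — does not.

## Quadrature

Descriptor integrals use atom-centered product grids glued by Becke
partition-of-unity weights (the smoothing polynomial
$f(\mu) = \tfrac32\mu - \tfrac12\mu^3$ iterated three times, no
atomic-radius adjustment). Radially, Gauss–Chebyshev nodes are mapped
through Becke's transformation $r = R\,(1+x)/(1-x)$ with an
element-dependent scale $R$; angularly, a Gauss–Legendre
$\times$ uniform-$\varphi$ spherical product rule with $2k^2$ points is
used (supported sizes 32–800). Defaults are 75 radial $\times$ 288
angular points per atom, chosen so that the closed-form descriptor suite
converges to $10^{-6}$ relative: one-center Gaussian moments are exact
to $\sim 10^{-9}$, bonded multicenter promolecules (water, CO$_2$)
integrate the electron count to $\sim 5\times10^{-7}$ relative.

Two numerical caveats are worth knowing. First, accuracy at the Becke
seam: for *diffuse* densities at intermediate **nonbonded** separations
(a few bohr beyond bonding range) the inter-atomic surface cuts through
the integrand where it still varies steeply, and the angular rule
becomes the accuracy bottleneck ($\sim10^{-5}$–$10^{-4}$ relative at the
default order; raising `n_angular` to 512 restores $\sim10^{-7}$). At
bonded separations and at large separations (≥ ~10 bohr for unit-width
Gaussians) the default grid is in its accurate regime. Second, point
ordering is deterministic (atom-major, radial-major) and summation order
is fixed, so integrals are bit-stable from run to run on one platform.

## Wavefunction-backed densities

Orbital-backed fields supply the positive-definite kinetic-energy
density $t = \sum_i \tfrac{\mathrm{occ}_i}{2}|\nabla\phi_i|^2$
(equivalently $\sum_i |\nabla\rho_i|^2/8\rho_i - \nabla^2\rho/8$ inside
the GBP integrand) needed by $S_{\mathrm{GBP}}$. Basis sets are
contracted Gaussians with real solid-harmonic angular parts, s through
f; contraction coefficients multiply unit-normalized primitives and the
contracted functions are used as-is. Cartesian d/f sets are rejected
rather than silently mis-normalized — a Molden file containing d or f
shells without a `[5D]`/`[7F]` flag raises an error. The Molden
reader/writer pair round-trips this convention byte-for-byte; files from
electronic-structure codes that renormalize contractions differently
may need renormalization upstream.

## Regression statistics

`fit_lr()` is OLS with intercept. Following the benchmark-table
conventions, the training-set quality measures are
$R^2 = 1 - \mathrm{SSR}/\mathrm{SST}$ (reported rounded to 3 decimals in
summaries) and $\mathrm{RMSD} = \sqrt{\mathrm{SSR}/n}$ over all fitted
points, in millihartree — a population-style deviation, not the
$n-2$-denominator regression standard error. Scaling a descriptor
column by a constant (the tables print some columns as
"$\,/10^3$") rescales the slope and leaves $R^2$ and RMSD unchanged.
Training-set fits and extrapolation are deliberately separate verbs:
`fit_all()` reports within-training-set statistics, while
`evaluate_lr()` measures deviations of predictions on points that were
not fitted, which is the honest number for the extrapolation use case.

The packaged tables are verbatim transcriptions, with provenance,
units, column scales and known defects recorded in `#` headers. Two
defects matter: the R²/RMSD summary rows of the polyyne and polyene
tables were interchanged in the source publication (established by
refitting both data sets: each reproduces the *other* table's printed
row to the printed decimal, while the remaining four tables reproduce
their own rows), and the CO$_2$-cluster `e2`/`e3` columns contain
duplicated rows; those columns are flagged and excluded from
summary-quality checks.

## GEBF

Primitive subsystems collect, for each fragment, all fragments whose
minimal interatomic distance is within $\zeta$ (default 4.0 Å, converted
to bohr; inter-fragment distance is the minimum over atom pairs, the
standard choice), truncated to the $\gamma_{\max}$ (default 6) nearest
with ties broken by lower fragment index; primitives contained in
another primitive are dropped. Coefficients come from the closure of
the primitive family under intersection, processed in decreasing size
with $C(S) = 1 - \sum_{T \supsetneq S} C(T)$. This is the
inclusion–exclusion expansion of the union indicator collapsed over
equal intersections, and it yields two exactness guarantees tested
against a brute-force subset-expansion oracle: every fragment is counted
exactly once ($\sum_{m:\,f\in S_m} C_m = 1$), and any pairwise
interaction between fragments that co-occur in some subsystem is
counted exactly once. Consequently additive and coverable-pairwise toy
energy models are reassembled to machine precision.

The total-energy assembly applies the point-charge double-counting
correction $-(\sum_m C_m - 1)\sum_{A<B} Q_A Q_B/R_{AB}$; charges are
user-supplied (zero by default — the charge model is a property of the
energy backend, not of the bookkeeping). The correlation-energy
combination `gebf_lr_correlation()` is $\sum_m C_m\,(a x_m + b)$ with
no charge term, since the classical correction carries no correlation
component; because $\sum_m C_m = 1$, the intercept is counted exactly
once and exactly additive descriptors make the combination telescope to
the whole-system prediction.

## Synthetic fixtures: what they do and do not show

`make_gaussian_system()` builds lines of identical Gaussian "atoms",
for which every descriptor has a closed form at one center and exact
extensivity at large separation; `make_homologous_series()` adds chain
and jittered-2-D-lattice (`ring_cluster`) families with recorded seeds
for reproducible fragment layouts. These fixtures emulate the two
properties the regression protocol actually relies on — extensivity and
series-wise linearity — and the geometry/overlap structure GEBF needs.
They do **not** emulate real electronic structure: no cusps, no shell
structure, no charge transfer, no interference between overlapping
fragments, and no genuine correlation energies (synthetic targets are
built from additive models). Passing tests therefore validate the
machinery (integrals, identities, bookkeeping, statistics) and the
workflow, not the chemical accuracy of any particular fitted model on
real systems — that is what the transcribed benchmark tables are for.

Problem sizes used by the test suite and the acceptance script were
chosen to keep the closed-form suite at $10^{-6}$ accuracy while staying
small: default 75×288 grids on one- to three-center systems,
reduced 40×72 grids where only linearity (not absolute accuracy) is
exercised, 200 random cluster layouts of 3–8 fragments for the
fragmentation identities, and a train-on-2–8 / predict-9–12 split for
the extrapolation workflow.

## Known limitations

* Total densities only: no spin-resolved descriptors, ECPs or periodic
  systems.
* $S_{\mathrm{GBP}}$ requires an orbital-backed field; it is reported
  `NA` on promolecular densities. Grid points with $t \le 0$
  (numerically possible near nuclei and far tails) are skipped and
  counted.
* Absolute values of the relative descriptors depend on the packaged
  reference atoms (see above); cross-code comparisons should compare
  trends, not absolute values.
* The Rényi orders are restricted to $n \in \{2, 3\}$, matching the
  descriptor vector.
* Published extrapolation deviations that depend on unpublished
  MP2-level reference energies for large benzene clusters cannot be
  recomputed from shipped data; the workflow is validated on synthetic
  extensive fixtures instead.
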