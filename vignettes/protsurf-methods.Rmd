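---
title: "Methods behind protsurf: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind protsurf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(protsurf)
```

`protsurf` implements the quantitative backbone of an integrative
surfactant–protein complexation study, with human growth hormone (hGH)
and sodium dodecyl sulfate (SDS) as the reference system: neutron
contrast planning, small-angle-scattering modelling with multi-contrast
co-refinement, indirect Fourier inversion, and benchtop titration
analytics (ITC, fluorescence, pyrene assay, CD). This vignette records
the models, the parameters that matter, and the numerical decisions, so
that every result the package produces can be traced to an explicit
assumption.

## Scattering length densities and contrast planning

Solvent SLDs follow ideal volume-fraction mixing between pure-water
endpoints, fixed at $\rho_{\mathrm{H_2O}} = -0.56\times10^{-6}$ and
$\rho_{\mathrm{D_2O}} = 6.39\times10^{-6}\,\mathrm{\AA^{-2}}$
(`water_sld_constants()`, overridable). Buffer salts at the 10 mM level
shift the solvent SLD by well under 1% and are neglected.

Protein SLDs are computed from the sequence with a shipped residue
table (`residue_scattering_table()`): atomic compositions per residue
(amino acid minus one water), labile-hydrogen counts for neutral side
chains, Zamyatnin consensus residue volumes, and Sears coherent
scattering lengths. Each labile hydrogen contributes a scattering
length interpolated between H and D by
$x_\mathrm{ex} f_{\mathrm{D_2O}}$, with the exchange fraction
$x_\mathrm{ex} = 0.90$ by default — the standard assumption for folded
proteins where a minority of amide sites exchange slowly. Users can
replace the table (CSV in, same columns) or the exchange fraction.

Two known tensions in the source data are documented rather than
resolved. First, the experimental match point of hGH is reported as
60.1% H2O paired with an SLD of $2.31\times10^{-6}$, whereas ideal
water mixing at 60.1% gives $2.21\times10^{-6}$; the package computes
whichever quantity is requested from its stated inputs and leaves the
reconciliation to the analyst. Second, see the note on shell coverage
below.

`experimental_match_point()` fits the *signed* square root of the
forward scattering against the H2O fraction. Since $\sqrt{I(0)}$ loses
the contrast sign, the fit tries every possible single flip position
along the sorted composition axis and keeps the sign pattern with the
lowest weighted residual — a deterministic search that cannot be fooled
by a near-match composition, unlike flipping at the empirical minimum.

The zero-average-contrast (ZAC) solvent is the volume-weighted mean SLD
of the particle's components,
$\rho_s = (\varphi_A\rho_A + \varphi_B\rho_B)/(\varphi_A+\varphi_B)$.
When the protein SLD itself depends on the solvent through exchange,
the condition is solved self-consistently by 1-D root finding on the
monotone difference function.

## Form factors and absolute scale

Supported geometries are the sphere, the rotational ellipsoid and the
core–shell ellipsoid with an equal-thickness shell on both axes. (The
equal-thickness choice is a modelling decision — the alternative, a
scaled-shell ellipsoid, is not offered because the decorated-micelle
picture gives no reason for the shell to scale with the core axes.)
Orientational averaging uses Gauss–Legendre quadrature over the cosine
of the angle between $q$ and the symmetry axis, 76 points by default;
doubling the order changes the curves by less than $10^{-5}$
relatively, which is the package's convergence test.

The absolute scale convention is
$I(q) = 10^{8}\,\varphi\,\langle A(q)^2\rangle / V_\mathrm{tot} + b$,
with $A$ the contrast-weighted amplitude in $\mathrm{\AA^{-2}\AA^{3}}$,
so that a uniform particle gives
$I(0) = 10^{8}\varphi V \Delta\rho^2$ in $\mathrm{cm^{-1}}$. The same
convention is used by the co-refinement, so fitted scale factors should
be near 1 for correctly calibrated data.

Resolution smearing interprets a `dq` column as the 1-sigma width of a
Gaussian resolution kernel and averages the model over $\pm3\sigma$
with fixed-node quadrature, dropping nodes outside the support and
renormalising — constants are therefore preserved exactly and a
`dq = 0` row is returned untouched.

`guinier_fit()` iterates the fit window until all included points obey
$qR_g \le 1.3$ and $R_g$ is stable to 1%. For spheres this window
carries a known upward bias of about 2%; the tests assert exactly that
bound rather than pretending the estimator is unbiased.

## Structure factor for charged complexes

Interparticle interference is modelled with the one-component macroion
picture: particles of effective diameter equal to the equal-volume
sphere of the (possibly anisotropic) particle, net charge $Z$, in a
monovalent electrolyte. The inverse Debye length includes the released
counterions ($\tfrac12|Z|n_p$ added to the ionic strength) by default.
The screened-Coulomb (Yukawa) potential has contact value
$\gamma_0 = Z^2\lambda_B/(\sigma(1+\kappa\sigma/2)^2)$.

The mean spherical approximation closure of the Ornstein–Zernike
equation is solved numerically: a damped Picard iteration on
$\gamma(r) = h(r) - c(r)$ using discrete sine transforms on a uniform
grid (spacing $\approx 6\times10^{-4}\,\sigma$, box of 20–80 $\sigma$
adapted to the screening length; FFT length a power of two). When the
contact value of $g(r)$ is negative — the unphysical MSA regime of
dilute, highly charged dispersions — the Hansen–Hayter rescaling maps
the system to a larger effective hard core $s\sigma$ at packing
fraction $\varphi s^3$, keeping the physical potential tail, with $s$
chosen so that $g$ vanishes at contact (Illinois-variant regula falsi).
Strongly coupled bare-MSA states that fail to converge within a capped
iteration budget are routed directly to the rescaling branch, which is
exactly the set of states for which the bare solution would be
unphysical anyway. A continuation ladder in the coupling strength
backs up the plain iteration.

Accuracy is controlled against the analytic Percus–Yevick solution
(Wertheim closed form, an independent oracle that the MSA reduces to at
$Z = 0$): the default grid agrees to a few $10^{-4}$ in $S(q)$ up to
$\varphi = 0.3$. A `fast`/`coarse` grid mode (a few $10^{-3}$) is used
inside fitting loops, where it is far below the noise level. The
$P(q)\,S(q)$ product neglects the orientation–amplitude coupling of
anisotropic particles (no $\beta(q)$ decoupling correction); at the
axial ratios of this system the approximation is conventional SAS
practice.

The dielectric constant (78.3), temperature (298.15 K) and 10 mM
monovalent salt defaults describe the study's phosphate-buffered water;
the source study does not state the values used for its charge fits, so
these are assumptions, exposed as parameters.

## Indirect Fourier transform

$p(r)$ is expanded in `n_basis = 30` sine functions vanishing at 0 and
$D_{max}$ and fitted to $I(q)$ by weighted linear least squares with a
second-difference roughness penalty evaluated on a 101-point $r$ grid.
The stacked system is solved by SVD, which tolerates the enormous
dynamic range of SANS weights; a numerically singular unregularised
system is refused with a pointer to a positive `alpha`. When the curve
carries `dq`, each basis function's forward transform is smeared before
fitting, so the inversion is of the ideal curve.

The smoothing weight is chosen deterministically: over a fixed grid of
16 decades (centred on the ratio of the mean squared entries of the
design and penalty operators), the package picks the *smoothest
solution whose misfit is within 10% of the best achievable* — a
discrepancy-style knee criterion. A classical L-curve chord corner was
tried first and proved unstable on these problems: the roughness norm
decreases monotonically with smoothing without saturating, so the
log–log trade-off curve has no corner in the geometric sense. The rule
is seedless and deterministic; `alpha` can always be pinned manually.

Negative $p(r)$ is permitted by default, matching common practice for
regularised inversions of noisy data; a soft non-negativity switch
(`nonneg = TRUE`, quadratic penalty with reweighting) is available.
Derived quantities use the tabulated $p(r)$:
$I(0) = 4\pi\int p\,dr$, $R_g^2 = \int r^2 p\,dr / (2\int p\,dr)$.

`dmax_scan()` refits over a $D_{max}$ grid and selects the smallest
value beyond which $R_g$ changes by less than 2% to the next grid point
while $\chi^2_\nu$ stays within 10% of the grid best; without such a
plateau it returns the best-misfit value flagged `"unstable"`.

## Multi-contrast co-refinement

`sans_cofit()` shares the core–shell geometry, the protein coverage of
the shell and the net charge across all contrasts; intensity scale and
flat background are per contrast. The shell SLD of contrast $j$ is the
two-component mix $c\,\rho_{\mathrm{prot},j} + (1-c)\,\rho_{\mathrm{solv},j}$,
so coverage is a shared, contrast-independent parameter — this is what
makes the four curves mutually constraining. The particle volume
fraction follows from the protein concentration (one protein per
complex), so it tracks the geometry rather than being a free scale.

Optimisation is Levenberg–Marquardt (trust-region, `minpack.lm`) on the
concatenated uncertainty-weighted residuals, with positive parameters
on a log scale and coverage on a logit scale. A small deterministic
start grid (nominal and two perturbed core/shell combinations)
mitigates local minima. Uncertainties come from the inverse of $J^TJ$
at the optimum and are propagated to derived quantities — aggregation
number $N_{agg} = v_\mathrm{core}/v_\mathrm{SDS}$, coverage, charge —
by the first-order delta method. The default surfactant molecular
volume is 412 $\mathrm{\AA^3}$ (whole SDS molecule), exposed as a
parameter.

On shell coverage: inverting the fitted shell SLD through the linear
mix gives $c = (\rho_s - \rho_\mathrm{shell})/(\rho_s - \rho_p)$. With
the decorated-micelle values ($\rho_\mathrm{shell} = 3.43\times10^{-6}$,
$\rho_p = 2.79\times10^{-6}$, $\rho_s = 6.37\times10^{-6}$) this
formula yields 0.82, whereas the source study quotes "ca. 66%" for the
same shell SLD; no linear mixing rule reproduces that pairing. The
package implements the transparent formula and reports its value.

The ZAC forward check evaluates the refined model at the solvent SLD
that zeroes the volume-weighted mean contrast of the dry complex
(surfactant core plus the protein fraction of the shell):
$\rho_s = (V_c\rho_c + cV_{sh}\rho_p)/(V_c + cV_{sh})$. At that
composition the $q \to 0$ amplitude cancels algebraically, so
$|I(0)| < 10^{-6} I_\mathrm{max}$ is a sharp correctness test of the
amplitude bookkeeping, while the surviving finite-$q$ bump is the
internal-correlation fingerprint of core/shell segregation.

## Benchtop analytics

* **Trp emission**: spectral centre of mass over 310–450 nm (the full
  band; configurable). Scale-invariant by construction.
* **Pyrene**: $I_3/I_1$ from band maxima within $\pm3$ nm of 384 and
  373 nm.
* **Breakpoints**: two-segment weighted fit with exhaustive split
  search (min. 3 points per segment); the reported abscissa is the
  intersection of the two lines with a delta-method error. A split must
  reduce the residual sum of squares by at least 20% over a single
  line, otherwise the series is flagged as break-free — this keeps the
  method from hallucinating kinks in linear data.
* **ITC**: cell concentrations use the standard perfusion displacement
  model $C_k = C_\mathrm{syr}(1-\prod_i(1-v_i/V_0))$. Transition
  proposal is an exact dynamic-programming segmentation of molar heat
  versus concentration (minimum SSE per segment count, BIC model
  selection with 3 parameters per segment); boundaries are intersections
  of adjacent fitted lines. The proposal is semi-automatic by design —
  an analyst can pin transitions manually, mirroring how enthalpograms
  are read in practice. The stoichiometry fit
  $[\mathrm{SDS}] = [\mathrm{SDS}]_\mathrm{unbound} + N_{agg}[\mathrm{hGH}]$
  is a weighted linear regression with protein in mM so the slope is
  dimensionless; protein is expressed in uM and SDS in mM throughout
  the interfaces.
* **CD**: mean residue ellipticity
  $\theta_{MR} = \theta_\mathrm{mdeg}\,\mathrm{MRW}/(10\,l\,c)$;
  descriptors at 209/220/292 nm by linear interpolation. The helix
  marker is the 220/209 ratio (the second helix band sits near 222 nm,
  but the ratio is conventionally taken at 220 nm and that convention
  is followed here).
* **A280**: Beer–Lambert with the hGH constants
  ($\varepsilon = 17670\,\mathrm{M^{-1}cm^{-1}}$, 22124 Da) as
  defaults.

## What the synthetic generators emulate — and what they do not

The generators exist so every analysis route has a ground truth.
Their defaults are the study conditions of the reference system:

* `gen_sans()`: the four-contrast scheme (protein/complex/surfactant
  SLD identities, near-fully deuterated surfactant for ZAC), a
  decorated-micelle complex (core $12\times12\times18$ Å, 12 Å shell,
  coverage 0.66, charge $-29$, $N_{agg} \approx 26$ at 0.135 mM
  protein), 5% relative Gaussian $q$ resolution, and counting-type
  noise $dI = 0.01\sqrt I + 0.002\,\mathrm{cm^{-1}}$.
* `gen_itc()`: five stages with bound numbers (6, 23, 32, 61, 61) and
  unbound concentrations (0.51, 0.81, 1.3, 4.1, 5.4) mM; piecewise
  linear molar heat relaxing to zero after the last stage; 70 × 5 uL
  injections of 60 mM titrant into a 1400 uL cell (the finer-than-usual
  schedule resolves the closely spaced early stages); Gaussian heat
  noise of 0.03 kcal/mol.
* `gen_fluorescence()` / `gen_cd()`: two- and three-state basis mixing
  with logistic transitions in the surfactant-to-protein ratio. The CD
  midpoints/widths (37/9.5 and 105/21) are chosen so the 10–90% spans
  match the observed onset/completion ratios (16–58 near-UV, 59–150
  far-UV); fluorescence uses midpoint 80, width 18 for the same reason.
* `gen_pyrene()`: two plateaus (0.62 to 0.95) joined linearly between
  the aggregation concentration and three times it.

They deliberately do *not* emulate: incoherent-background variation
between contrasts, detector artefacts or desmearing residuals,
exo/endothermic overlap within single ITC injections, solvent Raman
bands in emission spectra, or concentration-dependent complex
polydispersity. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under their own assumptions — not
that those assumptions exhaust real beamline or calorimeter data.

## Problem sizes and determinism

The shipped tests run the full pipeline at deliberately modest sizes:
60-point curves for co-refinement, 120-point curves for the IFT, six
seeded replicates for the uncertainty-calibration check, and
single-start refinements wherever the start is known to be in the
basin. These sizes were chosen as the smallest at which the statistical
assertions (3-sigma parameter recovery, 2-sigma stoichiometry recovery,
chi-squared calibration) are stable across seeds. All stochastic steps
take explicit seeds; the RMSA solver, the IFT smoothing selection and
the segmentations are seedless deterministic algorithms.

## Known limitations

* The residue table uses neutral side chains; at pH 7 the acidic
  protons of Asp/Glu are in fact dissociated, which shifts protein
  SLDs by well under 1% but matters if one pushes match points to three
  decimals.
* The macroion structure factor treats the complex as an equal-volume
  sphere; at axial ratios beyond ~2 the missing decoupling correction
  becomes visible around the interaction peak.
* The IFT reports regularised (correlated) point errors on $p(r)$;
  they are indicative, not a full posterior.
* `detect_transitions()` segments integrated molar heats only; raw
  heat-flow shapes within injections (which practitioners also consult)
  are out of scope.
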