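---
title: "Modelling protein-decorated supported bilayers with specular neutron reflectometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling protein-decorated supported bilayers with specular neutron reflectometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrslab)
```

## The measurement and the model

Specular neutron reflectometry (NR) measures the fraction of neutrons
reflected from a planar interface as a function of the wave-vector transfer
$Q_z = 4\pi \sin\theta / \lambda$. Because the reflectivity is determined by
the depth profile of the coherent scattering length density (SLD),
$\rho(z)$, it resolves the composition of a layered solid--liquid interface
normal to the surface with ångström-scale sensitivity. `nrslab` models such
interfaces as stacks of homogeneous slabs between two semi-infinite media
(the silicon substrate the beam travels through, and the bulk solvent) and
computes the exact specular reflectivity with the optical-matrix (Abelès)
method: in medium $n$, the normal wavevector is
$k_n = \sqrt{(Q/2)^2 - 4\pi(\rho_n - \rho_\mathrm{Si})}$, each interfacial
Fresnel coefficient is damped by the Névot--Croce factor
$\exp(-2 k_n k_{n+1} \sigma^2)$ for a Gaussian interface of width $\sigma$,
and the reflectivity is $|M_{21}/M_{11}|^2$ of the characteristic-matrix
product. The kernel is checked in the test suite against the closed-form
Fresnel solution and against an independent Parratt recursion on random
stacks.

Finite instrumental resolution is applied as a Gaussian convolution in $Q$
with constant fractional width. Throughout the package `dq_over_q` is the
*FWHM* of that kernel ($\sigma = \mathrm{FWHM}/2.355$), the convention used
when a time-of-flight reflectometer quotes a "nominal resolution" of a few
percent; the default is 3.5%. The model is always evaluated on a log-spaced
grid oversampled at least five-fold relative to the data and extended past
both ends of the measured range, so endpoint kernels are never truncated
and closely spaced Kiessig fringes are not aliased.

## Scattering-length bookkeeping and contrast variation

All SLDs derive from tabulated bound coherent scattering lengths
(`formula_sum_b()`), with the molecular volume of water fixed at
30.0&nbsp;Å³ so that the H₂O and D₂O endpoints take their conventional
values ($-0.56$ and $6.4 \times 10^{-6}$&nbsp;Å⁻²). Isotopic solvent
mixtures interpolate linearly between those endpoints.

Proteins are described by their amino-acid composition
(`protein_composition()`), using per-residue element counts, labile
(solvent-exchangeable) hydrogen counts at neutral protonation, and
Zamyatnin residue volumes. Labile hydrogens are assumed to exchange
completely and in proportion to the solvent D₂O fraction; no kinetic
retardation factor is applied. Both the protein and the solvent SLD are
then affine in the D₂O fraction, so the *contrast match point* — the
solvent composition at which the protein becomes invisible — has a closed
form (`match_point()`). For an average globular composition it falls near
42% D₂O, the usual "protein-matched water". Because the match point of any
specific protein depends (weakly) on its sequence, both the generic average
composition and an explicit sequence (FASTA input) are supported; the
bundled `synthetic_lipoprotein.fasta` is a synthetic sequence drawn from
average amino-acid frequencies, used by tests and examples in place of any
particular real protein.

DMPC is split into a headgroup component (319&nbsp;Å³) and a two-tail
component (782&nbsp;Å³, 54 substitutable hydrogens in the chain-deuterated
d54 form), literature values kept in a single editable registry
(`component_registry()`) so they can be overridden from a run
configuration.

## The five- and seven-layer interfacial models

The bilayer--lipoprotein model (`pqic_model_params()`) renders, from the
substrate outwards: a thin hydrated SiO₂ layer, inner headgroups, two
acyl-tail leaflets, outer headgroups, and a uniform protein slab for the
membrane-bound ring lipoprotein. Two deliberate constraints follow common
practice for supported-bilayer NR analysis:

* **Shared area per molecule.** Head and tail layer thicknesses are not
  free: they equal the component molecular volume divided by a single area
  per lipid molecule shared by both leaflets. This preserves the molar
  ratio of heads to tails whatever the area refines to.
* **Two water parameters plus coverage.** Defect water in the membrane is
  parameterised by separate head and tail hydration fractions together
  with an overall in-plane coverage — the minimal parameterisation that
  lets headgroups and tails hydrate differently.

The protein slab is a uniform mixture of protein and solvent with no shape
function, consistent with interpreting it as a ~50&nbsp;Å layer sitting in
and above the outer headgroups.

The trans-envelope model (`pqiabc_model_params()`) appends a thick but
dilute slab for the periplasm-spanning protein and a distal slab of mixed
protein and hydrogenous lipid (a second, lower-coverage membrane), plus a
mixing fraction that dilutes the deuterated proximal tails with
hydrogenous lipid — needed because lipid exchanges between the two
membranes during assembly. The mixing is applied to the tail layers only:
headgroup scattering sums are nearly isotope-independent apart from labile
hydrogens, so mixing there is invisible at these contrasts. The SLD of the
spanning layer is tied to the same protein composition as the lipoprotein
slab by default, with a free volume fraction; an independent composition
can be supplied if the two should differ.

The geometry (thicknesses, roughnesses, occupancies) is contrast-invariant
by construction: re-rendering the same parameters at a different solvent
changes only SLDs. This is the contract that makes simultaneous
multi-contrast fitting meaningful.

`volume_fraction_profile()` converts a parameter set into per-component
volume fractions versus depth, smearing each slab boundary with the same
error-function widths as the reflectivity kernel and filling all residual
volume with solvent, so fractions sum to one at every depth (a tested
invariant at 10⁻⁶). `intermembrane_distance()` reports the span between
the two modelled membranes as the sum of the lipoprotein and spanning
layer thicknesses, i.e. from the solution-side boundary of the proximal
outer headgroups to the substrate-side boundary of the distal layer. The
literature value this corresponds to is quoted without an explicit
endpoint convention; ours excludes headgroup thicknesses and is recorded
in the output's `convention` attribute rather than guessed both ways.

## Fitting and uncertainty

`fit_problem()` couples one parameter set to any number of
(curve, solvent) pairs. The objective is half the uncertainty-weighted sum
of squared residuals over all datasets, with the model curve per dataset
scaled by a multiplicative factor and offset by an additive background —
both free nuisance parameters by default, as is standard practice for NR
(normalisation and incoherent background are never known exactly). Priors
default to flat within bounds; normal priors can be declared per parameter
in the configuration.

`fit()` runs bounded L-BFGS-B on a unit-box reparameterisation of the
free parameters. The rescaling keeps finite-difference steps commensurate
across parameters whose natural magnitudes differ by eight orders
(areas in Å² versus backgrounds of 10⁻⁷), which is what makes the
optimisation reliable; given a start the result is deterministic.
Non-convergence is reported with diagnostics rather than raised.

`sample_posterior()` implements the affine-invariant ensemble sampler
(Goodman--Weare stretch move, scale $a = 2$), initialised in a small ball
around the best fit, with the burn-in discarded and all settings (walkers,
steps, burn-in, seed, acceptance fraction) recorded in the result
metadata. Ensemble moves need no step-size tuning across the very
differently scaled parameters, which is why this sampler family is the de
facto standard for reflectometry error analysis. An acceptance fraction
outside [0.1, 0.9] is flagged in the metadata. `credible_band()` extracts
pointwise central intervals of any functional of the parameters — a single
parameter, a model reflectivity curve, or a volume-fraction profile — with
65% as the default level, following the reflectometry convention of
quoting the central 65% of accepted fits.

Default sampler settings are 64 walkers and 5,000 steps with 1,000
discarded. The validation harnesses in the tests and the acceptance script
use deliberately smaller problems — 100-point curves, three to six free
parameters, 12 walkers and a few hundred steps — chosen so that the whole
round-trip study (twenty replicate experiments with full fits and chains)
completes in minutes on a single core while still giving stable coverage
statistics; these sizes are recorded here as the package's own validation
design.

## What the synthetic generator does and does not emulate

`simulate_experiment()` stands in for a measured contrast series: for each
solvent it builds the ground-truth stack, smears the exact reflectivity at
3.5% dQ/Q over a log-spaced Q grid on 0.01--0.3&nbsp;Å⁻¹, and perturbs it
with Gaussian noise of width $\sigma = 0.01\,R + 10^{-7}$ — a 1% relative
floor plus a constant instrument background, so the relative error grows
as the signal falls towards background, qualitatively like
counting-statistics error bars on a time-of-flight instrument. The quoted
uncertainty column holds the exact $\sigma$ used, so simulated z-scores
are standard normal by construction (a tested property). The generator
does *not* emulate instrument specifics: flux spectra, detector effects,
gravity on a hanging flow cell, per-point resolution variation, or
correlated backgrounds. Round-trip results on synthetic data therefore
demonstrate the self-consistency and calibration of the pipeline, not the
absence of systematic effects in real measurements.

The built-in catalogue (`builtin_scenarios()`) mirrors a four-stage
assembly — bare substrate, bilayer, bilayer plus a 50&nbsp;Å lipoprotein
layer, and the full trans-envelope structure with a 230&nbsp;Å spanning
layer (280&nbsp;Å intermembrane distance) — each at the four solvent
contrasts 100%, 80%, 42% and 0% D₂O.

## QCM-D and structure metrics

`sauerbrey_mass()` converts overtone frequency shifts to areal mass via
$\Delta m / A = -C \, \Delta f_n / n$ with
$C = \sqrt{\rho_q \mu_q} / (2 f_0^2)$ (17.7&nbsp;ng&nbsp;cm⁻²&nbsp;Hz⁻¹
for a 5&nbsp;MHz crystal). Two conventions are fixed and recorded in the
output: shifts are normalised by the overtone number before conversion,
and a frequency *decrease* is reported as *positive* adsorbed mass.
Viscoelastic (Voigt) modelling is out of scope; high-dissipation
depositions should be read qualitatively. `step_change()` uses windowed
medians, robust to injection spikes.

The structure module measures the geometry behind ring-assembly
interpretations: `superpose_rmsd()` (Kabsch SVD superposition, verified
against a quaternion-method oracle; optional iterative pruning of pairs
beyond a 2&nbsp;Å cutoff — an approximation to viewers' unstated pruning
rules, so the all-pair value is the reference number),
`find_salt_bridges()` (4.0&nbsp;Å heavy-atom cutoff between carboxylate
oxygens and Lys/Arg side-chain nitrogens; His only via an explicit flag),
`assembly_from_symmetry()` (operator expansion plus a contact-graph check
that the copies close into a single ring), and `pore_profile()` (largest
axis-centred probe sphere clearing all atoms, Bondi radii, reported per
axial station along with the minimum pore and maximum outer diameters).
C$\alpha$ atoms are assumed for alignments, noted in outputs. These are
probe-based, not solvent-rolled, definitions.

## Numerical choices and limitations

* Complex square roots take the principal branch, giving decaying
  evanescent waves below the critical edge; total reflection emerges from
  the algebra and no post-hoc clipping is applied.
* Imaginary SLD (absorption) is carried through the arithmetic but
  defaults to zero; magnetic scattering and off-specular signals are out
  of scope.
* Measured curves may dip slightly negative at background level after
  noise; the container tolerates small excursions rather than clamping,
  which would bias noise statistics.
* The two tail leaflets share one area per molecule and one hydration;
  asymmetric bilayers would need the registry and occupancy matrix
  extended.
* Slab models with error-function interfaces cannot represent strongly
  non-boxcar protein shapes; a shape-function extension would slot in at
  the occupancy matrix.
* Parameter recovery tolerances (thicknesses within ±2&nbsp;Å, area per
  molecule within ±2&nbsp;Å²) hold for the built-in scenarios at 1%
  noise; heavier noise, fewer contrasts, or strong parameter correlations
  (e.g. coverage against hydration) widen them, and the joint-fit-versus-
  single-contrast test exists precisely to document that sharing geometry
  across contrasts is what keeps them tight.
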