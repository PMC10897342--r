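# nrslab

Forward modelling and Bayesian analysis of **specular neutron
reflectometry (NR)** from layered solid–liquid interfaces, built for
supported lipid bilayers decorated with peripheral and trans-envelope
membrane proteins — the kind of system assembled when a membrane-bound
ring lipoprotein and a periplasm-spanning partner protein are
reconstituted, stage by stage, on a silicon-supported bilayer. It is aimed
at membrane biophysicists and structural biologists who collect contrast
variation NR (and companion QCM-D) data on such assemblies and want a
scriptable, testable pipeline from raw `Q R dR` files to structural
parameters with credible intervals.

## What it computes

**Reflectivity kernel.** The exact specular reflectivity of a slab stack
via the optical-matrix (Abelès) method, with wavevector
`k_n = sqrt((Q/2)^2 − 4π(ρ_n − ρ_Si))`, Névot–Croce roughness damping
`exp(−2 k_n k_{n+1} σ²)` per interface, and Gaussian dQ/Q resolution
smearing (FWHM convention, default 3.5%).

**Contrast bookkeeping.** SLDs from tabulated scattering lengths; lipid
head/tail component volumes in an editable registry; protein SLDs from
amino-acid composition with complete labile-H exchange, giving the
closed-form contrast match point (~42% D₂O for an average protein — the
"protein-matched water" contrast).

**Interfacial models.** A five-layer bilayer–lipoprotein model (oxide,
inner heads, two tail leaflets, outer heads, protein slab) in which head
and tail thicknesses derive from one shared area per lipid molecule
(`thickness = V / APM`), hydration enters as two water parameters plus a
coverage, and each slab SLD is defined by `SLD = Σb / V`; and a
seven-layer trans-envelope extension adding a thick dilute protein span
and a distal mixed protein/lipid membrane, with hydrogenous lipid mixing
into the proximal deuterated tails.

**Inference.** Simultaneous fitting of all solvent contrasts against one
shared geometry (χ² likelihood, per-dataset scale and background nuisance
parameters, bounded L-BFGS-B), affine-invariant ensemble MCMC
(Goodman–Weare stretch move), and 65% credible bands on parameters,
reflectivity curves and volume-fraction depth profiles.

**Companions.** A synthetic experiment generator (ground-truth stacks,
3.5% smearing, 1% relative noise with instrument-background inflation,
seeded); Sauerbrey conversion of QCM-D overtone shifts
(`Δm/A = −(Δf/n)·√(ρ_q μ_q)/(2 f₀²)`, 17.7 ng cm⁻² Hz⁻¹ at 5 MHz) with
robust step extraction; and geometry metrics for ring assemblies — Kabsch
superposition RMSD, salt-bridge detection, symmetry expansion into closed
rings, and axial pore-radius profiles.

## Worked example

Simulate the built-in "bilayer + lipoprotein" scenario (truth: 50 Å
protein layer, 60 Å² area per lipid, four contrasts at 1% noise) and
refit it from deliberately wrong start values:

```r
library(nrslab)

sc  <- builtin_scenarios()$bilayer_pqic
sim <- simulate_experiment(sc)

start <- pqic_model_params(sio2_thickness = 12, sio2_hydration = 0.08,
                           apm = 55, head_hydration = 0.30,
                           tail_hydration = 0.08, bilayer_coverage = 0.90,
                           pqic_thickness = 40, pqic_volume_fraction = 0.30)
problem <- fit_problem("pqic", start,
  free = list(apm = c(45, 75), head_hydration = c(0, 0.6),
              tail_hydration = c(0, 0.3), bilayer_coverage = c(0.6, 1),
              pqic_thickness = c(20, 80), pqic_volume_fraction = c(0.05, 0.6)),
  datasets = sim)
fit(problem)
#> <nr_fit>
#>   apm                      60.1062
#>   head_hydration           0.347409
#>   tail_hydration           0.0448018
#>   bilayer_coverage         0.945309
#>   pqic_thickness           49.9571
#>   pqic_volume_fraction     0.24924
#>   ...
#>   -log L = 206; chi^2/point = 1.21, 0.945, 0.985, 0.977; convergence = 0
```

The area per molecule comes back within 0.2 Å² of truth and the protein
layer within 0.05 Å, at χ²/point ≈ 1 — i.e. the fit is consistent with the
quoted uncertainties. `sample_posterior()` then draws the posterior and
`credible_band()` turns it into 65% intervals on any quantity:

```r
comp <- average_protein_composition()
match_point(comp)                     # 0.435 — matched by ~43% D2O water
sauerbrey_mass(-49, quartz_crystal(), harmonic = 3)
#> 288.6 ng/cm2 — a 49 Hz third-overtone drop on a 5 MHz crystal
```

A command-line front end (`inst/exec/nrslab`) wraps the same functions:
`simulate`, `fit`, `sample`, `profile`, `matchpoint`, `qcmd` and
`structure` subcommands, all driven by a YAML run configuration and
seeded for bit-identical regeneration of any report.

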