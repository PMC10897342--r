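# The five- and seven-layer interfacial models, their contrast-sharing
# contract, volume-fraction profiles and derived distances.

test_that("null protein layer reduces to a protein-free bilayer stack", {
  base <- list(sio2_thickness = 12, sio2_hydration = 0.1, apm = 60,
               head_hydration = 0.35, tail_hydration = 0.05,
               bilayer_coverage = 0.95)
  with_prot <- do.call(pqic_model_params,
                       c(base, pqic_thickness = 50,
                         pqic_volume_fraction = 0))
  no_prot <- do.call(pqic_model_params,
                     c(base, pqic_thickness = 50,
                       pqic_volume_fraction = 0))
  s1 <- build_pqic_stack(with_prot, solvent(0.8))
  s2 <- build_pqic_stack(no_prot, solvent(0.8))
  # protein slab contains pure solvent, so reflectivity matches a stack
  # whose protein layer is plain solvent
  q <- seq(0.01, 0.3, by = 0.002)
  expect_equal(reflectivity(s1, q), reflectivity(s2, q))
  expect_equal(s1$layers[[6]]$sld, solvent(0.8)$sld)
})

test_that("contrast variation changes SLDs only, never the geometry", {
  p <- pqic_model_params()
  stacks <- lapply(c(1.0, 0.8, 0.42, 0.0), function(f) {
    build_pqic_stack(p, solvent(f))
  })
  thick <- function(st) vapply(st$layers, function(l) l$thickness, numeric(1))
  rough <- function(st) vapply(st$layers, function(l) l$roughness, numeric(1))
  for (st in stacks[-1]) {
    expect_identical(thick(st), thick(stacks[[1]]))
    expect_identical(rough(st), rough(stacks[[1]]))
  }
  slds <- vapply(stacks, function(st) st$layers[[6]]$sld, numeric(1))
  expect_true(all(diff(rev(slds)) > 0))   # protein layer tracks the solvent
})

test_that("head and tail thicknesses derive from the area per molecule", {
  reg <- component_registry()
  p <- pqic_model_params(apm = 60, registry = reg)
  st <- build_pqic_stack(p, solvent(1))
  expect_equal(st$layers[[2]]$thickness,
               reg$dmpc_head$molecular_volume / 60)
  expect_equal(st$layers[[3]]$thickness,
               reg$dmpc_tails$molecular_volume / 60 / 2)
  expect_equal(st$layers[[3]]$thickness, st$layers[[4]]$thickness)
})

test_that("layer SLDs are convex mixtures of component and solvent SLDs", {
  p <- pqic_model_params()
  for (f in c(0, 0.42, 1)) {
    solv <- solvent(f)
    st <- build_pqic_stack(p, solv)
    comp_slds <- c(component_sld(p$registry$sio2),
                   component_sld(p$registry$dmpc_head),
                   component_sld(p$registry$dmpc_tails, TRUE),
                   protein_sld(p$protein, f), solv$sld)
    rng <- range(comp_slds)
    for (ly in st$layers) {
      expect_gte(ly$sld, rng[1] - 1e-18)
      expect_lte(ly$sld, rng[2] + 1e-18)
    }
  }
})

test_that("seven-layer model with empty extensions matches the five-layer model", {
  p7 <- pqiabc_model_params(pqib_thickness = 0, pqib_volume_fraction = 0,
                            distal_thickness = 0,
                            distal_protein_fraction = 0,
                            distal_lipid_fraction = 0,
                            hdmpc_mixing_fraction = 0)
  p5 <- pqic_model_params()
  q <- seq(0.01, 0.3, by = 0.002)
  for (f in c(1, 0)) {
    expect_equal(reflectivity(build_pqiabc_stack(p7, solvent(f)), q),
                 reflectivity(build_pqic_stack(p5, solvent(f)), q),
                 tolerance = 1e-12)
  }
})

test_that("full lipid mixing turns the proximal tails hydrogenous", {
  p <- pqiabc_model_params(hdmpc_mixing_fraction = 1, tail_hydration = 0,
                           bilayer_coverage = 1)
  st <- build_pqiabc_stack(p, solvent(1))
  expect_equal(st$layers[[3]]$sld,
               component_sld(p$registry$dmpc_tails, deuterated = FALSE))
})

test_that("trans-envelope stack produces fringes spaced by its total thickness", {
  p <- pqiabc_model_params(pqib_thickness = 230, roughness = 0)
  st <- build_pqiabc_stack(p, solvent(1))
  total <- sum(vapply(st$layers, function(l) l$thickness, numeric(1)))
  q <- seq(0.03, 0.12, by = 2e-5)
  lr <- log(reflectivity(st, q))
  minima <- q[which(diff(sign(diff(lr))) == 2) + 1]
  # dominant fringe spacing reflects the full interfacial thickness
  expect_equal(stats::median(diff(minima)), 2 * pi / total, tolerance = 0.1)
})

test_that("volume fractions sum to one everywhere and respect the slabs", {
  p <- pqiabc_model_params()
  set.seed(11)
  z <- sort(runif(1000, -40, 450))
  prof <- volume_fraction_profile(p, z)
  sums <- rowSums(prof[, setdiff(names(prof), "z")])
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(as.matrix(prof[, -1]) >= -1e-12))
  expect_true(all(as.matrix(prof[, -1]) <= 1 + 1e-12))

  # zero roughness: piecewise-constant profile equal to slab occupancies
  p0 <- pqic_model_params(roughness = 0)
  zmid <- c(-5, 6, 14, 20, 27, 33, 60, 200)   # one point inside each medium
  prof0 <- volume_fraction_profile(p0, zmid)
  expect_equal(prof0$substrate, c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(prof0$oxide[2], 1 - p0$sio2_hydration)
  expect_equal(prof0$tails[4],
               p0$bilayer_coverage * (1 - p0$tail_hydration))
  expect_equal(prof0$pqic[7], p0$pqic_volume_fraction)
  expect_equal(prof0$solvent[8], 1)
})

test_that("protein layer amount is conserved under roughness smearing", {
  p <- pqic_model_params(pqic_thickness = 50, pqic_volume_fraction = 0.25,
                         roughness = 6)
  z <- seq(-100, 300, by = 0.1)
  prof <- volume_fraction_profile(p, z)
  integral <- sum(prof$pqic) * 0.1
  expect_equal(integral, 50 * 0.25, tolerance = 0.005)
})

test_that("profile-weighted SLD reproduces the smeared slab SLD profile", {
  p <- pqic_model_params()
  solv <- solvent(0.8)
  st <- build_pqic_stack(p, solv)
  z <- seq(-30, 150, by = 0.5)
  prof <- volume_fraction_profile(p, z)
  comp_slds <- c(
    substrate = component_sld(p$registry$silicon),
    oxide = component_sld(p$registry$sio2),
    heads = component_sld(p$registry$dmpc_head),
    tails = component_sld(p$registry$dmpc_tails, TRUE),
    pqic = protein_sld(p$protein, solv$f_d2o),
    solvent = solv$sld
  )
  from_prof <- as.matrix(prof[, names(comp_slds)]) %*% comp_slds
  from_slab <- sld_profile(st, z)
  expect_equal(as.numeric(from_prof), from_slab, tolerance = 1e-6)
})

test_that("intermembrane distance is the protein span, hydration-invariant", {
  p <- pqiabc_model_params(pqic_thickness = 50, pqib_thickness = 230)
  expect_equal(as.numeric(intermembrane_distance(p)), 280)
  expect_match(attr(intermembrane_distance(p), "convention"), "headgroup")
  p2 <- pqiabc_model_params(pqic_thickness = 50, pqib_thickness = 230,
                            head_hydration = 0.6, tail_hydration = 0.2,
                            sio2_hydration = 0.3)
  expect_equal(as.numeric(intermembrane_distance(p2)), 280)
  p0 <- pqiabc_model_params(pqic_thickness = 0, pqib_thickness = 0)
  expect_equal(as.numeric(intermembrane_distance(p0)), 0)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(pqic_model_params(apm = -5), "> 0")
  expect_error(pqic_model_params(head_hydration = 1.3), "\\[0, 1\\]")
  expect_error(pqiabc_model_params(distal_protein_fraction = 0.7,
                                   distal_lipid_fraction = 0.5),
               "exceed 1")
  expect_error(volume_fraction_profile(pqic_model_params(), c(3, 2, 1)),
               "increasing")
})
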