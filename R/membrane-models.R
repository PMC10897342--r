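# Parametric interfacial models: the five-layer bilayer-lipoprotein (PqiC)
# structure and the seven-layer trans-envelope (PqiABC) structure, rendered
# into layer stacks per solvent contrast, plus volume-fraction depth
# profiles and derived distances.
#
# Geometry (thicknesses, roughnesses, occupancies) is shared across solvent
# contrasts; only SLDs change with the isotopic composition. Head and tail
# layer thicknesses are not free parameters: they derive from the shared
# area per lipid molecule through the component molecular volumes.

.check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]")
  }
}

# interfaces of the bilayer-lipoprotein stack, substrate side first
.PQIC_INTERFACES <- c("sio2", "heads_in", "tails_in", "tails_out",
                      "heads_out", "pqic", "backing")
.PQIABC_INTERFACES <- c(.PQIC_INTERFACES[-7], "pqib", "distal", "backing")

.expand_roughness <- function(roughness, interfaces) {
  n <- length(interfaces)
  if (length(roughness) == 1L) roughness <- rep(roughness, n)
  if (length(roughness) != n) {
    stop("roughness must be scalar or length ", n,
         " (", paste(interfaces, collapse = ", "), ")")
  }
  if (any(roughness < 0)) stop("roughness must be >= 0")
  stats::setNames(as.numeric(roughness), interfaces)
}

#' Parameters of the five-layer bilayer-lipoprotein model
#'
#' Describes a silicon-supported deuterated-DMPC bilayer carrying a surface
#' layer of a ring lipoprotein (PqiC) on its solution-side leaflet. Moving
#' from the substrate to the solution the slabs are: thin silicon oxide,
#' inner headgroups, two acyl-tail leaflets, outer headgroups, and the
#' protein layer. Headgroup and tail thicknesses derive from the shared
#' area per lipid molecule (`apm`) via the component molecular volumes; the
#' two hydration parameters and the overall bilayer coverage describe the
#' water associated with membrane defects.
#'
#' @param sio2_thickness oxide thickness, A.
#' @param sio2_hydration solvent volume fraction in the oxide.
#' @param apm area per lipid molecule shared by both leaflets, A^2.
#' @param head_hydration solvent fraction inside the headgroup regions.
#' @param tail_hydration solvent fraction inside the tail region.
#' @param bilayer_coverage in-plane coverage of the bilayer patch.
#' @param pqic_thickness protein layer thickness, A.
#' @param pqic_volume_fraction protein volume fraction in its layer.
#' @param roughness interfacial roughness, A: a scalar recycled to all
#'   interfaces or a vector over (sio2, heads_in, tails_in, tails_out,
#'   heads_out, pqic, backing).
#' @param protein a [protein_composition()] for the protein layer SLD;
#'   default the average globular composition.
#' @param registry component registry, see [component_registry()].
#' @return object of class `pqic_model_params`.
#' @export
pqic_model_params <- function(sio2_thickness = 12,
                              sio2_hydration = 0.10,
                              apm = 60,
                              head_hydration = 0.35,
                              tail_hydration = 0.05,
                              bilayer_coverage = 0.95,
                              pqic_thickness = 50,
                              pqic_volume_fraction = 0.25,
                              roughness = 3,
                              protein = average_protein_composition(),
                              registry = component_registry()) {
  if (apm <= 0) stop("apm must be > 0")
  if (sio2_thickness < 0 || pqic_thickness < 0) {
    stop("thicknesses must be >= 0")
  }
  for (nm in c("sio2_hydration", "head_hydration", "tail_hydration",
               "bilayer_coverage", "pqic_volume_fraction")) {
    .check_fraction(get(nm), nm)
  }
  structure(
    list(
      sio2_thickness = sio2_thickness, sio2_hydration = sio2_hydration,
      apm = apm, head_hydration = head_hydration,
      tail_hydration = tail_hydration, bilayer_coverage = bilayer_coverage,
      pqic_thickness = pqic_thickness,
      pqic_volume_fraction = pqic_volume_fraction,
      roughness = .expand_roughness(roughness, .PQIC_INTERFACES),
      protein = protein, registry = registry
    ),
    class = "pqic_model_params"
  )
}

#' Parameters of the seven-layer trans-envelope model
#'
#' Extends [pqic_model_params()] with two further slabs on the solution
#' side: a thick but diffuse layer of the periplasm-spanning protein (PqiB)
#' and a distal layer of mixed protein (PqiA) and hydrogenous lipid, i.e. a
#' second, lower-coverage membrane. A mixing fraction dilutes the
#' deuterated proximal tails with hydrogenous lipid.
#'
#' @inheritParams pqic_model_params
#' @param pqib_thickness span of the diffuse protein layer, A.
#' @param pqib_volume_fraction protein volume fraction in that layer.
#' @param distal_thickness thickness of the distal mixed layer, A.
#' @param distal_protein_fraction protein volume fraction in the distal layer.
#' @param distal_lipid_fraction hydrogenous-lipid volume fraction in the
#'   distal layer (protein + lipid fractions must not exceed 1; solvent
#'   fills the remainder).
#' @param hdmpc_mixing_fraction fraction of hydrogenous lipid mixed into the
#'   proximal deuterated tail region.
#' @return object of class `pqiabc_model_params` (also `pqic_model_params`).
#' @export
pqiabc_model_params <- function(...,
                                pqib_thickness = 230,
                                pqib_volume_fraction = 0.20,
                                distal_thickness = 45,
                                distal_protein_fraction = 0.15,
                                distal_lipid_fraction = 0.35,
                                hdmpc_mixing_fraction = 0.1) {
  base <- pqic_model_params(...)
  if (pqib_thickness < 0 || distal_thickness < 0) {
    stop("thicknesses must be >= 0")
  }
  for (nm in c("pqib_volume_fraction", "distal_protein_fraction",
               "distal_lipid_fraction", "hdmpc_mixing_fraction")) {
    .check_fraction(get(nm), nm)
  }
  if (distal_protein_fraction + distal_lipid_fraction > 1 + 1e-9) {
    stop("distal protein + lipid fractions exceed 1")
  }
  base$pqib_thickness <- pqib_thickness
  base$pqib_volume_fraction <- pqib_volume_fraction
  base$distal_thickness <- distal_thickness
  base$distal_protein_fraction <- distal_protein_fraction
  base$distal_lipid_fraction <- distal_lipid_fraction
  base$hdmpc_mixing_fraction <- hdmpc_mixing_fraction
  base$roughness <- .expand_roughness(
    unname(c(base$roughness[1:6], base$roughness[7], base$roughness[7],
             base$roughness[7])),
    .PQIABC_INTERFACES
  )
  class(base) <- c("pqiabc_model_params", "pqic_model_params")
  base
}

.SLAB_COMPONENTS <- c("oxide", "heads", "tails", "pqic", "pqib",
                      "distal_protein", "distal_lipid")

# internal: slab description shared by the stack builder, the likelihood
# and the volume-fraction profile. Returns slab names, thicknesses, a
# (nslab x ncomponent) dry-occupancy matrix with a trailing solvent column,
# and the interface roughness vector. Kept matrix-based: this sits on the
# MCMC hot path.
.slab_occupancy <- function(params) {
  reg <- params$registry
  d_head <- layer_thickness_from_apm(reg$dmpc_head$molecular_volume,
                                     params$apm)
  d_tail <- layer_thickness_from_apm(reg$dmpc_tails$molecular_volume,
                                     params$apm) / 2
  phi_head <- params$bilayer_coverage * (1 - params$head_hydration)
  phi_tail <- params$bilayer_coverage * (1 - params$tail_hydration)
  abc <- inherits(params, "pqiabc_model_params")
  nslab <- if (abc) 8L else 6L
  names <- c("sio2", "heads_in", "tails_in", "tails_out", "heads_out",
             "pqic", if (abc) c("pqib", "distal"))
  thickness <- c(params$sio2_thickness, d_head, d_tail, d_tail, d_head,
                 params$pqic_thickness,
                 if (abc) c(params$pqib_thickness, params$distal_thickness))
  m <- matrix(0, nslab, length(.SLAB_COMPONENTS),
              dimnames = list(names, .SLAB_COMPONENTS))
  m["sio2", "oxide"] <- 1 - params$sio2_hydration
  m[c("heads_in", "heads_out"), "heads"] <- phi_head
  m[c("tails_in", "tails_out"), "tails"] <- phi_tail
  m["pqic", "pqic"] <- params$pqic_volume_fraction
  if (abc) {
    m["pqib", "pqib"] <- params$pqib_volume_fraction
    m["distal", "distal_protein"] <- params$distal_protein_fraction
    m["distal", "distal_lipid"] <- params$distal_lipid_fraction
  }
  solvent <- 1 - rowSums(m)
  if (any(solvent < -1e-9)) stop("slab occupancies exceed 1")
  list(names = names, thickness = thickness,
       m = cbind(m, solvent = solvent), roughness = params$roughness)
}

# internal: per-contrast component SLDs, one per occupancy column
.component_slds <- function(params, solv, lipid_variant = "deuterated") {
  reg <- params$registry
  deut <- identical(lipid_variant, "deuterated")
  tail_sld <- component_sld(reg$dmpc_tails, deuterated = deut)
  if (!is.null(params$hdmpc_mixing_fraction) && deut) {
    mix <- params$hdmpc_mixing_fraction
    tail_sld <- (1 - mix) * tail_sld +
      mix * component_sld(reg$dmpc_tails, deuterated = FALSE)
  }
  prot <- protein_sld(params$protein, solv$f_d2o)
  # average SLD of a hydrogenous lipid molecule (head + tails over volumes)
  hlip <- (reg$dmpc_head$sum_b_h + reg$dmpc_tails$sum_b_h) /
    (reg$dmpc_head$molecular_volume + reg$dmpc_tails$molecular_volume)
  c(oxide = component_sld(reg$sio2),
    heads = component_sld(reg$dmpc_head),
    tails = tail_sld,
    pqic = prot, pqib = prot,
    distal_protein = prot, distal_lipid = hlip,
    solvent = solv$sld)
}

# internal shared builder
.build_stack <- function(params, solv, lipid_variant, occ = NULL) {
  if (is.null(occ)) occ <- .slab_occupancy(params)
  slds <- .component_slds(params, solv, lipid_variant)
  layer_sld <- as.numeric(occ$m %*% slds[colnames(occ$m)])
  layers <- lapply(seq_along(layer_sld), function(i) {
    layer(thickness = occ$thickness[i], sld = layer_sld[i],
          roughness = occ$roughness[[i]])
  })
  reg <- params$registry
  layer_stack(
    fronting_sld = component_sld(reg$silicon),
    layers = layers,
    backing_sld = solv$sld,
    backing_roughness = occ$roughness[[length(occ$roughness)]]
  )
}

#' Render the five-layer model into a layer stack
#'
#' Builds the substrate-to-solution slab sequence (oxide, inner heads, two
#' tail leaflets, outer heads, protein layer) for one solvent contrast.
#' Each slab SLD is the volume-weighted mixture of its component SLD and
#' the solvent SLD; the protein slab uses the labile-exchange protein SLD
#' at the solvent's D2O fraction.
#'
#' @param params a [pqic_model_params()].
#' @param solvent a [solvent()].
#' @param lipid_variant `"deuterated"` (d54 tails) or `"hydrogenous"`.
#' @return a [layer_stack()].
#' @export
build_pqic_stack <- function(params, solvent, lipid_variant = "deuterated") {
  stopifnot(inherits(params, "pqic_model_params"),
            inherits(solvent, "solvent"))
  lipid_variant <- match.arg(lipid_variant, c("deuterated", "hydrogenous"))
  .build_stack(params, solvent, lipid_variant)
}

#' Render the seven-layer trans-envelope model into a layer stack
#'
#' The five-layer structure plus a diffuse protein layer and a distal mixed
#' protein/hydrogenous-lipid layer on the solution side. The proximal tail
#' SLD is diluted by the hydrogenous-lipid mixing fraction.
#'
#' @param params a [pqiabc_model_params()].
#' @param solvent a [solvent()].
#' @return a [layer_stack()].
#' @export
build_pqiabc_stack <- function(params, solvent) {
  stopifnot(inherits(params, "pqiabc_model_params"),
            inherits(solvent, "solvent"))
  .build_stack(params, solvent, "deuterated")
}

#' Volume-fraction depth profile
#'
#' Renders each slab's component occupancy as an error-function-smeared
#' boxcar along the surface normal, using the same interface roughnesses as
#' the reflectivity model. The substrate occupies z < 0; solvent fills all
#' residual volume, so fractions sum to one at every depth.
#'
#' @param params model parameter object.
#' @param z_grid strictly increasing depths, A (0 = substrate surface).
#' @return object of class `volume_fraction_profile`: a data frame with `z`
#'   and one column per component (substrate, oxide, heads, tails, pqic,
#'   optionally pqib/distal_protein/distal_lipid, solvent).
#' @export
volume_fraction_profile <- function(params, z_grid) {
  stopifnot(inherits(params, "pqic_model_params"))
  if (is.unsorted(z_grid, strictly = TRUE)) {
    stop("z_grid must be strictly increasing")
  }
  occ <- .slab_occupancy(params)
  nslab <- length(occ$thickness)
  bounds <- c(0, cumsum(occ$thickness))        # interface positions
  sig <- occ$roughness                         # one per interface
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  cdf <- function(z, z0, s) {
    if (s <= 0) as.numeric(z >= z0) else 0.5 * (1 + erf((z - z0) / (sqrt(2) * s)))
  }
  # weight of each medium at every z; media = substrate, slabs..., backing
  up <- vapply(seq_len(nslab + 1L), function(j) {
    cdf(z_grid, bounds[j], sig[[j]])
  }, numeric(length(z_grid)))
  up <- matrix(up, nrow = length(z_grid))
  w_sub <- 1 - up[, 1]
  w_slab <- up[, seq_len(nslab), drop = FALSE] -
    up[, seq_len(nslab) + 1L, drop = FALSE]
  w_back <- up[, nslab + 1L]

  comp_cols <- setdiff(colnames(occ$m), "solvent")
  out <- data.frame(z = z_grid, substrate = w_sub)
  for (cc in comp_cols) {
    out[[cc]] <- as.numeric(w_slab %*% occ$m[, cc])
  }
  out$solvent <- as.numeric(w_slab %*% occ$m[, "solvent"]) + w_back
  keep <- vapply(out, function(col) any(col != 0), logical(1))
  keep[c("z", "substrate", "solvent")] <- TRUE
  out <- out[, keep]
  class(out) <- c("volume_fraction_profile", "data.frame")
  out
}

#' Smeared SLD depth profile of a layer stack
#'
#' The roughness-smeared slab SLD as a function of depth, for comparison
#' with component volume-fraction profiles.
#'
#' @param stack a [layer_stack()].
#' @param z depths, A (0 = first interface).
#' @return numeric vector of SLD values.
#' @export
sld_profile <- function(stack, z) {
  a <- .stack_arrays(stack)
  nslab <- length(stack$layers)
  bounds <- c(0, cumsum(a$d[seq_len(nslab) + 1L]))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  cdf <- function(zz, z0, s) {
    if (s <= 0) as.numeric(zz >= z0) else 0.5 * (1 + erf((zz - z0) / (sqrt(2) * s)))
  }
  up <- vapply(seq_len(nslab + 1L), function(j) cdf(z, bounds[j], a$sigma[j]),
               numeric(length(z)))
  up <- matrix(up, nrow = length(z))
  w_sub <- 1 - up[, 1]
  w_back <- up[, nslab + 1L]
  prof <- w_sub * Re(a$sld[1]) + w_back * Re(a$sld[nslab + 2L])
  if (nslab > 0) {
    w_slab <- up[, seq_len(nslab), drop = FALSE] -
      up[, seq_len(nslab) + 1L, drop = FALSE]
    prof <- prof + as.numeric(w_slab %*% Re(a$sld[seq_len(nslab) + 1L]))
  }
  prof
}

#' Distance between the two modelled membranes
#'
#' Span from the solution-side boundary of the proximal bilayer's outer
#' headgroups to the substrate-side boundary of the distal lipid layer,
#' i.e. the sum of the lipoprotein and periplasm-spanning layer
#' thicknesses. The endpoint convention (headgroup boundaries excluded) is
#' recorded in the `convention` attribute of the result.
#'
#' @param params a [pqiabc_model_params()] (or a five-layer parameter set,
#'   whose periplasm-spanning thickness is taken as zero).
#' @return distance in A, with attribute `convention`.
#' @export
intermembrane_distance <- function(params) {
  stopifnot(inherits(params, "pqic_model_params"))
  pqib <- if (is.null(params$pqib_thickness)) 0 else params$pqib_thickness
  d <- params$pqic_thickness + pqib
  attr(d, "convention") <-
    "outer headgroup boundary (proximal) to distal layer boundary; headgroup thicknesses excluded"
  d
}
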