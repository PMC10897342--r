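# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation: Parratt recursion instead of
# the Abeles matrix product, and Horn's quaternion method instead of the
# Kabsch SVD superposition.

# Parratt recursive reflectivity with Nevot-Croce roughness. sld, d and
# sigma as in a layer stack: media = fronting, layers..., backing; d has
# zero entries for the semi-infinite media; sigma has one entry per
# interface.
parratt_reflectivity <- function(fronting_sld, layers, backing_sld,
                                 backing_roughness, q) {
  sld <- c(fronting_sld,
           vapply(layers, function(l) l$sld, numeric(1)),
           backing_sld)
  d <- c(0, vapply(layers, function(l) l$thickness, numeric(1)), 0)
  sigma <- c(vapply(layers, function(l) l$roughness, numeric(1)),
             backing_roughness)
  n <- length(sld)
  vapply(q, function(qi) {
    k <- sqrt(as.complex((qi / 2)^2 - 4 * pi * (sld - sld[1])))
    # recursion from the bottom interface upwards
    rr <- 0 + 0i
    for (j in (n - 1):1) {
      fres <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
        exp(-2 * k[j] * k[j + 1] * sigma[j]^2)
      phase <- if (j + 1 <= n - 1) exp(2i * k[j + 1] * d[j + 1]) else 1 + 0i
      rr <- (fres + rr * phase) / (1 + fres * rr * phase)
    }
    Mod(rr)^2
  }, numeric(1))
}

# random slab stack with 1..10 layers and physically plausible values
random_stack <- function(n_layers = sample(1:10, 1)) {
  layers <- lapply(seq_len(n_layers), function(i) {
    layer(thickness = runif(1, 5, 200),
          sld = runif(1, -0.5e-6, 7e-6),
          roughness = runif(1, 0, 8))
  })
  layer_stack(fronting_sld = 2.07e-6, layers = layers,
              backing_sld = runif(1, -0.56e-6, 6.36e-6),
              backing_roughness = runif(1, 0, 8))
}

# Horn's quaternion closed-form superposition RMSD
quaternion_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  m <- t(b0) %*% a0
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda_max <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(a0^2) + sum(b0^2) - 2 * lambda_max
  sqrt(max(ssq, 0) / nrow(a))
}

# synthetic ring of spherical "protomers": n_chains dummy chains whose
# centroids sit on a circle of given radius about an axis through origin
make_ring_model <- function(n_chains = 8, ring_radius = 35,
                            atoms_per_chain = 24, blob_radius = 10,
                            axis = c(0, 0, 1), seed = 1) {
  set.seed(seed)
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  blob <- matrix(rnorm(atoms_per_chain * 3, sd = blob_radius / 2),
                 atoms_per_chain, 3)
  chains <- LETTERS[seq_len(n_chains)]
  rows <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
    ang <- 2 * pi * (i - 1) / n_chains
    centre <- ring_radius * (cos(ang) * e1 + sin(ang) * e2)
    xyz <- sweep(blob, 2, centre, `+`)
    data.frame(element = "C", name = "CA", resid = "ALA",
               resno = seq_len(atoms_per_chain), chain = chains[i],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }))
  atom_model(rows)
}

# quick four-contrast simulated dataset for fit tests
simulate_default <- function(scenario_name = "bilayer_pqic", seed = NULL,
                             n_points = NULL, noiseless = FALSE) {
  sc <- builtin_scenarios()[[scenario_name]]
  if (!is.null(seed)) sc$seed <- seed
  if (!is.null(n_points)) sc$n_points <- n_points
  simulate_experiment(sc, noiseless = noiseless)
}
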