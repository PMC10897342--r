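# Exact specular reflectivity of a stratified interface: Abeles optical
# matrix product with Nevot-Croce roughness and Gaussian dQ/Q resolution
# smearing.

#' A single slab layer
#'
#' @param thickness layer thickness, A (>= 0).
#' @param sld (real) scattering length density, A^-2. A small imaginary part
#'   may be supplied as a complex number for absorbing media.
#' @param roughness Gaussian width of the interface between this layer and
#'   the preceding (substrate-side) medium, A (>= 0).
#' @return object of class `nr_layer`.
#' @export
layer <- function(thickness, sld, roughness = 0) {
  if (thickness < 0) stop("thickness must be >= 0")
  if (roughness < 0) stop("roughness must be >= 0")
  structure(list(thickness = thickness, sld = sld, roughness = roughness),
            class = "nr_layer")
}

#' A stack of slab layers between two semi-infinite media
#'
#' Layers are ordered from the substrate (fronting, incident medium — here
#' silicon, through which the beam travels) towards the bulk solution
#' (backing).
#'
#' @param fronting_sld SLD of the semi-infinite incident medium, A^-2.
#' @param layers list of [layer()] objects, substrate side first. May be
#'   empty for a bare interface.
#' @param backing_sld SLD of the semi-infinite backing medium, A^-2.
#' @param backing_roughness roughness of the final interface, A.
#' @return object of class `layer_stack`.
#' @export
layer_stack <- function(fronting_sld, layers = list(), backing_sld,
                        backing_roughness = 0) {
  stopifnot(is.list(layers))
  for (ly in layers) stopifnot(inherits(ly, "nr_layer"))
  if (backing_roughness < 0) stop("backing_roughness must be >= 0")
  structure(
    list(fronting_sld = fronting_sld, layers = layers,
         backing_sld = backing_sld, backing_roughness = backing_roughness),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layer(s)\n", length(x$layers)))
  cat(sprintf("  fronting: SLD = %.3e\n", Re(x$fronting_sld)))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf("  layer %d: d = %7.2f A, SLD = %10.3e, rough = %.2f A\n",
                i, ly$thickness, Re(ly$sld), ly$roughness))
  }
  cat(sprintf("  backing: SLD = %.3e, rough = %.2f A\n",
              Re(x$backing_sld), x$backing_roughness))
  invisible(x)
}

# internal: stack -> vectors (sld, thickness, interface roughness)
.stack_arrays <- function(stack) {
  n <- length(stack$layers)
  sld <- c(stack$fronting_sld,
           if (n) vapply(stack$layers, function(l) l$sld + 0i, complex(1)),
           stack$backing_sld)
  d <- c(0, if (n) vapply(stack$layers, function(l) l$thickness, numeric(1)), 0)
  sig <- c(if (n) vapply(stack$layers, function(l) l$roughness, numeric(1)),
           stack$backing_roughness)
  list(sld = sld + 0i, d = d, sigma = sig)
}

#' Specular reflectivity of a layer stack
#'
#' Exact optical-matrix (Abeles) computation. In medium n the normal
#' wavevector is `k_n = sqrt((Q/2)^2 - 4 pi (rho_n - rho_fronting))` and each
#' interfacial Fresnel coefficient is damped by the Nevot-Croce factor
#' `exp(-2 k_n k_{n+1} sigma^2)` for Gaussian roughness. The reflectivity is
#' `|M21 / M11|^2` of the characteristic-matrix product; no post-hoc
#' clipping is applied.
#'
#' @param stack a [layer_stack()].
#' @param q wave-vector transfer grid, A^-1, strictly positive.
#' @return numeric vector of reflectivities, one per `q` point.
#' @examples
#' si_d2o <- layer_stack(2.07e-6, list(), 6.36e-6)
#' reflectivity(si_d2o, c(0.01, 0.05, 0.1))
#' @export
reflectivity <- function(stack, q) {
  stopifnot(inherits(stack, "layer_stack"))
  if (any(q <= 0)) stop("q must be > 0")
  a <- .stack_arrays(stack)
  nmed <- length(a$sld)
  qq <- (q / 2)^2

  # k in each medium, referenced to the fronting SLD
  k <- vector("list", nmed)
  for (j in seq_len(nmed)) {
    k[[j]] <- sqrt(as.complex(qq - 4 * pi * (a$sld[j] - a$sld[1])))
  }

  m11 <- rep(1 + 0i, length(q)); m12 <- rep(0i, length(q))
  m21 <- rep(0i, length(q));     m22 <- rep(1 + 0i, length(q))
  for (j in seq_len(nmed - 1L)) {
    kj <- k[[j]]; kj1 <- k[[j + 1L]]
    rj <- (kj - kj1) / (kj + kj1) * exp(-2 * kj * kj1 * a$sigma[j]^2)
    beta <- if (j == 1L) rep(0i, length(q)) else 1i * kj * a$d[j]
    e <- exp(beta); einv <- exp(-beta)
    c11 <- e; c12 <- rj * e; c21 <- rj * einv; c22 <- einv
    n11 <- m11 * c11 + m12 * c21
    n12 <- m11 * c12 + m12 * c22
    n21 <- m21 * c11 + m22 * c21
    n22 <- m21 * c12 + m22 * c22
    m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
  }
  r <- Mod(m21 / m11)^2
  as.numeric(r)
}

#' A measured or simulated reflectivity curve
#'
#' @param q strictly increasing, positive Q grid, A^-1.
#' @param r reflectivity values. Model curves lie in \[0, 1\]; for measured
#'   or simulated data, counting noise may push background-level points
#'   slightly negative, which is tolerated (down to -0.05) and never
#'   silently clamped.
#' @param dr 1-sigma uncertainties (>= 0); defaults to zero.
#' @param dq_over_q fractional Q resolution (FWHM convention), either a
#'   scalar or one value per point.
#' @return object of class `reflectivity_curve` (also a data frame).
#' @export
reflectivity_curve <- function(q, r, dr = 0, dq_over_q = 0) {
  if (any(q <= 0)) stop("q must be positive")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(r < -0.05) || any(r > 1.05)) {
    stop("reflectivity must lie in [0, 1] (small noise excursions tolerated)")
  }
  if (any(dr < 0)) stop("dr must be >= 0")
  df <- data.frame(q = q, r = r,
                   dr = rep_len(dr, length(q)),
                   dq_over_q = rep_len(dq_over_q, length(q)))
  class(df) <- c("reflectivity_curve", "data.frame")
  df
}

#' @export
plot.reflectivity_curve <- function(x, ..., add = FALSE) {
  if (!add) {
    graphics::plot(x$q, x$r, log = "xy", type = "p", pch = 20,
                   xlab = expression(Q ~ (ring(A)^-1)), ylab = "R", ...)
  } else {
    graphics::points(x$q, x$r, pch = 20, ...)
  }
  invisible(x)
}

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# internal: Gaussian smearing weight matrix mapping model-grid values to the
# data grid.  dq_over_q is the FWHM fractional resolution; the model grid is
# log-spaced, oversampled and extended past the data range so endpoint
# kernels are not truncated.
.smear_matrix <- function(q, dq_over_q, oversample = 5L, width = 3.5) {
  n <- length(q)
  res <- rep_len(dq_over_q, n)
  sigma <- res * q * .FWHM_TO_SIGMA
  lo <- min(q) * (1 - width * max(res, 1e-12))
  hi <- max(q) * (1 + width * max(res, 1e-12))
  lo <- max(lo, min(q) * 0.5)
  nm <- max(oversample * n, 60L)
  qm <- exp(seq(log(lo), log(hi), length.out = nm))
  w <- matrix(0, n, nm)
  for (i in seq_len(n)) {
    if (sigma[i] <= 0) {
      j <- which.min(abs(qm - q[i]))
      w[i, j] <- 1
    } else {
      wi <- stats::dnorm(qm, mean = q[i], sd = sigma[i])
      w[i, ] <- wi / sum(wi)
    }
  }
  list(q_model = qm, w = w)
}

#' Resolution-smeared model reflectivity
#'
#' Evaluates the stack reflectivity on an oversampled log-spaced grid
#' extending beyond the data range and convolves it with a Gaussian kernel
#' of constant fractional width (`dq_over_q` is the FWHM of the kernel at
#' each Q; sigma = FWHM / 2.355).
#'
#' @param stack a [layer_stack()].
#' @param q data Q grid, A^-1.
#' @param dq_over_q fractional resolution (FWHM), scalar or per point; 0
#'   gives the unsmeared kernel.
#' @param oversample oversampling factor for the model grid (>= 5 avoids
#'   aliasing of closely spaced fringes).
#' @return numeric vector of smeared reflectivities on `q`.
#' @export
smeared_reflectivity <- function(stack, q, dq_over_q = 0.035, oversample = 5L) {
  if (all(dq_over_q == 0)) return(reflectivity(stack, q))
  sm <- .smear_matrix(q, dq_over_q, oversample = oversample)
  as.numeric(sm$w %*% reflectivity(stack, sm$q_model))
}

#' Smear an existing reflectivity curve
#'
#' Gaussian Q-convolution of tabulated reflectivity values. Kernels are
#' renormalised over the available support, so points near the ends of the
#' measured range are smeared one-sidedly; when the underlying model is
#' available prefer [smeared_reflectivity()], which evaluates beyond the
#' data range instead.
#'
#' @param curve a [reflectivity_curve()].
#' @param dq_over_q fractional resolution (FWHM); 0 returns the curve
#'   unchanged.
#' @return a `reflectivity_curve` with smeared `r`.
#' @export
smear <- function(curve, dq_over_q) {
  stopifnot(inherits(curve, "reflectivity_curve"))
  if (dq_over_q < 0) stop("dq_over_q must be >= 0")
  if (dq_over_q == 0) return(curve)
  q <- curve$q
  sigma <- dq_over_q * q * .FWHM_TO_SIGMA
  r <- curve$r
  out <- vapply(seq_along(q), function(i) {
    w <- stats::dnorm(q, mean = q[i], sd = sigma[i])
    sum(w * r) / sum(w)
  }, numeric(1))
  reflectivity_curve(q, out, dr = curve$dr, dq_over_q = dq_over_q)
}

#' Closed-form Fresnel reflectivity of a bare interface
#'
#' Reference solution for a single sharp or rough interface between two
#' semi-infinite media.
#'
#' @param q Q grid, A^-1.
#' @param sld_fronting,sld_backing SLDs of the two media, A^-2.
#' @param roughness Gaussian interface width, A.
#' @return reflectivity values.
#' @export
fresnel_reflectivity <- function(q, sld_fronting, sld_backing, roughness = 0) {
  k0 <- sqrt(as.complex((q / 2)^2))
  k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (sld_backing - sld_fronting)))
  r <- (k0 - k1) / (k0 + k1) * exp(-2 * k0 * k1 * roughness^2)
  as.numeric(Mod(r)^2)
}
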