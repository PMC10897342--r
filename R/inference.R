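# Simultaneous multi-contrast fitting: chi-squared likelihood over shared
# interfacial geometry, bounded optimisation, affine-invariant ensemble
# MCMC, and central credible bands on parameters, curves and profiles.

#' Define a multi-contrast fit problem
#'
#' Couples one parametric interfacial model to several reflectivity data
#' sets measured under different isotopic contrasts. All geometric
#' parameters are shared between contrasts; per-dataset multiplicative
#' scale and additive background nuisance parameters are free by default.
#'
#' @param model `"pqic"` (five-layer) or `"pqiabc"` (seven-layer).
#' @param params starting parameter object ([pqic_model_params()] or
#'   [pqiabc_model_params()]); fixed parameters keep these values.
#' @param free named list of `c(lower, upper)` bounds for each free
#'   structural parameter (names are parameter fields, e.g. `"apm"`,
#'   `"pqic_thickness"`; roughness entries as `"roughness.backing"`).
#' @param datasets list of entries, each a list with elements `curve` (a
#'   [reflectivity_curve()]), `solvent` (a [solvent()]) and optionally
#'   `lipid_variant` (`"deuterated"` default).
#' @param fit_scale,fit_background free per-dataset nuisance parameters?
#' @param scale_bounds,background_bounds bounds for the nuisance parameters.
#' @param priors optional named list of normal priors `c(mean, sd)`;
#'   parameters without an entry get a flat prior within bounds.
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(model = c("pqic", "pqiabc"), params, free, datasets,
                        fit_scale = TRUE, fit_background = TRUE,
                        scale_bounds = c(0.5, 2),
                        background_bounds = c(0, 1e-5),
                        priors = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "pqic_model_params"))
  if (model == "pqiabc" && !inherits(params, "pqiabc_model_params")) {
    stop("seven-layer model needs pqiabc_model_params")
  }
  if (length(datasets) < 1L) stop("at least one dataset required")
  stopifnot(is.list(free), length(free) > 0,
            !is.null(names(free)), !anyDuplicated(names(free)))
  for (b in free) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("each free entry must be finite c(lower, upper)")
    }
  }
  datasets <- lapply(datasets, function(d) {
    stopifnot(inherits(d$curve, "reflectivity_curve"),
              inherits(d$solvent, "solvent"))
    if (is.null(d$lipid_variant)) d$lipid_variant <- "deuterated"
    res <- d$curve$dq_over_q
    d$smear <- if (all(res == 0)) NULL else .smear_matrix(d$curve$q, res)
    d
  })
  nms <- names(free)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  nd <- length(datasets)
  if (fit_scale) {
    nms <- c(nms, paste0("scale_", seq_len(nd)))
    lower <- c(lower, rep(scale_bounds[1], nd))
    upper <- c(upper, rep(scale_bounds[2], nd))
  }
  if (fit_background) {
    nms <- c(nms, paste0("background_", seq_len(nd)))
    lower <- c(lower, rep(background_bounds[1], nd))
    upper <- c(upper, rep(background_bounds[2], nd))
  }
  structure(
    list(model = model, params = params, free = free, datasets = datasets,
         par_names = nms,
         lower = stats::setNames(lower, nms),
         upper = stats::setNames(upper, nms),
         fit_scale = fit_scale, fit_background = fit_background,
         priors = priors),
    class = "fit_problem"
  )
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("<fit_problem> %s model, %d dataset(s), %d free parameter(s)\n",
              x$model, length(x$datasets), length(x$par_names)))
  invisible(x)
}

# internal: starting parameter vector (current param values; scale 1, bg 0)
.start_theta <- function(problem) {
  th <- vapply(names(problem$free), function(nm) {
    .get_param(problem$params, nm)
  }, numeric(1))
  nd <- length(problem$datasets)
  if (problem$fit_scale) {
    th <- c(th, stats::setNames(rep(1, nd), paste0("scale_", seq_len(nd))))
  }
  if (problem$fit_background) {
    th <- c(th, stats::setNames(rep(1e-7, nd),
                                paste0("background_", seq_len(nd))))
  }
  pmin(pmax(th[problem$par_names], problem$lower), problem$upper)
}

.get_param <- function(params, name) {
  if (grepl(".", name, fixed = TRUE)) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    params[[parts[1]]][[parts[2]]]
  } else {
    params[[name]]
  }
}

.apply_theta <- function(params, theta) {
  for (nm in names(theta)) {
    if (startsWith(nm, "scale_") || startsWith(nm, "background_")) next
    if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      params[[parts[1]]][[parts[2]]] <- theta[[nm]]
    } else {
      params[[nm]] <- theta[[nm]]
    }
  }
  params
}

# internal: per-dataset model reflectivity at parameter vector theta
.model_curves <- function(problem, theta) {
  p <- .apply_theta(problem$params, theta)
  occ <- .slab_occupancy(p)
  lapply(seq_along(problem$datasets), function(i) {
    d <- problem$datasets[[i]]
    stack <- .build_stack(p, d$solvent, d$lipid_variant, occ)
    rm <- if (is.null(d$smear)) {
      reflectivity(stack, d$curve$q)
    } else {
      as.numeric(d$smear$w %*% reflectivity(stack, d$smear$q_model))
    }
    sc <- if (problem$fit_scale) theta[[paste0("scale_", i)]] else 1
    bg <- if (problem$fit_background) theta[[paste0("background_", i)]] else 0
    sc * rm + bg
  })
}

#' Model reflectivity curves at a parameter vector
#'
#' @param problem a [fit_problem()].
#' @param theta named parameter vector over the problem's free parameters.
#' @return list of numeric vectors, one smeared model curve per dataset.
#' @export
model_curves <- function(problem, theta) {
  stopifnot(inherits(problem, "fit_problem"))
  .model_curves(problem, theta[problem$par_names])
}

#' Negative log-likelihood of a fit problem
#'
#' Half the summed squared, uncertainty-weighted residuals over all
#' datasets and points, plus any normal prior terms. Parameters outside
#' their bounds return `+Inf` rather than raising.
#'
#' @param problem a [fit_problem()].
#' @param theta named parameter vector (order-insensitive; matched by name).
#' @return scalar; `+Inf` out of bounds.
#' @export
neg_log_likelihood <- function(problem, theta) {
  stopifnot(inherits(problem, "fit_problem"))
  theta <- theta[problem$par_names]
  if (anyNA(theta) || any(theta < problem$lower) ||
      any(theta > problem$upper)) {
    return(Inf)
  }
  mods <- tryCatch(.model_curves(problem, theta), error = function(e) NULL)
  if (is.null(mods)) return(Inf)
  nll <- 0
  for (i in seq_along(problem$datasets)) {
    d <- problem$datasets[[i]]
    w <- (mods[[i]] - d$curve$r) / d$curve$dr
    w <- w[is.finite(w)]          # zero-weight points (dr = Inf) drop out
    nll <- nll + 0.5 * sum(w^2)
  }
  if (!is.null(problem$priors)) {
    for (nm in names(problem$priors)) {
      pr <- problem$priors[[nm]]
      nll <- nll + 0.5 * ((theta[[nm]] - pr[1]) / pr[2])^2
    }
  }
  nll
}

#' Fit a reflectivity model to multi-contrast data
#'
#' Bounded local optimisation (L-BFGS-B) of [neg_log_likelihood()] from the
#' problem's start values (or a supplied start). Deterministic given the
#' start. Non-convergence is reported in the result, with the best point
#' found returned rather than an error.
#'
#' @param problem a [fit_problem()].
#' @param start optional named start vector; defaults to the parameter
#'   object's current values (scale 1, background 1e-7).
#' @param maxit iteration cap for the optimiser.
#' @return object of class `nr_fit`: best-fit `par`, `value`, per-dataset
#'   `chisq_per_point`, `convergence` code and `message`.
#' @export
fit <- function(problem, start = NULL, maxit = 1000) {
  stopifnot(inherits(problem, "fit_problem"))
  th0 <- if (is.null(start)) .start_theta(problem) else start[problem$par_names]
  # optimise on the unit box: finite-difference steps are then commensurate
  # for parameters spanning A^2 down to background-sized magnitudes
  span <- problem$upper - problem$lower
  u0 <- (th0 - problem$lower) / span
  from_u <- function(u) {
    stats::setNames(problem$lower + pmin(pmax(u, 0), 1) * span,
                    problem$par_names)
  }
  opt <- stats::optim(
    par = u0,
    fn = function(u) {
      v <- neg_log_likelihood(problem, from_u(u))
      if (!is.finite(v)) 1e300 else v
    },
    method = "L-BFGS-B",
    lower = rep(0, length(u0)), upper = rep(1, length(u0)),
    control = list(maxit = maxit, factr = 1e7,
                   ndeps = rep(1e-5, length(u0)))
  )
  par <- from_u(opt$par)
  mods <- .model_curves(problem, par)
  chisq <- vapply(seq_along(problem$datasets), function(i) {
    d <- problem$datasets[[i]]
    w <- (mods[[i]] - d$curve$r) / d$curve$dr
    w <- w[is.finite(w)]
    if (length(w) == 0) return(NA_real_)
    sum(w^2) / length(w)
  }, numeric(1))
  if (opt$convergence != 0) {
    warning("optimiser did not converge cleanly: ", opt$message)
  }
  structure(
    list(par = par, value = opt$value, chisq_per_point = chisq,
         convergence = opt$convergence, message = opt$message,
         start = th0, problem = problem),
    class = "nr_fit"
  )
}

#' @export
print.nr_fit <- function(x, ...) {
  cat("<nr_fit>\n")
  for (nm in names(x$par)) cat(sprintf("  %-24s %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  -log L = %.4g; chi^2/point = %s; convergence = %d\n",
              x$value, paste(sprintf("%.3g", x$chisq_per_point),
                             collapse = ", "),
              x$convergence))
  invisible(x)
}

#' Ensemble MCMC over the posterior
#'
#' Affine-invariant ensemble sampler (Goodman-Weare stretch move). Walkers
#' start in a small ball around `start` (typically the best fit); the
#' burn-in portion of every chain is discarded. With flat priors the
#' posterior is proportional to `exp(-neg_log_likelihood)` inside the
#' bounds.
#'
#' @param problem a [fit_problem()].
#' @param start named centre of the initial walker ball; defaults to the
#'   problem start values.
#' @param n_walkers ensemble size; at least `2 * dim` (raised with a
#'   message if smaller).
#' @param n_steps ensemble steps.
#' @param burn_in steps discarded from the front of each chain.
#' @param seed RNG seed; identical seeds give identical draws.
#' @param stretch stretch-move scale parameter `a` (> 1).
#' @param ball_scale relative radius of the initial walker ball.
#' @return object of class `posterior_samples`: `draws` (rows = retained
#'   draws, columns = parameters), `log_prob`, and `metadata` (walkers,
#'   steps, burn-in, seed, acceptance fraction and any warnings).
#' @export
sample_posterior <- function(problem, start = NULL, n_walkers = 64,
                             n_steps = 5000, burn_in = 1000, seed = 1,
                             stretch = 2, ball_scale = 1e-2) {
  stopifnot(inherits(problem, "fit_problem"))
  if (burn_in >= n_steps) stop("burn_in must be smaller than n_steps")
  d <- length(problem$par_names)
  if (n_walkers < 2 * d) {
    message("raising n_walkers to 2 * dim = ", 2 * d)
    n_walkers <- 2L * d
  }
  th0 <- if (is.null(start)) .start_theta(problem) else start[problem$par_names]
  set.seed(seed)
  span <- problem$upper - problem$lower
  x <- matrix(rep(th0, each = n_walkers), n_walkers, d)
  x <- x + matrix(stats::rnorm(n_walkers * d), n_walkers, d) *
    rep(ball_scale * span, each = n_walkers)
  x <- pmin(pmax(x, rep(problem$lower + 1e-12 * span, each = n_walkers)),
            rep(problem$upper - 1e-12 * span, each = n_walkers))
  lp <- apply(x, 1, function(row) {
    -neg_log_likelihood(problem, stats::setNames(row, problem$par_names))
  })
  keep_draws <- vector("list", n_steps - burn_in)
  keep_lp <- vector("list", n_steps - burn_in)
  n_accept <- 0L
  for (step in seq_len(n_steps)) {
    for (k in seq_len(n_walkers)) {
      j <- sample.int(n_walkers - 1L, 1L)
      if (j >= k) j <- j + 1L
      z <- ((stretch - 1) * stats::runif(1) + 1)^2 / stretch
      prop <- x[j, ] + z * (x[k, ] - x[j, ])
      lp_prop <- -neg_log_likelihood(
        problem, stats::setNames(prop, problem$par_names))
      log_accept <- (d - 1) * log(z) + lp_prop - lp[k]
      if (is.finite(lp_prop) && log(stats::runif(1)) < log_accept) {
        x[k, ] <- prop
        lp[k] <- lp_prop
        n_accept <- n_accept + 1L
      }
    }
    if (step > burn_in) {
      keep_draws[[step - burn_in]] <- x
      keep_lp[[step - burn_in]] <- lp
    }
  }
  draws <- do.call(rbind, keep_draws)
  colnames(draws) <- problem$par_names
  acc <- n_accept / (n_steps * n_walkers)
  warn <- if (acc < 0.1 || acc > 0.9) {
    sprintf("acceptance fraction %.2f outside [0.1, 0.9]", acc)
  } else {
    NULL
  }
  if (!is.null(warn)) warning(warn)
  structure(
    list(draws = draws, log_prob = unlist(keep_lp),
         metadata = list(n_walkers = n_walkers, n_steps = n_steps,
                         burn_in = burn_in, seed = seed, stretch = stretch,
                         acceptance_fraction = acc, warning = warn)),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<posterior_samples> %d draws x %d parameters (%d walkers, %d steps, burn-in %d, seed %d, acceptance %.2f)\n",
    nrow(x$draws), ncol(x$draws), md$n_walkers, md$n_steps, md$burn_in,
    md$seed, md$acceptance_fraction
  ))
  invisible(x)
}

#' Central credible band of a posterior functional
#'
#' Pointwise central interval of a functional of the parameters (a single
#' parameter, a model reflectivity curve, a volume-fraction profile, ...)
#' over the posterior draws. The default 65% level follows the convention
#' of reporting the central 65% of accepted-fit spread.
#'
#' @param samples a `posterior_samples` object.
#' @param functional a parameter name, or a function taking a named
#'   parameter vector and returning a numeric vector.
#' @param level central probability mass, in (0, 1).
#' @param max_draws cap on the number of draws evaluated (evenly spaced
#'   thinning), relevant for expensive functionals.
#' @return data frame with columns `lower`, `median`, `upper` (one row per
#'   element of the functional's value).
#' @export
credible_band <- function(samples, functional, level = 0.65,
                          max_draws = 1000) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (nrow(samples$draws) == 0) stop("empty posterior sample")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  idx <- if (nrow(samples$draws) > max_draws) {
    unique(round(seq(1, nrow(samples$draws), length.out = max_draws)))
  } else {
    seq_len(nrow(samples$draws))
  }
  if (is.character(functional)) {
    vals <- matrix(samples$draws[idx, functional], ncol = 1)
  } else {
    tmpl <- functional(samples$draws[idx[1], ])
    vals <- vapply(idx, function(i) functional(samples$draws[i, ]),
                   numeric(length(tmpl)))
    vals <- if (length(tmpl) == 1L) matrix(vals, ncol = 1) else t(vals)
  }
  probs <- c((1 - level) / 2, 0.5, (1 + level) / 2)
  qs <- t(apply(vals, 2, stats::quantile, probs = probs, names = FALSE))
  data.frame(lower = qs[, 1], median = qs[, 2], upper = qs[, 3])
}
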