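# Readers and writers for the ASCII reflectivity dialect and the
# structured run-configuration file.

#' Read a reflectivity data file
#'
#' Parses whitespace- or comma-separated columns `Q R dR [dQ]`; lines
#' starting with `#` and blank lines are skipped. A fourth column is read
#' as the absolute resolution width dQ (FWHM) and converted to dQ/Q;
#' otherwise the `dq_over_q` argument applies to all points.
#'
#' @param path file path.
#' @param dq_over_q fractional resolution used when the file has no dQ
#'   column.
#' @return a [reflectivity_curve()].
#' @export
read_reflectivity <- function(path, dq_over_q = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  tokens <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  ncols <- lengths(tokens)
  if (length(tokens) == 0) stop("no data rows in ", path)
  bad <- which(ncols < 3L)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected >= 3 numeric columns, found %d",
                 path, rows[bad[1]], ncols[bad[1]]))
  }
  vals <- lapply(tokens, function(tk) suppressWarnings(as.numeric(tk)))
  nn <- vapply(vals, function(v) anyNA(v[1:3]), logical(1))
  if (any(nn)) {
    stop(sprintf("%s line %d: non-numeric value", path, rows[which(nn)[1]]))
  }
  q <- vapply(vals, `[`, numeric(1), 1)
  r <- vapply(vals, `[`, numeric(1), 2)
  dr <- vapply(vals, `[`, numeric(1), 3)
  nonmono <- which(diff(q) <= 0)
  if (length(nonmono)) {
    stop(sprintf("%s line %d: Q not strictly increasing",
                 path, rows[nonmono[1] + 1L]))
  }
  if (all(ncols >= 4L)) {
    dq <- vapply(vals, `[`, numeric(1), 4)
    dq_over_q <- dq / q
  }
  reflectivity_curve(q, r, dr = dr, dq_over_q = dq_over_q)
}

#' Write a reflectivity curve
#'
#' Emits the same dialect [read_reflectivity()] parses: a `#` header line
#' and four columns Q, R, dR and absolute dQ (FWHM, `dq_over_q * Q`).
#'
#' @param curve a [reflectivity_curve()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_reflectivity <- function(curve, path) {
  stopifnot(inherits(curve, "reflectivity_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Q(A^-1) R dR dQ(FWHM)", con)
  writeLines(sprintf("%.8e %.8e %.8e %.8e",
                     curve$q, curve$r, curve$dr, curve$dq_over_q * curve$q),
             con)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration naming the model kind, parameter values, free
#' parameters with bounds, datasets (file + D2O fraction each) and sampler
#' settings. Every dataset must reference an existing file and a D2O
#' fraction within \[0, 1\]; seeds must be present for stochastic commands.
#'
#' @param path YAML file.
#' @param base_dir directory against which relative dataset paths are
#'   resolved (defaults to the config file's directory).
#' @return the validated configuration list, class `run_config`.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model) || !cfg$model %in% c("pqic", "pqiabc")) {
    stop("config must set model: pqic or pqiabc")
  }
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0) {
    stop("config must list at least one dataset")
  }
  for (i in seq_along(cfg$datasets)) {
    d <- cfg$datasets[[i]]
    if (is.null(d$file) || is.null(d$f_d2o)) {
      stop("each dataset needs 'file' and 'f_d2o'")
    }
    f <- d$file
    if (!file.exists(f)) f <- file.path(base_dir, d$file)
    if (!file.exists(f)) stop("dataset file not found: ", d$file)
    if (d$f_d2o < 0 || d$f_d2o > 1) stop("dataset f_d2o must be in [0, 1]")
    cfg$datasets[[i]]$file <- f
  }
  class(cfg) <- "run_config"
  cfg
}

#' Build a fit problem from a run configuration
#'
#' @param cfg a [read_run_config()] result.
#' @return a [fit_problem()].
#' @export
problem_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  par_args <- cfg$parameters
  params <- if (cfg$model == "pqiabc") {
    do.call(pqiabc_model_params, as.list(par_args))
  } else {
    do.call(pqic_model_params, as.list(par_args))
  }
  free <- lapply(cfg$free, function(b) as.numeric(unlist(b)))
  datasets <- lapply(cfg$datasets, function(d) {
    list(curve = read_reflectivity(
           d$file,
           dq_over_q = if (is.null(d$dq_over_q)) 0.035 else d$dq_over_q),
         solvent = solvent(d$f_d2o),
         lipid_variant = if (is.null(d$lipid_variant)) "deuterated"
                         else d$lipid_variant)
  })
  fit_problem(
    model = cfg$model, params = params, free = free, datasets = datasets,
    fit_scale = !isFALSE(cfg$fit_scale),
    fit_background = !isFALSE(cfg$fit_background),
    priors = cfg$priors
  )
}
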