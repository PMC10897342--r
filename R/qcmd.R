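# Quartz crystal microbalance with dissipation: Sauerbrey conversion of
# frequency shifts to areal mass, and robust step-change extraction from
# deposition traces.

#' Quartz crystal properties
#'
#' @param f0 fundamental resonant frequency, Hz.
#' @param area piezoelectrically excited area, m^2 (not needed for areal
#'   mass, carried for total-mass conversion).
#' @param rho_q quartz density, kg m^-3.
#' @param mu_q quartz shear modulus, kg m^-1 s^-2.
#' @return object of class `quartz_crystal`.
#' @export
quartz_crystal <- function(f0 = 5e6, area = 0.2e-4,
                           rho_q = 2648, mu_q = 2.947e10) {
  vals <- c(f0 = f0, area = area, rho_q = rho_q, mu_q = mu_q)
  if (any(vals <= 0)) stop("all crystal properties must be > 0")
  structure(as.list(vals), class = "quartz_crystal")
}

#' Sauerbrey areal mass from a frequency shift
#'
#' Converts a frequency shift at an odd overtone into adsorbed areal mass
#' through the Sauerbrey relation: the overtone-normalised shift `delta_f/n`
#' is multiplied by the crystal's mass sensitivity
#' `sqrt(rho_q * mu_q) / (2 f0^2)` (about 17.7 ng cm^-2 Hz^-1 for a 5 MHz
#' crystal). Sign convention: a frequency decrease is reported as positive
#' adsorbed mass; this convention is recorded on the result.
#'
#' @param delta_f frequency shift, Hz (vectorised).
#' @param crystal a [quartz_crystal()].
#' @param harmonic odd overtone number at which `delta_f` was measured
#'   (vectorised alongside `delta_f`).
#' @return areal mass in ng cm^-2, with attribute `sign_convention`.
#' @examples
#' sauerbrey_mass(-27, quartz_crystal(), harmonic = 3)
#' @export
sauerbrey_mass <- function(delta_f, crystal = quartz_crystal(),
                           harmonic = 1) {
  stopifnot(inherits(crystal, "quartz_crystal"))
  if (any(harmonic %% 2 != 1)) stop("harmonic must be odd")
  c_kg_m2_hz <- sqrt(crystal$rho_q * crystal$mu_q) / (2 * crystal$f0^2)
  mass <- -(delta_f / harmonic) * c_kg_m2_hz * 1e8  # kg m^-2 -> ng cm^-2
  attr(mass, "sign_convention") <- "frequency decrease = positive mass"
  mass
}

#' Mass sensitivity of a crystal
#'
#' The Sauerbrey constant `sqrt(rho_q * mu_q) / (2 f0^2)` in ng cm^-2 Hz^-1.
#'
#' @param crystal a [quartz_crystal()].
#' @return sensitivity in ng cm^-2 per Hz of overtone-normalised shift.
#' @export
sauerbrey_sensitivity <- function(crystal = quartz_crystal()) {
  sqrt(crystal$rho_q * crystal$mu_q) / (2 * crystal$f0^2) * 1e8
}

#' A QCM-D trace
#'
#' @param time increasing time points, s.
#' @param delta_f data frame or matrix of frequency shifts, Hz, one column
#'   per harmonic; column names like `f3`, `f5`, ... name the odd harmonics.
#' @param delta_d optional matching dissipation columns, ppm.
#' @return object of class `qcmd_trace`.
#' @export
qcmd_trace <- function(time, delta_f, delta_d = NULL) {
  if (is.unsorted(time)) stop("time must be increasing")
  delta_f <- as.data.frame(delta_f)
  harmonics <- as.integer(sub("^[fd]", "", names(delta_f)))
  if (anyNA(harmonics) || any(harmonics %% 2 != 1)) {
    stop("delta_f columns must be named f<odd harmonic>")
  }
  if (nrow(delta_f) != length(time)) stop("time/delta_f length mismatch")
  if (!is.null(delta_d)) {
    delta_d <- as.data.frame(delta_d)
    if (nrow(delta_d) != length(time)) stop("time/delta_d length mismatch")
  }
  structure(list(time = time, delta_f = delta_f, delta_d = delta_d,
                 harmonics = harmonics),
            class = "qcmd_trace")
}

#' Step change between two time windows
#'
#' Difference of windowed medians (post minus pre) for every harmonic, for
#' both frequency and (when present) dissipation. Medians make the
#' estimate robust to transient spikes during injections.
#'
#' @param trace a [qcmd_trace()].
#' @param window_pre,window_post two-element time intervals, s; must lie
#'   within the trace and not overlap.
#' @return data frame with columns `harmonic`, `delta_f` and (if available)
#'   `delta_d`.
#' @export
step_change <- function(trace, window_pre, window_post) {
  stopifnot(inherits(trace, "qcmd_trace"))
  for (w in list(window_pre, window_post)) {
    if (length(w) != 2L || w[1] >= w[2]) stop("windows must be c(t0, t1)")
  }
  if (min(window_post) < max(window_pre) &&
      min(window_pre) < max(window_post)) {
    stop("windows must not overlap")
  }
  pre <- trace$time >= window_pre[1] & trace$time <= window_pre[2]
  post <- trace$time >= window_post[1] & trace$time <= window_post[2]
  if (!any(pre) || !any(post)) stop("empty window")
  out <- data.frame(
    harmonic = trace$harmonics,
    delta_f = vapply(trace$delta_f, function(col) {
      stats::median(col[post]) - stats::median(col[pre])
    }, numeric(1))
  )
  if (!is.null(trace$delta_d)) {
    out$delta_d <- vapply(trace$delta_d, function(col) {
      stats::median(col[post]) - stats::median(col[pre])
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Read a QCM-D trace from delimited text
#'
#' Expects a header row naming a `time` column and harmonic columns `f3`,
#' `f5`, ... (frequency, Hz) and optionally `d3`, `d5`, ... (dissipation,
#' ppm). Separator is any whitespace or comma; `#` comment lines skipped.
#'
#' @param path file path.
#' @return a [qcmd_trace()].
#' @export
read_qcmd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  tokens <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  header <- tolower(tokens[[1]])
  vals <- do.call(rbind, lapply(tokens[-1], as.numeric))
  colnames(vals) <- header
  fcols <- grep("^f\\d+$", header, value = TRUE)
  dcols <- grep("^d\\d+$", header, value = TRUE)
  if (!("time" %in% header) || length(fcols) == 0) {
    stop("QCM-D file needs 'time' and at least one f<harmonic> column")
  }
  qcmd_trace(vals[, "time"],
             as.data.frame(vals[, fcols, drop = FALSE]),
             if (length(dcols)) as.data.frame(vals[, dcols, drop = FALSE]))
}
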