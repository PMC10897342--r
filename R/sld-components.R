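# Scattering-length bookkeeping: solvents, lipid components, protein
# compositions with labile-hydrogen exchange, match points and the
# thickness/SLD conversions used by the slab models.

# Bound coherent neutron scattering lengths, fm (Sears 1992 compilation).
# 1 fm = 1e-5 Angstrom; all SLDs in the package are in A^-2.
.neutron_b_fm <- c(
  H  = -3.7390,
  D  = 6.6710,
  C  = 6.6460,
  N  = 9.3600,
  O  = 5.8030,
  P  = 5.1300,
  S  = 2.8470,
  Si = 4.1491
)

.FM_TO_A <- 1e-5

#' Coherent scattering-length sum of a chemical formula
#'
#' Sums bound coherent scattering lengths over an element-count vector.
#'
#' @param counts named numeric vector of atom counts; names must be elements
#'   from the built-in table (H, D, C, N, O, P, S, Si).
#' @return total scattering length in Angstrom (1 fm = 1e-5 A).
#' @examples
#' formula_sum_b(c(O = 1, H = 2))  # light water
#' @export
formula_sum_b <- function(counts) {
  stopifnot(is.numeric(counts), length(names(counts)) == length(counts))
  unknown <- setdiff(names(counts), names(.neutron_b_fm))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(counts * .neutron_b_fm[names(counts)]) * .FM_TO_A
}

# molecular volume of one water molecule, A^3 (fixed convention; reproduces
# the standard -0.56e-6 / 6.36e-6 endpoint SLDs of H2O and D2O)
.V_WATER <- 30.0

#' Construct a scattering component
#'
#' A component is a chemically defined unit (lipid headgroup, acyl tails,
#' oxide, water, ...) carrying a molecular volume, its scattering-length sum
#' in hydrogenous form, the number of solvent-exchangeable (labile) hydrogens
#' and the number of hydrogens substituted in its deuterated variant.
#'
#' @param name label.
#' @param molecular_volume volume in A^3, strictly positive.
#' @param sum_b_h total coherent scattering length of the hydrogenous form, A.
#' @param n_labile_h count of solvent-exchangeable hydrogens.
#' @param n_substitutable_h count of (non-labile) hydrogens replaced by
#'   deuterium in the deuterated variant (e.g. 54 for d54 acyl tails).
#' @return object of class `scattering_component`.
#' @export
scattering_component <- function(name, molecular_volume, sum_b_h,
                                 n_labile_h = 0, n_substitutable_h = 0) {
  if (!is.numeric(molecular_volume) || molecular_volume <= 0) {
    stop("molecular_volume must be > 0")
  }
  if (n_labile_h < 0 || n_substitutable_h < 0) {
    stop("hydrogen counts must be >= 0")
  }
  structure(
    list(
      name = as.character(name),
      molecular_volume = molecular_volume,
      sum_b_h = sum_b_h,
      n_labile_h = n_labile_h,
      n_substitutable_h = n_substitutable_h
    ),
    class = "scattering_component"
  )
}

#' @export
print.scattering_component <- function(x, ...) {
  cat(sprintf(
    "<scattering_component> %s: V = %.1f A^3, sum b(H) = %.3e A, labile H = %d, substitutable H = %d\n",
    x$name, x$molecular_volume, x$sum_b_h, x$n_labile_h, x$n_substitutable_h
  ))
  invisible(x)
}

#' Default component registry
#'
#' Named list of the built-in scattering components used by the membrane
#' models: silicon substrate, amorphous silicon oxide, water, and the DMPC
#' headgroup / acyl-tail split with literature molecular volumes (headgroup
#' 319 A^3; the two myristoyl tails 782 A^3, 54 substitutable hydrogens in
#' the chain-deuterated d54 variant). Every value can be overridden by
#' passing a modified registry to the model builders or via the run
#' configuration file.
#'
#' @return named list of `scattering_component` objects.
#' @export
component_registry <- function() {
  list(
    silicon = scattering_component(
      "silicon", 20.0, formula_sum_b(c(Si = 1))
    ),
    sio2 = scattering_component(
      "sio2", 45.4, formula_sum_b(c(Si = 1, O = 2))
    ),
    water = scattering_component(
      "water", .V_WATER, formula_sum_b(c(O = 1, H = 2)),
      n_labile_h = 0, n_substitutable_h = 2
    ),
    dmpc_head = scattering_component(
      # phosphocholine + glycerol + carbonyls: C10 H18 N O8 P
      "dmpc_head", 319, formula_sum_b(c(C = 10, H = 18, N = 1, O = 8, P = 1))
    ),
    dmpc_tails = scattering_component(
      # two C13H27 myristoyl chains: C26 H54
      "dmpc_tails", 782, formula_sum_b(c(C = 26, H = 54)),
      n_labile_h = 0, n_substitutable_h = 54
    )
  )
}

#' Scattering length density of an isotopic water mixture
#'
#' Linear interpolation between pure H2O and pure D2O SLDs, each computed as
#' the formula scattering-length sum over a fixed 30.0 A^3 molecular volume.
#'
#' @param f_d2o D2O volume fraction, in \[0, 1\]. Vectorised.
#' @return SLD in A^-2.
#' @examples
#' solvent_sld(1)     # D2O, ~6.4e-6
#' solvent_sld(0)     # H2O, ~-0.56e-6
#' solvent_sld(0.42)  # protein-matched water
#' @export
solvent_sld <- function(f_d2o) {
  if (any(!is.finite(f_d2o)) || any(f_d2o < 0) || any(f_d2o > 1)) {
    stop("f_d2o must lie in [0, 1]")
  }
  sld_h2o <- formula_sum_b(c(O = 1, H = 2)) / .V_WATER
  sld_d2o <- formula_sum_b(c(O = 1, D = 2)) / .V_WATER
  (1 - f_d2o) * sld_h2o + f_d2o * sld_d2o
}

#' A solvent at a given isotopic contrast
#'
#' @param f_d2o D2O volume fraction in \[0, 1\].
#' @return object of class `solvent` with fields `f_d2o` and `sld`.
#' @export
solvent <- function(f_d2o) {
  structure(list(f_d2o = f_d2o, sld = solvent_sld(f_d2o)), class = "solvent")
}

#' @export
print.solvent <- function(x, ...) {
  cat(sprintf("<solvent> %.0f%% D2O, SLD = %.3e A^-2\n", 100 * x$f_d2o, x$sld))
  invisible(x)
}

#' Scattering length density of a component
#'
#' Sigma-b of the chosen isotopic form divided by the molecular volume. The
#' deuterated form adds `n_substitutable_h * (b_D - b_H)` to the hydrogenous
#' scattering-length sum.
#'
#' @param component a `scattering_component`.
#' @param deuterated use the deuterated variant?
#' @return SLD in A^-2.
#' @export
component_sld <- function(component, deuterated = FALSE) {
  stopifnot(inherits(component, "scattering_component"))
  b <- component$sum_b_h
  if (isTRUE(deuterated)) {
    b <- b + component$n_substitutable_h *
      (.neutron_b_fm[["D"]] - .neutron_b_fm[["H"]]) * .FM_TO_A
  }
  b / component$molecular_volume
}
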