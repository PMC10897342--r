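# Protein compositions: per-residue scattering bookkeeping, labile-hydrogen
# exchange with the solvent, and contrast match points.

# Per-residue (in-chain, i.e. amino acid minus one water) element counts,
# solvent-exchangeable hydrogen counts (backbone amide + side-chain OH/NH/SH,
# neutral protonation states) and residue volumes (A^3, Zamyatnin).
.aa_table_cache <- new.env(parent = emptyenv())

.aa_table_build <- function() {
  tb <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
res C  H  N O S labile volume
A   3  5  1 1 0 1       88.6
R   6 12  4 1 0 5      173.4
N   4  6  2 2 0 3      114.1
D   4  5  1 3 0 2      111.1
C   3  5  1 1 1 2      108.5
E   5  7  1 3 0 2      138.4
Q   5  8  2 2 0 3      143.8
G   2  3  1 1 0 1       60.1
H   6  7  3 1 0 2      153.2
I   6 11  1 1 0 1      166.7
L   6 11  1 1 0 1      166.7
K   6 12  2 1 0 3      168.6
M   5  9  1 1 1 1      162.9
F   9  9  1 1 0 1      189.9
P   5  7  1 1 0 0      112.7
S   3  5  1 2 0 2       89.0
T   4  7  1 2 0 2      116.1
W  11 10  2 1 0 2      227.8
Y   9  9  1 2 0 2      193.6
V   5  9  1 1 0 1      140.0
")
  rownames(tb) <- tb$res
  b <- vapply(seq_len(nrow(tb)), function(i) {
    formula_sum_b(c(C = tb$C[i], H = tb$H[i], N = tb$N[i],
                    O = tb$O[i], S = tb$S[i]))
  }, numeric(1))
  tb$sum_b_h <- b
  tb
}

# lazy singleton (avoids relying on file load order at install time)
.aa_table <- function() {
  if (is.null(.aa_table_cache$tb)) .aa_table_cache$tb <- .aa_table_build()
  .aa_table_cache$tb
}

#' Per-residue scattering table
#'
#' The bundled amino-acid residue table: element counts per in-chain residue,
#' labile (solvent-exchangeable) hydrogen counts at neutral protonation, the
#' residue volume in A^3 and the hydrogenous scattering-length sum in A.
#'
#' @return data frame with one row per standard amino acid (one-letter rows).
#' @export
residue_table <- function() .aa_table()

#' Protein composition from a sequence or residue counts
#'
#' Tallies residues and accumulates the totals needed for contrast
#' calculations: total volume, hydrogenous scattering-length sum and labile
#' hydrogen count. Terminal groups (the extra H and OH) are neglected, which
#' is standard for proteins of more than a few residues.
#'
#' @param sequence one-letter amino-acid string (characters outside the 20
#'   standard letters are rejected), or `NULL` when `counts` is given.
#' @param counts named vector of per-residue counts, names one-letter codes.
#' @return object of class `protein_composition` with fields
#'   `residue_counts`, `total_volume` (A^3), `sum_b_nonexchanged` (A, all
#'   labile positions counted as H) and `n_labile_h`.
#' @examples
#' protein_composition("ACDEFGHIKLMNPQRSTVWY")
#' @export
protein_composition <- function(sequence = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    letters1 <- strsplit(toupper(gsub("[\\s*]", "", sequence, perl = TRUE)),
                         "")[[1]]
    bad <- setdiff(unique(letters1), rownames(.aa_table()))
    if (length(bad) > 0L) {
      stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
    }
    counts <- table(factor(letters1, levels = rownames(.aa_table())))
    counts <- stats::setNames(as.numeric(counts), rownames(.aa_table()))
  } else {
    stopifnot(all(names(counts) %in% rownames(.aa_table())), all(counts >= 0))
    full <- stats::setNames(numeric(nrow(.aa_table())), rownames(.aa_table()))
    full[names(counts)] <- counts
    counts <- full
  }
  if (sum(counts) <= 0) stop("empty composition")
  tb <- .aa_table()[names(counts), ]
  structure(
    list(
      residue_counts = counts,
      total_volume = sum(counts * tb$volume),
      sum_b_nonexchanged = sum(counts * tb$sum_b_h),
      n_labile_h = sum(counts * tb$labile)
    ),
    class = "protein_composition"
  )
}

#' @export
print.protein_composition <- function(x, ...) {
  cat(sprintf(
    "<protein_composition> %.0f residues, V = %.0f A^3, labile H = %.0f\n",
    sum(x$residue_counts), x$total_volume, x$n_labile_h
  ))
  cat(sprintf("  SLD(H2O) = %.3e, SLD(D2O) = %.3e A^-2, match point = %.1f%% D2O\n",
              protein_sld(x, 0), protein_sld(x, 1), 100 * match_point(x)))
  invisible(x)
}

#' Average globular-protein composition
#'
#' A reference composition built from average amino-acid frequencies over
#' the Swiss-Prot database, scaled to `n` residues. Its contrast match point
#' is close to 42% D2O, the conventional "protein-matched water".
#'
#' @param n number of residues (default 100).
#' @return a `protein_composition`.
#' @export
average_protein_composition <- function(n = 100) {
  freq <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
            E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
            M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
            Y = 2.92, V = 6.87)
  protein_composition(counts = n * freq / sum(freq))
}

#' Protein scattering length density under isotopic exchange
#'
#' Labile hydrogens are assumed to exchange completely with the solvent, in
#' proportion to its D2O fraction, so the SLD is affine in `f_d2o`:
#' `(sum_b_nonexchanged + n_labile_h * f_d2o * (b_D - b_H)) / total_volume`.
#'
#' @param comp a `protein_composition`.
#' @param f_d2o solvent D2O volume fraction in \[0, 1\]. Vectorised.
#' @return SLD in A^-2.
#' @export
protein_sld <- function(comp, f_d2o) {
  stopifnot(inherits(comp, "protein_composition"))
  if (any(f_d2o < 0) || any(f_d2o > 1)) stop("f_d2o must lie in [0, 1]")
  dbd <- (.neutron_b_fm[["D"]] - .neutron_b_fm[["H"]]) * .FM_TO_A
  (comp$sum_b_nonexchanged + comp$n_labile_h * f_d2o * dbd) / comp$total_volume
}

#' Contrast match point of a protein
#'
#' The solvent D2O fraction at which the protein SLD equals the solvent SLD,
#' rendering the protein invisible to neutrons ("protein-matched water").
#' Both SLDs are affine in `f_d2o`, so the intersection is closed-form and
#' unique unless the slopes coincide.
#'
#' @param comp a `protein_composition`.
#' @return the matching D2O fraction. A value outside \[0, 1\] is returned
#'   as-is (with a warning) rather than clamped; parallel SLD lines are an
#'   error.
#' @export
match_point <- function(comp) {
  stopifnot(inherits(comp, "protein_composition"))
  dbd <- (.neutron_b_fm[["D"]] - .neutron_b_fm[["H"]]) * .FM_TO_A
  p0 <- comp$sum_b_nonexchanged / comp$total_volume
  p_slope <- comp$n_labile_h * dbd / comp$total_volume
  s0 <- solvent_sld(0)
  s_slope <- solvent_sld(1) - s0
  if (abs(s_slope - p_slope) < 1e-16) {
    stop("protein and solvent SLD lines are parallel: no match point")
  }
  f <- (p0 - s0) / (s_slope - p_slope)
  if (f < 0 || f > 1) {
    warning(sprintf("match point %.3f lies outside [0, 1]", f))
  }
  f
}

#' Layer thickness from area per molecule
#'
#' Converts a component molecular volume and an in-plane area per molecule
#' into a slab thickness: `thickness = molecular_volume / area_per_molecule`.
#' This couples headgroup and tail layer thicknesses to a single shared
#' lipid area in the bilayer models.
#'
#' @param molecular_volume component volume, A^3 (> 0).
#' @param area_per_molecule in-plane area, A^2 (> 0).
#' @return thickness in A.
#' @export
layer_thickness_from_apm <- function(molecular_volume, area_per_molecule) {
  if (any(molecular_volume <= 0) || any(area_per_molecule <= 0)) {
    stop("molecular_volume and area_per_molecule must be > 0")
  }
  molecular_volume / area_per_molecule
}

#' Read a protein composition from a FASTA file
#'
#' Reads the first record of an amino-acid FASTA file and converts it to a
#' `protein_composition`.
#'
#' @param path FASTA file path.
#' @return a `protein_composition`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  protein_composition(as.character(seqs[[1]]))
}
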