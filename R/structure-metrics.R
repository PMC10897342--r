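# Geometry metrics on macromolecular coordinates: Kabsch superposition
# RMSD with optional iterative pruning, intermolecular salt-bridge
# detection, ring-assembly construction from symmetry operators, and axial
# pore-radius profiles of toroidal oligomers.

# Bondi van der Waals radii, A
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
.VDW_DEFAULT <- 1.7

#' Construct an atom model
#'
#' A light container for labelled 3-D coordinates: one row per atom with
#' element, atom name, residue name/number, chain and coordinates in A.
#'
#' @param atoms data frame with columns `element`, `name`, `resid`
#'   (residue name), `resno`, `chain`, `x`, `y`, `z` and optionally
#'   `occupancy` (defaults to 1).
#' @param symmetry optional list describing crystal symmetry (free-form;
#'   e.g. space group and cell), carried as metadata.
#' @return object of class `atom_model`.
#' @export
atom_model <- function(atoms, symmetry = NULL) {
  need <- c("element", "name", "resid", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("coordinates must be finite")
  }
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  structure(list(atoms = atoms, symmetry = symmetry), class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> %d atoms, %d chain(s)%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (is.null(x$symmetry)) "" else ", symmetry present"))
  invisible(x)
}

#' Read a structure file into an atom model
#'
#' Wraps bio3d's PDB/mmCIF readers and converts to the package's
#' `atom_model` container. Alternate locations other than the first are
#' dropped.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @return an [atom_model()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep & at$type %in% c("ATOM", "HETATM"), ]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9']", "", at$elety), 1, 1)
  }
  atom_model(data.frame(
    element = toupper(trimws(elem)),
    name = trimws(at$elety),
    resid = at$resid,
    resno = at$resno,
    chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    occupancy = if (is.null(at$o)) 1 else at$o,
    stringsAsFactors = FALSE
  ))
}

#' C-alpha coordinates of one chain
#'
#' @param model an [atom_model()].
#' @param chain chain identifier.
#' @return n x 3 coordinate matrix, one row per residue in residue order.
#' @export
ca_coords <- function(model, chain) {
  at <- model$atoms
  sel <- at$chain == chain & at$name == "CA"
  at <- at[sel, ]
  at <- at[order(at$resno), ]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$resno
  m
}

# internal: Kabsch optimal rotation mapping centred b onto centred a
.kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- t(b0) %*% a0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, center_a = ca, center_b = cb,
       transformed = sweep(b0 %*% t(r), 2, ca, `+`))
}

#' Optimal superposition RMSD of paired coordinates
#'
#' Least-squares rigid-body superposition (Kabsch algorithm) of two equal
#' length coordinate sets, e.g. C-alpha atoms of sequence-aligned residues.
#' With `prune_cutoff` set, the worst-fitting pair exceeding the cutoff is
#' dropped and the superposition repeated until all remaining deviations
#' are within the cutoff (an approximation to the pruning used by common
#' structure viewers; the all-pair value is the reference quantity).
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @param prune_cutoff per-pair deviation cutoff in A, or `NULL` for no
#'   pruning.
#' @return list with `rmsd` (A), `n_pairs` used, `rmsd_all`/`n_all` for the
#'   unpruned superposition and the fitted `rotation`.
#' @export
superpose_rmsd <- function(coords_a, coords_b, prune_cutoff = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3) {
    stop("coordinate sets must be equal-size n x 3 matrices")
  }
  if (nrow(coords_a) < 3) stop("at least 3 atom pairs required")
  fit_once <- function(a, b) {
    k <- .kabsch(a, b)
    dev <- sqrt(rowSums((k$transformed - a)^2))
    list(rmsd = sqrt(mean(dev^2)), dev = dev, rotation = k$rotation)
  }
  all_fit <- fit_once(coords_a, coords_b)
  use <- rep(TRUE, nrow(coords_a))
  cur <- all_fit
  if (!is.null(prune_cutoff)) {
    repeat {
      worst <- which.max(ifelse(use, cur$dev, -Inf))
      if (cur$dev[worst] <= prune_cutoff || sum(use) <= 3) break
      use[worst] <- FALSE
      sub <- fit_once(coords_a[use, , drop = FALSE],
                      coords_b[use, , drop = FALSE])
      cur$rmsd <- sub$rmsd
      cur$rotation <- sub$rotation
      dev <- rep(NA_real_, length(use))
      dev[use] <- sub$dev
      cur$dev <- dev
    }
  }
  list(rmsd = cur$rmsd, n_pairs = sum(use),
       rmsd_all = all_fit$rmsd, n_all = nrow(coords_a),
       rotation = cur$rotation)
}

# side-chain charged heavy atoms
.ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.HIS_ATOMS <- c("ND1", "NE2")

#' Intermolecular salt bridges between two chains
#'
#' Finds unique (acidic, basic) residue pairs across two chains where any
#' side-chain carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2) lies within
#' `cutoff` of a side-chain nitrogen of Lys (NZ) or Arg (NE/NH1/NH2);
#' histidine ND1/NE2 are counted as basic only when `include_his` is set.
#' Charged residues whose side-chain atoms are missing from the model are
#' skipped with a message.
#'
#' @param model an [atom_model()].
#' @param chain_a,chain_b chain identifiers (order-insensitive).
#' @param cutoff heavy-atom distance cutoff, A.
#' @param include_his treat histidine as basic?
#' @return data frame of bridges: acid chain/residue, base chain/residue
#'   and the minimal contact distance.
#' @export
find_salt_bridges <- function(model, chain_a, chain_b, cutoff = 4.0,
                              include_his = FALSE) {
  at <- model$atoms
  if (!all(c(chain_a, chain_b) %in% at$chain)) {
    stop("both chains must be present in the model")
  }
  basic <- .BASIC_ATOMS
  if (include_his) basic$HIS <- .HIS_ATOMS
  collect <- function(chain, spec) {
    res <- list()
    sub <- at[at$chain == chain & at$resid %in% names(spec), ]
    for (rn in unique(sub$resno)) {
      rsub <- sub[sub$resno == rn, ]
      want <- spec[[rsub$resid[1]]]
      rat <- rsub[rsub$name %in% want, ]
      if (nrow(rat) == 0) {
        message(sprintf("chain %s %s%d: side-chain atoms missing, skipped",
                        chain, rsub$resid[1], rn))
        next
      }
      res[[length(res) + 1]] <- rat
    }
    res
  }
  bridges <- list()
  for (dir in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    acids <- collect(dir[1], .ACIDIC_ATOMS)
    bases <- collect(dir[2], basic)
    for (ac in acids) {
      for (ba in bases) {
        dmat <- as.matrix(stats::dist(rbind(
          as.matrix(ac[, c("x", "y", "z")]),
          as.matrix(ba[, c("x", "y", "z")])
        )))[seq_len(nrow(ac)), nrow(ac) + seq_len(nrow(ba)), drop = FALSE]
        dmin <- min(dmat)
        if (dmin <= cutoff) {
          bridges[[length(bridges) + 1]] <- data.frame(
            acid_chain = ac$chain[1], acid_resid = ac$resid[1],
            acid_resno = ac$resno[1],
            base_chain = ba$chain[1], base_resid = ba$resid[1],
            base_resno = ba$resno[1],
            distance = dmin, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(bridges) == 0) {
    return(data.frame(acid_chain = character(), acid_resid = character(),
                      acid_resno = integer(), base_chain = character(),
                      base_resid = character(), base_resno = integer(),
                      distance = numeric()))
  }
  out <- do.call(rbind, bridges)
  out[order(out$distance), ]
}

#' Ring assembly of protomer copies
#'
#' @param models list of [atom_model()] protomer copies.
#' @param axis_point,axis_direction ring axis (point + unit vector); when
#'   omitted the axis is the principal normal of the protomer-centroid
#'   plane, through the centroid mean.
#' @return object of class `ring_assembly` with fields `models`, `order`,
#'   `axis_point`, `axis_direction`.
#' @export
ring_assembly <- function(models, axis_point = NULL, axis_direction = NULL) {
  stopifnot(is.list(models), length(models) >= 2)
  for (m in models) stopifnot(inherits(m, "atom_model"))
  centroids <- t(vapply(models, function(m) {
    colMeans(as.matrix(m$atoms[, c("x", "y", "z")]))
  }, numeric(3)))
  if (is.null(axis_direction)) {
    cc <- sweep(centroids, 2, colMeans(centroids))
    ev <- eigen(crossprod(cc), symmetric = TRUE)
    axis_direction <- ev$vectors[, 3]     # normal of the centroid plane
  }
  axis_direction <- axis_direction / sqrt(sum(axis_direction^2))
  if (is.null(axis_point)) axis_point <- colMeans(centroids)
  structure(list(models = models, order = length(models),
                 axis_point = axis_point, axis_direction = axis_direction),
            class = "ring_assembly")
}

#' @export
print.ring_assembly <- function(x, ...) {
  cat(sprintf("<ring_assembly> order %d, axis = (%.3f, %.3f, %.3f)\n",
              x$order, x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3]))
  invisible(x)
}

# internal: apply one 4x4 (or list(R, t)) operator to an atom model
.apply_operator <- function(model, op) {
  if (is.matrix(op) && all(dim(op) == c(4, 4))) {
    op <- list(R = op[1:3, 1:3], t = op[1:3, 4])
  }
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(op$R) + matrix(op$t, nrow(xyz), 3, byrow = TRUE)
  out <- model$atoms
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  atom_model(out, model$symmetry)
}

#' Build a ring assembly from symmetry operators
#'
#' Applies a list of transformation operators to a protomer model (or
#' accepts a pre-expanded multi-chain model with no operators) and checks
#' that the copies form a closed ring: the pairwise contact graph, with an
#' edge wherever two copies approach within `contact_cutoff`, must be a
#' single cycle. The ring axis is the principal normal of the protomer
#' centroids.
#'
#' @param model an [atom_model()]; with `operators = NULL` its chains are
#'   taken as the protomer copies (identity passthrough).
#' @param operators list of 4x4 matrices or `list(R = 3x3, t = length-3)`
#'   transformations, identity included.
#' @param contact_cutoff inter-copy contact distance, A.
#' @return a [ring_assembly()]; if no closed ring is found the assembly is
#'   still returned with a `diagnostics` attribute describing the contact
#'   graph, plus a warning.
#' @export
assembly_from_symmetry <- function(model, operators = NULL,
                                   contact_cutoff = 5) {
  stopifnot(inherits(model, "atom_model"))
  copies <- if (is.null(operators)) {
    chains <- unique(model$atoms$chain)
    if (length(chains) < 2) {
      stop("need symmetry operators or a multi-chain model")
    }
    lapply(chains, function(ch) {
      atom_model(model$atoms[model$atoms$chain == ch, ], model$symmetry)
    })
  } else {
    lapply(operators, function(op) .apply_operator(model, op))
  }
  n <- length(copies)
  xyz <- lapply(copies, function(m) as.matrix(m$atoms[, c("x", "y", "z")]))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmin <- sqrt(min(outer(rowSums(xyz[[i]]^2), rowSums(xyz[[j]]^2), `+`) -
                         2 * xyz[[i]] %*% t(xyz[[j]])))
      adj[i, j] <- adj[j, i] <- is.finite(dmin) && dmin <= contact_cutoff
    }
  }
  degrees <- rowSums(adj)
  ring <- ring_assembly(copies)
  if (!all(degrees == 2)) {
    attr(ring, "diagnostics") <- list(degrees = degrees, adjacency = adj)
    warning("copies do not form a single closed ring (see diagnostics attribute)")
  }
  ring
}

#' Axial pore-radius profile of a ring assembly
#'
#' At each axial station the pore radius is the largest probe sphere,
#' centred on the ring axis, that touches no atom: the minimum over atoms
#' of (centre distance minus van der Waals radius). Also reports the
#' minimum pore diameter and the maximum outer diameter of the assembly.
#'
#' @param assembly a [ring_assembly()].
#' @param step axial sampling interval, A.
#' @param radii named per-element van der Waals radii; defaults to the
#'   Bondi table. Set all to zero to profile point geometry.
#' @return object of class `pore_profile`: data frame of `z` (axial
#'   coordinate relative to the axis point) and `radius`, with attributes
#'   `min_pore_diameter` and `max_outer_diameter`.
#' @export
pore_profile <- function(assembly, step = 1, radii = .vdw_radii) {
  stopifnot(inherits(assembly, "ring_assembly"))
  atoms <- do.call(rbind, lapply(assembly$models, function(m) m$atoms))
  if (nrow(atoms) == 0) stop("empty assembly")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rv <- if (length(radii) == 1L && is.null(names(radii))) {
    rep(radii, nrow(atoms))
  } else {
    radii[atoms$element]
  }
  rv[is.na(rv)] <- if (all(radii == 0)) 0 else .VDW_DEFAULT
  u <- assembly$axis_direction
  rel <- sweep(xyz, 2, assembly$axis_point)
  z_atom <- as.numeric(rel %*% u)
  radial <- sqrt(pmax(rowSums(rel^2) - z_atom^2, 0))
  z_stations <- seq(min(z_atom), max(z_atom), by = step)
  if (length(z_stations) == 0) z_stations <- 0
  radius <- vapply(z_stations, function(z0) {
    min(sqrt(radial^2 + (z_atom - z0)^2) - rv)
  }, numeric(1))
  out <- data.frame(z = z_stations, radius = radius)
  attr(out, "min_pore_diameter") <- 2 * min(radius)
  attr(out, "max_outer_diameter") <- 2 * max(radial + rv)
  class(out) <- c("pore_profile", "data.frame")
  out
}
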