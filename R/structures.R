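# Construction of zinc-blende ZnS crystals, (110) slabs and spherical
# nanoparticles, plus coordination analysis, pruning and bonded topology.
# All coordinates in Angstrom.

#' Lattice specification for zinc-blende crystals
#'
#' @param a Cubic lattice constant in Angstrom.  Defaults to 5.41 A, the
#'   standard room-temperature value for zinc-blende ZnS.
#' @param origin Fractional origin offset (length 3) applied to all basis
#'   atoms before replication.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(a = 5.41, origin = c(0, 0, 0)) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("invalid lattice: 'a' must be a positive finite number")
  structure(list(a = a, structure = "zinc-blende", origin = origin),
            class = "lattice_spec")
}

# Conventional-cell basis: 4 cations (Zn) on the fcc sites, 4 anions (S)
# displaced by (1/4,1/4,1/4).
.zb_basis <- function() {
  zn <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  s  <- zn + 0.25
  list(frac = rbind(zn, s),
       species = c(rep("Zn", 4), rep("S", 4)))
}

.formal_charge <- function(species) {
  ifelse(species == "Zn", 2, ifelse(species == "S", -2, 0))
}

#' Construct a nanostructure object
#'
#' Low-level constructor; the builders [build_unit_cell()],
#' [build_slab_110()] and [build_nanoparticle()] are the usual entry points.
#'
#' @param species Character vector of atom labels.
#' @param xyz Numeric matrix (n x 3) of Cartesian positions in Angstrom.
#' @param box Length-3 box vector (orthorhombic), Angstrom.
#' @param periodic Length-3 logical, per-axis periodicity.
#' @param charge Formal charge per atom (e); derived from species if NULL.
#' @param bonds Integer matrix (m x 2) of 1-based bonded pairs, or NULL.
#' @param angles Integer matrix (k x 3) of 1-based (end, apex, end) triples.
#' @param surface Logical per-atom surface flag, or NULL.
#' @return Object of class `nanostructure`.
#' @export
nanostructure <- function(species, xyz, box, periodic = c(FALSE, FALSE, FALSE),
                          charge = NULL, bonds = NULL, angles = NULL,
                          surface = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3, length(species) == nrow(xyz))
  if (!all(is.finite(xyz))) stop("non-finite atom positions")
  if (is.null(charge)) charge <- .formal_charge(species)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  structure(list(species = as.character(species), xyz = xyz,
                 charge = as.numeric(charge), box = as.numeric(box),
                 periodic = as.logical(periodic),
                 bonds = bonds, angles = angles, surface = surface),
            class = "nanostructure")
}

#' @export
print.nanostructure <- function(x, ...) {
  cnt <- table(x$species)
  cat("nanostructure:", nrow(x$xyz), "atoms (",
      paste(sprintf("%s: %d", names(cnt), as.integer(cnt)), collapse = ", "),
      ")\n")
  cat(sprintf("  box: %.3f x %.3f x %.3f A, periodic: %s\n",
              x$box[1], x$box[2], x$box[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  cat(sprintf("  total formal charge: %+g e\n", sum(x$charge)))
  cat(sprintf("  bonds: %d, angles: %d", nrow(x$bonds), nrow(x$angles)))
  if (!is.null(x$surface))
    cat(sprintf(", surface atoms: %d", sum(x$surface)))
  cat("\n")
  invisible(x)
}

#' @export
summary.nanostructure <- function(object, ...) {
  print(object)
  if (nrow(object$bonds) > 0) {
    bl <- bond_lengths(object)
    cat(sprintf("  bond lengths: %.4f - %.4f A (mean %.4f)\n",
                min(bl), max(bl), mean(bl)))
  }
  invisible(object)
}

#' Number of atoms in a nanostructure
#' @param x A `nanostructure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$xyz)

#' Build the conventional zinc-blende unit cell
#'
#' Returns the cubic conventional cell with 4 Zn and 4 S atoms at the
#' standard zinc-blende fractional coordinates, fully periodic.
#'
#' @param lattice A [lattice_spec()].
#' @return A `nanostructure` with 8 atoms.
#' @examples
#' cell <- build_unit_cell(lattice_spec(5.41))
#' n_atoms(cell)  # 8
#' @export
build_unit_cell <- function(lattice = lattice_spec()) {
  stopifnot(inherits(lattice, "lattice_spec"))
  b <- .zb_basis()
  frac <- sweep(b$frac, 2, lattice$origin, "+") %% 1
  nanostructure(b$species, frac * lattice$a,
                box = rep(lattice$a, 3), periodic = c(TRUE, TRUE, TRUE))
}

#' Build a zinc-blende (110) slab
#'
#' The slab is periodic in X and Y and open in Z (the \[110\] surface
#' normal).  The lateral cell is `n_x` repeats of length `a` along the
#' \[001\]-type axis and `n_y` repeats of length `a*sqrt(2)` along the
#' \[-110\]-type axis; `n_layers` atomic (110) layers are stacked with
#' spacing `a/(2*sqrt(2))`.  Each layer holds 2 Zn + 2 S per surface cell,
#' so the slab is stoichiometric with `4 * n_x * n_y * n_layers` atoms.
#' Top- and bottom-layer atoms are flagged as surface.
#'
#' @param lattice A [lattice_spec()].
#' @param n_x,n_y Lateral surface-cell repeats (>= 1).
#' @param n_layers Number of atomic (110) layers (>= 1).
#' @return A `nanostructure`.
#' @examples
#' slab <- build_slab_110(lattice_spec(5.41), 2, 2, 4)
#' n_atoms(slab)  # 64
#' @export
build_slab_110 <- function(lattice = lattice_spec(), n_x, n_y, n_layers) {
  stopifnot(inherits(lattice, "lattice_spec"))
  n_x <- as.integer(n_x); n_y <- as.integer(n_y); n_layers <- as.integer(n_layers)
  if (any(c(n_x, n_y, n_layers) < 1)) stop("counts must be >= 1")
  a <- lattice$a
  lx <- n_x * a
  ly <- n_y * a * sqrt(2)
  dz <- a / (2 * sqrt(2))
  lz <- n_layers * dz

  b <- .zb_basis()
  # enumerate conventional cells, rotate to the (110) frame:
  #   x' = p.z (along [001]);  y' = (p.y - p.x)/sqrt(2);  z' = (p.x + p.y)/sqrt(2)
  nrep <- n_y + ceiling(n_layers / 2) + 3
  cells <- expand.grid(i = -nrep:nrep, j = -nrep:nrep, k = -1:n_x)
  frac <- b$frac
  tol <- 1e-6
  wrap <- function(v, L) {
    w <- v %% L
    w[w > L - 1e-4] <- w[w > L - 1e-4] - L   # snap near-edge values to 0
    w
  }
  pos <- list(); spc <- list()
  for (m in seq_len(nrow(frac))) {
    px <- (cells$i + frac[m, 1]) * a
    py <- (cells$j + frac[m, 2]) * a
    pz <- (cells$k + frac[m, 3]) * a
    xp <- wrap(pz, lx)
    yp <- wrap((py - px) / sqrt(2), ly)
    zp <- (px + py) / sqrt(2)
    keep <- zp > -tol & zp < lz - dz / 2
    pos[[m]] <- cbind(xp[keep], yp[keep], zp[keep])
    spc[[m]] <- rep(b$species[m], sum(keep))
  }
  xyz <- do.call(rbind, pos)
  species <- unlist(spc)
  # wrapped replicas of the same lattice site coincide; deduplicate
  key <- paste(round(xyz[, 1], 4), round(xyz[, 2], 4), round(xyz[, 3], 4))
  dup <- duplicated(key)
  xyz <- xyz[!dup, , drop = FALSE]
  species <- species[!dup]
  o <- order(xyz[, 3], xyz[, 2], xyz[, 1])
  xyz <- xyz[o, , drop = FALSE]
  species <- species[o]

  layer <- as.integer(round(xyz[, 3] / dz))
  surface <- layer == 0 | layer == max(layer)
  nanostructure(species, xyz, box = c(lx, ly, lz),
                periodic = c(TRUE, TRUE, FALSE), surface = surface)
}

#' Carve a spherical nanoparticle from the zinc-blende lattice
#'
#' Replicates the conventional cell, keeps all atoms within
#' `diameter / 2` of the centre, and (optionally) removes
#' single-coordinated surface atoms in one pass, following the usual
#' construction of faceted spherical nanoparticles.
#'
#' @param lattice A [lattice_spec()].
#' @param diameter Sphere diameter in Angstrom (must exceed `a`).
#' @param center Centre of the cut in fractional (cell) coordinates.  The
#'   default `c(0, 0, 0)` is a cation site.
#' @param prune If TRUE (default), single-coordinated atoms are removed
#'   (one pass; see [coordination_and_prune()] for fixpoint pruning).
#' @param bond_cutoff Neighbour cutoff (A) used for the pruning pass.
#' @return A non-periodic `nanostructure`; attributes `radius` (maximal
#'   radial extent, A) and `counts` (per-species table) report the cut.
#' @export
build_nanoparticle <- function(lattice = lattice_spec(), diameter,
                               center = c(0, 0, 0), prune = TRUE,
                               bond_cutoff = 2.9) {
  stopifnot(inherits(lattice, "lattice_spec"))
  a <- lattice$a
  if (diameter <= a) stop("diameter must exceed the lattice constant")
  r <- diameter / 2
  nrep <- ceiling(r / a) + 1
  b <- .zb_basis()
  cells <- expand.grid(i = -nrep:nrep, j = -nrep:nrep, k = -nrep:nrep)
  ctr <- center * a
  pos <- list(); spc <- list()
  for (m in seq_len(nrow(b$frac))) {
    p <- cbind((cells$i + b$frac[m, 1]) * a,
               (cells$j + b$frac[m, 2]) * a,
               (cells$k + b$frac[m, 3]) * a)
    d2 <- (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2
    keep <- d2 <= r^2
    pos[[m]] <- p[keep, , drop = FALSE]
    spc[[m]] <- rep(b$species[m], sum(keep))
  }
  xyz <- do.call(rbind, pos)
  if (nrow(xyz) == 0) stop("empty structure: diameter too small for this lattice")
  xyz <- sweep(xyz, 2, ctr)     # centre at origin
  species <- unlist(spc)
  side <- 2 * (r + a)
  np <- nanostructure(species, xyz, box = rep(side, 3),
                      periodic = c(FALSE, FALSE, FALSE))
  if (prune)
    np <- coordination_and_prune(np, bond_cutoff = bond_cutoff,
                                 min_coord = 2, iterate = FALSE)
  rad <- sqrt(max(rowSums(np$xyz^2)))
  cn <- coordination_numbers(np, bond_cutoff)
  np$surface <- cn < 4
  attr(np, "radius") <- rad
  attr(np, "counts") <- table(np$species)
  np
}

#' Scan candidate nanoparticle centres for neutral stoichiometric cuts
#'
#' Tries high-symmetry centres (cation site, anion site, bond midpoint,
#' tetrahedral hole) and reports species counts and net formal charge of
#' the resulting pruned cuts.
#'
#' @inheritParams build_nanoparticle
#' @return data.frame with one row per candidate centre.
#' @export
nanoparticle_center_scan <- function(lattice = lattice_spec(), diameter,
                                     prune = TRUE, bond_cutoff = 2.9) {
  centers <- list(cation = c(0, 0, 0), anion = c(.25, .25, .25),
                  bond_mid = c(.125, .125, .125),
                  tet_hole = c(.5, .5, .5))
  rows <- lapply(names(centers), function(nm) {
    np <- build_nanoparticle(lattice, diameter, centers[[nm]], prune, bond_cutoff)
    data.frame(center = nm, n_atoms = n_atoms(np),
               n_zn = sum(np$species == "Zn"), n_s = sum(np$species == "S"),
               net_charge = sum(np$charge), radius = attr(np, "radius"))
  })
  do.call(rbind, rows)
}

#' Heteroatomic coordination numbers
#'
#' Counts, for every atom, its unlike-species (Zn-S) contacts within
#' `bond_cutoff`, using the minimum image under the structure's
#' periodicity.
#'
#' @param structure A `nanostructure`.
#' @param bond_cutoff Contact distance cutoff in Angstrom.
#' @return Integer vector of per-atom coordination numbers.
#' @export
coordination_numbers <- function(structure, bond_cutoff = 2.9) {
  if (bond_cutoff <= 0) stop("bond_cutoff must be > 0")
  n <- n_atoms(structure)
  cn <- integer(n)
  if (n < 2) return(cn)
  pairs <- cpp_neighbor_pairs(structure$xyz, structure$box,
                              as.integer(structure$periodic), bond_cutoff)
  if (nrow(pairs) > 0) {
    het <- structure$species[pairs[, 1]] != structure$species[pairs[, 2]]
    pairs <- pairs[het, , drop = FALSE]
    tab <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
    cn <- as.integer(tab)
  }
  cn
}

#' Remove under-coordinated atoms
#'
#' Atoms with heteroatomic coordination below `min_coord` are removed in a
#' single pass (default), or repeatedly until no further atom falls below
#' the threshold when `iterate = TRUE`.  Single-pass semantics: removal
#' decisions are taken simultaneously on the input structure, so an atom
#' whose neighbours are removed in the same pass is retained.
#'
#' @param structure A `nanostructure`.
#' @param bond_cutoff Contact cutoff in Angstrom.
#' @param min_coord Minimum coordination to keep an atom (default 2 keeps
#'   everything except single- and zero-coordinated atoms).
#' @param iterate If TRUE, prune to fixpoint.
#' @return The pruned `nanostructure` (topology fields dropped).
#' @export
coordination_and_prune <- function(structure, bond_cutoff = 2.9,
                                   min_coord = 2, iterate = FALSE) {
  repeat {
    cn <- coordination_numbers(structure, bond_cutoff)
    drop <- cn < min_coord
    if (!any(drop)) return(structure)
    structure <- nanostructure(structure$species[!drop],
                               structure$xyz[!drop, , drop = FALSE],
                               structure$box, structure$periodic,
                               charge = structure$charge[!drop])
    if (!iterate) return(structure)
  }
}

#' Derive bond and angle topology
#'
#' Bonds are all heteroatomic (Zn-S type) pairs within `bond_cutoff`
#' (minimum image under the structure's periodicity); angles are all
#' bonded triples sharing an apex atom (S-Zn-S and Zn-S-Zn in ZnS).
#' Atoms with coordination < 4 are flagged as surface atoms.
#'
#' @param structure A `nanostructure`.
#' @param bond_cutoff Bond cutoff (A); must lie between the first and
#'   second neighbour shells (2.34 and 3.83 A at a = 5.41).
#' @return The structure with `bonds`, `angles` and `surface` fields set.
#' @export
derive_topology <- function(structure, bond_cutoff = 2.9) {
  if (bond_cutoff <= 0) stop("bond_cutoff must be > 0")
  n <- n_atoms(structure)
  pairs <- cpp_neighbor_pairs(structure$xyz, structure$box,
                              as.integer(structure$periodic), bond_cutoff)
  if (nrow(pairs) > 0) {
    het <- structure$species[pairs[, 1]] != structure$species[pairs[, 2]]
    pairs <- pairs[het, , drop = FALSE]
  }
  cn <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  if (n > 0 && mean(cn) > 4.5)
    stop("ambiguous topology: cutoff appears to reach beyond the first neighbour shell")
  # angles: for each apex, all unordered neighbour pairs
  nbr <- vector("list", n)
  for (m in seq_len(nrow(pairs))) {
    i <- pairs[m, 1]; j <- pairs[m, 2]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  ang <- list()
  for (apex in seq_len(n)) {
    nb <- nbr[[apex]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      ang[[length(ang) + 1]] <- cbind(cmb[1, ], apex, cmb[2, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else matrix(integer(0), 0, 3)
  structure$bonds <- pairs
  structure$angles <- angles
  structure$surface <- cn < 4
  structure
}

#' Bond lengths of a structure's bond list
#' @param structure A `nanostructure` with derived topology.
#' @return Numeric vector of bond lengths (A), minimum image.
#' @export
bond_lengths <- function(structure) {
  b <- structure$bonds
  if (nrow(b) == 0) return(numeric(0))
  d <- structure$xyz[b[, 1], , drop = FALSE] - structure$xyz[b[, 2], , drop = FALSE]
  for (k in 1:3) {
    if (structure$periodic[k]) {
      L <- structure$box[k]
      d[, k] <- d[, k] - L * round(d[, k] / L)
    }
  }
  sqrt(rowSums(d^2))
}
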