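#' Carbon nanotube chirality
#'
#' Wrapping indices `(m, n)` of a single-walled carbon nanotube together with
#' the graphene lattice constant `a0`. The tube diameter follows
#' `d = (a0 / pi) * sqrt(n^2 + m^2 + n m)`.
#'
#' @param m,n non-negative integer wrapping indices, not both zero.
#' @param a0 graphene lattice constant in nm (default 0.246).
#' @return A list of class `chirality`.
#' @export
chirality <- function(m, n, a0 = 0.246) {
  if (m < 0 || n < 0 || (m == 0 && n == 0)) {
    stop("chirality indices must be non-negative and not both zero",
         call. = FALSE)
  }
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  structure(list(m = as.integer(m), n = as.integer(n), a0 = a0),
            class = "chirality")
}

#' Nanotube diameter from chirality
#'
#' `d = (a0 / pi) * sqrt(n^2 + m^2 + n m)`, symmetric in `(m, n)` and
#' strictly increasing in either index.
#'
#' @param ch a [chirality()].
#' @return Diameter in nm.
#' @examples
#' tube_diameter(chirality(15, 20)) # ~ 2.38 nm, the C720-matched tube
#' @export
tube_diameter <- function(ch) {
  stopifnot(inherits(ch, "chirality"))
  (ch$a0 / pi) * sqrt(ch$n^2 + ch$m^2 + ch$n * ch$m)
}

#' Rank chiralities by closeness to a target diameter
#'
#' Enumerates every pair with `0 <= m <= n <= max_index` (the diameter is
#' symmetric in the indices, so only one triangle is searched), excluding
#' (0, 0), and sorts by `|d - target_d|` ascending. Ties are broken by
#' smaller `n`, then smaller `m`. Useful for matching a tube to a fullerene
#' end-cap: C720 has diameter ~2.4125 nm and the closest tube under this
#' metric is (12, 23), with (15, 20) the commonly quoted near match at
#' ~2.38 nm.
#'
#' @param target_d target diameter (nm), > 0.
#' @param a0 lattice constant (nm).
#' @param max_index largest wrapping index to consider, >= 1.
#' @return A tibble with columns `m`, `n`, `diameter`, `gap`, sorted by
#'   `gap`; contains every enumerated candidate.
#' @export
rank_chiralities <- function(target_d, a0 = 0.246, max_index = 40) {
  if (target_d <= 0) stop("target_d must be > 0", call. = FALSE)
  if (max_index < 1) stop("max_index must be >= 1", call. = FALSE)
  grid <- tidyr::expand_grid(m = 0:max_index, n = 0:max_index)
  grid <- dplyr::filter(grid, .data$m <= .data$n, !(.data$m == 0 & .data$n == 0))
  grid <- dplyr::mutate(grid,
    diameter = (a0 / pi) * sqrt(.data$n^2 + .data$m^2 + .data$n * .data$m),
    gap = abs(.data$diameter - target_d))
  dplyr::arrange(grid, .data$gap, .data$n, .data$m)
}

#' Nanocarrier construction bookkeeping
#'
#' Describes one of the two carrier types: a bare fullerene (C720) or an
#' end-capped carbon nanotube whose caps are C720 hemispheres. Each
#' cap-tube junction is stitched with a fixed number of new covalent bonds
#' (six per cap in the reference construction, twelve in total).
#'
#' @param kind `"fullerene"` or `"end-capped CNT"`.
#' @param radius carrier radius (nm).
#' @param length tube length (nm); must be `NULL` for a fullerene.
#' @param carbon_atoms number of carbon atoms in the carrier.
#' @param insulin_chains number of attached insulin chains.
#' @param junction_bonds_per_cap covalent bonds stitched per cap-tube
#'   junction (default 6).
#' @return A list of class `carrier_spec`.
#' @export
carrier_spec <- function(kind = c("end-capped CNT", "fullerene"),
                         radius = 2.41, length = NULL,
                         carbon_atoms = if (kind == "fullerene") 720L else 2200L,
                         insulin_chains = 4L,
                         junction_bonds_per_cap = 6L) {
  kind <- match.arg(kind)
  if (kind == "fullerene" && !is.null(length)) {
    stop("a fullerene has no length", call. = FALSE)
  }
  if (carbon_atoms < 0 || insulin_chains < 0 || junction_bonds_per_cap < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(list(kind = kind, radius = radius, length = length,
                 carbon_atoms = as.integer(carbon_atoms),
                 insulin_chains = as.integer(insulin_chains),
                 junction_bonds_per_cap = as.integer(junction_bonds_per_cap)),
            class = "carrier_spec")
}

#' Total cap-tube junction bonds of an end-capped nanotube
#'
#' Two caps, `junction_bonds_per_cap` new covalent bonds each; the default
#' construction stitches six atoms per cap section, twelve bonds in total.
#'
#' @param spec a [carrier_spec()] with `kind = "end-capped CNT"`.
#' @return Integer bond count.
#' @export
junction_bond_count <- function(spec) {
  stopifnot(inherits(spec, "carrier_spec"))
  if (spec$kind != "end-capped CNT") {
    stop("junction bonds are defined only for an end-capped CNT (fullerenes have no caps)",
         call. = FALSE)
  }
  2L * spec$junction_bonds_per_cap
}

#' Membrane atom bookkeeping
#'
#' Total atom count of the solvated bilayer model:
#' `lipid_atoms + atoms_per_water * water_molecules`. With 7784 TIP3P waters
#' (3 atoms each) around a 63,114-atom POPC bilayer the membrane model has
#' 86,466 atoms.
#'
#' @param water_molecules number of water molecules.
#' @param lipid_atoms number of lipid (bilayer) atoms.
#' @param atoms_per_water atoms per water molecule (3 for TIP3P).
#' @return Total atom count.
#' @export
membrane_atom_count <- function(water_molecules, lipid_atoms,
                                atoms_per_water = 3) {
  if (water_molecules < 0 || lipid_atoms < 0 || atoms_per_water < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  lipid_atoms + atoms_per_water * water_molecules
}

#' Build nanotube coordinates by rolling graphene
#'
#' Maps the two-atom hexagonal graphene cell onto a cylinder of radius
#' `tube_diameter(ch) / 2`. Lattice vectors `a1 = a0 (sqrt(3)/2, 1/2)`,
#' `a2 = a0 (sqrt(3)/2, -1/2)`; the chiral vector `C = n a1 + m a2` wraps
#' around the circumference and the perpendicular direction runs along the
#' tube axis. Nearest-neighbour distances are `a0 / sqrt(3)` on the sheet
#' (slightly shortened by curvature on the cylinder).
#'
#' @param ch a [chirality()].
#' @param length tube length along the axis (nm), > 0.
#' @return A tibble with columns `x`, `y`, `z` in nm; `z` is the tube axis.
#' @export
build_nanotube <- function(ch, length) {
  stopifnot(inherits(ch, "chirality"))
  if (length <= 0) stop("length must be > 0", call. = FALSE)
  a0 <- ch$a0
  a1 <- a0 * c(sqrt(3) / 2, 1 / 2)
  a2 <- a0 * c(sqrt(3) / 2, -1 / 2)
  C <- ch$n * a1 + ch$m * a2
  Cn <- sqrt(sum(C^2))
  chat <- C / Cn
  that <- c(-chat[2], chat[1])
  basis <- list(c(0, 0), (a1 + a2) / 3)
  # index range generous enough to cover the (s, t) window
  rng <- ceiling((Cn + length) / a0) + 2
  ij <- tidyr::expand_grid(i = -rng:rng, j = -rng:rng)
  pts <- purrr::map_dfr(basis, function(b) {
    x <- ij$i * a1[1] + ij$j * a2[1] + b[1]
    y <- ij$i * a1[2] + ij$j * a2[2] + b[2]
    tibble::tibble(s = x * chat[1] + y * chat[2],
                   t = x * that[1] + y * that[2])
  })
  eps <- 1e-9
  pts <- dplyr::filter(pts, .data$s >= -eps, .data$s < Cn - eps,
                       .data$t >= -eps, .data$t < length - eps)
  R <- Cn / (2 * pi)
  phi <- 2 * pi * pts$s / Cn
  tibble::tibble(x = R * cos(phi), y = R * sin(phi), z = pts$t)
}

#' Write carbon coordinates as a PDB file
#'
#' Fixed-column `ATOM` records, element C, 1-based serials. Coordinates are
#' supplied in nm and converted to Angstrom at this boundary (all geometry
#' arithmetic upstream stays in nm). An empty coordinate set produces a
#' header-only file.
#'
#' @param atoms tibble or data frame with columns `x`, `y`, `z` in nm.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(atoms, file) {
  n <- nrow(atoms)
  if (n > 99999) stop("PDB format cannot hold more than 99999 atoms", call. = FALSE)
  if (n == 0) {
    writeLines("END", file)
    return(invisible(file))
  }
  pdb_xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))) * 10
  bio3d::write.pdb(file = file, xyz = pdb_xyz,
                   type = rep("ATOM", n), resno = rep(1L, n),
                   resid = rep("CNT", n), eleno = seq_len(n),
                   elety = rep("C", n), chain = rep("A", n),
                   elesy = rep("C", n))
  invisible(file)
}
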