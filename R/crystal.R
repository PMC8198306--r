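# Hexagonal lattice geometry: d-spacings, Bragg angles, Cartesian embedding,
# supercell expansion. Only the hexagonal system is implemented; the plane
# formulas below are specific to it.

#' Hexagonal lattice
#'
#' A hexagonal cell is described by the basal edge `a` and the prismatic
#' edge `c`, both in Angstrom. The third basal vector is implied by the
#' 120-degree hexagonal geometry.
#'
#' @param a Basal lattice parameter (Angstrom), positive.
#' @param c Prismatic lattice parameter (Angstrom), positive.
#' @return An object of class `hex_lattice`.
#' @examples
#' hap <- hex_lattice(9.400, 6.930)
#' cell_volume(hap)
#' @export
hex_lattice <- function(a, c) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (a <= 0 || c <= 0)
    stop("hexagonal lattice parameters must be positive", call. = FALSE)
  structure(list(a = as.numeric(a), c = as.numeric(c)), class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("Hexagonal lattice: a = %.4f A, c = %.4f A, V = %.3f A^3\n",
              x$a, x$c, cell_volume(x)))
  invisible(x)
}

#' Miller plane (hkl)
#'
#' @param h,k,l Integer Miller indices; `(0,0,0)` is rejected.
#' @return An object of class `miller_plane`.
#' @export
miller_plane <- function(h, k, l) {
  idx <- c(h, k, l)
  if (length(idx) != 3L || !is.numeric(idx) || any(!is.finite(idx)) ||
      any(abs(idx - round(idx)) > 1e-9))
    stop("Miller indices must be three integers", call. = FALSE)
  idx <- as.integer(round(idx))
  if (all(idx == 0L))
    stop("(0,0,0) is not a valid plane", call. = FALSE)
  structure(list(h = idx[1], k = idx[2], l = idx[3]), class = "miller_plane")
}

#' @export
print.miller_plane <- function(x, ...) {
  cat(sprintf("(%d %d %d)\n", x$h, x$k, x$l))
  invisible(x)
}

#' @export
format.miller_plane <- function(x, ...) sprintf("(%d%d%d)", x$h, x$k, x$l)

# Coerce a length-3 numeric or a miller_plane.
as_miller <- function(plane) {
  if (inherits(plane, "miller_plane")) return(plane)
  if (is.numeric(plane) && length(plane) == 3L)
    return(miller_plane(plane[1], plane[2], plane[3]))
  stop("expected a miller_plane or a length-3 integer vector", call. = FALSE)
}

#' Interplanar spacing of a hexagonal lattice
#'
#' Evaluates the hexagonal plane-spacing relation
#' `1/d^2 = (4/3) (h^2 + hk + k^2)/a^2 + l^2/c^2`.
#'
#' @param lattice A [hex_lattice()].
#' @param plane A [miller_plane()] or length-3 integer vector.
#' @return d-spacing in Angstrom.
#' @examples
#' d_spacing(hex_lattice(9.400, 6.930), c(1, 0, 0))
#' @export
d_spacing <- function(lattice, plane) {
  stopifnot(inherits(lattice, "hex_lattice"))
  p <- as_miller(plane)
  inv_d2 <- (4 / 3) * (p$h^2 + p$h * p$k + p$k^2) / lattice$a^2 +
    p$l^2 / lattice$c^2
  1 / sqrt(inv_d2)
}

#' Bragg angle of a reflection
#'
#' @param d d-spacing (Angstrom).
#' @param wavelength X-ray wavelength (Angstrom); defaults to Cu K-alpha1.
#' @return Bragg angle theta in degrees (half the scattering angle 2-theta).
#' @export
bragg_angle <- function(d, wavelength = 1.5406) {
  stopifnot(is.numeric(d), all(d > 0), is.numeric(wavelength),
            wavelength > 0)
  s <- wavelength / (2 * d)
  if (any(s > 1 + 1e-12))
    stop("no diffraction: wavelength exceeds 2d", call. = FALSE)
  asin(pmin(s, 1)) * 180 / pi
}

#' Hexagonal cell volume
#'
#' `V = (sqrt(3)/2) a^2 c`.
#'
#' @inheritParams d_spacing
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  sqrt(3) / 2 * lattice$a^2 * lattice$c
}

#' Cartesian basis of a hexagonal cell
#'
#' Columns are the cell vectors in the conventional crystallographic
#' orientation: `a1 = (a, 0, 0)`, `a2 = (-a/2, a sqrt(3)/2, 0)`,
#' `a3 = (0, 0, c)`.
#'
#' @inheritParams d_spacing
#' @return A 3x3 matrix whose columns are the cell vectors (Angstrom).
#' @export
hex_basis <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  a <- lattice$a
  cbind(c(a, 0, 0), c(-a / 2, a * sqrt(3) / 2, 0), c(0, 0, lattice$c))
}

#' Fractional to Cartesian coordinates
#'
#' @param lattice A [hex_lattice()] or an explicit 3x3 basis matrix whose
#'   columns are the cell vectors.
#' @param frac Fractional coordinates: a length-3 vector or an n x 3 matrix.
#' @return Cartesian coordinates (Angstrom), same shape as `frac`.
#' @export
to_cartesian <- function(lattice, frac) {
  B <- if (is.matrix(lattice)) lattice else hex_basis(lattice)
  stopifnot(identical(dim(B), c(3L, 3L)))
  if (is.matrix(frac)) {
    stopifnot(ncol(frac) == 3L)
    frac %*% t(B)
  } else {
    stopifnot(length(frac) == 3L)
    as.numeric(B %*% frac)
  }
}

#' Crystal structure in P1
#'
#' Holds an explicit (symmetry-expanded) list of atomic sites together with
#' the cell basis. Site coordinates are fractional in the cell basis and are
#' folded into `[0, 1)`. Non-hexagonal boxes (used by the toy test fixtures)
#' are supported by passing an explicit `basis` instead of a lattice.
#'
#' @param sites A data.frame with columns `species` (character), `u`, `v`,
#'   `w` (fractional coordinates) and `radius` (Angstrom, positive).
#' @param lattice Optional [hex_lattice()]; its basis is used when `basis`
#'   is not given.
#' @param basis Optional explicit 3x3 basis matrix (columns = cell vectors).
#' @param supercell Positive integer replication factor already applied to
#'   this cell (1 for a plain unit cell).
#' @return An object of class `crystal_structure` with fields `lattice`,
#'   `basis`, `sites` and `supercell`.
#' @export
crystal_structure <- function(sites, lattice = NULL, basis = NULL,
                              supercell = 1L) {
  if (is.null(basis)) {
    if (is.null(lattice))
      stop("either a lattice or an explicit basis is required", call. = FALSE)
    basis <- hex_basis(lattice)
  }
  stopifnot(is.matrix(basis), identical(dim(basis), c(3L, 3L)),
            abs(det(basis)) > 0)
  need <- c("species", "u", "v", "w", "radius")
  if (!is.data.frame(sites) || !all(need %in% names(sites)) ||
      nrow(sites) == 0L)
    stop("sites must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(as.matrix(sites[, c("u", "v", "w", "radius")]))))
    stop("non-finite site coordinates or radii", call. = FALSE)
  if (any(sites$radius <= 0))
    stop("atomic radii must be positive", call. = FALSE)
  sites <- sites[, need]
  sites$species <- as.character(sites$species)
  for (col in c("u", "v", "w")) sites[[col]] <- sites[[col]] %% 1
  supercell <- as.integer(supercell)
  stopifnot(supercell >= 1L)
  structure(list(lattice = lattice, basis = basis, sites = sites,
                 supercell = supercell),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  kind <- if (x$supercell == 1L) "unit cell" else
    sprintf("%d x %d x %d supercell", x$supercell, x$supercell, x$supercell)
  cat(sprintf("Crystal structure (%s): %d sites, V = %.3f A^3\n",
              kind, nrow(x$sites), structure_volume(x)))
  print(table(x$sites$species))
  invisible(x)
}

#' Cell volume of a crystal structure
#'
#' Volume of the (super)cell box actually stored, i.e. the unit-cell volume
#' times `supercell^3`.
#'
#' @param structure A [crystal_structure()].
#' @return Volume in cubic Angstrom.
#' @export
structure_volume <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  abs(det(structure$basis))
}

#' Expand a structure to an n x n x n supercell
#'
#' Sites are replicated over all `n^3` cell translations and re-expressed as
#' fractional coordinates of the enlarged box; the basis vectors are scaled
#' by `n`. Miller indices passed to the planar-density functions are always
#' interpreted in the basis of the structure they are given, so `(0 2 0)` of
#' a 2 x 2 x 2 supercell is a geometrically different plane from `(0 2 0)`
#' of the unit cell.
#'
#' @param structure A [crystal_structure()].
#' @param n Positive integer replication factor.
#' @return A [crystal_structure()] with `n^3` times as many sites.
#' @export
build_supercell <- function(structure, n) {
  stopifnot(inherits(structure, "crystal_structure"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    stop("supercell factor must be a positive integer", call. = FALSE)
  if (n == 1L) return(structure)
  shifts <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1),
                                  k = 0:(n - 1)))
  base <- structure$sites
  out <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    d <- base
    d$u <- (d$u + shifts[s, 1]) / n
    d$v <- (d$v + shifts[s, 2]) / n
    d$w <- (d$w + shifts[s, 3]) / n
    d
  }))
  rownames(out) <- NULL
  crystal_structure(out, lattice = structure$lattice,
                    basis = structure$basis * n,
                    supercell = structure$supercell * n)
}

# Label used in planar-density records.
cell_kind <- function(structure) {
  if (structure$supercell == 1L) "unit" else
    paste0("supercell-", structure$supercell)
}
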