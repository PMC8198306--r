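# Hexagonal elasticity algebra. A hexagonal crystal has five independent
# stiffness constants C11, C12, C13, C33, C44 (C66 = (C11 - C12)/2). The
# compliance relations and the direction-dependent Young's modulus below are
# specific to this symmetry class.

#' Hexagonal stiffness constants
#'
#' The five independent Voigt stiffness constants of a hexagonal crystal,
#' in GPa. Born mechanical stability is enforced: `C44 > 0`,
#' `C11 > |C12|` and `C33 (C11 + C12) > 2 C13^2`; these conditions also
#' guarantee that the compliance conversion is well defined.
#'
#' @param C11,C12,C13,C33,C44 Stiffness constants (GPa).
#' @return An object of class `hex_stiffness`.
#' @examples
#' hex_stiffness(135.78, 49.21, 56.62, 179.22, 41.73)
#' @export
hex_stiffness <- function(C11, C12, C13, C33, C44) {
  v <- c(C11 = C11, C12 = C12, C13 = C13, C33 = C33, C44 = C44)
  if (any(!is.finite(v)))
    stop("stiffness constants must be finite numbers", call. = FALSE)
  if (C44 <= 0 || C11 <= abs(C12) || C33 * (C11 + C12) <= 2 * C13^2)
    stop("mechanically unstable hexagonal stiffness tensor", call. = FALSE)
  structure(as.list(v), class = "hex_stiffness")
}

#' Hexagonal compliance constants
#'
#' @param S11,S12,S13,S33,S44 Compliance constants (1/GPa).
#' @return An object of class `hex_compliance`.
#' @export
hex_compliance <- function(S11, S12, S13, S33, S44) {
  v <- c(S11 = S11, S12 = S12, S13 = S13, S33 = S33, S44 = S44)
  if (any(!is.finite(v)))
    stop("compliance constants must be finite numbers", call. = FALSE)
  if (S11 <= 0 || S33 <= 0 || S44 <= 0 || S11 <= abs(S12))
    stop("invalid hexagonal compliance tensor", call. = FALSE)
  structure(as.list(v), class = "hex_compliance")
}

#' @export
print.hex_stiffness <- function(x, ...) {
  cat("Hexagonal stiffness (GPa):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.hex_compliance <- function(x, ...) {
  cat("Hexagonal compliance (1/GPa):\n")
  print(unlist(x))
  invisible(x)
}

#' Stiffness to compliance conversion (hexagonal)
#'
#' Closed-form inversion of the hexagonal stiffness matrix. With
#' `D = C33 (C11 + C12) - 2 C13^2`:
#' `S11 = (C33/D + 1/(C11 - C12)) / 2`,
#' `S12 = (C33/D - 1/(C11 - C12)) / 2`,
#' `S33 = (C11 + C12)/D`, `S13 = -C13/D`, `S44 = 1/C44`.
#'
#' @param C A [hex_stiffness()] (GPa).
#' @return A [hex_compliance()] (1/GPa).
#' @export
stiffness_to_compliance <- function(C) {
  stopifnot(inherits(C, "hex_stiffness"))
  D <- C$C33 * (C$C11 + C$C12) - 2 * C$C13^2
  if (D <= 0 || C$C11 == C$C12 || C$C44 == 0)
    stop("mechanically unstable stiffness tensor", call. = FALSE)
  hex_compliance(
    S11 = 0.5 * (C$C33 / D + 1 / (C$C11 - C$C12)),
    S12 = 0.5 * (C$C33 / D - 1 / (C$C11 - C$C12)),
    S13 = -C$C13 / D,
    S33 = (C$C11 + C$C12) / D,
    S44 = 1 / C$C44)
}

#' Compliance to stiffness conversion (hexagonal)
#'
#' The algebraic inverse of [stiffness_to_compliance()]; the hexagonal
#' conversion is involutive in form, so the same expressions apply with S
#' and C exchanged.
#'
#' @param S A [hex_compliance()] (1/GPa).
#' @return A [hex_stiffness()] (GPa).
#' @export
compliance_to_stiffness <- function(S) {
  stopifnot(inherits(S, "hex_compliance"))
  D <- S$S33 * (S$S11 + S$S12) - 2 * S$S13^2
  if (D <= 0 || S$S11 == S$S12 || S$S44 == 0)
    stop("singular compliance tensor", call. = FALSE)
  hex_stiffness(
    C11 = 0.5 * (S$S33 / D + 1 / (S$S11 - S$S12)),
    C12 = 0.5 * (S$S33 / D - 1 / (S$S11 - S$S12)),
    C13 = -S$S13 / D,
    C33 = (S$S11 + S$S12) / D,
    C44 = 1 / S$S44)
}

#' Full 6x6 Voigt matrix of a hexagonal tensor
#'
#' @param x A [hex_stiffness()] or [hex_compliance()]. For compliances the
#'   shear entries follow the engineering Voigt convention
#'   (`S66 = 2 (S11 - S12)`).
#' @return A symmetric 6x6 matrix.
#' @export
voigt_matrix <- function(x) {
  if (inherits(x, "hex_stiffness")) {
    M <- diag(c(x$C11, x$C11, x$C33, x$C44, x$C44, (x$C11 - x$C12) / 2))
    M[1, 2] <- M[2, 1] <- x$C12
    M[1, 3] <- M[3, 1] <- M[2, 3] <- M[3, 2] <- x$C13
  } else if (inherits(x, "hex_compliance")) {
    M <- diag(c(x$S11, x$S11, x$S33, x$S44, x$S44, 2 * (x$S11 - x$S12)))
    M[1, 2] <- M[2, 1] <- x$S12
    M[1, 3] <- M[3, 1] <- M[2, 3] <- M[3, 2] <- x$S13
  } else {
    stop("expected a hex_stiffness or hex_compliance", call. = FALSE)
  }
  M
}

#' Direction-dependent Young's modulus E_hkl (hexagonal)
#'
#' Young's modulus for uniaxial loading normal to the (hkl) plane of a
#' hexagonal crystal, as a closed form in the compliances and the lattice
#' ratio `q = a l / c`:
#' \deqn{E_{hkl} = \frac{[h^2 + (h+2k)^2/3 + q^2]^2}
#'   {S_{11}(h^2 + (h+2k)^2/3)^2 + S_{33} q^4 +
#'    (2S_{13}+S_{44})(h^2 + (h+2k)^2/3) q^2}}
#' The basal and prismatic limits are exact: `E_(00l) = 1/S33` and
#' `E_(hk0) = 1/S11`.
#'
#' @param S A [hex_compliance()] (1/GPa).
#' @param lattice A [hex_lattice()].
#' @param plane A [miller_plane()] or length-3 integer vector.
#' @return Young's modulus in GPa.
#' @examples
#' S <- stiffness_to_compliance(hex_stiffness(135.78, 49.21, 56.62, 179.22, 41.73))
#' youngs_modulus_hkl(S, hex_lattice(9.400, 6.930), c(0, 0, 2))
#' @export
youngs_modulus_hkl <- function(S, lattice, plane) {
  stopifnot(inherits(S, "hex_compliance"), inherits(lattice, "hex_lattice"))
  p <- as_miller(plane)
  A <- p$h^2 + (p$h + 2 * p$k)^2 / 3
  q2 <- (lattice$a * p$l / lattice$c)^2
  num <- (A + q2)^2
  den <- S$S11 * A^2 + S$S33 * q2^2 + (2 * S$S13 + S$S44) * A * q2
  if (den <= 0)
    stop("non-positive compliance quadratic form for this direction",
         call. = FALSE)
  num / den
}

#' Shear modulus from Young's modulus and Poisson's ratio
#'
#' `G = E / (2 (1 + nu))` (isotropic relation).
#'
#' @param E Young's modulus (GPa), positive.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return Shear modulus (GPa).
#' @export
shear_modulus <- function(E, nu) {
  stopifnot(is.numeric(E), is.numeric(nu))
  if (any(E <= 0)) stop("Young's modulus must be positive", call. = FALSE)
  if (any(nu <= -1 | nu >= 0.5))
    stop("Poisson's ratio must lie in (-1, 0.5)", call. = FALSE)
  E / (2 * (1 + nu))
}

#' Dislocation line energy W = G b^2 l
#'
#' Energy (work) associated with a dislocation segment of length `l` and
#' Burgers vector `b` in a medium of shear modulus `G`. Alternatively pass
#' `E` and `nu` to use `W = E b^2 l / (2 (1 + nu))`.
#'
#' @param b Burgers vector magnitude (length units).
#' @param l Dislocation length (same length units).
#' @param G Shear modulus; or supply `E` and `nu` instead.
#' @param E,nu Young's modulus and Poisson's ratio (used when `G` is NULL).
#' @return Energy in `G * length^3` units (e.g. GPa A^3).
#' @export
dislocation_work <- function(b, l, G = NULL, E = NULL, nu = NULL) {
  if (any(c(b, l) <= 0)) stop("b and l must be positive", call. = FALSE)
  if (is.null(G)) {
    if (is.null(E) || is.null(nu))
      stop("supply either G or both E and nu", call. = FALSE)
    G <- shear_modulus(E, nu)
  } else if (G <= 0) {
    stop("shear modulus must be positive", call. = FALSE)
  }
  G * b^2 * l
}
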