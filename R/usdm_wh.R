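# Uniform stress deformation model (USDM) Williamson-Hall analysis, and the
# regression of direction-dependent Young's moduli against planar density
# that supplies its total Young's modulus.
#
# The USDM line is  beta cos(theta) = K lambda / L + 4 sigma sin(theta) / E_hkl,
# so plotting beta cos(theta) against 4 sin(theta) / E_hkl gives the uniform
# stress sigma as the slope and K lambda / L as the intercept.

#' Validated XRD peak table
#'
#' @param h,k,l Integer Miller indices per peak.
#' @param two_theta_deg Scattering angles 2-theta (degrees), in (0, 180).
#' @param fwhm_deg Peak full widths at half maximum (degrees), positive.
#' @return A data.frame of class `peak_table` with those five columns.
#' @export
peak_table <- function(h, k, l, two_theta_deg, fwhm_deg) {
  n <- length(h)
  stopifnot(length(k) == n, length(l) == n, length(two_theta_deg) == n,
            length(fwhm_deg) == n, n >= 1L)
  for (i in seq_len(n)) as_miller(c(h[i], k[i], l[i]))  # validates indices
  if (any(!is.finite(two_theta_deg)) || any(two_theta_deg <= 0) ||
      any(two_theta_deg >= 180))
    stop("two_theta_deg must lie in (0, 180)", call. = FALSE)
  if (any(!is.finite(fwhm_deg)) || any(fwhm_deg <= 0))
    stop("fwhm_deg must be positive", call. = FALSE)
  out <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                    two_theta_deg = as.numeric(two_theta_deg),
                    fwhm_deg = as.numeric(fwhm_deg))
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Instrumental correction of peak breadths
#'
#' Subtracts the instrumental broadening from the measured FWHM (both in
#' degrees) and converts the corrected breadth to radians. The correction is
#' a plain subtraction, applied before the degree-to-radian conversion.
#'
#' @param fwhm_deg Measured FWHM values (degrees).
#' @param instrumental_deg Instrumental broadening (degrees); default 0.02.
#' @return Corrected breadths beta in radians.
#' @export
correct_breadth <- function(fwhm_deg, instrumental_deg = 0.02) {
  stopifnot(is.numeric(fwhm_deg), is.numeric(instrumental_deg),
            instrumental_deg >= 0)
  if (any(fwhm_deg <= instrumental_deg))
    stop("FWHM must exceed the instrumental broadening", call. = FALSE)
  (fwhm_deg - instrumental_deg) * pi / 180
}

#' Attach direction-dependent Young's moduli to a peak table
#'
#' @param peaks A [peak_table()].
#' @param S A [hex_compliance()].
#' @param lattice A [hex_lattice()].
#' @return The peak table with an `E_hkl` column (GPa).
#' @export
attach_e_hkl <- function(peaks, S, lattice) {
  peaks$E_hkl <- vapply(seq_len(nrow(peaks)), function(i) {
    youngs_modulus_hkl(S, lattice, c(peaks$h[i], peaks$k[i], peaks$l[i]))
  }, numeric(1))
  peaks
}

#' USDM Williamson-Hall plot coordinates
#'
#' @param peaks A peak table carrying columns `two_theta_deg`, `beta_rad`
#'   (instrument-corrected breadths in radians) and `E_hkl` (GPa).
#' @return A data.frame with `x = 4 sin(theta) / E_hkl` (1/GPa) and
#'   `y = beta cos(theta)` (dimensionless).
#' @export
usdm_points <- function(peaks) {
  for (col in c("two_theta_deg", "beta_rad", "E_hkl")) {
    if (is.null(peaks[[col]]) || any(!is.finite(peaks[[col]])))
      stop("peak table is missing a finite ", col, " column", call. = FALSE)
  }
  theta <- peaks$two_theta_deg / 2 * pi / 180
  data.frame(x = 4 * sin(theta) / peaks$E_hkl,
             y = peaks$beta_rad * cos(theta))
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors of equal length (at least 2 points, `x` not
#'   constant). `x` may also be a two-column matrix or data.frame of
#'   (x, y) pairs.
#' @return An object of class `line_fit` with `slope`, `intercept`,
#'   `r_squared` and `n_points`.
#' @export
fit_line <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(ncol(x) == 2L)
    y <- x[[2]]
    x <- x[[1]]
  }
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::var(x) == 0)
    stop("degenerate fit: all x values are equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = min(max(r2, 0), 1), n_points = length(x)),
            class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("OLS fit: slope %.6g, intercept %.6g, R^2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' USDM Williamson-Hall analysis
#'
#' Corrects the peak breadths for instrumental broadening, forms the USDM
#' plot coordinates and fits the line by ordinary least squares. The slope
#' is the uniform stress sigma (GPa, tensile when positive), the intercept
#' `K lambda / L` yields the crystallite size, and the uniform strain is
#' `epsilon = sigma / E_total`.
#'
#' @param peaks A [peak_table()] with an `E_hkl` column (see
#'   [attach_e_hkl()]).
#' @param e_total Total Young's modulus (GPa) used for the strain; usually
#'   the intercept of the E-versus-planar-density regression
#'   ([fit_e_vs_pd()]).
#' @param K Scherrer shape factor (default 0.9).
#' @param wavelength X-ray wavelength (Angstrom).
#' @param instrumental_deg Instrumental broadening (degrees).
#' @param strain_per_plane If `TRUE`, also return per-plane strains
#'   `sigma / E_hkl`.
#' @return An object of class `usdm_result`: `sigma` (GPa),
#'   `crystallite_size` (nm, `NA` when the intercept is non-positive),
#'   `strain`, `stress_sense` ("tensile"/"compressive"), and the
#'   underlying `fit`.
#' @export
usdm_analyze <- function(peaks, e_total, K = 0.9, wavelength = 1.5406,
                         instrumental_deg = 0.02,
                         strain_per_plane = FALSE) {
  stopifnot(is.numeric(e_total), e_total > 0, K > 0, wavelength > 0)
  if (is.null(peaks$E_hkl))
    stop("peaks need an E_hkl column; see attach_e_hkl()", call. = FALSE)
  peaks$beta_rad <- correct_breadth(peaks$fwhm_deg, instrumental_deg)
  pts <- usdm_points(peaks)
  fit <- fit_line(pts$x, pts$y)
  sigma <- fit$slope
  size_nm <- if (fit$intercept > 0) {
    K * wavelength / fit$intercept / 10   # Angstrom -> nm
  } else {
    warning("non-positive intercept: crystallite size undefined")
    NA_real_
  }
  out <- list(sigma = sigma,
              crystallite_size = size_nm,
              strain = sigma / e_total,
              e_total = e_total,
              stress_sense = if (sigma >= 0) "tensile" else "compressive",
              K = K, wavelength = wavelength,
              instrumental_deg = instrumental_deg,
              fit = fit, points = pts)
  if (strain_per_plane) out$strain_hkl <- sigma / peaks$E_hkl
  structure(out, class = "usdm_result")
}

#' @export
print.usdm_result <- function(x, ...) {
  cat("USDM Williamson-Hall fit\n")
  cat(sprintf("  uniform stress sigma : %.5f GPa (%s)\n",
              x$sigma, x$stress_sense))
  cat(sprintf("  crystallite size L   : %s nm\n",
              if (is.na(x$crystallite_size)) "undefined"
              else sprintf("%.2f", x$crystallite_size)))
  cat(sprintf("  uniform strain eps   : %.5f (E_total = %.2f GPa)\n",
              x$strain, x$e_total))
  cat(sprintf("  fit R^2 = %.4f over %d peaks\n",
              x$fit$r_squared, x$fit$n_points))
  invisible(x)
}

#' Total Young's modulus from the E_hkl versus planar-density regression
#'
#' Ordinary least squares of the per-plane Young's moduli on the per-plane
#' planar densities. The intercept extrapolates to a plane of zero planar
#' density (a plane free of atoms) and is reported as the total Young's
#' modulus of the crystal.
#'
#' @param pd Planar densities (dimensionless fractions), or a list of
#'   [planar_density()] records.
#' @param E Per-plane Young's moduli (GPa).
#' @return An object of class `e_vs_pd` with `slope` (GPa per density
#'   unit), `intercept_E` (GPa) and the underlying `fit`.
#' @export
fit_e_vs_pd <- function(pd, E) {
  if (is.list(pd) && !is.data.frame(pd) && !is.numeric(pd))
    pd <- vapply(pd, function(r) r$density, numeric(1))
  stopifnot(is.numeric(pd), is.numeric(E), length(pd) == length(E))
  if (length(pd) < 2L || stats::var(pd) == 0)
    stop("need at least two records with distinct planar densities",
         call. = FALSE)
  fit <- fit_line(pd, E)
  structure(list(slope = fit$slope, intercept_E = fit$intercept, fit = fit),
            class = "e_vs_pd")
}

#' @export
print.e_vs_pd <- function(x, ...) {
  cat(sprintf(
    "E vs planar density: intercept (total E) %.2f GPa, slope %.2f GPa (R^2 %.3f)\n",
    x$intercept_E, x$slope, x$fit$r_squared))
  invisible(x)
}

#' End-to-end planar-density-weighted USDM report
#'
#' Runs the full pipeline on a hexagonal structure and an indexed peak
#' table: planar density of every diffracted plane on the unit cell and on
#' an n x n x n supercell, direction-dependent Young's moduli from the
#' stiffness constants, the E-versus-planar-density regression giving the
#' total Young's modulus for each cell, and the USDM Williamson-Hall fit
#' giving stress, crystallite size and strain for each cell.
#'
#' @param structure A hexagonal [crystal_structure()] (unit cell).
#' @param peaks A [peak_table()].
#' @param C A [hex_stiffness()] (GPa).
#' @param supercell Supercell replication factor (default 2).
#' @param K,wavelength,instrumental_deg USDM parameters, see
#'   [usdm_analyze()].
#' @param pd_tol Planar membership tolerance (Angstrom), see
#'   [planar_density()].
#' @return An object of class `usdm_report`: per-cell planar densities,
#'   `e_vs_pd` fits, and `usdm` results, plus the shared `E_hkl` values.
#' @export
usdm_report <- function(structure, peaks, C, supercell = 2, K = 0.9,
                        wavelength = 1.5406, instrumental_deg = 0.02,
                        pd_tol = 1e-3) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(C, "hex_stiffness"))
  if (is.null(structure$lattice))
    stop("the USDM report requires a hexagonal structure", call. = FALSE)
  S <- stiffness_to_compliance(C)
  peaks <- attach_e_hkl(peaks, S, structure$lattice)
  cells <- list(unit = structure,
                super = build_supercell(structure, supercell))
  out <- lapply(cells, function(cell) {
    pd <- vapply(seq_len(nrow(peaks)), function(i) {
      planar_density(cell, c(peaks$h[i], peaks$k[i], peaks$l[i]),
                     tol = pd_tol)$density
    }, numeric(1))
    epd <- fit_e_vs_pd(pd, peaks$E_hkl)
    usdm <- usdm_analyze(peaks, e_total = epd$intercept_E, K = K,
                         wavelength = wavelength,
                         instrumental_deg = instrumental_deg)
    list(planar_density = pd, e_vs_pd = epd, usdm = usdm)
  })
  structure(list(cells = out, peaks = peaks, compliance = S),
            class = "usdm_report")
}

#' @export
print.usdm_report <- function(x, ...) {
  for (nm in names(x$cells)) {
    cell <- x$cells[[nm]]
    cat(sprintf("== %s cell ==\n", nm))
    print(cell$e_vs_pd)
    print(cell$usdm)
  }
  invisible(x)
}
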