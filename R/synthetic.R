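# Seeded synthetic-data generators. These produce every input the analysis
# pipeline consumes -- toy crystal structures with known planar densities,
# peak tables built by inverting the USDM line from known stress/size ground
# truth, and ultrasonic replicate sets from known elastic constants -- so the
# whole toolkit can be exercised end to end without instrument data.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Deterministic toy crystal structures
#'
#' Three built-in fixtures with documented radii:
#' * `simple_cubic`: one atom per cell corner with touching spheres
#'   (radius `a/2`), the classic textbook case whose (100) planar density
#'   is `pi/4`.
#' * `fcc_like`: four atoms per cubic cell with touching spheres
#'   (radius `a sqrt(2)/4`); its (111) close-packed layer has planar
#'   density `pi / (2 sqrt(3))`.
#' * `ha_like`: an 18-site hexagonal apatite-like cell (a = 9.400 A,
#'   c = 6.930 A): 4 + 6 calcium sites on the two crystallographic calcium
#'   orbits, 6 phosphate-group sites and 2 hydroxyl sites on the c-axis
#'   channel, arranged on a P6_3/m-like pattern. Radii are Shannon-style
#'   ionic radii (Ca 1.00 A, P 0.38 A) with OH treated as a single 1.37 A
#'   sphere.
#'
#' @param kind One of `"simple_cubic"`, `"fcc_like"`, `"ha_like"`.
#' @param a Cubic cell edge for the two cubic fixtures (Angstrom).
#' @return A [crystal_structure()].
#' @export
make_toy_structure <- function(kind = c("simple_cubic", "fcc_like",
                                        "ha_like"), a = 4.0) {
  kind <- match.arg(kind)
  if (kind == "simple_cubic") {
    sites <- data.frame(species = "X", u = 0, v = 0, w = 0, radius = a / 2)
    return(crystal_structure(sites, basis = diag(3) * a))
  }
  if (kind == "fcc_like") {
    sites <- data.frame(
      species = "X",
      u = c(0, 0.5, 0.5, 0),
      v = c(0, 0.5, 0, 0.5),
      w = c(0, 0, 0.5, 0.5),
      radius = a * sqrt(2) / 4)
    return(crystal_structure(sites, basis = diag(3) * a))
  }
  # ha_like: hexagonal apatite-like 18-ion cell.
  lat <- hex_lattice(9.400, 6.930)
  orbit6h <- function(x, y, z) {
    rbind(c(x, y, z), c(-y, x - y, z), c(y - x, -x, z),
          c(-x, -y, 1 - z), c(y, y - x, 1 - z), c(x - y, x, 1 - z))
  }
  ca1 <- rbind(c(1 / 3, 2 / 3, 0), c(2 / 3, 1 / 3, 1 / 2),
               c(2 / 3, 1 / 3, 0), c(1 / 3, 2 / 3, 1 / 2))
  ca2 <- orbit6h(0.246, 0.993, 0.25)
  p6h <- orbit6h(0.400, 0.369, 0.25)
  oh <- rbind(c(0, 0, 0.25), c(0, 0, 0.75))
  frac <- rbind(ca1, ca2, p6h, oh)
  sites <- data.frame(
    species = c(rep("Ca", 10), rep("P", 6), rep("OH", 2)),
    u = frac[, 1], v = frac[, 2], w = frac[, 3],
    radius = c(rep(1.00, 10), rep(0.38, 6), rep(1.37, 2)))
  crystal_structure(sites, lattice = lat)
}

#' Ground truth for synthetic peak tables
#'
#' @param sigma Uniform stress (GPa), positive.
#' @param L Crystallite size (nm), positive.
#' @param e_map A data.frame with columns `h`, `k`, `l` and `E` (GPa): the
#'   planes to diffract and their direction-dependent Young's moduli.
#' @param noise_sd_fwhm Gaussian noise SD added to the FWHM (degrees).
#' @param seed Integer RNG seed fixing the noise stream.
#' @return A list of class `usdm_ground_truth`.
#' @export
usdm_ground_truth <- function(sigma, L, e_map, noise_sd_fwhm = 0.005,
                              seed = 1L) {
  stopifnot(sigma > 0, L > 0, is.data.frame(e_map),
            all(c("h", "k", "l", "E") %in% names(e_map)),
            all(e_map$E > 0), noise_sd_fwhm >= 0)
  structure(list(sigma = sigma, L = L, e_map = e_map,
                 noise_sd_fwhm = noise_sd_fwhm, seed = as.integer(seed)),
            class = "usdm_ground_truth")
}

#' Synthesize an XRD peak table from USDM ground truth
#'
#' Inverts the USDM line: for each plane the corrected breadth is
#' `beta = (K lambda / L + 4 sigma sin(theta) / E_hkl) / cos(theta)`, which
#' is converted to degrees, incremented by the instrumental broadening and
#' jittered with Gaussian noise. With zero noise the analysis pipeline
#' recovers the ground truth exactly.
#'
#' @param gt A [usdm_ground_truth()].
#' @param lattice A [hex_lattice()] used to place the Bragg angles.
#' @param wavelength X-ray wavelength (Angstrom).
#' @param K Scherrer factor.
#' @param instrumental_deg Instrumental broadening added to each FWHM
#'   (degrees).
#' @return A [peak_table()] with the `E_hkl` column attached. Planes that
#'   cannot diffract at this wavelength (`lambda > 2d`) are dropped with a
#'   warning.
#' @export
make_peak_table <- function(gt, lattice, wavelength = 1.5406, K = 0.9,
                            instrumental_deg = 0.02) {
  stopifnot(inherits(gt, "usdm_ground_truth"),
            inherits(lattice, "hex_lattice"))
  em <- gt$e_map
  d <- vapply(seq_len(nrow(em)), function(i) {
    d_spacing(lattice, c(em$h[i], em$k[i], em$l[i]))
  }, numeric(1))
  ok <- wavelength <= 2 * d
  if (!all(ok)) {
    warning(sprintf("%d plane(s) dropped: wavelength exceeds 2d",
                    sum(!ok)))
    em <- em[ok, , drop = FALSE]
    d <- d[ok]
  }
  if (nrow(em) == 0L) stop("no diffracting planes remain", call. = FALSE)
  theta_deg <- bragg_angle(d, wavelength)
  theta <- theta_deg * pi / 180
  beta <- (K * (wavelength / 10) / gt$L +
             4 * gt$sigma * sin(theta) / em$E) / cos(theta)
  fwhm <- beta * 180 / pi + instrumental_deg
  if (gt$noise_sd_fwhm > 0) {
    fwhm <- fwhm + with_seed(gt$seed,
                             stats::rnorm(length(fwhm),
                                          sd = gt$noise_sd_fwhm))
    fwhm <- pmax(fwhm, instrumental_deg + 1e-4)
  }
  out <- peak_table(em$h, em$k, em$l, 2 * theta_deg, fwhm)
  out$E_hkl <- em$E
  out
}

#' Synthesize pulse-echo replicates from known elastic constants
#'
#' Echo-time differences are computed from the Christoffel velocities of
#' the given stiffness tensor (longitudinal `V11`, transverse `V23`) and a
#' sample length, then jittered with Gaussian noise per replicate.
#'
#' @param C A [hex_stiffness()] (GPa).
#' @param rho Density (kg/m^3).
#' @param L_mm Sample length (mm).
#' @param jitter_sd_us Gaussian jitter SD on each echo time (microseconds).
#' @param n Number of replicates (at least 2).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `replicate`, `ts_us`, `tl_us`, `L_mm`.
#' @export
make_ultrasonic_replicates <- function(C, rho, L_mm = 11.6,
                                       jitter_sd_us = 0.01, n = 5,
                                       seed = 1L) {
  stopifnot(inherits(C, "hex_stiffness"), rho > 0, L_mm > 0, n >= 2,
            jitter_sd_us >= 0)
  v <- christoffel_velocities(C, rho)
  tl <- 2 * L_mm / v$V11 * 1000        # longitudinal echoes: faster wave
  ts <- 2 * L_mm / v$V23 * 1000        # transverse echoes: slower wave
  jit <- if (jitter_sd_us > 0) {
    with_seed(seed, matrix(stats::rnorm(2 * n, sd = jitter_sd_us), ncol = 2))
  } else {
    matrix(0, nrow = n, ncol = 2)
  }
  data.frame(replicate = seq_len(n),
             ts_us = ts + jit[, 1],
             tl_us = tl + jit[, 2],
             L_mm = L_mm)
}
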