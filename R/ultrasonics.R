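# Ultrasonic pulse-echo elasticity: sound velocities from echo-time
# differences, hexagonal stiffness constants from directional velocities
# (Christoffel relations), and the pulse-echo Young's modulus with replicate
# uncertainty.
#
# Unit conventions: sample length L in mm, echo-time differences in
# microseconds, density in kg/m^3, velocities in m/s, moduli in GPa.

#' A single pulse-echo replicate
#'
#' @param ts Transverse-wave echo-time difference (microseconds). Transverse
#'   waves are slower, so `ts > tl` is required.
#' @param tl Longitudinal-wave echo-time difference (microseconds).
#' @param L Sample length (mm).
#' @param replicate Integer replicate label.
#' @return An object of class `echo_measurement`.
#' @export
echo_measurement <- function(ts, tl, L, replicate = 1L) {
  stopifnot(is.numeric(ts), is.numeric(tl), is.numeric(L))
  if (!(ts > tl && tl > 0))
    stop("echo times must satisfy ts > tl > 0", call. = FALSE)
  if (L <= 0) stop("sample length must be positive", call. = FALSE)
  structure(list(ts = ts, tl = tl, L = L,
                 replicate = as.integer(replicate)),
            class = "echo_measurement")
}

#' Sound velocity from an echo-time difference
#'
#' `c = 2 L / t`: the wave travels the sample length twice between
#' consecutive back-wall echoes.
#'
#' @param L Sample length (mm).
#' @param t Echo-time difference (microseconds).
#' @return Velocity in m/s.
#' @examples
#' velocity_from_echoes(11.59, 6.26)  # transverse velocity, about 3703 m/s
#' @export
velocity_from_echoes <- function(L, t) {
  stopifnot(is.numeric(L), is.numeric(t))
  if (any(L <= 0) || any(t <= 0))
    stop("length and time must be positive", call. = FALSE)
  2 * L / t * 1000
}

#' Directional velocity set for a hexagonal medium
#'
#' Velocities `Vij` are for propagation along `Xi` with polarization along
#' `Xj` (i = j longitudinal, i != j transverse); `Vq12` and `Vq13` are the
#' quasi-longitudinal speeds at 45 degrees in the 1-2 and 1-3 planes. In a
#' hexagonal medium `X3` is the unique axis, so `V11` doubles for `V22` and
#' `V13` for `V31` etc.
#'
#' @param V11,V33,V23,V12,V13 Pure-mode velocities (m/s).
#' @param Vq12,Vq13 45-degree quasi-longitudinal velocities (m/s).
#' @param rho Density (kg/m^3).
#' @return An object of class `velocity_set`.
#' @export
velocity_set <- function(V11, V33, V23, V12, V13, Vq12, Vq13, rho) {
  v <- c(V11 = V11, V33 = V33, V23 = V23, V12 = V12, V13 = V13,
         Vq12 = Vq12, Vq13 = Vq13, rho = rho)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("velocities and density must be positive", call. = FALSE)
  structure(as.list(v), class = "velocity_set")
}

#' Hexagonal stiffness constants from directional velocities
#'
#' Pure modes give the diagonal constants directly: `C11 = rho V11^2`,
#' `C33 = rho V33^2`, `C44 = rho V23^2`, `C66 = rho V12^2`,
#' `C55 = rho V13^2`. The off-diagonal constants come from the 45-degree
#' quasi-wave speeds through the Christoffel secular relation, e.g.
#' `C13 = sqrt((C11 + C55 - 2 rho Vq13^2)(C33 + C55 - 2 rho Vq13^2)) - C55`
#' and analogously for `C12` with `C66` and the in-plane quasi wave. The
#' quasi-wave speed determines only `(C13 + C55)^2`; the physical branch
#' `C13 + C55 > 0` is returned.
#'
#' @param v A [velocity_set()].
#' @return A [hex_stiffness()] in GPa.
#' @export
stiffness_from_velocities <- function(v) {
  stopifnot(inherits(v, "velocity_set"))
  rho <- v$rho
  gpa <- function(x) rho * x^2 / 1e9
  C11 <- gpa(v$V11)
  C33 <- gpa(v$V33)
  C44 <- gpa(v$V23)
  C66 <- gpa(v$V12)
  C55 <- gpa(v$V13)
  rad12 <- (C11 + C66 - 2 * gpa(v$Vq12)) * (C11 + C66 - 2 * gpa(v$Vq12))
  rad13 <- (C11 + C55 - 2 * gpa(v$Vq13)) * (C33 + C55 - 2 * gpa(v$Vq13))
  if (rad12 < 0 || rad13 < 0)
    stop("inconsistent measurements: negative radicand in C12/C13",
         call. = FALSE)
  hex_stiffness(C11 = C11,
                C12 = sqrt(rad12) - C66,
                C13 = sqrt(rad13) - C55,
                C33 = C33,
                C44 = C44)
}

#' Directional velocities of a hexagonal medium (Christoffel forward map)
#'
#' Synthesizes the pure-mode and 45-degree quasi-longitudinal velocities
#' from a hexagonal stiffness tensor, the exact inverse of
#' [stiffness_from_velocities()]. In hexagonal symmetry `C55 = C44` and
#' `C66 = (C11 - C12)/2`.
#'
#' @param C A [hex_stiffness()] (GPa).
#' @param rho Density (kg/m^3).
#' @return A [velocity_set()].
#' @export
christoffel_velocities <- function(C, rho) {
  stopifnot(inherits(C, "hex_stiffness"), rho > 0)
  pa <- function(g) sqrt(g * 1e9 / rho)     # GPa -> m/s
  C66 <- (C$C11 - C$C12) / 2
  g11 <- (C$C11 + C$C44) / 2                # 45-degree Christoffel entries
  g33 <- (C$C33 + C$C44) / 2
  g13 <- (C$C13 + C$C44) / 2
  ql13 <- 0.5 * (g11 + g33 + sqrt((g11 - g33)^2 + 4 * g13^2))
  ql12 <- 0.5 * ((C$C11 + C66) + (C$C12 + C66))
  velocity_set(V11 = pa(C$C11), V33 = pa(C$C33), V23 = pa(C$C44),
               V12 = pa(C66), V13 = pa(C$C44),
               Vq12 = pa(ql12), Vq13 = pa(ql13), rho = rho)
}

#' Young's modulus from a pulse-echo measurement
#'
#' Evaluates `E = 4 rho (L/ts)^2 (3 ts^2 - 4 tl^2) / (ts^2 - tl^2)`, which
#' is the isotropic relation
#' `E = rho ct^2 (3 cl^2 - 4 ct^2) / (cl^2 - ct^2)` rewritten in echo times
#' through `c = 2L/t`. (The velocity form requires the `ct^2` prefactor to
#' be dimensionally consistent and to reduce to the time form.)
#'
#' @param m An [echo_measurement()], or a list/data.frame row with fields
#'   `ts`, `tl`, `L`.
#' @param rho Sample density (kg/m^3). Always required: the bulk density of
#'   a sintered pellet differs from the single-crystal density and must be
#'   measured on the sample itself.
#' @return Young's modulus in GPa.
#' @export
youngs_modulus_pulse_echo <- function(m, rho) {
  stopifnot(rho > 0)
  ts <- m$ts
  tl <- m$tl
  L <- m$L
  if (!(ts > tl && tl > 0) || L <= 0)
    stop("echo times must satisfy ts > tl > 0 with positive length",
         call. = FALSE)
  num <- 3 * ts^2 - 4 * tl^2
  if (num <= 0)
    stop("unphysical echo times: 3 ts^2 must exceed 4 tl^2", call. = FALSE)
  # (L/ts) in mm/us = 1000 m/s
  4 * rho * (1000 * L / ts)^2 * num / (ts^2 - tl^2) / 1e9
}

#' Young's modulus from longitudinal and transverse velocities
#'
#' Isotropic relation `E = rho ct^2 (3 cl^2 - 4 ct^2) / (cl^2 - ct^2)`.
#'
#' @param cl,ct Longitudinal and transverse velocities (m/s), `cl > ct`.
#' @param rho Density (kg/m^3).
#' @return Young's modulus in GPa.
#' @export
youngs_modulus_from_velocities <- function(cl, ct, rho) {
  stopifnot(rho > 0)
  if (any(cl <= ct) || any(ct <= 0))
    stop("velocities must satisfy cl > ct > 0", call. = FALSE)
  rho * ct^2 * (3 * cl^2 - 4 * ct^2) / (cl^2 - ct^2) / 1e9
}

#' Replicate summary of pulse-echo Young's moduli
#'
#' Computes the pulse-echo Young's modulus for each replicate and returns
#' the mean and sample standard deviation.
#'
#' @param measurements A list of [echo_measurement()] objects, or a
#'   data.frame with columns `replicate`, `ts_us`, `tl_us`, `L_mm`.
#' @param rho Sample density (kg/m^3).
#' @return A list with `E` (per-replicate values, GPa), `mean`, `sd` and
#'   `n`, of class `echo_summary`.
#' @export
replicate_summary <- function(measurements, rho) {
  if (is.data.frame(measurements)) {
    need <- c("ts_us", "tl_us", "L_mm")
    if (!all(need %in% names(measurements)))
      stop("measurement table needs columns ts_us, tl_us, L_mm",
           call. = FALSE)
    measurements <- lapply(seq_len(nrow(measurements)), function(i) {
      echo_measurement(measurements$ts_us[i], measurements$tl_us[i],
                       measurements$L_mm[i],
                       replicate = if ("replicate" %in% names(measurements))
                         measurements$replicate[i] else i)
    })
  }
  if (length(measurements) < 2L)
    stop("at least two replicates are required", call. = FALSE)
  E <- vapply(measurements, youngs_modulus_pulse_echo, numeric(1),
              rho = rho)
  structure(list(E = E, mean = mean(E), sd = stats::sd(E), n = length(E)),
            class = "echo_summary")
}

#' @export
print.echo_summary <- function(x, ...) {
  cat(sprintf("Pulse-echo Young's modulus: %.2f +/- %.2f GPa (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}
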