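# Shared fixtures: tabulated elastic constants, random stable tensors,
# Monte-Carlo area oracles, and a representative apatite plane list.

# Published stiffness columns (GPa): C11, C12, C13, C33, C44.
stiffness_columns <- list(
  ching = c(140.00, 42.40, 58.30, 174.80, 47.50),
  leeuw = c(134.40, 48.90, 68.50, 184.70, 51.40),
  katz  = c(137.00, 42.50, 54.90, 172.00, 39.60),
  theory_this = c(139.58, 48.03, 61.22, 181.08, 50.93),
  experiment_this = c(135.78, 49.21, 56.62, 179.22, 41.73))

# Corresponding tabulated compliances (1/GPa): S11, S12, S13, S33, S44.
compliance_columns <- list(
  ching = c(0.008607002, -0.001638900, -0.002324030, 0.007271063, 0.021052632),
  leeuw = c(0.009621806, -0.002074100, -0.002799231, 0.007490496, 0.019455253),
  katz  = c(0.008752330, -0.001829681, -0.002209613, 0.007224509, 0.025252525),
  theory_this = c(0.008881114, -0.002041879, -0.002312227, 0.007085868,
                  0.019634793),
  experiment_this = c(0.009126549, -0.002424797, -0.002117248, 0.006917516,
                      0.023963575))

stiffness_from_column <- function(v) {
  hex_stiffness(C11 = v[1], C12 = v[2], C13 = v[3], C33 = v[4], C44 = v[5])
}

# Five-replicate pulse-echo bench table: ts, tl (us), L (mm).
echo_table <- data.frame(
  replicate = 1:5,
  ts_us = c(6.26, 6.27, 6.26, 6.25, 6.24),
  tl_us = c(2.52, 2.50, 2.51, 2.53, 2.54),
  L_mm = c(11.59, 11.61, 11.59, 11.57, 11.55))

# Random mechanically stable hexagonal stiffness tensor.
random_stable_stiffness <- function() {
  repeat {
    C11 <- runif(1, 50, 300)
    C12 <- runif(1, -0.5, 0.9) * C11
    C33 <- runif(1, 50, 300)
    C13 <- runif(1, -0.5, 0.5) * sqrt(C33 * (C11 + C12) / 2)
    C44 <- runif(1, 10, 120)
    ok <- tryCatch({
      hex_stiffness(C11, C12, C13, C33, C44)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(hex_stiffness(C11, C12, C13, C33, C44))
  }
}

# Representative indexed apatite reflections (low to high angle).
apatite_planes <- rbind(
  c(0, 0, 2), c(1, 0, 2), c(2, 1, 0), c(2, 1, 1), c(1, 1, 2), c(3, 0, 0),
  c(2, 0, 2), c(3, 0, 1), c(2, 1, 2), c(3, 1, 0), c(3, 1, 1), c(1, 1, 3),
  c(2, 0, 3), c(2, 2, 2), c(3, 1, 2), c(3, 2, 0), c(2, 1, 3), c(3, 2, 1),
  c(4, 1, 0), c(4, 0, 2), c(0, 0, 4), c(1, 0, 4), c(3, 2, 2), c(4, 1, 2),
  c(3, 0, 4), c(5, 0, 1), c(4, 2, 2), c(5, 1, 0), c(4, 3, 0), c(5, 1, 1),
  c(4, 2, 3), c(5, 2, 0))

# E_hkl map for the apatite plane list under a given compliance.
apatite_e_map <- function(S, lattice = hex_lattice(9.400, 6.930)) {
  E <- apply(apatite_planes, 1, function(p) youngs_modulus_hkl(S, lattice, p))
  data.frame(h = apatite_planes[, 1], k = apatite_planes[, 2],
             l = apatite_planes[, 3], E = E)
}

# Monte-Carlo oracle: area of disc(center, r) clipped to convex CCW polygon.
mc_circle_polygon_area <- function(center, radius, P, n = 1e5) {
  lo <- c(center[1] - radius, center[2] - radius)
  q <- cbind(runif(n, lo[1], lo[1] + 2 * radius),
             runif(n, lo[2], lo[2] + 2 * radius))
  indisc <- (q[, 1] - center[1])^2 + (q[, 2] - center[2])^2 <= radius^2
  inpoly <- rep(TRUE, n)
  m <- nrow(P)
  for (i in seq_len(m)) {
    a <- P[i, ]
    b <- P[i %% m + 1, ]
    inpoly <- inpoly &
      ((b[1] - a[1]) * (q[, 2] - a[2]) -
         (b[2] - a[2]) * (q[, 1] - a[1]) >= 0)
  }
  mean(indisc & inpoly) * (2 * radius)^2
}

# Monte-Carlo oracle for the area of a plane/box section: sample the
# section plane's bounding rectangle and count points inside the box.
mc_section_area <- function(structure, section, n = 1e5) {
  r2 <- section$verts2
  lo <- apply(r2, 2, min) - 0.1
  hi <- apply(r2, 2, max) + 0.1
  q <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]))
  X <- sweep(q[, 1, drop = FALSE] %*% t(section$u) +
               q[, 2, drop = FALSE] %*% t(section$v), 2,
             -section$origin)
  F <- t(solve(structure$basis, t(X)))
  inside <- rowSums(F >= -1e-9 & F <= 1 + 1e-9) == 3L
  mean(inside) * prod(hi - lo)
}

# Random convex polygon (CCW) with roughly unit scale * size.
random_convex_polygon <- function(npts = 12, size = 3) {
  pts <- matrix(runif(2 * npts, -size, size), ncol = 2)
  hull <- grDevices::chull(pts)            # clockwise indices
  pts[rev(hull), , drop = FALSE]           # counter-clockwise
}
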