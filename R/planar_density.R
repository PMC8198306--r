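# Planar density of Miller planes: the fraction of the plane section inside
# the (super)cell box covered by cross-sections of atoms whose centers lie
# on that plane. All geometry is exact (plane/box clipping and circle/polygon
# areas via Green's theorem); Monte-Carlo appears only in the test oracles.

# Reciprocal basis: columns b_i with a_i . b_j = delta_ij (no 2*pi factor).
reciprocal_basis <- function(B) t(solve(B))

# Unit normal, d-spacing and a point on the zero-offset plane for (hkl) in
# the basis of `structure`.
plane_geometry <- function(structure, plane) {
  p <- as_miller(plane)
  g <- as.numeric(reciprocal_basis(structure$basis) %*% c(p$h, p$k, p$l))
  d <- 1 / sqrt(sum(g^2))
  list(normal = g * d, d = d)
}

#' Section of a Miller plane with the cell box
#'
#' Intersects the infinite plane `n . x = offset` (with `n` the unit normal
#' of the Miller plane) with the closed cell parallelepiped and returns the
#' resulting convex polygon, oriented counter-clockwise about the normal.
#'
#' @param structure A [crystal_structure()].
#' @param plane A [miller_plane()] or length-3 integer vector, interpreted
#'   in the basis of `structure`.
#' @param offset Signed distance (Angstrom) of the plane from the origin
#'   along the plane normal. Planes of the (hkl) family that pass through
#'   lattice points sit at integer multiples of the d-spacing.
#' @return An object of class `plane_section` with fields `plane`, `offset`,
#'   `normal`, `d`, in-plane axes `u`, `v`, `origin`, the 3D `vertices`,
#'   their 2D projections `verts2` and the polygon `area` (Angstrom^2).
#' @export
plane_section <- function(structure, plane, offset) {
  stopifnot(inherits(structure, "crystal_structure"),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  plane <- as_miller(plane)
  geom <- plane_geometry(structure, plane)
  n <- geom$normal
  B <- structure$basis
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  X <- corners %*% t(B)                       # 8 x 3 Cartesian corners
  s <- as.numeric(X %*% n) - offset
  eps <- 1e-9 * max(1, max(abs(X)))

  pts <- X[abs(s) <= eps, , drop = FALSE]
  for (i in 1:7) for (j in (i + 1):8) {
    if (sum(abs(corners[i, ] - corners[j, ])) != 1L) next   # not a box edge
    if ((s[i] < -eps && s[j] > eps) || (s[i] > eps && s[j] < -eps)) {
      t <- s[i] / (s[i] - s[j])
      pts <- rbind(pts, X[i, ] + t * (X[j, ] - X[i, ]))
    }
  }
  if (nrow(pts) > 0) {
    keep <- !duplicated(round(pts / max(1, max(abs(X))), 7))
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3L)
    stop("plane does not intersect the cell box", call. = FALSE)

  # in-plane orthonormal axes
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  origin <- offset * n
  rel <- sweep(pts, 2, origin)
  p2 <- cbind(rel %*% u, rel %*% v)
  ctr <- colMeans(p2)
  ord <- order(atan2(p2[, 2] - ctr[2], p2[, 1] - ctr[1]))
  pts <- pts[ord, , drop = FALSE]
  p2 <- p2[ord, , drop = FALSE]
  area <- shoelace(p2)
  if (area < 0) {                              # enforce CCW about the normal
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
    area <- -area
  }
  if (area <= eps^2)
    stop("plane touches the cell box only degenerately", call. = FALSE)
  structure(list(plane = plane, offset = offset, normal = n, d = geom$d,
                 u = u, v = v, origin = origin,
                 vertices = pts, verts2 = p2, area = area),
            class = "plane_section")
}

#' @export
print.plane_section <- function(x, ...) {
  cat(sprintf("Section of %s at offset %.4f A: %d vertices, area %.4f A^2\n",
              format(x$plane), x$offset, nrow(x$verts2), x$area))
  invisible(x)
}

shoelace <- function(p2) {
  m <- nrow(p2)
  i2 <- c(2:m, 1)
  sum(p2[, 1] * p2[i2, 2] - p2[i2, 1] * p2[, 2]) / 2
}

#' Atoms whose centers lie on a plane section
#'
#' Enumerates periodic images of the structure's sites in the 3 x 3 x 3
#' neighborhood of the cell, keeps those whose center is within `tol` of the
#' section plane, and drops images whose cross-section disc cannot overlap
#' the section polygon (in-plane distance to the polygon >= radius).
#'
#' @param structure A [crystal_structure()].
#' @param section A [plane_section()].
#' @param tol Center-to-plane distance tolerance (Angstrom), non-negative.
#' @return A data.frame with columns `species`, `radius`, the in-plane
#'   coordinates `px`, `py`, and the signed center-to-plane distance `dist`.
#' @export
atoms_on_plane <- function(structure, section, tol = 1e-3) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(section, "plane_section"), tol >= 0)
  img <- periodic_images(structure)
  dist <- as.numeric(img$X %*% section$normal) - section$offset
  on <- abs(dist) <= tol + 1e-12
  if (!any(on)) {
    return(data.frame(species = character(), radius = numeric(),
                      px = numeric(), py = numeric(), dist = numeric()))
  }
  X <- img$X[on, , drop = FALSE]
  rel <- sweep(X, 2, section$origin)
  px <- as.numeric(rel %*% section$u)
  py <- as.numeric(rel %*% section$v)
  radius <- img$radius[on]
  keep <- vapply(seq_along(px), function(i) {
    point_polygon_distance(c(px[i], py[i]), section$verts2) <
      radius[i] - 1e-9
  }, logical(1))
  data.frame(species = img$species[on][keep], radius = radius[keep],
             px = px[keep], py = py[keep], dist = dist[on][keep])
}

# All site images with cell shifts in {-1,0,1}^3, as Cartesian coordinates.
periodic_images <- function(structure) {
  sites <- structure$sites
  F0 <- as.matrix(sites[, c("u", "v", "w")])
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ns <- nrow(shifts)
  F <- F0[rep(seq_len(nrow(F0)), times = ns), , drop = FALSE] +
    shifts[rep(seq_len(ns), each = nrow(F0)), , drop = FALSE]
  list(X = F %*% t(structure$basis),
       species = rep(sites$species, times = ns),
       radius = rep(sites$radius, times = ns))
}

# Distance from a 2D point to a convex CCW polygon (0 if inside).
point_polygon_distance <- function(q, P) {
  m <- nrow(P)
  inside <- TRUE
  dmin <- Inf
  for (i in seq_len(m)) {
    a <- P[i, ]
    b <- P[i %% m + 1, ]
    e <- b - a
    w <- q - a
    if (e[1] * w[2] - e[2] * w[1] < 0) inside <- FALSE
    t <- sum(w * e) / sum(e * e)
    t <- min(max(t, 0), 1)
    dmin <- min(dmin, sqrt(sum((w - t * e)^2)))
  }
  if (inside) 0 else dmin
}

#' Exact area of a disc clipped to a convex polygon
#'
#' Green's-theorem decomposition over polygon edges: each edge contributes
#' either a circular sector or a sector-triangle-sector split at its chord
#' intersections with the circle. Exact up to floating point; the test suite
#' checks it against a Monte-Carlo oracle.
#'
#' @param center Disc center: length-2 coordinates in the polygon's plane.
#' @param radius Disc radius, positive.
#' @param polygon A [plane_section()] or an m x 2 matrix of CCW vertices.
#' @return Area of the intersection (same squared units as the inputs).
#' @export
circle_polygon_area <- function(center, radius, polygon) {
  stopifnot(is.numeric(center), length(center) == 2L, radius > 0)
  P <- polygon_coords(polygon)
  V <- sweep(P, 2, center)
  m <- nrow(V)
  tot <- 0
  for (i in seq_len(m))
    tot <- tot + edge_disc_area(V[i, ], V[i %% m + 1, ], radius)
  max(tot, 0)
}

polygon_coords <- function(polygon) {
  if (inherits(polygon, "plane_section")) polygon <- polygon$verts2
  if (!is.matrix(polygon) || ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("degenerate polygon", call. = FALSE)
  if (abs(shoelace(polygon)) <= 0)
    stop("degenerate polygon", call. = FALSE)
  polygon
}

cross2 <- function(p, q) p[1] * q[2] - p[2] * q[1]

# Signed area of triangle(origin, A, B) clipped to the disc |x| <= r.
edge_disc_area <- function(A, B, r) {
  sector <- function(P, Q) 0.5 * r^2 * atan2(cross2(P, Q), sum(P * Q))
  d <- B - A
  aa <- sum(d * d)
  if (aa == 0) return(0)
  bb <- 2 * sum(A * d)
  cc <- sum(A * A) - r^2
  disc <- bb^2 - 4 * aa * cc
  if (disc <= 0) return(sector(A, B))
  sq <- sqrt(disc)
  t1 <- (-bb - sq) / (2 * aa)
  t2 <- (-bb + sq) / (2 * aa)
  if (t2 <= 0 || t1 >= 1) return(sector(A, B))
  t1 <- max(t1, 0)
  t2 <- min(t2, 1)
  P1 <- A + t1 * d
  P2 <- A + t2 * d
  sector(A, P1) + 0.5 * cross2(P1, P2) + sector(P2, B)
}

# Area of the union of discs clipped to a convex CCW polygon, by arc
# decomposition of the union boundary (Green's theorem). Used when
# overlapping atomic cross-sections must not be double counted.
discs_union_polygon_area <- function(centers, radii, polygon) {
  P <- polygon_coords(polygon)
  nd <- nrow(centers)
  if (nd == 0L) return(0)
  scale <- max(abs(P), max(radii))
  eps <- 1e-9 * scale
  m <- nrow(P)
  inside_poly <- function(q) {
    for (i in seq_len(m)) {
      a <- P[i, ]
      b <- P[i %% m + 1, ]
      if ((b[1] - a[1]) * (q[2] - a[2]) -
          (b[2] - a[2]) * (q[1] - a[1]) < -eps) return(FALSE)
    }
    TRUE
  }
  in_other_disc <- function(q, skip) {
    for (j in seq_len(nd)) {
      if (j == skip) next
      if (sum((q - centers[j, ])^2) < (radii[j] - eps)^2) return(TRUE)
    }
    FALSE
  }
  total <- 0

  # Arcs of each circle on the union boundary and inside the polygon.
  for (i in seq_len(nd)) {
    ci <- centers[i, ]
    ri <- radii[i]
    br <- numeric()
    for (j in seq_len(nd)) {                 # circle-circle breakpoints
      if (j == i) next
      dv <- centers[j, ] - ci
      dd <- sqrt(sum(dv^2))
      if (dd >= ri + radii[j] || dd <= abs(ri - radii[j]) || dd == 0) next
      alpha <- atan2(dv[2], dv[1])
      co <- (dd^2 + ri^2 - radii[j]^2) / (2 * dd * ri)
      beta <- acos(min(max(co, -1), 1))
      br <- c(br, alpha - beta, alpha + beta)
    }
    for (e in seq_len(m)) {                  # circle-edge breakpoints
      A <- P[e, ] - ci
      Bv <- P[e %% m + 1, ] - ci
      d <- Bv - A
      aa <- sum(d * d)
      bb <- 2 * sum(A * d)
      cc <- sum(A * A) - ri^2
      disc <- bb^2 - 4 * aa * cc
      if (disc <= 0) next
      for (t in (c(-1, 1) * sqrt(disc) - bb) / (2 * aa)) {
        if (t > 0 && t < 1) {
          q <- A + t * d
          br <- c(br, atan2(q[2], q[1]))
        }
      }
    }
    br <- sort(unique(br %% (2 * pi)))
    if (length(br) == 0L) br <- c(0, 2 * pi)
    arcs <- cbind(br, c(br[-1], br[1] + 2 * pi))
    for (a in seq_len(nrow(arcs))) {
      th1 <- arcs[a, 1]
      th2 <- arcs[a, 2]
      mid <- (th1 + th2) / 2
      q <- ci + ri * c(cos(mid), sin(mid))
      if (!inside_poly(q) || in_other_disc(q, i)) next
      total <- total + 0.5 *
        (ri^2 * (th2 - th1) +
           ci[1] * ri * (sin(th2) - sin(th1)) -
           ci[2] * ri * (cos(th2) - cos(th1)))
    }
  }

  # Pieces of polygon edges lying inside at least one disc.
  for (e in seq_len(m)) {
    A <- P[e, ]
    Bv <- P[e %% m + 1, ]
    d <- Bv - A
    ts <- c(0, 1)
    for (i in seq_len(nd)) {
      Ar <- A - centers[i, ]
      aa <- sum(d * d)
      bb <- 2 * sum(Ar * d)
      cc <- sum(Ar * Ar) - radii[i]^2
      disc <- bb^2 - 4 * aa * cc
      if (disc <= 0) next
      tt <- (c(-1, 1) * sqrt(disc) - bb) / (2 * aa)
      ts <- c(ts, tt[tt > 0 & tt < 1])
    }
    ts <- sort(unique(ts))
    for (s in seq_len(length(ts) - 1)) {
      qa <- A + ts[s] * d
      qb <- A + ts[s + 1] * d
      midq <- (qa + qb) / 2
      cov <- FALSE
      for (i in seq_len(nd)) {
        if (sum((midq - centers[i, ])^2) < (radii[i] - eps)^2) {
          cov <- TRUE
          break
        }
      }
      if (cov) total <- total + 0.5 * cross2(qa, qb)
    }
  }
  max(total, 0)
}

# Candidate plane offsets: projections of atom-center images onto the plane
# normal, restricted to planes that actually slice the cell box, de-duplicated.
candidate_offsets <- function(structure, plane) {
  geom <- plane_geometry(structure, plane)
  img <- periodic_images(structure)
  o <- as.numeric(img$X %*% geom$normal)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) %*% t(structure$basis)
  rng <- range(corners %*% geom$normal)
  eps <- 1e-6 * max(1, diff(rng))
  o <- o[o >= rng[1] - eps & o <= rng[2] + eps]
  o <- sort(o)
  if (length(o) == 0L) return(numeric())
  o[c(TRUE, diff(o) > 1e-6)]
}

#' Planar density of a Miller plane
#'
#' The planar density is the total cross-sectional area of the atoms whose
#' centers lie on the plane, clipped to the plane's section with the cell
#' box, divided by the section area. Each atom on the plane contributes its
#' great-circle disc of its tabulated radius.
#'
#' When `offset` is `NULL` (the default) the plane family is scanned: every
#' distinct offset at which the plane passes through at least one atom
#' center and still slices the cell box is evaluated, and the maximum
#' density member is reported.
#'
#' @inheritParams plane_section
#' @param offset Plane offset along the normal (Angstrom), or `NULL` to
#'   scan atom-populated offsets and return the densest plane.
#' @param tol Center-to-plane membership tolerance (Angstrom).
#' @param union If `TRUE`, overlapping cross-sections are resolved exactly
#'   as the area of their union; by default they are summed, which matches
#'   the usual textbook convention and can exceed 1 for overlapping radii.
#' @return An object of class `planar_density_record`: a list with `plane`,
#'   `cell_kind`, `offset`, `density`, `atoms_counted`, `section_area` and
#'   `covered_area`.
#' @examples
#' sc <- make_toy_structure("simple_cubic")
#' planar_density(sc, c(1, 0, 0))$density  # pi/4 for touching spheres
#' @export
planar_density <- function(structure, plane, offset = NULL, tol = 1e-3,
                           union = FALSE) {
  stopifnot(inherits(structure, "crystal_structure"))
  plane <- as_miller(plane)
  if (is.null(offset)) {
    offs <- candidate_offsets(structure, plane)
    best <- NULL
    for (o in offs) {
      rec <- tryCatch(
        planar_density_at(structure, plane, o, tol, union),
        error = function(e) NULL)
      if (!is.null(rec) &&
          (is.null(best) || rec$density > best$density)) best <- rec
    }
    if (is.null(best))
      stop("no atom-populated plane of this family slices the cell box",
           call. = FALSE)
    return(best)
  }
  planar_density_at(structure, plane, offset, tol, union)
}

planar_density_at <- function(structure, plane, offset, tol, union) {
  section <- plane_section(structure, plane, offset)
  atoms <- atoms_on_plane(structure, section, tol)
  if (nrow(atoms) == 0L) {
    covered <- 0
  } else if (union) {
    covered <- discs_union_polygon_area(
      as.matrix(atoms[, c("px", "py")]), atoms$radius, section)
  } else {
    covered <- sum(vapply(seq_len(nrow(atoms)), function(i) {
      circle_polygon_area(c(atoms$px[i], atoms$py[i]), atoms$radius[i],
                          section)
    }, numeric(1)))
  }
  structure(list(plane = plane, cell_kind = cell_kind(structure),
                 offset = offset, density = covered / section$area,
                 atoms_counted = nrow(atoms),
                 section_area = section$area, covered_area = covered),
            class = "planar_density_record")
}

#' @export
print.planar_density_record <- function(x, ...) {
  cat(sprintf(
    "Planar density of %s [%s] at offset %.4f A: %.4f (%d atoms, area %.3f A^2)\n",
    format(x$plane), x$cell_kind, x$offset, x$density, x$atoms_counted,
    x$section_area))
  invisible(x)
}
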