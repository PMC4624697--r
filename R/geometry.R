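#' Cell geometry
#'
#' The cell cortex is an ellipsoid with semi-axes `a` (along x, the
#' pole-pole axis), `b = 0.9 a` and `c = 0.7 a`. The two spindle poles sit
#' at (+/- a/2, 0, 0); chromosomes are released inside the nuclear sphere of
#' radius `0.65 a` and the CENP-E activation shell has radius `0.45 a`.
#'
#' @param a major semi-axis, um.
#' @return list of class `cell_geometry` with fields `a`, `b`, `c`,
#'   `poles` (2 x 3 matrix, row 1 the -x pole, row 2 the +x pole),
#'   `r_nucleus`, `r_cenpe_shell`.
#' @export
#' @examples
#' g <- cell_geometry(15)
#' g$poles
cell_geometry <- function(a = 15) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  g <- list(
    a = a, b = 0.9 * a, c = 0.7 * a,
    poles = rbind(c(-a / 2, 0, 0), c(a / 2, 0, 0)),
    r_nucleus = 0.65 * a,
    r_cenpe_shell = 0.45 * a
  )
  structure(g, class = "cell_geometry")
}

#' Strict cortex containment
#'
#' @param p a length-3 point or an n x 3 matrix of points.
#' @param g a [cell_geometry()].
#' @return logical, TRUE where the point lies strictly inside the cortex.
#' @export
inside_cortex <- function(p, g) {
  if (is.matrix(p)) {
    (p[, 1] / g$a)^2 + (p[, 2] / g$b)^2 + (p[, 3] / g$c)^2 < 1
  } else {
    (p[1] / g$a)^2 + (p[2] / g$b)^2 + (p[3] / g$c)^2 < 1
  }
}

ellipsoid_value <- function(p, g) {
  if (is.matrix(p)) {
    (p[, 1] / g$a)^2 + (p[, 2] / g$b)^2 + (p[, 3] / g$c)^2
  } else {
    (p[1] / g$a)^2 + (p[2] / g$b)^2 + (p[3] / g$c)^2
  }
}

#' Distance from an interior point to the cortex along a ray
#'
#' Solves the ellipsoid-ray intersection; MT lengths are clamped to this
#' value so tips never leave the cell.
#'
#' @param origin interior point (length 3), typically a pole.
#' @param dir unit direction (length 3).
#' @param g a [cell_geometry()].
#' @return the positive ray parameter at which the ray meets the cortex.
#' @export
#' @examples
#' g <- cell_geometry(15)
#' max_ray_length(g$poles[1, ], c(1, 0, 0), g)  # 22.5
max_ray_length <- function(origin, dir, g) {
  A <- (dir[1] / g$a)^2 + (dir[2] / g$b)^2 + (dir[3] / g$c)^2
  B <- 2 * (origin[1] * dir[1] / g$a^2 + origin[2] * dir[2] / g$b^2 +
              origin[3] * dir[3] / g$c^2)
  C <- ellipsoid_value(origin, g) - 1
  disc <- B^2 - 4 * A * C
  if (C >= 0 || disc < 0)
    stop("ray origin is not strictly inside the cortex")
  (-B + sqrt(disc)) / (2 * A)
}

# vectorized over rows of origin/dir matrices
max_ray_length_vec <- function(origin, dir, g) {
  A <- (dir[, 1] / g$a)^2 + (dir[, 2] / g$b)^2 + (dir[, 3] / g$c)^2
  B <- 2 * (origin[, 1] * dir[, 1] / g$a^2 + origin[, 2] * dir[, 2] / g$b^2 +
              origin[, 3] * dir[, 3] / g$c^2)
  C <- ellipsoid_value(origin, g) - 1
  if (any(C >= 0)) stop("ray origin is not strictly inside the cortex")
  (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
}

#' Project a point back inside the cortex
#'
#' Hard-repulsion boundary condition for chromosomes: a position outside
#' the ellipsoid is pulled radially (towards the cell centre) back to just
#' inside the boundary.
#'
#' @param p point or n x 3 matrix.
#' @param g a [cell_geometry()].
#' @param shrink fraction of the boundary radius at which projected points
#'   are placed (slightly below 1 keeps the interior strict).
#' @return the projected point(s).
#' @export
project_into_cortex <- function(p, g, shrink = 1 - 1e-9) {
  v <- ellipsoid_value(p, g)
  out <- v >= 1
  if (is.matrix(p)) {
    if (any(out)) {
      s <- shrink / sqrt(v[out])
      p[out, ] <- p[out, , drop = FALSE] * s
    }
  } else if (out) {
    p <- p * shrink / sqrt(v)
  }
  p
}

#' Uniform random unit vectors
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit rows. Uses the session RNG.
#' @export
sample_directions <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Initial chromosome positions
#'
#' Chromosomes are released uniformly inside the nuclear sphere of radius
#' `0.65 a`; with `interpolar = TRUE` they are instead drawn uniformly
#' inside the CENP-E shell of radius `0.45 a` (all chromosomes start
#' between the poles).
#'
#' @param n_C number of chromosomes.
#' @param g a [cell_geometry()].
#' @param interpolar logical, see above.
#' @return n_C x 3 matrix of positions. Uses the session RNG; identical
#'   seeds give identical positions.
#' @export
sample_initial_chromosomes <- function(n_C, g, interpolar = FALSE) {
  stopifnot(n_C >= 1)
  r_max <- if (interpolar) g$r_cenpe_shell else g$r_nucleus
  dirs <- sample_directions(n_C)
  r <- r_max * stats::runif(n_C)^(1 / 3)
  dirs * r
}

#' Point-segment distance
#'
#' Minimum distance from point `p` to the segment from `a` to `b`.
#'
#' @param p,a,b length-3 points.
#' @return scalar distance.
#' @export
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((a + t * ab - p)^2))
}

#' Does an MT cross the chromosome arms?
#'
#' A microtubule exerts a polar ejection force on a chromosome when its
#' segment (pole to tip) crosses the chromosome arm cross-section within
#' `r_C` of the chromosome centre. With `arm_geometry = "disk"` the
#' cross-section is a disk normal to the pole-pole (x) axis, the plane in
#' which arms are aligned by the ejection forces themselves; with
#' `"sphere"` it is an orientation-free sphere of the same radius.
#'
#' @param origin MT origin (pole position), length 3.
#' @param dir MT unit direction.
#' @param len MT length, um.
#' @param centre chromosome centre, length 3.
#' @param r_C arm radius, um.
#' @param arm_geometry `"disk"` or `"sphere"`.
#' @return logical.
#' @export
arm_crossing_test <- function(origin, dir, len, centre, r_C,
                              arm_geometry = "disk") {
  if (arm_geometry == "sphere")
    return(point_segment_distance(centre, origin, origin + len * dir) <= r_C)
  if (dir[1] == 0) return(FALSE)
  t <- (centre[1] - origin[1]) / dir[1]
  if (t < 0 || t > len) return(FALSE)
  dy <- origin[2] + t * dir[2] - centre[2]
  dz <- origin[3] + t * dir[3] - centre[3]
  dy * dy + dz * dz <= r_C * r_C
}

#' Is an MT within lateral-attachment reach of a kinetochore?
#'
#' TRUE when the minimum distance from the MT segment to the chromosome
#' centre is at most the kinetochore interaction radius `r_k`.
#'
#' @inheritParams arm_crossing_test
#' @param r_k kinetochore interaction radius, um.
#' @return logical.
#' @export
kinetochore_proximity_test <- function(origin, dir, len, centre, r_k) {
  point_segment_distance(centre, origin, origin + len * dir) <= r_k
}

#' Which kinetochore does an MT tip touch?
#'
#' The kinetochore sphere is split into two hemispheres by the plane normal
#' to the pole-pole axis: the LEFT hemisphere faces the -x pole, the RIGHT
#' one the +x pole. A tip within `r_k` of the chromosome centre contacts
#' the hemisphere containing it; an exact tie goes to the hemisphere facing
#' the MT's own pole.
#'
#' @inheritParams kinetochore_proximity_test
#' @param pole index of the MT's pole (1 = -x, 2 = +x), used only to break
#'   exact ties.
#' @return `"LEFT"`, `"RIGHT"` or `"NONE"`.
#' @export
tip_contact_side <- function(origin, dir, len, centre, r_k, pole = 1L) {
  tip <- origin + len * dir
  if (sum((tip - centre)^2) > r_k * r_k) return("NONE")
  dx <- tip[1] - centre[1]
  if (dx < 0) "LEFT" else if (dx > 0) "RIGHT" else c("LEFT", "RIGHT")[pole]
}
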