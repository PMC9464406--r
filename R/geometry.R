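# -- small vector helpers ----------------------------------------------------

vecNorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vecNorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Construct a 3D line
#'
#' A line is stored as a base point and a unit direction. Lines carry the
#' measurement pipeline's axes (neck axis, shaft axis, posterior condylar
#' line, anterior wall line).
#'
#' @param point numeric length-3, a point on the line (mm).
#' @param direction numeric length-3 direction; normalised internally.
#' @return An object of class `line3d` with elements `point` and `direction`
#'   (unit vector).
#' @export
line3d <- function(point, direction) {
  stopifnot(length(point) == 3, length(direction) == 3,
            all(is.finite(point)), all(is.finite(direction)))
  structure(list(point = as.numeric(point), direction = unitize(direction)),
            class = "line3d")
}

#' Construct a 3D plane
#'
#' @param point numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3 normal; normalised internally.
#' @return An object of class `plane3d` with elements `point` and `normal`.
#' @export
plane3d <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3,
            all(is.finite(point)), all(is.finite(normal)))
  structure(list(point = as.numeric(point), normal = unitize(normal)),
            class = "plane3d")
}

# Orthonormal in-plane basis (e1, e2) with e1 x e2 = normal.
planeBasis <- function(normal) {
  n <- unitize(normal)
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(seed - sum(seed * n) * n)
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2, n = n)
}

#' Signed angle between two lines in a projection view
#'
#' Projects both directions onto the plane perpendicular to `view_normal`
#' and returns the angle between the projections in degrees. The magnitude
#' is the usual angle in [0, 180]; the sign is positive when the component
#' of `b` perpendicular to `a` (within the view plane) points along
#' `sign_reference`. This makes the result independent of the orientation
#' chosen for the view normal, which is what anatomical view conventions
#' (axial / AP / sagittal) require.
#'
#' @param a,b `line3d` objects (or length-3 directions).
#' @param view_normal length-3 view direction (projection axis).
#' @param sign_reference length-3 direction defining the positive side.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
projectedAngle <- function(a, b, view_normal, sign_reference) {
  da <- if (inherits(a, "line3d")) a$direction else unitize(a)
  db <- if (inherits(b, "line3d")) b$direction else unitize(b)
  n <- unitize(view_normal)
  pa <- da - sum(da * n) * n
  pb <- db - sum(db * n) * n
  if (vecNorm(pa) < sin(deg2rad(1)))
    stop("projection degenerates: first line is within 1 degree of the view normal")
  if (vecNorm(pb) < sin(deg2rad(1)))
    stop("projection degenerates: second line is within 1 degree of the view normal")
  pa <- unitize(pa); pb <- unitize(pb)
  ang <- rad2deg(atan2(vecNorm(cross3(pa, pb)), sum(pa * pb)))
  perp <- pb - sum(pb * pa) * pa
  s <- sum(perp * sign_reference)
  if (abs(s) < 1e-12) ang else ang * sign(s)
}

# -- sphere fitting ----------------------------------------------------------

# Algebraic (linear least squares) sphere fit; exact for noiseless data.
fitSphereAlgebraic <- function(points) {
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("singular sphere fit: points are coplanar or degenerate"))
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("singular sphere fit: non-positive squared radius")
  list(center = center, radius = sqrt(r2))
}

#' Least-squares sphere fit
#'
#' Fits a sphere to surface points: an algebraic linear solve provides the
#' starting value and Gauss-Newton iterations on the geometric residuals
#' \eqn{|p_i - c| - r} refine it. Used to locate the femoral head centre.
#'
#' @param points numeric matrix (n x 3) of surface points in mm, n >= 10,
#'   not coplanar.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on the parameter update (mm).
#' @return List with `center` (length 3), `radius`, and `rms_residual`, all mm.
#' @export
fitSphere <- function(points, max_iter = 50, tol = 1e-12) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  if (nrow(points) < 10) stop("sphere fit needs at least 10 points")
  init <- fitSphereAlgebraic(points)
  par <- c(init$center, init$radius)
  for (i in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(points, 2, par[1:3])^2))
    if (any(d < 1e-9)) d[d < 1e-9] <- 1e-9
    r <- d - par[4]
    # Jacobian of residuals wrt (cx, cy, cz, R)
    J <- cbind(-sweep(points, 2, par[1:3]) / d, -1)
    delta <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 4))
    par <- par + delta
    if (vecNorm(delta) < tol) break
  }
  d <- sqrt(rowSums(sweep(points, 2, par[1:3])^2))
  list(center = as.numeric(par[1:3]), radius = par[4],
       rms_residual = sqrt(mean((d - par[4])^2)))
}

# -- planar polygon utilities ------------------------------------------------

# Area and centroid of a closed polygon given as k x 2 coordinates
# (vertices in order, not repeated). Signed area; centroid exact.
polygonAreaCentroid2D <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) {
    return(list(area = 0, centroid = colMeans(xy)))
  }
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  list(area = A, centroid = c(cx, cy))
}

# Even-odd point-in-polygon test, xy is k x 2, p length 2.
pointInPolygon2D <- function(p, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > p[2]) != (yn > p[2])) &
    (p[1] < (xn - x) * (p[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

# Simple-polygon check: no two non-adjacent edges intersect. O(k^2); used
# on section contours which are small.
polygonIsSimple2D <- function(xy) {
  k <- nrow(xy)
  if (k < 3) return(FALSE)
  seg <- cbind(xy, rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]))
  intersects <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(k - 2)) {
    jmax <- if (i == 1) k - 1 else k
    for (j in (i + 2):jmax) {
      if (j > k) next
      if (intersects(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# Total-least-squares line through 2D points: first principal axis.
tlsLine2D <- function(xy) {
  ctr <- colMeans(xy)
  M <- sweep(xy, 2, ctr)
  sv <- svd(M, nu = 0, nv = 2)
  dir <- sv$v[, 1]
  rms <- if (length(sv$d) > 1) sqrt(mean((M %*% sv$v[, 2])^2)) else 0
  list(point = ctr, direction = dir, rms = rms)
}

# Rotation matrix about a unit axis (Rodrigues).
rotationAbout <- function(axis, angle_deg) {
  k <- unitize(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
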