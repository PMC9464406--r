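# Parametric proximal-femur phantom with closed-form ground truth.
#
# The phantom stands in for a CT surface reconstruction: a spherical head,
# a waisted neck of revolution set at a prescribed anteversion and
# neck-shaft angle, a vertical shaft cylinder whose axis is the canal-centre
# locus, a greater-trochanter block whose anterior face makes exactly the
# prescribed anterior-wall angle with the shaft axis in the sagittal
# projection, and two posterior condylar bosses whose most-posterior points
# define the posterior condylar line. Scanner frame (right femur):
# +x anterior, +y proximal, +z lateral. All lengths mm, angles degrees.

#' Phantom specification
#'
#' Dials are the three angles the measurement pipeline recovers plus the
#' main anatomical dimensions. The analytic ground truth depends only on
#' the dials, never on the seed, which controls optional triangulation
#' jitter.
#'
#' @param head_radius femoral head radius, mm.
#' @param head_center head centre in the scanner frame, mm.
#' @param true_anteversion anteversion dial, degrees; negative = retroversion.
#' @param true_neck_shaft_angle neck-shaft angle dial, degrees, in [110, 150].
#' @param true_aw_angle anterior-wall angle dial, degrees, in [-5, 45].
#' @param neck_narrowest_diameter diameter of the neck waist, mm.
#' @param shaft_radius,shaft_length shaft cylinder dimensions, mm.
#' @param gt_height height of the greater-trochanter block, mm.
#' @param lateral_ridge_point optional override for the lateral-ridge
#'   landmark (default: constructed superolateral edge midpoint).
#' @param condyle_offset translation applied to both condylar bosses, mm.
#' @param mesh_resolution `"coarse"`, `"medium"` or `"fine"`.
#' @param seed integer; controls triangulation jitter only.
#' @param vertex_jitter_sd isotropic vertex jitter SD, mm (default 0).
#' @return An object of class `phantomSpec`.
#' @export
phantomSpec <- function(head_radius = 24,
                        head_center = c(0, 0, 0),
                        true_anteversion = 14.8,
                        true_neck_shaft_angle = 127.3,
                        true_aw_angle = 17.5,
                        neck_narrowest_diameter = 28,
                        shaft_radius = 16,
                        shaft_length = 150,
                        gt_height = 35,
                        lateral_ridge_point = NULL,
                        condyle_offset = c(0, 0, 0),
                        mesh_resolution = c("medium", "coarse", "fine"),
                        seed = 1L,
                        vertex_jitter_sd = 0) {
  mesh_resolution <- match.arg(mesh_resolution)
  spec <- structure(list(
    head_radius = head_radius, head_center = as.numeric(head_center),
    true_anteversion = true_anteversion,
    true_neck_shaft_angle = true_neck_shaft_angle,
    true_aw_angle = true_aw_angle,
    neck_narrowest_diameter = neck_narrowest_diameter,
    shaft_radius = shaft_radius, shaft_length = shaft_length,
    gt_height = gt_height, lateral_ridge_point = lateral_ridge_point,
    condyle_offset = as.numeric(condyle_offset),
    mesh_resolution = mesh_resolution, seed = as.integer(seed),
    vertex_jitter_sd = vertex_jitter_sd), class = "phantomSpec")
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  with(spec, {
    if (!(head_radius > neck_narrowest_diameter / 2))
      stop("invalid phantom spec: head_radius must exceed the neck waist radius")
    if (true_neck_shaft_angle < 110 || true_neck_shaft_angle > 150)
      stop("invalid phantom spec: neck-shaft angle outside [110, 150] degrees")
    if (true_anteversion < -20 || true_anteversion > 45)
      stop("invalid phantom spec: anteversion outside [-20, 45] degrees")
    if (true_aw_angle < -5 || true_aw_angle > 45)
      stop("invalid phantom spec: anterior-wall angle outside [-5, 45] degrees")
    if (shaft_length < 100)
      stop("invalid phantom spec: shaft must be at least 100 mm long")
  })
  invisible(TRUE)
}

# Unit vector from neck waist toward the head centre, built so that the
# axial projection makes exactly `fa` with the condylar (mediolateral)
# direction and the AP projection makes exactly `nsa` with the shaft axis.
neckDirectionFromDials <- function(fa, nsa) {
  unitize(c(sin(deg2rad(nsa)) * tan(deg2rad(fa)),
            -cos(deg2rad(nsa)),
            -sin(deg2rad(nsa))))
}

# Internal construction constants shared by builder and landmarks.
phantomDerived <- function(spec) {
  u <- neckDirectionFromDials(spec$true_anteversion, spec$true_neck_shaft_angle)
  neck_len <- spec$head_radius + 26
  J <- spec$head_center - u * neck_len          # neck-shaft junction
  y_top <- J[2] + 25
  y_bot <- y_top - spec$shaft_length
  waist_t <- spec$head_radius + 14
  list(u = u, d = -u, neck_len = neck_len, J = J,
       y_top = y_top, y_bot = y_bot, waist_t = waist_t,
       waist_r = spec$neck_narrowest_diameter / 2,
       boss_radius = 22,
       boss_centers = rbind(
         spec$head_center * c(1, 0, 1) + c(-10, J[2] + 25 - spec$shaft_length + 10, -25) + spec$condyle_offset,
         spec$head_center * c(1, 0, 1) + c(-10, J[2] + 25 - spec$shaft_length + 10, +25) + spec$condyle_offset))
}

resolutionParams <- function(class) {
  switch(class,
    coarse = list(n_seg = 48, sph = c(20, 30), n_stations = 25),
    medium = list(n_seg = 64, sph = c(28, 42), n_stations = 41),
    fine = list(n_seg = 96, sph = c(40, 60), n_stations = 61))
}

#' Closed-form ground-truth angles of a phantom
#'
#' @param spec a `phantomSpec`.
#' @return An `angleSet` (fa, nsa, aw in degrees, side).
#' @export
groundTruthAngles <- function(spec) {
  validatePhantomSpec(spec)
  angleSet(fa = spec$true_anteversion, nsa = spec$true_neck_shaft_angle,
           aw = spec$true_aw_angle, side = "right")
}

#' Per-femur angle set
#'
#' @param fa anteversion, degrees, signed (negative = retroversion).
#' @param nsa neck-shaft angle, degrees, in (0, 180).
#' @param aw anterior-wall angle, degrees, signed (positive when the wall
#'   line tilts anteriorly going proximally).
#' @param side `"left"` or `"right"`.
#' @param diagnostics optional named list of measurement diagnostics.
#' @return An object of class `angleSet`.
#' @export
angleSet <- function(fa, nsa, aw, side = "right", diagnostics = list()) {
  side <- match.arg(side, c("right", "left"))
  stopifnot(is.finite(fa), is.finite(aw), is.finite(nsa), nsa > 0, nsa < 180)
  structure(list(fa = fa, nsa = nsa, aw = aw, side = side,
                 diagnostics = diagnostics), class = "angleSet")
}

#' @export
print.angleSet <- function(x, ...) {
  cat(sprintf("angleSet (%s): FA %.1f deg, NSA %.1f deg, AW %.1f deg\n",
              x$side, x$fa, x$nsa, x$aw))
  invisible(x)
}

#' Named anatomical landmarks
#'
#' @param lateral_ridge_GT lateral ridge of the greater trochanter, mm.
#' @param lesser_trochanter_base_point point on the shaft axis at the base
#'   of the lesser trochanter, mm; its station along the proximal axis is
#'   the `lesser_trochanter_base_level` of the measurement pipeline.
#' @param medial_posterior_condyle,lateral_posterior_condyle most posterior
#'   points of the condyles (posterior condylar line), mm.
#' @param epicondyle_midpoint midpoint between the epicondyles, mm.
#' @param hip_center_hint optional approximate hip centre, mm.
#' @return An object of class `landmarkSet`.
#' @export
landmarkSet <- function(lateral_ridge_GT, lesser_trochanter_base_point,
                        medial_posterior_condyle, lateral_posterior_condyle,
                        epicondyle_midpoint, hip_center_hint = NULL) {
  pts <- list(lateral_ridge_GT = lateral_ridge_GT,
              lesser_trochanter_base_point = lesser_trochanter_base_point,
              medial_posterior_condyle = medial_posterior_condyle,
              lateral_posterior_condyle = lateral_posterior_condyle,
              epicondyle_midpoint = epicondyle_midpoint)
  for (nm in names(pts)) {
    if (is.null(pts[[nm]]) || length(pts[[nm]]) != 3 || !all(is.finite(pts[[nm]])))
      stop(sprintf("landmark '%s' missing or not a finite 3-vector", nm))
    pts[[nm]] <- as.numeric(pts[[nm]])
  }
  if (sum((pts$medial_posterior_condyle - pts$lateral_posterior_condyle)^2) < 1)
    stop("condyle landmarks must be distinct")
  pts$hip_center_hint <- if (is.null(hip_center_hint)) NULL else as.numeric(hip_center_hint)
  structure(pts, class = "landmarkSet")
}

#' Build a phantom mesh with landmarks
#'
#' Constructs the phantom as a union of disjoint closed analytic shells
#' (sphere, neck of revolution, shaft cylinder, trochanter block, condylar
#' bosses), so every ground-truth angle is available in closed form and the
#' mesh is watertight at any resolution.
#'
#' @param spec a `phantomSpec`.
#' @return List with `mesh` (a `triMesh`), `landmarks` (a `landmarkSet`),
#'   and `truth` (an `angleSet`).
#' @export
buildPhantom <- function(spec) {
  validatePhantomSpec(spec)
  g <- phantomDerived(spec)
  res <- resolutionParams(spec$mesh_resolution)
  R <- spec$head_radius

  head <- uvSphereMesh(spec$head_center, R, res$sph[1], res$sph[2])

  # neck: surface of revolution along d = head -> trochanter with a waist
  t0 <- 0.7 * R
  t1 <- g$neck_len + 8
  head_circle <- 0.92 * sqrt(R^2 - t0^2)
  if (head_circle <= g$waist_r)
    stop("infeasible phantom geometry: neck waist too wide to attach to the head")
  r_head_end <- min(head_circle, 1.3 * g$waist_r)
  r_dist_end <- 1.2 * g$waist_r
  k_head <- (r_head_end - g$waist_r) / (g$waist_t - t0)^2
  k_dist <- (r_dist_end - g$waist_r) / (t1 - g$waist_t)^2
  stations <- sort(unique(c(seq(t0, t1, length.out = res$n_stations), g$waist_t)))
  radii <- ifelse(stations <= g$waist_t,
                  g$waist_r + k_head * (stations - g$waist_t)^2,
                  g$waist_r + k_dist * (stations - g$waist_t)^2)
  # neck must end inside the shaft cylinder
  end_pt <- spec$head_center + g$d * t1
  if (sqrt((end_pt[1] - g$J[1])^2 + (end_pt[3] - g$J[3])^2) > spec$shaft_radius ||
      end_pt[2] > g$y_top || end_pt[2] < g$y_bot)
    stop("infeasible phantom geometry: neck would not attach to the shaft")
  neck <- revolutionMesh(spec$head_center, g$d, stations, radii, res$n_seg)

  shaft <- revolutionMesh(c(g$J[1], g$y_bot, g$J[3]), c(0, 1, 0),
                          seq(0, spec$shaft_length, length.out = 7),
                          rep(spec$shaft_radius, 7), res$n_seg)

  # greater-trochanter block; anterior face plane has normal
  # (cos AW, -sin AW, 0): it makes exactly true_aw_angle with the shaft
  # axis in the sagittal projection.
  z0 <- g$J[3] + 2
  z1 <- g$J[3] + spec$shaft_radius + 10
  y_topGT <- g$J[2] + 20
  y0GT <- y_topGT - spec$gt_height
  x_post <- g$J[1] - 0.9 * spec$shaft_radius
  tanaw <- tan(deg2rad(spec$true_aw_angle))
  x_ant <- function(y) g$J[1] + 0.55 * spec$shaft_radius + tanaw * (y - y0GT)
  gt <- hexBlockMesh(
    rbind(c(x_post, y0GT, z0), c(x_ant(y0GT), y0GT, z0),
          c(x_ant(y0GT), y0GT, z1), c(x_post, y0GT, z1)),
    rbind(c(x_post, y_topGT, z0), c(x_ant(y_topGT), y_topGT, z0),
          c(x_ant(y_topGT), y_topGT, z1), c(x_post, y_topGT, z1)))

  boss_m <- uvSphereMesh(g$boss_centers[1, ], g$boss_radius,
                         res$sph[1], res$sph[2])
  boss_l <- uvSphereMesh(g$boss_centers[2, ], g$boss_radius,
                         res$sph[1], res$sph[2])

  mesh <- mergeMeshes(head, neck, shaft, gt, boss_m, boss_l,
                      frame_label = "scanner")

  if (spec$vertex_jitter_sd > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    mesh$vertices <- mesh$vertices +
      matrix(stats::rnorm(length(mesh$vertices), 0, spec$vertex_jitter_sd),
             ncol = 3)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }

  ridge <- if (!is.null(spec$lateral_ridge_point)) spec$lateral_ridge_point else
    c((x_post + x_ant(y_topGT)) / 2, y_topGT, z1)
  lm <- landmarkSet(
    lateral_ridge_GT = ridge,
    lesser_trochanter_base_point = c(g$J[1], g$J[2] - 30, g$J[3]),
    medial_posterior_condyle = g$boss_centers[1, ] - c(g$boss_radius, 0, 0),
    lateral_posterior_condyle = g$boss_centers[2, ] - c(g$boss_radius, 0, 0),
    epicondyle_midpoint = c(spec$head_center[1], g$boss_centers[1, 2],
                            spec$head_center[3]),
    hip_center_hint = spec$head_center)
  list(mesh = mesh, landmarks = lm, truth = groundTruthAngles(spec))
}

#' Mirror a phantom (or any femur mesh + landmarks) to the other side
#'
#' Mirrors across the sagittal-ish plane z = 0 of the scanner frame, with
#' face winding flipped so the surface stays outward-oriented. Landmark
#' labels are anatomical and therefore unchanged: the medial condyle of the
#' mirrored (left) femur sits at mirrored coordinates but is still medial.
#'
#' @param mesh a `triMesh`.
#' @param landmarks a `landmarkSet`.
#' @return List with mirrored `mesh` and `landmarks`.
#' @export
mirrorFemur <- function(mesh, landmarks) {
  M <- diag(c(1, 1, -1))
  lm2 <- landmarks
  for (nm in names(lm2)) if (!is.null(lm2[[nm]])) lm2[[nm]] <- lm2[[nm]] * c(1, 1, -1)
  list(mesh = transformMesh(mesh, M), landmarks = lm2)
}

#' Apply a rigid transform to landmarks
#'
#' @param landmarks a `landmarkSet`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector, mm.
#' @return Transformed `landmarkSet`.
#' @export
transformLandmarks <- function(landmarks, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  lm2 <- landmarks
  for (nm in names(lm2)) if (!is.null(lm2[[nm]]))
    lm2[[nm]] <- as.numeric(rotation %*% lm2[[nm]] + translation)
  lm2
}
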