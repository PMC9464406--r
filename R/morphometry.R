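# Geometric measurement pipeline: head-centre sphere fit, narrowest neck
# section, shaft axis from canal centres, simulated greater-trochanter cut,
# anterior-wall tangent line, anatomical frames, and the three projected
# angles (anteversion, neck-shaft, anterior-wall).

#' Anatomical reference frame
#'
#' @param origin frame origin, mm.
#' @param anterior,proximal,lateral right-handed orthonormal axis triad.
#' @param kind `"tabletop"` or `"ISB"`.
#' @return An object of class `femurFrame`.
#' @export
femurFrame <- function(origin, anterior, proximal, lateral,
                       kind = c("tabletop", "ISB")) {
  kind <- match.arg(kind)
  A <- cbind(anterior, proximal, lateral)
  if (max(abs(crossprod(A) - diag(3))) > 1e-9)
    stop("frame axes are not orthonormal")
  structure(list(origin = as.numeric(origin), anterior = as.numeric(anterior),
                 proximal = as.numeric(proximal), lateral = as.numeric(lateral),
                 kind = kind), class = "femurFrame")
}

#' Tabletop (scanner) frame
#'
#' The tabletop frame is the CT table frame of a supine, symmetrically
#' positioned acquisition: its axes are the scanner axes themselves. The AP
#' view projects along the anterior axis.
#'
#' @param landmarks a `landmarkSet` (used only for the origin).
#' @param scanner_axes 3x3 matrix whose columns are the scanner anterior,
#'   proximal and lateral directions (default identity).
#' @return A `femurFrame` of kind `"tabletop"`.
#' @export
buildTabletopFrame <- function(landmarks, scanner_axes = diag(3)) {
  femurFrame(origin = landmarks$epicondyle_midpoint,
             anterior = unitize(scanner_axes[, 1]),
             proximal = unitize(scanner_axes[, 2]),
             lateral = unitize(scanner_axes[, 3]),
             kind = "tabletop")
}

#' Femoral anatomical (ISB-style) frame
#'
#' Proximal axis from the epicondylar midpoint to the head centre; lateral
#' axis from the intercondylar direction orthogonalised against it;
#' anterior axis completes a right-handed triad on the stated side. The
#' sagittal view projects along the lateral axis.
#'
#' @param landmarks a `landmarkSet`.
#' @param head_center fitted femoral head centre, mm.
#' @param side `"right"` or `"left"`.
#' @return A `femurFrame` of kind `"ISB"`.
#' @export
buildIsbFrame <- function(landmarks, head_center, side = c("right", "left")) {
  side <- match.arg(side)
  prox <- head_center - landmarks$epicondyle_midpoint
  if (vecNorm(prox) < 10) stop("head centre and epicondylar midpoint nearly coincide")
  prox <- unitize(prox)
  inter <- landmarks$lateral_posterior_condyle - landmarks$medial_posterior_condyle
  lat <- inter - sum(inter * prox) * prox
  if (vecNorm(lat) < 1) stop("collinear landmarks: intercondylar direction degenerate")
  lat <- unitize(lat)
  ant <- if (side == "right") cross3(prox, lat) else cross3(lat, prox)
  femurFrame(origin = head_center, anterior = ant, proximal = prox,
             lateral = lat, kind = "ISB")
}

#' Femoral neck axis
#'
#' @param head_center fitted head centre, mm.
#' @param neck_midpoint midpoint of the narrowest neck section, mm.
#' @return A `line3d` through both points, direction oriented head-to-neck.
#' @export
neckAxis <- function(head_center, neck_midpoint) {
  if (vecNorm(neck_midpoint - head_center) <= 1)
    stop("head centre and neck midpoint coincide (separation <= 1 mm)")
  line3d(head_center, neck_midpoint - head_center)
}

#' Femoral shaft axis from canal-centre sections
#'
#' Cuts transverse sections at the base of the lesser trochanter and 50 mm
#' further distally and connects their contour centroids. For a (possibly
#' oblique) circular shaft the section centroid lies exactly on the canal
#' axis, so the choice of transverse direction does not bias the axis.
#'
#' @param mesh a `triMesh`.
#' @param lesser_troch_base_level station (mm) of the lesser-trochanter
#'   base along `proximal`.
#' @param proximal unit vector of the transverse-stack direction (scanner
#'   proximal axis).
#' @return A `line3d` oriented proximal-to-distal, with attribute
#'   `"centroids"`.
#' @export
shaftAxis <- function(mesh, lesser_troch_base_level, proximal = c(0, 1, 0)) {
  proximal <- unitize(proximal)
  stations <- as.numeric(mesh$vertices %*% proximal)
  if (min(stations) > lesser_troch_base_level - 50)
    stop("mesh does not extend 50 mm distal to the lesser-trochanter base level")
  if (max(stations) < lesser_troch_base_level)
    stop("lesser-trochanter base level lies beyond the mesh")
  centroidAt <- function(level) {
    loops <- crossSectionMesh(mesh, plane3d(level * proximal, proximal))
    if (length(loops) == 0)
      stop(sprintf("no closed canal contour at station %.1f mm", level))
    loops[[which.max(vapply(loops, `[[`, 0, "area"))]]$centroid
  }
  c1 <- centroidAt(lesser_troch_base_level)
  c2 <- centroidAt(lesser_troch_base_level - 50)
  structure(line3d(c1, c2 - c1), centroids = rbind(c1, c2))
}

#' Narrowest section of the femoral neck
#'
#' Scans cutting planes perpendicular to the current neck-axis estimate,
#' starting just beyond the fitted head surface, and returns the centroid
#' of the minimal-area closed contour. The axis estimate is re-derived from
#' head centre to the current midpoint and the scan repeated until the
#' midpoint moves less than 0.1 mm (at most `max_iter` iterations). Coarse
#' step 0.5 mm with a 0.1 mm refinement pass around the minimum.
#'
#' @param mesh a `triMesh`.
#' @param head_center fitted head centre, mm.
#' @param initial_direction unit vector from the head toward the
#'   trochanteric region.
#' @param head_radius fitted head radius, mm; the scan starts at
#'   `head_radius + 2`. Estimated from the mesh when `NULL`.
#' @param scan_length scan extent beyond the start, mm.
#' @param step coarse scan step, mm.
#' @param max_iter axis re-estimation cap.
#' @return List with `midpoint`, `area` (mm^2), `plane` (a `plane3d`),
#'   `non_unique` flag and `iterations`.
#' @export
narrowestNeckSection <- function(mesh, head_center, initial_direction,
                                 head_radius = NULL, scan_length = 45,
                                 step = 0.5, max_iter = 10) {
  dir <- unitize(initial_direction)
  if (is.null(head_radius)) {
    d_all <- sqrt(rowSums(sweep(mesh$vertices, 2, head_center)^2))
    head_radius <- stats::median(sort(d_all)[seq_len(min(200, length(d_all)))])
  }
  # The neck is the tube centred on the scan axis. The scan tracks it
  # station by station: the first contour is seeded by containment of the
  # axis point, later stations follow the running centroid with a tight
  # gate. This keeps slivers clipped off neighbouring structures (shaft
  # rim, trochanter corners) from masquerading as a narrow neck section.
  loopNear <- function(t, dir, target, gate, need_containment) {
    pl <- plane3d(head_center + t * dir, dir)
    loops <- crossSectionMesh(mesh, pl)
    if (length(loops) == 0) return(NULL)
    offs <- vapply(loops, function(L) vecNorm(L$centroid - target), 0)
    if (need_containment) {
      inc <- vapply(loops, function(L) pointInPolygon2D(c(0, 0), L$points2d), TRUE)
      offs[!inc] <- Inf
    }
    j <- which.min(offs)
    if (offs[j] > gate) return(NULL)
    list(loop = loops[[j]], plane = pl)
  }
  midpoint <- NULL; out <- NULL; iterations <- 0
  for (it in seq_len(max_iter)) {
    iterations <- it
    t0 <- head_radius + 2
    ts <- seq(t0, t0 + scan_length, by = step)
    areas <- rep(NA_real_, length(ts))
    secs <- vector("list", length(ts))
    best <- Inf; best_i <- NA
    prev <- NULL
    for (i in seq_along(ts)) {
      s <- if (is.null(prev)) {
        loopNear(ts[i], dir, head_center + ts[i] * dir, gate = 8,
                 need_containment = TRUE)
      } else {
        loopNear(ts[i], dir, prev + step * dir, gate = 3,
                 need_containment = FALSE)
      }
      if (is.null(s)) { if (is.null(prev)) next else break }
      prev <- s$loop$centroid
      secs[[i]] <- s
      areas[i] <- s$loop$area
      if (areas[i] < best) { best <- areas[i]; best_i <- i }
      # confirmed local minimum: stop once well past it
      past <- which(!is.na(areas) & seq_along(areas) > best_i)
      if (length(past) >= 5 && all(areas[utils::tail(past, 5)] > 1.1 * best)) break
    }
    valid <- which(!is.na(areas))
    if (length(valid) == 0)
      stop("no closed neck contour found along the scan axis")
    non_unique <- (max(areas[valid]) - best) / best < 0.01
    if (non_unique) best_i <- valid[ceiling(length(valid) / 2)]
    # refinement pass at 0.1 mm around the coarse minimum
    if (!non_unique) {
      ctr <- secs[[best_i]]$loop$centroid
      for (t in seq(ts[best_i] - step, ts[best_i] + step, by = 0.1)) {
        s <- loopNear(t, dir, ctr, gate = 3, need_containment = FALSE)
        if (!is.null(s) && s$loop$area < best) {
          best <- s$loop$area; secs[[best_i]] <- s; ts[best_i] <- t
        }
      }
    }
    sec <- secs[[best_i]]
    new_mid <- sec$loop$centroid
    out <- list(midpoint = new_mid, area = sec$loop$area, plane = sec$plane,
                non_unique = non_unique, iterations = iterations)
    if (!is.null(midpoint) && vecNorm(new_mid - midpoint) < 0.1) break
    midpoint <- new_mid
    dir <- unitize(new_mid - head_center)
  }
  out
}

#' Simulated cut of the greater trochanter
#'
#' The cut plane passes through the point 5 mm distal (along the shaft
#' axis) to the lateral ridge of the greater trochanter and is tilted about
#' the anteroposterior axis until the maximum thickness of the resected
#' cap, measured perpendicular to the plane, equals 10 mm (binary search,
#' 0.1 mm tolerance).
#'
#' @param mesh a `triMesh` containing the trochanter (other shells are
#'   ignored; the shell nearest `lateral_ridge` is used).
#' @param lateral_ridge lateral-ridge landmark, mm.
#' @param shaft measured shaft axis (`line3d`, proximal-to-distal).
#' @param frame a `femurFrame` providing anterior/lateral directions.
#' @param target_thickness resected-cap maximum thickness, mm.
#' @param tol thickness tolerance, mm.
#' @return List with `plane` (a `plane3d`), `contour` (a section loop),
#'   `tilt_deg` and `thickness`.
#' @export
simulateGtCut <- function(mesh, lateral_ridge, shaft, frame,
                          target_thickness = 10, tol = 0.1) {
  comps <- meshComponents(mesh)
  if (length(comps) > 1) {
    d <- vapply(comps, pointMeshEdgeDistance, 0, point = lateral_ridge)
    gt <- comps[[which.min(d)]]
  } else gt <- comps[[1]]
  prox <- -shaft$direction
  entry <- lateral_ridge - 5 * prox
  thicknessAt <- function(theta) {
    n <- cos(deg2rad(theta)) * prox - sin(deg2rad(theta)) * frame$lateral
    above <- as.numeric(sweep(gt$vertices, 2, entry) %*% n)
    list(n = n, thickness = max(above))
  }
  lo <- 0; hi <- 60
  th_lo <- thicknessAt(lo)$thickness
  th_hi <- thicknessAt(hi)$thickness
  if (th_lo > target_thickness + tol)
    stop(sprintf("no admissible tilt: untilted cap already %.1f mm thick", th_lo))
  if (th_hi < target_thickness - tol)
    stop(sprintf("no tilt in [0, 60] deg reaches %.0f mm (achieved %.1f mm)",
                 target_thickness, th_hi))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    th <- thicknessAt(mid)$thickness
    if (abs(th - target_thickness) < tol / 2) break
    if (th < target_thickness) lo <- mid else hi <- mid
  }
  sol <- thicknessAt(mid)
  pl <- plane3d(entry, sol$n)
  loops <- crossSectionMesh(gt, pl)
  if (length(loops) == 0) stop("trochanter cut produced no contour")
  d_entry <- vapply(loops, function(L)
    min(sqrt(rowSums(sweep(L$points, 2, entry)^2))), 0)
  list(plane = pl, contour = loops[[which.min(d_entry)]],
       tilt_deg = mid, thickness = sol$thickness)
}

#' Tangent line to the anterior wall of the trochanteric cut surface
#'
#' Identifies the anterior-wall arc of the cut contour: starting from the
#' most anterior contour vertex, contiguous edges are included while their
#' outward normals stay within `cone_deg` of the wall orientation at the
#' seed. A total-least-squares line is fitted to the arc vertices in the
#' cut plane and translated to pass through the most anterior vertex
#' (tangency). The arc must be at least `min_arc` mm long.
#'
#' @param contour a section loop (from [crossSectionMesh()] /
#'   [simulateGtCut()]).
#' @param frame a `femurFrame` providing the anterior direction.
#' @param cone_deg admissible deviation of edge normals from the seed
#'   normal, degrees.
#' @param min_arc minimum identifiable wall length, mm.
#' @param flat_tol rms deviation (mm) above which the wall is reported as
#'   not flat.
#' @return A `line3d` in the cut plane with attributes `"rms"` (mm, wall
#'   flatness) and `"flat"` (logical).
#' @export
anteriorWallLine <- function(contour, frame, cone_deg = 30, min_arc = 5,
                             flat_tol = 0.3) {
  P <- contour$points; xy <- contour$points2d; B <- contour$basis
  k <- nrow(P)
  nxt <- c(2:k, 1)
  tang <- xy[nxt, ] - xy
  len <- sqrt(rowSums(tang^2))
  tang <- tang / len
  nrm2 <- cbind(tang[, 2], -tang[, 1])             # outward for CCW polygons
  nrm3 <- nrm2[, 1] %o% B$e1 + nrm2[, 2] %o% B$e2  # k x 3
  ant_comp <- as.numeric(nrm3 %*% frame$anterior)
  ant_vert <- as.numeric(P %*% frame$anterior)
  seed_v <- which.max(ant_vert)
  adj <- c(seed_v, if (seed_v == 1) k else seed_v - 1)  # edges touching seed vertex
  seed_e <- adj[which.max(ant_comp[adj])]
  seed_n <- nrm3[seed_e, ]
  ok <- as.numeric(nrm3 %*% seed_n) > cos(deg2rad(cone_deg)) & ant_comp > 0
  # grow contiguously from the seed edge in both directions
  sel <- rep(FALSE, k); sel[seed_e] <- TRUE
  i <- seed_e
  repeat { i <- if (i == k) 1 else i + 1; if (!ok[i] || sel[i]) break; sel[i] <- TRUE }
  i <- seed_e
  repeat { i <- if (i == 1) k else i - 1; if (!ok[i] || sel[i]) break; sel[i] <- TRUE }
  arc_len <- sum(len[sel])
  if (arc_len < min_arc)
    stop(sprintf("anterior wall not identifiable: arc %.1f mm < %.0f mm", arc_len, min_arc))
  vsel <- unique(c(which(sel), nxt[sel]))
  fit <- tlsLine2D(xy[vsel, , drop = FALSE])
  dir3 <- unitize(fit$direction[1] * B$e1 + fit$direction[2] * B$e2)
  apex <- P[vsel[which.max(ant_vert[vsel])], ]
  flat <- fit$rms <= flat_tol
  if (!flat)
    warning(sprintf("anterior wall deviates from flat (rms %.2f mm); tangent at apex returned", fit$rms))
  structure(line3d(apex, dir3), rms = fit$rms, flat = flat)
}

#' Measure a femur surface
#'
#' Runs the full pipeline: sphere fit of the head, narrowest neck section,
#' neck and shaft axes, simulated trochanteric cut, anterior-wall tangent,
#' anatomical frames, and the three projected angles. Anteversion is
#' measured on the axial view against the posterior condylar line
#' (projection along the measured shaft axis by default, or along the
#' tabletop longitudinal axis with `axial_view = "tabletop"`); the
#' neck-shaft angle on the tabletop AP view; the anterior-wall angle on the
#' ISB sagittal view. Anteversion is positive, retroversion negative; the
#' anterior-wall angle is positive when the wall line tilts anteriorly
#' going proximally.
#'
#' @param mesh a `triMesh`.
#' @param landmarks a `landmarkSet`.
#' @param scanner_axes 3x3 matrix of scanner (tabletop) anterior, proximal,
#'   lateral axes in mesh coordinates.
#' @param axial_view `"shaft"` (plane perpendicular to the measured shaft
#'   axis) or `"tabletop"` (scanner transverse plane).
#' @return An `angleSet` with a `diagnostics` list (sphere fit rms, neck
#'   iterations, cut tilt and thickness, wall flatness rms, and the
#'   axial-view convention difference in degrees).
#' @export
measureFemur <- function(mesh, landmarks, scanner_axes = diag(3),
                         axial_view = c("shaft", "tabletop")) {
  axial_view <- match.arg(axial_view)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  tabletop <- stage("tabletop_frame", buildTabletopFrame(landmarks, scanner_axes))

  comps <- stage("components", meshComponents(mesh))
  hint <- if (!is.null(landmarks$hip_center_hint)) landmarks$hip_center_hint else
    landmarks$lateral_ridge_GT + 40 * (-tabletop$lateral + tabletop$proximal) / sqrt(2)
  head_comp <- if (length(comps) > 1) {
    # the head is the shell that is spherical about a centre near the hint
    score <- vapply(comps, function(m) {
      f <- tryCatch(fitSphere(m$vertices), error = function(e) NULL)
      if (is.null(f) || vecNorm(f$center - hint) > 15) Inf else f$rms_residual
    }, 0)
    if (all(!is.finite(score))) stop("no spherical head shell found near the hip centre hint")
    comps[[which.min(score)]]
  } else comps[[1]]
  sph <- stage("fit_sphere", fitSphere(head_comp$vertices))

  level <- sum(landmarks$lesser_trochanter_base_point * tabletop$proximal)
  shaft <- stage("shaft_axis", shaftAxis(mesh, level, tabletop$proximal))
  prox_dir <- -shaft$direction

  # neck scan aims at the shaft axis just distal to the trochanteric tip
  ridge_station <- sum(landmarks$lateral_ridge_GT * tabletop$proximal)
  foot <- shaft$point + sum((sph$center - shaft$point) * shaft$direction) * shaft$direction
  target <- foot + (ridge_station - 15 - sum(foot * tabletop$proximal)) * prox_dir
  init_dir <- unitize(target - sph$center)
  neck <- stage("narrowest_neck_section",
                narrowestNeckSection(mesh, sph$center, init_dir,
                                     head_radius = sph$radius))
  naxis <- stage("neck_axis", neckAxis(sph$center, neck$midpoint))
  u <- -naxis$direction  # neck -> head

  medial_dir <- unitize(landmarks$medial_posterior_condyle -
                          landmarks$lateral_posterior_condyle)
  side <- if (sum(cross3(tabletop$anterior, tabletop$proximal) * -medial_dir) > 0)
    "right" else "left"

  isb <- stage("isb_frame", buildIsbFrame(landmarks, sph$center, side))
  cut <- stage("simulate_gt_cut",
               simulateGtCut(mesh, landmarks$lateral_ridge_GT, shaft, isb))
  wall <- stage("anterior_wall_line", anteriorWallLine(cut$contour, isb))
  wdir <- if (sum(wall$direction * isb$proximal) >= 0) wall$direction else -wall$direction

  condylar <- line3d(landmarks$lateral_posterior_condyle, medial_dir)
  fa_shaft <- projectedAngle(condylar, line3d(neck$midpoint, u),
                             view_normal = shaft$direction,
                             sign_reference = tabletop$anterior)
  fa_table <- projectedAngle(condylar, line3d(neck$midpoint, u),
                             view_normal = tabletop$proximal,
                             sign_reference = tabletop$anterior)
  fa <- if (axial_view == "shaft") fa_shaft else fa_table
  nsa <- abs(projectedAngle(line3d(shaft$point, shaft$direction),
                            line3d(neck$midpoint, u),
                            view_normal = tabletop$anterior,
                            sign_reference = medial_dir))
  aw <- projectedAngle(line3d(shaft$point, prox_dir), line3d(wall$point, wdir),
                       view_normal = isb$lateral,
                       sign_reference = isb$anterior)

  angleSet(fa = fa, nsa = nsa, aw = aw, side = side, diagnostics = list(
    head_center = sph$center, head_radius = sph$radius,
    sphere_rms = sph$rms_residual,
    neck_midpoint = neck$midpoint, neck_area = neck$area,
    neck_iterations = neck$iterations, neck_non_unique = neck$non_unique,
    cut_tilt_deg = cut$tilt_deg, cut_thickness = cut$thickness,
    wall_rms = attr(wall, "rms"), wall_flat = attr(wall, "flat"),
    fa_axial_view_delta = fa_shaft - fa_table))
}
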