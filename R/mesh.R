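# Triangulated surface container and the geometry kernel the measurement
# pipeline runs on: watertightness/orientation checks, connected components,
# rigid transforms, and plane cross-sections with closed contour chaining.

#' Triangulated surface mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices with
#'   consistent outward (counter-clockwise seen from outside) winding.
#' @param frame_label one of `"scanner"`, `"tabletop"`, `"ISB"`.
#' @param validate run structural checks (degenerate triangles, index range).
#' @return An object of class `triMesh`.
#' @export
triMesh <- function(vertices, faces, frame_label = "scanner", validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  frame_label <- match.arg(frame_label, c("scanner", "tabletop", "ISB"))
  if (validate) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range")
    a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    if (any(sqrt(rowSums(cr^2)) < 1e-10))
      stop("degenerate (zero-area) triangles present")
  }
  structure(list(vertices = vertices, faces = faces, frame_label = frame_label),
            class = "triMesh")
}

#' @export
print.triMesh <- function(x, ...) {
  cat(sprintf("triMesh: %d vertices, %d faces [%s frame]\n",
              nrow(x$vertices), nrow(x$faces), x$frame_label))
  invisible(x)
}

# Directed edge table (m*3 x 2) in face winding order.
meshDirectedEdges <- function(mesh) {
  f <- mesh$faces
  rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
}

#' Check watertightness and winding consistency
#'
#' A closed, consistently oriented surface has every undirected edge shared
#' by exactly two faces, traversed once in each direction. A mesh made of
#' several disjoint closed shells (as the phantom is) passes this check.
#'
#' @param mesh a `triMesh`.
#' @return TRUE/FALSE with attribute `"why"` describing the first failure.
#' @export
meshIsWatertight <- function(mesh) {
  e <- meshDirectedEdges(mesh)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2))
    return(structure(FALSE, why = "edge not shared by exactly 2 faces"))
  dkey <- paste(e[, 1], e[, 2])
  if (any(duplicated(dkey)))
    return(structure(FALSE, why = "inconsistent winding: repeated directed edge"))
  TRUE
}

#' Connected components of a mesh
#'
#' Faces are grouped by shared vertices. The phantom's analytic primitives
#' never share vertices, so each shell comes back as one component.
#'
#' @param mesh a `triMesh`.
#' @return List of `triMesh` objects (vertices subset and reindexed).
#' @export
meshComponents <- function(mesh) {
  g <- igraph::graph_from_edgelist(meshDirectedEdges(mesh), directed = FALSE)
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp[mesh$faces[, 1]])), function(ci) {
    vid <- which(comp == ci)
    remap <- integer(nrow(mesh$vertices))
    remap[vid] <- seq_along(vid)
    fsel <- comp[mesh$faces[, 1]] == ci
    triMesh(mesh$vertices[vid, , drop = FALSE],
            matrix(remap[mesh$faces[fsel, ]], ncol = 3),
            mesh$frame_label, validate = FALSE)
  })
}

#' Apply a rigid-body (or mirror) transform to a mesh
#'
#' @param mesh a `triMesh`.
#' @param rotation 3x3 matrix (orthogonal; improper allowed for mirroring,
#'   in which case face winding is flipped to keep outward orientation).
#' @param translation length-3 vector, mm.
#' @return Transformed `triMesh`.
#' @export
transformMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  f <- mesh$faces
  if (det(rotation) < 0) f <- f[, c(1, 3, 2)]
  triMesh(v, f, mesh$frame_label, validate = FALSE)
}

# Enclosed volume via divergence theorem; positive for outward winding.
meshVolume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# Distance from a point to the nearest mesh wireframe edge (a surface-
# distance proxy that is exact on points lying on edges and much tighter
# than vertex distance on coarsely triangulated flat faces).
pointMeshEdgeDistance <- function(mesh, point) {
  e <- meshDirectedEdges(mesh)
  a <- mesh$vertices[e[, 1], , drop = FALSE]
  b <- mesh$vertices[e[, 2], , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, point, `+`)
  t <- pmin(1, pmax(0, rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-12)))
  d2 <- rowSums((ap - ab * t)^2)
  sqrt(min(d2))
}

# Merge meshes without welding vertices (disjoint shells).
mergeMeshes <- function(..., frame_label = "scanner") {
  ms <- list(...)
  offs <- cumsum(c(0, vapply(ms, function(m) nrow(m$vertices), 0)))
  triMesh(do.call(rbind, lapply(ms, `[[`, "vertices")),
          do.call(rbind, Map(function(m, o) m$faces + o, ms, offs[-length(offs)])),
          frame_label, validate = FALSE)
}

# -- primitives --------------------------------------------------------------

# Closed UV sphere; vertices exactly on the sphere. Outward winding.
uvSphereMesh <- function(center, radius, n_theta = 24, n_phi = 36) {
  th <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(phi = ph, theta = th)
  ring <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta)) * radius
  vtop <- c(0, 0, radius); vbot <- c(0, 0, -radius)
  V <- rbind(vtop, ring, vbot)
  V <- sweep(V, 2, center, `+`)
  idx <- function(i, j) 1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1  # ring i, slot j
  F <- list()
  # top fan: theta increases away from +z pole
  for (j in 1:n_phi) F[[length(F) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in 1:(n_theta - 2)) for (j in 1:n_phi) {
    a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j + 1); d <- idx(i + 1, j)
    F[[length(F) + 1]] <- c(a, d, c2)
    F[[length(F) + 1]] <- c(a, c2, b)
  }
  nb <- nrow(V)
  for (j in 1:n_phi) F[[length(F) + 1]] <- c(nb, idx(n_theta - 1, j + 1), idx(n_theta - 1, j))
  m <- triMesh(V, do.call(rbind, F), validate = FALSE)
  if (meshVolume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Closed surface of revolution about an arbitrary axis with end caps.
# stations: distances along the axis from axis_point; radii: matching radii.
revolutionMesh <- function(axis_point, axis_dir, stations, radii, n_seg = 48) {
  stopifnot(length(stations) == length(radii), length(stations) >= 2,
            all(radii > 0))
  B <- planeBasis(axis_dir)
  ph <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  nr <- length(stations)
  rings <- lapply(seq_len(nr), function(i) {
    ctr <- axis_point + stations[i] * B$n
    t(ctr + outer(B$e1, radii[i] * cos(ph)) + outer(B$e2, radii[i] * sin(ph)))
  })
  V <- do.call(rbind, rings)
  c0 <- axis_point + stations[1] * B$n
  c1 <- axis_point + stations[nr] * B$n
  V <- rbind(V, c0, c1)
  i0 <- nr * n_seg + 1; i1 <- nr * n_seg + 2
  idx <- function(i, j) (i - 1) * n_seg + ((j - 1) %% n_seg) + 1
  F <- list()
  for (i in 1:(nr - 1)) for (j in 1:n_seg) {
    a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j + 1); d <- idx(i + 1, j)
    F[[length(F) + 1]] <- c(a, b, c2)
    F[[length(F) + 1]] <- c(a, c2, d)
  }
  for (j in 1:n_seg) {
    F[[length(F) + 1]] <- c(i0, idx(1, j + 1), idx(1, j))       # start cap
    F[[length(F) + 1]] <- c(i1, idx(nr, j), idx(nr, j + 1))     # end cap
  }
  m <- triMesh(V, do.call(rbind, F), validate = FALSE)
  if (meshVolume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Closed hexahedral block from 8 corner points. Corners given as a list:
# bottom quad (b1..b4 counter-clockwise seen from below -> outward), top quad
# (t1..t4 matching order above b1..b4). Planar faces assumed.
hexBlockMesh <- function(bottom, top) {
  V <- rbind(bottom, top)  # 1:4 bottom, 5:8 top
  quads <- list(c(4, 3, 2, 1),       # bottom (outward = down)
                c(5, 6, 7, 8),       # top
                c(1, 2, 6, 5), c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  F <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  m <- triMesh(V, F, validate = FALSE)
  if (meshVolume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# -- plane cross-sections ----------------------------------------------------

#' Cross-section contours of a mesh with a plane
#'
#' Intersects every triangle with the plane and chains the resulting
#' segments into closed loops. Vertices lying numerically on the plane are
#' nudged by a tiny epsilon so every intersection is transversal.
#'
#' @param mesh a `triMesh`.
#' @param plane a `plane3d`.
#' @return List of loops; each loop is a list with `points` (k x 3 matrix of
#'   ordered contour vertices), `points2d` (k x 2 in-plane coordinates),
#'   `area` (mm^2, positive), `centroid` (length-3, mm), and `basis`.
#' @export
crossSectionMesh <- function(mesh, plane) {
  v <- mesh$vertices
  d <- as.numeric(sweep(v, 2, plane$point) %*% plane$normal)
  eps <- 1e-9 * max(1, max(abs(d)))
  d[d == 0] <- eps
  f <- mesh$faces
  s1 <- d[f[, 1]]; s2 <- d[f[, 2]]; s3 <- d[f[, 3]]
  cut <- !(sign(s1) == sign(s2) & sign(s2) == sign(s3))
  if (!any(cut)) return(list())
  f <- f[cut, , drop = FALSE]
  # for each cut triangle find the two crossing edges
  edgePoint <- function(i, j, di, dj) {
    t <- di / (di - dj)
    v[i, , drop = FALSE] + t * (v[j, , drop = FALSE] - v[i, , drop = FALSE])
  }
  segs_a <- matrix(0, nrow(f), 3); segs_b <- matrix(0, nrow(f), 3)
  key_a <- character(nrow(f)); key_b <- character(nrow(f))
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]; dd <- d[tri]
    crossing <- list()
    pairs <- list(c(1, 2), c(2, 3), c(3, 1))
    for (p in pairs) {
      if (sign(dd[p[1]]) != sign(dd[p[2]])) {
        i <- tri[p[1]]; j <- tri[p[2]]
        crossing[[length(crossing) + 1]] <-
          list(pt = edgePoint(i, j, dd[p[1]], dd[p[2]]),
               key = paste(min(i, j), max(i, j)))
      }
    }
    segs_a[r, ] <- crossing[[1]]$pt; key_a[r] <- crossing[[1]]$key
    segs_b[r, ] <- crossing[[2]]$pt; key_b[r] <- crossing[[2]]$key
  }
  # chain segments into loops via shared cut-edge keys
  loops <- list()
  used <- rep(FALSE, nrow(f))
  edge_map <- new.env(hash = TRUE)
  addmap <- function(k, r) assign(k, c(if (exists(k, edge_map)) get(k, edge_map), r), edge_map)
  for (r in seq_len(nrow(f))) { addmap(key_a[r], r); addmap(key_b[r], r) }
  B <- planeBasis(plane$normal)
  while (any(!used)) {
    r0 <- which(!used)[1]
    pts <- list(); keys_seq <- character()
    r <- r0; enter_key <- key_a[r0]
    repeat {
      used[r] <- TRUE
      out_key <- if (enter_key == key_a[r]) key_b[r] else key_a[r]
      out_pt <- if (enter_key == key_a[r]) segs_b[r, ] else segs_a[r, ]
      pts[[length(pts) + 1]] <- out_pt
      cands <- setdiff(get(out_key, edge_map), r)
      cands <- cands[!used[cands]]
      if (length(cands) == 0) break
      r <- cands[1]; enter_key <- out_key
    }
    P <- do.call(rbind, pts)
    if (nrow(P) < 3) next
    rel <- sweep(P, 2, plane$point)
    xy <- cbind(rel %*% B$e1, rel %*% B$e2)
    ac <- polygonAreaCentroid2D(xy)
    if (abs(ac$area) < 1e-8) next
    if (ac$area < 0) {  # store counter-clockwise in (e1, e2)
      P <- P[nrow(P):1, , drop = FALSE]
      xy <- xy[nrow(xy):1, , drop = FALSE]
      ac$area <- -ac$area
    }
    centroid3 <- plane$point + ac$centroid[1] * B$e1 + ac$centroid[2] * B$e2
    loops[[length(loops) + 1]] <- list(points = P, points2d = xy,
                                       area = ac$area, centroid = centroid3,
                                       basis = B)
  }
  loops
}
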