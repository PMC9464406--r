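# Shared I/O: STL (binary and ascii) and PLY (ascii) mesh readers/writers,
# landmark JSON, angle-set CSV, run configuration and the end-to-end
# pipeline driver.

#' Write a mesh to STL or PLY
#'
#' Format chosen from the file extension: `.stl` (binary by default, ascii
#' optional) or `.ply` (ascii).
#'
#' @param mesh a `triMesh`.
#' @param path output file path.
#' @param ascii write ascii STL instead of binary.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  nrm <- faceNormals(mesh)
  if (ext == "stl") {
    if (ascii) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid femur", con)
      for (i in seq_len(nrow(f))) {
        writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                     "    outer loop",
                     sprintf("      vertex %.9g %.9g %.9g",
                             v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                     "    endloop", "  endfacet"), con)
      }
      writeLines("endsolid femur", con)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      writeBin(as.raw(rep(0, 80)), con)
      writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4,
                 endian = "little")
        writeBin(as.integer(0), con, size = 2, endian = "little")
      }
    }
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

faceNormals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-12)
}

#' Read a mesh from STL or PLY
#'
#' STL dialect (ascii vs binary) is auto-detected. STL facets are welded
#' back into a shared-vertex mesh; the result is validated (finite
#' coordinates, no degenerate triangles) and its watertightness recorded.
#'
#' @param path mesh file path.
#' @param frame_label frame annotation for the returned mesh.
#' @return A `triMesh` with attribute `"watertight"`.
#' @export
readMesh <- function(path, frame_label = "scanner") {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    hdr <- readBin(path, "raw", n = 5)
    is_ascii <- identical(rawToChar(hdr), "solid") && {
      txt <- tryCatch(readLines(path, n = 10, warn = FALSE), error = function(e) "")
      any(grepl("facet", txt))
    }
    if (is_ascii) {
      txt <- readLines(path, warn = FALSE)
      vl <- grep("^\\s*vertex", txt, value = TRUE)
      if (length(vl) == 0 || length(vl) %% 3 != 0)
        stop("malformed ascii STL: vertex count not a multiple of 3")
      tri <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))[c(FALSE, TRUE, TRUE, TRUE)]),
                    ncol = 3, byrow = TRUE)
    } else {
      sz <- file.size(path)
      con <- file(path, "rb")
      on.exit(close(con))
      readBin(con, "raw", n = 80)
      nf <- readBin(con, "integer", size = 4, endian = "little")
      if (is.na(nf) || nf <= 0 || 84 + 50 * nf > sz)
        stop("malformed or truncated binary STL")
      tri <- matrix(NA_real_, nf * 3, 3)
      for (i in seq_len(nf)) {
        rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
        if (length(rec) < 12) stop("truncated binary STL facet record")
        tri[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
        readBin(con, "integer", n = 1, size = 2, endian = "little")
      }
    }
    key <- apply(round(tri, 9), 1, paste, collapse = ",")
    uid <- !duplicated(key)
    vmap <- match(key, key[uid])
    mesh <- triMesh(tri[uid, , drop = FALSE],
                    matrix(vmap, ncol = 3, byrow = TRUE), frame_label)
  } else if (ext == "ply") {
    txt <- readLines(path, warn = FALSE)
    endh <- which(txt == "end_header")
    if (length(endh) != 1) stop("malformed PLY: no end_header")
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)))
    if (length(txt) < endh + nv + nf) stop("truncated PLY file")
    v <- matrix(as.numeric(unlist(strsplit(txt[(endh + 1):(endh + nv)], "\\s+"))),
                ncol = 3, byrow = TRUE)
    frows <- strsplit(txt[(endh + nv + 1):(endh + nv + nf)], "\\s+")
    f <- t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
    mesh <- triMesh(v, f, frame_label)
  } else stop("unsupported mesh format: ", ext)
  attr(mesh, "watertight") <- isTRUE(meshIsWatertight(mesh))
  mesh
}

#' Write landmarks to JSON
#'
#' @param landmarks a `landmarkSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(unclass(landmarks), as.numeric), path,
                       auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path JSON file with named 3-vectors.
#' @return A `landmarkSet`.
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("lateral_ridge_GT", "lesser_trochanter_base_point",
                "medial_posterior_condyle", "lateral_posterior_condyle",
                "epicondyle_midpoint")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing required landmark(s): ", paste(missing, collapse = ", "))
  landmarkSet(lateral_ridge_GT = raw$lateral_ridge_GT,
              lesser_trochanter_base_point = raw$lesser_trochanter_base_point,
              medial_posterior_condyle = raw$medial_posterior_condyle,
              lateral_posterior_condyle = raw$lateral_posterior_condyle,
              epicondyle_midpoint = raw$epicondyle_midpoint,
              hip_center_hint = raw$hip_center_hint)
}

#' Write angle sets to CSV
#'
#' Deterministic column order with a schema-version header comment.
#'
#' @param angles a single `angleSet` or a list of them.
#' @param path output CSV path.
#' @param ids optional hip identifiers.
#' @return The written `data.frame`, invisibly.
#' @export
writeAngles <- function(angles, path, ids = NULL) {
  if (inherits(angles, "angleSet")) angles <- list(angles)
  if (is.null(ids)) ids <- seq_along(angles)
  df <- data.frame(
    hip_id = ids,
    side = vapply(angles, `[[`, "", "side"),
    fa_deg = vapply(angles, `[[`, 0, "fa"),
    nsa_deg = vapply(angles, `[[`, 0, "nsa"),
    aw_deg = vapply(angles, `[[`, 0, "aw"))
  con <- file(path, "w")
  writeLines("# femora angle table v1", con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(df)
}

#' Read an angle CSV written by [writeAngles()]
#'
#' @param path CSV path.
#' @return A `data.frame` with one row per hip.
#' @export
readAngles <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run configuration
#'
#' @param mode `"grid"` (phantom grid, measured and compared to ground
#'   truth) or `"cohort"` (simulated cohort, analysed).
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory.
#' @param n_hips cohort size (cohort mode).
#' @param fa_grid,aw_grid,nsa_grid dial grids (grid mode), degrees.
#' @param mesh_resolution phantom resolution class.
#' @param angle_tol,length_tol reporting tolerances (degrees, mm).
#' @param axial_view axial-view convention for anteversion.
#' @return An object of class `runConfig`.
#' @export
runConfig <- function(mode = c("cohort", "grid"), seed = 1L,
                      out_dir = tempfile("femora-run-"),
                      n_hips = 100,
                      fa_grid = c(-10, 0, 10, 20, 30, 38),
                      aw_grid = c(0, 10, 17.5, 30, 42.5),
                      nsa_grid = c(116.6, 127.3, 143.2),
                      mesh_resolution = "coarse",
                      angle_tol = 0.5, length_tol = 0.1,
                      axial_view = "shaft") {
  mode <- match.arg(mode)
  stopifnot(angle_tol > 0, length_tol > 0)
  structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                 n_hips = n_hips, fa_grid = fa_grid, aw_grid = aw_grid,
                 nsa_grid = nsa_grid, mesh_resolution = mesh_resolution,
                 angle_tol = angle_tol, length_tol = length_tol,
                 axial_view = axial_view), class = "runConfig")
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # analytic configuration only, not I/O placement
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Grid mode builds a phantom for every dial combination, measures it, and
#' writes per-femur measured vs ground-truth angles. Cohort mode simulates
#' a cohort, runs the statistical analysis (group summaries, forced-entry
#' regression, diagnostics) and writes the results bundle. Every output
#' directory gets a provenance log with the seed and config hash.
#'
#' @param config a `runConfig`.
#' @return List of result objects (also written under `config$out_dir`).
#' @export
runEndToEnd <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config_hash = configHash(config))
  if (config$mode == "grid") {
    grid <- expand.grid(fa = config$fa_grid, aw = config$aw_grid,
                        nsa = config$nsa_grid)
    res <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      ph <- buildPhantom(phantomSpec(
        true_anteversion = grid$fa[i], true_aw_angle = grid$aw[i],
        true_neck_shaft_angle = grid$nsa[i],
        mesh_resolution = config$mesh_resolution, seed = config$seed))
      m <- measureFemur(ph$mesh, ph$landmarks, axial_view = config$axial_view)
      res[[i]] <- data.frame(fa_true = grid$fa[i], aw_true = grid$aw[i],
                             nsa_true = grid$nsa[i], fa = m$fa, aw = m$aw,
                             nsa = m$nsa)
    }
    tab <- do.call(rbind, res)
    tab$fa_err <- tab$fa - tab$fa_true
    tab$aw_err <- tab$aw - tab$aw_true
    tab$nsa_err <- tab$nsa - tab$nsa_true
    utils::write.csv(tab, file.path(config$out_dir, "grid_recovery.csv"),
                     row.names = FALSE)
    out$grid <- tab
  } else {
    params <- cohortParams(n_hips = config$n_hips, seed = config$seed)
    cohort <- simulateCohort(params)
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    fit <- olsForced(cohort$fa, cohort$aw, cohort$sex_code)
    model <- makePredictionModel(fit)
    male <- cohort$sex == "male"
    summaries <- data.frame(
      parameter = c("Femoral anteversion angle", "Anterior wall angle",
                    "Femoral neck-shaft angle"),
      males = c(groupCompare(cohort$fa[male], cohort$fa[!male])$summary_a,
                groupCompare(cohort$aw[male], cohort$aw[!male])$summary_a,
                groupCompare(cohort$nsa[male], cohort$nsa[!male])$summary_a),
      females = c(groupCompare(cohort$fa[male], cohort$fa[!male])$summary_b,
                  groupCompare(cohort$aw[male], cohort$aw[!male])$summary_b,
                  groupCompare(cohort$nsa[male], cohort$nsa[!male])$summary_b),
      p_value = c(groupCompare(cohort$fa[male], cohort$fa[!male])$p_display,
                  groupCompare(cohort$aw[male], cohort$aw[!male])$p_display,
                  groupCompare(cohort$nsa[male], cohort$nsa[!male])$p_display))
    utils::write.csv(summaries, file.path(config$out_dir, "sex_summaries.csv"),
                     row.names = FALSE)
    reg <- data.frame(variable = c("Constant", "Anterior wall angle", "Sex"),
                      B = fit$coef, SE_B = fit$se, beta = fit$std_beta,
                      p = fit$p_values, ci_lower = fit$ci95[, 1],
                      ci_upper = fit$ci95[, 2])
    utils::write.csv(reg, file.path(config$out_dir, "regression_table.csv"),
                     row.names = FALSE)
    diagnostics <- list(
      n = nrow(cohort), r_squared = fit$r_squared,
      adj_r_squared = fit$adj_r_squared, f_stat = fit$f_stat,
      f_df = fit$f_df, durbin_watson = fit$durbin_watson,
      n_outliers = sum(fit$outlier_flags),
      shapiro_fa = normalityGate(cohort$fa)$p,
      shapiro_aw = normalityGate(cohort$aw)$p,
      error_gt10_fraction = errorGt10Fraction(cohort, model),
      prediction_model = model$rounded)
    jsonlite::write_json(diagnostics, file.path(config$out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    out$cohort <- cohort; out$fit <- fit; out$model <- model
    out$summaries <- summaries; out$diagnostics <- diagnostics
  }
  jsonlite::write_json(list(seed = config$seed, config_hash = out$config_hash,
                            timestamp = format(Sys.time(), tz = "UTC"),
                            package_version = tryCatch(
                              as.character(utils::packageVersion("femora")),
                              error = function(e) NA_character_)),
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  out
}
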