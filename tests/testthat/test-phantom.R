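# Phantom generator: ground truth, determinism, watertightness across the
# dial space, landmark consistency.

test_that("ground-truth angles echo the construction dials", {
  gt <- groundTruthAngles(phantomSpec(true_anteversion = 14.8,
                                      true_neck_shaft_angle = 127.3,
                                      true_aw_angle = 17.5))
  expect_equal(gt$fa, 14.8)
  expect_equal(gt$nsa, 127.3)
  expect_equal(gt$aw, 17.5)
  gt2 <- groundTruthAngles(phantomSpec(true_anteversion = -12.1))
  expect_equal(gt2$fa, -12.1)
  gt0 <- groundTruthAngles(phantomSpec(true_anteversion = 0, true_aw_angle = 0,
                                       true_neck_shaft_angle = 127.3))
  expect_equal(gt0$fa, 0)
  expect_equal(gt0$aw, 0)
  expect_equal(gt0$nsa, 127.3)
})

test_that("zero-dial construction aligns neck and wall with canonical axes", {
  ph <- buildPhantom(phantomSpec(true_anteversion = 0, true_aw_angle = 0,
                                 mesh_resolution = "coarse"))
  u <- femora:::neckDirectionFromDials(0, 127.3)
  expect_equal(u[1], 0)  # no anterior component: parallel to condylar plane
  m <- measureFemur(ph$mesh, ph$landmarks)
  expect_lt(abs(m$fa), 0.2)
  expect_lt(abs(m$aw), 0.2)  # wall parallel to shaft axis
})

test_that("identical spec and seed give byte-identical meshes", {
  s <- phantomSpec(seed = 11, vertex_jitter_sd = 0.05, mesh_resolution = "coarse")
  a <- buildPhantom(s); b <- buildPhantom(s)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  # jitter never touches the analytic ground truth
  expect_equal(a$truth$fa, 14.8)
})

test_that("spec invariants are enforced", {
  expect_error(phantomSpec(true_neck_shaft_angle = 100), "neck-shaft")
  expect_error(phantomSpec(true_anteversion = 50), "anteversion")
  expect_error(phantomSpec(true_aw_angle = -10), "anterior-wall")
  expect_error(phantomSpec(head_radius = 10, neck_narrowest_diameter = 28),
               "waist")
})

test_that("meshes are watertight across a sampled grid of specs", {
  set.seed(1)
  dials <- cbind(fa = runif(50, -20, 45), nsa = runif(50, 110, 150),
                 aw = runif(50, -5, 45))
  ok <- apply(dials, 1, function(d) {
    ph <- buildPhantom(phantomSpec(true_anteversion = d[1],
                                   true_neck_shaft_angle = d[2],
                                   true_aw_angle = d[3],
                                   mesh_resolution = "coarse"))
    isTRUE(meshIsWatertight(ph$mesh))
  })
  expect_true(all(ok))
})

test_that("landmarks lie within the mesh bounding box", {
  ph <- defaultPhantom()
  lo <- apply(ph$mesh$vertices, 2, min) - 1
  hi <- apply(ph$mesh$vertices, 2, max) + 1
  for (nm in c("lateral_ridge_GT", "lesser_trochanter_base_point",
               "medial_posterior_condyle", "lateral_posterior_condyle",
               "epicondyle_midpoint")) {
    p <- ph$landmarks[[nm]]
    expect_true(all(p >= lo & p <= hi), label = nm)
  }
})

test_that("infeasible geometry raises a construction error, not a bad mesh", {
  # a waist nearly as wide as the head cannot attach
  expect_error(buildPhantom(phantomSpec(head_radius = 15,
                                        neck_narrowest_diameter = 29)),
               "attach")
})
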