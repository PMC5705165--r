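test_that("cut-cell mesh volume matches the polygon area to round-off", {
  cv <- circle_curve(1, n = 512)
  mesh <- build_mesh(cv, 0.1)
  expect_equal(mesh$area, enclosed_area(cv), tolerance = 1e-12)
  expect_equal(mesh$area, pi, tolerance = 1e-2) # within 1% of the disk
  # group volumes are positive, volume fractions in [0, 1]
  expect_true(all(mesh$gvol > 0))
  expect_true(all(mesh$f >= 0 & mesh$f <= 1))
})

test_that("grid-aligned square gives exact volumes and apertures", {
  # h = 0.25 and the square [0.25, 1.25]^2 are binary-exact
  sq <- rect_curve(0.25, 1.25, 0.25, 1.25, nx = 9, ny = 9)
  mesh <- build_mesh(sq, 0.25)
  expect_equal(mesh$area, 1, tolerance = 1e-13)
  inside <- mesh$grp > 0
  expect_true(all(abs(mesh$f[inside] - 1) < 1e-13))
  expect_true(all(mesh$faper > 1 - 1e-13))
})

test_that("mesh construction rejects unresolvable curves", {
  expect_error(build_mesh(circle_curve(0.3, n = 64), 0.4), "decrease h")
  expect_error(build_mesh(circle_curve(1, n = 64), 0.005), "0.01")
})

test_that("boundary extrapolation is exact for constant and affine fields", {
  cv <- circle_curve(1, n = 512)
  mesh <- build_mesh(cv, 0.1)
  pts <- cv$markers[seq(1, 512, by = 16), ]
  nrm <- outward_normals(cv)[seq(1, 512, by = 16), ]
  for (method in c("ls", "bilinear")) {
    v3 <- extrapolate_to_boundary(mesh, rep(3, mesh$G), pts, nrm, method)
    expect_equal(as.numeric(v3), rep(3, nrow(pts)), tolerance = 1e-12)
    aff <- mesh$gcx + 2 * mesh$gcy
    va <- extrapolate_to_boundary(mesh, aff, pts, nrm, method)
    expect_equal(as.numeric(va), pts[, 1] + 2 * pts[, 2], tolerance = 1e-10)
  }
})

test_that("boundary extrapolation of x^2 refines at second order", {
  cv <- circle_curve(1, n = 1024)
  pts <- cv$markers[seq(1, 1024, by = 32), ]
  nrm <- outward_normals(cv)[seq(1, 1024, by = 32), ]
  errs <- sapply(c(0.1, 0.05), function(h) {
    mesh <- build_mesh(cv, h)
    for (method in "ls") {
      v <- extrapolate_to_boundary(mesh, mesh$gcx^2, pts, nrm, method)
    }
    max(abs(as.numeric(v) - pts[, 1]^2))
  })
  expect_gt(errs[1] / errs[2], 2.5) # ratio ~ 4 for a second-order scheme
})

test_that("extrapolation falls back to nearest cell where no stencil fits", {
  # a strip one cell high has no fully interior 2x2 block
  cv <- rect_curve(0.003, 2.003, 0.003, 0.303, nx = 128, ny = 24)
  mesh <- build_mesh(cv, 0.14)
  pts <- cv$markers[c(10, 40, 70), ]
  nrm <- outward_normals(cv)[c(10, 40, 70), ]
  v <- extrapolate_to_boundary(mesh, rep(1, mesh$G), pts, nrm, "bilinear")
  expect_gt(attr(v, "n_fallback"), 0)
  expect_equal(as.numeric(v), rep(1, 3))
})

test_that("mass transfer is the identity on a fixed mesh", {
  cv <- circle_curve(1, n = 256)
  mesh <- build_mesh(cv, 0.12)
  set.seed(1)
  m <- runif(mesh$G, 0.5, 2)
  tr <- transfer_mass(m, mesh, mesh)
  expect_equal(tr$m, m, tolerance = 1e-14)
})

test_that("mass transfer conserves mass exactly under boundary motion", {
  set.seed(42)
  cv <- circle_curve(1, n = 256)
  mesh <- build_mesh(cv, 0.12)
  m <- runif(mesh$G, 0, 3)
  total <- total_mass(mesh, m)
  for (k in 1:5) {
    th <- atan2(cv$markers[, 2], cv$markers[, 1])
    wig <- 0.04 * sin(3 * th + k) + 0.03 * runif(1)
    cv2 <- boundary_curve(cv$markers * (1 + wig),
                          target_spacing = cv$target_spacing)
    mesh2 <- build_mesh(cv2, 0.12)
    tr <- transfer_mass(m, mesh, mesh2)
    expect_lt(abs(sum(tr$mass) - total), 1e-12 * total)
    cv <- cv2; mesh <- mesh2; m <- tr$m; total <- sum(tr$mass)
  }
})

test_that("uniform fields stay uniform and conserved under transfer", {
  cv <- circle_curve(1, n = 256)
  mesh <- build_mesh(cv, 0.16)
  m <- rep(2, mesh$G)
  cv2 <- boundary_curve(cv$markers * 1.02, target_spacing = cv$target_spacing)
  mesh2 <- build_mesh(cv2, 0.16)
  tr <- transfer_mass(m, mesh, mesh2)
  expect_lt(abs(sum(tr$mass) - 2 * mesh$area), 1e-12)
  # donor redistribution cannot overshoot the uniform density, and cells
  # interior to both meshes keep it exactly (newly wetted rim cells start
  # empty; the transport solve refills them)
  expect_true(all(tr$m <= 2 + 1e-12))
  both <- mesh$grp > 0 & mesh$f > 0.999999 & mesh2$f > 0.999999
  expect_equal(tr$m[mesh2$grp[both]], rep(2, sum(both)), tolerance = 1e-13)
})
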