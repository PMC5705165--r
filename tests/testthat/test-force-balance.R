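test_that("uniform myosin under ZV gives the trivial zero flow", {
  mesh <- build_mesh(circle_curve(1, n = 256), 0.1)
  p <- motility_params("ZV", alpha = 0.5, beta = 5, mu_tot = pi, g = 0)
  u <- solve_force_balance(mesh, rep(1, mesh$G), p)
  expect_lt(max(abs(c(u$ux, u$uy))), 1e-12)
  expect_lt(u$residual, 1e-10)
})

test_that("1D slab with linear myosin matches the closed-form profile", {
  alpha <- 0.1; beta <- 2; cs <- 0.8; x0 <- 0.0037
  cv <- rect_curve(x0, x0 + 1, 0, 4, nx = 80, ny = 320)
  errs <- sapply(c(0.1, 0.05), function(h) {
    mesh <- build_mesh(cv, h)
    p <- motility_params("ZV", alpha = alpha, beta = beta, mu_tot = 1)
    m <- 1 + cs * (mesh$gcx - x0 - 0.5)
    u <- solve_force_balance(mesh, m, p)
    sel <- abs(mesh$gcy - 2) < 0.5 # mid-height band, away from the end caps
    ex <- oracle_slab_u(mesh$gcx[sel] - x0, alpha, beta, cs)
    max(abs(u$ux[sel] - ex)) / max(abs(ex))
  })
  expect_lt(errs[1], 0.03)
  expect_lt(errs[2], 0.01)
  expect_gt(errs[1] / errs[2], 2) # refinement improves the profile
})

test_that("ZS on a disk with uniform myosin drives inward rim flow matching the radial oracle", {
  mesh <- build_mesh(circle_curve(1, n = 512), 0.1)
  p <- motility_params("ZS", alpha = 0.5, beta = 5, mu_tot = pi, g = 0)
  u <- solve_force_balance(mesh, rep(1, mesh$G), p)
  r <- sqrt(mesh$gcx^2 + mesh$gcy^2)
  ur <- (u$ux * mesh$gcx + u$uy * mesh$gcy) / pmax(r, 1e-12)
  rim <- r > 0.8
  expect_true(all(ur[rim] < 0)) # centripetal at the rim
  sel <- r > 0.05 & r < 0.92
  ex <- oracle_zs_radial(r[sel], p$alpha, p$beta, 1)
  expect_lt(max(abs(ur[sel] - ex)) / max(abs(ex)), 0.015)
})

test_that("the force balance operator is linear in myosin", {
  mesh <- build_mesh(circle_curve(1, n = 256), 0.12)
  p <- motility_params("ZS", alpha = 0.5, beta = 5, mu_tot = pi)
  set.seed(3)
  m1 <- runif(mesh$G, 0, 2)
  m2 <- runif(mesh$G, 0, 2)
  u1 <- solve_force_balance(mesh, m1, p)
  u2 <- solve_force_balance(mesh, m2, p)
  u12 <- solve_force_balance(mesh, m1 + m2, p)
  expect_equal(u12$ux, u1$ux + u2$ux, tolerance = 1e-10)
  expect_equal(u12$uy, u1$uy + u2$uy, tolerance = 1e-10)
})

test_that("rescaling (beta, m) -> (beta/c, c m) leaves the flow unchanged", {
  mesh <- build_mesh(circle_curve(1, n = 256), 0.12)
  set.seed(4)
  m <- runif(mesh$G, 0, 2)
  for (variant in c("ZS", "ZV")) {
    p1 <- motility_params(variant, alpha = 0.5, beta = 5, mu_tot = pi)
    p2 <- motility_params(variant, alpha = 0.5, beta = 2.5, mu_tot = pi)
    u1 <- solve_force_balance(mesh, m, p1)
    u2 <- solve_force_balance(mesh, 2 * m, p2)
    expect_equal(u1$ux, u2$ux, tolerance = 1e-12)
    expect_equal(u1$uy, u2$uy, tolerance = 1e-12)
  }
})

test_that("the disk solve is equivariant under quarter-turn rotation", {
  mesh <- build_mesh(circle_curve(1, n = 512), 0.1)
  p <- motility_params("ZS", alpha = 0.5, beta = 5, mu_tot = pi)
  u1 <- solve_force_balance(mesh, 2 + mesh$gcx, p) # m = 2 + x
  u2 <- solve_force_balance(mesh, 2 + mesh$gcy, p) # the rotated field
  key <- function(x, y) paste(round(x, 9), round(y, 9))
  idx <- match(key(-mesh$gcy, mesh$gcx), key(mesh$gcx, mesh$gcy))
  interior <- sqrt(mesh$gcx^2 + mesh$gcy^2) < 0.7 & !is.na(idx)
  scale <- max(abs(c(u1$ux, u1$uy)))
  # small-cell merge tie-breaks differ between orientations, so the match is
  # within discretization error rather than exact
  expect_lt(max(abs(u2$uy[idx[interior]] - u1$ux[interior])) / scale, 0.02)
  expect_lt(max(abs(u2$ux[idx[interior]] + u1$uy[interior])) / scale, 0.02)
})
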