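test_that("closed-form tensors reduce to textbook limits", {
  # ellipsoid with equal semi-axes is a sphere: all diagonals 2/5 m r^2
  sph <- geometric_solid("ellipsoid",
                         list(semi_x = 0.1, semi_y = 0.1, semi_z = 0.1),
                         density = 1000)
  si <- solid_inertia(sph)
  expect_equal(unname(si$tensor$I),
               rep(2 / 5 * si$mass * 0.1^2, 3), tolerance = 1e-12)

  # frustum with equal radii is a cylinder: axial moment m r^2 / 2
  fr <- geometric_solid("conical_frustum",
                        list(radius_prox = 0.04, radius_dist = 0.04,
                             length = 0.3), density = 950)
  cyl <- geometric_solid("cylinder", list(radius = 0.04, length = 0.3),
                         density = 950)
  fi <- solid_inertia(fr); ci <- solid_inertia(cyl)
  expect_equal(fi$mass, ci$mass, tolerance = 1e-12)
  expect_equal(fi$tensor$I[["zz"]], fi$mass * 0.04^2 / 2, tolerance = 1e-12)
  expect_equal(unname(fi$tensor$I), unname(ci$tensor$I), tolerance = 1e-10)
  expect_equal(fi$com, ci$com, tolerance = 1e-12)
})

test_that("voxel oracle matches closed forms for a cone", {
  s <- geometric_solid("cone", list(radius = 0.05, length = 0.2),
                       density = 1000)
  a <- solid_inertia(s)
  n <- numeric_inertia(s, 200)
  expect_equal(n$mass, a$mass, tolerance = 0.005)
  expect_equal(unname(n$tensor$I), unname(a$tensor$I), tolerance = 0.005)
  expect_equal(n$com[3], a$com[3], tolerance = 0.005 * s$dimensions$length)
})

test_that("voxel oracle self-checks: box moment and sphere", {
  # near-degenerate frustum approximating a cylinder reproduces m r^2/2
  sph <- geometric_solid("ellipsoid",
                         list(semi_x = 0.1, semi_y = 0.1, semi_z = 0.1),
                         density = 1000)
  n <- numeric_inertia(sph, 200)
  expect_equal(unname(n$tensor$I), rep(2 / 5 * n$mass * 0.1^2, 3),
               tolerance = 0.01)
  # mass from integration vs analytic volume x density
  for (shape in solid_shapes) {
    s <- random_solid(shape, seed = 99)
    n <- numeric_inertia(s, 200)
    expect_equal(n$mass, s$density * solid_volume(s), tolerance = 0.005)
  }
  expect_error(numeric_inertia(sph, 20), "resolution")
})

test_that("closed forms agree with the voxel oracle across random solids", {
  # reduced sweep here; the full 100-per-shape sweep runs in the acceptance
  # suite
  for (shape in solid_shapes) {
    for (seed in 1:10) {
      s <- random_solid(shape, seed = seed)
      a <- solid_inertia(s)
      n <- numeric_inertia(s, 200)
      expect_lt(frob_rel_err(n$tensor, a$tensor), 0.01)
      expect_equal(n$mass, a$mass, tolerance = 0.01)
      tri <- triangle_check(a$tensor)
      expect_true(tri$ok)
      expect_true(triangle_check(n$tensor)$ok)
    }
  }
})

test_that("invalid geometry raises", {
  expect_error(geometric_solid("cylinder", list(radius = -0.1, length = 1),
                               density = 1000), "positive")
  expect_error(geometric_solid("cone", list(radius = 0.1), density = 1000),
               "needs dimensions")
  expect_error(inertia_tensor(1, NA, 1), "finite")
  expect_warning(inertia_tensor(-1, 1, 1), "negative diagonal")
})

test_that("parallel axis: identity, point mass, exact round trip", {
  it0 <- inertia_tensor(0.1, 0.2, 0.3, 0.01, -0.02, 0.03)
  expect_equal(as.matrix(parallel_axis(it0, 5, c(0, 0, 0))),
               as.matrix(it0))

  # point mass m at distance l along x: I_yy = I_zz = m l^2, I_xx = 0
  pm <- parallel_axis(inertia_tensor(0, 0, 0), mass = 2, d = c(0.7, 0, 0))
  expect_equal(unname(pm$I), c(0, 2 * 0.7^2, 2 * 0.7^2))

  for (seed in 1:25) {
    it <- random_tensor(seed)
    d <- withr::with_seed(seed + 1000, stats::rnorm(3, 0, 0.5))
    m <- withr::with_seed(seed + 2000, stats::runif(1, 0.5, 10))
    back <- parallel_axis(parallel_axis(it, m, d), m, d,
                          direction = "to_com")
    # round trip exact up to cancellation of the (much larger) m d^2 terms
    expect_lt(max(abs(as.matrix(back) - as.matrix(it))),
              1e-12 * (max(abs(as.matrix(it))) + m * sum(d^2)))
  }
})

test_that("moi_about_axis is the tensor quadratic form", {
  it <- inertia_tensor(1, 2, 3)
  expect_equal(moi_about_axis(it, c(1, 0, 0)), 1)
  u45 <- c(1, 1, 0) / sqrt(2)
  expect_equal(moi_about_axis(it, u45), 1.5)
  itp <- inertia_tensor(2, 3, 4, pxy = 0.5)
  expect_equal(moi_about_axis(itp, u45), 0.5 * (2 + 3) - 0.5)
  expect_error(moi_about_axis(it, c(1, 1, 0)), "unit")
  expect_warning(v <- moi_about_axis(it, c(2, 0, 0), normalize = TRUE),
                 "normaliz")
  expect_equal(v, 1)
})

test_that("trace of moments over any orthonormal triad is invariant", {
  for (seed in 1:20) {
    it <- random_tensor(seed)
    R <- withr::with_seed(seed + 3000, {
      qr.Q(qr(matrix(stats::rnorm(9), 3)))
    })
    tot <- sum(vapply(1:3, function(j) moi_about_axis(it, R[, j]),
                      numeric(1)))
    expect_equal(tot, sum(it$I), tolerance = 1e-10)
  }
})

test_that("rotation preserves eigenvalues and round-trips", {
  it <- random_tensor(7)
  R <- caninebsp:::rotation_about_axis(c(1, 2, 3), 0.8)
  rt <- rotate_tensor(it, R)
  expect_equal(sort(eigen(as.matrix(rt))$values),
               sort(eigen(as.matrix(it))$values), tolerance = 1e-10)
  back <- rotate_tensor(rt, t(R))
  expect_equal(as.matrix(back), as.matrix(it), tolerance = 1e-10)
})
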