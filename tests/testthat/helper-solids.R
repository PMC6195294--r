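# randomized but physically sensible solids for property tests
random_solid <- function(shape, seed = NULL) {
  draw <- function() {
    len <- stats::runif(1, 0.05, 0.5)
    r <- stats::runif(1, 0.02, 0.15)
    dens <- stats::runif(1, 800, 1100)
    switch(shape,
      cylinder = geometric_solid("cylinder", list(radius = r, length = len),
                                 density = dens),
      cone = geometric_solid("cone", list(radius = r, length = len),
                             density = dens),
      conical_frustum = geometric_solid(
        "conical_frustum",
        list(radius_prox = r, radius_dist = r * stats::runif(1, 0.3, 1),
             length = len), density = dens),
      ellipsoid = geometric_solid(
        "ellipsoid",
        list(semi_x = r, semi_y = r * stats::runif(1, 0.5, 2),
             semi_z = len / 2), density = dens),
      rectangular_pyramid = geometric_solid(
        "rectangular_pyramid",
        list(base_x = 2 * r, base_y = 2 * r * stats::runif(1, 0.5, 2),
             length = len), density = dens))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

solid_shapes <- c("cylinder", "rectangular_pyramid", "cone",
                  "conical_frustum", "ellipsoid")

# a random physically valid tensor: a random solid rotated by a random rotation
random_tensor <- function(seed) {
  withr::with_seed(seed, {
    shape <- sample(solid_shapes, 1)
    s <- random_solid(shape)
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, 0, pi)
    R <- caninebsp:::rotation_about_axis(ax, ang)
    rotate_tensor(solid_inertia(s)$tensor, R)
  })
}

frob_rel_err <- function(est, truth) {
  norm(as.matrix(est) - as.matrix(truth), "F") / norm(as.matrix(truth), "F")
}
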