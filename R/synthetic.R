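# Synthetic cadaver/pendulum data with known ground truth. Virtual dogs are
# assemblies of homogeneous geometric solids whose baseline dimensions,
# densities and landmark-calibrated morphometrics ship in
# inst/extdata/synthetic_solids.csv and synthetic_morphometrics.csv (built by
# data-raw/build_reference_tables.R from the packaged reference set).

# deterministic substream derivation: one global seed fans out to per-segment
# (or per-use) substreams so adding a segment never perturbs another's draws
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 7919
  as.integer(s %% 2147483647 + 1)
}

synthetic_baselines <- function() {
  list(solids = read_bsp_table("synthetic_solids.csv"),
       morph = read_bsp_table("synthetic_morphometrics.csv"))
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a synthetic dog with known ground truth
#'
#' Draws one virtual German Shepherd: each of the 11 segment types is a
#' homogeneous geometric solid (shape per segment fixed at the baseline:
#' cylinders, frusta, a cone, an ellipsoid and a pyramid) whose dimensions
#' and density scatter log-normally around the packaged baselines. Densities
#' are then rescaled by a common factor so the 17 segment masses (limbs
#' counted twice) sum exactly to the drawn body mass. Each segment is tilted
#' by a small random rotation inside its measurement box so the box-frame
#' ground-truth tensor has non-zero products of inertia. Morphometric
#' dimensions track the generating solid dimensions through fixed landmark
#' ratios, so the derived record is consistent with the solids by
#' construction.
#'
#' Left and right limb segments are identical within a dog (the cadavers are
#' positioned symmetrically); ground truth is therefore stored per segment
#' name.
#'
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param body_mass Whole-body mass (kg); default drawn uniformly on the
#'   reference cohort range 34.29-39.41 kg.
#' @param dim_cv Coefficient of variation of the log-normal dimension
#'   scatter (default 0.05).
#' @param tilt_deg Range (degrees) of the random in-box tilt per segment.
#' @return An object of class \code{"synthetic_dog"}: \code{body_mass},
#'   \code{segments} (per segment name: \code{solid}, \code{mass},
#'   \code{com} in solid frame, \code{tensor} box-frame about the CoM,
#'   \code{rotation}, \code{length}), \code{morphometrics} (list with
#'   \code{body_mass_kg} and named \code{dims}), \code{seed}.
#' @export
generate_dog <- function(seed, body_mass = NULL, dim_cv = 0.05,
                         tilt_deg = c(5, 15)) {
  bl <- synthetic_baselines()
  seg_ref <- read_bsp_table("segment_reference.csv")
  rng <- reference_dog()$body_mass_range
  if (is.null(body_mass)) {
    body_mass <- withr::with_seed(derive_seed(seed, 0),
                                  stats::runif(1, rng[1], rng[2]))
  }
  segs <- list()
  for (i in seq_along(segment_names())) {
    s <- segment_names()[i]
    rows <- bl$solids[bl$solids$segment == s, , drop = FALSE]
    dens_ref <- seg_ref$density_kg_m3[seg_ref$segment == s]
    dens_cv <- seg_ref$density_sd[seg_ref$segment == s] / dens_ref
    drawn <- withr::with_seed(derive_seed(seed, i), {
      mult <- exp(stats::rnorm(nrow(rows), 0, dim_cv))
      dens <- dens_ref * exp(stats::rnorm(1, 0, dens_cv))
      ax <- stats::rnorm(3); ang <- stats::runif(1, tilt_deg[1], tilt_deg[2])
      list(mult = mult, dens = dens, axis = ax, angle = ang * pi / 180)
    })
    dims <- stats::setNames(rows$dim_value * drawn$mult, rows$dim_name)
    solid <- geometric_solid(rows$shape[1], as.list(dims),
                             density = drawn$dens)
    segs[[s]] <- list(solid = solid,
                      rotation = rotation_about_axis(drawn$axis, drawn$angle),
                      dims = dims)
  }
  # enforce exact whole-body mass closure by a common density rescale
  masses <- vapply(segs, function(e) e$solid$density * solid_volume(e$solid),
                   numeric(1))
  axial <- c("head", "neck", "thorax", "abdomen", "tail")
  w <- ifelse(names(segs) %in% axial, 1, 2)
  k <- body_mass / sum(w * masses)
  for (s in names(segs)) {
    e <- segs[[s]]
    e$solid$density <- e$solid$density * k
    si <- solid_inertia(e$solid)
    e$mass <- si$mass
    e$com <- si$com
    e$tensor <- rotate_tensor(si$tensor, e$rotation)
    e$tensor$axes_label <- "box"
    e$length <- switch(e$solid$shape,
                       ellipsoid = 2 * e$solid$dimensions$semi_z,
                       e$solid$dimensions$length)
    segs[[s]] <- e
  }
  # morphometrics track the drawn solid dimensions via fixed landmark ratios
  dims_out <- numeric(0)
  for (j in seq_len(nrow(bl$morph))) {
    s <- bl$morph$segment[j]
    tracked <- bl$morph$tracks_dim[j]
    base_dim <- bl$solids$dim_value[bl$solids$segment == s &
                                      bl$solids$dim_name == tracked]
    val <- bl$morph$baseline_value[j] * segs[[s]]$dims[[tracked]] / base_dim
    dims_out[paste(s, bl$morph$key[j], sep = ".")] <- val
  }
  structure(list(body_mass = body_mass, segments = segs,
                 morphometrics = list(body_mass_kg = body_mass,
                                      dims = dims_out),
                 seed = seed),
            class = "synthetic_dog")
}

#' @export
print.synthetic_dog <- function(x, ...) {
  cat(sprintf("Synthetic dog (seed %s): body mass %.2f kg, %d segment types\n",
              format(x$seed), x$body_mass, length(x$segments)))
  invisible(x)
}

# known mechanical properties of a synthetic calibration box: homogeneous
# light cuboid sized to the segment with a margin
synthetic_box <- function(solid, margin = 0.05, foam_density = 25) {
  d <- solid$dimensions
  ext <- switch(solid$shape,
    cylinder = c(2 * d$radius, 2 * d$radius, d$length),
    cone = c(2 * d$radius, 2 * d$radius, d$length),
    conical_frustum = {
      r <- max(d$radius_prox, d$radius_dist)
      c(2 * r, 2 * r, d$length)
    },
    ellipsoid = c(2 * d$semi_x, 2 * d$semi_y, 2 * d$semi_z),
    rectangular_pyramid = c(d$base_x, d$base_y, d$length))
  ext <- ext + 2 * margin
  m <- foam_density * prod(ext)
  tensor <- inertia_tensor(
    m * (ext[2]^2 + ext[3]^2) / 12,
    m * (ext[1]^2 + ext[3]^2) / 12,
    m * (ext[1]^2 + ext[2]^2) / 12,
    frame_point = "com", axes_label = "box")
  list(mass = m, com = c(0, 0, 0), tensor = tensor, extent = ext)
}

simulate_trace <- function(period, fs, cycles, amplitude, noise_sd, phase) {
  t <- seq(0, cycles * period, by = 1 / fs)
  x <- amplitude * cos(2 * pi * t / period + phase)
  if (noise_sd > 0) x <- x + stats::rnorm(length(t), 0, noise_sd)
  data.frame(time_s = t, displacement = x)
}

#' Generate a six-axis pendulum session for one segment
#'
#' Forward-simulates the complete compound-pendulum protocol for a segment of
#' a \code{\link{generate_dog}} result: for each of the six box axes (xx, yy,
#' zz and the three coplanar skew axes at angle \code{theta}), the composite
#' (box plus segment) and the empty box swing about a horizontal pivot at
#' distance \code{l_pendulum} above the common CoM. Periods follow the
#' small-angle relation \eqn{T = 2\pi\sqrt{I_{pivot}/(mgl)}} with
#' \eqn{I_{pivot}} from the ground-truth tensors via the parallel-axis
#' theorem and the axis quadratic form. Oscillation traces are simple
#' harmonic motion plus Gaussian noise at \code{noise} times the amplitude,
#' repeated \code{n_trials} times per axis.
#'
#' The segment is saddled so its CoM coincides with the box centroid
#' (standard centring practice; it keeps the hanging box in equilibrium for
#' every axis and makes the slant-distance correction exact), so
#' \code{l_s = l_b = l_pendulum}.
#'
#' @param dog A \code{synthetic_dog}.
#' @param segment Segment name.
#' @param noise Trace noise as a fraction of the oscillation amplitude.
#' @param seed Integer seed for the trace noise.
#' @param l_pendulum Pivot-to-CoM distance (m).
#' @param theta Skew-axis angle (radians).
#' @param fs Capture rate (Hz).
#' @param cycles Full cycles per trace.
#' @param n_trials Repeated trials per axis (averaged downstream).
#' @param amplitude Swing amplitude (radians; small-angle regime).
#' @param g Gravitational acceleration (m/s^2).
#' @return A session list consumable by
#'   \code{\link{invert_pendulum_session}}: \code{trials} (data frame),
#'   \code{traces} (named list of trial lists), \code{l_s}, \code{theta},
#'   \code{box} (the calibration), \code{balance} (knife-edge balance points
#'   per axis), \code{truth} (ground-truth tensor and mass).
#' @export
generate_pendulum_session <- function(dog, segment, noise = 0, seed = 1,
                                      l_pendulum = 0.3, theta = pi / 4,
                                      fs = 100, cycles = 40, n_trials = 3,
                                      amplitude = 8 * pi / 180, g = 9.81) {
  stopifnot(inherits(dog, "synthetic_dog"))
  e <- dog$segments[[segment]]
  if (is.null(e)) stop("unknown segment: ", segment, call. = FALSE)
  box <- synthetic_box(e$solid)
  m_s <- e$mass; m_b <- box$mass; m_c <- m_s + m_b
  axes <- c("xx", "yy", "zz", "xy", "xz", "yz")
  unit_of <- function(ax) switch(ax,
    xx = c(1, 0, 0), yy = c(0, 1, 0), zz = c(0, 0, 1),
    skew_axis_unit(ax, theta))
  trials <- list(); traces <- list()
  stream <- 0L
  for (ax in axes) {
    u <- unit_of(ax)
    I_seg <- moi_about_axis(e$tensor, u)
    I_box <- moi_about_axis(box$tensor, u)
    T_c <- 2 * pi * sqrt((I_seg + I_box + m_c * l_pendulum^2) /
                           (m_c * g * l_pendulum))
    T_b <- 2 * pi * sqrt((I_box + m_b * l_pendulum^2) /
                           (m_b * g * l_pendulum))
    trials[[paste0(ax, "_c")]] <- data.frame(
      axis = ax, label = "composite", mass = m_c,
      pivot_to_com = l_pendulum, period_true = T_c,
      stringsAsFactors = FALSE)
    trials[[paste0(ax, "_b")]] <- data.frame(
      axis = ax, label = "empty_box", mass = m_b,
      pivot_to_com = l_pendulum, period_true = T_b,
      stringsAsFactors = FALSE)
    for (lab in c("composite", "empty_box")) {
      Tt <- if (lab == "composite") T_c else T_b
      key <- paste(ax, lab, sep = "_")
      stream <- stream + 1L
      traces[[key]] <- withr::with_seed(derive_seed(seed, stream), {
        lapply(seq_len(n_trials), function(k) {
          simulate_trace(Tt, fs, cycles, amplitude,
                         noise_sd = noise * amplitude,
                         phase = stats::runif(1, 0, 2 * pi))
        })
      })
    }
  }
  list(trials = do.call(rbind, trials),
       traces = traces,
       l_s = l_pendulum, theta = theta, box = box,
       # segment CoM at box centroid: composite balances at the centroid
       balance = list(composite_balance = box$com, box_mass = m_b,
                      box_com = box$com, m_s = m_s),
       truth = list(tensor = e$tensor, mass = m_s))
}

#' Generate a morphometric cohort with known ground truth
#'
#' Two modes. With \code{equation} given (a one-row data frame from
#' \code{\link{bsp_equations}}), the cohort is generated from that printed
#' equation: body masses uniform on the reference range, dimensions
#' log-normal around the packaged baselines, observations equal to the
#' equation value plus Gaussian noise scaled to the mean absolute clean
#' value. The generating coefficients are returned for recovery tests.
#' Without \code{equation}, the cohort is a set of
#' \code{\link{generate_dog}} results and their derived records (solids
#' mode).
#'
#' @param n Number of records (paper-style pooling of sides gives n = 12
#'   from six dogs).
#' @param seed Integer seed.
#' @param equation Optional one-row equation data frame.
#' @param noise Observation noise fraction (equation mode).
#' @param dim_cv Dimension scatter (log-normal cv).
#' @return Equation mode: list with \code{records} (data frame), \code{observed},
#'   \code{truth} (named generating coefficients), \code{sigma},
#'   \code{equation}. Solids mode: list with \code{records} and \code{dogs}.
#' @export
generate_cohort <- function(n = 12, seed = 1, equation = NULL, noise = 0.01,
                            dim_cv = 0.05) {
  stopifnot(n >= 1)
  rng <- reference_dog()$body_mass_range
  if (is.null(equation)) {
    dogs <- lapply(seq_len(n), function(i) generate_dog(derive_seed(seed, i),
                                                        dim_cv = dim_cv))
    records <- do.call(rbind, lapply(dogs, function(d) {
      as.data.frame(c(list(body_mass_kg = d$body_mass),
                      as.list(d$morphometrics$dims)),
                    check.names = FALSE)
    }))
    return(list(records = records, dogs = dogs))
  }
  stopifnot(is.data.frame(equation), nrow(equation) == 1L)
  bl <- synthetic_baselines()$morph
  keys <- eq_keys(equation)
  full <- paste(equation$segment, keys, sep = ".")
  base <- vapply(keys, function(k) {
    bl$baseline_value[bl$segment == equation$segment & bl$key == k]
  }, numeric(1))
  out <- withr::with_seed(derive_seed(seed, 1), {
    a <- stats::runif(n, rng[1], rng[2])
    dims <- sapply(seq_along(keys), function(j) {
      base[j] * exp(stats::rnorm(n, 0, dim_cv))
    })
    dims <- matrix(dims, nrow = n)
    colnames(dims) <- full
    records <- data.frame(body_mass_kg = a, check.names = FALSE)
    records <- cbind(records, as.data.frame(dims, check.names = FALSE))
    clean <- vapply(seq_len(n), function(i) {
      evaluate_equation(equation, a[i],
                        stats::setNames(as.numeric(dims[i, ]), full))$value
    }, numeric(1))
    sigma <- noise * mean(abs(clean))
    observed <- clean + stats::rnorm(n, 0, sigma)
    list(records = records, observed = observed, sigma = sigma)
  })
  out$truth <- c(intercept = equation$intercept, a = equation$coef_a,
                 geom = equation$coef_geom)
  out$equation <- equation
  out
}
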