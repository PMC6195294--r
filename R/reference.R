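# Packaged German Shepherd reference parameter set: transcribed segment table
# (normalised masses, CoM ratios, densities, volumes), measured inertia table
# (stored in units of 1e-4 kg m^2; accessors return SI), per-segment axis maps
# and derived reference segment lengths. CSVs live in inst/extdata and are
# rebuilt by data-raw/build_reference_tables.R.

.bsp_cache <- new.env(parent = emptyenv())

bsp_data_file <- function(name) {
  path <- system.file("extdata", name, package = "caninebsp")
  if (!nzchar(path)) {
    # during development (pkgload), fall back to the source tree
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", name,
                               call. = FALSE)
  path
}

read_bsp_table <- function(name) {
  key <- paste0("tbl_", name)
  if (!is.null(.bsp_cache[[key]])) return(.bsp_cache[[key]])
  x <- utils::read.csv(bsp_data_file(name), comment.char = "#",
                       stringsAsFactors = FALSE)
  .bsp_cache[[key]] <- x
  x
}

# scale of the stored inertia table relative to SI kg m^2
.moi_table_scale <- 1e-4

#' The 11 segment names and the 17 concrete segments
#'
#' The dog is divided into 17 segments: five axial (head, neck, thorax,
#' abdomen, tail) and six paired limb segments (brachium, antebrachium, manus,
#' thigh, crus, pes), each with a left and right side. Reference values pool
#' left and right, so lookups are by segment name.
#'
#' @return \code{segment_names()}: character vector of the 11 names.
#'   \code{bsp_segments()}: data frame of the 17 concrete segments with
#'   columns \code{segment} and \code{side} (\code{"none"} for axial).
#' @export
segment_names <- function() {
  c("head", "neck", "thorax", "abdomen", "tail",
    "brachium", "antebrachium", "manus", "thigh", "crus", "pes")
}

#' @rdname segment_names
#' @export
bsp_segments <- function() {
  axial <- c("head", "neck", "thorax", "abdomen", "tail")
  limb <- setdiff(segment_names(), axial)
  rbind(
    data.frame(segment = axial, side = "none", stringsAsFactors = FALSE),
    data.frame(segment = rep(limb, each = 2),
               side = rep(c("left", "right"), times = length(limb)),
               stringsAsFactors = FALSE))
}

#' Reference dog (cohort) metadata
#'
#' Cohort-level constants behind the packaged tables: six male German Shepherd
#' service dogs, mean body mass 36.8 kg (range 34.29-39.41 kg), mean age 4.75
#' years, with an average dissection cut waste of 0.182 kg per dog.
#'
#' @return Named list with \code{body_mass}, \code{body_mass_range}, \code{n},
#'   \code{mean_age_years}, \code{cut_waste_kg}, \code{sex},
#'   \code{occupation}.
#' @export
reference_dog <- function() {
  list(body_mass = 36.8,
       body_mass_range = c(34.29, 39.41),
       n = 6L,
       mean_age_years = 4.75,
       cut_waste_kg = 0.182,
       sex = "male",
       occupation = "police service")
}

#' Look up packaged reference values for one segment
#'
#' Returns the packaged segment parameters (mass fraction, CoM ratios,
#' density, volume, derived reference length) and the measured inertia set
#' (moments about the three anatomical axes and the three products, in SI
#' kg m^2, plus the mapping from box axes xx/yy/zz to anatomical axes).
#' Left and right limb segments return identical values: the reference tables
#' pool sides.
#'
#' @param segment Segment name (one of \code{\link{segment_names}}).
#' @return List with elements \code{reference} (named list of Table-level
#'   segment parameters) and \code{inertia} (named list: \code{I} and
#'   \code{I_sd} named by anatomical axis, \code{P} and \code{P_sd} named
#'   xy/xz/yz, all SI; \code{axis_map} mapping xx/yy/zz to anatomical axes).
#' @examples
#' ref_segment("head")$reference$mass_fraction  # 0.0770
#' @export
ref_segment <- function(segment) {
  segment <- match.arg(segment, segment_names())
  seg <- read_bsp_table("segment_reference.csv")
  ine <- read_bsp_table("segment_inertia.csv")
  r <- seg[seg$segment == segment, , drop = FALSE]
  i <- ine[ine$segment == segment, , drop = FALSE]
  if (nrow(r) != 1L || nrow(i) != 1L)
    stop("segment not found in packaged tables: ", segment, call. = FALSE)
  axis_map <- c(xx = i$axis_xx, yy = "flx_ext", zz = i$axis_zz)
  sc <- .moi_table_scale
  list(
    reference = list(
      segment = segment,
      endpoints = r$endpoints,
      mass_fraction = r$mass_fraction, mass_fraction_sd = r$mass_fraction_sd,
      com_ratio_prox = r$com_prox, com_ratio_prox_sd = r$com_prox_sd,
      com_ratio_dist = r$com_dist, com_ratio_dist_sd = r$com_dist_sd,
      density = r$density_kg_m3, density_sd = r$density_sd,
      volume_cm3 = r$volume_cm3, volume_cm3_sd = r$volume_sd,
      length_ref = r$length_ref_m),
    inertia = list(
      I = sc * c(int_ext = i$I_int_ext, abd_add = i$I_abd_add,
                 flx_ext = i$I_flx_ext),
      I_sd = sc * c(int_ext = i$I_int_ext_sd, abd_add = i$I_abd_add_sd,
                    flx_ext = i$I_flx_ext_sd),
      P = sc * c(xy = i$P_xy, xz = i$P_xz, yz = i$P_yz),
      P_sd = sc * c(xy = i$P_xy_sd, xz = i$P_xz_sd, yz = i$P_yz_sd),
      axis_map = axis_map))
}

#' Packaged reference tensor for a segment, in box axes
#'
#' Maps the anatomical-axis moments of the packaged inertia set onto the box
#' xx/yy/zz axes via the segment's axis map and returns an
#' \code{\link{inertia_tensor}} in SI units about the segment CoM.
#'
#' @param segment Segment name.
#' @return An \code{inertia_tensor}.
#' @export
ref_tensor <- function(segment) {
  x <- ref_segment(segment)$inertia
  I <- x$I[x$axis_map]
  inertia_tensor(I[[1]], I[[2]], I[[3]],
                 pxy = x$P[["xy"]], pxz = x$P[["xz"]], pyz = x$P[["yz"]],
                 frame_point = "com", axes_label = "box")
}

#' Whole-body mass closure of the packaged table
#'
#' Sums the normalised segment masses with limb segments counted twice (left
#' and right) and axial segments once. A complete, internally consistent table
#' should sum to 1 within the dissection cut waste.
#'
#' @param table Optional data frame to audit instead of the packaged table
#'   (columns \code{segment}, \code{mass_fraction}).
#' @return The mass-fraction sum (dimensionless; packaged table: 0.9998).
#' @export
mass_closure <- function(table = NULL) {
  if (is.null(table)) table <- read_bsp_table("segment_reference.csv")
  axial <- c("head", "neck", "thorax", "abdomen", "tail")
  w <- ifelse(table$segment %in% axial, 1, 2)
  sum(w * table$mass_fraction)
}

#' Equivalent-cylinder reference length
#'
#' The reference tables report volumes and moments but not segment lengths.
#' A reference length is recovered by treating the segment as a homogeneous
#' cylinder matching the packaged mass, volume and mean transverse moment of
#' inertia: with \eqn{I_t = m(3r^2 + L^2)/12} and \eqn{V = \pi r^2 L},
#' eliminating \eqn{r} gives the depressed cubic
#' \deqn{L^3 - (12 I_t / m) L + 3V/\pi = 0,}
#' whose largest positive root is taken (the slender branch). The transverse
#' moment is the mean of the two largest diagonal moments (the smallest being
#' the long-axis moment).
#'
#' @param mass Segment mass (kg).
#' @param volume Segment volume (m^3).
#' @param I_transverse Mean transverse moment of inertia (kg m^2).
#' @return Equivalent-cylinder length (m), or \code{NA} if no positive root
#'   exists (segment inconsistent with a homogeneous cylinder).
#' @export
equivalent_cylinder_length <- function(mass, volume, I_transverse) {
  stopifnot(mass > 0, volume > 0, I_transverse > 0)
  roots <- polyroot(c(3 * volume / pi, -12 * I_transverse / mass, 0, 1))
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * max(1, abs(Re(roots)))]
  re <- re[re > 0]
  if (length(re) == 0L) return(NA_real_)
  max(re)
}

#' Scale packaged reference values to a target dog
#'
#' Applies the standard BSP normalisation conventions in reverse: segment mass
#' is the packaged mass fraction times the target body mass; the CoM sits at
#' the proximal CoM ratio times the segment length, on the proximal-distal
#' axis (lateral and dorso-ventral offsets are not reported in the reference
#' set, so they are zero and the output carries an approximation flag); the
#' inertia tensor scales linearly in body mass and quadratically in segment
#' length relative to the reference length.
#'
#' @param segment Segment name.
#' @param body_mass Target whole-body mass (kg). Outside the reference cohort
#'   range (34.29-39.41 kg) an extrapolation warning is raised.
#' @param segment_length Target segment length (m); defaults to the reference
#'   length (identity scaling).
#' @return List with \code{mass} (kg), \code{com_from_proximal} (m),
#'   \code{tensor} (\code{\link{inertia_tensor}}, box axes, about the CoM),
#'   \code{length} (m) and \code{approx_flags} (character).
#' @examples
#' scale_to_dog("head", body_mass = 36.8)$mass  # 0.0770 * 36.8 = 2.834
#' @export
scale_to_dog <- function(segment, body_mass, segment_length = NULL) {
  if (!is.finite(body_mass) || body_mass <= 0)
    stop("body_mass must be positive", call. = FALSE)
  x <- ref_segment(segment)
  rng <- reference_dog()$body_mass_range
  if (body_mass < rng[1] || body_mass > rng[2])
    warning(sprintf("body mass %.2f kg outside reference cohort range [%.2f, %.2f]: extrapolating",
                    body_mass, rng[1], rng[2]), call. = FALSE)
  L_ref <- x$reference$length_ref
  if (is.null(segment_length)) segment_length <- L_ref
  if (!is.finite(segment_length) || segment_length <= 0)
    stop("segment_length must be positive", call. = FALSE)
  mass <- x$reference$mass_fraction * body_mass
  com <- x$reference$com_ratio_prox * segment_length
  k <- (body_mass / reference_dog()$body_mass) * (segment_length / L_ref)^2
  t0 <- ref_tensor(segment)
  tensor <- inertia_tensor(
    k * t0$I[["xx"]], k * t0$I[["yy"]], k * t0$I[["zz"]],
    k * t0$P[["xy"]], k * t0$P[["xz"]], k * t0$P[["yz"]],
    frame_point = "com", axes_label = "box")
  list(mass = mass, com_from_proximal = com, tensor = tensor,
       length = segment_length,
       approx_flags = "com_on_long_axis")
}
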