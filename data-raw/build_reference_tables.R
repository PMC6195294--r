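# Rebuilds every CSV under inst/extdata from the transcribed German Shepherd
# reference parameter set. Run from the package root:
#   Rscript data-raw/build_reference_tables.R
#
# Contents:
#   segment_reference.csv      normalised masses, CoM ratios, densities,
#                              volumes (+SDs) and the derived equivalent-
#                              cylinder reference length per segment
#   segment_inertia.csv        measured moments/products of inertia
#                              (stored in 1e-4 kg m^2) + box->anatomical axis map
#   regression_equations.csv   the 44 morphometric regression equations
#   dimension_dictionary.csv   measurement definitions for the dimension keys
#   synthetic_solids.csv       baseline generating solids for the synthetic cohort
#   synthetic_morphometrics.csv baseline morphometric values and the solid
#                              dimension each one tracks

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- segment parameter table --------------------------------------------

seg <- data.frame(
  segment = c("manus", "antebrachium", "brachium", "pes", "crus", "thigh",
              "head", "neck", "abdomen", "thorax", "tail"),
  endpoints = c(
    "mid carpus to distal 3rd phalanx",
    "lateral epicondyle to carpal joint",
    "glenohumeral joint to lateral epicondyle",
    "tuber calcaneus to distal 3rd phalanx",
    "femoral condyle to lateral malleolus",
    "greater trochanter to femoral condyle",
    "inion to prosthion",
    "atlas/axis to C7/T1",
    "T13/L1 to tail base",
    "C7/T1 to T13/L1",
    "base of tail to tip"),
  mass_fraction    = c(0.0072, 0.0138, 0.0240, 0.0082, 0.0150, 0.0451,
                       0.0770, 0.0661, 0.2415, 0.3806, 0.0080),
  mass_fraction_sd = c(0.0002, 0.0005, 0.0013, 0.0002, 0.0006, 0.0028,
                       0.0039, 0.0068, 0.0153, 0.0101, 0.0005),
  com_prox    = c(0.4848, 0.3941, 0.4183, 0.5140, 0.3659, 0.4463,
                  0.3165, 0.5627, 0.4677, 0.5368, 0.3128),
  com_prox_sd = c(0.0089, 0.0055, 0.0183, 0.0044, 0.0113, 0.0115,
                  0.0081, 0.0122, 0.0047, 0.0110, 0.0158),
  com_dist    = c(0.5185, 0.6076, 0.5869, 0.4880, 0.6364, 0.5601,
                  0.6842, 0.4431, 0.5343, 0.4670, 0.6892),
  com_dist_sd = c(0.0091, 0.0053, 0.0197, 0.0042, 0.0111, 0.0124,
                  0.0082, 0.0128, 0.0050, 0.0109, 0.0162),
  density_kg_m3 = c(934.02, 977.54, 974.37, 1013.58, 1010.60, 939.78,
                    1004.18, 970.01, 963.89, 1083.39, 900.63),
  density_sd    = c(18.10, 17.10, 12.71, 12.45, 19.38, 13.40,
                    20.29, 25.53, 7.71, 83.44, 63.73),
  volume_cm3 = c(287, 521, 908, 305, 548, 1760, 1000, 2550, 9260, 13300, 345),
  volume_sd  = c(12.9, 30.7, 86.2, 12.6, 33.3, 183.0, 20.3, 292.0, 714.0,
                 1070.0, 45.1),
  stringsAsFactors = FALSE)

## ---- measured inertia table (1e-4 kg m^2) -------------------------------

ine <- data.frame(
  segment = seg$segment,
  I_int_ext    = c(6.37, 9.82, 29.87, 18.86, 15.48, 100.61,
                   253.67, 155.04, 1164.68, 2811.71, 8.21),
  I_int_ext_sd = c(0.79, 1.23, 4.06, 1.59, 1.95, 9.24,
                   5.53, 15.89, 185.52, 160.47, 1.41),
  I_abd_add    = c(10.26, 32.68, 51.46, 8.93, 28.55, 79.74,
                   191.61, 160.27, 737.53, 1350.62, 60.70),
  I_abd_add_sd = c(1.25, 2.64, 8.07, 0.80, 1.98, 12.24,
                   16.20, 11.19, 105.81, 35.68, 4.37),
  I_flx_ext    = c(9.83, 26.86, 43.69, 17.34, 28.00, 109.91,
                   248.60, 142.75, 1457.73, 2825.10, 48.50),
  I_flx_ext_sd = c(1.17, 1.85, 7.16, 0.51, 1.69, 11.69,
                   10.24, 19.62, 213.35, 170.99, 4.27),
  P_xy    = c(2.64, 6.84, 8.85, 5.36, 3.77, 19.00,
              51.79, 50.00, 162.88, 318.51, 21.19),
  P_xy_sd = c(1.11, 1.12, 3.27, 0.82, 3.18, 3.27,
              5.16, 7.23, 20.11, 10.12, 2.41),
  P_xz    = c(4.02, 24.32, 17.16, 7.29, 29.28, 28.01,
              78.18, 34.66, 246.50, 701.83, -435.32),
  P_xz_sd = c(1.01, 4.67, 2.96, 0.76, 2.49, 3.71,
              6.94, 3.88, 58.04, 43.53, 1915.34),
  P_yz    = c(1.68, -5.33, 19.12, 2.40, 3.14, 38.78,
              82.20, 46.17, 70.23, 1004.15, -2039.36),
  P_yz_sd = c(0.74, 5.57, 9.80, 0.98, 6.80, 3.51,
              7.29, 9.04, 283.44, 153.99, 628.28),
  # box -> anatomical axis map (yy is flexion/extension for every segment)
  axis_xx = c("int_ext", "abd_add", "abd_add", "abd_add", "abd_add",
              "abd_add", "int_ext", "int_ext", "int_ext", "int_ext",
              "abd_add"),
  axis_zz = c("abd_add", "int_ext", "int_ext", "int_ext", "int_ext",
              "int_ext", "abd_add", "abd_add", "abd_add", "abd_add",
              "int_ext"),
  stringsAsFactors = FALSE)

## ---- derived reference lengths ------------------------------------------
# Equivalent-cylinder assumption: match packaged mass, volume and the mean of
# the two largest diagonal moments (the transverse pair) to a homogeneous
# cylinder; eliminate the radius to get L^3 - (12 I_t / m) L + 3 V / pi = 0
# and take the largest positive root (the slender branch).

ref_body_mass <- 36.8
eq_cyl_length <- function(mass, volume, I_t) {
  roots <- polyroot(c(3 * volume / pi, -12 * I_t / mass, 0, 1))
  re <- Re(roots)[abs(Im(roots)) < 1e-8]
  re <- re[re > 0]
  if (length(re) == 0L) return(NA_real_)
  max(re)
}
seg$length_ref_m <- vapply(seq_len(nrow(seg)), function(i) {
  m <- seg$mass_fraction[i] * ref_body_mass
  V <- seg$volume_cm3[i] * 1e-6
  I3 <- sort(c(ine$I_int_ext[i], ine$I_abd_add[i], ine$I_flx_ext[i]),
             decreasing = TRUE) * 1e-4
  eq_cyl_length(m, V, mean(I3[1:2]))
}, numeric(1))
stopifnot(all(is.finite(seg$length_ref_m)), all(seg$length_ref_m > 0.05))
seg$length_ref_m <- round(seg$length_ref_m, 5)

write.csv(seg, file.path(out, "segment_reference.csv"), row.names = FALSE)

f <- file(file.path(out, "segment_inertia.csv"), "w")
writeLines("# moments and products of inertia stored in units of 1e-4 kg m^2", f)
write.csv(ine, f, row.names = FALSE)
close(f)

## ---- regression equation transcription ----------------------------------
# term kinds (geometry regressor g evaluated on the listed keys, in order):
#   mass_only                (no geometry term)
#   cylinder_volume          k1 * k2^2
#   frustum_volume           k1 * (k2^2 + k2 k3 + k3^2)
#   box_volume               k1 * k2 * k3
#   transverse_cylinder      0.076 k1^2 + k2^2      (0.076 ~= 3/(4 pi^2))
#   transverse_cylinder_circ (k1/pi)^2 + k2^2
#   axial_frustum            (k1^5 - k2^5)/(k1^3 - k2^3); limit (5/3) k1^2
#   dim_squared              k1^2
#   ellipsoid_sum            k1^2 + k2^2
# geom_includes_a = 1 when the printed regressor is a * g (all MoI equations).

eqs <- rbind(
  data.frame(segment="manus", quantity="mass", axis="", coef_a=-0.003,
             coef_geom=69.762, intercept=0.077, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.867, note=""),
  data.frame(segment="manus", quantity="I_xx", axis="int_ext", coef_a=-0.00012,
             coef_geom=NA, intercept=0.0052, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.721, note=""),
  data.frame(segment="manus", quantity="I_yy", axis="flx_ext", coef_a=-0.00015,
             coef_geom=NA, intercept=0.00654, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.689, note=""),
  data.frame(segment="manus", quantity="I_zz", axis="abd_add", coef_a=0.00018,
             coef_geom=NA, intercept=-0.00558, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.870, note=""),

  data.frame(segment="antebrachium", quantity="mass", axis="", coef_a=0.012,
             coef_geom=101.084, intercept=-0.463, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.903, note=""),
  data.frame(segment="antebrachium", quantity="I_xx", axis="abd_add",
             coef_a=-0.00032, coef_geom=0.00066, intercept=0.01406,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.595, note=""),
  data.frame(segment="antebrachium", quantity="I_yy", axis="flx_ext",
             coef_a=-0.00005, coef_geom=0.00160, intercept=0.00168,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.459, note=""),
  data.frame(segment="antebrachium", quantity="I_zz", axis="int_ext",
             coef_a=0.0001, coef_geom=0.00173, intercept=-0.00496,
             term_kind="dim_squared", keys="b", geom_includes_a=1L,
             r_squared=0.886, note=""),

  data.frame(segment="brachium", quantity="mass", axis="", coef_a=0.092,
             coef_geom=25.062, intercept=-3.811, term_kind="frustum_volume",
             keys="b;c;d", geom_includes_a=0L, r_squared=0.646, note=""),
  data.frame(segment="brachium", quantity="I_xx", axis="abd_add",
             coef_a=0.00053, coef_geom=0.00223, intercept=-0.1990,
             term_kind="transverse_cylinder_circ", keys="c;b",
             geom_includes_a=1L, r_squared=0.883,
             note="intercept -0.1990 transcribed as printed"),
  data.frame(segment="brachium", quantity="I_yy", axis="flx_ext",
             coef_a=0.00082, coef_geom=0.00465, intercept=-0.03308,
             term_kind="transverse_cylinder_circ", keys="c;b",
             geom_includes_a=1L, r_squared=0.728, note=""),
  data.frame(segment="brachium", quantity="I_zz", axis="int_ext",
             coef_a=0.00015, coef_geom=0.003, intercept=-0.02139,
             term_kind="axial_frustum", keys="c;d", geom_includes_a=1L,
             r_squared=0.408, note="intercept printed as 00.02139"),

  data.frame(segment="pes", quantity="mass", axis="", coef_a=-0.009,
             coef_geom=633.875, intercept=0.357, term_kind="box_volume",
             keys="b;c;d", geom_includes_a=0L, r_squared=0.895, note=""),
  data.frame(segment="pes", quantity="I_xx", axis="abd_add", coef_a=0.00009,
             coef_geom=NA, intercept=-0.00256, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.870, note=""),
  data.frame(segment="pes", quantity="I_yy", axis="flx_ext", coef_a=-0.00007,
             coef_geom=NA, intercept=0.00417, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.687, note=""),
  data.frame(segment="pes", quantity="I_zz", axis="int_ext", coef_a=-0.00016,
             coef_geom=NA, intercept=0.00786, term_kind="mass_only",
             keys="", geom_includes_a=0L, r_squared=0.594, note=""),

  data.frame(segment="crus", quantity="mass", axis="", coef_a=0.075,
             coef_geom=139.127, intercept=-3.393, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.576, note=""),
  data.frame(segment="crus", quantity="I_xx", axis="abd_add", coef_a=0.00023,
             coef_geom=0.00137, intercept=-0.00785,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.903, note=""),
  data.frame(segment="crus", quantity="I_yy", axis="flx_ext", coef_a=0.00021,
             coef_geom=0.00108, intercept=-0.00659,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.985, note=""),
  data.frame(segment="crus", quantity="I_zz", axis="int_ext", coef_a=0.00009,
             coef_geom=-0.00423, intercept=0.00454, term_kind="dim_squared",
             keys="c", geom_includes_a=1L, r_squared=0.941, note=""),

  data.frame(segment="thigh", quantity="mass", axis="", coef_a=0.018,
             coef_geom=105.849, intercept=-0.711, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.709, note=""),
  data.frame(segment="thigh", quantity="I_xx", axis="abd_add", coef_a=-0.00091,
             coef_geom=0.00258, intercept=0.03813,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.732, note=""),
  data.frame(segment="thigh", quantity="I_yy", axis="flx_ext", coef_a=-0.0006,
             coef_geom=0.00536, intercept=0.02502,
             term_kind="transverse_cylinder", keys="c;b", geom_includes_a=1L,
             r_squared=0.792, note="a-coefficient printed as -00.0006a"),
  data.frame(segment="thigh", quantity="I_zz", axis="int_ext", coef_a=-0.00067,
             coef_geom=0.00001, intercept=0.03467, term_kind="dim_squared",
             keys="c", geom_includes_a=1L, r_squared=0.466, note=""),

  data.frame(segment="head", quantity="mass", axis="", coef_a=0.243,
             coef_geom=1602.163, intercept=-11.739, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.778, note=""),
  data.frame(segment="head", quantity="I_xx", axis="int_ext", coef_a=0.0008,
             coef_geom=0.15568, intercept=-0.09160, term_kind="dim_squared",
             keys="c", geom_includes_a=1L, r_squared=0.984, note=""),
  data.frame(segment="head", quantity="I_yy", axis="flx_ext", coef_a=-0.00112,
             coef_geom=-0.00283, intercept=0.07403, term_kind="ellipsoid_sum",
             keys="b;c", geom_includes_a=1L, r_squared=0.720,
             note="a-coefficient printed as -00.00112a"),
  data.frame(segment="head", quantity="I_zz", axis="abd_add", coef_a=-0.00007,
             coef_geom=-0.00613, intercept=0.04484, term_kind="ellipsoid_sum",
             keys="b;c", geom_includes_a=1L, r_squared=0.708, note=""),

  data.frame(segment="neck", quantity="mass", axis="", coef_a=0.063,
             coef_geom=98.915, intercept=-3.527, term_kind="cylinder_volume",
             keys="b;d", geom_includes_a=0L, r_squared=0.952, note=""),
  data.frame(segment="neck", quantity="I_xx", axis="int_ext", coef_a=-0.00154,
             coef_geom=-0.00313, intercept=0.11749, term_kind="axial_frustum",
             keys="e;c", geom_includes_a=1L, r_squared=0.816, note=""),
  data.frame(segment="neck", quantity="I_yy", axis="flx_ext", coef_a=-0.0007,
             coef_geom=0.01245, intercept=0.01634,
             term_kind="transverse_cylinder_circ", keys="e;b",
             geom_includes_a=1L, r_squared=0.871,
             note="a-coefficient printed as -00.0007a"),
  data.frame(segment="neck", quantity="I_zz", axis="abd_add", coef_a=-0.00129,
             coef_geom=0.00719, intercept=0.04938,
             term_kind="transverse_cylinder_circ", keys="e;b",
             geom_includes_a=1L, r_squared=0.976, note=""),

  data.frame(segment="abdomen", quantity="mass", axis="", coef_a=0.030,
             coef_geom=16.692, intercept=0.106, term_kind="frustum_volume",
             keys="c;b;d", geom_includes_a=0L, r_squared=0.957, note=""),
  data.frame(segment="abdomen", quantity="I_xx", axis="int_ext",
             coef_a=0.00814, coef_geom=0.00471, intercept=-0.28462,
             term_kind="axial_frustum", keys="b;d", geom_includes_a=1L,
             r_squared=0.929, note=""),
  data.frame(segment="abdomen", quantity="I_yy", axis="flx_ext",
             coef_a=0.01457, coef_geom=0.01824, intercept=-0.50031,
             term_kind="transverse_cylinder_circ", keys="b;c",
             geom_includes_a=1L, r_squared=0.653,
             note="a-coefficient printed as 00.01457a"),
  data.frame(segment="abdomen", quantity="I_zz", axis="abd_add",
             coef_a=-0.02726, coef_geom=0.00616, intercept=10.08268,
             term_kind="transverse_cylinder_circ", keys="b;c",
             geom_includes_a=1L, r_squared=0.687,
             note="intercept +10.08268 transcribed as printed (likely misprint)"),

  data.frame(segment="thorax", quantity="mass", axis="", coef_a=0.094,
             coef_geom=11.135, intercept=4.966, term_kind="frustum_volume",
             keys="c;d;b", geom_includes_a=0L, r_squared=0.978, note=""),
  data.frame(segment="thorax", quantity="I_xx", axis="int_ext", coef_a=0.00384,
             coef_geom=0.00183, intercept=-0.05972, term_kind="axial_frustum",
             keys="d;b", geom_includes_a=1L, r_squared=0.935, note=""),
  data.frame(segment="thorax", quantity="I_yy", axis="flx_ext",
             coef_a=-0.00514, coef_geom=0.04659, intercept=0.12633,
             term_kind="transverse_cylinder_circ", keys="d;c",
             geom_includes_a=1L, r_squared=0.739,
             note="a-coefficient printed as -00.00514a"),
  data.frame(segment="thorax", quantity="I_zz", axis="abd_add",
             coef_a=-0.00566, coef_geom=0.04428, intercept=0.16146,
             term_kind="transverse_cylinder_circ", keys="d;c",
             geom_includes_a=1L, r_squared=0.763, note=""),

  data.frame(segment="tail", quantity="mass", axis="", coef_a=0.020,
             coef_geom=22.123, intercept=-0.667, term_kind="cylinder_volume",
             keys="b;c", geom_includes_a=0L, r_squared=0.934, note=""),
  data.frame(segment="tail", quantity="I_xx", axis="abd_add", coef_a=0.00015,
             coef_geom=0.00198, intercept=-0.01353,
             term_kind="transverse_cylinder_circ", keys="c;b",
             geom_includes_a=1L, r_squared=0.944, note=""),
  data.frame(segment="tail", quantity="I_yy", axis="flx_ext", coef_a=-0.00042,
             coef_geom=0.00148, intercept=0.00989,
             term_kind="transverse_cylinder_circ", keys="c;b",
             geom_includes_a=1L, r_squared=0.960, note=""),
  data.frame(segment="tail", quantity="I_zz", axis="int_ext", coef_a=0.0001,
             coef_geom=0.00173, intercept=-0.00410, term_kind="dim_squared",
             keys="c", geom_includes_a=1L, r_squared=0.913, note=""))

stopifnot(nrow(eqs) == 44L,
          sum(eqs$quantity == "mass") == 11L,
          sum(eqs$quantity != "mass") == 33L)
write.csv(eqs, file.path(out, "regression_equations.csv"), row.names = FALSE)

## ---- dimension dictionary ------------------------------------------------

dict <- rbind(
  c("all", "a", "whole body mass (kg)", 0),
  c("manus", "b", "length of caudal edge of metacarpal pad to podactylion III (m)", 0),
  c("manus", "c", "bistyloidal circumference at carpal joint (m)", 0),
  c("antebrachium", "b", "length of antebrachium, proximal to distal joint centers (m)", 0),
  c("antebrachium", "c", "bistyloidal circumference at carpal joint (m)", 0),
  c("brachium", "b", "length of brachium, proximal to distal joint centers (m)", 0),
  c("brachium", "c", "circumference at highest point in the axilla, perpendicular to long axis (m)", 0),
  c("brachium", "d", "circumference at olecranon process across epicondyles (m)", 0),
  c("pes", "b", "length of proximal joint center to podactylion III (m)", 0),
  c("pes", "c", "breadth across metatarsal phalangeal joints (m)", 0),
  c("pes", "d", "depth of pes at midpoint between malleoli and base of the pes (m)", 0),
  c("crus", "b", "length of crus, proximal to distal joint centers (m)", 0),
  c("crus", "c", "circumference of hock at malleoli (m)", 0),
  c("thigh", "b", "mid centroid of femoral head (m); far endpoint unstated", 1),
  c("thigh", "c", "circumference of stifle joint at mid-patella (m)", 0),
  c("head", "b", "length of head, atlas/axis joint center to end of nose (m)", 0),
  c("head", "c", "ecto-orbitale breadth (m)", 0),
  c("neck", "b", "length from axis (base of the head) to C7 (m)", 0),
  c("neck", "c", "circumference at axis/atlas joint (base of head) (m)", 0),
  c("neck", "d", "circumference at mid length, halfway between the axis and C7 (m)", 0),
  c("neck", "e", "circumference at C7/T1 (base of neck/shoulders) (m)", 0),
  c("abdomen", "b", "circumference at T13/L1 joint (base of ribs) (m)", 0),
  c("abdomen", "c", "length of T13/L1 to L7/S1 (spinous processes) (m)", 0),
  c("abdomen", "d", "circumference at level of waist (narrowest point) (m)", 0),
  c("thorax", "b", "circumference at C7/T1 (base of neck/shoulders) (m)", 0),
  c("thorax", "c", "length of C7/T1 joint center to T13/L1 joint center (m)", 0),
  c("thorax", "d", "circumference at T13/L1 joint (base of ribs) (m)", 0),
  c("tail", "b", "length from sacrum to tip of tail (m)", 0),
  c("tail", "c", "circumference at sacrum (m)", 0))
dict <- data.frame(segment = dict[, 1], key = dict[, 2],
                   definition = dict[, 3],
                   ambiguous = as.integer(dict[, 4]),
                   stringsAsFactors = FALSE)
write.csv(dict, file.path(out, "dimension_dictionary.csv"), row.names = FALSE)

## ---- synthetic-cohort baselines -----------------------------------------
# One generating solid per segment, consistent with the packaged mass,
# density and volume at the cohort-mean body mass; baseline morphometrics
# solve the printed mass equations exactly at the cohort mean (measurement-
# landmark calibration) and each tracks one generating solid dimension.

m_ref <- seg$mass_fraction * ref_body_mass
V_ref <- m_ref / seg$density_kg_m3   # self-consistent volume (m^3)
names(m_ref) <- names(V_ref) <- seg$segment
L <- seg$length_ref_m; names(L) <- seg$segment

shape_of <- c(manus = "cylinder", antebrachium = "conical_frustum",
              brachium = "conical_frustum", pes = "rectangular_pyramid",
              crus = "conical_frustum", thigh = "conical_frustum",
              head = "ellipsoid", neck = "conical_frustum",
              abdomen = "conical_frustum", thorax = "conical_frustum",
              tail = "cone")
# distal/proximal radius ratio for frustum segments (taper towards the
# anatomically narrower end)
taper <- c(antebrachium = 0.80, brachium = 0.75, crus = 0.75, thigh = 0.75,
           neck = 0.80, abdomen = 0.80, thorax = 0.85)
# which end is the narrow one: "dist" means radius_dist = taper * radius_prox
narrow_end <- c(antebrachium = "dist", brachium = "dist", crus = "dist",
                thigh = "dist", neck = "prox", abdomen = "dist",
                thorax = "prox")

solid_rows <- list()
add_solid <- function(segment, ...) {
  dims <- c(...)
  solid_rows[[segment]] <<- data.frame(
    segment = segment, shape = shape_of[[segment]],
    dim_name = names(dims), dim_value = round(as.numeric(dims), 6),
    stringsAsFactors = FALSE)
}
frustum_radii <- function(segment) {
  tau <- taper[[segment]]
  r_big <- sqrt(3 * V_ref[[segment]] /
                (pi * L[[segment]] * (1 + tau + tau^2)))
  r_small <- tau * r_big
  if (narrow_end[[segment]] == "dist")
    c(radius_prox = r_big, radius_dist = r_small)
  else
    c(radius_prox = r_small, radius_dist = r_big)
}
for (s in seg$segment) {
  switch(shape_of[[s]],
    cylinder = add_solid(s, radius = sqrt(V_ref[[s]] / (pi * L[[s]])),
                         length = L[[s]]),
    cone = add_solid(s, radius = sqrt(3 * V_ref[[s]] / (pi * L[[s]])),
                     length = L[[s]]),
    conical_frustum = add_solid(s, frustum_radii(s), length = L[[s]]),
    ellipsoid = {
      sz <- L[[s]] / 2
      sw <- sqrt(3 * V_ref[[s]] / (4 * pi * sz))
      add_solid(s, semi_x = sw, semi_y = sw, semi_z = sz)
    },
    rectangular_pyramid = {
      aspect <- 1.5                   # paw breadth : depth
      bx <- sqrt(3 * V_ref[[s]] * aspect / L[[s]])
      add_solid(s, base_x = bx, base_y = bx / aspect, length = L[[s]])
    })
}
solids <- do.call(rbind, solid_rows)
write.csv(solids, file.path(out, "synthetic_solids.csv"), row.names = FALSE)

# geometry-term targets from the printed mass equations at the cohort mean
gstar <- sapply(seg$segment, function(s) {
  e <- eqs[eqs$segment == s & eqs$quantity == "mass", ]
  (m_ref[[s]] - e$coef_a * ref_body_mass - e$intercept) / e$coef_geom
})
stopifnot(all(gstar > 0))

dimval <- function(s, name) {
  solids$dim_value[solids$segment == s & solids$dim_name == name]
}
morph_rows <- list()
add_morph <- function(segment, key, value, tracks) {
  stopifnot(is.finite(value), value > 0)
  morph_rows[[paste(segment, key)]] <<- data.frame(
    segment = segment, key = key, baseline_value = round(value, 6),
    tracks_dim = tracks, stringsAsFactors = FALSE)
}

# manus: b c^2 with b a sub-length of the paw
b <- 0.6 * L[["manus"]]
add_morph("manus", "b", b, "length")
add_morph("manus", "c", sqrt(gstar[["manus"]] / b), "radius")
# antebrachium: b c^2, c at the distal (carpal) end
add_morph("antebrachium", "b", L[["antebrachium"]], "length")
add_morph("antebrachium", "c", sqrt(gstar[["antebrachium"]] / L[["antebrachium"]]),
          "radius_dist")
# brachium: b (c^2 + c d + d^2); d anchored to the distal frustum girth
b <- L[["brachium"]]
d <- 2 * pi * dimval("brachium", "radius_dist")
cc <- (-d + sqrt(4 * gstar[["brachium"]] / b - 3 * d^2)) / 2
add_morph("brachium", "b", b, "length")
add_morph("brachium", "c", cc, "radius_prox")
add_morph("brachium", "d", d, "radius_dist")
# pes: b c d; c anchored to the pyramid base breadth
b <- L[["pes"]]; cc <- dimval("pes", "base_x")
add_morph("pes", "b", b, "length")
add_morph("pes", "c", cc, "base_x")
add_morph("pes", "d", gstar[["pes"]] / (b * cc), "base_y")
# crus / thigh / tail: b c^2
for (s in c("crus", "thigh", "tail")) {
  add_morph(s, "b", L[[s]], "length")
  tr <- if (s == "tail") "radius" else "radius_dist"
  add_morph(s, "c", sqrt(gstar[[s]] / L[[s]]), tr)
}
# head: b c^2 (b = length, c = breadth)
add_morph("head", "b", L[["head"]], "semi_z")
add_morph("head", "c", sqrt(gstar[["head"]] / L[["head"]]), "semi_x")
# neck: mass uses b d^2 (d the mid circumference); c and e are the end
# circumferences, carrying the same landmark factor as d
b <- L[["neck"]]
d <- sqrt(gstar[["neck"]] / b)
r_p <- dimval("neck", "radius_prox"); r_d <- dimval("neck", "radius_dist")
kappa <- d / (2 * pi * (r_p + r_d) / 2)
add_morph("neck", "b", b, "length")
add_morph("neck", "c", kappa * 2 * pi * r_p, "radius_prox")
add_morph("neck", "d", d, "radius_dist")
add_morph("neck", "e", kappa * 2 * pi * r_d, "radius_dist")
# abdomen: c (b^2 + b d + d^2), b cranial girth, d waist girth
for (s in c("abdomen", "thorax")) {
  len_key <- "c"
  if (s == "abdomen") { big_key <- "b"; small_key <- "d" }
  else { big_key <- "d"; small_key <- "b" }
  r_p <- dimval(s, "radius_prox"); r_d <- dimval(s, "radius_dist")
  tau <- min(r_p, r_d) / max(r_p, r_d)
  big <- sqrt((gstar[[s]] / L[[s]]) / (1 + tau + tau^2))
  small <- tau * big
  big_tracks <- if (r_p >= r_d) "radius_prox" else "radius_dist"
  small_tracks <- if (r_p >= r_d) "radius_dist" else "radius_prox"
  add_morph(s, len_key, L[[s]], "length")
  add_morph(s, big_key, big, big_tracks)
  add_morph(s, small_key, small, small_tracks)
}
morph <- do.call(rbind, morph_rows)
rownames(morph) <- NULL
write.csv(morph, file.path(out, "synthetic_morphometrics.csv"), row.names = FALSE)

cat("wrote", length(list.files(out)), "files to", out, "\n")
print(seg[, c("segment", "length_ref_m")])
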