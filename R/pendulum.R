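#' Pendulum trial record
#'
#' One compound-pendulum measurement: the swinging mass, the pivot-to-CoM
#' distance and the small-angle oscillation period, for either the composite
#' (box plus segment) or the empty box.
#'
#' @param mass Swinging mass (kg).
#' @param pivot_to_com Pivot-to-CoM distance (m).
#' @param period Oscillation period (s).
#' @param label \code{"composite"} or \code{"empty_box"}.
#' @return An object of class \code{"pendulum_trial"}.
#' @export
pendulum_trial <- function(mass, pivot_to_com, period,
                           label = c("composite", "empty_box")) {
  label <- match.arg(label)
  vals <- c(mass, pivot_to_com, period)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("mass, pivot_to_com and period must all be positive", call. = FALSE)
  structure(list(mass = mass, pivot_to_com = pivot_to_com,
                 period = period, label = label),
            class = "pendulum_trial")
}

#' Estimate the oscillation period of a trace
#'
#' Period estimation for a recorded pendulum swing: the trace is mean-centred,
#' lightly smoothed with a centred moving average (window about one eighth of
#' the dominant period, which preserves zero-crossing phase of a sinusoid
#' exactly), zero crossings are located by linear interpolation between
#' samples, and the period is taken from a least-squares regression of
#' crossing time on crossing index (each consecutive crossing advances the
#' phase by half a period). For simple harmonic motion this estimator is
#' unbiased; regression over all crossings makes it far less noise-sensitive
#' than the spacing of any single pair.
#'
#' @param trace Data frame with columns \code{time_s} and \code{displacement}
#'   (uniform sampling; displacement units arbitrary).
#' @param min_cycles Minimum number of full cycles that must be present
#'   (default 3; fewer raises an insufficient-data error).
#' @return Estimated period (s).
#' @examples
#' t <- seq(0, 18, by = 0.01)
#' estimate_period(data.frame(time_s = t, displacement = cos(2 * pi * t / 1.8)))
#' @export
estimate_period <- function(trace, min_cycles = 3) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "displacement") %in% names(trace)))
  tt <- trace$time_s
  x <- trace$displacement - mean(trace$displacement)
  nsamp <- length(x)
  if (nsamp < 8L || all(abs(x) < .Machine$double.eps * 100))
    stop("insufficient data: trace has no oscillation", call. = FALSE)
  dt <- stats::median(diff(tt))
  # dominant period from the periodogram, used only to size the smoothing window
  sp <- stats::spec.pgram(x, plot = FALSE, detrend = FALSE, taper = 0.1)
  f0 <- sp$freq[which.max(sp$spec)] / dt
  if (f0 <= 0) stop("insufficient data: no dominant frequency", call. = FALSE)
  w <- max(1L, round(1 / (8 * f0 * dt)))
  if (w > 1L) {
    if (w %% 2L == 0L) w <- w + 1L
    xs <- stats::filter(x, rep(1 / w, w), sides = 2)
    keep <- !is.na(xs)
    x <- as.numeric(xs[keep]); tt <- tt[keep]
  }
  s <- sign(x)
  s[s == 0] <- 1
  ch <- which(diff(s) != 0)
  if (length(ch) < 2 * min_cycles + 1)
    stop("insufficient data: fewer than ", min_cycles,
         " full cycles in trace", call. = FALSE)
  # linear interpolation of each crossing time
  tc <- tt[ch] - x[ch] * (tt[ch + 1] - tt[ch]) / (x[ch + 1] - x[ch])
  k <- seq_along(tc)
  slope <- stats::cov(k, tc) / stats::var(k)
  2 * slope
}

#' Moment of inertia of a compound pendulum about its pivot
#'
#' The small-angle relation \eqn{T = 2\pi\sqrt{I_p/(mgl)}} inverted for the
#' pivot moment of inertia: \eqn{I_p = m g l T^2 / (4\pi^2)}.
#'
#' @param m Swinging mass (kg).
#' @param l Pivot-to-CoM distance (m).
#' @param T_s Oscillation period (s).
#' @param g Gravitational acceleration (m/s^2), default 9.81.
#' @return Moment of inertia about the pivot axis (kg m^2).
#' @examples
#' pivot_moi(1, 1, 2 * pi / sqrt(9.81))  # point mass at 1 m: exactly 1
#' @export
pivot_moi <- function(m, l, T_s, g = 9.81) {
  vals <- c(m, l, T_s, g)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all pendulum inputs must be positive", call. = FALSE)
  m * g * l * T_s^2 / (4 * pi^2)
}

#' Segment moment of inertia about its CoM by box subtraction
#'
#' The measurement-side workhorse: the composite (box plus segment) and
#' empty-box pivot moments are obtained from their periods, subtracted, and
#' the parallel-axis term removed, giving the segment moment of inertia about
#' the axis through its own CoM:
#' \deqn{I_{CoM} = \frac{m_c g l_c T_c^2 - m_b g l_b T_b^2}{4\pi^2} - m_s l_s^2.}
#'
#' A negative result (physically impossible for a true moment) is returned
#' with a measurement-inconsistency warning rather than clamped: packaged
#' measured data contain such values and fidelity is preferred.
#'
#' @param composite \code{\link{pendulum_trial}} with label
#'   \code{"composite"}.
#' @param box \code{\link{pendulum_trial}} with label \code{"empty_box"}.
#' @param m_s Segment mass (kg); should equal the composite/box mass
#'   difference within \code{mass_tol}.
#' @param l_s Pivot-to-segment-CoM distance (m).
#' @param g Gravitational acceleration (m/s^2).
#' @param mass_tol Relative tolerance for the mass-consistency precondition.
#' @param neg_tol Absolute slack before a negative result triggers a warning.
#' @return Segment moment of inertia about its CoM (kg m^2).
#' @export
segment_com_moi <- function(composite, box, m_s, l_s, g = 9.81,
                            mass_tol = 1e-6, neg_tol = 1e-12) {
  stopifnot(inherits(composite, "pendulum_trial"),
            inherits(box, "pendulum_trial"))
  if (composite$label != "composite" || box$label != "empty_box")
    stop("trials must be labelled composite and empty_box", call. = FALSE)
  if (m_s < 0 || l_s < 0)
    stop("m_s and l_s must be non-negative", call. = FALSE)
  dm <- composite$mass - box$mass
  if (abs(dm - m_s) > mass_tol * max(1, composite$mass))
    stop("segment mass inconsistent with composite minus box mass",
         call. = FALSE)
  Ic <- composite$mass * g * composite$pivot_to_com * composite$period^2
  Ib <- box$mass * g * box$pivot_to_com * box$period^2
  out <- (Ic - Ib) / (4 * pi^2) - m_s * l_s^2
  if (out < -neg_tol)
    warning("negative segment MoI (", format(out),
            " kg m^2): measurement inconsistency", call. = FALSE)
  out
}

#' Product of inertia from a coplanar skew-axis measurement
#'
#' Recovers the product of inertia \eqn{P_{ab}} of a pair of orthogonal axes
#' from the three moments measured about axis a, axis b and a coplanar skew
#' axis at angle \eqn{\theta} from axis b:
#' \deqn{P_{ab} = \frac{I_{bb} + I_{aa}\tan^2\theta -
#'       (1+\tan^2\theta) I^*}{2\tan\theta}.}
#' With the skew axis \eqn{u = \sin\theta\,\hat a + \cos\theta\,\hat b} and
#' \eqn{I^* = u^T M u}, this is the exact algebraic inverse of
#' \code{\link{moi_about_axis}}: the numerator reduces to
#' \eqn{2 P_{ab}\tan\theta} identically. All three moments must be taken about
#' axes through a common point.
#'
#' For the canonical xy pair, \eqn{a = x}, \eqn{b = y} and \eqn{\theta} is the
#' angle between the yy axis and the skew xy axis.
#'
#' @param I_aa,I_bb Moments about the two orthogonal axes (kg m^2).
#' @param I_star Moment about the coplanar skew axis (kg m^2).
#' @param theta Angle (radians) between axis b and the skew axis, in
#'   (0, pi/2) and away from both ends (ill-conditioned otherwise).
#' @param cond_tol Minimum distance (radians) from 0 and pi/2.
#' @return The product of inertia \eqn{P_{ab}} (kg m^2).
#' @examples
#' product_moi(I_aa = 2, I_bb = 3, I_star = 2, theta = pi / 4)  # 0.5
#' @export
product_moi <- function(I_aa, I_bb, I_star, theta, cond_tol = 1e-3) {
  if (!is.finite(theta) || theta <= cond_tol || theta >= pi / 2 - cond_tol)
    stop("theta = ", format(theta),
         " rad is outside (0, pi/2) or too close to its ends: ill-conditioned",
         call. = FALSE)
  t2 <- tan(theta)^2
  (I_bb + I_aa * t2 - (1 + t2) * I_star) / (2 * tan(theta))
}

#' Segment CoM from knife-edge balance
#'
#' Moment balance per axis: the composite (box plus segment) balances at
#' \eqn{x_c}, the empty box CoM is known, and the segment CoM follows from
#' \eqn{x_s = (m_c x_c - m_b x_b)/m_s} with \eqn{m_c = m_s + m_b}.
#'
#' @param composite_balance 3-vector of composite balance points (m, box
#'   frame).
#' @param box_mass Empty box mass (kg).
#' @param box_com 3-vector box CoM (m, box frame).
#' @param m_s Segment mass (kg, > 0).
#' @return 3-vector segment CoM (m, box frame).
#' @examples
#' com_from_balance(c(0.4, 0, 0), box_mass = 1, box_com = c(0.5, 0, 0), m_s = 2)
#' @export
com_from_balance <- function(composite_balance, box_mass, box_com, m_s) {
  if (!is.finite(m_s) || m_s <= 0)
    stop("segment mass must be positive", call. = FALSE)
  stopifnot(length(composite_balance) == 3L, length(box_com) == 3L,
            box_mass >= 0)
  m_c <- m_s + box_mass
  (m_c * composite_balance - box_mass * box_com) / m_s
}

#' Average repeated segment mass measurements
#'
#' Segment masses are taken three times over storage to monitor sublimation
#' loss; the arithmetic mean is used for inertial calculations and the maximum
#' relative spread is reported (and warned about beyond a threshold).
#'
#' @param m1,m2,m3 The three mass measurements (kg, > 0).
#' @param spread_warn Relative spread (range/mean) above which to warn.
#' @return List with \code{mean} (kg) and \code{spread} (relative range).
#' @examples
#' average_masses(0.99, 1.00, 1.01)
#' @export
average_masses <- function(m1, m2, m3, spread_warn = 0.05) {
  m <- c(m1, m2, m3)
  if (!all(is.finite(m)) || any(m <= 0))
    stop("all three masses must be positive", call. = FALSE)
  mu <- mean(m)
  spread <- (max(m) - min(m)) / mu
  if (spread > spread_warn)
    warning(sprintf("mass spread %.1f%% exceeds %.1f%%: possible sublimation or recording error",
                    100 * spread, 100 * spread_warn), call. = FALSE)
  list(mean = mu, spread = spread)
}

# skew-axis unit vectors for the three coplanar pairs, theta measured from the
# second axis of the pair (xy: from yy; xz: from zz; yz: from zz)
skew_axis_unit <- function(pair, theta) {
  switch(pair,
    xy = c(sin(theta), cos(theta), 0),
    xz = c(sin(theta), 0, cos(theta)),
    yz = c(0, sin(theta), cos(theta)),
    stop("unknown axis pair: ", pair, call. = FALSE))
}

#' Invert a full six-axis pendulum session to a segment tensor
#'
#' Runs the complete measurement-side computation for one segment: estimates
#' the period of every trace (mean over repeated trials), converts the three
#' primary-axis trial pairs to CoM moments via \code{\link{segment_com_moi}},
#' converts the three skew-axis pairs to skew moments the same way, and
#' recovers the products of inertia via \code{\link{product_moi}}. Returns the
#' reconstructed 6-component tensor about the segment CoM in box axes.
#'
#' @param session One segment's session as produced by
#'   \code{\link{generate_pendulum_session}}: a list with \code{trials} (data
#'   frame of axis, label, mass, pivot_to_com) and \code{traces} (named list
#'   of lists of trace data frames, names \code{"<axis>_<label>"}).
#' @param theta Skew-axis angle (radians) used in the session.
#' @param g Gravitational acceleration (m/s^2).
#' @param use_true_periods If \code{TRUE}, bypass trace period estimation and
#'   use the noise-free periods stored in \code{trials$period_true} (useful
#'   for isolating trace-estimation error).
#' @return List with \code{tensor} (an \code{\link{inertia_tensor}} about the
#'   CoM, box axes), \code{moments} (named vector of the six measured CoM
#'   moments) and \code{m_s} (segment mass used).
#' @export
invert_pendulum_session <- function(session, theta = pi / 4, g = 9.81,
                                    use_true_periods = FALSE) {
  trials <- session$trials
  stopifnot(is.data.frame(trials))
  axes <- c("xx", "yy", "zz", "xy", "xz", "yz")
  period_of <- function(axis, label) {
    row <- trials[trials$axis == axis & trials$label == label, , drop = FALSE]
    if (nrow(row) != 1L) stop("missing trial ", axis, "/", label, call. = FALSE)
    if (use_true_periods) return(row$period_true)
    key <- paste(axis, label, sep = "_")
    reps <- session$traces[[key]]
    mean(vapply(reps, estimate_period, numeric(1)))
  }
  trial_of <- function(axis, label) {
    row <- trials[trials$axis == axis & trials$label == label, , drop = FALSE]
    pendulum_trial(row$mass, row$pivot_to_com, period_of(axis, label),
                   label = if (label == "composite") "composite" else "empty_box")
  }
  m_s <- trials$mass[trials$label == "composite"][1] -
    trials$mass[trials$label == "empty_box"][1]
  l_s <- session$l_s
  moments <- vapply(axes, function(ax) {
    segment_com_moi(trial_of(ax, "composite"), trial_of(ax, "empty_box"),
                    m_s = m_s, l_s = l_s, g = g)
  }, numeric(1))
  P_xy <- product_moi(moments[["xx"]], moments[["yy"]], moments[["xy"]], theta)
  P_xz <- product_moi(moments[["xx"]], moments[["zz"]], moments[["xz"]], theta)
  P_yz <- product_moi(moments[["yy"]], moments[["zz"]], moments[["yz"]], theta)
  tensor <- inertia_tensor(moments[["xx"]], moments[["yy"]], moments[["zz"]],
                           P_xy, P_xz, P_yz,
                           frame_point = "com", axes_label = "box")
  list(tensor = tensor, moments = moments, m_s = m_s)
}
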