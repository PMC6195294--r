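#' The packaged morphometric regression equations
#'
#' Loads the transcription of the 44 regression equations (11 segment masses,
#' 33 moments of inertia) predicting BSPs from whole-body mass and geometric
#' terms built from named linear dimensions. Each row carries the segment,
#' the predicted quantity (\code{mass} or a box-axis moment \code{I_xx} /
#' \code{I_yy} / \code{I_zz}), the anatomical axis label, the three
#' coefficients (body-mass slope, geometry-term coefficient, intercept), the
#' geometry-term kind with its ordered dimension keys, whether the printed
#' regressor multiplies the geometry term by body mass, and the printed R^2.
#'
#' @param segment Optional segment name filter.
#' @param quantity Optional quantity filter (\code{"mass"}, \code{"I_xx"},
#'   \code{"I_yy"}, \code{"I_zz"}).
#' @return Data frame of equations.
#' @export
bsp_equations <- function(segment = NULL, quantity = NULL) {
  eqs <- read_bsp_table("regression_equations.csv")
  eqs$note[is.na(eqs$note)] <- ""
  if (!is.null(segment)) eqs <- eqs[eqs$segment %in% segment, , drop = FALSE]
  if (!is.null(quantity)) eqs <- eqs[eqs$quantity %in% quantity, , drop = FALSE]
  eqs
}

#' Dimension-key dictionary
#'
#' Maps each regression dimension key (\code{<segment>.<letter>}) to its
#' measurement definition. The \code{ambiguous} flag marks dimensions whose
#' printed definition does not fully specify the measurement.
#'
#' @return Data frame with columns \code{segment}, \code{key},
#'   \code{definition}, \code{ambiguous}.
#' @export
dimension_dictionary <- function() {
  read_bsp_table("dimension_dictionary.csv")
}

#' Evaluate a geometry regressor term
#'
#' Computes the geometric-solid regressor used by the regression equations.
#' Kinds and their formulas on the ordered key values \eqn{k_1, k_2, k_3}:
#' \itemize{
#'   \item \code{cylinder_volume}: \eqn{k_1 k_2^2}
#'   \item \code{frustum_volume}: \eqn{k_1 (k_2^2 + k_2 k_3 + k_3^2)}
#'   \item \code{box_volume}: \eqn{k_1 k_2 k_3}
#'   \item \code{transverse_cylinder}: \eqn{0.076 k_1^2 + k_2^2}. The printed
#'     constant 0.076 is \eqn{3/(4\pi^2)} to three figures: a transverse
#'     cylinder moment is \eqn{m(3r^2+L^2)/12} and with circumference
#'     \eqn{k_1 = 2\pi r} the bracket \eqn{3r^2 + L^2} becomes
#'     \eqn{3 k_1^2/(4\pi^2) + k_2^2}.
#'   \item \code{transverse_cylinder_circ}: \eqn{(k_1/\pi)^2 + k_2^2}
#'     (diameter-squared form of the same identity).
#'   \item \code{axial_frustum}: \eqn{(k_1^5 - k_2^5)/(k_1^3 - k_2^3)}; at
#'     \eqn{k_1 = k_2} the analytic limit \eqn{(5/3)k_1^2} is used.
#'   \item \code{dim_squared}: \eqn{k_1^2}
#'   \item \code{ellipsoid_sum}: \eqn{k_1^2 + k_2^2}
#'   \item \code{mass_only}: no geometry term (returns 0)
#' }
#'
#' @param term_kind One of the kinds above.
#' @param values Numeric vector of key values, in key order (m).
#' @return The regressor value.
#' @examples
#' build_term("transverse_cylinder", c(2 * pi, 0))  # 0.076 * 4 pi^2 ~= 3
#' build_term("axial_frustum", c(1, 1))             # limit 5/3
#' @export
build_term <- function(term_kind, values) {
  values <- as.numeric(values)
  arity <- c(mass_only = 0L, cylinder_volume = 2L, frustum_volume = 3L,
             box_volume = 3L, transverse_cylinder = 2L,
             transverse_cylinder_circ = 2L, axial_frustum = 2L,
             dim_squared = 1L, ellipsoid_sum = 2L)
  if (!term_kind %in% names(arity))
    stop("unknown term kind: ", term_kind, call. = FALSE)
  if (length(values) != arity[[term_kind]])
    stop(term_kind, " needs ", arity[[term_kind]], " key values, got ",
         length(values), call. = FALSE)
  switch(term_kind,
    mass_only = 0,
    cylinder_volume = values[1] * values[2]^2,
    frustum_volume = values[1] * (values[2]^2 + values[2] * values[3] +
                                    values[3]^2),
    box_volume = values[1] * values[2] * values[3],
    transverse_cylinder = 0.076 * values[1]^2 + values[2]^2,
    transverse_cylinder_circ = (values[1] / pi)^2 + values[2]^2,
    axial_frustum = {
      if (isTRUE(all.equal(values[1], values[2])))
        5 / 3 * values[1]^2
      else
        (values[1]^5 - values[2]^5) / (values[1]^3 - values[2]^3)
    },
    dim_squared = values[1]^2,
    ellipsoid_sum = values[1]^2 + values[2]^2)
}

eq_keys <- function(eq) {
  if (!nzchar(eq$keys)) character(0) else strsplit(eq$keys, ";")[[1]]
}

lookup_dims <- function(eq, dims) {
  keys <- eq_keys(eq)
  if (length(keys) == 0L) return(numeric(0))
  full <- paste(eq$segment, keys, sep = ".")
  missing <- full[!full %in% names(dims)]
  if (length(missing) > 0L) {
    dict <- dimension_dictionary()
    defs <- vapply(missing, function(k) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      hit <- dict$definition[dict$segment == parts[1] & dict$key == parts[2]]
      if (length(hit)) hit else "(no definition)"
    }, character(1))
    stop("missing dimension(s) for ", eq$segment, " ", eq$quantity, ": ",
         paste(sprintf("%s [%s]", missing, defs), collapse = "; "),
         call. = FALSE)
  }
  as.numeric(dims[full])
}

#' Evaluate one regression equation on a morphometric record
#'
#' Literal evaluation of a transcribed equation:
#' \eqn{\beta_a a + \beta_g (a^{p}) g(\mathrm{dims}) + \beta_0} where
#' \eqn{a} is whole-body mass (kg), \eqn{g} the geometry regressor of the
#' equation's term kind and \eqn{p \in \{0,1\}} records whether the printed
#' regressor includes body mass. The result carries validity flags: body mass
#' outside the reference cohort range (34.29-39.41 kg) marks the prediction
#' as extrapolated, and a non-positive prediction is flagged non-physical
#' (but returned; the caller decides).
#'
#' @param eq One-row data frame from \code{\link{bsp_equations}}.
#' @param body_mass Whole-body mass (kg).
#' @param dims Named numeric vector of dimensions, names
#'   \code{<segment>.<letter>} (m).
#' @return List with \code{value} (kg or kg m^2), \code{quantity},
#'   \code{segment}, \code{axis}, \code{extrapolated}, \code{non_physical}.
#' @examples
#' eq <- bsp_equations("manus", "mass")
#' evaluate_equation(eq, body_mass = 36.8,
#'                   dims = c(manus.b = 0.20, manus.c = 0.14))
#' @export
evaluate_equation <- function(eq, body_mass, dims = numeric(0)) {
  stopifnot(is.data.frame(eq), nrow(eq) == 1L,
            is.finite(body_mass), body_mass >= 0)
  g <- build_term(eq$term_kind, lookup_dims(eq, dims))
  geom <- if (is.na(eq$coef_geom)) 0 else {
    eq$coef_geom * (if (eq$geom_includes_a == 1L) body_mass else 1) * g
  }
  value <- eq$coef_a * body_mass + geom + eq$intercept
  rng <- reference_dog()$body_mass_range
  list(value = value,
       quantity = eq$quantity, segment = eq$segment, axis = eq$axis,
       extrapolated = body_mass < rng[1] || body_mass > rng[2],
       non_physical = value <= 0)
}

#' Predict all segment BSPs from one morphometric record
#'
#' Applies every applicable packaged equation to a record, returning segment
#' masses and the three primary-axis moments of inertia per segment, with the
#' box-axis quantities mapped to anatomical axes. Segments whose dimensions
#' are missing from the record are skipped and listed in the
#' \code{missing} attribute.
#'
#' @param body_mass Whole-body mass (kg).
#' @param dims Named numeric vector of dimensions (\code{<segment>.<letter>},
#'   m).
#' @return Data frame with columns \code{segment}, \code{quantity},
#'   \code{axis}, \code{value}, \code{unit}, \code{extrapolated},
#'   \code{non_physical}; attribute \code{missing} lists skipped
#'   segment/quantity pairs and their missing keys.
#' @export
predict_bsp <- function(body_mass, dims = numeric(0)) {
  eqs <- bsp_equations()
  rows <- list(); missing <- list()
  for (i in seq_len(nrow(eqs))) {
    eq <- eqs[i, , drop = FALSE]
    res <- tryCatch(evaluate_equation(eq, body_mass, dims),
                    error = function(e) e)
    key <- paste(eq$segment, eq$quantity, sep = ".")
    if (inherits(res, "error")) {
      missing[[key]] <- conditionMessage(res)
      next
    }
    rows[[key]] <- data.frame(
      segment = res$segment, quantity = res$quantity, axis = res$axis,
      value = res$value,
      unit = if (res$quantity == "mass") "kg" else "kg m^2",
      extrapolated = res$extrapolated, non_physical = res$non_physical,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Fit a body-mass + geometry-term regression on a cohort
#'
#' Ordinary least squares of an observed BSP on an intercept, whole-body mass
#' and one geometry regressor — the model family behind the packaged
#' equations. The regressor is built per record from the term kind and keys
#' (multiplied by body mass when \code{geom_includes_a}).
#'
#' @param records Data frame with column \code{body_mass_kg} and dimension
#'   columns named \code{<segment>.<letter>}.
#' @param observed Numeric vector of observed values (kg or kg m^2), one per
#'   record.
#' @param term_kind Geometry term kind (see \code{\link{build_term}}); use
#'   \code{"mass_only"} for a body-mass-only fit.
#' @param keys Character vector of full dimension keys for the term, in
#'   order.
#' @param geom_includes_a Multiply the geometry term by body mass (as the
#'   packaged MoI equations do)?
#' @return Object of class \code{"bsp_fit"}: coefficients (intercept,
#'   body-mass slope, geometry coefficient), their standard errors, R^2,
#'   residuals, \code{n} and the term description.
#' @export
fit_bsp <- function(records, observed, term_kind, keys = character(0),
                    geom_includes_a = FALSE) {
  stopifnot(is.data.frame(records), "body_mass_kg" %in% names(records),
            length(observed) == nrow(records))
  n <- nrow(records)
  p <- if (term_kind == "mass_only") 2L else 3L
  if (n < p + 1L)
    stop("need at least ", p + 1L, " records, got ", n, call. = FALSE)
  a <- records$body_mass_kg
  dat <- data.frame(y = observed, a = a)
  if (term_kind != "mass_only") {
    g <- vapply(seq_len(n), function(i) {
      build_term(term_kind, as.numeric(records[i, keys]))
    }, numeric(1))
    dat$g <- g * (if (geom_includes_a) a else 1)
    X <- cbind(1, dat$a, dat$g)
  } else {
    X <- cbind(1, dat$a)
  }
  if (qr(X)$rank < ncol(X))
    stop("collinear or constant regressors: design matrix is singular",
         call. = FALSE)
  fit <- if (term_kind == "mass_only") stats::lm(y ~ a, data = dat)
         else stats::lm(y ~ a + g, data = dat)
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    r_squared = sm$r.squared,
    residuals = stats::residuals(fit),
    n = n, term_kind = term_kind, keys = keys,
    geom_includes_a = geom_includes_a,
    lm = fit), class = "bsp_fit")
}

#' @export
print.bsp_fit <- function(x, ...) {
  cat(sprintf("BSP regression fit (n = %d, term = %s%s)\n", x$n, x$term_kind,
              if (length(x$keys)) paste0(" on ", paste(x$keys, collapse = ",")) else ""))
  print(round(rbind(coef = x$coefficients, se = x$se), 6))
  cat(sprintf("R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Select the best-fitting geometry term for a cohort
#'
#' Fits each candidate geometry term with \code{\link{fit_bsp}} and returns
#' the maximal-R^2 candidate, with the full ranking. Ties are broken by fewer
#' fitted parameters, then lexically by term kind.
#'
#' @param records,observed As in \code{\link{fit_bsp}}.
#' @param candidates List of candidates, each a list with \code{term_kind},
#'   \code{keys} and optionally \code{geom_includes_a}.
#' @return List with \code{best} (a \code{bsp_fit}), \code{best_kind} and
#'   \code{ranking} (data frame of term kind, R^2, parameter count).
#' @export
select_shape <- function(records, observed, candidates) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(cand) {
    fit_bsp(records, observed, term_kind = cand$term_kind,
            keys = cand$keys %||% character(0),
            geom_includes_a = isTRUE(cand$geom_includes_a))
  })
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  npar <- vapply(fits, function(f) length(f$coefficients), numeric(1))
  kinds <- vapply(candidates, function(cand) cand$term_kind, character(1))
  ord <- order(-r2, npar, kinds)
  ranking <- data.frame(term_kind = kinds[ord], r_squared = r2[ord],
                        n_par = npar[ord], stringsAsFactors = FALSE)
  list(best = fits[[ord[1]]], best_kind = kinds[ord[1]], ranking = ranking)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired-sample repeatability filter
#'
#' Two-sided paired t-test computed from first principles (mean difference
#' over its standard error, p-value from the t distribution), used to decide
#' whether a morphometric dimension measured before and after segmentation is
#' repeatable enough to keep. Significant differences (p below \code{alpha})
#' exclude the measure.
#'
#' Degenerate cases follow the measurement logic: identical sets give t = 0/0
#' which is treated as p = 1 (include); zero variance of the differences with
#' a non-zero mean is a systematic shift and excludes with p = 0.
#'
#' @param set1,set2 Paired numeric vectors, equal length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with \code{include} (logical), \code{p_value}, \code{t},
#'   \code{df}, \code{mean_diff}.
#' @export
repeatability_filter <- function(set1, set2, alpha = 0.05) {
  stopifnot(length(set1) == length(set2), length(set1) >= 3L)
  d <- set1 - set2
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(include = TRUE, p_value = 1, t = 0, df = n - 1L,
                  mean_diff = 0))
    return(list(include = FALSE, p_value = 0, t = Inf, df = n - 1L,
                mean_diff = md))
  }
  t_stat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(include = p >= alpha, p_value = p, t = t_stat, df = n - 1L,
       mean_diff = md)
}

#' Read a morphometric cohort CSV
#'
#' One row per dog (or per side), columns \code{body_mass_kg} plus dimension
#' columns named \code{<segment>.<letter>} in metres.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_morphometrics <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"body_mass_kg" %in% names(x))
    stop("morphometric CSV must have a body_mass_kg column", call. = FALSE)
  x
}
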