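test_that("geometry terms evaluate to their documented identities", {
  # transverse cylinder: 0.076 ~= 3/(4 pi^2); with c = 2 pi the term is ~3
  expect_equal(build_term("transverse_cylinder", c(2 * pi, 0)),
               0.076 * 4 * pi^2)
  expect_equal(0.076, 3 / (4 * pi^2), tolerance = 2e-3)
  expect_equal(build_term("axial_frustum", c(1, 1)), 5 / 3)
  # continuity at equal radii
  expect_equal(build_term("axial_frustum", c(1, 1 - 1e-9)), 5 / 3,
               tolerance = 1e-6)
  # frustum volume term with equal end dimensions: 3 b^2 c
  expect_equal(build_term("frustum_volume", c(0.4, 0.2, 0.2)),
               0.4 * 3 * 0.2^2)
  expect_gte(build_term("transverse_cylinder", c(0.3, 0.2)), 0)
  expect_error(build_term("cylinder_volume", 1), "needs 2")
  expect_error(build_term("nonsense", 1), "unknown term")
})

test_that("equation transcription cardinality and evaluation examples", {
  eqs <- bsp_equations()
  expect_equal(nrow(eqs), 44L)
  expect_equal(sum(eqs$quantity == "mass"), 11L)
  expect_equal(sum(eqs$quantity != "mass"), 33L)
  expect_true(all(eqs$r_squared > 0 & eqs$r_squared <= 1))

  eq <- bsp_equations("manus", "mass")
  # all dimensions zero: the intercept
  expect_equal(evaluate_equation(eq, 0, c(manus.b = 0, manus.c = 0))$value,
               0.077)
  # independent arithmetic: -0.003*36.8 + 69.762*0.20*0.14^2 + 0.077
  expect_equal(evaluate_equation(eq, 36.8,
                                 c(manus.b = 0.20, manus.c = 0.14))$value,
               0.2401, tolerance = 1e-3)
  # manus I_yy at the coefficient root: zero, flagged outside calibration
  r <- evaluate_equation(bsp_equations("manus", "I_yy"), 43.6)
  expect_lt(abs(r$value), 1e-12)
  expect_true(r$extrapolated)
  expect_error(evaluate_equation(eq, 36.8, c(manus.b = 0.2)),
               "missing dimension")
})

test_that("finite-difference body-mass slope matches every transcribed a-coefficient", {
  # geometry regressors are evaluated at zero dimensions so the a(geometry)
  # product terms vanish and the slope in body mass is the a-coefficient
  eqs <- bsp_equations()
  for (i in seq_len(nrow(eqs))) {
    eq <- eqs[i, , drop = FALSE]
    keys <- caninebsp:::eq_keys(eq)
    dims <- if (length(keys))
      stats::setNames(rep(0, length(keys)),
                      paste(eq$segment, keys, sep = ".")) else numeric(0)
    f1 <- evaluate_equation(eq, 37.8, dims)$value
    f0 <- evaluate_equation(eq, 35.8, dims)$value
    expect_equal((f1 - f0) / 2, eq$coef_a, tolerance = 1e-9)
  }
})

test_that("predict_bsp covers 11 masses + 33 MoIs and reports missing keys", {
  dog <- generate_dog(21)
  pred <- predict_bsp(dog$morphometrics$body_mass_kg, dog$morphometrics$dims)
  expect_equal(nrow(pred), 44L)
  expect_equal(sum(pred$quantity == "mass"), 11L)
  expect_length(attr(pred, "missing"), 0L)

  # dropping the sacrum circumference removes exactly the tail outputs
  dims <- dog$morphometrics$dims
  dims <- dims[names(dims) != "tail.c"]
  p2 <- predict_bsp(dog$morphometrics$body_mass_kg, dims)
  expect_false("tail" %in% p2$segment)
  expect_equal(nrow(p2), 40L)
  expect_true(all(grepl("^tail", names(attr(p2, "missing")))))
})

test_that("predicted segment masses sum near the generating body mass", {
  # regression equations are approximations; the landmark-calibrated
  # synthetic cohort should land well within 15 percent in total
  axial <- c("head", "neck", "thorax", "abdomen", "tail")
  for (seed in c(2, 12, 22)) {
    dog <- generate_dog(seed)
    pred <- predict_bsp(dog$morphometrics$body_mass_kg,
                        dog$morphometrics$dims)
    m <- pred[pred$quantity == "mass", ]
    tot <- sum(ifelse(m$segment %in% axial, 1, 2) * m$value)
    expect_equal(tot, dog$body_mass, tolerance = 0.15)
  }
})

test_that("fit_bsp recovers generating coefficients", {
  # noise-free synthetic cohort: exact recovery, R^2 = 1
  co <- generate_cohort(12, seed = 4, equation = bsp_equations("crus", "I_yy"),
                        noise = 0)
  # lm warns that the noise-free fit is "essentially perfect" - expected here
  suppressWarnings(
    f <- fit_bsp(co$records, co$observed, "transverse_cylinder",
                 paste0("crus.", c("c", "b")), geom_includes_a = TRUE))
  expect_equal(unname(f$coefficients), unname(co$truth), tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # with noise at n = 12: coefficients within 2 SE of truth
  co <- generate_cohort(12, seed = 4, equation = bsp_equations("crus", "I_yy"),
                        noise = 0.01)
  f <- fit_bsp(co$records, co$observed, "transverse_cylinder",
               paste0("crus.", c("c", "b")), geom_includes_a = TRUE)
  expect_true(all(abs(f$coefficients - co$truth) <= 2 * f$se))

  # constant regressor: collinearity error
  rec <- co$records
  rec$body_mass_kg <- 36.8
  rec[["crus.c"]] <- 0.2; rec[["crus.b"]] <- 0.25
  expect_error(fit_bsp(rec, co$observed, "transverse_cylinder",
                       paste0("crus.", c("c", "b")), geom_includes_a = TRUE),
               "singular")
  expect_error(fit_bsp(co$records[1:3, ], co$observed[1:3],
                       "transverse_cylinder", paste0("crus.", c("c", "b"))),
               "at least")
})

test_that("select_shape ranks candidates and breaks ties deterministically", {
  co <- generate_cohort(12, seed = 8, equation = bsp_equations("abdomen", "mass"),
                        noise = 0.01)
  k <- paste0("abdomen.", c("c", "b", "d"))
  cands <- list(list(term_kind = "frustum_volume", keys = k),
                list(term_kind = "cylinder_volume", keys = k[1:2]),
                list(term_kind = "ellipsoid_sum", keys = k[2:3]))
  sel <- select_shape(co$records, co$observed, cands)
  expect_equal(sel$best_kind, "frustum_volume")
  expect_equal(nrow(sel$ranking), 3L)
  # single candidate returned unchanged
  one <- select_shape(co$records, co$observed, cands[2])
  expect_equal(one$best_kind, "cylinder_volume")
  # identical candidates: first by tie-break (fewer params, then lexical)
  two <- select_shape(co$records, co$observed,
                      list(cands[[1]], cands[[1]]))
  expect_equal(two$best_kind, "frustum_volume")
})

test_that("repeatability filter matches first principles and t.test", {
  # identical sets: t = 0/0 handled as include with p = 1
  r <- repeatability_filter(c(1, 2, 3), c(1, 2, 3))
  expect_true(r$include); expect_equal(r$p_value, 1)
  # constant non-zero shift: systematic difference, exclude with p = 0
  r <- repeatability_filter(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_false(r$include); expect_equal(r$p_value, 0)
  # near-constant shift with tiny jitter: excluded
  set1 <- c(1, 2, 3, 4, 5)
  set2 <- set1 + 1 + c(1, -1, 2, -2, 0) * 1e-6
  expect_false(repeatability_filter(set1, set2)$include)
  # cross-check t statistic and p against the reference implementation
  withr::with_seed(77, {
    a <- stats::rnorm(6, 10, 1); b <- a + stats::rnorm(6, 0.3, 0.5)
  })
  r <- repeatability_filter(a, b)
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(r$include, tt$p.value >= 0.05)
  expect_error(repeatability_filter(1:2, 1:2), "length")
})

test_that("morphometric CSV round trip", {
  dog <- generate_dog(33)
  df <- as.data.frame(c(list(body_mass_kg = dog$body_mass),
                        as.list(dog$morphometrics$dims)),
                      check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_morphometrics(path)
  expect_equal(back$body_mass_kg, dog$body_mass, tolerance = 1e-9)
  pred <- predict_bsp(back$body_mass_kg[1],
                      unlist(back[1, setdiff(names(back), "body_mass_kg")]))
  expect_equal(nrow(pred), 44L)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_morphometrics(bad), "body_mass_kg")
})
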