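make_trace <- function(T_s, fs = 100, cycles = 10, noise = 0, seed = 1,
                       phase = 0) {
  t <- seq(0, cycles * T_s, by = 1 / fs)
  x <- cos(2 * pi * t / T_s + phase)
  if (noise > 0)
    x <- x + withr::with_seed(seed, stats::rnorm(length(t), 0, noise))
  data.frame(time_s = t, displacement = x)
}

test_that("period estimation: clean, noisy and degenerate traces", {
  tr <- make_trace(1.8, fs = 100, cycles = 10)
  expect_equal(estimate_period(tr), 1.8, tolerance = 0.01 / 1.8)

  trn <- make_trace(1.8, fs = 100, cycles = 10, noise = 0.05, seed = 42)
  expect_equal(estimate_period(trn), 1.8, tolerance = 0.01)

  flat <- data.frame(time_s = seq(0, 10, 0.01), displacement = 1)
  expect_error(estimate_period(flat), "insufficient")
  short <- make_trace(1.8, cycles = 2)
  expect_error(estimate_period(short), "insufficient")
})

test_that("pivot_moi implements m g l T^2 / (4 pi^2)", {
  # point mass at 1 m: T = 2 pi / sqrt(g) gives I = m l^2 = 1
  expect_equal(pivot_moi(1, 1, 2 * pi / sqrt(9.81)), 1, tolerance = 1e-12)
  expect_equal(pivot_moi(2, 0.5, 1.5, g = 9.81), 0.55910, tolerance = 1e-4)
  expect_equal(pivot_moi(1, 1, 2), 4 * pivot_moi(1, 1, 1))  # T^2 scaling
  expect_error(pivot_moi(-1, 1, 1), "positive")
})

test_that("segment_com_moi subtracts box and parallel-axis terms", {
  T0 <- 2 * pi / sqrt(9.81)
  box <- pendulum_trial(1, 1, T0, "empty_box")
  comp <- pendulum_trial(2, 1, T0, "composite")
  # point-mass segment hanging at the pivot distance: zero CoM inertia
  expect_equal(segment_com_moi(comp, box, m_s = 1, l_s = 1), 0,
               tolerance = 1e-10)
  # composite identical to box: m_s = 0 segment contributes nothing
  comp0 <- pendulum_trial(1, 1, T0, "composite")
  expect_equal(segment_com_moi(comp0, box, m_s = 0, l_s = 1), 0,
               tolerance = 1e-12)
  expect_error(segment_com_moi(comp, box, m_s = 0.5, l_s = 1),
               "inconsistent")
  # forward-simulated cylinder recovered through the period relation
  s <- geometric_solid("cylinder", list(radius = 0.04, length = 0.3),
                       density = 1000)
  si <- solid_inertia(s)
  g <- 9.81; l <- 0.3
  m_b <- 0.8; I_b <- 0.01
  for (ax in c("xx", "zz")) {
    I_s <- si$tensor$I[[ax]]
    m_c <- si$mass + m_b
    T_c <- 2 * pi * sqrt((I_s + I_b + m_c * l^2) / (m_c * g * l))
    T_b <- 2 * pi * sqrt((I_b + m_b * l^2) / (m_b * g * l))
    got <- segment_com_moi(pendulum_trial(m_c, l, T_c, "composite"),
                           pendulum_trial(m_b, l, T_b, "empty_box"),
                           m_s = si$mass, l_s = l)
    expect_equal(got, I_s, tolerance = 0.005)
  }
  # negative extracted MoI warns but returns
  bad <- pendulum_trial(2, 1, T0 * 0.99, "composite")
  expect_warning(v <- segment_com_moi(bad, box, m_s = 1, l_s = 1),
                 "negative")
  expect_lt(v, 0)
})

test_that("product_moi inverts the skew-axis quadratic form exactly", {
  itp <- inertia_tensor(2, 3, 4, pxy = 0.5)
  I_star <- moi_about_axis(itp, c(1, 1, 0) / sqrt(2))
  expect_equal(I_star, 2.0)
  expect_equal(product_moi(2, 3, I_star, pi / 4), 0.5, tolerance = 1e-12)
  # diagonal tensor at 45 degrees: I* is the mean, product is zero
  expect_equal(product_moi(2, 3, 2.5, pi / 4), 0, tolerance = 1e-12)
  # property: exact recovery for random tensors and angles in (10, 80) deg
  for (seed in 1:50) {
    it <- random_tensor(seed)
    th <- withr::with_seed(seed + 5000,
                           stats::runif(1, 10, 80)) * pi / 180
    for (pair in c("xy", "xz", "yz")) {
      u <- caninebsp:::skew_axis_unit(pair, th)
      I_star <- moi_about_axis(it, u)
      ab <- switch(pair, xy = c("xx", "yy"), xz = c("xx", "zz"),
                   yz = c("yy", "zz"))
      got <- product_moi(it$I[[ab[1]]], it$I[[ab[2]]], I_star, th)
      scale <- max(abs(unlist(it$I)))
      expect_lt(abs(got - it$P[[pair]]), 1e-9 * scale)
    }
  }
  expect_error(product_moi(1, 1, 1, 1e-6), "ill-conditioned")
  expect_error(product_moi(1, 1, 1, pi / 2), "ill-conditioned")
})

test_that("com_from_balance solves the moment balance", {
  expect_equal(com_from_balance(c(0.4, 0, 0), box_mass = 1,
                                box_com = c(0.5, 0, 0), m_s = 2)[1], 0.35)
  # segment CoM coincident with box CoM: composite balances there
  expect_equal(com_from_balance(c(0.5, 0.2, 0.1), box_mass = 1,
                                box_com = c(0.5, 0.2, 0.1), m_s = 3),
               c(0.5, 0.2, 0.1))
  # heavy segment, negligible box: balance point is the segment CoM
  expect_equal(com_from_balance(c(0.31, 0, 0), box_mass = 1e-9,
                                box_com = c(0, 0, 0), m_s = 50)[1], 0.31,
               tolerance = 1e-9)
  expect_error(com_from_balance(c(0, 0, 0), 1, c(0, 0, 0), m_s = 0),
               "positive")
})

test_that("average_masses reports mean and spread", {
  r <- average_masses(1, 1, 1)
  expect_equal(r$mean, 1); expect_equal(r$spread, 0)
  r <- average_masses(0.99, 1.00, 1.01)
  expect_equal(r$mean, 1.00)
  expect_equal(r$spread, 0.02, tolerance = 1e-10)
  expect_warning(r <- average_masses(1.0, 1.0, 0.5), "spread")
  expect_equal(r$mean, 0.8333, tolerance = 1e-4)
})

test_that("six-axis sessions invert to ground-truth tensors", {
  dog <- generate_dog(3)
  # noise-free: full tensor within 1 percent (period estimation from traces)
  for (seg in c("manus", "thorax")) {
    sess <- generate_pendulum_session(dog, seg, noise = 0, seed = 5)
    rec <- invert_pendulum_session(sess, theta = sess$theta)
    expect_lt(frob_rel_err(rec$tensor, sess$truth$tensor), 0.01)
    expect_equal(rec$m_s, sess$truth$mass, tolerance = 1e-9)
    # box-only trials invert to the known calibration
    b <- sess$trials[sess$trials$label == "empty_box" &
                       sess$trials$axis == "xx", ]
    I_b <- pivot_moi(b$mass, b$pivot_to_com, b$period_true) -
      b$mass * b$pivot_to_com^2
    expect_equal(I_b, sess$box$tensor$I[["xx"]], tolerance = 1e-9)
    # knife-edge balance recovers the segment CoM placement
    expect_equal(com_from_balance(sess$balance$composite_balance,
                                  sess$balance$box_mass,
                                  sess$balance$box_com, sess$balance$m_s),
                 sess$box$com)
  }
  # 5 percent trace noise still recovers within a few percent
  sess <- generate_pendulum_session(dog, "crus", noise = 0.05, seed = 11)
  rec <- invert_pendulum_session(sess, theta = sess$theta)
  expect_lt(frob_rel_err(rec$tensor, sess$truth$tensor), 0.05)
})
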