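# synthetic-data generator: input model, compartment model, frame binning,
# cohort sampling

test_that("parametric input curve matches direct formula evaluation", {
  p <- input_model_params()
  # independent closed-form evaluation at t = 1 min (u = 0.5)
  u <- 1 - 0.5
  expected <- (600 * u - 6 - 1.6) * exp(-4 * u) +
    6 * exp(-0.25 * u) + 1.6 * exp(-0.012 * u)
  expect_equal(generate_input_curve(p, 1), expected, tolerance = 1e-12)

  # zero amplitudes give the zero curve; values before the delay are zero
  p0 <- input_model_params(a1 = 0, a2 = 0, a3 = 0)
  expect_equal(generate_input_curve(p0, c(0, 1, 5, 50)), rep(0, 4))
  expect_equal(generate_input_curve(p, c(0, 0.2, 0.49)), rep(0, 3))

  # domain validation
  expect_error(generate_input_curve(p, c(2, 1)), "sorted")
  expect_error(generate_input_curve(p, c(-1, 1)), "nonnegative")
  expect_error(input_model_params(l1 = -0.1, l2 = -4), "l1 <= l2")
})

test_that("tissue curve obeys the compartment model closed forms", {
  cp <- default_cp()
  times <- c(1, 5, 20, 40)

  # no exchange: C_T is the blood-volume fraction of the input
  kp <- kinetic_params(0, 0.1, 0.05, vb = 0.05)
  expect_equal(simulate_tissue_curve(kp, cp, times), 0.05 * cp(times),
               tolerance = 1e-10)

  # constant input, irreversible: closed-form solution of the linear system
  k1 <- 0.1; k2 <- 0.15; k3 <- 0.05; b <- k2 + k3; c0 <- 2
  kp <- kinetic_params(k1, k2, k3, vb = 0)
  const_cp <- function(t) rep(c0, length(t))
  got <- simulate_tissue_curve(kp, const_cp, times)
  c1 <- k1 * c0 / b * (1 - exp(-b * times))
  c2 <- k3 * k1 * c0 / b * (times - (1 - exp(-b * times)) / b)
  expect_equal(got, c1 + c2, tolerance = 1e-7)

  # its late-time slope approaches Ki_true * Cp
  tt <- c(60, 61)
  slope <- diff(simulate_tissue_curve(kp, const_cp, tt))
  expect_equal(slope, ki_true(kp) * c0, tolerance = 1e-3)
  expect_equal(ki_true(kp), k1 * k3 / b)
  expect_equal(ki_true(kinetic_params(0.1, 0.2, 0)), 0)

  # reversible tracer plateaus at (K1/k2) * Cp
  kpr <- kinetic_params(0.1, 0.2, 0, vb = 0)
  plateau <- simulate_tissue_curve(kpr, const_cp, 120)
  expect_equal(plateau, 0.1 / 0.2 * c0, tolerance = 1e-4)
})

test_that("frame averaging equals analytic and quadrature means", {
  sched <- fs_thorax()
  # constant curve: every frame equals the constant
  expect_equal(frame_average(function(t) rep(3.2, length(t)), sched)$activity,
               rep(3.2, nrow(sched)))
  # linear 0 -> 2 kBq/mL over a single [0, 60 s] frame averages to 1
  lin <- frame_average(function(t) 2 * t, frame_schedule(0, 60))
  expect_equal(lin$activity, 1.0)
  # smooth curve: matches adaptive quadrature to 1e-6
  f <- function(t) 3 + 0.5 * t - 0.02 * t^2 + exp(-t)
  got <- frame_average(f, sched)
  want <- vapply(seq_len(nrow(sched)), function(i) {
    a <- sched$start_s[i] / 60; b <- sched$end_s[i] / 60
    stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
  }, numeric(1))
  expect_equal(got$activity, want, tolerance = 1e-6)
  expect_error(frame_schedule(0, 0), "positive")
  expect_error(frame_schedule(c(0, 10), c(20, 10)), "overlap")
})

test_that("frame schedules match the acquisition protocol", {
  th <- fs_thorax()
  expect_equal(nrow(th), 20L)                  # 4+6+2+2+6 frames
  expect_equal(max(th$end_s), 2400)            # 0-40 min
  expect_equal(nrow(fs_abdomen()), 3L)
  expect_equal(fs_static(4800)$dur_s, 600)
})

test_that("frame-noise variance scales inversely with frame duration", {
  sched <- frame_schedule(c(0, 60), c(60, 240))
  base <- tac(sched, c(4, 4))
  set.seed(42)
  reps <- replicate(1500, tac_add_noise(base, scale = 0.3)$activity)
  v <- apply(reps, 1, var)
  # sd = scale * sqrt(value / dur_min): variances 0.09*4 and 0.09*1
  expect_equal(v[1] / v[2], 4, tolerance = 0.25)
  expect_equal(v[1], 0.3^2 * 4 / 1, tolerance = 0.15)
})

test_that("cohort sampling honors the group specifications", {
  # n = 0 in both groups gives an empty cohort
  co0 <- simulate_cohort(lr_group_spec(0), hr_group_spec(0), seed = 1)
  expect_equal(nrow(co0$meta), 0L)
  expect_length(co0$subjects, 0L)

  # sd = 0 everywhere makes all subjects in a group identical
  lr_const <- lr_group_spec(4)
  lr_const$vars <- lapply(lr_const$vars, function(x) c(x[1], 0, x[3]))
  hr_const <- hr_group_spec(2)
  hr_const$vars <- lapply(hr_const$vars, function(x) c(x[1], 0, x[3]))
  md <- simulate_metadata(lr_const, hr_const, seed = 5)
  lrv <- md[md$group == "LR", !(names(md) %in% c("id", "group"))]
  expect_true(all(vapply(lrv, function(col) length(unique(col)) == 1L,
                         logical(1))))

  # impossible truncated spec is rejected
  bad <- lr_group_spec(2)
  bad$vars$mass_vat <- c(-1, 0, 0)
  expect_error(group_spec("LR", 2, bad$vars), "impossible")

  # LR M-value sample mean is within 3 standard errors of 58.0
  md <- simulate_metadata(lr_group_spec(), hr_group_spec(), seed = 11)
  m_lr <- md$m_value[md$group == "LR"]
  expect_lt(abs(mean(m_lr) - 58.0), 3 * 14.7 / sqrt(22))
  # truncation bounds are respected
  expect_true(all(md$mass_vat >= 0.2))
  expect_true(all(md$urine_frac >= 0.02))
})

test_that("identical seeds reproduce the cohort bit for bit", {
  lr <- lr_group_spec(2); hr <- hr_group_spec(2)
  a <- simulate_cohort(lr, hr, seed = 9)
  b <- simulate_cohort(lr, hr, seed = 9)
  expect_identical(a, b)
  d <- simulate_cohort(lr, hr, seed = 10)
  expect_false(identical(a$meta, d$meta))
})

test_that("noise-free simulated TACs obey Patlak consistency", {
  # asymptotic Patlak slope equals K1 k3 / (k2 + k3) within 1% for a late
  # fit window, across a spread of kinetic parameters
  cp <- default_cp()
  sched <- long_schedule()
  cases <- list(c(0.1, 0.15, 0.05), c(0.05, 0.3, 0.1), c(0.3, 0.6, 0.04))
  for (cs in cases) {
    kp <- kinetic_params(cs[1], cs[2], cs[3], vb = 0)
    x <- sim_tac(kp, sched, cp)
    est <- patlak_fit(x, cp, t_star = 45)
    expect_equal(est$rate, ki_true(kp), tolerance = 0.01)
  }
})
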