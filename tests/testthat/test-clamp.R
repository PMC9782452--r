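# clamp-derived whole-body indices

test_that("M value equals mean GIR minus space and urinary corrections", {
  # constant glucose, no urinary loss: M is the mean GIR
  t <- seq(0, 120, by = 10)
  rec <- clamp_record(t, gir = rep(50, length(t)),
                      glucose = rep(5.3, length(t)), window = c(60, 120))
  res <- m_value(rec, weight = 70, ffm = 59)
  expect_equal(res$m, 50)
  expect_equal(res$space_correction, 0)

  # hand arithmetic oracle: glucose 5.0 -> 5.2 mmol/L over 60 min,
  # vd = 0.19 L/kg: SC = 0.2 * 1000 * 0.19 / 60 = 0.6333
  gl <- seq(5.0, 5.2, length.out = length(t))
  gl[t < 60] <- 5.0
  gl[t >= 60] <- seq(5.0, 5.2, length.out = sum(t >= 60))
  rec2 <- clamp_record(t, rep(50, length(t)), gl, window = c(60, 120))
  res2 <- m_value(rec2, 70, 59, vd = 0.19)
  expect_equal(res2$space_correction, 0.2 * 1000 * 0.19 / 60,
               tolerance = 1e-12)
  expect_equal(res2$m, 50 - 0.6333333, tolerance = 1e-6)
  # a rising glucose trend lowers M
  expect_lt(res2$m, res$m)

  # M_ffm / M equals weight / FFM
  expect_equal(res$m_ffm / res$m, 70 / 59)
  expect_equal(m_value(rec, 70.3, 59.2)$m_ffm,
               m_value(rec, 70.3, 59.2)$m * 70.3 / 59.2)

  # urinary loss correction, expressed per kg and per minute
  res3 <- m_value(rec, 70, 59, urinary_glucose = 70 * 60 * 2)
  expect_equal(res3$m, 50 - 2)

  expect_error(clamp_record(t, rep(50, 13), rep(5.3, 13),
                            window = c(130, 140)), "within the record")
  rec4 <- clamp_record(t, rep(50, 13), rep(5.3, 13), window = c(0, 120))
  attr(rec4, "window") <- c(55, 56)
  expect_error(m_value(rec4, 70, 59), "window")
})

test_that("noise-free cohort clamp records return the target M exactly", {
  co <- simulate_cohort(lr_group_spec(3), hr_group_spec(0), seed = 4,
                        config = noise_free_config())
  for (id in names(co$subjects)) {
    meta <- co$meta[co$meta$id == id, ]
    res <- m_value(co$subjects[[id]]$clamp, meta$weight, meta$ffm)
    expect_equal(res$m, meta$m_value, tolerance = 1e-6)
  }
})

test_that("tracer-based Rd matches the analytic clearance formula", {
  # Cp = C0 exp(-lambda t): closed form Rd = (dose * lambda / C0) *
  # glucose_umol / (lc * weight)
  lam <- 0.04; c0 <- 8; dose <- 150; w <- 70; glc <- 5.3
  tknots <- seq(0, 60, by = 0.25)
  f <- input_function(tknots, c0 * exp(-lam * tknots))
  tb <- tracer_balance(dose, 0, w)
  want <- (dose * lam / c0) * glc * 1000 / (1.0 * w)
  expect_equal(rd_from_tracer(tb, f, glc), want, tolerance = 1e-3)

  # all excreted -> Rd = 0; linear in glucose
  expect_equal(rd_from_tracer(tracer_balance(dose, dose, w), f, glc), 0)
  expect_equal(rd_from_tracer(tb, f, 2 * glc),
               2 * rd_from_tracer(tb, f, glc))

  # invariant under common rescaling of dose and plasma curve
  f2 <- input_function(tknots, 3 * c0 * exp(-lam * tknots))
  tb2 <- tracer_balance(3 * dose, 0, w)
  expect_equal(rd_from_tracer(tb2, f2, glc), rd_from_tracer(tb, f, glc),
               tolerance = 1e-10)

  expect_error(tracer_balance(100, 101, 70), "injected")
  expect_error(tracer_balance(100, 0, 0), "positive")
})

test_that("EGP is Rd minus GIR, exactly", {
  expect_equal(egp(40, 40), 0)
  expect_equal(egp(40.0, 43.4), -3.4)
  set.seed(8)
  rd <- stats::runif(2000, 0, 100)
  gir <- stats::runif(2000, 0, 100)
  expect_equal(egp(rd[1], gir[1]) + gir[1], rd[1])
  expect_true(all(abs(mapply(egp, rd, gir) + gir - rd) < 1e-12))
})

test_that("Matsuda index follows the standard definition and scaling", {
  # hand oracle with pre-converted values G0 = 90 mg/dL, I0 = 10 uU/mL,
  # Gmean = 100, Imean = 50: 10000 / sqrt(90*10*100*50) = 4.714
  got <- matsuda_isi(90 / 18.016, 10 * 6, 100 / 18.016, 50 * 6)
  expect_equal(got, 10000 / sqrt(90 * 10 * 100 * 50), tolerance = 1e-10)
  expect_equal(got, 4.714045, tolerance = 1e-6)
  # doubling both insulin values halves the index
  expect_equal(matsuda_isi(5, 80, 6, 200),
               2 * matsuda_isi(5, 160, 6, 400), tolerance = 1e-12)
  expect_error(matsuda_isi(0, 10, 5, 10), "positive")
})

test_that("HbA1c master equation reproduces the cohort table rows", {
  expect_equal(round(ifcc_to_ngsp(29), 1), 4.8)
  expect_equal(round(ifcc_to_ngsp(32), 1), 5.1)
  # algebraic inverse round-trips
  x <- c(20, 29, 32, 48, 97)
  expect_equal(ngsp_to_ifcc(ifcc_to_ngsp(x)), x, tolerance = 1e-10)
  expect_error(ifcc_to_ngsp(0), "positive")
})

test_that("FFA suppression percentage behaves across the sign range", {
  expect_equal(ffa_suppression(0.3, 0.3), 0)
  # arithmetic oracle from the cohort table: 0.3 fasting, 0.03 clamped
  expect_equal(ffa_suppression(0.3, 0.03), 90)
  expect_lt(ffa_suppression(0.3, 0.4), 0)
  expect_error(ffa_suppression(0, 0.1), "positive")
})
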