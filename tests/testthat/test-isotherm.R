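test_that("sorbed amount follows the batch mass balance", {
  expect_equal(compute_sorbed_amount(30, 28, 10, 5), 4)
  expect_equal(compute_sorbed_amount(12, 12, 10, 5), 0)   # no depletion
  expect_equal(compute_sorbed_amount(10, 0, 10, 5), 20)   # complete removal
  expect_error(compute_sorbed_amount(10, 5, 0, 5), "volume")
  expect_error(compute_sorbed_amount(10, 5, 10, -1), "mass")
})

test_that("Freundlich linearized fit recovers generating parameters exactly", {
  cases <- list(trt_freundlich$CK, c(kf = 1, inv_n = 1), c(kf = 2, inv_n = 0.5))
  for (p in cases) {
    rec <- isotherm_data(batch_ce_levels, p["kf"] * batch_ce_levels^p["inv_n"])
    fit <- fit_freundlich(rec)
    expect_equal(fit$kf, unname(p["kf"]), tolerance = 1e-6)
    expect_equal(fit$inv_n, unname(p["inv_n"]), tolerance = 1e-6)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
  }
})

test_that("Freundlich fit matches a hand-computed log-log regression", {
  # qe = 2 * ce^0.5 at ce = 1, 4, 9, 16: ln-ln points are exactly linear
  rec <- isotherm_data(c(1, 4, 9, 16), 2 * sqrt(c(1, 4, 9, 16)))
  fit <- fit_freundlich(rec)
  expect_equal(fit$kf, 2, tolerance = 1e-9)
  expect_equal(fit$inv_n, 0.5, tolerance = 1e-9)
})

test_that("Freundlich fit is invariant to record order and duplication", {
  set.seed(42)
  rec <- isotherm_data(batch_ce_levels,
                       0.2 * batch_ce_levels^0.9 * exp(rnorm(5, sd = 0.05)))
  f1 <- fit_freundlich(rec)
  f2 <- fit_freundlich(rec[5:1, ])
  f3 <- fit_freundlich(rbind(rec, rec))
  expect_equal(f1$kf, f2$kf)
  expect_equal(f1$inv_n, f2$inv_n)
  expect_equal(f1$kf, f3$kf)
  expect_equal(f1$inv_n, f3$inv_n)
})

test_that("nonpositive records are excluded with a warning, error if too few", {
  rec <- data.frame(ce = c(0, batch_ce_levels), qe = c(5, batch_ce_levels))
  expect_warning(fit <- fit_freundlich(rec), "excluded")
  expect_equal(fit$n_obs, 5L)
  expect_equal(fit$inv_n, 1, tolerance = 1e-9)
  few <- data.frame(ce = c(-1, 0, 2, 3), qe = c(1, 1, 2, 3))
  expect_warning(expect_error(fit_freundlich(few), "fewer than 3"))
})

test_that("Langmuir linearized fit recovers generating parameters exactly", {
  for (p in trt_langmuir) {
    qe <- p["qmax"] * p["kl"] * batch_ce_levels / (1 + p["kl"] * batch_ce_levels)
    fit <- fit_langmuir(isotherm_data(batch_ce_levels, qe))
    expect_true(fit$converged)
    expect_equal(fit$kl, unname(p["kl"]), tolerance = 1e-6)
    expect_equal(fit$qmax, unname(p["qmax"]), tolerance = 1e-6)
  }
  fit <- fit_langmuir(isotherm_data(c(1, 5, 20),
                                    10 * 0.1 * c(1, 5, 20) / (1 + 0.1 * c(1, 5, 20))))
  expect_equal(fit$qmax, 10, tolerance = 1e-9)
  expect_equal(fit$kl, 0.1, tolerance = 1e-9)
})

test_that("Freundlich data with exponent above 1 drives Langmuir to NA", {
  # ce/qe = ce^(1 - 1.015)/kf is decreasing, forcing a negative slope
  p <- trt_freundlich$Cu10
  eq <- solve_batch_equilibrium(batch_design(),
                                freundlich_params(p["kf"], p["inv_n"]))
  fit <- fit_langmuir(eq)
  expect_false(fit$converged)
  expect_true(is.na(fit$kl) && is.na(fit$qmax) && is.na(fit$r2))
  expect_error(predict_isotherm(fit, 5), "non-converged")
})

test_that("isotherm prediction evaluates the forward laws", {
  fr <- freundlich_params(0.181, 0.952)
  expect_equal(predict_isotherm(fr, 10), 1.621, tolerance = 1e-3)
  expect_equal(predict_isotherm(fr, 0), 0)
  lg <- langmuir_params(0.010, 20.870)
  expect_equal(predict_isotherm(lg, 10), 1.897, tolerance = 1e-3)
  expect_equal(predict_isotherm(lg, 0), 0)
})

test_that("fitted isotherms reproduce noise-free data through prediction", {
  qe <- 0.25 * batch_ce_levels^0.88
  fit <- fit_freundlich(isotherm_data(batch_ce_levels, qe))
  expect_equal(predict_isotherm(fit, batch_ce_levels), qe, tolerance = 1e-9)
})

test_that("Langmuir prediction is nondecreasing and bounded by qmax", {
  lg <- langmuir_params(0.05, 25)
  ce <- seq(0, 500, length.out = 200)
  q <- predict_isotherm(lg, ce)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 25))
})

test_that("isotherm shape classification follows the 1/n rule", {
  expect_equal(classify_isotherm(freundlich_params(0.181, 0.952)), "L")
  expect_equal(classify_isotherm(freundlich_params(1, 1)), "C")
  expect_equal(classify_isotherm(freundlich_params(0.156, 1.015)), "S")
})
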