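test_that("batch equilibrium solves the closed-system mass balance", {
  design <- batch_design()
  # no sorption: ce = c0, qe = 0
  eq0 <- solve_batch_equilibrium(design, freundlich_params(0, 1))
  expect_equal(eq0$ce, design$initial_concentrations)
  expect_equal(eq0$qe, rep(0, 5))
  # linear isotherm, kd = 1 L/kg, m/V = 0.5 kg/L: ce = c0 / 1.5 closed form
  eq1 <- solve_batch_equilibrium(design, freundlich_params(1, 1))
  expect_equal(eq1$ce, design$initial_concentrations / 1.5, tolerance = 1e-9)
})

test_that("equilibrium records satisfy the mass balance to high precision", {
  p <- trt_freundlich$CK
  design <- batch_design()
  eq <- solve_batch_equilibrium(design, freundlich_params(p["kf"], p["inv_n"]))
  qe_mb <- compute_sorbed_amount(eq$c0, eq$ce, design$solution_volume,
                                 design$soil_mass)
  expect_equal(eq$qe, qe_mb, tolerance = 1e-8)
  resid <- eq$ce + 0.5 * eq$qe - eq$c0
  expect_true(all(abs(resid) < 1e-8))
})

test_that("root-finding agrees with a brute-force grid search", {
  p <- trt_freundlich$CK
  fit <- freundlich_params(p["kf"], p["inv_n"])
  design <- batch_design(initial_concentrations = 30)
  eq <- solve_batch_equilibrium(design, fit)
  grid <- seq(0, 30, by = 1e-5)
  g <- abs(grid + 0.5 * predict_isotherm(fit, grid) - 30)
  expect_equal(eq$ce, grid[which.min(g)], tolerance = 1e-4)
})

test_that("noise-free generation equals the equilibrium solution", {
  p <- trt_freundlich$Zn100
  fit <- freundlich_params(p["kf"], p["inv_n"])
  eq <- solve_batch_equilibrium(batch_design(), fit)
  gen <- gen_isotherm_dataset(batch_design(), fit, noise_model())
  expect_equal(gen$ce, eq$ce)
  expect_equal(gen$qe, eq$qe)
})

test_that("isotherm generation is deterministic under a fixed seed", {
  fit <- freundlich_params(0.181, 0.952)
  nm <- noise_model("multiplicative_gaussian", 0.02, seed = 7)
  g1 <- gen_isotherm_dataset(batch_design(), fit, nm)
  g2 <- gen_isotherm_dataset(batch_design(), fit, nm)
  expect_identical(g1$ce, g2$ce)
  g3 <- gen_isotherm_dataset(batch_design(), fit,
                             noise_model("multiplicative_gaussian", 0.02,
                                         seed = 8))
  expect_false(identical(g1$ce, g3$ce))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(gen_isotherm_dataset(batch_design(), freundlich_params(0.2, 0.9),
                                 noise_model("additive_gaussian", 0.1,
                                             seed = 99)))
  expect_identical(a, rnorm(1))
})

test_that("small measurement noise leaves the fitted Kf nearly unbiased", {
  # the batch mass balance magnifies Ce noise ~12x into qe at these weakly
  # sorbing conditions, so "small" must be judged after magnification:
  # sd = 0.005 on Ce is ~6% on qe and keeps the log-scale bias below 5%
  p <- trt_freundlich$CK
  fit <- freundlich_params(p["kf"], p["inv_n"])
  kfs <- vapply(seq_len(1000), function(s) {
    ds <- gen_isotherm_dataset(batch_design(), fit,
                               noise_model("multiplicative_gaussian", 0.005,
                                           seed = s))
    fit_freundlich(ds)$kf
  }, numeric(1))
  expect_equal(mean(kfs), unname(p["kf"]), tolerance = 0.05)
})

test_that("noise-free BTC generation equals the forward simulation", {
  sim <- simulate_tracer(ref_column(), ref_hydraulics(), tracer_pulse(),
                         pv_out = seq(0, 8, 0.1))
  gen <- gen_btc(ref_column(), ref_hydraulics(), NULL, tracer_pulse())
  expect_equal(gen$pv, sim$pv)
  expect_equal(gen$c_rel, sim$c_rel)
  expect_equal(attr(gen, "hours_per_pv"),
               pv_time_conversion(ref_column(), ref_hydraulics()))
})

test_that("BTC generation is deterministic and clips negatives", {
  nm <- noise_model("additive_gaussian", 0.05, seed = 3)
  g1 <- gen_btc(ref_column(), ref_hydraulics(), NULL, tracer_pulse(),
                noise = nm)
  g2 <- gen_btc(ref_column(), ref_hydraulics(), NULL, tracer_pulse(),
                noise = nm)
  expect_identical(g1$c_rel, g2$c_rel)
  expect_true(all(g1$c_rel >= 0))
})

test_that("seeded noisy replicates recover the sorption parameters", {
  p <- trt_two_site$CuZn
  sorb <- two_site_sorption(p["f"], p["kd"], p["alpha"])
  opts <- fit_options(starts = rbind(c(0.5, 0.5, 0.01), c(0.2, 0.3, 0.001)),
                      max_iter = 40)
  hits_f <- hits_kd <- 0L
  for (s in 1:5) {
    obs <- gen_btc(ref_column(), ref_hydraulics(), sorb, sdz_pulse(),
                   noise = noise_model("multiplicative_gaussian", 0.01,
                                       seed = s))
    fit <- fit_two_site_btc(obs, ref_column(), ref_hydraulics(), sdz_pulse(),
                            options = opts)
    if (abs(fit$params$f - p["f"]) / p["f"] < 0.15) hits_f <- hits_f + 1L
    if (abs(fit$params$kd - p["kd"]) / p["kd"] < 0.15) hits_kd <- hits_kd + 1L
  }
  expect_gte(hits_f, 4L)
  expect_gte(hits_kd, 4L)
})
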