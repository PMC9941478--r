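test_that("buffered diffusion reproduces the closed-form reduction", {
  expect_equal(effective_D(S_T = 0, ip3 = 0.1), 283)
  expect_equal(effective_D(S_T = 0.542, ip3 = 1e9), 283, tolerance = 1e-6)
  expect_equal(effective_D(S_T = 0.542, ip3 = 0.119),
               283 / (1 + 0.542 / (4 * 0.119)), tolerance = 1e-12)
  expect_equal(round(effective_D(S_T = 0.542, ip3 = 0.119), 1), 132.3)
  # strictly decreasing in S_T, increasing in [IP3]
  st <- seq(0.05, 2, length.out = 40)
  expect_true(all(diff(effective_D(S_T = st, ip3 = 0.1)) < 0))
  ip <- seq(0.01, 2, length.out = 40)
  expect_true(all(diff(effective_D(S_T = 0.542, ip3 = ip)) > 0))
  expect_error(effective_D(S_T = -1, ip3 = 0.1), "invalid")
})

test_that("range of action scales with the square root of D_I", {
  expect_equal(range_of_action(283), 24)
  expect_equal(range_of_action(100), 14)
  expect_equal(range_of_action(10), 4.5)
})

test_that("theta calibration inverts the latency curve and solves the mass balance", {
  mask <- build_mask(shape_ellipse(25, 5), h = 0.25)
  p <- model_params()
  # synthetic strictly-decreasing curve standing in for the simulated one
  curve <- data.frame(ip3 = exp(seq(log(0.06), log(0.4), length.out = 8)),
                      ml = c(30, 20, 12, 7, 4, 2.5, 1.5, 1),
                      ml_sem = 0.1, mfp_min = 0.3, n = 50)
  tg <- data.frame(t_ph = c(0.1, 0.2, 0.5), ml = c(12, 7, 2.5))
  cal <- calibrate_theta(tg, mask, p, curve = curve)
  # targets sit exactly on curve points -> inversion returns grid points
  expect_equal(cal$targets$c_target, curve$ip3[c(3, 4, 6)], tolerance = 1e-6)
  # mass balance: least-squares theta over c = basal + theta * a_k
  b <- puffr:::bind_protocol(protocol_distributed(1, t_ph = 1), mask)
  a_k <- tg$t_ph * b$n_cells_per_spot / mask$n
  dc <- cal$targets$c_target - p$ip3_basal
  expect_equal(cal$theta, sum(a_k * dc) / sum(a_k^2), tolerance = 1e-9)
  # single target lying on the curve: exact mass-balance identity
  cal1 <- calibrate_theta(data.frame(t_ph = 0.2, ml = 7), mask, p,
                          curve = curve)
  expect_equal(cal1$theta, (curve$ip3[4] - p$ip3_basal) / a_k[2],
               tolerance = 1e-6)

  expect_error(calibrate_theta(data.frame(t_ph = c(0.1, 0.2), ml = c(5, 7)),
                               mask, p, curve = curve), "decrease")
  expect_error(calibrate_theta(data.frame(t_ph = 0.2, ml = 100), mask, p,
                               curve = curve), "extrapolation")
})

test_that("the fast first-opening sampler matches the hybrid simulation", {
  p <- model_params()
  mask <- build_mask(shape_ellipse(12.5, 2.5), h = 0.25)
  spot <- c(1, 2.5)
  d <- 4
  # full hybrid route: stop at first opening
  cl <- puffr:::scan_sites(mask, spot, d, p)
  full <- vapply(1:60, function(r) {
    tr <- simulate_puffs(mask, cl, protocol_spot(600, 0.2, spot), p,
                         t_end = 30, seed = 300 + r, stop_on = "opening")
    tr$stop_time
  }, 1.0)
  # sampler route
  fast <- latency_scan(mask, spot, d, 600, 0.2, p, n_rep = 300, seed = 4,
                       t_pde = 20)
  ks <- suppressWarnings(ks.test(full, fast$latency_s))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single candidate is returned with its score", {
  mask <- build_mask(shape_ellipse(25, 5), h = 0.25)
  obs <- generate_parametric_dataset(
    data.frame(condition = c(5, 10, 15), ml = c(3, 5, 8)), n_rep = 50,
    seed = 2)
  res <- estimate_DI(obs, candidates = 100, theta = 250, mask = mask,
                     n_rep = 50, seed = 3)
  expect_equal(res$best, 100)
  expect_length(res$scores, 1L)
  expect_gte(res$scores, 0)
  expect_error(estimate_DI(obs[obs$condition < 6, ], 100, 250, mask),
               "3 distances")
})

test_that("ground truth wins the candidate grid (single recovery trial)", {
  mask <- build_mask(shape_ellipse(25, 5), h = 0.25)
  dists <- seq(5, 25, by = 5)
  obs <- generate_spot_dataset(100, 250, dists, n_rep = 50, mask = mask,
                               seed = 61)
  res <- estimate_DI(obs, candidates = c(10, 100), theta = 250, mask = mask,
                     n_rep = 100, seed = 62)
  expect_equal(res$best, 100)
  obs10 <- generate_spot_dataset(10, 250, dists, n_rep = 50, mask = mask,
                                 seed = 63)
  res10 <- estimate_DI(obs10, candidates = c(10, 100), theta = 250,
                       mask = mask, n_rep = 100, seed = 64)
  expect_equal(res10$best, 10)
})
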