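test_that("diffusion preserves uniform fields and total mass", {
  m <- build_mask(shape_ellipse(5, 2), h = 0.25)
  f <- rep(0.3, m$n)
  expect_equal(diffusion_step(f, 100, stability_dt(m, D = 100), m), f)

  # mass conservation over many steps in an ER-obstructed mask
  er <- add_er_obstacles(m, er_bars(0.2, seed = 2))
  set.seed(1)
  g <- runif(er$n)
  total0 <- sum(g)
  dt <- stability_dt(er, D = 100)
  for (i in 1:1000) g <- diffusion_step(g, 100, dt, er)
  expect_lt(abs(sum(g) / total0 - 1), 1e-9)
})

test_that("a point source relaxes to the free-space Gaussian kernel", {
  m <- build_mask(shape_rectangle(24, 24), h = 0.25)
  src <- puffr:::pos_to_cell(m, c(12, 12))
  ctr <- puffr:::cell_centre(m, src)
  f <- rep(0, m$n)
  f[src] <- 1 / m$h^2 # unit amount per unit depth
  D <- 100
  dt <- stability_dt(m, D = D)
  nst <- round(0.1 / dt)
  for (i in seq_len(nst)) f <- diffusion_step(f, D, dt, m)
  tt <- nst * dt
  r2 <- rowSums(sweep((m$cells - 0.5) * m$h, 2, ctr)^2)
  pred <- exp(-r2 / (4 * D * tt)) / (4 * pi * D * tt)
  sel <- r2 <= 9
  expect_lt(max(abs(f[sel] - pred[sel]) / pred[sel]), 0.01)
})

test_that("stability bound and negativity are enforced", {
  m <- tiny_mask()
  expect_error(diffusion_step(rep(1, m$n), 100, 1, m), "stability")
  expect_error(diffusion_step(rep(-1, m$n), 100, 1e-5, m), "negative")
})

test_that("photorelease adds theta*dt inside the spot while t <= t_ph", {
  m <- build_mask(shape_ellipse(25, 5), h = 0.25)
  pr <- protocol_spot(theta = 600, t_ph = 0.2, center = c(1.25, 5))
  f0 <- rep(0.05, m$n)
  f1 <- apply_photorelease(f0, pr, t = 0.1, dt = 1e-3, mask = m)
  b <- puffr:::bind_protocol(pr, m)
  expect_equal(f1[b$cells], rep(0.05 + 0.6, length(b$cells)))
  expect_equal(f1[-b$cells], f0[-b$cells])
  # boundary instant included, later times add nothing
  expect_false(identical(apply_photorelease(f0, pr, 0.2, 1e-3, m), f0))
  expect_identical(apply_photorelease(f0, pr, 0.201, 1e-3, m), f0)
})

test_that("distributed and spot protocols release the same total amount", {
  m <- build_mask(shape_ellipse(25, 5), h = 0.25)
  f0 <- rep(0, m$n)
  sp <- apply_photorelease(f0, protocol_spot(600, 0.2, c(25, 5)), 0, 1e-3, m)
  di <- apply_photorelease(f0, protocol_distributed(600, 0.2), 0, 1e-3, m)
  expect_equal(sum(di), sum(sp), tolerance = 1e-12)
  # a spot centre outside the cytosol is rejected
  expect_error(
    apply_photorelease(f0, protocol_spot(600, 0.2, c(0.1, 0.1)), 0, 1e-3, m),
    "outside cytosol")
})

test_that("the basal state is stationary under the deterministic step", {
  p <- model_params()
  m <- tiny_mask()
  st <- field_state(m, p)
  dt <- stability_dt(m, p)
  for (i in 1:10000) st <- step_deterministic(st, list(), p, dt)
  expect_lt(max(abs(st$ca - p$ca_basal)), 1e-6)
  expect_lt(max(abs(st$ip3 - p$ip3_basal)), 1e-12)
})

test_that("a cluster held open drives its detection volume over threshold", {
  p <- model_params()
  cfg <- preset("puffs_1cl", params = p)
  tr <- simulate_puffs(cfg$mask, cfg$clusters, protocol_uniform_step(0.15),
                       p, t_end = 1.5, seed = 1, record_dt = 0.002,
                       clamp_states = "O")
  expect_gt(max(tr$ca_local), p$puff_threshold)
  # and the rise of the 1 fL average is slow enough to set a latency floor
  cross <- tr$t[which(tr$ca_local[, 1] >= p$puff_threshold)[1]]
  expect_gt(cross, 0.1)
  expect_lt(cross, 0.5)
})

test_that("local_concentration averages the detection region", {
  m <- build_mask(shape_rectangle(5, 5), h = 0.25)
  cl <- place_clusters(m, 1L, "explicit", positions = c(2.5, 2.5))[[1]]
  st <- const_state(m, 0.05, 0.2)
  expect_equal(local_concentration(st, cl), 0.2)
  st$ca <- seq_len(m$n) * 1e-3 # asymmetric ramp
  expect_equal(local_concentration(st, cl), mean(st$ca[cl$detect]))
})

test_that("uniform-step fields stay spatially constant forever", {
  p <- model_params()
  cfg <- preset("puffs_1cl", params = p)
  tr <- simulate_puffs(cfg$mask, cfg$clusters, protocol_uniform_step(0.2), p,
                       t_end = 1, seed = 3, stochastic = FALSE)
  expect_true(all(abs(tr$ip3_local - 0.2) < 1e-12))
})
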