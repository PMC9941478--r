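test_that("opening propensity follows the fourth-power IP3 saturation", {
  p <- model_params()
  expect_equal(propensity_CO(0.1, 0, p), 0)
  expect_equal(propensity_CO(0, 10, p), 0)
  expect_equal(propensity_CO(0.1, p$k_ip, p), p$k_co * 0.1 / 16)
  expect_equal(propensity_CO(0.1, 1e9, p), p$k_co * 0.1, tolerance = 1e-6)
  expect_error(propensity_CO(-1, 0.1, p), "negative")
  # monotone in both arguments
  ip <- seq(0.01, 1, length.out = 30)
  expect_true(all(diff(propensity_CO(0.1, ip, p)) > 0))
  expect_true(all(diff(propensity_CO(ip, 0.1, p)) > 0))
})

test_that("hybrid step fires nothing when all propensities vanish", {
  p <- model_params()
  m <- tiny_mask()
  cl <- place_clusters(m, 1L, "explicit", positions = c(1, 1))
  st <- const_state(m, 0, 0) # no IP3, no Ca: closed cluster cannot open
  for (i in 1:50) {
    out <- hybrid_step(st, cl, p, dt = 0.01)
    expect_equal(nrow(out$events), 0L)
  }
})

test_that("first-transition times are exponential with the Eq.-2 rate", {
  p <- model_params()
  cfg <- preset("puffs_1cl", params = p)
  lam <- propensity_CO(p$ca_basal, 0.3, p)
  lat <- vapply(1:400, function(r) {
    tr <- simulate_puffs(cfg$mask, cfg$clusters, protocol_uniform_step(0.3),
                         p, t_end = 30, seed = 5000 + r, stop_on = "opening")
    tr$stop_time
  }, 1.0)
  expect_true(all(is.finite(lat)))
  ks <- suppressWarnings(ks.test(lat, "pexp", rate = lam))
  expect_gt(ks$p.value, 0.01)
})

test_that("halving dt leaves the mean first-transition time within 2% of exact", {
  p <- model_params()
  m <- tiny_mask()
  cl <- place_clusters(m, 1L, "explicit", positions = c(1, 1))
  st <- const_state(m, 0.3, p$ca_basal)
  lam <- propensity_CO(p$ca_basal, 0.3, p)
  first_time <- function(dt, n = 4000, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      t <- 0
      repeat {
        t <- t + dt
        if (runif(1) < -expm1(-lam * dt)) return(t)
      }
    }, 1.0)
  }
  m1 <- mean(first_time(0.02, seed = 1))
  m2 <- mean(first_time(0.01, seed = 2))
  set.seed(3)
  ex <- mean(rexp(4000, lam)) # exact Gillespie first transition
  expect_lt(abs(m1 - m2) / ex, 0.02)
  expect_lt(abs(m2 - ex) / ex, 0.03)
})

test_that("traces are reproducible and the event log replays to the final state", {
  p <- model_params()
  cfg <- preset("spikes_10cl", ip3 = 0.2, params = p, seed = 2, h = 0.5)
  a <- simulate_puffs(cfg$mask, cfg$clusters, cfg$protocol, p, t_end = 30,
                      seed = 11)
  b <- simulate_puffs(cfg$mask, cfg$clusters, cfg$protocol, p, t_end = 30,
                      seed = 11)
  expect_identical(a$ca_local, b$ca_local)
  expect_identical(a$events, b$events)

  # replay: last transition of each cluster gives its final state
  final <- vapply(seq_along(cfg$clusters), function(i) {
    ev <- a$events[a$events$cluster == i, ]
    if (nrow(ev)) ev$to[nrow(ev)] else "C"
  }, "")
  expect_identical(final, a$state)
  # times strictly increasing per cluster
  for (i in unique(a$events$cluster))
    expect_true(all(diff(a$events$time[a$events$cluster == i]) > 0))
})

test_that("empty horizon produces an empty trace", {
  p <- model_params()
  cfg <- preset("puffs_1cl", params = p)
  tr <- simulate_puffs(cfg$mask, cfg$clusters, cfg$protocol, p, t_end = 0,
                       seed = 1)
  expect_equal(nrow(tr$events), 0L)
  expect_equal(length(tr$t), 1L) # initial sample only
})

test_that("seed derivation is deterministic and stays in integer range", {
  s1 <- puffr:::derive_seed(1L, 1:1000)
  s2 <- puffr:::derive_seed(1L, 1:1000)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_equal(length(unique(s1)), 1000L)
})
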