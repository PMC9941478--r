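test_that("puff detection finds maximal above-threshold excursions", {
  t <- seq(0, 10, by = 0.1)
  expect_equal(nrow(detect_puffs(t, rep(0.05, length(t)), 0.1)), 0L)
  expect_error(detect_puffs(numeric(0), numeric(0)), "empty trace")

  ca <- rep(0.05, length(t))
  ca[t >= 2.3 & t < 2.5] <- 0.15
  one <- detect_puffs(t, ca, 0.1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$onset, 2.3)
  expect_equal(one$end, 2.5)
  expect_equal(one$peak, 0.15)

  ca[t >= 4 & t < 4.3] <- 0.2
  ca[t >= 6 & t < 6.1] <- 0.09  # sub-threshold bump
  ca[t >= 8 & t < 8.2] <- 0.11
  expect_equal(nrow(detect_puffs(t, ca, 0.1)), 3L)
})

test_that("first-puff latency is measured from the flash and censors cleanly", {
  puffs <- data.frame(onset = c(4, 7), end = c(5, 8), peak = c(0.2, 0.2))
  expect_equal(first_puff_latency(puffs, t_flash = 0), 4)
  expect_equal(first_puff_latency(puffs, t_flash = 5), 2)
  expect_true(is.na(first_puff_latency(puffs, t_flash = 9))) # only before flash
  expect_true(is.na(first_puff_latency(puffs[0, ], t_flash = 0)))
})

test_that("ML and MFP summaries follow the grouped-minima definition", {
  d <- latency_dataset(rep(1, 10), 1:10, 1:10)
  s <- summarize_latencies(d, grouping = c(2L, 5L))
  expect_equal(s$ml, 5.5)
  expect_equal(s$mfp, (1 + 6) / 2)
  expect_true(s$mfp <= s$ml)

  d2 <- latency_dataset(rep(1, 10), 1:10, rep(3, 10))
  s2 <- summarize_latencies(d2, grouping = c(2L, 5L))
  expect_equal(s2$ml, 3)
  expect_equal(s2$mfp, 3)
  expect_equal(s2$ml_sem, 0)

  # brute-force oracle on exponential draws
  set.seed(99)
  lat <- rexp(50, 1 / 5)
  d3 <- latency_dataset(rep(2, 50), 1:50, lat)
  s3 <- summarize_latencies(d3, grouping = c(10L, 5L))
  mins <- vapply(split(lat, rep(1:10, each = 5)), min, 1.0)
  expect_equal(s3$ml, mean(lat))
  expect_equal(s3$ml_sem, sd(lat) / sqrt(50))
  expect_equal(s3$mfp, mean(mins))
  expect_equal(s3$mfp_sem, sd(mins) / sqrt(10))
  expect_true(s3$mfp <= s3$ml)
})

test_that("censored rows are excluded with a warning above 10%", {
  d <- latency_dataset(rep(1, 10), 1:10, c(1:8, 60, 60),
                       censored = c(rep(FALSE, 8), TRUE, TRUE))
  expect_warning(s <- summarize_latencies(d, grouping = c(2L, 4L)),
                 "censored")
  expect_equal(s$ml, mean(1:8))
  expect_equal(s$n_censored, 2L)
})

test_that("interevent statistics use sample SD and need two events", {
  s <- interevent_stats(c(0, 2, 4, 6))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  s2 <- interevent_stats(c(0, 1, 3))
  expect_equal(s2$mean, 1.5)
  expect_equal(s2$sd, sd(c(1, 2))) # sample SD = 0.7071
  expect_error(interevent_stats(3), "fewer than 2")
})

test_that("exponential fit recovers the mean and rejects degenerate input", {
  set.seed(7)
  x <- rexp(500, 1 / 3)
  fit <- fit_exponential(x)
  expect_lt(abs(fit$tau - 3) / 3, 0.1)
  expect_true(fit$ci[1] < fit$tau && fit$tau < fit$ci[2])
  expect_error(fit_exponential(rep(2, 10)), "degenerate")
  expect_error(fit_exponential(c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_exponential(c(0.4, 2, 3, 4, 5), offset = 0.5), "exceed")
})

test_that("latency datasets round-trip through CSV losslessly", {
  d <- generate_parametric_dataset(
    data.frame(condition = c(5, 10, 20), ml = c(2, 4, 8)), n_rep = 20,
    seed = 3)
  path <- tempfile(fileext = ".csv")
  write_latency_dataset(d, path, sidecar = list(kind = "test", seed = 3))
  d2 <- read_latency_dataset(path)
  expect_equal(as.data.frame(d), as.data.frame(d2))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 3)
})
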