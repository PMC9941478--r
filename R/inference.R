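## Analytical calculators and simulation-based inference.

#' Effective IP3 diffusion coefficient under receptor buffering
#'
#' Rapid-buffering reduction of the free IP3 diffusion coefficient by
#' non-fully-bound IP3R monomers:
#' `D_I = D / (1 + R)`, `R = S_T * K_D / (K_D + IP3)^2`.
#'
#' @param D free IP3 diffusion coefficient (um^2/s), default 283.
#' @param S_T concentration of IP3R monomers (uM).
#' @param K_D equilibrium dissociation constant (uM), default 0.119.
#' @param ip3 IP3 concentration (uM).
#' @return Effective diffusion coefficient (um^2/s); vectorized over any
#'   argument.
#' @export
effective_D <- function(S_T, ip3, D = 283, K_D = 0.119) {
  if (any(D <= 0) || any(K_D <= 0) || any(S_T < 0) || any(ip3 < 0))
    stop("invalid buffered-diffusion parameters")
  D / (1 + S_T * K_D / (K_D + ip3)^2)
}

#' Range of action of IP3
#'
#' The distance a messenger spreads before removal scales as the square root
#' of its diffusion coefficient; anchored at `r_ref` for `D_ref`.
#'
#' @param D_I effective diffusion coefficient (um^2/s).
#' @param r_ref,D_ref reference range (um) and diffusivity (um^2/s).
#' @return Range (um), rounded to 2 significant figures for reporting.
#' @export
range_of_action <- function(D_I, r_ref = 24, D_ref = 283) {
  stopifnot(all(D_I > 0), r_ref > 0, D_ref > 0)
  signif(r_ref * sqrt(D_I / D_ref), 2)
}

## Deterministic IP3 time course and the first-opening sampler ----------------

# Deterministic IP3 course at cluster detection volumes for a unit-rate
# source (theta = 1). The diffusion PDE is linear in the source, so
# IP3(t) = basal + theta * unit_course(t). Returns list(t, course, lam_tail
# info) with course a (time x site) matrix.
ip3_unit_course <- function(mask, protocol, clusters, D_I, t_pde = 20,
                            record_dt = 0.002, dt = NULL) {
  p1 <- protocol
  p1$theta <- 1
  b <- bind_protocol(p1, mask)
  if (is.null(dt)) dt <- 0.4 * mask$h^2 / (2 * mask$dim * D_I)
  n_steps <- ceiling(t_pde / dt)
  record_every <- max(1L, round(record_dt / dt))
  ctrl <- list(dt = dt, n_steps = as.double(n_steps),
               record_every = as.integer(record_every),
               ip3_dynamic = TRUE, alpha_ip3 = D_I * dt / mask$h^2,
               src_cells = as.integer(b$cells - 1L), src_rate = b$rate,
               t_ph = b$t_ph, ca_dynamic = FALSE, alpha_ca = 0,
               vp = 0, kp = 1, j_leak = 0, j_rel = 0,
               stochastic = FALSE, k_co = 0, k_ip = 1, k_oc = 0, k_oi1 = 0,
               k_i1o = 0, k_i1i2 = 0, i1i2_hill = 1, k_i2i1 = 0, k_i2c = 0,
               ca_offset = 0, threshold = Inf, stop_mode = 0L, t0 = 0)
  res <- cpp_sim(rep(0, mask$n), rep(0, mask$n), mask$nbr,
                 vapply(clusters, function(cl) cl$cell - 1L, 1L),
                 lapply(clusters, function(cl) cl$detect - 1L),
                 integer(length(clusters)), rep(-1L, length(clusters)), ctrl)
  keep <- seq_len(res$n_recorded)
  list(t = res$t[keep], course = res$ip3_local[keep, , drop = FALSE])
}

# Sample n first-opening times of a closed cluster whose opening propensity
# follows the deterministic IP3 course: inhomogeneous Poisson first passage
# via inversion of the integrated rate. Beyond the recorded course the rate
# is held at its final value. Returns times (s), NA when beyond t_max.
sample_first_openings <- function(times, lam, n, t_max = 120) {
  dt <- diff(times)
  cum <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
  e <- rexp(n)
  out <- approx(cum, times, xout = e, ties = "ordered")$y
  tail_i <- is.na(out) & e > cum[length(cum)]
  lam_end <- lam[length(lam)]
  if (any(tail_i) && lam_end > 0)
    out[tail_i] <- times[length(times)] +
      (e[tail_i] - cum[length(cum)]) / lam_end
  out[is.na(out) | out > t_max] <- NA_real_
  out
}

# Opening propensity along an IP3 course (uses the calibrated Eq.-2 form and
# the stationary pre-opening Ca level plus any ambient offset).
lambda_course <- function(ip3, params) {
  propensity_CO(params$ca_basal + params$ca_offset, pmax(ip3, 0), params)
}

# deterministic IP3 horizon: long enough to cover mixing across the domain
# (clamped to [20, 60] s); beyond it the opening rate is held constant.
default_t_pde <- function(mask, D_I) {
  L <- max(dim(mask$occ)) * mask$h
  min(60, max(20, 0.4 * L^2 / D_I))
}

# cluster sites along the major axis at given distances from a spot center
scan_sites <- function(mask, spot_center, distances, params) {
  ext <- dim(mask$occ) * mask$h
  pos <- cbind(spot_center[1] + distances,
               matrix(rep(spot_center[-1], each = length(distances)),
                      nrow = length(distances)))
  if (any(pos[, 1] >= ext[1]) ||
      any(apply(pos, 1L, function(p) pos_to_cell(mask, p) == 0L)))
    stop("cluster distance falls outside the cell")
  cl <- place_clusters(mask, length(distances), "explicit", positions = pos,
                       detection_volume_fl = params$detection_volume_fl)
  for (i in seq_along(cl)) cl[[i]]$distance <- distances[i]
  cl
}

#' First-puff latencies versus distance from a photorelease spot
#'
#' Runs the spot-photorelease, one-cluster-at-a-time (EGTA-uncoupled)
#' protocol: the IP3 field evolves deterministically, and for each cluster
#' site the first-opening time is drawn from the inhomogeneous Poisson
#' process defined by the opening propensity along the local IP3 course (the
#' Ca field is stationary until the first opening, so this sampling is exact
#' for the latency-to-first-opening; see the methods vignette).
#'
#' @param mask a `domain_mask`.
#' @param spot_center spot position (um).
#' @param distances cluster distances from the spot (um).
#' @param theta,t_ph photorelease rate (uM/s) and flash duration (s).
#' @param params a `model_params` (supplies `D_I` unless overridden).
#' @param n_rep replicates per distance.
#' @param seed integer seed.
#' @param D_I optional override of `params$D_I`.
#' @param t_pde deterministic IP3 horizon (s); the propensity is held at its
#'   final value beyond it.
#' @param t_max censoring time (s).
#' @param course optional precomputed [ip3_unit_course()] result (reused
#'   across calls that share mask, spot, `t_ph` and `D_I`).
#' @return A `latency_dataset` keyed by distance.
#' @export
latency_scan <- function(mask, spot_center, distances, theta, t_ph,
                         params = model_params(), n_rep = 50L, seed = 1L,
                         D_I = params$D_I, t_pde = NULL, t_max = 120,
                         course = NULL) {
  if (is.null(t_pde)) t_pde <- default_t_pde(mask, D_I)
  cl <- scan_sites(mask, spot_center, distances, params)
  if (is.null(course))
    course <- ip3_unit_course(mask, protocol_spot(1, t_ph, spot_center),
                              cl, D_I, t_pde = t_pde)
  rows <- vector("list", length(distances))
  for (i in seq_along(distances)) {
    ip3 <- params$ip3_basal + theta * course$course[, i]
    lam <- lambda_course(ip3, params)
    set.seed(derive_seed(seed, i))
    lat <- sample_first_openings(course$t, lam, n_rep, t_max = t_max)
    cens <- is.na(lat)
    lat[cens] <- t_max
    rows[[i]] <- latency_dataset(rep(distances[i], n_rep), seq_len(n_rep),
                                 lat, cens)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("latency_dataset", "data.frame")
  out
}

## Theta calibration -----------------------------------------------------------

#' Mean first-puff latency versus uniform IP3 concentration
#'
#' Single-cluster simulations in a small square domain under the uniform-step
#' protocol; the latency of each replicate is the first threshold crossing of
#' the detection-volume Ca average (the puff definition).
#'
#' @param concentrations IP3 grid (uM).
#' @param params a `model_params`.
#' @param n_rep replicates per concentration.
#' @param seed integer seed.
#' @param t_max censoring time per replicate (s).
#' @return data.frame (ip3, ml, ml_sem, mfp_min, n) where `mfp_min` is the
#'   minimum latency across replicates.
#' @export
ml_vs_ip3 <- function(concentrations, params = model_params(), n_rep = 50L,
                      seed = 1L, t_max = 90) {
  cfg <- preset("puffs_1cl", params = params)
  out <- lapply(seq_along(concentrations), function(k) {
    lat <- vapply(seq_len(n_rep), function(r) {
      tr <- simulate_puffs(cfg$mask, cfg$clusters,
                           protocol_uniform_step(concentrations[k]),
                           params, t_end = t_max,
                           seed = derive_seed(seed, (k - 1L) * n_rep + r),
                           stop_on = "crossing")
      if (is.na(tr$stop_time)) NA_real_ else tr$stop_time
    }, 1.0)
    ok <- !is.na(lat)
    data.frame(ip3 = concentrations[k], ml = mean(lat[ok]),
               ml_sem = sd(lat[ok]) / sqrt(sum(ok)),
               mfp_min = if (any(ok)) min(lat[ok]) else NA_real_,
               n = sum(ok))
  })
  do.call(rbind, out)
}

#' Calibrate the photorelease rate from distributed-flash latency targets
#'
#' Two-stage procedure: (1) build the mean-latency versus uniform [IP3] curve
#' from single-cluster simulations and invert it (monotone interpolation) at
#' each observed mean latency, giving the spatially uniform concentration
#' each flash must reach; (2) solve the closed mass balance of distributed
#' release, `c_k = basal + theta * t_ph_k * V_spot / V_cell` (ten sites at
#' rate theta/10, measured on the lattice), for the least-squares theta over
#' all targets.
#'
#' @param latency_targets data.frame with columns `t_ph` (s) and `ml` (s);
#'   mean latency must decrease strictly with flash duration.
#' @param mask the cell geometry used for the mass balance (and for the
#'   default distributed spot layout).
#' @param params a `model_params`.
#' @param concentrations inversion grid (uM), default 8 log-spaced points
#'   over 0.06-0.40.
#' @param n_rep replicates per concentration for the simulated curve.
#' @param seed integer seed.
#' @param curve optional precomputed [ml_vs_ip3()] table.
#' @return list(theta, targets, curve): `targets` gains columns `c_target`
#'   (uM) and `residual` (uM, mass-balance residual at the fitted theta).
#' @export
calibrate_theta <- function(latency_targets, mask, params = model_params(),
                            concentrations = exp(seq(log(0.06), log(0.40),
                                                     length.out = 8L)),
                            n_rep = 50L, seed = 1L, curve = NULL) {
  tg <- latency_targets[order(latency_targets$t_ph), ]
  if (any(diff(tg$ml) >= 0))
    stop("mean latency must decrease strictly with flash duration")
  if (is.null(curve))
    curve <- ml_vs_ip3(concentrations, params, n_rep = n_rep, seed = seed)
  if (any(diff(curve$ml) >= 0))
    warning("simulated ML curve is not strictly decreasing in [IP3]")
  if (any(tg$ml > max(curve$ml)) || any(tg$ml < min(curve$ml)))
    stop("target mean latency outside the simulated curve range ",
         "(extrapolation refused)")
  # invert ML([IP3]) by monotone interpolation on log-concentration
  ord <- order(curve$ml)
  c_target <- exp(approx(curve$ml[ord], log(curve$ip3)[ord], xout = tg$ml,
                         ties = "ordered")$y)
  # lattice mass balance of the ten-site distributed flash
  b <- bind_protocol(protocol_distributed(1, t_ph = 1), mask)
  a_k <- tg$t_ph * b$n_cells_per_spot / mask$n
  dc <- c_target - params$ip3_basal
  theta <- sum(a_k * dc) / sum(a_k^2)
  tg$c_target <- c_target
  tg$residual <- dc - theta * a_k
  list(theta = theta, targets = tg, curve = curve)
}

## D_I grid search --------------------------------------------------------------

#' Estimate the effective IP3 diffusion coefficient by grid search
#'
#' For each candidate `D_I`, simulates the spot-photorelease latency scan at
#' the observed distances (via [latency_scan()]), summarizes ML and MFP with
#' [summarize_latencies()], and scores the weighted squared deviation from
#' the observed curves: `sum[(ML_sim-ML_obs)^2/(SEM_obs^2+SEM_sim^2) +
#' (MFP_sim-MFP_obs)^2/(SEM_obs^2+SEM_sim^2)]` (unit weights where both SEMs
#' are missing or zero). Both curves enter the objective because mean
#' latencies alone cannot discriminate between diffusivity and release-rate
#' changes; the simulated SEM enters the weight because the per-candidate
#' curves are themselves Monte Carlo estimates.
#'
#' @param observed a `latency_dataset` keyed by distance (um).
#' @param candidates candidate `D_I` grid (um^2/s), default
#'   `c(10, 50, 100, 200)`.
#' @param theta photorelease rate used in the simulations (uM/s).
#' @param mask a `domain_mask`.
#' @param params a `model_params`.
#' @param t_ph flash duration (s).
#' @param spot_center spot position (um); default near the left extremity at
#'   mid-height.
#' @param n_rep replicates per distance and candidate.
#' @param grouping passed to [summarize_latencies()].
#' @param seed integer seed.
#' @param t_pde,t_max see [latency_scan()].
#' @param courses optional named list of precomputed unit courses per
#'   candidate (names = candidate values).
#' @return An `inference_result`: list(candidates, scores, best, theta,
#'   n_rep, seed, summaries).
#' @export
estimate_DI <- function(observed, candidates = c(10, 50, 100, 200), theta,
                        mask, params = model_params(), t_ph = 0.2,
                        spot_center = NULL, n_rep = 200L,
                        grouping = c(10L, 5L), seed = 1L,
                        t_pde = NULL, t_max = 120, courses = NULL) {
  if (length(unique(observed$condition)) < 3L)
    stop("observed dataset needs at least 3 distances")
  if (length(candidates) < 1L) stop("no candidates")
  if (is.null(spot_center))
    spot_center <- c(1.25, dim(mask$occ)[-1] * mask$h / 2)
  obs <- summarize_latencies(observed, grouping = grouping)
  distances <- obs$condition

  scores <- numeric(length(candidates))
  summaries <- vector("list", length(candidates))
  for (j in seq_along(candidates)) {
    course <- if (!is.null(courses)) courses[[as.character(candidates[j])]]
    sim <- latency_scan(mask, spot_center, distances, theta, t_ph, params,
                        n_rep = n_rep, seed = derive_seed(seed, 1000L + j),
                        D_I = candidates[j],
                        t_pde = if (is.null(t_pde))
                          default_t_pde(mask, candidates[j]) else t_pde,
                        t_max = t_max, course = course)
    if (any(tapply(sim$censored, sim$condition, all))) {
      warning(sprintf("candidate D_I = %g: all-censored distance, scored Inf",
                      candidates[j]))
      scores[j] <- Inf
      next
    }
    grp_sim <- c(max(1L, n_rep %/% grouping[2]), grouping[2])
    s <- summarize_latencies(sim, grouping = grp_sim)
    v_ml <- pmax(obs$ml_sem^2 + s$ml_sem^2, 1e-12)
    v_mfp <- pmax(obs$mfp_sem^2 + s$mfp_sem^2, 1e-12)
    scores[j] <- sum((s$ml - obs$ml)^2 / v_ml + (s$mfp - obs$mfp)^2 / v_mfp)
    summaries[[j]] <- s
  }
  best <- candidates[which.min(scores)]
  structure(list(candidates = candidates, scores = scores, best = best,
                 theta = theta, n_rep = n_rep, seed = seed,
                 observed = obs, summaries = summaries),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat("<inference_result> candidate D_I grid (um^2/s):\n")
  print(setNames(signif(x$scores, 4), x$candidates))
  cat(sprintf("best: D_I = %g um^2/s (theta = %g uM/s, %d replicates)\n",
              x$best, x$theta, x$n_rep))
  invisible(x)
}
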