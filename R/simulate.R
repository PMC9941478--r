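#' Run a full hybrid simulation
#'
#' Advances the deterministic fields (IP3 diffusion + photorelease; Ca
#' diffusion + leak/SERCA + release at open clusters) and the stochastic
#' cluster states with a single global time step, recording the
#' detection-volume Ca and IP3 averages per cluster, the domain-average Ca,
#' and every state transition.
#'
#' @param mask a `domain_mask`.
#' @param clusters list of `cluster_site`s from [place_clusters()].
#' @param protocol a `puffr_protocol` (or `NULL` for constant basal IP3).
#' @param params a `model_params`.
#' @param t_end biological end time (s).
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @param record_dt output cadence (s), default 10 ms.
#' @param dt time step (s); default `stability_dt(mask, params)`.
#' @param stop_on `"none"`, `"opening"` (first C->O anywhere) or
#'   `"crossing"` (detection average of the first cluster reaches the puff
#'   threshold); the simulation then halts and the time is returned.
#' @param stochastic set `FALSE` to freeze cluster states (deterministic
#'   fields only).
#' @param clamp_states optional character vector of states to pin clusters in
#'   (e.g. `"O"` to force a cluster open); `NA` leaves a cluster free.
#' @return A `sim_trace`: list with `t`, `ca_local` (time x cluster),
#'   `ip3_local`, `ca_domain`, `events` data.frame, `stop_time`, `max_adt`,
#'   final `state`, and the echoed configuration.
#' @export
simulate_puffs <- function(mask, clusters, protocol = NULL,
                           params = model_params(), t_end, seed = 1L,
                           record_dt = 0.01, dt = NULL,
                           stop_on = c("none", "opening", "crossing"),
                           stochastic = TRUE, clamp_states = NULL) {
  stop_on <- match.arg(stop_on)
  ip3_moves <- !is.null(protocol) && protocol$kind != "uniform_step"
  if (is.null(dt))
    dt <- stability_dt(mask,
                       D = if (ip3_moves) max(params$D_I, params$D_Ca)
                           else params$D_Ca)
  n_steps <- max(0L, ceiling(t_end / dt))
  record_every <- max(1L, round(record_dt / dt))

  ip3 <- rep(params$ip3_basal, mask$n)
  ca <- rep(params$ca_basal, mask$n)
  src_cells <- integer(0)
  src_rate <- 0
  t_ph <- 0
  ip3_dynamic <- FALSE
  if (!is.null(protocol)) {
    b <- bind_protocol(protocol, mask)
    if (protocol$kind == "uniform_step") {
      ip3[] <- b$target
    } else {
      ip3_dynamic <- TRUE
      src_cells <- b$cells - 1L
      src_rate <- b$rate
      t_ph <- b$t_ph
    }
  }

  cl_cell <- vapply(clusters, function(cl) cl$cell - 1L, 1L)
  cl_det <- lapply(clusters, function(cl) cl$detect - 1L)
  cl_state <- vapply(clusters, function(cl) state_code(cl$state), 1L)
  clamp <- rep(-1L, length(clusters))
  if (!is.null(clamp_states)) {
    pin <- !is.na(clamp_states)
    clamp[pin] <- state_code(clamp_states[pin])
    cl_state[pin] <- clamp[pin]
  }

  ctrl <- list(dt = dt, n_steps = as.double(n_steps),
               record_every = as.integer(record_every),
               ip3_dynamic = ip3_dynamic,
               alpha_ip3 = params$D_I * dt / mask$h^2,
               src_cells = as.integer(src_cells), src_rate = src_rate,
               t_ph = t_ph, ca_dynamic = TRUE,
               alpha_ca = params$D_Ca * dt / mask$h^2,
               vp = params$serca_vmax, kp = params$serca_k,
               j_leak = params$leak,
               j_rel = params$j_release / cell_volume_um3(mask),
               stochastic = stochastic, k_co = params$k_co,
               k_ip = params$k_ip, k_oc = params$k_oc, k_oi1 = params$k_oi1,
               k_i1o = params$k_i1o, k_i1i2 = params$k_i1i2,
               i1i2_hill = params$i1i2_hill,
               k_i2i1 = params$k_i2i1, k_i2c = params$k_i2c,
               ca_offset = params$ca_offset,
               threshold = params$puff_threshold,
               stop_mode = match(stop_on, c("none", "opening", "crossing")) - 1L,
               t0 = 0)

  set.seed(seed)
  res <- cpp_sim(ip3, ca, mask$nbr, cl_cell, cl_det,
                 as.integer(cl_state), as.integer(clamp), ctrl)
  if (isTRUE(res$negative))
    stop("negative or non-finite concentration produced during simulation")
  if (res$max_adt > 0.1)
    warning(sprintf("max a_tot*dt = %.3g exceeded 0.1", res$max_adt))

  keep <- seq_len(res$n_recorded)
  events <- data.frame(time = res$ev_t, cluster = res$ev_cluster,
                       from = STATE_LEVELS[res$ev_from + 1L],
                       to = STATE_LEVELS[res$ev_to + 1L],
                       stringsAsFactors = FALSE)
  structure(list(
    t = res$t[keep],
    ca_local = res$ca_local[keep, , drop = FALSE],
    ip3_local = res$ip3_local[keep, , drop = FALSE],
    ca_domain = res$ca_domain[keep],
    events = events,
    stop_time = res$stop_time,
    state = STATE_LEVELS[res$state + 1L],
    max_adt = res$max_adt,
    t_end = res$t_end,
    config = list(seed = seed, dt = dt, record_dt = record_dt,
                  t_end = t_end, n_clusters = length(clusters),
                  protocol = if (!is.null(protocol)) protocol$kind else "none",
                  stop_on = stop_on)),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d clusters, %d samples to t = %g s, %d transitions%s\n",
              ncol(x$ca_local), length(x$t), x$t_end, nrow(x$events),
              if (!is.na(x$stop_time)) sprintf(", stopped at %g s", x$stop_time)
              else ""))
  invisible(x)
}

#' Simulation presets
#'
#' Ready-made configurations: `"puffs_1cl"` (one cluster centred in a
#' 5 x 5 um^2 square, uniform IP3), `"spikes_10cl"` (ten clusters in
#' 5 x 10 um^2, uniform IP3, coupled by Ca diffusion), `"waves_200cl"`
#' (200 clusters in 50 x 10 um^2), `"ellipse_spot"` (50 x 10 um ellipse with
#' a spot photorelease at one extremity and twelve clusters along the major
#' axis), `"ellipsoid"` (50 x 10 x 5 um ellipsoid, 20 clusters near the
#' membrane), `"astrocyte"` (synthetic body-plus-process geometry).
#'
#' @param name preset name.
#' @param ip3 uniform IP3 concentration (uM) for the uniform presets.
#' @param theta,t_ph photorelease rate (uM/s) and flash duration (s) for the
#'   spot presets.
#' @param params a `model_params`.
#' @param seed placement seed.
#' @param h grid spacing (um) for the rectangle presets.
#' @return list(mask, clusters, protocol, params).
#' @export
preset <- function(name = c("puffs_1cl", "spikes_10cl", "waves_200cl",
                            "ellipse_spot", "ellipsoid", "astrocyte"),
                   ip3 = 0.15, theta = 250, t_ph = 0.2,
                   params = model_params(), seed = 1L, h = 0.25) {
  name <- match.arg(name)
  switch(name,
    puffs_1cl = {
      mask <- build_mask(shape_rectangle(5, 5), h = h)
      cl <- place_clusters(mask, 1L, "explicit", positions = c(2.5, 2.5),
                           detection_volume_fl = params$detection_volume_fl)
      list(mask = mask, clusters = cl,
           protocol = protocol_uniform_step(ip3), params = params)
    },
    spikes_10cl = {
      mask <- build_mask(shape_rectangle(5, 10), h = h)
      cl <- place_clusters(mask, 10L, "uniform_random", seed = seed,
                           detection_volume_fl = params$detection_volume_fl)
      list(mask = mask, clusters = cl,
           protocol = protocol_uniform_step(ip3), params = params)
    },
    waves_200cl = {
      mask <- build_mask(shape_rectangle(50, 10), h = h)
      cl <- place_clusters(mask, 200L, "uniform_random", seed = seed,
                           detection_volume_fl = params$detection_volume_fl)
      list(mask = mask, clusters = cl,
           protocol = protocol_uniform_step(ip3), params = params)
    },
    ellipse_spot = {
      mask <- build_mask(shape_ellipse(25, 5))
      xs <- seq(5, 32.5, length.out = 12L)
      cl <- place_clusters(mask, 12L, "explicit",
                           positions = cbind(xs, rep(5, 12L)),
                           detection_volume_fl = params$detection_volume_fl)
      sp <- c(1.25, 5)
      for (i in seq_along(cl))
        cl[[i]]$distance <- sqrt(sum((cl[[i]]$pos - sp)^2))
      list(mask = mask, clusters = cl,
           protocol = protocol_spot(theta, t_ph, sp), params = params,
           spot_center = sp)
    },
    ellipsoid = {
      mask <- build_mask(shape_ellipsoid(25, 5, 2.5), h = 0.5)
      cl <- place_clusters(mask, 20L, "near_membrane", delta = 0.1,
                           seed = seed,
                           detection_volume_fl = params$detection_volume_fl)
      sp <- c(2, 5, 2.5)
      for (i in seq_along(cl))
        cl[[i]]$distance <- sqrt(sum((cl[[i]]$pos - sp)^2))
      list(mask = mask, clusters = cl,
           protocol = protocol_spot(theta * 10, t_ph, sp), params = params,
           spot_center = sp)
    },
    astrocyte = {
      mask <- astrocyte_mask()
      sp <- c(16, 8) # junction between body and process
      list(mask = mask, clusters = list(),
           protocol = protocol_spot(theta, t_ph, sp), params = params,
           spot_center = sp)
    })
}
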