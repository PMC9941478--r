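#' Spatial concentration fields
#'
#' A `field_state` holds the IP3 and Ca concentration vectors over the
#' interior cells of a `domain_mask`, plus the simulation clock.
#'
#' @param mask a `domain_mask`.
#' @param params a `model_params`; fields start at the basal concentrations.
#' @param t initial time (s).
#' @return A `field_state` object.
#' @export
field_state <- function(mask, params = model_params(), t = 0) {
  structure(list(mask = mask,
                 ip3 = rep(params$ip3_basal, mask$n),
                 ca = rep(params$ca_basal, mask$n),
                 t = t),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state> t = %g s, [IP3] %.4g-%.4g uM, [Ca] %.4g-%.4g uM\n",
              x$t, min(x$ip3), max(x$ip3), min(x$ca), max(x$ca)))
  invisible(x)
}

#' One explicit diffusion step with no-flux boundaries
#'
#' 5-point (2D) / 7-point (3D) Laplacian on the interior lattice; walls
#' reflect. The update is flux-symmetric, so the total amount is conserved to
#' round-off.
#'
#' @param field numeric vector over the interior cells.
#' @param D diffusivity (um^2/s).
#' @param dt time step (s); must satisfy `dt <= h^2/(2*dim*D)`.
#' @param mask a `domain_mask`.
#' @export
diffusion_step <- function(field, D, dt, mask) {
  stopifnot(length(field) == mask$n)
  if (any(field < 0)) stop("negative concentrations on input")
  if (dt > mask$h^2 / (2 * mask$dim * D) + 1e-15)
    stop("dt violates the explicit stability bound h^2/(2*dim*D)")
  cpp_diffuse(field, mask$nbr, D * dt / mask$h^2)
}

#' Apply a photorelease source over one step
#'
#' Adds `theta * dt` (spot) or `theta/10 * dt` (each distributed site) to the
#' cells of each spot while `t <= t_ph`; the uniform step protocol sets the
#' field at t = 0 and adds nothing afterwards.
#'
#' @param field IP3 vector over interior cells.
#' @param protocol a `puffr_protocol`.
#' @param t current time (s), evaluated against `t_ph`.
#' @param dt step (s).
#' @param mask a `domain_mask`.
#' @export
apply_photorelease <- function(field, protocol, t, dt, mask) {
  b <- bind_protocol(protocol, mask)
  if (protocol$kind == "uniform_step") {
    if (t == 0) field[] <- b$target
    return(field)
  }
  if (t <= b$t_ph) field[b$cells] <- field[b$cells] + b$rate * dt
  field
}

#' Advance both fields deterministically by one step
#'
#' Operator-split update: IP3 diffusion + photorelease; Ca diffusion + ER
#' leak + SERCA uptake everywhere, plus the release flux at the cells of
#' every cluster currently open. With no open cluster and fields at basal
#' values the state is stationary (leak balances SERCA at basal by
#' construction of [model_params()]).
#'
#' @param state a `field_state`.
#' @param clusters list of `cluster_site`s.
#' @param params a `model_params`.
#' @param dt time step (s).
#' @param protocol optional `puffr_protocol` acting on IP3.
#' @return The advanced `field_state`.
#' @export
step_deterministic <- function(state, clusters, params, dt,
                               protocol = NULL) {
  mask <- state$mask
  dt_max <- mask$h^2 / (2 * mask$dim * max(params$D_I, params$D_Ca))
  if (dt > dt_max + 1e-15) stop("dt violates the explicit stability bound")
  ip3 <- cpp_diffuse(state$ip3, mask$nbr, params$D_I * dt / mask$h^2)
  if (!is.null(protocol)) ip3 <- apply_photorelease(ip3, protocol, state$t,
                                                    dt, mask)
  ca <- cpp_diffuse(state$ca, mask$nbr, params$D_Ca * dt / mask$h^2)
  nh <- params$serca_hill
  ca <- ca + dt * (params$leak -
                     params$serca_vmax * ca^nh / (params$serca_k^nh + ca^nh))
  for (cl in clusters) {
    if (cl$state == "O")
      ca[cl$cell] <- ca[cl$cell] + dt * params$j_release / cell_volume_um3(mask)
  }
  if (any(ca < 0) || any(ip3 < 0))
    stop("negative concentration produced; reduce dt or check parameters")
  state$ip3 <- ip3
  state$ca <- ca
  state$t <- state$t + dt
  state
}

#' Detection-volume average concentration at a cluster site
#'
#' Volume-weighted mean of the Ca field over the cluster's detection region
#' (all cells share one volume on the regular lattice, so this is the
#' arithmetic mean).
#'
#' @param state a `field_state` (or a bare numeric field with `mask`).
#' @param site a `cluster_site`.
#' @export
local_concentration <- function(state, site) {
  mean(state$ca[site$detect])
}

#' Deterministic IP3 field at a given time
#'
#' Integrates only the IP3 equation (diffusion + photorelease) and returns
#' the field at time `t_eval`, e.g. to inspect spatial gradients or compute
#' the spatial coefficient of variation after a flash.
#'
#' @param mask a `domain_mask`.
#' @param protocol a `puffr_protocol`.
#' @param t_eval evaluation time (s).
#' @param params a `model_params` (supplies `D_I` and basal IP3).
#' @param D_I optional override.
#' @return Numeric vector over interior cells (uM).
#' @export
ip3_field_at <- function(mask, protocol, t_eval, params = model_params(),
                         D_I = params$D_I) {
  b <- bind_protocol(protocol, mask)
  dt <- stability_dt(mask, D = D_I)
  ctrl <- list(dt = dt, n_steps = as.double(ceiling(t_eval / dt)),
               record_every = 1000000L, ip3_dynamic = TRUE,
               alpha_ip3 = D_I * dt / mask$h^2,
               src_cells = as.integer(b$cells - 1L), src_rate = b$rate,
               t_ph = b$t_ph, ca_dynamic = FALSE, alpha_ca = 0,
               vp = 0, kp = 1, j_leak = 0, j_rel = 0, stochastic = FALSE,
               k_co = 0, k_ip = 1, k_oc = 0, k_oi1 = 0, k_i1o = 0,
               k_i1i2 = 0, i1i2_hill = 1, k_i2i1 = 0, k_i2c = 0,
               ca_offset = 0, threshold = Inf, stop_mode = 0L, t0 = 0)
  if (protocol$kind == "uniform_step") return(rep(b$target, mask$n))
  res <- cpp_sim(rep(params$ip3_basal, mask$n), rep(0, mask$n), mask$nbr,
                 0L, list(0L), 0L, -1L, ctrl)
  res$ip3
}
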