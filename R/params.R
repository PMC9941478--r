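#' Model parameters
#'
#' All kinetic and transport constants of the hybrid puff model, with
#' defaults calibrated so that the model reproduces the reference statistics
#' of an isolated cluster (interpuff intervals, the latency-concentration
#' relation and the ~0.3 s minimal-latency floor; see the methods vignette).
#'
#' Units: concentrations uM, times s, diffusivities um^2/s, rates 1/s unless
#' noted. The cluster opening propensity is
#' `k_co * Ca * (IP3/(IP3 + k_ip))^4` (1/s), with `Ca` and `IP3` the
#' detection-volume averages; `k_ip` is the IP3 dissociation constant
#' expressed as a concentration (the molecule-number form carries a factor
#' Omega that cancels in the saturating ratio).
#'
#' @param D_I effective IP3 diffusion coefficient (um^2/s).
#' @param D_Ca effective cytosolic Ca diffusion coefficient (um^2/s).
#' @param ip3_basal,ca_basal resting concentrations (uM).
#' @param omega extensivity parameter (molecules per uM per fL); bookkeeping
#'   only, concentrations are the state variables.
#' @param k_co C->O rate constant (1/(uM s)).
#' @param k_ip IP3 dissociation constant of the IP3R (uM).
#' @param k_oc,k_oi1,k_i1o,k_i2i1,k_i2c state transition rate constants (1/s).
#' @param k_i1i2 Ca-dependent I1->I2 rate constant (1/(uM^hill s)); the
#'   transition into the deeply inhibited state scales as `Ca^i1i2_hill`.
#' @param i1i2_hill Hill exponent of the I1->I2 Ca dependence; the steep
#'   default separates collective inhibition during spikes from the weak
#'   self-inhibition of an isolated puffing cluster.
#' @param serca_vmax,serca_k,serca_hill SERCA uptake V*c^n/(K^n + c^n).
#' @param leak ER leak (uM/s); `NULL` balances SERCA at `ca_basal` so the
#'   resting state is stationary.
#' @param j_release Ca release rate of an open cluster (uM um^3/s, i.e.
#'   amount per second); applied to the cluster's grid cell, so the local
#'   concentration rate is `j_release / cell volume`.
#' @param puff_threshold detection threshold on the monitored Ca average (uM).
#' @param detection_volume_fl monitoring volume (fL).
#' @param ca_offset ambient Ca offset added to the opening propensity only
#'   (uM); emulates residual Ca under incomplete EGTA buffering.
#' @return A `model_params` list.
#' @export
model_params <- function(D_I = 100, D_Ca = 40,
                         ip3_basal = 0.05, ca_basal = 0.05,
                         omega = 602,
                         k_co = 553, k_ip = 0.345,
                         k_oc = 0.583, k_oi1 = 0.25,
                         k_i1o = 2.5, k_i1i2 = 150, i1i2_hill = 4,
                         k_i2i1 = 0.02, k_i2c = 0.02,
                         serca_vmax = 3, serca_k = 0.2, serca_hill = 2,
                         leak = NULL, j_release = 3,
                         puff_threshold = 0.1, detection_volume_fl = 1,
                         ca_offset = 0) {
  if (is.null(leak))
    leak <- serca_vmax * ca_basal^serca_hill /
      (serca_k^serca_hill + ca_basal^serca_hill)
  p <- list(D_I = D_I, D_Ca = D_Ca, ip3_basal = ip3_basal,
            ca_basal = ca_basal, omega = omega, k_co = k_co, k_ip = k_ip,
            k_oc = k_oc, k_oi1 = k_oi1, k_i1o = k_i1o, k_i1i2 = k_i1i2,
            i1i2_hill = i1i2_hill,
            k_i2i1 = k_i2i1, k_i2c = k_i2c, serca_vmax = serca_vmax,
            serca_k = serca_k, serca_hill = serca_hill, leak = leak,
            j_release = j_release, puff_threshold = puff_threshold,
            detection_volume_fl = detection_volume_fl, ca_offset = ca_offset)
  rates <- c("D_I", "D_Ca", "omega", "k_co", "k_ip", "k_oc", "k_oi1",
             "k_i1o", "k_i1i2", "k_i2i1", "k_i2c", "serca_vmax", "serca_k",
             "j_release")
  for (nm in rates) if (p[[nm]] <= 0) stop(nm, " must be strictly positive")
  if (puff_threshold <= ca_basal)
    stop("puff_threshold must exceed ca_basal")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Explicit-stability time step
#'
#' Largest admissible explicit Euler step for the fastest diffusing species,
#' `dt <= h^2 / (2 * dim * D)`, scaled by a safety `factor` (default 0.4).
#'
#' @param mask a `domain_mask`.
#' @param params a `model_params` (or a diffusivity via `D`).
#' @param D override diffusivity (um^2/s).
#' @param factor safety factor in (0, 1].
#' @export
stability_dt <- function(mask, params = NULL, D = NULL, factor = 0.4) {
  if (is.null(D)) D <- max(params$D_I, params$D_Ca)
  factor * mask$h^2 / (2 * mask$dim * D)
}

# fixed seed-splitting rule for per-replica reproducibility
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 69621) %%
               2147483647)
}
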