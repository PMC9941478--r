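## Four-state cluster stochastics: C, O, I1, I2.
## Allowed edges: C->O (IP3- and Ca-dependent), O->C, O<->I1, I1<->I2, I2->C.

STATE_LEVELS <- c("C", "O", "I1", "I2")

state_code <- function(s) match(s, STATE_LEVELS) - 1L # C=0, O=1, I1=2, I2=3

#' Opening propensity of a closed cluster
#'
#' `k_co * Ca * (IP3 / (IP3 + k_ip))^4` in 1/s, with concentrations in uM.
#' The fourth power reflects that a tetrameric IP3R opens only when all four
#' monomers are IP3-bound; the propensity is monotonically increasing in both
#' arguments and saturates to `k_co * Ca` as IP3 grows.
#'
#' @param ca_local,ip3_local detection-volume average concentrations (uM).
#' @param params a `model_params`.
#' @export
propensity_CO <- function(ca_local, ip3_local, params) {
  if (any(ca_local < 0) || any(ip3_local < 0)) stop("negative inputs")
  params$k_co * ca_local * (ip3_local / (ip3_local + params$k_ip))^4
}

# all outgoing propensities from a state, given local concentrations
cluster_propensities <- function(state, ca_local, ip3_local, params) {
  switch(state,
    C = c(O = propensity_CO(ca_local, ip3_local, params)),
    O = c(C = params$k_oc, I1 = params$k_oi1),
    I1 = c(O = params$k_i1o,
           I2 = params$k_i1i2 * ca_local^params$i1i2_hill),
    I2 = c(I1 = params$k_i2i1, C = params$k_i2c))
}

#' One hybrid stochastic step over all clusters
#'
#' Propensities are frozen at the current local concentrations; each cluster
#' fires at most one transition during `dt`, with firing probability
#' `1 - exp(-a_tot*dt)` and category chosen proportionally to the individual
#' propensities. A warning is raised when `a_tot*dt` exceeds 0.1 (time step
#' too coarse for the frozen-propensity approximation) and an error when it
#' reaches 1.
#'
#' @param state a `field_state`.
#' @param clusters list of `cluster_site`s.
#' @param params a `model_params`.
#' @param dt time step (s).
#' @return `list(clusters =, events =)`, events a data.frame
#'   (time, cluster, from, to).
#' @export
hybrid_step <- function(state, clusters, params, dt) {
  ev <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    cab <- mean(state$ca[cl$detect]) + params$ca_offset
    ipb <- mean(state$ip3[cl$detect])
    a <- cluster_propensities(cl$state, cab, ipb, params)
    atot <- sum(a)
    if (atot <= 0) next
    if (atot * dt >= 1) stop("a_tot*dt >= 1: dt far too large")
    if (atot * dt > 0.1)
      warning("a_tot*dt > 0.1; frozen-propensity step is coarse")
    if (runif(1) < -expm1(-atot * dt)) {
      to <- names(a)[sample.int(length(a), 1L, prob = a)]
      ev[[length(ev) + 1L]] <- data.frame(
        time = state$t + dt, cluster = cl$id, from = cl$state, to = to,
        stringsAsFactors = FALSE)
      clusters[[i]]$state <- to
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), cluster = integer(0),
               from = character(0), to = character(0))
  list(clusters = clusters, events = events)
}

#' Exact Gillespie simulation of a single cluster at fixed concentrations
#'
#' Zero-dimensional stochastic simulation algorithm used as the reference
#' against which the fixed-step hybrid scheme is checked: exponential waiting
#' times with the exact total propensity, no time discretization.
#'
#' @param ca_local,ip3_local fixed concentrations (uM).
#' @param params a `model_params`.
#' @param t_end end time (s).
#' @param state0 initial state.
#' @return data.frame of transitions (time, from, to).
#' @export
gillespie_exact <- function(ca_local, ip3_local, params, t_end,
                            state0 = "C") {
  t <- 0
  s <- state0
  out <- list()
  repeat {
    a <- cluster_propensities(s, ca_local, ip3_local, params)
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + rexp(1L, atot)
    if (t > t_end) break
    to <- names(a)[sample.int(length(a), 1L, prob = a)]
    out[[length(out) + 1L]] <- data.frame(time = t, from = s, to = to,
                                          stringsAsFactors = FALSE)
    s <- to
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), from = character(0), to = character(0))
}
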