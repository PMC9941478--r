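## Synthetic "observed" datasets with the statistical structure the analysis
## assumes, so calibration and D_I inference are testable end to end.

#' Generate a spot-photorelease latency dataset at known ground truth
#'
#' Runs the simulator's spot-photorelease latency scan at ground-truth
#' `(true_DI, theta)` and returns per-distance first-puff latencies in the
#' `latency_dataset` schema. When written to disk, provenance (ground truth,
#' seed) goes into a sidecar JSON that the inference functions never read.
#'
#' @param true_DI ground-truth effective diffusion coefficient (um^2/s).
#' @param theta photorelease rate (uM/s).
#' @param distances cluster distances from the spot (um).
#' @param n_rep replicates per distance (match the grouping, e.g. 50).
#' @param mask a `domain_mask`.
#' @param params a `model_params`.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param t_ph flash duration (s).
#' @param spot_center spot position (um).
#' @param path optional CSV path; sidecar metadata written to `<path>.json`.
#' @param t_pde,t_max,course see [latency_scan()].
#' @return A `latency_dataset` (invisibly the path when `path` is given).
#' @export
generate_spot_dataset <- function(true_DI, theta, distances, n_rep, mask,
                                  params = model_params(), seed = 1L,
                                  t_ph = 0.2, spot_center = NULL,
                                  path = NULL, t_pde = NULL, t_max = 120,
                                  course = NULL) {
  if (is.null(spot_center))
    spot_center <- c(1.25, dim(mask$occ)[-1] * mask$h / 2)
  d <- latency_scan(mask, spot_center, distances, theta, t_ph, params,
                    n_rep = n_rep, seed = seed, D_I = true_DI,
                    t_pde = t_pde, t_max = t_max, course = course)
  if (!is.null(path)) {
    write_latency_dataset(d, path,
                          sidecar = list(true_DI = true_DI, theta = theta,
                                         seed = seed, t_ph = t_ph,
                                         n_rep = n_rep,
                                         mask = mask$label))
    return(invisible(d))
  }
  d
}

#' Generate a parametric (simulator-free) latency dataset
#'
#' Exponential latencies around a given mean-latency curve:
#' `latency = offset + Exp(mean = ML - offset)` per condition, matching the
#' observed exponential dispersion of first-puff latencies with a fixed
#' minimal-latency floor. Useful for unit-testing the statistics without the
#' simulator.
#'
#' @param ml_curve data.frame with columns `condition` and `ml` (s).
#' @param n_rep replicates per condition.
#' @param offset latency floor (s), default 0.3.
#' @param seed integer seed.
#' @param path optional CSV path (sidecar JSON records the curve and seed).
#' @return A `latency_dataset`.
#' @export
generate_parametric_dataset <- function(ml_curve, n_rep, offset = 0.3,
                                        seed = 1L, path = NULL) {
  if (any(ml_curve$ml <= offset)) stop("ML must exceed the offset")
  if (n_rep == 0L)
    return(latency_dataset(numeric(0), integer(0), numeric(0), logical(0)))
  rows <- lapply(seq_len(nrow(ml_curve)), function(i) {
    set.seed(derive_seed(seed, i))
    latency_dataset(rep(ml_curve$condition[i], n_rep), seq_len(n_rep),
                    offset + rexp(n_rep, 1 / (ml_curve$ml[i] - offset)))
  })
  d <- do.call(rbind, rows)
  class(d) <- c("latency_dataset", "data.frame")
  if (!is.null(path)) {
    write_latency_dataset(d, path,
                          sidecar = list(kind = "parametric", seed = seed,
                                         offset = offset,
                                         ml = ml_curve$ml,
                                         condition = ml_curve$condition))
    return(invisible(d))
  }
  d
}
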