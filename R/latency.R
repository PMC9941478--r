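## Puff detection and first-passage latency statistics.

#' Detect puffs in a local Ca trace
#'
#' A puff is a maximal excursion of the monitored Ca average above the
#' threshold; the onset is the first sample at or above the threshold, the
#' end the first sample back below it.
#'
#' @param t,ca uniformly sampled time and concentration vectors (or a
#'   `sim_trace` passed as `t` with `cluster` selecting the column).
#' @param threshold detection threshold (uM), default 0.1.
#' @param cluster column of `ca_local` when `t` is a `sim_trace`.
#' @return data.frame (onset, end, peak); `end` is `NA` for an excursion
#'   still above threshold at the end of the trace.
#' @export
detect_puffs <- function(t, ca = NULL, threshold = 0.1, cluster = 1L) {
  if (inherits(t, "sim_trace")) {
    ca <- t$ca_local[, cluster]
    t <- t$t
  }
  if (!length(t)) stop("empty trace")
  above <- ca >= threshold
  d <- diff(c(FALSE, above))
  on_i <- which(d == 1L)
  off_i <- which(d == -1L) # first index below threshold after an excursion
  if (!length(on_i))
    return(data.frame(onset = numeric(0), end = numeric(0),
                      peak = numeric(0)))
  out <- data.frame(onset = t[on_i], end = NA_real_, peak = NA_real_)
  for (k in seq_along(on_i)) {
    stop_i <- off_i[off_i > on_i[k]][1]
    out$end[k] <- if (is.na(stop_i)) NA_real_ else t[stop_i]
    last <- if (is.na(stop_i)) length(ca) else stop_i - 1L
    out$peak[k] <- max(ca[on_i[k]:last])
  }
  out
}

#' First-puff latency of a trace
#'
#' Onset of the first puff at or after `t_flash`, minus `t_flash`; `NA`
#' (censored) when no puff occurs.
#'
#' @param trace a `sim_trace` or data.frame of puffs from [detect_puffs()].
#' @param t_flash flash time (s).
#' @param threshold,cluster passed to [detect_puffs()] for a `sim_trace`.
#' @export
first_puff_latency <- function(trace, t_flash = 0, threshold = 0.1,
                               cluster = 1L) {
  puffs <- if (inherits(trace, "sim_trace"))
    detect_puffs(trace, threshold = threshold, cluster = cluster) else trace
  onset <- puffs$onset[puffs$onset >= t_flash]
  if (!length(onset)) NA_real_ else onset[1] - t_flash
}

#' Latency dataset container
#'
#' Tabular first-puff latencies keyed by an experimental condition (distance
#' in um, flash duration in s, or [IP3] in uM) and replicate. Censored rows
#' carry the simulation end time in `latency_s` with `censored = TRUE`.
#'
#' @param condition condition key per row.
#' @param replicate replicate id per row.
#' @param latency_s latency (s), or `t_end` for censored rows.
#' @param censored logical.
#' @export
latency_dataset <- function(condition, replicate, latency_s,
                            censored = FALSE) {
  d <- data.frame(condition = condition, replicate = replicate,
                  latency_s = latency_s,
                  censored = rep_len(censored, length(latency_s)))
  if (any(d$latency_s[!d$censored] <= 0, na.rm = TRUE))
    stop("latencies must be > 0")
  class(d) <- c("latency_dataset", "data.frame")
  d
}

#' Write/read a latency dataset as CSV
#'
#' Plain CSV with header `condition,replicate,latency_s,censored`; an
#' optional sidecar JSON (same path + `.json`) records provenance metadata
#' and is never consumed by the inference functions.
#'
#' @param data a `latency_dataset`.
#' @param path CSV path.
#' @param sidecar optional named list written as `<path>.json`.
#' @export
write_latency_dataset <- function(data, path, sidecar = NULL) {
  write.csv(as.data.frame(data)[, c("condition", "replicate", "latency_s",
                                    "censored")],
            path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_latency_dataset
#' @export
read_latency_dataset <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  latency_dataset(d$condition, d$replicate, d$latency_s,
                  as.logical(d$censored))
}

#' Mean and minimal first-puff latencies per condition
#'
#' ML is the mean (+/- SEM) of the uncensored latencies; MFP is the mean
#' (+/- SEM) of per-group minima, with replicates assigned to groups in
#' replicate order (replicates 1..group_size form group 1, and so on).
#' Censored rows are dropped with a warning when they exceed 10% of a
#' condition.
#'
#' @param data a `latency_dataset`.
#' @param grouping `c(n_groups, group_size)`; the default 10 x 5 matches 50
#'   replicates per condition.
#' @param strict require exactly `n_groups * group_size` uncensored
#'   replicates per condition (otherwise groups are formed from the available
#'   replicates in order).
#' @return data.frame (condition, ml, ml_sem, mfp, mfp_sem, n, n_censored,
#'   grouping).
#' @export
summarize_latencies <- function(data, grouping = c(10L, 5L), strict = FALSE) {
  stopifnot(length(grouping) == 2L, all(grouping >= 1L))
  out <- lapply(split(as.data.frame(data), data$condition), function(d) {
    d <- d[order(d$replicate), ]
    cens <- sum(d$censored)
    if (cens > 0.1 * nrow(d))
      warning(sprintf("condition %s: %d/%d censored runs excluded (bias risk)",
                      format(d$condition[1]), cens, nrow(d)))
    lat <- d$latency_s[!d$censored]
    if (strict && length(lat) != grouping[1] * grouping[2])
      stop("insufficient replicates for the requested grouping")
    if (!length(lat)) return(NULL)
    grp <- ceiling(seq_along(lat) / grouping[2])
    grp <- grp[grp <= grouping[1]]
    mins <- tapply(lat[seq_along(grp)], grp, min)
    data.frame(condition = d$condition[1],
               ml = mean(lat), ml_sem = sd(lat) / sqrt(length(lat)),
               mfp = mean(mins),
               mfp_sem = if (length(mins) > 1) sd(mins) / sqrt(length(mins))
                         else 0,
               n = length(lat), n_censored = cens,
               grouping = paste(grouping, collapse = "x"))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out[order(out$condition), ]
}

#' Interevent interval statistics
#'
#' Successive onset-to-onset differences of detected events; sample (n-1)
#' standard deviation and CV = SD/mean. Used both for interpuff intervals
#' (local detection-volume trace) and interspike intervals (domain-average
#' trace) -- the same threshold detector applied to different observables.
#'
#' @param onsets event onset times (s), or a `sim_trace` (then `observable`
#'   selects the local or domain-average Ca and `threshold`/`cluster` are
#'   passed to [detect_puffs()]).
#' @param observable `"local"` or `"domain"` for a `sim_trace`.
#' @param threshold,cluster see [detect_puffs()].
#' @param min_gap debouncing window (s): onsets closer than this to the
#'   previous one are merged into the same event (useful for spikes whose
#'   domain average flickers around the threshold).
#' @return list(mean, sd, cv, n, intervals).
#' @export
interevent_stats <- function(onsets, observable = c("local", "domain"),
                             threshold = 0.1, cluster = 1L, min_gap = 0) {
  if (inherits(onsets, "sim_trace")) {
    observable <- match.arg(observable)
    tr <- onsets
    ca <- if (observable == "domain") tr$ca_domain else
      tr$ca_local[, cluster]
    onsets <- detect_puffs(tr$t, ca, threshold = threshold)$onset
  }
  onsets <- sort(onsets)
  if (min_gap > 0 && length(onsets) > 1L)
    onsets <- onsets[c(TRUE, diff(onsets) > min_gap)]
  if (length(onsets) < 2L) stop("fewer than 2 events")
  iv <- diff(sort(onsets))
  m <- mean(iv)
  s <- sd(iv)
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_,
       n = length(iv), intervals = iv)
}

#' Maximum-likelihood exponential fit of latencies
#'
#' After subtracting `offset`, the MLE of the exponential mean is the sample
#' mean; the CI uses the normal approximation `tau_hat * (1 +/- z/sqrt(n))`.
#'
#' @param latencies uncensored latencies (s), n >= 5.
#' @param offset fixed offset subtracted before fitting (s).
#' @param level confidence level.
#' @return list(tau, ci, n).
#' @export
fit_exponential <- function(latencies, offset = 0, level = 0.95) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) < 5L) stop("need at least 5 uncensored latencies")
  x <- latencies - offset
  if (any(x <= 0)) stop("latencies must exceed the offset")
  if (sd(x) == 0) stop("degenerate (all-equal) latencies")
  tau <- mean(x)
  z <- qnorm(1 - (1 - level) / 2)
  list(tau = tau,
       ci = c(tau / (1 + z / sqrt(length(x))),
              tau / (1 - z / sqrt(length(x)))),
       n = length(x))
}
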