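#' Photorelease protocols
#'
#' Source terms describing flash photorelease of caged IP3. Three kinds:
#' \describe{
#'   \item{uniform_step}{[IP3] is set to `target` everywhere at t = 0 and no
#'     source acts afterwards (instantaneous uniform uncaging).}
#'   \item{spot}{IP3 is produced at rate `theta` (uM/s) in every cell of a
#'     disk/sphere of radius `radius` around `center` while t <= t_ph.}
#'   \item{distributed}{ten spots share the same total production: each cell
#'     of each spot produces at `theta/10` while t <= t_ph. Default centers
#'     are evenly spaced along the major axis at mid-height.}
#' }
#'
#' @param target uniform [IP3] after the step (uM).
#' @param theta IP3 production rate at the flash location (uM/s).
#' @param t_ph flash duration (s); the boundary instant t = t_ph is included.
#' @param center,centers spot centre(s) in um (matrix rows for `centers`).
#' @param radius spot radius (um).
#' @return A `puffr_protocol` object.
#' @export
protocol_uniform_step <- function(target) {
  stopifnot(target > 0)
  structure(list(kind = "uniform_step", target = target, theta = 0,
                 t_ph = Inf), class = "puffr_protocol")
}

#' @rdname protocol_uniform_step
#' @export
protocol_spot <- function(theta, t_ph, center, radius = 0.25) {
  stopifnot(theta >= 0, t_ph > 0, radius > 0)
  structure(list(kind = "spot", theta = theta, t_ph = t_ph,
                 centers = matrix(center, nrow = 1L), radius = radius),
            class = "puffr_protocol")
}

#' @rdname protocol_uniform_step
#' @export
protocol_distributed <- function(theta, t_ph, centers = NULL, radius = 0.25) {
  stopifnot(theta >= 0, t_ph > 0, radius > 0)
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    if (nrow(centers) != 10L) stop("distributed protocol has exactly 10 centers")
  }
  structure(list(kind = "distributed", theta = theta, t_ph = t_ph,
                 centers = centers, radius = radius),
            class = "puffr_protocol")
}

# resolve a protocol against a mask: source cell indices and per-cell rate
bind_protocol <- function(protocol, mask) {
  if (protocol$kind == "uniform_step")
    return(list(cells = integer(0), rate = 0, t_ph = 0,
                target = protocol$target))
  centers <- protocol$centers
  if (is.null(centers)) { # default layout along the major axis, mid-height
    ext <- dim(mask$occ) * mask$h
    xs <- seq(ext[1] / 20, ext[1] * 19 / 20, length.out = 10L)
    centers <- cbind(xs, matrix(rep(ext[-1] / 2, each = 10L), nrow = 10L))
  }
  cells <- integer(0)
  for (r in seq_len(nrow(centers))) {
    cc <- cells_within_radius(mask, centers[r, ], protocol$radius)
    if (!length(cc) || pos_to_cell(mask, centers[r, ]) == 0L)
      stop("spot center outside cytosol")
    cells <- c(cells, cc)
  }
  rate <- if (protocol$kind == "spot") protocol$theta else protocol$theta / 10
  list(cells = unique(cells), rate = rate, t_ph = protocol$t_ph, target = NULL,
       n_cells_per_spot = length(cells) / nrow(centers))
}
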