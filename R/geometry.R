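#' @useDynLib puffr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rexp runif sd setNames qnorm ks.test complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

## Shape specifications -------------------------------------------------------

#' Built-in shape descriptors
#'
#' Constructors for the shape specifications accepted by [build_mask()].
#' Dimensions are in micrometres. `shape_ellipse(a, b)` has semi-axes `a`
#' (along x) and `b` (along y); `shape_ellipsoid(a, b, c)` adds the z
#' semi-axis. `shape_mask_image()` points to an 8-bit PNG or PGM image whose
#' pixels at or above 50% intensity are interpreted as cytosol, with
#' `px` micrometres per pixel.
#'
#' @param Lx,Ly rectangle side lengths (um).
#' @param a,b,c semi-axes (um).
#' @param path path to a PNG/PGM mask image.
#' @param px pixel size (um per pixel).
#' @return A shape specification list consumed by [build_mask()].
#' @export
shape_rectangle <- function(Lx, Ly) {
  stopifnot(Lx > 0, Ly > 0)
  structure(list(kind = "rectangle", Lx = Lx, Ly = Ly), class = "puffr_shape")
}

#' @rdname shape_rectangle
#' @export
shape_ellipse <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(kind = "ellipse", a = a, b = b), class = "puffr_shape")
}

#' @rdname shape_rectangle
#' @export
shape_ellipsoid <- function(a, b, c) {
  stopifnot(a > 0, b > 0, c > 0)
  structure(list(kind = "ellipsoid", a = a, b = b, c = c),
            class = "puffr_shape")
}

#' @rdname shape_rectangle
#' @export
shape_mask_image <- function(path, px) {
  stopifnot(is.character(path), length(path) == 1L, px > 0)
  structure(list(kind = "mask_image", path = path, px = px),
            class = "puffr_shape")
}

## DomainMask ------------------------------------------------------------------

# Internal constructor: occ is a logical matrix (2D) or array (3D),
# TRUE = cytosol. Cell (i,j) spans [ (i-1)*h, i*h ) from the bounding-box
# corner; coordinates of a cell centre are ((i-0.5)*h, (j-0.5)*h[, ...]).
new_domain_mask <- function(occ, h, d_eff = 1 / 2.25, label = "custom",
                            check_connected = TRUE) {
  dim_n <- length(dim(occ))
  stopifnot(dim_n %in% c(2L, 3L), h > 0)
  if (dim_n == 2L) stopifnot(d_eff > 0)
  n <- sum(occ)
  if (n < 1L) stop("mask has an empty interior")
  idx <- array(0L, dim = dim(occ))
  idx[occ] <- seq_len(n)
  cells <- which(occ, arr.ind = TRUE)
  nbr <- neighbour_table(occ, idx)
  m <- structure(
    list(dim = dim_n, h = h, occ = occ, d_eff = if (dim_n == 2L) d_eff else NA_real_,
         label = label, idx = idx, cells = cells, nbr = nbr, n = n),
    class = "domain_mask")
  if (check_connected && !mask_connected(m)) {
    warning("cytosol mask is not a single connected component; ",
            "latencies at unreachable clusters will be infinite")
  }
  m
}

# Per interior cell, 0-based interior index of each face neighbour (-1 = wall).
neighbour_table <- function(occ, idx) {
  d <- dim(occ)
  nd <- length(d)
  cells <- which(occ, arr.ind = TRUE)
  n <- nrow(cells)
  nbr <- matrix(-1L, n, 2L * nd)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      shifted <- cells
      shifted[, ax] <- shifted[, ax] + s
      ok <- shifted[, ax] >= 1L & shifted[, ax] <= d[ax]
      j <- integer(n)
      j[ok] <- idx[shifted[ok, , drop = FALSE]]
      col <- (ax - 1L) * 2L + (if (s < 0) 1L else 2L)
      nbr[, col] <- ifelse(ok & j > 0L, j - 1L, -1L)
    }
  }
  nbr
}

mask_connected <- function(mask) {
  if (mask$n == 1L) return(TRUE)
  all(cpp_flood(mask$nbr, 0L))
}

#' Build a discretized simulation domain
#'
#' Discretizes a built-in shape (rectangle, ellipse, ellipsoid) or a binary
#' mask image onto a regular square/cubic lattice with spacing `h`. Cells are
#' cytosol when their centre lies inside the analytic shape (or on a >= 50%
#' grey pixel). In 2D an effective depth `d_eff` converts areal elements into
#' volumes; the default 1/2.25 um equates the 1.5 x 1.5 um^2 detection
#' footprint with 1 fL.
#'
#' @param shape a shape specification from [shape_rectangle()] and friends.
#' @param h grid spacing (um). Default 0.25 in 2D, 0.5 in 3D.
#' @param d_eff effective depth (um, 2D only).
#' @param check_connected warn when the cytosol is not a single connected
#'   component.
#' @return A `domain_mask` object.
#' @export
build_mask <- function(shape, h = NULL, d_eff = 1 / 2.25,
                       check_connected = TRUE) {
  stopifnot(inherits(shape, "puffr_shape"))
  if (is.null(h)) h <- if (shape$kind == "ellipsoid") 0.5 else 0.25
  if (h <= 0) stop("h must be > 0")
  occ <- switch(shape$kind,
    rectangle = {
      nx <- max(1L, round(shape$Lx / h))
      ny <- max(1L, round(shape$Ly / h))
      matrix(TRUE, nx, ny)
    },
    ellipse = {
      nx <- ceiling(2 * shape$a / h)
      ny <- ceiling(2 * shape$b / h)
      cx <- (seq_len(nx) - 0.5) * h - shape$a
      cy <- (seq_len(ny) - 0.5) * h - shape$b
      outer(cx, cy, function(x, y) (x / shape$a)^2 + (y / shape$b)^2 < 1)
    },
    ellipsoid = {
      nx <- ceiling(2 * shape$a / h)
      ny <- ceiling(2 * shape$b / h)
      nz <- ceiling(2 * shape$c / h)
      cx <- (seq_len(nx) - 0.5) * h - shape$a
      cy <- (seq_len(ny) - 0.5) * h - shape$b
      cz <- (seq_len(nz) - 0.5) * h - shape$c
      r2 <- outer(outer((cx / shape$a)^2, (cy / shape$b)^2, `+`),
                  (cz / shape$c)^2, `+`)
      r2 < 1
    },
    mask_image = {
      img <- read_mask_image(shape$path)
      h <- shape$px
      # image rows run top-down; x = column, y = reversed row index
      t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
    },
    stop("unknown shape kind: ", shape$kind))
  if (!any(occ)) stop("mask has an empty interior")
  new_domain_mask(occ, h = h, d_eff = d_eff, label = shape$kind,
                  check_connected = check_connected)
}

read_mask_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image: ", path)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    img <- read_pgm(path)
  } else {
    a <- png::readPNG(path)
    img <- if (length(dim(a)) == 3L) apply(a[, , seq_len(min(3L, dim(a)[3])),
                                            drop = FALSE], c(1, 2), mean) else a
  }
  img >= 0.5
}

# minimal P2/P5 PGM reader (8-bit)
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("unreadable image: not a P2/P5 PGM")
  toks <- character(0)
  while (length(toks) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    toks <- c(toks, strsplit(trimws(line), "\\s+")[[1]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1]); ht <- as.integer(toks[2]); mx <- as.numeric(toks[3])
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", w * ht))
  } else {
    v <- scan(con, what = integer(), n = w * ht, quiet = TRUE)
  }
  matrix(v / mx, nrow = ht, ncol = w, byrow = TRUE)
}

#' @export
print.domain_mask <- function(x, ...) {
  vol <- x$n * x$h^x$dim * if (x$dim == 2L) x$d_eff else 1
  cat(sprintf("<domain_mask> %s, %dD, h = %g um, %d interior cells (%s %g um^%d, %g um^3)\n",
              x$label, x$dim, x$h, x$n,
              if (x$dim == 2L) "area" else "volume",
              x$n * x$h^x$dim, x$dim, vol))
  invisible(x)
}

# volume of one grid cell in um^3 (2D cells carry the effective depth)
cell_volume_um3 <- function(mask)
  if (mask$dim == 2L) mask$h^2 * mask$d_eff else mask$h^3

#' Interior area/volume of a mask
#' @param mask a `domain_mask`.
#' @return Interior area (um^2, 2D) or volume (um^3, 3D) of the lattice.
#' @export
mask_measure <- function(mask) mask$n * mask$h^mask$dim

# position (um) -> interior index (or 0); pos is a length-dim vector
pos_to_cell <- function(mask, pos) {
  ij <- pmin(pmax(ceiling(pos / mask$h), 1L), dim(mask$occ))
  mask$idx[matrix(as.integer(ij), 1L)]
}

cell_centre <- function(mask, i) {
  unname((mask$cells[i, , drop = FALSE] - 0.5) * mask$h)
}

# interior indices whose centres lie within `radius` um of `pos`
cells_within_radius <- function(mask, pos, radius) {
  ctr <- sweep(mask$cells - 0.5, 2L, pos / mask$h, `-`)
  which(rowSums(ctr^2) * mask$h^2 <= radius^2 + 1e-12)
}

# detection region: interior cells inside the monitoring volume centred on
# cell i. 2D: square footprint of `area` um^2 (default 2.25 -> 1 fL with
# d_eff); 3D: sphere of volume `vol_fl` fL.
detection_region <- function(mask, i, vol_fl = 1) {
  ctr <- cell_centre(mask, i)
  if (mask$dim == 2L) {
    half <- sqrt(vol_fl / mask$d_eff) / 2
    d <- abs(sweep(mask$cells - 0.5, 2L, ctr / mask$h, `-`)) * mask$h
    which(d[, 1] <= half + 1e-9 & d[, 2] <= half + 1e-9)
  } else {
    r <- (3 * vol_fl / (4 * pi))^(1 / 3)
    cells_within_radius(mask, ctr, r)
  }
}

# grid distance (um) of every interior cell to the nearest wall-adjacent cell,
# counted in boundary shells (multi-source BFS over the interior graph).
distance_to_boundary <- function(mask) {
  has_wall <- rowSums(mask$nbr < 0L) > 0L
  dist <- rep(Inf, mask$n)
  dist[has_wall] <- 0
  frontier <- which(has_wall)
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    nb <- mask$nbr[frontier, , drop = FALSE]
    nb <- unique(nb[nb >= 0L]) + 1L
    frontier <- nb[dist[nb] == Inf]
    dist[frontier] <- lvl * mask$h
  }
  dist
}

## ER obstacles ----------------------------------------------------------------

#' Procedural ER obstacle specification
#'
#' A random scattering of short bars (1 x `len` cells) carved out of the
#' cytosol until `fill` of the interior is occupied, emulating sections
#' through ER sheets. Use a [shape_mask_image()] for a drawn ER shape.
#'
#' @param fill target fraction of interior cells converted to ER.
#' @param len bar length in cells.
#' @param seed integer seed for reproducible placement.
#' @export
er_bars <- function(fill, len = 3L, seed = 1L) {
  stopifnot(fill >= 0, fill < 1, len >= 1L)
  structure(list(kind = "bars", fill = fill, len = as.integer(len),
                 seed = as.integer(seed)), class = "puffr_er_spec")
}

#' Insert ER obstacles into a domain mask
#'
#' Removes ER-occupied cells from the cytosol. The remaining cytosol must
#' stay connected; clusters already placed must not be covered (pass their
#' sites via `clusters` to enforce this).
#'
#' @param mask a `domain_mask`.
#' @param er_spec an [er_bars()] spec or a [shape_mask_image()] whose TRUE
#'   pixels mark ER (must lie inside the cytosol).
#' @param clusters optional list of `cluster_site`s that must remain free.
#' @return A new `domain_mask` with attribute `cytosol_fraction` (fraction of
#'   the original interior that remains).
#' @export
add_er_obstacles <- function(mask, er_spec, clusters = NULL) {
  stopifnot(inherits(mask, "domain_mask"))
  occ <- mask$occ
  keep <- rep(TRUE, mask$n)
  if (inherits(er_spec, "puffr_er_spec")) {
    if (er_spec$fill == 0) {
      out <- mask
      attr(out, "cytosol_fraction") <- 1
      return(out)
    }
    target <- floor(er_spec$fill * mask$n)
    d <- dim(occ)
    dd <- as.integer(d)
    # keep one cell of clearance from the cell wall so thin regions (e.g.
    # ellipse tips) are never sealed; each bar must also leave the cytosol
    # connected (checked by flood fill before it is accepted)
    clear <- rep(TRUE, mask$n)
    clear[rowSums(mask$nbr < 0L) > 0L] <- FALSE
    if (!is.null(clusters)) # bars avoid cluster (and other protected) cells
      for (cl in clusters) clear[cl$cell] <- FALSE
    clear_arr <- array(FALSE, d)
    clear_arr[mask$cells[clear, , drop = FALSE]] <- TRUE
    occ_new <- occ
    stride <- cumprod(c(1, d[-length(d)]))
    set.seed(er_spec$seed)
    n_er <- 0L
    tries <- 0L
    while (n_er < target && tries < 200L * target) {
      tries <- tries + 1L
      ax <- sample.int(mask$dim, 1L)
      anchor <- vapply(d, function(k) sample.int(k, 1L), 1L)
      span <- anchor[ax] + 0L:(er_spec$len - 1L)
      if (max(span) > d[ax]) next
      cells <- matrix(rep(anchor, each = er_spec$len), ncol = mask$dim)
      cells[, ax] <- span
      if (!all(occ_new[cells]) || !all(clear_arr[cells])) next
      occ_try <- occ_new
      occ_try[cells] <- FALSE
      start <- which(occ_try)[1] - 1L
      if (cpp_flood_count(occ_try, dd, start) != sum(occ_try)) next
      occ_new <- occ_try
      n_er <- n_er + er_spec$len
    }
  } else if (inherits(er_spec, "puffr_shape") && er_spec$kind == "mask_image") {
    img <- read_mask_image(er_spec$path)
    er2 <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE]
    if (!identical(dim(er2), dim(occ)))
      stop("ER mask image does not match the domain lattice")
    if (any(er2 & !occ)) stop("ER mask extends outside the cell mask")
    occ_new <- occ & !er2
  } else stop("unsupported er_spec")

  if (!is.null(clusters)) {
    for (cl in clusters) {
      ij <- mask$cells[cl$cell, , drop = FALSE]
      if (!occ_new[ij]) stop("ER covers a cluster position")
    }
  }
  if (!any(occ_new)) stop("ER removed the whole cytosol")
  out <- new_domain_mask(occ_new, h = mask$h, d_eff = mask$d_eff,
                         label = paste0(mask$label, "+ER"),
                         check_connected = FALSE)
  if (!mask_connected(out)) stop("cytosol disconnected")
  attr(out, "cytosol_fraction") <- out$n / mask$n
  out
}

## Cluster placement -----------------------------------------------------------

new_cluster_site <- function(mask, cell, id, vol_fl = 1) {
  det <- detection_region(mask, cell, vol_fl)
  stopifnot(length(det) > 0L, cell %in% det)
  structure(list(id = id, cell = cell, pos = drop(cell_centre(mask, cell)),
                 state = "C", detect = det, distance = NA_real_),
            class = "cluster_site")
}

#' @export
print.cluster_site <- function(x, ...) {
  cat(sprintf("<cluster_site> #%d at (%s) um, state %s, %d detection cells\n",
              x$id, paste(signif(x$pos, 4), collapse = ", "), x$state,
              length(x$detect)))
  invisible(x)
}

#' Place IP3R cluster sites in a domain
#'
#' @param mask a `domain_mask`.
#' @param n number of clusters.
#' @param placement `"uniform_random"`, `"near_membrane"`, or `"explicit"`.
#' @param delta near-membrane tolerance (um); clamped to the boundary-adjacent
#'   cell layer when smaller than `h`.
#' @param positions for `"explicit"`: matrix (n x dim) of positions in um.
#' @param seed integer seed (random placements are deterministic given it).
#' @param detection_volume_fl monitoring volume per cluster (fL).
#' @return List of `cluster_site` objects.
#' @export
place_clusters <- function(mask, n, placement = c("uniform_random",
                                                  "near_membrane", "explicit"),
                           delta = 0.1, positions = NULL, seed = 1L,
                           detection_volume_fl = 1) {
  placement <- match.arg(placement)
  stopifnot(n >= 1L)
  if (placement == "explicit") {
    stopifnot(!is.null(positions))
    positions <- matrix(positions, ncol = mask$dim)
    stopifnot(nrow(positions) == n)
    cells <- apply(positions, 1L, function(p) pos_to_cell(mask, p))
    if (any(cells == 0L)) stop("explicit cluster position outside the cytosol")
  } else {
    eligible <- seq_len(mask$n)
    if (placement == "near_membrane") {
      dlt <- max(delta, mask$h) # clamp: sub-grid placement is meaningless
      db <- distance_to_boundary(mask)
      eligible <- which(db <= dlt - mask$h + 1e-9) # cells within the shell
      if (!length(eligible)) eligible <- which(db == min(db))
    }
    if (length(eligible) < n) stop("n exceeds eligible cells")
    set.seed(seed)
    cells <- sample(eligible, n)
  }
  lapply(seq_len(n), function(i)
    new_cluster_site(mask, cells[i], id = i, vol_fl = detection_volume_fl))
}

# internal: astrocyte-like synthetic geometry (disk body + narrow process),
# used for shape-effect checks; not derived from any published image.
astrocyte_mask <- function(h = 0.25, body_radius = 8, proc_len = 22,
                           proc_width = 2, d_eff = 1 / 2.25) {
  Lx <- 2 * body_radius + proc_len
  Ly <- 2 * body_radius
  nx <- ceiling(Lx / h); ny <- ceiling(Ly / h)
  cx <- (seq_len(nx) - 0.5) * h
  cy <- (seq_len(ny) - 0.5) * h
  body <- outer(cx, cy, function(x, y)
    (x - body_radius)^2 + (y - body_radius)^2 < body_radius^2)
  proc <- outer(cx, cy, function(x, y)
    x >= body_radius & x <= 2 * body_radius + proc_len &
      abs(y - body_radius) <= proc_width / 2)
  new_domain_mask(body | proc, h = h, d_eff = d_eff, label = "astrocyte")
}
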