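test_that("builtin shapes discretize to the analytic area/volume", {
  m <- build_mask(shape_rectangle(50, 10), h = 0.5)
  expect_identical(dim(m$occ), c(100L, 20L))
  expect_equal(mask_measure(m), 500) # exact tiling

  e <- build_mask(shape_ellipse(25, 5), h = 0.25)
  expect_lt(abs(mask_measure(e) / (pi * 25 * 5) - 1), 0.02)

  s <- build_mask(shape_ellipsoid(25, 5, 2.5), h = 0.5)
  expect_lt(abs(mask_measure(s) / (4 / 3 * pi * 25 * 5 * 2.5) - 1), 0.05)
})

test_that("degenerate shape specs are rejected", {
  expect_error(shape_rectangle(0, 5))
  expect_error(build_mask(shape_ellipse(1, 1), h = -0.1), "h must be > 0")
  expect_error(build_mask(shape_mask_image(tempfile(), px = 0.5)),
               "unreadable")
})

test_that("mask images threshold at 50% grey with top row = max y", {
  img <- matrix(0, 6, 8) # 6 rows (y), 8 cols (x)
  img[1, ] <- 1          # top row bright -> max-y cells
  img[, 1] <- 0.6        # left column just above threshold
  img[6, 8] <- 0.49      # below threshold
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  m <- build_mask(shape_mask_image(path, px = 0.5))
  expect_identical(dim(m$occ), c(8L, 6L)) # x = columns, y = rows
  expect_true(all(m$occ[, 6]))            # top image row -> y index 6
  expect_true(all(m$occ[1, ]))
  expect_false(m$occ[8, 1])               # bottom-right pixel was 0.49
  expect_equal(m$h, 0.5)
})

test_that("ER obstacles remove cytosol but keep it connected", {
  e <- build_mask(shape_ellipse(25, 5), h = 0.25)
  same <- add_er_obstacles(e, er_bars(0))
  expect_equal(same$n, e$n)
  expect_equal(attr(same, "cytosol_fraction"), 1)

  er <- add_er_obstacles(e, er_bars(0.30, seed = 4))
  expect_lt(abs(attr(er, "cytosol_fraction") - 0.70), 0.02)
  expect_true(all(er$occ <= e$occ)) # never creates cells outside the cell
  expect_true(puffr:::mask_connected(er))
})

test_that("an ER wall sealing the midline is rejected as disconnected", {
  img <- matrix(1, 10, 20) # cell: all cytosol, 20 x 10 cells
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  cellm <- build_mask(shape_mask_image(path, px = 0.5))
  er <- img * 0
  er[, 10] <- 1 # full-height wall
  er_path <- tempfile(fileext = ".pgm")
  write_pgm(er, er_path)
  expect_error(add_er_obstacles(cellm, shape_mask_image(er_path, px = 0.5)),
               "cytosol disconnected")
})

test_that("ER must not cover a cluster position", {
  m <- build_mask(shape_rectangle(3, 3), h = 0.5)
  cl <- place_clusters(m, 1L, "explicit", positions = c(1.5, 1.5))
  er <- matrix(0, 6, 6)
  er[3:4, 3:4] <- 1 # centre block, covers the cluster
  path <- tempfile(fileext = ".pgm")
  write_pgm(er, path)
  expect_error(
    add_er_obstacles(m, shape_mask_image(path, px = 0.5), clusters = cl),
    "covers a cluster")
})

test_that("cluster placement is valid, seeded, and boundary-aware", {
  m <- build_mask(shape_rectangle(5, 5), h = 0.25)
  one <- place_clusters(m, 1L, "explicit", positions = c(2.5, 2.5))
  expect_equal(one[[1]]$pos, c(2.375, 2.375)) # centre cell
  expect_true(one[[1]]$cell %in% one[[1]]$detect)
  expect_equal(length(one[[1]]$detect), 49L) # 7x7 cells = 1.5x1.5 um in 2D

  big <- build_mask(shape_rectangle(50, 10), h = 0.25)
  a <- place_clusters(big, 200L, "uniform_random", seed = 42L)
  b <- place_clusters(big, 200L, "uniform_random", seed = 42L)
  expect_identical(vapply(a, `[[`, 1L, "cell"), vapply(b, `[[`, 1L, "cell"))
  expect_equal(length(unique(vapply(a, `[[`, 1L, "cell"))), 200L)

  expect_error(place_clusters(tiny_mask(), 1000L), "exceeds eligible")

  # near-membrane: every site within one boundary-adjacent shell of the wall
  ell <- build_mask(shape_ellipsoid(10, 4, 2), h = 0.5)
  nm <- place_clusters(ell, 20L, "near_membrane", delta = 0.1, seed = 7L)
  out_cells <- which(!ell$occ, arr.ind = TRUE)
  lims <- dim(ell$occ)
  for (cl in nm) {
    ij <- ell$cells[cl$cell, ]
    # brute force: nearest excluded-or-outside lattice cell
    d_out <- min(sqrt(colSums((t(out_cells) - ij)^2))) * ell$h
    d_edge <- min(ij - 1L, lims - ij) * ell$h + ell$h
    expect_lte(min(d_out, d_edge), ell$h + 1e-9)
  }
})

test_that("disconnected masks trigger a warning", {
  img <- matrix(1, 5, 9)
  img[, 5] <- 0 # split in two
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  expect_warning(build_mask(shape_mask_image(path, px = 0.5)),
                 "connected")
})
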