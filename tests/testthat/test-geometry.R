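test_that("inscribed square follows the Pythagorean construction", {
  g <- inscribe_square_grid(fov_circle(0, 0, 16.6))
  # the conventionally quoted side for d = 16.6 is 11.73 (a truncation of
  # 11.7380...); agree with it to the quoted precision
  expect_lt(abs(g$side_a - 11.73), 0.01)
  expect_equal(g$side_a, 16.6 / sqrt(2), tolerance = 1e-12)
  expect_equal(inscribe_square_grid(fov_circle(0, 0, sqrt(2)))$side_a, 1)

  g200 <- inscribe_square_grid(fov_circle(100, 100, 200), n_per_side = 10)
  expect_equal(g200$cell_side, 200 / sqrt(2) / 10, tolerance = 1e-12)
  corners <- grid_corners(g200)
  expect_equal(corners$dist_to_center, rep(100, 4), tolerance = 1e-9)
})

test_that("grid cells are congruent, tile the square, and are 1% each at n=10", {
  set.seed(11)
  for (d in runif(25, 10, 1e4)) {
    g <- inscribe_square_grid(fov_circle(0, 0, d), n_per_side = 10)
    expect_equal(g$side_a / d, 1 / sqrt(2), tolerance = 1e-15)
    expect_equal(g$side_a^2, d^2 / 2, tolerance = 1e-12)
    expect_identical(nrow(g$cells), 100L)
    widths <- g$cells$x1 - g$cells$x0
    heights <- g$cells$y1 - g$cells$y0
    expect_equal(widths, rep(g$cell_side, 100), tolerance = 1e-12)
    expect_equal(heights, rep(g$cell_side, 100), tolerance = 1e-12)
    # cell area is exactly 1% of the grid area
    expect_equal(widths[1] * heights[1] / g$side_a^2, 0.01, tolerance = 1e-12)
    # cells tile: total area equals square area, extremes touch the square
    expect_equal(sum(widths * heights), g$side_a^2, tolerance = 1e-9 * g$side_a^2)
    expect_equal(min(g$cells$x0), -g$side_a / 2, tolerance = 1e-9)
    expect_equal(max(g$cells$x1), g$side_a / 2, tolerance = 1e-9)
    # corners on the circle within 1e-6 relative tolerance, never outside
    corners <- grid_corners(g)
    expect_equal(corners$dist_to_center / (d / 2), rep(1, 4), tolerance = 1e-6)
  }
})

test_that("invalid grid parameters are rejected", {
  expect_error(fov_circle(0, 0, 0), class = "gridquant_bad_parameter")
  expect_error(fov_circle(0, 0, -3), class = "gridquant_bad_parameter")
  expect_error(inscribe_square_grid(fov_circle(0, 0, 10), n_per_side = 0),
               class = "gridquant_bad_parameter")
})

test_that("circle fitting recovers a synthetic bright disk", {
  img <- array(0.05, dim = c(512, 512, 3))
  px <- matrix(rep(seq_len(512) - 0.5, each = 512), 512, 512)
  py <- matrix(rep(seq_len(512) - 0.5, times = 512), 512, 512)
  disk <- (px - 256)^2 + (py - 256)^2 <= 200^2
  for (ch in 1:3) { b <- img[, , ch]; b[disk] <- 0.95; img[, , ch] <- b }
  fov <- fit_fov_circle(img)
  expect_equal(fov$center_x, 256, tolerance = 2)
  expect_equal(fov$center_y, 256, tolerance = 2)
  expect_equal(fov$diameter_d, 400, tolerance = 4)
})

test_that("circle fitting recovers generator ground truth under default noise", {
  for (seed in c(3, 14)) {
    f <- generate_field(counts = list(n_T = 30, n_S = 60, n_L = 0, n_NA = 10),
                        seed = seed)
    fov <- fit_fov_circle(f$image)
    expect_equal(fov$center_x, f$fov$center_x, tolerance = 2)
    expect_equal(fov$center_y, f$fov$center_y, tolerance = 2)
    expect_lt(abs(fov$diameter_d - f$fov$diameter_d) / f$fov$diameter_d, 0.01)
  }
})

test_that("manual circle override bypasses detection, black image errors", {
  img <- array(0, dim = c(64, 64, 3))
  fov <- fit_fov_circle(img, circle = c(100, 100, 150))
  expect_equal(c(fov$center_x, fov$center_y, fov$diameter_d), c(100, 100, 150))
  expect_error(fit_fov_circle(img), class = "gridquant_detection_failure")
  # no-vignette mode uses the largest centered inscribed circle
  fov2 <- fit_fov_circle(array(0.5, dim = c(64, 128, 3)), no_vignette = TRUE)
  expect_equal(c(fov2$center_x, fov2$center_y, fov2$diameter_d), c(64, 32, 64))
})

test_that("overlay draws only grid lines, annotates labels, and round-trips PNG", {
  img <- array(0.7, dim = c(512, 512, 3))
  grid <- inscribe_square_grid(fov_circle(256, 256, 200))
  ov <- render_overlay(img, grid)
  # input untouched
  expect_equal(img, array(0.7, dim = c(512, 512, 3)))
  changed <- which(ov != img, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # all changed pixels lie on one of the 11 + 11 grid lines
  xs <- 256 + c(-1, 1) * grid$side_a / 2
  line_cols <- as.integer(floor(xs[1] + 0:10 * grid$cell_side)) + 1L
  on_line <- changed[, 2] %in% line_cols | changed[, 1] %in% line_cols
  expect_true(all(on_line))
  # idempotent on the non-line pixel set
  ov2 <- render_overlay(ov, grid)
  expect_equal(ov2, ov)

  labels <- matrix("S", 10, 10)
  ovl <- render_overlay(img, grid, labels = labels)
  # every cell received an annotation (pixels off the grid lines changed)
  n_annotated <- 0
  for (i in seq_len(nrow(grid$cells))) {
    r <- grid$cells[i, ]
    rows <- seq(ceiling(r$y0 + 1.5), floor(r$y1 - 0.5))
    cols <- seq(ceiling(r$x0 + 1.5), floor(r$x1 - 0.5))
    interior_changed <- any(ovl[rows, cols, ] != ov[rows, cols, ])
    n_annotated <- n_annotated + interior_changed
  }
  expect_equal(n_annotated, 100)
  expect_error(render_overlay(img, grid, labels = matrix("S", 9, 9)),
               class = "gridquant_label_mismatch")

  tmp <- withr::local_tempfile(fileext = ".png")
  write_image(ovl, tmp)
  back <- read_image(tmp)
  expect_equal(back, ovl, tolerance = 1 / 255)
})

test_that("grid geometry exports to JSON and tidies to a cell tibble", {
  g <- inscribe_square_grid(fov_circle(128, 128, 200))
  js <- jsonlite::fromJSON(grid_to_json(g))
  expect_equal(js$side_a, g$side_a)
  expect_identical(nrow(js$cells), 100L)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 100L)
  expect_error(render_overlay(array(0.5, dim = c(64, 64, 3)), g),
               class = "gridquant_bad_parameter")
})
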