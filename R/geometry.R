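# Circle geometry of the microphotograph field of view and the inscribed
# equal-cell square grid. The square inscribed in a circle of diameter d has
# side a = d/sqrt(2) (the diameter is the square's diagonal), so for the
# default 10x10 grid each small square is exactly 1% of the grid area.

#' Circular field of view
#'
#' @param center_x,center_y Circle center in pixel coordinates (origin
#'   top-left, x right, y down).
#' @param diameter_d Circle diameter in pixels; must be positive.
#' @return An object of class `fov_circle`.
#' @examples
#' fov_circle(256, 256, 400)
#' @export
fov_circle <- function(center_x, center_y, diameter_d) {
  if (!is.finite(diameter_d) || diameter_d <= 0) {
    abort("diameter must be a positive number", class = "gridquant_bad_parameter")
  }
  structure(
    list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         diameter_d = as.numeric(diameter_d)),
    class = "fov_circle"
  )
}

#' @export
print.fov_circle <- function(x, ...) {
  cat(sprintf("<fov_circle> center (%.2f, %.2f), diameter %.2f px\n",
              x$center_x, x$center_y, x$diameter_d))
  invisible(x)
}

#' Fit the circular field of view of a microphotograph
#'
#' Eyepiece microphotographs show a bright circular field on a dark surround.
#' The circle is recovered by Otsu-thresholding the luminance, keeping the
#' largest connected bright component, filling holes, and least-squares
#' fitting a circle (Kasa's algebraic fit) to the component boundary.
#'
#' @param image RGB array (see [read_image()]).
#' @param circle Optional manual override `c(center_x, center_y, diameter)`;
#'   returned verbatim, skipping detection.
#' @param no_vignette If `TRUE`, skip detection and use the largest centered
#'   circle inscribed in the image (for full-frame digital fields without a
#'   vignette).
#' @param threshold Luminance threshold in `[0, 1]`; `NULL` (default) uses
#'   Otsu's method.
#' @param min_fov_fraction Detection fails unless the fitted diameter is at
#'   least this fraction of the shorter image side.
#' @param margin Tolerance, in pixels, by which the fitted circle may extend
#'   beyond the image bounds before a warning is raised.
#' @return A [fov_circle()].
#' @examples
#' img <- array(0, dim = c(64, 64, 3))
#' fit_fov_circle(img, circle = c(32, 32, 48))
#' @export
fit_fov_circle <- function(image, circle = NULL, no_vignette = FALSE,
                           threshold = NULL, min_fov_fraction = 0.2, margin = 5) {
  check_rgb(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (!is.null(circle)) {
    if (length(circle) != 3) {
      abort("`circle` override must be c(center_x, center_y, diameter)",
            class = "gridquant_bad_parameter")
    }
    return(fov_circle(circle[1], circle[2], circle[3]))
  }
  if (isTRUE(no_vignette)) {
    return(fov_circle(w / 2, h / 2, min(w, h)))
  }
  lum <- luminance(image)
  thr <- if (is.null(threshold)) {
    as.numeric(EBImage::otsu(EBImage::Image(t(lum)), range = c(0, 1)))
  } else threshold
  mask <- lum > thr
  if (!any(mask)) {
    abort("field-of-view detection failed: no bright region found",
          class = "gridquant_detection_failure")
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which.max(sizes)
  comp <- labm == keep
  comp <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(comp)))) > 0)
  boundary <- comp & !shrink_mask(comp)
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) < 8) {
    abort("field-of-view detection failed: bright region too small",
          class = "gridquant_detection_failure")
  }
  fit <- kasa_circle_fit(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5)
  if (2 * fit$r < min_fov_fraction * min(w, h)) {
    abort(sprintf(
      "field-of-view detection failed: fitted diameter %.1f px is below %.0f%% of the short image side",
      2 * fit$r, 100 * min_fov_fraction), class = "gridquant_detection_failure")
  }
  overhang <- max(fit$r - fit$cx, fit$r - fit$cy,
                  fit$cx + fit$r - w, fit$cy + fit$r - h)
  if (overhang > margin) {
    warn(sprintf("fitted field of view extends %.1f px beyond the image bounds", overhang),
         class = "gridquant_fov_overhang")
  }
  fov_circle(fit$cx, fit$cy, 2 * fit$r)
}

# 4-neighbour erosion: TRUE where the pixel and its N/S/E/W neighbours are all
# TRUE (image border counts as outside).
shrink_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  out[2:(h - 1), 2:(w - 1)] <-
    mask[2:(h - 1), 2:(w - 1)] &
    mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
    mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  out
}

# Kasa algebraic least-squares circle fit: solve x^2 + y^2 = A x + B y + C.
kasa_circle_fit <- function(x, y) {
  z <- x^2 + y^2
  coef <- stats::lm.fit(cbind(x, y, 1), z)$coefficients
  cx <- coef[1] / 2
  cy <- coef[2] / 2
  r <- sqrt(coef[3] + cx^2 + cy^2)
  list(cx = unname(cx), cy = unname(cy), r = unname(r))
}

#' Inscribe an equal-cell square grid in a circular field of view
#'
#' The largest square inscribed in a circle of diameter `d` has its diagonal
#' on the diameter, so its side is `a = d / sqrt(2)`; all four corners lie on
#' the circle. The square is split into `n_per_side^2` congruent cells, each
#' `100 / n_per_side^2` percent of the grid area (1% each for the default
#' 10x10 grid). Cells are axis-aligned, indexed row-major from the top-left,
#' 0-based, as half-open rectangles `[x0, x1) x [y0, y1)`.
#'
#' @param fov A [fov_circle()].
#' @param n_per_side Cells per side (default 10).
#' @return An object of class `grid_geometry` with fields `fov`,
#'   `n_per_side`, `side_a`, `cell_side` and a `cells` tibble
#'   (`row`, `col`, `x0`, `y0`, `x1`, `y1`).
#' @examples
#' g <- inscribe_square_grid(fov_circle(0, 0, 16.6))
#' round(g$side_a, 2)  # 11.73
#' @export
inscribe_square_grid <- function(fov, n_per_side = 10) {
  if (!inherits(fov, "fov_circle")) {
    abort("`fov` must be a fov_circle", class = "gridquant_bad_parameter")
  }
  n_per_side <- as.integer(n_per_side)
  if (is.na(n_per_side) || n_per_side < 1) {
    abort("`n_per_side` must be a positive integer", class = "gridquant_bad_parameter")
  }
  side_a <- fov$diameter_d / sqrt(2)
  cell_side <- side_a / n_per_side
  x_left <- fov$center_x - side_a / 2
  y_top <- fov$center_y - side_a / 2
  ij <- expand.grid(col = 0:(n_per_side - 1), row = 0:(n_per_side - 1))
  cells <- tibble(
    row = ij$row, col = ij$col,
    x0 = x_left + ij$col * cell_side,
    y0 = y_top + ij$row * cell_side,
    x1 = x_left + (ij$col + 1) * cell_side,
    y1 = y_top + (ij$row + 1) * cell_side
  )
  structure(
    list(fov = fov, n_per_side = n_per_side, side_a = side_a,
         cell_side = cell_side, cells = cells),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %dx%d cells, side a = %.4f px (d = %.4f), cell %.4f px\n",
              x$n_per_side, x$n_per_side, x$side_a, x$fov$diameter_d, x$cell_side))
  invisible(x)
}

#' Per-cell rectangles of a grid
#'
#' @param x A `grid_geometry` from [inscribe_square_grid()].
#' @param ... Unused.
#' @return A tibble with one row per cell: 0-based `row`, `col` and the
#'   half-open rectangle `x0`, `y0`, `x1`, `y1` in pixel coordinates.
#' @method tidy grid_geometry
#' @export
tidy.grid_geometry <- function(x, ...) {
  x$cells
}

#' Corner coordinates of the inscribed square
#'
#' The four corners all lie on the field-of-view circle (at distance `d/2`
#' from its center) — the defining property of the construction.
#'
#' @param grid A `grid_geometry`.
#' @return A tibble with columns `corner`, `x`, `y`, `dist_to_center`.
#' @export
grid_corners <- function(grid) {
  half <- grid$side_a / 2
  cx <- grid$fov$center_x
  cy <- grid$fov$center_y
  x <- cx + c(-1, 1, 1, -1) * half
  y <- cy + c(-1, -1, 1, 1) * half
  tibble(
    corner = c("top_left", "top_right", "bottom_right", "bottom_left"),
    x = x, y = y,
    dist_to_center = sqrt((x - cx)^2 + (y - cy)^2)
  )
}

#' Export grid geometry as JSON
#'
#' @param grid A `grid_geometry`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
grid_to_json <- function(grid, path = NULL) {
  obj <- list(
    center_x = grid$fov$center_x, center_y = grid$fov$center_y,
    diameter_d = grid$fov$diameter_d, side_a = grid$side_a,
    n_per_side = grid$n_per_side, cell_side = grid$cell_side,
    cells = grid$cells
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# ---- overlay rendering ------------------------------------------------------

# 5x7 bitmap glyphs for cell annotations; enough for T/S/L/NA.
glyph_rows <- list(
  T = c("11111", "00100", "00100", "00100", "00100", "00100", "00100"),
  S = c("01111", "10000", "10000", "01110", "00001", "00001", "11110"),
  L = c("10000", "10000", "10000", "10000", "10000", "10000", "11111"),
  N = c("10001", "11001", "10101", "10011", "10001", "10001", "10001"),
  A = c("01110", "10001", "10001", "11111", "10001", "10001", "10001")
)

glyph_matrix <- function(ch) {
  rows <- glyph_rows[[ch]]
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]]) == 1L))
}

#' Superimpose the grid (and optional cell labels) on an image
#'
#' Returns a copy of the image with the grid lines drawn and, when `labels`
#' are supplied, a letter annotation (T/S/L/NA) rendered in each cell. The
#' input image is not modified; only grid-line and glyph pixels change.
#'
#' @param image RGB array.
#' @param grid A `grid_geometry`; must fit inside the image.
#' @param labels Optional per-cell labels: an `n x n` character matrix, or a
#'   row-major vector of length `n^2`, with values in `T`, `S`, `L`, `NA`
#'   (the string "NA" or a missing value both mean not assessable).
#' @param line_color Grid line RGB, default near-black.
#' @param label_colors Named RGB list for the four labels.
#' @return A new RGB array of the same dimensions.
#' @export
render_overlay <- function(image, grid, labels = NULL,
                           line_color = c(0.1, 0.1, 0.1),
                           label_colors = list(T = c(0.75, 0, 0),
                                               S = c(0, 0.5, 0),
                                               L = c(0, 0, 0.8),
                                               `NA` = c(0.35, 0.35, 0.35))) {
  check_rgb(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  xs <- grid$fov$center_x + c(-1, 1) * grid$side_a / 2
  ys <- grid$fov$center_y + c(-1, 1) * grid$side_a / 2
  if (xs[1] < 0 || ys[1] < 0 || xs[2] > w || ys[2] > h) {
    abort("grid does not fit inside the image", class = "gridquant_bad_parameter")
  }
  out <- image
  n <- grid$n_per_side
  row_px <- pixel_range(ys[1], ys[2], h)
  col_px <- pixel_range(xs[1], xs[2], w)
  for (k in 0:n) {
    x <- xs[1] + k * grid$cell_side
    y <- ys[1] + k * grid$cell_side
    cpx <- min(max(1L, as.integer(floor(x)) + 1L), w)
    rpx <- min(max(1L, as.integer(floor(y)) + 1L), h)
    for (ch in 1:3) {
      out[row_px, cpx, ch] <- line_color[ch]
      out[rpx, col_px, ch] <- line_color[ch]
    }
  }
  if (!is.null(labels)) {
    labels <- normalize_labels(labels, n)
    for (r in 0:(n - 1)) {
      for (cc in 0:(n - 1)) {
        lab <- labels[r + 1, cc + 1]
        if (is.na(lab)) lab <- "NA"
        rect <- grid$cells[grid$cells$row == r & grid$cells$col == cc, ]
        col_rgb <- label_colors[[lab]]
        chars <- strsplit(lab, "")[[1]]
        draw_glyphs(out, chars, rect, col_rgb) -> out
      }
    }
  }
  out
}

# Stamp 5x7 glyphs (integer-scaled to ~40% of the cell) centered in the cell.
draw_glyphs <- function(image, chars, rect, col_rgb) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n_ch <- length(chars)
  cw <- rect$x1 - rect$x0
  chh <- rect$y1 - rect$y0
  scale <- max(1L, as.integer(floor(min(cw * 0.4 / (n_ch * 6), chh * 0.4 / 7))))
  gw <- scale * (6 * n_ch - 1)
  gh <- scale * 7
  x_start <- (rect$x0 + rect$x1) / 2 - gw / 2
  y_start <- (rect$y0 + rect$y1) / 2 - gh / 2
  for (i in seq_along(chars)) {
    gm <- glyph_matrix(chars[i])
    for (gr in 1:7) {
      for (gc in 1:5) {
        if (!gm[gr, gc]) next
        x0 <- x_start + ((i - 1) * 6 + gc - 1) * scale
        y0 <- y_start + (gr - 1) * scale
        rows <- pixel_range(y0, y0 + scale, h)
        cols <- pixel_range(x0, x0 + scale, w)
        if (length(rows) == 0 || length(cols) == 0) next
        for (ch in 1:3) image[rows, cols, ch] <- col_rgb[ch]
      }
    }
  }
  image
}

# Accept an n x n matrix or a row-major length-n^2 vector of labels.
normalize_labels <- function(labels, n) {
  if (is.matrix(labels)) {
    if (!all(dim(labels) == c(n, n))) {
      abort(sprintf("labels must be %d x %d to match the grid", n, n),
            class = "gridquant_label_mismatch")
    }
    m <- labels
  } else {
    if (length(labels) != n * n) {
      abort(sprintf("labels must have length %d to match the grid", n * n),
            class = "gridquant_label_mismatch")
    }
    m <- matrix(labels, nrow = n, byrow = TRUE)
  }
  storage.mode(m) <- "character"
  ok <- is.na(m) | m %in% c("T", "S", "L", "NA")
  if (!all(ok)) {
    abort("labels must be one of T, S, L, NA", class = "gridquant_label_mismatch")
  }
  m
}
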