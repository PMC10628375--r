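# Seeded synthetic H&E-like circular-field images with per-cell ground truth.
#
# A field is a bright disk (the eyepiece field of view) on a dark surround.
# Each grid cell is painted according to its ground-truth label inside a
# centered sub-rectangle covering `dominant_fraction` of the cell: tumor cells
# as a dense hematoxylin block (a nuclear nest), stroma cells as eosin fiber
# texture with 0-2 sparse small nuclei, lymphocyte cells as stroma plus k
# small round hematoxylin disks, NA cells left empty (near-white). Colors are
# synthesized from the same optical-density stain vectors the analysis
# defaults use, and lymphocyte disks are drawn inside the detector's default
# diameter band, so detector-band changes fail tests loudly.

#' Generate one synthetic field image with ground truth
#'
#' @param counts Target label tallies: a list or one-row data frame with
#'   `n_T`, `n_S`, `n_L`, `n_NA` summing (with `n_L <= n_S`) to
#'   `n_per_side^2`; cell positions are shuffled by `seed`. Ignored when
#'   `labels` is given.
#' @param labels Optional explicit `n x n` character matrix (or row-major
#'   vector) of cell labels `T`/`S`/`L`/`NA`.
#' @param image_size Image side in pixels (square image).
#' @param fov_diameter Bright-disk diameter in pixels; must fit in the image.
#' @param n_per_side Grid cells per side.
#' @param lymph_per_cell Lymphocyte disks drawn in each L cell (>= 5 so the
#'   count rule fires by construction).
#' @param lymph_diameter_px Diameter of a drawn lymphocyte disk.
#' @param dominant_fraction Fraction of each cell's area covered by its
#'   dominant class.
#' @param noise_sd Gaussian pixel noise standard deviation (RGB units).
#' @param seed Integer seed; the image is fully determined by it.
#' @param config A [quant_config()]; its stain vectors define the synthetic
#'   colors.
#' @return An object of class `synthetic_field`: `image` (RGB array),
#'   `labels` (n x n character matrix), `counts` (ground-truth
#'   [field_counts()]), `grid`, `fov`, and the generating parameters.
#' @examples
#' f <- generate_field(counts = list(n_T = 25, n_S = 75, n_L = 50, n_NA = 0),
#'                     seed = 7)
#' f$counts
#' @export
generate_field <- function(counts = NULL, labels = NULL,
                           image_size = 384, fov_diameter = 336,
                           n_per_side = 10, lymph_per_cell = 8,
                           lymph_diameter_px = 5,
                           dominant_fraction = 0.9, noise_sd = 0.01,
                           seed = 1, config = quant_config()) {
  if (fov_diameter > image_size) {
    abort("fov_diameter must not exceed image_size", class = "gridquant_infeasible_spec")
  }
  if (lymph_per_cell < 1) {
    abort("lymph_per_cell must be >= 1", class = "gridquant_infeasible_spec")
  }
  n <- as.integer(n_per_side)
  withr::local_seed(seed)
  if (is.null(labels)) {
    if (is.null(counts)) {
      abort("supply `counts` or `labels`", class = "gridquant_infeasible_spec")
    }
    labels <- labels_from_counts(counts, n)
  } else {
    labels <- normalize_labels(labels, n)
    labels[is.na(labels)] <- "NA"
  }
  fov <- fov_circle(image_size / 2, image_size / 2, fov_diameter)
  grid <- inscribe_square_grid(fov, n_per_side = n)

  h <- image_size; w <- image_size
  conc_h <- matrix(0, h, w)
  conc_e <- matrix(0, h, w)
  for (r in 0:(n - 1)) {
    for (cc in 0:(n - 1)) {
      lab <- labels[r + 1, cc + 1]
      if (lab == "NA") next
      rect <- grid$cells[grid$cells$row == r & grid$cells$col == cc, ]
      sub <- sub_rect(rect, sqrt(dominant_fraction))
      rows <- pixel_range(sub$y0, sub$y1, h)
      cols <- pixel_range(sub$x0, sub$x1, w)
      if (lab == "T") {
        conc_h[rows, cols] <- 0.8
      } else {
        conc_e[rows, cols] <- stroma_texture(rows, cols)
        if (lab == "L") {
          pts <- lattice_points(sub, lymph_per_cell, spacing = lymph_diameter_px + 2,
                                strict = TRUE)
          for (i in seq_len(nrow(pts))) {
            conc_h <- paint_disk(conc_h, pts$x[i], pts$y[i],
                                 lymph_diameter_px / 2, 1.0)
          }
        } else {
          n_nuc <- sample(0:2, 1)
          if (n_nuc > 0) {
            pts <- lattice_points(sub, n_nuc, spacing = 8)
            for (i in seq_len(nrow(pts))) {
              conc_h <- paint_disk(conc_h, pts$x[i], pts$y[i], 2, 0.9)
            }
          }
        }
      }
    }
  }
  # compose: dark surround, bright disk attenuated by Beer-Lambert stain ODs
  px_x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  px_y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  in_disk <- (px_x - fov$center_x)^2 + (px_y - fov$center_y)^2 <= (fov_diameter / 2)^2
  img <- array(0.06, dim = c(h, w, 3))
  sh <- config$stain_h
  se <- config$stain_e
  for (ch in 1:3) {
    plane <- 0.96 * 10^-(conc_h * sh[ch] + conc_e * se[ch])
    band <- img[, , ch]
    band[in_disk] <- plane[in_disk]
    img[, , ch] <- band
  }
  if (noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 1)

  gt <- tally_labels(as.vector(t(labels)))
  structure(
    list(image = img, labels = labels, counts = gt, grid = grid, fov = fov,
         seed = seed, n_per_side = n, lymph_per_cell = lymph_per_cell,
         dominant_fraction = dominant_fraction, noise_sd = noise_sd),
    class = "synthetic_field"
  )
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %d px, %dx%d grid, seed %d; T=%d S=%d L=%d NA=%d\n",
              dim(x$image)[1], x$n_per_side, x$n_per_side, x$seed,
              x$counts$n_T, x$counts$n_S, x$counts$n_L, x$counts$n_NA))
  invisible(x)
}

labels_from_counts <- function(counts, n) {
  n_T <- counts$n_T %||% 0L
  n_S <- counts$n_S %||% 0L
  n_L <- counts$n_L %||% 0L
  n_NA <- counts$n_NA %||% (n * n - n_T - n_S)
  if (n_L > n_S || any(c(n_T, n_S, n_L, n_NA) < 0) || n_T + n_S + n_NA != n * n) {
    abort(sprintf("infeasible counts: need n_T + n_S + n_NA = %d and 0 <= n_L <= n_S", n * n),
          class = "gridquant_infeasible_spec")
  }
  labs <- c(rep("T", n_T), rep("L", n_L), rep("S", n_S - n_L), rep("NA", n_NA))
  matrix(sample(labs), nrow = n, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sub_rect <- function(rect, scale) {
  mx <- (rect$x0 + rect$x1) / 2
  my <- (rect$y0 + rect$y1) / 2
  hw <- (rect$x1 - rect$x0) / 2 * scale
  hh <- (rect$y1 - rect$y0) / 2 * scale
  list(x0 = mx - hw, x1 = mx + hw, y0 = my - hh, y1 = my + hh)
}

# Eosin fiber texture: base density modulated by a sinusoid along a random
# orientation — enough structure to look fibrous to the deconvolution without
# dropping below the stained-stroma threshold.
stroma_texture <- function(rows, cols) {
  theta <- runif(1, 0, pi)
  freq <- runif(1, 0.15, 0.35)
  gx <- outer(rows - 0.5, cols - 0.5, function(y, x) cos(theta) * x + sin(theta) * y)
  0.35 * (0.85 + 0.15 * sin(2 * pi * freq * gx))
}

# k jittered points on a shuffled lattice inside the rectangle, guaranteeing
# pairwise separation >= spacing - 2 so drawn nuclei never merge. With
# `strict`, refuse rather than crowd the points when they cannot fit.
lattice_points <- function(rect, k, spacing, strict = FALSE) {
  side <- ceiling(sqrt(k))
  wx <- (rect$x1 - rect$x0)
  wy <- (rect$y1 - rect$y0)
  step_x <- max(spacing, wx / side)
  step_y <- max(spacing, wy / side)
  nx <- max(1, floor(wx / step_x))
  ny <- max(1, floor(wy / step_y))
  if (nx * ny < k) {
    if (strict) {
      abort(sprintf(
        "infeasible spec: %d nuclei at %.0f px spacing do not fit a %.0f x %.0f px cell interior",
        k, spacing, wx, wy), class = "gridquant_infeasible_spec")
    }
    nx <- side; ny <- side
    step_x <- wx / nx; step_y <- wy / ny
  }
  grid <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  grid <- grid[sample(nrow(grid), min(k, nrow(grid))), , drop = FALSE]
  tibble(
    x = rect$x0 + (grid$i - 0.5) * step_x + runif(nrow(grid), -0.5, 0.5),
    y = rect$y0 + (grid$j - 0.5) * step_y + runif(nrow(grid), -0.5, 0.5)
  )
}

paint_disk <- function(mat, cx, cy, radius, value) {
  h <- nrow(mat); w <- ncol(mat)
  rows <- pixel_range(cy - radius, cy + radius, h)
  cols <- pixel_range(cx - radius, cx + radius, w)
  for (r in rows) {
    for (cc in cols) {
      if ((cc - 0.5 - cx)^2 + (r - 0.5 - cy)^2 <= radius^2) mat[r, cc] <- value
    }
  }
  mat
}

#' Generate a synthetic case: multiple fields with ground truth
#'
#' Builds the conventional 10 fields of a case, either from explicit
#' per-field counts or from a case-level target percentage, and computes the
#' expected case report by running [aggregate_case()] on the ground-truth
#' counts — so the expectation comes from the quantification formulas, never
#' from the images.
#'
#' @param target_percent Case-level target (TSR or sTIL percent); per-field
#'   counts are sampled near it. Ignored when `field_counts` is given.
#' @param mode `"TSR"` or `"sTIL"`.
#' @param n_fields Number of fields (default 10).
#' @param field_counts Optional data frame of per-field `n_T`, `n_S`, `n_L`,
#'   `n_NA` rows.
#' @param seed Integer seed.
#' @param ... Passed to [generate_field()] (image size, noise, ...).
#' @return An object of class `synthetic_case`: `fields` (list of
#'   `synthetic_field`), `counts` (ground-truth tibble), and `expected`
#'   (the ground-truth `case_report`).
#' @export
generate_case <- function(target_percent = NULL, mode = c("TSR", "sTIL"),
                          n_fields = 10, field_counts = NULL, seed = 1, ...) {
  mode <- normalize_parameter(mode)
  withr::local_seed(seed)
  if (is.null(field_counts)) {
    if (is.null(target_percent)) {
      abort("supply `target_percent` or `field_counts`", class = "gridquant_infeasible_spec")
    }
    field_counts <- sample_case_counts(target_percent, mode, n_fields)
  }
  field_seeds <- sample.int(2^30, n_fields)
  fields <- lapply(seq_len(n_fields), function(i) {
    generate_field(counts = as.list(field_counts[i, ]), seed = field_seeds[i], ...)
  })
  gt_counts <- dplyr::bind_rows(lapply(seq_len(n_fields), function(i) {
    fc <- fields[[i]]$counts
    fc$field_id <- i
    fc
  }))
  expected <- aggregate_case(gt_counts, parameter = mode)
  structure(
    list(fields = fields, counts = gt_counts, expected = expected,
         mode = mode, seed = seed),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s, %d fields, seed %d; expected %.2f%% (score %d)\n",
              x$mode, length(x$fields), x$seed,
              x$expected$mean_percent, x$expected$score))
  invisible(x)
}

# Per-field tallies scattered around a case-level target percentage. A few
# cells per field are NA (empty/inconclusive patches); sTIL fields carry a
# modest tumor component excluded from the calculation.
sample_case_counts <- function(target, mode, n_fields) {
  if (target < 0 || target > 100) {
    abort("target_percent must be in [0, 100]", class = "gridquant_infeasible_spec")
  }
  rows <- lapply(seq_len(n_fields), function(i) {
    n_NA <- sample(0:4, 1)
    assessable <- 100L - n_NA
    jitter <- runif(1, -3, 3)
    p <- min(100, max(0, target + jitter))
    if (mode == "TSR") {
      n_S <- as.integer(round(p / 100 * assessable))
      list(n_T = assessable - n_S, n_S = n_S, n_L = 0L, n_NA = n_NA)
    } else {
      n_T <- sample(10:25, 1)
      n_S <- assessable - n_T
      list(n_T = n_T, n_S = n_S, n_L = as.integer(round(p / 100 * n_S)), n_NA = n_NA)
    }
  })
  dplyr::bind_rows(rows)
}

#' Simulate two observers' case scores with a designed agreement
#'
#' Rater A draws from the category distribution; rater B copies A with the
#' given probability, otherwise re-samples uniformly from the *other*
#' categories. Under this scheme the expected observed agreement equals the
#' copy probability, and the analytic kappa is available from
#' [designed_kappa()].
#'
#' @param n_cases Number of cases (>= 2).
#' @param categories Score categories (default 1:4).
#' @param prob Category distribution for rater A (uniform by default).
#' @param agreement_prob Probability that rater B copies rater A.
#' @param seed Integer seed.
#' @return A tibble: `case_id`, `rater_a_score`, `rater_b_score`.
#' @export
generate_observer_scores <- function(n_cases, categories = 1:4,
                                     prob = NULL, agreement_prob = 0.9, seed = 1) {
  if (n_cases < 2) {
    abort("n_cases must be >= 2", class = "gridquant_infeasible_spec")
  }
  if (!is.finite(agreement_prob) || agreement_prob < 0 || agreement_prob > 1) {
    abort("agreement_prob must be in [0, 1]", class = "gridquant_bad_parameter")
  }
  k <- length(categories)
  if (is.null(prob)) prob <- rep(1 / k, k)
  if (length(prob) != k || any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    abort("prob must be a probability vector over `categories`",
          class = "gridquant_bad_parameter")
  }
  withr::local_seed(seed)
  a <- sample(categories, n_cases, replace = TRUE, prob = prob)
  copy <- runif(n_cases) < agreement_prob
  b <- a
  for (i in which(!copy)) {
    others <- categories[categories != a[i]]
    b[i] <- others[sample.int(length(others), 1)]
  }
  tibble(case_id = seq_len(n_cases), rater_a_score = a, rater_b_score = b)
}

#' Analytic kappa of the simulated-observer design
#'
#' For the [generate_observer_scores()] scheme: observed agreement
#' \eqn{p_o = q} (the copy probability; a re-sample never matches), rater A's
#' marginal is `prob`, rater B's marginal is
#' \eqn{m_b(k) = q p_k + (1-q)(1-p_k)/(K-1)}, and
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_e = \sum_k p_k m_b(k)}.
#'
#' @param prob Rater A's category distribution.
#' @param agreement_prob Copy probability q.
#' @return The population kappa of the design.
#' @export
designed_kappa <- function(prob, agreement_prob) {
  k <- length(prob)
  q <- agreement_prob
  m_b <- q * prob + (1 - q) * (1 - prob) / (k - 1)
  p_e <- sum(prob * m_b)
  (q - p_e) / (1 - p_e)
}
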