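# Per-cell tissue composition and the T/S/L/NA labeling rules.
#
# Pixel-level classes are computed once per field: nuclear blobs are split by
# size into lymphocyte-band blobs and larger tumor nuclei; tumor nuclei are
# morphologically closed into nests; everything stained but neither background
# nor tumor is stroma (lymphocytes live inside the stroma compartment).

#' Detect lymphocyte nuclei on the hematoxylin channel
#'
#' Thresholds the hematoxylin concentration, labels connected blobs, and
#' keeps blobs whose equivalent diameter lies in the configured lymphocyte
#' band and whose circularity clears the floor — small round dense nuclei.
#' Mononuclear cells (lymphocytes and plasma cells) are not distinguished.
#'
#' @param stains A [separate_stains()] result.
#' @param config A [quant_config()].
#' @param region Optional logical matrix (same size) restricting detection.
#' @return A tibble of accepted blobs: `x`, `y` (centroid, pixel
#'   coordinates), `area`, `diameter`, `circularity`. Zero rows when nothing
#'   is found.
#' @export
detect_lymphocytes <- function(stains, config = quant_config(), region = NULL) {
  blobs <- nuclear_blobs(stains, config, region)
  blobs$tbl[blobs$tbl$kind == "lymphocyte",
            c("x", "y", "area", "diameter", "circularity")]
}

# Label nuclear blobs and classify each as lymphocyte / tumor / other.
# Returns the label matrix, the per-blob table, and the set memberships.
nuclear_blobs <- function(stains, config, region = NULL) {
  mask <- stains$hematoxylin > config$nuclear_threshold & !stains$background_mask
  if (!is.null(region)) mask <- mask & region
  empty <- list(
    tbl = tibble(id = integer(), x = numeric(), y = numeric(),
                 area = numeric(), diameter = numeric(),
                 circularity = numeric(), kind = character()),
    labels = matrix(0L, nrow(mask), ncol(mask))
  )
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  n_blob <- max(lab)
  if (n_blob == 0) return(empty)
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  diameter <- 2 * sqrt(area / pi)
  circularity <- pmin(4 * pi * area / perim^2, 1.5)
  kind <- rep("other", n_blob)
  in_band <- diameter >= config$lymph_diameter[1] &
    diameter <= config$lymph_diameter[2] &
    circularity >= config$lymph_circularity
  kind[in_band] <- "lymphocyte"
  kind[diameter > config$lymph_diameter[2]] <- "tumor"
  tbl <- tibble(
    id = seq_len(n_blob),
    # EBImage moments are in its (x, y) frame, already matching our x/y axes
    x = unname(mom[, "m.cx"]), y = unname(mom[, "m.cy"]),
    area = unname(area), diameter = unname(diameter),
    circularity = unname(circularity), kind = kind
  )
  list(tbl = tbl, labels = t(EBImage::imageData(lab)))
}

# Field-wide per-pixel compartments + lymphocyte centroids. Codes:
# 0 background, 1 tumor, 2 stroma.
pixel_classes <- function(image, stains, config) {
  blobs <- nuclear_blobs(stains, config)
  tumor_ids <- blobs$tbl$id[blobs$tbl$kind == "tumor"]
  tumor_mask <- matrix(blobs$labels %in% tumor_ids,
                       nrow(blobs$labels), ncol(blobs$labels))
  if (any(tumor_mask) && config$tumor_close_size >= 3) {
    brush <- EBImage::makeBrush(config$tumor_close_size, shape = "disc")
    tumor_mask <- t(EBImage::imageData(
      EBImage::closing(EBImage::Image(t(tumor_mask)), brush))) > 0
  }
  tumor_mask <- tumor_mask & !stains$background_mask
  stained <- !stains$background_mask &
    (stains$eosin > config$eosin_threshold |
       stains$hematoxylin > config$nuclear_threshold)
  stroma_mask <- stained & !tumor_mask
  cls <- matrix(0L, nrow(tumor_mask), ncol(tumor_mask))
  cls[stroma_mask] <- 2L
  cls[tumor_mask] <- 1L
  lymph_mask <- matrix(blobs$labels %in% blobs$tbl$id[blobs$tbl$kind == "lymphocyte"],
                       nrow(blobs$labels), ncol(blobs$labels)) & stroma_mask
  list(classes = cls,
       lymph_mask = lymph_mask,
       lymphocytes = blobs$tbl[blobs$tbl$kind == "lymphocyte", ])
}

#' Tissue composition of one grid cell
#'
#' Fractions of the cell's pixels (pixel-center-in-rectangle membership)
#' assigned to tumor, stroma and background, plus the number of detected
#' lymphocytes whose centroid falls in the cell and the fraction of the cell
#' covered by lymphocyte nuclei. The lymphocyte fraction is a sub-fraction of
#' stroma, so `tumor + stroma + background = 1` while lymphocytes are
#' accounted separately.
#'
#' @param image RGB array.
#' @param stains A [separate_stains()] result for the image.
#' @param grid A `grid_geometry`.
#' @param row,col 0-based cell indices.
#' @param config A [quant_config()].
#' @param .classes Precomputed [pixel_classes] result (internal; avoids
#'   recomputation when composing all cells of a field).
#' @return A one-row tibble: `row`, `col`, `tumor_fraction`,
#'   `stroma_fraction`, `lymphocyte_fraction`, `background_fraction`,
#'   `lymphocyte_count`.
#' @export
compose_cell <- function(image, stains, grid, row, col, config = quant_config(),
                         .classes = NULL) {
  if (row < 0 || row >= grid$n_per_side || col < 0 || col >= grid$n_per_side) {
    abort(sprintf("cell (%d, %d) is outside the %d x %d grid",
                  row, col, grid$n_per_side, grid$n_per_side),
          class = "gridquant_bad_index")
  }
  if (is.null(.classes)) .classes <- pixel_classes(image, stains, config)
  rect <- grid$cells[grid$cells$row == row & grid$cells$col == col, ]
  rows <- pixel_range(rect$y0, rect$y1, nrow(.classes$classes))
  cols <- pixel_range(rect$x0, rect$x1, ncol(.classes$classes))
  sub <- .classes$classes[rows, cols, drop = FALSE]
  n_px <- length(sub)
  lsub <- .classes$lymph_mask[rows, cols, drop = FALSE]
  ly <- .classes$lymphocytes
  in_cell <- ly$x >= rect$x0 & ly$x < rect$x1 & ly$y >= rect$y0 & ly$y < rect$y1
  tibble(
    row = as.integer(row), col = as.integer(col),
    tumor_fraction = mean(sub == 1L),
    stroma_fraction = mean(sub == 2L),
    lymphocyte_fraction = if (n_px > 0) mean(lsub) else 0,
    background_fraction = mean(sub == 0L),
    lymphocyte_count = sum(in_cell)
  )
}

#' Label a cell composition as T, S, L or NA
#'
#' Applies the predominance rules in order: a cell is `NA` when background
#' exceeds the predominance threshold (empty/inconclusive) or when no
#' compartment does; `T` when tumor exceeds it; in sTIL mode, `L` when the
#' cell is stroma-predominant and the lymphocyte rule fires (area fraction
#' above the threshold and/or at least `lymph_min_count` lymphocytes);
#' otherwise `S` when stroma-predominant. In TSR mode the admissible labels
#' are `T`, `S`, `NA` only. Exact ties at the threshold are inconclusive
#' (`NA`).
#'
#' @param comp A composition row from [compose_cell()] (or any list with the
#'   same fields).
#' @param mode `"TSR"` or `"sTIL"`.
#' @param config A [quant_config()].
#' @return One of `"T"`, `"S"`, `"L"`, `"NA"`.
#' @examples
#' classify_cell(list(tumor_fraction = 0.8, stroma_fraction = 0.15,
#'                    lymphocyte_fraction = 0, background_fraction = 0.05,
#'                    lymphocyte_count = 0), mode = "TSR")
#' @export
classify_cell <- function(comp, mode = c("TSR", "sTIL"), config = quant_config()) {
  mode <- normalize_parameter(mode)
  thr <- config$predominance
  if (comp$background_fraction > thr) return("NA")
  if (comp$tumor_fraction > thr) return("T")
  if (comp$stroma_fraction > thr) {
    if (mode == "sTIL") {
      frac_hit <- comp$lymphocyte_fraction > thr
      count_hit <- comp$lymphocyte_count >= config$lymph_min_count
      l_hit <- if (config$l_rule == "or") frac_hit || count_hit else frac_hit && count_hit
      if (l_hit) return("L")
    }
    return("S")
  }
  "NA"
}

#' Classify every grid cell of a field image
#'
#' Runs the full per-field pipeline: stain separation, pixel classification,
#' per-cell composition, and the T/S/L/NA labeling rules. When `grid` is not
#' supplied, the field of view is fitted from the image and the default grid
#' inscribed.
#'
#' @param image RGB array (or a file path).
#' @param mode `"TSR"` or `"sTIL"`.
#' @param grid Optional `grid_geometry`; fitted+inscribed when `NULL`.
#' @param config A [quant_config()].
#' @param exclusion Optional data frame of 0-based `row`, `col` pairs forced
#'   to `NA` (manual exclusion zones: necrosis, DCIS, mucin, artifacts).
#' @param n_per_side Grid size used when fitting the grid.
#' @param ... Passed to [fit_fov_circle()] when the grid is fitted.
#' @return A tibble with one row per cell: indices, composition fractions,
#'   lymphocyte count and `label`.
#' @export
classify_field <- function(image, mode = c("TSR", "sTIL"), grid = NULL,
                           config = quant_config(), exclusion = NULL,
                           n_per_side = 10, ...) {
  mode <- normalize_parameter(mode)
  if (is.character(image)) image <- read_image(image)
  check_rgb(image)
  if (is.null(grid)) {
    grid <- inscribe_square_grid(fit_fov_circle(image, ...), n_per_side = n_per_side)
  }
  stains <- separate_stains(image, config)
  classes <- pixel_classes(image, stains, config)
  comps <- purrr::pmap(grid$cells[, c("row", "col")], function(row, col) {
    compose_cell(image, stains, grid, row, col, config, .classes = classes)
  })
  out <- dplyr::bind_rows(comps)
  out$label <- vapply(seq_len(nrow(out)), function(i) {
    classify_cell(out[i, ], mode = mode, config = config)
  }, character(1))
  if (!is.null(exclusion)) {
    if (is.null(exclusion$row) || is.null(exclusion$col)) {
      abort("exclusion mask needs `row` and `col` columns (0-based)",
            class = "gridquant_bad_parameter")
    }
    forced <- paste(out$row, out$col) %in% paste(exclusion$row, exclusion$col)
    if (any(forced)) {
      out$label[forced] <- "NA"
      warn(paste0(sum(forced), " cell(s) forced to NA by the exclusion mask"),
           class = "gridquant_forced_na")
    }
  }
  out
}

#' Tally cell labels into field counts
#'
#' `n_S` counts all stroma-predominant cells, including those labeled `L`
#' (an L cell is a stroma cell meeting the lymphocyte rule), so the sTIL
#' denominator matches the grid construction.
#'
#' @param labels Character vector of cell labels (`T`/`S`/`L`/`NA`), or a
#'   [classify_field()] tibble with a `label` column.
#' @param field_id Optional field identifier.
#' @return A one-row [field_counts()] tibble.
#' @export
tally_labels <- function(labels, field_id = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels[is.na(labels)] <- "NA"
  if (!all(labels %in% c("T", "S", "L", "NA"))) {
    abort("labels must be T, S, L or NA", class = "gridquant_label_mismatch")
  }
  field_counts(
    n_T = sum(labels == "T"),
    n_S = sum(labels %in% c("S", "L")),
    n_L = sum(labels == "L"),
    n_NA = sum(labels == "NA"),
    field_id = field_id
  )
}
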