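#' Analysis configuration
#'
#' Collects the tunable thresholds of the imaging pipeline. Defaults are
#' engineering choices for eyepiece microphotographs at roughly the scale of
#' the synthetic generator (10x10 grid cells of ~20-30 px); the stain vectors
#' are the standard published H&E optical-density vectors and should be
#' re-measured per camera/scanner when white balance differs.
#'
#' @param stain_h,stain_e Optical-density RGB vectors for hematoxylin and
#'   eosin (normalized internally).
#' @param white_threshold Luminance above which a pixel is background
#'   (empty space / glass), in `[0, 1]`.
#' @param nuclear_threshold Hematoxylin concentration above which a pixel is
#'   nuclear.
#' @param eosin_threshold Eosin concentration above which a non-nuclear,
#'   non-background pixel is counted as stained stroma.
#' @param lymph_diameter Two-element band (px) of blob equivalent diameters
#'   accepted as lymphocyte nuclei; larger nuclear blobs count as tumor.
#' @param lymph_circularity Minimum circularity (4*pi*area/perimeter^2) for a
#'   lymphocyte blob; screens out fibroblast nuclei and debris.
#' @param tumor_close_size Diameter (px, odd) of the disc used to
#'   morphologically close the tumor-nucleus mask into nests.
#' @param predominance Fraction a compartment must strictly exceed to claim a
#'   grid cell (the ">50%" rule).
#' @param lymph_min_count Minimum lymphocytes per small square for the L
#'   label (the ">= 5 per small square" rule).
#' @param l_rule `"or"` (default): a stroma cell is L when the lymphocyte
#'   area fraction exceeds `predominance` *or* the count reaches
#'   `lymph_min_count`; `"and"` requires both.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(stain_h = c(0.650, 0.704, 0.286),
                         stain_e = c(0.072, 0.990, 0.105),
                         white_threshold = 0.85,
                         nuclear_threshold = 0.30,
                         eosin_threshold = 0.10,
                         lymph_diameter = c(3, 9),
                         lymph_circularity = 0.40,
                         tumor_close_size = 5,
                         predominance = 0.5,
                         lymph_min_count = 5,
                         l_rule = c("or", "and")) {
  l_rule <- match.arg(l_rule)
  stopifnot(white_threshold > 0, white_threshold <= 1,
            length(lymph_diameter) == 2, lymph_diameter[1] < lymph_diameter[2],
            predominance > 0, predominance < 1, lymph_min_count >= 1)
  structure(
    list(stain_h = stain_h / sqrt(sum(stain_h^2)),
         stain_e = stain_e / sqrt(sum(stain_e^2)),
         white_threshold = white_threshold,
         nuclear_threshold = nuclear_threshold,
         eosin_threshold = eosin_threshold,
         lymph_diameter = lymph_diameter,
         lymph_circularity = lymph_circularity,
         tumor_close_size = as.integer(tumor_close_size),
         predominance = predominance,
         lymph_min_count = lymph_min_count,
         l_rule = l_rule),
    class = "quant_config"
  )
}

#' Separate hematoxylin and eosin by color deconvolution
#'
#' Converts RGB to optical density (Beer-Lambert, `-log10`) and inverts the
#' 3x3 stain matrix built from the configured hematoxylin and eosin vectors
#' plus their orthogonal residual, yielding per-pixel stain concentrations.
#' Negative concentrations (noise) are clipped to zero. Near-white pixels are
#' flagged as background.
#'
#' @param image RGB array in `[0, 1]`.
#' @param config A [quant_config()].
#' @return An object of class `stain_maps`: matrices `hematoxylin`, `eosin`
#'   (non-negative concentrations) and logical `background_mask`, all of the
#'   image's height x width.
#' @export
separate_stains <- function(image, config = quant_config()) {
  check_rgb(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  res <- stain_residual(config$stain_h, config$stain_e)
  M <- rbind(config$stain_h, config$stain_e, res)
  od <- -log10(pmax(matrix(image, ncol = 3), 1e-4))
  conc <- od %*% solve(M)
  structure(
    list(
      hematoxylin = matrix(pmax(conc[, 1], 0), h, w),
      eosin = matrix(pmax(conc[, 2], 0), h, w),
      background_mask = luminance(image) > config$white_threshold
    ),
    class = "stain_maps"
  )
}

stain_residual <- function(h, e) {
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r / sqrt(sum(r^2))
}

#' @export
print.stain_maps <- function(x, ...) {
  cat(sprintf("<stain_maps> %d x %d px, %.1f%% background\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin),
              100 * mean(x$background_mask)))
  invisible(x)
}
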