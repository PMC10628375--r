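# File round-tripping for the two workflows: manual count tables and score
# tables in, JSON/CSV reports out. Every applied threshold is echoed into the
# report header so a report is auditable and reproducible on its own.

#' Read a per-field count table
#'
#' Expected CSV columns: `case_id`, `field_id`, `n_T`, `n_S`, `n_L`, `n_NA`
#' (`case_id`, `n_L` and `n_NA` may be omitted; they default to a single case
#' and zeros).
#'
#' @param path CSV file path.
#' @return A tibble validated against the count invariants.
#' @export
read_counts <- function(path) {
  df <- read_checked_csv(path)
  need <- c("field_id", "n_T", "n_S")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("malformed counts CSV ", path, ": missing column(s) ",
                 paste(miss, collapse = ", ")), class = "gridquant_malformed_csv")
  }
  if (is.null(df$case_id)) df$case_id <- "case"
  if (is.null(df$n_L)) df$n_L <- 0L
  if (is.null(df$n_NA)) df$n_NA <- 0L
  for (col in c("n_T", "n_S", "n_L", "n_NA")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0) {
      abort(paste0("malformed counts CSV ", path, ": non-integer or negative `",
                   col, "` in row(s) ", paste(head(bad, 5), collapse = ", ")),
            class = "gridquant_malformed_csv")
    }
    df[[col]] <- v
  }
  bad <- which(df$n_L > df$n_S)
  if (length(bad) > 0) {
    abort(paste0("malformed counts CSV ", path, ": n_L > n_S in row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "gridquant_malformed_csv")
  }
  as_tibble(df)
}

#' Read a two-rater score table
#'
#' Expected CSV columns: `case_id`, `rater_a_score`, `rater_b_score`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_scores <- function(path) {
  df <- read_checked_csv(path)
  need <- c("case_id", "rater_a_score", "rater_b_score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("malformed scores CSV ", path, ": missing column(s) ",
                 paste(miss, collapse = ", ")), class = "gridquant_malformed_csv")
  }
  bad <- which(is.na(df$rater_a_score) | is.na(df$rater_b_score))
  if (length(bad) > 0) {
    abort(paste0("malformed scores CSV ", path, ": missing score(s) in row(s) ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "gridquant_malformed_csv")
  }
  as_tibble(df)
}

read_checked_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file not found: ", path), class = "gridquant_missing_input")
  }
  tryCatch(read.csv(path, stringsAsFactors = FALSE),
           error = function(e) abort(paste0("malformed CSV ", path, ": ",
                                            conditionMessage(e)),
                                     class = "gridquant_malformed_csv"))
}

#' Write a case report to JSON
#'
#' The report embeds the effective configuration (all applied thresholds) so
#' it can be audited and re-run.
#'
#' @param report A `case_report` (optionally carrying `$config` and `$cells`
#'   from [run_quantify()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  obj <- list(
    case_id = report$case_id,
    parameter = report$parameter,
    summary = glance(report),
    fields = report$fields,
    config = report$config %||% NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Reload a case report written by [write_case_report()]
#'
#' @param path JSON path.
#' @return A `case_report` object equivalent to the one written.
#' @export
read_case_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- obj$summary
  fields <- as_tibble(obj$fields)
  structure(
    list(
      case_id = s$case_id,
      parameter = s$parameter,
      fields = fields,
      n_fields = s$n_fields,
      n_used = s$n_used,
      mean_percent = s$mean_percent,
      rounded_percent = as.integer(s$rounded_percent),
      reportable_percent = as.integer(s$reportable_percent),
      clamped = s$clamped,
      score = as.integer(s$score),
      config = obj$config
    ),
    class = "case_report"
  )
}

config_echo <- function(config) {
  config[c("white_threshold", "nuclear_threshold", "eosin_threshold",
           "lymph_diameter", "lymph_circularity", "tumor_close_size",
           "predominance", "lymph_min_count", "l_rule")]
}

#' Quantify one case end to end
#'
#' The two workflows of the method: *manual-count mode* takes a per-field
#' count table (data frame or CSV path) and applies the formulas; *image
#' mode* takes a directory of field microphotographs (one case; field order
#' is the lexicographic filename sort), fits the field of view of each, and
#' classifies every grid cell before tallying.
#'
#' @param input A counts data frame, a counts CSV path, or a directory of
#'   PNG/JPEG/TIFF field images.
#' @param mode `"TSR"` or `"sTIL"`.
#' @param config A [quant_config()].
#' @param output_dir Optional directory: writes `report_<mode>.json`, and in
#'   image mode `cells_<mode>.csv` plus (optionally) labeled overlay PNGs.
#' @param overlays Write per-field overlay images (image mode only).
#' @param exclusion Optional per-cell exclusion mask (data frame of 0-based
#'   `row`, `col`) applied to every field.
#' @param case_id Case identifier for the report.
#' @param ... Passed to [classify_field()] in image mode (e.g. `n_per_side`,
#'   `circle`, `no_vignette`).
#' @return The `case_report`, with `$config` (threshold echo) and, in image
#'   mode, `$cells` (per-cell tibble across fields) attached.
#' @export
run_quantify <- function(input, mode = c("TSR", "sTIL"), config = quant_config(),
                         output_dir = NULL, overlays = FALSE, exclusion = NULL,
                         case_id = "case", ...) {
  mode <- normalize_parameter(mode)
  cells <- NULL
  if (is.data.frame(input)) {
    counts <- input
  } else if (dir.exists(input)) {
    paths <- sort(list.files(input, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(paths) == 0) {
      abort(paste0("no images found in ", input), class = "gridquant_missing_input")
    }
    per_field <- lapply(seq_along(paths), function(i) {
      img <- read_image(paths[i])
      grid <- inscribe_square_grid(fit_fov_circle(img), n_per_side = 10)
      cell_tbl <- classify_field(img, mode = mode, grid = grid, config = config,
                                 exclusion = exclusion, ...)
      cell_tbl$field_id <- i
      cell_tbl$file <- basename(paths[i])
      if (isTRUE(overlays) && !is.null(output_dir)) {
        lab_m <- matrix(cell_tbl$label, nrow = grid$n_per_side, byrow = TRUE)
        ov <- render_overlay(img, grid, labels = lab_m)
        write_image(ov, file.path(output_dir, paste0("overlay_", i, ".png")))
      }
      cell_tbl
    })
    cells <- dplyr::bind_rows(per_field)
    counts <- dplyr::bind_rows(lapply(per_field, function(tbl) {
      tally_labels(tbl$label, field_id = tbl$field_id[1])
    }))
  } else if (file.exists(input)) {
    counts <- read_counts(input)
  } else {
    abort(paste0("input not found: ", input), class = "gridquant_missing_input")
  }
  report <- aggregate_case(counts, parameter = mode, case_id = case_id)
  report$config <- config_echo(config)
  report$cells <- cells
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_case_report(report, file.path(output_dir,
                                        paste0("report_", tolower(report$parameter), ".json")))
    if (!is.null(cells)) {
      write.csv(cells, file.path(output_dir, paste0("cells_", tolower(report$parameter), ".csv")),
                row.names = FALSE)
    }
  }
  report
}

#' Inter-observer agreement from a score table
#'
#' @param input A scores data frame or CSV path (columns `case_id`,
#'   `rater_a_score`, `rater_b_score`).
#' @param output Optional JSON output path.
#' @param ... Passed to [rater_agreement()].
#' @return An `agreement_result`.
#' @export
run_agreement <- function(input, output = NULL, ...) {
  scores <- if (is.data.frame(input)) input else read_scores(input)
  res <- rater_agreement(scores, ...)
  if (!is.null(output)) {
    jsonlite::write_json(
      list(kappa = res$kappa, percent_agreement = res$percent_agreement,
           interpretation = res$interpretation, n = res$n_items,
           kappa_se = res$kappa_se, conf_level = res$conf_level,
           kappa_ci = res$kappa_ci),
      output, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  }
  res
}
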