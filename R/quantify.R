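#' Build a per-field grid count table
#'
#' Constructs the tally of grid-cell labels for one or more microscope fields:
#' `n_T` tumor-predominant squares, `n_S` stroma-predominant squares
#' (including those that are additionally lymphocyte-predominant), `n_L`
#' lymphocyte-predominant squares, and `n_NA` inconclusive/empty squares.
#'
#' `n_S` counts *all* stroma-predominant squares: a lymphocyte-predominant
#' square is a stroma square that also satisfies the lymphocyte rule, so
#' `n_L <= n_S` always and `n_T + n_S + n_NA` equals the number of grid cells.
#'
#' @param n_T,n_S,n_L,n_NA Integer vectors (recycled to a common length) of
#'   per-field label tallies. `n_NA` defaults to whatever tops the field up to
#'   `n_total` when `n_total` is supplied, otherwise 0.
#' @param n_total Optional total number of grid squares per field (100 for the
#'   default 10x10 grid). When omitted it is taken as `n_T + n_S + n_NA`.
#' @param field_id Optional field identifiers.
#' @return A tibble with class `field_counts` and columns `field_id`, `n_T`,
#'   `n_S`, `n_L`, `n_NA`, `n_total`.
#' @examples
#' field_counts(n_T = 25, n_S = 75, n_L = 50)
#' @export
field_counts <- function(n_T, n_S, n_L = 0L, n_NA = NULL, n_total = NULL,
                         field_id = NULL) {
  if (is.null(n_NA)) {
    n_NA <- if (is.null(n_total)) 0L else n_total - n_T - n_S
  }
  len <- max(length(n_T), length(n_S), length(n_L), length(n_NA))
  n_T <- rep_len(as.integer(n_T), len)
  n_S <- rep_len(as.integer(n_S), len)
  n_L <- rep_len(as.integer(n_L), len)
  n_NA <- rep_len(as.integer(n_NA), len)
  if (is.null(field_id)) field_id <- seq_len(len)
  counts <- tibble(
    field_id = rep_len(field_id, len),
    n_T = n_T, n_S = n_S, n_L = n_L, n_NA = n_NA,
    n_total = n_T + n_S + n_NA
  )
  validate_field_counts(counts)
  class(counts) <- c("field_counts", class(counts))
  counts
}

validate_field_counts <- function(counts) {
  need <- c("n_T", "n_S", "n_L", "n_NA")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gridquant_bad_counts")
  }
  bad <- which(counts$n_T < 0 | counts$n_S < 0 | counts$n_L < 0 |
                 counts$n_NA < 0 | counts$n_L > counts$n_S)
  if (length(bad) > 0) {
    abort(paste0("invalid counts in row(s) ", paste(head(bad, 5), collapse = ", "),
                 ": tallies must be non-negative and n_L <= n_S"),
          class = "gridquant_bad_counts")
  }
  invisible(counts)
}

#' Tumor-stroma ratio of a field
#'
#' TSR(%) = 100 * n_S / (n_T + n_S): the share of stroma-predominant squares
#' among the tumor and stroma squares. Inconclusive (`NA`-labelled) squares
#' are excluded from the denominator.
#'
#' @param counts A data frame with columns `n_T` and `n_S` (one row per
#'   field), e.g. from [field_counts()].
#' @return A numeric vector of percentages in `[0, 100]`, one per row.
#'   Fields with `n_T + n_S == 0` yield `NA` with a
#'   `gridquant_undefined` warning.
#' @examples
#' compute_tsr(field_counts(n_T = 30, n_S = 60, n_NA = 10))
#' @export
compute_tsr <- function(counts) {
  validate_field_counts(as_counts_df(counts, need_L = FALSE))
  denom <- counts$n_T + counts$n_S
  out <- ifelse(denom > 0, 100 * counts$n_S / denom, NA_real_)
  if (anyNA(out)) {
    warn("TSR undefined for field(s) with no tumor or stroma squares (n_T + n_S = 0)",
         class = "gridquant_undefined")
  }
  out
}

#' Stromal tumor-infiltrating lymphocyte percentage of a field
#'
#' sTIL(%) = 100 * n_L / n_S: the share of lymphocyte-predominant squares
#' among the stroma-predominant squares. Tumor and inconclusive squares are
#' excluded from the calculation entirely.
#'
#' @param counts A data frame with columns `n_S` and `n_L` (one row per
#'   field), e.g. from [field_counts()].
#' @return A numeric vector of percentages in `[0, 100]`, one per row.
#'   Fields with `n_S == 0` yield `NA` with a `gridquant_undefined` warning.
#' @examples
#' compute_stil(field_counts(n_T = 25, n_S = 75, n_L = 50))
#' @export
compute_stil <- function(counts) {
  validate_field_counts(as_counts_df(counts, need_L = TRUE))
  out <- ifelse(counts$n_S > 0, 100 * counts$n_L / counts$n_S, NA_real_)
  if (anyNA(out)) {
    warn("sTIL undefined for field(s) with no stroma squares (n_S = 0)",
         class = "gridquant_undefined")
  }
  out
}

# Fill implied columns so the validator can run on partial tables.
as_counts_df <- function(counts, need_L) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame (see field_counts())",
          class = "gridquant_bad_counts")
  }
  if (is.null(counts$n_L)) counts$n_L <- 0L
  if (is.null(counts$n_NA)) counts$n_NA <- 0L
  counts
}

#' Round a percentage half-up to a whole number
#'
#' Decimal digits are rounded to the nearest whole number with halves rounded
#' up (67.76 becomes 68; 49.5 becomes 50). This is arithmetic round-half-up,
#' not banker's rounding.
#'
#' @param x Numeric vector of percentages in `[0, 100]`.
#' @return Integer vector.
#' @examples
#' round_percent(c(67.76, 49.5, 50))
#' @export
round_percent <- function(x) {
  if (any(!is.finite(x)) || any(x < 0 | x > 100)) {
    abort("percentages must be finite and within [0, 100]",
          class = "gridquant_range")
  }
  as.integer(floor(x + 0.5))
}

#' Clamp a whole-number percentage to the reportable range 1-99
#'
#' Reporting 0% or 100% for a case is avoided (a field is never entirely one
#' compartment once empty space between cells is considered), so 0 is raised
#' to 1 and 100 lowered to 99; all other values pass through. A
#' `gridquant_clamped` warning is emitted whenever clamping occurs.
#'
#' @param p Integer vector of percentages in `[0, 100]`.
#' @return Integer vector in `[1, 99]`.
#' @export
clamp_reportable <- function(p) {
  if (any(p < 0 | p > 100)) {
    abort("percentages must be within [0, 100]", class = "gridquant_range")
  }
  out <- as.integer(pmin(pmax(p, 1L), 99L))
  n_clamped <- sum(out != p)
  if (n_clamped > 0) {
    warn(paste0(n_clamped, " value(s) clamped into the reportable range [1, 99]"),
         class = "gridquant_clamped")
  }
  out
}

#' Four-tier score for a rounded percentage
#'
#' Bins a whole-number percentage into the method's four tiers:
#' 0-25 -> 1, 26-50 -> 2, 51-75 -> 3, 76-100 -> 4. The same tiers apply to
#' TSR and sTIL. See [score_tiers()] for the table.
#'
#' @param p Integer vector of whole-number percentages in `[0, 100]`.
#' @return Integer scores in 1..4.
#' @examples
#' score_percent(c(25, 26, 75, 76))
#' @export
score_percent <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 100)) {
    abort("percentages must be within [0, 100]", class = "gridquant_range")
  }
  if (any(abs(p - round(p)) > 1e-9)) {
    abort("score_percent() expects whole-number percentages; round first (round_percent())",
          class = "gridquant_range")
  }
  findInterval(p, c(0, 26, 51, 76))
}

#' The four-tier scoring table
#'
#' @return A tibble with columns `score`, `lower`, `upper`, `range_label`.
#' @export
score_tiers <- function() {
  tibble(
    score = 1:4,
    lower = c(0L, 26L, 51L, 76L),
    upper = c(25L, 50L, 75L, 100L),
    range_label = c("0-25%", "26-50%", "51-75%", "76-100%")
  )
}

#' Aggregate per-field counts into a case report
#'
#' Computes the per-field percentage (TSR or sTIL) for each row of the count
#' table, averages the defined values across fields (conventionally 10 fields
#' per case), rounds half-up, clamps to the reportable range 1-99 and assigns
#' the four-tier score. Fields with an undefined percentage (zero
#' denominator) are skipped with a warning rather than treated as 0.
#'
#' @param counts A data frame of per-field tallies (see [field_counts()]).
#' @param parameter `"TSR"` or `"sTIL"` (case-insensitive).
#' @param case_id Optional case identifier carried into the report.
#' @return An object of class `case_report`; see [tidy.case_report()] and
#'   [glance.case_report()].
#' @examples
#' counts <- field_counts(n_T = c(25, 0), n_S = c(75, 100), n_L = c(50, 50))
#' aggregate_case(counts, parameter = "sTIL")
#' @export
aggregate_case <- function(counts, parameter = c("TSR", "sTIL"), case_id = NA_character_) {
  parameter <- normalize_parameter(parameter)
  counts <- as_counts_df(counts, need_L = parameter == "sTIL")
  validate_field_counts(counts)
  if (nrow(counts) == 0) {
    abort("no fields supplied", class = "gridquant_no_fields")
  }
  percent <- withCallingHandlers(
    if (parameter == "TSR") compute_tsr(counts) else compute_stil(counts),
    gridquant_undefined = function(w) invokeRestart("muffleWarning")
  )
  fields <- as_tibble(counts)
  if (is.null(fields$field_id)) fields$field_id <- seq_len(nrow(fields))
  fields$percent <- percent
  n_undef <- sum(is.na(percent))
  if (n_undef == nrow(fields)) {
    abort("all fields have an undefined percentage (zero denominator)",
          class = "gridquant_undefined")
  }
  if (n_undef > 0) {
    warn(paste0(n_undef, " field(s) with undefined percentage skipped from the case mean"),
         class = "gridquant_skipped_fields")
  }
  mean_percent <- mean(percent, na.rm = TRUE)
  rounded <- round_percent(mean_percent)
  reportable <- withCallingHandlers(
    clamp_reportable(rounded),
    gridquant_clamped = function(w) invokeRestart("muffleWarning")
  )
  structure(
    list(
      case_id = case_id,
      parameter = parameter,
      fields = fields,
      n_fields = nrow(fields),
      n_used = nrow(fields) - n_undef,
      mean_percent = mean_percent,
      rounded_percent = rounded,
      reportable_percent = reportable,
      clamped = reportable != rounded,
      score = score_percent(reportable)
    ),
    class = "case_report"
  )
}

normalize_parameter <- function(parameter) {
  p <- toupper(parameter[1])
  if (p %in% c("TSR")) return("TSR")
  if (p %in% c("STIL", "TIL")) return("sTIL")
  abort("`parameter` must be \"TSR\" or \"sTIL\"", class = "gridquant_bad_mode")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s%s\n", x$parameter,
              if (is.na(x$case_id)) "" else paste0(" for case ", x$case_id)))
  cat(sprintf("  fields: %d (%d used)\n", x$n_fields, x$n_used))
  cat(sprintf("  mean %%: %.2f -> rounded %d -> reportable %d%s\n",
              x$mean_percent, x$rounded_percent, x$reportable_percent,
              if (x$clamped) " (clamped)" else ""))
  tier <- score_tiers()$range_label[x$score]
  cat(sprintf("  score: %d (%s)\n", x$score, tier))
  invisible(x)
}

#' Per-field detail of a case report
#'
#' @param x A `case_report` from [aggregate_case()].
#' @param ... Unused.
#' @return A tibble with one row per field: the tallies and the field
#'   percentage (`NA` where undefined).
#' @method tidy case_report
#' @export
tidy.case_report <- function(x, ...) {
  out <- x$fields
  out$parameter <- x$parameter
  out$case_id <- x$case_id
  dplyr::relocate(out, "case_id", "parameter", "field_id")
}

#' One-row case summary
#'
#' @param x A `case_report` from [aggregate_case()].
#' @param ... Unused.
#' @return A one-row tibble: case id, parameter, number of fields used, mean,
#'   rounded, reportable percent, clamping flag and tier score.
#' @method glance case_report
#' @export
glance.case_report <- function(x, ...) {
  tibble(
    case_id = x$case_id,
    parameter = x$parameter,
    n_fields = x$n_fields,
    n_used = x$n_used,
    mean_percent = x$mean_percent,
    rounded_percent = x$rounded_percent,
    reportable_percent = x$reportable_percent,
    clamped = x$clamped,
    score = x$score
  )
}
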