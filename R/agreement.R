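#' Percent agreement between two raters
#'
#' @param a,b Vectors of categorical ratings for the same items in the same
#'   order.
#' @return Exact-match agreement as a percentage in `[0, 100]`.
#' @examples
#' percent_agreement(c(1, 2, 3), c(1, 2, 4))
#' @export
percent_agreement <- function(a, b) {
  check_rating_pair(a, b)
  100 * mean(a == b)
}

check_rating_pair <- function(a, b) {
  if (length(a) != length(b)) {
    abort("the two raters must score the same items: lengths differ",
          class = "gridquant_length_mismatch")
  }
  if (length(a) < 2) {
    abort("at least 2 rated items are required", class = "gridquant_too_few")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("ratings must not contain missing values", class = "gridquant_bad_ratings")
  }
  invisible(TRUE)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, where
#' \eqn{p_o} is the observed exact-match proportion and
#' \eqn{p_e = \sum_k m_a(k)\, m_b(k)} the chance agreement from the two
#' raters' marginal category frequencies. Unweighted by default; linear or
#' quadratic weights are available for ordinal scores but are not the
#' standard reading of plain Cohen's kappa.
#'
#' When both raters assign one identical constant category, \eqn{p_e = 1}
#' and kappa has the indeterminate form 0/0; agreement is perfect, so 1 is
#' returned with a `gridquant_degenerate_kappa` warning.
#'
#' @param a,b Vectors of categorical ratings for the same items in the same
#'   order.
#' @param categories Optional vector of all admissible categories (so unused
#'   categories keep their place in the weighting). Defaults to the sorted
#'   union of observed values.
#' @param weights `"none"` (default), `"linear"` or `"quadratic"`.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(rep(1:2, each = 15), rep(c(1, 2, 1, 2), c(10, 5, 5, 10)))
#' @export
cohen_kappa <- function(a, b, categories = NULL, weights = c("none", "linear", "quadratic")) {
  check_rating_pair(a, b)
  weights <- match.arg(weights)
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  if (!all(c(a, b) %in% categories)) {
    abort("all ratings must belong to `categories`", class = "gridquant_bad_ratings")
  }
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  n <- length(a)
  tab <- table(fa, fb) / n
  k <- length(categories)
  w <- switch(weights,
    none = diag(k),
    linear = 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2
  )
  p_o <- sum(w * tab)
  p_e <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    warn("both raters constant and identical: kappa is 0/0, returning 1",
         class = "gridquant_degenerate_kappa")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Verbal interpretation of a kappa value
#'
#' Cohen's conventional bands: kappa of 0 or below indicates no agreement,
#' 0.01-0.20 none to slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial and 0.81-1.00 almost perfect agreement. Values strictly
#' between 0 and 0.01 fall in the none-to-slight band.
#'
#' @param k Numeric vector of kappa values in `[-1, 1]`.
#' @return Character vector of band labels.
#' @examples
#' interpret_kappa(c(0.78, 0.51, -0.1))
#' @export
interpret_kappa <- function(k) {
  if (any(!is.finite(k)) || any(k < -1 | k > 1)) {
    abort("kappa must lie in [-1, 1]", class = "gridquant_range")
  }
  bands <- c("no agreement", "none to slight", "fair", "moderate",
             "substantial", "almost perfect")
  # upper-inclusive cut points at the printed band edges
  idx <- findInterval(k, c(-1, 0, 0.2, 0.4, 0.6, 0.8), left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[k <= 0] <- 1L
  bands[idx]
}

#' Inter-observer agreement on case scores
#'
#' Computes percent agreement, Cohen's kappa and its verbal interpretation
#' for two observers' case-level scores.
#'
#' @param scores A data frame with one row per case and the two raters'
#'   scores in the columns named by `rater_a` and `rater_b`.
#' @param rater_a,rater_b Column names of the two raters' scores.
#' @param categories Optional admissible score set (defaults to observed).
#' @param weights Kappa weighting, see [cohen_kappa()].
#' @param conf_level Confidence level for the optional normal-approximation
#'   interval on unweighted kappa (a standard large-sample extra, reported
#'   alongside the point estimate).
#' @return An object of class `agreement_result`; see
#'   [tidy.agreement_result()] and [glance.agreement_result()].
#' @examples
#' scores <- tibble::tibble(
#'   case_id = 1:30,
#'   rater_a_score = rep(1:2, each = 15),
#'   rater_b_score = rep(c(1, 2, 1, 2), c(10, 5, 5, 10))
#' )
#' rater_agreement(scores)
#' @export
rater_agreement <- function(scores, rater_a = "rater_a_score", rater_b = "rater_b_score",
                            categories = NULL, weights = "none", conf_level = 0.95) {
  if (!is.data.frame(scores)) {
    abort("`scores` must be a data frame", class = "gridquant_bad_ratings")
  }
  for (col in c(rater_a, rater_b)) {
    if (is.null(scores[[col]])) {
      abort(paste0("scores table is missing column `", col, "`"),
            class = "gridquant_bad_ratings")
    }
  }
  a <- scores[[rater_a]]
  b <- scores[[rater_b]]
  check_rating_pair(a, b)
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  n <- length(a)
  kap <- withCallingHandlers(
    cohen_kappa(a, b, categories = categories, weights = weights),
    gridquant_degenerate_kappa = function(w) invokeRestart("muffleWarning")
  )
  degenerate <- length(unique(c(a, b))) == 1
  pa <- percent_agreement(a, b)
  p_o <- pa / 100
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  p_e <- sum((table(fa) / n) * (table(fb) / n))
  se <- if (degenerate) NA_real_ else sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      kappa = kap,
      percent_agreement = pa,
      interpretation = interpret_kappa(kap),
      n_items = n,
      categories = categories,
      weights = weights,
      kappa_se = se,
      conf_level = conf_level,
      kappa_ci = if (is.na(se)) c(NA_real_, NA_real_) else
        pmin(pmax(kap + c(-1, 1) * z * se, -1), 1),
      degenerate = degenerate,
      table = table(rater_a = fa, rater_b = fb)
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result>\n")
  cat(sprintf("  n cases: %d, categories: %s\n", x$n_items,
              paste(x$categories, collapse = ", ")))
  cat(sprintf("  kappa: %.4f (%s)%s\n", x$kappa, x$interpretation,
              if (x$degenerate) " [degenerate: both raters constant]" else ""))
  cat(sprintf("  percent agreement: %.2f%%\n", x$percent_agreement))
  invisible(x)
}

#' Cross-tabulation behind an agreement result
#'
#' @param x An `agreement_result` from [rater_agreement()].
#' @param ... Unused.
#' @return A tibble with columns `rater_a`, `rater_b`, `n`: the contingency
#'   table of the two raters' scores in long form.
#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$table, responseName = "n"))
  names(out) <- c("rater_a", "rater_b", "n")
  out
}

#' One-row agreement summary
#'
#' @param x An `agreement_result` from [rater_agreement()].
#' @param ... Unused.
#' @return A one-row tibble with kappa, its normal-approximation standard
#'   error and interval, percent agreement, interpretation and item count.
#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble(
    kappa = x$kappa,
    kappa_se = x$kappa_se,
    kappa_low = x$kappa_ci[1],
    kappa_high = x$kappa_ci[2],
    percent_agreement = x$percent_agreement,
    interpretation = x$interpretation,
    n_items = x$n_items
  )
}
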