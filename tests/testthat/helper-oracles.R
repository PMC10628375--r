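# Independent oracles, coded separately from the package implementations.

# Cohen's kappa from the full contingency table, by explicit double loop.
oracle_kappa <- function(a, b, categories = sort(unique(c(a, b)))) {
  n <- length(a)
  k <- length(categories)
  tab <- matrix(0, k, k, dimnames = list(categories, categories))
  for (i in seq_len(n)) {
    ia <- match(a[i], categories)
    ib <- match(b[i], categories)
    tab[ia, ib] <- tab[ia, ib] + 1
  }
  p <- tab / n
  p_o <- sum(diag(p))
  p_e <- 0
  for (j in seq_len(k)) p_e <- p_e + sum(p[j, ]) * sum(p[, j])
  (p_o - p_e) / (1 - p_e)
}

# A tiny one-field synthetic image wrapper used across imaging tests.
small_field <- function(counts, seed = 1, ...) {
  generate_field(counts = counts, image_size = 256, fov_diameter = 224,
                 seed = seed, ...)
}
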