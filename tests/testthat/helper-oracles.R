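# Brute-force Fleiss' kappa oracle: observed agreement from explicit
# enumeration of all rater pairs per item, expected agreement from the
# probability that two independent draws from the pooled assignment
# distribution coincide. Deliberately loop-based and independent of the
# package's matrix formulation.
oracle_fleiss_kappa <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  per_item <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    agree <- 0L
    pairs <- 0L
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        pairs <- pairs + 1L
        if (identical(x[i, a], x[i, b])) agree <- agree + 1L
      }
    }
    per_item[i] <- agree / pairs
  }
  p_bar <- mean(per_item)
  pooled <- table(as.vector(x))
  p_j <- as.numeric(pooled) / sum(pooled)
  p_e <- sum(p_j^2)
  list(
    kappa = (p_bar - p_e) / (1 - p_e),
    observed = p_bar,
    expected = p_e
  )
}

random_rating_matrix <- function(n_items, n_raters, n_categories) {
  m <- matrix(
    sample.int(n_categories, n_items * n_raters, replace = TRUE) - 1L,
    nrow = n_items
  )
  rownames(m) <- sprintf("%04d", 1100 + seq_len(n_items))
  m
}

# A small hand-writable valid rating table for consensus tests.
ratings_row <- function(rater, code, l, f = NA, i = NA, round = 2L) {
  tibble::tibble(
    rater_id = rater, code4 = code, round = round,
    likelihood = as.integer(l), frequency = as.integer(f),
    intensity = as.integer(i)
  )
}

make_ratings <- function(...) dplyr::bind_rows(...)
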