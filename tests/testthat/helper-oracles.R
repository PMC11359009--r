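# Independent brute-force oracles used across test files. These stay
# deliberately naive (double loops, direct formula evaluation) so they never
# share code with the implementation they check.

# per-pixel max-min over an odd window with replicate padding
oracle_range_filter <- function(img, window = 3) {
  h <- (window - 1) %/% 2
  j <- nrow(img); k <- ncol(img)
  out <- matrix(0, j, k)
  for (r in seq_len(j)) {
    for (c in seq_len(k)) {
      rr <- pmin(pmax((r - h):(r + h), 1), j)
      cc <- pmin(pmax((c - h):(c + h), 1), k)
      block <- img[rr, cc]
      out[r, c] <- max(block) - min(block)
    }
  }
  out
}

# direct evaluation of the normalised moment sum
oracle_moment <- function(mask, m, n) {
  j <- nrow(mask); k <- ncol(mask)
  acc <- 0
  for (x in seq_len(j)) {
    for (y in seq_len(k)) {
      acc <- acc + x^m * y^n * mask[x, y]
    }
  }
  acc / (j^m * k^n)
}

# rasterised disk mask centred at (cr, cc)
raster_disk <- function(j, k, cr, cc, radius) {
  dr <- matrix(seq_len(j) - cr, j, k)
  dc <- matrix(seq_len(k) - cc, j, k, byrow = TRUE)
  (dr^2 + dc^2 <= radius^2) * 1
}

random_mask <- function(j, k, p = 0.4) {
  matrix(rbinom(j * k, 1, p), j, k)
}

random_image <- function(j, k) {
  matrix(sample(0:255, j * k, replace = TRUE), j, k)
}

# feature table with two well-separated classes on the named features
separable_table <- function(n_pos = 10, n_neg = 10, features = "f1",
                            gap = 6, seed = 11) {
  withr::with_seed(seed, {
    rows <- lapply(features, function(f) {
      c(rnorm(n_pos, gap / 2, 0.5), rnorm(n_neg, -gap / 2, 0.5))
    })
    names(rows) <- features
    tibble::as_tibble(rows) |>
      dplyr::mutate(label = c(rep("normal", n_pos), rep("ad", n_neg)))
  })
}
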