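#' Local range filter
#'
#' Slides an odd `window x window` neighbourhood over the image and replaces
#' each pixel with the local intensity range (max minus min). Vessel edges
#' produce large ranges while homogeneous tissue produces small ones, which
#' sharpens the histogram structure the FC/FWHM features are read from.
#' Borders are handled by replicate padding, so no intensity absent from the
#' image is ever introduced.
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @param window Odd window size >= 3 (default 3).
#' @return Matrix of the same shape with the local ranges.
#' @export
range_filter <- function(img, window = 3) {
  .check_gray(img)
  if (window %% 2 == 0 || window < 3) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  j <- nrow(img); k <- ncol(img)
  if (window > j || window > k) {
    stop("window (", window, ") exceeds image extent ", j, "x", k,
         call. = FALSE)
  }
  h <- (window - 1) %/% 2
  ridx <- pmin(pmax(seq(1 - h, j + h), 1), j)
  cidx <- pmin(pmax(seq(1 - h, k + h), 1), k)
  pad <- img[ridx, cidx, drop = FALSE]
  mx <- matrix(-Inf, j, k)
  mn <- matrix(Inf, j, k)
  for (dr in 0:(window - 1)) {
    for (dc in 0:(window - 1)) {
      block <- pad[dr + seq_len(j), dc + seq_len(k), drop = FALSE]
      mx <- pmax(mx, block)
      mn <- pmin(mn, block)
    }
  }
  mx - mn
}

#' 256-bin intensity histogram
#'
#' Counts integer-rounded intensities into bins 0..255.
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @return A tibble with columns `intensity` (0..255) and `count`; the
#'   counts sum to the pixel count.
#' @export
intensity_histogram <- function(img) {
  .check_gray(img)
  v <- pmin(pmax(round(img), 0), 255)
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  tibble::tibble(intensity = 0:255, count = counts)
}

#' Central intensity (FC) and full width at half maximum (FWHM)
#'
#' Reads the two histogram features off a 256-bin histogram `H(x)`:
#' the central intensity `fc` is the smallest `x` attaining the peak count
#' `h_max`; with `h_half = h_max / 2`, `x_half1` is the smallest
#' `x <= fc` with `H(x) > h_half` and `x_half2` is the smallest `x > fc`
#' with `H(x) < h_half` (falling back to 255 when the count never drops,
#' flagged in `x_half2_fallback`). The FWHM is `x_half2 - x_half1`. The two
#' search conditions are deliberately asymmetric (strictly above before the
#' peak, strictly below after it); the single-spike histogram therefore
#' yields FWHM 1. Features are invariant to rescaling all counts by a
#' positive constant.
#'
#' @param hist A tibble from [intensity_histogram()] (columns `intensity`,
#'   `count`), or a bare numeric vector of 256 counts for bins 0..255.
#' @return One-row tibble: `fc`, `fwhm`, `h_max`, `x_half1`, `x_half2`,
#'   `x_half1_fallback`, `x_half2_fallback`.
#' @export
extract_fc_fwhm <- function(hist) {
  counts <- if (is.data.frame(hist)) hist$count else hist
  if (length(counts) != 256L || any(counts < 0)) {
    stop("expected 256 non-negative histogram counts", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty histogram", call. = FALSE)
  x <- 0:255
  h_max <- max(counts)
  fc <- x[which.max(counts)]           # smallest index on ties
  h_half <- h_max / 2
  below <- which(x <= fc & counts > h_half)
  half1_fallback <- length(below) == 0L
  x_half1 <- if (half1_fallback) 0L else x[min(below)]
  above <- which(x > fc & counts < h_half)
  half2_fallback <- length(above) == 0L
  x_half2 <- if (half2_fallback) 255L else x[min(above)]
  tibble::tibble(
    fc = fc, fwhm = x_half2 - x_half1, h_max = h_max,
    x_half1 = x_half1, x_half2 = x_half2,
    x_half1_fallback = half1_fallback, x_half2_fallback = half2_fallback
  )
}
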