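#' Read a grayscale image
#'
#' Reads a PNG or TIFF file and returns a single-channel intensity matrix on
#' the 0--255 scale. Colour images are collapsed to luminance with the
#' standard Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); an alpha channel,
#' if present, is ignored. Rows run top to bottom and columns left to right,
#' both 1-based, so `img[j, k]` is the pixel in scan row `j`, column `k`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix with values in `[0, 255]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(100), 10, 10), f)
#' img <- load_image(f)
#' dim(img)
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (length(raw) == 0L || any(dim(raw)[1:2] == 0L)) {
    stop("zero-sized image: ", path, call. = FALSE)
  }
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    raw <- if (nc >= 3L) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  }
  img <- raw * 255
  .check_gray(img)
  img
}

#' Write a grayscale image or binary mask as PNG
#'
#' Intensity matrices (0--255) are rescaled to the unit range; binary masks
#' are written as 0/255.
#'
#' @param img Numeric matrix, intensities in `[0, 255]` or a 0/1 mask.
#'   A matrix whose values are all 0 or 1 is treated as a mask and written
#'   as 0/255.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  .check_gray(img)
  if (all(img %in% c(0, 1))) img <- img * 255
  png::writePNG(img / 255, path)
  invisible(path)
}

.check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("expected a numeric intensity matrix", call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop("image has zero extent", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

.check_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("expected a 0/1 binary mask matrix", call. = FALSE)
  }
  invisible(mask)
}

#' Photographic negative
#'
#' Maps each pixel `v` to `255 - v`, so vessels (bright on OCT-A angiograms)
#' become dark. Applying it twice returns the original image.
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @return The inverted intensity matrix.
#' @export
to_negative <- function(img) {
  .check_gray(img)
  255 - img
}

#' Global threshold to a binary mask
#'
#' Pixels with intensity greater than or equal to `threshold` map to 1,
#' all others to 0. The `>=` tie rule is fixed so results are deterministic.
#'
#' @param img Intensity matrix in `[0, 255]`.
#' @param threshold Scalar threshold in `[0, 255]`.
#' @return A 0/1 matrix of the same shape.
#' @export
binarize <- function(img, threshold) {
  .check_gray(img)
  if (length(threshold) != 1L || threshold < 0 || threshold > 255) {
    stop("threshold must be a scalar in [0, 255]", call. = FALSE)
  }
  (img >= threshold) * 1
}

#' Crop away uninformative borders
#'
#' OCT-A device exports often carry uniform margins around the scan. In
#' `"auto"` mode, contiguous border rows and columns whose intensity variance
#' falls below `cfg$crop_var_floor` are trimmed from each side. `"fixed"`
#' mode applies `cfg$crop_box = c(row0, row1, col0, col1)`; `"none"` is the
#' identity. Auto-cropping an already cropped image is a no-op.
#'
#' @param img Intensity matrix.
#' @param cfg A [preprocess_config()].
#' @return The cropped intensity matrix.
#' @export
crop_auto <- function(img, cfg = preprocess_config()) {
  .check_gray(img)
  mode <- cfg$crop_mode
  if (mode == "none") {
    return(img)
  }
  if (mode == "fixed") {
    b <- cfg$crop_box
    if (is.null(b) || length(b) != 4L) {
      stop("crop_mode 'fixed' requires crop_box = c(row0, row1, col0, col1)",
           call. = FALSE)
    }
    if (b[1] < 1 || b[2] > nrow(img) || b[3] < 1 || b[4] > ncol(img) ||
        b[1] > b[2] || b[3] > b[4]) {
      stop("crop_box out of image bounds", call. = FALSE)
    }
    return(img[b[1]:b[2], b[3]:b[4], drop = FALSE])
  }
  floor_var <- cfg$crop_var_floor
  rv <- apply(img, 1, stats::var)
  cv <- apply(img, 2, stats::var)
  keep_range <- function(v) {
    live <- which(v >= floor_var)
    if (length(live) == 0L) {
      stop("auto crop removed the entire image (no content found)",
           call. = FALSE)
    }
    range(live)
  }
  rr <- keep_range(rv)
  cc <- keep_range(cv)
  img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

# --- morphology ------------------------------------------------------------
# EBImage treats pixels outside the image as foreground during erosion, which
# would make blobs touching the border lose their boundary. All wrappers pad
# with background first so out-of-image is background everywhere.

.disc <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")

.pad <- function(mask, r, value = 0) {
  j <- nrow(mask); k <- ncol(mask)
  out <- matrix(value, j + 2 * r, k + 2 * r)
  out[(r + 1):(r + j), (r + 1):(r + k)] <- mask
  out
}

.unpad <- function(mask, r, j, k) {
  mask[(r + 1):(r + j), (r + 1):(r + k), drop = FALSE]
}

.erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  j <- nrow(mask); k <- ncol(mask)
  m <- .pad(mask, radius)
  .unpad(as.matrix(EBImage::erode(m, .disc(radius))), radius, j, k)
}

.dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  j <- nrow(mask); k <- ncol(mask)
  m <- .pad(mask, radius)
  .unpad(as.matrix(EBImage::dilate(m, .disc(radius))), radius, j, k)
}

# Opening and closing use EBImage's native border convention (out-of-image
# counts as foreground during erosion), so blobs and bands touching the
# image edge pass through unchanged; features are judged by their in-image
# width only. The subset laws still hold: opening never adds pixels and
# closing never removes them, with out-of-image treated as part of the
# foreground universe.
.open <- function(mask, radius) {
  if (radius <= 0) return(mask)
  b <- .disc(radius)
  as.matrix(EBImage::dilate(EBImage::erode(mask, b), b))
}

.close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  b <- .disc(radius)
  as.matrix(EBImage::erode(EBImage::dilate(mask, b), b))
}

#' Morphological opening then closing
#'
#' Opening (erosion followed by dilation) with a disc of `open_radius_px`
#' removes foreground features thinner than the disc; closing with a disc of
#' `close_radius_px` then fills background gaps thinner than its disc. A
#' radius of 0 skips the corresponding step. Pixels outside the image are
#' treated as background.
#'
#' @param mask A 0/1 matrix.
#' @param open_radius_px,close_radius_px Disc radii in pixels (>= 0).
#' @return The cleaned 0/1 matrix.
#' @export
morph_open_close <- function(mask, open_radius_px, close_radius_px) {
  .check_mask(mask)
  if (open_radius_px < 0 || close_radius_px < 0) {
    stop("structuring-element radii must be >= 0", call. = FALSE)
  }
  .close(.open(mask, open_radius_px), close_radius_px)
}

# Connected components with true 8-connectivity. EBImage::bwlabel is
# 4-connected, so labels that touch diagonally are merged afterwards with a
# union-find pass. Returned labels are renumbered 1..n in row-major order of
# each component's first pixel.
label_components <- function(mask) {
  .check_mask(mask)
  lab <- as.matrix(EBImage::bwlabel(mask))
  mx <- max(lab)
  if (mx <= 1L) return(lab)
  j <- nrow(lab); k <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-j, -k]), as.vector(lab[-1, -1])),  # \ diagonal
    cbind(as.vector(lab[-1, -k]), as.vector(lab[-j, -1]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(mx)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(mx), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  # renumber by first pixel in row-major scan order
  flat <- as.vector(t(lab))
  first <- match(sort(unique(flat[flat > 0])), flat)
  ord <- sort(unique(flat[flat > 0]))[order(first)]
  remap <- integer(mx)
  remap[ord] <- seq_along(ord)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# Fill interior holes of a mask (holes touching the border stay open).
fill_holes <- function(mask) {
  .check_mask(mask)
  as.matrix(EBImage::fillHull(mask)) * 1
}
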