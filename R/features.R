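#' Histogram of oriented gradients for a 28x28 image
#'
#' Computes per-cell orientation histograms with the geometry used by the
#' model's retina-to-thalamus code: 14x14 pixel cells applied at a stride of
#' 7 pixels over a 28x28 image (a 3x3 grid of overlapping cells, offsets
#' 0/7/14 in each dimension), 9 unsigned orientation bins over \[0, 180)
#' degrees.  Gradients are central differences (one-sided at the borders),
#' votes are hard-assigned to the bin containing the gradient orientation
#' and weighted by gradient magnitude, and each cell's 9-bin histogram is
#' L2-normalised.
#'
#' @param image numeric 28x28 matrix of finite grayscale values.
#' @return A 9x9 numeric matrix: rows are cells (row-major over the 3x3
#'   grid), columns are orientation bins.
#' @export
#' @examples
#' img <- matrix(0, 28, 28); img[, 14:28] <- 1   # vertical step edge
#' h <- compute_hog(img)
#' dim(h)  # 9 cells x 9 bins
compute_hog <- function(image) {
  if (!is.matrix(image) || !all(dim(image) == c(28, 28)))
    stop("image must be a 28x28 matrix")
  if (!all(is.finite(image))) stop("image values must be finite")
  g <- image_gradients(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- (atan2(g$gy, g$gx) * 180 / pi) %% 180            # unsigned
  bin <- pmin(floor(ang / 20), 8)                          # 9 bins of 20 deg
  offs <- c(0, 7, 14)
  out <- matrix(0, 9, 9)
  cell <- 1
  for (oy in offs) {
    for (ox in offs) {
      rows <- (oy + 1):(oy + 14); cols <- (ox + 1):(ox + 14)
      b <- bin[rows, cols]; m <- mag[rows, cols]
      h <- vapply(0:8, function(k) sum(m[b == k]), numeric(1))
      nrm <- sqrt(sum(h^2))
      if (nrm > 0) h <- h / nrm
      out[cell, ] <- h
      cell <- cell + 1
    }
  }
  out
}

# central-difference gradients, one-sided at borders; x runs along columns
image_gradients <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, nc] <- image[, nc] - image[, nc - 1]
  gy[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]
  gy[nr, ] <- image[nr, ] - image[nr - 1, ]
  list(gx = gx, gy = gy)
}

#' Quantisation boundaries for the 4-level binary code
#'
#' The binary feature code maps every HOG bin value to one of four mutually
#' exclusive levels.  Boundaries are the quartiles of the nonzero bin values
#' observed over a training set of histograms, so that a value of zero (and
#' anything below the first quartile) falls in level 0 and values above the
#' third quartile saturate at level 3.
#'
#' @param hogs a list of 9x9 HOG matrices (see [compute_hog()]).
#' @return Sorted numeric vector of 3 level boundaries.
#' @export
hog_level_breaks <- function(hogs) {
  v <- unlist(hogs)
  v <- v[v > 0]
  if (length(v) < 4) stop("not enough nonzero bin values to set boundaries")
  unname(quantile(v, c(0.25, 0.5, 0.75)))
}

#' Binarise a HOG into the 324-bit one-hot-blocked feature vector
#'
#' Each of the 81 bin values is mapped to a one-hot code over 4 levels by
#' fixed boundaries; the 81 blocks are concatenated cell-major, bin-minor,
#' level-innermost, giving a 324-length binary vector -- one element per
#' thalamic relay cell.
#'
#' @param hog a 9x9 matrix from [compute_hog()] (non-negative values).
#' @param breaks 3 sorted level boundaries, e.g. from [hog_level_breaks()].
#' @return Integer vector of length 324 in which every consecutive block of
#'   4 entries contains exactly one 1.
#' @export
binarize <- function(hog, breaks) {
  if (!is.matrix(hog) || !all(dim(hog) == c(9, 9)))
    stop("hog must be a 9x9 matrix")
  if (any(hog < 0)) stop("bin values must be non-negative")
  stopifnot(length(breaks) == 3, !is.unsorted(breaks))
  vals <- as.vector(t(hog))                    # cell-major, bin-minor
  lev <- findInterval(vals, breaks, left.open = TRUE)   # 0..3
  out <- integer(324)
  out[(seq_along(vals) - 1) * 4 + lev + 1] <- 1L
  out
}

#' Validate the one-hot block structure of a feature vector
#'
#' @param v candidate feature vector.
#' @return `TRUE` invisibly if `v` has length 324 and every consecutive
#'   4-level block sums to exactly 1; otherwise an error.
#' @export
validate_feature_vector <- function(v) {
  if (length(v) != 324) stop("feature vector must have length 324")
  if (!all(v %in% c(0, 1))) stop("feature vector must be binary")
  s <- colSums(matrix(v, nrow = 4))
  if (!all(s == 1)) stop("each 4-level block must sum to exactly 1")
  invisible(TRUE)
}

# lenient input check for retrieval/classification probes: any binary
# 324-vector is presentable (including the all-zero blank), whereas
# training inputs must satisfy the full one-hot block structure
validate_input_vector <- function(v) {
  if (length(v) != 324) stop("feature vector must have length 324")
  if (!all(v %in% c(0, 1))) stop("feature vector must be binary")
  invisible(TRUE)
}

#' Map a feature vector to thalamic Poisson drive
#'
#' Thalamic relay cell `i` receives an independent Poisson spike train at
#' `rate` Hz with synaptic efficacy `eff` nS if and only if element `i` of
#' the feature vector is 1; cells whose feature is 0 receive nothing.
#'
#' @param v a 324-length binary feature vector (one element per relay cell).
#' @param rate Poisson rate of the active drive, Hz (default 30 kHz).
#' @param eff conductance increment per event, nS (default 8).
#' @param t_start,t_stop active window, ms.
#' @return A tibble of Poisson sources with thalamus-local target indices
#'   (empty if the vector is all zero).
#' @export
features_to_drive <- function(v, rate = 30000, eff = 8,
                              t_start = 0, t_stop = Inf) {
  if (length(v) != 324)
    stop("feature vector length must equal the thalamic population size (324)")
  on <- which(v == 1)
  if (length(on) == 0) {
    return(tibble::tibble(targets = list(), rate = numeric(0),
                          eff = numeric(0), t_start = numeric(0),
                          t_stop = numeric(0)))
  }
  poisson_source(on, rate, eff, t_start, t_stop)
}

#' Encode a set of images into feature vectors
#'
#' Convenience pipeline: HOG for every image, level boundaries computed over
#' the whole set (unless supplied), then binarisation.
#'
#' @param images list of 28x28 matrices.
#' @param breaks optional fixed level boundaries; computed from `images` by
#'   [hog_level_breaks()] when `NULL`.
#' @return `list(features = <list of 324-vectors>, breaks = <boundaries>)`.
#' @export
encode_images <- function(images, breaks = NULL) {
  hogs <- lapply(images, compute_hog)
  if (is.null(breaks)) breaks <- hog_level_breaks(hogs)
  feats <- lapply(hogs, binarize, breaks = breaks)
  list(features = feats, breaks = breaks)
}
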