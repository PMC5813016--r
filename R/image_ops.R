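# Elementary image operators of the TIRF puncta pipeline. All operate on
# plain numeric matrices (row, col), 1-based coordinates.

#' Pipeline configuration
#'
#' Parameters of the puncta-detection chain. Defaults are the tuned values of
#' the analysis the package reimplements: square-root 16-to-8-bit transform,
#' Gaussian smoothing with half-width 2 px and sigma 1, top-hat background
#' suppression with a radius-30 disk followed by signal enhancement with a
#' radius-5 disk, and non-maximal suppression with a 3 px radius at
#' threshold 20 (8-bit units).
#'
#' @param gaussian_halfwidth_px truncation half-width of the smoothing kernel.
#' @param gaussian_sigma_px Gaussian sigma of the smoothing kernel.
#' @param tophat_large_radius_px disk radius of the background-removal top-hat.
#' @param tophat_small_radius_px disk radius of the enhancement top-hat
#'   (must be smaller than the large radius).
#' @param nms_radius_px Chebyshev radius of the non-maximal suppression window.
#' @param nms_threshold peak detection threshold in 8-bit units, `[0, 255]`.
#' @param gate_min_area_px optional post-hoc gate: drop puncta smaller than
#'   this area.
#' @param gate_min_mean_intensity optional post-hoc gate: drop puncta whose
#'   mean 8-bit intensity falls below this value.
#' @param cell_image which image feeds Otsu cell segmentation: the smoothed
#'   8-bit image (default) or the raw square-root 8-bit image.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gaussian_halfwidth_px = 2L, gaussian_sigma_px = 1,
                            tophat_large_radius_px = 30L,
                            tophat_small_radius_px = 5L,
                            nms_radius_px = 3L, nms_threshold = 20,
                            gate_min_area_px = NULL,
                            gate_min_mean_intensity = NULL,
                            cell_image = c("smoothed", "sqrt")) {
  stopifnot_scalar_num(gaussian_halfwidth_px, "gaussian_halfwidth_px", positive = TRUE)
  stopifnot_scalar_num(gaussian_sigma_px, "gaussian_sigma_px", positive = TRUE)
  stopifnot_scalar_num(tophat_large_radius_px, "tophat_large_radius_px", positive = TRUE)
  stopifnot_scalar_num(tophat_small_radius_px, "tophat_small_radius_px", positive = TRUE)
  stopifnot_scalar_num(nms_radius_px, "nms_radius_px", positive = TRUE)
  stopifnot_scalar_num(nms_threshold, "nms_threshold")
  if (nms_threshold < 0 || nms_threshold > 255) {
    stop("`nms_threshold` must lie in [0, 255]", call. = FALSE)
  }
  if (tophat_small_radius_px >= tophat_large_radius_px) {
    stop("small top-hat radius must be smaller than the large one", call. = FALSE)
  }
  structure(list(
    gaussian_halfwidth_px = as.integer(gaussian_halfwidth_px),
    gaussian_sigma_px = gaussian_sigma_px,
    tophat_large_radius_px = as.integer(tophat_large_radius_px),
    tophat_small_radius_px = as.integer(tophat_small_radius_px),
    nms_radius_px = as.integer(nms_radius_px),
    nms_threshold = nms_threshold,
    gate_min_area_px = gate_min_area_px,
    gate_min_mean_intensity = gate_min_mean_intensity,
    cell_image = match.arg(cell_image)
  ), class = "pipeline_config")
}

field_pixels <- function(x) {
  if (inherits(x, "tirf_field")) x$pixels else x
}

#' Square-root transform of a 16-bit image to the 8-bit range
#'
#' `v8 = min(255, floor(sqrt(v16)))`: maps `[0, 65535]` onto `[0, 255]`,
#' compressing bright puncta of widely varying intensity onto a common scale.
#' Monotone non-decreasing and integer-valued.
#'
#' @param field a `tirf_field` or an integer matrix with values in
#'   `[0, 65535]`.
#' @return integer matrix in `[0, 255]`.
#' @export
sqrt_to_8bit <- function(field) {
  img <- field_pixels(field)
  if (!is_uint16(img)) {
    stop("pixel values must be integers in [0, 65535]", call. = FALSE)
  }
  out <- floor(sqrt(img))
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

gaussian_kernel_1d <- function(halfwidth, sigma) {
  x <- -halfwidth:halfwidth
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized, truncated Gaussian kernel (separable; the
#' 2-D kernel is the outer product of the 1-D kernel with itself, truncated at
#' `+/- halfwidth` in each direction). Borders use edge replication, so a
#' constant image maps to itself exactly.
#'
#' @param img numeric matrix.
#' @param halfwidth,sigma kernel truncation half-width (px) and Gaussian sigma.
#' @return smoothed numeric matrix, same shape.
#' @export
smooth_gaussian <- function(img, halfwidth = 2L, sigma = 1) {
  stopifnot(is.matrix(img))
  k <- gaussian_kernel_1d(halfwidth, sigma)
  h <- as.integer(halfwidth)
  nr <- nrow(img)
  nc <- ncol(img)
  # replicate-pad, then separable convolution
  ridx <- c(rep(1L, h), seq_len(nr), rep(nr, h))
  cidx <- c(rep(1L, h), seq_len(nc), rep(nc, h))
  pad <- img[ridx, cidx, drop = FALSE]
  tmp <- matrix(0, nr, nc + 2L * h)
  for (i in seq_along(k)) {
    tmp <- tmp + k[i] * pad[(i):(i + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {
    out <- out + k[i] * tmp[, (i):(i + nc - 1L), drop = FALSE]
  }
  out
}

#' White top-hat transform
#'
#' `img - opening(img, disk(radius))` where the opening is an erosion followed
#' by a dilation with a discrete disk (Euclidean radius test, centre
#' included). Removes structures wider than the disk: with a large radius it
#' flattens the non-uniform background; with a small radius it isolates
#' punctate signal from local intensity variation. The result is nonnegative
#' and invariant to adding a constant offset.
#'
#' @param img numeric matrix.
#' @param radius_px disk radius in pixels (>= 1, smaller than the image).
#' @return numeric matrix of the same shape.
#' @export
tophat <- function(img, radius_px) {
  stopifnot(is.matrix(img))
  stopifnot_scalar_num(radius_px, "radius_px", positive = TRUE)
  if (2 * radius_px + 1 > max(nrow(img), ncol(img))) {
    stop("`radius_px` is too large for the image", call. = FALSE)
  }
  off <- disk_offsets(radius_px)
  opened <- cpp_dilate(cpp_erode(img, off), off)
  img - opened
}

#' Peak detection by non-maximal suppression
#'
#' A pixel is a peak when its value is at least `nms_threshold` and no pixel
#' within Chebyshev distance `nms_radius_px` exceeds it. Connected
#' equal-valued plateaus of candidate pixels are collapsed to their
#' lexicographically smallest `(row, col)` member. Peaks are returned sorted
#' by `(row, col)`.
#'
#' @param enhanced numeric matrix (the twice-top-hatted image).
#' @param cfg a [pipeline_config()] supplying radius and threshold.
#' @return integer matrix with columns `row`, `col` (1-based), zero rows when
#'   no peak qualifies.
#' @export
find_peaks_nms <- function(enhanced, cfg = pipeline_config()) {
  stopifnot(is.matrix(enhanced), inherits(cfg, "pipeline_config"))
  peaks <- cpp_nms(enhanced, cfg$nms_radius_px, cfg$nms_threshold)
  colnames(peaks) <- c("row", "col")
  peaks
}

#' Marker-controlled watershed segmentation of puncta
#'
#' Floods the negated enhanced image from the detected peaks (foreground
#' markers) and from all sub-threshold pixels (background marker), assigning
#' every pixel to a basin by priority flooding with 8-connectivity. Each peak
#' yields exactly one labelled region containing it; regions are disjoint.
#'
#' @param enhanced numeric matrix used for detection.
#' @param peaks integer matrix of peak coordinates from [find_peaks_nms()].
#' @param cfg a [pipeline_config()]; its `nms_threshold` defines the
#'   background marker.
#' @return integer label matrix (0 = background, `i` = region of peak `i`).
#' @export
segment_puncta_watershed <- function(enhanced, peaks, cfg = pipeline_config()) {
  stopifnot(is.matrix(enhanced), inherits(cfg, "pipeline_config"))
  n <- nrow(peaks)
  labels <- matrix(0L, nrow(enhanced), ncol(enhanced))
  if (n == 0L) return(labels)
  if (any(peaks[, 1] < 1 | peaks[, 1] > nrow(enhanced) |
          peaks[, 2] < 1 | peaks[, 2] > ncol(enhanced))) {
    stop("peaks must lie inside the image", call. = FALSE)
  }
  markers <- matrix(0L, nrow(enhanced), ncol(enhanced))
  bg_label <- n + 1L
  markers[enhanced < cfg$nms_threshold] <- bg_label
  markers[peaks] <- seq_len(n)
  out <- cpp_watershed(-enhanced, markers, bg_label)
  out[out == bg_label] <- 0L
  out
}

#' Measure puncta on the unprocessed square-root image
#'
#' Quantifies each labelled region on the 8-bit square-root-transformed (but
#' otherwise unprocessed) image: pixel area, mean intensity, integrated
#' intensity (mean x area, i.e. the pixel sum), and centroid.
#'
#' @param labels integer label matrix from [segment_puncta_watershed()].
#' @param sqrt_image the output of [sqrt_to_8bit()] (same shape).
#' @return data.frame with columns `label`, `centroid_row`, `centroid_col`,
#'   `area_px`, `mean_intensity`, `integrated_intensity`.
#' @export
measure_puncta <- function(labels, sqrt_image) {
  if (!is.matrix(labels) || !is.matrix(sqrt_image) ||
      !all(dim(labels) == dim(sqrt_image))) {
    stop("`labels` and `sqrt_image` must be matrices of the same shape", call. = FALSE)
  }
  idx <- which(labels > 0)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0),
                      mean_intensity = numeric(0),
                      integrated_intensity = numeric(0)))
  }
  lab <- labels[idx]
  vals <- as.numeric(sqrt_image[idx])
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tapply(vals, lab, length)
  total <- tapply(vals, lab, sum)
  data.frame(
    label = as.integer(names(area)),
    centroid_row = as.numeric(tapply(rows, lab, mean)),
    centroid_col = as.numeric(tapply(cols, lab, mean)),
    area_px = as.integer(area),
    mean_intensity = as.numeric(total / area),
    integrated_intensity = as.numeric(total),
    row.names = NULL
  )
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustive search over the 256 candidate thresholds for the value
#' maximizing the between-class variance of the histogram; ties resolve to
#' the smallest threshold. Foreground is `img > threshold`.
#'
#' @param img integer matrix with values in `[0, 255]`.
#' @return the threshold (scalar in 0..254).
#' @export
otsu_threshold <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.integer(round(img))
  if (any(v < 0 | v > 255)) stop("Otsu input must lie in [0, 255]", call. = FALSE)
  if (length(unique(v)) < 2L) {
    stop("degenerate single-valued image: no foreground", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)              # P(class0) for threshold t = level
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  t_cand <- 1:255                 # thresholds t = 0..254 (index t+1)
  w0 <- omega[t_cand]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[t_cand][valid])^2 /
    (w0[valid] * w1[valid])
  which.max(sigma_b) - 1L
}

#' Cell segmentation via Otsu's method
#'
#' Thresholds the image with [otsu_threshold()], fills interior holes, and
#' keeps the largest 8-connected component as the cell foreground.
#'
#' @param img integer matrix in `[0, 255]` (by default the smoothed 8-bit
#'   image; see [pipeline_config()]).
#' @return list of class `cell_mask` with `foreground` (logical matrix),
#'   `foreground_area_px`, and `threshold`.
#' @export
segment_cells <- function(img) {
  t <- otsu_threshold(img)
  mask <- img > t
  if (!any(mask)) stop("no foreground found above Otsu threshold", call. = FALSE)
  mask <- cpp_fill_holes(mask)
  labs <- cpp_label(mask, 8L)
  sizes <- tabulate(labs[labs > 0])
  keep <- which.max(sizes)
  fg <- labs == keep
  structure(list(foreground = fg,
                 foreground_area_px = sum(fg),
                 threshold = t),
            class = "cell_mask")
}
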