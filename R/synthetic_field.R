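# Synthetic TIRF field generator. Emulates the statistical structure the
# puncta pipeline assumes: dark background with a smooth low-frequency
# non-uniformity, one or more elliptical cell footprints carrying a constant
# diffuse plateau, bright sub-resolution Gaussian puncta restricted to the
# cell area, shot + read noise, and 16-bit quantization. Every injected
# punctum is reported as ground truth so detection can be scored exactly.

#' Specification of a synthetic TIRF field
#'
#' Bundles and validates all parameters of [generate_field()]. Defaults
#' describe a 192x192 px field with a single cell and bright, well-separated
#' puncta whose enhanced-image peak height is several times the detection
#' threshold; see the methods vignette for how each default was chosen.
#'
#' @param image_height_px,image_width_px field dimensions in pixels.
#' @param n_cells number of non-overlapping cells to place.
#' @param cell_radius_px length-2 numeric `c(mean, jitter)`: ellipse semi-axes
#'   are drawn as `Normal(mean, jitter)`, floored at 4 px.
#' @param cell_intensity diffuse plateau added over each cell footprint
#'   (16-bit counts).
#' @param n_puncta_per_cell number of puncta injected per cell.
#' @param puncta_sigma_px isotropic Gaussian spot width (truncated at 4 sigma).
#' @param puncta_amplitude length-2 range `c(min, max)` of peak amplitudes in
#'   16-bit counts; each punctum draws uniformly from it.
#' @param min_separation_px minimum Euclidean distance between puncta centres
#'   within a cell.
#' @param background_level constant 16-bit baseline.
#' @param background_gradient_amplitude peak amplitude of the smooth
#'   low-frequency background non-uniformity (a Gaussian blob with spatial
#'   scale of order the field size).
#' @param noise list with elements `shot` (logical: Poisson noise on the
#'   expected signal) and `read_sd` (Gaussian read noise sd, 16-bit counts).
#' @param seed integer RNG seed; identical specs give bit-identical fields.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(image_height_px = 192L, image_width_px = 192L,
                       n_cells = 1L, cell_radius_px = c(40, 4),
                       cell_intensity = 2500,
                       n_puncta_per_cell = 10L, puncta_sigma_px = 1.5,
                       puncta_amplitude = c(15000, 50000),
                       min_separation_px = 8,
                       background_level = 400,
                       background_gradient_amplitude = 300,
                       noise = list(shot = TRUE, read_sd = 100),
                       seed = 1L) {
  stopifnot_scalar_num(image_height_px, "image_height_px", positive = TRUE)
  stopifnot_scalar_num(image_width_px, "image_width_px", positive = TRUE)
  stopifnot_scalar_num(n_cells, "n_cells", positive = TRUE)
  stopifnot_scalar_num(n_puncta_per_cell, "n_puncta_per_cell", nonneg = TRUE)
  stopifnot_scalar_num(puncta_sigma_px, "puncta_sigma_px", positive = TRUE)
  stopifnot_scalar_num(cell_intensity, "cell_intensity", nonneg = TRUE)
  stopifnot_scalar_num(min_separation_px, "min_separation_px", nonneg = TRUE)
  if (length(cell_radius_px) != 2L || any(cell_radius_px < 0) ||
      cell_radius_px[1] <= 0) {
    stop("`cell_radius_px` must be c(mean > 0, jitter >= 0)", call. = FALSE)
  }
  if (length(puncta_amplitude) != 2L || any(puncta_amplitude < 0) ||
      any(puncta_amplitude > 65535) ||
      puncta_amplitude[1] > puncta_amplitude[2]) {
    stop("`puncta_amplitude` must be an increasing range within [0, 65535]",
         call. = FALSE)
  }
  if (background_level < 0 || background_level > 65535 ||
      background_gradient_amplitude < 0 ||
      background_gradient_amplitude > 65535) {
    stop("background levels must lie in [0, 65535]", call. = FALSE)
  }
  if (!is.list(noise) || !all(c("shot", "read_sd") %in% names(noise)) ||
      noise$read_sd < 0) {
    stop("`noise` must be list(shot = logical, read_sd = sd >= 0)", call. = FALSE)
  }
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_cells = as.integer(n_cells),
    cell_radius_px = as.numeric(cell_radius_px),
    cell_intensity = cell_intensity,
    n_puncta_per_cell = as.integer(n_puncta_per_cell),
    puncta_sigma_px = puncta_sigma_px,
    puncta_amplitude = as.numeric(puncta_amplitude),
    min_separation_px = min_separation_px,
    background_level = background_level,
    background_gradient_amplitude = background_gradient_amplitude,
    noise = list(shot = isTRUE(noise$shot), read_sd = noise$read_sd),
    seed = as.integer(seed)
  )
  class(spec) <- "field_spec"
  spec
}

ellipse_mask <- function(nr, nc, centre, rx, ry, theta) {
  dr <- matrix(seq_len(nr) - centre[1], nr, nc)
  dc <- matrix(seq_len(nc) - centre[2], nr, nc, byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate a synthetic TIRF field with ground truth
#'
#' Renders `background + gradient + diffuse cell plateaus + Gaussian puncta`,
#' applies Poisson shot noise to the expected signal followed by Gaussian read
#' noise, then rounds and clips to the 16-bit range. Cells are placed without
#' overlap (an error is raised if placement fails after bounded retries), and
#' every punctum centre falls inside a cell footprint.
#'
#' @param spec a [field_spec()].
#' @param field_id,treatment_label,batch_id metadata carried on the result.
#' @return list of class `tirf_field` with elements
#'   `pixels` (integer matrix), `field_id`, `treatment_label`, `batch_id`, and
#'   `truth`: a list with `puncta_centers` (n x 2 matrix of 1-based
#'   `(row, col)`, sub-pixel), `puncta_amplitudes`, and `cell_masks` (list of
#'   logical matrices).
#' @export
generate_field <- function(spec, field_id = "field1",
                           treatment_label = NA_character_,
                           batch_id = NA_character_) {
  stopifnot(inherits(spec, "field_spec"))
  nr <- spec$image_height_px
  nc <- spec$image_width_px
  with_seed(spec$seed, {
    img <- matrix(spec$background_level, nr, nc)
    if (spec$background_gradient_amplitude > 0) {
      centre <- c(runif(1, 1, nr), runif(1, 1, nc))
      sg <- 0.75 * max(nr, nc)
      dr <- matrix(seq_len(nr) - centre[1], nr, nc)
      dc <- matrix(seq_len(nc) - centre[2], nr, nc, byrow = TRUE)
      img <- img + spec$background_gradient_amplitude *
        exp(-(dr^2 + dc^2) / (2 * sg^2))
    }
    # place non-overlapping elliptical cells
    cell_masks <- vector("list", spec$n_cells)
    occupied <- matrix(FALSE, nr, nc)
    for (i in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        rx <- max(4, rnorm(1, spec$cell_radius_px[1], spec$cell_radius_px[2]))
        ry <- max(4, rnorm(1, spec$cell_radius_px[1], spec$cell_radius_px[2]))
        theta <- runif(1, 0, pi)
        rmax <- max(rx, ry)
        if (2 * rmax + 4 > min(nr, nc)) next
        centre <- c(runif(1, rmax + 2, nr - rmax - 1),
                    runif(1, rmax + 2, nc - rmax - 1))
        m <- ellipse_mask(nr, nc, centre, rx, ry, theta)
        if (!any(m & occupied)) {
          cell_masks[[i]] <- m
          occupied <- occupied | m
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place ", spec$n_cells,
             " non-overlapping cells after bounded retries", call. = FALSE)
      }
    }
    for (m in cell_masks) img[m] <- img[m] + spec$cell_intensity
    # puncta: uniform over the cell footprint with a minimum separation
    centers <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("row", "col")))
    amplitudes <- numeric(0)
    for (m in cell_masks) {
      if (spec$n_puncta_per_cell == 0L) next
      pix <- which(m, arr.ind = TRUE)
      pts <- matrix(numeric(0), 0, 2)
      guard <- 0L
      while (nrow(pts) < spec$n_puncta_per_cell) {
        guard <- guard + 1L
        if (guard > 2000L) {
          stop("could not place puncta at the requested separation", call. = FALSE)
        }
        p <- pix[sample.int(nrow(pix), 1L), ] + runif(2, -0.49, 0.49)
        if (nrow(pts) > 0 &&
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) < spec$min_separation_px) {
          next
        }
        pts <- rbind(pts, p)
      }
      amps <- runif(spec$n_puncta_per_cell,
                    spec$puncta_amplitude[1], spec$puncta_amplitude[2])
      centers <- rbind(centers, pts)
      amplitudes <- c(amplitudes, amps)
    }
    # render puncta as isotropic Gaussians truncated at 4 sigma
    half <- ceiling(4 * spec$puncta_sigma_px)
    for (i in seq_len(nrow(centers))) {
      r0 <- max(1L, floor(centers[i, 1] - half))
      r1 <- min(nr, ceiling(centers[i, 1] + half))
      c0 <- max(1L, floor(centers[i, 2] - half))
      c1 <- min(nc, ceiling(centers[i, 2] + half))
      rs <- r0:r1
      cs <- c0:c1
      d2 <- outer((rs - centers[i, 1])^2, (cs - centers[i, 2])^2, `+`)
      g <- amplitudes[i] * exp(-d2 / (2 * spec$puncta_sigma_px^2))
      g[d2 > (4 * spec$puncta_sigma_px)^2] <- 0
      img[rs, cs] <- img[rs, cs] + g
    }
    if (spec$noise$shot) {
      img <- matrix(rpois(length(img), lambda = img), nr, nc)
    }
    if (spec$noise$read_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise$read_sd), nr, nc)
    }
    img <- matrix(pmin(65535, pmax(0, round(img))), nr, nc)
    storage.mode(img) <- "integer"
    rownames(centers) <- NULL
    structure(list(
      pixels = img,
      field_id = field_id,
      treatment_label = treatment_label,
      batch_id = batch_id,
      truth = list(puncta_centers = centers,
                   puncta_amplitudes = amplitudes,
                   cell_masks = cell_masks)
    ), class = "tirf_field")
  })
}
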