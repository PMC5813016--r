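# Per-field orchestration of the puncta pipeline and the experiment-level
# endpoint normalization.

#' Run the full detection chain on one field
#'
#' From a raw 16-bit field to measured puncta: square-root 8-bit transform,
#' Gaussian smoothing, large-radius top-hat (background removal), small-radius
#' top-hat (signal enhancement), non-maximal-suppression peak finding,
#' marker-controlled watershed, and region measurement on the unprocessed
#' square-root image. Cell boundaries come from Otsu segmentation of the
#' smoothed (default) or square-root image.
#'
#' @param field a `tirf_field` from [generate_field()], or a 16-bit integer
#'   matrix.
#' @param cfg a [pipeline_config()].
#' @return list of class `field_detection` with elements `sqrt_image`,
#'   `enhanced`, `peaks`, `labels`, `records` (the puncta table), `cell_mask`,
#'   and the field metadata.
#' @export
detect_puncta <- function(field, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  img8 <- sqrt_to_8bit(field)
  smoothed <- smooth_gaussian(img8, cfg$gaussian_halfwidth_px, cfg$gaussian_sigma_px)
  flat <- tophat(smoothed, cfg$tophat_large_radius_px)
  enhanced <- tophat(flat, cfg$tophat_small_radius_px)
  peaks <- find_peaks_nms(enhanced, cfg)
  labels <- segment_puncta_watershed(enhanced, peaks, cfg)
  records <- measure_puncta(labels, img8)
  cell_img <- if (cfg$cell_image == "smoothed") round(smoothed) else img8
  mask <- segment_cells(matrix(as.integer(pmin(255, pmax(0, cell_img))),
                               nrow(img8), ncol(img8)))
  structure(list(
    sqrt_image = img8, enhanced = enhanced, peaks = peaks, labels = labels,
    records = records, cell_mask = mask,
    field_id = if (inherits(field, "tirf_field")) field$field_id else NA_character_,
    treatment_label = if (inherits(field, "tirf_field")) field$treatment_label else NA_character_,
    batch_id = if (inherits(field, "tirf_field")) field$batch_id else NA_character_
  ), class = "field_detection")
}

#' Per-image normalization factors from pooled foreground areas
#'
#' All cell foreground areas across the experiment are pooled and each is
#' divided by their median, giving a factor per image that adjusts puncta
#' counts and integrated intensities for differences in imaged cell area.
#'
#' @param areas numeric vector of foreground areas (px), all > 0.
#' @return numeric vector of factors, same length; their median is 1 for odd
#'   sample sizes.
#' @export
normalization_factors <- function(areas) {
  if (length(areas) < 1L || any(!is.finite(areas)) || any(areas <= 0)) {
    stop("`areas` must be positive and non-empty", call. = FALSE)
  }
  areas / median(areas)
}

#' Cell-area-normalized endpoints for one field
#'
#' Filters out puncta whose centroid pixel lies outside the cell mask,
#' applies the optional post-hoc area/intensity gates, and reports the two
#' endpoints: puncta count per normalized cell area and integrated puncta
#' intensity per normalized cell area.
#'
#' @param records puncta table from [measure_puncta()] / [detect_puncta()].
#' @param mask a `cell_mask` from [segment_cells()].
#' @param factor normalization factor for this image (> 0), from
#'   [normalization_factors()].
#' @param cfg a [pipeline_config()] carrying the gates.
#' @param field_id identifier carried through to the result.
#' @return data.frame (one row) with `field_id`, `n_puncta_raw`,
#'   `puncta_count_norm`, `integrated_intensity_norm`, `normalization_factor`.
#' @export
field_endpoints <- function(records, mask, factor = 1,
                            cfg = pipeline_config(), field_id = NA_character_) {
  stopifnot_scalar_num(factor, "factor", positive = TRUE)
  stopifnot(inherits(mask, "cell_mask"))
  keep <- rep(TRUE, nrow(records))
  if (nrow(records) > 0) {
    pr <- pmin(nrow(mask$foreground), pmax(1L, floor(records$centroid_row + 0.5)))
    pc <- pmin(ncol(mask$foreground), pmax(1L, floor(records$centroid_col + 0.5)))
    keep <- mask$foreground[cbind(pr, pc)]
    if (!is.null(cfg$gate_min_area_px)) {
      keep <- keep & records$area_px >= cfg$gate_min_area_px
    }
    if (!is.null(cfg$gate_min_mean_intensity)) {
      keep <- keep & records$mean_intensity >= cfg$gate_min_mean_intensity
    }
  }
  inside <- records[keep, , drop = FALSE]
  data.frame(
    field_id = field_id,
    n_puncta_raw = nrow(inside),
    puncta_count_norm = nrow(inside) / factor,
    integrated_intensity_norm = sum(inside$integrated_intensity) / factor,
    normalization_factor = factor
  )
}

#' Endpoints for a set of detected fields
#'
#' Pools the cell foreground areas of all fields to compute per-image
#' normalization factors, then derives each field's endpoints.
#'
#' @param detections list of `field_detection` objects from [detect_puncta()].
#' @param cfg a [pipeline_config()].
#' @return data.frame with one row per field (plus `treatment_label`,
#'   `batch_id`).
#' @export
experiment_endpoints <- function(detections, cfg = pipeline_config()) {
  stopifnot(length(detections) >= 1L)
  areas <- vapply(detections, function(d) d$cell_mask$foreground_area_px, numeric(1))
  factors <- normalization_factors(areas)
  out <- do.call(rbind, lapply(seq_along(detections), function(i) {
    d <- detections[[i]]
    fe <- field_endpoints(d$records, d$cell_mask, factors[i], cfg, d$field_id)
    fe$treatment_label <- d$treatment_label
    fe$batch_id <- d$batch_id
    fe
  }))
  rownames(out) <- NULL
  out
}
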