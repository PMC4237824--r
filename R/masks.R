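#' Vessel-wall analysis mask with near-lumen exclusion
#'
#' Builds the pixel mask over which plaque kinetics are averaged: pixels
#' whose centers lie inside the outer-wall contour, outside the lumen
#' contour, and at Euclidean distance greater than `exclusion_mm` from the
#' lumen polygon. The 1 mm default exclusion ring suppresses contamination
#' of wall pixels by the bright lumen signal (partial volume, blurring,
#' motion) in bright-blood DCE imaging. Point-in-polygon uses the even-odd
#' rule on pixel centers; distances are to the polygon segments.
#'
#' @param lumen_contour,outer_contour Two-column vertex matrices, mm, with
#'   the lumen strictly inside the outer contour.
#' @param dim Integer `c(n_rows, n_cols)` of the image grid.
#' @param pixel_size Pixel size, mm.
#' @param exclusion_mm Width of the near-lumen exclusion ring, mm (>= 0).
#'
#' @return A logical rows x cols matrix.
#' @export
#' @examples
#' ph <- build_phantom(acq_protocol("GE"))
#' m <- wall_mask_with_exclusion(ph$lumen_contour, ph$outer_contour,
#'                               dim = rep(ph$grid_size, 2),
#'                               pixel_size = ph$pixel_size)
wall_mask_with_exclusion <- function(lumen_contour, outer_contour, dim,
                                     pixel_size, exclusion_mm = 1.0) {
  if (exclusion_mm < 0) stop("'exclusion_mm' must be >= 0")
  lumen_inside_outer <- point_in_polygon(lumen_contour[, 1], lumen_contour[, 2],
                                         outer_contour)
  if (!all(lumen_inside_outer))
    stop("contours cross: lumen contour is not strictly inside the outer contour")

  ctr <- pixel_centers(dim[1], dim[2], pixel_size)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  in_outer <- point_in_polygon(px, py, outer_contour)
  in_lumen <- point_in_polygon(px, py, lumen_contour)
  mask <- in_outer & !in_lumen
  if (exclusion_mm > 0) {
    idx <- which(mask)
    d <- dist_to_polygon(px[idx], py[idx], lumen_contour)
    mask[idx] <- d > exclusion_mm
  }
  matrix(mask, dim[1], dim[2])
}

#' Plaque-mean kinetic measurement over a wall mask
#'
#' Averages the raw per-pixel Ktrans and vp estimates over the valid
#' pixels of the analysis mask, and reports the analyzed area. An empty
#' mask yields a measurement marked missing (`NA` means), never zeros.
#'
#' @param map A `kinetic_map`.
#' @param mask Logical rows x cols analysis mask (e.g. from
#'   [wall_mask_with_exclusion()]).
#' @param pixel_size Pixel size, mm; default from the map.
#' @param subject_id,scan_index Optional identifiers carried through.
#' @param max_wall_thickness Optional maximum wall thickness (mm) carried
#'   through for downstream inclusion filtering.
#'
#' @return A one-row data.frame with `subject_id`, `scan_index`,
#'   `mean_ktrans`, `mean_vp`, `analyzed_area` (mm^2),
#'   `max_wall_thickness`, `n_pixels`, `missing`.
#' @export
measure_plaque <- function(map, mask, pixel_size = map$pixel_size,
                           subject_id = NA_character_, scan_index = NA_integer_,
                           max_wall_thickness = NA_real_) {
  stopifnot(inherits(map, "kinetic_map"))
  if (!identical(base::dim(mask), base::dim(map$ktrans)))
    stop("mask dimensions do not match the kinetic map")
  use <- mask & map$valid_mask
  n <- sum(use)
  data.frame(
    subject_id = subject_id,
    scan_index = scan_index,
    mean_ktrans = if (n > 0) mean(map$ktrans[use]) else NA_real_,
    mean_vp = if (n > 0) mean(map$vp[use]) else NA_real_,
    analyzed_area = n * pixel_size^2,
    max_wall_thickness = max_wall_thickness,
    n_pixels = n,
    missing = n == 0,
    stringsAsFactors = FALSE
  )
}

#' Maximum-wall-thickness inclusion filter
#'
#' Retains measurements whose index plaque has maximum wall thickness
#' strictly greater than the threshold (bright-blood DCE cannot assess
#' near-normal thin walls).
#'
#' @param measurements A data.frame with a `max_wall_thickness` column (mm).
#' @param threshold_mm Inclusion threshold, mm; strict inequality.
#' @return The filtered data.frame.
#' @export
apply_inclusion <- function(measurements, threshold_mm = 1.0) {
  if (!"max_wall_thickness" %in% names(measurements))
    stop("'measurements' must carry a max_wall_thickness column")
  measurements[measurements$max_wall_thickness > threshold_mm, , drop = FALSE]
}
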