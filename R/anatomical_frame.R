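#' Latitude band on the femoral head
#'
#' The region of interest used for the femoral head fit is the band of
#' surface points whose latitude (elevation above the head's equatorial
#' plane, cranial positive) lies inside a closed interval. The default band,
#' +45 deg cranial to -10 deg caudal, excludes the fovea capitis at the
#' cranial pole and the head-neck junction caudally, both of which would
#' otherwise corrupt a sphericity-based fit.
#'
#' @param cranial_limit upper latitude bound in degrees (default +45).
#' @param caudal_limit lower latitude bound in degrees (default -10).
#' @return An object of class `latitude_band`.
#' @export
latitude_band <- function(cranial_limit = 45, caudal_limit = -10) {
  cranial_limit <- as.numeric(cranial_limit)
  caudal_limit <- as.numeric(caudal_limit)
  if (!is.finite(cranial_limit) || !is.finite(caudal_limit))
    abort_validation("band limits must be finite")
  if (caudal_limit >= cranial_limit)
    abort_validation("caudal_limit must be below cranial_limit")
  if (cranial_limit >= 90 || caudal_limit <= -90)
    abort_validation("band limits must lie strictly inside (-90, 90) degrees")
  structure(list(cranial_limit = cranial_limit, caudal_limit = caudal_limit),
            class = "latitude_band")
}

#' Initial temporary femoral head center
#'
#' The centroid (arithmetic mean) of the head-labeled points, used to seed
#' the neck reference frame and the iterative center search.
#'
#' @param head_points n x 3 matrix of head-region points (mm).
#' @return length-3 numeric center (mm).
#' @export
initial_center <- function(head_points) {
  p <- as_points(head_points, "head_points")
  if (nrow(p) < 50L)
    warning("fewer than 50 head points; centroid may be unstable",
            call. = FALSE)
  colMeans(p)
}

#' Femoral-neck reference frame
#'
#' The line from the femoral-neck cross-section center to the initial
#' temporary head center defines the neck reference axis; the plane through
#' the temporary center perpendicular to that axis is the equatorial plane.
#' Latitudes are measured against this frame. The frame is built once, from
#' the initial centroid, and held fixed while the center search runs.
#'
#' @param head_points n x 3 matrix of head points, or a precomputed centroid
#'   may be supplied via `temp_center`.
#' @param neck_center length-3 point: centroid of a "neck"-labeled region or
#'   the midpoint of two neck landmarks.
#' @param temp_center optional: bypass the centroid computation.
#' @return An object of class `anatomical_frame` with fields `temp_center`,
#'   `neck_center`, `neck_axis` (unit vector from neck toward head) and
#'   `equator_normal` (same vector).
#' @export
build_frame <- function(head_points, neck_center, temp_center = NULL) {
  temp_center <- if (is.null(temp_center)) initial_center(head_points)
                 else as_point3(temp_center, "temp_center")
  neck_center <- as_point3(neck_center, "neck_center")
  v <- temp_center - neck_center
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    abort_validation("neck_center coincides with the head centroid: degenerate frame")
  if (len < 5)
    warning(sprintf(paste0("neck_center is only %.2f mm from the head centroid; ",
                           "the neck axis may be unreliable"), len),
            call. = FALSE)
  structure(list(temp_center = temp_center, neck_center = neck_center,
                 neck_axis = v / len, equator_normal = v / len),
            class = "anatomical_frame")
}

#' Latitude of surface points
#'
#' Signed elevation in degrees of each point above the equatorial plane:
#' +90 at the cranial pole (along the neck axis, away from the neck), 0 on
#' the equatorial plane, negative toward the neck.
#'
#' @param points n x 3 matrix or a single length-3 point (mm).
#' @param frame an [build_frame()] result.
#' @return numeric vector of latitudes in degrees.
#' @export
latitude <- function(points, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  p <- as_points(points)
  v <- sweep(p, 2L, frame$temp_center)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12))
    abort_validation("point coincides with the temporary center: latitude undefined")
  as.numeric(asin(pmin(1, pmax(-1, (v %*% frame$neck_axis) / r)))) * 180 / pi
}

#' Extract the latitude-band region of interest
#'
#' Returns the subset of points whose latitude lies in the closed interval
#' `[caudal_limit, cranial_limit]`. Point order is preserved; the operation
#' is idempotent.
#'
#' @param head_points n x 3 matrix of head points (mm).
#' @param frame an [build_frame()] result.
#' @param band a [latitude_band()].
#' @return matrix of the retained points, with attribute `"index"` giving
#'   their row indices in `head_points`.
#' @export
extract_roi <- function(head_points, frame, band = latitude_band()) {
  stopifnot(inherits(band, "latitude_band"))
  p <- as_points(head_points, "head_points")
  lat <- latitude(p, frame)
  keep <- which(lat >= band$caudal_limit & lat <= band$cranial_limit)
  if (length(keep) == 0L)
    abort_computation("latitude-band ROI is empty: check labels, neck landmarks and band limits")
  out <- p[keep, , drop = FALSE]
  attr(out, "index") <- keep
  out
}
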