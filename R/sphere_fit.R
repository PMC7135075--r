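#' Search specification for the center search
#'
#' The center estimator hovers a temporary center inside a cubic search
#' range, evaluating candidate positions on a regular grid and moving to the
#' candidate with the smallest standard deviation of point-to-center
#' distances, re-centering the cube each round. Defaults follow the clinical
#' protocol: a +/- 5.0 mm range scanned in 0.1 mm increments.
#'
#' @param range half-width of the per-axis search cube, mm (default 5.0).
#' @param step grid increment, mm (default 0.1).
#' @param max_rounds maximum descent rounds across all resolutions
#'   (default 50).
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(range = 5.0, step = 0.1, max_rounds = 50L) {
  range <- as.numeric(range); step <- as.numeric(step)
  max_rounds <- as.integer(max_rounds)
  if (!is.finite(range) || !is.finite(step) || step <= 0 || step > range)
    abort_validation("search_spec requires 0 < step <= range")
  if (is.na(max_rounds) || max_rounds < 1L)
    abort_validation("max_rounds must be a positive integer")
  structure(list(range = range, step = step, max_rounds = max_rounds),
            class = "search_spec")
}

#' Radial distance statistics
#'
#' Mean and population standard deviation (divisor N) of the Euclidean
#' distances from each point to a candidate center. The population SD is the
#' objective minimized by the center search; the mean at the optimum is
#' reported as the radius of curvature.
#'
#' @param points n x 3 matrix (mm), n >= 2.
#' @param center length-3 candidate center (mm).
#' @return named numeric vector `c(mean =, sd =)`, mm.
#' @export
radial_stats <- function(points, center) {
  p <- as_points(points)
  if (nrow(p) < 2L) abort_validation("radial_stats requires at least 2 points")
  center <- as_point3(center, "center")
  out <- radial_stats_cpp(p, center)
  c(mean = out[1], sd = out[2])
}

#' SD-minimizing center search
#'
#' Iterative grid descent: each round evaluates candidate centers on a
#' step-spaced cubic lattice around the current center and moves to the
#' candidate minimizing the population SD of point-to-center distances; the
#' cube re-centers every round, so the walk can travel beyond the nominal
#' range. The search stops when the incumbent center is the minimizer of its
#' own cube (fixed point) or when `max_rounds` is exhausted. Ties are broken
#' deterministically: smallest displacement from the current center, then
#' lexicographic (x, y, z) offset order.
#'
#' With the default 0.1 mm step over a +/- 5 mm range a literal
#' single-resolution scan is costly, so a coarse-to-fine schedule (powers of
#' two times the target step, each a multiple of the final step so all
#' resolutions share one lattice) is used when the literal cube would exceed
#' ~50k candidates; on the well-conditioned objectives arising from
#' near-spherical surfaces it reaches the same fixed point, which the test
#' suite verifies against the literal scan.
#'
#' @param points n x 3 matrix of surface points (mm).
#' @param init length-3 initial center (mm).
#' @param spec a [search_spec()].
#' @param schedule `"auto"` (default), `"literal"` (single-resolution full
#'   cube every round) or `"coarse_to_fine"`.
#' @param asphericity_threshold mm; fits with SD strictly above it are
#'   flagged aspherical (default 1.0).
#' @return An object of class `sphere_fit`: `center`, `radius` (mean
#'   distance at the final center), `sd`, `n_points`, `rounds`, `converged`,
#'   `aspherical`.
#' @export
fit_center_min_sd <- function(points, init, spec = search_spec(),
                              schedule = c("auto", "literal", "coarse_to_fine"),
                              asphericity_threshold = 1.0) {
  schedule <- match.arg(schedule)
  p <- as_points(points)
  if (nrow(p) < 2L) abort_validation("need at least 2 points to fit a center")
  if (nrow(p) < 50L)
    warning("fewer than 50 points; the center fit may be poorly constrained",
            call. = FALSE)
  init <- as_point3(init, "init")
  stopifnot(inherits(spec, "search_spec"))

  full_half_n <- as.integer(round(spec$range / spec$step))
  if (schedule == "auto")
    schedule <- if ((2L * full_half_n + 1L)^3 <= 50000L) "literal"
                else "coarse_to_fine"

  stages <- if (schedule == "literal") {
    list(list(step = spec$step, half_n = full_half_n))
  } else {
    k <- 0L
    while (spec$step * 2^(k + 1L) <= spec$range / 4) k <- k + 1L
    lapply(rev(2^(0:k)), function(m) {
      s <- spec$step * m
      list(step = s, half_n = min(as.integer(round(spec$range / s)), 10L))
    })
  }

  center <- init
  rounds <- 0L
  converged <- FALSE
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    converged <- FALSE
    while (rounds < spec$max_rounds) {
      rounds <- rounds + 1L
      res <- cube_scan_cpp(p, center, st$step, st$half_n)
      if (all(res$offset == 0L)) { converged <- TRUE; break }
      center <- center + res$offset * st$step
    }
    if (!converged) break
  }
  if (!converged)
    warning(sprintf("center search did not converge within %d rounds",
                    spec$max_rounds), call. = FALSE)

  stats <- radial_stats_cpp(p, center)
  structure(list(center = center, radius = stats[1], sd = stats[2],
                 n_points = nrow(p), rounds = rounds, converged = converged,
                 aspherical = stats[2] > asphericity_threshold),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(paste0("<sphere_fit> center (%.3f, %.3f, %.3f) mm, ",
                     "radius %.3f mm, sd %.4f mm\n"),
              x$center[1], x$center[2], x$center[3], x$radius, x$sd))
  cat(sprintf("  n=%d, rounds=%d, converged=%s, aspherical=%s\n",
              x$n_points, x$rounds, x$converged, x$aspherical))
  invisible(x)
}

#' Asphericity rule
#'
#' A fitted head is labeled aspherical when the SD of point-to-center
#' distances at the definitive center strictly exceeds the threshold
#' (default 1.0 mm); such heads were excluded from the clinical evaluation
#' this method was developed for. The rule is strict: sd exactly at the
#' threshold is still spherical.
#'
#' @param fit a [sphere_fit] object (or anything with an `sd` field).
#' @param threshold mm, non-negative (default 1.0).
#' @return logical.
#' @export
classify_asphericity <- function(fit, threshold = 1.0) {
  threshold <- as.numeric(threshold)
  if (!is.finite(threshold) || threshold < 0)
    abort_validation("asphericity threshold must be non-negative")
  fit$sd > threshold
}

# Resolve the neck cross-section center from whatever the caller supplied:
# an explicit point, a pair of landmarks (midpoint), or a "neck" region.
resolve_neck_center <- function(model, neck_center = NULL,
                                neck_landmarks = NULL) {
  if (!is.null(neck_center)) return(as_point3(neck_center, "neck_center"))
  if (!is.null(neck_landmarks)) {
    lm <- as_points(neck_landmarks, "neck_landmarks")
    if (nrow(lm) != 2L)
      abort_validation("neck_landmarks must be exactly two points")
    return(colMeans(lm))
  }
  if ("neck" %in% names(model$labels))
    return(colMeans(region_points(model, "neck")))
  abort_validation("no neck information: supply neck_center, neck_landmarks, or a \"neck\" label")
}

#' Fit the femoral head
#'
#' Full femoral pipeline: centroid of the head region as the initial
#' temporary center, femoral-neck reference frame, latitude-band ROI
#' (default +45 to -10 deg, excluding fovea capitis and head-neck junction),
#' then the SD-minimizing center search on the ROI points. The mean distance
#' at the definitive center is the 3D femoral head radius of curvature; the
#' SD drives the asphericity flag.
#'
#' @param model a [surface_model()] with a `"head"` label and neck
#'   information (a `"neck"` label, or see `neck_center`/`neck_landmarks`).
#' @param neck_center optional explicit neck cross-section center (mm).
#' @param neck_landmarks optional 2 x 3 matrix; the midpoint is used.
#' @param spec a [search_spec()].
#' @param band a [latitude_band()].
#' @param asphericity_threshold mm (default 1.0).
#' @param use_roi set `FALSE` to fit on the whole head region (diagnostic;
#'   quantifies what the ROI buys).
#' @return a [sphere_fit] with extra fields `frame` (the
#'   [build_frame()] result) and `roi_index` (indices of the fitted points
#'   within the head region).
#' @export
fit_femoral_head <- function(model, neck_center = NULL, neck_landmarks = NULL,
                             spec = search_spec(), band = latitude_band(),
                             asphericity_threshold = 1.0, use_roi = TRUE) {
  stopifnot(inherits(model, "surface_model"))
  head_pts <- region_points(model, "head")
  nc <- resolve_neck_center(model, neck_center, neck_landmarks)
  frame <- build_frame(head_pts, nc)
  if (use_roi) {
    roi <- extract_roi(head_pts, frame, band)
    roi_index <- attr(roi, "index")
  } else {
    roi <- head_pts
    roi_index <- seq_len(nrow(head_pts))
  }
  fit <- fit_center_min_sd(roi, frame$temp_center, spec,
                           asphericity_threshold = asphericity_threshold)
  fit$frame <- frame
  fit$roi_index <- roi_index
  fit
}

#' Fit the acetabular lunate surface
#'
#' The definitive femoral head center seeds the acetabular search: the same
#' SD-minimizing descent is run on the lunate-surface points (fossa
#' acetabuli excluded upstream, at labeling time). The mean distance at the
#' optimum is the 3D acetabular radius of curvature. No asphericity
#' exclusion applies to the acetabulum, so the returned flag is always
#' `FALSE`.
#'
#' @param lunate_points n x 3 matrix of lunate-surface points (mm), or a
#'   [surface_model()] with a `"lunate"` label.
#' @param head_center length-3 definitive femoral head center (mm).
#' @param spec a [search_spec()].
#' @return a [sphere_fit].
#' @export
fit_acetabulum <- function(lunate_points, head_center, spec = search_spec()) {
  if (inherits(lunate_points, "surface_model"))
    lunate_points <- region_points(lunate_points, "lunate")
  fit <- fit_center_min_sd(lunate_points, as_point3(head_center, "head_center"),
                           spec, asphericity_threshold = Inf)
  fit$aspherical <- FALSE
  fit
}
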