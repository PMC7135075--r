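#' Axis convention for anatomical components
#'
#' Input coordinates are scanner axes of a supine, neutrally positioned
#' subject; a three-letter tag declares what each world axis means
#' anatomically, one letter per axis in x, y, z order, drawn from R/L
#' (patient right/left), A/P (anterior/posterior), S/I (superior/inferior),
#' covering all three pairs. The letter names the direction of increasing
#' coordinate, as in common medical-imaging orientation codes. The package
#' default is `"RAI"`: +x to the patient's right, +y anterior, +z inferior,
#' under which the reported (ML, PA, SI) components read off directly for a
#' right hip.
#'
#' @param tag three-letter orientation code, e.g. `"RAI"`, `"LPS"`.
#' @return 3 x 3 matrix `M` with rows (rightward, anterior, inferior) such
#'   that `M %*% v` expresses a world vector in those components.
#' @export
axis_convention <- function(tag = "RAI") {
  if (!is.character(tag) || length(tag) != 1L || nchar(tag) != 3L)
    abort_validation("axis convention must be a 3-letter code like \"RAI\"")
  letters3 <- strsplit(toupper(tag), "")[[1]]
  pair <- c(R = 1L, L = 1L, A = 2L, P = 2L, S = 3L, I = 3L)
  sgn  <- c(R = 1,  L = -1, A = 1,  P = -1, S = -1, I = 1)
  if (any(!letters3 %in% names(pair)) ||
      !setequal(pair[letters3], 1:3))
    abort_validation(sprintf("invalid axis convention \"%s\"", tag))
  M <- matrix(0, 3L, 3L,
              dimnames = list(c("rightward", "anterior", "inferior"), NULL))
  for (ax in 1:3) M[pair[[letters3[ax]]], ax] <- sgn[[letters3[ax]]]
  M
}

#' 3D curvature mismatch ratio
#'
#' Ratio of the 3D acetabular radius of curvature to the 3D femoral head
#' radius of curvature. In a perfectly congruent concentric joint the ratio
#' is close to unity (somewhat above 1 on bone surfaces, because cartilage
#' occupies the gap); it grows with dysplasia severity.
#'
#' @param ra acetabular radius of curvature, mm.
#' @param rf femoral head radius of curvature, mm.
#' @return dimensionless ratio `ra / rf`.
#' @export
mismatch_ratio <- function(ra, rf) {
  ra <- as.numeric(ra); rf <- as.numeric(rf)
  if (!all(is.finite(c(ra, rf))) || any(ra <= 0) || any(rf <= 0))
    abort_validation("radii must be positive and finite")
  ra / rf
}

#' 3D center discrepancy
#'
#' Distance and direction from the femoral head center to the acetabular
#' curvature center, the package's index of joint eccentricity. The
#' direction is reported as a unit vector in anatomical components —
#' mediolateral (+: lateral), posteroanterior (+: anterior), superoinferior
#' (+: inferior) — so left and right hips pool on the same axes: the
#' mediolateral sign is flipped for left hips, where lateral points the
#' other way in world coordinates.
#'
#' @param head_center length-3 femoral head center (mm, world frame).
#' @param acet_center length-3 acetabular curvature center (mm, world
#'   frame).
#' @param side `"left"` or `"right"`.
#' @param frame axis-convention tag, see [axis_convention()].
#' @return list with `cd_distance` (mm) and `cd_unit` (named ML/PA/SI unit
#'   vector, or `NULL` when the centers coincide and the direction is
#'   undefined).
#' @export
center_discrepancy <- function(head_center, acet_center, side,
                               frame = "RAI") {
  head_center <- as_point3(head_center, "head_center")
  acet_center <- as_point3(acet_center, "acet_center")
  side <- check_side(side)
  M <- axis_convention(frame)
  v <- acet_center - head_center
  d <- sqrt(sum(v^2))
  if (d == 0)
    return(list(cd_distance = 0, cd_unit = NULL))
  comp <- as.numeric(M %*% v)
  ml <- if (side == "right") comp[1] else -comp[1]
  u <- c(ml = ml, pa = comp[2], si = comp[3]) / d
  list(cd_distance = d, cd_unit = u)
}

#' Congruity indices for one hip
#'
#' Combines a femoral head fit and an acetabular fit into the two congruity
#' indices: the curvature mismatch ratio RA/RF and the center discrepancy
#' (distance plus ML/PA/SI direction unit vector).
#'
#' @param head_fit,acet_fit [sphere_fit] objects.
#' @param side `"left"` or `"right"`.
#' @param frame axis-convention tag.
#' @return An object of class `congruity_indices`.
#' @export
congruity_indices <- function(head_fit, acet_fit, side, frame = "RAI") {
  cd <- center_discrepancy(head_fit$center, acet_fit$center, side, frame)
  structure(list(mismatch_ratio = mismatch_ratio(acet_fit$radius,
                                                 head_fit$radius),
                 cd_distance = cd$cd_distance, cd_unit = cd$cd_unit,
                 side = check_side(side)),
            class = "congruity_indices")
}

#' @export
print.congruity_indices <- function(x, ...) {
  cat(sprintf("<congruity_indices> ratio %.2f (RA/RF), CD %.2f mm, side=%s\n",
              round_half_up(x$mismatch_ratio), x$cd_distance, x$side))
  if (!is.null(x$cd_unit))
    cat(sprintf("  direction (ML, PA, SI) = (%.2f, %.2f, %.2f)\n",
                x$cd_unit[1], x$cd_unit[2], x$cd_unit[3]))
  invisible(x)
}

#' Grade a Pearson correlation coefficient
#'
#' Conventional strength bins: |r| >= 0.7 very strong; 0.40-0.69 strong;
#' 0.30-0.39 moderate; 0.20-0.29 weak; otherwise negligible. The published
#' bins leave (0.69, 0.70) formally unassigned; "strong" is extended up to
#' (but excluding) 0.7 to close the gap. Signed grades carry a
#' positive/negative suffix; negligible does not.
#'
#' @param r Pearson correlation in `[-1, 1]` (vectorized).
#' @return character grade(s), e.g. `"strong positive"`, `"negligible"`.
#' @export
grade_correlation <- function(r) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(abs(r) > 1))
    abort_validation("correlation must lie in [-1, 1]")
  a <- abs(r)
  strength <- ifelse(a >= 0.7, "very strong",
              ifelse(a >= 0.40, "strong",
              ifelse(a >= 0.30, "moderate",
              ifelse(a >= 0.20, "weak", "negligible"))))
  suffix <- ifelse(r > 0, " positive", ifelse(r < 0, " negative", ""))
  ifelse(strength == "negligible", strength, paste0(strength, suffix))
}
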