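#' Camera calibration via the target's physical dimension
#'
#' For a fronto-parallel plane, a single scaling factor converts image
#' pixels to millimeters: the ratio of the target's physical length to its
#' length in the image.
#'
#' @param d_mm physical length of the tracked target, millimeters (> 0).
#' @param d_pixel the same length measured in image pixels (> 0).
#' @return A `camera_calibration` object with `sf` (mm/pixel) and
#'   `method = "target_dimension"`.
#' @examples
#' scaling_factor_from_target(25, 250)$sf  # 0.1 mm/px
#' @export
scaling_factor_from_target <- function(d_mm, d_pixel) {
  if (!is.numeric(d_mm) || !is.numeric(d_pixel) ||
      !is.finite(d_mm) || !is.finite(d_pixel) || d_mm <= 0 || d_pixel <= 0) {
    stop_scg("scg_domain_error",
             "target dimensions must be positive (got %s mm, %s px)",
             format(d_mm), format(d_pixel))
  }
  structure(
    list(sf = d_mm / d_pixel, method = "target_dimension",
         d_mm = d_mm, d_pixel = d_pixel),
    class = "camera_calibration"
  )
}

#' Camera calibration from pinhole intrinsics
#'
#' Uses the camera-to-object distance, the sensor unit length and the focal
#' length: `sf = d * p / f`, with `p` converted from micrometers to
#' millimeters internally.
#'
#' @param distance_d camera-to-object distance, millimeters (> 0).
#' @param unit_length_p sensor unit length, micrometers per pixel (> 0).
#' @param focal_f focal length, millimeters (> 0).
#' @return A `camera_calibration` object with `sf` (mm/pixel) and
#'   `method = "intrinsics"`.
#' @examples
#' scaling_factor_from_intrinsics(500, 2, 5)$sf  # 0.2 mm/px
#' @export
scaling_factor_from_intrinsics <- function(distance_d, unit_length_p, focal_f) {
  vals <- c(distance_d, unit_length_p, focal_f)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop_scg("scg_domain_error", "all intrinsic quantities must be positive")
  }
  structure(
    list(sf = distance_d * (unit_length_p * 1e-3) / focal_f,
         method = "intrinsics", distance_d = distance_d,
         unit_length_p = unit_length_p, focal_f = focal_f),
    class = "camera_calibration"
  )
}

#' @export
print.camera_calibration <- function(x, ...) {
  cat(sprintf("<camera_calibration> sf = %g mm/px (%s)\n", x$sf, x$method))
  invisible(x)
}

#' Convert a pixel trajectory to millimeters
#'
#' Multiplies both displacement axes by the scaling factor and flips the
#' unit flag. Applying a calibration twice is an error.
#'
#' @param traj a [track_sequence()] result with `units = "pixel"`.
#' @param cal a `camera_calibration`.
#' @return The trajectory with `ux`, `uy` in millimeters, `units = "mm"`.
#' @export
apply_calibration <- function(traj, cal) {
  stopifnot(inherits(traj, "displacement_trajectory"),
            inherits(cal, "camera_calibration"))
  if (!identical(traj$units, "pixel")) {
    stop_scg("scg_units_error",
             "trajectory is already in '%s'; calibration applies to pixel units",
             traj$units)
  }
  traj$ux <- traj$ux * cal$sf
  traj$uy <- traj$uy * cal$sf
  traj$units <- "mm"
  traj$sf <- cal$sf
  traj
}
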