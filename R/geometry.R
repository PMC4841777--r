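#' Nuclear volume from projected area
#'
#' Converts a nucleus's projected (maximum-projection) area to a volume by
#' treating the nucleus as a sphere whose circular cross-section has that
#' area.  Two variants are provided.  The default ("as-printed") form,
#' `V = 4/3 * (A/pi)^(3/2)`, omits a factor of pi relative to the true
#' sphere volume `V = 4/3 * pi * (A/pi)^(3/2)`.  Because downstream
#' concentrations are reported in arbitrary units and all comparisons are
#' relative, the constant cancels everywhere; both forms are kept so that
#' either convention can be reproduced exactly.
#'
#' @param area Projected nuclear area in square micrometres. Vectorised.
#' @param corrected If `FALSE` (default) use the pi-less as-printed form;
#'   if `TRUE` use the true sphere volume for a circular cross-section of
#'   the given area.
#' @return Nuclear volume(s) in cubic micrometres.
#' @seealso [nuclear_volume_from_diameter()] for the diameter-based form.
#' @examples
#' nuclear_volume_from_area(pi)                   # 4/3
#' nuclear_volume_from_area(pi, corrected = TRUE) # 4*pi/3, unit-radius sphere
#' @export
nuclear_volume_from_area <- function(area, corrected = FALSE) {
  if (any(!is.finite(area)) || any(area < 0)) {
    stop("'area' must be finite and non-negative", call. = FALSE)
  }
  v <- (4 / 3) * (area / pi)^1.5
  if (corrected) v <- v * pi
  v
}

#' Nuclear volume from diameter
#'
#' Sphere volume `V = pi * d^3 / 6` for a nucleus of measured diameter `d`,
#' as used when nuclei are marked by a nuclear-localised fluorescent
#' protein and their diameters read off maximum-projection images.
#'
#' @param d Nuclear diameter in micrometres. Vectorised.
#' @return Nuclear volume(s) in cubic micrometres.
#' @examples
#' nuclear_volume_from_diameter(2)  # unit-radius sphere, 4*pi/3
#' @export
nuclear_volume_from_diameter <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("'d' must be finite and non-negative", call. = FALSE)
  }
  pi * d^3 / 6
}

#' Cell volume from an ellipsoid approximation
#'
#' Cell volume `V = pi * a * b^2 / 6` for a cell approximated as a prolate
#' spheroid with major axis `a` and minor axis `b` measured on a mid-plane
#' image.  When `a == b` this reduces to the sphere volume of diameter `a`.
#'
#' @param a Major axis in micrometres. Vectorised.
#' @param b Minor axis in micrometres; must not exceed `a`.
#' @return Cell volume(s) in cubic micrometres.
#' @examples
#' cell_volume_ellipsoid(10, 6)  # 60 * pi
#' @export
cell_volume_ellipsoid <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a < 0) || any(b < 0)) {
    stop("axes must be finite and non-negative", call. = FALSE)
  }
  if (any(a < b)) {
    stop("major axis 'a' must be >= minor axis 'b'", call. = FALSE)
  }
  pi * a * b^2 / 6
}

#' Nucleocytoplasmic (N/C) volume ratio
#'
#' Total nuclear volume divided by cell volume.  For a multinucleate
#' (dividing) cell, `total_nuclear_volume` is the sum over all nuclei.
#'
#' @param total_nuclear_volume Summed nuclear volume, cubic micrometres.
#' @param cell_volume Cell volume, cubic micrometres; must be positive.
#' @return Dimensionless N/C ratio(s).
#' @export
nc_ratio <- function(total_nuclear_volume, cell_volume) {
  if (any(!is.finite(cell_volume)) || any(cell_volume <= 0)) {
    stop("'cell_volume' must be positive", call. = FALSE)
  }
  if (any(!is.finite(total_nuclear_volume)) || any(total_nuclear_volume < 0)) {
    stop("'total_nuclear_volume' must be non-negative", call. = FALSE)
  }
  total_nuclear_volume / cell_volume
}
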