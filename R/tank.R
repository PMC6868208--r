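#' Tank geometry
#'
#' Describes the experimental arena: a rectangular tank with coordinates in
#' centimetres, origin at one corner and axes along the walls. The defaults
#' are a 45 x 25 cm footprint filled to 20 cm, the standard novel-tank assay
#' arena used throughout this package.
#'
#' @param length_cm Tank length (x extent), cm.
#' @param width_cm Tank width (y extent), cm.
#' @param water_depth_cm Water depth (z extent), cm.
#'
#' @return An object of class `tank_geometry`: a named list with elements
#'   `length_cm`, `width_cm`, `water_depth_cm`.
#' @examples
#' tank_geometry()
#' tank_geometry(60, 30, 25)
#' @export
tank_geometry <- function(length_cm = 45, width_cm = 25, water_depth_cm = 20) {
  for (v in c(length_cm, width_cm, water_depth_cm)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort("all tank dimensions must be single, finite, strictly positive numbers")
    }
  }
  structure(
    list(length_cm = length_cm, width_cm = width_cm, water_depth_cm = water_depth_cm),
    class = "tank_geometry"
  )
}

#' @exportS3Method base::print
print.tank_geometry <- function(x, ...) {
  cat(sprintf(
    "<tank_geometry> %g x %g cm footprint, water depth %g cm\n",
    x$length_cm, x$width_cm, x$water_depth_cm
  ))
  invisible(x)
}

as_tank <- function(tank) {
  if (inherits(tank, "tank_geometry")) return(tank)
  if (is.numeric(tank) && length(tank) %in% 2:3) {
    return(tank_geometry(tank[[1]], tank[[2]],
                         if (length(tank) == 3) tank[[3]] else 20))
  }
  abort("`tank` must be a tank_geometry object or a numeric vector of dimensions")
}
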