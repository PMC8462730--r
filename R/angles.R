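# Angle conventions: directions are degrees on [0, 360) externally,
# radians only inside trig calls; prime/target distances live on [0, 180].

deg2rad <- function(x) x * pi / 180

#' Normalize a direction to the [0, 360) circle
#'
#' @param x Numeric vector of directions in degrees.
#' @return Numeric vector of the same length, wrapped onto `[0, 360)`.
#' @examples
#' wrap_direction(c(-15, 360, 405))
#' @export
wrap_direction <- function(x) {
  stopifnot(is.numeric(x))
  ((x %% 360) + 360) %% 360
}

#' Smallest angular distance between two directions
#'
#' The unsigned distance on the circle, reduced to `[0, 180]`. This is the
#' x-axis of a priming curve: the distance between the prime's drift
#' direction and the target's drift direction.
#'
#' @param a,b Numeric vectors of directions in degrees (recycled).
#' @return Numeric vector of distances in `[0, 180]`.
#' @examples
#' angular_distance(0, 180)
#' angular_distance(350, 10)
#' @export
angular_distance <- function(a, b) {
  d <- abs(wrap_direction(a) - wrap_direction(b))
  pmin(d, 360 - d)
}
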