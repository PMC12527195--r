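## Geomorphic metrics from cross-shore elevation profiles and tidal datums.

#' Tidal datums
#'
#' Vertical reference elevations in the site's datum (any consistent frame):
#' Mean Higher High Water, Mean Sea Level and Mean Lower Low Water.
#'
#' @param mhhw,msl,mllw Elevations in m, `mhhw > msl > mllw`.
#' @return List of class `tidal_datums`.
#' @export
tidal_datums <- function(mhhw, msl, mllw) {
  stopifnot(is.finite(mhhw), is.finite(msl), is.finite(mllw))
  if (!(mhhw > msl && msl > mllw))
    stop("datums must satisfy mhhw > msl > mllw")
  structure(list(mhhw = mhhw, msl = msl, mllw = mllw),
            class = "tidal_datums")
}

#' Cross-shore elevation profile
#'
#' Ordered (distance, elevation) points running seaward from the bluff or
#' armor toe (the landward-most analysis point) to below MLLW.
#'
#' @param distance Strictly increasing cross-shore distances, m.
#' @param elevation Elevations, m, same length.
#' @param toe_index Index of the toe point (default 1, the landward end).
#' @return List of class `elevation_profile`.
#' @export
elevation_profile <- function(distance, elevation, toe_index = 1L) {
  if (length(distance) < 2 || length(distance) != length(elevation))
    stop("profile needs >= 2 (distance, elevation) points")
  if (any(diff(distance) <= 0))
    stop("profile distances must be strictly increasing")
  if (toe_index < 1 || toe_index > length(distance))
    stop("toe_index outside profile")
  structure(list(distance = as.numeric(distance),
                 elevation = as.numeric(elevation),
                 toe_index = as.integer(toe_index)),
            class = "elevation_profile")
}

#' Relative encroachment of the bluff or armor toe
#'
#' Difference between MHHW and the toe elevation. Positive values mean the
#' toe sits below MHHW, encroaching into the intertidal; negative values mean
#' the beach continues above MHHW into supratidal habitat.
#'
#' @param toe_elevation Toe elevation, m, in the datum frame.
#' @param datums A [tidal_datums()] object.
#' @return Signed encroachment, m.
#' @examples
#' d <- tidal_datums(3.0, 2.0, 0.0)
#' relative_encroachment(2.73, d)  # toe 0.27 m below MHHW
#' @export
relative_encroachment <- function(toe_elevation, datums) {
  stopifnot(inherits(datums, "tidal_datums"))
  datums$mhhw - toe_elevation
}

## first seaward crossing of a datum elevation; returns interpolated distance
.first_crossing <- function(profile, level) {
  d <- profile$distance; e <- profile$elevation
  i0 <- profile$toe_index
  for (i in seq(i0, length(d) - 1L)) {
    e1 <- e[i]; e2 <- e[i + 1L]
    if ((e1 - level) == 0) return(d[i])
    if ((e1 - level) * (e2 - level) < 0 || e2 == level) {
      return(d[i] + (level - e1) / (e2 - e1) * (d[i + 1L] - d[i]))
    }
  }
  if (e[i0] == level) return(d[i0])
  NA_real_
}

#' Beach slope from toe to MSL
#'
#' Vertical drop from the toe to MSL divided by the horizontal distance to
#' the first seaward MSL crossing (linearly interpolated between bracketing
#' points). Reported as a positive magnitude for descending profiles.
#'
#' @param profile An [elevation_profile()].
#' @param datums A [tidal_datums()].
#' @return Slope, m/m.
#' @export
slope_toe_msl <- function(profile, datums) {
  stopifnot(inherits(profile, "elevation_profile"),
            inherits(datums, "tidal_datums"))
  toe_d <- profile$distance[profile$toe_index]
  toe_e <- profile$elevation[profile$toe_index]
  x <- .first_crossing(profile, datums$msl)
  if (is.na(x)) stop("profile does not cross MSL")
  run <- x - toe_d
  if (run <= 0) stop("MSL crossing not seaward of toe")
  abs(toe_e - datums$msl) / run
}

#' Beach width from toe to MLLW
#'
#' Horizontal distance from the toe to the first seaward MLLW crossing
#' (linearly interpolated). Zero if the toe itself sits at MLLW elevation.
#'
#' @inheritParams slope_toe_msl
#' @return Width, m.
#' @export
width_toe_mllw <- function(profile, datums) {
  stopifnot(inherits(profile, "elevation_profile"),
            inherits(datums, "tidal_datums"))
  x <- .first_crossing(profile, datums$mllw)
  if (is.na(x)) stop("profile does not cross MLLW")
  x - profile$distance[profile$toe_index]
}

#' All geomorphic metrics for one profile
#'
#' @inheritParams slope_toe_msl
#' @return List: `relative_encroachment`, `slope_toe_msl`, `width_toe_mllw`.
#' @export
geomorph_metrics <- function(profile, datums) {
  toe_e <- profile$elevation[profile$toe_index]
  list(relative_encroachment = relative_encroachment(toe_e, datums),
       slope_toe_msl = slope_toe_msl(profile, datums),
       width_toe_mllw = width_toe_mllw(profile, datums))
}
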