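# Planar projection of GPS fixes.

#' Project geographic coordinates to a local plane
#'
#' Equirectangular projection about the stream's median latitude/longitude,
#' in meters. Adequate at city scale (the daily movement ranges considered
#' here), and exactly invertible via [plane_to_geo()].
#'
#' @param points data.frame with `latitude`, `longitude` (decimal degrees)
#'   and any other columns (carried through).
#' @return The input with `x`, `y` columns (meters) added and the projection
#'   origin in attribute `origin` (`c(lat0, lon0)`).
#' @export
project_to_plane <- function(points) {
  if (nrow(points) == 0) stop("cannot project an empty stream")
  lat0 <- stats::median(points$latitude)
  lon0 <- stats::median(points$longitude)
  rad <- pi / 180
  points$x <- EARTH_R * cos(lat0 * rad) * (points$longitude - lon0) * rad
  points$y <- EARTH_R * (points$latitude - lat0) * rad
  attr(points, "origin") <- c(lat0 = lat0, lon0 = lon0)
  points
}

#' @rdname project_to_plane
#' @param planar data.frame with `x`, `y` columns (meters).
#' @param origin `c(lat0, lon0)` as recorded by [project_to_plane()].
#' @export
plane_to_geo <- function(planar, origin) {
  rad <- pi / 180
  planar$latitude <- origin[["lat0"]] + planar$y / (EARTH_R * rad)
  planar$longitude <- origin[["lon0"]] +
    planar$x / (EARTH_R * cos(origin[["lat0"]] * rad) * rad)
  planar
}
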