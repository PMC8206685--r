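#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectors
#'   recycle).
#' @param radius_km sphere radius; the default 6371 km is the Earth's mean
#'   radius.
#' @return distance(s) in km.
#' @examples
#' # Cairo (30 N, 31 E) to Addis Ababa
#' great_circle_distance(30, 31, 9.02, 38.75)
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude out of range [-180, 180]")
  }
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = radius_km * 1000) / 1000
}

#' Land-route distance through waypoints
#'
#' Sum of great-circle legs origin -> waypoint 1 -> ... -> destination, a
#' pragmatic stand-in for least-cost land routing when distances are used
#' only as a regression covariate. With no waypoints it reduces to the
#' great-circle distance.
#'
#' @param origin,dest numeric `c(lat, lon)` in decimal degrees.
#' @param waypoints matrix/data.frame with columns lat, lon (one row per
#'   waypoint, in travel order), or NULL.
#' @param radius_km sphere radius in km.
#' @return distance in km.
#' @export
land_route_distance <- function(origin, dest, waypoints = NULL,
                                radius_km = 6371) {
  pts <- rbind(matrix(origin, ncol = 2L),
               if (!is.null(waypoints)) as.matrix(waypoints)[, 1:2,
                                                             drop = FALSE],
               matrix(dest, ncol = 2L))
  legs <- great_circle_distance(pts[-nrow(pts), 1L], pts[-nrow(pts), 2L],
                                pts[-1L, 1L], pts[-1L, 2L],
                                radius_km = radius_km)
  sum(legs)
}

#' Default waypoint routes out of Africa
#'
#' A small documented routing table for land-only distances: all routes leave
#' Africa through the Levant; routes to the Americas additionally pass the
#' Bering land bridge. These are deliberately coarse -- the resulting
#' distances are an ordering covariate, not geodesy.
#'
#' @return named list of waypoint matrices (`lat`, `lon`).
#' @export
default_waypoints <- function() {
  list(
    levant = matrix(c(30.5, 34.9), ncol = 2,
                    dimnames = list(NULL, c("lat", "lon"))),
    bering = matrix(c(30.5, 34.9,   55, 60,   66, -169.5),
                    ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("lat", "lon"))))
}
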