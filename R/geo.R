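#' Geodesic distance between two points in metres
#'
#' Distance on the WGS84 ellipsoid between longitude/latitude pairs, as used
#' for all movement distances. Vectorised over rows when matrices are given.
#'
#' @param a,b Numeric vectors `c(lon, lat)` in decimal degrees, or two-column
#'   matrices of such points.
#' @return Distance(s) in metres.
#' @export
geodesic_distance_m <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (anyNA(a) || anyNA(b)) stop("NaN/NA coordinate in geodesic_distance_m")
  if (any(abs(a[, 2]) > 90) || any(abs(b[, 2]) > 90))
    stop("latitude out of range [-90, 90]")
  geosphere::distGeo(a, b)
}

#' Ellipsoidal area of a lon/lat polygon ring in square metres
#'
#' @param ring Two-column matrix of lon/lat vertices (closed or open ring).
#' @return Area in m^2.
#' @export
polygon_area_m2 <- function(ring) {
  ring <- close_ring(ring)
  abs(geosphere::areaPolygon(ring))
}

#' Centroid of a lon/lat polygon ring
#'
#' @param ring Two-column matrix of lon/lat vertices.
#' @return Length-2 vector `c(lon, lat)`.
#' @export
polygon_centroid <- function(ring) {
  ring <- close_ring(ring)
  as.numeric(geosphere::centroid(ring))
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || nrow(ring) < 3) stop("polygon ring needs >= 3 lon/lat vertices")
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

ring_is_valid <- function(ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  if (n < 3L) return(FALSE)
  if (anyNA(ring)) return(FALSE)
  # non-adjacent edge crossing test in the plane (adequate for small meadows)
  seg <- function(i) ring[c(i, i + 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (segments_intersect(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(s1, s2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(s2[1, ], s2[2, ], s1[1, ]); d2 <- d(s2[1, ], s2[2, ], s1[2, ])
  d3 <- d(s1[1, ], s1[2, ], s2[1, ]); d4 <- d(s1[1, ], s1[2, ], s2[2, ])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Test whether points fall inside a polygon ring
#'
#' @param pts Two-column matrix of lon/lat points.
#' @param ring Two-column matrix of lon/lat polygon vertices.
#' @return Logical vector.
#' @export
points_in_ring <- function(pts, ring) {
  ring <- close_ring(ring)
  pts <- rbind(pts)
  mgcv::in.out(ring, pts)
}

#' Distance from points to a polygon boundary in metres
#'
#' Geodesic distance from each point to the nearest location on the ring.
#' Zero is returned for points lying inside the ring.
#'
#' @param pts Two-column matrix of lon/lat points.
#' @param ring Polygon ring (lon/lat matrix).
#' @return Numeric vector of distances in metres (0 for interior points).
#' @export
distance_to_patch_m <- function(pts, ring) {
  ring <- close_ring(ring)
  pts <- rbind(pts)
  inside <- points_in_ring(pts, ring)
  out <- numeric(nrow(pts))
  if (any(!inside)) {
    d <- geosphere::dist2Line(pts[!inside, , drop = FALSE], ring)
    out[!inside] <- d[, "distance"]
  }
  out
}

# Local tangent-plane frame: metric x/y (m) <-> lon/lat, anchored at
# (lon0, lat0).  Equirectangular with per-degree scales measured on the
# ellipsoid at the anchor, so geodesic distances between frame points match
# metric distances to <0.1% over the few-km extent of a meadow study system.
local_frame <- function(lon0, lat0) {
  m_per_deg_lat <- geosphere::distGeo(c(lon0, lat0 - 0.05),
                                      c(lon0, lat0 + 0.05)) / 0.1
  m_per_deg_lon <- geosphere::distGeo(c(lon0 - 0.05, lat0),
                                      c(lon0 + 0.05, lat0)) / 0.1
  list(
    lon0 = lon0, lat0 = lat0,
    to_xy = function(lon, lat) {
      cbind(x = (lon - lon0) * m_per_deg_lon, y = (lat - lat0) * m_per_deg_lat)
    },
    to_lonlat = function(x, y) {
      cbind(lon = lon0 + x / m_per_deg_lon, lat = lat0 + y / m_per_deg_lat)
    }
  )
}
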