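# Planar-coordinate polygon utilities on the sphere. Polygons are stored as
# lists of rings; a ring is an n x 2 matrix of (lon, lat) in decimal degrees
# with straight edges in lon/lat space (the plate-carree model used by
# degree-grid vegetation maps). Areas integrate cos(lat) along those straight
# edges, which reduces to the spherical band formula on grid-aligned
# rectangles.

# Authalic Earth radius in km: the sphere with the ellipsoid's surface area.
.EARTH_RADIUS_KM <- 6371.0072

#' Spherical area of a lon/lat polygon ring
#'
#' Computes the signed surface area of a polygon whose edges are straight
#' lines in longitude/latitude space, by the closed-form line integral of
#' `cos(lat)` along each edge on a sphere of authalic radius 6371.0072 km.
#' Counter-clockwise rings are positive. For a grid-aligned rectangle this is
#' exactly `R^2 * dlon * (sin(lat_max) - sin(lat_min))`.
#'
#' @param ring numeric matrix with two columns (lon, lat) in degrees; the ring
#'   may be open or explicitly closed.
#' @return signed area in km^2.
#' @export
sphere_ring_area <- function(ring) {
  ring <- as.matrix(ring)
  if (nrow(ring) < 3) return(0)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  d2r <- pi / 180
  lam <- ring[, 1] * d2r
  phi <- ring[, 2] * d2r
  n <- length(lam) - 1
  dl <- lam[-1] - lam[-(n + 1)]
  p1 <- phi[-(n + 1)]
  p2 <- phi[-1]
  dp <- p2 - p1
  # edge integral of sin(phi) d lambda, linear phi(lambda)
  seg <- ifelse(abs(dp) < 1e-14,
                dl * sin(p1),
                dl * (cos(p1) - cos(p2)) / ifelse(dp == 0, 1, dp))
  # signed area = -R^2 * integral of sin(phi) d lambda; CCW positive
  -(.EARTH_RADIUS_KM^2) * sum(seg)
}

#' Spherical area of a lon/lat rectangle
#'
#' Closed-form band area `R^2 * dlon * (sin(lat_max) - sin(lat_min))` on the
#' authalic sphere.
#'
#' @param lon_min,lat_min,lon_max,lat_max rectangle bounds in degrees.
#' @return area in km^2.
#' @export
rect_area <- function(lon_min, lat_min, lon_max, lat_max) {
  d2r <- pi / 180
  .EARTH_RADIUS_KM^2 * (lon_max - lon_min) * d2r *
    (sin(lat_max * d2r) - sin(lat_min * d2r))
}

# Sutherland-Hodgman clip of a single ring against an axis-aligned rectangle.
# Returns an n x 2 matrix (possibly with 0 rows when the intersection is
# empty or degenerate).
clip_ring_rect <- function(ring, lon_min, lat_min, lon_max, lat_max) {
  ring <- as.matrix(ring)
  if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  inside <- list(
    function(p) p[1] >= lon_min, function(p) p[1] <= lon_max,
    function(p) p[2] >= lat_min, function(p) p[2] <= lat_max)
  cross <- list(
    function(p, q) { t <- (lon_min - p[1]) / (q[1] - p[1]); c(lon_min, p[2] + t * (q[2] - p[2])) },
    function(p, q) { t <- (lon_max - p[1]) / (q[1] - p[1]); c(lon_max, p[2] + t * (q[2] - p[2])) },
    function(p, q) { t <- (lat_min - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), lat_min) },
    function(p, q) { t <- (lat_max - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), lat_max) })
  pts <- lapply(seq_len(nrow(ring)), function(i) ring[i, ])
  for (e in 1:4) {
    if (length(pts) == 0) break
    out <- list()
    n <- length(pts)
    for (i in seq_len(n)) {
      p <- pts[[if (i == 1) n else i - 1]]
      q <- pts[[i]]
      pin <- inside[[e]](p); qin <- inside[[e]](q)
      if (qin) {
        if (!pin) out[[length(out) + 1]] <- cross[[e]](p, q)
        out[[length(out) + 1]] <- q
      } else if (pin) {
        out[[length(out) + 1]] <- cross[[e]](p, q)
      }
    }
    pts <- out
  }
  if (length(pts) < 3) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, pts)
}

# Area (km^2, non-negative) of polygon-with-holes clipped to a rectangle.
# `polygon` is a list of rings, first ring exterior, the rest holes.
clip_polygon_area <- function(polygon, lon_min, lat_min, lon_max, lat_max) {
  areas <- vapply(polygon, function(ring) {
    cl <- clip_ring_rect(ring, lon_min, lat_min, lon_max, lat_max)
    if (nrow(cl) < 3) 0 else abs(sphere_ring_area(cl))
  }, numeric(1))
  if (!length(areas)) return(0)
  max(areas[1] - sum(areas[-1]), 0)
}

#' Read polygon features from a GeoJSON file
#'
#' Parses a GeoJSON FeatureCollection (or bare Polygon/MultiPolygon geometry)
#' into a list of features, each `list(veg_type = <chr or NA>, polygons =
#' <list of polygons, each a list of rings>)`. Rings with repeated or fewer
#' than three distinct vertices are dropped (light-weight repair); an empty
#' feature is an error.
#'
#' @param path GeoJSON file path.
#' @param type_property property name holding the vegetation class label.
#' @return list of features.
#' @export
read_geojson_polygons <- function(path, type_property = "veg_type") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- if (identical(gj$type, "FeatureCollection")) {
    lapply(gj$features, function(f) list(geom = f$geometry, props = f$properties))
  } else if (identical(gj$type, "Feature")) {
    list(list(geom = gj$geometry, props = gj$properties))
  } else {
    list(list(geom = gj, props = NULL))
  }
  parse_ring <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    m[!duplicated(round(m, 12)) | seq_len(nrow(m)) == nrow(m), , drop = FALSE]
  }
  lapply(geoms, function(g) {
    ty <- g$geom$type
    polys <- if (identical(ty, "Polygon")) {
      list(lapply(g$geom$coordinates, parse_ring))
    } else if (identical(ty, "MultiPolygon")) {
      lapply(g$geom$coordinates, function(pp) lapply(pp, parse_ring))
    } else stop("unsupported geometry type: ", ty)
    polys <- lapply(polys, function(p) Filter(function(r) nrow(r) >= 3, p))
    polys <- Filter(length, polys)
    if (!length(polys)) stop("feature has no valid rings after repair")
    vt <- if (!is.null(g$props) && !is.null(g$props[[type_property]]))
      as.character(g$props[[type_property]]) else NA_character_
    list(veg_type = vt, polygons = polys)
  })
}

#' Per-cell zonal vegetation statistics
#'
#' For each fishnet cell computes: `geo_fraction`, the fraction of the cell's
#' spherical area inside the study region; `veg_fraction`, the fraction of the
#' in-region cell area covered by the vegetation layer (0 when the cell has no
#' in-region area); and `veg_type_count`, the number of distinct vegetation
#' classes intersecting the cell with positive area. Vegetation polygons are
#' assumed to lie within the study region and to be mutually non-overlapping
#' (a map partition), as in a classified vegetation-type map.
#'
#' @param cells data.frame from [build_fishnet()].
#' @param region feature list from [read_geojson_polygons()] (types ignored),
#'   the study-region polygon(s).
#' @param veg_layer feature list with `veg_type` labels, or `NULL` to skip
#'   vegetation statistics (fractions then equal `geo_fraction` context only).
#' @return data.frame `cell_id`, `geo_fraction`, `veg_fraction`,
#'   `veg_type_count`.
#' @export
zonal_vegetation <- function(cells, region, veg_layer = NULL) {
  res <- lapply(seq_len(nrow(cells)), function(i) {
    b <- cells[i, ]
    cell_a <- rect_area(b$lon_min, b$lat_min, b$lon_max, b$lat_max)
    reg_a <- sum(vapply(region, function(f)
      sum(vapply(f$polygons, clip_polygon_area,
                 numeric(1), b$lon_min, b$lat_min, b$lon_max, b$lat_max)),
      numeric(1)))
    reg_a <- min(reg_a, cell_a)
    geo_fraction <- reg_a / cell_a
    veg_a <- 0; types <- character(0)
    if (!is.null(veg_layer) && reg_a > 0) {
      for (f in veg_layer) {
        a <- sum(vapply(f$polygons, clip_polygon_area,
                        numeric(1), b$lon_min, b$lat_min, b$lon_max, b$lat_max))
        if (a > 1e-12 * cell_a) {
          veg_a <- veg_a + a
          types <- union(types, f$veg_type)
        }
      }
    }
    veg_fraction <- if (reg_a > 0) min(veg_a / reg_a, 1) else 0
    data.frame(cell_id = b$cell_id, geo_fraction = geo_fraction,
               veg_fraction = veg_fraction, veg_type_count = length(types),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a per-cell vegetation attribute table
#'
#' Alternative to polygon zonal statistics: a CSV with columns `cell_id`,
#' `veg_fraction`, `veg_type_count` (optionally `geo_fraction`) supplies the
#' vegetation information directly.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_veg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "veg_fraction", "veg_type_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("vegetation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"geo_fraction" %in% names(df)) df$geo_fraction <- NA_real_
  df[, c("cell_id", "geo_fraction", "veg_fraction", "veg_type_count")]
}
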