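# Utilization distribution from telemetry fixes: equal-area projection,
# bivariate normal kernel density, highest-density isopleth contours, and
# point-in-region queries.

#' Azimuthal equal-area projection specification
#'
#' @param lon0,lat0 projection centre (degrees).
#' @return object of class `laea_proj`.
#' @export
laea_proj <- function(lon0, lat0) {
  .assert(.is_number(lon0) && .is_number(lat0) && abs(lat0) <= 90,
          "invalid projection centre", "invalid_input")
  structure(list(lon0 = lon0, lat0 = lat0), class = "laea_proj")
}

.norm_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Project geographic coordinates to planar kilometres
#'
#' Lambert azimuthal equal-area projection on a spherical Earth, so that a
#' metric kernel bandwidth (in km) is meaningful. Errors if any point is more
#' than 90 degrees of arc from the projection centre.
#'
#' @param lon,lat coordinates in degrees.
#' @param proj a [laea_proj()].
#' @return matrix with columns `x`, `y` in km.
#' @export
laea_project <- function(lon, lat, proj) {
  .assert(all(abs(lat) <= 90), "latitude outside [-90, 90]", "invalid_input")
  lam <- (. <- pi / 180) * .norm_lon(lon)
  phi <- . * lat
  lam0 <- . * .norm_lon(proj$lon0)
  phi0 <- . * proj$lat0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  .assert(all(cosc > -1e-12), "points span more than a hemisphere",
          "invalid_input")
  k <- sqrt(2 / pmax(1e-12, 1 + cosc))
  cbind(x = .EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
        y = .EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) -
                                      sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' Back-project planar kilometres to geographic coordinates
#'
#' Inverse of [laea_project()].
#'
#' @param x,y planar coordinates in km.
#' @param proj a [laea_proj()].
#' @return matrix with columns `lon`, `lat` in degrees.
#' @export
laea_unproject <- function(x, y, proj) {
  rho <- sqrt(x^2 + y^2)
  lam0 <- (pi / 180) * .norm_lon(proj$lon0)
  phi0 <- (pi / 180) * proj$lat0
  cc <- 2 * asin(pmin(1, rho / (2 * .EARTH_RADIUS_KM)))
  lat <- lon <- numeric(length(x))
  at_centre <- rho < 1e-12
  lat[at_centre] <- proj$lat0
  lon[at_centre] <- .norm_lon(proj$lon0)
  if (any(!at_centre)) {
    r <- rho[!at_centre]
    c1 <- cc[!at_centre]
    lat[!at_centre] <- asin(cos(c1) * sin(phi0) +
                              y[!at_centre] * sin(c1) * cos(phi0) / r) * 180 / pi
    lon[!at_centre] <- .norm_lon((lam0 + atan2(
      x[!at_centre] * sin(c1),
      r * cos(phi0) * cos(c1) - y[!at_centre] * sin(phi0) * sin(c1))) * 180 / pi)
  }
  cbind(lon = lon, lat = lat)
}

#' Project a telemetry fix table
#'
#' @param fixes data frame with columns `lon` and `lat` (degrees); `lon` may
#'   be given in [-180, 360) and is normalized to [-180, 180).
#' @param proj optional [laea_proj()]; defaults to the fix centroid.
#' @return data frame with `x`, `y` (km) and the projection in the
#'   `"proj"` attribute.
#' @export
project_locations <- function(fixes, proj = NULL) {
  .assert(all(c("lon", "lat") %in% names(fixes)),
          "fixes need lon and lat columns", "schema_error")
  lon <- .norm_lon(fixes$lon)
  lat <- fixes$lat
  .assert(all(is.finite(lon)) && all(is.finite(lat)) && all(abs(lat) <= 90),
          "invalid coordinates", "invalid_input")
  if (is.null(proj)) proj <- laea_proj(mean(lon), mean(lat))
  xy <- laea_project(lon, lat, proj)
  out <- data.frame(x = xy[, "x"], y = xy[, "y"])
  attr(out, "proj") <- proj
  out
}

#' Bivariate normal kernel utilization distribution
#'
#' Evaluates the fixed-bandwidth Gaussian kernel density
#' \deqn{\hat f(x) = \frac{1}{n}\sum_i \frac{1}{2\pi h^2}
#'       e^{-\lVert x - x_i\rVert^2 / (2h^2)}}
#' on a regular grid padded by at least `pad` bandwidths around the fixes,
#' then normalizes the grid mass to 1. All fixes are pooled with equal
#' weight.
#'
#' @param points projected locations (data frame or matrix with x, y in km,
#'   e.g. from [project_locations()]).
#' @param bandwidth_km smoothing parameter h in km (default 250).
#' @param grid_res_km grid cell size in km (default `bandwidth_km / 10`, so
#'   discretization error is small relative to the smoothing).
#' @param pad grid padding in bandwidths (default 3).
#' @return object of class `seal_ud`: grid vectors `x`, `y`, matrices
#'   `density` (normalized to unit grid mass) and `density_raw` (the kernel
#'   formula before grid normalization, km^-2), `cell_area_km2`,
#'   `bandwidth_km`, `n`, and the projection (if carried by `points`).
#' @export
kernel_density <- function(points, bandwidth_km = 250,
                           grid_res_km = bandwidth_km / 10, pad = 3) {
  .assert(.is_number(bandwidth_km) && bandwidth_km > 0,
          "bandwidth must be positive")
  px <- points[["x"]] %||% points[, 1]
  py <- points[["y"]] %||% points[, 2]
  n <- length(px)
  .assert(n >= 5L, "need at least 5 points", "invalid_input")
  h <- bandwidth_km
  gx <- seq(min(px) - pad * h, max(px) + pad * h, by = grid_res_km)
  gy <- seq(min(py) - pad * h, max(py) + pad * h, by = grid_res_km)
  kx <- exp(-outer(gx, px, "-")^2 / (2 * h^2))
  ky <- exp(-outer(gy, py, "-")^2 / (2 * h^2))
  raw <- (kx %*% t(ky)) / (2 * pi * h^2 * n)
  cell <- grid_res_km^2
  structure(list(x = gx, y = gy,
                 density = raw / (sum(raw) * cell),
                 density_raw = raw,
                 cell_area_km2 = cell, bandwidth_km = h, n = n,
                 proj = attr(points, "proj")),
            class = "seal_ud")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Density threshold enclosing a probability mass
#'
#' Highest-density-region convention: cells are sorted by density and
#' accumulated until the requested mass is enclosed; the threshold is the
#' density of the last cell included.
#'
#' @param ud a `seal_ud`.
#' @param p probability mass in (0, 1).
#' @return density threshold (same units as `ud$density`).
#' @export
iso_level <- function(ud, p = 0.95) {
  .assert(.is_number(p) && p > 0 && p < 1, "p must be in (0, 1)")
  dens <- sort(as.vector(ud$density), decreasing = TRUE)
  mass <- cumsum(dens) * ud$cell_area_km2
  dens[which(mass >= p)[1]]
}

#' Isopleth region of a utilization distribution
#'
#' The smallest-threshold region whose enclosed grid mass reaches `p`,
#' returned as contour polygons in planar and (when a projection is
#' available) geographic coordinates, with its area.
#'
#' @param ud a `seal_ud`.
#' @param p probability mass (default 0.95).
#' @return object of class `ud_region`: `polygons` (list of data frames with
#'   x, y km), `polygons_lonlat`, `threshold`, `area_km2` (area of the
#'   enclosed grid cells), `mass` (grid mass actually enclosed), `p`, `proj`.
#' @export
contour_region <- function(ud, p = 0.95) {
  thr <- iso_level(ud, p)
  inside <- ud$density >= thr
  area <- sum(inside) * ud$cell_area_km2
  mass <- sum(ud$density[inside]) * ud$cell_area_km2
  lines <- contourLines(ud$x, ud$y, ud$density, levels = thr)
  polys <- lapply(lines, function(l) data.frame(x = l$x, y = l$y))
  polys_ll <- NULL
  if (!is.null(ud$proj)) {
    polys_ll <- lapply(polys, function(pp) {
      ll <- laea_unproject(pp$x, pp$y, ud$proj)
      data.frame(lon = ll[, "lon"], lat = ll[, "lat"])
    })
  }
  structure(list(polygons = polys, polygons_lonlat = polys_ll,
                 threshold = thr, area_km2 = area, mass = mass, p = p,
                 proj = ud$proj),
            class = "ud_region")
}

# even-odd point-in-polygon with boundary counted as inside
.point_in_poly <- function(px, py, poly, eps = 1e-9) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # on-segment check
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len2 <- dx * dx + dy * dy
    tt <- if (len2 > 0) ((px - x[i]) * dx + (py - y[i]) * dy) / len2 else 0
    tt <- min(1, max(0, tt))
    qx <- x[i] + tt * dx; qy <- y[i] + tt * dy
    if ((px - qx)^2 + (py - qy)^2 <= eps^2) return(TRUE)
    if ((y[i] > py) != (y[j] > py)) {
      xint <- (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Test whether geographic points fall inside a UD region
#'
#' Points are projected with the region's projection and tested against the
#' contour polygons (even-odd rule, boundary counts as inside).
#'
#' @param region a `ud_region` from [contour_region()].
#' @param lon,lat coordinates in degrees.
#' @return logical vector.
#' @export
region_contains <- function(region, lon, lat) {
  .assert(inherits(region, "ud_region"), "region must be a ud_region",
          "invalid_input")
  .assert(!is.null(region$proj), "region has no projection", "invalid_input")
  xy <- laea_project(lon, lat, region$proj)
  vapply(seq_len(nrow(xy)), function(i) {
    any(vapply(region$polygons, function(pp) {
      .point_in_poly(xy[i, 1], xy[i, 2], pp)
    }, logical(1)))
  }, logical(1))
}

#' Write a UD region to GeoJSON
#'
#' @param region a `ud_region` with geographic polygons.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path) {
  .assert(!is.null(region$polygons_lonlat), "region has no geographic polygons",
          "invalid_input")
  feats <- lapply(region$polygons_lonlat, function(pp) {
    ring <- cbind(pp$lon, pp$lat)
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(isopleth = region$p, threshold = region$threshold),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a UD region onto a lon/lat grid
#'
#' @param region a `ud_region`.
#' @param lon_grid,lat_grid cell-centre coordinate vectors (degrees).
#' @return logical matrix `length(lat_grid)` x `length(lon_grid)`.
#' @export
region_mask_grid <- function(region, lon_grid, lat_grid) {
  g <- expand.grid(lat = lat_grid, lon = lon_grid)
  matrix(region_contains(region, g$lon, g$lat),
         nrow = length(lat_grid), ncol = length(lon_grid))
}
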