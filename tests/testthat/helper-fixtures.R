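options(gridsuff.verbose = FALSE)

# Write a small occurrence CSV and return its path.
write_occ_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

occ_row <- function(q, lon, lat, sp, veg = NA_character_) {
  data.frame(quadrat_id = q, lon = lon, lat = lat, species = sp,
             vegetation_type = veg, stringsAsFactors = FALSE)
}

# Small synthetic scenario for fast unit tests (4 x 4 degree region,
# 16 fine / 4 coarse cells, modest pools).
small_lconf <- function(seed = 11) {
  landscape_config(region_bounds = c(70, 10, 74, 14), resolution = 1,
                   n_veg_types = 4, pool_size_range = c(30, 60),
                   shared_fraction = 0.3, seed = seed)
}

small_sconf <- function(seed = 12, quadrats = 20, bias = 0) {
  survey_config(quadrats_per_cell = quadrats, detection_per_quadrat = 8,
                accessibility_bias = bias, seed = seed)
}

# Independent brute-force oracle: exact mean accumulation over all orderings
# of exactly three quadrat sets (the 6 permutations written out by hand).
exhaustive_mean_3 <- function(sets) {
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  acc <- c(0, 0, 0)
  for (o in orders) {
    seen <- character(0)
    for (k in 1:3) {
      seen <- union(seen, sets[[o[k]]])
      acc[k] <- acc[k] + length(seen)
    }
  }
  acc / 6
}

# Independent dense logarithmic grid search for the Clench SSE minimum.
grid_search_sse <- function(x, y, n = 400) {
  a_grid <- exp(seq(log(max(min(y), 1e-3) / 50), log(max(y) * 20 + 10),
                    length.out = n))
  b_grid <- exp(seq(log(1e-6), log(10), length.out = n))
  sy <- sum(y^2)
  best <- Inf
  for (b in b_grid) {
    m <- x / (1 + b * x)
    c1 <- sum(m^2); c2 <- sum(m * y)
    sse <- a_grid^2 * c1 - 2 * a_grid * c2 + sy
    best <- min(best, min(sse))
  }
  best
}

# Independent spherical-area oracle: Riemann sum of R^2 cos(lat) over a fine
# lat subdivision of a lon/lat rectangle.
riemann_rect_area <- function(lon_min, lat_min, lon_max, lat_max, n = 20000) {
  R <- 6371.0072
  d2r <- pi / 180
  lat <- seq(lat_min, lat_max, length.out = n + 1)
  mid <- (lat[-1] + lat[-(n + 1)]) / 2
  sum(R^2 * cos(mid * d2r) * diff(lat * d2r)) * (lon_max - lon_min) * d2r
}
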