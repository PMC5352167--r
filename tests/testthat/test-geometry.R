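test_that("spherical rectangle area matches an independent Riemann sum", {
  for (b in list(c(70, 10, 71, 11), c(0, -1, 5, 3), c(88, 60, 92, 70))) {
    expect_equal(rect_area(b[1], b[2], b[3], b[4]),
                 riemann_rect_area(b[1], b[2], b[3], b[4]),
                 tolerance = 1e-7)
  }
  ring <- rbind(c(70, 10), c(71, 10), c(71, 11), c(70, 11))
  expect_equal(sphere_ring_area(ring), rect_area(70, 10, 71, 11),
               tolerance = 1e-12)
  expect_equal(sphere_ring_area(ring[4:1, ]), -rect_area(70, 10, 71, 11),
               tolerance = 1e-12)
})

feature <- function(ring, type = NA_character_) {
  list(veg_type = type, polygons = list(list(ring)))
}
rect_ring <- function(x0, y0, x1, y1)
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))

test_that("zonal statistics handle full, empty and split coverage", {
  cells <- build_fishnet(c(70, 10, 71, 11), 1)
  region_full <- list(feature(rect_ring(69, 9, 72, 12)))
  veg_one <- list(feature(rect_ring(69, 9, 72, 12), "forest"))
  z <- zonal_vegetation(cells, region_full, veg_one)
  expect_equal(c(z$geo_fraction, z$veg_fraction, z$veg_type_count), c(1, 1, 1))

  region_out <- list(feature(rect_ring(80, 9, 82, 12)))
  z0 <- zonal_vegetation(cells, region_out, veg_one)
  expect_equal(c(z0$geo_fraction, z0$veg_fraction, z0$veg_type_count), c(0, 0, 0))

  # region covers only the western half of the cell, fully vegetated, 2 types
  region_half <- list(feature(rect_ring(69, 9, 70.5, 12)))
  veg_two <- list(feature(rect_ring(69, 9, 70.25, 12), "forest"),
                  feature(rect_ring(70.25, 9, 70.5, 12), "scrub"))
  zh <- zonal_vegetation(cells, region_half, veg_two)
  expect_equal(zh$geo_fraction, 0.5, tolerance = 1e-9)
  expect_equal(zh$veg_fraction, 1.0, tolerance = 1e-9)
  expect_equal(zh$veg_type_count, 2)
})

test_that("vegetation fraction is independent of cell subdivision", {
  parent <- build_fishnet(c(70, 10, 72, 12), 2)
  children <- build_fishnet(c(70, 10, 72, 12), 1, origin = c(70, 10))
  region <- list(feature(rbind(c(69.5, 9.5), c(72.5, 10.2), c(71.8, 12.4),
                               c(69.8, 11.9))))
  veg <- list(feature(rbind(c(70.1, 10.1), c(71.9, 10.3), c(71.2, 11.8)),
                      "forest"))
  zp <- zonal_vegetation(parent, region, veg)
  zc <- zonal_vegetation(children, region, veg)
  area_p <- rect_area(70, 10, 72, 12)
  areas_c <- rect_area(children$lon_min, children$lat_min,
                       children$lon_max, children$lat_max)
  # area-weighted child fractions reproduce the parent value
  reg_c <- sum(zc$geo_fraction * areas_c)
  expect_equal(reg_c / area_p, zp$geo_fraction, tolerance = 1e-9)
  veg_c <- sum(zc$veg_fraction * zc$geo_fraction * areas_c)
  expect_equal(veg_c / reg_c, zp$veg_fraction, tolerance = 1e-9)
  expect_true(all(zc$geo_fraction >= 0 & zc$geo_fraction <= 1))
  expect_true(all(zc$veg_fraction >= 0 & zc$veg_fraction <= 1))
})

test_that("polygon clipping agrees with geosphere on a grid-aligned rectangle", {
  skip_if_not_installed("geosphere")
  # thin equatorial rectangle: plate-carree edges and great-circle edges
  # nearly coincide, so the two area models must agree closely
  ring <- rect_ring(10, -0.05, 10.2, 0.05)
  ours <- abs(sphere_ring_area(ring))
  gs <- geosphere::areaPolygon(ring, a = 6371007.2, f = 0) / 1e6
  expect_equal(ours, gs, tolerance = 1e-5)
})

test_that("per-cell vegetation tables substitute for polygon layers", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(cell_id = c("1_70_10", "1_71_10"),
                              veg_fraction = c(0.4, 0.02),
                              veg_type_count = c(5L, 1L)), p, row.names = FALSE)
  vt <- read_veg_table(p)
  expect_equal(vt$veg_fraction, c(0.4, 0.02))
  expect_true(all(is.na(vt$geo_fraction)))
  expect_error(read_veg_table(write_occ_csv(occ_row("q", 1, 1, "x"))),
               "missing column")
})
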