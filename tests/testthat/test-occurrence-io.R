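test_that("CSV records pass through with normalization applied", {
  p <- write_occ_csv(rbind(
    occ_row("q1", 75.1, 12.2, "Shorea robusta"),
    occ_row("q1", 75.1, 12.2, "Tectona grandis"),
    occ_row("q2", 75.6, 12.9, "Madhuca indica")))
  recs <- read_occurrences(p)
  expect_equal(nrow(recs), 3)
  expect_equal(attr(recs, "n_dropped"), 0)
  expect_equal(sort(unique(recs$species)),
               c("madhuca indica", "shorea robusta", "tectona grandis"))
})

test_that("whitespace and case variants of a name collapse to one species", {
  p <- write_occ_csv(rbind(
    occ_row("q1", 75, 12, "  Shorea  robusta "),
    occ_row("q1", 75, 12, "shorea robusta")))
  q <- aggregate_quadrats(read_occurrences(p))
  expect_equal(q$species[[1]], "shorea robusta")
  expect_equal(lengths(q$species), 1L)
})

test_that("rows with out-of-range or unparseable coordinates are rejected, rest kept", {
  p <- write_occ_csv(rbind(
    occ_row("q1", 75, 95, "a"),          # lat out of range
    occ_row("q2", "oops", 12, "b"),      # unparseable lon
    occ_row("q3", 75, 12, "c")))
  recs <- read_occurrences(p)
  expect_equal(recs$quadrat_id, "q3")
  expect_equal(attr(recs, "n_dropped"), 2)
})

test_that("a missing required column is a format error", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(quadrat_id = "q1", lon = 1, lat = 1), p,
                   row.names = FALSE)
  expect_error(read_occurrences(p), "missing required column")
})

test_that("aggregation unions species per quadrat and is order-independent", {
  recs <- rbind(occ_row("q1", 75, 12, "a"), occ_row("q1", 75, 12, "a"),
                occ_row("q1", 75, 12, "b"), occ_row("q2", 76, 13, "c"))
  q1 <- aggregate_quadrats(recs)
  expect_equal(q1$species[[which(q1$quadrat_id == "q1")]], c("a", "b"))
  set.seed(42)
  q2 <- aggregate_quadrats(recs[sample(nrow(recs)), ])
  expect_identical(q1, q2)
  expect_equal(nrow(aggregate_quadrats(recs[0, ])), 0)
})

test_that("conflicting coordinates within one quadrat id raise an error naming it", {
  recs <- rbind(occ_row("q9", 75, 12, "a"), occ_row("q9", 75.5, 12, "b"))
  expect_error(aggregate_quadrats(recs), "q9")
})

test_that("quadrat count equals the number of distinct ids at scale", {
  survey <- simulate_survey(simulate_landscape(small_lconf()), small_sconf())
  q <- aggregate_quadrats(survey$records)
  # independent one-pass scan over the raw records
  seen <- new.env()
  for (id in survey$records$quadrat_id) assign(id, TRUE, envir = seen)
  expect_equal(nrow(q), length(ls(seen)))
})

test_that("grid outputs round-trip through CSV and GeoJSON", {
  cells <- build_fishnet(c(70, 10, 72, 11), 1)
  results <- data.frame(
    cell_id = cells$cell_id, n_quadrats = c(7L, 0L),
    S_obs = c(31L, 0L), a = c(5.123456789012, NA), b = c(0.1, NA),
    asymptote = c(51.23456789012, NA), r2 = c(0.987654321, NA),
    ratio = c(0.605, NA), sufficient_q70 = c(FALSE, NA),
    n_q = c(23.3333333333333, NA), stringsAsFactors = FALSE)
  out <- tempfile()
  paths <- write_grid_outputs(cells, results, out)
  expect_equal(nrow(utils::read.csv(paths["csv"])), 2)
  back <- read_grid_geojson(paths["geojson"])
  expect_equal(nrow(back), 2)
  i <- match(cells$cell_id, back$cell_id)
  expect_equal(back$lon_min[i], cells$lon_min)
  # fitted reals survive to 12 significant digits; unfitted cells stay NA
  j <- which(back$cell_id[i] == results$cell_id[1])
  expect_equal(back$a[i][1], results$a[1], tolerance = 1e-12)
  expect_equal(back$n_q[i][1], results$n_q[1], tolerance = 1e-12)
  expect_true(is.na(back$a[i][2]))
  expect_false(any(back$asymptote[i][2] %in% 0))
})

test_that("GeoJSON point input reads like the CSV dialect", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(75.1, 12.2)),
         properties = list(quadrat_id = "q1", species = "Shorea robusta"))))
  p <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
  recs <- read_occurrences(p, format = "geojson")
  expect_equal(recs$lon, 75.1)
  expect_equal(recs$species, "shorea robusta")
})
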