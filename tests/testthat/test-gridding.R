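test_that("fishnets tile boxes at the requested resolution", {
  expect_equal(nrow(build_fishnet(c(68, 6, 98, 36), 1)), 900)
  expect_equal(nrow(build_fishnet(c(68, 6, 98, 36), 2)), 225)
  one <- build_fishnet(c(0, 0, 1, 1), 2)
  expect_equal(nrow(one), 1)
  expect_equal(unlist(one[, c("lon_min", "lat_min", "lon_max", "lat_max")],
                      use.names = FALSE), c(0, 0, 2, 2))
  expect_error(build_fishnet(c(10, 10, 5, 20), 1), "inverted")
})

test_that("cell edges lie on the origin lattice", {
  net <- build_fishnet(c(68.3, 6.7, 70.2, 8.1), 1, origin = c(68, 6))
  expect_true(all((net$lon_min - 68) %% 1 == 0))
  expect_true(all(net$lon_max - net$lon_min == 1))
})

test_that("quadrats join to cells under the half-open boundary rule", {
  cells <- build_fishnet(c(68, 6, 98, 36), 1, origin = c(68, 6))
  q <- data.frame(quadrat_id = c("edge", "inner"), lon = c(70.0, 70.5),
                  lat = c(10.0, 10.5), stringsAsFactors = FALSE)
  q$species <- list(c("a", "b"), c("b", "c"))
  a <- assign_quadrats(q, cells)
  expect_equal(sort(unique(a$assignment$cell_id)), "1_70_10")
  expect_equal(a$cells$S_obs[a$cells$cell_id == "1_70_10"], 3L)
  expect_equal(nrow(a$unassigned), 0)
})

test_that("every in-box quadrat is assigned exactly once (brute-force check)", {
  cells <- build_fishnet(c(70, 10, 75, 15), 1)
  set.seed(7)
  n <- 1000
  q <- data.frame(quadrat_id = sprintf("q%04d", 1:n),
                  lon = runif(n, 70, 75 - 1e-9),
                  lat = runif(n, 10, 15 - 1e-9), stringsAsFactors = FALSE)
  q$species <- replicate(n, "sp", simplify = FALSE)
  a <- assign_quadrats(q, cells)
  expect_equal(nrow(a$assignment) + nrow(a$unassigned), n)
  expect_equal(nrow(a$unassigned), 0)
  # brute force: count containing cells for every point
  hits <- vapply(seq_len(n), function(i) {
    sum(q$lon[i] >= cells$lon_min & q$lon[i] < cells$lon_max &
        q$lat[i] >= cells$lat_min & q$lat[i] < cells$lat_max)
  }, numeric(1))
  expect_true(all(hits == 1))
  expect_equal(sum(a$cells$n_quadrats), n)
})

test_that("out-of-extent quadrats are reported, not dropped", {
  cells <- build_fishnet(c(70, 10, 72, 12), 1)
  q <- data.frame(quadrat_id = c("in", "out"), lon = c(70.5, 80),
                  lat = c(10.5, 10.5), stringsAsFactors = FALSE)
  q$species <- list("a", "b")
  a <- assign_quadrats(q, cells)
  expect_equal(a$unassigned$quadrat_id, "out")
  expect_equal(nrow(a$assignment), 1)
})

test_that("fine cells nest in the coarse net sharing the origin", {
  fine <- build_fishnet(c(68, 6, 76, 14), 1, origin = c(68, 6))
  coarse <- build_fishnet(c(68, 6, 76, 14), 2, origin = c(68, 6))
  nested <- nest_cells(fine, coarse)
  expect_equal(nested$parent_id[nested$cell_id == "1_71_11"], "2_70_10")
  expect_true(all(table(nested$parent_id) == 4))
  shifted <- build_fishnet(c(68.5, 6.5, 76.5, 14.5), 1, origin = c(68.5, 6.5))
  expect_error(nest_cells(shifted, coarse), "origin")
  expect_error(nest_cells(fine, build_fishnet(c(68, 6, 76, 14), 1.5,
                                              origin = c(68, 6))),
               "integer multiple")
})

test_that("coarse richness is bounded by its children's union structure", {
  survey <- simulate_survey(simulate_landscape(small_lconf()), small_sconf())
  q <- aggregate_quadrats(survey$records)
  fine <- build_fishnet(c(70, 10, 74, 14), 1, origin = c(70, 10))
  coarse <- build_fishnet(c(70, 10, 74, 14), 2, origin = c(70, 10))
  af <- assign_quadrats(q, fine)
  ac <- assign_quadrats(q, coarse)
  nested <- nest_cells(af$cells, coarse)
  for (pid in unique(nested$parent_id)) {
    kids <- nested[nested$parent_id == pid, ]
    S_c <- ac$cells$S_obs[ac$cells$cell_id == pid]
    expect_gte(S_c, max(kids$S_obs))
    expect_lte(S_c, sum(kids$S_obs))
    # nesting conservation: coarse quadrat multiset = union over children
    expect_equal(ac$cells$n_quadrats[ac$cells$cell_id == pid],
                 sum(kids$n_quadrats))
  }
})
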