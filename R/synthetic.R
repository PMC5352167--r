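# Synthetic landscapes and quadrat surveys with known ground truth. The
# generator emulates the structure of a national quadrat database: a mosaic
# of vegetation types over a degree grid, each type carrying its own species
# pool with log-series abundances, surveyed by small fixed-area quadrats with
# optional accessibility bias that under-samples remote (high-elevation)
# cells.

#' Landscape generator configuration
#'
#' Defaults describe the package's reference scenario: an 8 x 8 degree region
#' gridded at 1 degree (64 cells, 16 at the nested 2-degree level), 8
#' vegetation types with per-type pools of 150-400 species of which 30% come
#' from a common regional pool, rank-abundances following a log-series shape,
#' per-cell vegetation fractions drawn from Beta(1.5, 2.5), and remote cells
#' defined as the top 20% of a synthetic elevation field that increases with
#' latitude.
#'
#' @param region_bounds `c(lon_min, lat_min, lon_max, lat_max)` degrees.
#' @param resolution fine fishnet resolution in degrees.
#' @param n_veg_types number of vegetation types in the mosaic.
#' @param pool_size_range `c(min, max)` species per type pool.
#' @param shared_fraction fraction of each type pool drawn from the common
#'   regional pool (controls pool overlap between types).
#' @param abundance_alpha log-series shape; rank-r relative abundance is
#'   proportional to `x^r / r` with `x = alpha / (alpha + 1)`.
#' @param veg_cover `c(shape1, shape2)` of the Beta distribution of per-cell
#'   vegetation fraction.
#' @param max_types_per_cell most vegetation types a single cell can hold.
#' @param occupancy_floor minimum share of a cell's candidate pool realised
#'   even at zero vegetation fraction; the realised share is
#'   `occupancy_floor + (1 - occupancy_floor) * veg_fraction`.
#' @param remote_quantile elevation quantile above which cells are "remote".
#' @param seed integer seed; identical configs give identical landscapes.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(region_bounds = c(70, 10, 78, 18),
                             resolution = 1,
                             n_veg_types = 8,
                             pool_size_range = c(150, 400),
                             shared_fraction = 0.3,
                             abundance_alpha = 20,
                             veg_cover = c(shape1 = 1.5, shape2 = 2.5),
                             max_types_per_cell = 4,
                             occupancy_floor = 0.3,
                             remote_quantile = 0.8,
                             seed = 1) {
  stopifnot(n_veg_types >= 1, all(pool_size_range > 0),
            shared_fraction >= 0, shared_fraction <= 1, abundance_alpha > 0)
  structure(as.list(environment()), class = "landscape_config")
}

#' Survey generator configuration
#'
#' @param quadrats_per_cell quadrats laid per cell (scalar, or named vector
#'   keyed by cell_id).
#' @param detection_per_quadrat expected species detected per quadrat; the
#'   realised count is Poisson-distributed (floored at 1, capped at the cell
#'   pool size) and species are drawn abundance-weighted without replacement
#'   within the quadrat.
#' @param accessibility_bias in `[0, 1]`: effort in remote cells is scaled by
#'   `1 - accessibility_bias` (1 = remote cells receive no quadrats).
#' @param seed integer seed.
#' @return a `survey_config` list.
#' @export
survey_config <- function(quadrats_per_cell = 50,
                          detection_per_quadrat = 12,
                          accessibility_bias = 0.6,
                          seed = 1) {
  stopifnot(all(quadrats_per_cell >= 0), detection_per_quadrat >= 1,
            accessibility_bias >= 0, accessibility_bias <= 1)
  structure(as.list(environment()), class = "survey_config")
}

# Log-series rank-abundance weights for a pool of size n.
logseries_weights <- function(n, alpha) {
  x <- alpha / (alpha + 1)
  r <- seq_len(n)
  w <- x^r / r
  w / sum(w)
}

#' Simulate a vegetation landscape with known species pools
#'
#' Builds the fishnet over the configured region, assembles per-type species
#' pools (partly shared through a common regional pool), assigns each cell
#' 1..`max_types_per_cell` types, a vegetation fraction and a synthetic
#' elevation, and realises the cell's species pool as an abundance-weighted
#' subsample of the union of its type pools, scaled by vegetation occupancy.
#' Deterministic for a fixed seed.
#'
#' @param config a [landscape_config()].
#' @return list of class `landscape`: `cells` (fishnet plus `veg_type_count`,
#'   `veg_fraction`, `elevation`, `remote`, `primary_type`, `S_true`),
#'   `pools` (named list cell_id -> data.frame `species`, `weight`),
#'   `veg_table` (per-cell vegetation CSV analogue) and the config.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  cells <- build_fishnet(config$region_bounds, config$resolution)
  with_seed(config$seed, {
    # per-type pools: shared slice from a common regional pool + own species
    common_n <- config$pool_size_range[2]
    common <- sprintf("common_%04d", seq_len(common_n))
    next_id <- 0
    type_pools <- lapply(seq_len(config$n_veg_types), function(t) {
      p <- if (config$pool_size_range[1] == config$pool_size_range[2])
        config$pool_size_range[1]
      else sample(config$pool_size_range[1]:config$pool_size_range[2], 1)
      n_sh <- round(config$shared_fraction * p)
      n_sh <- min(n_sh, common_n)
      own <- sprintf("type%02d_%04d", t, seq_len(p - n_sh))
      sp <- c(if (n_sh > 0) sample(common, n_sh) else character(0), own)
      sp <- sample(sp)  # random rank order for the abundance curve
      data.frame(species = sp,
                 weight = logseries_weights(length(sp), config$abundance_alpha),
                 stringsAsFactors = FALSE)
    })
    n <- nrow(cells)
    k_types <- sample(seq_len(min(config$max_types_per_cell, config$n_veg_types)),
                      n, replace = TRUE)
    veg_fraction <- stats::rbeta(n, config$veg_cover[1], config$veg_cover[2])
    lat_span <- config$region_bounds[4] - config$region_bounds[2]
    elevation <- 3000 * (cells$lat_min - config$region_bounds[2]) / lat_span +
      stats::rnorm(n, 0, 400)
    types_per_cell <- lapply(k_types, function(k)
      sample(config$n_veg_types, k))
    pools <- vector("list", n)
    for (i in seq_len(n)) {
      u <- do.call(rbind, type_pools[types_per_cell[[i]]])
      agg <- stats::aggregate(weight ~ species, data = u, FUN = sum)
      share <- config$occupancy_floor +
        (1 - config$occupancy_floor) * veg_fraction[i]
      n_keep <- max(5, min(nrow(agg), ceiling(nrow(agg) * share)))
      keep <- sample(nrow(agg), n_keep, prob = agg$weight)
      pool <- agg[sort(keep), , drop = FALSE]
      pool$weight <- pool$weight / sum(pool$weight)
      rownames(pool) <- NULL
      pools[[i]] <- pool
    }
    names(pools) <- cells$cell_id
    cells$veg_type_count <- k_types
    cells$veg_fraction <- veg_fraction
    cells$elevation <- elevation
    cells$remote <- elevation >
      stats::quantile(elevation, config$remote_quantile)
    cells$primary_type <- sprintf("type_%02d",
                                  vapply(types_per_cell, `[`, integer(1), 1))
    cells$S_true <- vapply(pools, nrow, integer(1))
  })
  veg_table <- data.frame(cell_id = cells$cell_id, geo_fraction = 1,
                          veg_fraction = cells$veg_fraction,
                          veg_type_count = cells$veg_type_count,
                          stringsAsFactors = FALSE)
  structure(list(cells = cells, pools = pools, veg_table = veg_table,
                 config = config), class = "landscape")
}

#' Simulate a quadrat survey of a landscape
#'
#' Lays quadrats uniformly at random within each cell (the vegetated area is
#' not resolved spatially below the cell), scales effort in remote cells by
#' `1 - accessibility_bias`, and fills each quadrat with a
#' Poisson-distributed number of species drawn abundance-weighted without
#' replacement from the cell's pool. Deterministic for a fixed seed.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param config a [survey_config()].
#' @return list of class `survey`: `records` (occurrence data.frame:
#'   `quadrat_id`, `lon`, `lat`, `species`, `vegetation_type`), `truth`
#'   (`cell_id`, `S_true`) and the config.
#' @export
simulate_survey <- function(landscape, config = survey_config()) {
  cells <- landscape$cells
  qpc <- config$quadrats_per_cell
  recs <- vector("list", nrow(cells))
  with_seed(config$seed, {
    for (i in seq_len(nrow(cells))) {
      cid <- cells$cell_id[i]
      n_i <- if (length(qpc) > 1) {
        if (is.null(names(qpc)) || !cid %in% names(qpc))
          stop("per-cell quadrat map missing cell ", cid)
        qpc[[cid]]
      } else qpc
      if (cells$remote[i]) n_i <- round(n_i * (1 - config$accessibility_bias))
      if (cells$veg_fraction[i] <= 0) n_i <- 0
      if (n_i <= 0) next
      pool <- landscape$pools[[cid]]
      lon <- stats::runif(n_i, cells$lon_min[i], cells$lon_max[i])
      lat <- stats::runif(n_i, cells$lat_min[i], cells$lat_max[i])
      k <- pmin(nrow(pool),
                pmax(1, stats::rpois(n_i, config$detection_per_quadrat)))
      qrec <- lapply(seq_len(n_i), function(j) {
        sp <- pool$species[sample.int(nrow(pool), k[j], prob = pool$weight)]
        data.frame(quadrat_id = sprintf("%s_q%04d", cid, j),
                   lon = lon[j], lat = lat[j], species = sp,
                   vegetation_type = cells$primary_type[i],
                   stringsAsFactors = FALSE)
      })
      recs[[i]] <- do.call(rbind, qrec)
    }
  })
  records <- do.call(rbind, recs)
  if (is.null(records))
    records <- data.frame(quadrat_id = character(), lon = numeric(),
                          lat = numeric(), species = character(),
                          vegetation_type = character())
  rownames(records) <- NULL
  structure(list(records = records,
                 truth = data.frame(cell_id = cells$cell_id,
                                    S_true = cells$S_true,
                                    stringsAsFactors = FALSE),
                 config = config), class = "survey")
}

#' Ground truth for a coarser nesting of a landscape
#'
#' True richness of each coarse cell: the size of the union of the species
#' pools of its fine constituent cells.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param coarse_resolution coarse cell size (integer multiple of the fine).
#' @return data.frame `cell_id`, `S_true` at the coarse resolution.
#' @export
coarse_ground_truth <- function(landscape, coarse_resolution) {
  fine <- landscape$cells
  coarse <- build_fishnet(landscape$config$region_bounds, coarse_resolution,
                          origin = c(min(fine$lon_min), min(fine$lat_min)))
  fine2 <- nest_cells(fine, coarse)
  sp_by_parent <- tapply(seq_len(nrow(fine2)), fine2$parent_id, function(ix)
    length(unique(unlist(lapply(landscape$pools[fine2$cell_id[ix]],
                                function(p) p$species)))))
  data.frame(cell_id = names(sp_by_parent),
             S_true = as.integer(sp_by_parent), stringsAsFactors = FALSE)
}

#' Effort-recovery experiment on synthetic data
#'
#' Runs the full pipeline (survey -> grid -> accumulate -> fit) on one
#' simulated landscape at a ladder of per-cell efforts and reports, per
#' effort, the mean sufficiency ratio and the mean relative error of the
#' Clench asymptote against the true per-cell pool size.
#'
#' @param efforts integer vector of quadrats per cell to test.
#' @param lconf,sconf generator configurations.
#' @param n_perm permutations per accumulation curve.
#' @param q_effort completeness target passed through to the assessment.
#' @return data.frame `effort`, `mean_ratio`, `mean_asymptote_rel_error`,
#'   `n_cells_fitted`.
#' @export
recovery_experiment <- function(efforts = c(10, 25, 50, 100),
                                lconf = landscape_config(),
                                sconf = survey_config(accessibility_bias = 0),
                                n_perm = 50, q_effort = 0.70) {
  landscape <- simulate_landscape(lconf)
  cells <- landscape$cells[, c("cell_id", "resolution", "lon_min", "lat_min",
                               "lon_max", "lat_max")]
  rows <- lapply(efforts, function(e) {
    sc <- sconf
    sc$quadrats_per_cell <- e
    sc$seed <- sconf$seed + e  # independent surveys per effort level
    survey <- simulate_survey(landscape, sc)
    quadrats <- aggregate_quadrats(survey$records)
    assigned <- assign_quadrats(quadrats, cells)
    res <- assess_sufficiency(assigned, veg = landscape$veg_table,
                              n_perm = n_perm, global_seed = sc$seed,
                              q_effort = q_effort)
    res <- merge(res, survey$truth, by = "cell_id")
    ok <- res$asymptotic %in% TRUE
    data.frame(effort = e,
               mean_ratio = mean(res$ratio[ok]),
               mean_asymptote_rel_error =
                 mean(abs(res$asymptote[ok] - res$S_true[ok]) / res$S_true[ok]),
               n_cells_fitted = sum(ok))
  })
  do.call(rbind, rows)
}

#' Scale-effect experiment: fine vs coarse sufficiency
#'
#' For each replicate, simulates the default scenario, analyses it at the
#' fine resolution and at a coarse resolution pooling its cells, and records
#' the proportion of analysed cells sufficiently sampled at threshold `q` at
#' each scale. Used to test the qualitative claim that sampling sufficiency
#' increases at coarser grids.
#'
#' @param n_rep number of seeded replicates.
#' @param base_seed seed of the first replicate (replicate r uses
#'   `base_seed + r - 1`).
#' @param coarse_factor coarse resolution as a multiple of the fine one.
#' @param q sufficiency threshold.
#' @param n_perm permutations per accumulation curve.
#' @param lconf,sconf generator configurations (seeds overridden per
#'   replicate).
#' @return data.frame `replicate`, `seed`, `prop_sufficient_fine`,
#'   `prop_sufficient_coarse`.
#' @export
scale_effect_experiment <- function(n_rep = 50, base_seed = 1,
                                    coarse_factor = 2, q = 0.70, n_perm = 50,
                                    lconf = landscape_config(),
                                    sconf = survey_config()) {
  rows <- lapply(seq_len(n_rep), function(r) {
    sd <- base_seed + r - 1
    lc <- lconf; lc$seed <- sd
    sc <- sconf; sc$seed <- sd + 1000003
    landscape <- simulate_landscape(lc)
    survey <- simulate_survey(landscape, sc)
    quadrats <- aggregate_quadrats(survey$records)
    fine_cells <- landscape$cells[, c("cell_id", "resolution", "lon_min",
                                      "lat_min", "lon_max", "lat_max")]
    origin <- c(min(fine_cells$lon_min), min(fine_cells$lat_min))
    coarse_cells <- build_fishnet(lc$region_bounds,
                                  lc$resolution * coarse_factor, origin)
    prop <- function(cells) {
      assigned <- assign_quadrats(quadrats, cells)
      res <- assess_sufficiency(assigned, veg = NULL, thresholds = q,
                                n_perm = n_perm, global_seed = sd)
      d <- res[!res$excluded_few_plots, , drop = FALSE]
      col <- sprintf("sufficient_q%02d", round(100 * q))
      mean(d[[col]] %in% TRUE)
    }
    data.frame(replicate = r, seed = sd,
               prop_sufficient_fine = prop(fine_cells),
               prop_sufficient_coarse = prop(coarse_cells))
  })
  do.call(rbind, rows)
}
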