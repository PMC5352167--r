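# Degree fishnets: regular lat/lon grids, quadrat-to-cell spatial join, and
# exact nesting of a fine net inside a coarser one sharing the same origin.

#' Build a degree fishnet over a bounding box
#'
#' Tiles the box with square cells of the given resolution whose edges lie at
#' `origin + k * resolution`. Cells are half-open, `[lon_min, lon_max) x
#' [lat_min, lat_max)`, so every interior point of the box belongs to exactly
#' one cell. The default origin floors the box corner to a whole multiple of
#' the resolution; pass a common origin explicitly when two resolutions must
#' nest.
#'
#' @param bounds numeric `c(lon_min, lat_min, lon_max, lat_max)` in degrees.
#' @param resolution cell size in degrees (> 0).
#' @param origin numeric `c(lon, lat)` grid origin, or `NULL` for the default.
#' @return data.frame with columns `cell_id` (`"res_lonmin_latmin"`),
#'   `resolution`, `lon_min`, `lat_min`, `lon_max`, `lat_max`.
#' @examples
#' nrow(build_fishnet(c(68, 6, 98, 36), 1))   # 900 cells
#' nrow(build_fishnet(c(68, 6, 98, 36), 2))   # 225 cells
#' @export
build_fishnet <- function(bounds, resolution, origin = NULL) {
  stopifnot(length(bounds) == 4, resolution > 0)
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    stop("inverted bounding box")
  if (is.null(origin)) origin <- resolution * floor(bounds[1:2] / resolution)
  if (!all(is.finite(origin))) stop("origin must be finite")
  kx0 <- floor((bounds[1] - origin[1]) / resolution)
  kx1 <- ceiling((bounds[3] - origin[1]) / resolution) - 1
  ky0 <- floor((bounds[2] - origin[2]) / resolution)
  ky1 <- ceiling((bounds[4] - origin[2]) / resolution) - 1
  g <- expand.grid(kx = kx0:kx1, ky = ky0:ky1)
  lon_min <- origin[1] + g$kx * resolution
  lat_min <- origin[2] + g$ky * resolution
  cells <- data.frame(
    cell_id = paste(fmt_coord(resolution), fmt_coord(lon_min),
                    fmt_coord(lat_min), sep = "_"),
    resolution = resolution,
    lon_min = lon_min, lat_min = lat_min,
    lon_max = lon_min + resolution, lat_max = lat_min + resolution,
    stringsAsFactors = FALSE)
  cells[order(cells$lat_min, cells$lon_min), ]
}

#' Spatially join quadrats to fishnet cells
#'
#' Assigns each quadrat to the unique cell whose half-open bounds contain its
#' location, and populates per-cell quadrat counts and observed richness
#' (`S_obs` = size of the species union over member quadrats). Quadrats
#' falling outside the fishnet extent are returned in an `unassigned` table,
#' never silently dropped.
#'
#' @param quadrats data.frame from [aggregate_quadrats()].
#' @param cells fishnet data.frame from [build_fishnet()] (one resolution).
#' @return list with `cells` (input plus `n_quadrats`, `S_obs`), `assignment`
#'   (data.frame `quadrat_id`, `cell_id`), `unassigned` (data.frame of
#'   quadrats outside the net), and `quadrat_sets` (named list: cell_id ->
#'   list of species sets of its member quadrats).
#' @export
assign_quadrats <- function(quadrats, cells) {
  stopifnot(length(unique(cells$resolution)) == 1)
  res <- cells$resolution[1]
  olon <- min(cells$lon_min); olat <- min(cells$lat_min)
  id <- paste(fmt_coord(res),
              fmt_coord(olon + res * floor((quadrats$lon - olon) / res)),
              fmt_coord(olat + res * floor((quadrats$lat - olat) / res)),
              sep = "_")
  hit <- id %in% cells$cell_id
  assignment <- data.frame(quadrat_id = quadrats$quadrat_id[hit],
                           cell_id = id[hit], stringsAsFactors = FALSE)
  unassigned <- quadrats[!hit, , drop = FALSE]
  if (nrow(unassigned) > 0)
    gs_log(nrow(unassigned), " quadrat(s) outside the fishnet extent")
  sets_by_cell <- split(quadrats$species[hit], assignment$cell_id)
  n_q <- integer(nrow(cells)); s_obs <- integer(nrow(cells))
  idx <- match(names(sets_by_cell), cells$cell_id)
  n_q[idx] <- lengths(sets_by_cell)
  s_obs[idx] <- vapply(sets_by_cell,
                       function(s) length(unique(unlist(s))), integer(1))
  cells$n_quadrats <- n_q
  cells$S_obs <- s_obs
  list(cells = cells, assignment = assignment, unassigned = unassigned,
       quadrat_sets = sets_by_cell)
}

#' Nest a fine fishnet inside a coarser one
#'
#' Sets each fine cell's `parent_id` to the unique coarse cell containing its
#' lower-left corner. The two nets must share an origin (every fine cell must
#' fall inside exactly one coarse cell) and the coarse resolution must be an
#' integer multiple of the fine one.
#'
#' @param fine,coarse fishnet data.frames from [build_fishnet()].
#' @return `fine` with a `parent_id` column added.
#' @export
nest_cells <- function(fine, coarse) {
  rf <- fine$resolution[1]; rc <- coarse$resolution[1]
  if (abs(rc / rf - round(rc / rf)) > 1e-9)
    stop("coarse resolution must be an integer multiple of the fine resolution")
  olon <- min(coarse$lon_min); olat <- min(coarse$lat_min)
  pid <- paste(fmt_coord(rc),
               fmt_coord(olon + rc * floor((fine$lon_min - olon) / rc)),
               fmt_coord(olat + rc * floor((fine$lat_min - olat) / rc)),
               sep = "_")
  inside <- pid %in% coarse$cell_id
  # a shifted origin leaves fine lower-left corners off the fine lattice
  # anchored at the coarse origin
  mis <- function(d, r) { m <- ((d %% r) + r) %% r; pmin(m, r - m) }
  if (any(mis(fine$lon_min - olon, rf) > 1e-9) ||
      any(mis(fine$lat_min - olat, rf) > 1e-9))
    stop("fishnet origins do not match; fine cells are not aligned to the coarse lattice")
  fine$parent_id <- ifelse(inside, pid, NA_character_)
  fine
}
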