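# Reading and writing the tabular and geospatial survey formats:
# occurrence CSV / GeoJSON points in, per-grid CSV + GeoJSON polygons out.

#' Read quadrat-level occurrence records
#'
#' Reads species occurrence records from a CSV file (columns `quadrat_id`,
#' `lon`, `lat`, `species`, optional `vegetation_type`) or a GeoJSON
#' FeatureCollection of points carrying the same properties. Species names are
#' normalized (trim, collapse whitespace, case-fold); rows with unparseable or
#' out-of-range coordinates (|lon| > 180, |lat| > 90) or empty species are
#' dropped and the drop count reported via a message and the `"n_dropped"`
#' attribute.
#'
#' @param path path to the input file.
#' @param format `"csv"` or `"geojson"`.
#' @return data.frame with columns `quadrat_id`, `lon`, `lat`, `species`,
#'   `vegetation_type` (NA when absent), one row per record, with attribute
#'   `n_dropped`.
#' @export
read_occurrences <- function(path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    need <- c("quadrat_id", "lon", "lat", "species")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
    if (!"vegetation_type" %in% names(raw)) raw$vegetation_type <- NA_character_
    df <- raw[, c("quadrat_id", "lon", "lat", "species", "vegetation_type")]
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("GeoJSON input must be a FeatureCollection")
    rows <- lapply(gj$features, function(f) {
      p <- f$properties
      if (is.null(p$quadrat_id) || is.null(p$species))
        stop("GeoJSON feature missing required property quadrat_id or species")
      cc <- f$geometry$coordinates
      data.frame(quadrat_id = as.character(p$quadrat_id),
                 lon = as.character(cc[[1]]), lat = as.character(cc[[2]]),
                 species = as.character(p$species),
                 vegetation_type = if (is.null(p$vegetation_type)) NA_character_
                                   else as.character(p$vegetation_type),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(quadrat_id = character(), lon = character(),
                                      lat = character(), species = character(),
                                      vegetation_type = character())
  }
  n0 <- nrow(df)
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  df$species <- normalize_species(df$species)
  keep <- is.finite(df$lon) & is.finite(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90 &
    nzchar(df$species) & nzchar(trimws(df$quadrat_id))
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  n_drop <- n0 - nrow(df)
  if (n_drop > 0) gs_log(n_drop, " malformed row(s) dropped while reading ", path)
  attr(df, "n_dropped") <- n_drop
  df
}

#' Aggregate occurrence records into quadrats
#'
#' Collapses validated occurrence records to one row per quadrat, holding the
#' deduplicated set of species observed there. All records of one quadrat must
#' share identical coordinates.
#'
#' @param records data.frame as returned by [read_occurrences()].
#' @return data.frame with columns `quadrat_id`, `lon`, `lat` and a list
#'   column `species` (character vector of distinct normalized names per
#'   quadrat), ordered by `quadrat_id`.
#' @export
aggregate_quadrats <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(quadrat_id = character(), lon = numeric(), lat = numeric(),
                      species = I(list())))
  sp <- split(records, records$quadrat_id)
  ids <- names(sp)
  lon <- vapply(sp, function(d) d$lon[1], numeric(1))
  lat <- vapply(sp, function(d) d$lat[1], numeric(1))
  bad <- vapply(sp, function(d)
    length(unique(d$lon)) > 1 || length(unique(d$lat)) > 1, logical(1))
  if (any(bad))
    stop("conflicting coordinates for quadrat id(s): ",
         paste(ids[bad], collapse = ", "))
  sets <- lapply(sp, function(d) sort(unique(d$species)))
  out <- data.frame(quadrat_id = ids, lon = unname(lon), lat = unname(lat),
                    stringsAsFactors = FALSE)
  out$species <- unname(sets)
  rownames(out) <- NULL
  out
}

#' Write per-grid analysis outputs
#'
#' Emits (i) a per-grid CSV with one row per cell (bounds, quadrat count,
#' observed richness, Clench fit parameters, sufficiency ratio, per-threshold
#' flags, effort estimates, vegetation statistics, priority score when
#' present) and (ii) a GeoJSON FeatureCollection of the cell polygons carrying
#' the same attributes. Cells without a fit carry `NA`/`null` fit fields, not
#' zeros.
#'
#' @param cells data.frame of grid cells (from [build_fishnet()], possibly
#'   augmented).
#' @param results data.frame of per-cell analysis rows keyed by `cell_id`.
#' @param out_dir output directory (created if needed).
#' @param stem file name stem; files are `<stem>.csv` and `<stem>.geojson`.
#' @return invisible character vector of the two paths written.
#' @export
write_grid_outputs <- function(cells, results, out_dir, stem = "grid") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  tab <- merge(cells, results, by = "cell_id", all.x = TRUE, sort = TRUE)
  tab <- tab[order(tab$cell_id), , drop = FALSE]
  drop_cols <- names(tab)[vapply(tab, is.list, logical(1))]
  tab <- tab[, setdiff(names(tab), drop_cols), drop = FALSE]
  csv_path <- file.path(out_dir, paste0(stem, ".csv"))
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   csv_path, row.names = FALSE, na = "")
  gj_path <- file.path(out_dir, paste0(stem, ".geojson"))
  write_cells_geojson(tab, gj_path)
  invisible(c(csv = csv_path, geojson = gj_path))
}

# Serialize a cells-with-attributes table to an RFC 7946 FeatureCollection
# (WGS84 lon/lat order, cell rectangles as Polygon rings).
write_cells_geojson <- function(tab, path) {
  feats <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, , drop = FALSE]
    ring <- list(
      c(r$lon_min, r$lat_min), c(r$lon_max, r$lat_min),
      c(r$lon_max, r$lat_max), c(r$lon_min, r$lat_max),
      c(r$lon_min, r$lat_min))
    props <- as.list(r[, setdiff(names(r), c("lon_min", "lat_min", "lon_max", "lat_max")),
                       drop = FALSE])
    props <- lapply(props, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       always_decimal = FALSE)
  invisible(path)
}

#' Read a per-cell grid attribute table back from GeoJSON
#'
#' Inverse of the GeoJSON side of [write_grid_outputs()]: reconstructs the
#' flat attribute table (including cell bounds recovered from the polygon
#' rings).
#'
#' @param path GeoJSON file written by [write_grid_outputs()].
#' @return data.frame of cell attributes.
#' @export
read_grid_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    props <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
    c(list(lon_min = min(xs), lat_min = min(ys),
           lon_max = max(xs), lat_max = max(ys)), props)
  })
  nm <- unique(unlist(lapply(rows, names)))
  cols <- lapply(nm, function(n)
    unlist(lapply(rows, function(r) if (is.null(r[[n]])) NA else r[[n]])))
  names(cols) <- nm
  as.data.frame(cols, stringsAsFactors = FALSE)
}
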