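# Resurvey prioritization of under-sampled grids: each criterion (vegetation
# heterogeneity = number of vegetation types; vegetation area) is rescaled to
# 0-100 by min-max normalization over the under-sampled cohort, then combined
# by a weighted sum (default 50/50).

#' Min-max score on the 0-100 scale
#'
#' `100 * (value - vmin) / (vmax - vmin)`, with the normalization bounds
#' taken over the cohort being ranked. When the cohort is degenerate
#' (`vmax == vmin`) every grid ties at the most-desired outcome, 100. A value
#' outside `[vmin, vmax]` is an error: bounds must come from the cohort.
#'
#' @param value raw criterion value(s).
#' @param vmin,vmax cohort minimum and maximum.
#' @return score(s) in `[0, 100]`.
#' @examples
#' minmax_score(13, 1, 13)  # 100
#' minmax_score(1, 1, 13)   # 0
#' @export
minmax_score <- function(value, vmin, vmax) {
  if (vmax < vmin) stop("vmax must be >= vmin")
  if (any(value < vmin - 1e-12) || any(value > vmax + 1e-12))
    stop("value outside the cohort normalization bounds [vmin, vmax]")
  if (vmax == vmin) return(rep(100, length(value)))
  100 * (value - vmin) / (vmax - vmin)
}

#' Weighted priority score
#'
#' Weighted sum of the two criterion scores; weights must be non-negative and
#' sum to 1.
#'
#' @param type_score 0-100 score for vegetation-type count (heterogeneity).
#' @param area_score 0-100 score for vegetation area.
#' @param weights numeric `c(w_type, w_area)`.
#' @return weighted score in `[0, 100]`.
#' @export
priority_score <- function(type_score, area_score, weights = c(0.5, 0.5)) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  weights[1] * type_score + weights[2] * area_score
}

#' Rank under-sampled grids for additional survey effort
#'
#' The cohort is every analysed grid that is insufficiently sampled at
#' threshold `q` (by its ratio alone, i.e. excluding-mode). Normalization
#' bounds for each criterion are taken over that cohort, scores combined by
#' the weighted sum, and grids ordered by descending score (ties broken by
#' `cell_id`), rank 1 = highest priority.
#'
#' @param results data.frame from [assess_sufficiency()] carrying
#'   `veg_type_count` and the area criterion column.
#' @param q sufficiency threshold defining "under-sampled".
#' @param weights `c(w_type, w_area)` criterion weights.
#' @param area_measure `"fraction"` to use `veg_fraction`, `"area"` to use an
#'   absolute `veg_area` column.
#' @return data.frame `cell_id`, `veg_type_count`, area value, `type_score`,
#'   `area_score`, `weighted`, `rank`, ordered by rank; zero rows when no
#'   grid is under-sampled.
#' @export
rank_undersampled <- function(results, q = 0.70, weights = c(0.5, 0.5),
                              area_measure = c("fraction", "area")) {
  area_measure <- match.arg(area_measure)
  area_col <- if (area_measure == "fraction") "veg_fraction" else "veg_area"
  col <- sprintf("sufficient_q%02d", round(100 * q))
  if (!col %in% names(results))
    stop("results carry no classification at threshold ", q)
  cohort <- results[!results$excluded_few_plots &
                      results[[col]] %in% FALSE, , drop = FALSE]
  cohort <- cohort[!is.na(cohort$veg_type_count) & !is.na(cohort[[area_col]]), ,
                   drop = FALSE]
  if (nrow(cohort) == 0)
    return(data.frame(cell_id = character(), veg_type_count = integer(),
                      area_value = numeric(), type_score = numeric(),
                      area_score = numeric(), weighted = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  tv <- cohort$veg_type_count
  av <- cohort[[area_col]]
  out <- data.frame(cell_id = cohort$cell_id, veg_type_count = tv,
                    area_value = av,
                    type_score = minmax_score(tv, min(tv), max(tv)),
                    area_score = minmax_score(av, min(av), max(av)),
                    stringsAsFactors = FALSE)
  out$weighted <- priority_score(out$type_score, out$area_score, weights)
  out <- out[order(-out$weighted, out$cell_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
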