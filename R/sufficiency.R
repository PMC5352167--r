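# Sampling sufficiency: the ratio of observed richness to the fitted Clench
# asymptote, classified against a ladder of thresholds (60-80%), plus the
# theoretical effort n_q = q / (b*(1-q)) required to record a fraction q of
# the predicted species list.

#' Sufficiency ratio of a grid cell
#'
#' `S_obs / (a/b)`, observed richness over the Clench asymptote. Values above
#' 1 (observed exceeding the predicted asymptote) are permitted and flagged
#' with a warning. Non-asymptotic fits have no defined ratio and yield `NA`.
#'
#' @param S_obs observed species richness.
#' @param fit a [fit_clench()] result.
#' @return the ratio, or `NA` when the fit is non-asymptotic.
#' @export
sufficiency_ratio <- function(S_obs, fit) {
  if (!isTRUE(fit$asymptotic)) return(NA_real_)
  r <- S_obs / fit$asymptote
  if (is.finite(r) && r > 1)
    gs_log("observed richness exceeds predicted asymptote (ratio ", round(r, 3),
           ")", level = "DEBUG")
  r
}

#' Classify a sufficiency ratio against thresholds
#'
#' A cell is sufficiently sampled at threshold `q` when `ratio >= q`
#' (boundary inclusive). Classification is monotone: sufficiency at `q`
#' implies sufficiency at every smaller threshold.
#'
#' @param ratio sufficiency ratio (may be `NA`).
#' @param thresholds numeric vector of `q` values in (0, 1).
#' @return named logical vector, `TRUE` = sufficient; all `NA` when the ratio
#'   is `NA`.
#' @export
classify_sufficiency <- function(ratio, thresholds = c(0.60, 0.65, 0.70, 0.75, 0.80)) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  out <- if (is.na(ratio)) rep(NA, length(thresholds)) else ratio >= thresholds
  names(out) <- sprintf("q%02d", round(100 * thresholds))
  out
}

#' Theoretical effort to reach a completeness fraction
#'
#' The number of quadrats at which the Clench curve reaches a fraction `q` of
#' its asymptote: `n_q = q / (b * (1 - q))`. By construction
#' `clench(n_q, a, b) = q * a/b` exactly.
#'
#' @param fit a [fit_clench()] result, or a list with element `b`.
#' @param q target completeness fraction in (0, 1).
#' @return effort in quadrats.
#' @examples
#' effort_required(list(b = 0.1, asymptotic = TRUE), 0.7)  # 23.333...
#' @export
effort_required <- function(fit, q = 0.70) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  b <- fit$b
  if (!is.finite(b) || b <= 0) stop("effort estimate requires b > 0")
  q / (b * (1 - q))
}

#' Assess sampling sufficiency for every cell of a gridded survey
#'
#' Runs accumulation curve -> Clench fit -> ratio -> threshold classification
#' -> effort estimate for each cell with at least `min_plots` quadrats; cells
#' below that are flagged `excluded_few_plots` and carry no fit. Cells whose
#' vegetation fraction falls below `veg_area_criterion` are flagged
#' `low_vegetation` (used by the including-mode summary). The per-cell random
#' seed is `cell_seed(global_seed, cell_id)` and is recorded in the output.
#'
#' @param assigned result of [assign_quadrats()].
#' @param veg data.frame `cell_id`, `veg_fraction`, `veg_type_count`
#'   (optionally `geo_fraction`), or `NULL`.
#' @param thresholds sufficiency threshold ladder.
#' @param q_effort completeness target for the effort estimate.
#' @param mode,n_perm,global_seed accumulation settings (see
#'   [accumulation_curve()]).
#' @param min_plots minimum quadrats for a fit (cells below are excluded).
#' @param veg_area_criterion vegetation fraction under which a cell is
#'   excused from the insufficiency count in including mode.
#' @param tol,max_iter,b_min fitter settings (see [fit_clench()]).
#' @return data.frame with one row per cell: identifiers, `n_quadrats`,
#'   `S_obs`, fit fields (`a`, `b`, `asymptote`, `r2`, `sse`, `converged`,
#'   `asymptotic`), `ratio`, one logical `sufficient_qNN` column per
#'   threshold, `n_q`, `n_additional` (`n_q - n_quadrats`), `seed`,
#'   vegetation fields and the two exclusion flags.
#' @export
assess_sufficiency <- function(assigned, veg = NULL,
                               thresholds = c(0.60, 0.65, 0.70, 0.75, 0.80),
                               q_effort = 0.70, mode = "permutation_mean",
                               n_perm = 100, global_seed = 1, min_plots = 5,
                               veg_area_criterion = 0.05,
                               tol = 1e-10, max_iter = 200, b_min = 1e-8) {
  cells <- assigned$cells
  sets <- assigned$quadrat_sets
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cid <- cells$cell_id[i]
    nq <- cells$n_quadrats[i]
    base <- data.frame(cell_id = cid, resolution = cells$resolution[i],
                       n_quadrats = nq, S_obs = cells$S_obs[i],
                       a = NA_real_, b = NA_real_, asymptote = NA_real_,
                       r2 = NA_real_, sse = NA_real_,
                       converged = NA, asymptotic = NA, ratio = NA_real_,
                       n_q = NA_real_, n_additional = NA_real_,
                       seed = NA_integer_,
                       excluded_few_plots = nq < min_plots,
                       stringsAsFactors = FALSE)
    cls <- classify_sufficiency(NA_real_, thresholds)
    if (nq >= min_plots) {
      sd <- cell_seed(global_seed, cid)
      curve <- accumulation_curve(sets[[cid]], mode = mode, n_perm = n_perm,
                                  seed = sd, cell_id = cid)
      fit <- suppressWarnings(
        fit_clench(curve, tol = tol, max_iter = max_iter, b_min = b_min))
      base$a <- fit$a; base$b <- fit$b; base$asymptote <- fit$asymptote
      base$r2 <- fit$r2; base$sse <- fit$sse
      base$converged <- fit$converged; base$asymptotic <- fit$asymptotic
      base$seed <- sd
      base$ratio <- sufficiency_ratio(cells$S_obs[i], fit)
      cls <- classify_sufficiency(base$ratio, thresholds)
      if (fit$asymptotic) {
        base$n_q <- effort_required(fit, q_effort)
        base$n_additional <- base$n_q - nq
      }
      gs_log("cell ", cid, ": n=", nq, " S_obs=", cells$S_obs[i],
             " ratio=", round(base$ratio, 3), level = "DEBUG")
    }
    for (nm in names(cls)) base[[paste0("sufficient_", nm)]] <- unname(cls[nm])
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(veg)) {
    out <- merge(out, veg, by = "cell_id", all.x = TRUE, sort = FALSE)
  } else {
    out$geo_fraction <- NA_real_
    out$veg_fraction <- NA_real_
    out$veg_type_count <- NA_integer_
  }
  out$low_vegetation <- !is.na(out$veg_fraction) &
    out$veg_fraction < veg_area_criterion
  out[order(out$cell_id), , drop = FALSE]
}

#' Threshold summary table of sufficiency counts
#'
#' For each threshold, counts sufficiently sampled grids in two reporting
#' modes. In `"excluding"` mode every analysed grid is counted by its ratio
#' alone. In `"including"` mode grids whose vegetation fraction is below the
#' low-vegetation criterion are counted as sufficient regardless of their
#' ratio (the rationale: almost no vegetated area means almost no species to
#' miss, so the apparent insufficiency is an artefact of area restriction).
#' Grids excluded for having too few quadrats are omitted from both counts
#' and from the denominator.
#'
#' @param results data.frame from [assess_sufficiency()], one resolution.
#' @param thresholds threshold ladder matching the classification columns.
#' @return data.frame `threshold`, `mode`, `n_sufficient`, `pct_sufficient`,
#'   `n_insufficient`, `n_total`.
#' @export
summarize_sufficiency <- function(results,
                                  thresholds = c(0.60, 0.65, 0.70, 0.75, 0.80)) {
  if (length(unique(results$resolution)) > 1)
    stop("summary requires results from a single fishnet resolution")
  d <- results[!results$excluded_few_plots, , drop = FALSE]
  n_total <- nrow(d)
  rows <- list()
  for (q in thresholds) {
    col <- sprintf("sufficient_q%02d", round(100 * q))
    if (!col %in% names(d)) stop("missing classification column: ", col)
    suff <- d[[col]] %in% TRUE
    for (mode in c("excluding", "including")) {
      s <- if (mode == "including") suff | d$low_vegetation else suff
      rows[[length(rows) + 1]] <- data.frame(
        threshold = q, mode = mode, n_sufficient = sum(s),
        pct_sufficient = if (n_total > 0) 100 * sum(s) / n_total else NA_real_,
        n_insufficient = n_total - sum(s), n_total = n_total,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
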