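# Sample-based species-accumulation curves: expected cumulative richness as
# quadrats are added to a grid cell, averaged over random orderings
# (sample-based rarefaction) or taken in a single fixed order.

#' Observed species richness of a set of quadrats
#'
#' @param quadrat_sets list of character vectors (species sets).
#' @return integer size of the union of all sets.
#' @examples
#' observed_richness(list(c("a", "b"), c("b", "c")))  # 3
#' @export
observed_richness <- function(quadrat_sets) {
  length(unique(unlist(quadrat_sets, use.names = FALSE)))
}

#' Build a species-accumulation curve
#'
#' For effort `k = 1..n` (quadrats pooled), computes the expected cumulative
#' species richness. Modes:
#' * `"permutation_mean"` — mean over `n_perm` seeded random orderings of the
#'   quadrats (sample-based rarefaction). The input list is first put into a
#'   canonical order (sorted by species signature) so the curve depends only
#'   on the multiset of quadrats, not their input order.
#' * `"observed_order"` — a single pass in the input order.
#' * `"exhaustive"` — exact mean over all `n!` orderings (n <= 8), the
#'   enumeration limit of the permutation mean.
#'
#' @param quadrat_sets list of character vectors; at least one non-empty.
#' @param mode one of `"permutation_mean"`, `"observed_order"`, `"exhaustive"`.
#' @param n_perm number of random orderings averaged (permutation mode).
#' @param seed integer seed for the orderings.
#' @param cell_id optional label carried on the result.
#' @return object of class `accumulation_curve`: list with `cell_id`, `x`
#'   (1..n), `S_mean`, `n_perm`, `seed`, `mode`.
#' @export
accumulation_curve <- function(quadrat_sets,
                               mode = c("permutation_mean", "observed_order",
                                        "exhaustive"),
                               n_perm = 100, seed = 1, cell_id = NA_character_) {
  mode <- match.arg(mode)
  n <- length(quadrat_sets)
  if (n == 0 || all(lengths(quadrat_sets) == 0))
    stop("accumulation requires at least one non-empty quadrat")
  sets <- lapply(quadrat_sets, function(s) unique(as.character(s)))
  cum_for_order <- function(ord) {
    v <- unlist(sets[ord], use.names = FALSE)
    ends <- cumsum(lengths(sets[ord]))
    cumsum(!duplicated(v))[pmax(ends, 1)]
  }
  if (mode == "observed_order") {
    S <- as.numeric(cum_for_order(seq_len(n)))
    np <- 1L
  } else if (mode == "exhaustive") {
    if (n > 8) stop("exhaustive enumeration limited to 8 quadrats")
    perms <- all_permutations(n)
    S <- Reduce(`+`, lapply(perms, cum_for_order)) / length(perms)
    np <- length(perms)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    # canonical order: curve depends only on the multiset of quadrats
    key <- vapply(sets, function(s) paste(sort(s), collapse = "\r"), character(1))
    sets <- sets[order(key)]
    acc <- numeric(n)
    with_seed(seed, {
      for (j in seq_len(n_perm)) acc <- acc + cum_for_order(sample.int(n))
    })
    S <- acc / n_perm
    np <- as.integer(n_perm)
  }
  structure(list(cell_id = cell_id, x = seq_len(n), S_mean = S,
                 n_perm = np, seed = as.integer(seed), mode = mode),
            class = "accumulation_curve")
}

# All permutations of 1..n as a list of integer vectors (n <= 8).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve%s: %d quadrats, S_obs = %g (%s%s)\n",
              if (is.na(x$cell_id)) "" else paste0(" [", x$cell_id, "]"),
              length(x$x), x$S_mean[length(x$S_mean)], x$mode,
              if (x$mode == "permutation_mean")
                sprintf(", %d permutations", x$n_perm) else ""))
  invisible(x)
}
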