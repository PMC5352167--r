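#' @keywords internal
"_PACKAGE"

# Simple stderr logger. Level filter set via option gridsuff.verbose
# (TRUE -> INFO messages shown; DEBUG only when gridsuff.debug = TRUE).
gs_log <- function(..., level = "INFO") {
  if (level == "DEBUG" && !isTRUE(getOption("gridsuff.debug", FALSE))) return(invisible())
  if (level == "INFO" && !isTRUE(getOption("gridsuff.verbose", TRUE))) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Normalize a species name
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds to lower case. Identity of a species is exact
#' string match after this normalization; no taxonomic synonym resolution is
#' attempted.
#'
#' @param x character vector of raw species names.
#' @return character vector of normalized names.
#' @examples
#' normalize_species(c("  Shorea  robusta ", "SHOREA ROBUSTA"))
#' @export
normalize_species <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Derive a per-cell random seed from a global seed
#'
#' Combines a global seed with a deterministic hash of the cell identifier by
#' bitwise XOR, so every cell gets an independent, reproducible random stream.
#' The result is always a non-negative integer below 2^31.
#'
#' @param global_seed integer global seed.
#' @param cell_id character cell identifier.
#' @return integer seed.
#' @export
cell_seed <- function(global_seed, cell_id) {
  h = 0
  for (cc in utf8ToInt(as.character(cell_id))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  bitwAnd(bitwXor(as.integer(global_seed), as.integer(h)), 2147483647L)
}

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Format a grid coordinate for use inside a cell_id: integers print without
# decimals, fractional resolutions keep up to 6 significant digits.
fmt_coord <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", as.integer(round(x))),
         sub("0+$", "", sprintf("%.6f", x)))
}
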