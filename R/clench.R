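# The Clench saturation model S(x) = a*x / (1 + b*x) fitted to accumulation
# curves by damped Gauss-Newton nonlinear least squares with an analytic
# Jacobian. a is the initial accumulation rate (species per quadrat), b the
# saturation parameter; a/b is the predicted asymptotic richness.

#' Clench model prediction
#'
#' Evaluates `S(x) = a*x / (1 + b*x)`, the two-parameter saturating
#' accumulation model: `a` is the slope at the origin and `a/b` the asymptote
#' approached as effort grows.
#'
#' @param x sampling effort (number of quadrats); vectorized.
#' @param a initial accumulation rate.
#' @param b saturation parameter.
#' @return predicted richness at each `x`.
#' @examples
#' clench(10, 5, 0.1)  # 25
#' @export
clench <- function(x, a, b) {
  denom <- 1 + b * x
  if (any(denom == 0)) stop("Clench model undefined at x = -1/b")
  a * x / denom
}

#' Starting values for the Clench fit
#'
#' `a0` is the curve's first point (a one-quadrat slope estimate, floored at
#' 1e-6) and `b0 = a0 / S_end`, so the starting asymptote `a0/b0` equals the
#' observed end-of-curve richness.
#'
#' @param curve an [accumulation_curve()].
#' @return named numeric `c(a = a0, b = b0)`.
#' @export
initial_params <- function(curve) {
  S <- curve$S_mean
  if (length(S) < 2) stop("curve must have at least 2 points")
  a0 <- max(S[1], 1e-6)
  b0 <- a0 / max(S[length(S)], 1e-6)
  c(a = a0, b = b0)
}

#' Fit the Clench model by damped Gauss-Newton
#'
#' Minimizes the sum of squared residuals of `S(x) = a*x/(1+b*x)` against the
#' accumulation curve, iterating Gauss-Newton steps with the analytic
#' Jacobian (`dS/da = x/(1+bx)`, `dS/db = -a*x^2/(1+bx)^2`) and step-halving
#' (up to 30 halvings) whenever a full step would increase the SSE.
#' Convergence is declared when the relative SSE change drops below `tol`.
#' Fits ending with `a <= 0` are marked not converged (a negative initial
#' slope is non-physical); fits with `b <= b_min` are marked non-asymptotic
#' and carry no asymptote (the curve is still effectively linear).
#'
#' @param curve an [accumulation_curve()] with at least 5 points (cells with
#'   fewer quadrats are excluded from analysis).
#' @param tol relative SSE convergence tolerance.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param b_min threshold below which the asymptote is deemed undefined.
#' @return object of class `clench_fit`: list with `cell_id`, `a`, `b`,
#'   `asymptote` (`a/b`, `NA` when non-asymptotic), `sse`, `r2`, `n_iter`,
#'   `converged`, `asymptotic`.
#' @export
fit_clench <- function(curve, tol = 1e-10, max_iter = 200, b_min = 1e-8) {
  stopifnot(tol > 0)
  x <- as.numeric(curve$x)
  y <- as.numeric(curve$S_mean)
  if (length(x) < 5) stop("Clench fit requires at least 5 curve points")
  th <- initial_params(curve)
  sse_at <- function(th) {
    d <- 1 + th[2] * x
    if (any(d <= 0)) return(Inf)
    sum((y - th[1] * x / d)^2)
  }
  sse <- sse_at(th)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d <- 1 + th[2] * x
    r <- y - th[1] * x / d
    J <- cbind(x / d, -th[1] * x^2 / d^2)
    delta <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    step <- 1
    new_th <- th + delta
    new_sse <- sse_at(new_th)
    h <- 0
    while (new_sse > sse && h < 30) {
      step <- step / 2
      h <- h + 1
      new_th <- th + step * delta
      new_sse <- sse_at(new_th)
    }
    if (new_sse > sse) break  # no SSE-reducing step exists
    rel <- (sse - new_sse) / max(sse, 1e-30)
    th <- new_th
    sse <- new_sse
    if (rel < tol) { converged <- TRUE; break }
  }
  if (iter == max_iter && !converged)
    warning("Clench fit reached max_iter without converging; ",
            "best-so-far parameters returned")
  a <- unname(th[1]); b <- unname(th[2])
  if (a <= 0) converged <- FALSE
  asymptotic <- is.finite(b) && b > b_min && a > 0
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  structure(list(cell_id = curve$cell_id, a = a, b = b,
                 asymptote = if (asymptotic) a / b else NA_real_,
                 sse = sse, r2 = r2, n_iter = iter,
                 converged = converged, asymptotic = asymptotic),
            class = "clench_fit")
}

#' Goodness of fit of a Clench fit
#'
#' Coefficient of determination `r2 = 1 - SSE/SST` (SST about the curve mean)
#' and the SSE, recomputed against the curve. A zero-variance curve has no
#' defined `r2` and yields `NA`.
#'
#' @param fit a [fit_clench()] result.
#' @param curve the curve the fit was produced from.
#' @return named numeric `c(r2 = ..., sse = ...)`.
#' @export
goodness_of_fit <- function(fit, curve) {
  y <- as.numeric(curve$S_mean)
  pred <- clench(as.numeric(curve$x), fit$a, fit$b)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  c(r2 = if (sst > 0) 1 - sse / sst else NA_real_, sse = sse)
}

#' @export
print.clench_fit <- function(x, ...) {
  cat(sprintf(
    "Clench fit%s: a = %.4g, b = %.4g, asymptote = %s, r2 = %.4f (%s)\n",
    if (is.na(x$cell_id)) "" else paste0(" [", x$cell_id, "]"),
    x$a, x$b,
    if (x$asymptotic) sprintf("%.4g", x$asymptote) else "undefined",
    x$r2,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
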