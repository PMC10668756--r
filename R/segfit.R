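# One-breakpoint segmented (broken-line) linear regression,
#   y = b0 + b1 * x + b2 * (x - psi)_+ ,
# fitted by iterative linearization: the working linear model is augmented
# with the breakpoint derivative covariate V = -(x > psi) whose
# coefficient, scaled by b2, is the Newton update for psi (Muggeo's
# method). Initialization picks the best SSE on a coarse psi grid.

#' Fit a one-breakpoint segmented linear regression
#'
#' Models a continuous piecewise-linear relationship with a single
#' changepoint `psi`: slope `b1` left of `psi` and `b1 + b2` to its right.
#' Standard errors for both slopes are Wald intervals from the final
#' working linear model; the adjusted R-squared counts four estimated
#' parameters (intercept, two slope parameters, and the breakpoint).
#'
#' @param x,y numeric vectors (n >= 6; x must take at least 3 distinct
#'   values on each side of any admissible breakpoint).
#' @param psi_init optional starting breakpoint; by default the best of a
#'   50-point grid across the interior 10-90% quantile range of `x`.
#' @param tol convergence tolerance on the breakpoint update.
#' @param max_iter iteration cap.
#' @param conf_level confidence level for the slope intervals.
#' @return Object of class `segfit` with components `coefficients`
#'   (`b0`, `b1`, `b2`), `psi`, `slope1`, `slope2`, `ci_slope1`,
#'   `ci_slope2`, `r_squared`, `adj_r_squared`, `sigma`, `residuals`,
#'   `fitted.values`, `converged`, `iterations`, `psi_constrained`, `n`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
#'   `fitted`, `simulate`.
#' @examples
#' fem <- load_female_table()
#' fit <- fit_segmented(fem$storage_time, fem$viability)
#' coef(fit)       # breakpoint near 4.2 months
#' summary(fit)
#' @export
fit_segmented <- function(x, y, psi_init = NULL, tol = 1e-8, max_iter = 50L,
                          conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 6) stop("need at least 6 observations")
  ux <- sort(unique(x))
  if (length(ux) < 4) stop("x must take at least 4 distinct values")
  lo <- ux[2]; hi <- ux[length(ux) - 1]   # psi must keep points on both sides
  if (is.null(psi_init)) {
    grid <- unique(stats::quantile(x, seq(0.1, 0.9, length.out = 50),
                                   names = FALSE, type = 7))
    grid <- grid[grid > min(x) & grid < max(x)]
    sse <- vapply(grid, function(p) seg_sse(x, y, p), 0)
    # the SSE profile can be multimodal with near-tied basins when x has
    # gaps; iterate from every coarse local minimum and keep the best
    ng <- length(sse)
    local_min <- which(sse <= c(Inf, sse[-ng]) & sse <= c(sse[-1], Inf))
    starts <- grid[local_min[order(sse[local_min])]]
    starts <- utils::head(starts, 4L)
  } else {
    starts <- psi_init
  }
  best <- NULL
  for (s in starts) {
    res <- seg_iterate(x, y, s, lo, hi, tol, max_iter)
    if (is.null(best) ||
        (res$converged && !best$converged) ||
        (res$converged == best$converged && res$sse < best$sse - 1e-12)) {
      best <- res
    }
  }
  if (!best$converged) {
    cond <- errorCondition(
      sprintf("breakpoint estimation did not converge in %d iterations (last psi = %.6g)",
              max_iter, best$psi),
      class = c("cometseg_convergence_error", "cometseg_error"))
    cond$psi <- best$psi
    stop(cond)
  }
  psi <- best$psi
  converged <- best$converged
  constrained <- best$constrained
  iter <- best$iterations
  U <- pmax(x - psi, 0)
  fm <- stats::lm(y ~ x + U)
  b <- stats::coef(fm)
  V <- -(x > psi)
  wm <- stats::lm(y ~ x + U + V)  # working model at the solution, for SEs
  vc <- stats::vcov(wm)
  se1 <- sqrt(vc["x", "x"])
  se2 <- sqrt(vc["x", "x"] + vc["U", "U"] + 2 * vc["x", "U"])
  df <- n - 4L                     # b0, b1, b2 and psi are all estimated
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  rss <- sum(stats::resid(fm)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  fit <- structure(list(
    coefficients = c(b0 = unname(b[1]), b1 = unname(b[["x"]]), b2 = unname(b[["U"]])),
    psi = unname(psi),
    slope1 = unname(b[["x"]]),
    slope2 = unname(b[["x"]] + b[["U"]]),
    ci_slope1 = unname(b[["x"]] + c(-1, 1) * tq * se1),
    ci_slope2 = unname(b[["x"]] + b[["U"]] + c(-1, 1) * tq * se2),
    se_slope1 = se1, se_slope2 = se2,
    conf_level = conf_level,
    r_squared = r2,
    adj_r_squared = 1 - (rss / df) / (tss / (n - 1)),
    sigma = sqrt(rss / df),
    residuals = unname(stats::resid(fm)),
    fitted.values = unname(stats::fitted(fm)),
    converged = converged, iterations = iter,
    psi_constrained = constrained,
    n = n, x = x, y = y, call = match.call()
  ), class = "segfit")
  fit
}

seg_sse <- function(x, y, psi) {
  sum(stats::.lm.fit(cbind(1, x, pmax(x - psi, 0)), y)$residuals^2)
}

# Muggeo update loop from one starting breakpoint, with step-halving so no
# update ever increases the SSE profile
seg_iterate <- function(x, y, psi, lo, hi, tol, max_iter) {
  converged <- FALSE
  constrained <- FALSE
  iter <- 0L
  psi <- min(max(psi, lo), hi)
  sse_now <- seg_sse(x, y, psi)
  gamma <- Inf
  for (iter in seq_len(max_iter)) {
    U <- pmax(x - psi, 0)
    V <- -(x > psi)
    b <- stats::coef(stats::lm(y ~ x + U + V))
    if (anyNA(b) || b[["U"]] == 0) break
    gamma <- b[["V"]]
    step <- gamma / b[["U"]]
    psi_new <- psi; sse_new <- sse_now
    for (h in 0:8) {
      cand <- min(max(psi + step / 2^h, lo), hi)
      sse_cand <- seg_sse(x, y, cand)
      if (sse_cand <= sse_now + 1e-12) { psi_new <- cand; sse_new <- sse_cand; break }
    }
    constrained <- constrained || psi_new %in% c(lo, hi)
    if (abs(psi_new - psi) < tol) { psi <- psi_new; converged <- TRUE; break }
    psi <- psi_new; sse_now <- sse_new
  }
  if (!converged && abs(gamma) < 1e-8) converged <- TRUE
  list(psi = psi, sse = seg_sse(x, y, psi), converged = converged,
       constrained = constrained, iterations = iter)
}

#' Profile the breakpoint by exhaustive grid search
#'
#' Independent of the iterative fitter: evaluates the residual sum of
#' squares of the working linear model on a dense grid of breakpoints and
#' returns the minimizer. Used as a cross-check oracle.
#'
#' @param x,y data.
#' @param step grid step on the x scale.
#' @return list with `psi` (grid minimizer), `grid`, `sse`.
#' @export
profile_breakpoint <- function(x, y, step = 0.01) {
  ux <- sort(unique(x))
  grid <- seq(ux[2], ux[length(ux) - 1], by = step)
  sse <- vapply(grid, function(p) seg_sse(x, y, p), 0)
  list(psi = grid[which.min(sse)], grid = grid, sse = sse)
}

#' @export
print.segfit <- function(x, ...) {
  cat("One-breakpoint segmented linear regression\n")
  cat(sprintf("  breakpoint psi = %.4g\n", x$psi))
  cat(sprintf("  slope left  = %.4g, slope right = %.4g\n", x$slope1, x$slope2))
  cat(sprintf("  R2 = %.4f (adjusted %.4f), n = %d\n",
              x$r_squared, x$adj_r_squared, x$n))
  invisible(x)
}

#' @export
summary.segfit <- function(object, ...) {
  structure(object, class = c("summary.segfit", "segfit"))
}

#' @export
print.summary.segfit <- function(x, ...) {
  print.segfit(x)
  lv <- 100 * x$conf_level
  cat(sprintf("  intercept = %.4g\n", x$coefficients[["b0"]]))
  cat(sprintf("  %.0f%% CI slope left : [%.4f, %.4f]\n", lv, x$ci_slope1[1], x$ci_slope1[2]))
  cat(sprintf("  %.0f%% CI slope right: [%.4f, %.4f]\n", lv, x$ci_slope2[1], x$ci_slope2[2]))
  cat(sprintf("  residual sigma = %.4g on %d df; converged in %d iteration(s)%s\n",
              x$sigma, x$n - 4L, x$iterations,
              if (x$psi_constrained) " (psi constrained to data range)" else ""))
  invisible(x)
}

#' @export
coef.segfit <- function(object, ...) {
  c(object$coefficients, psi = object$psi)
}

#' @export
predict.segfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  b <- object$coefficients
  unname(b[["b0"]] + b[["b1"]] * x + b[["b2"]] * pmax(x - object$psi, 0))
}

#' @export
residuals.segfit <- function(object, ...) object$residuals

#' @export
fitted.segfit <- function(object, ...) object$fitted.values

#' @export
simulate.segfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(object$n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.segfit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  graphics::abline(v = x$psi, lty = 2, col = "grey40")
  invisible(x)
}
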