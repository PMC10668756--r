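# Downstream statistics: per-female aggregation, tie-corrected Spearman
# rank correlation, and ridgeline-style kernel density summaries. The
# one-breakpoint segmented regression lives in segfit.R.

#' Per-female means of a comet metric
#'
#' Each female is the experimental unit, so downstream models use the
#' arithmetic mean of the per-comet metric within each female.
#'
#' @param values numeric per-comet values (e.g. tail moments).
#' @param female factor or character vector identifying the female of each
#'   comet.
#' @return Named numeric vector of means, one per female, in first-seen
#'   order.
#' @export
per_female_means <- function(values, female) {
  stopifnot(length(values) == length(female))
  female <- as.character(female)
  keys <- unique(female)
  out <- vapply(keys, function(k) {
    v <- values[female == k & !is.na(values)]
    if (!length(v)) {
      stop(errorCondition(sprintf("female '%s' has no accepted comets", k),
                          class = c("cometseg_empty_group_error", "cometseg_error")))
    }
    mean(v)
  }, 0)
  names(out) <- keys
  out
}

#' Spearman rank correlation with tie correction
#'
#' Average ranks for ties; the coefficient is the Pearson correlation of
#' the two rank vectors. The two-sided p-value uses the t approximation
#' with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list of class `spearman_result` with `r`, `n` and `p_value`.
#' @examples
#' fem <- load_female_table()
#' spearman_cor(fem$storage_time, fem$viability)
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop(errorCondition("correlation undefined for a constant vector",
                        class = c("cometseg_constant_error", "cometseg_error")))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r <- stats::cor(rx, ry)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, n = n, p_value = p), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r = %.4f (n = %d, two-sided p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Ridgeline-style per-group density summaries
#'
#' Gaussian kernel density per group on a shared evaluation grid
#' (Silverman's rule-of-thumb bandwidth per group by default). Modes are
#' the local maxima of each curve above 10% of the tallest density across
#' all groups.
#'
#' @param values numeric observations (e.g. per-comet tail moments).
#' @param group grouping vector (e.g. storage time); one summary per
#'   distinct value, ordered by the group key.
#' @param bw bandwidth rule or numeric bandwidth, passed to
#'   [stats::density()].
#' @param n_grid grid resolution.
#' @return list of class `ridgeline_summary`; one element per group with
#'   `group`, `n`, `grid`, `density` and `modes`.
#' @export
ridgeline_summary <- function(values, group, bw = "nrd0", n_grid = 512L) {
  stopifnot(length(values) == length(group))
  keys <- sort(unique(group))
  splits <- split(values, group)
  for (k in names(splits)) {
    if (length(splits[[k]]) < 2L || stats::sd(splits[[k]]) == 0) {
      stop(errorCondition(
        sprintf("group '%s' needs at least 2 distinct values for a density", k),
        class = c("cometseg_degenerate_density_error", "cometseg_error")))
    }
  }
  bws <- vapply(splits, function(v) if (is.numeric(bw)) bw else stats::bw.nrd0(v), 0)
  lo <- min(values) - 3 * max(bws)
  hi <- max(values) + 3 * max(bws)
  dens <- lapply(seq_along(keys), function(i) {
    v <- splits[[as.character(keys[i])]]
    d <- stats::density(v, bw = bws[[as.character(keys[i])]],
                        from = lo, to = hi, n = n_grid)
    list(group = keys[i], n = length(v), grid = d$x, density = d$y)
  })
  peak <- max(vapply(dens, function(d) max(d$density), 0))
  out <- lapply(dens, function(d) {
    y <- d$density
    is_mode <- which(diff(sign(diff(y))) == -2) + 1L
    is_mode <- is_mode[y[is_mode] >= 0.1 * peak]
    d$modes <- d$grid[is_mode]
    d
  })
  structure(out, class = "ridgeline_summary")
}

#' @export
print.ridgeline_summary <- function(x, ...) {
  cat(sprintf("<ridgeline_summary> %d group(s)\n", length(x)))
  for (d in x) {
    cat(sprintf("  group %s: n = %d, mode(s) at %s\n", format(d$group), d$n,
                paste(signif(d$modes, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Plot stacked group densities
#'
#' Minimal base-graphics ridgeline rendering of a [ridgeline_summary()];
#' convenience only.
#'
#' @param x a `ridgeline_summary`.
#' @param gap vertical offset between stacked curves, as a multiple of the
#'   tallest density.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ridgeline_summary <- function(x, gap = 0.8, ...) {
  peak <- max(vapply(x, function(d) max(d$density), 0))
  off <- gap * peak
  n <- length(x)
  graphics::plot(NA, xlim = range(x[[1]]$grid),
                 ylim = c(0, off * n + peak),
                 xlab = "value", ylab = "", yaxt = "n", ...)
  cols <- grDevices::hcl.colors(n, "Zissou 1")
  for (i in seq_len(n)) {
    d <- x[[n - i + 1L]]
    base <- off * (i - 1L)
    graphics::polygon(c(d$grid, rev(d$grid)),
                      c(base + d$density, rep(base, length(d$grid))),
                      col = grDevices::adjustcolor(cols[n - i + 1L], 0.6),
                      border = cols[n - i + 1L])
    for (m in d$modes) graphics::lines(c(m, m), base + c(0, max(d$density)), lty = 2)
    graphics::text(min(d$grid), base + 0.1 * peak, labels = format(d$group), pos = 4)
  }
  invisible(x)
}
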