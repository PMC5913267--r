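#' Plot abundance (and mean genotype) trajectories
#'
#' Basic line plots of per-level abundance over iterations, averaged across
#' replicates within each branch; evolving levels get a second panel with
#' the mean genotype trajectory.
#'
#' @param records A `"run_record"`.
#' @param levels Levels to draw (default: all).
#' @param what `"abundance"` or `"mean_G"`.
#' @export
plot_run <- function(records, levels = NULL, what = c("abundance", "mean_G")) {
  what <- match.arg(what)
  records <- .with_groups(as.data.frame(records))
  if (is.null(levels)) levels <- sort(unique(records$level))
  branches <- unique(records$branch)
  op <- graphics::par(mfrow = c(length(levels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (l in levels) {
    d <- records[records$level == l, ]
    agg <- stats::aggregate(d[[what]],
                            by = list(iteration = d$iteration,
                                      branch = d$branch),
                            FUN = mean)
    rng <- range(agg$x, na.rm = TRUE)
    graphics::plot(NA, xlim = range(agg$iteration), ylim = rng,
                   xlab = "iteration", ylab = sprintf("%s (level %d)", what, l))
    for (i in seq_along(branches)) {
      dd <- agg[agg$branch == branches[i], ]
      graphics::lines(dd$iteration, dd$x, col = i)
    }
    if (l == levels[1] && length(branches) > 1) {
      graphics::legend("topright", legend = branches,
                       col = seq_along(branches), lty = 1, bty = "n")
    }
  }
  invisible(NULL)
}

#' Plot a yield curve
#'
#' Mean long-term yield against harvest intensity for each branch, with the
#' MSY estimates marked.
#'
#' @param yc The result of [yield_curve()].
#' @export
plot_yield_curve <- function(yc) {
  tab <- yc$table
  branches <- unique(tab$branch)
  graphics::plot(NA, xlim = range(tab$f), ylim = range(tab$yield),
                 xlab = "harvest intensity f", ylab = "mean yield")
  for (i in seq_along(branches)) {
    d <- tab[tab$branch == branches[i], ]
    d <- d[order(d$f), ]
    graphics::lines(d$f, d$yield, col = i, type = "b", pch = 16)
    graphics::abline(v = yc$msy[[branches[i]]], col = i, lty = 3)
  }
  graphics::legend("topleft", legend = branches, col = seq_along(branches),
                   lty = 1, bty = "n")
  invisible(NULL)
}
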