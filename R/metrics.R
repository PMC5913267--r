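#' Mean generation time from a run record
#'
#' A generation is the interval between an individual's birth and the birth
#' of one of its offspring. [step_community()] accumulates those intervals
#' per iteration (`gen_sum`, `gen_n`); this averages them for one level over
#' an iteration window.
#'
#' @param record A `"run_record"` from [run_phase()].
#' @param level Trophic level.
#' @param window Iteration range `c(first, last)` (inclusive), or `NULL`
#'   for the whole record.
#' @return Mean parent-offspring birth interval `T`, in iterations.
#' @export
generation_time <- function(record, level, window = NULL) {
  rows <- record$level == level
  if (!is.null(window)) {
    rows <- rows & record$iteration >= window[1] & record$iteration <= window[2]
  }
  n <- sum(record$gen_n[rows], na.rm = TRUE)
  if (n == 0) stop("no births with recorded parent birth time in window")
  sum(record$gen_sum[rows], na.rm = TRUE) / n
}

#' Realized heritability by parent-offspring regression
#'
#' Under clonal (single-parent) inheritance the slope of offspring phenotype
#' on parent phenotype estimates the effective heritability directly. The
#' estimator is invariant to affine rescaling of the phenotype.
#'
#' @param parent,offspring Paired phenotype vectors (one offspring per
#'   parent), conventionally the attack rate.
#' @return The regression slope `h2`.
#' @export
realized_heritability <- function(parent, offspring) {
  stopifnot(length(parent) == length(offspring), length(parent) >= 2)
  v <- stats::var(parent)
  if (!is.finite(v) || v == 0) {
    stop("degenerate parent phenotypic variance; heritability undefined")
  }
  stats::cov(parent, offspring) / v
}

#' Simulate one reproductive cycle and estimate heritability
#'
#' Draws founder genotypes `Normal(mean, sd)`, realizes parent phenotypes
#' with environmental noise, produces exactly one offspring per parent
#' (inheritance plus mutation, fresh noise) and regresses offspring attack
#' rate on parent attack rate.
#'
#' @param params A [trophic_params()] for the evolving level.
#' @param n_pairs Number of parent-offspring pairs.
#' @param founder List with `mean` and `sd` of founder genotypes.
#' @param mutation List with `prob` and `sd`.
#' @return The estimated heritability (regression slope).
#' @export
#' @examples
#' set.seed(1)
#' p <- producer_base_params(A = 29.5, V = 39.3, M = 25, evolve = TRUE)
#' estimate_heritability(p, n_pairs = 2000)
estimate_heritability <- function(params, n_pairs = 10000,
                                  founder = list(mean = 0, sd = 0.25),
                                  mutation = list(prob = 0.12, sd = 0.05)) {
  G <- stats::rnorm(n_pairs, founder$mean, founder$sd)
  parents <- new_population(G, params, birth = 0, parent_birth = NA_real_)
  off <- spawn_offspring(parents, rep(1L, n_pairs), params, mutation,
                         t = 1, frozen = NA_real_)
  realized_heritability(parents$attack, off$attack)
}

## normalize a record to always carry branch and replicate columns
.with_groups <- function(record) {
  if (is.null(record$branch)) record$branch <- "run"
  if (is.null(record$replicate)) record$replicate <- 1L
  record
}

## terminal window of a record: last `frac` of the iteration span
.terminal_rows <- function(record, frac) {
  lo <- max(record$iteration) - frac * (max(record$iteration) -
                                          min(record$iteration))
  record$iteration >= lo
}

#' Summarize run records
#'
#' Replicate-wise then cross-replicate aggregation of abundance, yield and
#' mean genotype per branch and level. The coefficient of variation of
#' abundance within a replicate is the stability metric; its cross-replicate
#' SD columns are `NA` (absent, not zero) with a single replicate.
#'
#' @param records A `"run_record"` (with or without `branch`/`replicate`
#'   columns).
#' @param window_frac Terminal fraction of iterations to summarize
#'   (default 1: all).
#' @return A data frame with one row per branch and level: `n_replicates`,
#'   `abundance` (mean of replicate means), `abundance_sd` (SD across
#'   replicate means), `abundance_cv` (mean within-replicate CV), `yield`,
#'   `yield_sd` and `mean_G`.
#' @export
summarize_timeseries <- function(records, window_frac = 1) {
  stopifnot(nrow(records) > 0)
  records <- .with_groups(records)
  if (window_frac < 1) records <- records[.terminal_rows(records, window_frac), ]
  per_rep <- do.call(rbind, by(records,
                               records[c("branch", "replicate", "level")],
                               function(d) {
    m <- mean(d$abundance)
    data.frame(branch = d$branch[1], replicate = d$replicate[1],
               level = d$level[1], abundance = m,
               cv = if (m > 0) stats::sd(d$abundance) / m else NA_real_,
               yield = mean(d$yield),
               mean_G = mean(d$mean_G, na.rm = TRUE))
  }))
  out <- do.call(rbind, by(per_rep, per_rep[c("branch", "level")],
                           function(d) {
    nr <- nrow(d)
    data.frame(branch = d$branch[1], level = d$level[1], n_replicates = nr,
               abundance = mean(d$abundance),
               abundance_sd = if (nr > 1) stats::sd(d$abundance) else NA_real_,
               abundance_cv = mean(d$cv),
               yield = mean(d$yield),
               yield_sd = if (nr > 1) stats::sd(d$yield) else NA_real_,
               mean_G = mean(d$mean_G))
  }))
  rownames(out) <- NULL
  out
}

#' Compare eco-evolutionary and ecology-only branches
#'
#' Computes, over a terminal window of the harvest phase, the
#' replicate-paired difference (eco-evolutionary minus ecology-only) in mean
#' harvested-species abundance and yield, a one-sample test of the abundance
#' difference against zero, a sign classification, and per-branch collapse
#' fractions.
#'
#' @param runs A `"bifurcated_runs"` from [run_bifurcated_experiment()].
#' @param window_frac Terminal fraction of the harvest phase to average
#'   (default 0.25).
#' @param alpha Significance level for the sign classification.
#' @return An object of class `"comparison_summary"`: list with `scenario`,
#'   `harvest_level`, per-branch means and SDs, per-replicate differences
#'   (`diff_abundance`, `diff_yield`), `p_value`, `sign` (one of
#'   `"bolsters"`, `"undermines"`, `"neutral"`) and `collapse_frac` per
#'   branch.
#' @export
compare_models <- function(runs, window_frac = 0.25, alpha = 0.05) {
  stopifnot(inherits(runs, "bifurcated_runs"))
  rec <- runs$records
  hl <- runs$plan$harvest_level
  rec <- rec[rec$level == hl & rec$branch %in% c("ecoevo", "ecoonly"), ]
  rec <- rec[.terminal_rows(rec, window_frac), ]
  reps <- sort(unique(rec$replicate))
  stat <- function(branch, fld) {
    vapply(reps, function(r) {
      d <- rec[rec$replicate == r & rec$branch == branch, ]
      if (nrow(d) == 0) stop("unpaired records: replicate ", r,
                             " missing branch ", branch)
      mean(d[[fld]])
    }, numeric(1))
  }
  ab_evo <- stat("ecoevo", "abundance")
  ab_eco <- stat("ecoonly", "abundance")
  y_evo <- stat("ecoevo", "yield")
  y_eco <- stat("ecoonly", "yield")
  d_ab <- ab_evo - ab_eco
  d_y <- y_evo - y_eco
  p <- if (length(d_ab) >= 2 && stats::sd(d_ab) > 0) {
    stats::t.test(d_ab)$p.value
  } else if (all(d_ab == 0)) 1 else NA_real_
  sgn <- if (!is.na(p) && p < alpha && mean(d_ab) > 0) {
    "bolsters"
  } else if (!is.na(p) && p < alpha && mean(d_ab) < 0) {
    "undermines"
  } else {
    "neutral"
  }
  terminal_zero <- function(branch) {
    vapply(reps, function(r) {
      d <- rec[rec$replicate == r & rec$branch == branch, ]
      d$abundance[which.max(d$iteration)] == 0
    }, logical(1))
  }
  structure(list(
    scenario = runs$plan$scenario, harvest_level = hl,
    n_replicates = length(reps),
    abundance = c(ecoevo = mean(ab_evo), ecoonly = mean(ab_eco)),
    abundance_sd = c(ecoevo = stats::sd(ab_evo), ecoonly = stats::sd(ab_eco)),
    yield = c(ecoevo = mean(y_evo), ecoonly = mean(y_eco)),
    diff_abundance = d_ab, diff_yield = d_y,
    mean_diff_abundance = mean(d_ab), mean_diff_yield = mean(d_y),
    p_value = p, sign = sgn,
    collapse_frac = c(ecoevo = mean(terminal_zero("ecoevo")),
                      ecoonly = mean(terminal_zero("ecoonly")))
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<comparison_summary> %s (harvested level %d, %d replicates)\n",
           "  abundance: ecoevo %.1f vs ecoonly %.1f (diff %+.1f, p = %.3g)",
           " -> %s\n  yield diff %+.3f; collapse ecoevo %.0f%%, ecoonly %.0f%%\n"),
    x$scenario, x$harvest_level, x$n_replicates,
    x$abundance[["ecoevo"]], x$abundance[["ecoonly"]],
    x$mean_diff_abundance, x$p_value, x$sign, x$mean_diff_yield,
    100 * x$collapse_frac[["ecoevo"]], 100 * x$collapse_frac[["ecoonly"]]))
  invisible(x)
}

#' Yield against harvest intensity, MSY and collapse threshold
#'
#' Aggregates a harvest-intensity sweep into per-branch mean long-term yield
#' per grid point, the maximum-sustainable-yield estimate (grid argmax of
#' mean yield) and the collapse threshold (smallest `f` at which the
#' harvested species went extinct in at least half of the replicates).
#'
#' @param sweep A `"sweep_runs"` over the harvest axis.
#' @param window_frac Terminal fraction of the harvest phase to average.
#' @return A list with `table` (data frame: `f`, `branch`, `yield`,
#'   `collapse_frac`), `msy` (named per-branch `f` of maximum yield) and
#'   `collapse_threshold` (named per branch, `NA` if no collapse).
#' @export
yield_curve <- function(sweep, window_frac = 0.25) {
  stopifnot(inherits(sweep, "sweep_runs"), sweep$axis == "harvest")
  rows <- list()
  for (i in seq_along(sweep$grid)) {
    cmp <- compare_models(sweep$runs[[i]], window_frac = window_frac)
    for (br in c("ecoevo", "ecoonly")) {
      rows[[length(rows) + 1L]] <- data.frame(
        f = sweep$grid[i], branch = br, yield = cmp$yield[[br]],
        collapse_frac = cmp$collapse_frac[[br]])
    }
  }
  yield_curve_table(do.call(rbind, rows))
}

#' Summarize a yield table into MSY and collapse threshold
#'
#' Lower-level worker behind [yield_curve()]; useful for synthetic tables.
#'
#' @param tab Data frame with columns `f`, `branch`, `yield`,
#'   `collapse_frac`.
#' @return Same shape as the [yield_curve()] return value.
#' @export
yield_curve_table <- function(tab) {
  stopifnot(all(c("f", "branch", "yield", "collapse_frac") %in% names(tab)))
  branches <- unique(tab$branch)
  msy <- vapply(branches, function(br) {
    d <- tab[tab$branch == br, ]
    d$f[which.max(d$yield)]
  }, numeric(1))
  thr <- vapply(branches, function(br) {
    d <- tab[tab$branch == br, ]
    d <- d[order(d$f), ]
    hit <- d$f[d$collapse_frac >= 0.5]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  list(table = tab, msy = msy, collapse_threshold = thr)
}
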