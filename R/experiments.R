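## Regime setpoint tradeoff coefficients (A, V) per evolving level, chosen in
## the middle of the range that produces marked harvest-induced evolution.
.setpoints <- list(
  top_predator = list(`1` = c(A = 29.5, V = 39.3),
                      `2` = c(A = 22.0, V = 45.4),
                      `3` = c(A = 19.1, V = 52.5)),
  secondary_consumer = list(`1` = c(A = 20.5, V = 48.8),
                            `2` = c(A = 17.0, V = 58.8))
)

## Default burn-in/harvest phase length keyed by the highest evolving level.
.phase_length <- function(evolve) {
  if (length(evolve) == 0L) return(12500L)
  c(12500L, 20000L, 50000L)[max(evolve)]
}

.default_init_sizes <- function(n_levels) {
  if (n_levels == 4L) c(1850L, 1130L, 210L, 140L) else c(3500L, 420L, 550L)
}

#' Define an experiment
#'
#' An experiment plan fixes the community (chain length, per-level tradeoff
#' coefficients, which levels evolve), the harvest (level and intensity),
#' the phase lengths, the replicate count and the base seed. Phase lengths
#' default to the evolving-level convention (12,500 iterations when the
#' producer is the highest evolving level; 20,000 for the primary consumer;
#' 50,000 for the secondary consumer), for both the burn-in and the harvest
#' phase.
#'
#' `phase_scale` shrinks both phases proportionally. `pop_scale` shrinks
#' population sizes while preserving every per-capita rate (attack rates are
#' divided by it and the resource cap and initial sizes multiplied by it),
#' so scaled runs are faster but dynamically equivalent apart from stronger
#' demographic stochasticity.
#'
#' @param scenario Scenario label.
#' @param n_levels Chain length (3 or 4).
#' @param harvest_level Harvested level index.
#' @param f Harvest intensity.
#' @param f_error_cv Relative SD of the effort error.
#' @param evolve Integer vector of evolving levels (never the harvested one).
#' @param tradeoffs Named list mapping level index (as character) to
#'   `c(A =, V =)`; `M = 25` is applied to listed levels.
#' @param burn_in,harvest_iters Phase lengths; `NULL` for the convention
#'   above.
#' @param replicates Number of independent replicate worlds (default 12).
#' @param base_seed Base RNG seed.
#' @param phase_scale,pop_scale Scale factors, see Details.
#' @param rate_scale Producer rate scale, see [producer_base_params()].
#' @param resource,founder,mutation,init_sizes Community settings
#'   ([community_config()]); `init_sizes = NULL` uses calibrated defaults.
#' @return An object of class `"experiment_plan"`.
#' @export
experiment_plan <- function(scenario = "custom",
                            n_levels = 4L,
                            harvest_level = n_levels,
                            f = 9e-4,
                            f_error_cv = 0.05,
                            evolve = integer(0),
                            tradeoffs = .setpoints$top_predator,
                            burn_in = NULL,
                            harvest_iters = NULL,
                            replicates = 12L,
                            base_seed = 1L,
                            phase_scale = 1,
                            pop_scale = 1,
                            rate_scale = 100,
                            resource = list(R_max = 24500, r = 0.5,
                                            graze_scale = 0.4),
                            founder = list(mean = 0, sd = 0.25),
                            mutation = list(prob = 0.12, sd = 0.05),
                            init_sizes = NULL) {
  n_levels <- as.integer(n_levels)
  if (!n_levels %in% c(3L, 4L)) stop("n_levels must be 3 or 4")
  if (harvest_level < 1 || harvest_level > n_levels) {
    stop("harvest_level out of range")
  }
  evolve <- sort(unique(as.integer(evolve)))
  if (any(evolve < 1 | evolve >= harvest_level)) {
    stop("evolving levels must lie strictly below the harvested level")
  }
  if (f < 0 || f >= 1) stop("harvest intensity f must satisfy 0 <= f < 1")
  if (f_error_cv < 0) stop("f_error_cv must be >= 0")
  tradeoffs <- lapply(tradeoffs, function(tk) {
    c(A = as.numeric(tk[["A"]]), V = as.numeric(tk[["V"]]))
  })
  if (replicates < 1) stop("replicates must be >= 1")
  if (phase_scale <= 0 || pop_scale <= 0) stop("scale factors must be > 0")
  base <- .phase_length(evolve)
  if (is.null(burn_in)) burn_in <- max(1L, as.integer(round(base * phase_scale)))
  if (is.null(harvest_iters)) {
    harvest_iters <- max(1L, as.integer(round(base * phase_scale)))
  }
  if (burn_in < 1 || harvest_iters < 1) stop("phase lengths must be >= 1")
  if (is.null(init_sizes)) init_sizes <- .default_init_sizes(n_levels)
  structure(
    list(scenario = scenario, n_levels = n_levels,
         harvest_level = as.integer(harvest_level), f = f,
         f_error_cv = f_error_cv, evolve = evolve, tradeoffs = tradeoffs,
         burn_in = as.integer(burn_in),
         harvest_iters = as.integer(harvest_iters),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         phase_scale = phase_scale, pop_scale = pop_scale,
         rate_scale = rate_scale, resource = resource, founder = founder,
         mutation = mutation, init_sizes = as.integer(init_sizes)),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_plan> %s\n  %d levels, harvest level %d at f = %g, ",
           "evolving: %s\n  burn-in %d + harvest %d iterations, ",
           "%d replicates, seed %d\n"),
    x$scenario, x$n_levels, x$harvest_level, x$f,
    if (length(x$evolve)) paste(x$evolve, collapse = ", ") else "none",
    x$burn_in, x$harvest_iters, x$replicates, x$base_seed))
  invisible(x)
}

#' Build the community configuration of a plan
#'
#' Expands an [experiment_plan()] into a [community_config()]: derives every
#' level's base rates from the producer by the geometric progression,
#' attaches the tradeoff coefficients (`M = 25` at levels with a tradeoff),
#' sets evolve flags and applies the population scale.
#'
#' @param plan An `"experiment_plan"`.
#' @return A `"community_config"`.
#' @export
community_from_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  s <- plan$pop_scale
  prod <- producer_base_params(rate_scale = plan$rate_scale)
  prod$a0 <- prod$a0 / s
  levels <- vector("list", plan$n_levels)
  for (i in seq_len(plan$n_levels)) {
    tk <- plan$tradeoffs[[as.character(i)]]
    has_tradeoff <- !is.null(tk) && i < plan$harvest_level
    levels[[i]] <- derive_level_params(
      prod, i,
      A = if (has_tradeoff) tk[["A"]] else 0,
      V = if (has_tradeoff) tk[["V"]] else 0,
      M = if (has_tradeoff) 25 else 0,
      evolve = i %in% plan$evolve
    )
  }
  res <- plan$resource
  res$R_max <- res$R_max * s
  community_config(levels,
                   init_sizes = pmax(1L, as.integer(round(plan$init_sizes * s))),
                   resource = res, founder = plan$founder,
                   mutation = plan$mutation)
}

#' Deterministic seed stream for replicates and branches
#'
#' Derives the RNG seed of one replicate world and branch from the base
#' seed. Branch 0 is the burn-in (shared by both branches of a bifurcated
#' experiment), 1 the eco-evolutionary and 2 the ecology-only harvest
#' phase.
#'
#' @param base Base seed.
#' @param replicate Replicate index.
#' @param branch Branch code (0, 1 or 2).
#' @return An integer seed below 2^31.
#' @export
seed_for <- function(base, replicate, branch = 0L) {
  ((abs(base) %% 100000L) * 20011L + replicate * 101L + branch) %% 2147483647L
}

#' Run a fixed number of iterations
#'
#' Advances the community `iterations` times, recording the per-level
#' ledger each iteration. The default engine is a compiled loop; the
#' `"reference"` engine applies the pure-R [step_community()] repeatedly.
#' Both engines draw random numbers in the same order, so for a given seed
#' they produce identical trajectories.
#'
#' @param state A `"community_state"`.
#' @param iterations Number of iterations (>= 1).
#' @param harvest A [harvest_spec()] or `NULL` for a harvest-free phase.
#' @param verbose Emit a log line when a level goes extinct?
#' @param engine `"compiled"` or `"reference"`.
#' @return List with the final `state` and `record`, a `"run_record"`
#'   data frame with one row per iteration per level (columns `iteration`,
#'   `level`, `abundance`, `births`, `deaths`, `n_eaten`, `yield`,
#'   `mean_G`, `sd_G`, `gen_sum`, `gen_n`, `resource`).
#' @export
run_phase <- function(state, iterations, harvest = NULL, verbose = FALSE,
                      engine = c("compiled", "reference")) {
  stopifnot(inherits(state, "community_state"), iterations >= 1)
  engine <- match.arg(engine)
  nl <- length(state$pops)
  alive <- abundances(state) > 0L
  iters <- as.integer(iterations)
  cols <- c("abundance", "births", "deaths", "n_eaten", "yield",
            "mean_G", "sd_G", "gen_sum", "gen_n")
  if (engine == "compiled") {
    cfg <- state$config
    par <- t(vapply(cfg$levels, function(p) {
      c(p$a0, p$v0, p$b, p$h, p$d0, p$A, p$V, p$M, p$noise_cv)
    }, numeric(9)))
    gs <- cfg$resource$graze_scale
    out <- .run_phase_loop(
      state$pops, par, state$resource, cfg$resource$R_max, cfg$resource$r,
      if (is.null(gs)) 1 else gs,
      as.numeric(state$frozen), cfg$mutation$prob, cfg$mutation$sd,
      if (is.null(harvest)) 0L else harvest$level,
      if (is.null(harvest)) 0 else harvest$f,
      if (is.null(harvest)) 0 else harvest$error_cv,
      if (is.null(harvest)) 0 else harvest$onset,
      state$t, iters)
    state$pops <- out$pops
    state$resource <- out$resource
    state$t <- out$t
    rec <- out[cols]
    res_vec <- out$res_vec
    it_vec <- out$it_vec
  } else {
    rec <- lapply(cols, function(.) matrix(NA_real_, nrow = iters, ncol = nl))
    names(rec) <- cols
    res_vec <- numeric(iters)
    it_vec <- integer(iters)
    for (k in seq_len(iters)) {
      out <- step_community(state, harvest)
      state <- out$state
      lg <- out$ledger
      for (cn in cols) rec[[cn]][k, ] <- lg[[cn]]
      res_vec[k] <- lg$resource
      it_vec[k] <- state$t
    }
  }
  if (verbose) {
    for (l in which(alive)) {
      hit <- which(rec$abundance[, l] == 0)
      if (length(hit)) {
        message(sprintf("iteration %d: level %d extinct", it_vec[hit[1]], l))
      }
    }
  }
  record <- data.frame(
    iteration = rep(it_vec, times = nl),
    level = rep(seq_len(nl), each = iters),
    abundance = as.vector(rec$abundance),
    births = as.vector(rec$births),
    deaths = as.vector(rec$deaths),
    n_eaten = as.vector(rec$n_eaten),
    yield = as.vector(rec$yield),
    mean_G = as.vector(rec$mean_G),
    sd_G = as.vector(rec$sd_G),
    gen_sum = as.vector(rec$gen_sum),
    gen_n = as.vector(rec$gen_n),
    resource = rep(res_vec, times = nl)
  )
  class(record) <- c("run_record", "data.frame")
  list(state = state, record = record)
}

#' Freeze genotypes at their current population mean
#'
#' Switches the given levels to the ecology-only regime: every current and
#' future individual carries the level's current mean genotype (not zero),
#' mutation stops there, but phenotypes keep their environmental noise, so
#' phenotypic variance stays positive.
#'
#' @param state A `"community_state"`.
#' @param levels Integer vector of levels to freeze.
#' @return The modified state.
#' @export
freeze_genotypes <- function(state, levels) {
  stopifnot(inherits(state, "community_state"))
  for (l in as.integer(levels)) {
    if (l < 1 || l > length(state$pops)) stop("no such level: ", l)
    if (pop_size(state$pops[[l]]) == 0L) {
      stop("cannot freeze level ", l, ": population is extinct")
    }
    m <- mean(state$pops[[l]]$G)
    state$frozen[l] <- m
    state$pops[[l]]$G[] <- m
  }
  state
}

#' Run a bifurcated eco-evolutionary vs ecology-only experiment
#'
#' For each replicate: initializes an independent world, burns it in with
#' evolution on at the plan's evolving levels, then clones the end state and
#' runs the harvest phase twice from that identical state — once with
#' evolution continuing (`branch = "ecoevo"`) and once with the evolving
#' levels' genotypes frozen at the harvest-onset mean
#' (`branch = "ecoonly"`) — with independent demographic randomness per
#' branch.
#'
#' @param plan An [experiment_plan()].
#' @param record_burnin Keep the burn-in records (`branch = "burnin"`)?
#'   Default `FALSE` to bound memory.
#' @param verbose Log phase boundaries and extinction events?
#' @param replicate_ids Replicate indices to run (default
#'   `1:plan$replicates`). Replicate `r` always uses the same seed stream
#'   regardless of which other replicates are run, so an experiment can be
#'   extended with further replicates without recomputing earlier ones.
#' @return An object of class `"bifurcated_runs"`: list with `plan`,
#'   `records` (row-bound [run_phase()] records with `branch` and
#'   `replicate` columns) and `onset` (per replicate and level, the
#'   abundance and mean genotype at harvest onset).
#' @export
run_bifurcated_experiment <- function(plan, record_burnin = FALSE,
                                      verbose = FALSE,
                                      replicate_ids = seq_len(plan$replicates)) {
  stopifnot(inherits(plan, "experiment_plan"))
  cfg <- community_from_plan(plan)
  harv <- harvest_spec(plan$harvest_level, plan$f, plan$f_error_cv)
  recs <- list()
  onset <- list()
  for (r in as.integer(replicate_ids)) {
    if (verbose) {
      message(sprintf("replicate %d: burn-in (%d iterations)", r, plan$burn_in))
    }
    set.seed(seed_for(plan$base_seed, r, 0L))
    state0 <- init_community(cfg)
    burn <- run_phase(state0, plan$burn_in, harvest = NULL, verbose = verbose)
    if (record_burnin) {
      br <- burn$record
      br$branch <- "burnin"
      br$replicate <- r
      recs[[length(recs) + 1L]] <- br
    }
    onset[[r]] <- data.frame(
      replicate = r, level = seq_len(plan$n_levels),
      abundance = abundances(burn$state),
      mean_G = vapply(burn$state$pops, function(p) {
        if (length(p$G)) mean(p$G) else NA_real_
      }, numeric(1))
    )
    for (b in 1:2) {
      branch <- c("ecoevo", "ecoonly")[b]
      st <- burn$state
      if (b == 2L && length(plan$evolve)) {
        st <- freeze_genotypes(st, plan$evolve)
      }
      if (verbose) {
        message(sprintf("replicate %d: harvest phase, branch %s (%d iterations)",
                        r, branch, plan$harvest_iters))
      }
      set.seed(seed_for(plan$base_seed, r, b))
      run <- run_phase(st, plan$harvest_iters, harvest = harv,
                       verbose = verbose)
      rr <- run$record
      rr$branch <- branch
      rr$replicate <- r
      recs[[length(recs) + 1L]] <- rr
    }
  }
  records <- do.call(rbind, recs)
  class(records) <- c("run_record", "data.frame")
  structure(list(plan = plan, records = records,
                 onset = do.call(rbind, onset)),
            class = "bifurcated_runs")
}

#' @export
print.bifurcated_runs <- function(x, ...) {
  cat(sprintf("<bifurcated_runs> %s: %d replicates x 2 branches x %d iterations\n",
              x$plan$scenario, x$plan$replicates, x$plan$harvest_iters))
  invisible(x)
}

#' Sweep an experiment over harvest intensity or tradeoff ratio
#'
#' Runs one bifurcated experiment per grid point. For the harvest axis the
#' grid values replace `f`. For the tradeoff axis each grid value is a
#' multiplier `rho` on the setpoint tradeoff ratio `A/V` of every evolving
#' level, applied at constant `A*V` (`A -> A sqrt(rho)`,
#' `V -> V / sqrt(rho)`), so `rho < 1` makes defense cheap and `rho > 1`
#' makes competition cheap.
#'
#' @param plan An [experiment_plan()].
#' @param axis `"harvest"` or `"tradeoff"`.
#' @param grid Numeric grid (non-empty).
#' @param ... Passed to [run_bifurcated_experiment()].
#' @return An object of class `"sweep_runs"`: list with `axis`, `grid` and
#'   `runs` (one `"bifurcated_runs"` per grid value, named by it).
#' @export
sweep_experiment <- function(plan, axis = c("harvest", "tradeoff"), grid, ...) {
  axis <- match.arg(axis)
  stopifnot(inherits(plan, "experiment_plan"), length(grid) >= 1)
  runs <- vector("list", length(grid))
  names(runs) <- as.character(grid)
  for (i in seq_along(grid)) {
    p <- if (axis == "harvest") {
      plan$f <- grid[i]
      plan
    } else {
      tradeoff_scaled_plan(plan, grid[i])
    }
    runs[[i]] <- run_bifurcated_experiment(p, ...)
  }
  structure(list(axis = axis, grid = grid, runs = runs), class = "sweep_runs")
}

#' Rescale the tradeoff ratio of every evolving level
#'
#' @param plan An [experiment_plan()].
#' @param rho Multiplier on the tradeoff ratio `A/V`, applied at constant
#'   `A*V`.
#' @return The modified plan.
#' @export
tradeoff_scaled_plan <- function(plan, rho) {
  stopifnot(rho > 0)
  for (l in plan$evolve) {
    tk <- plan$tradeoffs[[as.character(l)]]
    plan$tradeoffs[[as.character(l)]] <-
      c(A = unname(tk[["A"]] * sqrt(rho)), V = unname(tk[["V"]] / sqrt(rho)))
  }
  plan$scenario <- sprintf("%s_rho%g", plan$scenario, rho)
  plan
}

#' Scenario presets
#'
#' Returns the experiment plan of a named preset. Presets cover top-predator
#' harvest (`f = 0.0009`) with every single evolving level, every pair and
#' all levels below the harvested one; secondary-consumer harvest
#' (`f = 0.0077`) with its single-level variants; and the three-level
#' "fishing down the food web" chain whose top (the secondary consumer) is
#' harvested. Tradeoff coefficients are the regime setpoints and `M = 25`
#' at every level carrying a tradeoff.
#'
#' @param name Preset name; see [scenario_names()].
#' @param ... Overrides passed to [experiment_plan()] (e.g. `replicates`,
#'   `base_seed`, `phase_scale`, `pop_scale`, `f`).
#' @return An `"experiment_plan"`.
#' @export
#' @examples
#' scenario_preset("top_predator_harvest_producer", replicates = 2)
scenario_preset <- function(name, ...) {
  specs <- .scenario_specs()
  if (!name %in% names(specs)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(specs), collapse = ", "))
  }
  args <- utils::modifyList(specs[[name]], list(...))
  do.call(experiment_plan, c(list(scenario = name), args))
}

.scenario_specs <- function() {
  tp <- function(evolve) {
    list(n_levels = 4L, harvest_level = 4L, f = 9e-4, evolve = evolve,
         tradeoffs = .setpoints$top_predator)
  }
  sc <- function(evolve, n_levels = 4L) {
    list(n_levels = n_levels, harvest_level = 3L, f = 0.0077,
         evolve = evolve, tradeoffs = .setpoints$secondary_consumer)
  }
  list(
    top_predator_harvest                     = tp(c(1L, 2L, 3L)),
    top_predator_harvest_secondary_consumer  = tp(3L),
    top_predator_harvest_primary_consumer    = tp(2L),
    top_predator_harvest_producer            = tp(1L),
    top_predator_harvest_secondary_primary   = tp(c(2L, 3L)),
    top_predator_harvest_secondary_producer  = tp(c(1L, 3L)),
    top_predator_harvest_primary_producer    = tp(c(1L, 2L)),
    secondary_consumer_harvest               = sc(c(1L, 2L)),
    secondary_consumer_harvest_primary_consumer = sc(2L),
    secondary_consumer_harvest_producer      = sc(1L),
    fishing_down_three_level                 = sc(c(1L, 2L), n_levels = 3L)
  )
}

#' Names of the shipped scenario presets
#'
#' @return Character vector of preset names.
#' @export
scenario_names <- function() names(.scenario_specs())
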