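#' Harvest specification
#'
#' Consistent-effort harvest: each iteration the harvested level suffers an
#' extra mortality fraction `f` perturbed by a mean-zero normal error with
#' relative standard deviation `error_cv` (effort variability).
#'
#' @param level Harvested trophic level index.
#' @param f Harvest intensity (per-iteration mortality fraction), `0 <= f < 1`.
#' @param error_cv Relative standard deviation of the effort error (default
#'   0.05, i.e. a 5% error term).
#' @param onset Iteration at which harvest starts (default 0: immediately).
#' @return An object of class `"harvest_spec"`.
#' @export
harvest_spec <- function(level, f, error_cv = 0.05, onset = 0) {
  if (f < 0 || f >= 1) stop("harvest intensity f must satisfy 0 <= f < 1")
  if (error_cv < 0) stop("error_cv must be >= 0")
  structure(list(level = as.integer(level), f = f, error_cv = error_cv,
                 onset = as.numeric(onset)),
            class = "harvest_spec")
}

#' Holling type II functional response
#'
#' Per-prey capture rate `a / (1 + h a N_prey)`: linear in prey abundance at
#' low density, saturating at a total intake of `1/h` as prey become
#' abundant.
#'
#' @param a Attack rate (scalar or vector over consumers).
#' @param h Handling time.
#' @param N_prey Prey abundance.
#' @return Per-prey capture rate(s), same length as `a`.
#' @export
#' @examples
#' functional_response(0.01, 2e-10, 1e6)
functional_response <- function(a, h, N_prey) {
  stopifnot(all(a >= 0), h >= 0, N_prey >= 0)
  a / (1 + h * a * N_prey)
}

#' Per-individual expected offspring
#'
#' Expected offspring of consumer `i` is its conversion efficiency times its
#' share of the prey actually eaten, the share being its functional response
#' relative to the population mean:
#' `L_i = b * f_i * N_prey_eaten / (mean(f) * N)`.
#' Summed over the population this returns exactly `b * N_prey_eaten`
#' regardless of trait heterogeneity, so biomass conversion is conserved and
#' selection acts only on the shares.
#'
#' @param pop A population (as inside a [init_community()] state).
#' @param params The level's [trophic_params()].
#' @param N_prey Prey abundance at the start of the iteration.
#' @param N_prey_eaten Prey deaths attributed to predation this iteration
#'   (see [count_predation_deaths()]); resource units consumed, for
#'   producers.
#' @return Numeric vector of expected offspring `L_i`.
#' @export
birth_probabilities <- function(pop, params, N_prey, N_prey_eaten) {
  n <- pop_size(pop)
  if (n == 0L) stop("population is empty")
  if (N_prey_eaten < 0) stop("N_prey_eaten must be >= 0")
  if (N_prey_eaten == 0) return(numeric(n))
  fr <- functional_response(pop$attack, params$h, N_prey)
  mfr <- mean(fr)
  if (mfr == 0) {
    stop("inconsistent state: prey were eaten but mean functional response is 0")
  }
  params$b * fr * N_prey_eaten / (mfr * n)
}

#' Per-individual predation death probability
#'
#' Probability that a focal individual is killed by predation this
#' iteration: the mean per-prey capture rate over all predators, times the
#' individual's vulnerability, times predator abundance; clipped to \[0, 1\].
#'
#' @param vuln Vulnerability phenotype(s) of the focal individuals.
#' @param predators The predator population (may be empty).
#' @param pred_params The predator level's [trophic_params()].
#' @param n_consumers Abundance of the focal (prey) level, which saturates
#'   the predators' functional response.
#' @return Predation death probabilities, same length as `vuln`.
#' @export
predation_death_prob <- function(vuln, predators, pred_params, n_consumers) {
  n_pred <- pop_size(predators)
  if (n_pred == 0L) return(rep(0, length(vuln)))
  mfr <- mean(functional_response(predators$attack, pred_params$h, n_consumers))
  pmin(mfr * vuln * n_pred, 1)
}

#' Combine intrinsic, predation and harvest mortality
#'
#' Independent-hazard combination
#' `D = 1 - (1 - d)(1 - d_P)(1 - f - eps_f)`, with the realized effort
#' `f + eps_f` clipped to \[0, 1\]; the harvest factor is dropped for
#' unharvested levels (`f = 0`).
#'
#' @param d Intrinsic death probability (scalar or vector).
#' @param d_P Predation death probability.
#' @param f Harvest intensity (0 for unharvested levels).
#' @param eps_f Realized effort error draw.
#' @return Total death probability in \[0, 1\].
#' @export
#' @examples
#' combine_death_probs(0.1, 0.05)              # 0.145
#' combine_death_probs(0.1, 0.05, f = 0.0009)  # 0.14577
combine_death_probs <- function(d, d_P, f = 0, eps_f = 0) {
  stopifnot(all(d >= 0 & d <= 1), all(d_P >= 0 & d_P <= 1))
  eff <- min(max(f + eps_f, 0), 1)
  1 - (1 - d) * (1 - d_P) * (1 - eff)
}

#' Realize demographic stochasticity
#'
#' Draws each individual's offspring count from `Poisson(L_i)` and its death
#' flag from `Bernoulli(D_i)`. Identical seeds give identical realizations.
#'
#' @param L Expected offspring per individual.
#' @param D Death probability per individual.
#' @return List with integer vector `offspring` and logical vector `dead`.
#' @export
realize_demography <- function(L, D) {
  stopifnot(all(L >= 0), all(D >= 0 & D <= 1), length(L) == length(D))
  n <- length(L)
  list(offspring = stats::rpois(n, L),
       dead = stats::rbinom(n, 1L, D) == 1L)
}

#' Attribute deaths to predation
#'
#' For the individuals that died, sums the fraction of each total death
#' probability that was due to predation, `N_eaten = sum(d_P_i / D_i)`. The
#' result feeds the birth probabilities of the next higher level as
#' `N_prey_eaten`.
#'
#' @param d_P_dead Predation death probabilities of the dead individuals.
#' @param D_dead Total death probabilities of the dead individuals.
#' @return `N_eaten`, a real number in `[0, number dead]`.
#' @export
count_predation_deaths <- function(d_P_dead, D_dead) {
  if (any(D_dead <= 0)) stop("inconsistent state: dead individual with D = 0")
  sum(d_P_dead / D_dead)
}

#' Harvest yield of one iteration
#'
#' The harvest-attributed fraction of deaths at the harvested level,
#' `Y = sum((f + eps_f) / D_i)` over dead individuals.
#'
#' @param eff Realized effort `f + eps_f` (clipped to \[0, 1\]).
#' @param D_dead Total death probabilities of the dead individuals.
#' @return Yield `Y` in `[0, number dead]`.
#' @export
compute_yield <- function(eff, D_dead) {
  if (length(D_dead) == 0L) return(0)
  if (any(D_dead <= 0)) stop("inconsistent state: dead individual with D = 0")
  sum(eff / D_dead)
}

#' Spawn offspring
#'
#' Each offspring clones its parent's genotype plus a
#' `Bernoulli(P_mutation) * Normal(0, sigma_mutation)` mutational increment
#' (inheritance is asexual, sampling directly from standing variation);
#' at frozen levels all offspring carry the frozen genotype and no mutation
#' is applied. Phenotypes are realized with fresh environmental noise, and
#' each offspring records its parent's birth iteration for generation-time
#' accounting.
#'
#' @param pop Parent population.
#' @param counts Integer offspring counts, one per parent (from
#'   [realize_demography()], so fitness weighting is emergent).
#' @param params The level's [trophic_params()].
#' @param mutation List with `prob` and `sd`.
#' @param t Birth iteration to stamp on the offspring.
#' @param frozen `NA` while the level evolves, otherwise the frozen genotype
#'   value.
#' @return The offspring population.
#' @export
spawn_offspring <- function(pop, counts, params, mutation, t, frozen = NA_real_) {
  idx <- rep.int(seq_along(counts), counts)
  n <- length(idx)
  if (n == 0L) {
    return(list(G = numeric(0), attack = numeric(0), vuln = numeric(0),
                death = numeric(0), birth = numeric(0),
                parent_birth = numeric(0)))
  }
  G <- if (is.na(frozen)) {
    G <- pop$G[idx]
    mut <- stats::runif(n) < mutation$prob
    nm <- sum(mut)
    if (nm > 0L) G[mut] <- G[mut] + stats::rnorm(nm, 0, mutation$sd)
    G
  } else {
    rep(frozen, n)
  }
  off <- new_population(G, params, birth = t, parent_birth = NA_real_)
  off$parent_birth <- pop$birth[idx]
  off
}

#' Replenish the basal resource
#'
#' Linear restocking toward the cap: the pool first replenishes by
#' `r*(R_max - R)` and is then grazed; the result is clamped to
#' `[0, R_max]`. `consumed` is computed by the caller from the producers'
#' functional responses on the replenished pool and may not exceed it.
#'
#' @param R Current resource pool.
#' @param R_max Resource cap.
#' @param r Replenishment fraction per iteration.
#' @param consumed Resource units grazed this iteration.
#' @return The updated pool.
#' @export
update_resource <- function(R, R_max, r, consumed = 0) {
  stopifnot(R >= 0, R <= R_max, consumed >= 0)
  min(max(R + r * (R_max - R) - consumed, 0), R_max)
}

#' Advance the community by one iteration
#'
#' One synchronous Monte-Carlo step. Using start-of-iteration abundances it
#' computes every individual's total death probability (intrinsic x
#' predation x harvest), realizes deaths, attributes them to predation
#' (`N_eaten`), then realizes births level by level with the next-lower
#' level's `N_eaten` as the prey-eaten input (the producers graze the
#' replenished resource pool, which is consumed in proportion to their mean
#' functional response and capped at the pool), spawns offspring (frozen
#' levels clone the frozen genotype with fresh environmental noise), updates
#' the resource and increments the clock. An extinct level stays extinct.
#'
#' Random draws occur in a fixed order (effort error; Bernoulli deaths
#' bottom-up; Poisson births and mutations bottom-up), so a fixed seed fully
#' determines the trajectory.
#'
#' @param state A `"community_state"`.
#' @param harvest A [harvest_spec()] or `NULL`; ignored before its onset
#'   iteration.
#' @return List with the updated `state` and a one-iteration `ledger`: per
#'   level, post-update abundance, births, deaths, `n_eaten`, `yield`, mean
#'   and SD of genotype, and the summed parent-offspring birth intervals
#'   (`gen_sum`, `gen_n`); plus the post-update `resource`.
#' @export
step_community <- function(state, harvest = NULL) {
  cfg <- state$config
  lpar <- cfg$levels
  nl <- length(lpar)
  pops <- state$pops
  t <- state$t
  Ns <- integer(nl)
  for (i in seq_len(nl)) Ns[i] <- length(pops[[i]]$G)

  R_avail <- state$resource +
    cfg$resource$r * (cfg$resource$R_max - state$resource)

  ## functional responses of each level on its prey pool
  fr <- vector("list", nl)
  mfr <- numeric(nl)
  gs <- cfg$resource$graze_scale
  if (is.null(gs)) gs <- 1
  for (i in seq_len(nl)) {
    if (Ns[i] > 0L) {
      n_prey <- if (i == 1L) R_avail else Ns[i - 1L]
      ## producers encounter resource units at graze_scale * attack
      a <- if (i == 1L) gs * pops[[i]]$attack else pops[[i]]$attack
      fri <- a / (1 + (lpar[[i]]$h * n_prey) * a)
      fr[[i]] <- fri
      mfr[i] <- sum(fri) / Ns[i]
    }
  }

  ## realized harvest effort this iteration
  eff <- 0
  hl <- 0L
  if (!is.null(harvest) && t >= harvest$onset) {
    hl <- harvest$level
    eps_f <- stats::rnorm(1, 0, harvest$error_cv * harvest$f)
    eff <- min(max(harvest$f + eps_f, 0), 1)
  }

  ## deaths and predation accounting, bottom-up (Bernoulli per individual)
  dead <- vector("list", nl)
  deaths <- integer(nl)
  n_eaten <- numeric(nl)
  yield <- numeric(nl)
  for (i in seq_len(nl)) {
    if (Ns[i] == 0L) next
    if (i < nl && Ns[i + 1L] > 0L) {
      dP <- (mfr[i + 1L] * Ns[i + 1L]) * pops[[i]]$vuln
      if (max(dP) > 1) dP <- pmin(dP, 1)
      surv <- (1 - pops[[i]]$death) * (1 - dP)
    } else {
      dP <- 0
      surv <- 1 - pops[[i]]$death
    }
    Di <- 1 - (if (i == hl) surv * (1 - eff) else surv)
    di <- stats::runif(Ns[i]) < Di
    dead[[i]] <- di
    deaths[i] <- sum(di)
    if (deaths[i] > 0L) {
      if (i < nl && Ns[i + 1L] > 0L) n_eaten[i] <- sum(dP[di] / Di[di])
      if (i == hl && eff > 0) yield[i] <- sum(eff / Di[di])
    }
  }

  ## producers graze the replenished pool
  consumed <- if (Ns[1L] > 0L) min(mfr[1L] * Ns[1L], 1) * R_avail else 0

  ## births, spawning, population update
  births <- integer(nl)
  gen_sum <- numeric(nl)
  gen_n <- integer(nl)
  mean_G <- rep(NA_real_, nl)
  sd_G <- rep(NA_real_, nl)
  for (i in seq_len(nl)) {
    if (Ns[i] == 0L) next
    prey_eaten <- if (i == 1L) consumed else n_eaten[i - 1L]
    if (prey_eaten > 0) {
      if (mfr[i] == 0) {
        stop("inconsistent state: prey eaten but mean functional response is 0")
      }
      Li <- lpar[[i]]$b * fr[[i]] * prey_eaten / (mfr[i] * Ns[i])
      counts <- stats::rpois(Ns[i], Li)
    } else {
      counts <- integer(Ns[i])
    }
    off <- spawn_offspring(pops[[i]], counts, lpar[[i]], cfg$mutation,
                           t = t + 1, frozen = state$frozen[i])
    nb <- length(off$G)
    births[i] <- nb
    if (nb > 0L) {
      ## parent-offspring birth interval, measured as the parent's age at
      ## the reproductive draw (iteration counter at the start of this step
      ## minus the parent's birth stamp): a parent reproducing at its first
      ## opportunity contributes 0
      gen_sum[i] <- nb * t - sum(off$parent_birth)
      gen_n[i] <- nb
    }
    keep <- !dead[[i]]
    p <- pops[[i]]
    pops[[i]] <- list(G = c(p$G[keep], off$G),
                      attack = c(p$attack[keep], off$attack),
                      vuln = c(p$vuln[keep], off$vuln),
                      death = c(p$death[keep], off$death),
                      birth = c(p$birth[keep], off$birth),
                      parent_birth = c(p$parent_birth[keep], off$parent_birth))
    ni <- length(pops[[i]]$G)
    if (ni > 0L) {
      g <- pops[[i]]$G
      m <- sum(g) / ni
      mean_G[i] <- m
      sd_G[i] <- if (ni > 1L) sqrt(sum((g - m)^2) / (ni - 1L)) else 0
    }
  }

  state$pops <- pops
  state$resource <- min(max(R_avail - consumed, 0), cfg$resource$R_max)
  state$t <- t + 1L

  ledger <- list(
    abundance = Ns + births - deaths,
    births = births, deaths = deaths,
    n_eaten = n_eaten, yield = yield,
    mean_G = mean_G, sd_G = sd_G,
    gen_sum = gen_sum, gen_n = gen_n,
    resource = state$resource
  )
  list(state = state, ledger = ledger)
}
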