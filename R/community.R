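#' Map genotypes to phenotypes
#'
#' Realizes the three traits of an individual from its quantitative genotype
#' `G` and environmental error draws:
#' attack `a = (a0 + eps_a) (1 + A G / 100)`,
#' vulnerability `v = (v0 + eps_v) (1 + V G / 100)`,
#' death `d = (d0 + eps_d) (1 + M G^2 / 100)`.
#' Attack and vulnerability rise with `G` (more competitive, less defended);
#' the death penalty is quadratic in `G` (canalization), so extreme trait
#' values are costly in either direction. Attack and vulnerability are
#' floored at 0 and the death probability is clipped to \[0, 1\], so arbitrary
#' error draws cannot produce out-of-range rates.
#'
#' @param G Numeric vector of genotypes.
#' @param params A [trophic_params()] object.
#' @param eps_attack,eps_vuln,eps_death Environmental error draws (scalar or
#'   vectors the length of `G`); defaults 0.
#' @return A list with numeric vectors `attack`, `vuln`, `death`.
#' @export
#' @examples
#' p <- producer_base_params(rate_scale = 1, A = 29.5, V = 39.3, M = 25)
#' genotype_to_phenotype(c(-1, 0, 1), p)
genotype_to_phenotype <- function(G, params, eps_attack = 0, eps_vuln = 0,
                                  eps_death = 0) {
  stopifnot(inherits(params, "trophic_params"))
  attack <- (params$a0 + eps_attack) * (1 + params$A * G / 100)
  vuln   <- (params$v0 + eps_vuln)  * (1 + params$V * G / 100)
  death  <- (params$d0 + eps_death) * (1 + params$M * G * G / 100)
  list(attack = pmax(attack, 0),
       vuln   = pmax(vuln, 0),
       death  = pmin(pmax(death, 0), 1))
}

## Draw phenotypes with fresh environmental noise (one draw per trait per
## individual, fixed for life). Uses the current RNG stream.
draw_phenotypes <- function(G, params) {
  n <- length(G)
  cv <- params$noise_cv
  genotype_to_phenotype(
    G, params,
    eps_attack = stats::rnorm(n, 0, cv * params$a0),
    eps_vuln   = stats::rnorm(n, 0, cv * params$v0),
    eps_death  = stats::rnorm(n, 0, cv * params$d0)
  )
}

#' Build a population from genotypes
#'
#' A population is a list of parallel vectors, one entry per individual:
#' genotype `G`, the three realized phenotypes (`attack`, `vuln`, `death`,
#' drawn here with fresh environmental noise via the level's `noise_cv`),
#' the birth iteration and the parent's birth iteration (`NA` for
#' founders).
#'
#' @param G Numeric vector of genotypes.
#' @param params The level's [trophic_params()].
#' @param birth Birth iteration stamp (recycled).
#' @param parent_birth Parent birth iteration stamp (recycled).
#' @return A population list.
#' @export
new_population <- function(G, params, birth, parent_birth = NA_real_) {
  ph <- draw_phenotypes(G, params)
  list(G = G, attack = ph$attack, vuln = ph$vuln, death = ph$death,
       birth = rep_len(as.numeric(birth), length(G)),
       parent_birth = rep_len(as.numeric(parent_birth), length(G)))
}

pop_size <- function(pop) length(pop$G)

pop_subset <- function(pop, keep) lapply(pop, `[`, keep)

pop_bind <- function(a, b) {
  if (pop_size(a) == 0L) return(b)
  if (pop_size(b) == 0L) return(a)
  Map(c, a, b)
}

#' Assemble a community configuration
#'
#' Collects everything needed to initialize and iterate a community: the
#' per-level parameters, the basal resource pool, founder genotype
#' distribution, mutation kernel and initial population sizes.
#'
#' @param levels List of [trophic_params()] objects ordered by level
#'   (1 = producer).
#' @param init_sizes Integer vector of initial population sizes, one per
#'   level.
#' @param resource List with `R_max` (resource carrying pool), `r`
#'   (fraction of the deficit replenished per iteration) and `graze_scale`
#'   (resource-unit granularity: the producers' per-resource-unit encounter
#'   rate is `graze_scale * a0`; values below 1 mean a finer-grained, more
#'   abundant resource that is never fully grazed in one iteration).
#' @param founder List with `mean` and `sd` of founder genotypes at evolving
#'   levels.
#' @param mutation List with `prob` (mutation probability per birth) and
#'   `sd` (standard deviation of mutation effect).
#' @return An object of class `"community_config"`.
#' @export
community_config <- function(levels, init_sizes,
                             resource = list(R_max = 24500, r = 0.5,
                                             graze_scale = 0.4),
                             founder = list(mean = 0, sd = 0.25),
                             mutation = list(prob = 0.12, sd = 0.05)) {
  stopifnot(length(levels) >= 2L, length(init_sizes) == length(levels))
  lv <- vapply(levels, function(p) p$level, integer(1))
  if (!identical(lv, seq_along(levels))) {
    stop("levels must be ordered 1..n with matching level indices")
  }
  if (any(init_sizes <= 0)) stop("initial population sizes must be positive")
  if (is.null(resource$graze_scale)) resource$graze_scale <- 1
  if (resource$R_max <= 0 || resource$r < 0 || resource$r > 1 ||
      resource$graze_scale <= 0) {
    stop("resource must satisfy R_max > 0, 0 <= r <= 1 and graze_scale > 0")
  }
  if (mutation$prob < 0 || mutation$prob > 1 || mutation$sd < 0) {
    stop("mutation must satisfy 0 <= prob <= 1 and sd >= 0")
  }
  if (founder$sd < 0) stop("founder sd must be >= 0")
  structure(list(levels = levels, init_sizes = as.integer(init_sizes),
                 resource = resource, founder = founder, mutation = mutation),
            class = "community_config")
}

#' Initialize a community
#'
#' Creates the starting populations: founder genotypes are drawn
#' `Normal(mean, sd)` at evolving levels and pinned at 0 elsewhere,
#' phenotypes are realized with fresh environmental noise, the resource pool
#' starts full and the iteration counter at 0. Founders carry a missing
#' parent birth time.
#'
#' @param config A [community_config()].
#' @return An object of class `"community_state"`: list with `pops` (one
#'   population per level), `resource` (current pool), `config`, `frozen`
#'   (per-level frozen genotype value, `NA` while evolving) and `t`.
#' @export
init_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  frozen <- vapply(config$levels, function(p) if (p$evolve) NA_real_ else 0,
                   numeric(1))
  pops <- vector("list", length(config$levels))
  for (i in seq_along(config$levels)) {
    p <- config$levels[[i]]
    n <- config$init_sizes[i]
    G <- if (p$evolve) {
      stats::rnorm(n, config$founder$mean, config$founder$sd)
    } else {
      rep(0, n)
    }
    pops[[i]] <- new_population(G, p, birth = 0, parent_birth = NA_real_)
  }
  structure(list(pops = pops, resource = config$resource$R_max,
                 config = config, frozen = frozen, t = 0L),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  n <- vapply(x$pops, pop_size, integer(1))
  cat(sprintf("<community_state> t = %d, resource = %.4g\n", x$t, x$resource))
  for (i in seq_along(n)) {
    g <- x$pops[[i]]$G
    cat(sprintf("  level %d: N = %d, mean G = %s%s\n", i, n[i],
                if (n[i]) sprintf("%.3f", mean(g)) else "-",
                if (is.na(x$frozen[i])) " (evolving)"
                else sprintf(" (frozen at %.3f)", x$frozen[i])))
  }
  invisible(x)
}

#' Abundances of a community state
#'
#' @param state A `"community_state"`.
#' @return Integer vector of population sizes, one per level.
#' @export
abundances <- function(state) {
  vapply(state$pops, pop_size, integer(1))
}
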