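#' Per-level demographic and tradeoff parameters
#'
#' Bundles the base demographic rates of one trophic level with its
#' competition-defense tradeoff coefficients. Base rates are the realized
#' per-iteration rates of a genotype-0 individual before environmental noise;
#' the quantitative trait shifts them via [genotype_to_phenotype()].
#'
#' @param level Trophic level index, 1 = producer.
#' @param a0 Inherent attack rate (prey encountered and captured per prey
#'   per iteration, before saturation).
#' @param v0 Inherent vulnerability (dimensionless multiplier on the
#'   consumption rate of this level's predators).
#' @param b Conversion efficiency (offspring per prey eaten).
#' @param h Handling time (iterations per prey item).
#' @param d0 Inherent death probability per iteration.
#' @param A,V Percent change in attack rate / vulnerability per unit genotype
#'   (the competition and defense arms of the tradeoff).
#' @param M Canalization coefficient: percent increase of the death rate per
#'   squared genotype unit; penalizes extreme trait values.
#' @param evolve Logical; does the genotype at this level evolve?
#' @param noise_cv Coefficient of variation of the environmental error added
#'   to each base rate at birth. `NULL` calibrates it with
#'   [calibrate_noise_cv()] (target effective heritability 0.6) when `A > 0`,
#'   and falls back to 0.06 otherwise.
#'
#' @return An object of class `"trophic_params"` (a named list).
#' @seealso [producer_base_params()], [derive_level_params()]
#' @export
#' @examples
#' trophic_params(1, a0 = 6e-6, v0 = 1, b = 1e-3, h = 2e-10, d0 = 1e-3)
trophic_params <- function(level, a0, v0, b, h, d0,
                           A = 0, V = 0, M = 0,
                           evolve = FALSE, noise_cv = NULL) {
  stopifnot(length(level) == 1L, level >= 1)
  rates <- c(a0 = a0, v0 = v0, b = b, h = h, d0 = d0)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("base rates (a0, v0, b, h, d0) must be finite and non-negative")
  }
  if (any(c(A, V, M) < 0)) stop("tradeoff coefficients A, V, M must be >= 0")
  if (is.null(noise_cv)) {
    noise_cv <- if (A > 0) calibrate_noise_cv(A) else 0.06
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(
    list(level = as.integer(level), a0 = a0, v0 = v0, b = b, h = h, d0 = d0,
         A = A, V = V, M = M, evolve = isTRUE(evolve), noise_cv = noise_cv),
    class = "trophic_params"
  )
}

#' @export
print.trophic_params <- function(x, ...) {
  cat(sprintf(
    "<trophic_params> level %d%s\n  a0=%g v0=%g b=%g h=%g d0=%g\n  A=%g V=%g M=%g noise_cv=%.4g\n",
    x$level, if (x$evolve) " (evolving)" else "",
    x$a0, x$v0, x$b, x$h, x$d0, x$A, x$V, x$M, x$noise_cv))
  invisible(x)
}

#' Producer base rates
#'
#' Canonical starting rates of the basal (producer) level. With
#' `rate_scale = 1` these are the tabulated starting values of the model
#' (attack 6e-6, vulnerability 1, conversion 1e-3, handling 2e-10, death
#' 1e-3). The default `rate_scale = 100` multiplies attack, conversion and
#' death by 100, fixing the per-iteration time scale of the default community
#' so that generation times span roughly 1.5 (producer) to 640 (top
#' predator) iterations and population sizes stay desk-scale; vulnerability
#' is a dimensionless multiplier and is never scaled, and handling time is
#' left unscaled. See the methods vignette for the derivation.
#'
#' @param rate_scale Multiplier applied to attack, conversion and death.
#' @param ... Passed on to [trophic_params()] (e.g. `A`, `V`, `M`, `evolve`).
#' @return A `"trophic_params"` object for level 1.
#' @export
#' @examples
#' producer_base_params(rate_scale = 1) # tabulated starting values
producer_base_params <- function(rate_scale = 100, ...) {
  trophic_params(1L,
                 a0 = 6e-6 * rate_scale,
                 v0 = 1,
                 b  = 1e-3 * rate_scale,
                 h  = 2e-10,
                 d0 = 1e-3 * rate_scale,
                 ...)
}

#' Geometric scaling of rates with trophic level
#'
#' Derives the base rates of any level of the chain from the producer's by
#' the model's geometric progression: per level above the producer the
#' attack rate halves, handling time grows 100-fold and the death rate
#' quarters; vulnerability and conversion efficiency are unchanged. The
#' progression makes population size decrease and generation time increase
#' up the chain.
#'
#' @param producer_params `"trophic_params"` for level 1.
#' @param level Target level, between 1 and 4.
#' @param ... Tradeoff settings for the derived level, passed to
#'   [trophic_params()] (e.g. `A`, `V`, `M`, `evolve`, `noise_cv`).
#' @return A `"trophic_params"` object for `level`.
#' @export
#' @examples
#' p1 <- producer_base_params(rate_scale = 1)
#' derive_level_params(p1, 4) # a0 = 7.5e-7, h = 2e-4, d0 = 1.5625e-5
derive_level_params <- function(producer_params, level, ...) {
  stopifnot(inherits(producer_params, "trophic_params"))
  if (length(level) != 1L || is.na(level) || level < 1 || level > 4) {
    stop("level must be a single integer in 1..4")
  }
  if (producer_params$level != 1L) {
    stop("producer_params must describe level 1")
  }
  k <- as.integer(level) - 1L
  trophic_params(level,
                 a0 = producer_params$a0 / 2^k,
                 v0 = producer_params$v0,
                 b  = producer_params$b,
                 h  = producer_params$h * 100^k,
                 d0 = producer_params$d0 / 4^k,
                 ...)
}

#' Competition-defense tradeoff slope
#'
#' Slope of the realized tradeoff between attack rate (competition) and
#' vulnerability (inverse defense),
#' `S = (da/dG) / (dv/dG) = a0 * A / (v0 * V)`, evaluated at zero
#' environmental error. A large slope means cheap competition (attack moves a
#' lot per unit of vulnerability); a small slope means cheap defense.
#'
#' @param params A `"trophic_params"` object.
#' @return The slope `S` (units of attack rate per unit vulnerability).
#' @export
#' @examples
#' p <- producer_base_params(rate_scale = 1, A = 29.5, V = 39.3, M = 25)
#' tradeoff_slope(p) # 4.504e-06
tradeoff_slope <- function(params) {
  stopifnot(inherits(params, "trophic_params"))
  if (params$V == 0 || params$v0 == 0) {
    stop("tradeoff slope undefined: V and v0 must both be > 0")
  }
  params$a0 * params$A / (params$v0 * params$V)
}

#' Calibrate the environmental noise coefficient to a target heritability
#'
#' The phenotypic attack rate of an individual is
#' `a = (a0 + eps) * (1 + A G / 100)` with `eps ~ Normal(0, (cv a0)^2)` drawn
#' once at birth. For founder genotypes with standard deviation `founder_sd`
#' the parent-offspring regression slope of attack rate (the realized
#' heritability under clonal inheritance) is
#' `h2 = k2s2 / (k2s2 + cv^2 (1 + k2s2))` with `k2s2 = (A founder_sd / 100)^2`.
#' This inverts that relation:
#' `cv = sqrt(k2s2 (1/h2 - 1) / (1 + k2s2))`.
#'
#' @param A Genotype contribution to attack rate (percent per genotype unit).
#' @param founder_sd Genotypic standard deviation at calibration (default
#'   0.25, the founder value).
#' @param h2 Target effective heritability (default 0.6).
#' @return The coefficient of variation `cv` of the environmental error.
#' @export
#' @examples
#' calibrate_noise_cv(29.5) # about 0.060
calibrate_noise_cv <- function(A, founder_sd = 0.25, h2 = 0.6) {
  stopifnot(A > 0, founder_sd > 0, h2 > 0, h2 <= 1)
  k2s2 <- (A * founder_sd / 100)^2
  sqrt(k2s2 * (1 / h2 - 1) / (1 + k2s2))
}
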