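test_that("Holling type II response: linear limit, direct value, saturation", {
  expect_equal(functional_response(0.37, 0, 1e9), 0.37)
  expect_equal(functional_response(0.01, 2e-10, 1e6), 0.01 / (1 + 2e-6))
  # total intake saturates at 1/h
  h <- 2e-6
  N <- 1e12
  expect_equal(functional_response(0.01, h, N) * N, 1 / h, tolerance = 1e-3)
})

test_that("birth probabilities share prey eaten exactly in proportion to response", {
  p <- table_producer()
  single <- noise_free_pop(0, p)
  expect_equal(birth_probabilities(single, p, N_prey = 1e6,
                                   N_prey_eaten = 500),
               0.5)

  # homogeneous population: equal shares
  pop <- noise_free_pop(rep(0, 8), p)
  L <- birth_probabilities(pop, p, N_prey = 1e5, N_prey_eaten = 200)
  expect_equal(L, rep(1e-3 * 200 / 8, 8))

  # heterogeneous population: total conserved exactly (brute-force check)
  set.seed(7)
  for (k in 1:20) {
    G <- rnorm(100, 0, 0.5)
    pp <- table_producer(A = 29.5, V = 39.3, M = 25, noise_cv = 0.06)
    pop <- new_population(G, pp, birth = 0, parent_birth = NA_real_)
    NE <- runif(1, 0, 1000)
    L <- birth_probabilities(pop, pp, N_prey = 1e4, N_prey_eaten = NE)
    # independent summation from the raw formula
    f <- pop$attack / (1 + pp$h * pop$attack * 1e4)
    brute <- 0
    for (i in 1:100) brute <- brute + pp$b * f[i] * NE / (mean(f) * 100)
    expect_equal(sum(L), pp$b * NE, tolerance = 1e-12)
    expect_equal(sum(L), brute, tolerance = 1e-12)
  }

  expect_error(birth_probabilities(noise_free_pop(numeric(0), p), p, 1, 1),
               "empty")
})

test_that("predation death probability: empty predators, direct value, linear in v", {
  p2 <- derive_level_params(table_producer(), 2)
  none <- noise_free_pop(numeric(0), p2)
  expect_equal(predation_death_prob(c(1, 2), none, p2, 100), c(0, 0))

  # predators with response exactly 1e-3: a = 1e-3, h = 0
  pp <- trophic_params(2, a0 = 1e-3, v0 = 1, b = 1e-3, h = 0, d0 = 0.01,
                       noise_cv = 0)
  pred <- noise_free_pop(rep(0, 50), pp)
  expect_equal(predation_death_prob(1, pred, pp, n_consumers = 1e4), 0.05)
  expect_equal(predation_death_prob(2, pred, pp, n_consumers = 1e4), 0.10)
  # clipped at 1
  expect_equal(predation_death_prob(50, pred, pp, n_consumers = 1e4), 1)
})

test_that("mortality sources combine as independent hazards", {
  expect_equal(combine_death_probs(0.1, 0.05), 0.145)
  expect_equal(combine_death_probs(0.1, 0.05, f = 0.0009),
               1 - 0.9 * 0.95 * 0.9991)
  expect_equal(combine_death_probs(0.1, 0.05, f = 0.0009), 0.14577,
               tolerance = 1e-4)
  expect_equal(combine_death_probs(0.3, 0.7, f = 1), 1)
  # effort error is clipped so D stays a probability
  expect_equal(combine_death_probs(0, 0, f = 0.5, eps_f = 0.9), 1)
  expect_equal(combine_death_probs(0.2, 0, f = 0.1, eps_f = -0.9), 0.2)
})

test_that("demographic realization matches Poisson/Bernoulli moments and is reproducible", {
  out <- realize_demography(rep(0.1, 50), rep(1, 50))
  expect_true(all(out$dead))

  set.seed(5)
  a <- realize_demography(runif(100), runif(100))
  set.seed(5)
  b <- realize_demography(runif(100), runif(100))
  expect_identical(a, b)

  set.seed(11)
  totals <- replicate(300, sum(realize_demography(rep(0.5, 10000),
                                                  rep(0, 10000))$offspring))
  expect_equal(mean(totals), 5000, tolerance = 0.005)
  expect_equal(var(totals), 5000, tolerance = 0.35)
})

test_that("predation accounting and yield split deaths by cause", {
  expect_equal(count_predation_deaths(0.05, 0.1), 0.5)
  expect_equal(count_predation_deaths(numeric(0), numeric(0)), 0)
  # all mortality from predation: every dead individual counts fully
  dP <- c(0.2, 0.4, 0.9)
  expect_equal(count_predation_deaths(dP, dP), 3)
  expect_error(count_predation_deaths(0.1, 0), "D = 0")

  expect_equal(compute_yield(0.1, 0.2), 0.5)
  expect_equal(compute_yield(0, c(0.3, 0.5)), 0)
  # harvest as sole cause of death: each dead contributes 1
  expect_equal(compute_yield(0.25, rep(0.25, 4)), 4)
})

test_that("offspring inherit clonally with rare mutational input", {
  p <- table_producer(A = 29.5, V = 39.3, M = 25, noise_cv = 0)
  pop <- noise_free_pop(rnorm(100, 0, 0.25), p, birth = 3)

  set.seed(2)
  off <- spawn_offspring(pop, rep(2L, 100), p, list(prob = 0, sd = 0.05),
                         t = 10)
  expect_identical(off$G, pop$G[rep(1:100, each = 2)])
  expect_identical(off$parent_birth, rep(3, 200))
  expect_identical(off$birth, rep(10, 200))

  # mutation kernel: mean zero, variance P * sigma^2
  set.seed(3)
  n <- 1e5
  parents <- noise_free_pop(rep(0, n), p)
  off <- spawn_offspring(parents, rep(1L, n), p,
                         list(prob = 0.12, sd = 0.05), t = 1)
  d <- off$G
  expect_equal(mean(d), 0, tolerance = 3e-4)
  expect_equal(var(d), 0.12 * 0.05^2, tolerance = 0.15)

  # frozen level: offspring all carry the frozen genotype
  offf <- spawn_offspring(pop, rep(1L, 100), p, list(prob = 0.5, sd = 0.1),
                          t = 4, frozen = 0.31)
  expect_identical(offf$G, rep(0.31, 100))
})

test_that("resource replenishes linearly and never overshoots", {
  expect_equal(update_resource(40, 100, 0.5, consumed = 0), 70)
  expect_equal(update_resource(100, 100, 1, consumed = 0), 100)
  expect_equal(update_resource(10, 100, 1, consumed = 100), 0)
  expect_equal(update_resource(80, 100, 0.1, consumed = 12), 70)
})

test_that("one community step conserves individuals and respects ledger bounds", {
  plan <- baseline_plan()
  cfg <- community_from_plan(plan)
  set.seed(8)
  st <- init_community(cfg)
  harv <- harvest_spec(4, 0.0009)
  for (k in 1:60) {
    n_before <- abundances(st)
    out <- step_community(st, harv)
    lg <- out$ledger
    st <- out$state
    expect_identical(abundances(st),
                     as.integer(n_before + lg$births - lg$deaths))
    expect_identical(as.integer(lg$abundance), abundances(st))
    expect_true(all(lg$n_eaten >= 0 & lg$n_eaten <= lg$deaths + 1e-9))
    expect_true(all(lg$yield >= 0))
    expect_true(lg$yield[4] <= lg$deaths[4] + 1e-9)
    expect_true(st$resource >= 0 && st$resource <= cfg$resource$R_max)
  }
})

test_that("frozen genotypes stay constant without mutation", {
  plan <- baseline_plan()
  cfg <- community_from_plan(plan)
  cfg$mutation$prob <- 0
  set.seed(9)
  st <- init_community(cfg)
  out <- run_phase(st, 300)
  expect_true(all(out$record$mean_G == 0, na.rm = TRUE))
})

test_that("compiled and reference engines produce identical trajectories", {
  plan <- baseline_plan()
  plan$evolve <- c(1L, 2L, 3L)
  cfg <- community_from_plan(plan)
  set.seed(21)
  st <- init_community(cfg)
  harv <- harvest_spec(4, 0.0009)

  set.seed(77)
  a <- run_phase(st, 150, harvest = harv, engine = "compiled")
  set.seed(77)
  b <- run_phase(st, 150, harvest = harv, engine = "reference")

  for (cn in c("iteration", "level", "abundance", "births", "deaths",
               "yield", "gen_sum", "gen_n")) {
    expect_identical(a$record[[cn]], b$record[[cn]])
  }
  expect_equal(a$record$resource, b$record$resource, tolerance = 1e-9)
  expect_equal(a$record$n_eaten, b$record$n_eaten, tolerance = 1e-9)
  expect_equal(a$record$mean_G, b$record$mean_G, tolerance = 1e-9)
  expect_equal(a$record$sd_G, b$record$sd_G, tolerance = 1e-9)
  expect_equal(a$state$pops, b$state$pops, tolerance = 1e-12)
})
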