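test_that("phase lengths follow the evolving-level convention and scale", {
  expect_identical(scenario_preset("top_predator_harvest_producer")$burn_in,
                   12500L)
  expect_identical(
    scenario_preset("top_predator_harvest_primary_consumer")$burn_in, 20000L)
  expect_identical(
    scenario_preset("top_predator_harvest_secondary_consumer")$burn_in, 50000L)
  # multi-level sets take the longest requirement
  expect_identical(scenario_preset("top_predator_harvest")$burn_in, 50000L)
  expect_identical(scenario_preset("secondary_consumer_harvest")$burn_in,
                   20000L)
  p <- scenario_preset("top_predator_harvest_secondary_consumer",
                       phase_scale = 0.25)
  expect_identical(p$burn_in, 12500L)
  expect_identical(p$harvest_iters, 12500L)
})

test_that("population scaling preserves per-capita rates", {
  p1 <- scenario_preset("top_predator_harvest_producer")
  p2 <- scenario_preset("top_predator_harvest_producer", pop_scale = 0.5)
  c1 <- community_from_plan(p1)
  c2 <- community_from_plan(p2)
  expect_equal(c2$levels[[1]]$a0, 2 * c1$levels[[1]]$a0)
  expect_equal(c2$resource$R_max, 0.5 * c1$resource$R_max)
  expect_equal(c2$init_sizes, as.integer(round(0.5 * c1$init_sizes)))
  # the predation pressure a * N and grazing a * N1 are invariant
  expect_equal(c2$levels[[2]]$a0 * c2$init_sizes[2],
               c1$levels[[2]]$a0 * c1$init_sizes[2], tolerance = 0.01)
})

test_that("run_phase records every iteration and zero-harvest yield is zero", {
  cfg <- micro_config(n1 = 60, n2 = 10)
  set.seed(4)
  st <- init_community(cfg)
  out <- run_phase(st, 37)
  expect_identical(nrow(out$record), 37L * 2L)
  expect_true(all(out$record$yield == 0))
  expect_identical(out$state$t, 37L)
  expect_identical(sort(unique(out$record$iteration)), 1:37)
})

test_that("freezing pins genotypes at the current mean while noise persists", {
  plan <- baseline_plan()
  plan$evolve <- 1L
  cfg <- community_from_plan(plan)
  set.seed(13)
  st <- init_community(cfg)
  st <- run_phase(st, 200)$state
  m0 <- mean(st$pops[[1]]$G)
  expect_false(m0 == 0)

  stf <- freeze_genotypes(st, 1L)
  expect_equal(stf$frozen[1], m0)
  expect_true(all(stf$pops[[1]]$G == m0))
  out <- run_phase(stf, 300)
  g <- out$record$mean_G[out$record$level == 1]
  expect_true(all(abs(g - m0) < 1e-12))
  # phenotypic variance retained through environmental noise
  expect_gt(sd(out$state$pops[[1]]$attack), 0)

  st$pops[[2]] <- lapply(st$pops[[2]], `[`, integer(0))
  expect_error(freeze_genotypes(st, 2L), "extinct")
  expect_error(freeze_genotypes(st, 9L), "no such level")
})

test_that("bifurcated runs share the burn-in state and are fully reproducible", {
  plan <- scenario_preset("top_predator_harvest_producer",
                          replicates = 2, burn_in = 150, harvest_iters = 120,
                          base_seed = 31)
  runs <- run_bifurcated_experiment(plan)
  expect_identical(sort(unique(runs$records$branch)),
                   c("ecoevo", "ecoonly"))
  expect_identical(sort(unique(runs$records$replicate)), 1:2)
  expect_identical(nrow(runs$records), 2L * 2L * 120L * 4L)
  # both branches resume from the recorded onset abundance
  for (r in 1:2) {
    on <- runs$onset[runs$onset$replicate == r, ]
    for (br in c("ecoevo", "ecoonly")) {
      first <- runs$records[runs$records$replicate == r &
                              runs$records$branch == br &
                              runs$records$iteration == plan$burn_in + 1, ]
      expect_identical(first$abundance - first$births + first$deaths,
                       as.numeric(on$abundance))
    }
  }
  # same plan, same seed: identical output
  runs2 <- run_bifurcated_experiment(plan)
  expect_identical(runs$records, runs2$records)
  # branches use independent post-onset randomness
  evo <- runs$records[runs$records$branch == "ecoevo", "abundance"]
  eco <- runs$records[runs$records$branch == "ecoonly", "abundance"]
  expect_false(identical(evo, eco))
})

test_that("scenario presets carry the documented setpoints", {
  expect_true(all(c("top_predator_harvest", "secondary_consumer_harvest",
                    "fishing_down_three_level") %in% scenario_names()))
  expect_error(scenario_preset("nope"), "top_predator_harvest")

  tp <- scenario_preset("top_predator_harvest")
  expect_identical(tp$n_levels, 4L)
  expect_identical(tp$harvest_level, 4L)
  expect_equal(tp$f, 0.0009)
  expect_equal(tp$tradeoffs[["3"]], c(A = 19.1, V = 52.5))
  expect_equal(tp$tradeoffs[["2"]], c(A = 22.0, V = 45.4))
  expect_equal(tp$tradeoffs[["1"]], c(A = 29.5, V = 39.3))

  sc <- scenario_preset("secondary_consumer_harvest")
  expect_equal(sc$f, 0.0077)
  expect_equal(sc$tradeoffs[["2"]], c(A = 17.0, V = 58.8))
  expect_equal(sc$tradeoffs[["1"]], c(A = 20.5, V = 48.8))

  fd <- scenario_preset("fishing_down_three_level")
  expect_identical(fd$n_levels, 3L)
  expect_identical(fd$harvest_level, 3L)
  expect_identical(fd$evolve, c(1L, 2L))

  # canalization set to 25 at every level carrying a tradeoff
  for (nm in scenario_names()) {
    cfg <- community_from_plan(scenario_preset(nm))
    plan <- scenario_preset(nm)
    for (l in seq_len(plan$n_levels)) {
      if (!is.null(plan$tradeoffs[[as.character(l)]]) &&
          l < plan$harvest_level) {
        expect_equal(cfg$levels[[l]]$M, 25)
      }
    }
    for (l in plan$evolve) expect_true(cfg$levels[[l]]$evolve)
    expect_false(cfg$levels[[plan$harvest_level]]$evolve)
  }
})

test_that("sweeps key runs by grid value and rescale tradeoffs at constant A*V", {
  plan <- scenario_preset("top_predator_harvest_producer",
                          replicates = 1, burn_in = 60, harvest_iters = 50,
                          base_seed = 9)
  sw <- sweep_experiment(plan, "harvest", grid = 0.0009)
  expect_identical(names(sw$runs), "9e-04")
  direct <- run_bifurcated_experiment(plan)
  expect_identical(sw$runs[[1]]$records, direct$records)

  p2 <- tradeoff_scaled_plan(plan, 4)
  tk0 <- plan$tradeoffs[["1"]]
  tk <- p2$tradeoffs[["1"]]
  expect_equal(tk[["A"]] / tk[["V"]], 4 * tk0[["A"]] / tk0[["V"]])
  expect_equal(tk[["A"]] * tk[["V"]], tk0[["A"]] * tk0[["V"]])

  expect_error(sweep_experiment(plan, "harvest", grid = numeric(0)))
})
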