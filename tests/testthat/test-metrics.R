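# a synthetic run_record with known structure
fake_record <- function(iters, levels = 1, branch = NULL, replicate = NULL,
                        abundance = 100, yield = 0, mean_G = 0,
                        gen_gap = 10, births = 5) {
  rec <- expand.grid(iteration = seq_len(iters), level = levels)
  n <- nrow(rec)
  rec$abundance <- rep_len(abundance, n)
  rec$births <- births
  rec$deaths <- births
  rec$n_eaten <- 0
  rec$yield <- rep_len(yield, n)
  rec$mean_G <- rep_len(mean_G, n)
  rec$sd_G <- 0
  rec$gen_sum <- gen_gap * births
  rec$gen_n <- births
  rec$resource <- 0
  if (!is.null(branch)) rec$branch <- branch
  if (!is.null(replicate)) rec$replicate <- replicate
  class(rec) <- c("run_record", "data.frame")
  rec
}

test_that("generation time recovers a known parent-offspring spacing exactly", {
  rec <- fake_record(50, gen_gap = 10)
  expect_equal(generation_time(rec, 1), 10)
  expect_equal(generation_time(rec, 1, window = c(10, 20)), 10)
  rec$gen_n <- 0
  rec$gen_sum <- 0
  expect_error(generation_time(rec, 1), "no births")
})

test_that("generation time in a simulated lineage matches the recorded intervals", {
  cfg <- micro_config(n1 = 200, n2 = 20)
  set.seed(6)
  st <- init_community(cfg)
  out <- run_phase(st, 400)
  # producer turnover is fast; its measured generation time must be finite
  # and positive, and the pooled mean equals total interval / total births
  r <- out$record[out$record$level == 1, ]
  expect_equal(generation_time(out$record, 1),
               sum(r$gen_sum) / sum(r$gen_n))
  expect_gt(generation_time(out$record, 1), 0)
})

test_that("heritability estimator: exact limits and affine invariance", {
  # no environmental noise, no mutation: phenotype is a deterministic map of
  # the clonally inherited genotype, so the slope is exactly 1
  p <- table_producer(A = 29.5, V = 39.3, M = 25, noise_cv = 0)
  set.seed(14)
  expect_equal(estimate_heritability(p, n_pairs = 500,
                                     mutation = list(prob = 0, sd = 0)), 1)

  # constant genotype: no genetic variance, slope collapses to about 0
  pn <- table_producer(A = 29.5, V = 39.3, M = 25, noise_cv = 0.06)
  set.seed(15)
  expect_equal(estimate_heritability(pn, n_pairs = 20000,
                                     founder = list(mean = 0.4, sd = 0)),
               0, tolerance = 0.02)

  set.seed(16)
  parent <- rnorm(500)
  offspring <- 0.5 * parent + rnorm(500, 0, 0.5)
  s1 <- realized_heritability(parent, offspring)
  s2 <- realized_heritability(3 + 2e-6 * parent, 3 + 2e-6 * offspring)
  expect_equal(s1, s2)
  expect_error(realized_heritability(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("time-series summaries aggregate replicate-wise then across replicates", {
  one <- fake_record(40, abundance = 50)
  s1 <- summarize_timeseries(one)
  expect_equal(s1$abundance, 50)
  expect_equal(s1$abundance_cv, 0)
  expect_true(is.na(s1$abundance_sd)) # absent with a single replicate, not 0

  two <- rbind(fake_record(40, abundance = 50, replicate = 1, branch = "run"),
               fake_record(40, abundance = 50, replicate = 2, branch = "run"))
  s2 <- summarize_timeseries(two)
  expect_identical(s2$n_replicates, 2L)
  expect_equal(s2$abundance_sd, 0) # identical replicates

  vr <- rbind(fake_record(40, abundance = 10, replicate = 1, branch = "b"),
              fake_record(40, abundance = 30, replicate = 2, branch = "b"))
  s3 <- summarize_timeseries(vr)
  expect_equal(s3$abundance, 20)
  expect_equal(s3$abundance_sd, sd(c(10, 30)))
})

test_that("branch comparison flags neutral, bolstering and undermining patterns", {
  mk <- function(evo_ab, eco_ab) {
    recs <- do.call(rbind, lapply(seq_along(evo_ab), function(r) {
      rbind(fake_record(80, levels = 4, abundance = evo_ab[r],
                        branch = "ecoevo", replicate = r),
            fake_record(80, levels = 4, abundance = eco_ab[r],
                        branch = "ecoonly", replicate = r))
    }))
    plan <- scenario_preset("top_predator_harvest_producer", replicates =
                              length(evo_ab))
    structure(list(plan = plan, records = recs, onset = NULL),
              class = "bifurcated_runs")
  }
  neutral <- compare_models(mk(c(50, 50, 50), c(50, 50, 50)))
  expect_equal(neutral$mean_diff_abundance, 0)
  expect_identical(neutral$sign, "neutral")

  up <- compare_models(mk(c(60, 62, 61, 63), c(50, 51, 49, 50)))
  expect_identical(up$sign, "bolsters")
  expect_gt(up$mean_diff_abundance, 0)

  down <- compare_models(mk(c(40, 41, 42, 39), c(50, 51, 49, 50)))
  expect_identical(down$sign, "undermines")

  # unpaired replicates are an error
  broken <- mk(c(50, 50), c(50, 50))
  broken$records <- broken$records[broken$records$branch == "ecoevo" |
                                     broken$records$replicate == 1, ]
  expect_error(compare_models(broken), "unpaired")
})

test_that("yield curves locate the MSY and the collapse threshold", {
  tab <- data.frame(
    f = rep(c(0.001, 0.002, 0.004, 0.008), each = 2),
    branch = rep(c("ecoevo", "ecoonly"), 4),
    yield = c(1, 1, 3, 2.5, 2, 4, 0.5, 0.2),
    collapse_frac = c(0, 0, 0, 0, 0, 0.5, 1, 1))
  yc <- yield_curve_table(tab)
  expect_equal(yc$msy[["ecoevo"]], 0.002)
  expect_equal(yc$msy[["ecoonly"]], 0.004)
  expect_equal(yc$collapse_threshold[["ecoevo"]], 0.008)
  expect_equal(yc$collapse_threshold[["ecoonly"]], 0.004)

  # monotone-increasing yields put the MSY at the last grid point
  mono <- data.frame(f = 1:5, branch = "ecoevo", yield = 1:5,
                     collapse_frac = 0)
  ycm <- yield_curve_table(mono)
  expect_equal(ycm$msy[["ecoevo"]], 5)
  expect_true(is.na(ycm$collapse_threshold[["ecoevo"]]))
})
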