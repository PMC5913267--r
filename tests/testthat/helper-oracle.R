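# Independent mean-field / exhaustive oracles, written directly from the
# model equations with plain loops; they share no code with the package.

# One-iteration expectations for a homogeneous (genotype-0, noise-free)
# community described by plain per-level rate lists.
oracle_rates <- function(N, R_avail, lv) {
  nl <- length(N)
  fr <- numeric(nl)
  for (i in seq_len(nl)) {
    np <- if (i == 1) R_avail else N[i - 1]
    fr[i] <- lv[[i]]$a0 / (1 + lv[[i]]$h * lv[[i]]$a0 * np)
  }
  dP <- numeric(nl)
  for (i in seq_len(nl - 1)) {
    dP[i] <- min(fr[i + 1] * lv[[i]]$v0 * N[i + 1], 1)
  }
  D <- numeric(nl)
  for (i in seq_len(nl)) D[i] <- 1 - (1 - lv[[i]]$d0) * (1 - dP[i])
  consumed <- if (N[1] > 0) min(fr[1] * N[1], 1) * R_avail else 0
  exp_births <- numeric(nl)
  exp_births[1] <- lv[[1]]$b * consumed
  for (i in seq_len(nl)[-1]) exp_births[i] <- lv[[i]]$b * dP[i - 1] * N[i - 1]
  list(fr = fr, dP = dP, D = D, consumed = consumed,
       exp_deaths = D * N, exp_births = exp_births)
}

# Deterministic mean-field recursion (expected-value dynamics).
oracle_recursion <- function(N0, lv, R_max, r, iters) {
  N <- N0
  R <- R_max
  traj <- matrix(NA_real_, iters, length(N0))
  for (k in seq_len(iters)) {
    R_avail <- R + r * (R_max - R)
    o <- oracle_rates(N, R_avail, lv)
    N <- N - o$exp_deaths + o$exp_births
    R <- min(max(R_avail - o$consumed, 0), R_max)
    traj[k, ] <- N
  }
  list(N = N, traj = traj)
}

# Exhaustive per-individual expectations for a two-level community with
# arbitrary (heterogeneous) phenotypes: expected deaths per level, expected
# prey-eaten, and expected births given an amount of prey eaten.
oracle_micro <- function(pop1, pop2, p1, p2, R_avail) {
  n1 <- length(pop1$G)
  n2 <- length(pop2$G)
  # predator responses saturate on prey abundance n1
  fr2 <- numeric(n2)
  for (k in seq_len(n2)) {
    fr2[k] <- pop2$attack[k] / (1 + p2$h * pop2$attack[k] * n1)
  }
  mfr2 <- sum(fr2) / n2
  D1 <- dP1 <- numeric(n1)
  for (j in seq_len(n1)) {
    dP1[j] <- min(mfr2 * pop1$vuln[j] * n2, 1)
    D1[j] <- 1 - (1 - pop1$death[j]) * (1 - dP1[j])
  }
  # expected prey-eaten: each individual dies w.p. D and then contributes
  # dP/D, so its expectation is exactly dP
  exp_NE1 <- sum(dP1)
  # producer side: graze the pool
  fr1 <- numeric(n1)
  for (j in seq_len(n1)) {
    fr1[j] <- pop1$attack[j] / (1 + p1$h * pop1$attack[j] * R_avail)
  }
  mfr1 <- sum(fr1) / n1
  consumed <- min(mfr1 * n1, 1) * R_avail
  L1 <- numeric(n1)
  for (j in seq_len(n1)) L1[j] <- p1$b * fr1[j] * consumed / (mfr1 * n1)
  exp_births2_given <- function(NE) {
    L2 <- numeric(n2)
    for (k in seq_len(n2)) L2[k] <- p2$b * fr2[k] * NE / (mfr2 * n2)
    sum(L2)
  }
  list(fr2 = fr2, dP1 = dP1, D1 = D1, D2 = pop2$death,
       exp_deaths1 = sum(D1), exp_deaths2 = sum(pop2$death),
       exp_NE1 = exp_NE1, exp_births1 = sum(L1), L1 = L1,
       exp_births2_given = exp_births2_given, consumed = consumed)
}

# realized level-parameter list of a plan's community, for the oracles;
# the producer's effective per-resource-unit encounter rate folds in the
# resource granularity
plain_levels <- function(cfg) {
  lv <- lapply(cfg$levels, function(p) {
    list(a0 = p$a0, v0 = p$v0, b = p$b, h = p$h, d0 = p$d0)
  })
  gs <- cfg$resource$graze_scale
  if (!is.null(gs)) lv[[1]]$a0 <- lv[[1]]$a0 * gs
  lv
}
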