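test_that("conditioning the game on policies is the bilinear mixture", {
  spec <- fixture_canyon(2, hare = 0, stag = 1)
  kern <- joint_kernel(single_agent_kernel(spec))
  set.seed(70)
  p1 <- random_policy(spec)
  p2 <- random_policy(spec)
  P <- condition_chain(kern, p1, p2)
  expect_equal(P, brute_condition_chain(kern, p1, p2), tolerance = 1e-14)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  # deterministic policies pick out a single joint-action row
  d1 <- matrix(0, 4, 3, dimnames = list(NULL, canyon_actions()))
  d1[, "left"] <- 1
  d2 <- matrix(0, 4, 3, dimnames = list(NULL, canyon_actions()))
  d2[, "right"] <- 1
  expect_equal(condition_chain(kern, d1, d2), unclass(kern[["left|right"]]),
               ignore_attr = TRUE)
  # uniform policies average the nine joint-action kernels
  u <- uniform_policy(spec)
  expect_equal(condition_chain(kern, u, u),
               Reduce(`+`, lapply(kern, unclass)) / 9, ignore_attr = TRUE)
})

test_that("stationary distribution solves rho = rho P", {
  # two-state closed form: (q, p) / (p + q)
  P2 <- matrix(c(0.7, 0.3, 0.1, 0.9), 2, byrow = TRUE)
  sd2 <- stationary_distribution(P2)
  expect_equal(sd2$rho, c(0.25, 0.75), tolerance = 1e-12)
  # doubly stochastic chain: uniform
  P3 <- matrix(c(0.5, 0.25, 0.25,
                 0.25, 0.5, 0.25,
                 0.25, 0.25, 0.5), 3, byrow = TRUE)
  expect_equal(stationary_distribution(P3)$rho, rep(1 / 3, 3),
               tolerance = 1e-12)
  # reducible chains are a diagnosed error
  expect_error(stationary_distribution(diag(2)), "reducible")
  expect_error(stationary_distribution(matrix(c(0.5, 0.6, 0.2, 0.4), 2)),
               "sum to 1")
})

test_that("policy-conditioned canyon chains meet the stationary invariants", {
  spec <- canyon_spec()
  kern <- joint_kernel(single_agent_kernel(spec))
  set.seed(71)
  for (i in 1:3) {
    p1 <- random_policy(spec)
    p2 <- random_policy(spec)
    P <- condition_chain(kern, p1, p2)
    sd <- stationary_distribution(P)
    expect_true(all(sd$rho >= 0))
    expect_equal(sum(sd$rho), 1, tolerance = 1e-10)
    expect_lt(max(abs(as.numeric(sd$rho %*% P) - sd$rho)), 1e-10)
  }
})

test_that("coordination metrics sum the right joint-state sets", {
  spec <- canyon_spec()
  # point mass on the joint stag state
  rho <- numeric(256)
  rho[joint_index(11, 11, 16)] <- 1
  m <- coordination_metrics(rho, spec)
  expect_equal(m$stag_mass, 1)
  expect_equal(m$hare_mass, 0)
  # uniform occupancy
  mu <- coordination_metrics(rep(1 / 256, 256), spec)
  expect_equal(mu$stag_mass, 1 / 256)
  expect_equal(mu$hare_mass, 31 / 256) # 16 + 16 - 1 joint states touch the hare
  # random rho: metrics match direct summation and marginals stay consistent
  set.seed(72)
  r <- runif(256)
  r <- r / sum(r)
  mr <- coordination_metrics(r, spec)
  st <- joint_states(16)
  expect_equal(mr$stag_mass, sum(r[st$s1 == 11 & st$s2 == 11]))
  expect_equal(mr$hare_mass, sum(r[st$s1 == 3 | st$s2 == 3]))
  agg1 <- mr$marginals[mr$marginals$agent == 1, ]
  expect_equal(sum(agg1$probability), 1, tolerance = 1e-12)
  expect_equal(agg1$probability[agg1$position == 3], sum(r[st$s1 == 3]))
})

test_that("levels-grid sweeps anchor at the uniform chain and swap symmetrically", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  sw <- run_sweep("levels_grid", spec, markov_cpt_params(),
                  planning_config(0.9), k_max = 1)
  expect_equal(nrow(sw), 4L)
  # (0, 0): stationary distribution of the uniform-policy chain
  kern <- joint_kernel(single_agent_kernel(spec))
  u <- uniform_policy(spec)
  rho00 <- stationary_distribution(condition_chain(kern, u, u))$rho
  expect_equal(sw$rho[[which(sw$k1 == 0 & sw$k2 == 0)]], rho00,
               tolerance = 1e-9)
  # identical agents: (k1, k2) and (k2, k1) are agent swaps of each other
  r01 <- sw$rho[[which(sw$k1 == 0 & sw$k2 == 1)]]
  r10 <- sw$rho[[which(sw$k1 == 1 & sw$k2 == 0)]]
  expect_equal(swap_agents(r01, 3), r10, tolerance = 1e-9)
  expect_equal(sw$stag_mass[sw$k1 == 0 & sw$k2 == 1],
               sw$stag_mass[sw$k1 == 1 & sw$k2 == 0], tolerance = 1e-9)
  # symmetric cells are swap-invariant distributions
  r11 <- sw$rho[[which(sw$k1 == 1 & sw$k2 == 1)]]
  expect_equal(swap_agents(r11, 3), r11, tolerance = 1e-9)
  expect_true(all(sw$residual < 1e-10))
})

test_that("sweep kinds carry their setting columns", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  cfg <- planning_config(0.9)
  swb <- run_sweep("reference_points", spec, markov_cpt_params(), cfg,
                   k_max = 1, b_values = c(0, 2))
  expect_setequal(unique(swb$b), c(0, 2))
  expect_equal(nrow(swb), 4L)
  swm <- run_sweep("agent_mix", spec, config = cfg, k_max = 1,
                   mixes = list(eut = list(eut_params(), eut_params())))
  expect_equal(unique(swm$mix), "eut")
  swg <- run_sweep("concavity", spec, markov_cpt_params(), cfg, k_max = 1,
                   gamma_values = 0.95)
  expect_equal(unique(swg$gamma), 0.95)
  expect_s3_class(ggplot2::autoplot(swb), "ggplot")
})

test_that("tower stationary distributions are tidy-able and plottable", {
  spec <- fixture_canyon(3, hare = 0, stag = 2)
  tw <- level_k_tower(1, spec, markov_cpt_params())
  rho <- tower_stationary(tw, 1, 1)
  td <- tidy(rho)
  expect_equal(nrow(td), 9L)
  expect_equal(sum(td$probability), 1, tolerance = 1e-10)
  expect_s3_class(ggplot2::autoplot(rho), "ggplot")
})
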